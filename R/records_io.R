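#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

CONDITIONS <- c("elevated", "reduced")

#' Canonicalize a taxon label
#'
#' Trims surrounding whitespace, collapses internal whitespace runs to a
#' single space, upper-cases the first letter and lower-cases everything
#' else, following binomial-nomenclature casing ("Bacteroides fragilis").
#' The transformation is deterministic and idempotent, so labels coming
#' from differently formatted reports collapse onto one canonical key.
#'
#' @param label Character vector of taxon labels at any rank.
#' @return Character vector of canonical labels, same length as `label`.
#' @examples
#' normalize_label("  bacteroides   fragilis ")
#' @export
normalize_label <- function(label) {
  if (!is.character(label)) {
    abort("`label` must be a character vector.")
  }
  x <- gsub("[[:space:]]+", " ", trimws(label))
  if (any(!nzchar(x) | is.na(x))) {
    abort("taxon labels must be non-empty after trimming")
  }
  paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
}

corpus_columns <- c(
  "organism_label", "ncbi_taxid", "condition", "disease_name",
  "meddra_id", "sample_type", "detection_method"
)

mandatory_fields <- c("organism_label", "disease_name", "condition", "sample_type")

new_corpus <- function(df, provenance = NA_character_, skipped = 0L) {
  df <- as_tibble(df)
  stopifnot(all(corpus_columns %in% names(df)))
  df <- df[corpus_columns]
  structure(df,
    class = c("dysbiosis_corpus", class(tibble())),
    provenance = provenance, skipped = skipped
  )
}

#' Validate a dysbiosis corpus
#'
#' Checks the per-record invariants: condition restricted to
#' elevated/reduced, non-blank organism labels, and positive taxids where
#' present. Exact duplicate rows are legal but reported through the
#' returned summary.
#'
#' @param corpus A `dysbiosis_corpus`.
#' @return `corpus`, invisibly. Errors describe the first violated invariant.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "dysbiosis_corpus"))
  if (nrow(corpus) == 0L) return(invisible(corpus))
  if (!all(corpus$condition %in% CONDITIONS)) {
    abort("corpus contains a condition outside {elevated, reduced}")
  }
  if (any(!nzchar(trimws(corpus$organism_label)))) {
    abort("corpus contains a blank organism label")
  }
  taxid <- corpus$ncbi_taxid
  if (any(!is.na(taxid) & taxid <= 0)) {
    abort("ncbi_taxid must be a positive integer when present")
  }
  ndup <- sum(duplicated(corpus))
  if (ndup > 0L) {
    inform(sprintf("corpus contains %d exact duplicate record(s)", ndup))
  }
  invisible(corpus)
}

get_field <- function(rec, field, i, required = FALSE) {
  v <- rec[[field]]
  if (is.null(v) || length(v) == 0L || (is.character(v) && !nzchar(trimws(v)))) {
    if (required) {
      abort(sprintf("record %d is missing mandatory field `%s`", i, field))
    }
    return(NA)
  }
  v
}

#' Parse a record-array export of qualitative dysbiosis records
#'
#' Reads a JSON document whose top level is an array of flat records, the
#' structure of a Disbiome-style database export. Each record must carry
#' at least an organism label, disease name, condition and sample type;
#' taxid, MedDRA id and detection method are optional. Condition strings
#' are matched case-insensitively against `elevated`/`reduced`; records
#' with any other condition (e.g. "Unchanged") are dropped and counted in
#' the `skipped` attribute.
#'
#' @param input Path to a JSON file, or a JSON string.
#' @param field_map Optional named character vector translating the
#'   canonical field names (names of the vector) to the field names used
#'   by the export dialect (values), e.g.
#'   `c(organism_label = "organism_name")`.
#' @param provenance Free-text source tag stored on the corpus.
#' @return A `dysbiosis_corpus` tibble with one row per retained record,
#'   in input order, and attributes `provenance` and `skipped`.
#' @export
parse_records <- function(input, field_map = NULL, provenance = NULL) {
  src <- if (length(input) == 1L && file.exists(input)) input else input
  recs <- tryCatch(
    jsonlite::fromJSON(src, simplifyVector = FALSE),
    error = function(e) {
      abort(sprintf("malformed record-array document: %s", conditionMessage(e)))
    }
  )
  if (!is.list(recs)) abort("record-array document must be a top-level array")
  fields <- stats::setNames(corpus_columns, corpus_columns)
  if (!is.null(field_map)) fields[names(field_map)] <- field_map

  skipped <- 0L
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (!is.list(rec)) abort(sprintf("record %d is not an object", i))
    names(rec) <- names(rec) # keep as-is
    get <- function(canon, required = FALSE) get_field(rec, fields[[canon]], i, required)
    cond <- tolower(trimws(as.character(get("condition", required = TRUE))))
    if (!cond %in% CONDITIONS) {
      skipped <- skipped + 1L
      next
    }
    taxid <- get("ncbi_taxid")
    taxid <- if (is.na(taxid[[1]])) NA_integer_ else as.integer(taxid)
    if (!is.na(taxid) && taxid <= 0) {
      abort(sprintf("record %d: ncbi_taxid must be > 0", i))
    }
    rows[[i]] <- tibble(
      organism_label = trimws(as.character(get("organism_label", required = TRUE))),
      ncbi_taxid = taxid,
      condition = cond,
      disease_name = trimws(as.character(get("disease_name", required = TRUE))),
      meddra_id = as.character(get("meddra_id")),
      sample_type = trimws(as.character(get("sample_type", required = TRUE))),
      detection_method = as.character(get("detection_method"))
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) dplyr::bind_rows(rows) else
    new_corpus(tibble(
      organism_label = character(), ncbi_taxid = integer(),
      condition = character(), disease_name = character(),
      meddra_id = character(), sample_type = character(),
      detection_method = character()
    ))
  if (skipped > 0L) {
    inform(sprintf("skipped %d record(s) with condition outside {elevated, reduced}", skipped))
  }
  prov <- provenance %||% if (length(input) == 1L && file.exists(input)) input else "inline"
  out <- new_corpus(df, provenance = prov, skipped = skipped)
  validate_corpus(out)
  out
}

#' Filter a corpus by sample type
#'
#' Keeps the records whose sample type equals `sample_type` after
#' case-insensitive trimming; order is preserved. Restricting to "Feces"
#' selects the gut community from a mixed-site export.
#'
#' @param corpus A `dysbiosis_corpus`.
#' @param sample_type Sample-type string, e.g. `"Feces"`.
#' @return The filtered `dysbiosis_corpus` (possibly empty).
#' @export
filter_by_sample <- function(corpus, sample_type) {
  stopifnot(inherits(corpus, "dysbiosis_corpus"), is.character(sample_type),
            length(sample_type) == 1L)
  keep <- tolower(trimws(corpus$sample_type)) == tolower(trimws(sample_type))
  new_corpus(corpus[keep, , drop = FALSE],
             provenance = attr(corpus, "provenance"),
             skipped = attr(corpus, "skipped"))
}

#' Deduplicate a corpus by record identity
#'
#' Record identity is (taxid when present, otherwise the normalized
#' organism label) x disease x condition; the taxid takes precedence over
#' the label because qualitative exports mix ranks and spellings. The
#' first record of each identity group is kept and the multiplicity of
#' each collapsed group is reported.
#'
#' @param corpus A `dysbiosis_corpus`.
#' @return The deduplicated corpus, with a `multiplicity` attribute: a
#'   tibble of the identity keys that occurred more than once.
#' @export
dedupe_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "dysbiosis_corpus"))
  if (nrow(corpus) == 0L) return(corpus)
  key_taxon <- ifelse(is.na(corpus$ncbi_taxid),
                      normalize_label(corpus$organism_label),
                      paste0("taxid:", corpus$ncbi_taxid))
  key <- paste(key_taxon, tolower(corpus$disease_name), corpus$condition, sep = "\r")
  tab <- table(key)
  dup <- tab[tab > 1L]
  keep <- !duplicated(key)
  out <- new_corpus(corpus[keep, , drop = FALSE],
                    provenance = attr(corpus, "provenance"),
                    skipped = attr(corpus, "skipped"))
  mult <- tibble(key = names(dup), n = as.integer(dup))
  if (nrow(mult) > 0L) {
    inform(sprintf("collapsed %d duplicated record identitie(s)", nrow(mult)))
  }
  attr(out, "multiplicity") <- mult
  out
}

#' Load the packaged cross-disease corpus fixture
#'
#' Returns the packaged transcription of the commonly affected bacterial
#' groups reported across Multiple sclerosis, Alzheimer's disease,
#' Amyotrophic lateral sclerosis and Parkinson's disease: 13 distinct
#' (organism, condition) entries expanded to one record per disease
#' sub-row, all with sample type "Feces".
#'
#' @return A `dysbiosis_corpus`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_records.json", package = "dysbiosim")
  if (!nzchar(path) || !file.exists(path)) {
    abort("packaged fixture table1_records.json not found")
  }
  parse_records(path, provenance = "table1_fixture")
}

#' Write a corpus as TSV
#'
#' @param corpus A `dysbiosis_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  stopifnot(inherits(corpus, "dysbiosis_corpus"))
  utils::write.table(as.data.frame(corpus), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a corpus from TSV written by [write_corpus_tsv()]
#'
#' @param path TSV file path.
#' @return A `dysbiosis_corpus`.
#' @export
read_corpus_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "", colClasses = "character")
  df$ncbi_taxid <- as.integer(df$ncbi_taxid)
  out <- new_corpus(df, provenance = path)
  validate_corpus(out)
  out
}

#' Write a corpus back to the record-array JSON dialect
#'
#' Produces the same flat-record JSON array that [parse_records()] reads,
#' so generated corpora exercise the full input path.
#'
#' @param corpus A `dysbiosis_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_json <- function(corpus, path) {
  stopifnot(inherits(corpus, "dysbiosis_corpus"))
  df <- as.data.frame(corpus)
  jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
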