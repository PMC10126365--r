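PATHWAY_CATEGORIES <- c("SCFA", "polyamine", "neurotransmitter_precursor")

#' Pathway completeness score
#'
#' The fraction of a pathway's constituent reactions that are annotated
#' in a genome:
#' \deqn{PS = \frac{|A \cap R|}{|R|}}
#' where \eqn{R} is the pathway's reaction set and \eqn{A} the genome's
#' annotated reaction set. A score of 1 means every enzyme needed for the
#' pathway is present in the genome; 0 means none is. Reactions annotated
#' in the genome but outside the pathway contribute nothing.
#'
#' @param annotated_reactions Character vector of reaction ids annotated
#'   in the genome.
#' @param pathway_reactions Non-empty character vector of the reaction
#'   ids constituting the pathway.
#' @return A number in \[0, 1\], always `k / length(pathway_reactions)`
#'   for an integer `k`.
#' @examples
#' pathway_score(c("r1", "r3"), c("r1", "r2", "r3", "r4"))
#' @export
pathway_score <- function(annotated_reactions, pathway_reactions) {
  pathway_reactions <- unique(as.character(pathway_reactions))
  if (length(pathway_reactions) == 0L) {
    rlang::abort("pathway must have at least one reaction")
  }
  hit <- sum(pathway_reactions %in% as.character(annotated_reactions))
  hit / length(pathway_reactions)
}

#' Aggregate several pathway scores into one
#'
#' Collapses the scores of multiple strains carrying the same taxon label
#' onto a single taxon-level score. `max` reads the collection as "the
#' best metabolic capability observed for this taxon"; `mean` as the
#' average capability.
#'
#' @param scores Non-empty numeric vector of scores in \[0, 1\].
#' @param policy `"max"` (default) or `"mean"`.
#' @return A single score, still in \[0, 1\].
#' @export
aggregate_scores <- function(scores, policy = c("max", "mean")) {
  policy <- match.arg(policy)
  scores <- as.numeric(scores)
  if (length(scores) == 0L || anyNA(scores)) {
    rlang::abort("`scores` must be non-empty and free of missing values")
  }
  if (any(scores < 0 | scores > 1)) rlang::abort("scores must lie in [0, 1]")
  if (policy == "max") max(scores) else mean(scores)
}

#' Load a pathway panel
#'
#' A panel file defines the pathways to score: TSV with columns
#' `pathway_id`, `name`, `category` (one of `SCFA`, `polyamine`,
#' `neurotransmitter_precursor`) and `reactions` (semicolon-joined
#' reaction ids). Reaction ids are opaque strings; MetaCyc-style ids pass
#' through verbatim.
#'
#' @param path TSV path.
#' @return A `pathway_panel` tibble with a list-column `reactions`.
#' @export
load_pathway_panel <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need <- c("pathway_id", "name", "category", "reactions")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("panel lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  as_pathway_panel(tibble::tibble(
    pathway_id = df$pathway_id,
    name = df$name,
    category = df$category,
    reactions = strsplit(df$reactions, ";", fixed = TRUE)
  ))
}

as_pathway_panel <- function(df) {
  if (anyDuplicated(df$pathway_id)) {
    rlang::abort("duplicate pathway ids in panel")
  }
  if (!all(df$category %in% PATHWAY_CATEGORIES)) {
    rlang::abort(sprintf("pathway category must be one of: %s",
                         paste(PATHWAY_CATEGORIES, collapse = ", ")))
  }
  df$reactions <- lapply(df$reactions, function(r) {
    r <- trimws(as.character(r))
    r <- r[nzchar(r)]
    if (length(r) == 0L) rlang::abort("a pathway has an empty reaction set")
    if (anyDuplicated(r)) rlang::abort("duplicate reaction ids within a pathway")
    r
  })
  structure(tibble::as_tibble(df),
            class = c("pathway_panel", class(tibble::tibble())))
}

#' Load genome annotations
#'
#' TSV with columns `taxon`, `strain` and `reactions` (semicolon-joined
#' annotated reaction ids); one row per strain genome.
#'
#' @param path TSV path.
#' @return A `genome_annotations` tibble with a list-column `reactions`.
#' @export
load_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  need <- c("taxon", "strain", "reactions")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("annotation table lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  as_annotations(tibble::tibble(
    taxon = df$taxon,
    strain = df$strain,
    reactions = strsplit(df$reactions, ";", fixed = TRUE)
  ))
}

as_annotations <- function(df) {
  df$taxon <- normalize_label(df$taxon)
  df$reactions <- lapply(df$reactions, function(r) {
    r <- trimws(as.character(r))
    unique(r[nzchar(r)])
  })
  structure(tibble::as_tibble(df),
            class = c("genome_annotations", class(tibble::tibble())))
}

#' Assemble the taxa-by-pathway score matrix
#'
#' One row per (taxon, group) — a taxon reported in both the elevated and
#' the reduced group yields two rows — and one column per panel pathway.
#' Each cell is the aggregated completeness score over all annotation
#' rows (strains) carrying that taxon label; taxa with no annotation row
#' get a row of missing cells and are listed in the `missing_taxa`
#' attribute.
#'
#' @param groups Named list, names drawn from
#'   `c("elevated", "reduced")`, each a character vector of taxon labels.
#' @param panel A `pathway_panel`.
#' @param annotations A `genome_annotations` table.
#' @param policy Strain-aggregation policy, `"max"` or `"mean"`.
#' @return A `score_matrix`: list with `scores` (numeric matrix, NA for
#'   missing), `taxon`, `group`, `pathway_ids` and attribute-like field
#'   `missing_taxa`.
#' @export
build_score_matrix <- function(groups, panel, annotations,
                               policy = c("max", "mean")) {
  policy <- match.arg(policy)
  stopifnot(inherits(panel, "pathway_panel"),
            inherits(annotations, "genome_annotations"))
  if (nrow(panel) == 0L) rlang::abort("pathway panel must be non-empty")
  if (length(groups) == 0L || is.null(names(groups)) ||
      !all(names(groups) %in% CONDITIONS)) {
    rlang::abort("`groups` must be named with elevated/reduced")
  }
  rows <- dplyr::bind_rows(lapply(names(groups), function(g) {
    taxa <- unique(normalize_label(as.character(groups[[g]])))
    if (length(taxa) == 0L) return(NULL)
    tibble::tibble(taxon = taxa, group = g)
  }))
  if (is.null(rows) || nrow(rows) == 0L) rlang::abort("`groups` contain no taxa")

  m <- matrix(NA_real_, nrow = nrow(rows), ncol = nrow(panel),
              dimnames = list(paste(rows$taxon, rows$group, sep = "|"),
                              panel$pathway_id))
  missing_taxa <- character(0)
  for (i in seq_len(nrow(rows))) {
    strains <- which(annotations$taxon == rows$taxon[i])
    if (length(strains) == 0L) {
      missing_taxa <- union(missing_taxa, rows$taxon[i])
      next
    }
    for (j in seq_len(nrow(panel))) {
      per_strain <- vapply(strains, function(s) {
        pathway_score(annotations$reactions[[s]], panel$reactions[[j]])
      }, numeric(1))
      m[i, j] <- aggregate_scores(per_strain, policy)
    }
  }
  if (length(missing_taxa) > 0L) {
    rlang::inform(sprintf("no annotations for %d taxon/taxa: %s",
                          length(missing_taxa),
                          paste(missing_taxa, collapse = ", ")))
  }
  structure(
    list(scores = m, taxon = rows$taxon, group = rows$group,
         pathway_ids = panel$pathway_id, missing_taxa = missing_taxa,
         policy = policy),
    class = "score_matrix"
  )
}

#' Replace missing score-matrix cells for clustering
#'
#' A taxon with no annotation record carries no evidence for any pathway;
#' for clustering that absence is read as completeness 0. The replacement
#' is explicit and logged so the distinction between "absent" and
#' "scored 0" is never silent.
#'
#' @param sm A `score_matrix`.
#' @param value Imputation value (default 0).
#' @return The `score_matrix` with no missing cells.
#' @export
impute_missing_scores <- function(sm, value = 0) {
  stopifnot(inherits(sm, "score_matrix"))
  n_missing <- sum(is.na(sm$scores))
  if (n_missing > 0L) {
    rlang::warn(sprintf("imputing %d missing score cell(s) with %g",
                        n_missing, value))
    sm$scores[is.na(sm$scores)] <- value
  }
  sm
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d taxon rows x %d pathways (policy=%s, %d missing taxa)\n",
              nrow(x$scores), ncol(x$scores), x$policy, length(x$missing_taxa)))
  invisible(x)
}

#' Tidy a score matrix
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `group` and one column per
#'   pathway id.
#' @method as_tibble score_matrix
#' @export
as_tibble.score_matrix <- function(x, ...) {
  out <- tibble::tibble(taxon = x$taxon, group = x$group)
  dplyr::bind_cols(out, tibble::as_tibble(x$scores, .name_repair = "minimal"))
}

#' Write a score matrix as TSV (with a group column)
#'
#' @param sm A `score_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(sm, path) {
  df <- as.data.frame(as_tibble.score_matrix(sm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @param path TSV path.
#' @return A `score_matrix`.
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", check.names = FALSE)
  stopifnot(all(c("taxon", "group") %in% names(df)))
  ids <- setdiff(names(df), c("taxon", "group"))
  m <- as.matrix(df[ids])
  rownames(m) <- paste(df$taxon, df$group, sep = "|")
  structure(
    list(scores = m, taxon = df$taxon, group = df$group,
         pathway_ids = ids, missing_taxa = character(0), policy = NA_character_),
    class = "score_matrix"
  )
}
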