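#' Build per-disease elevated/reduced taxon signatures
#'
#' For each requested disease (matched case-insensitively against the
#' corpus), collects the distinct canonical taxon labels reported as
#' elevated and as reduced. Diseases with no matching records yield two
#' empty sets, so downstream overlap matrices stay rectangular. The two
#' sets of one disease may intersect: a taxon reported in both directions
#' (by different studies) is legal and surfaced by [conflict_report()].
#'
#' @param corpus A `dysbiosis_corpus`, already sample-filtered.
#' @param diseases Character vector of disease names.
#' @return A named list of `disease_signature` objects (fields
#'   `disease_name`, `elevated`, `reduced`), one per requested disease.
#' @export
build_signatures <- function(corpus, diseases) {
  stopifnot(inherits(corpus, "dysbiosis_corpus"))
  if (length(diseases) == 0L || any(!nzchar(trimws(diseases)))) {
    rlang::abort("`diseases` must be a non-empty list of disease names")
  }
  corpus_disease <- tolower(trimws(corpus$disease_name))
  sigs <- lapply(diseases, function(d) {
    hit <- corpus_disease == tolower(trimws(d))
    sub <- corpus[hit, , drop = FALSE]
    set_for <- function(cond) {
      lab <- sub$organism_label[sub$condition == cond]
      if (length(lab) == 0L) character(0) else sort(unique(normalize_label(lab)))
    }
    structure(
      list(disease_name = d,
           elevated = set_for("elevated"),
           reduced = set_for("reduced")),
      class = "disease_signature"
    )
  })
  stats::setNames(sigs, diseases)
}

#' Disjoint Venn partition of a family of named sets
#'
#' Assigns every element of the union to the unique cell identified by
#' the exact subset of set names containing it — the multi-list
#' comparison underlying cross-disease taxon tables. Cells with no
#' members are omitted. Cell keys are the member set names joined by
#' `"&"` in the order the sets were supplied.
#'
#' @param sets Named list of character vectors (at least one set).
#' @return A `venn_partition`: list with `universe` (all elements),
#'   `cells` (named list, disjoint, covering the universe) and
#'   `set_names`.
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 1L || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rlang::abort("`sets` must be a non-empty named list")
  }
  if (anyDuplicated(names(sets))) rlang::abort("set names must be distinct")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) universe <- character(0)
  cells <- list()
  if (length(universe) > 0L) {
    membership <- vapply(sets, function(s) universe %in% s,
                         FUN.VALUE = logical(length(universe)))
    membership <- matrix(membership, nrow = length(universe))
    keys <- apply(membership, 1L, function(m) paste(names(sets)[m], collapse = "&"))
    cells <- split(universe, keys)
    cells <- lapply(cells, function(x) sort(x))
  }
  out <- structure(
    list(universe = sort(universe), cells = cells, set_names = names(sets)),
    class = "venn_partition"
  )
  validate_venn(out)
  out
}

#' Assert the structural invariants of a Venn partition
#'
#' Cells must be pairwise disjoint and their union must equal the
#' universe; every output of [venn_partition()] is checked against this
#' before being returned.
#'
#' @param vp A `venn_partition`.
#' @return `vp`, invisibly; errors on violation.
#' @export
validate_venn <- function(vp) {
  stopifnot(inherits(vp, "venn_partition"))
  members <- unlist(vp$cells, use.names = FALSE)
  if (is.null(members)) members <- character(0)
  if (anyDuplicated(members)) {
    rlang::abort("venn partition cells are not disjoint")
  }
  if (!setequal(members, vp$universe) ||
      sum(lengths(vp$cells)) != length(vp$universe)) {
    rlang::abort("venn partition cells do not cover the universe")
  }
  invisible(vp)
}

condition_sets <- function(signatures, condition) {
  condition <- match.arg(condition, CONDITIONS)
  lapply(signatures, function(s) s[[condition]])
}

#' Pairwise overlap matrix between disease signatures
#'
#' Entry (d1, d2) is the size of the intersection of the two diseases'
#' taxon sets for the chosen condition; the diagonal carries each
#' disease's own set size. Symmetric by construction.
#'
#' @param signatures Named list from [build_signatures()].
#' @param condition `"elevated"` or `"reduced"`.
#' @return An integer matrix with disease names as dimnames.
#' @export
pairwise_overlap <- function(signatures, condition) {
  if (length(signatures) < 2L) {
    rlang::abort("pairwise overlap needs at least two diseases")
  }
  sets <- condition_sets(signatures, condition)
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

#' Taxa common to a subset of diseases under one condition
#'
#' @param signatures Named list from [build_signatures()].
#' @param subset Character vector of disease names present in
#'   `signatures`.
#' @param condition `"elevated"` or `"reduced"`.
#' @return Sorted character vector: the intersection of the chosen
#'   condition's sets across `subset`.
#' @export
common_taxa <- function(signatures, subset, condition) {
  if (length(subset) == 0L) rlang::abort("`subset` must be non-empty")
  missing <- setdiff(subset, names(signatures))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("disease(s) not in signatures: %s",
                         paste(missing, collapse = ", ")))
  }
  sets <- condition_sets(signatures[subset], condition)
  sort(Reduce(intersect, sets))
}

#' Taxa reported in both directions for one disease
#'
#' @param signature A `disease_signature`.
#' @return Sorted character vector `elevated` \eqn{\cap} `reduced`
#'   (taxa reported both elevated and reduced, like Blautia).
#' @export
conflict_report <- function(signature) {
  stopifnot(inherits(signature, "disease_signature"))
  sort(intersect(signature$elevated, signature$reduced))
}

#' Export a Venn partition as a cell table
#'
#' @param vp A `venn_partition`.
#' @param path Optional TSV output path.
#' @return A tibble with columns `subset`, `size`, `members`
#'   (comma-joined), written to `path` when given.
#' @export
venn_cell_table <- function(vp, path = NULL) {
  stopifnot(inherits(vp, "venn_partition"))
  df <- tibble::tibble(
    subset = names(vp$cells),
    size = unname(lengths(vp$cells)),
    members = vapply(vp$cells, paste, collapse = ",", FUN.VALUE = character(1))
  )
  df <- df[order(df$subset), ]
  if (!is.null(path)) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}
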