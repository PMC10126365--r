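#' Specify a corpus with planted set overlaps
#'
#' Describes a synthetic dysbiosis export by its Venn decomposition: for
#' each non-empty subset of diseases, how many taxa belong to exactly
#' that subset under the chosen condition. Generating from the planted
#' decomposition makes every downstream overlap count known in advance.
#'
#' @param diseases Character vector of distinct disease names.
#' @param condition `"elevated"` or `"reduced"`.
#' @param planted_cells Named list/vector: names are disease subsets
#'   joined by `"&"` (e.g. `"AD&PD"`), values are non-negative cell
#'   sizes.
#' @param label_prefix Prefix for the generated taxon labels.
#' @param seed Integer seed controlling record order.
#' @return An `overlap_spec` object.
#' @export
overlap_spec <- function(diseases, condition, planted_cells,
                         label_prefix = "Syntax", seed = 1L) {
  condition <- match.arg(condition, CONDITIONS)
  diseases <- as.character(diseases)
  if (length(diseases) == 0L || anyDuplicated(diseases)) {
    rlang::abort("`diseases` must be distinct and non-empty")
  }
  sizes <- unlist(planted_cells)
  if (length(sizes) > 0L) {
    if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
      rlang::abort("`planted_cells` must be named by '&'-joined disease subsets")
    }
    if (any(sizes < 0)) rlang::abort("cell sizes must be >= 0")
    members <- strsplit(names(sizes), "&", fixed = TRUE)
    bad <- !vapply(members, function(m) all(m %in% diseases) && !anyDuplicated(m)
                   && length(m) > 0L, logical(1))
    if (any(bad)) {
      rlang::abort(sprintf("invalid cell key(s): %s",
                           paste(names(sizes)[bad], collapse = ", ")))
    }
    if (anyDuplicated(vapply(members, function(m) paste(sort(m), collapse = "&"),
                             character(1)))) {
      rlang::abort("duplicate cell keys (after ordering) in planted_cells")
    }
  }
  structure(list(diseases = diseases, condition = condition,
                 planted_cells = sizes, label_prefix = label_prefix,
                 seed = as.integer(seed)),
            class = "overlap_spec")
}

#' Generate a dysbiosis corpus with planted Venn cells
#'
#' Emits one record per (taxon, disease) membership, all with sample
#' type "Feces" and the spec's condition. Taxon labels are
#' `<prefix><integer>` with globally unique integers, so distinct cells
#' can never collide. The record order is shuffled deterministically by
#' the spec seed; rebuilding signatures and partitioning them recovers
#' the planted cells exactly.
#'
#' @param spec An [overlap_spec()].
#' @return A `dysbiosis_corpus`.
#' @export
gen_dysbiosis_corpus <- function(spec) {
  stopifnot(inherits(spec, "overlap_spec"))
  sizes <- spec$planted_cells
  sizes <- sizes[order(names(sizes))]
  counter <- 0L
  rows <- list()
  for (key in names(sizes)) {
    k <- sizes[[key]]
    if (k == 0L) next
    members <- strsplit(key, "&", fixed = TRUE)[[1]]
    labels <- paste0(spec$label_prefix, counter + seq_len(k))
    counter <- counter + k
    for (d in members) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        organism_label = labels,
        ncbi_taxid = NA_integer_,
        condition = spec$condition,
        disease_name = d,
        meddra_id = NA_character_,
        sample_type = "Feces",
        detection_method = "synthetic"
      )
    }
  }
  df <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    organism_label = character(), ncbi_taxid = integer(),
    condition = character(), disease_name = character(),
    meddra_id = character(), sample_type = character(),
    detection_method = character()
  )
  if (nrow(df) > 0L) {
    df <- withr::with_seed(spec$seed, df[sample.int(nrow(df)), , drop = FALSE])
  }
  out <- new_corpus(df, provenance = sprintf("synthetic(seed=%d)", spec$seed))
  validate_corpus(out)
  out
}

#' Recover the Venn cells planted by an overlap spec
#'
#' Convenience wrapper running the real analysis path
#' ([build_signatures()] then [venn_partition()]) over a generated
#' corpus.
#'
#' @param corpus A `dysbiosis_corpus` from [gen_dysbiosis_corpus()].
#' @param spec The [overlap_spec()] that produced it.
#' @return Named integer vector of recovered cell sizes, keyed like
#'   `spec$planted_cells`.
#' @export
recover_planted_cells <- function(corpus, spec) {
  sigs <- build_signatures(corpus, spec$diseases)
  vp <- venn_partition(condition_sets(sigs, spec$condition))
  out <- lengths(vp$cells)
  stats::setNames(as.integer(out), names(out))
}

#' Specify a pathway database with planted completeness scores
#'
#' @param pathways Data frame / tibble with columns `pathway_id` and
#'   `reaction_count` (>= 1).
#' @param taxa Character vector of taxon labels.
#' @param target_scores Tibble with columns `taxon`, `pathway_id`,
#'   `score`; each score must equal `k / reaction_count` for an integer
#'   `k` of its pathway.
#' @param seed Integer seed (controls which reactions are annotated).
#' @return A `panel_spec` object.
#' @export
panel_spec <- function(pathways, taxa, target_scores, seed = 1L) {
  pathways <- tibble::as_tibble(pathways)
  stopifnot(all(c("pathway_id", "reaction_count") %in% names(pathways)))
  if (anyDuplicated(pathways$pathway_id)) rlang::abort("duplicate pathway ids")
  if (any(pathways$reaction_count < 1L)) rlang::abort("reaction_count must be >= 1")
  taxa <- as.character(taxa)
  if (length(taxa) == 0L || anyDuplicated(taxa)) {
    rlang::abort("`taxa` must be distinct and non-empty")
  }
  target_scores <- tibble::as_tibble(target_scores)
  stopifnot(all(c("taxon", "pathway_id", "score") %in% names(target_scores)))
  n <- pathways$reaction_count[match(target_scores$pathway_id, pathways$pathway_id)]
  if (anyNA(n)) rlang::abort("target references an unknown pathway id")
  if (!all(target_scores$taxon %in% taxa)) {
    rlang::abort("target references an unknown taxon")
  }
  k <- target_scores$score * n
  if (any(abs(k - round(k)) > 1e-9) || any(target_scores$score < 0) ||
      any(target_scores$score > 1)) {
    rlang::abort("every target score must be k/reaction_count for integer 0 <= k <= reaction_count")
  }
  structure(list(pathways = pathways, taxa = taxa,
                 target_scores = target_scores, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a pathway panel and annotations with planted scores
#'
#' Every pathway gets `reaction_count` unique reaction ids; for each
#' (taxon, pathway) target `k/n` the generated annotation holds exactly
#' `k` of that pathway's reactions (which `k` is seed-determined).
#' Scoring the generated database recovers every target exactly.
#' Pathways are assigned cyclically to the three panel categories so the
#' panel validates without implying any biology.
#'
#' @param spec A [panel_spec()].
#' @return List with `panel` (a `pathway_panel`), `annotations` (a
#'   `genome_annotations` table, one strain per taxon) and `groups_hint`
#'   (alternating elevated/reduced assignment of the taxa, convenient
#'   for matrix-level tests).
#' @export
gen_pathway_db <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  reactions <- lapply(seq_len(nrow(spec$pathways)), function(i) {
    sprintf("%s_r%02d", spec$pathways$pathway_id[i],
            seq_len(spec$pathways$reaction_count[i]))
  })
  panel <- as_pathway_panel(tibble::tibble(
    pathway_id = spec$pathways$pathway_id,
    name = spec$pathways$pathway_id,
    category = PATHWAY_CATEGORIES[(seq_len(nrow(spec$pathways)) - 1L) %%
                                    length(PATHWAY_CATEGORIES) + 1L],
    reactions = reactions
  ))
  annotations <- withr::with_seed(spec$seed, {
    ann <- lapply(spec$taxa, function(tx) {
      hits <- spec$target_scores[spec$target_scores$taxon == tx, ]
      unlist(lapply(seq_len(nrow(hits)), function(r) {
        j <- match(hits$pathway_id[r], panel$pathway_id)
        n <- length(panel$reactions[[j]])
        k <- round(hits$score[r] * n)
        if (k == 0L) character(0) else sample(panel$reactions[[j]], k)
      }), use.names = FALSE)
    })
    tibble::tibble(
      taxon = spec$taxa,
      strain = paste0(spec$taxa, "_s1"),
      reactions = ann
    )
  })
  groups_hint <- split(
    spec$taxa,
    CONDITIONS[(seq_along(spec$taxa) - 1L) %% 2L + 1L]
  )
  list(panel = panel, annotations = as_annotations(annotations),
       groups_hint = groups_hint)
}

#' Generate a synthetic ranked lineage table
#'
#' Assigns each taxon a complete lineage down to genus: a
#' seed-deterministic phylum drawn from `phyla`, with class/order/family
#' names derived from the phylum so that every taxon of one phylum
#' shares the same internal path, and the taxon label itself as the
#' genus.
#'
#' @param taxa Character vector of taxon labels (may be empty).
#' @param phyla Non-empty character vector of phylum names.
#' @param seed Integer seed.
#' @return A `lineage_table`.
#' @export
gen_lineage_table <- function(taxa, phyla, seed = 1L) {
  phyla <- as.character(phyla)
  if (length(phyla) == 0L) rlang::abort("`phyla` must be non-empty")
  taxa <- normalize_label(as.character(unique(taxa)))
  assigned <- if (length(taxa) == 0L) character(0) else
    withr::with_seed(as.integer(seed),
                     sample(phyla, length(taxa), replace = TRUE))
  df <- tibble::tibble(
    label = taxa,
    taxid = NA_integer_,
    superkingdom = rep("Bacteria", length(taxa)),
    phylum = assigned,
    class = if (length(taxa)) paste0(assigned, " classis") else character(0),
    order = if (length(taxa)) paste0(assigned, " ordo") else character(0),
    family = if (length(taxa)) paste0(assigned, " familia") else character(0),
    genus = taxa,
    species = rep(NA_character_, length(taxa))
  )
  structure(df, class = c("lineage_table", class(tibble::tibble())))
}

#' Draw a random overlap spec
#'
#' Randomized study conditions for planted-recovery checks: 2-5
#' diseases and uniformly random cell sizes up to `max_cell` for every
#' non-empty disease subset.
#'
#' @param seed Integer seed (drives both the drawn spec and the
#'   generated corpus).
#' @param max_diseases Maximum number of diseases (>= 2; at most 5).
#' @param max_cell Maximum planted cell size.
#' @return An `overlap_spec`.
#' @export
random_overlap_spec <- function(seed, max_diseases = 5L, max_cell = 20L) {
  withr::with_seed(as.integer(seed), {
    k <- sample(2:max_diseases, 1L)
    diseases <- paste0("Disease", seq_len(k))
    subsets <- unlist(lapply(seq_len(k), function(sz) {
      utils::combn(diseases, sz, FUN = paste, collapse = "&", simplify = FALSE)
    }))
    sizes <- sample(0:max_cell, length(subsets), replace = TRUE)
    cond <- sample(CONDITIONS, 1L)
    overlap_spec(diseases, cond,
                 stats::setNames(as.list(sizes), subsets),
                 label_prefix = sprintf("Tax%d_", seed), seed = seed)
  })
}

#' Draw a random panel spec
#'
#' 2-6 pathways of 1-12 reactions, 2-8 taxa, and a full grid of
#' representable random targets `k/n`.
#'
#' @param seed Integer seed.
#' @return A `panel_spec`.
#' @export
random_panel_spec <- function(seed) {
  withr::with_seed(as.integer(seed), {
    np <- sample(2:6, 1L)
    nt <- sample(2:8, 1L)
    pathways <- tibble::tibble(
      pathway_id = sprintf("pwy%d_%d", seed, seq_len(np)),
      reaction_count = sample(1:12, np, replace = TRUE)
    )
    taxa <- sprintf("Gen%d_%d", seed, seq_len(nt))
    grid <- expand.grid(taxon = taxa, pathway_id = pathways$pathway_id,
                        stringsAsFactors = FALSE)
    n <- pathways$reaction_count[match(grid$pathway_id, pathways$pathway_id)]
    k <- vapply(n, function(nn) sample(0:nn, 1L), integer(1))
    grid$score <- k / n
    panel_spec(pathways, taxa, tibble::as_tibble(grid), seed = seed)
  })
}
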