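# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's own implementation paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop corpus bookkeeping attributes for whole-table comparisons.
strip_corpus <- function(x) {
  df <- as.data.frame(x)
  attr(df, "provenance") <- NULL
  attr(df, "skipped") <- NULL
  attr(df, "multiplicity") <- NULL
  df
}

# Venn partition by per-element membership-vector enumeration.
brute_venn_cells <- function(sets) {
  universe <- unique(unlist(sets, use.names = FALSE))
  cells <- list()
  for (el in universe) {
    key <- paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
                 collapse = "&")
    cells[[key]] <- c(cells[[key]], el)
  }
  lapply(cells, sort)
}

# Two-loop Euclidean distance oracle.
brute_euclidean <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(ncol(m))) s <- s + (m[i, k] - m[j, k])^2
      d[i, j] <- sqrt(s)
    }
  }
  d
}

# Naive O(n^3) Ward: recompute the within-cluster sum-of-squares increase
# for every candidate pair from raw coordinates at every step; heights on
# the ward.D2 scale (sqrt of twice the ESS increase).
naive_ward <- function(m) {
  n <- nrow(m)
  ess <- function(rows) {
    if (length(rows) == 1L) return(0)
    x <- m[rows, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  steps <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (ii >= jj) next
        a <- active[ii]; b <- active[jj]
        d <- ess(c(members[[a]], members[[b]])) - ess(members[[a]]) - ess(members[[b]])
        if (d < bestd - 1e-12) { bestd <- d; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    steps[[s]] <- list(parts = list(sort(members[[a]]), sort(members[[b]])),
                       all = sort(c(members[[a]], members[[b]])),
                       height = sqrt(2 * bestd))
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  steps
}

# Decode an hclust merge matrix into the same step structure.
hclust_steps <- function(hc) {
  merges <- vector("list", nrow(hc$merge))
  get <- function(i) if (i < 0) -i else merges[[i]]$all
  for (s in seq_len(nrow(hc$merge))) {
    a <- sort(get(hc$merge[s, 1]))
    b <- sort(get(hc$merge[s, 2]))
    merges[[s]] <- list(parts = list(a, b), all = sort(c(a, b)),
                        height = hc$height[s])
  }
  merges
}

same_merge_step <- function(x, y, tol = 1e-8) {
  pair_eq <- setequal_list(x$parts, y$parts)
  pair_eq && identical(x$all, y$all) && abs(x$height - y$height) < tol
}

setequal_list <- function(a, b) {
  (identical(a[[1]], b[[1]]) && identical(a[[2]], b[[2]])) ||
    (identical(a[[1]], b[[2]]) && identical(a[[2]], b[[1]]))
}

# Random rooted trees for serialization round trips.
random_tree <- function(seed, max_leaves = 8L, quoted = FALSE,
                        lengths = FALSE) {
  label_pool <- if (quoted) {
    c("plain", "two words", "mid,comma", "par(en", "quo'te", "colon:x", "semi;x")
  } else {
    paste0("leaf", 1:26)
  }
  withr::with_seed(seed, {
    counter <- 0L
    new_label <- function() {
      counter <<- counter + 1L
      paste0(sample(label_pool, 1L), "_", counter)
    }
    grow <- function(n_leaves) {
      len <- if (lengths) sample(0:8, 1L) / 2 else NA_real_
      if (n_leaves == 1L) {
        return(structure(list(label = new_label(), length = len,
                              children = list()), class = "taxon_tree"))
      }
      k <- sample(seq_len(n_leaves - 1L), 1L)
      lab <- if (stats::runif(1) < 0.5) new_label() else NA_character_
      structure(list(label = lab, length = len,
                     children = list(grow(k), grow(n_leaves - k))),
                class = "taxon_tree")
    }
    root <- grow(sample(2:max_leaves, 1L))
    root$length <- NA_real_
    root
  })
}

tree_equal <- function(a, b, tol = 1e-9) {
  if (!identical(is.na(a$label), is.na(b$label))) return(FALSE)
  if (!is.na(a$label) && a$label != b$label) return(FALSE)
  if (is.na(a$length) != is.na(b$length)) return(FALSE)
  if (!is.na(a$length) && abs(a$length - b$length) > tol) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  all(vapply(seq_along(a$children),
             function(i) tree_equal(a$children[[i]], b$children[[i]], tol),
             logical(1)))
}

# Random named sets over a small symbol alphabet.
random_named_sets <- function(seed, max_sets = 5L, alphabet = 50L) {
  withr::with_seed(seed, {
    k <- sample(2:max_sets, 1L)
    symbols <- paste0("s", seq_len(alphabet))
    sets <- lapply(seq_len(k), function(i) {
      sample(symbols, sample.int(alphabet, 1L))
    })
    stats::setNames(sets, paste0("Set", seq_len(k)))
  })
}

# Corpus JSON snippets used by parser tests.
corpus_json <- function(records) {
  jsonlite::toJSON(records, auto_unbox = TRUE)
}

# A small, fully coherent synthetic study on disk: corpus JSON, lineage
# TSV, pathway panel and annotations covering every generated taxon.
write_mini_study <- function(dir, seed = 11L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp_el <- overlap_spec(c("DiseaseA", "DiseaseB"), "elevated",
                        list("DiseaseA&DiseaseB" = 3, "DiseaseA" = 2,
                             "DiseaseB" = 2),
                        label_prefix = "Eltax", seed = seed)
  sp_re <- overlap_spec(c("DiseaseA", "DiseaseB"), "reduced",
                        list("DiseaseA&DiseaseB" = 2, "DiseaseB" = 1),
                        label_prefix = "Retax", seed = seed + 1L)
  df <- dplyr::bind_rows(as.data.frame(gen_dysbiosis_corpus(sp_el)),
                         as.data.frame(gen_dysbiosis_corpus(sp_re)))
  corpus_path <- file.path(dir, "corpus.json")
  jsonlite::write_json(df, corpus_path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE)
  corpus <- suppressMessages(parse_records(corpus_path))

  taxa <- sort(unique(normalize_label(corpus$organism_label)))
  lineages <- gen_lineage_table(taxa, c("PhylumOne", "PhylumTwo"), seed = seed)
  lineage_path <- file.path(dir, "lineages.tsv")
  utils::write.table(as.data.frame(lineages), lineage_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  pspec <- panel_spec(
    tibble::tibble(pathway_id = c("pwy_a", "pwy_b", "pwy_c"),
                   reaction_count = c(4L, 5L, 2L)),
    taxa,
    tibble::tibble(
      taxon = rep(taxa, each = 3L),
      pathway_id = rep(c("pwy_a", "pwy_b", "pwy_c"), length(taxa)),
      score = unlist(lapply(seq_along(taxa), function(i) {
        withr::with_seed(seed + i, c(sample(0:4, 1L) / 4, sample(0:5, 1L) / 5,
                                     sample(0:2, 1L) / 2))
      }))
    ),
    seed = seed
  )
  db <- gen_pathway_db(pspec)
  panel_path <- file.path(dir, "panel.tsv")
  utils::write.table(
    data.frame(pathway_id = db$panel$pathway_id, name = db$panel$name,
               category = db$panel$category,
               reactions = vapply(db$panel$reactions, paste, collapse = ";",
                                  FUN.VALUE = character(1))),
    panel_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann_path <- file.path(dir, "annotations.tsv")
  utils::write.table(
    data.frame(taxon = db$annotations$taxon, strain = db$annotations$strain,
               reactions = vapply(db$annotations$reactions, paste,
                                  collapse = ";", FUN.VALUE = character(1))),
    ann_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(records = corpus_path, lineages = lineage_path, panel = panel_path,
       annotations = ann_path, diseases = c("DiseaseA", "DiseaseB"),
       panel_spec = pspec, corpus = corpus)
}
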