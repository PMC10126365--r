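test_that("pathway_score is the annotated fraction of the pathway's reactions", {
  rxn <- paste0("r", 1:5)
  expect_identical(pathway_score(rxn, rxn), 1)
  expect_identical(pathway_score(paste0("q", 1:5), rxn), 0)
  expect_equal(pathway_score(c("r1", "r3"), c("r1", "r2", "r3", "r4")), 0.5)
  # out-of-pathway annotations contribute nothing
  expect_equal(pathway_score(c("r1", "r9"), c("r1", "r2")), 0.5)
  expect_error(pathway_score("r1", character(0)), "at least one")
})

test_that("pathway_score boundary, monotonicity and quantization properties hold", {
  for (seed in 1:80) {
    trial <- withr::with_seed(seed, {
      n <- sample(1:12, 1L)
      pool <- paste0("rx", 1:20)
      list(pathway = sample(pool, n),
           ann = sample(pool, sample(0:20, 1L)),
           extra = sample(pool, 1L))
    })
    ps <- pathway_score(trial$ann, trial$pathway)
    # brute-force per-reaction counting oracle
    count <- 0L
    for (r in trial$pathway) if (r %in% trial$ann) count <- count + 1L
    expect_identical(ps, count / length(trial$pathway))
    # quantization: k/|reactions|
    expect_lt(abs(ps * length(trial$pathway) - round(ps * length(trial$pathway))),
              1e-12)
    # boundaries iff subset / empty intersection
    expect_identical(ps == 1, all(trial$pathway %in% trial$ann))
    expect_identical(ps == 0, !any(trial$pathway %in% trial$ann))
    # monotone in the annotation set
    expect_gte(pathway_score(union(trial$ann, trial$extra), trial$pathway), ps)
  }
})

test_that("aggregate_scores applies max and mean policies on [0,1]", {
  expect_equal(aggregate_scores(c(0.2, 0.8), "max"), 0.8)
  expect_equal(aggregate_scores(c(0.2, 0.8), "mean"), 0.5)
  expect_equal(aggregate_scores(0.4, "max"), 0.4)
  expect_equal(aggregate_scores(0.4, "mean"), 0.4)
  expect_error(aggregate_scores(numeric(0)), "non-empty")
  expect_error(aggregate_scores(c(0.5, 1.2)), "\\[0, 1\\]")
})

write_panel_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("load_pathway_panel validates ids, categories and reaction sets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(data.frame(
    pathway_id = c("ac_ferm", "put_iii", "spd_i"),
    name = c("acetate fermentation", "putrescine biosynthesis III",
             "spermidine biosynthesis I"),
    category = c("SCFA", "polyamine", "polyamine"),
    reactions = c("r1;r2;r3", "r4;r5", "r6")
  ), path)
  panel <- load_pathway_panel(path)
  expect_equal(nrow(panel), 3L)
  expect_equal(panel$reactions[[1]], c("r1", "r2", "r3"))

  dup <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(data.frame(
    pathway_id = c("p1", "p1"), name = c("a", "b"),
    category = c("SCFA", "SCFA"), reactions = c("r1", "r2")
  ), dup)
  expect_error(load_pathway_panel(dup), "duplicate pathway ids")

  badcat <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(data.frame(
    pathway_id = "p1", name = "a", category = "lipids", reactions = "r1"
  ), badcat)
  expect_error(load_pathway_panel(badcat), "category")

  duprxn <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(data.frame(
    pathway_id = "p1", name = "a", category = "SCFA", reactions = "r1;r1"
  ), duprxn)
  expect_error(load_pathway_panel(duprxn), "duplicate reaction ids")
})

mini_db <- function() {
  panel_path <- withr::local_tempfile(fileext = ".tsv",
                                      .local_envir = parent.frame())
  write_panel_tsv(data.frame(
    pathway_id = c("pwy1", "pwy2", "pwy3"),
    name = c("p one", "p two", "p three"),
    category = c("SCFA", "polyamine", "neurotransmitter_precursor"),
    reactions = c("a1;a2", "b1;b2;b3;b4", "c1")
  ), panel_path)
  ann_path <- withr::local_tempfile(fileext = ".tsv",
                                    .local_envir = parent.frame())
  write_panel_tsv(data.frame(
    taxon = c("Taxone", "Taxone", "Taxtwo"),
    strain = c("s1", "s2", "s3"),
    reactions = c("a1;b1;b2", "a1;a2;c1", "b1;b2;b3;b4")
  ), ann_path)
  list(panel = load_pathway_panel(panel_path),
       annotations = load_annotations(ann_path))
}

test_that("build_score_matrix emits one row per (taxon, group) with aggregated scores", {
  db <- mini_db()
  groups <- list(elevated = c("Taxone", "Taxtwo"), reduced = "Taxone")
  sm <- build_score_matrix(groups, db$panel, db$annotations, policy = "max")
  expect_equal(dim(sm$scores), c(3L, 3L))
  expect_false(anyNA(sm$scores))
  # max policy takes the best strain of Taxone per pathway
  expect_equal(unname(sm$scores["Taxone|elevated", ]), c(1, 0.5, 1))
  # a taxon reported in both groups appears as two identical-score rows
  expect_equal(sm$scores["Taxone|elevated", ], sm$scores["Taxone|reduced", ])
  mean_sm <- build_score_matrix(groups, db$panel, db$annotations,
                                policy = "mean")
  expect_equal(unname(mean_sm$scores["Taxone|elevated", ]), c(0.75, 0.25, 0.5))
})

test_that("taxa without annotations yield missing rows that imputation fills", {
  db <- mini_db()
  groups <- list(elevated = c("Taxone", "Ghost"))
  expect_message(
    sm <- build_score_matrix(groups, db$panel, db$annotations), "Ghost")
  expect_equal(sm$missing_taxa, "Ghost")
  expect_true(all(is.na(sm$scores["Ghost|elevated", ])))
  expect_warning(filled <- impute_missing_scores(sm), "imputing 3")
  expect_equal(unname(filled$scores["Ghost|elevated", ]), c(0, 0, 0))
})

test_that("score matrices round-trip through TSV with the group column", {
  db <- mini_db()
  sm <- build_score_matrix(list(elevated = "Taxone", reduced = "Taxtwo"),
                           db$panel, db$annotations)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(sm, path)
  back <- read_score_matrix(path)
  expect_equal(back$scores, sm$scores)
  expect_equal(back$group, sm$group)
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  expect_true("group" %in% header)
})

test_that("planted synthetic databases are recovered exactly", {
  spec <- random_panel_spec(42)
  db <- gen_pathway_db(spec)
  sm <- build_score_matrix(db$groups_hint, db$panel, db$annotations,
                           policy = "max")
  for (i in seq_len(nrow(spec$target_scores))) {
    row <- paste(normalize_label(spec$target_scores$taxon[i]),
                 sm$group[sm$taxon == normalize_label(spec$target_scores$taxon[i])][1],
                 sep = "|")
    expect_identical(sm$scores[row, spec$target_scores$pathway_id[i]],
                     spec$target_scores$score[i])
  }
})
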