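table1_diseases <- c("Alzheimer's disease", "Parkinson's disease",
                     "Multiple sclerosis", "Amyotrophic lateral sclerosis")

table1_signatures <- function() {
  build_signatures(filter_by_sample(load_table1_fixture(), "Feces"),
                   table1_diseases)
}

test_that("build_signatures collects distinct normalized labels per condition", {
  sigs <- table1_signatures()
  pd <- sigs[["Parkinson's disease"]]
  expect_true(all(c("Alistipes", "Bacteroides", "Bifidobacterium", "Blautia",
                    "Lactobacillus", "Ruminococcaceae", "Shigella")
                  %in% pd$elevated))
  # disease matching is case-insensitive: rows printed as
  # "Alzheimer's Disease" count toward "Alzheimer's disease"
  ad <- sigs[["Alzheimer's disease"]]
  expect_true(all(c("Lactobacillus", "Ruminococcaceae") %in% ad$elevated))

  expect_error(build_signatures(load_table1_fixture(), character(0)),
               "non-empty")
  none <- build_signatures(load_table1_fixture(), "No such disease")
  expect_equal(none[[1]]$elevated, character(0))
  expect_equal(none[[1]]$reduced, character(0))

  again <- table1_signatures()
  expect_identical(sigs, again)
})

test_that("single-record corpora yield one singleton set", {
  js <- corpus_json(list(
    list(organism_label = "Dorea", condition = "reduced",
         disease_name = "MS", sample_type = "Feces")
  ))
  sig <- build_signatures(parse_records(js), "MS")[["MS"]]
  expect_equal(sig$reduced, "Dorea")
  expect_equal(sig$elevated, character(0))
})

test_that("venn_partition handles identical, disjoint and empty families", {
  vp <- venn_partition(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(vp$cells, list(`A&B` = c("x", "y")))

  vp2 <- venn_partition(list(A = "x", B = "y"))
  expect_equal(vp2$cells[["A"]], "x")
  expect_equal(vp2$cells[["B"]], "y")
  expect_null(vp2$cells[["A&B"]])

  vp3 <- venn_partition(list(A = character(0)))
  expect_equal(length(vp3$cells), 0L)
  expect_error(venn_partition(list()), "named")
})

test_that("venn_partition agrees with brute-force membership enumeration", {
  for (seed in 1:40) {
    sets <- random_named_sets(seed, max_sets = 4L, alphabet = 20L)
    vp <- venn_partition(sets)
    oracle <- brute_venn_cells(sets)
    expect_identical(vp$cells[order(names(vp$cells))],
                     oracle[order(names(oracle))])
  }
})

test_that("pairwise_overlap is symmetric with set sizes on the diagonal", {
  sigs <- list(
    d1 = structure(list(disease_name = "d1", elevated = paste0("t", 1:5),
                        reduced = character(0)), class = "disease_signature"),
    d2 = structure(list(disease_name = "d2", elevated = paste0("t", 1:5),
                        reduced = character(0)), class = "disease_signature"),
    d3 = structure(list(disease_name = "d3", elevated = paste0("u", 1:3),
                        reduced = character(0)), class = "disease_signature")
  )
  ov <- pairwise_overlap(sigs, "elevated")
  expect_equal(ov["d1", "d2"], 5L)
  expect_equal(ov["d1", "d3"], 0L)
  expect_equal(diag(ov), c(d1 = 5L, d2 = 5L, d3 = 3L))
  expect_identical(ov, t(ov))
  expect_error(pairwise_overlap(sigs, "weird"), "elevated")
  expect_error(pairwise_overlap(sigs["d1"], "elevated"), "two")
})

test_that("pairwise overlaps equal sums of venn cells containing both diseases", {
  for (cond in c("elevated", "reduced")) {
    sigs <- table1_signatures()
    sets <- lapply(sigs, function(s) s[[cond]])
    ov <- pairwise_overlap(sigs, cond)
    vp <- venn_partition(sets)
    keys <- strsplit(names(vp$cells), "&", fixed = TRUE)
    for (d1 in names(sets)) {
      for (d2 in setdiff(names(sets), d1)) {
        in_both <- vapply(keys, function(k) all(c(d1, d2) %in% k), logical(1))
        expect_equal(ov[d1, d2], sum(lengths(vp$cells)[in_both]))
      }
    }
  }
})

test_that("common_taxa matches the published cross-disease memberships", {
  sigs <- table1_signatures()
  expect_setequal(
    common_taxa(sigs, c("Alzheimer's disease", "Multiple sclerosis",
                        "Parkinson's disease"), "elevated"),
    c("Alistipes", "Bacteroides", "Bifidobacterium", "Blautia",
      "Lactobacillus", "Shigella"))
  expect_setequal(common_taxa(sigs, table1_diseases, "reduced"),
                  c("Clostridium", "Dorea"))
  expect_identical(
    common_taxa(sigs, "Multiple sclerosis", "elevated"),
    sort(sigs[["Multiple sclerosis"]]$elevated))
  expect_error(common_taxa(sigs, "Nonexistent", "elevated"), "Nonexistent")
})

test_that("common_taxa equals the union of venn cells whose key covers the subset", {
  sigs <- table1_signatures()
  sets <- lapply(sigs, function(s) s$elevated)
  vp <- venn_partition(sets)
  keys <- strsplit(names(vp$cells), "&", fixed = TRUE)
  diseases <- names(sets)
  for (size in seq_along(diseases)) {
    combos <- utils::combn(diseases, size, simplify = FALSE)
    for (sub in combos) {
      covered <- vapply(keys, function(k) all(sub %in% k), logical(1))
      expect_setequal(common_taxa(sigs, sub, "elevated"),
                      unlist(vp$cells[covered], use.names = FALSE) %||% character(0))
    }
  }
})

test_that("conflict_report surfaces taxa reported in both directions", {
  sigs <- table1_signatures()
  expect_true("Blautia" %in% conflict_report(sigs[["Multiple sclerosis"]]))
  disjoint <- structure(list(disease_name = "x", elevated = "A", reduced = "B"),
                        class = "disease_signature")
  expect_equal(conflict_report(disjoint), character(0))
  full <- structure(list(disease_name = "x", elevated = c("A", "B"),
                         reduced = c("B", "A")), class = "disease_signature")
  expect_setequal(conflict_report(full), c("A", "B"))
})

test_that("venn cell tables serialize the partition faithfully", {
  sets <- random_named_sets(99, max_sets = 4L, alphabet = 15L)
  vp <- venn_partition(sets)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- venn_cell_table(vp, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$subset, df$subset)
  expect_equal(back$size, df$size)
  expect_equal(sum(df$size), length(vp$universe))
})
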