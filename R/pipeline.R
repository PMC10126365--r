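#' Build and validate a pipeline configuration
#'
#' @param records Path to a record-array JSON export.
#' @param lineages Path to a ranked-lineage TSV.
#' @param panel Path to a pathway-panel TSV.
#' @param annotations Path to a genome-annotation TSV.
#' @param diseases Non-empty character vector of disease names.
#' @param out_dir Output directory (created on run).
#' @param sample_type Sample type to keep (default `"Feces"`).
#' @param conditions Conditions to analyse (default both).
#' @param policy Strain aggregation policy for scoring.
#' @param cluster_cols Cluster heatmap columns too (default `TRUE`).
#' @param seed Top-level seed; the single source of randomness.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(records, lineages, panel, annotations, diseases,
                            out_dir, sample_type = "Feces",
                            conditions = CONDITIONS,
                            policy = c("max", "mean"),
                            cluster_cols = TRUE, seed = 1L) {
  policy <- match.arg(policy)
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  if (length(diseases) == 0L) {
    rlang::abort("config invalid: disease list is empty")
  }
  paths <- c(records = records, lineages = lineages, panel = panel,
             annotations = annotations)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0L) {
    rlang::abort(sprintf("config invalid: missing input file(s): %s",
                         paste(sprintf("%s=%s", names(absent), absent),
                               collapse = ", ")))
  }
  structure(list(records = records, lineages = lineages, panel = panel,
                 annotations = annotations, diseases = as.character(diseases),
                 out_dir = out_dir, sample_type = sample_type,
                 conditions = conditions, policy = policy,
                 cluster_cols = isTRUE(cluster_cols), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Every field of [pipeline_config()] has a JSON twin of the same name;
#' relative paths are resolved against the config file's directory.
#'
#' @param path JSON config path.
#' @param overrides Named list of fields overriding the file (CLI flags
#'   win over the file).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  do.call(pipeline_config, c(
    list(records = rel(raw$records), lineages = rel(raw$lineages),
         panel = rel(raw$panel), annotations = rel(raw$annotations),
         diseases = raw$diseases, out_dir = raw$out_dir %||% "dysbiosim_out"),
    raw[intersect(names(raw), c("sample_type", "conditions", "policy",
                                "cluster_cols", "seed"))]
  ))
}

slug <- function(x) gsub("_+", "_", gsub("[^A-Za-z0-9]+", "_", x))

#' Run the full dysbiosis analysis pipeline
#'
#' Executes extract, compare, tree, score and cluster in order, each
#' stage reading only the original inputs and its predecessors' files,
#' and writes `manifest.tsv` listing every output with its MD5 digest.
#' Identical config and inputs yield identical digests. Any stage
#' failure aborts with the stage name; the manifest then records the
#' files written so far with status `"partial"`.
#'
#' @param config A `pipeline_config`.
#' @return A tibble manifest (stage, file, md5, status), invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble::tibble(stage = character(), file = character())
  add <- function(stage, files) {
    manifest <<- dplyr::bind_rows(manifest,
                                  tibble::tibble(stage = stage,
                                                 file = unname(files)))
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      finish(manifest, config$out_dir, status = "partial")
      rlang::abort(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                   parent = e)
    })
  }
  finish <- function(manifest, out_dir, status) {
    manifest$md5 <- unname(tools::md5sum(manifest$file))
    manifest$status <- status
    utils::write.table(as.data.frame(manifest),
                       file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest
  }

  sigs <- NULL
  corpus <- NULL
  stage("extract", function() {
    corpus <<- dedupe_corpus(filter_by_sample(
      parse_records(config$records), config$sample_type))
    sigs <<- build_signatures(corpus, config$diseases)
    for (d in config$diseases) {
      for (cond in config$conditions) {
        f <- file.path(config$out_dir, sprintf("%s.%s.tsv", slug(d), cond))
        utils::write.table(data.frame(organism = sigs[[d]][[cond]]), f,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add("extract", f)
      }
    }
  })

  stage("compare", function() {
    for (cond in config$conditions) {
      sets <- condition_sets(sigs, cond)
      ov <- pairwise_overlap(sigs, cond)
      f1 <- file.path(config$out_dir, sprintf("overlap.%s.tsv", cond))
      utils::write.table(ov, f1, sep = "\t", quote = FALSE, col.names = NA)
      vp <- venn_partition(sets)
      f2 <- file.path(config$out_dir, sprintf("venn.%s.tsv", cond))
      venn_cell_table(vp, f2)
      add("compare", c(f1, f2))
    }
  })

  lineages <- NULL
  stage("tree", function() {
    lineages <<- read_lineage_table(config$lineages)
    for (cond in config$conditions) {
      taxa <- sort(unique(unlist(condition_sets(sigs, cond))))
      if (length(taxa) == 0L) next
      tr <- build_common_tree(taxa, lineages)
      f1 <- file.path(config$out_dir, sprintf("tree.%s.nwk", cond))
      write_newick(tr, f1)
      groups <- group_by_phylum(taxa, lineages)
      f2 <- file.path(config$out_dir, sprintf("phyla.%s.tsv", cond))
      utils::write.table(
        data.frame(phylum = rep(names(groups), lengths(groups)),
                   taxon = unlist(groups, use.names = FALSE)),
        f2, sep = "\t", quote = FALSE, row.names = FALSE)
      add("tree", c(f1, f2))
    }
  })

  sm <- NULL
  stage("score", function() {
    panel <- load_pathway_panel(config$panel)
    ann <- load_annotations(config$annotations)
    groups <- stats::setNames(
      lapply(config$conditions,
             function(cond) sort(unique(unlist(condition_sets(sigs, cond))))),
      config$conditions)
    groups <- groups[lengths(groups) > 0L]
    sm <<- build_score_matrix(groups, panel, ann, policy = config$policy)
    f <- file.path(config$out_dir, "scores.tsv")
    write_score_matrix(sm, f)
    add("score", f)
  })

  stage("cluster", function() {
    imputed <- impute_missing_scores(sm)
    cm <- cluster_matrix(imputed$scores, cluster_cols = config$cluster_cols)
    files <- export_heatmap(cm, file.path(config$out_dir, "heatmap"))
    add("cluster", files)
  })

  out <- finish(manifest, config$out_dir, status = "complete")
  invisible(out)
}
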