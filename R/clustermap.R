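#' Standardize features (auto-scale) for clustering
#'
#' Transforms every column to `(x - mean) / sd` with the sample (n-1)
#' standard deviation — the "auto-scale" standardization conventionally
#' applied before distance-based clustering of score matrices.
#' Zero-variance columns carry no ordering information and map to
#' all-zeros (noted in the result).
#'
#' @param m Numeric matrix, at least two rows, no missing cells.
#' @return A `scaled_matrix`: list with `values` (the scaled matrix),
#'   `center`, `scale` (per-feature mean and sd) and `zero_var` (names of
#'   flattened columns).
#' @export
autoscale <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) rlang::abort("matrix must be numeric")
  if (anyNA(m)) rlang::abort("matrix must have no missing cells (impute first)")
  if (nrow(m) < 2L) {
    rlang::abort("auto-scaling needs at least two rows (sd undefined)")
  }
  ctr <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  zero <- sds == 0
  sds_safe <- ifelse(zero, 1, sds)
  values <- sweep(sweep(m, 2L, ctr, "-"), 2L, sds_safe, "/")
  values[, zero] <- 0
  if (any(zero)) {
    rlang::inform(sprintf("%d zero-variance feature(s) set to 0: %s",
                          sum(zero),
                          paste(colnames(m)[zero], collapse = ", ")))
  }
  structure(list(values = values, center = ctr, scale = sds,
                 zero_var = colnames(m)[zero]),
            class = "scaled_matrix")
}

#' Pairwise Euclidean row distances
#'
#' @param m Numeric matrix with no missing cells.
#' @return A `dist` object (condensed lower triangle) of Euclidean
#'   distances between rows.
#' @export
euclidean_distances <- function(m) {
  if (inherits(m, "scaled_matrix")) m <- m$values
  m <- as.matrix(m)
  if (!is.numeric(m)) rlang::abort("matrix must be numeric")
  if (anyNA(m)) rlang::abort("matrix must have no missing cells")
  stats::dist(m, method = "euclidean")
}

#' Ward minimum-variance agglomeration
#'
#' Agglomerative clustering under Ward's criterion in its `ward.D2` form:
#' the Lance-Williams recurrence is applied to squared Euclidean
#' distances and merge heights are reported back on the distance scale.
#' With Euclidean input the merge heights are monotone non-decreasing.
#'
#' @param distances A `dist` object from [euclidean_distances()].
#' @return An `hclust` object (`n - 1` merges for `n` leaves).
#' @export
ward_linkage <- function(distances) {
  stopifnot(inherits(distances, "dist"))
  if (attr(distances, "Size") < 2L) {
    rlang::abort("clustering needs at least two rows")
  }
  stats::hclust(distances, method = "ward.D2")
}

#' Deterministic left-to-right dendrogram leaf order
#'
#' At every merge the cluster created earlier in the merge sequence is
#' placed on the left (leaves count as created before any merge; between
#' two leaves, the smaller leaf index goes left). The convention fixes
#' the heatmap layout so identical inputs always produce identical
#' output files.
#'
#' @param linkage An `hclust` object.
#' @return Integer permutation of `1:n` (leaf indices left to right).
#' @export
leaf_order <- function(linkage) {
  stopifnot(inherits(linkage, "hclust"))
  merge <- linkage$merge
  rec <- function(i) {
    if (i < 0) return(-i)
    a <- merge[i, 1]; b <- merge[i, 2]
    a_first <- if (a < 0 && b < 0) (-a) < (-b) else if (a < 0) TRUE
      else if (b < 0) FALSE else a < b
    if (a_first) c(rec(a), rec(b)) else c(rec(b), rec(a))
  }
  rec(nrow(merge))
}

#' Cluster a score matrix for heatmap display
#'
#' Runs the full clustering recipe: auto-scale features, Euclidean row
#' (and optionally column) distances, Ward (`ward.D2`) agglomeration,
#' and the deterministic leaf order of [leaf_order()].
#'
#' @param m Numeric matrix (e.g. the `scores` of an imputed
#'   [build_score_matrix()] result) or a `scaled_matrix`.
#' @param cluster_cols Also cluster the columns (default `TRUE`).
#' @param scale Auto-scale features first (default `TRUE`); ignored when
#'   `m` is already a `scaled_matrix`.
#' @return A `clustered_matrix`: list with `scaled` (matrix as
#'   clustered), `row_linkage`, `col_linkage` (or `NULL`), `row_order`,
#'   `col_order` (label permutations).
#' @export
cluster_matrix <- function(m, cluster_cols = TRUE, scale = TRUE) {
  scaled <- if (inherits(m, "scaled_matrix")) m$values
    else if (scale) autoscale(m)$values else as.matrix(m)
  if (is.null(rownames(scaled))) rownames(scaled) <- as.character(seq_len(nrow(scaled)))
  if (is.null(colnames(scaled))) colnames(scaled) <- as.character(seq_len(ncol(scaled)))
  row_hc <- ward_linkage(euclidean_distances(scaled))
  row_ord <- leaf_order(row_hc)
  col_hc <- NULL
  col_ord <- seq_len(ncol(scaled))
  if (isTRUE(cluster_cols)) {
    if (ncol(scaled) < 2L) {
      rlang::abort("column clustering needs at least two columns")
    }
    col_hc <- ward_linkage(euclidean_distances(t(scaled)))
    col_ord <- leaf_order(col_hc)
  }
  structure(
    list(scaled = scaled,
         row_linkage = row_hc, col_linkage = col_hc,
         row_order = rownames(scaled)[row_ord] %||% row_ord,
         col_order = colnames(scaled)[col_ord] %||% col_ord),
    class = "clustered_matrix"
  )
}

#' Export a clustered heatmap as text files (and optionally an image)
#'
#' Writes `matrix.tsv` (the scaled matrix reordered to the dendrogram
#' leaf orders), `rows.nwk` and — when columns were clustered —
#' `cols.nwk` (dendrograms in Newick, merge heights as branch lengths),
#' and optionally a raster heatmap via pheatmap.
#'
#' @param cm A `clustered_matrix`.
#' @param out_dir Output directory (created if needed).
#' @param image Also write `heatmap.png` (requires the pheatmap package).
#' @return Named character vector of the files written, invisibly.
#' @export
export_heatmap <- function(cm, out_dir, image = FALSE) {
  stopifnot(inherits(cm, "clustered_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ord <- cm$scaled[match(cm$row_order, rownames(cm$scaled)),
                   match(cm$col_order, colnames(cm$scaled)), drop = FALSE]
  files <- c(matrix = file.path(out_dir, "matrix.tsv"))
  df <- data.frame(row = rownames(ord), ord, check.names = FALSE)
  utils::write.table(df, files[["matrix"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_newick(hclust_to_tree(cm$row_linkage), file.path(out_dir, "rows.nwk"))
  files <- c(files, rows = file.path(out_dir, "rows.nwk"))
  if (!is.null(cm$col_linkage)) {
    write_newick(hclust_to_tree(cm$col_linkage), file.path(out_dir, "cols.nwk"))
    files <- c(files, cols = file.path(out_dir, "cols.nwk"))
  }
  if (isTRUE(image)) {
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
      rlang::warn("pheatmap not installed; skipping heatmap image")
    } else {
      png_path <- file.path(out_dir, "heatmap.png")
      grDevices::png(png_path, width = 900, height = 700)
      pheatmap::pheatmap(cm$scaled,
                         cluster_rows = cm$row_linkage,
                         cluster_cols = cm$col_linkage %||% FALSE,
                         scale = "none")
      grDevices::dev.off()
      files <- c(files, image = png_path)
    }
  }
  invisible(files)
}
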