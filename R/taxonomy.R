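RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus", "species")

#' Read a ranked-lineage table
#'
#' The table is the offline stand-in for a live taxonomy service: one row
#' per taxon with columns `label`, `taxid` and the seven canonical ranks
#' superkingdom..species (blank below the taxon's own rank). The package
#' ships one covering the taxa of the cross-disease analysis; see
#' [load_lineage_fixture()].
#'
#' @param path TSV path.
#' @return A `lineage_table` tibble.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), colClasses = "character",
                          fill = TRUE, quote = "")
  need <- c("label", "taxid", RANKS)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("lineage table lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[need])
  df$label <- normalize_label(df$label)
  df$taxid <- suppressWarnings(as.integer(df$taxid))
  if (anyDuplicated(df$label)) rlang::abort("duplicate labels in lineage table")
  structure(df, class = c("lineage_table", class(tibble::tibble())))
}

#' Load the packaged lineage table
#'
#' @return A `lineage_table` covering the taxa of the packaged
#'   cross-disease corpus and the surrounding comparative analysis.
#' @export
load_lineage_fixture <- function() {
  path <- system.file("extdata", "lineages.tsv", package = "dysbiosim")
  if (!nzchar(path)) rlang::abort("packaged lineages.tsv not found")
  read_lineage_table(path)
}

#' Resolve a taxon to its ranked lineage
#'
#' Looks up by taxid when a number is given, otherwise by canonical
#' label. Unknown taxa raise an error that lists near-miss spellings
#' (edit distance at most 2) as a hint.
#'
#' @param x A taxon label (character) or NCBI taxid (numeric).
#' @param table A `lineage_table`.
#' @return A tibble with columns `rank` and `name`, highest rank first,
#'   containing only the ranks present for that taxon.
#' @export
resolve_lineage <- function(x, table) {
  stopifnot(inherits(table, "lineage_table"))
  if (is.numeric(x)) {
    hit <- which(!is.na(table$taxid) & table$taxid == as.integer(x))
    what <- paste0("taxid ", x)
  } else {
    lab <- normalize_label(as.character(x))
    hit <- which(table$label == lab)
    what <- lab
  }
  if (length(hit) == 0L) {
    hint <- character(0)
    if (!is.numeric(x)) {
      d <- utils::adist(normalize_label(as.character(x)), table$label)
      hint <- table$label[d <= 2]
    }
    msg <- sprintf("taxon not found in lineage table: %s", what)
    if (length(hint) > 0L) {
      msg <- paste0(msg, "; did you mean: ", paste(hint, collapse = ", "), "?")
    }
    rlang::abort(msg, class = "dysbiosim_lookup_error")
  }
  row <- table[hit[1L], ]
  names <- unlist(row[RANKS], use.names = FALSE)
  keep <- !is.na(names)
  tibble::tibble(rank = RANKS[keep], name = names[keep])
}

# --- rooted-tree representation -------------------------------------------
# A tree node is list(label, length, children); leaves have no children.
# This carries both cladograms (no lengths) and dendrograms (heights).

tree_node <- function(label = NA_character_, children = list(), length = NA_real_) {
  structure(list(label = label, length = length, children = children),
            class = "taxon_tree")
}

is_leaf <- function(node) length(node$children) == 0L

#' Leaf labels of a tree, left to right
#'
#' @param tree A `taxon_tree` node.
#' @return Character vector of leaf labels.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Depth of a tree in edges
#'
#' @param tree A `taxon_tree` node.
#' @return Integer: longest root-to-leaf path length in edges.
#' @export
tree_depth <- function(tree) {
  if (is_leaf(tree)) return(0L)
  1L + max(vapply(tree$children, tree_depth, integer(1)))
}

#' Build a common-taxonomy cladogram from lineages
#'
#' Merges the resolved lineages of the input taxa on shared rank-name
#' prefixes (the NCBI "common tree" construction), then collapses unary
#' internal chains so that every internal node except the root has at
#' least two children. Leaves are exactly the input taxa; internal nodes
#' carry the shared lineage names. Branch lengths are omitted: the result
#' is a cladogram.
#'
#' @param taxa Character vector of taxon labels (any rank).
#' @param table A `lineage_table` resolving all of them.
#' @return A `taxon_tree` rooted at `"root"`.
#' @export
build_common_tree <- function(taxa, table) {
  stopifnot(inherits(table, "lineage_table"))
  taxa <- unique(normalize_label(as.character(taxa)))
  if (length(taxa) == 0L) rlang::abort("`taxa` must be non-empty")
  fails <- character(0)
  paths <- list()
  for (t in taxa) {
    lin <- tryCatch(resolve_lineage(t, table), error = function(e) NULL)
    if (is.null(lin)) { fails <- c(fails, t); next }
    p <- lin$name
    if (length(p) == 0L || p[length(p)] != t) p <- c(p, t)
    paths[[t]] <- p
  }
  if (length(fails) > 0L) {
    rlang::abort(sprintf("unresolvable taxa: %s", paste(fails, collapse = ", ")))
  }

  build <- function(paths_here, label) {
    done <- vapply(paths_here, length, integer(1)) == 0L
    leaves_here <- names(paths_here)[done]
    rest <- paths_here[!done]
    heads <- vapply(rest, `[`, character(1), 1L)
    kids <- list()
    for (h in unique(heads)) {
      sub <- lapply(rest[heads == h], function(p) p[-1L])
      kids[[length(kids) + 1L]] <- build(sub, h)
    }
    for (lf in leaves_here) kids[[length(kids) + 1L]] <- tree_node(lf)
    tree_node(label, kids)
  }
  root <- build(lapply(paths, identity), "root")

  # Unary chains collapse onto their topmost label (a phylum survives a
  # phylum->class->order chain); a chain ending in a leaf collapses to
  # the leaf itself.
  collapse <- function(node) {
    if (is_leaf(node)) return(node)
    while (length(node$children) == 1L) {
      child <- node$children[[1L]]
      if (is_leaf(child)) return(child)
      node$children <- child$children
    }
    node$children <- lapply(node$children, collapse)
    node
  }
  collapse(root)
}

#' Group taxa by the phylum of their lineage
#'
#' @param taxa Character vector of taxon labels.
#' @param table A `lineage_table`.
#' @return Named list phylum -> sorted character vector of taxa; taxa
#'   whose lineage has no phylum rank fall under `"unranked"`.
#' @export
group_by_phylum <- function(taxa, table) {
  taxa <- unique(normalize_label(as.character(taxa)))
  if (length(taxa) == 0L) return(stats::setNames(list(), character(0)))
  phyla <- vapply(taxa, function(t) {
    lin <- resolve_lineage(t, table)
    p <- lin$name[lin$rank == "phylum"]
    if (length(p) == 0L) "unranked" else p
  }, character(1))
  lapply(split(taxa, phyla), sort)
}

# --- Newick serialization --------------------------------------------------
# ape's reader/writer does not preserve quoted labels or one-leaf trees,
# so serialization that must round-trip exactly is done here; ape remains
# the cross-check for plain trees.

newick_quote <- function(label) {
  if (is.na(label)) return("")
  if (grepl("[\\s()\\[\\],:;']", label, perl = TRUE)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Serialize a tree to Newick
#'
#' Standard rooted Newick; labels containing Newick metacharacters
#' (parentheses, commas, colons, semicolons, quotes, brackets or
#' whitespace) are single-quoted with `''` escaping. Branch lengths are
#' written only where present. Exactly one terminating semicolon.
#'
#' @param tree A `taxon_tree`.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "taxon_tree"))
  rec <- function(node) {
    lab <- newick_quote(node$label)
    core <- if (is_leaf(node)) lab else {
      paste0("(", paste(vapply(node$children, rec, character(1)), collapse = ","),
             ")", lab)
    }
    if (!is.na(node$length)) core <- paste0(core, ":", format(node$length, digits = 15))
    core
  }
  text <- paste0(rec(tree), ";")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Parse a Newick string into a tree
#'
#' Recursive-descent parser accepting quoted labels (with `''` escapes)
#' and optional branch lengths; errors report the character position of
#' the problem.
#'
#' @param text A Newick string (exactly one tree).
#' @return A `taxon_tree`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- length(chars)
  fail <- function(msg) {
    rlang::abort(sprintf("newick parse error at position %d: %s", pos, msg))
  }
  peek <- function() if (pos <= n) chars[pos] else ""
  skip_ws <- function() {
    while (pos <= n && grepl("[[:space:]]", chars[pos])) pos <<- pos + 1L
  }
  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      pos <<- pos + 1L
      out <- character(0)
      repeat {
        if (pos > n) fail("unterminated quoted label")
        ch <- chars[pos]
        if (ch == "'") {
          if (pos + 1L <= n && chars[pos + 1L] == "'") {
            out <- c(out, "'"); pos <<- pos + 2L
          } else { pos <<- pos + 1L; break }
        } else { out <- c(out, ch); pos <<- pos + 1L }
      }
      return(paste(out, collapse = ""))
    }
    out <- character(0)
    while (pos <= n && !chars[pos] %in% c("(", ")", ",", ":", ";") &&
           !grepl("[[:space:]]", chars[pos])) {
      out <- c(out, chars[pos]); pos <<- pos + 1L
    }
    paste(out, collapse = "")
  }
  read_length <- function() {
    skip_ws()
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    skip_ws()
    out <- character(0)
    while (pos <= n && grepl("[-+0-9.eE]", chars[pos])) {
      out <- c(out, chars[pos]); pos <<- pos + 1L
    }
    if (length(out) == 0L) fail("expected branch length after ':'")
    as.numeric(paste(out, collapse = ""))
  }
  read_node <- function() {
    skip_ws()
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list(read_node())
      repeat {
        skip_ws()
        if (peek() == ",") { pos <<- pos + 1L; kids[[length(kids) + 1L]] <- read_node() }
        else if (peek() == ")") { pos <<- pos + 1L; break }
        else fail("expected ',' or ')'")
      }
      lab <- read_label()
      tree_node(if (nzchar(lab)) lab else NA_character_, kids, read_length())
    } else {
      lab <- read_label()
      if (!nzchar(lab)) fail("expected a label")
      tree_node(lab, list(), read_length())
    }
  }
  root <- read_node()
  skip_ws()
  if (peek() != ";") fail("expected terminating ';'")
  pos <- pos + 1L
  skip_ws()
  if (pos <= n) fail("dangling tokens after ';'")
  root
}

#' @export
print.taxon_tree <- function(x, ...) {
  cat("taxon_tree:", length(tree_leaves(x)), "leaves, depth", tree_depth(x), "\n")
  cat(substr(write_newick(x), 1, 200), "\n")
  invisible(x)
}

#' Convert an hclust dendrogram to a branch-length tree
#'
#' Merge heights become node heights; each branch length is the height
#' difference between parent and child (leaves sit at height 0), so the
#' exported Newick encodes the dendrogram geometry.
#'
#' @param hc An `hclust` object.
#' @return A `taxon_tree` with branch lengths.
#' @export
hclust_to_tree <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  node_at <- function(i, parent_h) {
    if (i < 0) {
      return(tree_node(labels[-i], list(), parent_h))
    }
    h <- hc$height[i]
    kids <- list(node_at(hc$merge[i, 1], h), node_at(hc$merge[i, 2], h))
    tree_node(NA_character_, kids, parent_h - h)
  }
  root <- node_at(nrow(hc$merge), hc$height[length(hc$height)])
  root$length <- NA_real_
  root
}

#' Export the flat leaf list of a tree
#'
#' One leaf label per line — the plain carrier-file form of a taxonomy
#' download that has no sequence data attached.
#'
#' @param tree A `taxon_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_leaf_list <- function(tree, path) {
  writeLines(tree_leaves(tree), path)
  invisible(path)
}
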