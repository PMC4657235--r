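#' UPGMA guide tree
#'
#' Textbook UPGMA (size-weighted average linkage, each merge at half the
#' cluster distance), computed with [stats::hclust()].  The returned tree
#' is rooted, binary and ultrametric: every internal node has a height at
#' least that of its children and leaves sit at height 0.
#'
#' @param d Symmetric distance matrix with zero diagonal (as from
#'   [distance_matrix()]), `n >= 2`.
#' @return An object of class `guide_tree` with fields `merge` (hclust
#'   merge matrix: negative entries are leaves), `heights` (node heights,
#'   i.e. half the merge distances), `labels`.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two sequences to build a guide tree")
  if (max(abs(d - t(d))) > 1e-9 || any(diag(d) != 0))
    stop("distance matrix must be symmetric with a zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("s", seq_len(n) - 1L)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(merge = hc$merge, heights = hc$height / 2, labels = labels),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("<guide_tree> %d leaves, root height %.4g\n",
              length(x$labels), max(x$heights)))
  invisible(x)
}

#' Serialize a guide tree as Newick
#'
#' Branch lengths are parent height minus child height, hence
#' non-negative; root-to-leaf path lengths all equal the root height.
#'
#' @param t A [upgma()] tree.
#' @return Newick string terminated by `;`.
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "guide_tree"))
  node_str <- function(idx, parent_h) {
    if (idx < 0L) {  # leaf
      sprintf("%s:%.10g", t$labels[-idx], parent_h)
    } else {
      h <- t$heights[idx]
      sprintf("(%s,%s):%.10g",
              node_str(t$merge[idx, 1L], h), node_str(t$merge[idx, 2L], h),
              parent_h - h)
    }
  }
  root <- nrow(t$merge)
  h <- t$heights[root]
  sprintf("(%s,%s);",
          node_str(t$merge[root, 1L], h), node_str(t$merge[root, 2L], h))
}

# leaf indices (1-based) under each internal node, in merge order
tree_leaf_sets <- function(t) {
  sets <- vector("list", nrow(t$merge))
  for (i in seq_len(nrow(t$merge))) {
    get1 <- function(v) if (v < 0L) -v else sets[[v]]
    sets[[i]] <- c(get1(t$merge[i, 1L]), get1(t$merge[i, 2L]))
  }
  sets
}

#' Root-to-leaf depths of a guide tree
#'
#' @param t A [upgma()] tree.
#' @return Named numeric vector of root-to-leaf path lengths (all equal,
#'   up to floating point, by ultrametricity).
#' @export
leaf_depths <- function(t) {
  root <- nrow(t$merge)
  depths <- stats::setNames(numeric(length(t$labels)), t$labels)
  walk <- function(idx, acc) {
    if (idx < 0L) {
      depths[t$labels[-idx]] <<- acc
    } else {
      h <- t$heights[idx]
      walk(t$merge[idx, 1L], acc + h - node_height(t, t$merge[idx, 1L]))
      walk(t$merge[idx, 2L], acc + h - node_height(t, t$merge[idx, 2L]))
    }
  }
  walk(root, 0)
  depths
}

node_height <- function(t, idx) if (idx < 0L) 0 else t$heights[idx]
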