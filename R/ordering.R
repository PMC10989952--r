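#' @importFrom stats dist hclust as.dendrogram cor is.leaf kmeans cutree
#'   as.hclust order.dendrogram dendrapply
NULL

# Build a stats::dist object for the rows of `m` under a distance spec.
# `method` may be "euclidean", "pearson" (1 - Pearson correlation), a pairwise
# function f(x, y), or a function f(m) returning a dist over rows.
build_distance <- function(m, method = "euclidean") {
  if (is.function(method)) {
    if (length(formals(method)) >= 2L) {
      n <- nrow(m)
      d <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
          d[i, j] <- d[j, i] <- method(m[i, ], m[j, ])
        }
      }
      if (any(d < 0)) stop("pairwise distance function returned a negative value",
                           call. = FALSE)
      return(stats::as.dist(d))
    }
    out <- method(m)
    if (!inherits(out, "dist")) out <- stats::as.dist(as.matrix(out))
    return(out)
  }
  method <- match.arg(method, c("euclidean", "pearson"))
  if (method == "euclidean") {
    dist(m, method = "euclidean")
  } else {
    # pairwise-complete correlation keeps rows with scattered missing values usable
    stats::as.dist(1 - cor(t(m), use = "pairwise.complete.obs"))
  }
}

#' Hierarchically cluster one axis of a matrix
#'
#' Agglomerative clustering of the rows or columns of a numeric matrix, under
#' a predefined or user-supplied distance and a linkage method, returned as a
#' `stats` dendrogram whose leaves index the clustered axis.
#'
#' @param m A numeric matrix or numeric `value_matrix`.
#' @param axis `"row"` or `"column"`.
#' @param dist_method `"euclidean"`, `"pearson"` (1 - Pearson correlation), a
#'   pairwise function `f(x, y)`, or a function of the whole matrix returning
#'   a `dist`.
#' @param linkage Linkage method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return A `dendrogram` over the axis indices.
#' @export
hcluster <- function(m, axis = c("row", "column"), dist_method = "euclidean",
                     linkage = "complete") {
  axis <- match.arg(axis)
  if (is_value_matrix(m)) {
    if (m$kind != "numeric") {
      stop("cannot cluster a categorical matrix without an explicit label distance",
           call. = FALSE)
    }
    m <- m$values
  }
  if (!is.numeric(m)) stop("`m` must be numeric", call. = FALSE)
  x <- if (axis == "row") m else t(m)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  all_na <- which(rowSums(!is.na(x)) == 0L)
  if (length(all_na)) {
    stop(sprintf("%s %d has no non-missing values and cannot be clustered",
                 axis, all_na[1L]), call. = FALSE)
  }
  d <- build_distance(x, dist_method)
  hc <- hclust(d, method = linkage)
  as.dendrogram(hc)
}

#' Leaf order of a dendrogram
#' @param dend A `dendrogram`.
#' @return Integer vector: item indices in left-to-right leaf order.
#' @export
leaf_order <- function(dend) order.dendrogram(dend)

#' Reorder a dendrogram by leaf weights
#'
#' Rotates branches (without altering any merge) so that at every internal
#' node the child subtree with the smaller mean leaf weight sits on the left.
#' Ties keep the incoming child order. The default heatmap use weights each
#' leaf by its item's mean value, so low-mean items drift left/top.
#'
#' @param dend A `dendrogram` over items `1..n`.
#' @param weights Numeric vector of length `n` (indexed by item, not by leaf
#'   position); must be finite.
#' @return The reordered `dendrogram`.
#' @export
reorder_dendrogram <- function(dend, weights) {
  n <- length(order.dendrogram(dend))
  if (length(weights) != n) {
    stop(sprintf("`weights` has length %d but the dendrogram has %d leaves",
                 length(weights), n), call. = FALSE)
  }
  if (!all(is.finite(weights))) stop("`weights` must be finite", call. = FALSE)
  rec <- function(node) {
    if (is.leaf(node)) {
      idx <- as.integer(node)
      return(list(node = node, sum = weights[idx], n = 1L))
    }
    left <- rec(node[[1L]])
    right <- rec(node[[2L]])
    if (left$sum / left$n > right$sum / right$n) {
      node[[1L]] <- right$node; node[[2L]] <- left$node
    } else {
      node[[1L]] <- left$node; node[[2L]] <- right$node
    }
    list(node = node, sum = left$sum + right$sum, n = left$n + right$n)
  }
  rec(dend)$node
}

#' Resolve an explicit ordering to a numeric permutation
#'
#' @param n Axis length.
#' @param indices A permutation of `1..n`, or of `names`.
#' @param names Optional axis names used to resolve character indices.
#' @return Integer permutation of `1..n`.
#' @export
order_by_indices <- function(n, indices, names = NULL) {
  if (is.character(indices)) {
    if (is.null(names)) stop("character indices need axis names", call. = FALSE)
    pos <- match(indices, names)
    if (anyNA(pos)) {
      stop(sprintf("unknown name '%s'", indices[is.na(pos)][1L]), call. = FALSE)
    }
    indices <- pos
  }
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) {
    stop(sprintf("duplicated index %d in ordering", indices[duplicated(indices)][1L]),
         call. = FALSE)
  }
  if (length(indices) != n || any(indices < 1L | indices > n)) {
    stop(sprintf("ordering must be a permutation of 1..%d", n), call. = FALSE)
  }
  indices
}

# Heights of all internal merges of a binary dendrogram (length n - 1).
dend_merge_heights <- function(dend) {
  hs <- numeric(0)
  walk <- function(node) {
    if (!is.leaf(node)) {
      hs[[length(hs) + 1L]] <<- as.numeric(attr(node, "height"))
      walk(node[[1L]])
      walk(node[[2L]])
    }
  }
  walk(dend)
  hs
}

# Accept externally built trees: a dendrogram, an hclust, or a minimal nested
# merge list (list(left, right, height = h); leaves are bare item indices).
as_dendrogram_any <- function(x) {
  if (inherits(x, "dendrogram")) return(x)
  if (inherits(x, "hclust")) return(as.dendrogram(x))
  if (is.list(x)) return(nested_to_dendrogram(x))
  stop("cannot interpret object as a dendrogram", call. = FALSE)
}

nested_to_dendrogram <- function(x) {
  build <- function(node) {
    if (is.numeric(node) && length(node) == 1L && is.null(attr(node, "height")) &&
        !is.list(node)) {
      leaf <- as.integer(node)
      attr(leaf, "leaf") <- TRUE
      attr(leaf, "height") <- 0
      attr(leaf, "members") <- 1L
      attr(leaf, "label") <- as.character(node)
      return(leaf)
    }
    if (!is.list(node) || length(node) < 2L || is.null(node$height %||% attr(node, "height"))) {
      stop("nested merge list nodes need two children and a `height`", call. = FALSE)
    }
    l <- build(node[[1L]])
    r <- build(node[[2L]])
    out <- list(l, r)
    attr(out, "height") <- as.numeric(node$height %||% attr(node, "height"))
    attr(out, "members") <- attr(l, "members") + attr(r, "members")
    attr(out, "midpoint") <- (attr(l, "members") - 1) / 2
    class(out) <- "dendrogram"
    out
  }
  build(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
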