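#' Construct a slice specification
#'
#' An ordered partition of row or column indices into labeled slices. The
#' order of slices is the render order; every construction path checks that
#' the slices are disjoint, exhaustive over `1..n`, and uniquely labeled.
#'
#' @param items List of integer index vectors, one per slice, in render order.
#' @param labels Character vector of unique slice labels.
#' @param axis `"row"` or `"column"`.
#' @param n Total axis length the slices must partition.
#' @return A `slice_spec` object.
#' @export
slice_spec <- function(items, labels, axis = c("row", "column"), n = NULL) {
  axis <- match.arg(axis)
  items <- lapply(items, as.integer)
  labels <- as.character(labels)
  if (length(items) != length(labels)) {
    stop("`items` and `labels` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicated slice label '%s'", labels[duplicated(labels)][1L]),
         call. = FALSE)
  }
  all_idx <- unlist(items, use.names = FALSE)
  if (is.null(n)) n <- length(all_idx)
  if (anyDuplicated(all_idx)) {
    stop("slices overlap: some indices occur in more than one slice", call. = FALSE)
  }
  if (length(all_idx) != n || !setequal(all_idx, seq_len(n))) {
    stop(sprintf("slices must exactly partition 1..%d", n), call. = FALSE)
  }
  structure(list(items = items, labels = labels, axis = axis, n = as.integer(n)),
            class = "slice_spec")
}

#' @export
print.slice_spec <- function(x, ...) {
  cat(sprintf("<slice_spec> %s axis, %d slice(s): %s\n", x$axis,
              length(x$items),
              paste(sprintf("%s[%d]", x$labels, lengths(x$items)), collapse = " ")))
  invisible(x)
}

n_slices <- function(s) length(s$items)

# Trivial one-slice spec covering an axis.
single_slice <- function(n, axis) {
  slice_spec(list(seq_len(n)), "all", axis, n)
}

#' Split an axis by consensus k-means
#'
#' Runs k-means `repeats` times with consecutive seeds, builds the
#' co-association matrix (fraction of runs placing two items in the same
#' cluster), clusters `1 - coassociation` with average linkage and cuts into
#' `k` groups. Repetition damps the run-to-run randomness of a single k-means;
#' the result is fully determined by `(m, k, repeats, seed)`. Missing values
#' are imputed by column means for the clustering only (a message notes this).
#'
#' @param m Numeric matrix or numeric `value_matrix`.
#' @param axis `"row"` or `"column"`.
#' @param k Number of slices (2..axis length).
#' @param repeats Number of k-means runs to aggregate (>= 1).
#' @param seed Integer seed; run `r` uses `seed + r - 1`.
#' @return A `slice_spec` with `k` slices labeled `"1".."k"` by first
#'   occurrence in item order.
#' @export
split_kmeans <- function(m, axis = c("row", "column"), k, repeats = 10L,
                         seed = 1L) {
  axis <- match.arg(axis)
  if (is_value_matrix(m)) {
    if (m$kind != "numeric") stop("k-means splitting needs a numeric matrix", call. = FALSE)
    m <- m$values
  }
  x <- if (axis == "row") m else t(m)
  n <- nrow(x)
  if (k < 2L || k > n) {
    stop(sprintf("`k` must be in 2..%d (axis size)", n), call. = FALSE)
  }
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  if (anyNA(x)) {
    message("split_kmeans: imputing missing values by column means for clustering")
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  if (k == n) {
    return(slice_spec(as.list(seq_len(n)), as.character(seq_len(n)), axis, n))
  }
  co <- matrix(0, n, n)
  for (r in seq_len(repeats)) {
    cl <- with_seed(seed + r - 1L, kmeans(x, centers = k, nstart = 1L)$cluster)
    co <- co + outer(cl, cl, "==")
  }
  co <- co / repeats
  if (repeats == 1L) {
    membership <- with_seed(seed, kmeans(x, centers = k, nstart = 1L)$cluster)
  } else {
    hc <- hclust(stats::as.dist(1 - co), method = "average")
    membership <- cutree(hc, k = k)
  }
  membership_to_slices(membership, axis, n)
}

# Relabel membership ids 1..k by first occurrence in item order.
membership_to_slices <- function(membership, axis, n) {
  first <- membership[!duplicated(membership)]
  lab <- match(membership, first)
  items <- split(seq_len(n), lab)
  slice_spec(unname(items), as.character(seq_along(items)), axis, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Split an axis by one or more categorical vectors
#'
#' One slice per observed combination of levels (empty combinations omitted),
#' labeled by joining the levels with `","`. Slices are ordered
#' lexicographically over the level orders (factor levels are honored;
#' character vectors use sorted unique values).
#'
#' @param labels A vector/factor, or a list/data.frame of several.
#' @param axis `"row"` or `"column"`.
#' @param n Expected axis length (defaults to the vector length).
#' @return A `slice_spec`.
#' @export
split_by_factor <- function(labels, axis = c("row", "column"), n = NULL) {
  axis <- match.arg(axis)
  if (is.data.frame(labels)) labels <- as.list(labels)
  if (!is.list(labels)) labels <- list(labels)
  labels <- lapply(labels, function(v) if (is.factor(v)) v else factor(v, levels = sort(unique(as.character(v)))))
  len <- unique(lengths(labels))
  if (length(len) != 1L) stop("all label vectors must have equal length", call. = FALSE)
  if (is.null(n)) n <- len
  if (len != n) {
    stop(sprintf("label vectors have length %d but the axis has %d items", len, n),
         call. = FALSE)
  }
  key <- do.call(paste, c(lapply(labels, as.character), sep = ","))
  ord_levels <- levels(interaction(labels, drop = TRUE, lex.order = TRUE, sep = ","))
  idx <- split(seq_len(n), factor(key, levels = ord_levels))
  idx <- idx[lengths(idx) > 0L]
  slice_spec(unname(idx), names(idx), axis, n)
}

#' Split by cutting a dendrogram into k groups
#'
#' Cuts the merge tree at the height that yields exactly `k` groups, i.e.
#' removes the `k - 1` highest merges. If tied merge heights straddle that
#' boundary, exactly `k` groups are unattainable by a height cut and an error
#' lists the attainable counts. Slice order follows the dendrogram's leaf
#' order; labels are `"1".."k"` by leaf-order occurrence.
#'
#' @param dend A `dendrogram` (or object coercible via [as_dendrogram_any()]).
#' @param k Number of groups (2..leaf count).
#' @param axis Axis the partition applies to.
#' @return A `slice_spec`.
#' @export
split_by_cut <- function(dend, k, axis = c("row", "column")) {
  axis <- match.arg(axis)
  dend <- as_dendrogram_any(dend)
  lo <- order.dendrogram(dend)
  n <- length(lo)
  if (k < 2L || k > n) stop(sprintf("`k` must be in 2..%d", n), call. = FALSE)
  hs <- sort(dend_merge_heights(dend), decreasing = TRUE)
  if (k <= length(hs) && hs[k - 1L] == hs[k]) {
    ok <- c(which(diff(hs) < 0), length(hs)) + 1L
    stop(sprintf(
      "tied merge heights: cannot cut into exactly %d groups; attainable counts: %s",
      k, paste(sort(unique(c(1L, ok))), collapse = ", ")), call. = FALSE)
  }
  thr <- hs[k - 1L]
  groups <- list()
  walk <- function(node) {
    h <- as.numeric(attr(node, "height"))
    if (is.leaf(node) || h < thr) {
      groups[[length(groups) + 1L]] <<- sort(dend_leaves(node))
    } else {
      walk(node[[1L]])
      walk(node[[2L]])
    }
  }
  walk(dend)
  # order groups by first appearance in leaf order
  pos <- vapply(groups, function(g) min(match(g, lo)), numeric(1))
  groups <- groups[order(pos)]
  slice_spec(groups, as.character(seq_along(groups)), axis, n)
}

dend_leaves <- function(node) {
  if (is.leaf(node)) return(as.integer(node))
  c(dend_leaves(node[[1L]]), dend_leaves(node[[2L]]))
}

#' Cluster within slices, then order slices by their means
#'
#' Hierarchical clustering is performed independently inside every slice, and
#' a second clustering over the slice mean vectors determines the display
#' order of the slices themselves. Singleton slices get trivial dendrograms.
#'
#' @param m Numeric matrix (items on `axis`).
#' @param slices A `slice_spec`.
#' @param dist_method,linkage As in [hcluster()].
#' @param reorder Reorder each within-slice dendrogram (and the slice-level
#'   dendrogram) by mean weights (default `TRUE`).
#' @return List with `dends` (per-slice dendrograms or `NULL` for singletons,
#'   in input slice order), `slice_order` (permutation of slices for display)
#'   and `item_order` (per-slice display order of that slice's items).
#' @export
cluster_within_slices <- function(m, slices, dist_method = "euclidean",
                                  linkage = "complete", reorder = TRUE) {
  if (is_value_matrix(m)) m <- m$values
  x <- if (slices$axis == "row") m else t(m)
  stopifnot(nrow(x) == slices$n)
  k <- n_slices(slices)
  dends <- vector("list", k)
  item_order <- vector("list", k)
  for (s in seq_len(k)) {
    idx <- slices$items[[s]]
    if (length(idx) < 2L) {
      item_order[[s]] <- idx
      next
    }
    d <- hcluster(x[idx, , drop = FALSE], "row", dist_method, linkage)
    if (reorder) d <- reorder_dendrogram(d, rowMeans(x[idx, , drop = FALSE], na.rm = TRUE))
    dends[[s]] <- d
    item_order[[s]] <- idx[leaf_order(d)]
  }
  if (k >= 2L) {
    means <- matrix(NA_real_, k, max(1L, ncol(x)))
    for (s in seq_len(k)) {
      means[s, ] <- if (ncol(x)) colMeans(x[slices$items[[s]], , drop = FALSE],
                                          na.rm = TRUE) else 0
    }
    sd_ <- hcluster(means, "row", "euclidean", "average")
    if (reorder) sd_ <- reorder_dendrogram(sd_, rowMeans(means))
    slice_order <- leaf_order(sd_)
  } else {
    slice_order <- 1L
  }
  list(dends = dends, slice_order = slice_order, item_order = item_order)
}
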