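#' Construct a single heatmap model
#'
#' The basic unit of complex heatmap visualization: a matrix with an exact
#' color mapping, row/column ordering (hierarchical clustering with weighted
#' dendrogram reordering, or explicit index orders), up to three splitting
#' mechanisms per axis (consensus k-means via `row_km`/`column_km`, categorical
#' combinations or dendrogram cutting via `row_split`/`column_split`), side
#' annotations, raster policy and per-cell/per-slice draw hooks. Nothing is
#' computed until the model is resolved for drawing or concatenation.
#'
#' @param m Matrix (numeric or character) or `value_matrix`.
#' @param name Heatmap name; doubles as legend title and layout registry prefix.
#' @param colors A `color_mapping`, or `NULL` for an automatic one.
#' @param cluster_rows,cluster_columns Logical, or an externally built tree
#'   (`dendrogram`, `hclust`, or nested merge list) to use as-is.
#' @param clustering_distance_rows,clustering_distance_columns Distance spec
#'   for [hcluster()].
#' @param clustering_linkage_rows,clustering_linkage_columns Linkage method.
#' @param reorder Reorder dendrograms so branches with smaller mean values sit
#'   left/top (default `TRUE`); weights are item means of the matrix.
#' @param row_order,column_order Explicit permutation (numeric or names);
#'   overrides clustering for that axis.
#' @param row_km,column_km Number of consensus k-means slices.
#' @param row_km_repeats,column_km_repeats k-means repetitions (default 10).
#' @param row_split,column_split A vector/factor/data.frame of categorical
#'   labels, or a single number k to cut the axis dendrogram into k slices.
#' @param row_title,column_title,title Titles.
#' @param show_row_dend,show_column_dend,show_row_names,show_column_names
#'   Component visibility.
#' @param top_annotation,bottom_annotation,left_annotation,right_annotation
#'   `annotation_block` objects for the four sides.
#' @param raster_policy A [raster_policy()]; default `"auto"`.
#' @param cell_fun Called once per visible cell with
#'   `(i, j, value, color, x, y, w, h)` (body-slice local coordinates); may
#'   return primitives to overlay.
#' @param layer_fun Vectorized variant, called once per body slice with
#'   vectors `(i, j, value, color, x, y, w, h)`.
#' @param width,height Relative body weights used when several heatmaps share
#'   a device (default: the matrix dimension).
#' @param seed Seed for the seeded operations of this heatmap (k-means).
#' @return A `heat_map` object.
#' @export
heat_map <- function(m, name = "matrix", colors = NULL,
                     cluster_rows = TRUE, cluster_columns = TRUE,
                     clustering_distance_rows = "euclidean",
                     clustering_distance_columns = "euclidean",
                     clustering_linkage_rows = "complete",
                     clustering_linkage_columns = "complete",
                     reorder = TRUE,
                     row_order = NULL, column_order = NULL,
                     row_km = NULL, row_km_repeats = 10L,
                     column_km = NULL, column_km_repeats = 10L,
                     row_split = NULL, column_split = NULL,
                     row_title = NULL, column_title = NULL, title = NULL,
                     show_row_dend = TRUE, show_column_dend = TRUE,
                     show_row_names = TRUE, show_column_names = TRUE,
                     top_annotation = NULL, bottom_annotation = NULL,
                     left_annotation = NULL, right_annotation = NULL,
                     raster_policy = NULL, cell_fun = NULL, layer_fun = NULL,
                     width = NULL, height = NULL, seed = 1L) {
  vm <- as_value_matrix(m)
  if (is.null(colors)) colors <- auto_color_mapping(vm)
  stopifnot(inherits(colors, "color_mapping"))
  if (vm$kind == "categorical" && colors$mode == "continuous") {
    stop("a categorical matrix cannot use a continuous (interpolating) color mapping",
         call. = FALSE)
  }
  check_split_arg <- function(split, km, n, axis) {
    if (!is.null(km) && !is.null(split)) {
      stop(sprintf("give either %s_km or %s_split, not both", axis, axis), call. = FALSE)
    }
    if (!is.null(km) && (km < 2L || km > n)) {
      stop(sprintf("%s_km must be in 2..%d", axis, n), call. = FALSE)
    }
  }
  check_split_arg(row_split, row_km, nrow(vm$values), "row")
  check_split_arg(column_split, column_km, ncol(vm$values), "column")
  anno_ok <- function(b, axis, n, where) {
    if (is.null(b)) return(invisible())
    stopifnot(inherits(b, "annotation_block"))
    if (b$axis != axis) {
      stop(sprintf("%s annotation must be a %s-axis block", where, axis), call. = FALSE)
    }
    for (tr in b$tracks) check_track_length(tr, n)
  }
  anno_ok(top_annotation, "column", ncol(vm$values), "top")
  anno_ok(bottom_annotation, "column", ncol(vm$values), "bottom")
  anno_ok(left_annotation, "row", nrow(vm$values), "left")
  anno_ok(right_annotation, "row", nrow(vm$values), "right")
  structure(list(
    matrix = vm, name = name, colors = colors,
    cluster = list(row = cluster_rows, column = cluster_columns),
    dist = list(row = clustering_distance_rows, column = clustering_distance_columns),
    linkage = list(row = clustering_linkage_rows, column = clustering_linkage_columns),
    reorder = isTRUE(reorder),
    explicit_order = list(row = row_order, column = column_order),
    km = list(row = row_km, column = column_km),
    km_repeats = list(row = row_km_repeats, column = column_km_repeats),
    split = list(row = row_split, column = column_split),
    titles = list(row = row_title, column = column_title, main = title),
    show = list(row_dend = show_row_dend, column_dend = show_column_dend,
                row_names = show_row_names, column_names = show_column_names),
    annotations = list(top = top_annotation, bottom = bottom_annotation,
                       left = left_annotation, right = right_annotation),
    raster_policy = raster_policy %||% raster_policy_default(),
    cell_fun = cell_fun, layer_fun = layer_fun,
    weight = list(width = width, height = height),
    seed = as.integer(seed),
    resolved = NULL
  ), class = c("heat_map", "hm_item"))
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map> '%s': %d x %d (%s)\n", x$name,
              nrow(x$matrix$values), ncol(x$matrix$values), x$matrix$kind))
  invisible(x)
}

is_heat_map <- function(x) inherits(x, "heat_map")

# ---- axis resolution ---------------------------------------------------------

# A resolved axis is:
#   order        full display permutation of original indices
#   slice_items  list of index vectors (display order within and across slices)
#   slice_labels character labels, display order
#   dends        per-slice dendrograms (display order; NULL where absent)
#   sizes        lengths(slice_items)
resolve_axis <- function(hm, axis) {
  vm <- hm$matrix
  n <- vm_axis_n(vm, axis)
  x <- if (axis == "row") vm$values else t(vm$values)
  cl <- hm$cluster[[axis]]
  external_dend <- NULL
  if (!isTRUE(cl) && !isFALSE(cl) && !is.null(cl)) {
    external_dend <- as_dendrogram_any(cl)
    cl <- TRUE
  }
  can_cluster <- vm$kind == "numeric" || !is.null(external_dend) ||
    is.function(hm$dist[[axis]])
  if (isTRUE(cl) && !can_cluster) {
    cl <- FALSE  # categorical matrices are not numerically clustered by default
  }
  explicit <- hm$explicit_order[[axis]]
  split <- hm$split[[axis]]
  km <- hm$km[[axis]]

  # dendrogram-cut split: single global clustering, cut into k subtrees
  if (!is.null(split) && is.numeric(split) && length(split) == 1L &&
      is.null(dim(split))) {
    k <- as.integer(split)
    dend <- external_dend %||% hcluster(x, "row", hm$dist[[axis]], hm$linkage[[axis]])
    if (hm$reorder) dend <- reorder_dendrogram(dend, rowMeans(x, na.rm = TRUE))
    cut <- cut_dendrogram(dend, k)
    lo <- leaf_order(dend)
    slice_items <- lapply(cut$groups, function(g) lo[lo %in% g])
    return(list(order = unlist(slice_items, use.names = FALSE),
                slice_items = slice_items,
                slice_labels = as.character(seq_along(slice_items)),
                dends = cut$subtrees, sizes = lengths(slice_items)))
  }

  # slices from k-means or categorical labels (or a single slice)
  slices <- if (!is.null(km)) {
    split_kmeans(x, "row", km, hm$km_repeats[[axis]], hm$seed)
  } else if (!is.null(split)) {
    split_by_factor(split, "row", n)
  } else {
    single_slice(n, "row")
  }

  if (!is.null(explicit)) {
    perm <- order_by_indices(n, explicit, vm_axis_names(vm, axis))
    pos <- integer(n); pos[perm] <- seq_len(n)
    slice_items <- lapply(slices$items, function(idx) idx[order(pos[idx])])
    labels <- slices$labels
    dends <- vector("list", length(slice_items))
    slice_order <- seq_along(slice_items)
  } else if (isTRUE(cl)) {
    if (!is.null(external_dend) && n_slices(slices) == 1L) {
      dend <- external_dend
      if (hm$reorder) dend <- reorder_dendrogram(dend, rowMeans(x, na.rm = TRUE))
      return(list(order = leaf_order(dend), slice_items = list(leaf_order(dend)),
                  slice_labels = slices$labels, dends = list(dend),
                  sizes = n))
    }
    cw <- cluster_within_slices(x, slices, hm$dist[[axis]], hm$linkage[[axis]],
                                reorder = hm$reorder)
    slice_items <- cw$item_order
    dends <- cw$dends
    labels <- slices$labels
    slice_order <- cw$slice_order
  } else {
    slice_items <- slices$items
    labels <- slices$labels
    dends <- vector("list", length(slice_items))
    slice_order <- seq_along(slice_items)
  }
  slice_items <- slice_items[slice_order]
  dends <- dends[slice_order]
  labels <- labels[slice_order]
  if (!is.null(km)) {
    # k-means slices are numbered by occurrence along the display order
    labels <- as.character(seq_along(slice_items))
  }
  list(order = unlist(slice_items, use.names = FALSE),
       slice_items = slice_items, slice_labels = labels, dends = dends,
       sizes = lengths(slice_items))
}

# Cut into k subtrees at the height achieving exactly k groups.
cut_dendrogram <- function(dend, k) {
  n <- length(leaf_order(dend))
  if (k < 2L || k > n) stop(sprintf("`k` must be in 2..%d", n), call. = FALSE)
  hs <- sort(dend_merge_heights(dend), decreasing = TRUE)
  if (k <= length(hs) && hs[k - 1L] == hs[k]) {
    ok <- c(which(diff(hs) < 0), length(hs)) + 1L
    stop(sprintf(
      "tied merge heights: cannot cut into exactly %d groups; attainable counts: %s",
      k, paste(sort(unique(c(1L, ok))), collapse = ", ")), call. = FALSE)
  }
  thr <- hs[k - 1L]
  groups <- list(); subtrees <- list()
  walk <- function(node) {
    h <- as.numeric(attr(node, "height"))
    if (is.leaf(node) || h < thr) {
      groups[[length(groups) + 1L]] <<- dend_leaves(node)
      subtrees[[length(subtrees) + 1L]] <<- if (is.leaf(node)) NULL else node
    } else {
      walk(node[[1L]]); walk(node[[2L]])
    }
  }
  walk(dend)
  list(groups = groups, subtrees = subtrees)
}

#' Resolve a heatmap's orders and splits
#'
#' Computes (and caches) the display permutation, slices and per-slice
#' dendrograms for both axes.
#'
#' @param hm A `heat_map`.
#' @return The heatmap with `$resolved$row` and `$resolved$column` filled in.
#' @export
resolve_heatmap <- function(hm) {
  stopifnot(is_heat_map(hm))
  if (!is.null(hm$resolved)) return(hm)
  hm$resolved <- list(row = resolve_axis(hm, "row"),
                      column = resolve_axis(hm, "column"))
  hm
}

# Impose an external (main-heatmap) row resolution onto a heatmap.
impose_axis <- function(hm, axis, res) {
  hm <- resolve_heatmap(hm)
  own <- hm$resolved[[axis]]
  had_own <- isTRUE(hm$cluster[[axis]]) || !is.null(hm$explicit_order[[axis]]) ||
    !is.null(hm$km[[axis]]) || !is.null(hm$split[[axis]])
  if (had_own && !identical(own$order, res$order)) {
    hc_log(sprintf("heatmap '%s': %s ordering/splitting overridden by the main heatmap",
                   hm$name, axis))
  }
  hm$resolved[[axis]] <- res
  hm
}

#' Extract the display permutation of an axis
#' @param hm A resolved `heat_map`.
#' @param axis `"row"` or `"column"`.
#' @return Integer permutation (display order of original indices).
#' @export
heatmap_order <- function(hm, axis = c("row", "column")) {
  axis <- match.arg(axis)
  resolve_heatmap(hm)$resolved[[axis]]$order
}

#' Extract the slice specification of an axis
#' @param hm A resolved `heat_map`.
#' @param axis `"row"` or `"column"`.
#' @return A `slice_spec` in display order.
#' @export
heatmap_slices <- function(hm, axis = c("row", "column")) {
  axis <- match.arg(axis)
  res <- resolve_heatmap(hm)$resolved[[axis]]
  slice_spec(res$slice_items, res$slice_labels, axis,
             vm_axis_n(hm$matrix, axis))
}
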