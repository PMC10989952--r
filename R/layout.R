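# Heatmap lists and main-heatmap-driven alignment.

#' Concatenate heatmaps and annotation blocks into a list model
#'
#' All items must agree on the aligned axis (rows for horizontal lists,
#' columns for vertical lists). The main heatmap — by default the first
#' numeric heatmap, or the first heatmap if none is numeric — drives the
#' ordering and splitting of every member.
#'
#' @param items List of `heat_map` / `annotation_block` objects (nested
#'   `hm_list`s are flattened).
#' @param direction `"horizontal"` or `"vertical"`.
#' @param main Name or index of the main heatmap (optional).
#' @param title Optional global title.
#' @return An `hm_list`.
#' @export
hm_list <- function(items, direction = c("horizontal", "vertical"),
                    main = NULL, title = NULL) {
  direction <- match.arg(direction)
  flat <- list()
  for (it in items) {
    if (inherits(it, "hm_list")) flat <- c(flat, it$items)
    else flat <- c(flat, list(it))
  }
  items <- flat
  is_hm <- vapply(items, is_heat_map, logical(1))
  is_anno <- vapply(items, inherits, logical(1), "annotation_block")
  if (!all(is_hm | is_anno)) {
    stop("list items must be heat_map or annotation_block objects", call. = FALSE)
  }
  if (!any(is_hm)) stop("a heatmap list needs at least one heatmap", call. = FALSE)
  axis <- if (direction == "horizontal") "row" else "column"
  lens <- vapply(seq_along(items), function(i) {
    it <- items[[i]]
    if (is_hm[i]) vm_axis_n(it$matrix, axis) else {
      if (it$axis != axis) {
        stop(sprintf("item %d: a %s list needs %s-axis annotation blocks",
                     i, direction, axis), call. = FALSE)
      }
      block_axis_n(it)
    }
  }, numeric(1))
  known <- lens[!is.na(lens)]
  if (length(unique(known)) > 1L) {
    bad <- which(!is.na(lens) & lens != known[1L])
    stop(sprintf("aligned-axis (%s) length mismatch: item %s has %d items but item 1 has %d",
                 axis, bad[1L], lens[bad[1L]], known[1L]), call. = FALSE)
  }
  main_index <- if (is.null(main)) {
    numeric_hms <- which(is_hm & vapply(items, function(it)
      is_heat_map(it) && it$matrix$kind == "numeric", logical(1)))
    if (length(numeric_hms)) numeric_hms[1L] else which(is_hm)[1L]
  } else if (is.character(main)) {
    nm <- vapply(items, function(it) if (is_heat_map(it)) it$name else "", character(1))
    idx <- match(main, nm)
    if (is.na(idx)) stop(sprintf("no heatmap named '%s' in the list", main), call. = FALSE)
    idx
  } else {
    as.integer(main)
  }
  if (!is_hm[main_index]) stop("the main item must be a heatmap", call. = FALSE)
  structure(list(items = items, direction = direction,
                 main_index = main_index, title = title, alignment = NULL),
            class = c("hm_list", "hm_item"))
}

#' @export
print.hm_list <- function(x, ...) {
  cat(sprintf("<hm_list> %s, %d item(s), main = %d\n", x$direction,
              length(x$items), x$main_index))
  invisible(x)
}

#' Concatenate heatmaps horizontally
#'
#' `a + b` builds (or extends) a horizontal `hm_list`; rows are the aligned
#' axis.
#' @param e1,e2 `heat_map`, `annotation_block` or `hm_list` objects.
#' @return An `hm_list`.
#' @export
#' @method + hm_item
"+.hm_item" <- function(e1, e2) hm_list(list(e1, e2), "horizontal")

#' Concatenate heatmaps vertically
#'
#' `a %v% b` builds (or extends) a vertical `hm_list`; columns are the
#' aligned axis.
#' @param e1,e2 `heat_map`, `annotation_block` or `hm_list` objects.
#' @return An `hm_list`.
#' @export
`%v%` <- function(e1, e2) hm_list(list(e1, e2), "vertical")

as_hm_list <- function(x, direction = "horizontal") {
  if (inherits(x, "hm_list")) x
  else hm_list(list(x), direction)
}

#' Impose the main heatmap's ordering and splitting on a list
#'
#' Resolves the main heatmap, then overwrites every other heatmap's
#' aligned-axis resolution with the main's permutation and slices (a log line
#' records each override of a member's own request). Non-main heatmaps keep
#' their own off-axis ordering.
#'
#' @param hl An `hm_list`.
#' @return The list with `$alignment` (the shared axis resolution) filled and
#'   all heatmap items resolved.
#' @export
resolve_alignment <- function(hl) {
  stopifnot(inherits(hl, "hm_list"))
  axis <- if (hl$direction == "horizontal") "row" else "column"
  main <- resolve_heatmap(hl$items[[hl$main_index]])
  res <- main$resolved[[axis]]
  hl$items[[hl$main_index]] <- main
  for (i in seq_along(hl$items)) {
    if (i == hl$main_index) next
    if (is_heat_map(hl$items[[i]])) {
      hl$items[[i]] <- impose_axis(hl$items[[i]], axis, res)
    }
  }
  hl$alignment <- res
  hl
}

#' Shared axis order of a resolved list
#' @param hl A resolved `hm_list` (see [resolve_alignment()]).
#' @param i Item index.
#' @return The aligned-axis permutation of item `i` (identical across items).
#' @export
list_item_order <- function(hl, i) {
  axis <- if (hl$direction == "horizontal") "row" else "column"
  it <- hl$items[[i]]
  if (is_heat_map(it)) it$resolved[[axis]]$order else hl$alignment$order
}

# ---- component sizing --------------------------------------------------------

COMPONENT_SIZES <- list(
  dend = 0.6, names = 0.6, title = 0.3, item_gap = 0.15, legend_w = 1.2,
  legend_item_h = 1.6
)

# Heights (column-side components) and widths (row-side) of one heatmap item.
hm_side_sizes <- function(hm, is_main) {
  top <- 0
  if (!is.null(hm$titles$column)) top <- top + COMPONENT_SIZES$title
  if (isTRUE(hm$show$column_dend) &&
      any(!vapply(hm$resolved$column$dends, is.null, logical(1)))) {
    top <- top + COMPONENT_SIZES$dend
  }
  if (!is.null(hm$annotations$top)) top <- top + block_size(hm$annotations$top)
  bottom <- 0
  if (isTRUE(hm$show$column_names) && !is.null(colnames(hm$matrix$values))) {
    bottom <- bottom + COMPONENT_SIZES$names
  }
  if (!is.null(hm$annotations$bottom)) bottom <- bottom + block_size(hm$annotations$bottom)
  left <- 0
  if (!is.null(hm$titles$row)) left <- left + COMPONENT_SIZES$title
  if (is_main && isTRUE(hm$show$row_dend) &&
      any(!vapply(hm$resolved$row$dends, is.null, logical(1)))) {
    left <- left + COMPONENT_SIZES$dend
  }
  if (!is.null(hm$annotations$left)) left <- left + block_size(hm$annotations$left)
  right <- 0
  if (isTRUE(hm$show$row_names) && !is.null(rownames(hm$matrix$values))) {
    right <- right + COMPONENT_SIZES$names
  }
  if (!is.null(hm$annotations$right)) right <- right + block_size(hm$annotations$right)
  list(top = top, bottom = bottom, left = left, right = right)
}
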