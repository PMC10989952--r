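# Built-in annotation track constructors. A track holds a graphic kind, its
# payload, a size along the off-axis (inches) and per-kind parameters; the
# axis is fixed when the track enters an annotation_block.

new_track <- function(kind, payload, size = 0.4, params = list(),
                      colors = NULL) {
  structure(list(kind = kind, payload = payload, size = size,
                 params = params, colors = colors, name = NULL, axis = NULL),
            class = "anno_track")
}

#' @export
print.anno_track <- function(x, ...) {
  cat(sprintf("<anno_track> kind '%s'\n", x$kind))
  invisible(x)
}

#' Simple (heatmap-like) annotation
#' @param x Numeric or character vector, or a matrix (one mini-row per column).
#' @param colors Optional `color_mapping`.
#' @param size Track size in inches.
#' @return An `anno_track`.
#' @export
anno_simple <- function(x, colors = NULL, size = 0.2) {
  new_track("simple", x, size, colors = colors)
}

#' Points annotation
#' @param x Numeric vector or matrix (one series per column).
#' @param size Track size in inches.
#' @param pt_color Point fill color(s).
#' @return An `anno_track`.
#' @export
anno_points <- function(x, size = 0.6, pt_color = "#000000") {
  new_track("points", x, size, list(pt_color = pt_color))
}

#' Lines annotation
#' @inheritParams anno_points
#' @param line_color Line color(s), one per series.
#' @return An `anno_track`.
#' @export
anno_lines <- function(x, size = 0.6, line_color = "#000000") {
  new_track("lines", x, size, list(line_color = line_color))
}

#' Smoothed-lines annotation
#'
#' Draws a local-regression curve over the ordered values (loess, span 0.75,
#' degree 2).
#' @inheritParams anno_lines
#' @param span,degree Loess parameters.
#' @return An `anno_track`.
#' @export
anno_smooth <- function(x, size = 0.6, line_color = "#B2182B", span = 0.75,
                        degree = 2) {
  new_track("smoothed_lines", x, size,
            list(line_color = line_color, span = span, degree = degree))
}

#' Barplot annotation (stacked for matrix input)
#' @param x Numeric vector, or a non-negative matrix whose columns are stacked.
#' @param size Track size in inches.
#' @param fill Bar fill color(s), one per stack series.
#' @param baseline Baseline value (default 0).
#' @return An `anno_track`.
#' @export
anno_barplot <- function(x, size = 0.6, fill = NULL, baseline = 0) {
  new_track("barplot", x, size, list(fill = fill, baseline = baseline))
}

#' Percent annotation (bar plus numeric text)
#' @param x Numeric vector of fractions in `[0, 1]`.
#' @param size Track size in inches.
#' @param fill Bar fill color.
#' @return An `anno_track`.
#' @export
anno_percent <- function(x, size = 0.8, fill = "#4292C6") {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("percent annotation expects fractions in [0, 1]", call. = FALSE)
  }
  new_track("percent", x, size, list(fill = fill))
}

#' Boxplot annotation
#' @param x Numeric matrix (one distribution per row/column item) or a list of
#'   numeric vectors, one per item.
#' @param size Track size in inches.
#' @param fill Box fill color.
#' @return An `anno_track`.
#' @export
anno_boxplot <- function(x, size = 0.8, fill = "#BDBDBD") {
  new_track("boxplot", x, size, list(fill = fill))
}

#' Text annotation
#' @param labels Character vector, one label per item.
#' @param size Track size in inches.
#' @param rot Rotation in degrees.
#' @param cex Text size multiplier.
#' @return An `anno_track`.
#' @export
anno_text <- function(labels, size = 0.5, rot = 0, cex = 0.8) {
  new_track("text", as.character(labels), size, list(rot = rot, cex = cex))
}

#' Histogram annotation
#' @inheritParams anno_boxplot
#' @param breaks Number of histogram bins over the shared value range.
#' @return An `anno_track`.
#' @export
anno_histogram <- function(x, size = 0.8, fill = "#9ECAE1", breaks = 11) {
  new_track("histogram", x, size, list(fill = fill, breaks = breaks))
}

#' Violin annotation
#' @inheritParams anno_boxplot
#' @return An `anno_track`.
#' @export
anno_violin <- function(x, size = 0.8, fill = "#C7E9C0") {
  new_track("violin", x, size, list(fill = fill))
}

#' Joyplot annotation
#'
#' Overlapping per-item density silhouettes; peaks may extend into the
#' neighbouring items' bands (clipped only at the block boundary).
#' @inheritParams anno_boxplot
#' @param overlap Peak height in units of one item band (default 2).
#' @return An `anno_track`.
#' @export
anno_joyplot <- function(x, size = 1, fill = "#807DBA", overlap = 2) {
  new_track("joyplot", x, size, list(fill = fill, overlap = overlap))
}

#' Horizon-chart annotation
#'
#' Each item's series is drawn as an area chart vertically cut into uniform
#' bands which are then layered on top of each other inside the item's band,
#' compressing the vertical space.
#' @param x List of numeric series (one per item) or a matrix (one row per
#'   item).
#' @param size Track size in inches.
#' @param n_bands Number of horizon bands.
#' @param band_height Value height of one band; default `max(abs(x))/n_bands`.
#' @param pos_colors,neg_colors Band colors (light to dark).
#' @return An `anno_track`.
#' @export
anno_horizon <- function(x, size = 1, n_bands = 4, band_height = NULL,
                         pos_colors = NULL, neg_colors = NULL) {
  new_track("horizon", x, size,
            list(n_bands = n_bands, band_height = band_height,
                 pos_colors = pos_colors, neg_colors = neg_colors))
}

#' Image annotation
#' @param paths Character vector of image file paths (png supported), one per
#'   item; `NA` skips an item.
#' @param size Track size in inches.
#' @return An `anno_track`.
#' @export
anno_image <- function(paths, size = 0.8) {
  new_track("image", as.character(paths), size)
}

#' Mark annotation
#'
#' Labels a subset of rows/columns; labels are shifted from their anchor
#' positions just enough to remove overlaps (an order-preserving least-squares
#' displacement), and connector lines join each label to its row or column.
#' @param at Integer vector of original item indices to label.
#' @param labels Character vector, same length as `at`.
#' @param size Track size in inches.
#' @param cex Label size multiplier.
#' @param extent Label extent along the axis as a fraction of the region
#'   (default `NULL`: estimated from `cex`).
#' @return An `anno_track`.
#' @export
anno_mark <- function(at, labels, size = 0.8, cex = 0.8, extent = NULL) {
  if (length(at) != length(labels)) {
    stop("`at` and `labels` must have equal length", call. = FALSE)
  }
  new_track("mark", list(at = as.integer(at), labels = as.character(labels)),
            size, list(cex = cex, extent = extent))
}

#' Link annotation
#'
#' Connects panels to subsets of heatmap rows/columns with quadrilaterals;
#' each panel's callback receives the panel box and the subset's original
#' indices and may return primitives drawn inside the panel.
#' @param at List of integer vectors: the linked subsets (original indices;
#'   each must be contiguous after display ordering).
#' @param panel_fun `function(indices, slice_id)` returning primitives (or
#'   `NULL`).
#' @param size Track size in inches.
#' @param min_panel Minimum panel extent as a fraction of the axis.
#' @return An `anno_track`.
#' @export
anno_link <- function(at, panel_fun = NULL, size = 1.2, min_panel = 0.05) {
  if (!is.list(at)) at <- list(at)
  new_track("link", list(at = lapply(at, as.integer), panel_fun = panel_fun),
            size, list(min_panel = min_panel))
}

#' Textbox annotation
#'
#' Word lists attached to slices, packed greedily into rows with font sizes
#' scaled linearly by word importance.
#' @param words Named list (one element per slice label) of data frames with
#'   columns `word` and `score`.
#' @param size Track size in inches.
#' @param cex_range Smallest and largest text size multiplier.
#' @return An `anno_track`.
#' @export
anno_textbox <- function(words, size = 1.2, cex_range = c(0.5, 1.2)) {
  new_track("textbox", words, size, list(cex_range = cex_range))
}

SUBSET_KINDS <- c("mark", "link", "textbox")

check_track_length <- function(track, n) {
  if (track$kind %in% SUBSET_KINDS) {
    if (track$kind == "mark" && length(track$payload$at) &&
        any(track$payload$at < 1L | track$payload$at > n)) {
      stop(sprintf("mark annotation '%s' addresses indices outside 1..%d",
                   track$name %||% "", n), call. = FALSE)
    }
    return(invisible())
  }
  len <- if (is.matrix(track$payload)) nrow(track$payload)
         else length(track$payload)
  if (len != n) {
    stop(sprintf("annotation '%s' has payload length %d but the axis has %d items",
                 track$name %||% track$kind, len, n), call. = FALSE)
  }
  invisible()
}

#' Build an annotation block from name-value pairs
#'
#' Raw vectors, matrices and data frames become simple (heatmap-like) tracks;
#' `anno_*()` tracks pass through unchanged. Track order is the call order.
#'
#' @param ... Named payloads or `anno_track` objects.
#' @param axis `"row"` or `"column"` (the annotated axis).
#' @param gap Gap between tracks in inches.
#' @return An `annotation_block`.
#' @examples
#' ha <- annotation_block(
#'   foo = runif(10),
#'   bar = sample(letters[1:4], 10, replace = TRUE),
#'   pt = anno_points(runif(10)),
#'   txt = anno_text(month.name[1:10]),
#'   axis = "column")
#' @export
annotation_block <- function(..., axis = c("column", "row"), gap = 0.04) {
  axis <- match.arg(axis)
  pairs <- list(...)
  if (length(pairs) && (is.null(names(pairs)) || any(names(pairs) == ""))) {
    stop("all annotations must be named", call. = FALSE)
  }
  if (anyDuplicated(names(pairs))) {
    stop(sprintf("duplicated annotation name '%s'",
                 names(pairs)[duplicated(names(pairs))][1L]), call. = FALSE)
  }
  tracks <- list()
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (inherits(p, "anno_track")) {
      trs <- list(p)
    } else if (is.data.frame(p)) {
      trs <- lapply(p, anno_simple)
      names(trs) <- paste0(nm, ".", names(p))
    } else if (is.vector(p) || is.factor(p) || is.matrix(p)) {
      if (is.factor(p)) p <- as.character(p)
      trs <- list(anno_simple(p))
    } else {
      stop(sprintf("annotation '%s': cannot interpret payload of class %s",
                   nm, class(p)[1L]), call. = FALSE)
    }
    if (is.null(names(trs))) names(trs) <- nm
    for (i in seq_along(trs)) {
      trs[[i]]$name <- names(trs)[i]
      trs[[i]]$axis <- axis
    }
    tracks <- c(tracks, trs)
  }
  structure(list(tracks = tracks, axis = axis, gap = gap),
            class = c("annotation_block", "hm_item"))
}

#' Row-axis annotation block
#' @param ... Passed to [annotation_block()].
#' @param gap Gap between tracks in inches.
#' @return An `annotation_block` on the row axis.
#' @export
row_annotation <- function(..., gap = 0.04) {
  annotation_block(..., axis = "row", gap = gap)
}

#' @export
print.annotation_block <- function(x, ...) {
  cat(sprintf("<annotation_block> %s axis, %d track(s): %s\n", x$axis,
              length(x$tracks),
              paste(vapply(x$tracks, function(t) sprintf("%s(%s)", t$name, t$kind),
                           character(1)), collapse = ", ")))
  invisible(x)
}

block_size <- function(b) {
  if (!length(b$tracks)) return(0)
  sum(vapply(b$tracks, function(t) t$size, numeric(1))) +
    b$gap * (length(b$tracks) - 1L)
}

block_axis_n <- function(b) {
  for (t in b$tracks) {
    if (!(t$kind %in% SUBSET_KINDS)) {
      return(if (is.matrix(t$payload)) nrow(t$payload) else length(t$payload))
    }
  }
  NA_integer_
}
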