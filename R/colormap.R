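#' @importFrom grDevices col2rgb convertColor rgb rgb2hsv hsv
NULL

# Canonical hex form "#RRGGBB" for any R color (name or hex); alpha dropped.
normalize_color <- function(x) {
  m <- col2rgb(x)
  sprintf("#%02X%02X%02X", m[1L, ], m[2L, ], m[3L, ])
}

DEFAULT_NA_COLOR <- "#808080"

# Fixed qualitative palette; cycled deterministically over sorted level order so
# the same levels always receive the same colors without any seed.
QUALITATIVE_PALETTE <- c(
  "#1F78B4", "#E31A1C", "#33A02C", "#FF7F00", "#6A3D9A", "#B15928",
  "#A6CEE3", "#FB9A99", "#B2DF8A", "#FDBF6F", "#CAB2D6", "#FFFF99"
)

srgb_to_space <- function(hex, space) {
  m <- t(col2rgb(hex)) / 255
  switch(space,
    sRGB = m,
    Lab = convertColor(m, from = "sRGB", to = "Lab"),
    HSV = t(rgb2hsv(t(m * 255), maxColorValue = 255))
  )
}

space_to_srgb_hex <- function(coords, space) {
  rgb01 <- switch(space,
    sRGB = coords,
    Lab = convertColor(coords, from = "Lab", to = "sRGB"),
    HSV = t(col2rgb(hsv(pmin(pmax(coords[, 1L], 0), 1),
                        pmin(pmax(coords[, 2L], 0), 1),
                        pmin(pmax(coords[, 3L], 0), 1)))) / 255
  )
  rgb01 <- pmin(pmax(rgb01, 0), 1)
  rgb(rgb01[, 1L], rgb01[, 2L], rgb01[, 3L])
}

#' Exact continuous color mapping from breaks and anchor colors
#'
#' Defines a value-to-color function by a strictly increasing vector of breaks
#' and one anchor color per break. At a break the mapped color equals the
#' anchor color exactly; inside an interval each channel is linearly
#' interpolated in the chosen color space; values outside the break range are
#' clamped to the end colors. Two mappings built from identical breaks and
#' colors produce identical outputs on any input, which makes colors
#' comparable across heatmaps sharing a mapping.
#'
#' @param breaks Strictly increasing numeric vector, length >= 2.
#' @param colors Vector of colors (names or hex), same length as `breaks`.
#' @param space Interpolation color space: `"Lab"` (perceptually uniform
#'   default), `"sRGB"` or `"HSV"`.
#' @param na_color Color for missing values (default mid grey).
#' @return A `color_mapping` object with `mode = "continuous"`.
#' @examples
#' cm <- color_mapping(c(-2, 0, 2), c("blue", "white", "red"))
#' map_colors(cm, c(-5, 0, 2))
#' @export
color_mapping <- function(breaks, colors, space = c("Lab", "sRGB", "HSV"),
                          na_color = DEFAULT_NA_COLOR) {
  space <- match.arg(space)
  if (!is.numeric(breaks) || length(breaks) < 2L) {
    stop("`breaks` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (anyNA(breaks)) stop("`breaks` must not contain missing values", call. = FALSE)
  if (any(diff(breaks) <= 0)) {
    stop("`breaks` must be strictly increasing (no duplicates)", call. = FALSE)
  }
  if (length(colors) != length(breaks)) {
    stop(sprintf("`colors` has length %d but `breaks` has length %d",
                 length(colors), length(breaks)), call. = FALSE)
  }
  hex <- normalize_color(colors)
  structure(
    list(
      mode = "continuous",
      breaks = as.numeric(breaks),
      colors = hex,
      space = space,
      coords = srgb_to_space(hex, space),
      na_color = normalize_color(na_color)
    ),
    class = "color_mapping"
  )
}

#' Discrete color mapping for categorical levels
#'
#' @param colors Either a named color vector (`level = color`) or an unnamed
#'   color vector paired with `levels`.
#' @param levels Optional character vector of levels when `colors` is unnamed.
#' @param na_color Color for missing values.
#' @return A `color_mapping` object with `mode = "categorical"`.
#' @export
discrete_color_mapping <- function(colors, levels = NULL,
                                   na_color = DEFAULT_NA_COLOR) {
  if (is.null(levels)) {
    levels <- names(colors)
    if (is.null(levels)) {
      stop("`colors` must be named by level, or `levels` supplied", call. = FALSE)
    }
  }
  if (length(colors) != length(levels)) {
    stop("`colors` and `levels` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop(sprintf("duplicated level: '%s'", levels[duplicated(levels)][1L]),
         call. = FALSE)
  }
  hex <- normalize_color(colors)
  names(hex) <- levels
  structure(
    list(mode = "categorical", levels = as.character(levels), colors = hex,
         na_color = normalize_color(na_color)),
    class = "color_mapping"
  )
}

#' Default discrete mapping for a set of levels
#'
#' Colors are drawn by cycling a fixed qualitative palette over the sorted
#' level order, so identical level sets always map identically (no seed).
#'
#' @param levels Character vector of levels (deduplicated, sorted internally).
#' @param na_color Color for missing values.
#' @return A categorical `color_mapping`.
#' @export
default_discrete_mapping <- function(levels, na_color = DEFAULT_NA_COLOR) {
  lv <- sort(unique(as.character(levels[!is.na(levels)])))
  cols <- QUALITATIVE_PALETTE[((seq_along(lv) - 1L) %% length(QUALITATIVE_PALETTE)) + 1L]
  discrete_color_mapping(cols, lv, na_color)
}

#' @export
print.color_mapping <- function(x, ...) {
  if (x$mode == "continuous") {
    cat(sprintf("<color_mapping> continuous in %s; breaks: %s\n",
                x$space, paste(x$breaks, collapse = ", ")))
  } else {
    cat(sprintf("<color_mapping> categorical over %d levels\n", length(x$levels)))
  }
  invisible(x)
}

#' Apply a color mapping to values
#'
#' Vectorized elementwise application. Missing values map to the mapping's
#' `na_color`; for continuous mappings, values outside the break range are
#' clamped to the end colors; at a break the anchor color is returned exactly.
#' Matrix input keeps its shape.
#'
#' @param cm A `color_mapping`.
#' @param values Numeric values (continuous mode) or labels (categorical mode).
#' @return Character vector/matrix of hex colors, shape of `values`.
#' @export
map_colors <- function(cm, values) {
  stopifnot(inherits(cm, "color_mapping"))
  dims <- dim(values)
  v <- as.vector(values)
  out <- character(length(v))
  if (length(v) == 0L) {
    dim(out) <- dims
    return(out)
  }
  if (cm$mode == "categorical") {
    v <- as.character(v)
    idx <- match(v, cm$levels)
    bad <- which(!is.na(v) & is.na(idx))
    if (length(bad)) {
      stop(sprintf("unknown level '%s' not present in the color mapping", v[bad[1L]]),
           call. = FALSE)
    }
    out <- unname(cm$colors[idx])
    out[is.na(v)] <- cm$na_color
  } else {
    if (!is.numeric(v)) stop("continuous mapping requires numeric values", call. = FALSE)
    na <- is.na(v)
    x <- pmin(pmax(v, cm$breaks[1L]), cm$breaks[length(cm$breaks)])
    x[na] <- cm$breaks[1L]
    i <- findInterval(x, cm$breaks, rightmost.closed = TRUE, all.inside = TRUE)
    t <- (x - cm$breaks[i]) / (cm$breaks[i + 1L] - cm$breaks[i])
    coords <- (1 - t) * cm$coords[i, , drop = FALSE] +
      t * cm$coords[i + 1L, , drop = FALSE]
    out <- space_to_srgb_hex(coords, cm$space)
    # anchor exactness: values landing on a break return its color bit-exactly
    exact <- match(x, cm$breaks)
    hit <- which(!is.na(exact))
    out[hit] <- cm$colors[exact[hit]]
    out[na] <- cm$na_color
  }
  dim(out) <- dims
  out
}

# Stable identity key for legend deduplication.
cm_key <- function(cm) {
  if (cm$mode == "continuous") {
    paste("c", cm$space, paste(format(cm$breaks, digits = 15), collapse = "|"),
          paste(cm$colors, collapse = "|"), sep = ";")
  } else {
    paste("d", paste(cm$levels, collapse = "|"),
          paste(cm$colors, collapse = "|"), sep = ";")
  }
}

# Default mapping for a value_matrix: blue-white-red across the numeric range,
# or the deterministic qualitative palette over sorted observed levels.
auto_color_mapping <- function(vm) {
  if (vm$kind == "numeric") {
    rng <- range(vm$values, na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    color_mapping(c(rng[1L], mean(rng), rng[2L]), c("#2166AC", "#FFFFFF", "#B2182B"))
  } else {
    default_discrete_mapping(unique(as.vector(vm$values)))
  }
}
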