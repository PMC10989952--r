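#' Rasterization policy for large heatmap bodies
#'
#' Controls when and how a heatmap body's per-cell vector drawing is replaced
#' by a reduced bitmap. `"auto"` rasterizes with the offscreen-render strategy
#' once the matrix exceeds `trigger` cells; `"off"` never rasterizes.
#'
#' @param strategy `"auto"`, `"off"`, `"offscreen_render"` (render the body at
#'   device pixel resolution), `"matrix_aggregate"` (reduce the matrix first,
#'   then map colors), or `"render_then_resize"` (render at one pixel per cell,
#'   then resample down).
#' @param aggregator For `matrix_aggregate`: `"mean"`, `"median"`, `"max"`,
#'   `"min"` or `"random"`.
#' @param resize_filter For `render_then_resize`: `"nearest"`, `"bilinear"` or
#'   `"lanczos"`.
#' @param trigger Cell-count threshold for `"auto"` (default 1e6).
#' @return A `raster_policy` object.
#' @export
raster_policy <- function(strategy = c("auto", "off", "offscreen_render",
                                       "matrix_aggregate", "render_then_resize"),
                          aggregator = c("mean", "median", "max", "min", "random"),
                          resize_filter = c("nearest", "bilinear", "lanczos"),
                          trigger = 1e6) {
  structure(list(strategy = match.arg(strategy),
                 aggregator = match.arg(aggregator),
                 resize_filter = match.arg(resize_filter),
                 trigger = trigger),
            class = "raster_policy")
}

raster_policy_default <- function() raster_policy()

#' Pixel budget of a heatmap body region
#'
#' The body region of `w x h` inches at `dpi` dots per inch offers
#' `p_r = round(h * dpi)` row pixels and `p_c = round(w * dpi)` column pixels;
#' reduction applies only when the matrix has more rows and/or columns than
#' pixels.
#'
#' @param n_r,n_c Matrix dimensions.
#' @param width,height Body region size in inches.
#' @param dpi Device resolution.
#' @return List with `p_r`, `p_c`, and logicals `reduce_rows`, `reduce_cols`.
#' @export
target_pixels <- function(n_r, n_c, width, height, dpi = 100) {
  stopifnot(width > 0, height > 0, dpi > 0)
  p_r <- max(1L, as.integer(round(height * dpi)))
  p_c <- max(1L, as.integer(round(width * dpi)))
  list(p_r = p_r, p_c = p_c,
       reduce_rows = n_r > p_r, reduce_cols = n_c > p_c)
}

# Map source index i (1..n) to block 1..p by even partitioning.
block_index <- function(n, p) {
  pmin(floor((seq_len(n) - 1L) * p / n) + 1L, p)
}

#' Reduce a matrix to a pixel grid by block aggregation
#'
#' Each output cell summarizes the block of input rows/columns mapping to it
#' under even partitioning (row `i` goes to block `floor((i-1)*p_r/n_r)+1`).
#' Color mapping is applied after aggregation, so one value corresponds to one
#' pixel.
#'
#' @param m Matrix or `value_matrix`.
#' @param p_r,p_c Output dimensions (each at most the input dimension).
#' @param aggregator `"mean"`, `"median"`, `"max"`, `"min"` or `"random"`
#'   (the only choice valid for categorical matrices).
#' @param seed Seed for the `"random"` aggregator.
#' @return A matrix of size `p_r x p_c` (same mode as the input).
#' @export
aggregate_matrix <- function(m, p_r, p_c,
                             aggregator = c("mean", "median", "max", "min", "random"),
                             seed = 1L) {
  aggregator <- match.arg(aggregator)
  vm_in <- is_value_matrix(m)
  if (vm_in) m <- m$values
  n_r <- nrow(m); n_c <- ncol(m)
  stopifnot(p_r >= 1, p_c >= 1)
  if (p_r > n_r || p_c > n_c) {
    stop("aggregation targets must not exceed the matrix dimensions", call. = FALSE)
  }
  if (!is.numeric(m) && aggregator != "random") {
    stop("a categorical matrix can only be aggregated with aggregator = \"random\"",
         call. = FALSE)
  }
  if (p_r == n_r && p_c == n_c) {
    return(if (vm_in) value_matrix(m) else m)
  }
  rb <- block_index(n_r, p_r)
  cb <- block_index(n_c, p_c)
  out <- matrix(if (is.numeric(m)) NA_real_ else NA_character_, p_r, p_c)
  if (aggregator == "random") {
    picks <- with_seed(seed, {
      lapply(seq_len(p_r), function(a) {
        ri <- which(rb == a)
        vapply(seq_len(p_c), function(b) {
          ci <- which(cb == b)
          m[sample(ri, 1L), ci[sample.int(length(ci), 1L)]]
        }, m[1L, 1L])
      })
    })
    out <- do.call(rbind, picks)
  } else {
    f <- switch(aggregator,
                mean = function(x) mean(x, na.rm = TRUE),
                median = function(x) stats::median(x, na.rm = TRUE),
                max = function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE),
                min = function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
    for (a in seq_len(p_r)) {
      ri <- which(rb == a)
      sub <- m[ri, , drop = FALSE]
      for (b in seq_len(p_c)) {
        out[a, b] <- f(sub[, which(cb == b)])
      }
    }
  }
  if (vm_in) value_matrix(out) else out
}

# Offscreen render of a cell-color matrix at p_r x p_c pixels: each pixel
# center samples the cell covering it (strategy 1).
render_body_raster <- function(color_matrix, p_r, p_c) {
  n_r <- nrow(color_matrix); n_c <- ncol(color_matrix)
  ri <- pmin(floor((seq_len(p_r) - 0.5) * n_r / p_r) + 1L, n_r)
  ci <- pmin(floor((seq_len(p_c) - 0.5) * n_c / p_c) + 1L, n_c)
  color_matrix[ri, ci, drop = FALSE]
}

#' Resample a rendered raster down to a pixel target
#'
#' Operates on a hex color matrix (one entry per pixel). `"nearest"` samples
#' the source pixel under each target pixel center; `"bilinear"` averages the
#' four surrounding pixels with bilinear weights; `"lanczos"` uses a separable
#' 3-lobe windowed-sinc kernel.
#'
#' @param img Hex color matrix (rows = y).
#' @param p_r,p_c Target dimensions (at most the input dimensions).
#' @param filter `"nearest"`, `"bilinear"` or `"lanczos"`.
#' @return Hex color matrix `p_r x p_c`.
#' @export
reduce_rendered <- function(img, p_r, p_c,
                            filter = c("nearest", "bilinear", "lanczos")) {
  filter <- match.arg(filter)
  n_r <- nrow(img); n_c <- ncol(img)
  if (p_r > n_r || p_c > n_c) {
    stop("resize targets must not exceed the image dimensions", call. = FALSE)
  }
  if (p_r == n_r && p_c == n_c) return(img)
  if (filter == "nearest") {
    return(render_body_raster(img, p_r, p_c))
  }
  ch <- col2rgb(img) / 255
  arr <- array(t(ch), dim = c(n_r, n_c, 3L))
  out <- array(0, dim = c(p_r, p_c, 3L))
  for (k in 1:3) {
    out[, , k] <- resample_channel(arr[, , k], p_r, p_c, filter)
  }
  out <- pmin(pmax(out, 0), 1)
  hexm <- rgb(out[, , 1L], out[, , 2L], out[, , 3L])
  dim(hexm) <- c(p_r, p_c)
  hexm
}

resample_channel <- function(ch, p_r, p_c, filter) {
  ch2 <- apply_resample_1d(ch, p_r, filter)          # rows
  t(apply_resample_1d(t(ch2), p_c, filter))          # then columns
}

# 1-D separable resampling along the first dimension.
apply_resample_1d <- function(m, p, filter) {
  n <- nrow(m)
  if (p == n) return(m)
  scale <- n / p
  centers <- (seq_len(p) - 0.5) * scale  # target centers in source coordinates
  if (filter == "bilinear") {
    pos <- centers - 0.5
    i0 <- floor(pos)
    t <- pos - i0
    i0 <- pmin(pmax(i0 + 1, 1L), n)      # to 1-based, clamped
    i1 <- pmin(i0 + 1L, n)
    (1 - t) * m[i0, , drop = FALSE] + t * m[i1, , drop = FALSE]
  } else { # lanczos, a = 3, kernel widened by the downscale factor
    a <- 3
    W <- matrix(0, p, n)
    for (j in seq_len(p)) {
      lo <- max(1L, floor(centers[j] - a * scale + 0.5))
      hi <- min(n, ceiling(centers[j] + a * scale - 0.5))
      x <- ((seq(lo, hi) - 0.5) - centers[j]) / scale
      w <- lanczos_kernel(x, a)
      if (sum(w) != 0) W[j, lo:hi] <- w / sum(w)
    }
    W %*% m
  }
}

lanczos_kernel <- function(x, a) {
  out <- rep(0, length(x))
  nz <- abs(x) < a
  xz <- x[nz]
  out[nz] <- ifelse(xz == 0, 1,
                    a * sin(pi * xz) * sin(pi * xz / a) / (pi^2 * xz^2))
  out
}

# Decide whether (and how) to rasterize a body of n_r x n_c cells.
effective_raster_strategy <- function(policy, n_r, n_c, p_r, p_c) {
  if (policy$strategy == "off") return(NULL)
  need <- n_r > p_r || n_c > p_c
  if (policy$strategy == "auto") {
    if (as.double(n_r) * n_c > policy$trigger && need) return("offscreen_render")
    return(NULL)
  }
  if (!need) return(NULL)
  policy$strategy
}

# Produce the reduced color raster for one body slice under a policy.
rasterize_body_slice <- function(vm_slice, cm, policy, p_r, p_c, seed = 1L) {
  p_r <- min(p_r, nrow(vm_slice)); p_c <- min(p_c, ncol(vm_slice))
  switch(effective_raster_strategy(policy, nrow(vm_slice), ncol(vm_slice),
                                   p_r, p_c) %||% "offscreen_render",
    offscreen_render = {
      render_body_raster(map_colors(cm, vm_slice), p_r, p_c)
    },
    matrix_aggregate = {
      red <- aggregate_matrix(vm_slice, p_r, p_c, policy$aggregator, seed)
      map_colors(cm, red)
    },
    render_then_resize = {
      reduce_rendered(map_colors(cm, vm_slice), p_r, p_c, policy$resize_filter)
    })
}
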