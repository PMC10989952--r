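#' Shift mark labels to remove overlaps
#'
#' Given label anchor positions (sorted in display order), label extents and
#' the track bounds, returns label center positions that (i) preserve the
#' input order, (ii) do not overlap, (iii) stay inside the bounds, and
#' (iv) minimize the sum of squared displacements from the anchors among all
#' order-preserving feasible layouts. The problem reduces, after subtracting
#' the cumulative minimum spacings, to an isotonic least-squares regression
#' with box constraints, solved by pool-adjacent-violators and a final clamp.
#'
#' @param anchors Numeric vector of anchor positions, non-decreasing.
#' @param extents Positive numeric vector of label extents (same length).
#' @param bounds Length-2 numeric interval the labels must fit into.
#' @return Numeric vector of label center positions.
#' @export
place_mark_labels <- function(anchors, extents, bounds) {
  n <- length(anchors)
  if (n == 0L) return(numeric(0))
  if (length(extents) == 1L) extents <- rep(extents, n)
  stopifnot(length(extents) == n, length(bounds) == 2L)
  if (any(extents <= 0)) stop("`extents` must be positive", call. = FALSE)
  if (is.unsorted(anchors)) stop("`anchors` must be sorted", call. = FALSE)
  if (sum(extents) > diff(bounds) + 1e-9) {
    stop("labels do not fit: total extent exceeds the bounds; use fewer labels or smaller text",
         call. = FALSE)
  }
  # required center-to-center gaps and the cumulative offset transform
  gaps <- if (n > 1L) (extents[-n] + extents[-1L]) / 2 else numeric(0)
  D <- c(0, cumsum(gaps))
  lo <- bounds[1L] + extents[1L] / 2
  hi <- bounds[2L] - extents[n] / 2 - D[n]
  fit <- pava(anchors - D)
  pmin(pmax(fit, lo), hi) + D
}

# Pool-adjacent-violators for unweighted nondecreasing least squares.
pava <- function(y) {
  n <- length(y)
  means <- y
  counts <- rep(1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    means[k] <- y[i]
    counts[k] <- 1L
    while (k > 1L && means[k - 1L] > means[k]) {
      m <- (means[k - 1L] * counts[k - 1L] + means[k] * counts[k]) /
        (counts[k - 1L] + counts[k])
      counts[k - 1L] <- counts[k - 1L] + counts[k]
      means[k - 1L] <- m
      k <- k - 1L
    }
  }
  rep(means[seq_len(k)], counts[seq_len(k)])
}

#' Allocate link panels along an axis
#'
#' Panels are allocated proportionally to subset sizes, floored at a minimum
#' extent, and the remainder is renormalized over the unfloored panels; the
#' panel extents partition the axis without overlap.
#'
#' @param sizes Integer vector of subset sizes (display order).
#' @param min_panel Minimum panel extent as a fraction of the axis.
#' @return Data frame with `start` and `end` in `[0, 1]`, one row per subset.
#' @export
link_panel_extents <- function(sizes, min_panel = 0) {
  stopifnot(all(sizes > 0), min_panel * length(sizes) <= 1 + 1e-9)
  frac <- sizes / sum(sizes)
  if (min_panel > 0) {
    small <- frac < min_panel
    # iterate: flooring one panel can push others below the floor
    repeat {
      need <- frac < min_panel - 1e-12
      if (!any(need & !small) && all(frac[small] >= min_panel - 1e-12)) break
      small <- small | need
      rest <- 1 - min_panel * sum(small)
      frac[small] <- min_panel
      if (any(!small)) {
        w <- sizes[!small] / sum(sizes[!small])
        frac[!small] <- rest * w
      }
      if (!any(frac < min_panel - 1e-12)) break
    }
  }
  ends <- cumsum(frac)
  data.frame(start = c(0, ends[-length(ends)]), end = ends)
}
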