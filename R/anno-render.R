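#' @importFrom stats loess predict density
#' @importFrom grDevices boxplot.stats colorRampPalette
NULL

# Axis geometry: display bands for n items partitioned into slices of the
# given sizes, separated by gaps (fraction of the whole region). Returns per
# display position (1..n) the band [start, end] and center, plus slice spans.
axis_bands <- function(sizes, gap_frac = 0.025) {
  k <- length(sizes)
  n <- sum(sizes)
  avail <- 1 - gap_frac * (k - 1L)
  if (avail <= 0) stop("slice gaps exceed the available extent", call. = FALSE)
  widths <- avail * sizes / n
  s_start <- cumsum(c(0, widths[-k] + gap_frac))
  starts <- numeric(n); ends <- numeric(n)
  p <- 0L
  for (s in seq_len(k)) {
    if (sizes[s] == 0L) next
    b <- seq_len(sizes[s])
    starts[p + b] <- s_start[s] + (b - 1L) / sizes[s] * widths[s]
    ends[p + b] <- s_start[s] + b / sizes[s] * widths[s]
    p <- p + sizes[s]
  }
  list(start = starts, end = ends, center = (starts + ends) / 2,
       slice_start = s_start, slice_end = s_start + widths, widths = widths)
}

pad_range <- function(r, frac = 0.05) {
  if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)
  r + c(-1, 1) * frac * diff(r)
}

scale_to <- function(v, r) (v - r[1L]) / (r[2L] - r[1L])

payload_matrix <- function(p) {
  if (is.matrix(p)) p else matrix(p, ncol = 1L)
}

payload_list <- function(p) {
  if (is.list(p) && !is.data.frame(p)) p
  else if (is.matrix(p)) lapply(seq_len(nrow(p)), function(i) p[i, ])
  else as.list(p)
}

series_palette <- function(k, override = NULL) {
  if (!is.null(override)) return(rep_len(normalize_color(override), k))
  QUALITATIVE_PALETTE[((seq_len(k) - 1L) %% length(QUALITATIVE_PALETTE)) + 1L]
}

# ---- per-kind slice renderers ------------------------------------------------
# Each receives the slice's payload rows in display order and draws into the
# unit box with items along x; `ctx` carries axis-wide shared state.

render_simple <- function(p, params, ctx) {
  m <- payload_matrix(p)
  ns <- nrow(m); nsub <- ncol(m)
  cols <- map_colors(ctx$cm, m)
  xs <- rep((seq_len(ns) - 1L) / ns, times = nsub)
  ys <- rep((rev(seq_len(nsub)) - 1L) / nsub, each = ns)
  prim_rect(xs, ys, 1 / ns, 1 / nsub, fill = as.vector(cols))
}

render_points <- function(p, params, ctx) {
  m <- payload_matrix(p)
  ns <- nrow(m)
  out <- empty_prims()
  cx <- (seq_len(ns) - 0.5) / ns
  cols <- series_palette(ncol(m), params$pt_color)
  for (j in seq_len(ncol(m))) {
    y <- scale_to(m[, j], ctx$range)
    ok <- !is.na(y)
    out <- prims_concat(out, prim_point(cx[ok], y[ok], r = 0.035, fill = cols[j]))
  }
  out
}

render_lines <- function(p, params, ctx, values = NULL) {
  m <- payload_matrix(p)
  ns <- nrow(m)
  out <- empty_prims()
  cx <- (seq_len(ns) - 0.5) / ns
  cols <- series_palette(ncol(m), params$line_color)
  for (j in seq_len(ncol(m))) {
    y <- scale_to(if (is.null(values)) m[, j] else values[, j], ctx$range)
    ok <- which(!is.na(y))
    if (length(ok) >= 2L) {
      i0 <- ok[-length(ok)]; i1 <- ok[-1L]
      out <- prims_concat(out, prim_segment(cx[i0], y[i0], cx[i1], y[i1],
                                            col = cols[j]))
    }
  }
  out
}

render_smoothed_lines <- function(p, params, ctx) {
  m <- payload_matrix(p)
  fitted <- m
  for (j in seq_len(ncol(m))) {
    idx <- seq_len(nrow(m))
    ok <- !is.na(m[, j])
    if (sum(ok) >= 4L) {
      fit <- tryCatch(
        suppressWarnings(loess(m[ok, j] ~ idx[ok], span = params$span %||% 0.75,
                               degree = params$degree %||% 2)),
        error = function(e) NULL)
      if (!is.null(fit)) fitted[ok, j] <- suppressWarnings(predict(fit, idx[ok]))
    }
  }
  render_lines(p, params, ctx, values = fitted)
}

render_barplot <- function(p, params, ctx) {
  m <- payload_matrix(p)
  ns <- nrow(m)
  base <- scale_to(params$baseline %||% 0, ctx$range)
  cols <- series_palette(ncol(m), params$fill)
  out <- empty_prims()
  x0 <- (seq_len(ns) - 1L) / ns + 0.1 / ns
  w <- 0.8 / ns
  if (ncol(m) == 1L) {
    y <- scale_to(m[, 1L], ctx$range)
    ok <- !is.na(y)
    out <- prim_rect(x0[ok], pmin(base, y[ok]), w, abs(y[ok] - base),
                     fill = cols[1L])
  } else {
    cum0 <- rep(0, ns)
    for (j in seq_len(ncol(m))) {
      v <- ifelse(is.na(m[, j]), 0, m[, j])
      y0 <- scale_to(cum0, ctx$range)
      y1 <- scale_to(cum0 + v, ctx$range)
      out <- prims_concat(out, prim_rect(x0, y0, w, y1 - y0, fill = cols[j]))
      cum0 <- cum0 + v
    }
  }
  out
}

render_percent <- function(p, params, ctx) {
  v <- as.numeric(p)
  ns <- length(v)
  x0 <- (seq_len(ns) - 1L) / ns + 0.1 / ns
  w <- 0.8 / ns
  ok <- !is.na(v)
  out <- prim_rect(x0[ok], 0, w, v[ok] * 0.8, fill = params$fill %||% "#4292C6")
  lab <- sprintf("%.1f%%", 100 * v[ok])
  prims_concat(out, prim_text(x0[ok] + w / 2, v[ok] * 0.8 + 0.08, lab,
                              cex = min(0.7, 3 / ns), rot = 0))
}

render_boxplot <- function(p, params, ctx) {
  xs <- payload_list(p)
  ns <- length(xs)
  out <- empty_prims()
  for (i in seq_len(ns)) {
    v <- xs[[i]][!is.na(xs[[i]])]
    if (!length(v)) next
    bs <- boxplot.stats(v)
    st <- scale_to(bs$stats, ctx$range)
    c0 <- (i - 0.5) / ns
    hw <- 0.3 / ns
    out <- prims_concat(
      out,
      prim_segment(c0, st[1L], c0, st[2L]),
      prim_segment(c0, st[4L], c0, st[5L]),
      prim_rect(c0 - hw, st[2L], 2 * hw, st[4L] - st[2L],
                fill = params$fill %||% "#BDBDBD", col = "#000000", lwd = 0.5),
      prim_segment(c0 - hw, st[3L], c0 + hw, st[3L], lwd = 1.5)
    )
    if (length(bs$out)) {
      out <- prims_concat(out, prim_point(rep(c0, length(bs$out)),
                                          scale_to(bs$out, ctx$range), r = 0.02))
    }
  }
  out
}

render_text <- function(p, params, ctx) {
  lab <- as.character(p)
  ns <- length(lab)
  cx <- (seq_len(ns) - 0.5) / ns
  prim_text(cx, 0.05, lab, cex = params$cex %||% 0.8,
            rot = params$rot %||% 90, vjust = 0, hjust = 0)
}

render_histogram <- function(p, params, ctx) {
  xs <- payload_list(p)
  ns <- length(xs)
  nb <- params$breaks %||% 11
  brk <- seq(ctx$range[1L], ctx$range[2L], length.out = nb + 1L)
  counts <- lapply(xs, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(rep(0L, nb))
    tabulate(pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE,
                                    all.inside = TRUE), 1L), nb), nbins = nb)
  })
  mx <- max(1L, unlist(counts))
  out <- empty_prims()
  for (i in seq_len(ns)) {
    x0 <- (i - 1L) / ns
    bw <- 0.9 / ns
    h <- counts[[i]] / mx
    y0 <- scale_to(brk[-length(brk)], c(ctx$range[1L], ctx$range[2L]))
    y1 <- scale_to(brk[-1L], c(ctx$range[1L], ctx$range[2L]))
    keep <- h > 0
    if (any(keep)) {
      out <- prims_concat(out, prim_rect(x0, y0[keep], bw * h[keep],
                                         (y1 - y0)[keep],
                                         fill = params$fill %||% "#9ECAE1"))
    }
  }
  out
}

render_violin <- function(p, params, ctx) {
  xs <- payload_list(p)
  ns <- length(xs)
  out <- empty_prims()
  for (i in seq_len(ns)) {
    v <- xs[[i]][!is.na(xs[[i]])]
    c0 <- (i - 0.5) / ns
    hw <- 0.38 / ns
    if (length(v) < 2L || diff(range(v)) == 0) {
      y <- scale_to(v[1L] %||% NA_real_, ctx$range)
      if (!is.na(y)) out <- prims_concat(out, prim_segment(c0 - hw, y, c0 + hw, y))
      next
    }
    d <- density(v)
    y <- scale_to(d$x, ctx$range)
    w <- d$y / max(d$y) * hw
    out <- prims_concat(out, prim_polygon(c(c0 - w, rev(c0 + w)), c(y, rev(y)),
                                          fill = params$fill %||% "#C7E9C0",
                                          col = "#000000"))
  }
  out
}

render_joyplot <- function(p, params, ctx) {
  xs <- payload_list(p)
  ns <- length(xs)
  overlap <- params$overlap %||% 2
  dens <- lapply(xs, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L || diff(range(v)) == 0) return(NULL)
    density(v)
  })
  mx <- max(c(1e-12, unlist(lapply(dens, function(d) if (is.null(d)) NULL else max(d$y)))))
  out <- empty_prims()
  for (i in rev(seq_len(ns))) {           # draw back (top) first so fronts overlay
    d <- dens[[i]]
    if (is.null(d)) next
    base <- 1 - i / ns                    # item bands run top-down
    x <- scale_to(d$x, ctx$range)
    h <- d$y / mx * overlap / ns
    y <- pmin(base + h, 1)                # peaks may overflow into neighbours,
    out <- prims_concat(out, prim_polygon(c(x[1L], x, x[length(x)]),
                                          c(base, y, base),
                                          fill = params$fill %||% "#807DBA",
                                          col = "#000000"))
  }
  out
}

#' Horizon band decomposition of a series
#'
#' Cuts an area chart into uniform value bands: band `b` receives
#' `min(max(v - (b-1)*H, 0), H) / H` of each value `v` (and symmetrically for
#' negative values), so stacking/overlaying the bands reconstitutes the chart.
#'
#' @param v Numeric series.
#' @param n_bands Number of bands.
#' @param band_height Band value height `H`; default `max(abs(v))/n_bands`.
#' @return List with matrices `pos` and `neg`, each `n_bands x length(v)` of
#'   band fill fractions in `[0, 1]`.
#' @export
horizon_bands <- function(v, n_bands, band_height = NULL) {
  H <- band_height %||% (max(abs(v), na.rm = TRUE) / n_bands)
  if (!is.finite(H) || H <= 0) H <- 1
  pos <- matrix(0, n_bands, length(v))
  neg <- matrix(0, n_bands, length(v))
  vv <- ifelse(is.na(v), 0, v)
  for (b in seq_len(n_bands)) {
    pos[b, ] <- pmin(pmax(vv - (b - 1) * H, 0), H) / H
    neg[b, ] <- pmin(pmax(-vv - (b - 1) * H, 0), H) / H
  }
  list(pos = pos, neg = neg, band_height = H)
}

render_horizon <- function(p, params, ctx) {
  xs <- payload_list(p)
  ns <- length(xs)
  nb <- params$n_bands %||% 4
  pos_cols <- params$pos_colors %||% colorRampPalette(c("#C6DBEF", "#08306B"))(nb)
  neg_cols <- params$neg_colors %||% colorRampPalette(c("#FCBBA1", "#67000D"))(nb)
  out <- empty_prims()
  for (i in seq_len(ns)) {
    v <- xs[[i]]
    if (!length(v)) next
    hb <- horizon_bands(v, nb, params$band_height)
    u0 <- 1 - i / ns                      # item bands top-down
    bw <- 1 / ns
    t <- if (length(v) > 1L) (seq_along(v) - 1L) / (length(v) - 1L) else 0.5
    for (side in c("pos", "neg")) {
      cols <- if (side == "pos") pos_cols else neg_cols
      for (b in seq_len(nb)) {
        a <- hb[[side]][b, ]
        if (all(a == 0)) next
        out <- prims_concat(out, prim_polygon(
          c(t, rev(t)),
          c(u0 + a * bw, rep(u0, length(t))),
          fill = cols[b]))
      }
    }
  }
  out
}

render_image <- function(p, params, ctx) {
  paths <- as.character(p)
  ns <- length(paths)
  out <- empty_prims()
  for (i in seq_len(ns)) {
    if (is.na(paths[i]) || paths[i] == "") next
    ext <- tolower(tools::file_ext(paths[i]))
    if (ext != "png") {
      stop(sprintf("image annotation: unsupported format '%s' (png supported)", ext),
           call. = FALSE)
    }
    a <- png::readPNG(paths[i])
    hexm <- raster_array_to_hex(a)
    out <- prims_concat(out, prim_image(hexm, (i - 1L) / ns + 0.05 / ns, 0.05,
                                        0.9 / ns, 0.9))
  }
  out
}

raster_array_to_hex <- function(a) {
  if (length(dim(a)) == 2L) {
    m <- rgb(a, a, a)
  } else {
    m <- rgb(a[, , 1L], a[, , 2L], a[, , 3L])
  }
  dim(m) <- dim(a)[1:2]
  m
}

ANNO_RENDERERS <- list(
  simple = render_simple, image = render_image, points = render_points,
  lines = render_lines, smoothed_lines = render_smoothed_lines,
  barplot = render_barplot, percent = render_percent, boxplot = render_boxplot,
  text = render_text, histogram = render_histogram, violin = render_violin,
  joyplot = render_joyplot, horizon = render_horizon,
  mark = "whole-axis", link = "whole-axis", textbox = "whole-axis"
)

#' Registered annotation kinds
#' @return Character vector of all kinds with a registered renderer.
#' @export
annotation_kinds <- function() names(ANNO_RENDERERS)

numeric_kind <- function(kind) {
  kind %in% c("points", "lines", "smoothed_lines", "barplot", "percent",
              "boxplot", "histogram", "violin", "joyplot", "horizon")
}

track_value_range <- function(track) {
  p <- track$payload
  v <- if (is.list(p) && !is.data.frame(p)) unlist(p) else as.vector(payload_matrix(p))
  v <- v[is.finite(v)]
  if (!length(v)) return(c(0, 1))
  if (track$kind == "barplot" && is.matrix(p)) {
    tot <- rowSums(ifelse(is.na(p), 0, p))
    return(pad_range(range(c(0, tot))))
  }
  if (track$kind %in% c("barplot", "percent")) return(pad_range(range(c(0, v))))
  pad_range(range(v))
}

# Permute a track's payload so that rendering it with the identity order
# reproduces rendering the original with `order` (the commutation contract).
permute_track <- function(track, order) {
  n <- length(order)
  pos <- integer(n); pos[order] <- seq_len(n)
  p <- track$payload
  if (track$kind == "mark") {
    track$payload$at <- pos[p$at]
  } else if (track$kind == "link") {
    track$payload$at <- lapply(p$at, function(s) pos[s])
  } else if (track$kind == "textbox") {
    # slice-keyed; unaffected by item permutation
  } else if (is.matrix(p)) {
    track$payload <- p[order, , drop = FALSE]
  } else if (is.list(p) && !is.data.frame(p)) {
    track$payload <- p[order]
  } else {
    track$payload <- p[order]
  }
  track
}

#' Render one annotation track
#'
#' The payload is permuted by `order` and partitioned by `slices` before
#' drawing: one sub-region per slice, separated by the same gaps as the
#' heatmap body. Returns drawing primitives in region-local coordinates
#' (items run left-to-right for column tracks, top-to-bottom for row tracks).
#'
#' @param track An `anno_track` (its `axis` field set, e.g. via
#'   [annotation_block()]).
#' @param order Display permutation of the axis (original indices).
#' @param slices Slice sizes in display order (integer vector), or a
#'   `slice_spec` whose items are display-ordered.
#' @param gap_frac Slice gap as a fraction of the region extent.
#' @return A primitive set.
#' @export
render_track <- function(track, order, slices = NULL, gap_frac = 0.025) {
  stopifnot(inherits(track, "anno_track"))
  n <- length(order)
  if (!setequal(order, seq_len(n))) {
    stop("`order` must be a permutation of the axis indices", call. = FALSE)
  }
  if (is.null(slices)) slices <- n
  labels <- NULL
  if (inherits(slices, "slice_spec")) {
    labels <- slices$labels
    slices <- lengths(slices$items)
  }
  sizes <- as.integer(slices)
  if (sum(sizes) != n) stop("slice sizes must sum to the axis length", call. = FALSE)
  if (is.null(ANNO_RENDERERS[[track$kind]])) {
    stop(sprintf("unknown annotation kind '%s'", track$kind), call. = FALSE)
  }
  if (numeric_kind(track$kind)) {
    v <- track$payload
    vv <- if (is.list(v) && !is.data.frame(v)) unlist(v) else as.vector(payload_matrix(v))
    if (!is.numeric(vv)) {
      stop(sprintf("annotation kind '%s' needs a numeric payload", track$kind),
           call. = FALSE)
    }
  }
  check_track_length(track, n)
  bands <- axis_bands(sizes, gap_frac)
  prims <- if (track$kind == "mark") {
    render_mark_track(track, order, bands)
  } else if (track$kind == "link") {
    render_link_track(track, order, bands)
  } else if (track$kind == "textbox") {
    render_textbox_track(track, sizes, labels %||% as.character(seq_along(sizes)),
                         bands)
  } else {
    ctx <- list(range = track_value_range(track),
                cm = track$colors %||% track_color_mapping(track))
    disp <- permute_track(track, order)
    out <- empty_prims()
    offset <- 0L
    renderer <- ANNO_RENDERERS[[track$kind]]
    for (s in seq_along(sizes)) {
      if (sizes[s] == 0L) next
      rows <- offset + seq_len(sizes[s])
      sp <- slice_payload(disp$payload, rows)
      pr <- renderer(sp, disp$params, ctx)
      out <- prims_concat(out, prims_into(pr, bands$slice_start[s], 0,
                                          bands$widths[s], 1))
      offset <- offset + sizes[s]
    }
    out
  }
  if ((track$axis %||% "column") == "row") prims <- prims_row_transform(prims)
  prims
}

track_color_mapping <- function(track) {
  if (track$kind != "simple") return(NULL)
  p <- payload_matrix(track$payload)
  vm <- value_matrix(p)
  auto_color_mapping(vm)
}

slice_payload <- function(p, rows) {
  if (is.matrix(p)) p[rows, , drop = FALSE]
  else if (is.list(p) && !is.data.frame(p)) p[rows]
  else p[rows]
}

render_mark_track <- function(track, order, bands) {
  at <- track$payload$at
  labels <- track$payload$labels
  n <- length(order)
  pos <- match(at, order)
  if (anyNA(pos)) stop("mark annotation addresses indices not on the axis", call. = FALSE)
  o <- order(pos)
  pos <- pos[o]; labels <- labels[o]
  anchors <- bands$center[pos]
  cex <- track$params$cex %||% 0.8
  extent <- track$params$extent %||% min(0.08, 0.9 / length(at))
  placed <- place_mark_labels(anchors, rep(extent, length(anchors)), c(0, 1))
  prims_concat(
    prim_segment(anchors, 0, placed, 0.55, col = "#555555", lwd = 0.7),
    prim_text(placed, 0.6, labels, cex = cex, rot = 90, hjust = 0, vjust = 0.5)
  )
}

render_link_track <- function(track, order, bands) {
  subsets <- track$payload$at
  n <- length(order)
  posmap <- integer(n); posmap[order] <- seq_len(n)
  pos <- lapply(subsets, function(s) sort(posmap[s]))
  allpos <- unlist(pos)
  if (anyDuplicated(allpos)) stop("link annotation subsets overlap", call. = FALSE)
  contiguous <- vapply(pos, function(p) length(p) == 0L ||
                         (max(p) - min(p) + 1L) == length(p), logical(1))
  if (!all(contiguous)) {
    stop("link annotation subsets must be contiguous in display order", call. = FALSE)
  }
  ord <- order(vapply(pos, min, numeric(1)))
  pos <- pos[ord]; subsets <- subsets[ord]
  ext <- link_panel_extents(lengths(pos), track$params$min_panel %||% 0)
  out <- empty_prims()
  for (i in seq_along(pos)) {
    a0 <- bands$start[min(pos[[i]])]
    a1 <- bands$end[max(pos[[i]])]
    p0 <- ext$start[i]; p1 <- ext$end[i]
    out <- prims_concat(out,
      prim_polygon(c(a0, a1, p1, p0), c(0, 0, 0.35, 0.35),
                   fill = "#DDDDDD", col = "#888888"))
    if (!is.null(track$payload$panel_fun)) {
      pp <- track$payload$panel_fun(subsets[[i]], i)
      if (!is.null(pp)) {
        out <- prims_concat(out, prims_into(pp, p0, 0.35, p1 - p0, 0.65))
      }
    } else {
      out <- prims_concat(out, prim_rect(p0, 0.35, p1 - p0, 0.65,
                                         fill = NA_character_, col = "#888888",
                                         lwd = 0.7))
    }
  }
  out
}

render_textbox_track <- function(track, sizes, labels, bands) {
  words <- track$payload
  cexr <- track$params$cex_range %||% c(0.5, 1.2)
  out <- empty_prims()
  for (s in seq_along(sizes)) {
    wl <- words[[labels[s]]]
    if (is.null(wl) || !nrow(wl)) next
    wl <- wl[order(-wl$score), , drop = FALSE]
    sc <- wl$score
    cex <- if (diff(range(sc)) == 0) rep(mean(cexr), length(sc)) else
      cexr[1L] + (sc - min(sc)) / diff(range(sc)) * diff(cexr)
    # greedy row packing inside the slice span
    x0 <- bands$slice_start[s]
    w_avail <- bands$widths[s]
    x <- 0; y <- 0.9
    char_w <- 0.012
    for (i in seq_len(nrow(wl))) {
      ww <- (nchar(wl$word[i]) + 1L) * char_w * cex[i]
      if (x + ww > w_avail && x > 0) { x <- 0; y <- y - 0.18 }
      out <- prims_concat(out, prim_text(x0 + x, y, wl$word[i], cex = cex[i],
                                         hjust = 0, vjust = 1))
      x <- x + ww
    }
    out <- prims_concat(out, prim_rect(x0, 0, w_avail, 1, fill = NA_character_,
                                       col = "#AAAAAA", lwd = 0.5))
  }
  out
}

# Rotate column-orientation primitives into row orientation:
# (x, y) -> (y, 1 - x); items then run top-to-bottom, values point right.
prims_row_transform <- function(p) {
  q <- empty_prims()
  q$rects <- data.frame(x = p$rects$y, y = 1 - p$rects$x - p$rects$w,
                        w = p$rects$h, h = p$rects$w, fill = p$rects$fill,
                        col = p$rects$col, lwd = p$rects$lwd,
                        stringsAsFactors = FALSE)
  q$segments <- data.frame(x0 = p$segments$y0, y0 = 1 - p$segments$x0,
                           x1 = p$segments$y1, y1 = 1 - p$segments$x1,
                           col = p$segments$col, lwd = p$segments$lwd,
                           stringsAsFactors = FALSE)
  q$points <- data.frame(x = p$points$y, y = 1 - p$points$x, r = p$points$r,
                         fill = p$points$fill, col = p$points$col,
                         stringsAsFactors = FALSE)
  q$texts <- data.frame(x = p$texts$y, y = 1 - p$texts$x, label = p$texts$label,
                        cex = p$texts$cex, col = p$texts$col,
                        rot = p$texts$rot - 90, hjust = p$texts$hjust,
                        vjust = p$texts$vjust, stringsAsFactors = FALSE)
  q$polygons <- lapply(p$polygons, function(pg) {
    list(x = pg$y, y = 1 - pg$x, fill = pg$fill, col = pg$col)
  })
  q$images <- lapply(p$images, function(im) {
    list(x = im$y, y = 1 - im$x - im$w, w = im$h, h = im$w,
         raster = rotate_raster_cw(im$raster))
  })
  q
}

rotate_raster_cw <- function(m) {
  t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
}
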