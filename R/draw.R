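# Scene composition: models -> layout tree (named regions in device inches,
# origin bottom-left) + per-region primitives. The scene is the persistent
# registry: every heatmap component keeps its named region after drawing, so
# decoration can return to it.

new_scene <- function(width, height) {
  structure(list(width = width, height = height,
                 regions = list(), prims = list()),
            class = "hm_scene")
}

#' @export
print.hm_scene <- function(x, ...) {
  cat(sprintf("<hm_scene> %.3g x %.3g in, %d region(s)\n", x$width, x$height,
              length(x$regions)))
  invisible(x)
}

add_region <- function(scene, name, x, y, w, h, prims = NULL) {
  if (name %in% names(scene$regions)) {
    stop(sprintf("duplicate region name '%s'", name), call. = FALSE)
  }
  scene$regions[[name]] <- list(x = x, y = y, w = w, h = h)
  scene$prims[[name]] <- prims %||% empty_prims()
  scene
}

#' Region registry of a scene
#' @param scene An `hm_scene`.
#' @return Named list of regions (`x`, `y`, `w`, `h` in inches).
#' @export
scene_regions <- function(scene) scene$regions

MARGIN <- 0.15

#' Compose a heatmap (list) into a drawable scene
#'
#' Resolves alignment, computes the layout tree for the requested device size
#' and renders every component to primitives. Body slices are sized
#' proportionally to slice item counts with fixed inter-slice gaps; dendrogram,
#' name, title, annotation and legend components receive fixed absolute sizes
#' and the body absorbs the remaining space.
#'
#' @param model A `heat_map` or `hm_list`.
#' @param width,height Device size in inches.
#' @param dpi Device resolution (drives rasterization pixel budgets).
#' @param gap_frac Slice gap as a fraction of the body extent.
#' @return An `hm_scene`.
#' @export
compose_scene <- function(model, width = 7, height = 7, dpi = 100,
                          gap_frac = 0.025) {
  stopifnot(width > 0, height > 0)
  hl <- resolve_alignment(as_hm_list(model))
  if (hl$direction == "horizontal") {
    compose_horizontal(hl, width, height, dpi, gap_frac)
  } else {
    compose_vertical(hl, width, height, dpi, gap_frac)
  }
}

item_weight <- function(it, direction) {
  if (!is_heat_map(it)) return(NA_real_)
  if (direction == "horizontal") {
    it$weight$width %||% ncol(it$matrix$values)
  } else {
    it$weight$height %||% nrow(it$matrix$values)
  }
}

compose_horizontal <- function(hl, width, height, dpi, gap_frac) {
  items <- hl$items
  k <- length(items)
  is_hm <- vapply(items, is_heat_map, logical(1))
  sides <- lapply(seq_len(k), function(i) {
    if (is_hm[i]) hm_side_sizes(items[[i]], i == hl$main_index) else NULL
  })
  title_h <- if (!is.null(hl$title)) 0.35 else 0
  top_stack <- max(c(0, vapply(sides[is_hm], function(s) s$top, numeric(1))))
  bottom_stack <- max(c(0, vapply(sides[is_hm], function(s) s$bottom, numeric(1))))
  legends <- build_legends(items[is_hm])
  legend_w <- if (length(legends)) COMPONENT_SIZES$legend_w else 0
  body_h <- height - 2 * MARGIN - title_h - top_stack - bottom_stack
  if (body_h <= 0) {
    stop(sprintf("components exceed the device height by %.2f in", -body_h + 0.1),
         call. = FALSE)
  }
  fixed <- vapply(seq_len(k), function(i) {
    if (is_hm[i]) sides[[i]]$left + sides[[i]]$right else block_size(items[[i]])
  }, numeric(1))
  flexible <- width - 2 * MARGIN - legend_w - COMPONENT_SIZES$item_gap * (k - 1L) -
    sum(fixed)
  weights <- vapply(items, item_weight, numeric(1), direction = "horizontal")
  if (any(is_hm) && flexible <= 0) {
    stop(sprintf("components exceed the device width by %.2f in", -flexible + 0.1),
         call. = FALSE)
  }
  body_w <- rep(0, k)
  body_w[is_hm] <- flexible * weights[is_hm] / sum(weights[is_hm])

  scene <- new_scene(width, height)
  body_y <- MARGIN + bottom_stack
  if (title_h > 0) {
    scene <- add_region(scene, "global_title", MARGIN, height - MARGIN - title_h,
                        width - 2 * MARGIN, title_h,
                        prim_text(0.5, 0.5, hl$title, cex = 1.2))
  }
  x <- MARGIN
  row_res <- hl$alignment
  for (i in seq_len(k)) {
    it <- items[[i]]
    if (is_hm[i]) {
      scene <- emit_heatmap(scene, it, i == hl$main_index, x, body_y,
                            body_w[i], body_h, sides[[i]], dpi, gap_frac,
                            row_res = row_res)
      x <- x + fixed[i] + body_w[i]
    } else {
      scene <- emit_annotation_item(scene, it, i, x, body_y, body_h,
                                    row_res, gap_frac)
      x <- x + fixed[i]
    }
    x <- x + COMPONENT_SIZES$item_gap
  }
  emit_legends(scene, legends, width - MARGIN - legend_w, body_y, legend_w, body_h)
}

compose_vertical <- function(hl, width, height, dpi, gap_frac) {
  items <- hl$items
  k <- length(items)
  is_hm <- vapply(items, is_heat_map, logical(1))
  sides <- lapply(seq_len(k), function(i) {
    if (is_hm[i]) hm_side_sizes(items[[i]], i == hl$main_index) else NULL
  })
  title_h <- if (!is.null(hl$title)) 0.35 else 0
  left_stack <- max(c(0, vapply(sides[is_hm], function(s) s$left, numeric(1))))
  right_stack <- max(c(0, vapply(sides[is_hm], function(s) s$right, numeric(1))))
  legends <- build_legends(items[is_hm])
  legend_w <- if (length(legends)) COMPONENT_SIZES$legend_w else 0
  body_w <- width - 2 * MARGIN - legend_w - left_stack - right_stack
  if (body_w <= 0) {
    stop(sprintf("components exceed the device width by %.2f in", -body_w + 0.1),
         call. = FALSE)
  }
  fixed <- vapply(seq_len(k), function(i) {
    if (is_hm[i]) sides[[i]]$top + sides[[i]]$bottom else block_size(items[[i]])
  }, numeric(1))
  flexible <- height - 2 * MARGIN - title_h - COMPONENT_SIZES$item_gap * (k - 1L) -
    sum(fixed)
  if (flexible <= 0) {
    stop(sprintf("components exceed the device height by %.2f in", -flexible + 0.1),
         call. = FALSE)
  }
  weights <- vapply(items, item_weight, numeric(1), direction = "vertical")
  body_h <- rep(0, k)
  body_h[is_hm] <- flexible * weights[is_hm] / sum(weights[is_hm])

  scene <- new_scene(width, height)
  if (title_h > 0) {
    scene <- add_region(scene, "global_title", MARGIN, height - MARGIN - title_h,
                        width - 2 * MARGIN, title_h,
                        prim_text(0.5, 0.5, hl$title, cex = 1.2))
  }
  body_x <- MARGIN + left_stack
  y_top <- height - MARGIN - title_h
  col_res <- hl$alignment
  for (i in seq_len(k)) {
    it <- items[[i]]
    if (is_hm[i]) {
      y <- y_top - sides[[i]]$top - body_h[i]
      scene <- emit_heatmap(scene, it, i == hl$main_index, body_x, y,
                            body_w, body_h[i], sides[[i]], dpi, gap_frac,
                            col_res = col_res)
      y_top <- y - sides[[i]]$bottom
    } else {
      y_top <- y_top - fixed[i]
      scene <- emit_annotation_item(scene, it, i, body_x, y_top, body_w,
                                    col_res, gap_frac, horizontal = FALSE)
    }
    y_top <- y_top - COMPONENT_SIZES$item_gap
  }
  emit_legends(scene, legends, width - MARGIN - legend_w, MARGIN, legend_w,
               height - 2 * MARGIN - title_h)
}

# Slice spans along a body extent; returns start/size vectors in inches,
# display slice 1 at the top (rows) or left (columns).
slice_spans <- function(sizes, extent, origin, gap_frac, top_down = FALSE) {
  b <- axis_bands(sizes, gap_frac)
  k <- length(sizes)
  if (top_down) {
    start <- origin + extent * (1 - b$slice_end)
  } else {
    start <- origin + extent * b$slice_start
  }
  list(start = start, size = extent * b$widths, bands = b)
}

emit_heatmap <- function(scene, hm, is_main, bx, by, bw, bh, sides, dpi,
                         gap_frac, row_res = NULL, col_res = NULL) {
  nm <- hm$name
  row_res <- row_res %||% hm$resolved$row
  col_res <- col_res %||% hm$resolved$column
  bx <- bx + sides$left
  rs <- slice_spans(row_res$sizes, bh, by, gap_frac, top_down = TRUE)
  cs <- slice_spans(col_res$sizes, bw, bx, gap_frac)
  nr_slices <- length(row_res$sizes)
  nc_slices <- length(col_res$sizes)
  for (r in seq_len(nr_slices)) {
    for (cc in seq_len(nc_slices)) {
      pr <- body_slice_prims(hm, row_res$slice_items[[r]],
                             col_res$slice_items[[cc]],
                             cs$size[cc], rs$size[r], dpi)
      scene <- add_region(scene, sprintf("%s:body:%d:%d", nm, r, cc),
                          cs$start[cc], rs$start[r], cs$size[cc], rs$size[r], pr)
    }
  }
  # column-side stack above the body
  y <- by + bh
  if (!is.null(hm$annotations$top)) {
    blk <- hm$annotations$top
    for (t in rev(seq_along(blk$tracks))) {
      tr <- blk$tracks[[t]]
      pr <- render_track(tr, col_res$order, col_res$sizes, gap_frac)
      scene <- add_region(scene, sprintf("%s:anno:top:%s", nm, tr$name),
                          bx, y, bw, tr$size, pr)
      y <- y + tr$size + if (t > 1L) blk$gap else 0
    }
  }
  if (isTRUE(hm$show$column_dend)) {
    drawn <- FALSE
    for (cc in seq_len(nc_slices)) {
      d <- col_res$dends[[cc]]
      if (is.null(d)) next
      pr <- dend_prims(d, col_res$slice_items[[cc]], orient = "top")
      scene <- add_region(scene, sprintf("%s:dend_col:%d", nm, cc),
                          cs$start[cc], y, cs$size[cc], COMPONENT_SIZES$dend, pr)
      drawn <- TRUE
    }
    if (drawn) y <- y + COMPONENT_SIZES$dend
  }
  if (!is.null(hm$titles$column)) {
    scene <- add_region(scene, sprintf("%s:col_title", nm), bx, y, bw,
                        COMPONENT_SIZES$title,
                        prim_text(0.5, 0.5, hm$titles$column, cex = 1))
  }
  # column names below the body
  yb <- by
  if (isTRUE(hm$show$column_names) && !is.null(colnames(hm$matrix$values))) {
    labs <- colnames(hm$matrix$values)[col_res$order]
    pr <- prim_text(cs$bands$center, 0.95, labs, cex = min(0.7, 25 / length(labs)),
                    rot = 90, hjust = 1, vjust = 0.5)
    yb <- yb - COMPONENT_SIZES$names
    scene <- add_region(scene, sprintf("%s:col_names", nm), bx, yb, bw,
                        COMPONENT_SIZES$names, pr)
  }
  if (!is.null(hm$annotations$bottom)) {
    blk <- hm$annotations$bottom
    for (t in seq_along(blk$tracks)) {
      tr <- blk$tracks[[t]]
      pr <- render_track(tr, col_res$order, col_res$sizes, gap_frac)
      yb <- yb - tr$size
      scene <- add_region(scene, sprintf("%s:anno:bottom:%s", nm, tr$name),
                          bx, yb, bw, tr$size, pr)
      yb <- yb - blk$gap
    }
  }
  # row-side stack left of the body
  xl <- bx
  if (is_main && isTRUE(hm$show$row_dend)) {
    drawn <- FALSE
    for (r in seq_len(nr_slices)) {
      d <- row_res$dends[[r]]
      if (is.null(d)) next
      pr <- dend_prims(d, row_res$slice_items[[r]], orient = "left")
      scene <- add_region(scene, sprintf("%s:dend_row:%d", nm, r),
                          xl - COMPONENT_SIZES$dend, rs$start[r],
                          COMPONENT_SIZES$dend, rs$size[r], pr)
      drawn <- TRUE
    }
    if (drawn) xl <- xl - COMPONENT_SIZES$dend
  }
  if (!is.null(hm$annotations$left)) {
    blk <- hm$annotations$left
    for (t in seq_along(blk$tracks)) {
      tr <- blk$tracks[[t]]
      pr <- render_track(tr, row_res$order, row_res$sizes, gap_frac)
      xl <- xl - tr$size
      scene <- add_region(scene, sprintf("%s:anno:left:%s", nm, tr$name),
                          xl, by, tr$size, bh, pr)
      xl <- xl - blk$gap
    }
  }
  if (!is.null(hm$titles$row)) {
    scene <- add_region(scene, sprintf("%s:row_title", nm),
                        xl - COMPONENT_SIZES$title, by, COMPONENT_SIZES$title, bh,
                        prim_text(0.5, 0.5, hm$titles$row, cex = 1, rot = 90))
  }
  # row-side stack right of the body
  xr <- bx + bw
  if (isTRUE(hm$show$row_names) && !is.null(rownames(hm$matrix$values))) {
    labs <- rownames(hm$matrix$values)[row_res$order]
    centers <- 1 - rs$bands$center
    pr <- prim_text(0.05, centers, labs, cex = min(0.7, 25 / length(labs)),
                    hjust = 0, vjust = 0.5)
    scene <- add_region(scene, sprintf("%s:row_names", nm), xr, by,
                        COMPONENT_SIZES$names, bh, pr)
    xr <- xr + COMPONENT_SIZES$names
  }
  if (!is.null(hm$annotations$right)) {
    blk <- hm$annotations$right
    for (t in seq_along(blk$tracks)) {
      tr <- blk$tracks[[t]]
      pr <- render_track(tr, row_res$order, row_res$sizes, gap_frac)
      scene <- add_region(scene, sprintf("%s:anno:right:%s", nm, tr$name),
                          xr, by, tr$size, bh, pr)
      xr <- xr + tr$size + blk$gap
    }
  }
  scene
}

emit_annotation_item <- function(scene, blk, idx, x, y, extent, res, gap_frac,
                                 horizontal = TRUE) {
  pos <- 0
  for (t in seq_along(blk$tracks)) {
    tr <- blk$tracks[[t]]
    pr <- render_track(tr, res$order, res$sizes, gap_frac)
    rn <- sprintf("anno_item%d:%s", idx, tr$name)
    if (horizontal) {
      scene <- add_region(scene, rn, x + pos, y, tr$size, extent, pr)
    } else {
      scene <- add_region(scene, rn, x, y + pos, extent, tr$size, pr)
    }
    pos <- pos + tr$size + blk$gap
  }
  scene
}

emit_legends <- function(scene, legends, x, y, w, h) {
  if (!length(legends)) return(scene)
  lh <- min(COMPONENT_SIZES$legend_item_h, h / length(legends))
  for (i in seq_along(legends)) {
    scene <- add_region(scene, sprintf("legend:%d", i),
                        x, y + h - i * lh, w, lh, legend_prims(legends[[i]]))
  }
  scene
}

# ---- body slices -------------------------------------------------------------

body_slice_prims <- function(hm, ridx, cidx, w_in, h_in, dpi) {
  m <- hm$matrix$values[ridx, cidx, drop = FALSE]
  nr <- nrow(m); nc <- ncol(m)
  cols <- map_colors(hm$colors, m)
  tp <- target_pixels(nr, nc, w_in, h_in, dpi)
  strat <- effective_raster_strategy(hm$raster_policy, nr, nc, tp$p_r, tp$p_c)
  if (is.null(strat)) {
    jj <- rep(seq_len(nc), each = nr)
    ii <- rep(seq_len(nr), times = nc)
    out <- prim_rect((jj - 1L) / nc, 1 - ii / nr, 1 / nc, 1 / nr,
                     fill = as.vector(cols))
  } else {
    ras <- rasterize_body_slice(m, hm$colors, hm$raster_policy,
                                min(tp$p_r, nr), min(tp$p_c, nc), hm$seed)
    out <- prim_image(ras, 0, 0, 1, 1)
  }
  if (!is.null(hm$layer_fun) || !is.null(hm$cell_fun)) {
    jj <- rep(seq_len(nc), each = nr)
    ii <- rep(seq_len(nr), times = nc)
    xs <- (jj - 1L) / nc; ys <- 1 - ii / nr
    vals <- as.vector(m); cl <- as.vector(cols)
    oi <- ridx[ii]; oj <- cidx[jj]
    if (!is.null(hm$layer_fun)) {
      pr <- hm$layer_fun(oi, oj, vals, cl, xs, ys, rep(1 / nc, length(xs)),
                         rep(1 / nr, length(xs)))
      if (!is.null(pr)) out <- prims_concat(out, pr)
    }
    if (!is.null(hm$cell_fun)) {
      for (q in seq_along(ii)) {
        pr <- hm$cell_fun(oi[q], oj[q], vals[q], cl[q], xs[q], ys[q],
                          1 / nc, 1 / nr)
        if (!is.null(pr)) out <- prims_concat(out, pr)
      }
    }
  }
  out
}

# ---- dendrogram drawing ------------------------------------------------------

# Segments of a dendrogram in a unit box: leaves on the u axis in display
# order (slice_items gives original indices in display order), heights scaled
# to [0, 1]. orient "top": u along x, root up; "left": u along y (top-down),
# root at x = 0.
dend_prims <- function(dend, slice_items, orient = c("top", "left")) {
  orient <- match.arg(orient)
  n <- length(slice_items)
  hmax <- as.numeric(attr(dend, "height"))
  if (!is.finite(hmax) || hmax <= 0) hmax <- 1
  segs <- list()
  rec <- function(node) {
    if (is.leaf(node)) {
      pos <- match(as.integer(node), slice_items)
      return(list(u = (pos - 0.5) / n, h = 0))
    }
    l <- rec(node[[1L]]); r <- rec(node[[2L]])
    h <- as.numeric(attr(node, "height")) / hmax
    segs[[length(segs) + 1L]] <<- c(l$u, l$h, l$u, h)
    segs[[length(segs) + 1L]] <<- c(r$u, r$h, r$u, h)
    segs[[length(segs) + 1L]] <<- c(l$u, h, r$u, h)
    list(u = (l$u + r$u) / 2, h = h)
  }
  rec(dend)
  s <- do.call(rbind, segs)
  if (orient == "top") {
    prim_segment(s[, 1L], s[, 2L], s[, 3L], s[, 4L], lwd = 0.7)
  } else {
    prim_segment(1 - s[, 2L], 1 - s[, 1L], 1 - s[, 4L], 1 - s[, 3L], lwd = 0.7)
  }
}

# ---- drawing and decoration --------------------------------------------------

#' Draw a heatmap model to a file
#'
#' Composes the scene and writes it as SVG (serialized by the package itself,
#' byte-deterministic for a given model), PNG or PDF (via the corresponding
#' graphics device).
#'
#' @param model A `heat_map` or `hm_list` (or an already composed `hm_scene`).
#' @param file Output path; the format is inferred from the extension unless
#'   `format` is given.
#' @param format `"svg"`, `"png"` or `"pdf"`.
#' @param width,height Device size in inches.
#' @param dpi Resolution for PNG output and rasterization decisions.
#' @return The composed `hm_scene`, invisibly.
#' @export
draw <- function(model, file = NULL, format = NULL, width = 7, height = 7,
                 dpi = 100) {
  scene <- if (inherits(model, "hm_scene")) model
           else compose_scene(model, width, height, dpi)
  if (!is.null(file)) {
    format <- format %||% tolower(tools::file_ext(file))
    write_scene(scene, file, format, dpi)
  }
  invisible(scene)
}

#' Write a composed scene to a file
#' @param scene An `hm_scene`.
#' @param file Output path.
#' @param format `"svg"`, `"png"` or `"pdf"`.
#' @param dpi Resolution for PNG output.
#' @return `file`, invisibly.
#' @export
write_scene <- function(scene, file, format = c("svg", "png", "pdf"),
                        dpi = 100) {
  format <- match.arg(format)
  dir <- dirname(file)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot write '%s': directory does not exist", file), call. = FALSE)
  }
  if (format == "svg") {
    write_scene_svg(scene, file)
  } else {
    write_scene_device(scene, file, format, dpi)
  }
  invisible(file)
}

#' Add graphics to a recorded component region
#'
#' Every heatmap component keeps its plotting region in the scene registry
#' after drawing; `decorate()` goes back to a named region and overlays
#' self-defined graphics in that region's coordinate frame (the unit box).
#' Prior content is retained.
#'
#' @param scene An `hm_scene`.
#' @param region_name A name from [scene_regions()].
#' @param fun `function(region)` returning primitives (the region argument
#'   carries `x`, `y`, `w`, `h` in inches).
#' @return The updated scene.
#' @export
decorate <- function(scene, region_name, fun) {
  stopifnot(inherits(scene, "hm_scene"))
  if (!region_name %in% names(scene$regions)) {
    stop(sprintf("unknown region '%s'; available regions: %s", region_name,
                 paste(names(scene$regions), collapse = ", ")), call. = FALSE)
  }
  pr <- fun(scene$regions[[region_name]])
  if (!is.null(pr)) {
    scene$prims[[region_name]] <- prims_concat(scene$prims[[region_name]], pr)
  }
  scene
}

#' Layout tree of a model at a device size
#'
#' @param model A `heat_map` or `hm_list`.
#' @param width,height Device size in inches.
#' @param dpi Device resolution.
#' @return Named list of regions (`x`, `y`, `w`, `h` in inches).
#' @export
heatmap_layout <- function(model, width = 7, height = 7, dpi = 100) {
  scene_regions(compose_scene(model, width, height, dpi))
}
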