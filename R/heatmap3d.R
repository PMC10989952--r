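# 3D bar heatmap: grid cells become bars projected obliquely onto the plate.

#' Back-to-front bar drawing order for a 3D heatmap
#'
#' With a cavalier oblique projection whose depth offset points up-right,
#' row 1 sits at the back of the plate. Painting back-to-front (and, within a
#' row, right-to-left so the left neighbour overpaints the depth overhang)
#' makes nearer bars occlude farther ones.
#'
#' @param n_r,n_c Matrix dimensions.
#' @return Data frame with columns `i`, `j` in drawing order.
#' @export
bar_draw_order <- function(n_r, n_c) {
  g <- expand.grid(j = rev(seq_len(n_c)), i = seq_len(n_r))
  data.frame(i = g$i, j = g$j)
}

#' Three-dimensional heatmap
#'
#' Converts heatmap grids to 3D bars drawn as projections onto the 2D plate:
#' bar height is proportional to the cell value and the face color comes from
#' the color mapping (mapping both encodings to the data is recommended).
#' Bars are drawn back-to-front so nearer bars occlude farther ones.
#'
#' @param m Non-negative numeric matrix (negative matrices are shifted to
#'   non-negative with a logged offset).
#' @param colors Optional continuous `color_mapping`.
#' @param angle Projection angle of the depth axis in degrees (default 45,
#'   cavalier oblique).
#' @param depth_scale Foreshortening of the depth axis (default 0.5).
#' @param bar_rel Maximum bar height as a fraction of the panel (default 0.4).
#' @return An `hm_scene` with a single `body3d` region.
#' @export
heatmap_3d <- function(m, colors = NULL, angle = 45, depth_scale = 0.5,
                       bar_rel = 0.4) {
  if (is_value_matrix(m)) m <- m$values
  if (!is.numeric(m)) stop("`m` must be numeric", call. = FALSE)
  if (anyNA(m)) m[is.na(m)] <- 0
  if (any(m < 0)) {
    off <- min(m)
    hc_log(sprintf("heatmap_3d: shifting values by %+g to make them non-negative", -off))
    m <- m - off
  }
  if (is.null(colors)) colors <- auto_color_mapping(value_matrix(m))
  n_r <- nrow(m); n_c <- ncol(m)
  vmax <- max(m)
  rad <- angle * pi / 180
  # one depth unit = one row band of the plate
  band <- 1 / (n_r + 1)
  ddx <- depth_scale * cos(rad) * band
  ddy <- depth_scale * sin(rad) * band
  total_dx <- ddx * n_r
  cw <- (1 - total_dx) / n_c
  hmax <- bar_rel
  ord <- bar_draw_order(n_r, n_c)
  prims <- empty_prims()
  for (q in seq_len(nrow(ord))) {
    i <- ord$i[q]; j <- ord$j[q]
    d <- n_r - i                       # depth: row 1 farthest
    x <- (j - 1L) * cw + d * ddx
    y <- 0.05 + d * ddy
    hbar <- if (vmax > 0) m[i, j] / vmax * hmax else 0
    fc <- map_colors(colors, m[i, j])
    prims <- prims_concat(prims,
      # top face
      prim_polygon(c(x, x + cw, x + cw + ddx, x + ddx),
                   c(y + hbar, y + hbar, y + hbar + ddy, y + hbar + ddy),
                   fill = shade_color(fc, 0.85), col = "#333333"),
      # right face
      prim_polygon(c(x + cw, x + cw + ddx, x + cw + ddx, x + cw),
                   c(y, y + ddy, y + hbar + ddy, y + hbar),
                   fill = shade_color(fc, 0.6), col = "#333333"))
    if (hbar > 0) {
      prims <- prims_concat(prims,
        prim_rect(x, y, cw, hbar, fill = fc, col = "#333333", lwd = 0.4))
    }
  }
  scene <- new_scene(6, 6)
  add_region(scene, "body3d", 0.3, 0.3, 5.4, 5.4, prims)
}

shade_color <- function(hex, factor) {
  m <- col2rgb(hex) / 255 * factor
  rgb(m[1L, ], m[2L, ], m[3L, ])
}
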