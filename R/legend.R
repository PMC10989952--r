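#' Build legends for a set of heatmaps
#'
#' One continuous legend per distinct continuous mapping (ticks exactly at the
#' breaks) and one discrete legend per distinct categorical mapping; heatmaps
#' sharing a mapping share a single merged legend.
#'
#' @param models List of `heat_map` objects (or `color_mapping`s).
#' @return List of legend descriptors (`title`, `cm`).
#' @export
build_legends <- function(models) {
  if (inherits(models, "heat_map") || inherits(models, "color_mapping")) {
    models <- list(models)
  }
  seen <- character(0)
  out <- list()
  for (m in models) {
    cm <- if (is_heat_map(m)) m$colors else m
    if (!inherits(cm, "color_mapping")) next
    key <- cm_key(cm)
    if (key %in% seen) next
    seen <- c(seen, key)
    title <- if (is_heat_map(m)) m$name else ""
    out[[length(out) + 1L]] <- list(title = title, cm = cm)
  }
  out
}

# Primitives for one legend in a unit box.
legend_prims <- function(legend) {
  cm <- legend$cm
  out <- prim_text(0, 0.97, legend$title, cex = 0.8, hjust = 0, vjust = 1)
  if (cm$mode == "continuous") {
    nstrip <- 48L
    b0 <- cm$breaks[1L]; b1 <- cm$breaks[length(cm$breaks)]
    mids <- b0 + (seq_len(nstrip) - 0.5) / nstrip * (b1 - b0)
    cols <- map_colors(cm, mids)
    y0 <- 0.08; y1 <- 0.88
    ys <- y0 + (seq_len(nstrip) - 1L) / nstrip * (y1 - y0)
    out <- prims_concat(out,
      prim_rect(0.05, ys, 0.25, (y1 - y0) / nstrip, fill = cols),
      prim_rect(0.05, y0, 0.25, y1 - y0, fill = NA_character_,
                col = "#000000", lwd = 0.5))
    tick_y <- y0 + (cm$breaks - b0) / (b1 - b0) * (y1 - y0)
    out <- prims_concat(out,
      prim_segment(0.30, tick_y, 0.34, tick_y),
      prim_text(0.38, tick_y, format(cm$breaks, trim = TRUE), cex = 0.65,
                hjust = 0))
  } else {
    k <- length(cm$levels)
    y <- 0.9 - (seq_len(k) - 1L) * min(0.16, 0.82 / k)
    h <- min(0.12, 0.6 / k)
    out <- prims_concat(out,
      prim_rect(0.05, y - h, 0.18, h, fill = unname(cm$colors),
                col = "#000000", lwd = 0.3),
      prim_text(0.3, y - h / 2, cm$levels, cex = 0.65, hjust = 0))
  }
  out
}
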