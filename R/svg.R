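# Deterministic SVG serialization: the scene is written as plain text with
# fixed number formatting and no timestamps or generated ids, so the same
# model always produces byte-identical output.

fmt <- function(x) sprintf("%.3f", x)

svg_color <- function(x) ifelse(is.na(x), "none", x)

# Place region-local primitives into device inches (y still bottom-up).
place_prims <- function(p, rg) {
  q <- prims_into(p, rg$x, rg$y, rg$w, rg$h)
  # point radii are region-fraction of the smaller region side
  q$points$r <- p$points$r * min(rg$w, rg$h)
  q
}

write_scene_svg <- function(scene, file) {
  W <- scene$width * 72; H <- scene$height * 72
  con <- file(file, open = "wb")
  on.exit(close(con))
  out <- function(lines) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  out(c('<?xml version="1.0" encoding="UTF-8"?>',
        sprintf('<svg xmlns="http://www.w3.org/2000/svg" xmlns:xlink="http://www.w3.org/1999/xlink" width="%spt" height="%spt" viewBox="0 0 %s %s">',
                fmt(W), fmt(H), fmt(W), fmt(H)),
        sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
                fmt(W), fmt(H))))
  for (nm in names(scene$regions)) {
    p <- place_prims(scene$prims[[nm]], scene$regions[[nm]])
    out(sprintf('<g id="%s">', xml_escape(nm)))
    if (nrow(p$rects)) {
      r <- p$rects
      stroke <- ifelse(is.na(r$col), "",
                       sprintf(' stroke="%s" stroke-width="%s"', r$col, fmt(r$lwd)))
      out(sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
                  fmt(r$x * 72), fmt(H - (r$y + r$h) * 72),
                  fmt(pmax(r$w, 0) * 72), fmt(pmax(r$h, 0) * 72),
                  svg_color(r$fill), stroke))
    }
    for (im in p$images) {
      out(sprintf('<image x="%s" y="%s" width="%s" height="%s" preserveAspectRatio="none" xlink:href="data:image/png;base64,%s"/>',
                  fmt(im$x * 72), fmt(H - (im$y + im$h) * 72),
                  fmt(im$w * 72), fmt(im$h * 72), raster_to_base64(im$raster)))
    }
    for (pg in p$polygons) {
      pts <- paste(sprintf("%s,%s", fmt(pg$x * 72), fmt(H - pg$y * 72)),
                   collapse = " ")
      stroke <- if (is.na(pg$col)) "" else sprintf(' stroke="%s" stroke-width="0.75"', pg$col)
      out(sprintf('<polygon points="%s" fill="%s"%s/>', pts,
                  svg_color(pg$fill), stroke))
    }
    if (nrow(p$segments)) {
      s <- p$segments
      out(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
                  fmt(s$x0 * 72), fmt(H - s$y0 * 72), fmt(s$x1 * 72),
                  fmt(H - s$y1 * 72), svg_color(s$col), fmt(s$lwd)))
    }
    if (nrow(p$points)) {
      pt <- p$points
      out(sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                  fmt(pt$x * 72), fmt(H - pt$y * 72), fmt(pt$r * 72),
                  svg_color(pt$fill)))
    }
    if (nrow(p$texts)) {
      tx <- p$texts
      anchor <- ifelse(tx$hjust < 0.25, "start",
                       ifelse(tx$hjust > 0.75, "end", "middle"))
      rotat <- ifelse(tx$rot == 0, "",
                      sprintf(' transform="rotate(%s %s %s)"', fmt(-tx$rot),
                              fmt(tx$x * 72), fmt(H - tx$y * 72)))
      out(sprintf('<text x="%s" y="%s" font-size="%s" font-family="sans-serif" fill="%s" text-anchor="%s" dy="%sem"%s>%s</text>',
                  fmt(tx$x * 72), fmt(H - tx$y * 72), fmt(tx$cex * 10),
                  svg_color(tx$col), anchor, fmt(tx$vjust * 0.72), rotat,
                  xml_escape(tx$label)))
    }
    out('</g>')
  }
  out('</svg>')
  invisible(file)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

raster_to_base64 <- function(hexm) {
  ch <- col2rgb(hexm) / 255
  arr <- array(0, dim = c(nrow(hexm), ncol(hexm), 3L))
  arr[, , 1L] <- matrix(ch[1L, ], nrow(hexm), ncol(hexm))
  arr[, , 2L] <- matrix(ch[2L, ], nrow(hexm), ncol(hexm))
  arr[, , 3L] <- matrix(ch[3L, ], nrow(hexm), ncol(hexm))
  base64enc::base64encode(png::writePNG(arr))
}

# ---- grid-device rendering (png/pdf) ----------------------------------------

#' @importFrom grDevices png pdf dev.off as.raster
write_scene_device <- function(scene, file, format, dpi = 100) {
  if (format == "png") {
    png(file, width = scene$width, height = scene$height, units = "in",
        res = dpi)
  } else {
    pdf(file, width = scene$width, height = scene$height)
  }
  on.exit(dev.off())
  grid::grid.newpage()
  for (nm in names(scene$regions)) {
    rg <- scene$regions[[nm]]
    p <- scene$prims[[nm]]
    if (prims_is_empty(p)) next
    grid::pushViewport(grid::viewport(
      x = grid::unit(rg$x, "in"), y = grid::unit(rg$y, "in"),
      width = grid::unit(max(rg$w, 1e-6), "in"),
      height = grid::unit(max(rg$h, 1e-6), "in"),
      just = c("left", "bottom"), clip = "off"))
    if (nrow(p$rects)) {
      r <- p$rects
      grid::grid.rect(x = r$x, y = r$y, width = r$w, height = r$h,
                      just = c("left", "bottom"), default.units = "npc",
                      gp = grid::gpar(fill = ifelse(is.na(r$fill), NA, r$fill),
                                      col = ifelse(is.na(r$col), NA, r$col),
                                      lwd = pmax(r$lwd, 0.1)))
    }
    for (im in p$images) {
      grid::grid.raster(as.raster(im$raster), x = im$x, y = im$y,
                        width = im$w, height = im$h,
                        just = c("left", "bottom"), default.units = "npc",
                        interpolate = FALSE)
    }
    for (pg in p$polygons) {
      grid::grid.polygon(x = pg$x, y = pg$y, default.units = "npc",
                         gp = grid::gpar(fill = ifelse(is.na(pg$fill), NA, pg$fill),
                                         col = ifelse(is.na(pg$col), NA, pg$col)))
    }
    if (nrow(p$segments)) {
      s <- p$segments
      grid::grid.segments(s$x0, s$y0, s$x1, s$y1, default.units = "npc",
                          gp = grid::gpar(col = s$col, lwd = pmax(s$lwd, 0.1)))
    }
    if (nrow(p$points)) {
      pt <- p$points
      grid::grid.circle(pt$x, pt$y,
                        r = grid::unit(pt$r * min(rg$w, rg$h), "in"),
                        default.units = "npc",
                        gp = grid::gpar(fill = pt$fill, col = NA))
    }
    if (nrow(p$texts)) {
      tx <- p$texts
      for (q in seq_len(nrow(tx))) {
        grid::grid.text(tx$label[q], x = tx$x[q], y = tx$y[q],
                        default.units = "npc", rot = tx$rot[q],
                        just = c(tx$hjust[q], tx$vjust[q]),
                        gp = grid::gpar(cex = tx$cex[q], col = tx$col[q]))
      }
    }
    grid::popViewport()
  }
  invisible(file)
}
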