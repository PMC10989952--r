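# Drawing primitives are the currency between model code and output backends.
# A primitive set is a list of typed tables/lists in *region-local normalized*
# coordinates: x grows right, y grows up, both in [0, 1] of the region unless
# a renderer deliberately overflows (joyplots may). Backends place them into
# device inches and serialize (SVG) or draw (grid devices).

empty_prims <- function() {
  list(
    rects = data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                       h = numeric(0), fill = character(0), col = character(0),
                       lwd = numeric(0), stringsAsFactors = FALSE),
    segments = data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                          y1 = numeric(0), col = character(0), lwd = numeric(0),
                          stringsAsFactors = FALSE),
    points = data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                        fill = character(0), col = character(0),
                        stringsAsFactors = FALSE),
    texts = data.frame(x = numeric(0), y = numeric(0), label = character(0),
                       cex = numeric(0), col = character(0), rot = numeric(0),
                       hjust = numeric(0), vjust = numeric(0),
                       stringsAsFactors = FALSE),
    polygons = list(),  # each: list(x, y, fill, col)
    images = list()     # each: list(x, y, w, h, raster = hex color matrix)
  )
}

prim_rect <- function(x, y, w, h, fill = "#000000", col = NA_character_,
                      lwd = 0) {
  k <- max(length(x), length(y), length(w), length(h), length(fill))
  p <- empty_prims()
  p$rects <- data.frame(x = rep_len(x, k), y = rep_len(y, k),
                        w = rep_len(w, k), h = rep_len(h, k),
                        fill = rep_len(as.character(fill), k),
                        col = rep_len(as.character(col), k),
                        lwd = rep_len(lwd, k), stringsAsFactors = FALSE)
  p
}

prim_segment <- function(x0, y0, x1, y1, col = "#000000", lwd = 1) {
  k <- max(length(x0), length(y0), length(x1), length(y1))
  p <- empty_prims()
  p$segments <- data.frame(x0 = rep_len(x0, k), y0 = rep_len(y0, k),
                           x1 = rep_len(x1, k), y1 = rep_len(y1, k),
                           col = rep_len(as.character(col), k),
                           lwd = rep_len(lwd, k), stringsAsFactors = FALSE)
  p
}

prim_point <- function(x, y, r = 0.02, fill = "#000000", col = NA_character_) {
  k <- max(length(x), length(y))
  p <- empty_prims()
  p$points <- data.frame(x = rep_len(x, k), y = rep_len(y, k),
                         r = rep_len(r, k), fill = rep_len(as.character(fill), k),
                         col = rep_len(as.character(col), k),
                         stringsAsFactors = FALSE)
  p
}

prim_text <- function(x, y, label, cex = 1, col = "#000000", rot = 0,
                      hjust = 0.5, vjust = 0.5) {
  k <- max(length(x), length(y), length(label))
  p <- empty_prims()
  p$texts <- data.frame(x = rep_len(x, k), y = rep_len(y, k),
                        label = rep_len(as.character(label), k),
                        cex = rep_len(cex, k), col = rep_len(as.character(col), k),
                        rot = rep_len(rot, k), hjust = rep_len(hjust, k),
                        vjust = rep_len(vjust, k), stringsAsFactors = FALSE)
  p
}

prim_polygon <- function(x, y, fill = "#808080", col = NA_character_) {
  p <- empty_prims()
  p$polygons <- list(list(x = x, y = y, fill = as.character(fill),
                          col = as.character(col)))
  p
}

prim_image <- function(raster, x = 0, y = 0, w = 1, h = 1) {
  p <- empty_prims()
  p$images <- list(list(x = x, y = y, w = w, h = h, raster = raster))
  p
}

prims_concat <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  out <- empty_prims()
  for (s in sets) {
    out$rects <- rbind(out$rects, s$rects)
    out$segments <- rbind(out$segments, s$segments)
    out$points <- rbind(out$points, s$points)
    out$texts <- rbind(out$texts, s$texts)
    out$polygons <- c(out$polygons, s$polygons)
    out$images <- c(out$images, s$images)
  }
  out
}

prims_is_empty <- function(p) {
  nrow(p$rects) == 0L && nrow(p$segments) == 0L && nrow(p$points) == 0L &&
    nrow(p$texts) == 0L && length(p$polygons) == 0L && length(p$images) == 0L
}

# Affine-map region-local primitives into a sub-rectangle of the region
# (sub given in local coordinates). Used to pack slice renderings.
prims_into <- function(p, x, y, w, h) {
  q <- p
  q$rects$x <- x + p$rects$x * w; q$rects$y <- y + p$rects$y * h
  q$rects$w <- p$rects$w * w; q$rects$h <- p$rects$h * h
  q$segments$x0 <- x + p$segments$x0 * w; q$segments$y0 <- y + p$segments$y0 * h
  q$segments$x1 <- x + p$segments$x1 * w; q$segments$y1 <- y + p$segments$y1 * h
  q$points$x <- x + p$points$x * w; q$points$y <- y + p$points$y * h
  q$texts$x <- x + p$texts$x * w; q$texts$y <- y + p$texts$y * h
  q$polygons <- lapply(p$polygons, function(pg) {
    pg$x <- x + pg$x * w; pg$y <- y + pg$y * h; pg
  })
  q$images <- lapply(p$images, function(im) {
    im$x <- x + im$x * w; im$y <- y + im$y * h
    im$w <- im$w * w; im$h <- im$h * h; im
  })
  q
}
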