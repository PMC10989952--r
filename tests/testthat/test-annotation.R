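# Annotation blocks, renderers, and the reorder/split commutation contract.

make_all_tracks <- function(n = 10, seed = 2) {
  set.seed(seed)
  series <- lapply(seq_len(n), function(i) rnorm(20, mean = i / 2))
  list(
    simple = anno_simple(runif(n)),
    simple_cat = anno_simple(sample(letters[1:3], n, TRUE)),
    points = anno_points(runif(n)),
    lines = anno_lines(rnorm(n)),
    smoothed_lines = anno_smooth(rnorm(n) + seq_len(n) / 3),
    barplot = anno_barplot(runif(n)),
    barplot_stacked = anno_barplot(matrix(runif(3 * n), n, 3)),
    percent = anno_percent(runif(n)),
    boxplot = anno_boxplot(series[seq_len(n)]),
    text = anno_text(sprintf("it%02d", seq_len(n))),
    histogram = anno_histogram(series[seq_len(n)]),
    violin = anno_violin(series[seq_len(n)]),
    joyplot = anno_joyplot(series[seq_len(n)]),
    horizon = anno_horizon(series[seq_len(n)], n_bands = 3),
    mark = anno_mark(at = c(2L, 5L, 9L), labels = c("a", "b", "c")),
    link = anno_link(at = list(1:3, 6:9))
  )
}

test_that("name-value pairs build tracks in call order", {
  set.seed(1)
  ha <- annotation_block(
    foo = runif(10),
    bar = sample(letters[1:4], 10, replace = TRUE),
    pt = anno_points(runif(10)),
    txt = anno_text(month.name[1:10]),
    axis = "column")
  expect_length(ha$tracks, 4L)
  expect_identical(unname(vapply(ha$tracks, function(t) t$name, character(1))),
                   c("foo", "bar", "pt", "txt"))
  expect_identical(unname(vapply(ha$tracks, function(t) t$kind, character(1))),
                   c("simple", "simple", "points", "text"))
})

test_that("an empty block is valid and has zero size", {
  b <- annotation_block(axis = "row")
  expect_length(b$tracks, 0L)
  expect_equal(block_size(b), 0)
})

test_that("payload length mismatches and duplicate names are rejected", {
  hm <- heat_map(matrix(rnorm(40), 10, 4))
  expect_error(
    heat_map(matrix(rnorm(40), 10, 4),
             top_annotation = annotation_block(v = runif(9), axis = "column")),
    "length 9")
  expect_error(annotation_block(a = 1:3, a = 4:6, axis = "row"), "duplicated")
})

test_that("every built-in annotation kind has a registered renderer", {
  expect_setequal(annotation_kinds(),
                  c("simple", "image", "points", "lines", "smoothed_lines",
                    "barplot", "percent", "boxplot", "text", "histogram",
                    "violin", "joyplot", "horizon", "mark", "link", "textbox"))
})

test_that("simple track colors follow the permuted payload", {
  tr <- anno_simple(c(1, 2, 3),
                    colors = color_mapping(c(1, 3), c("black", "white")))
  tr$axis <- "column"
  pr <- render_track(tr, order = c(3L, 1L, 2L))
  # display sequence is payload[order] = (3, 1, 2)
  expect_identical(pr$rects$fill,
                   as.vector(map_colors(tr$colors, c(3, 1, 2))))
})

test_that("rendering commutes with permutation and splitting for all kinds", {
  n <- 10
  tracks <- make_all_tracks(n)
  set.seed(33)
  order <- sample(n)
  # link subsets must stay contiguous in display order, so the link track is
  # exercised with a block permutation of its subsets
  link_order <- c(6:9, 10L, 3:1, 5L, 4L)
  sizes <- c(4L, 6L)
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    ord <- if (nm == "link") link_order else order
    for (axis in c("column", "row")) {
      tr$axis <- axis
      a <- render_track(tr, ord, sizes)
      b <- render_track(heatcompose:::permute_track(tr, ord), seq_len(n), sizes)
      expect_identical(a, b, label = sprintf("%s (%s axis)", nm, axis))
    }
  }
})

test_that("a constant boxplot payload degenerates to a zero-IQR box", {
  tr <- anno_boxplot(list(rep(5, 10), c(1, 2, 3)))
  tr$axis <- "column"
  pr <- render_track(tr, 1:2)
  box1 <- pr$rects[1, ]
  expect_equal(box1$h, 0, tolerance = 1e-12)  # zero IQR
})

test_that("stacked barplot heights sum to the row totals", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  tr <- anno_barplot(m)
  tr$axis <- "column"
  pr <- render_track(tr, 1:2)
  rng <- heatcompose:::track_value_range(tr)
  for (item in 1:2) {
    rects <- pr$rects[seq(item, nrow(pr$rects), by = 2), ]
    total_h <- sum(rects$h)
    want <- sum(m[item, ]) / diff(rng)
    expect_equal(total_h, want, tolerance = 1e-9)
  }
})

test_that("percent annotation prints the rendered fraction to one decimal", {
  tr <- anno_percent(c(0.123, 0.5, 1))
  tr$axis <- "column"
  pr <- render_track(tr, 1:3)
  expect_identical(pr$texts$label, c("12.3%", "50.0%", "100.0%"))
  # bar extents proportional to the fraction
  expect_equal(pr$rects$h / pr$rects$h[3], c(0.123, 0.5, 1), tolerance = 1e-9)
})

test_that("horizon bands equal the cut-and-stack oracle", {
  # triangle wave peaking at exactly 2 bands
  H <- 1.5
  v <- c(0, H, 2 * H, H, 0)
  hb <- horizon_bands(v, n_bands = 2, band_height = H)
  # oracle: cut the area chart at multiples of H and stack
  band1 <- pmin(v, H) / H
  band2 <- pmin(pmax(v - H, 0), H) / H
  expect_equal(hb$pos[1, ], band1)
  expect_equal(hb$pos[2, ], band2)
  # at the peak band 2 exactly overlays band 1 (both full)
  expect_equal(hb$pos[1, 3], hb$pos[2, 3])
  expect_equal(hb$pos[2, 3], 1)
})

test_that("numeric kinds reject non-numeric payloads and unknown kinds error", {
  tr <- anno_points(1:3)
  tr$payload <- letters[1:3]
  tr$axis <- "column"
  expect_error(render_track(tr, 1:3), "numeric")
  bad <- heatcompose:::new_track("nope", 1:3)
  bad$axis <- "column"
  expect_error(render_track(bad, 1:3), "unknown annotation kind")
})

test_that("smoothed lines follow a loess fit of the ordered values", {
  set.seed(4)
  y <- sin(seq(0, pi, length.out = 12)) + rnorm(12, sd = 0.05)
  tr <- anno_smooth(y)
  tr$axis <- "column"
  pr <- render_track(tr, 1:12)
  fit <- predict(loess(y ~ x, data.frame(x = 1:12, y = y), span = 0.75,
                       degree = 2), 1:12)
  rng <- heatcompose:::track_value_range(tr)
  want <- (fit - rng[1]) / diff(rng)
  # segment endpoints hit the fitted values
  expect_equal(pr$segments$y0, want[-12], tolerance = 1e-9)
  expect_equal(pr$segments$y1, want[-1], tolerance = 1e-9)
})
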