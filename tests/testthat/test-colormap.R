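# Exact value -> color mapping: anchors, clamping, interpolation spaces.

test_that("anchor values map to their anchor colors bit-exactly", {
  cm <- color_mapping(c(0, 1), c("black", "white"))
  expect_identical(map_colors(cm, 0), "#000000")
  expect_identical(map_colors(cm, 1), "#FFFFFF")
  cm2 <- color_mapping(c(-2, 0, 2), c("blue", "white", "red"), space = "Lab")
  expect_identical(map_colors(cm2, c(-2, 0, 2)),
                   c("#0000FF", "#FFFFFF", "#FF0000"))
})

test_that("values outside the break range clamp to the end colors", {
  cm <- color_mapping(c(-2, 0, 2), c("blue", "white", "red"))
  expect_identical(map_colors(cm, -5), "#0000FF")
  expect_identical(map_colors(cm, 100), "#FF0000")
  # clamp idempotence over a grid
  x <- seq(-10, 10, by = 0.37)
  clamped <- pmin(pmax(x, -2), 2)
  expect_identical(map_colors(cm, x), map_colors(cm, clamped))
})

test_that("sRGB interpolation matches per-channel linear arithmetic", {
  cm <- color_mapping(c(0, 1), c("black", "white"), space = "sRGB")
  got <- col2rgb(map_colors(cm, 0.5))[, 1]
  expect_equal(unname(got), rep(round(255 * 0.5), 3), tolerance = 1 / 255)
  # arbitrary colors at arbitrary t, channelwise oracle
  cm2 <- color_mapping(c(0, 1), c("#102030", "#90A0B0"), space = "sRGB")
  for (t in c(0.25, 0.5, 0.8)) {
    want <- (1 - t) * c(0x10, 0x20, 0x30) + t * c(0x90, 0xA0, 0xB0)
    got <- col2rgb(map_colors(cm2, t))[, 1]
    expect_true(all(abs(got - want) <= 1))
  }
})

test_that("Lab interpolation matches a forward/backward conversion oracle", {
  cm <- color_mapping(c(0, 1), c("#123456", "#C0FFEE"), space = "Lab")
  lab <- grDevices::convertColor(t(col2rgb(c("#123456", "#C0FFEE"))) / 255,
                                 from = "sRGB", to = "Lab")
  for (t in c(0.3, 0.5, 0.75)) {
    mid <- (1 - t) * lab[1, ] + t * lab[2, ]
    want <- grDevices::convertColor(matrix(mid, 1), from = "Lab", to = "sRGB")
    got <- col2rgb(map_colors(cm, t))[, 1] / 255
    expect_equal(unname(got), unname(as.vector(want)), tolerance = 2 / 255)
  }
})

test_that("Lab ramp agrees with an independent color-ramp implementation", {
  skip_if_not_installed("circlize")
  cm <- color_mapping(c(-1, 0, 1), c("blue", "#EEEEEE", "red"), space = "Lab")
  f <- circlize::colorRamp2(c(-1, 0, 1), c("blue", "#EEEEEE", "red"))
  x <- seq(-1, 1, by = 0.1)
  got <- t(col2rgb(map_colors(cm, x)))
  want <- t(col2rgb(f(x)))
  expect_true(max(abs(got - want)) <= 2)
})

test_that("channels are monotone within an interval in the mapping space", {
  cm <- color_mapping(c(0, 1), c("#203040", "#D0C0B0"), space = "sRGB")
  x <- seq(0, 1, length.out = 41)
  ch <- t(col2rgb(map_colors(cm, x)))
  for (k in 1:3) {
    d <- diff(ch[, k])
    expect_true(all(d >= -1e-9) || all(d <= 1e-9))
  }
})

test_that("identical breaks and colors give identical mappings", {
  a <- color_mapping(c(0, 5, 10), c("navy", "white", "firebrick"))
  b <- color_mapping(c(0, 5, 10), c("navy", "white", "firebrick"))
  x <- runif(100, -5, 15)
  expect_identical(map_colors(a, x), map_colors(b, x))
})

test_that("categorical mappings map levels exactly and reject unknowns", {
  cm <- discrete_color_mapping(c(a = "red", b = "blue"))
  expect_identical(map_colors(cm, c("b", "a", "b")),
                   c("#0000FF", "#FF0000", "#0000FF"))
  expect_error(map_colors(cm, c("a", "zz")), "zz")
  expect_identical(map_colors(cm, NA_character_), "#808080")
})

test_that("missing and empty inputs are handled", {
  cm <- color_mapping(c(0, 1), c("black", "white"))
  expect_identical(map_colors(cm, NA_real_), "#808080")
  out <- map_colors(cm, matrix(numeric(0), 0, 3))
  expect_identical(dim(out), c(0L, 3L))
})

test_that("invalid break specifications are rejected", {
  expect_error(color_mapping(c(1, 0), c("black", "white")), "increasing")
  expect_error(color_mapping(c(0, 0, 1), c("black", "grey", "white")), "increasing")
  expect_error(color_mapping(c(0, 1), "black"), "length")
  expect_error(color_mapping(0, "black"), "length")
})

test_that("the default discrete palette is deterministic over level sets", {
  a <- default_discrete_mapping(c("x", "y", "z"))
  b <- default_discrete_mapping(c("z", "x", "y"))
  expect_identical(a$colors, b$colors)
})

test_that("shapes are preserved by vectorized mapping", {
  cm <- color_mapping(c(0, 1), c("black", "white"))
  m <- matrix(runif(12), 3, 4)
  out <- map_colors(cm, m)
  expect_identical(dim(out), dim(m))
})
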