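# Concatenation, main-heatmap alignment, layout geometry, drawing, hooks.

mk_hm <- function(n = 12, m = 5, name = "a", seed = 1, ...) {
  set.seed(seed)
  heat_map(matrix(rnorm(n * m), n, m,
                  dimnames = list(sprintf("r%02d", 1:n), sprintf("c%d", 1:m))),
           name = name, ...)
}

test_that("horizontal concatenation validates the aligned axis", {
  a <- mk_hm(20, 5, "A")
  b <- mk_hm(20, 3, "B", seed = 2)
  ra <- row_annotation(x = anno_points(runif(20)))
  hl <- a + b + ra
  expect_s3_class(hl, "hm_list")
  expect_length(hl$items, 3L)
  expect_identical(hl$main_index, 1L)
  expect_error(mk_hm(20, 5) + mk_hm(19, 5, seed = 3), "mismatch")
})

test_that("the main heatmap defaults to the first numeric heatmap", {
  cat_hm <- heat_map(matrix(sample(letters[1:3], 20, TRUE), 10, 2), name = "cat")
  num_hm <- mk_hm(10, 4, "num")
  hl <- cat_hm + num_hm
  expect_identical(hl$main_index, 2L)
  # explicit override by name
  hl2 <- hm_list(list(num_hm, mk_hm(10, 3, "other", seed = 5)), main = "other")
  expect_identical(hl2$main_index, 2L)
})

test_that("alignment imposes the main order and slices on every item", {
  a <- mk_hm(16, 5, "A", row_km = 2, seed = 7)
  b <- mk_hm(16, 4, "B", seed = 8)                      # own clustering request
  cc <- mk_hm(16, 3, "C", seed = 9, cluster_rows = FALSE)
  hl <- resolve_alignment(a + b + cc)
  o1 <- list_item_order(hl, 1)
  expect_identical(list_item_order(hl, 2), o1)
  expect_identical(list_item_order(hl, 3), o1)
  for (i in 1:3) {
    expect_identical(hl$items[[i]]$resolved$row$sizes, hl$alignment$sizes)
  }
})

test_that("overriding a member's own clustering is logged", {
  a <- mk_hm(10, 4, "A", seed = 1)
  b <- mk_hm(10, 4, "B", seed = 2)   # clusters rows itself -> overridden
  withr::local_options(heatcompose.quiet = FALSE)
  expect_message(resolve_alignment(a + b), "overridden by the main heatmap")
})

test_that("row slices get heights proportional to item counts", {
  hm <- heat_map(matrix(rnorm(9), 3, 3), name = "p",
                 row_split = c("x", "x", "y"), cluster_rows = FALSE,
                 cluster_columns = FALSE, show_row_names = FALSE,
                 show_column_names = FALSE)
  tree <- heatmap_layout(hm, width = 5, height = 5)
  h1 <- tree[["p:body:1:1"]]$h
  h2 <- tree[["p:body:2:1"]]$h
  expect_equal(h1 / h2, 2, tolerance = 1e-9)
})

test_that("width weights allocate body widths in the requested ratio", {
  a <- mk_hm(8, 4, "A", width = 2, show_row_names = FALSE)
  b <- mk_hm(8, 4, "B", width = 1, seed = 2, show_row_names = FALSE)
  cc <- mk_hm(8, 4, "C", width = 1, seed = 3, show_row_names = FALSE)
  tree <- heatmap_layout(a + b + cc, width = 9, height = 5)
  wa <- tree[["A:body:1:1"]]$w
  wb <- tree[["B:body:1:1"]]$w
  wc <- tree[["C:body:1:1"]]$w
  expect_equal(wa / wb, 2, tolerance = 1e-9)
  expect_equal(wb, wc, tolerance = 1e-9)
  # closed-form allocation: flexible space minus fixed parts, split 2:1:1
  expect_equal(wa + wb + wc,
               wa / 2 * 4, tolerance = 1e-9)
})

test_that("leaf regions never overlap (shared borders allowed)", {
  hm <- mk_hm(14, 6, "hm", row_km = 2, seed = 4,
              top_annotation = annotation_block(v = runif(6), axis = "column"))
  tree <- heatmap_layout(hm + mk_hm(14, 3, "B", seed = 5), width = 8, height = 7)
  nms <- names(tree)
  for (i in seq_along(nms)) {
    for (j in seq_len(i - 1)) {
      a <- tree[[i]]; b <- tree[[j]]
      overlap_x <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x)
      overlap_y <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y)
      expect_false(overlap_x > 1e-6 && overlap_y > 1e-6,
                   info = sprintf("%s vs %s", nms[i], nms[j]))
    }
  }
})

test_that("components exceeding the device raise a measured overflow error", {
  hm <- mk_hm(10, 4, top_annotation = annotation_block(
    a = anno_points(runif(4), size = 3), b = anno_points(runif(4), size = 3),
    axis = "column"))
  expect_error(compose_scene(hm, width = 5, height = 5), "exceed the device")
})

test_that("cell hooks fire once per visible cell with correct triples", {
  calls <- list()
  hm <- heat_map(matrix(1:4, 2, 2), name = "h", cluster_rows = FALSE,
                 cluster_columns = FALSE,
                 cell_fun = function(i, j, value, color, x, y, w, h) {
                   calls[[length(calls) + 1]] <<- c(i, j, value)
                   NULL
                 })
  compose_scene(hm, 5, 5)
  expect_length(calls, 4L)
  got <- do.call(rbind, calls)
  expect_setequal(paste(got[, 1], got[, 2], got[, 3]),
                  c("1 1 1", "2 1 2", "1 2 3", "2 2 4"))
})

test_that("layer hooks fire once per body slice", {
  n_calls <- 0L
  hm <- heat_map(matrix(rnorm(36), 12, 3), name = "h",
                 row_split = rep(c("a", "b", "c"), each = 4),
                 layer_fun = function(i, j, value, color, x, y, w, h) {
                   n_calls <<- n_calls + 1L
                   NULL
                 })
  compose_scene(hm, 5, 5)
  expect_identical(n_calls, 3L)
})

test_that("drawing the same model twice gives byte-identical svg", {
  hm <- mk_hm(15, 6, "det", row_km = 2, seed = 6,
              top_annotation = annotation_block(v = runif(6), axis = "column"))
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  draw(hm, f1)
  draw(mk_hm(15, 6, "det", row_km = 2, seed = 6,
             top_annotation = annotation_block(v = runif(6), axis = "column")),
       f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("decoration retains prior content and rejects unknown regions", {
  hm <- mk_hm(6, 4, "d")
  scene <- draw(hm)
  expect_error(decorate(scene, "nonexistent", function(r) NULL),
               "d:body:1:1")
  dec <- decorate(scene, "d:body:1:1",
                  function(r) heatcompose:::prim_segment(0, 0.5, 1, 0.5))
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  write_scene(scene, f1); write_scene(dec, f2)
  l1 <- readLines(f1); l2 <- readLines(f2)
  # non-decorated regions byte-identical: only one extra line in the body group
  expect_identical(setdiff(l1, l2), character(0))
  expect_length(setdiff(l2, l1), 1L)
})

test_that("split rendering equals slice-wise rendering of the submatrices", {
  set.seed(17)
  m <- matrix(rnorm(48), 12, 4)
  cm <- color_mapping(range(m), c("white", "black"))
  split <- rep(c("a", "b"), each = 6)
  hm <- heat_map(m, colors = cm, row_split = split, cluster_columns = FALSE)
  hm <- resolve_heatmap(hm)
  # pixel rendering of each displayed slice at 4 px/cell...
  px <- lapply(1:2, function(r) {
    idx <- hm$resolved$row$slice_items[[r]]
    cidx <- hm$resolved$column$slice_items[[1]]
    heatcompose:::render_body_raster(map_colors(cm, m[idx, cidx, drop = FALSE]),
                                     length(idx) * 4, length(cidx) * 4)
  })
  # ...equals the abutted rendering of the whole displayed matrix
  full_idx <- hm$resolved$row$order
  cidx <- hm$resolved$column$slice_items[[1]]
  full <- heatcompose:::render_body_raster(
    map_colors(cm, m[full_idx, cidx, drop = FALSE]), 12 * 4, 4 * 4)
  expect_identical(rbind(px[[1]], px[[2]]), full)
})

test_that("vertical concatenation aligns columns", {
  a <- heat_map(matrix(rnorm(40), 5, 8), name = "A")
  b <- heat_map(matrix(rnorm(24), 3, 8), name = "B")
  hl <- resolve_alignment(a %v% b)
  expect_identical(hl$direction, "vertical")
  expect_identical(hl$items[[1]]$resolved$column$order,
                   hl$items[[2]]$resolved$column$order)
  f <- tempfile(fileext = ".svg")
  draw(hl, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("legends merge duplicate mappings and tick at breaks", {
  cm <- color_mapping(c(-2, 0, 2), c("blue", "white", "red"))
  a <- heat_map(matrix(rnorm(12), 3, 4), name = "A", colors = cm)
  b <- heat_map(matrix(rnorm(12), 3, 4), name = "B", colors = cm)
  legs <- build_legends(list(a, b))
  expect_length(legs, 1L)
  cat_cm <- default_discrete_mapping(letters[1:4])
  legs2 <- build_legends(list(a, heat_map(matrix(letters[1:4], 2, 2),
                                          name = "C", colors = cat_cm)))
  expect_length(legs2, 2L)
  pr <- heatcompose:::legend_prims(list(title = "x", cm = cat_cm))
  expect_identical(sum(pr$texts$label %in% letters[1:4]), 4L)
  prc <- heatcompose:::legend_prims(list(title = "A", cm = cm))
  expect_identical(sum(prc$texts$label %in% c("-2", "0", "2")), 3L)
})
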