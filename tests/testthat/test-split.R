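# Slice specs and the three splitting mechanisms.

test_that("slice specs must exactly partition the axis", {
  s <- slice_spec(list(1:2, 3L), c("a", "b"), "row")
  expect_equal(s$n, 3L)
  expect_error(slice_spec(list(1:2, 2:3), c("a", "b"), "row"), "overlap")
  expect_error(slice_spec(list(1:2), "a", "row", n = 3), "partition")
  expect_error(slice_spec(list(1:2, 3L), c("a", "a"), "row"), "duplicated")
})

test_that("consensus k-means recovers planted groups exactly", {
  skip_if_not_installed("mclust")
  fx <- fixture_grouped_matrix(n_rows = 40, n_cols = 10, k = 2, delta = 10,
                               seed = 3)
  s <- split_kmeans(fx$matrix, "row", k = 2, repeats = 10, seed = 3)
  membership <- integer(40)
  for (i in seq_along(s$items)) membership[s$items[[i]]] <- i
  expect_equal(mclust::adjustedRandIndex(membership, fx$row_groups), 1)
})

test_that("k equal to the axis size yields singletons", {
  m <- matrix(rnorm(12), 4, 3)
  s <- split_kmeans(m, "row", k = 4, seed = 1)
  expect_true(all(lengths(s$items) == 1L))
})

test_that("a single repeat equals one plain seeded k-means run", {
  set.seed(99)
  m <- matrix(rnorm(60), 20, 3)
  s <- split_kmeans(m, "row", k = 3, repeats = 1, seed = 5)
  plain <- local({ set.seed(5); kmeans(m, centers = 3, nstart = 1)$cluster })
  membership <- integer(20)
  for (i in seq_along(s$items)) membership[s$items[[i]]] <- i
  # same partition up to label permutation
  expect_equal(length(unique(paste(membership, plain))), 3L)
})

test_that("consensus k-means is reproducible for a fixed seed", {
  m <- fixture_grouped_matrix(n_rows = 30, k = 3, seed = 8)$matrix
  a <- split_kmeans(m, "row", k = 3, repeats = 5, seed = 42)
  b <- split_kmeans(m, "row", k = 3, repeats = 5, seed = 42)
  expect_identical(a, b)
})

test_that("factor splits enumerate observed combinations in lexicographic order", {
  s <- split_by_factor(c("a", "a", "b"), "row")
  expect_identical(s$labels, c("a", "b"))
  expect_identical(s$items, list(c(1L, 2L), 3L))
  s2 <- split_by_factor(list(c("a", "b", "a"), c("x", "x", "y")), "row")
  expect_identical(s2$labels, c("a,x", "a,y", "b,x"))
  expect_identical(s2$items, list(1L, 3L, 2L))
  s3 <- split_by_factor(c("z", "z", "z"), "row")
  expect_identical(s3$items, list(1:3))
  expect_error(split_by_factor(c("a", "b"), "row", n = 3), "length")
})

test_that("cutting a simple tree gives the expected two groups", {
  nested <- list(list(1, 2, height = 1), 3, height = 5)
  d <- as_dendrogram_any(nested)
  s <- split_by_cut(d, 2)
  expect_identical(lapply(s$items, sort), list(c(1L, 2L), 3L))
  s_all <- split_by_cut(d, 3)
  expect_true(all(lengths(s_all$items) == 1L))
})

test_that("cut partitions match the connected-component oracle", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(rnorm(16), 8, 2)
    d <- hcluster(m, "row")
    for (k in c(2, 3, 5)) {
      got <- lapply(split_by_cut(d, k)$items, sort)
      want <- cut_oracle(d, k)
      expect_setequal(vapply(got, paste, character(1), collapse = ","),
                      vapply(want, paste, character(1), collapse = ","))
    }
  }
})

test_that("tied merge heights make some group counts unattainable", {
  # four equidistant singletons in pairs: heights 1, 1, then a top merge
  nested <- list(list(1, 2, height = 1), list(3, 4, height = 1), height = 4)
  d <- as_dendrogram_any(nested)
  expect_error(split_by_cut(d, 3), "attainable")
  expect_identical(lengths(split_by_cut(d, 2)$items), c(2L, 2L))
})

test_that("cut partitions are invariant under dendrogram reordering", {
  set.seed(31)
  m <- matrix(rnorm(14), 7, 2)
  d <- hcluster(m, "row")
  r <- reorder_dendrogram(d, rnorm(7))
  for (k in 2:4) {
    a <- lapply(split_by_cut(d, k)$items, sort)
    b <- lapply(split_by_cut(r, k)$items, sort)
    expect_setequal(vapply(a, paste, character(1), collapse = ","),
                    vapply(b, paste, character(1), collapse = ","))
  }
})

test_that("within-slice clustering never moves items across slices", {
  set.seed(41)
  m <- matrix(rnorm(60), 20, 3)
  s <- split_by_factor(rep(c("a", "b"), each = 10), "row")
  cw <- cluster_within_slices(m, s)
  for (i in seq_along(s$items)) {
    expect_setequal(cw$item_order[[i]], s$items[[i]])
  }
})

test_that("singleton slices are ordered purely by their means", {
  m <- matrix(c(10, 0), 2, 1)   # item 1 mean 10, item 2 mean 0
  s <- slice_spec(list(1L, 2L), c("hi", "lo"), "row")
  cw <- cluster_within_slices(m, s)
  expect_identical(cw$slice_order, c(2L, 1L))  # smaller mean first
})

test_that("slice order matches clustering the slice-mean matrix", {
  set.seed(51)
  m <- rbind(matrix(rnorm(20, 0), 5, 4), matrix(rnorm(20, 50), 5, 4),
             matrix(rnorm(20, 10), 5, 4))
  s <- split_by_factor(rep(c("a", "b", "c"), each = 5), "row")
  cw <- cluster_within_slices(m, s)
  means <- t(vapply(s$items, function(idx) colMeans(m[idx, , drop = FALSE]),
                    numeric(4)))
  d <- hcluster(means, "row", "euclidean", "average")
  d <- reorder_dendrogram(d, rowMeans(means))
  expect_identical(cw$slice_order, leaf_order(d))
})
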