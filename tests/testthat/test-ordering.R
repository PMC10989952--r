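# Hierarchical clustering, dendrogram reordering, explicit orders.

test_that("identical rows merge first at height zero", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9))
  d <- hcluster(m, "row")
  hs <- sort(sapply_internal_heights(d))
  expect_equal(hs[1], 0)
  # the pair {1,2} is a subtree
  cut <- split_by_cut(d, 2)
  expect_true(any(vapply(cut$items, function(x) setequal(x, c(1, 2)), logical(1))))
})

test_that("merge heights match the brute-force agglomerative oracle", {
  set.seed(42)
  for (linkage in c("complete", "average")) {
    for (n in c(5, 8, 10)) {
      m <- matrix(rnorm(n * 3), n, 3)
      d <- hcluster(m, "row", "euclidean", linkage)
      oracle <- brute_hclust(m, linkage)
      expect_equal(sort(sapply_internal_heights(d)), sort(oracle$heights),
                   tolerance = 1e-9)
      # partition sequence: cutting at every k must match the oracle partition
      for (k in 2:(n - 1)) {
        got <- lapply(split_by_cut(d, k)$items, sort)
        want <- oracle$partitions[[n - k]]
        expect_setequal(vapply(got, paste, character(1), collapse = ","),
                        vapply(want, paste, character(1), collapse = ","))
      }
    }
  }
})

test_that("pearson distance is zero for perfectly correlated rows", {
  x <- c(1, 2, 3, 4)
  m <- rbind(x, 2 * x + 5, rev(x))
  d <- build_distance(m, "pearson")
  dm <- as.matrix(d)
  expect_equal(dm[1, 2], 0, tolerance = 1e-12)
  expect_equal(dm[1, 3], 2, tolerance = 1e-12)
})

test_that("clustering rejects degenerate inputs", {
  expect_error(hcluster(matrix(1, 1, 3), "row"), "at least 2")
  m <- matrix(rnorm(9), 3, 3)
  m[2, ] <- NA
  expect_error(hcluster(m, "row"), "row 2")
  vm <- value_matrix(matrix(letters[1:6], 2, 3))
  expect_error(hcluster(vm, "row"), "categorical")
})

test_that("two-leaf reordering puts the smaller weight left", {
  m <- matrix(c(0, 0.2), ncol = 1)
  d <- hcluster(m, "row")
  # weights: item 1 = 3, item 2 = 1 -> leaf order (2, 1)
  r <- reorder_dendrogram(d, c(3, 1))
  expect_identical(leaf_order(r), c(2L, 1L))
})

test_that("all-equal weights leave the leaf order unchanged", {
  d <- tiny_tree()
  r <- reorder_dendrogram(d, rep(1, 6))
  expect_identical(leaf_order(r), leaf_order(d))
})

test_that("reordering matches the recursive subtree-mean oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    m <- matrix(rnorm(n * 2), n, 2)
    d <- hcluster(m, "row")
    w <- sample(seq_len(n))
    r <- reorder_dendrogram(d, w)
    expect_identical(leaf_order(r), reorder_oracle_order(d, w))
  }
})

test_that("reordering preserves merge heights and the leaf set", {
  set.seed(11)
  m <- matrix(rnorm(16), 8, 2)
  d <- hcluster(m, "row")
  w <- rnorm(8)
  r <- reorder_dendrogram(d, w)
  expect_equal(sort(sapply_internal_heights(r)),
               sort(sapply_internal_heights(d)))
  expect_setequal(leaf_order(r), 1:8)
})

test_that("after reordering every node has left mean <= right mean", {
  set.seed(13)
  m <- matrix(rnorm(20), 10, 2)
  d <- hcluster(m, "row")
  w <- rnorm(10)
  r <- reorder_dendrogram(d, w)
  check <- function(node) {
    if (is.leaf(node)) return(invisible())
    lv <- heatcompose:::dend_leaves(node[[1]])
    rv <- heatcompose:::dend_leaves(node[[2]])
    expect_lte(mean(w[lv]), mean(w[rv]) + 1e-12)
    check(node[[1]]); check(node[[2]])
  }
  check(r)
})

test_that("explicit index orders resolve names and reject duplicates", {
  expect_identical(order_by_indices(3, c("c", "a", "b"), c("a", "b", "c")),
                   c(3L, 1L, 2L))
  expect_identical(order_by_indices(4, 1:4), 1:4)
  expect_error(order_by_indices(3, c(1, 1, 2)), "duplicated")
  expect_error(order_by_indices(3, c("a", "q", "b"), c("a", "b", "c")), "q")
})

test_that("externally built nested merge lists are accepted", {
  nested <- list(list(1, 2, height = 1), 3, height = 5)
  d <- as_dendrogram_any(nested)
  expect_s3_class(d, "dendrogram")
  expect_identical(sort(leaf_order(d)), 1:3)
  expect_identical(lapply(split_by_cut(d, 2)$items, sort), list(c(1L, 2L), 3L))
})
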