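# Density heatmap, 3D heatmap, oncoPrint, UpSet.

test_that("the KS distance of a sample with itself is zero", {
  set.seed(1)
  x <- rnorm(100)
  expect_equal(ks_distance(x, x), 0)
})

test_that("KS distances match direct ECDF computation", {
  set.seed(2)
  x <- rnorm(200); y <- runif(200)
  grid <- sort(c(x, y))
  want <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(ks_distance(x, y), want, tolerance = 1e-12)
  d <- as.matrix(ks_distance_matrix(list(a = x, b = y, c = rnorm(50))))
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
})

test_that("per-column density mass integrates to about one", {
  set.seed(3)
  m <- fixture_distributions(normal = 4, uniform = 4, n = 500, seed = 3)
  hm <- density_heatmap(m, grid_points = 400)
  step <- attr(hm, "grid_step")
  mass <- colSums(hm$matrix$values) * step
  expect_true(all(mass >= 0.95 & mass <= 1.01))
})

test_that("a uniform sample's density is near one on the central support", {
  u <- fixture_distributions(normal = 0, uniform = 1, n = 10000, seed = 4)[, 1]
  hm <- density_heatmap(cbind(u), grid_points = 500)
  grid <- attr(hm, "grid")
  central <- grid >= 0.1 & grid <= 0.9
  dens <- hm$matrix$values[central, 1]
  expect_true(all(dens >= 0.9 & dens <= 1.1))
})

test_that("constant distributions are rejected with guidance", {
  expect_error(density_heatmap(cbind(rep(1, 10), rnorm(10))), "bandwidth")
})

test_that("density columns can be clustered by KS distance", {
  set.seed(5)
  m <- cbind(a = rnorm(300), b = rnorm(300), c = runif(300), d = runif(300))
  hm <- density_heatmap(m, cluster_columns = TRUE, grid_points = 200)
  ord <- heatmap_order(hm, "column")
  # the two normal and the two uniform columns end up adjacent
  pos <- match(1:4, ord)
  expect_equal(abs(pos[1] - pos[2]), 1L)
  expect_equal(abs(pos[3] - pos[4]), 1L)
})

test_that("3D heatmap bar order matches the painter's depth sort", {
  ord <- bar_draw_order(3, 3)
  # oracle: back-to-front (descending depth = ascending row), ties broken
  # right-to-left so the depth overhang never hides a nearer bar
  g <- expand.grid(i = 1:3, j = 1:3)
  oracle <- g[order(-(3 - g$i), -g$j), ]
  expect_identical(ord$i, oracle$i)
  expect_identical(ord$j, oracle$j)
})

test_that("an all-zero matrix yields a flat plate and full-range scaling holds", {
  sc0 <- heatmap_3d(matrix(0, 2, 2))
  expect_identical(nrow(sc0$prims$body3d$rects), 0L)
  sc1 <- heatmap_3d(matrix(c(5, 0, 0, 0), 2, 2), bar_rel = 0.4)
  r <- sc1$prims$body3d$rects
  expect_equal(max(r$h), 0.4, tolerance = 1e-9)
})

test_that("genes are ordered by decreasing altered-sample counts", {
  ev <- data.frame(gene = c("g1", "g1", "g1", "g2"),
                   sample = c("s1", "s2", "s3", "s1"),
                   type = "SNV")
  tab <- alteration_table(ev)
  ord <- oncoprint_order(tab)
  expect_identical(tab$genes[ord$gene_order], c("g1", "g2"))
})

test_that("one-gene sample ordering is altered-first and stable", {
  ev <- data.frame(gene = "g", sample = c("s2", "s4"), type = "SNV")
  tab <- alteration_table(ev, samples = paste0("s", 1:5))
  ord <- oncoprint_order(tab)
  expect_identical(tab$samples[ord$sample_order],
                   c("s2", "s4", "s1", "s3", "s5"))
})

test_that("memo-sorted samples match the exhaustive lexicographic oracle", {
  set.seed(7)
  for (rep in 1:10) {
    ng <- sample(2:4, 1); ns <- sample(4:8, 1)
    b <- matrix(runif(ng * ns) < 0.4, ng, ns)
    ev_idx <- which(b, arr.ind = TRUE)
    if (!nrow(ev_idx)) next
    tab <- alteration_table(
      data.frame(gene = paste0("g", ev_idx[, 1]),
                 sample = paste0("s", sprintf("%02d", ev_idx[, 2])),
                 type = "SNV"),
      genes = paste0("g", 1:ng), samples = paste0("s", sprintf("%02d", 1:ns)))
    ord <- oncoprint_order(tab)
    # oracle: rank every sample's binary vector (over ordered genes)
    # lexicographically; sort descending, stable
    ranks <- apply(b[ord$gene_order, , drop = FALSE], 2,
                   function(v) sum(v * 2^(rev(seq_along(v)) - 1)))
    oracle <- order(-ranks, seq_len(ns))
    expect_identical(ord$sample_order, oracle)
  }
})

test_that("oncoPrint annotation bar totals equal event recounts", {
  tab <- fixture_alteration_table(n_genes = 6, n_samples = 20, seed = 11)
  hm <- onco_print(tab)
  right <- hm$annotations$right$tracks[[1]]$payload
  top <- hm$annotations$top$tracks[[1]]$payload
  for (g in tab$genes) {
    expect_equal(sum(right[g, ]), sum(tab$events$gene == g))
  }
  for (s in tab$samples) {
    expect_equal(sum(top[s, ]), sum(tab$events$sample == s))
  }
})

test_that("unregistered alteration types are reported by name", {
  ev <- data.frame(gene = "g", sample = "s", type = "weird")
  expect_error(onco_print(alteration_table(ev), glyphs = list()), "weird")
})

test_that("oncoPrint cell glyphs stack in catalogue z-order", {
  ev <- data.frame(gene = c("g", "g"), sample = c("s", "s"),
                   type = c("CNV", "SNV"))
  tab <- alteration_table(ev)
  hm <- onco_print(tab, show_annotations = FALSE)
  pr <- hm$cell_fun(1, 1, "", "#EDEDED", 0, 0, 1, 1)
  expect_identical(nrow(pr$rects), 2L)
  glyphs <- attr(hm, "glyphs")
  # drawn from low z to high z
  expect_identical(pr$rects$fill, c(glyphs$CNV$fill, glyphs$SNV$fill))
})

test_that("the worked three-set example gives the documented sizes", {
  member <- make_membership(list(A = 1:3, B = 2:4, C = 3:5))
  dis <- upset_combinations(member, "distinct", drop_empty = FALSE)
  expect_equal(dis$size[dis$combination == "A&B&C"], 1)
  expect_equal(dis$size[dis$combination == "A"], 1)
  int <- upset_combinations(member, "intersect", drop_empty = FALSE)
  expect_equal(int$size[int$combination == "A&B"], 2)
  uni <- upset_combinations(member, "union", drop_empty = FALSE)
  expect_equal(uni$size[uni$combination == "A&B"], 4)
})

test_that("combination sizes match per-element enumeration on random sets", {
  set.seed(13)
  for (rep in 1:10) {
    s <- sample(2:5, 1)
    n <- sample(10:40, 1)
    member <- matrix(runif(n * s) < 0.4, n, s,
                     dimnames = list(NULL, LETTERS[1:s]))
    for (mode in c("distinct", "intersect", "union")) {
      got <- upset_combinations(member, mode, drop_empty = FALSE)
      oracle <- upset_oracle(member, mode)
      for (i in seq_len(nrow(got))) {
        expect_equal(got$size[i], oracle[[got$combination[i]]],
                     info = sprintf("%s %s", mode, got$combination[i]))
      }
    }
  }
})

test_that("distinct sizes partition the covered elements", {
  set.seed(14)
  member <- matrix(runif(50 * 4) < 0.3, 50, 4,
                   dimnames = list(NULL, LETTERS[1:4]))
  got <- upset_combinations(member, "distinct", drop_empty = FALSE)
  expect_equal(sum(got$size), sum(rowSums(member) > 0))
  single <- make_membership(list(A = letters))
  expect_equal(upset_combinations(single, "distinct")$size, 26)
})

test_that("upset_plot exposes its combination table and draws", {
  member <- make_membership(list(A = 1:10, B = 5:15, C = 12:20))
  hm <- upset_plot(member)
  comb <- attr(hm, "combinations")
  expect_true(all(comb$size > 0))
  f <- tempfile(fileext = ".svg")
  draw(hm, f)
  expect_gt(file.size(f), 0)
})
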