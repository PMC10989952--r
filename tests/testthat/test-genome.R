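# Genomic interval machinery: region UpSet, genome binning, signal
# normalization, anchored enrichment.

test_that("interval construction enforces 0-based half-open coordinates", {
  expect_error(genomic_intervals("chr1", 100, 50), "start")
  expect_error(genomic_intervals("chr1", -5, 50), "negative")
  gi <- genomic_intervals("chr1", 0, 100)
  expect_equal(gi$end - gi$start, 100)
})

test_that("flattening merges overlaps within a list", {
  gi <- genomic_intervals(rep("chr1", 3), c(0, 50, 200), c(100, 150, 250))
  f <- flatten_intervals(gi)
  expect_identical(f$start, c(0, 200))
  expect_identical(f$end, c(150, 250))
})

test_that("the worked two-list case gives 50/50/50 bp distinct sizes", {
  lists <- list(A = genomic_intervals("chr1", 0, 100),
                B = genomic_intervals("chr1", 50, 150))
  comb <- region_upset(lists, "distinct")$combinations
  sz <- function(cmb) comb$size[comb$combination == cmb]
  expect_equal(sz("A"), 50)
  expect_equal(sz("A&B"), 50)
  expect_equal(sz("B"), 50)
})

test_that("identical and disjoint lists give the degenerate sizes", {
  a <- genomic_intervals("chr1", c(0, 500), c(100, 700))
  comb_same <- region_upset(list(A = a, B = a), "distinct",
                            drop_empty = FALSE)$combinations
  expect_equal(comb_same$size[comb_same$combination == "A"], 0)
  expect_equal(comb_same$size[comb_same$combination == "A&B"], 300)
  dis <- list(A = genomic_intervals("chr1", 0, 100),
              B = genomic_intervals("chr1", 200, 300))
  comb_dis <- region_upset(dis, "distinct", drop_empty = FALSE)$combinations
  expect_equal(comb_dis$size[comb_dis$combination == "A&B"], 0)
})

test_that("region combination sizes match the per-base oracle", {
  genome <- c(chr1 = 2000, chr2 = 1000)
  set.seed(21)
  for (rep in 1:5) {
    lists <- fixture_interval_lists(n_lists = 3, genome = genome,
                                    coverage = 0.3, mean_len = 80,
                                    seed = 100 + rep)
    for (mode in c("distinct", "intersect", "union")) {
      comb <- region_upset(lists, mode, drop_empty = FALSE)$combinations
      oracle <- region_oracle(lists, genome, mode)
      for (i in seq_len(nrow(comb))) {
        expect_equal(comb$size[i], oracle[[comb$combination[i]]],
                     info = sprintf("%s %s seed %d", mode, comb$combination[i],
                                    100 + rep))
      }
    }
  }
})

test_that("distinct region sizes sum to the union coverage", {
  lists <- fixture_interval_lists(n_lists = 4, genome = c(chr1 = 5000),
                                  seed = 31)
  comb <- region_upset(lists, "distinct")$combinations
  all_iv <- do.call(rbind, lapply(lists, function(x) x[, 1:3]))
  uni <- flatten_intervals(genomic_intervals(all_iv$chrom, all_iv$start,
                                             all_iv$end))
  expect_equal(sum(comb$size), sum(uni$end - uni$start))
})

test_that("genome binning tiles each chromosome exactly", {
  bins <- bin_genome(c(chrA = 250), 100)
  expect_identical(bins$start, c(0, 100, 200))
  expect_identical(bins$end, c(100, 200, 250))
  one <- bin_genome(c(chrA = 80, chrB = 50), 100)
  expect_identical(nrow(one), 2L)
  big <- bin_genome(c(chr1 = 1234, chr2 = 999), 100)
  expect_equal(sum(big$end - big$start), 1234 + 999)
})

test_that("signal statistics follow the covered-portion convention", {
  bins <- bin_genome(c(chr1 = 200), 100)
  full <- genomic_intervals("chr1", 0, 100, value = 2)
  expect_equal(signal_to_bins(full, bins, "weighted_mean")[1], 2)
  expect_equal(signal_to_bins(full, bins, "coverage_fraction"), c(1, 0))
  half <- genomic_intervals("chr1", 0, 50, value = 2)
  # mean over the covered portion only, not diluted by the uncovered half
  expect_equal(signal_to_bins(half, bins, "weighted_mean")[1], 2)
  expect_equal(signal_to_bins(half, bins, "coverage_fraction")[1], 0.5)
  expect_true(is.na(signal_to_bins(half, bins, "weighted_mean")[2]))
  expect_error(signal_to_bins(genomic_intervals("chrX", 0, 10, value = 1), bins),
               "chrX")
})

test_that("weighted means mix overlapping values by overlap length", {
  bins <- bin_genome(c(chr1 = 100), 100)
  sig <- genomic_intervals(c("chr1", "chr1"), c(0, 60), c(60, 100),
                           value = c(1, 3))
  expect_equal(signal_to_bins(sig, bins, "weighted_mean"),
               (60 * 1 + 40 * 3) / 100)
  expect_equal(signal_to_bins(sig, bins, "max"), 3)
})

test_that("coverage fractions stay within [0, 1] and constants pass through", {
  set.seed(41)
  bins <- bin_genome(c(chr1 = 3000), 250)
  lists <- fixture_interval_lists(1, c(chr1 = 3000), seed = 55)[[1]]
  lists$value <- 7
  cov <- signal_to_bins(lists, bins, "coverage_fraction")
  expect_true(all(cov >= 0 & cov <= 1))
  wm <- signal_to_bins(lists, bins, "weighted_mean")
  expect_true(all(is.na(wm) | wm == 7))
})

test_that("plus-strand enrichment rows match the per-base oracle", {
  sig <- genomic_intervals("chr1", 900, 950, value = 1)
  tg <- genomic_intervals("chr1", 1000, 1500, strand = "+")
  M <- normalize_to_targets(sig, tg, extend = 100, window = 50)
  expect_equal(unname(M[1, ]), c(1, NA, NA, NA))
  expect_equal(unname(M[1, ]),
               enrich_oracle_row(sig, "chr1", 1000, "+", 100, 50))
})

test_that("minus-strand rows are the reverse of the plus-strand computation", {
  sig <- genomic_intervals("chr1", 1050, 1100, value = 1)
  tg_minus <- genomic_intervals("chr1", 500, 1000, strand = "-")
  M <- normalize_to_targets(sig, tg_minus, extend = 100, window = 50)
  expect_equal(unname(M[1, ]), c(1, NA, NA, NA))
  tg_plus <- genomic_intervals("chr1", 1000, 1500, strand = "+")
  Mp <- normalize_to_targets(sig, tg_plus, extend = 100, window = 50)
  expect_equal(unname(M[1, ]), rev(unname(Mp[1, ])))
})

test_that("a constant signal field fills the matrix with the constant", {
  sig <- genomic_intervals("chr1", 0, 100000, value = 4)
  tg <- genomic_intervals("chr1", c(5000, 20000), c(5500, 20500),
                          strand = c("+", "-"))
  M <- normalize_to_targets(sig, tg, extend = 1000, window = 100)
  expect_true(all(M == 4))
})

test_that("randomized rows match the oracle and rows are independent", {
  fx <- fixture_signal_track(genome_size = 30000, n_targets = 8, seed = 61)
  M <- normalize_to_targets(fx$signal, fx$targets, extend = 500, window = 100)
  for (t in seq_len(nrow(fx$targets))) {
    anchor <- if (fx$targets$strand[t] == "-") fx$targets$end[t] else fx$targets$start[t]
    expect_equal(unname(M[t, ]),
                 enrich_oracle_row(fx$signal, "chr1", anchor,
                                   fx$targets$strand[t], 500, 100),
                 tolerance = 1e-9)
  }
  shuffle <- c(3, 1, 2, 8, 7, 4, 6, 5)
  tg2 <- fx$targets[shuffle, ]
  class(tg2) <- class(fx$targets)
  M2 <- normalize_to_targets(fx$signal, tg2, extend = 500, window = 100)
  expect_equal(unname(M2), unname(M[shuffle, ]), ignore_attr = TRUE)
})

test_that("categorical signals give per-category coverage fractions", {
  sig <- genomic_intervals(rep("chr1", 2), c(900, 1000), c(1000, 1100),
                           name = c("active", "inactive"))
  tg <- genomic_intervals("chr1", 1000, 1500, strand = "+")
  M <- normalize_to_targets(sig, tg, extend = 100, window = 50,
                            value_kind = "categorical")
  expect_setequal(names(M), c("active", "inactive"))
  expect_equal(unname(M$active[1, ]), c(1, 1, 0, 0))
  expect_equal(unname(M$inactive[1, ]), c(0, 0, 1, 1))
})

test_that("enrichment profiles are column means per slice", {
  m <- rbind(c(0, 2), c(2, 0))
  p <- enriched_profile(m)
  expect_equal(unname(p[1, ]), c(1, 1))
  s <- slice_spec(list(1L, 2L), c("a", "b"), "row")
  p2 <- enriched_profile(m, s)
  expect_equal(unname(p2["a", ]), c(0, 2))
  m3 <- matrix(rnorm(30), 10, 3)
  s3 <- split_by_factor(rep(c("x", "y"), each = 5), "row")
  p3 <- enriched_profile(m3, s3)
  expect_equal(unname(p3["x", ]), colMeans(m3[1:5, ]))
  expect_equal(unname(p3["y", ]), colMeans(m3[6:10, ]))
  expect_error(enriched_profile(m, slice_spec(list(1:2, integer(0)),
                                              c("a", "b"), "row", n = 2)),
               "empty")
})

test_that("identical slices give identical profiles", {
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  s <- slice_spec(list(c(1L, 3L), c(2L, 4L)), c("a", "b"), "row")
  p <- enriched_profile(m, s)
  expect_equal(p["a", ], p["b", ])
})
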