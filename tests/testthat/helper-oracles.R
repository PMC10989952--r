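# Independent oracles used by the tests. These deliberately reimplement the
# operations by the most transparent (often brute-force) route so they share
# no code with the package implementation.

options(heatcompose.quiet = TRUE)

# O(n^3) agglomerative clustering that rescans the full element-level distance
# matrix at every step. Returns merge heights (in merge order) and the
# partition after each merge.
brute_hclust <- function(m, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        pd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        cd <- switch(linkage, complete = max(pd), average = mean(pd),
                     single = min(pd))
        if (cd < best_d) { best_d <- cd; best <- c(j, i) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Recursive reorder oracle: reorders children by explicitly recomputed leaf
# means at every node, top-down on leaf lists.
reorder_oracle_order <- function(dend, weights) {
  leaves_of <- function(node) {
    if (is.leaf(node)) as.integer(node)
    else c(leaves_of(node[[1]]), leaves_of(node[[2]]))
  }
  rec <- function(node) {
    if (is.leaf(node)) return(as.integer(node))
    lm <- mean(weights[leaves_of(node[[1]])])
    rm <- mean(weights[leaves_of(node[[2]])])
    if (lm > rm) c(rec(node[[2]]), rec(node[[1]]))
    else c(rec(node[[1]]), rec(node[[2]]))
  }
  rec(dend)
}

# Cut oracle: leaves i, j belong to the same group iff the height of their
# lowest common ancestor is strictly below the cut threshold (the k-1 highest
# merge heights are removed).
cut_oracle <- function(dend, k) {
  leaves_of <- function(node) {
    if (is.leaf(node)) as.integer(node)
    else c(leaves_of(node[[1]]), leaves_of(node[[2]]))
  }
  n <- length(leaves_of(dend))
  lca <- matrix(0, n, n)
  rec <- function(node) {
    if (is.leaf(node)) return(as.integer(node))
    l <- rec(node[[1]]); r <- rec(node[[2]])
    h <- attr(node, "height")
    lca[l, r] <<- h; lca[r, l] <<- h
    c(l, r)
  }
  rec(dend)
  hs <- sort(unique(lca[upper.tri(lca)]), decreasing = TRUE)
  all_h <- sort(sapply_internal_heights(dend), decreasing = TRUE)
  thr <- all_h[k - 1L]
  groups <- list()
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    g <- which(lca[i, ] < thr | seq_len(n) == i)
    g <- g[!assigned[g]]
    # transitive closure (ultrametric, so one pass suffices)
    groups[[length(groups) + 1L]] <- sort(g)
    assigned[g] <- TRUE
  }
  groups
}

sapply_internal_heights <- function(dend) {
  hs <- numeric(0)
  rec <- function(node) {
    if (!is.leaf(node)) {
      hs <<- c(hs, attr(node, "height"))
      rec(node[[1]]); rec(node[[2]])
    }
  }
  rec(dend)
  hs
}

# Mark-label pooling oracle: place labels at their anchors, then repeatedly
# merge overlapping runs and place each run at the mean of its anchors,
# clipped to the bounds, until feasible.
mark_pool_oracle <- function(anchors, extents, bounds) {
  n <- length(anchors)
  runs <- lapply(seq_len(n), function(i) list(idx = i, anchor = anchors[i],
                                              ext = extents[i]))
  repeat {
    changed <- FALSE
    # positions of runs: run center minus/plus half extents, members spaced
    centers <- vapply(runs, function(r) {
      ctr <- mean(anchors[r$idx])
      half <- sum(extents[r$idx]) / 2
      min(max(ctr, bounds[1] + half), bounds[2] - half)
    }, numeric(1))
    i <- 1L
    while (i < length(runs)) {
      hi_i <- centers[i] + sum(extents[runs[[i]]$idx]) / 2
      lo_j <- centers[i + 1L] - sum(extents[runs[[i + 1L]]$idx]) / 2
      if (hi_i > lo_j + 1e-9) {
        runs[[i]]$idx <- c(runs[[i]]$idx, runs[[i + 1L]]$idx)
        runs <- runs[-(i + 1L)]
        changed <- TRUE
        break
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  pos <- numeric(n)
  for (r in runs) {
    ctr <- mean(anchors[r$idx])
    half <- sum(extents[r$idx]) / 2
    ctr <- min(max(ctr, bounds[1] + half), bounds[2] - half)
    start <- ctr - half
    for (q in r$idx) {
      pos[q] <- start + extents[q] / 2
      start <- start + extents[q]
    }
  }
  pos
}

# Per-element set combination oracle.
upset_oracle <- function(member, mode) {
  s <- ncol(member)
  set_names <- colnames(member)
  combos <- list()
  for (cd in seq_len(2^s - 1)) {
    in_combo <- as.logical(bitwAnd(cd, 2^(seq_len(s) - 1)) > 0)
    cnt <- 0L
    for (e in seq_len(nrow(member))) {
      row <- member[e, ]
      if (!any(row)) next
      hit <- switch(mode,
        distinct = all(row == in_combo),
        intersect = all(row[in_combo]),
        union = any(row[in_combo]))
      if (hit) cnt <- cnt + 1L
    }
    combos[[paste(set_names[in_combo], collapse = "&")]] <- cnt
  }
  combos
}

# Per-base genomic combination oracle on a small genome.
region_oracle <- function(lists, genome, mode) {
  set_names <- names(lists)
  s <- length(lists)
  base_member <- list()
  for (ch in names(genome)) {
    L <- genome[[ch]]
    memb <- matrix(FALSE, L, s)
    for (k in seq_len(s)) {
      gi <- lists[[k]]
      idx <- which(gi$chrom == ch)
      for (q in idx) {
        rng <- seq(gi$start[q] + 1L, gi$end[q])  # base b covers [b-1, b)
        memb[rng[rng <= L], k] <- TRUE
      }
    }
    base_member[[ch]] <- memb
  }
  memb <- do.call(rbind, base_member)
  colnames(memb) <- set_names
  upset_oracle(memb, mode)
}

# Per-base enrichment oracle: mean signal value over the covered bases of
# each window around the anchor (NA when uncovered).
enrich_oracle_row <- function(signal, chrom, anchor, strand, extend, window) {
  nw <- 2 * extend / window
  vals <- rep(NA_real_, 2 * extend)   # per-base value, offset 1 = anchor-extend
  for (q in seq_len(nrow(signal))) {
    if (signal$chrom[q] != chrom) next
    b0 <- max(signal$start[q], anchor - extend)
    b1 <- min(signal$end[q], anchor + extend)
    if (b1 <= b0) next
    off <- (b0 + 1):b1 - (anchor - extend)
    vals[off] <- signal$value[q]
  }
  row <- vapply(seq_len(nw), function(w) {
    sub <- vals[((w - 1) * window + 1):(w * window)]
    if (all(is.na(sub))) NA_real_ else mean(sub, na.rm = TRUE)
  }, numeric(1))
  if (!is.na(strand) && strand == "-") rev(row) else row
}

# Random feasible order-preserving label layout (for objective comparisons).
random_feasible_layout <- function(anchors, extents, bounds) {
  n <- length(anchors)
  slack <- diff(bounds) - sum(extents)
  cuts <- sort(runif(n + 1)) ; cuts <- cuts / sum(cuts) * slack
  pos <- numeric(n)
  x <- bounds[1]
  for (i in seq_len(n)) {
    x <- x + cuts[i]
    pos[i] <- x + extents[i] / 2
    x <- x + extents[i]
  }
  pos
}

skip_nothing <- function() invisible(TRUE)

tiny_tree <- function() {
  # fixed 6-leaf dendrogram built from an explicit matrix
  m <- matrix(c(0, 0.1, 5, 5.1, 20, 20.1), ncol = 1)
  as.dendrogram(hclust(dist(m), method = "complete"))
}
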