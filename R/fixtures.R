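# Seeded fixture generators. Every demonstration dataset the package's plots
# are exercised on is random by construction, so generators with documented
# statistical structure (plus ground-truth sidecars) stand in for real data
# in examples and tests. The same recipe and seed always reproduce the same
# bytes.

#' @importFrom stats rnorm runif rbinom rexp
NULL

#' Grouped random matrix with planted row/column structure
#'
#' `k` row groups and `g` column groups of equal size; cell values are
#' unit-variance Gaussian noise around a group-mean offset: row group `a`
#' (0-based) adds `a * delta`, column group `b` adds `b * delta / 2`.
#'
#' @param n_rows,n_cols Matrix size.
#' @param k,g Number of row and column groups.
#' @param delta Group mean offset in noise standard deviations (default 5).
#' @param sd Noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return List with `matrix` (named numeric matrix), `row_groups`,
#'   `col_groups` (integer ground-truth labels).
#' @export
fixture_grouped_matrix <- function(n_rows = 60, n_cols = 20, k = 3, g = 1,
                                   delta = 5, sd = 1, seed = 1L) {
  with_seed(seed, {
    row_groups <- rep(seq_len(k), length.out = n_rows, each = ceiling(n_rows / k))[seq_len(n_rows)]
    col_groups <- rep(seq_len(g), length.out = n_cols, each = ceiling(n_cols / g))[seq_len(n_cols)]
    m <- matrix(rnorm(n_rows * n_cols, sd = sd), n_rows, n_cols)
    m <- m + (row_groups - 1L) * delta
    m <- m + matrix((col_groups - 1L) * delta / 2, n_rows, n_cols, byrow = TRUE)
    dimnames(m) <- list(sprintf("r%02d", seq_len(n_rows)),
                        sprintf("c%02d", seq_len(n_cols)))
    list(matrix = m, row_groups = row_groups, col_groups = col_groups)
  })
}

#' Random alteration table with optional engineered exclusivity
#'
#' Each gene alters each sample independently at its event rate; when
#' `exclusive_block` is set, the first `exclusive_block` genes partition the
#' first half of the samples so their alterations are mutually exclusive.
#'
#' @param n_genes,n_samples Table size.
#' @param rates Per-gene alteration rates (recycled; default 0.3 to 0.05).
#' @param types Alteration type catalogue to sample from.
#' @param exclusive_block Number of leading genes made mutually exclusive
#'   (0 = none).
#' @param seed Integer seed.
#' @return An `alteration_table`.
#' @export
fixture_alteration_table <- function(n_genes = 8, n_samples = 40,
                                     rates = seq(0.3, 0.05, length.out = n_genes),
                                     types = c("SNV", "CNV", "Indel"),
                                     exclusive_block = 0, seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("gene%02d", seq_len(n_genes))
    samples <- sprintf("s%03d", seq_len(n_samples))
    rates <- rep_len(rates, n_genes)
    ev <- list()
    altered <- matrix(FALSE, n_genes, n_samples)
    if (exclusive_block > 1L) {
      half <- seq_len(floor(n_samples / 2))
      owner <- rep(seq_len(exclusive_block), length.out = length(half))
      altered[cbind(owner, half)] <- TRUE
    }
    rnd <- matrix(runif(n_genes * n_samples), n_genes, n_samples)
    free <- if (exclusive_block > 1L) {
      seq_len(n_samples) > floor(n_samples / 2)
    } else rep(TRUE, n_samples)
    altered[, free] <- rnd[, free, drop = FALSE] < rates
    idx <- which(altered, arr.ind = TRUE)
    ev <- data.frame(gene = genes[idx[, 1L]], sample = samples[idx[, 2L]],
                     type = sample(types, nrow(idx), replace = TRUE),
                     stringsAsFactors = FALSE)
    alteration_table(ev, genes = genes, samples = samples)
  })
}

#' Random interval lists on a toy genome
#'
#' Each list covers roughly `coverage` of the genome with intervals of
#' exponential length; lists share structure only through chance overlap.
#'
#' @param n_lists Number of lists.
#' @param genome Named numeric vector of chromosome sizes (default one 10 kb
#'   chromosome).
#' @param coverage Target coverage fraction per list.
#' @param mean_len Mean interval length in bp.
#' @param seed Integer seed.
#' @return Named list of `genomic_intervals`.
#' @export
fixture_interval_lists <- function(n_lists = 3, genome = c(chr1 = 10000),
                                   coverage = 0.3, mean_len = 300, seed = 1L) {
  with_seed(seed, {
    out <- lapply(seq_len(n_lists), function(i) {
      parts <- lapply(names(genome), function(ch) {
        L <- genome[[ch]]
        n_iv <- max(1L, round(coverage * L / mean_len))
        st <- floor(runif(n_iv, 0, L - 2))
        len <- pmax(1, round(rexp(n_iv, 1 / mean_len)))
        en <- pmin(st + len, L)
        data.frame(chrom = ch, start = st, end = en, stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, parts)
      flatten_intervals(genomic_intervals(d$chrom, d$start, d$end))
    })
    names(out) <- paste0("list", seq_len(n_lists))
    out
  })
}

#' Random signal track and anchored targets
#'
#' A piecewise-constant signal over a toy chromosome plus `n_targets` anchor
#' features; around each anchor the signal is boosted by `enrich` within
#' `peak_halfwidth`, emulating TSS-centred enrichment.
#'
#' @param genome_size Chromosome length in bp.
#' @param n_targets Number of anchored targets.
#' @param segment Signal segment length in bp.
#' @param enrich Additive signal boost near anchors.
#' @param peak_halfwidth Half-width of the boosted region in bp.
#' @param frac_minus Fraction of minus-strand targets.
#' @param seed Integer seed.
#' @return List with `signal` and `targets` (`genomic_intervals`).
#' @export
fixture_signal_track <- function(genome_size = 100000, n_targets = 40,
                                 segment = 100, enrich = 3,
                                 peak_halfwidth = 500, frac_minus = 0.5,
                                 seed = 1L) {
  with_seed(seed, {
    st <- seq(0, genome_size - segment, by = segment)
    val <- abs(rnorm(length(st), mean = 1, sd = 0.3))
    anchors <- sort(floor(runif(n_targets, peak_halfwidth + 2000,
                                genome_size - peak_halfwidth - 2000)))
    mid <- st + segment / 2
    for (a in anchors) {
      near <- abs(mid - a) <= peak_halfwidth
      val[near] <- val[near] + enrich * (1 - abs(mid[near] - a) / peak_halfwidth)
    }
    strand <- ifelse(runif(n_targets) < frac_minus, "-", "+")
    t_start <- ifelse(strand == "-", anchors - 1500, anchors)
    t_end <- ifelse(strand == "-", anchors, anchors + 1500)
    list(
      signal = genomic_intervals("chr1", st, st + segment, value = val),
      targets = genomic_intervals("chr1", t_start, t_end, strand = strand,
                                  name = sprintf("t%03d", seq_len(n_targets)))
    )
  })
}

#' Columns drawn from named distribution families
#'
#' Emulates a density-heatmap demonstration: the first `normal` columns are
#' standard normal, the next `uniform` columns are uniform on `[0, 1]`.
#'
#' @param normal,uniform Number of columns per family.
#' @param n Observations per column.
#' @param seed Integer seed.
#' @return Numeric matrix with family-labelled column names.
#' @export
fixture_distributions <- function(normal = 10, uniform = 10, n = 1000,
                                  seed = 1L) {
  with_seed(seed, {
    m <- cbind(
      matrix(rnorm(n * normal), n, normal),
      matrix(runif(n * uniform), n, uniform)
    )
    colnames(m) <- c(sprintf("norm%02d", seq_len(normal)),
                     sprintf("unif%02d", seq_len(uniform)))
    m
  })
}

#' Generate fixture files from a recipe
#'
#' Writes the generator's outputs (matrices as TSV, intervals as BED,
#' alterations as MAF-like TSV) plus a JSON sidecar with the ground truth,
#' into `dir`. The same recipe and seed produce byte-identical files.
#'
#' @param recipe List with `generator` (one of `grouped_matrix`,
#'   `alteration_table`, `interval_lists`, `signal_track`, `distributions`),
#'   `seed`, and generator parameters in `params`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
generate_fixture <- function(recipe, dir = ".") {
  stopifnot(is.list(recipe), !is.null(recipe$generator))
  gens <- c("grouped_matrix", "alteration_table", "interval_lists",
            "signal_track", "distributions")
  if (!recipe$generator %in% gens) {
    stop(sprintf("unknown generator '%s'; available: %s", recipe$generator,
                 paste(gens, collapse = ", ")), call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- recipe$params %||% list()
  params$seed <- recipe$seed %||% 1L
  files <- character(0)
  wjson <- function(x, f) {
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    f
  }
  out <- switch(recipe$generator,
    grouped_matrix = {
      fx <- do.call(fixture_grouped_matrix, params)
      f1 <- file.path(dir, "matrix.tsv")
      write_matrix(value_matrix(fx$matrix), f1)
      f2 <- wjson(list(row_groups = fx$row_groups, col_groups = fx$col_groups,
                       seed = params$seed), file.path(dir, "truth.json"))
      c(f1, f2)
    },
    alteration_table = {
      tab <- do.call(fixture_alteration_table, params)
      f1 <- file.path(dir, "alterations.tsv")
      utils::write.table(
        data.frame(gene = tab$events$gene, sample = tab$events$sample,
                   alteration_type = tab$events$type),
        f1, sep = "\t", quote = FALSE, row.names = FALSE)
      f2 <- wjson(list(genes = tab$genes, samples = tab$samples,
                       seed = params$seed), file.path(dir, "truth.json"))
      c(f1, f2)
    },
    interval_lists = {
      lst <- do.call(fixture_interval_lists, params)
      fs <- vapply(names(lst), function(nm) {
        write_bed(lst[[nm]], file.path(dir, paste0(nm, ".bed")))
        file.path(dir, paste0(nm, ".bed"))
      }, character(1))
      f2 <- wjson(list(lists = names(lst), seed = params$seed),
                  file.path(dir, "truth.json"))
      c(fs, f2)
    },
    signal_track = {
      fx <- do.call(fixture_signal_track, params)
      f1 <- file.path(dir, "signal.bed"); write_bed(fx$signal, f1)
      f2 <- file.path(dir, "targets.bed"); write_bed(fx$targets, f2)
      f3 <- wjson(list(seed = params$seed), file.path(dir, "truth.json"))
      c(f1, f2, f3)
    },
    distributions = {
      m <- do.call(fixture_distributions, params)
      f1 <- file.path(dir, "distributions.tsv")
      write_matrix(value_matrix(m), f1)
      f2 <- wjson(list(families = colnames(m), seed = params$seed),
                  file.path(dir, "truth.json"))
      c(f1, f2)
    })
  hc_log(sprintf("generate_fixture: wrote %d file(s) with seed %d",
                 length(out), params$seed))
  invisible(out)
}
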