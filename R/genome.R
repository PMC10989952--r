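# Genomic interval sets and genome-level operations. All coordinates are
# 0-based half-open ([start, end)) throughout the package; readers convert at
# the boundary if their source uses another convention.

#' Construct a genomic interval set
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like positions, 0-based half-open (`start < end`).
#' @param value Optional numeric score per interval.
#' @param strand Optional strand (`"+"`, `"-"` or `NA`).
#' @param name Optional interval names.
#' @return A `genomic_intervals` data frame.
#' @export
genomic_intervals <- function(chrom, start, end, value = NA_real_,
                              strand = NA_character_, name = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("interval %d: start (%g) must be < end (%g) in 0-based half-open coordinates",
                 bad[1L], start[bad[1L]], end[bad[1L]]), call. = FALSE)
  }
  if (any(start < 0)) stop("negative coordinates are not allowed", call. = FALSE)
  out <- data.frame(chrom = chrom, start = start, end = end,
                    value = rep_len(as.numeric(value), n),
                    strand = rep_len(as.character(strand), n),
                    name = rep_len(as.character(name), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Merge overlapping intervals within a set
#'
#' @param gi A `genomic_intervals`.
#' @return A `genomic_intervals` with disjoint, sorted intervals per
#'   chromosome (values/strands dropped).
#' @export
flatten_intervals <- function(gi) {
  if (!nrow(gi)) return(gi)
  parts <- lapply(split(seq_len(nrow(gi)), gi$chrom), function(idx) {
    s <- gi$start[idx]; e <- gi$end[idx]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    ms <- s[1L]; me <- e[1L]
    out_s <- numeric(0); out_e <- numeric(0)
    for (i in seq_along(s)[-1L]) {
      if (s[i] <= me) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    out_s <- c(out_s, ms); out_e <- c(out_e, me)
    data.frame(chrom = gi$chrom[idx[1L]], start = out_s, end = out_e,
               stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, parts)
  genomic_intervals(flat$chrom, flat$start, flat$end)
}

#' Combination sizes of genomic region lists
#'
#' The genome is segmented at the union of all interval breakpoints of the
#' (flattened) lists; each segment's membership vector records which lists
#' cover it, and combination sizes are the summed segment lengths in base
#' pairs under the chosen mode.
#'
#' @param lists Named list of `genomic_intervals`.
#' @param mode `"distinct"`, `"intersect"` or `"union"` (see
#'   [upset_combinations()]).
#' @param drop_empty Drop zero-size combinations.
#' @return List with `combinations` (data frame: `combination`, `degree`,
#'   `size` in bp, per-list flags) and `segments` (the segment map with one
#'   logical column per list).
#' @export
region_upset <- function(lists, mode = c("distinct", "intersect", "union"),
                         drop_empty = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.list(lists), length(lists) >= 1L)
  if (is.null(names(lists)) || any(names(lists) == "")) {
    stop("all region lists must be named", call. = FALSE)
  }
  flat <- lapply(lists, flatten_intervals)
  s <- length(flat)
  chroms <- sort(unique(unlist(lapply(flat, function(f) unique(f$chrom)))))
  seg_list <- list()
  for (ch in chroms) {
    bp <- sort(unique(unlist(lapply(flat, function(f) {
      idx <- f$chrom == ch
      c(f$start[idx], f$end[idx])
    }))))
    if (length(bp) < 2L) next
    st <- bp[-length(bp)]; en <- bp[-1L]
    seg <- data.frame(chrom = ch, start = st, end = en, stringsAsFactors = FALSE)
    for (k in seq_len(s)) {
      f <- flat[[k]]
      idx <- which(f$chrom == ch)
      covered <- rep(FALSE, nrow(seg))
      if (length(idx)) {
        # flattened intervals are disjoint & sorted: a segment is covered iff
        # it lies inside the interval whose start is the last one <= seg start
        pos <- findInterval(st, f$start[idx])
        has <- pos >= 1L
        covered[has] <- en[has] <= f$end[idx][pos[has]]
      }
      seg[[names(flat)[k]]] <- covered
    }
    seg_list[[ch]] <- seg
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(segments) <- NULL
  set_names <- names(flat)
  if (!nrow(segments)) {
    return(list(combinations = data.frame(combination = character(0),
                                          degree = numeric(0), size = numeric(0)),
                segments = segments))
  }
  memb <- as.matrix(segments[, set_names, drop = FALSE])
  mask <- as.integer(memb %*% 2L^(seq_len(s) - 1L))
  len <- segments$end - segments$start
  codes <- seq_len(2L^s - 1L)
  size <- vapply(codes, function(cd) {
    switch(mode,
      distinct = sum(len[mask == cd]),
      intersect = sum(len[bitwAnd(mask, cd) == cd & mask > 0L]),
      union = sum(len[bitwAnd(mask, cd) > 0L]))
  }, numeric(1))
  degree <- vapply(codes, function(cd) sum(bitwAnd(cd, 2L^(seq_len(s) - 1L)) > 0L),
                   numeric(1))
  flags <- t(vapply(codes, function(cd) bitwAnd(cd, 2L^(seq_len(s) - 1L)) > 0L,
                    logical(s)))
  colnames(flags) <- set_names
  comb <- data.frame(combination = vapply(codes, combo_name, character(1), set_names),
                     degree = degree, size = size, stringsAsFactors = FALSE)
  comb <- cbind(comb, as.data.frame(flags))
  if (drop_empty) comb <- comb[comb$size > 0, , drop = FALSE]
  comb <- comb[order(-comb$size, comb$degree), , drop = FALSE]
  rownames(comb) <- NULL
  list(combinations = comb, segments = segments)
}

#' Bin a genome into fixed-width windows
#'
#' @param chrom_sizes Data frame with columns `chrom` and `size` (or a named
#'   numeric vector).
#' @param bin_width Bin width in bp (> 0).
#' @return A `genomic_intervals` of consecutive bins
#'   `[k*w, min((k+1)*w, L))` per chromosome, in chromosome input order, with
#'   the bin width attached as `attr(, "bin_width")`.
#' @export
bin_genome <- function(chrom_sizes, bin_width) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- data.frame(chrom = names(chrom_sizes),
                              size = unname(chrom_sizes))
  }
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)),
            bin_width > 0, all(chrom_sizes$size > 0))
  parts <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    L <- chrom_sizes$size[i]
    st <- (seq_len(ceiling(L / bin_width)) - 1) * bin_width
    data.frame(chrom = chrom_sizes$chrom[i], start = st,
               end = pmin(st + bin_width, L), stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, parts)
  out <- genomic_intervals(b$chrom, b$start, b$end)
  attr(out, "bin_width") <- bin_width
  out
}

#' Normalize genomic signals to genome bins
#'
#' @param signal A `genomic_intervals` with a `value` column (finite where
#'   used by `weighted_mean`/`max`).
#' @param bins Bins from [bin_genome()].
#' @param statistic `"weighted_mean"` (overlap-length-weighted mean of values
#'   over the covered portion of the bin; a bin with no coverage is `NA`),
#'   `"coverage_fraction"` (covered bp / bin length, overlaps merged) or
#'   `"max"` (maximum value among overlapping intervals).
#' @return Numeric vector, one value per bin.
#' @export
signal_to_bins <- function(signal,
                           bins,
                           statistic = c("weighted_mean", "max", "coverage_fraction")) {
  statistic <- match.arg(statistic)
  bad <- setdiff(unique(signal$chrom), unique(bins$chrom))
  if (length(bad)) {
    stop(sprintf("signal chromosome '%s' is absent from the binned genome", bad[1L]),
         call. = FALSE)
  }
  if (statistic == "coverage_fraction") signal <- flatten_intervals(signal)
  out <- rep(if (statistic == "coverage_fraction") 0 else NA_real_, nrow(bins))
  w <- rep(0, nrow(bins))
  acc <- rep(0, nrow(bins))
  bin_row <- seq_len(nrow(bins))
  for (ch in unique(signal$chrom)) {
    bidx <- which(bins$chrom == ch)
    if (!length(bidx)) next
    b_start <- bins$start[bidx]; b_end <- bins$end[bidx]
    sidx <- which(signal$chrom == ch)
    for (q in sidx) {
      s <- signal$start[q]; e <- signal$end[q]
      hit <- which(b_end > s & b_start < e)
      if (!length(hit)) next
      ov <- pmin(b_end[hit], e) - pmax(b_start[hit], s)
      rows <- bidx[hit]
      if (statistic == "coverage_fraction") {
        out[rows] <- out[rows] + ov / (b_end[hit] - b_start[hit])
      } else if (statistic == "weighted_mean") {
        v <- signal$value[q]
        if (is.na(v)) next
        acc[rows] <- acc[rows] + ov * v
        w[rows] <- w[rows] + ov
      } else {
        v <- signal$value[q]
        if (is.na(v)) next
        out[rows] <- pmax(out[rows], v, na.rm = TRUE)
        out[rows][is.infinite(out[rows])] <- v
      }
    }
  }
  if (statistic == "weighted_mean") {
    covered <- w > 0
    out[covered] <- acc[covered] / w[covered]
  }
  out
}

#' Read a chrom.sizes file
#' @param path Two-column whitespace-separated file: chromosome, length.
#' @return Data frame with `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("chrom.sizes needs two columns", call. = FALSE)
  data.frame(chrom = as.character(d[[1L]]), size = as.numeric(d[[2L]]),
             stringsAsFactors = FALSE)
}
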