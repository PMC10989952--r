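# Anchored signal-enrichment matrices: how a genomic signal distributes
# around a list of genomic features (TSS-style anchors).

#' Normalize a genomic signal to windows around target anchors
#'
#' Each target contributes one matrix row covering
#' `[anchor - extend, anchor + extend)` divided into equal windows. The anchor
#' is the target start for `+`/unstranded targets and the target end for `-`
#' targets, and minus-strand rows are reversed so that upstream is always the
#' leftmost column. Continuous signals give the overlap-length-weighted mean
#' of `value` per window (covered portion only; an uncovered window is `NA`);
#' categorical signals give one matrix per category holding the fraction of
#' the window covered by that category.
#'
#' @param signal A `genomic_intervals`; `value` holds numbers (continuous) or
#'   category labels in `name` (categorical).
#' @param targets A `genomic_intervals` of features (strand honored).
#' @param extend Extension in bp on both sides of the anchor.
#' @param window Window width in bp; if it does not divide `2*extend` the
#'   trailing window is short (a log line notes it).
#' @param value_kind `"continuous"` or `"categorical"`.
#' @return For `continuous`: a numeric matrix (targets x windows) with
#'   `attr(, "windows")` giving signed window offsets. For `categorical`: a
#'   named list of such matrices, one per category.
#' @export
normalize_to_targets <- function(signal, targets, extend = 1000, window = 50,
                                 value_kind = c("continuous", "categorical")) {
  value_kind <- match.arg(value_kind)
  if (!nrow(targets)) stop("`targets` is empty", call. = FALSE)
  stopifnot(extend > 0, window > 0)
  span <- 2 * extend
  nw <- ceiling(span / window)
  if (nw * window != span) {
    hc_log(sprintf("normalize_to_targets: %d bp span is not a multiple of %d bp; trailing window is short",
                   span, window))
  }
  anchors <- ifelse(!is.na(targets$strand) & targets$strand == "-",
                    targets$end, targets$start)
  minus <- !is.na(targets$strand) & targets$strand == "-"
  cats <- if (value_kind == "categorical") {
    lv <- sort(unique(signal$name[!is.na(signal$name)]))
    if (!length(lv)) stop("categorical signal needs labels in `name`", call. = FALSE)
    lv
  } else NULL
  one_cat <- function(sig) {
    M <- matrix(NA_real_, nrow(targets), nw)
    W <- matrix(0, 1L, nw)
    for (ti in seq_len(nrow(targets))) {
      a <- anchors[ti]
      w_start <- a - extend + (seq_len(nw) - 1L) * window
      w_end <- pmin(w_start + window, a + extend)
      sidx <- which(sig$chrom == targets$chrom[ti] & sig$end > a - extend &
                      sig$start < a + extend)
      acc <- rep(0, nw); wt <- rep(0, nw)
      for (q in sidx) {
        ov <- pmin(w_end, sig$end[q]) - pmax(w_start, sig$start[q])
        hit <- ov > 0
        if (value_kind == "continuous") {
          v <- sig$value[q]
          if (is.na(v)) next
          acc[hit] <- acc[hit] + ov[hit] * v
          wt[hit] <- wt[hit] + ov[hit]
        } else {
          acc[hit] <- acc[hit] + ov[hit]
          wt[hit] <- 1
        }
      }
      row <- rep(NA_real_, nw)
      if (value_kind == "continuous") {
        row[wt > 0] <- acc[wt > 0] / wt[wt > 0]
      } else {
        row <- acc / (w_end - w_start)
      }
      if (minus[ti]) row <- rev(row)
      M[ti, ] <- row
    }
    offs <- -extend + (seq_len(nw) - 0.5) * window
    colnames(M) <- sprintf("%+d", as.integer(round(offs)))
    rownames(M) <- if (!all(is.na(targets$name))) targets$name else NULL
    attr(M, "windows") <- offs
    M
  }
  if (value_kind == "continuous") {
    one_cat(signal)
  } else {
    out <- lapply(cats, function(cc) {
      sub <- signal[!is.na(signal$name) & signal$name == cc, , drop = FALSE]
      one_cat(flatten_intervals_keep(sub))
    })
    names(out) <- cats
    out
  }
}

# flatten while keeping the set's identity (categorical coverage must not
# double count overlapping intervals of the same category)
flatten_intervals_keep <- function(gi) {
  if (!nrow(gi)) return(gi)
  f <- flatten_intervals(gi)
  genomic_intervals(f$chrom, f$start, f$end)
}

#' Average enrichment profile per slice
#'
#' Summarizes an enrichment matrix over row slices: one profile per slice,
#' the column-wise mean over that slice's rows (missing values excluded per
#' column).
#'
#' @param m Enrichment matrix (targets x windows).
#' @param slices A `slice_spec` over the rows (default: one slice of all
#'   rows).
#' @return Numeric matrix (slices x windows), row-named by slice labels.
#' @export
enriched_profile <- function(m, slices = NULL) {
  m <- as.matrix(m)
  if (is.null(slices)) slices <- single_slice(nrow(m), "row")
  stopifnot(inherits(slices, "slice_spec"), slices$n == nrow(m))
  if (any(lengths(slices$items) == 0L)) {
    stop("empty slice in enrichment profile", call. = FALSE)
  }
  prof <- t(vapply(slices$items, function(idx) {
    colMeans(m[idx, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(m))))
  rownames(prof) <- slices$labels
  prof
}

#' Enrichment heatmap
#'
#' Wraps an enrichment matrix from [normalize_to_targets()] as a heatmap with
#' columns in positional order (no column clustering) and an average
#' enrichment profile drawn as a top lines annotation.
#'
#' @param m Enrichment matrix.
#' @param name Heatmap name.
#' @param colors Optional `color_mapping`.
#' @param ... Passed to [heat_map()] (e.g. `row_km`, `row_split`).
#' @return A `heat_map`.
#' @export
enriched_heatmap <- function(m, name = "enrichment", colors = NULL, ...) {
  m2 <- m
  if (anyNA(m2)) m2[is.na(m2)] <- 0
  prof <- colMeans(m, na.rm = TRUE)
  heat_map(m2, name = name, colors = colors,
           cluster_columns = FALSE, show_column_names = FALSE,
           show_row_names = FALSE,
           top_annotation = annotation_block(
             enrichment = anno_lines(prof, size = 0.7), axis = "column"),
           ...)
}
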