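#' @importFrom stats ks.test bw.nrd0
NULL

#' Kolmogorov-Smirnov distance between two samples
#'
#' The supremum distance between the two empirical distribution functions;
#' zero for identical samples, symmetric and non-negative.
#'
#' @param x,y Numeric vectors.
#' @return A single number in `[0, 1]`.
#' @export
ks_distance <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  unname(suppressWarnings(ks.test(x, y)$statistic))
}

#' Pairwise Kolmogorov-Smirnov distance matrix
#' @param data List of numeric vectors or a matrix (one sample per column).
#' @return A `dist` object over the samples.
#' @export
ks_distance_matrix <- function(data) {
  cols <- if (is.matrix(data)) lapply(seq_len(ncol(data)), function(j) data[, j])
          else data
  k <- length(cols)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- ks_distance(cols[[i]], cols[[j]])
    }
  }
  stats::as.dist(d)
}

#' Density heatmap of many distributions
#'
#' One column per input distribution: the column holds Gaussian kernel density
#' estimates (Silverman's bandwidth) evaluated on a value grid shared across
#' all inputs, and color maps the density. Boxes and violins stop scaling to
#' hundreds of distributions; a density heatmap does. Columns can optionally
#' be clustered by the Kolmogorov-Smirnov distance between the raw samples.
#'
#' @param data Numeric matrix (one distribution per column) or a named list of
#'   numeric vectors.
#' @param grid_points Number of grid points spanning the pooled value range.
#' @param cluster_columns Cluster columns by KS distance (default `FALSE`).
#' @param colors Optional continuous `color_mapping` for the density values.
#' @param name Heatmap name.
#' @return A `heat_map` whose matrix rows are the value grid (top = high).
#' @export
density_heatmap <- function(data, grid_points = 500, cluster_columns = FALSE,
                            colors = NULL, name = "density") {
  cols <- if (is.matrix(data)) {
    out <- lapply(seq_len(ncol(data)), function(j) data[, j])
    names(out) <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
    out
  } else {
    if (is.null(names(data))) names(data) <- paste0("V", seq_along(data))
    data
  }
  if (!length(cols)) stop("need at least one distribution", call. = FALSE)
  cols <- lapply(cols, function(v) v[is.finite(v)])
  bad <- which(lengths(cols) < 2L)
  if (length(bad)) {
    stop(sprintf("distribution '%s' has fewer than 2 finite values",
                 names(cols)[bad[1L]]), call. = FALSE)
  }
  const <- which(vapply(cols, function(v) diff(range(v)) == 0, logical(1)))
  if (length(const)) {
    stop(sprintf(
      "distribution '%s' is constant: its kernel bandwidth degenerates; jitter the values or drop the column",
      names(cols)[const[1L]]), call. = FALSE)
  }
  rng <- range(unlist(cols))
  grid <- seq(rng[1L], rng[2L], length.out = grid_points)
  D <- vapply(cols, function(v) {
    stats::density(v, bw = bw.nrd0(v), from = rng[1L], to = rng[2L],
                   n = grid_points)$y
  }, numeric(grid_points))
  # top of the heatmap shows high values
  D <- D[rev(seq_len(grid_points)), , drop = FALSE]
  rownames(D) <- format(rev(grid), digits = 3)
  cl <- FALSE
  if (isTRUE(cluster_columns) && length(cols) >= 2L) {
    cl <- as.dendrogram(hclust(ks_distance_matrix(cols), method = "complete"))
  }
  if (is.null(colors)) {
    colors <- color_mapping(c(0, max(D) / 2, max(D)),
                            c("#FFFFFF", "#FEB24C", "#BD0026"))
  }
  hm <- heat_map(D, name = name, colors = colors, cluster_rows = FALSE,
                 cluster_columns = cl, show_row_names = FALSE,
                 show_column_names = TRUE)
  attr(hm, "grid") <- rev(grid)
  attr(hm, "grid_step") <- diff(grid)[1L]
  hm
}
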