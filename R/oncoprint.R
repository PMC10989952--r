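# oncoPrint: gene x sample grids of alteration glyphs, ordered to expose
# mutual exclusivity of events across samples.

#' Construct an alteration table
#'
#' @param events Data frame with columns `gene`, `sample`, `type` (one row per
#'   alteration event; repeated events are deduplicated).
#' @param genes,samples Optional full gene/sample universes (default: observed,
#'   in first-occurrence order).
#' @return An `alteration_table` with fields `genes`, `samples`, `types` and
#'   the deduplicated `events`.
#' @export
alteration_table <- function(events, genes = NULL, samples = NULL) {
  stopifnot(is.data.frame(events),
            all(c("gene", "sample", "type") %in% names(events)))
  events <- unique(events[, c("gene", "sample", "type")])
  events$gene <- as.character(events$gene)
  events$sample <- as.character(events$sample)
  events$type <- as.character(events$type)
  genes <- genes %||% unique(events$gene)
  samples <- samples %||% unique(events$sample)
  if (!all(events$gene %in% genes)) stop("events refer to genes outside `genes`", call. = FALSE)
  if (!all(events$sample %in% samples)) stop("events refer to samples outside `samples`", call. = FALSE)
  structure(list(genes = as.character(genes), samples = as.character(samples),
                 types = sort(unique(events$type)), events = events),
            class = "alteration_table")
}

#' @export
print.alteration_table <- function(x, ...) {
  cat(sprintf("<alteration_table> %d gene(s) x %d sample(s), %d event(s), types: %s\n",
              length(x$genes), length(x$samples), nrow(x$events),
              paste(x$types, collapse = ", ")))
  invisible(x)
}

# gene x sample logical matrix: any alteration (a sample with several
# alteration types in one gene counts once).
alteration_binary <- function(tab) {
  b <- matrix(FALSE, length(tab$genes), length(tab$samples),
              dimnames = list(tab$genes, tab$samples))
  gi <- match(tab$events$gene, tab$genes)
  si <- match(tab$events$sample, tab$samples)
  b[cbind(gi, si)] <- TRUE
  b
}

#' oncoPrint gene and sample ordering
#'
#' Genes are sorted by decreasing number of altered samples (ties keep input
#' order). Samples are then memo-sorted: ordered by the decreasing
#' lexicographic rank of their binary alteration vector over the ordered
#' genes (ties keep input order), which pushes mutually exclusive alteration
#' patterns into the staircase layout.
#'
#' @param tab An `alteration_table`.
#' @return List with integer vectors `gene_order` and `sample_order`.
#' @export
oncoprint_order <- function(tab) {
  stopifnot(inherits(tab, "alteration_table"))
  if (!nrow(tab$events)) {
    return(list(gene_order = seq_along(tab$genes),
                sample_order = seq_along(tab$samples)))
  }
  b <- alteration_binary(tab)
  counts <- rowSums(b)
  gene_order <- order(-counts, seq_along(tab$genes))
  keys <- lapply(gene_order, function(g) -as.integer(b[g, ]))
  sample_order <- do.call(order, c(keys, list(seq_len(ncol(b)))))
  list(gene_order = gene_order, sample_order = sample_order)
}

default_glyphs <- function(types) {
  k <- length(types)
  cols <- QUALITATIVE_PALETTE[((seq_len(k) - 1L) %% length(QUALITATIVE_PALETTE)) + 1L]
  out <- lapply(seq_len(k), function(i) {
    list(fill = cols[i], width = 0.9, height = max(0.35, 0.9 - 0.22 * (i - 1L)),
         z = i)
  })
  names(out) <- types
  out
}

#' oncoPrint heatmap
#'
#' Builds a gene x sample heatmap whose cells stack one glyph per alteration
#' category (in catalogue z-order) over a background glyph, with per-sample
#' (top) and per-gene (right) stacked barplot annotations counting events by
#' type. Rows and columns use [oncoprint_order()]. The result is an ordinary
#' `heat_map`, so it concatenates to heatmaps of other genomic data.
#'
#' @param tab An `alteration_table`.
#' @param glyphs Named list (one entry per alteration type) of
#'   `list(fill, width, height, z)` glyph descriptors; default catalogue
#'   derived from the qualitative palette. Every type occurring in the events
#'   must be registered.
#' @param background Background cell color.
#' @param show_annotations Attach the count barplot annotations.
#' @return A `heat_map`.
#' @export
onco_print <- function(tab, glyphs = NULL, background = "#EDEDED",
                       show_annotations = TRUE) {
  stopifnot(inherits(tab, "alteration_table"))
  glyphs <- glyphs %||% default_glyphs(tab$types)
  missing_types <- setdiff(unique(tab$events$type), names(glyphs))
  if (length(missing_types)) {
    stop(sprintf("no glyph registered for alteration type '%s'", missing_types[1L]),
         call. = FALSE)
  }
  ord <- oncoprint_order(tab)
  ng <- length(tab$genes); ns <- length(tab$samples)
  # cell sets: per (gene, sample) the types present, in z-order
  key <- paste(match(tab$events$gene, tab$genes),
               match(tab$events$sample, tab$samples))
  cells <- split(tab$events$type, key)
  body <- matrix("", ng, ns, dimnames = list(tab$genes, tab$samples))
  cm <- discrete_color_mapping(background, levels = "")
  zord <- names(glyphs)[order(vapply(glyphs, function(g) g$z, numeric(1)))]
  cell_fun <- function(i, j, value, color, x, y, w, h) {
    types <- cells[[paste(i, j)]]
    if (is.null(types)) return(NULL)
    types <- zord[zord %in% types]
    out <- empty_prims()
    for (tp in types) {
      g <- glyphs[[tp]]
      gw <- w * g$width; gh <- h * g$height
      out <- prims_concat(out, prim_rect(x + (w - gw) / 2, y + (h - gh) / 2,
                                         gw, gh, fill = g$fill))
    }
    out
  }
  top_anno <- right_anno <- NULL
  if (show_annotations) {
    counts_by <- function(margin) {
      idx <- if (margin == "sample") tab$samples else tab$genes
      m <- matrix(0, length(idx), length(tab$types),
                  dimnames = list(idx, tab$types))
      t_ <- table(tab$events[[margin]], tab$events$type)
      m[rownames(t_), colnames(t_)] <- t_
      m
    }
    glyph_fill <- vapply(glyphs[tab$types], function(g) g$fill, character(1))
    top_anno <- annotation_block(
      alterations = anno_barplot(counts_by("sample"), fill = NULL, size = 0.7),
      axis = "column")
    top_anno$tracks[[1L]]$params$fill <- glyph_fill
    right_anno <- row_annotation(
      alterations = anno_barplot(counts_by("gene"), fill = NULL, size = 0.7))
    right_anno$tracks[[1L]]$params$fill <- glyph_fill
  }
  hm <- heat_map(body, name = "oncoprint", colors = cm,
                 cluster_rows = FALSE, cluster_columns = FALSE,
                 row_order = ord$gene_order, column_order = ord$sample_order,
                 cell_fun = cell_fun, top_annotation = top_anno,
                 right_annotation = right_anno,
                 show_row_names = TRUE, show_column_names = FALSE)
  attr(hm, "alteration_table") <- tab
  attr(hm, "glyphs") <- glyphs
  hm
}
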