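# UpSet: set-intersection sizes in distinct / intersect / union modes.

#' Build a membership matrix from a list of sets
#' @param sets Named list of element vectors.
#' @return Logical matrix (elements x sets) over the union of all elements.
#' @export
make_membership <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all sets must be named", call. = FALSE)
  }
  elements <- sort(unique(unlist(lapply(sets, as.character))))
  m <- vapply(sets, function(s) elements %in% as.character(s),
              logical(length(elements)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(elements))
  dimnames(m) <- list(elements, names(sets))
  m
}

combo_name <- function(code, set_names) {
  paste(set_names[bitwAnd(code, 2L^(seq_along(set_names) - 1L)) > 0L],
        collapse = "&")
}

#' Set combination sizes for an UpSet plot
#'
#' For every non-empty subset S of the sets, `distinct` counts elements
#' belonging to exactly the sets of S, `intersect` counts elements belonging
#' to at least all of S, and `union` counts elements belonging to at least one
#' of S. Elements in no set are excluded from counting.
#'
#' @param member Logical membership matrix (elements x sets), e.g. from
#'   [make_membership()].
#' @param mode `"distinct"` (default), `"intersect"` or `"union"`.
#' @param drop_empty Drop combinations with size 0.
#' @return Data frame with `combination` (set names joined by `&`), `degree`,
#'   `size`, and one logical column per set.
#' @export
upset_combinations <- function(member, mode = c("distinct", "intersect", "union"),
                               drop_empty = TRUE) {
  mode <- match.arg(mode)
  member <- as.matrix(member)
  storage.mode(member) <- "logical"
  s <- ncol(member)
  stopifnot(s >= 1L, s <= 25L)
  set_names <- colnames(member) %||% paste0("S", seq_len(s))
  mask <- as.integer(member %*% 2L^(seq_len(s) - 1L))
  mask <- mask[mask > 0L]                    # all-FALSE rows excluded
  codes <- seq_len(2L^s - 1L)
  size <- vapply(codes, function(cd) {
    switch(mode,
      distinct = sum(mask == cd),
      intersect = sum(bitwAnd(mask, cd) == cd),
      union = sum(bitwAnd(mask, cd) > 0L))
  }, numeric(1))
  degree <- vapply(codes, function(cd) sum(bitwAnd(cd, 2L^(seq_len(s) - 1L)) > 0L),
                   numeric(1))
  flags <- t(vapply(codes, function(cd) bitwAnd(cd, 2L^(seq_len(s) - 1L)) > 0L,
                    logical(s)))
  colnames(flags) <- set_names
  out <- data.frame(combination = vapply(codes, combo_name, character(1), set_names),
                    degree = degree, size = size, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  if (drop_empty) out <- out[out$size > 0, , drop = FALSE]
  out <- out[order(-out$size, out$degree), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' UpSet plot as a heatmap model
#'
#' The combination matrix (sets x combinations, dots for membership) becomes
#' a categorical heatmap with a top barplot of combination sizes and a right
#' barplot of per-set sizes.
#'
#' @param member Membership matrix, or a named list of sets, or a named list
#'   of `genomic_intervals` (then sizes are base pairs via [region_upset()]).
#' @param mode Combination mode, see [upset_combinations()].
#' @return A `heat_map` with the combination table in
#'   `attr(, "combinations")`.
#' @export
upset_plot <- function(member, mode = "distinct") {
  if (is.list(member) && length(member) &&
      inherits(member[[1L]], "genomic_intervals")) {
    comb <- region_upset(member, mode)$combinations
    set_names <- names(member)
    set_sizes <- vapply(member, function(gi) {
      f <- flatten_intervals(gi); sum(f$end - f$start)
    }, numeric(1))
  } else {
    if (is.list(member) && !is.matrix(member)) member <- make_membership(member)
    comb <- upset_combinations(member, mode)
    set_names <- colnames(member)
    set_sizes <- colSums(member)
  }
  comb <- comb[comb$size > 0, , drop = FALSE]
  k <- nrow(comb)
  body <- matrix("out", length(set_names), max(k, 1L),
                 dimnames = list(set_names, comb$combination))
  for (i in seq_len(k)) {
    body[as.logical(unlist(comb[i, set_names])), i] <- "in"
  }
  cm <- discrete_color_mapping(c("in" = "#252525", "out" = "#E8E8E8"))
  hm <- heat_map(body, name = "upset", colors = cm,
                 cluster_rows = FALSE, cluster_columns = FALSE,
                 top_annotation = annotation_block(
                   size = anno_barplot(comb$size, size = 0.9), axis = "column"),
                 right_annotation = row_annotation(
                   set_size = anno_barplot(unname(set_sizes), size = 0.7)),
                 show_column_names = FALSE)
  attr(hm, "combinations") <- comb
  hm
}
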