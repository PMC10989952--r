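# File readers/writers. Delimited tables are parsed line-by-line so that
# ragged input can be reported with its line number.

split_fields <- function(lines, sep) strsplit(lines, sep, fixed = TRUE)

#' Read a matrix from TSV/CSV
#'
#' The whole-matrix type rule applies: if every data cell parses as a number
#' the matrix is numeric, otherwise the entire matrix is categorical (a
#' heatmap has one color mapping) and a log line notes the decision. Empty
#' strings and `"NA"` are missing.
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"` (default: from the file extension).
#' @param header First line holds column names.
#' @param row_names First column holds row names.
#' @return A `value_matrix`.
#' @export
read_matrix <- function(path, format = NULL, header = TRUE, row_names = TRUE) {
  format <- format %||% (if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv")
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("'%s' is empty", path), call. = FALSE)
  fields <- split_fields(lines, sep)
  widths <- lengths(fields)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("'%s': ragged row at line %d (%d fields, expected %d)",
                 path, bad, widths[bad], widths[1L]), call. = FALSE)
  }
  cn <- NULL
  if (header) {
    cn <- fields[[1L]]
    fields <- fields[-1L]
    if (!length(fields)) stop(sprintf("'%s' has a header but no data", path), call. = FALSE)
  }
  rn <- NULL
  if (row_names) {
    rn <- vapply(fields, `[[`, character(1), 1L)
    fields <- lapply(fields, `[`, -1L)
    if (header && length(cn) == length(fields[[1L]]) + 1L) cn <- cn[-1L]
  }
  raw <- do.call(rbind, fields)
  raw[raw %in% c("", "NA")] <- NA
  num <- suppressWarnings(as.numeric(raw))
  if (all(!is.na(num) | is.na(raw))) {
    m <- matrix(num, nrow(raw), ncol(raw))
  } else {
    hc_log(sprintf("read_matrix: '%s' contains non-numeric cells; reading the whole matrix as categorical",
                   basename(path)))
    m <- raw
  }
  value_matrix(m, row_names = rn, col_names = cn)
}

#' Write a value matrix to TSV/CSV
#' @param vm A `value_matrix` (or matrix).
#' @param path Output path.
#' @param format `"tsv"` or `"csv"` (default: from the extension).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(vm, path, format = NULL) {
  vm <- as_value_matrix(vm)
  format <- format %||% (if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv")
  sep <- if (format == "csv") "," else "\t"
  m <- vm$values
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cn <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  body <- apply(m, 1L, function(r) paste(ifelse(is.na(r), "NA",
    if (is.numeric(m)) format(r, digits = 15, trim = TRUE, scientific = FALSE) else r),
    collapse = sep))
  lines <- c(paste(c("id", cn), collapse = sep), paste(rn, body, sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file
#'
#' Three or more whitespace/tab-separated columns: chrom, start, end
#' (0-based half-open), with an optional 4th column read as a numeric value
#' when it parses as a number and as a name otherwise, and an optional 6th
#' strand column.
#'
#' @param path File path.
#' @return A `genomic_intervals`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lnum <- which(keep)
  fields <- strsplit(lines[keep], "[ \t]+")
  if (!length(fields)) {
    return(genomic_intervals(character(0), numeric(0), numeric(0) + 1))
  }
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop(sprintf("'%s': line %d has fewer than 3 BED columns", path,
                 lnum[which(ncols < 3L)[1L]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("'%s': invalid coordinates at line %d (start must be a non-negative number < end)",
                 path, lnum[bad[1L]]), call. = FALSE)
  }
  value <- rep(NA_real_, length(chrom))
  name <- rep(NA_character_, length(chrom))
  has4 <- ncols >= 4L
  if (any(has4)) {
    col4 <- rep(NA_character_, length(chrom))
    col4[has4] <- vapply(fields[has4], `[[`, character(1), 4L)
    v <- suppressWarnings(as.numeric(col4))
    value[has4 & !is.na(v)] <- v[has4 & !is.na(v)]
    name[has4 & is.na(v)] <- col4[has4 & is.na(v)]
  }
  strand <- rep(NA_character_, length(chrom))
  has6 <- ncols >= 6L
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[[`, character(1), 6L)
    s6[!s6 %in% c("+", "-")] <- NA_character_
    strand[has6] <- s6
  }
  genomic_intervals(chrom, start, end, value = value, strand = strand,
                    name = name)
}

#' Write genomic intervals as BED
#' @param gi A `genomic_intervals`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gi, path) {
  score <- ifelse(is.na(gi$value),
                  ifelse(is.na(gi$name), ".", gi$name),
                  format(gi$value, trim = TRUE, digits = 10, scientific = FALSE))
  has_strand <- !all(is.na(gi$strand))
  lines <- if (has_strand) {
    sprintf("%s\t%d\t%d\t%s\t.\t%s", gi$chrom, as.integer(gi$start),
            as.integer(gi$end), score, ifelse(is.na(gi$strand), ".", gi$strand))
  } else {
    sprintf("%s\t%d\t%d\t%s", gi$chrom, as.integer(gi$start),
            as.integer(gi$end), score)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF-like alteration table
#'
#' Tab-separated with a header naming (at least) `gene`, `sample` and
#' `alteration_type` (or `type`); one row per alteration event.
#'
#' @param path File path.
#' @return An `alteration_table`.
#' @export
read_alterations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(d) <- tolower(names(d))
  if ("alteration_type" %in% names(d)) d$type <- d$alteration_type
  need <- c("gene", "sample", "type")
  if (!all(need %in% names(d))) {
    stop(sprintf("'%s' must have columns gene, sample, alteration_type", path),
         call. = FALSE)
  }
  alteration_table(d[, need])
}

#' Read an annotation table (TSV)
#'
#' One column per simple annotation; the first column holds item identifiers.
#' @param path File path.
#' @return Data frame (rows in file order, identifiers as row names).
#' @export
read_annotation_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(d) <- d[[1L]]
  d[, -1L, drop = FALSE]
}
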