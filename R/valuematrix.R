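#' Construct a value matrix
#'
#' A `value_matrix` is the object every heatmap visualizes: a rectangular
#' numeric or categorical matrix with optional unique row/column names.
#' Numeric input gives a `"numeric"` matrix whose values are color-interpolated;
#' any non-numeric input gives a `"categorical"` matrix whose labels are mapped
#' through a discrete palette (interpolation between labels is meaningless and
#' refused downstream). Missing values are permitted and flagged.
#'
#' @param values A matrix, or something coercible to one (vectors become
#'   one-column matrices).
#' @param row_names,col_names Optional character vectors of names; lengths must
#'   match the matrix dimensions and entries must be unique.
#' @return An object of class `value_matrix` with fields `values`, `kind`
#'   (`"numeric"` or `"categorical"`) and `has_na`.
#' @export
value_matrix <- function(values, row_names = NULL, col_names = NULL) {
  if (!is.matrix(values)) {
    values <- as.matrix(values)
  }
  if (length(dim(values)) != 2L) {
    stop("`values` must be two-dimensional", call. = FALSE)
  }
  kind <- if (is.numeric(values)) "numeric" else "categorical"
  if (kind == "categorical") {
    storage.mode(values) <- "character"
  }
  if (!is.null(row_names)) rownames(values) <- row_names
  if (!is.null(col_names)) colnames(values) <- col_names
  check_dimnames <- function(nm, n, what) {
    if (is.null(nm)) return(invisible())
    if (length(nm) != n) {
      stop(sprintf("%s names have length %d but the matrix has %d %ss",
                   what, length(nm), n, what), call. = FALSE)
    }
    if (anyDuplicated(nm)) {
      stop(sprintf("duplicated %s name: '%s'", what, nm[duplicated(nm)][1L]),
           call. = FALSE)
    }
  }
  check_dimnames(rownames(values), nrow(values), "row")
  check_dimnames(colnames(values), ncol(values), "column")
  structure(
    list(values = values, kind = kind, has_na = anyNA(values)),
    class = "value_matrix"
  )
}

#' Test for a value matrix
#' @param x Any object.
#' @return `TRUE` if `x` is a `value_matrix`.
#' @export
is_value_matrix <- function(x) inherits(x, "value_matrix")

#' Coerce to a value matrix
#' @param x A matrix, data frame or `value_matrix`.
#' @return A `value_matrix`.
#' @export
as_value_matrix <- function(x) {
  if (is_value_matrix(x)) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  value_matrix(x)
}

#' @export
dim.value_matrix <- function(x) dim(x$values)

#' @export
print.value_matrix <- function(x, ...) {
  cat(sprintf("<value_matrix> %d x %d, %s%s\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (x$has_na) ", has missing values" else ""))
  invisible(x)
}

vm_values <- function(x) x$values

vm_axis_n <- function(x, axis) {
  if (axis == "row") nrow(x$values) else ncol(x$values)
}

vm_axis_names <- function(x, axis) {
  if (axis == "row") rownames(x$values) else colnames(x$values)
}

match_axis <- function(axis) match.arg(axis, c("row", "column"))
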