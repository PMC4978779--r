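#' Construct an ordinal response matrix
#'
#' Wraps an `n x p` matrix of ordered category codes `1..q` together with the
#' declared number of categories `q`.  `q` is always declared by the caller:
#' it is never inferred from the observed maximum, so rare top categories
#' that happen not to occur in a sample are still modelled.
#'
#' @param x matrix (or object coercible to one) of integer codes in `1..q`.
#' @param q declared number of ordered categories, `q >= 2`.
#' @return an `ordinal_matrix`: an integer matrix with attribute `q`.
#' @examples
#' y <- ordinal_matrix(matrix(c(1, 2, 3, 3, 2, 1), 2, 3), q = 3)
#' attr(y, "q")
#' @export
ordinal_matrix <- function(x, q) {
  x <- as.matrix(x)
  if (length(q) != 1L || is.na(q) || q < 2 || q != round(q))
    stop("`q` must be a single integer >= 2", call. = FALSE)
  q <- as.integer(q)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("the response matrix must have at least one row and one column",
         call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x))
    stop("missing or non-integer entries are not permitted", call. = FALSE)
  if (any(x < 1L) || any(x > q))
    stop("all entries must be category codes in 1..q (q = ", q, ")",
         call. = FALSE)
  structure(x, q = q, class = c("ordinal_matrix", "matrix", "array"))
}

#' @export
print.ordinal_matrix <- function(x, ...) {
  cat(sprintf("ordinal_matrix: %d x %d, q = %d categories\n",
              nrow(x), ncol(x), attr(x, "q")))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(y, ...)
  invisible(x)
}

#' Read an ordinal matrix from CSV
#'
#' Reads a comma-separated grid of integer category codes.  No missing values
#' are permitted (models here assume complete cases).
#'
#' @param path CSV file of integers.
#' @param q declared number of categories.
#' @param header does the file carry a single header row?
#' @param zero_based if `TRUE`, codes on file are `0..q-1` and are shifted up
#'   by one on read.
#' @return an [ordinal_matrix()].
#' @export
read_ordinal_csv <- function(path, q, header = FALSE, zero_based = FALSE) {
  df <- utils::read.csv(path, header = header, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("CSV must contain only integer category codes", call. = FALSE)
  if (any(m != round(m)))
    stop("CSV contains non-integer values", call. = FALSE)
  if (zero_based) m <- m + 1
  dimnames(m) <- NULL
  ordinal_matrix(m, q)
}

#' Write an ordinal matrix to CSV
#'
#' @param x an [ordinal_matrix()] (or plain integer matrix).
#' @param path output file.
#' @export
write_ordinal_csv <- function(x, path) {
  y <- as.matrix(x)
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  utils::write.table(y, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
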