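#' Jaccard similarity for binary leaf orientation images
#'
#' The similarity between two binary edge-orientation images is measured by
#' the Jaccard coefficient, which ignores positions where both images are 0.
#' For sparse edge maps (most pixels background) this is the natural metric:
#' shared background carries no information about shared shape.
#'
#' Inputs may be binary vectors or 32x16 binary matrices (matrices are
#' flattened row-major via [vectorize()]).  Counting is exact integer
#' arithmetic; the single division happens at the end, so printed worked
#' values such as 2/7 reproduce bit-exactly.
#'
#' @param a,b binary vectors (values 0/1) of equal length, or binary
#'   matrices of equal shape.
#' @return `jaccard_counts()` returns a list with integer fields `m11`
#'   (both 1), `m01` (`a` 0, `b` 1) and `m10` (`a` 1, `b` 0).
#' @examples
#' v1 <- c(1, 0, 0, 1, 0, 0, 1, 1, 0, 0)
#' v2 <- c(0, 0, 1, 1, 0, 1, 0, 1, 1, 0)
#' jaccard_counts(v1, v2)       # m11 = 2, m01 = 3, m10 = 2
#' jaccard_coefficient(v1, v2)  # 2/7
#' jaccard_distance(v1, v2)     # 5/7
#' @export
jaccard_counts <- function(a, b) {
  a <- as_binary_vector(a)
  b <- as_binary_vector(b)
  if (length(a) != length(b)) {
    stop("binary vectors must have equal length (", length(a), " vs ",
         length(b), ")")
  }
  m11 <- sum(a == 1L & b == 1L)
  m01 <- sum(a == 0L & b == 1L)
  m10 <- sum(a == 1L & b == 0L)
  list(m11 = as.integer(m11), m01 = as.integer(m01), m10 = as.integer(m10))
}

#' @rdname jaccard_counts
#' @param allow_empty if `TRUE`, a pair of all-zero vectors (empty union) is
#'   treated as identical: coefficient 1, distance 0.  The default `FALSE`
#'   raises an error, because an all-zero orientation image signals failed
#'   preprocessing and should surface loudly rather than silently score as
#'   NaN or a perfect match.
#' @return `jaccard_coefficient()` returns M11 / (M11 + M01 + M10) in
#'   \[0, 1\]; `jaccard_distance()` its complement.
#' @export
jaccard_coefficient <- function(a, b, allow_empty = FALSE) {
  cn <- jaccard_counts(a, b)
  denom <- cn$m11 + cn$m01 + cn$m10
  if (denom == 0L) {
    if (allow_empty) return(1)
    stop("degenerate pair: both binary vectors are all-zero (empty union)")
  }
  cn$m11 / denom
}

#' @rdname jaccard_counts
#' @export
jaccard_distance <- function(a, b, allow_empty = FALSE) {
  1 - jaccard_coefficient(a, b, allow_empty = allow_empty)
}

#' Average Jaccard coefficient of a test image against each training class
#'
#' Averaging within a class damps the influence of unusual or irregular
#' individual leaves: a single odd training leaf cannot pull its class to
#' the top or bottom of the ranking on its own.  The per-class averages are
#' the statistic on which the coarse candidate-selection stage ranks
#' species.
#'
#' @param y binary vector (or 32x16 binary matrix): the test orientation
#'   image.
#' @param x matrix of training vectors, one column per training image (a
#'   list of vectors/matrices is also accepted).
#' @param labels class label per column of `x`.
#' @param allow_empty passed through to [jaccard_coefficient()].
#' @return an object of class `class_average_table`: a data.frame with one
#'   row per class and columns `class`, `avg_jaccard`, `n`.
#' @export
average_class_coefficient <- function(y, x, labels, allow_empty = FALSE) {
  y <- as_binary_vector(y)
  x <- as_binary_matrix(x, length(y))
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    stop("need one class label per training vector")
  }
  classes <- sort(unique(labels))
  coefs <- vapply(seq_len(ncol(x)), function(j) {
    jaccard_coefficient(y, x[, j], allow_empty = allow_empty)
  }, numeric(1))
  avg <- vapply(classes, function(cl) mean(coefs[labels == cl]), numeric(1))
  n <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  tab <- data.frame(class = classes, avg_jaccard = unname(avg),
                    n = unname(n), stringsAsFactors = FALSE)
  class(tab) <- c("class_average_table", "data.frame")
  tab
}

## ---- input coercion helpers ------------------------------------------------

as_binary_vector <- function(a) {
  if (is.matrix(a)) a <- vectorize(a, target_shape = dim(a))
  if (length(a) == 0L) stop("empty binary vector")
  av <- as.integer(a)
  if (anyNA(av) || !all(av %in% c(0L, 1L))) {
    stop("binary vector must contain only 0 and 1")
  }
  av
}

as_binary_matrix <- function(x, d) {
  if (is.list(x)) x <- vapply(x, as_binary_vector, integer(d))
  if (!is.matrix(x)) x <- matrix(x, nrow = d)
  if (nrow(x) != d) stop("training vectors must have length ", d)
  if (ncol(x) < 1L) stop("need at least one training vector")
  storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L))) stop("training vectors must be binary")
  x
}
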