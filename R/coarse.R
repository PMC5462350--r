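#' Coarse recognition: shortlist candidate species by average Jaccard
#'
#' Ranks classes by their average Jaccard coefficient with the test image
#' (largest first) and keeps the top `S`; the remaining classes are
#' excluded from all further computation.  This screening removes
#' dissimilar species cheaply before the expensive sparse solve, and drops
#' atoms that would otherwise only add noise to the representation.
#'
#' Ties at the cut are broken deterministically by sorting on
#' (-score, class label), so the shortlist is reproducible across runs and
#' platforms.
#'
#' @param table a `class_average_table` from [average_class_coefficient()]
#'   (or a data.frame with columns `class` and `avg_jaccard`).
#' @param S number of classes to keep, `1 <= S <= C`.
#' @return an object of class `candidate_shortlist`: list with
#'   `selected_classes`, `scores` (named, descending), `excluded_classes`
#'   and `S`.
#' @export
select_candidates <- function(table, S) {
  stopifnot(is.data.frame(table), all(c("class", "avg_jaccard") %in% names(table)))
  C <- nrow(table)
  S <- as.integer(S)
  if (length(S) != 1L || is.na(S) || S < 1L || S > C) {
    stop("S must be an integer in [1, ", C, "]")
  }
  ord <- order(-table$avg_jaccard, table$class)
  sel <- ord[seq_len(S)]
  structure(list(
    selected_classes = table$class[sel],
    scores = stats::setNames(table$avg_jaccard[sel], table$class[sel]),
    excluded_classes = table$class[ord[-seq_len(S)]],
    S = S
  ), class = "candidate_shortlist")
}

#' Default shortlist size: half of the available classes
#'
#' @param C number of training classes, `C >= 2`.
#' @return `floor(C / 2)`.
#' @export
default_S <- function(C) {
  C <- as.integer(C)
  if (length(C) != 1L || is.na(C) || C < 2L) stop("need at least 2 classes")
  C %/% 2L
}

#' @export
print.candidate_shortlist <- function(x, ...) {
  cat("Candidate shortlist: ", x$S, " of ",
      x$S + length(x$excluded_classes), " classes\n", sep = "")
  print(round(x$scores, 4))
  invisible(x)
}
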