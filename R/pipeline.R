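#' Pipeline configuration
#'
#' @param preprocess a [preprocess_config()].
#' @param S shortlist size: a positive integer, or `"half"` for
#'   `floor(C / 2)` computed from the classes present in each run.
#' @param solver a [solver_config()].
#' @param seed RNG seed for fold partitioning (the only source of
#'   randomness; everything downstream is deterministic).
#' @param folds number of cross-validation folds (default 5).
#' @param repeats number of independent cross-validation repetitions
#'   (default 10).
#' @param allow_empty propagate to the Jaccard routines: treat all-zero
#'   orientation-image pairs as identical instead of erroring.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(), S = "half",
                            solver = solver_config(), seed = 1L,
                            folds = 5L, repeats = 10L,
                            allow_empty = FALSE) {
  stopifnot(folds >= 2, repeats >= 1)
  if (!identical(S, "half")) {
    S <- as.integer(S)
    stopifnot(length(S) == 1L, !is.na(S), S >= 1L)
  }
  structure(list(preprocess = preprocess, S = S, solver = solver,
                 seed = as.integer(seed), folds = as.integer(folds),
                 repeats = as.integer(repeats),
                 allow_empty = isTRUE(allow_empty)),
            class = "pipeline_config")
}

resolve_S <- function(S, C) {
  if (identical(S, "half")) default_S(C) else min(as.integer(S), C)
}

#' Recognize a single leaf
#'
#' Runs the full two-stage procedure for one test leaf against a labeled
#' training set: preprocessing to a binary orientation vector, per-class
#' average Jaccard coefficients, candidate shortlisting, dictionary
#' construction from the shortlisted classes, Jaccard-distance-weighted
#' sparse solve, per-class residuals, and the smallest-residual decision.
#'
#' @param test a color array, `gray_image`, 32x16 binary matrix, or
#'   already-vectorized binary feature vector.
#' @param train training images in any of the same forms (list), or a
#'   D x n binary matrix of already-preprocessed feature vectors.
#' @param labels class label per training image.
#' @param cfg a [pipeline_config()].
#' @return list with `predicted_class`, `solution` (the `wsrc_fit` plus
#'   `contributions`, `residuals`, `predicted_class`), and `shortlist`.
#' @export
recognize <- function(test, train, labels, cfg = pipeline_config()) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("training set must cover >= 2 classes")
  y <- as_feature_vector(test, cfg$preprocess)
  X <- as_feature_matrix(train, cfg$preprocess)
  if (length(labels) != ncol(X)) stop("need one label per training image")
  recognize_vector(y, X, labels, cfg)
}

# core of the two-stage decision, on preprocessed feature vectors
recognize_vector <- function(y, X, labels, cfg) {
  tab <- average_class_coefficient(y, X, labels,
                                   allow_empty = cfg$allow_empty)
  S <- resolve_S(cfg$S, nrow(tab))
  shortlist <- select_candidates(tab, S)
  dict <- build_dictionary(shortlist, X, labels)
  w <- compute_weights(y, dict, weight_floor = cfg$solver$weight_floor,
                       allow_empty = cfg$allow_empty)
  fit <- solve_wsrc(dict, y, w, cfg$solver)
  cr <- class_residuals(dict, y, fit)
  pred <- classify(cr$residuals)
  fit$contributions <- cr$contributions
  fit$residuals <- cr$residuals
  fit$predicted_class <- pred
  list(predicted_class = pred, solution = fit, shortlist = shortlist)
}

as_feature_vector <- function(x, pcfg) {
  if (is.numeric(x) && is.null(dim(x)) &&
      length(x) == prod(pcfg$target_shape)) {
    return(as_binary_vector(x))
  }
  if (is.matrix(x) && all(dim(x) == pcfg$target_shape) &&
      all(x %in% c(0, 1))) {
    return(vectorize(x, pcfg$target_shape))
  }
  vectorize(preprocess_image(x, pcfg), pcfg$target_shape)
}

as_feature_matrix <- function(x, pcfg) {
  d <- prod(pcfg$target_shape)
  if (is.matrix(x) && nrow(x) == d) return(as_binary_matrix(x, d))
  if (!is.list(x)) stop("training set must be a list of images or a D x n matrix")
  vapply(x, function(im) as_feature_vector(im, pcfg), integer(d))
}

#' Cross-validated evaluation of the recognition pipeline
#'
#' Repeats a stratified k-fold protocol: within every class the samples
#' are randomly partitioned into `folds` equal-sized subsets (seeded);
#' each fold in turn is held out, every held-out leaf is recognized
#' against the remaining training folds, and per-class recognition rates
#' are computed.  Results across `repeats` x `folds` runs are aggregated
#' as mean and standard deviation of the fold-level macro rates.
#'
#' @param x dataset: a list of images (any form [recognize()] accepts) or
#'   a D x n feature matrix.
#' @param labels class label per sample.
#' @param cfg a [pipeline_config()].
#' @param classifier the per-sample decision function, by default the
#'   package's two-stage recognizer; replaceable (e.g. by a stub) for
#'   protocol-level testing.  Called as `classifier(y, X_train,
#'   train_labels, cfg)` and expected to return a class label.
#' @return an object of class `recognition_report`: list with
#'   `per_sample` (data.frame: sample, repeat, fold, true_class,
#'   predicted_class, shortlist_hit, min_residual), `per_class_rates`
#'   (percent, over all predictions), `macro_rate` (mean of
#'   `per_class_rates`), `fold_macro_rates`, `fold_mean`, `fold_sd`,
#'   `seed`, `folds`, `repeats`, `elapsed_s`.
#' @export
cross_validate <- function(x, labels, cfg = pipeline_config(),
                           classifier = NULL) {
  t0 <- proc.time()[["elapsed"]]
  labels <- as.character(labels)
  X <- as_feature_matrix(x, cfg$preprocess)
  if (length(labels) != ncol(X)) stop("need one label per sample")
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < cfg$folds)) {
    stop("every class needs at least `folds` samples; smallest has ",
         min(counts))
  }
  rows <- list()
  fold_macros <- numeric(0)
  for (rep_i in seq_len(cfg$repeats)) {
    fold_of <- with_seed(cfg$seed + 7919L * (rep_i - 1L),
                         assign_folds(labels, cfg$folds))
    for (fold in seq_len(cfg$folds)) {
      test_idx <- which(fold_of == fold)
      train_idx <- which(fold_of != fold)
      res <- lapply(test_idx, function(i) {
        if (is.null(classifier)) {
          r <- recognize_vector(X[, i], X[, train_idx, drop = FALSE],
                                labels[train_idx], cfg)
          data.frame(sample = i, rep = rep_i, fold = fold,
                     true_class = labels[i],
                     predicted_class = r$predicted_class,
                     shortlist_hit =
                       labels[i] %in% r$shortlist$selected_classes,
                     min_residual = min(r$solution$residuals),
                     stringsAsFactors = FALSE)
        } else {
          p <- classifier(X[, i], X[, train_idx, drop = FALSE],
                          labels[train_idx], cfg)
          data.frame(sample = i, rep = rep_i, fold = fold,
                     true_class = labels[i], predicted_class = p,
                     shortlist_hit = NA, min_residual = NA_real_,
                     stringsAsFactors = FALSE)
        }
      })
      res <- do.call(rbind, res)
      rows[[length(rows) + 1L]] <- res
      fold_macros <- c(fold_macros, macro_rate(res, classes))
    }
  }
  per_sample <- do.call(rbind, rows)
  pcr <- vapply(classes, function(cl) {
    sub <- per_sample[per_sample$true_class == cl, ]
    100 * mean(sub$predicted_class == cl)
  }, numeric(1))
  structure(list(per_sample = per_sample,
                 per_class_rates = pcr,
                 macro_rate = mean(pcr),
                 fold_macro_rates = fold_macros,
                 fold_mean = mean(fold_macros),
                 fold_sd = stats::sd(fold_macros),
                 seed = cfg$seed, folds = cfg$folds, repeats = cfg$repeats,
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "recognition_report")
}

# stratified fold labels: within each class, a random permutation is cut
# into `folds` (nearly) equal parts
assign_folds <- function(labels, folds) {
  fold_of <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    perm <- sample(idx)
    fold_of[perm] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

macro_rate <- function(res, classes) {
  present <- intersect(classes, unique(res$true_class))
  rates <- vapply(present, function(cl) {
    sub <- res[res$true_class == cl, ]
    100 * mean(sub$predicted_class == cl)
  }, numeric(1))
  mean(rates)
}

#' @export
print.recognition_report <- function(x, ...) {
  cat("Cross-validated recognition report\n")
  cat(sprintf("  %d folds x %d repeats (seed %d), %d predictions\n",
              x$folds, x$repeats, x$seed, nrow(x$per_sample)))
  cat(sprintf("  macro recognition rate: %.2f%%\n", x$macro_rate))
  cat(sprintf("  fold-level mean +/- sd: %.2f%% +/- %.2f%%\n",
              x$fold_mean, x$fold_sd))
  invisible(x)
}
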