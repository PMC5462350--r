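#' Solver configuration for the weighted l2-l1 problem
#'
#' @param mu regularization weight balancing reconstruction error against
#'   the (weighted) l1 penalty.  Default 0.001.
#' @param tol convergence tolerance on the relative objective change per
#'   coordinate-descent sweep.  Default 1e-6.
#' @param max_iter sweep cap.  Default 10000.
#' @param weight_floor lower bound applied to Jaccard-distance weights; a
#'   raw weight of 0 (atom identical to the test vector) would otherwise
#'   leave that coefficient unpenalized and break the change of variables
#'   in the solver.  Default 1e-8.
#' @param normalize_atoms l2-normalize dictionary columns before solving.
#'   Defaults to `FALSE`: binary atoms are used as-is.
#' @return a list of class `solver_config`.
#' @export
solver_config <- function(mu = 0.001, tol = 1e-6, max_iter = 10000L,
                          weight_floor = 1e-8, normalize_atoms = FALSE) {
  if (mu < 0) stop("mu must be >= 0")
  stopifnot(tol > 0, max_iter >= 1, weight_floor > 0)
  structure(list(mu = mu, tol = tol, max_iter = as.integer(max_iter),
                 weight_floor = weight_floor,
                 normalize_atoms = isTRUE(normalize_atoms)),
            class = "solver_config")
}

#' Build the sparse-representation dictionary from shortlisted classes
#'
#' Concatenates the training vectors of the shortlisted classes, one
#' column (atom) per training image, grouped by class in shortlist order
#' with the within-class input order preserved.
#'
#' @param shortlist a `candidate_shortlist` from [select_candidates()], or
#'   a character vector of class labels to keep (in order).
#' @param x matrix of training vectors (one column each) or list of
#'   vectors/32x16 binary matrices.
#' @param labels class label per training vector.
#' @return an object of class `src_dictionary`: list with `atoms` (D x m
#'   binary matrix), `labels` (length m), `class_index` (named list of
#'   column indices), `D`, `m`.
#' @export
build_dictionary <- function(shortlist, x, labels) {
  keep <- if (inherits(shortlist, "candidate_shortlist")) {
    shortlist$selected_classes
  } else {
    as.character(shortlist)
  }
  labels <- as.character(labels)
  if (is.list(x)) {
    d <- length(as_binary_vector(x[[1]]))
    x <- as_binary_matrix(x, d)
  }
  if (!is.matrix(x)) stop("training vectors must form a matrix or list")
  if (length(labels) != ncol(x)) stop("need one label per training vector")
  missing <- setdiff(keep, labels)
  if (length(missing)) {
    stop("shortlisted classes with no training vectors: ",
         paste(missing, collapse = ", "))
  }
  cols <- unlist(lapply(keep, function(cl) which(labels == cl)),
                 use.names = FALSE)
  atoms <- x[, cols, drop = FALSE]
  storage.mode(atoms) <- "double"
  lab <- labels[cols]
  structure(list(
    atoms = atoms, labels = lab,
    class_index = split(seq_along(lab), factor(lab, levels = keep)),
    D = nrow(atoms), m = ncol(atoms)
  ), class = "src_dictionary")
}

#' Jaccard-distance weights of the dictionary atoms
#'
#' The penalty weight of atom i is its Jaccard distance to the test
#' vector: dissimilar atoms are penalized more heavily in the l1 term, so
#' the representation concentrates on atoms that resemble the test leaf.
#' Weights are floored at `weight_floor` (a raw distance of 0 means the
#' atom equals the test vector).
#'
#' @param y binary test vector of length `dict$D`.
#' @param dict an `src_dictionary`.
#' @param weight_floor lower bound on each weight.
#' @param allow_empty treat all-zero pairs as identical rather than
#'   erroring (see [jaccard_coefficient()]).
#' @return numeric weight vector of length `dict$m`, values in
#'   `[weight_floor, 1]`.
#' @export
compute_weights <- function(y, dict, weight_floor = 1e-8,
                            allow_empty = FALSE) {
  y <- as_binary_vector(y)
  stopifnot(inherits(dict, "src_dictionary"), length(y) == dict$D)
  m11 <- as.numeric(crossprod(dict$atoms, y))
  union <- sum(y) + colSums(dict$atoms) - m11
  if (any(union == 0)) {
    if (!allow_empty) {
      stop("degenerate pair: test vector and an atom are both all-zero")
    }
    m11[union == 0] <- 1
    union[union == 0] <- 1
  }
  pmax(1 - m11 / union, weight_floor)
}

#' Weighted sparse representation of a test vector
#'
#' Solves the weighted l2-l1 problem
#' \deqn{\min_A \|GA - y\|_2^2 + \mu \|W'A\|_1}
#' where `diag(W')` holds the per-atom penalty weights.  The change of
#' variables B = W'A (scaling column j of G by 1/w_j) reduces the problem
#' to a standard-form LASSO, solved by cyclic coordinate descent; any
#' exact l1 solver (LARS included) reaches the same optimum of this convex
#' problem.  Convergence is declared when the relative objective decrease
#' over a full sweep drops below `cfg$tol`.
#'
#' @param dict an `src_dictionary` (or a plain D x m numeric matrix).
#' @param y numeric test vector of length D.
#' @param weights per-atom penalty weights (length m, positive), e.g. from
#'   [compute_weights()].
#' @param cfg a [solver_config()].
#' @return an object of class `wsrc_fit`: list with `coefficients` (length
#'   m), `objective`, `objective_trace`, `iterations`, `converged`,
#'   `nonzero` (count of |coef| > 1e-8).
#' @export
solve_wsrc <- function(dict, y, weights = NULL, cfg = solver_config()) {
  G <- if (inherits(dict, "src_dictionary")) dict$atoms else as.matrix(dict)
  y <- as.numeric(y)
  stopifnot(nrow(G) == length(y), ncol(G) >= 1)
  if (cfg$mu < 0) stop("mu must be >= 0")
  m <- ncol(G)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights <= 0)) {
    stop("weights must be positive and aligned with the dictionary columns")
  }
  if (cfg$normalize_atoms) {
    nrm <- sqrt(colSums(G^2)); nrm[nrm == 0] <- 1
    G <- sweep(G, 2, nrm, "/")
  }
  # substitution B = W'A: scale columns by 1/w, uniform penalty mu on B
  Gt <- sweep(G, 2, weights, "/")
  b <- coord_descent_lasso(Gt, y, cfg$mu, cfg$tol, cfg$max_iter)
  a <- b$coef / weights
  if (cfg$normalize_atoms) a <- a / nrm
  structure(list(coefficients = a, objective = b$objective,
                 objective_trace = b$trace, iterations = b$iterations,
                 converged = b$converged,
                 nonzero = sum(abs(a) > 1e-8)),
            class = "wsrc_fit")
}

#' @rdname solve_wsrc
#' @details `solve_src()` is the unweighted special case (all weights 1),
#'   i.e. the classical SRC objective `||GA - y||^2 + mu * ||A||_1`.
#' @export
solve_src <- function(dict, y, cfg = solver_config()) {
  G <- if (inherits(dict, "src_dictionary")) dict$atoms else as.matrix(dict)
  solve_wsrc(G, y, weights = rep(1, ncol(G)), cfg = cfg)
}

# Cyclic coordinate descent for min ||Xb - y||^2 + mu * ||b||_1 (note: no
# 1/2 on the quadratic term, hence the mu/2 soft threshold).
coord_descent_lasso <- function(X, y, mu, tol, max_iter) {
  m <- ncol(X)
  cn <- colSums(X^2)
  active <- which(cn > 0)
  b <- numeric(m)
  r <- y
  obj <- sum(r^2)
  trace <- obj
  converged <- FALSE
  it <- 0L
  if (length(active)) {
    for (it in seq_len(max_iter)) {
      for (j in active) {
        rho <- sum(X[, j] * r) + cn[j] * b[j]
        bj <- soft_threshold(rho, mu / 2) / cn[j]
        if (bj != b[j]) {
          r <- r - X[, j] * (bj - b[j])
          b[j] <- bj
        }
      }
      new_obj <- sum(r^2) + mu * sum(abs(b))
      trace <- c(trace, new_obj)
      if (new_obj > obj + 1e-10 * max(1, obj)) {
        warning("objective increased during coordinate descent")
      }
      if (abs(obj - new_obj) <= tol * max(1, abs(obj))) {
        obj <- new_obj
        converged <- TRUE
        break
      }
      obj <- new_obj
    }
    if (!converged) {
      warning("coordinate descent did not converge in ", max_iter,
              " sweeps; returning best iterate")
    }
  } else {
    converged <- TRUE
  }
  list(coef = b, objective = obj, trace = trace, iterations = it,
       converged = converged)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Closed-form ridge baseline
#'
#' Solves `A = (G'G + mu I)^{-1} G'y`, the l2-penalized (ridge)
#' counterpart of the sparse problem.  This is a diagnostic baseline only
#' — it is dense, not sparse, and never enters the classification path.
#'
#' @param dict an `src_dictionary` or D x m matrix.
#' @param y numeric vector of length D.
#' @param mu ridge penalty, strictly positive.
#' @return numeric coefficient vector of length m.
#' @export
ridge_closed_form <- function(dict, y, mu) {
  G <- if (inherits(dict, "src_dictionary")) dict$atoms else as.matrix(dict)
  if (mu <= 0) stop("ridge baseline requires mu > 0")
  as.numeric(solve(crossprod(G) + diag(mu, ncol(G)), crossprod(G, y)))
}

#' Per-class contributions and residuals
#'
#' The contribution of class i is the reconstruction using only that
#' class's atoms and coefficients; its residual is the l2 deviation of the
#' test vector from that contribution.  The class contributions sum to the
#' full reconstruction GA.
#'
#' @param dict an `src_dictionary`.
#' @param y numeric test vector of length `dict$D`.
#' @param coefficients coefficient vector aligned with the dictionary
#'   columns (a `wsrc_fit` is also accepted).
#' @return list with `contributions` (D x S matrix, one column per class)
#'   and `residuals` (named numeric, one per class).
#' @export
class_residuals <- function(dict, y, coefficients) {
  if (inherits(coefficients, "wsrc_fit")) {
    coefficients <- coefficients$coefficients
  }
  stopifnot(inherits(dict, "src_dictionary"),
            length(coefficients) == dict$m, length(y) == dict$D)
  y <- as.numeric(y)
  classes <- names(dict$class_index)
  contrib <- vapply(classes, function(cl) {
    idx <- dict$class_index[[cl]]
    as.numeric(dict$atoms[, idx, drop = FALSE] %*% coefficients[idx])
  }, numeric(dict$D))
  res <- vapply(classes, function(cl) {
    sqrt(sum((y - contrib[, cl])^2))
  }, numeric(1))
  list(contributions = contrib, residuals = res)
}

#' Smallest-residual decision rule
#'
#' @param residuals named numeric vector of per-class residuals.
#' @return the label with the smallest residual; exact ties go to the
#'   lexicographically smallest label.
#' @export
classify <- function(residuals) {
  if (is.list(residuals) && !is.null(residuals$residuals)) {
    residuals <- residuals$residuals
  }
  if (length(residuals) == 0L || is.null(names(residuals))) {
    stop("need a named, nonempty residual vector")
  }
  ord <- order(residuals, names(residuals))
  names(residuals)[ord[1]]
}

#' Single-atom deviation diagnostic
#'
#' Squared l2 deviation of the test vector from the contribution of one
#' atom, `||y - alpha_i g_i||^2`.  A per-atom diagnostic of representation
#' quality; the class-level residual of [class_residuals()] is the
#' decision statistic.
#'
#' @param y,g numeric vectors of equal length.
#' @param alpha coefficient of atom `g`.
#' @return nonnegative scalar.
#' @export
atom_deviation <- function(y, g, alpha) {
  stopifnot(length(y) == length(g))
  sum((as.numeric(y) - alpha * as.numeric(g))^2)
}
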