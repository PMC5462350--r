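random_instance <- function(D, m, binary = FALSE) {
  G <- if (binary) matrix(rbinom(D * m, 1, 0.4), D, m)
       else matrix(rnorm(D * m), D, m)
  y <- if (binary) rbinom(D, 1, 0.4) else rnorm(D)
  list(G = G, y = y)
}

test_that("dictionary construction groups atoms by shortlist order", {
  set.seed(41)
  x <- matrix(rbinom(20 * 9, 1, 0.5), 20)
  labels <- rep(c("b", "a", "c"), each = 3)
  d <- build_dictionary(c("c", "a"), x, labels)
  expect_equal(d$m, 6)
  expect_equal(d$D, 20)
  expect_identical(d$labels, rep(c("c", "a"), each = 3))
  expect_identical(names(d$class_index), c("c", "a"))
  expect_equal(d$atoms[, 1:3], x[, labels == "c"] + 0)
  # single atom
  d1 <- build_dictionary("z", matrix(rbinom(512, 1, 0.3), 512), "z")
  expect_equal(dim(d1$atoms), c(512, 1))
  # shuffling the input columns only reorders within-class atoms
  perm <- sample(9)
  d2 <- build_dictionary(c("c", "a"), x[, perm], labels[perm])
  expect_identical(d2$labels, d$labels)
  expect_equal(sort(colSums(d2$atoms)), sort(colSums(d$atoms)))
  expect_error(build_dictionary(c("q"), x, labels), "no training vectors")
})

test_that("weights are the Jaccard distances of the atoms, floored", {
  set.seed(43)
  y <- rbinom(10, 1, 0.5); y[1] <- 1
  atoms <- cbind(y, 1 - y, V2)
  d <- build_dictionary(c("a", "b", "c"), atoms, c("a", "b", "c"))
  w <- compute_weights(V1, build_dictionary("c", matrix(V2, 10), "c"))
  expect_equal(w, 5 / 7)
  w2 <- unname(compute_weights(y, d))
  expect_equal(w2[1], 1e-8)       # identical atom hits the floor
  expect_equal(w2[2], 1)          # disjoint support
})

test_that("orthonormal designs match the soft-threshold closed form", {
  set.seed(47)
  for (i in 1:10) {
    G <- random_orthonormal(30, 8)
    y <- rnorm(30)
    w <- runif(8, 0.1, 1)
    mu <- runif(1, 0.01, 0.5)
    fit <- solve_wsrc(G, y, w, solver_config(mu = mu, tol = 1e-12))
    ref <- vapply(1:8, function(j) {
      z <- sum(G[, j] * y)
      sign(z) * max(abs(z) - mu * w[j] / 2, 0)
    }, numeric(1))
    expect_lt(max(abs(fit$coefficients - ref)), 1e-6)
  }
})

test_that("mu = 0 recovers the least-squares solution", {
  set.seed(53)
  inst <- random_instance(25, 6)
  fit <- solve_wsrc(inst$G, inst$y, rep(1, 6),
                    solver_config(mu = 0, tol = 1e-14, max_iter = 50000))
  ls <- as.numeric(qr.solve(inst$G, inst$y))
  expect_lt(max(abs(fit$coefficients - ls)), 1e-5)
  r <- inst$y - inst$G %*% fit$coefficients
  expect_lt(max(abs(crossprod(inst$G, r))), 1e-5)
})

test_that("unit weights reproduce the unweighted solver on 100 random instances", {
  set.seed(59)
  for (i in 1:100) {
    inst <- random_instance(15, 6)
    cfg <- solver_config(mu = 0.05, tol = 1e-10)
    a1 <- solve_wsrc(inst$G, inst$y, rep(1, 6), cfg)$coefficients
    a2 <- solve_src(inst$G, inst$y, cfg)$coefficients
    expect_lt(max(abs(a1 - a2)), 1e-8)
  }
})

test_that("solver reaches the optimum found by independent references", {
  set.seed(61)
  cfg <- solver_config(mu = 0.1, tol = 1e-12, max_iter = 50000)
  for (i in 1:5) {
    inst <- random_instance(20, 8)
    w <- runif(8, 0.2, 1)
    fit <- solve_wsrc(inst$G, inst$y, w, cfg)
    # slow proximal-gradient reference
    b_ref <- ista_lasso(inst$G, inst$y, cfg$mu, w)
    expect_lt(abs(lasso_objective(inst$G, inst$y, fit$coefficients, cfg$mu, w) -
                    lasso_objective(inst$G, inst$y, b_ref, cfg$mu, w)), 1e-8)
  }
  # glmnet as a second, library-grade reference on an unweighted instance
  inst <- random_instance(40, 12)
  fit <- solve_src(inst$G, inst$y, solver_config(mu = 0.2, tol = 1e-12))
  gn <- glmnet::glmnet(inst$G, inst$y, lambda = 0.2 / (2 * 40),
                       intercept = FALSE, standardize = FALSE,
                       thresh = 1e-14)
  expect_lt(max(abs(fit$coefficients - as.numeric(gn$beta))), 1e-4)
})

test_that("objective trace is non-increasing and large mu zeroes the solution", {
  set.seed(67)
  inst <- random_instance(20, 10, binary = TRUE)
  fit <- solve_src(inst$G, inst$y, solver_config(mu = 0.01, tol = 1e-10))
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  big <- solve_src(inst$G, inst$y, solver_config(mu = 1e6))
  expect_true(all(big$coefficients == 0))
  expect_error(solver_config(mu = -1), "mu")
})

test_that("sparsity is non-increasing in mu on a fixed instance", {
  set.seed(71)
  inst <- random_instance(60, 30, binary = TRUE)
  nnz <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1), function(mu) {
    solve_src(inst$G, inst$y, solver_config(mu = mu, tol = 1e-10))$nonzero
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("ridge baseline matches its closed form and limits", {
  y <- c(1, 2, 3)
  expect_equal(ridge_closed_form(diag(3), y, mu = 1), y / 2)
  set.seed(73)
  G <- matrix(rnorm(50), 10, 5); y <- rnorm(10)
  a <- ridge_closed_form(G, y, 0.3)
  expect_equal(as.numeric(solve(crossprod(G) + diag(0.3, 5)) %*% crossprod(G, y)), a)
  a_small <- ridge_closed_form(G, y, 1e-10)
  expect_lt(max(abs(a_small - qr.solve(G, y))), 1e-6)
  expect_error(ridge_closed_form(G, y, 0), "mu > 0")
})

test_that("class contributions partition the reconstruction", {
  set.seed(79)
  x <- matrix(rbinom(30 * 8, 1, 0.4), 30)
  labels <- rep(c("a", "b"), each = 4)
  d <- build_dictionary(c("a", "b"), x, labels)
  y <- rbinom(30, 1, 0.4)
  a <- rnorm(8)
  cr <- class_residuals(d, y, a)
  expect_equal(rowSums(cr$contributions), as.numeric(d$atoms %*% a))
  # all-zero coefficients: every residual is ||y||
  cr0 <- class_residuals(d, y, rep(0, 8))
  expect_equal(unname(cr0$residuals), rep(sqrt(sum(y^2)), 2))
  # one class holding all nonzeros: its residual is the global error
  a1 <- c(rnorm(4), rep(0, 4))
  cr1 <- class_residuals(d, y, a1)
  expect_equal(unname(cr1$residuals["a"]),
               sqrt(sum((y - d$atoms %*% a1)^2)))
})

test_that("smallest-residual decision with lexicographic tie-break", {
  expect_identical(classify(c(A = 0.5, B = 0.2, C = 0.9)), "B")
  expect_identical(classify(c(A = 0.3, B = 0.3)), "A")
  expect_error(classify(numeric(0)), "nonempty")
  # permutation invariance of the decision
  r <- c(x = 0.4, y = 0.1, z = 0.7)
  perm <- c(z = 0.7, x = 0.4, y = 0.1)
  expect_identical(classify(r), classify(perm))
})

test_that("a test vector equal to a training atom is assigned that atom's class", {
  set.seed(83)
  x <- matrix(rbinom(64 * 12, 1, 0.35), 64)
  labels <- rep(paste0("c", 1:4), each = 3)
  d <- build_dictionary(paste0("c", 1:4), x, labels)
  y <- x[, 8]                              # class c3
  w <- compute_weights(y, d)
  fit <- solve_wsrc(d, y, w, solver_config(mu = 0.001))
  expect_identical(classify(class_residuals(d, y, fit)$residuals), "c3")
  expect_equal(which.max(abs(fit$coefficients)), 8)
})

test_that("atom deviation is the squared distance to a scaled atom", {
  y <- c(1, 0, 1, 1)
  expect_equal(atom_deviation(y, c(0, 1, 0, 0), 0), sum(y^2))
  expect_equal(atom_deviation(y, y, 1), 0)
  set.seed(89)
  g <- rnorm(4); al <- rnorm(1)
  expect_equal(atom_deviation(y, g, al), sum((y - al * g)^2))
})
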