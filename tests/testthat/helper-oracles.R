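# Independent reference implementations used as oracles.  These are kept
# deliberately naive and separate from the package's own code paths.

# per-position loop for the Jaccard counts
naive_jaccard_counts <- function(a, b) {
  m11 <- 0L; m01 <- 0L; m10 <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) m11 <- m11 + 1L
    if (a[i] == 0 && b[i] == 1) m01 <- m01 + 1L
    if (a[i] == 1 && b[i] == 0) m10 <- m10 + 1L
  }
  list(m11 = m11, m01 = m01, m10 = m10)
}

# slow proximal-gradient (ISTA) reference for min ||Xb-y||^2 + mu*sum(w|b|)
ista_lasso <- function(X, y, mu, w = rep(1, ncol(X)), iters = 50000) {
  L <- 2 * max(eigen(crossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values)
  t <- 1 / L
  b <- numeric(ncol(X))
  for (i in seq_len(iters)) {
    g <- 2 * crossprod(X, X %*% b - y)
    bn <- sign(b - t * g) * pmax(abs(b - t * g) - t * mu * w, 0)
    if (max(abs(bn - b)) < 1e-12) { b <- bn; break }
    b <- bn
  }
  as.numeric(b)
}

lasso_objective <- function(X, y, b, mu, w = rep(1, ncol(X))) {
  sum((X %*% b - y)^2) + mu * sum(w * abs(b))
}

# random orthonormal-column matrix (D x m, m <= D)
random_orthonormal <- function(D, m) {
  qr.Q(qr(matrix(rnorm(D * m), D, m)))[, seq_len(m), drop = FALSE]
}

# principal-axis angle of a binary mask from brute-force second moments
mask_axis_angle <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  r <- idx[, 1] - mean(idx[, 1]); c <- idx[, 2] - mean(idx[, 2])
  srr <- mean(r * r); scc <- mean(c * c); src <- mean(r * c)
  0.5 * atan2(2 * src, srr - scc)   # 0 = vertical (row axis)
}

# elliptical binary mask, axis `angle` radians from the row direction
ellipse_mask <- function(nr, nc, a, b, angle = 0) {
  gr <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- gr$r - (nr + 1) / 2; dc <- gr$c - (nc + 1) / 2
  u <- cos(angle) * dr + sin(angle) * dc
  v <- -sin(angle) * dr + cos(angle) * dc
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), nr, nc)
}

# printed worked-example vectors
V1 <- c(1, 0, 0, 1, 0, 0, 1, 1, 0, 0)
V2 <- c(0, 0, 1, 1, 0, 1, 0, 1, 1, 0)
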