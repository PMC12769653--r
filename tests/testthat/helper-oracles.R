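# Independent brute-force oracles. These re-derive the same quantities as
# the package by a different route (explicit loops, classical textbook
# algorithms) and are deliberately not shared with the implementation.

# Speed mask: forward/backward difference speeds over the non-missing
# subsequence, robust threshold, strict comparison.
oracle_speed_mask <- function(p, t, n = 16) {
  out <- rep(FALSE, length(p))
  idx <- which(!is.na(p))
  if (length(idx) < 3L) return(out)
  pv <- p[idx]; tv <- t[idx]
  m <- length(pv)
  d <- numeric(m)
  for (i in seq_len(m)) {
    cand <- c()
    if (i < m) cand <- c(cand, abs(pv[i + 1] - pv[i]) / (tv[i + 1] - tv[i]))
    if (i > 1) cand <- c(cand, abs(pv[i] - pv[i - 1]) / (tv[i] - tv[i - 1]))
    d[i] <- max(cand)
  }
  med <- median(d)
  thr <- med + n * median(abs(d - med))
  out[idx[d > thr]] <- TRUE
  out
}

oracle_zscore_mask <- function(p, z_thr = 2.5, cv_thr = 0.1) {
  out <- rep(FALSE, length(p))
  idx <- which(!is.na(p))
  if (length(idx) < 2L) return(out)
  pv <- p[idx]
  mu <- sum(pv) / length(pv)
  if (mu == 0) return(out)
  s <- sqrt(sum((pv - mu)^2) / (length(pv) - 1))
  if (s / mu <= cv_thr || s == 0) return(out)
  for (i in seq_along(idx))
    if (abs((pv[i] - mu) / s) > z_thr) out[idx[i]] <- TRUE
  out
}

# Natural cubic spline: classical tridiagonal solve for the knot second
# derivatives (M_1 = M_n = 0), then piecewise cubic evaluation.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  M <- numeric(n)
  if (n > 2) {
    k <- n - 2
    A <- matrix(0, k, k)
    rhs <- numeric(k)
    for (i in seq_len(k)) {
      A[i, i] <- 2 * (h[i] + h[i + 1])
      if (i > 1) A[i, i - 1] <- h[i]
      if (i < k) A[i, i + 1] <- h[i + 1]
      rhs[i] <- 6 * ((y[i + 2] - y[i + 1]) / h[i + 1] -
                       (y[i + 1] - y[i]) / h[i])
    }
    M[2:(n - 1)] <- solve(A, rhs)
  }
  vapply(xout, function(t) {
    j <- max(1L, min(n - 1L, findInterval(t, x)))
    dx1 <- t - x[j]; dx2 <- x[j + 1] - t
    (M[j] * dx2^3 + M[j + 1] * dx1^3) / (6 * h[j]) +
      (y[j] / h[j] - M[j] * h[j] / 6) * dx2 +
      (y[j + 1] / h[j] - M[j + 1] * h[j] / 6) * dx1
  }, numeric(1))
}

# Winding-number point-in-polygon (angle summation) — a different
# algorithm from the package's even-odd ray cast; valid off-boundary.
oracle_point_in_polygon <- function(pt, poly) {
  n <- nrow(poly) - 1L
  total <- 0
  for (i in seq_len(n)) {
    v1 <- c(poly[i, 1] - pt[1], poly[i, 2] - pt[2])
    v2 <- c(poly[i + 1, 1] - pt[1], poly[i + 1, 2] - pt[2])
    total <- total + atan2(v1[1] * v2[2] - v1[2] * v2[1],
                           v1[1] * v2[1] + v1[2] * v2[2])
  }
  abs(total) > pi
}

raw_mad <- function(v) median(abs(v - median(v)))
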