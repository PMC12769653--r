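# Minimal IIR machinery: Butterworth low-pass design via the bilinear
# transform and zero-phase (forward-backward) filtering with steady-state
# initial conditions and odd-reflection padding. Self-contained because no
# signal-processing package is assumed at run time.

# Low-pass Butterworth coefficients; returns list(b, a) with a[1] == 1.
butter_lowpass <- function(order, cutoff_hz, sampling_rate) {
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate / 2)
    stopf("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)",
          cutoff_hz, sampling_rate / 2)
  n <- as.integer(order)
  wn <- cutoff_hz / (sampling_rate / 2)
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 4                          # 2 * internal sampling rate of 2
  warped <- 2 * 2 * tan(pi * wn / 2)  # pre-warped analog edge frequency
  p <- p * warped
  gain <- warped^n
  # bilinear transform z = (fs2 + s) / (fs2 - s)
  zd <- (fs2 + p) / (fs2 - p)
  gain_d <- gain / Re(prod(fs2 - p))
  a <- Re(poly_from_roots(zd))
  b <- gain_d * Re(poly_from_roots(rep(-1 + 0i, n)))
  list(b = b, a = a)
}

# Monic polynomial coefficients from roots (descending powers).
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

# Direct-form II transposed difference equation with initial state zi.
iir_filter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2)
      for (j in seq_len(nf - 2))
        z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial conditions for a unit step (per scipy's lfilter_zi):
# scaling zi by x[1] removes the startup transient on near-constant edges.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  m <- nf - 1
  if (m == 0) return(numeric(0))
  # companion matrix of a (monic, descending)
  comp <- matrix(0, m, m)
  comp[1, ] <- -a[-1]
  if (m > 1) comp[cbind(2:m, 1:(m - 1))] <- 1
  iminusa <- diag(m) - t(comp)
  bsum <- b[-1] - a[-1] * b[1]
  solve(iminusa, bsum)
}

# Zero-phase filtering: odd-reflection pad, forward pass, backward pass.
# The signal is centred on its mean first (identical result in exact
# arithmetic for a unit-DC-gain filter, much better conditioning).
filtfilt_zero_phase <- function(b, a, x) {
  mu <- mean(x)
  x <- x - mu
  n <- length(x)
  ntaps <- max(length(a), length(b))
  padlen <- min(3 * (ntaps - 1), n - 1)
  if (n <= 1) return(x)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2, length.out = padlen)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen, length.out = padlen)]
  if (padlen == 0) { pre <- numeric(0); post <- numeric(0) }
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)] + mu
}
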