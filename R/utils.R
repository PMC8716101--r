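# Internal numerical helpers shared across modules.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal of a real vector: the original signal
#' plus i times its Hilbert transform. `Mod()` of the result is the
#' instantaneous amplitude (envelope) and `Arg()` the instantaneous phase in
#' (-pi, pi]. With the `x = A*cos(phi)` convention used throughout the
#' package, the trough of an oscillation sits at phase pi.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = 0))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Wrap angles into (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return wrapped angles.
#' @export
wrap_phase <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# z-score a vector (population sd denominator n-1); tolerates constant input.
zscore <- function(x, center = mean(x), scale = stats::sd(x)) {
  if (!is.finite(scale) || scale == 0) return(x - center)
  (x - center) / scale
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a label.
# One RNG stream per sub-generator: each generator calls set.seed(sub_seed(...))
# so that components are individually reproducible.
sub_seed <- function(seed, label) {
  h <- sum(as.integer(charToRaw(label)) * seq_along(charToRaw(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

# Gaussian kernel on a sample grid, truncated at +/- 5 sigma, unit integral
# (sums to 1/dt so that convolution with a delta train yields rate in Hz).
gaussian_kernel <- function(sigma_s, fs) {
  half <- max(1L, ceiling(5 * sigma_s * fs))
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigma_s^2))
  k / sum(k) * fs
}

# Convolve keeping length, reflecting the series at both edges so that a
# constant input maps to itself (mass conservation near boundaries).
conv_reflect <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  pad_l <- x[pmin(n, seq(half, 1L))]
  pad_r <- x[pmax(1L, seq(n, n - half + 1L))]
  if (half == 0L) return(as.numeric(stats::convolve(x, rev(kernel), type = "open")))
  xp <- c(pad_l, x, pad_r)
  out <- stats::convolve(xp, rev(kernel), type = "open")
  out[(2L * half + 1L):(2L * half + n)] / sum(kernel)
}

# Moving-average smoother (centered, edge-truncated window).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm). kappa = 0 gives
# the circular uniform. Returns angles in (-pi, pi].
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    nacc <- sum(ok)
    if (nacc > 0L) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nacc)] <- theta
      got <- got + nacc
    }
  }
  wrap_phase(mu + out)
}

# Dilate a logical vector: TRUE spreads +/- `radius` samples, clipped at edges.
dilate_logical <- function(flag, radius) {
  if (!any(flag) || radius <= 0L) return(flag)
  n <- length(flag)
  idx <- which(flag)
  out <- logical(n)
  for (d in c(0L, seq_len(radius))) {
    out[pmax(1L, idx - d)] <- TRUE
    out[pmin(n, idx + d)] <- TRUE
  }
  out
}

# Runs of TRUE in a logical vector -> matrix with columns start, end (inclusive).
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Do intervals [a1, a2] and [b1, b2] (inclusive, sample units) overlap?
intervals_overlap <- function(a1, a2, b1, b2) {
  outer(a1, b2, "<=") & outer(a2, b1, ">=")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
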