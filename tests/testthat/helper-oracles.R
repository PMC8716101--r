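# Independent oracles and small fixtures shared across tests.

# Brute-force PPC: explicit double loop over all pairs.
ppc_double_loop <- function(phases) {
  N <- length(phases)
  acc <- 0
  for (j in 1:(N - 1)) for (k in (j + 1):N)
    acc <- acc + cos(phases[j] - phases[k])
  2 * acc / (N * (N - 1))
}

# Exact dip via linear programming: enumerate modal intervals, solve the
# tube-fit feasibility LP with boot::simplex. Independent of the package's
# convex-envelope implementation.
lp_dip_oracle <- function(x, w = rep(1 / length(x), length(x))) {
  o <- order(x); x <- x[o]; w <- w[o] / sum(w)
  ux <- unique(x)
  if (length(ux) < length(x)) {
    w <- vapply(ux, function(v) sum(w[x == v]), numeric(1)); x <- ux
  }
  n <- length(x)
  Fi <- cumsum(w); Flo <- c(0, Fi[-n])
  best <- Inf
  for (k in 0:n) {
    nv <- n + 1L
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    add1 <- function(row, rhs) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
    add2 <- function(row, rhs) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
    for (i in seq_len(n)) {
      r <- numeric(nv); r[i] <- 1; r[nv] <- -1; add1(r, Flo[i])
      r <- numeric(nv); r[i] <- 1; r[nv] <- 1; add2(r, Fi[i])
    }
    for (i in seq_len(n - 1L)) {
      r <- numeric(nv); r[i] <- 1; r[i + 1L] <- -1; add1(r, 0)
    }
    if (k >= 3L) for (i in 2:(k - 1L)) {
      d1 <- x[i] - x[i - 1L]; d2 <- x[i + 1L] - x[i]
      r <- numeric(nv)
      r[i - 1L] <- -1 / d1; r[i] <- 1 / d1 + 1 / d2; r[i + 1L] <- -1 / d2
      add1(r, 0)
    }
    if (k <= n - 3L) for (i in (k + 2L):(n - 1L)) {
      d1 <- x[i] - x[i - 1L]; d2 <- x[i + 1L] - x[i]
      r <- numeric(nv)
      r[i - 1L] <- 1 / d1; r[i] <- -1 / d1 - 1 / d2; r[i + 1L] <- 1 / d2
      add1(r, 0)
    }
    r <- numeric(nv); r[n] <- 1; add1(r, 1)
    obj <- numeric(nv); obj[nv] <- 1
    sol <- try(boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                             maxi = FALSE, n.iter = 500), silent = TRUE)
    if (!inherits(sol, "try-error") && sol$solved == 1)
      best <- min(best, sol$value)
  }
  best
}

# Welch-style PSD via averaged periodograms of Hann-windowed segments.
welch_psd <- function(x, fs, seg_s = 2) {
  nseg <- round(seg_s * fs)
  starts <- seq(1, length(x) - nseg + 1, by = nseg %/% 2)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * win
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc / length(starts) / sum(win^2) / fs
  k <- 2:(nseg %/% 2)
  list(freq = (k - 1) * fs / nseg, psd = p[k])
}

# Fraction of `truth` intervals overlapped by a detected event on the same
# channel.
recall_of <- function(events, truth) {
  if (nrow(truth) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(i) {
    e <- events[events$channel == truth$channel[i], , drop = FALSE]
    any(e$start_sample <= truth$end_sample[i] &
          e$end_sample - 1L >= truth$start_sample[i])
  }, logical(1)))
}

# Small fast session for pipeline-level tests.
tiny_sim_config <- function(seed = 1L, ...) {
  sim_config(session_duration = 30, n_mea_channels = 4, n_ieeg_channels = 2,
             seed = seed, ...)
}
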