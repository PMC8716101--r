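# Cluster-based permutation test across frequencies (sign-flip null).

# Per-frequency one-sample t statistics for all sign-flip patterns at once.
# S: permutations x participants matrix of +/-1; X: participants x nf.
.signflip_t <- function(S, X) {
  k <- nrow(X)
  ss <- colSums(X^2)                      # invariant under sign flips
  m <- (S %*% X) / k                      # perms x nf means
  v <- sweep(-k * m^2, 2L, ss, "+") / (k - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / k)
}

# Clusters of adjacent significant frequencies with a common sign.
# Returns matrix with columns start, end, stat (sum of t within cluster).
.t_clusters <- function(tvec, tcrit) {
  sig <- abs(tvec) > tcrit
  if (!any(sig)) return(NULL)
  key <- ifelse(sig, sign(tvec), 0)
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep)) return(NULL)
  cbind(start = starts[keep], end = ends[keep],
        stat = mapply(function(s, e) sum(tvec[s:e]), starts[keep], ends[keep]))
}

#' Cluster-based permutation test of a spectrum across participants
#'
#' Tests whether per-participant values (e.g. z-scored PPC) deviate from
#' zero at any frequency, correcting for multiple comparisons across
#' frequencies. Per frequency a one-sample t-test against zero defines
#' significance at `alpha`; adjacent significant frequencies with a common
#' sign form clusters scored by the sum of their t-statistics. The null
#' distribution of the maximum (signed) cluster score is built by randomly
#' reversing the sign of each participant's values (all `2^k` patterns are
#' enumerated when feasible, otherwise `n_perm` random patterns), and each
#' observed cluster receives the exceedance probability of its score. The
#' test is thereby directed at positive deviations — the direction the
#' phase-locking analyses ask about; to test the opposite direction, negate
#' `values`.
#'
#' For a paired two-condition comparison, pass the per-participant
#' difference of condition values: swapping condition labels within a
#' participant is exactly a sign flip of the difference.
#'
#' @param values participants x frequencies matrix (k >= 3 participants; a
#'   single participant is rejected since 2 sign patterns are degenerate).
#' @param n_perm permutation budget.
#' @param alpha per-frequency cluster-forming threshold.
#' @param cluster_alpha significance level for clusters.
#' @param seed RNG seed (unused when patterns are enumerated).
#' @return list: `t` (per-frequency), `clusters` (data.frame start, end,
#'   stat, p, significant), `null_max`, `exhaustive`.
#' @export
cluster_permutation_across_frequencies <- function(values, n_perm = 1000,
                                                   alpha = 0.05,
                                                   cluster_alpha = 0.05,
                                                   seed = 1L) {
  X <- as.matrix(values)
  k <- nrow(X)
  if (k < 2L) stop("cluster permutation needs >= 2 participants")
  tcrit <- stats::qt(1 - alpha / 2, df = k - 1)
  t_obs <- .signflip_t(matrix(1, 1L, k), X)[1L, ]
  cl <- .t_clusters(t_obs, tcrit)

  exhaustive <- 2^k <= n_perm
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * k, replace = TRUE), n_perm, k)
  }
  Tm <- .signflip_t(S, X)
  # signed maximum cluster statistic per permutation: the test is directed
  # at positive deviations (flip the sign of `values` for the other
  # direction); negative observed clusters receive p near 1
  null_max <- apply(Tm, 1L, function(tv) {
    cc <- .t_clusters(tv, tcrit)
    if (is.null(cc)) 0 else max(cc[, "stat"])
  })

  if (is.null(cl)) {
    clusters <- data.frame(start = integer(), end = integer(),
                           stat = numeric(), p = numeric(),
                           significant = logical())
  } else {
    # small tolerance so the identity pattern always counts against itself
    # (p is never 0)
    p <- vapply(cl[, "stat"], function(s) {
      thr <- s - max(1e-12, abs(s) * 1e-12)
      if (exhaustive) mean(null_max >= thr)
      else (1 + sum(null_max >= thr)) / (length(null_max) + 1)
    }, numeric(1))
    clusters <- data.frame(start = cl[, "start"], end = cl[, "end"],
                           stat = cl[, "stat"], p = p,
                           significant = p < cluster_alpha)
  }
  list(t = t_obs, clusters = clusters, null_max = null_max,
       exhaustive = exhaustive)
}
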