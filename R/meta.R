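# Correlation effect sizes and random-effects meta-analysis across
# participants.

#' Correlation effect size referenced to a shuffle null (r equivalent)
#'
#' The observed correlation is z-scored against its own shuffle-null
#' distribution; the resulting value is treated as the effect size with
#' sampling variance `1/(n - 3)` (the Fisher-z large-sample variance for a
#' correlation from `n` samples).
#'
#' @param participant participant identifier.
#' @param r_true observed correlation.
#' @param null_r vector of shuffle-null correlations.
#' @param n number of samples behind the correlation (> 3).
#' @return one-row data.frame of class `effect_record`: participant,
#'   effect, vi, n.
#' @export
effect_record <- function(participant, r_true, null_r, n) {
  if (n <= 3L) stop("effect variance undefined for n <= 3")
  s <- stats::sd(null_r)
  if (!is.finite(s) || s == 0) stop("degenerate shuffle null")
  out <- data.frame(participant = participant,
                    effect = (r_true - mean(null_r)) / s,
                    vi = 1 / (n - 3), n = n)
  class(out) <- c("effect_record", "data.frame")
  out
}

#' Random-effects meta-analysis of per-participant effects (REML)
#'
#' Fits a random-effects model by restricted maximum likelihood: the
#' between-participant variance tau^2 is estimated by REML and the pooled
#' mean is the inverse-variance weighted average with weights
#' `1/(vi + tau^2)`. Returns 95% confidence intervals per participant and
#' for the pooled estimate, in the layout of a forest plot.
#'
#' @param effects data.frame with columns `participant`, `effect`, `vi`
#'   (sampling variance > 0), e.g. stacked [effect_record()]s.
#' @return list: `pooled`, `ci` (pooled 95% CI), `se`, `tau2`, `k`,
#'   `table` (per-study forest table), `model` (the underlying
#'   `metafor::rma` fit).
#' @export
random_effects_meta <- function(effects) {
  if (nrow(effects) < 2L) stop("meta-analysis needs >= 2 studies")
  if (any(effects$vi <= 0)) stop("sampling variances must be positive")
  fit <- metafor::rma(yi = effects$effect, vi = effects$vi, method = "REML")
  zc <- stats::qnorm(0.975)
  tab <- data.frame(participant = effects$participant,
                    effect = effects$effect,
                    ci_lo = effects$effect - zc * sqrt(effects$vi),
                    ci_hi = effects$effect + zc * sqrt(effects$vi))
  list(pooled = as.numeric(fit$beta), se = fit$se,
       ci = c(fit$ci.lb, fit$ci.ub), tau2 = fit$tau2,
       k = nrow(effects), table = tab, model = fit)
}
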