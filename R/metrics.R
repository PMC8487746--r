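#' Gini coefficient of payoffs (dispersion)
#'
#' Relative mean absolute difference,
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \mu),}
#' computed in the equivalent sorted form. `G = 0` when all payoffs are
#' equal; when a single individual holds everything `G = (n - 1) / n`,
#' which approaches 1 for large groups. No small-sample `n / (n - 1)`
#' correction is applied. The index is invariant to multiplying all payoffs
#' by a positive constant, which is what makes it comparable across
#' experiments with different incentive scales.
#'
#' @param x Numeric vector of `n >= 2` non-negative payoffs.
#' @return The Gini coefficient, in \[0, 1). An all-zero vector yields 0
#'   (with a note), since no inequality is expressible.
#' @examples
#' gini(c(5, 5, 5, 5))  # 0
#' gini(c(3, 1))        # 0.25
#' gini(c(1, 0, 0, 0))  # 0.75
#' @export
gini <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) stop("'x' must be numeric with n >= 2")
  if (any(is.na(x))) stop("'x' must not contain NA")
  if (any(x < 0)) stop("Gini is defined here for non-negative payoffs")
  n <- length(x)
  mu <- mean(x)
  if (mu == 0) {
    message("all payoffs are zero; Gini reported as 0")
    return(0)
  }
  s <- sort(x)
  sum((2 * seq_len(n) - n - 1) * s) / (n^2 * mu)
}

#' Pearson correspondence between cooperation and payoff
#'
#' Product-moment correlation between each agent's cooperation rate (the
#' proportion of periods in which it executed C) and its final accumulated
#' payoff. A value of 1 means higher cooperation is always proportionally
#' rewarded; -1 indicates perfect inverse proportionality. When either
#' vector is constant the correlation is undefined and `NA_real_` is
#' returned (the undefined sentinel); such runs are excluded, not
#' zero-imputed, from sweep-cell means.
#'
#' @param coop_rates Numeric vector of per-agent cooperation rates.
#' @param payoffs Numeric vector of per-agent final payoffs, same length.
#' @return Correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @examples
#' pearson_correspondence(c(0, 0.5, 1), c(0, 5, 10))   # 1
#' pearson_correspondence(c(0, 0.5, 1), c(10, 5, 0))   # -1
#' @export
pearson_correspondence <- function(coop_rates, payoffs) {
  if (length(coop_rates) != length(payoffs)) stop("length mismatch")
  if (length(coop_rates) < 2L) stop("need n >= 2")
  if (stats::var(coop_rates) == 0 || stats::var(payoffs) == 0)
    return(NA_real_)
  stats::cor(coop_rates, payoffs)
}
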