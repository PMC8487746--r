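#' Simulation parameters for the network cooperation game
#'
#' Collects and validates every parameter of the agent-based model in a
#' single record: population size and composition, game payoffs, reputation
#' window, behavioural thresholds, error rates, network regime, horizon and
#' seed. The fraction of conditional cooperators `p_R` is derived as
#' `1 - p_A - p_D`.
#'
#' The defaults are the reference configuration of the model: `N = 100`
#' agents with average degree `m = 2` play for `T = 100` periods with
#' Prisoner's Dilemma payoffs CC = 5, CD = 0, DC = 8, DD = 2, execution and
#' network-update error rates `epsilon = gamma = 0.005`, reciprocation
#' threshold `theta_C = 0.5` and reputation effects `a_0 = 0.1`,
#' `a_C = 0.05`. The initial cooperation propensity `theta_0` defaults to
#' `p_A`, i.e. the probability of meeting an unconditional cooperator on a
#' first encounter.
#'
#' Effective reputation-adjusted quantities are clamped to \[0, 1\]: the
#' initial cooperation probability is `min(1, max(0, theta0 + a0 * r))` and
#' the reciprocation threshold is `min(1, max(0, thetaC - aC * r))`. At the
#' default values the clamping is inert.
#'
#' @param p_A Fraction of persistent altruists, in \[0, 1\].
#' @param p_D Fraction of persistent defectors, in \[0, 1\];
#'   `p_A + p_D <= 1` is required.
#' @param r Reputation window length in periods; a non-negative integer.
#'   `r = 0` means no reputational information beyond one's own partners'
#'   last-period actions.
#' @param N Population size (number of agents), at least 2.
#' @param m Target average node degree, with `1 <= m < N`. Under strategic
#'   updating the hard degree cap is `2 * m`.
#' @param T Number of periods, at least 1.
#' @param theta0 Initial cooperation propensity baseline in \[0, 1\];
#'   defaults to `p_A`.
#' @param thetaC Reciprocation threshold baseline in \[0, 1\].
#' @param a0,aC Strength of the reputation effect on the initial cooperation
#'   probability and on the reciprocation threshold, in (0, 1).
#' @param payoff_CC,payoff_CD,payoff_DC,payoff_DD Per-interaction payoffs
#'   (game units) for the four action pairs, row = own action.
#' @param epsilon Action-execution error probability in \[0, 1): with this
#'   probability an agent executes the opposite of its intended action.
#' @param gamma Network-update omission error probability in \[0, 1): with
#'   this probability an agent skips its whole strategic update for the
#'   period.
#' @param mode Network regime: `"random_rewiring"` (the whole network is a
#'   fresh random draw every period) or `"strategic_updating"` (agents drop
#'   defecting partners and form new links by mutual consent under the
#'   `2 * m` cap).
#' @param seed Optional integer seed fixing the run's random stream.
#'
#' @return An object of class `sim_params`: a named list with all fields
#'   above plus the derived `p_R`.
#' @seealso [run_simulation()], [run_sweep()], [assign_strategies()]
#' @examples
#' p <- sim_params(p_A = 0.1, p_D = 0.1, r = 1, seed = 42)
#' p$p_R
#' @export
sim_params <- function(p_A, p_D, r = 0, N = 100, m = 2, T = 100,
                       theta0 = p_A, thetaC = 0.5, a0 = 0.1, aC = 0.05,
                       payoff_CC = 5, payoff_CD = 0,
                       payoff_DC = 8, payoff_DD = 2,
                       epsilon = 0.005, gamma = 0.005,
                       mode = c("random_rewiring", "strategic_updating"),
                       seed = NULL) {
  mode <- match.arg(mode)
  raw <- list(N = N, m = m, T = T, p_A = p_A, p_D = p_D, r = r,
              theta0 = theta0, thetaC = thetaC, a0 = a0, aC = aC,
              payoff_CC = payoff_CC, payoff_CD = payoff_CD,
              payoff_DC = payoff_DC, payoff_DD = payoff_DD,
              epsilon = epsilon, gamma = gamma, mode = mode, seed = seed)
  validate_params(raw)
}

#' Validate a raw parameter record
#'
#' Checks every model invariant on a named list of raw parameter values and
#' returns a validated `sim_params` object with the conditional-cooperator
#' fraction `p_R = 1 - p_A - p_D` derived. Most users should call
#' [sim_params()], which fills in defaults before validating.
#'
#' @param raw Named list containing all `sim_params` fields except `p_R`.
#' @return A validated object of class `sim_params`.
#' @export
validate_params <- function(raw) {
  required <- c("N", "m", "T", "p_A", "p_D", "r", "theta0", "thetaC",
                "a0", "aC", "payoff_CC", "payoff_CD", "payoff_DC",
                "payoff_DD", "epsilon", "gamma", "mode")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  p <- raw[c(required, if ("seed" %in% names(raw)) "seed")]
  if (is.null(p$seed)) p["seed"] <- list(NULL)

  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number")
    x
  }
  for (nm in setdiff(required, "mode")) chk_num(p[[nm]], nm)

  if (p$N < 2 || p$N != round(p$N)) stop("'N' must be an integer >= 2")
  if (p$m < 1 || p$m >= p$N) stop("'m' must satisfy 1 <= m < N")
  if (p$T < 1 || p$T != round(p$T)) stop("'T' must be an integer >= 1")
  if (p$r < 0 || p$r != round(p$r)) stop("'r' must be a non-negative integer")
  for (nm in c("p_A", "p_D", "theta0", "thetaC"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop("'", nm, "' must lie in [0, 1]")
  if (p$p_A + p$p_D > 1 + 1e-12)
    stop("'p_A' + 'p_D' must not exceed 1")
  for (nm in c("a0", "aC"))
    if (p[[nm]] <= 0 || p[[nm]] >= 1) stop("'", nm, "' must lie in (0, 1)")
  for (nm in c("epsilon", "gamma"))
    if (p[[nm]] < 0 || p[[nm]] >= 1) stop("'", nm, "' must lie in [0, 1)")
  if (!p$mode %in% c("random_rewiring", "strategic_updating"))
    stop("'mode' must be \"random_rewiring\" or \"strategic_updating\"")
  if (!is.null(p$seed)) {
    chk_num(p$seed, "seed")
    p$seed <- as.integer(p$seed)
  }

  p$N <- as.integer(p$N)
  p$T <- as.integer(p$T)
  p$r <- as.integer(p$r)
  p$p_R <- 1 - p$p_A - p$p_D
  if (p$p_R < 0) p$p_R <- 0
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Network cooperation game parameters\n")
  cat(sprintf("  population : N = %d (p_A = %.3g, p_D = %.3g, p_R = %.3g)\n",
              x$N, x$p_A, x$p_D, x$p_R))
  cat(sprintf("  network    : m = %g, mode = %s\n", x$m, x$mode))
  cat(sprintf("  horizon    : T = %d periods, reputation window r = %d\n",
              x$T, x$r))
  cat(sprintf("  payoffs    : CC = %g, CD = %g, DC = %g, DD = %g\n",
              x$payoff_CC, x$payoff_CD, x$payoff_DC, x$payoff_DD))
  cat(sprintf("  behaviour  : theta0 = %.3g, thetaC = %.3g, a0 = %.3g, aC = %.3g\n",
              x$theta0, x$thetaC, x$a0, x$aC))
  cat(sprintf("  errors     : epsilon = %.3g, gamma = %.3g\n",
              x$epsilon, x$gamma))
  if (!is.null(x$seed)) cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}

# clamp to [0,1]; applied to the reputation-adjusted propensity and threshold
clamp01 <- function(x) pmin(1, pmax(0, x))

# effective initial-cooperation probability and reciprocation threshold
initial_coop_prob <- function(params) clamp01(params$theta0 + params$a0 * params$r)
reciprocation_threshold <- function(params) clamp01(params$thetaC - params$aC * params$r)
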