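#' Agent state record
#'
#' A light container for one agent: its fixed strategy type, the sequence of
#' actions it actually executed (post execution-error, one per completed
#' period) and its accumulated payoff. The strategy never changes within a
#' run; histories record executed (not intended) actions because observers
#' can only see what was done.
#'
#' @param id Agent index (1-based).
#' @param strategy One of `"altruist"`, `"defector"`, `"conditional"`.
#' @param actions Character vector of executed actions, `"C"` or `"D"`, one
#'   per completed period (oldest first).
#' @param payoff Accumulated payoff in game units.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(id, strategy, actions = character(0), payoff = 0) {
  strategy <- match.arg(strategy, c("altruist", "defector", "conditional"))
  if (length(actions) && !all(actions %in% c("C", "D")))
    stop("'actions' must contain only \"C\" and \"D\"")
  structure(list(id = as.integer(id), strategy = strategy,
                 actions = actions, payoff = payoff),
            class = "agent_state")
}

#' Deterministic strategy counts for a population
#'
#' Apportions `N` agents to the three strategy types by the
#' largest-remainder method on the target fractions `(p_A, p_D, p_R)`:
#' each type receives `floor(p * N)` agents and the remaining seats go to
#' the largest fractional remainders, ties broken in the fixed order
#' altruist, defector, conditional. Exact multiples are reproduced exactly
#' and the counts always sum to `N`, so grid cells with the same
#' composition are directly comparable across runs.
#'
#' @param params A [sim_params()] object.
#' @return Named integer vector `c(altruist=, defector=, conditional=)`.
#' @export
strategy_counts <- function(params) {
  N <- params$N
  q <- c(altruist = params$p_A, defector = params$p_D,
         conditional = params$p_R) * N
  n <- floor(q + 1e-9)                      # guard float noise on exact multiples
  left <- N - sum(n)
  if (left > 0) {
    rem <- q - n
    give <- order(-rem, seq_along(rem))[seq_len(left)]
    n[give] <- n[give] + 1L
  }
  stats::setNames(as.integer(n), names(q))
}

#' Assign strategy types to agents
#'
#' Draws a uniformly random permutation of the deterministic composition
#' from [strategy_counts()] over agent indices.
#'
#' @param params A [sim_params()] object.
#' @return Character vector of length `N` with entries `"altruist"`,
#'   `"defector"` or `"conditional"`.
#' @export
assign_strategies <- function(params) {
  n <- strategy_counts(params)
  sample(rep(names(n), times = n))
}

#' Reputation score of an agent
#'
#' The reputational information visible to others: the fraction of the
#' agent's executed actions equal to `"C"` over the last
#' `min(r, completed periods)` periods. Returns `NA_real_` when the agent
#' has no history yet (the no-history sentinel).
#'
#' @param agent An [agent_state()] object (or plain character vector of
#'   executed actions).
#' @param r Reputation window length; must be at least 1 -- with `r = 0`
#'   reputational information is unavailable and calling this is an error.
#' @return A fraction in \[0, 1\], or `NA_real_` if no periods completed.
#' @examples
#' a <- agent_state(1, "conditional", c("C", "D", "C", "C"))
#' reputation_score(a, r = 2)  # 1
#' reputation_score(a, r = 4)  # 0.75
#' @export
reputation_score <- function(agent, r) {
  if (r < 1) stop("reputation is unavailable when r = 0")
  actions <- if (inherits(agent, "agent_state")) agent$actions else agent
  k <- length(actions)
  if (k == 0L) return(NA_real_)
  w <- min(r, k)
  mean(actions[(k - w + 1L):k] == "C")
}

#' Choose an agent's intended action
#'
#' Implements the per-agent decision rules. Altruists always cooperate and
#' defectors never do. A conditional cooperator cooperates in the first
#' period with probability `clamp(theta0 + a0 * r)`; from the second period
#' on it reciprocates: it cooperates if and only if the observed partners'
#' cooperation score is at least `clamp(thetaC - aC * r)`. The score is the
#' mean, over the observed partners, of each partner's fraction of executed
#' `"C"` actions over the last `max(r, 1)` completed periods; partners with
#' no recorded history are left out of the average. Ties cooperate (the
#' comparison is `>=`). A conditional cooperator with no observed partners
#' (or whose partners all lack history) repeats the initial-cooperation
#' draw.
#'
#' Who the observed partners are depends on the information regime: with
#' reputational information (`r >= 1`) the records of the agent's *current*
#' neighbours are visible, so those are passed; without it (`r = 0`) the
#' agent knows only its own experience, i.e. the last-period actions of its
#' *previous-period* partners (in a persistent network the two coincide up
#' to the partners replaced in between).
#'
#' @param agent An [agent_state()] object.
#' @param neighbours List of [agent_state()] objects: the agent's observed
#'   partners as defined above. Order is irrelevant.
#' @param params A [sim_params()] object.
#' @param period Current period index, 1-based (`period = 1` is the first).
#' @return `"C"` or `"D"` (the intended action, before execution error).
#' @export
choose_action <- function(agent, neighbours, params, period) {
  switch(agent$strategy,
    altruist = "C",
    defector = "D",
    conditional = {
      initial <- function() {
        if (stats::runif(1) < initial_coop_prob(params)) "C" else "D"
      }
      if (period <= 1L) return(initial())
      w <- max(params$r, 1L)
      fr <- vapply(neighbours, function(nb) {
        a <- nb$actions
        k <- length(a)
        if (k == 0L) return(NA_real_)
        mean(a[(k - min(w, k) + 1L):k] == "C")
      }, numeric(1))
      fr <- fr[!is.na(fr)]
      if (!length(fr)) return(initial())
      if (mean(fr) >= reciprocation_threshold(params)) "C" else "D"
    })
}

#' Apply the action-execution error
#'
#' With probability `epsilon` the executed action is the opposite of the
#' intended one. The executed action (not the intention) is what enters
#' histories, payoffs and reputations. Vectorised over `intended`.
#'
#' @param intended Character vector of `"C"`/`"D"` intended actions.
#' @param epsilon Flip probability in \[0, 1\].
#' @return Character vector of executed actions, same length as `intended`.
#' @export
apply_execution_error <- function(intended, epsilon) {
  stopifnot(all(intended %in% c("C", "D")))
  flip <- stats::runif(length(intended)) < epsilon
  out <- intended
  out[flip] <- ifelse(intended[flip] == "C", "D", "C")
  out
}
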