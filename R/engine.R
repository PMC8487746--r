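#' Per-agent payoffs for one period
#'
#' Each agent receives the mean, over its neighbours, of the dyadic payoff
#' from the 2x2 matrix (row = own action, column = neighbour's action), so
#' payoffs do not depend on the number of interaction partners. Agents with
#' no neighbours earn the isolate payoff of 0 for the period: with no
#' interactions nothing is earned, which is also what makes exclusion
#' costly.
#'
#' @param network An [interaction_network()].
#' @param executed Executed action per agent: character `"C"`/`"D"` or
#'   logical (`TRUE` = C).
#' @param params A [sim_params()] object (supplies the payoff matrix).
#' @return Numeric vector of per-agent payoffs for the period.
#' @examples
#' p <- sim_params(p_A = 0, p_D = 0, N = 3, m = 1, T = 1)
#' net <- interaction_network(matrix(c(FALSE, TRUE, TRUE,
#'                                     TRUE, FALSE, FALSE,
#'                                     TRUE, FALSE, FALSE), 3, 3))
#' compute_payoffs(net, c("D", "C", "C"), p)  # centre agent earns (8+8)/2
#' @export
compute_payoffs <- function(network, executed, params) {
  if (is.character(executed)) {
    stopifnot(all(executed %in% c("C", "D")))
    executed <- executed == "C"
  }
  if (length(executed) != network$n) stop("one action per agent required")
  A <- network$adj + 0
  payoffs_adj(A, as.double(executed), rowSums(A), params)
}

# adjacency-level payoff kernel shared with the period loop; `coop` numeric
# 0/1, `deg` precomputed row sums
payoffs_adj <- function(A, coop, deg, params) {
  nC <- as.vector(A %*% coop)
  pay <- numeric(length(coop))
  nb <- deg > 0
  pC <- params$payoff_CC * nC + params$payoff_CD * (deg - nC)
  pD <- params$payoff_DC * nC + params$payoff_DD * (deg - nC)
  pay[nb] <- ifelse(coop[nb] > 0, pC[nb], pD[nb]) / deg[nb]
  pay
}

#' Initialise the state of a simulation run
#'
#' Assigns strategies, draws the initial Erdos-Renyi network and prepares
#' the action-history window. Under strategic updating the initial network
#' is additionally capped at degree `2 * m` (uniformly-chosen excess edges
#' removed), since the cap is a structural constraint of that regime.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `sim_state` holding the mutable run state.
#' @export
init_sim_state <- function(params) {
  N <- params$N
  strat <- assign_strategies(params)
  A <- er_adjacency(N, params$m)
  if (params$mode == "strategic_updating") A <- cap_degrees(A, 2 * params$m)
  w <- max(params$r, 1L)
  structure(list(
    strategies = strat,
    is_alt = strat == "altruist",
    is_def = strat == "defector",
    A = A,
    A_prev = NULL,                  # network played on in the previous period
    hist = matrix(NA_real_, N, w),  # executed actions (0/1), most recent column last
    filled = 0L,                  # how many history columns are valid
    completed = 0L,               # periods completed so far
    coop_count = integer(N),
    payoff = numeric(N),
    coop_level = numeric(0),
    max_degree = numeric(0)
  ), class = "sim_state")
}

#' Run one period of the game
#'
#' Executes the fixed within-period event order: intended actions (by
#' strategy type and, for conditional cooperators, the reputation-adjusted
#' rules of [choose_action()]) -> execution error -> payoffs computed on the
#' current network -> payoffs accumulated and histories appended -> network
#' updated for the next period ([rewire_random()] or the strategic update,
#' per `params$mode`). The network is not updated after the final period.
#'
#' @param state A `sim_state` from [init_sim_state()].
#' @param params The [sim_params()] the state was created with.
#' @return The updated `sim_state`. The just-completed period's record is
#'   attached as `state$last_record`, a list with `period`,
#'   `executed_actions` (logical, `TRUE` = C), `per_agent_payoff` and
#'   `cooperation_level`.
#' @export
run_period <- function(state, params) {
  t <- state$completed + 1L
  if (t > params$T) stop("all T periods already completed")
  N <- params$N
  r <- params$r
  A <- state$A
  deg <- .rowSums(A, N, N)
  w <- max(r, 1L)

  intended <- state$is_alt            # altruists C, others filled below
  cond <- !state$is_alt & !state$is_def
  p0 <- initial_coop_prob(params)
  if (t == 1L) {
    nc <- sum(cond)
    if (nc) intended[cond] <- stats::runif(nc) < p0
  } else if (any(cond)) {
    # Observed partners: with reputational information (r >= 1) the records
    # of the *current* neighbours are visible; without it (r = 0) an agent
    # has only its own experience -- the last-period executed actions of its
    # *previous* partners.
    if (r >= 1L) {
      k <- min(w, state$filled)
      f <- .rowMeans(state$hist[, seq.int(to = state$filled, length.out = k),
                                drop = FALSE], N, k)
      Aobs <- A
      degobs <- deg
    } else {
      f <- state$hist[, state$filled]
      Aobs <- state$A_prev
      degobs <- .rowSums(Aobs, N, N)
    }
    score <- as.vector(Aobs %*% f)
    thr <- reciprocation_threshold(params)
    dec <- score >= thr * degobs       # mean over observed partners >= threshold
    condiso <- cond & degobs == 0
    if (any(condiso)) dec[condiso] <- stats::runif(sum(condiso)) < p0
    intended[cond] <- dec[cond]
  }

  executed <- xor(intended, stats::runif(N) < params$epsilon)
  ex_num <- as.double(executed)
  pay <- payoffs_adj(A, ex_num, deg, params)

  state$payoff <- state$payoff + pay
  state$coop_count <- state$coop_count + executed
  state$coop_level[t] <- mean(ex_num)
  state$max_degree[t] <- max(deg)

  if (state$filled < w) {
    state$hist[, state$filled + 1L] <- ex_num
    state$filled <- state$filled + 1L
  } else if (w == 1L) {
    state$hist[, 1L] <- ex_num
  } else {
    state$hist <- cbind(state$hist[, -1L, drop = FALSE], ex_num)
  }
  state$completed <- t
  state$A_prev <- A

  if (t < params$T) {
    if (params$mode == "random_rewiring") {
      state$A <- er_adjacency(N, params$m)
    } else {
      repok <- NULL
      if (r >= 1L) {
        k <- min(r, state$filled)
        rs <- .rowMeans(state$hist[, seq.int(to = state$filled,
                                             length.out = k),
                                   drop = FALSE], N, k)
        repok <- rs >= params$thetaC
      }
      state$A <- strategic_update_adj(A = state$A, coop_last = executed,
                                      repok = repok, two_m = 2 * params$m,
                                      gamma = params$gamma)
    }
  }

  state$last_record <- list(period = t, executed_actions = executed,
                            per_agent_payoff = pay,
                            cooperation_level = mean(ex_num))
  state
}

#' Run a full simulation
#'
#' Plays `T` periods from a fresh initial network and returns the run-level
#' result. Deterministic given `params$seed` (or the current RNG state if no
#' seed is set): the same parameters and seed always reproduce the same
#' result bit for bit.
#'
#' @param params A [sim_params()] object.
#' @param keep `"summary"` (default) or `"periods"`, which additionally
#'   retains the full `N x T` executed-action and per-period payoff
#'   matrices.
#' @return An object of class `coopsim` with fields `params`, `strategies`,
#'   `cooperation_rate` (per agent, fraction of the `T` periods executing
#'   C), `final_payoff` (per agent, accumulated), `cooperation_level`
#'   (per-period trace), `max_degree` (per-period trace of the maximum node
#'   degree of the network played on) and, with `keep = "periods"`,
#'   `actions` and `period_payoffs`.
#' @examples
#' res <- run_simulation(sim_params(p_A = 0.1, p_D = 0.1, r = 1, T = 20,
#'                                  seed = 1))
#' summary(res)
#' @export
run_simulation <- function(params, keep = c("summary", "periods")) {
  keep <- match.arg(keep)
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- init_sim_state(params)
  full <- keep == "periods"
  if (full) {
    acts <- matrix(NA, params$N, params$T)
    pays <- matrix(NA_real_, params$N, params$T)
  }
  for (t in seq_len(params$T)) {
    state <- run_period(state, params)
    if (full) {
      acts[, t] <- state$last_record$executed_actions
      pays[, t] <- state$last_record$per_agent_payoff
    }
  }
  out <- list(params = params,
              strategies = state$strategies,
              cooperation_rate = state$coop_count / params$T,
              final_payoff = state$payoff,
              cooperation_level = state$coop_level,
              max_degree = state$max_degree)
  if (full) {
    out$actions <- acts
    out$period_payoffs <- pays
  }
  structure(out, class = "coopsim")
}

#' @export
print.coopsim <- function(x, ...) {
  cat(sprintf("Network cooperation game run: N = %d, T = %d, r = %d, %s\n",
              x$params$N, x$params$T, x$params$r, x$params$mode))
  cat(sprintf("  mean cooperation level : %.3f\n", mean(x$cooperation_level)))
  cat(sprintf("  mean final payoff      : %.2f\n", mean(x$final_payoff)))
  invisible(x)
}

#' Summarise a simulation run
#'
#' Computes the two group-level inequality outcomes for the run: the Gini
#' coefficient of final payoffs and the Pearson correspondence between
#' cooperation rate and final payoff.
#'
#' @param object A `coopsim` object.
#' @param ... Unused.
#' @return A list of class `summary.coopsim` with `gini`, `pearson`,
#'   `mean_cooperation`, `mean_payoff` and the strategy composition.
#' @export
summary.coopsim <- function(object, ...) {
  structure(list(
    params = object$params,
    gini = gini(object$final_payoff),
    pearson = pearson_correspondence(object$cooperation_rate,
                                     object$final_payoff),
    mean_cooperation = mean(object$cooperation_level),
    mean_payoff = mean(object$final_payoff),
    composition = table(object$strategies)
  ), class = "summary.coopsim")
}

#' @export
print.summary.coopsim <- function(x, ...) {
  cat(sprintf("Run summary (N = %d, T = %d, r = %d, %s)\n",
              x$params$N, x$params$T, x$params$r, x$params$mode))
  cat(sprintf("  Gini of final payoffs      : %.4f\n", x$gini))
  cat(sprintf("  Pearson correspondence     : %s\n",
              if (is.na(x$pearson)) "undefined (constant input)"
              else sprintf("%.4f", x$pearson)))
  cat(sprintf("  mean cooperation level     : %.4f\n", x$mean_cooperation))
  cat(sprintf("  mean final payoff          : %.2f\n", x$mean_payoff))
  invisible(x)
}

#' @export
plot.coopsim <- function(x, ...) {
  graphics::plot(seq_along(x$cooperation_level), x$cooperation_level,
                 type = "l", ylim = c(0, 1), xlab = "period",
                 ylab = "cooperation level",
                 main = sprintf("Cooperation level (r = %d, %s)",
                                x$params$r, x$params$mode), ...)
  graphics::abline(h = c(x$params$p_A, 1 - x$params$p_D), lty = 3,
                   col = "grey50")
  invisible(x)
}

#' Simulate replicate runs from a parameter record
#'
#' [stats::simulate()] method for [sim_params()]: runs `nsim` independent
#' replicates, each on its own substream derived from `seed`.
#'
#' @param object A [sim_params()] object.
#' @param nsim Number of replicate runs.
#' @param seed Master seed for the replicate substreams; defaults to
#'   `object$seed`.
#' @param ... Passed to [run_simulation()].
#' @return A list of `coopsim` objects of length `nsim`.
#' @export
simulate.sim_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seq_len(nsim), function(i) {
    p <- object
    p$seed <- subseeds[i]
    run_simulation(p, ...)
  })
}

#' Replicated parameter sweep over population compositions
#'
#' Runs the model over a grid of `(p_D, p_A)` cells crossed with a set of
#' conditions (reputation window `r` and network regime), with `reps`
#' independent replicate runs per cell and condition, and aggregates the
#' per-run Gini, Pearson correspondence and mean cooperation level into
#' cell means. Undefined Pearson values (constant cooperation or payoff)
#' are excluded from the cell mean and counted in `n_pearson_excluded`.
#' Replicate substreams are drawn once from `master_seed` and consumed in a
#' fixed iteration order, so the whole sweep is bit-reproducible.
#'
#' @param grid Data frame with columns `p_D` and `p_A`, one row per cell.
#'   Cells violating `p_A + p_D <= 1` are skipped with a warning.
#' @param conditions Data frame with columns `r` and `mode`, one row per
#'   condition.
#' @param reps Replicate runs per cell and condition.
#' @param base A [sim_params()] template supplying every other parameter.
#' @param master_seed Integer master seed for the replicate substreams.
#' @param theta0_tracks_p_A If `TRUE` (default, the reference protocol) the
#'   initial cooperation propensity `theta0` is set to each cell's `p_A`;
#'   otherwise `base$theta0` is used everywhere.
#' @param keep_runs Also return the per-run outcome table (needed e.g. to
#'   feed the meta-analysis layer).
#' @return An object of class `coopsweep`; its `table` field is a tidy data
#'   frame with one row per cell x condition and columns `p_D`, `p_A`, `r`,
#'   `mode`, `mean_gini`, `mean_pearson`, `mean_cooperation`, `reps`,
#'   `n_pearson_excluded`.
#' @export
run_sweep <- function(grid, conditions, reps, base, master_seed,
                      theta0_tracks_p_A = TRUE, keep_runs = FALSE) {
  stopifnot(inherits(base, "sim_params"),
            all(c("p_D", "p_A") %in% names(grid)),
            all(c("r", "mode") %in% names(conditions)),
            reps >= 1)
  ok <- grid$p_A + grid$p_D <= 1 + 1e-12
  if (any(!ok)) {
    warning(sprintf("skipping %d grid cell(s) with p_A + p_D > 1", sum(!ok)))
    grid <- grid[ok, , drop = FALSE]
  }
  cells <- merge(grid, conditions, by = NULL)   # full crossing, fixed order
  cells <- cells[order(cells$mode, cells$r, cells$p_D, cells$p_A), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  set.seed(master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max, nrow(cells) * reps),
                  nrow = nrow(cells))

  agg <- vector("list", nrow(cells))
  runs <- if (keep_runs) vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- base
    p$p_A <- cells$p_A[i]
    p$p_D <- cells$p_D[i]
    p$p_R <- 1 - p$p_A - p$p_D
    p$r <- as.integer(cells$r[i])
    p$mode <- as.character(cells$mode[i])
    if (theta0_tracks_p_A) p$theta0 <- p$p_A
    g <- pe <- cl <- numeric(reps)
    for (j in seq_len(reps)) {
      p$seed <- seeds[i, j]
      res <- run_simulation(p)
      g[j] <- gini(res$final_payoff)
      pe[j] <- pearson_correspondence(res$cooperation_rate, res$final_payoff)
      cl[j] <- mean(res$cooperation_level)
    }
    agg[[i]] <- data.frame(
      p_D = p$p_D, p_A = p$p_A, r = p$r, mode = p$mode,
      mean_gini = mean(g),
      mean_pearson = if (all(is.na(pe))) NA_real_ else mean(pe, na.rm = TRUE),
      mean_cooperation = mean(cl),
      reps = reps,
      n_pearson_excluded = sum(is.na(pe)))
    if (keep_runs)
      runs[[i]] <- data.frame(p_D = p$p_D, p_A = p$p_A, r = p$r,
                              mode = p$mode, run = seq_len(reps),
                              gini = g, pearson = pe, mean_cooperation = cl)
  }
  structure(list(table = do.call(rbind, agg),
                 runs = if (keep_runs) do.call(rbind, runs),
                 reps = reps, master_seed = master_seed,
                 theta0_tracks_p_A = theta0_tracks_p_A,
                 base = base),
            class = "coopsweep")
}

#' @export
print.coopsweep <- function(x, ...) {
  cat(sprintf("Parameter sweep: %d cell-conditions x %d reps (master seed %d)\n",
              nrow(x$table), x$reps, x$master_seed))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat(sprintf("  ... %d more rows\n", nrow(x$table) - 10))
  invisible(x)
}

#' Heatmaps of sweep outcomes
#'
#' Draws one `(p_D, p_A)` heatmap per condition for the chosen outcome,
#' mirroring the usual presentation of composition sweeps.
#'
#' @param x A `coopsweep` object.
#' @param outcome One of `"mean_gini"`, `"mean_pearson"`,
#'   `"mean_cooperation"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.coopsweep <- function(x, outcome = c("mean_gini", "mean_pearson",
                                          "mean_cooperation"), ...) {
  outcome <- match.arg(outcome)
  tab <- x$table
  conds <- unique(tab[, c("r", "mode")])
  op <- graphics::par(mfrow = c(1, nrow(conds)))
  on.exit(graphics::par(op))
  for (k in seq_len(nrow(conds))) {
    sub <- tab[tab$r == conds$r[k] & tab$mode == conds$mode[k], ]
    xs <- sort(unique(sub$p_D)); ys <- sort(unique(sub$p_A))
    z <- matrix(NA_real_, length(xs), length(ys))
    z[cbind(match(sub$p_D, xs), match(sub$p_A, ys))] <- sub[[outcome]]
    graphics::image(xs, ys, z, xlab = "p_D", ylab = "p_A",
                    main = sprintf("%s (r = %d, %s)", outcome,
                                   conds$r[k], conds$mode[k]), ...)
  }
  invisible(x)
}
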