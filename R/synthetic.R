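#' Design of a synthetic group-level experiment
#'
#' Describes one experiment whose per-network outcomes are to be generated:
#' a control condition plus one or more treatment conditions, each with a
#' number of networks, and a location-shift effect specification for the
#' two outcomes. The generated structure (networks nested in conditions
#' nested in experiments, 4-16 networks per condition, network sizes in the
#' tens) emulates the shape of published network cooperation experiments
#' without reproducing any particular study.
#'
#' @param experiment Experiment identifier.
#' @param treatments Character vector of treatment condition labels.
#' @param n_networks Networks per condition; recycled over control plus
#'   treatments.
#' @param g0,rho0 Control-condition centres of the Gini and Pearson
#'   distributions.
#' @param delta_g,delta_rho Treatment shifts of the two centres; recycled
#'   over treatments. The neutral default 0 gives a null (no-effect)
#'   design.
#' @param sd_g,sd_rho Between-network standard deviations.
#' @param network_size Range of (nominal) network sizes, recorded in the
#'   design for bookkeeping.
#' @return An object of class `experiment_design`.
#' @seealso [generate_outcomes()]
#' @export
experiment_design <- function(experiment, treatments = "treatment",
                              n_networks = 8,
                              g0 = 0.3, rho0 = 0.25,
                              delta_g = 0, delta_rho = 0,
                              sd_g = 0.08, sd_rho = 0.2,
                              network_size = c(10, 24)) {
  stopifnot(length(treatments) >= 1, all(n_networks >= 1),
            g0 >= 0, g0 < 1, rho0 >= -1, rho0 <= 1,
            sd_g > 0, sd_rho > 0)
  conditions <- c("control", treatments)
  structure(list(
    experiment = experiment,
    conditions = conditions,
    n_networks = rep_len(as.integer(n_networks), length(conditions)),
    g0 = g0, rho0 = rho0,
    delta_g = rep_len(delta_g, length(treatments)),
    delta_rho = rep_len(delta_rho, length(treatments)),
    sd_g = sd_g, sd_rho = sd_rho,
    network_size = network_size
  ), class = "experiment_design")
}

# truncated-normal draws by inverse-CDF; bounds are respected exactly
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate synthetic group-level outcomes
#'
#' Draws one `(gini, pearson)` pair per network from truncated-normal
#' location-shift distributions: control networks centred at
#' `(g0, rho0)`, treatment networks at `(g0 + delta_g, rho0 + delta_rho)`,
#' with between-network standard deviations `sd_g` and `sd_rho`. Gini draws
#' are truncated to \[0, 1) and Pearson draws to \[-1, 1\].
#'
#' @param designs An [experiment_design()] or a list of them.
#' @param seed Optional integer seed.
#' @return A validated `outcome_table` (see [as_outcome_table()]).
#' @examples
#' d <- experiment_design("E1", delta_g = -0.1)
#' generate_outcomes(d, seed = 1)
#' @export
generate_outcomes <- function(designs, seed = NULL) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  stopifnot(all(vapply(designs, inherits, logical(1), "experiment_design")))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (d in designs) {
    for (ci in seq_along(d$conditions)) {
      cond <- d$conditions[ci]
      nn <- d$n_networks[ci]
      if (cond == "control") {
        mg <- d$g0; mr <- d$rho0
      } else {
        ti <- ci - 1L
        mg <- d$g0 + d$delta_g[ti]
        mr <- d$rho0 + d$delta_rho[ti]
      }
      out[[length(out) + 1L]] <- data.frame(
        experiment = d$experiment, condition = cond,
        network = seq_len(nn),
        gini = pmin(rtruncnorm(nn, mg, d$sd_g, 0, 1), 1 - 1e-12),
        pearson = rtruncnorm(nn, mr, d$sd_rho, -1, 1))
    }
  }
  as_outcome_table(do.call(rbind, out))
}

#' Generate an outcome table by running the simulator
#'
#' End-to-end bridge from the agent-based model to the meta-analysis layer:
#' runs the model under each condition (a reputation window and network
#' regime) with `reps` independent replicate runs, treating every run as
#' one "network", and packages the per-run Gini and Pearson correspondence
#' as an `outcome_table`. The full pipeline -- simulate, measure,
#' meta-analyse -- is then [compare_conditions()] applied to the result.
#'
#' @param conditions Data frame with columns `label`, `r`, `mode`; the row
#'   whose label equals `control_label` plays the control role downstream.
#' @param base A [sim_params()] template (population composition, payoffs,
#'   errors, horizon).
#' @param reps Replicate runs per condition.
#' @param experiment Experiment identifier for the output rows.
#' @param seed Master seed for the replicate substreams.
#' @param control_label Label of the control condition (default
#'   `"control"`).
#' @return A validated `outcome_table` with `reps` rows per condition.
#' @examples
#' conds <- data.frame(label = c("control", "r1"), r = c(0, 1),
#'                     mode = "random_rewiring")
#' tab <- generate_from_simulator(conds, sim_params(0.1, 0.1, T = 20),
#'                                reps = 3, seed = 1)
#' @export
generate_from_simulator <- function(conditions, base, reps,
                                    experiment = "sim", seed = NULL,
                                    control_label = "control") {
  stopifnot(inherits(base, "sim_params"),
            all(c("label", "r", "mode") %in% names(conditions)),
            reps >= 1)
  if (!control_label %in% conditions$label)
    warning("no condition labelled '", control_label,
            "'; downstream meta-analysis will need an explicit control")
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, nrow(conditions) * reps),
                  nrow = nrow(conditions))
  out <- list()
  for (i in seq_len(nrow(conditions))) {
    p <- base
    p$r <- as.integer(conditions$r[i])
    p$mode <- as.character(conditions$mode[i])
    g <- pe <- numeric(reps)
    for (j in seq_len(reps)) {
      p$seed <- seeds[i, j]
      res <- run_simulation(p)
      g[j] <- gini(res$final_payoff)
      pe[j] <- pearson_correspondence(res$cooperation_rate, res$final_payoff)
    }
    out[[i]] <- data.frame(experiment = experiment,
                           condition = as.character(conditions$label[i]),
                           network = seq_len(reps),
                           gini = pmin(pmax(g, 0), 1 - 1e-12),
                           pearson = pe)
  }
  as_outcome_table(do.call(rbind, out))
}
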