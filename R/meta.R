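#' Exact binomial sign test
#'
#' Tests whether positive and negative effect directions are equally likely
#' (null success probability 1/2) from the count of positive directions
#' among control-treatment pairs. One-sided (`"greater"`) is the upper tail
#' `P(X >= k)`; `"less"` is `P(X <= k)`; two-sided is twice the smaller
#' tail, capped at 1 (at a null of 1/2 this coincides with the
#' minimum-likelihood convention).
#'
#' @param k Number of positive directions (successes), `0 <= k <= n`.
#' @param n Number of pairs (trials), `n >= 1`.
#' @param alternative `"greater"` (default; the one-sided test that the
#'   positive direction dominates), `"less"`, or `"two.sided"`.
#' @return An object of class `htest`.
#' @examples
#' sign_test(7, 8)$p.value                            # 9/256
#' sign_test(10, 23, "two.sided")$p.value             # ~0.678
#' @export
sign_test <- function(k, n, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stop("need integer counts with 0 <= k <= n and n >= 1")
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  lower <- stats::pbinom(k, n, 0.5)                          # P(X <= k)
  p <- switch(alternative,
              greater = upper,
              less = lower,
              two.sided = min(1, 2 * min(lower, upper)))
  structure(list(statistic = c(`positive directions` = k),
                 parameter = c(`n pairs` = n),
                 p.value = p,
                 alternative = alternative,
                 method = "Exact binomial sign test (null probability 1/2)",
                 data.name = sprintf("%d positive of %d pairs", k, n)),
            class = "htest")
}

#' Mann-Whitney U test
#'
#' Rank-sum test of whether values in `x` tend to exceed values in `y`. The
#' statistic is the number of pairs `(x_i, y_j)` with `x_i > y_j` plus half
#' the tied pairs. The p-value is exact -- by complete enumeration of all
#' `choose(n + m, n)` assignments of the pooled values to the two groups --
#' when both sample sizes are at most `exact_limit`; otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used. The method actually used is reported in the returned object.
#'
#' @param x,y Numeric samples, both nonempty.
#' @param alternative `"two.sided"` (default), `"greater"` (`x` tends to
#'   exceed `y`) or `"less"`.
#' @param exact_limit Largest per-group size for which the exact
#'   enumeration is used (default 8).
#' @return An object of class `htest` with the U statistic (for `x` over
#'   `y`), the p-value and the method used.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")$p.value   # 1/20
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "greater", "less"),
                           exact_limit = 8) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (any(is.na(c(x, y)))) stop("samples must not contain NA")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  R <- rank(pooled)                       # midranks handle ties
  U <- sum(R[seq_len(n)]) - n * (n + 1) / 2

  if (n <= exact_limit && m <= exact_limit) {
    method <- "Mann-Whitney U test, exact (complete enumeration)"
    idx <- utils::combn(n + m, n)
    Us <- colSums(matrix(R[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    pg <- mean(Us >= U - eps)
    pl <- mean(Us <= U + eps)
    p <- switch(alternative, greater = pg, less = pl,
                two.sided = min(1, 2 * min(pg, pl)))
  } else {
    method <- "Mann-Whitney U test, normal approximation (tie and continuity corrected)"
    mu <- n * m / 2
    ties <- table(pooled)
    s2 <- n * m / 12 *
      ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    if (s2 == 0) {
      p <- 1                               # all values tied: no evidence
    } else {
      sg <- sqrt(s2)
      zg <- (U - mu - 0.5) / sg
      zl <- (U - mu + 0.5) / sg
      p <- switch(alternative,
                  greater = stats::pnorm(zg, lower.tail = FALSE),
                  less = stats::pnorm(zl),
                  two.sided = min(1, 2 * min(stats::pnorm(zg, lower.tail = FALSE),
                                             stats::pnorm(zl))))
    }
  }
  structure(list(statistic = c(U = U),
                 parameter = c(n = n, m = m),
                 p.value = p,
                 alternative = alternative,
                 method = method,
                 data.name = paste(deparse1(substitute(x)), "vs",
                                   deparse1(substitute(y)))),
            class = "htest")
}

#' Outcome table of group-level experiment results
#'
#' Validates a data frame of per-network group-level outcomes: one row per
#' network, with columns `experiment`, `condition`, `network`, `gini`
#' (in \[0, 1)) and `pearson` (in \[-1, 1\], or `NA` when undefined). Each
#' `(experiment, condition, network)` combination must be unique.
#'
#' @param df A data frame with the columns above.
#' @return The validated table, classed `outcome_table`.
#' @seealso [compare_conditions()], [generate_outcomes()],
#'   [read_outcome_table()]
#' @export
as_outcome_table <- function(df) {
  req <- c("experiment", "condition", "network", "gini", "pearson")
  if (!all(req %in% names(df)))
    stop("outcome table needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[req]
  if (anyDuplicated(df[c("experiment", "condition", "network")]))
    stop("each (experiment, condition, network) must appear once")
  if (any(is.na(df$gini)) || any(df$gini < 0 | df$gini >= 1))
    stop("'gini' values must lie in [0, 1)")
  pz <- df$pearson[!is.na(df$pearson)]
  if (any(pz < -1 | pz > 1)) stop("'pearson' values must lie in [-1, 1]")
  class(df) <- c("outcome_table", "data.frame")
  df
}

#' Read / write an outcome table as CSV
#'
#' The on-disk format is a plain CSV with header
#' `experiment,condition,network,gini,pearson`.
#'
#' @param file Path to the CSV file.
#' @return [read_outcome_table()] returns a validated `outcome_table`.
#' @export
read_outcome_table <- function(file) {
  as_outcome_table(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_outcome_table
#' @param table An `outcome_table` (or data frame coercible to one).
#' @export
write_outcome_table <- function(table, file) {
  utils::write.csv(as_outcome_table(table), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Meta-analysis of control-treatment pairs
#'
#' For every experiment in the table, pairs each treatment condition with
#' the experiment's control condition and, for the chosen outcome, records
#' the effect direction (the sign of treatment summary minus control
#' summary; medians by default, consistent with the rank-based test) and a
#' Mann-Whitney U test of the per-network values. Across all pairs it then
#' runs the exact binomial [sign_test()] on the counts of positive versus
#' negative directions; exact zero differences are dropped from the sign
#' test (and reported).
#'
#' @param table An `outcome_table` (see [as_outcome_table()]).
#' @param outcome `"gini"` or `"pearson"`.
#' @param control Condition label identifying the control (default
#'   `"control"`).
#' @param summary_fun `"median"` (default) or `"mean"`: the per-condition
#'   summary whose difference defines the effect direction.
#' @param alternative Sidedness of the sign test (see [sign_test()]).
#' @param mw_alternative Sidedness of the per-pair Mann-Whitney tests.
#' @param mw_exact_limit Passed to [mann_whitney_u()].
#' @return An object of class `repnet_meta`: a list with `pairs` (one row
#'   per control-treatment pair: summaries, direction, U, p), `sign_test`
#'   (an `htest`), the direction counts and the number of dropped ties.
#' @export
compare_conditions <- function(table, outcome = c("gini", "pearson"),
                               control = "control",
                               summary_fun = c("median", "mean"),
                               alternative = c("greater", "less", "two.sided"),
                               mw_alternative = "two.sided",
                               mw_exact_limit = 8) {
  outcome <- match.arg(outcome)
  summary_fun <- match.arg(summary_fun)
  alternative <- match.arg(alternative)
  table <- as_outcome_table(table)
  sfun <- match.fun(summary_fun)

  rows <- list()
  for (exp_id in unique(table$experiment)) {
    sub <- table[table$experiment == exp_id, ]
    if (!control %in% sub$condition)
      stop(sprintf("experiment '%s' has no control condition '%s'",
                   exp_id, control))
    ctrl <- sub[[outcome]][sub$condition == control]
    ctrl <- ctrl[!is.na(ctrl)]
    if (!length(ctrl))
      stop(sprintf("experiment '%s': control has no defined '%s' values",
                   exp_id, outcome))
    for (cond in setdiff(unique(sub$condition), control)) {
      trt <- sub[[outcome]][sub$condition == cond]
      trt <- trt[!is.na(trt)]
      if (!length(trt))
        stop(sprintf("experiment '%s', condition '%s': no defined '%s' values",
                     exp_id, cond, outcome))
      mw <- mann_whitney_u(trt, ctrl, alternative = mw_alternative,
                           exact_limit = mw_exact_limit)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = exp_id, condition = cond,
        n_control = length(ctrl), n_treatment = length(trt),
        control_summary = sfun(ctrl), treatment_summary = sfun(trt),
        direction = sign(sfun(trt) - sfun(ctrl)),
        U = unname(mw$statistic), p_mw = mw$p.value,
        mw_method = if (grepl("exact", mw$method)) "exact" else "normal")
    }
  }
  pairs <- do.call(rbind, rows)
  n_pos <- sum(pairs$direction > 0)
  n_neg <- sum(pairs$direction < 0)
  n_tie <- sum(pairs$direction == 0)
  st <- if (n_pos + n_neg >= 1) sign_test(n_pos, n_pos + n_neg, alternative)
  structure(list(pairs = pairs, outcome = outcome,
                 summary_fun = summary_fun,
                 n_positive = n_pos, n_negative = n_neg,
                 n_ties_dropped = n_tie,
                 sign_test = st),
            class = "repnet_meta")
}

#' @export
print.repnet_meta <- function(x, ...) {
  cat(sprintf("Meta-analysis of control-treatment pairs (outcome: %s, %s difference)\n",
              x$outcome, x$summary_fun))
  print(x$pairs, digits = 4, row.names = FALSE)
  cat(sprintf("\nDirections: %d positive, %d negative (%d tie(s) dropped)\n",
              x$n_positive, x$n_negative, x$n_ties_dropped))
  if (!is.null(x$sign_test))
    cat(sprintf("Sign test (%s): p = %.4g\n",
                x$sign_test$alternative, x$sign_test$p.value))
  invisible(x)
}
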