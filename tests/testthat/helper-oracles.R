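# Independent oracles used across the suite. These deliberately use the
# slow, transparent formulation of each quantity (double loops, pairwise
# counting) so they share no code with the package implementations.

# Gini as the literal relative mean absolute difference over all pairs
gini_pairwise_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# tie-aware U by direct pairwise counting
mw_U_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact Mann-Whitney p by brute force over all C(n+m, n) group assignments,
# with U recomputed by pairwise counting for every split
mw_exact_oracle <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n <- length(x)
  splits <- utils::combn(length(pooled), n, simplify = FALSE)
  Us <- vapply(splits, function(ix) mw_U_oracle(pooled[ix], pooled[-ix]),
               numeric(1))
  U <- mw_U_oracle(x, y)
  pg <- mean(Us >= U - 1e-9)
  pl <- mean(Us <= U + 1e-9)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# build a list of agent_state objects from a strategy vector and a history
# matrix (rows = agents, columns = periods, entries "C"/"D")
make_agents <- function(strategies, history = NULL) {
  lapply(seq_along(strategies), function(i) {
    acts <- if (is.null(history)) character(0) else history[i, ]
    agent_state(i, strategies[i], acts)
  })
}

# small symmetric adjacency from an edge list (1-based pairs)
adj_from_edges <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- TRUE
    A[e[2], e[1]] <- TRUE
  }
  A
}
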