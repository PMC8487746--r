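#' Interaction network over N agents
#'
#' A simple undirected graph (no self-loops, no multi-edges) stored as a
#' logical adjacency matrix. Under strategic updating every node's degree is
#' capped at `2 * m` after each update step.
#'
#' @param adj Logical symmetric `N x N` matrix with a `FALSE` diagonal.
#' @return An object of class `interaction_network` with fields `n` and
#'   `adj`.
#' @seealso [init_random_network()], [rewire_random()], [strategic_update()]
#' @export
interaction_network <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("'adj' must be square")
  mode(adj) <- "logical"
  if (any(is.na(adj))) stop("'adj' must not contain NA")
  if (!isTRUE(all(adj == t(adj)))) stop("'adj' must be symmetric")
  if (any(diag(adj))) stop("self-loops are not allowed")
  structure(list(n = nrow(adj), adj = adj), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges (mean degree %.3g)\n",
              x$n, sum(x$adj) / 2, mean(rowSums(x$adj))))
  invisible(x)
}

#' Node degrees of an interaction network
#' @param network An [interaction_network()].
#' @return Integer vector of node degrees.
#' @export
net_degree <- function(network) as.integer(rowSums(network$adj))

#' Edge list of an interaction network
#'
#' @param network An [interaction_network()].
#' @param zero_based Use 0-based node ids (the on-disk CSV convention) or
#'   R's 1-based ids.
#' @return Two-column integer matrix with columns `tail`, `head`, one row
#'   per undirected edge with `tail < head`.
#' @export
as_edge_list <- function(network, zero_based = FALSE) {
  idx <- which(network$adj & upper.tri(network$adj), arr.ind = TRUE)
  e <- cbind(tail = idx[, 1L], head = idx[, 2L])
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  if (zero_based) e <- e - 1L
  e
}

#' Write an edge list to CSV (for debugging and replay)
#'
#' Two columns `tail,head` with 0-based node ids.
#'
#' @param network An [interaction_network()].
#' @param file Path to write.
#' @export
write_edge_list <- function(network, file) {
  utils::write.csv(as.data.frame(as_edge_list(network, zero_based = TRUE)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# ---- internal adjacency-level machinery ------------------------------------
# The engine works on plain numeric 0/1 adjacency matrices; the exported
# interaction_network wrapper stores a logical copy for users. The two
# per-period hot spots (the fresh Erdos-Renyi draw and the strategic update)
# are compiled kernels driven by R's RNG stream, so set.seed() fully
# determines every run.

# fresh Erdos-Renyi adjacency with edge probability m/(N-1)
er_adjacency <- function(N, m) {
  .er_adj_cpp(as.integer(N), m / (N - 1))
}

# remove uniformly-chosen excess edges until no node exceeds `cap`
cap_degrees <- function(A, cap) {
  repeat {
    deg <- rowSums(A)
    over <- which(deg > cap)
    if (!length(over)) return(A)
    i <- over[1L]
    nb <- which(A[i, ] > 0)
    j <- nb[sample.int(length(nb), 1L)]
    A[i, j] <- A[j, i] <- 0
  }
}

#' Create the initial random network
#'
#' Erdos-Renyi graph in which each of the `N (N - 1) / 2` possible links
#' forms independently with probability `m / (N - 1)`, giving expected mean
#' degree `m`, low clustering and a Poisson-like degree distribution.
#'
#' @param N Number of nodes (at least 2).
#' @param m Target average degree, `1 <= m < N`.
#' @return An [interaction_network()].
#' @export
init_random_network <- function(N, m) {
  if (length(N) != 1L || N < 2 || N != round(N)) stop("'N' must be an integer >= 2")
  if (length(m) != 1L || m < 1 || m >= N) stop("'m' must satisfy 1 <= m < N")
  interaction_network(er_adjacency(as.integer(N), m))
}

#' Draw a fresh random network for the next period
#'
#' Under random rewiring agents are placed in a completely new network every
#' period: an independent Erdos-Renyi draw with the same `N` and edge
#' probability `m / (N - 1)`; no state is carried over.
#'
#' @param params A [sim_params()] object with `mode = "random_rewiring"`.
#' @return An [interaction_network()].
#' @export
rewire_random <- function(params) {
  if (params$mode != "random_rewiring")
    stop("rewire_random() applies to mode = \"random_rewiring\"")
  interaction_network(er_adjacency(params$N, params$m))
}

# core strategic update on a plain adjacency matrix.
#   A         logical adjacency
#   coop_last logical, TRUE if the agent's last-period executed action was C
#   repok     logical eligibility-by-reputation vector, or NULL when r = 0
#   two_m     degree cap
#   gamma     per-agent probability of skipping the whole update
strategic_update_adj <- function(A, coop_last, repok, two_m, gamma) {
  .strategic_update_cpp(A, coop_last, repok, as.integer(two_m), gamma)
}

#' Strategic network update
#'
#' One round of strategic partner replacement, performed after a period's
#' actions have been observed. In order: (1) each agent independently skips
#' its entire update with probability `gamma`; (2) each non-skipping agent
#' with at least one neighbour whose last-period executed action was D drops
#' exactly one such neighbour (uniformly at random among them); all drops
#' are applied simultaneously -- a link dies if either endpoint drops it;
#' (3) each non-skipping agent nominates up to `2m - degree` new potential
#' partners from its eligible pool (see [eligible_partners()]), sampled
#' uniformly without replacement; (4) a link forms for every mutual
#' nomination, processed in random order, skipping any formation that would
#' push either endpoint above degree `2m`.
#'
#' @param network An [interaction_network()].
#' @param agents List of [agent_state()] objects with at least one completed
#'   period of history (updating responds to observed behaviour).
#' @param params A [sim_params()] with `mode = "strategic_updating"`.
#' @return The updated [interaction_network()].
#' @export
strategic_update <- function(network, agents, params) {
  if (params$mode != "strategic_updating")
    stop("strategic_update() applies to mode = \"strategic_updating\"")
  last <- vapply(agents, function(a) {
    k <- length(a$actions)
    if (k == 0L) stop("strategic updating requires at least one completed period")
    a$actions[k] == "C"
  }, logical(1))
  repok <- NULL
  if (params$r >= 1L) {
    rs <- vapply(agents, reputation_score, numeric(1), r = params$r)
    repok <- !is.na(rs) & rs >= params$thetaC   # no-history agents ineligible
  }
  interaction_network(strategic_update_adj(network$adj + 0, last, repok,
                                           2 * params$m, params$gamma))
}

#' Eligible new partners for an agent
#'
#' The pool an agent nominates from during strategic updating. Without
#' reputational information (`r = 0`) it contains every non-neighbour except
#' the agent itself and the partner it dropped this period. With
#' reputational information (`r >= 1`) the pool is further filtered to
#' agents whose [reputation_score()] over the last `r` periods is at least
#' `thetaC` (the unadjusted partner-choice threshold); agents with no
#' recorded history cannot demonstrate the required record and are
#' ineligible.
#'
#' @param agent The nominating [agent_state()].
#' @param network The current (post-drop) [interaction_network()].
#' @param agents List of all [agent_state()] objects, indexed by agent id.
#' @param params A [sim_params()] object.
#' @param dropped Optional id of the partner dropped this period.
#' @return Integer vector of candidate agent ids.
#' @export
eligible_partners <- function(agent, network, agents, params,
                              dropped = integer(0)) {
  elig <- !network$adj[agent$id, ]
  elig[agent$id] <- FALSE
  elig[dropped] <- FALSE
  if (params$r >= 1L) {
    rs <- vapply(agents, reputation_score, numeric(1), r = params$r)
    elig <- elig & !is.na(rs) & rs >= params$thetaC
  }
  which(elig)
}
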