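# Cost-thresholded binary graph analysis: efficiency curves, small-world
# omega, and per-node degree/betweenness averaged over a cost range.
#
# The cost of a binary graph is the fraction of retained edges out of all
# k(k-1)/2 possible node pairs. Thresholding keeps the largest weights
# (signed, most-positive first), so any strictly increasing transform of the
# weights - including the Fisher z - yields the same graph.

new_binary_graph <- function(adjacency, cost) {
  structure(list(adjacency = adjacency, cost = cost), class = "basc_graph")
}

graph_adjacency <- function(g) {
  if (inherits(g, "basc_graph")) g$adjacency else as.matrix(g)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(graph_adjacency(g), mode = "undirected",
                                      diag = FALSE)
}

#' Threshold a weight matrix at a fixed cost
#'
#' Keeps the `floor(cost * k(k-1)/2)` largest off-diagonal weights (signed
#' value, descending; ties broken by lexicographic (i, j) order) and returns
#' the binary adjacency.
#'
#' @param W Symmetric numeric matrix with finite off-diagonal entries.
#' @param cost Fraction of edges to retain, in (0, 1].
#' @return A `basc_graph` (0/1 adjacency with zero diagonal, plus the cost).
#' @export
threshold_by_cost <- function(W, cost) {
  W <- as.matrix(W)
  k <- nrow(W)
  if (cost <= 0 || cost > 1) abort("`cost` must lie in (0, 1].")
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  if (any(!is.finite(w))) abort("Off-diagonal weights must be finite.")
  m <- floor(cost * k * (k - 1) / 2)
  if (m < 1) abort(sprintf("cost %.4g yields zero edges for k = %d.", cost, k))
  ord <- order(-w, ut[, 1], ut[, 2])
  sel <- ord[seq_len(m)]
  A <- matrix(0L, k, k)
  A[ut[sel, , drop = FALSE]] <- 1L
  A <- A + t(A)
  dimnames(A) <- dimnames(W)
  new_binary_graph(A, cost)
}

#' Node degree of a binary graph
#'
#' @param g A `basc_graph` or 0/1 adjacency matrix.
#' @return Integer vector of per-node edge counts.
#' @export
node_degree <- function(g) {
  as.integer(rowSums(graph_adjacency(g)))
}

#' Betweenness centrality
#'
#' Unnormalised shortest-path betweenness with fractional credit when
#' several shortest paths tie (Brandes), endpoints excluded.
#'
#' @param g A `basc_graph` or adjacency matrix.
#' @return Numeric vector of per-node betweenness values.
#' @export
node_betweenness <- function(g) {
  as.numeric(igraph::betweenness(as_igraph(g), directed = FALSE,
                                 normalized = FALSE))
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over unordered node pairs;
#' disconnected pairs contribute zero.
#'
#' @param g A `basc_graph` or adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  A <- graph_adjacency(g)
  k <- nrow(A)
  if (k < 2) return(0)
  D <- igraph::distances(as_igraph(g))
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (zero for nodes of degree < 2).
#'
#' @param g A `basc_graph` or adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  A <- graph_adjacency(g)
  k <- nrow(A)
  vals <- vapply(seq_len(k), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# characteristic path length over reachable pairs of the largest component
char_path_length <- function(ig) {
  D <- igraph::distances(ig)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) return(0)
  mean(d)
}

mean_clustering <- function(ig) {
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0  # degree-1 nodes
  mean(cc)
}

# Degree-preserving latticization: double-edge swaps accepted only when they
# reduce the total ring distance of the edge set, pulling edges toward a
# ring-lattice ordering.
latticize <- function(A, n_attempts) {
  k <- nrow(A)
  ring_dist <- function(i, j) {
    d <- abs(i - j)
    pmin(d, k - d)
  }
  for (t in seq_len(n_attempts)) {
    e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    if (nrow(e) < 2) break
    pick <- sample.int(nrow(e), 2)
    a <- e[pick[1], 1]; b <- e[pick[1], 2]
    c_ <- e[pick[2], 1]; d_ <- e[pick[2], 2]
    if (length(unique(c(a, b, c_, d_))) < 4) next
    # two possible rewirings; evaluate both, take the better admissible one
    cands <- list(rbind(c(a, d_), c(c_, b)), rbind(c(a, c_), c(b, d_)))
    old_cost <- ring_dist(a, b) + ring_dist(c_, d_)
    best <- NULL; best_cost <- old_cost
    for (cand in cands) {
      if (A[cand[1, 1], cand[1, 2]] == 1 || A[cand[2, 1], cand[2, 2]] == 1) next
      new_cost <- ring_dist(cand[1, 1], cand[1, 2]) +
        ring_dist(cand[2, 1], cand[2, 2])
      if (new_cost < best_cost) {
        best <- cand; best_cost <- new_cost
      }
    }
    if (is.null(best)) next
    A[a, b] <- A[b, a] <- 0L
    A[c_, d_] <- A[d_, c_] <- 0L
    A[best[1, 1], best[1, 2]] <- A[best[1, 2], best[1, 1]] <- 1L
    A[best[2, 1], best[2, 2]] <- A[best[2, 2], best[2, 1]] <- 1L
  }
  A
}

#' Small-world omega
#'
#' `omega = L_rand / L - C / C_latt`, where `L` is the characteristic path
#' length and `C` the mean clustering coefficient of the graph, `L_rand`
#' averages over degree-preserving randomised surrogates, and `C_latt`
#' averages over latticized surrogates (degree-preserving rewiring toward a
#' ring-lattice ordering). Values near 0 indicate small-world topology;
#' lattices give negative and random graphs positive omega.
#'
#' @param g A `basc_graph` or adjacency matrix. Disconnected graphs are
#'   reduced to their largest component with a warning.
#' @param n_surrogates Surrogates per family (default 10).
#' @param seed Optional integer seed.
#' @param rewire_per_edge Rewiring attempts per edge (default 10).
#' @return Scalar omega.
#' @export
small_world_omega <- function(g, n_surrogates = 10, seed = NULL,
                              rewire_per_edge = 10) {
  if (!is.null(seed)) set.seed(seed)
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) {
    warn("Graph is disconnected; omega computed on the largest component.")
    comp <- igraph::components(ig)
    ig <- igraph::induced_subgraph(ig, which(comp$membership ==
                                               which.max(comp$csize)))
  }
  A <- as.matrix(igraph::as_adjacency_matrix(ig))
  n_edges <- sum(A) / 2
  L <- char_path_length(ig)
  C <- mean_clustering(ig)
  n_attempts <- max(1, round(rewire_per_edge * n_edges))
  L_rand <- mean(vapply(seq_len(n_surrogates), function(s) {
    rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = n_attempts))
    char_path_length(rg)
  }, numeric(1)))
  C_latt <- mean(vapply(seq_len(n_surrogates), function(s) {
    Al <- latticize(A, n_attempts)
    mean_clustering(igraph::graph_from_adjacency_matrix(Al, "undirected"))
  }, numeric(1)))
  c_ratio <- if (C_latt > 0) C / C_latt else if (C == 0) 1 else NA_real_
  l_ratio <- if (L > 0) L_rand / L else 1
  l_ratio - c_ratio
}

#' Efficiency and omega as a function of cost
#'
#' Thresholds `W` at every cost of `costs`, computes global efficiency and
#' cost efficiency (`E_glob - cost`), records the argmax of cost efficiency,
#' and optionally evaluates omega on a sub-grid of costs.
#'
#' @param W Symmetric weight matrix.
#' @param costs Cost grid (default 0.005 to 0.5 in 0.005 steps). Costs that
#'   would retain zero edges are dropped.
#' @param omega_costs Optional subset of `costs` at which to compute
#'   [small_world_omega()] (omega is `NA` elsewhere).
#' @param n_surrogates,seed Passed to [small_world_omega()].
#' @return A tibble of class `basc_cost_curve` with columns `cost`,
#'   `n_edges`, `global_efficiency`, `cost_efficiency`, `omega`, and
#'   attribute `argmax_cost`.
#' @export
cost_scan <- function(W, costs = seq(0.005, 0.5, by = 0.005),
                      omega_costs = NULL, n_surrogates = 10, seed = NULL) {
  if (is.unsorted(costs, strictly = TRUE)) abort("`costs` must be strictly increasing.")
  k <- nrow(as.matrix(W))
  m <- floor(costs * k * (k - 1) / 2)
  costs <- costs[m >= 1]
  rows <- lapply(costs, function(co) {
    g <- threshold_by_cost(W, co)
    eg <- global_efficiency(g)
    om <- if (!is.null(omega_costs) && any(abs(omega_costs - co) < 1e-9)) {
      small_world_omega(g, n_surrogates = n_surrogates,
                        seed = if (is.null(seed)) NULL else
                          stage_seed(seed, sprintf("omega_%g", co)))
    } else NA_real_
    tibble(cost = co, n_edges = sum(graph_adjacency(g)) / 2,
           global_efficiency = eg, cost_efficiency = eg - co, omega = om)
  })
  out <- bind_rows(rows)
  attr(out, "argmax_cost") <- out$cost[which.max(out$cost_efficiency)]
  class(out) <- c("basc_cost_curve", class(out))
  out
}

#' Degree and betweenness averaged over a cost range
#'
#' Thresholds `W` at each cost of the range (default 18-24% in 0.5% steps,
#' 13 graphs), computes per-node degree and betweenness at each cost, and
#' averages across costs.
#'
#' @param W Symmetric weight matrix.
#' @param costs Cost range (default `seq(0.18, 0.24, by = 0.005)`).
#' @return Tibble with columns `cluster`, `degree_avg`, `betweenness_avg`
#'   and attribute `cost_range`.
#' @export
node_metrics_over_range <- function(W, costs = seq(0.18, 0.24, by = 0.005)) {
  k <- nrow(as.matrix(W))
  deg <- matrix(0, length(costs), k)
  btw <- matrix(0, length(costs), k)
  for (i in seq_along(costs)) {
    g <- threshold_by_cost(W, costs[i])
    deg[i, ] <- node_degree(g)
    btw[i, ] <- node_betweenness(g)
  }
  out <- tibble(cluster = seq_len(k),
                degree_avg = colMeans(deg),
                betweenness_avg = colMeans(btw))
  attr(out, "cost_range") <- range(costs)
  out
}
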