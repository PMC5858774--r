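#' Topology statistics of the state graph
#'
#' Summary statistics that the controllability experiments relate to the
#' minimum control density: the average degree, the degree heterogeneity H
#' (standard deviation of the degree sequence) and the clustering
#' coefficient C of the undirected projection.
#'
#' @name netstats
NULL

state_degrees <- function(net, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  pattern <- net$A != 0
  kin <- rowSums(pattern)
  kout <- colSums(pattern)
  switch(mode, total = kin + kout, "in" = kin, out = kout)
}

#' Degree heterogeneity
#'
#' \deqn{H = \sqrt{\tfrac{1}{N} \sum_i (k_i - \langle k\rangle)^2}}
#' over the state nodes; `H = 0` for any regular graph.  Self-loops count
#' once towards in- and once towards out-degree.
#'
#' @param net a [control_network()].
#' @param mode degree flavour: `"total"` (in + out, the default), `"in"`
#'   or `"out"`.
#' @return Non-negative number in units of degree.
#' @export
degree_heterogeneity <- function(net, mode = c("total", "in", "out")) {
  k <- state_degrees(net, mode)
  sqrt(mean((k - mean(k))^2))
}

#' Clustering coefficient
#'
#' Mean over state nodes of \eqn{E_i / \binom{k_i}{2}}, where \eqn{E_i}
#' counts the edges among node i's neighbours; computed on the undirected
#' simple projection of the state graph (weights and self-loops ignored).
#' Nodes with fewer than two neighbours contribute zero.
#'
#' @param net a [control_network()].
#' @return Number in [0, 1]; 1 for a complete graph, 0 for any tree.
#' @export
clustering_coefficient <- function(net) {
  pattern <- (net$A != 0) | t(net$A != 0)
  diag(pattern) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(pattern, mode = "undirected")
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  local[is.na(local)] <- 0    # degree-1 nodes
  mean(local)
}

#' Topology summary
#'
#' Bundles average degree (`2L/N` with L the state-arc count), degree
#' heterogeneity and clustering coefficient, optionally with a maximum
#' likelihood power-law tail exponent of the total-degree sequence.
#'
#' @param net a [control_network()].
#' @param tail_fit fit a power-law tail exponent (`gamma_hat`) to the
#'   degree sequence via [igraph::fit_power_law()]?
#' @return List with `k_avg`, `H`, `C` and `gamma_hat` (`NA` unless
#'   requested).
#' @export
summarize_topology <- function(net, tail_fit = FALSE) {
  L <- sum(net$A != 0)
  k <- state_degrees(net, "total")
  gamma_hat <- NA_real_
  if (tail_fit && any(k > 0)) {
    fit <- igraph::fit_power_law(k[k > 0], implementation = "plfit")
    gamma_hat <- fit$alpha
  }
  list(k_avg = 2 * L / net$N,
       H = degree_heterogeneity(net),
       C = clustering_coefficient(net),
       gamma_hat = gamma_hat)
}
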