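#' Minimum-driver baselines
#'
#' Three independent ways of counting the minimum number of driver/control
#' nodes, used to validate the optimiser: structural maximum matching
#' (`mm_driver_count`), the maximum geometric multiplicity of the
#' eigenvalues (`mmt_driver_count`), and exhaustive enumeration over the
#' candidate controls (`brute_force_min_controls`).
#'
#' @name baselines
NULL

driver_result <- function(n_d, N, driver_nodes = NULL) {
  structure(list(n_d = as.integer(n_d), density = n_d / N,
                 driver_nodes = driver_nodes),
            class = "driver_result")
}

#' @export
print.driver_result <- function(x, ...) {
  cat(sprintf("driver_result: n_d = %d (density %.4f)\n", x$n_d, x$density))
  invisible(x)
}

#' Structural (maximum matching) driver count
#'
#' Builds the bipartite out-copy/in-copy graph of the state graph (one
#' matching edge per nonzero entry of `A`, self-loops included) and counts
#' `max(N - |maximum matching|, 1)` drivers; the unmatched in-copies are
#' the driver nodes.  Weights are ignored.  The floor of one driver for a
#' perfectly matched network follows the structural-controllability
#' convention that at least one external signal is always required.
#'
#' @param net a [control_network()] (only the pattern of `net$A` is used).
#' @return A `driver_result` with fields `n_d`, `density` and
#'   `driver_nodes` (empty when the matching is perfect).
#' @export
mm_driver_count <- function(net) {
  N <- net$N
  idx <- which(net$A != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(driver_result(N, N, seq_len(N)))
  ## out-copy of source j -> in-copy of target i
  edges <- rbind(idx[, 2L], N + idx[, 1L])
  g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), each = N),
                                    edges = as.vector(edges))
  mt <- igraph::max_bipartite_match(g)
  unmatched <- which(is.na(mt$matching[N + seq_len(N)]))
  driver_result(max(N - mt$matching_size, 1L), N, unmatched)
}

#' Maximum-multiplicity driver count
#'
#' The exact-controllability count for an unconstrained input matrix:
#' \eqn{n_d = \max_\lambda (N - rank(\lambda I - A))} over the candidate
#' eigenvalues (an explicit zero candidate is included when `A` is rank
#' deficient), floored at 1.
#'
#' @param A square numeric state matrix.
#' @param tol_group eigenvalue merging tolerance.
#' @param tol_rank rank threshold (see [pbh_deficiency()]).
#' @return A `driver_result` (no driver placement).
#' @export
mmt_driver_count <- function(A, tol_group = 1e-8, tol_rank = NULL) {
  A <- as.matrix(A)
  N <- nrow(A)
  lam <- pbh_candidates(A, tol_group, tol_rank)
  mults <- vapply(lam, function(l)
    N - num_rank(diag(as.complex(l), N) - A, tol_rank), 0)
  driver_result(max(max(mults), 1L), N)
}

#' Exhaustive minimum control count
#'
#' Enumerates candidate-control subsets in increasing cardinality and
#' returns the first cardinality at which some subset makes the network
#' fully controllable.  Intended as an oracle for small P.
#'
#' @param net a [control_network()].
#' @param max_P refuse networks with more candidate controls than this
#'   (default 15; the enumeration is exponential in P).
#' @param evaluator optional prebuilt [pbh_evaluator()] for `net`.
#' @return A `driver_result`; `driver_nodes` holds one optimal selection,
#'   and attributes `optima` (up to 64 optimal selections) and `n_optima`
#'   record the ties at the minimum cardinality.
#' @export
brute_force_min_controls <- function(net, max_P = 15L, evaluator = NULL) {
  if (net$P > max_P)
    stop("P = ", net$P, " exceeds max_P = ", max_P,
         "; exhaustive enumeration is exponential in P")
  if (is.null(evaluator)) evaluator <- pbh_evaluator(net)
  P <- net$P
  for (r in 0:P) {
    subsets <- utils::combn(P, r, simplify = FALSE)
    feas <- vapply(subsets, function(s) {
      bits <- integer(P); bits[s] <- 1L
      evaluator$penalty(bits) == 0
    }, TRUE)
    if (any(feas)) {
      opt <- subsets[feas]
      res <- driver_result(r, net$N, opt[[1L]])
      attr(res, "optima") <- utils::head(opt, 64L)
      attr(res, "n_optima") <- sum(feas)
      return(res)
    }
  }
  stop("no feasible scheme exists: even the all-ones selection fails the ",
       "PBH condition")
}
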