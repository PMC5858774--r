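#' Synthetic network ensembles
#'
#' Generators for the benchmark ensembles: uniform random digraphs
#' ([gen_er()]), static-model scale-free digraphs ([gen_sf()]),
#' Newman-Watts-type small-world digraphs ([gen_sw()]), random regular
#' digraphs ([gen_regular()]) and complete digraphs ([gen_complete()]).
#' All state-to-state arc weights are drawn i.i.d. uniform(0, 1); the
#' generators never create self-loops or duplicate arcs.  Candidate
#' control nodes are wired by [attach_controls()].
#'
#' The arc count is `L = round(N * k_avg)` under the default
#' `degree_convention = "out"` (so `k_avg` is the mean out-degree, equal to
#' the mean in-degree) and `L = round(N * k_avg / 2)` under `"total"` (so
#' `k_avg` is the mean total degree `2L/N`).
#'
#' @name generators
NULL

arc_count <- function(N, k_avg, degree_convention = c("out", "total")) {
  degree_convention <- match.arg(degree_convention)
  L <- if (degree_convention == "out") round(N * k_avg) else
    round(N * k_avg / 2)
  if (L > N * (N - 1L))
    stop("requested ", L, " arcs but only ", N * (N - 1L),
         " distinct non-self arcs exist")
  as.integer(L)
}

## decode arc ids 1..N(N-1) into (source, target) pairs, skipping the
## diagonal, so uniform sampling without replacement is exact
decode_arcs <- function(idx, N) {
  s <- (idx - 1L) %/% (N - 1L) + 1L
  o <- (idx - 1L) %% (N - 1L) + 1L
  t <- o + (o >= s)
  cbind(s, t)
}

## rejection sampler for distinct non-self arcs with endpoint weights
sample_arcs_weighted <- function(N, L, prob_src, prob_tgt,
                                 exclude = NULL, max_tries = 200L) {
  have <- if (is.null(exclude)) integer(0) else
    (exclude[, 1L] - 1L) * N + exclude[, 2L]
  arcs <- integer(0)
  for (try in seq_len(max_tries)) {
    need <- L - length(arcs)
    if (need <= 0L) break
    n_draw <- max(2L * need, 64L)
    s <- sample.int(N, n_draw, replace = TRUE, prob = prob_src)
    t <- sample.int(N, n_draw, replace = TRUE, prob = prob_tgt)
    key <- (s - 1L) * N + t
    ok <- s != t & !duplicated(key) & !(key %in% c(have, arcs))
    arcs <- c(arcs, utils::head(key[ok], need))
  }
  if (length(arcs) < L)
    stop("arc sampling failed to reach ", L, " distinct arcs after ",
         max_tries, " rounds (duplicate saturation)")
  cbind((arcs - 1L) %/% N + 1L, (arcs - 1L) %% N + 1L)
}

arcs_to_network <- function(arcs, N, P, control_attachment, seed_weights) {
  A <- matrix(0, N, N)
  if (nrow(arcs))
    A[cbind(arcs[, 2L], arcs[, 1L])] <- stats::runif(nrow(arcs))
  net <- control_network(A)
  if (P >= 1L) net <- attach_controls(net, P, control_attachment)
  net
}

#' @rdname generators
#' @param N number of state nodes.
#' @param P number of candidate control nodes (default `N`; 0 for none).
#' @param k_avg target average degree (see Details on the convention).
#' @param degree_convention `"out"` (default): `k_avg` is the mean
#'   out-degree, L = N k; `"total"`: `k_avg` is the mean total degree,
#'   L = N k / 2.
#' @param control_attachment control wiring rule, see [attach_controls()];
#'   the default `"auto"` uses a random bijection when P = N.
#' @param seed optional integer seed; the same seed and configuration
#'   reproduce the network bit for bit.
#' @export
gen_er <- function(N, P = N, k_avg,
                   degree_convention = c("out", "total"),
                   control_attachment = c("auto", "permutation", "uniform", "identity"),
                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- arc_count(N, k_avg, degree_convention)
  arcs <- if (L > 0L) decode_arcs(sample.int(N * (N - 1L), L), N) else
    matrix(0L, 0L, 2L)
  arcs_to_network(arcs, N, P, match.arg(control_attachment))
}

#' @rdname generators
#' @param gamma power-law degree exponent (> 2).  Endpoints of every arc
#'   are drawn with probability proportional to `i^(-xi)` over node ranks,
#'   `xi = 1/(gamma - 1)`, on both the source and the target side.
#' @export
gen_sf <- function(N, P = N, k_avg, gamma,
                   degree_convention = c("out", "total"),
                   control_attachment = c("auto", "permutation", "uniform", "identity"),
                   seed = NULL) {
  if (gamma <= 2) stop("'gamma' must exceed 2")
  if (!is.null(seed)) set.seed(seed)
  L <- arc_count(N, k_avg, degree_convention)
  xi <- 1 / (gamma - 1)
  w <- seq_len(N)^(-xi)
  arcs <- if (L > 0L) sample_arcs_weighted(N, L, w, w) else
    matrix(0L, 0L, 2L)
  arcs_to_network(arcs, N, P, match.arg(control_attachment))
}

#' @rdname generators
#' @param sw_base ring-lattice neighbour count: each node is joined to its
#'   `sw_base` nearest clockwise neighbours.  Default
#'   `max(1, floor(k_avg / 2))`.
#' @param ring_orientation `"random"` (default): each lattice edge becomes
#'   one arc with a fair-coin direction; `"clockwise"`: all lattice arcs
#'   point clockwise (this variant admits a perfect matching, so the
#'   network is controllable from a single node).
#' @details
#' The small-world generator lays down the ring lattice first and then adds
#' uniformly random shortcut arcs until the arc total reaches `L`, the
#' Newman-Watts "added shortcuts" construction.
#' @export
gen_sw <- function(N, P = N, k_avg,
                   degree_convention = c("out", "total"),
                   sw_base = max(1L, floor(k_avg / 2)),
                   ring_orientation = c("random", "clockwise"),
                   control_attachment = c("auto", "permutation", "uniform", "identity"),
                   seed = NULL) {
  ring_orientation <- match.arg(ring_orientation)
  if (!is.null(seed)) set.seed(seed)
  L <- arc_count(N, k_avg, degree_convention)
  if (sw_base >= N / 2) stop("'sw_base' too large for N")
  if (N * sw_base > L)
    stop("ring lattice alone (", N * sw_base, " arcs) exceeds the target ",
         "arc count ", L, "; lower 'sw_base'")
  arcs <- NULL
  for (d in seq_len(sw_base)) {
    i <- seq_len(N)
    j <- ((i - 1L + d) %% N) + 1L
    if (ring_orientation == "random") {
      flip <- stats::runif(N) < 0.5
      arcs <- rbind(arcs, cbind(ifelse(flip, i, j), ifelse(flip, j, i)))
    } else {
      arcs <- rbind(arcs, cbind(i, j))
    }
  }
  if (L > nrow(arcs)) {
    extra <- sample_arcs_weighted(N, L - nrow(arcs), NULL, NULL,
                                  exclude = arcs)
    arcs <- rbind(arcs, extra)
  }
  arcs_to_network(arcs, N, P, match.arg(control_attachment))
}

#' @rdname generators
#' @param k degree of the regular digraph: every node gets in-degree and
#'   out-degree `k/2` (`k` must be even), via superposed random
#'   single-cycle permutations.
#' @export
gen_regular <- function(N, k, P = N,
                        control_attachment = c("auto", "permutation", "uniform", "identity"),
                        seed = NULL) {
  if (k %% 2 != 0) stop("'k' must be even (in-degree = out-degree = k/2)")
  d <- k %/% 2
  if (d >= N) stop("degree too large for N")
  if (!is.null(seed)) set.seed(seed)
  arcs <- matrix(0L, 0L, 2L)
  key <- integer(0)
  for (round in seq_len(d)) {
    for (try in 1:200) {
      perm <- sample.int(N)                 # one random N-cycle
      s <- perm
      t <- perm[c(2:N, 1L)]
      k2 <- (s - 1L) * N + t
      if (!any(k2 %in% key)) { arcs <- rbind(arcs, cbind(s, t));
        key <- c(key, k2); break }
      if (try == 200L) stop("failed to superpose disjoint cycles")
    }
  }
  arcs_to_network(arcs, N, P, match.arg(control_attachment))
}

#' @rdname generators
#' @export
gen_complete <- function(N, P = N,
                         control_attachment = c("auto", "permutation", "uniform", "identity"),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- which(!diag(N) == 1)
  A <- matrix(0, N, N)
  A[idx] <- stats::runif(length(idx))
  net <- control_network(A)
  if (P >= 1L) net <- attach_controls(net, P, match.arg(control_attachment))
  net
}

#' Attach candidate control nodes
#'
#' Gives every state node exactly one incoming candidate-control link, with
#' i.i.d. uniform(0, 1) link weights, so B has exactly N nonzeros, one per
#' row.  Under `"permutation"` (the default when P = N) the assignment is a
#' uniformly random bijection, which makes B invertible and guarantees that
#' the fully wired network is controllable -- the precondition of the
#' optimiser's feasibility argument at initialisation.  Under `"uniform"`
#' every state draws its control independently, so two states may share a
#' control; a shared control cannot separate two states that are otherwise
#' indistinguishable (e.g. two zero-in-degree states), and the all-selected
#' scheme can then be infeasible.  `"identity"` wires state i to control i
#' (diagonal B).  `"auto"` resolves to `"permutation"` when P = N and
#' `"uniform"` otherwise.
#'
#' @param net a [control_network()] (any existing B is replaced).
#' @param P number of candidate control nodes.
#' @param attachment `"auto"`, `"permutation"`, `"uniform"` or
#'   `"identity"`.
#' @param seed optional integer seed.
#' @return A [control_network()] with the new input matrix.
#' @export
attach_controls <- function(net, P,
                            attachment = c("auto", "permutation",
                                           "uniform", "identity"),
                            seed = NULL) {
  attachment <- match.arg(attachment)
  if (!is.null(seed)) set.seed(seed)
  N <- net$N
  if (P < 1L) stop("'P' must be at least 1")
  if (attachment == "auto")
    attachment <- if (P == N) "permutation" else "uniform"
  owner <- switch(attachment,
    identity = {
      if (P != N) stop("identity attachment requires P = N")
      seq_len(N)
    },
    permutation = {
      if (P != N) stop("permutation attachment requires P = N")
      sample.int(N)
    },
    uniform = sample.int(P, N, replace = TRUE))
  B <- matrix(0, N, P)
  B[cbind(seq_len(N), owner)] <- stats::runif(N)
  control_network(net$A, B, net$labels)
}
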