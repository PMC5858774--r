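#' Parameters of the quantum-inspired control-node optimiser
#'
#' The optimiser evolves `m` qubit chromosomes, each carrying two amplitude
#' chains of length P, so the population holds `2m` candidate control
#' schemes per generation.
#'
#' @param m chromosome count; the population size is `2m` individuals.
#'   Default 15 (population 30).
#' @param maxgen iteration cap, default 100.
#' @param p_c0 initial crossover probability, default 0.06.
#' @param schedule a [penalty_schedule()].
#' @param patience generations of identical best fitness that trigger the
#'   population catastrophe, default 10.  Shorter patience resets the
#'   amplitude asymmetry that drives late-stage pruning and measurably
#'   worsens the found minima.
#' @param angle_small rotation magnitude base used when the candidate is
#'   fitter than the incumbent, default `0.01 * pi` (radians).
#' @param angle_large rotation magnitude base used otherwise, default
#'   `0.03 * pi`.
#' @param amplitude_floor lower bound on the magnitude of each amplitude
#'   after rotation (default 0.1, i.e. every gene keeps at least a 1%
#'   chance of observing either bit).  Bounding the amplitudes away from
#'   the poles is the standard quantum-evolutionary guard against
#'   premature convergence: without it a saturated gene can never be
#'   flipped again and late-stage pruning stalls.  Set 0 to disable.
#' @param workers width of parallel fitness evaluation (forked via the
#'   parallel package when > 1).  Fitness evaluations are pure functions of
#'   the bit pattern and the reduction order is fixed by individual index,
#'   so results are identical for any value.
#' @param seed optional integer seed for the optimiser's random stream.
#' @return Object of class `paqga_params`.
#' @export
paqga_params <- function(m = 15L, maxgen = 100L, p_c0 = 0.06,
                         schedule = penalty_schedule(), patience = 10L,
                         angle_small = 0.01 * pi, angle_large = 0.03 * pi,
                         amplitude_floor = 0.1, workers = 1L, seed = NULL) {
  stopifnot(m >= 1L, maxgen >= 1L, p_c0 > 0, p_c0 <= 1, patience >= 2L,
            angle_small < angle_large, angle_small > 0, workers >= 1L,
            amplitude_floor >= 0, amplitude_floor < 1 / sqrt(2))
  structure(list(m = as.integer(m), maxgen = as.integer(maxgen),
                 p_c0 = p_c0, schedule = schedule,
                 patience = as.integer(patience),
                 angle_small = angle_small, angle_large = angle_large,
                 amplitude_floor = amplitude_floor,
                 workers = as.integer(workers), seed = seed),
            class = "paqga_params")
}

#' Observe a qubit gene chain
#'
#' Collapses each amplitude pair to a bit: gene k yields 1 with probability
#' \eqn{\beta_k^2} (the squared amplitude of the \eqn{|1\rangle} state).
#'
#' @param alpha,beta amplitude vectors with `alpha^2 + beta^2 = 1` per gene.
#' @param u optional uniform draws (one per gene), mainly for testing.
#' @return Integer 0/1 vector.
#' @export
observe_chain <- function(alpha, beta, u = stats::runif(length(beta))) {
  as.integer(u < beta^2)
}

#' Adaptive crossover probability
#'
#' \deqn{p_c(i) = \frac{m}{Q} p_{c0} \exp\!\big(-\tfrac{f_{max} - f(G_i)}
#'   {f_{max} - f_{min}}\big)}
#' with the exponential dropped when `f_max == f_min`.  `Q` counts the
#' current individuals strictly fitter (smaller fitness) than the
#' historical best and is clamped to at least 1.  Worse individuals (near
#' `f_max`) cross over more strongly towards the incumbent.  The result is
#' truncated to 1.
#'
#' @param f_i fitness of the individual(s); vectorised.
#' @param f_max,f_min worst and best fitness in the current population.
#' @param n_better count of current individuals strictly fitter than the
#'   historical best.
#' @param m chromosome count.
#' @param p_c0 initial crossover probability.
#' @return Crossover probability in (0, 1].
#' @export
crossover_probability <- function(f_i, f_max, f_min, n_better, m, p_c0) {
  q <- max(1L, n_better)
  base <- (m / q) * p_c0
  p <- if (f_max > f_min) base * exp(-(f_max - f_i) / (f_max - f_min))
       else rep(base, length(f_i))
  pmin(p, 1)
}

#' Crossover with the incumbent scheme
#'
#' Each gene is replaced by the incumbent's bit with probability `p_c`,
#' otherwise kept.
#'
#' @param bits observed binary individual.
#' @param d_best incumbent bit vector (diagonal of the best scheme).
#' @param p_c per-individual crossover probability.
#' @param u optional uniform draws (one per gene), mainly for testing.
#' @return Integer 0/1 vector.
#' @export
crossover_bits <- function(bits, d_best, p_c,
                           u = stats::runif(length(bits))) {
  out <- as.integer(bits)
  take <- u < p_c
  out[take] <- as.integer(d_best)[take]
  out
}

## Rotation sign lookup.  Rows of the rule table, indexed by
## (bit_c, bit_best, fitter = f_c < f_best); columns by the amplitude
## configuration.  "2" encodes a fair-coin +/-1.
## Under P(bit 1) = beta^2 a positive angle moves probability towards 1.
rotation_sign <- function(bit_c, bit_best, fitter, alpha, beta,
                          u = stats::runif(length(alpha)), zero_tol = 1e-9) {
  n <- length(alpha)
  s <- numeric(n)
  ab <- alpha * beta
  pos <- ab > zero_tol
  neg <- ab < -zero_tol
  a0 <- abs(alpha) <= zero_tol
  b0 <- abs(beta) <= zero_tol & !a0
  diff <- bit_c != bit_best
  coin <- ifelse(u < 0.5, 1, -1)
  ## candidate 0, incumbent 1
  i <- diff & bit_c == 0L & !fitter
  s[i & pos] <- 1;  s[i & neg] <- -1; s[i & a0] <- 0; s[i & b0] <- coin[i & b0]
  i <- diff & bit_c == 0L & fitter
  s[i & pos] <- -1; s[i & neg] <- 1;  s[i & a0] <- coin[i & a0]; s[i & b0] <- 0
  ## candidate 1, incumbent 0
  i <- diff & bit_c == 1L & !fitter
  s[i & pos] <- -1; s[i & neg] <- 1;  s[i & a0] <- coin[i & a0]; s[i & b0] <- 0
  i <- diff & bit_c == 1L & fitter
  s[i & pos] <- 1;  s[i & neg] <- -1; s[i & a0] <- 0; s[i & b0] <- coin[i & b0]
  s
}

#' Adaptive Q-gate rotation angle
#'
#' Implements the adaptive lookup rules: no rotation where the candidate
#' bit equals the incumbent bit; otherwise the magnitude is
#' \eqn{(f_c / f_{best}) \cdot 0.03\pi} when the candidate is no fitter
#' than the incumbent and \eqn{(f_c / f_{best}) \cdot 0.01\pi} when it is
#' fitter, and the sign steers the amplitude pair towards the fitter of the
#' two bits (ambiguous cells at `alpha = 0` or `beta = 0` are resolved by a
#' fair coin).  The magnitude is capped at \eqn{\pi/2} so that
#' penalty-inflated fitness ratios cannot wrap an amplitude past the pole.
#'
#' @param bit_c,bit_best candidate and incumbent bits (vectorised over
#'   genes).
#' @param f_c,f_best candidate and incumbent fitness (scalars).
#' @param alpha,beta current amplitudes.
#' @param angle_small,angle_large magnitude bases (radians).
#' @param u optional uniform draws for the coin cells.
#' @return Signed rotation angles, one per gene.
#' @export
rotation_angle <- function(bit_c, bit_best, f_c, f_best, alpha, beta,
                           angle_small = 0.01 * pi,
                           angle_large = 0.03 * pi,
                           u = stats::runif(length(alpha))) {
  stopifnot(f_best > 0)
  fitter <- f_c < f_best
  delta <- ifelse(bit_c == bit_best, 0,
                  (f_c / f_best) * if (fitter) angle_small else angle_large)
  delta <- pmin(delta, pi / 2)
  delta * rotation_sign(as.integer(bit_c), as.integer(bit_best), fitter,
                        alpha, beta, u)
}

#' Q-gate rotation of an amplitude pair
#'
#' \eqn{(\alpha', \beta') = (\cos\theta\,\alpha - \sin\theta\,\beta,\;
#' \sin\theta\,\alpha + \cos\theta\,\beta)}; the norm is preserved.
#' A nonzero `floor` then pushes any amplitude whose magnitude fell below
#' it back to the floor (rescaling its partner), so no gene ever becomes
#' impossible to flip.
#'
#' @param alpha,beta amplitude vectors.
#' @param theta rotation angles (radians), one per gene.
#' @param floor amplitude magnitude lower bound (0 disables).
#' @return List with rotated `alpha` and `beta`.
#' @export
qgate_rotate <- function(alpha, beta, theta, floor = 0) {
  ct <- cos(theta); st <- sin(theta)
  a <- ct * alpha - st * beta
  b <- st * alpha + ct * beta
  if (floor > 0) {
    hi <- sqrt(1 - floor^2)
    sg <- function(x) ifelse(x < 0, -1, 1)
    low_b <- abs(b) < floor
    b[low_b] <- floor * sg(b[low_b]); a[low_b] <- hi * sg(a[low_b])
    low_a <- abs(a) < floor
    a[low_a] <- floor * sg(a[low_a]); b[low_a] <- hi * sg(b[low_a])
  }
  list(alpha = a, beta = b)
}

## population container: four m x P amplitude matrices (two chains)
init_population <- function(m, P) {
  h <- matrix(1 / sqrt(2), m, P)
  list(a1 = h, b1 = h, a2 = h, b2 = h)
}

## amplitudes that re-observe a bit pattern deterministically:
## bit 1 -> (alpha, beta) = (0, 1); bit 0 -> (1, 0)
elite_amplitudes <- function(bits) {
  list(alpha = as.numeric(bits == 0L), beta = as.numeric(bits == 1L))
}

#' Population catastrophe
#'
#' Restart operator applied after stagnation: the incumbent's bit pattern
#' is written into the first chromosome (both chains, with saturated
#' amplitudes so re-observation reproduces it deterministically) and every
#' other chromosome is reset to the uniform 1/sqrt(2) superposition.
#'
#' @param pop population as returned by the optimiser internals (four
#'   `m x P` amplitude matrices `a1`, `b1`, `a2`, `b2`).
#' @param elite_bits incumbent bit vector to preserve.
#' @return The rebuilt population.
#' @export
catastrophe <- function(pop, elite_bits) {
  m <- nrow(pop$a1); P <- ncol(pop$a1)
  new <- init_population(m, P)
  el <- elite_amplitudes(as.integer(elite_bits))
  new$a1[1L, ] <- el$alpha; new$b1[1L, ] <- el$beta
  new$a2[1L, ] <- el$alpha; new$b2[1L, ] <- el$beta
  new
}

eval_bits_list <- function(evaluator, bits_list, workers) {
  if (workers > 1L) {
    keys <- vapply(bits_list, paste, "", collapse = "")
    miss <- !duplicated(keys)
    vals <- parallel::mclapply(bits_list[miss], evaluator$fitness,
                               mc.cores = workers)
    ## warm the memo in the parent so later generations reuse the values
    miss_idx <- which(miss)
    for (k in seq_along(miss_idx))
      evaluator$prime(bits_list[[miss_idx[k]]], vals[[k]])
    lookup <- stats::setNames(unlist(vals), keys[miss])
    unname(lookup[keys])
  } else {
    vapply(bits_list, evaluator$fitness, 0)
  }
}

#' Minimum control-node search by quantum-inspired evolution
#'
#' Optimises the binary control scheme of a network under the PBH penalty.
#' Per generation: both gene chains of every chromosome are observed into
#' binary individuals; the adaptive crossover mixes each individual with
#' the incumbent; all individuals are evaluated (cached, optionally in
#' parallel); the incumbent is replaced only by a strictly fitter scheme,
#' which with \eqn{\sigma_1 = 10P} keeps it feasible at every generation
#' after initialisation; the Q-gate rotates both chains towards the fitter
#' bit pattern; and a population catastrophe restarts the amplitudes after
#' `patience` stagnant generations.  The search starts from the all-ones
#' scheme, whose fitness is P when the fully wired network is controllable
#' (otherwise no scheme is feasible and the run aborts with a diagnostic).
#'
#' @param net a [control_network()] with `net$P >= 1`.
#' @param params a [paqga_params()].
#' @param evaluator optional prebuilt [pbh_evaluator()] for `net` (reused
#'   across runs on the same network).
#' @return Object of class `paqga_run`: list with the best
#'   [control_scheme()] (`scheme`), `n_cm`, `N_cm = n_cm / N`, `f_best`,
#'   the per-generation `history` data frame (`generation`, `best_f`,
#'   `mean_f`, `penalty`, `n_c`) and `convergence_generation` (first
#'   generation attaining the final best fitness).
#' @examples
#' net <- gen_complete(8, seed = 1)
#' run <- paqga(net, paqga_params(maxgen = 20, seed = 1))
#' run$n_cm   # a complete weighted digraph needs a single controller
#' @export
paqga <- function(net, params = paqga_params(), evaluator = NULL) {
  stopifnot(inherits(net, "control_network"))
  if (net$P < 1L) stop("network has no candidate control nodes")
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(evaluator))
    evaluator <- pbh_evaluator(net, schedule = params$schedule)
  m <- params$m; P <- net$P; N <- net$N

  d_best <- rep(1L, P)
  f_best <- evaluator$fitness(d_best)
  if (f_best > P + 1e-9)
    stop("the fully wired network (all candidate controls selected) is not ",
         "controllable: no feasible scheme exists under this input matrix ",
         "(initial penalty ", format(f_best - P), ")")

  pop <- init_population(m, P)
  hist_best <- numeric(params$maxgen)
  hist_mean <- numeric(params$maxgen)
  hist_pen <- numeric(params$maxgen)
  hist_nc <- integer(params$maxgen)

  for (gen in seq_len(params$maxgen)) {
    ## observe both chains of every chromosome (2m individuals)
    obs <- vector("list", 2L * m)
    for (i in seq_len(m)) {
      obs[[i]] <- observe_chain(pop$a1[i, ], pop$b1[i, ])
      obs[[m + i]] <- observe_chain(pop$a2[i, ], pop$b2[i, ])
    }
    f_obs <- eval_bits_list(evaluator, obs, params$workers)
    f_max <- max(f_obs); f_min <- min(f_obs)
    n_better <- sum(f_obs < f_best)
    p_c <- crossover_probability(f_obs, f_max, f_min, n_better, m,
                                 params$p_c0)

    cand <- vector("list", 2L * m)
    for (i in seq_along(obs))
      cand[[i]] <- crossover_bits(obs[[i]], d_best, p_c[i])
    f_cand <- eval_bits_list(evaluator, cand, params$workers)

    ## strict improvement only; earliest index wins ties, observed
    ## individuals considered before their crossed versions
    j <- which.min(f_obs)
    if (f_obs[j] < f_best) {
      d_best <- obs[[j]]
      f_best <- f_obs[j]
    }
    j <- which.min(f_cand)
    if (f_cand[j] < f_best) {
      d_best <- cand[[j]]
      f_best <- f_cand[j]
    }

    hist_best[gen] <- f_best
    hist_mean[gen] <- mean(f_cand)
    hist_pen[gen] <- f_best - sum(d_best)   # zero while incumbent feasible
    hist_nc[gen] <- sum(d_best)

    ## Q-gate rotation of both chains against the incumbent
    for (i in seq_len(m)) {
      th <- rotation_angle(cand[[i]], d_best, f_cand[i], f_best,
                           pop$a1[i, ], pop$b1[i, ],
                           params$angle_small, params$angle_large)
      rot <- qgate_rotate(pop$a1[i, ], pop$b1[i, ], th,
                          params$amplitude_floor)
      pop$a1[i, ] <- rot$alpha; pop$b1[i, ] <- rot$beta
      th <- rotation_angle(cand[[m + i]], d_best, f_cand[m + i], f_best,
                           pop$a2[i, ], pop$b2[i, ],
                           params$angle_small, params$angle_large)
      rot <- qgate_rotate(pop$a2[i, ], pop$b2[i, ], th,
                          params$amplitude_floor)
      pop$a2[i, ] <- rot$alpha; pop$b2[i, ] <- rot$beta
    }

    ## stagnation -> catastrophe
    if (gen >= params$patience &&
        length(unique(hist_best[(gen - params$patience + 1L):gen])) == 1L)
      pop <- catastrophe(pop, d_best)
  }

  history <- data.frame(generation = seq_len(params$maxgen),
                        best_f = hist_best, mean_f = hist_mean,
                        penalty = hist_pen, n_c = hist_nc)
  structure(list(scheme = control_scheme(d_best),
                 n_cm = sum(d_best), N_cm = sum(d_best) / N,
                 f_best = f_best, history = history,
                 convergence_generation =
                   which(hist_best == f_best)[1L],
                 params = params),
            class = "paqga_run")
}

#' @export
print.paqga_run <- function(x, ...) {
  cat(sprintf(
    "paqga_run: n_cm = %d (density %.4f), converged at generation %d/%d\n",
    x$n_cm, x$N_cm, x$convergence_generation, nrow(x$history)))
  invisible(x)
}

#' Serialise an optimisation run
#'
#' Writes the run summary to JSON and/or the per-generation history to a
#' tidy CSV (`generation`, `best_f`, `mean_f`, `penalty`, `n_c`).
#'
#' @param run a [paqga()] result.
#' @param json,csv optional output paths.
#' @export
write_run <- function(run, json = NULL, csv = NULL) {
  if (!is.null(json)) {
    obj <- list(n_cm = run$n_cm, N_cm = run$N_cm, f_best = run$f_best,
                convergence_generation = run$convergence_generation,
                selected = which(run$scheme$d == 1L),
                history = run$history)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), json)
  }
  if (!is.null(csv))
    utils::write.csv(run$history, csv, row.names = FALSE)
  invisible(run)
}
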