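#' Scripted experiments
#'
#' Reproducible drivers for the benchmark studies: single-run convergence
#' traces, multi-method benchmark tables and topology sweeps relating the
#' minimum control density to average degree, power-law exponent,
#' heterogeneity and clustering.
#'
#' @name experiments
NULL

generate_network <- function(family, N, P, k_avg, gamma = NA, seed = NULL,
                             ...) {
  switch(family,
         ER = gen_er(N, P, k_avg, seed = seed, ...),
         SF = gen_sf(N, P, k_avg, gamma = gamma, seed = seed, ...),
         SW = gen_sw(N, P, k_avg, seed = seed, ...),
         regular = gen_regular(N, k_avg, P, seed = seed, ...),
         complete = gen_complete(N, P, seed = seed, ...),
         stop("unknown family: ", family))
}

method_n_cm <- function(method, net, params, evaluator = NULL) {
  switch(method,
         paqga = {
           run <- paqga(net, params, evaluator = evaluator)
           c(n_cm = run$n_cm, convergence = run$convergence_generation)
         },
         mm = c(n_cm = mm_driver_count(net)$n_d, convergence = NA),
         mmt = c(n_cm = mmt_driver_count(net$A)$n_d, convergence = NA),
         brute = c(n_cm = brute_force_min_controls(net)$n_d,
                   convergence = NA),
         stop("unknown method: ", method))
}

#' Convergence trace of a single optimisation
#'
#' Runs the optimiser once with full per-generation logging and asserts
#' that the incumbent's penalty is identically zero (the incumbent never
#' leaves the feasible region).
#'
#' @param net a [control_network()].
#' @param params a [paqga_params()].
#' @param csv optional path for the per-generation CSV.
#' @return The [paqga()] run.
#' @export
run_convergence <- function(net, params = paqga_params(), csv = NULL) {
  run <- paqga(net, params)
  if (any(run$history$penalty != 0))
    stop("incumbent left the feasible region; penalty history nonzero")
  if (!is.null(csv)) write_run(run, csv = csv)
  run
}

#' Benchmark table over network configurations
#'
#' For every row of `configs` and every replicate, generates a network and
#' applies each requested method, returning a tidy per-replicate table.
#'
#' @param configs data frame with columns `family`, `N`, `P`, `k_avg` and
#'   optionally `gamma`.
#' @param methods subset of `c("paqga", "mm", "mmt", "brute")`.
#' @param replicates independent networks per configuration (default 10).
#' @param seeds replicate seeds (default `1:replicates`); replicate r of
#'   every configuration uses `seeds[r]` for both the generator and the
#'   optimiser, so methods see identical instances.
#' @param params a [paqga_params()].
#' @return Data frame with columns `family`, `N`, `k_avg`, `gamma`,
#'   `method`, `replicate`, `seed`, `n_cm`, `N_cm`,
#'   `convergence_generation`.
#' @export
run_benchmark <- function(configs, methods = c("paqga", "mm"),
                          replicates = 10L, seeds = seq_len(replicates),
                          params = paqga_params()) {
  stopifnot(length(seeds) == replicates)
  out <- list()
  for (ci in seq_len(nrow(configs))) {
    cfg <- configs[ci, ]
    gamma <- if ("gamma" %in% names(cfg)) cfg$gamma else NA
    for (r in seq_len(replicates)) {
      net <- generate_network(cfg$family, cfg$N, cfg$P, cfg$k_avg,
                              gamma = gamma, seed = seeds[r])
      evaluator <- if ("paqga" %in% methods) pbh_evaluator(net) else NULL
      for (mth in methods) {
        p <- params; p$seed <- seeds[r]
        res <- method_n_cm(mth, net, p, evaluator)
        out[[length(out) + 1L]] <- data.frame(
          family = cfg$family, N = cfg$N, k_avg = cfg$k_avg, gamma = gamma,
          method = mth, replicate = r, seed = seeds[r],
          n_cm = unname(res["n_cm"]),
          N_cm = unname(res["n_cm"]) / cfg$N,
          convergence_generation = unname(res["convergence"]))
      }
    }
  }
  do.call(rbind, out)
}

#' Summarise a benchmark table
#'
#' Mean and standard deviation of `n_cm` (and of the convergence
#' generation) per configuration and method.  With one replicate the
#' standard deviation is zero.
#'
#' @param bench result of [run_benchmark()].
#' @return Aggregated data frame.
#' @export
summarize_benchmark <- function(bench) {
  key <- paste(bench$family, bench$N, bench$k_avg, bench$gamma,
               bench$method)
  parts <- split(bench, key)
  out <- lapply(parts, function(d) {
    data.frame(family = d$family[1L], N = d$N[1L], k_avg = d$k_avg[1L],
               gamma = d$gamma[1L], method = d$method[1L],
               replicates = nrow(d),
               n_cm_mean = mean(d$n_cm),
               n_cm_sd = if (nrow(d) > 1L) stats::sd(d$n_cm) else 0,
               N_cm_mean = mean(d$N_cm),
               convergence_mean = mean(d$convergence_generation))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Topology sweep
#'
#' For every grid point, generates `replicates` networks, measures the
#' minimum control density with the chosen method and the topology summary,
#' and returns a tidy table; [sweep_trends()] reports the sign of the rank
#' correlation of `N_cm` with each structural covariate.
#'
#' @param grid data frame with columns `family`, `N`, `P`, `k_avg` and
#'   optionally `gamma`.
#' @param method one of `"paqga"`, `"mm"`, `"mmt"`, `"brute"`.
#' @param replicates networks per grid point.
#' @param seeds replicate seeds (default `1:replicates`).
#' @param params a [paqga_params()].
#' @return Data frame with the grid columns plus `replicate`, `n_cm`,
#'   `N_cm`, `k_avg_obs`, `H`, `C`.
#' @export
run_topology_sweep <- function(grid, method = "paqga", replicates = 5L,
                               seeds = seq_len(replicates),
                               params = paqga_params()) {
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    cfg <- grid[gi, ]
    gamma <- if ("gamma" %in% names(cfg)) cfg$gamma else NA
    for (r in seq_len(replicates)) {
      net <- generate_network(cfg$family, cfg$N, cfg$P, cfg$k_avg,
                              gamma = gamma, seed = seeds[r])
      p <- params; p$seed <- seeds[r]
      res <- method_n_cm(method, net, p)
      topo <- summarize_topology(net)
      out[[length(out) + 1L]] <- data.frame(
        family = cfg$family, N = cfg$N, k_avg = cfg$k_avg, gamma = gamma,
        replicate = r, n_cm = unname(res["n_cm"]),
        N_cm = unname(res["n_cm"]) / cfg$N,
        k_avg_obs = topo$k_avg, H = topo$H, C = topo$C)
    }
  }
  do.call(rbind, out)
}

#' @rdname run_topology_sweep
#' @param sweep result of `run_topology_sweep`.
#' @return `sweep_trends` returns the Spearman rank correlation of `N_cm`
#'   with `k_avg`, `gamma`, `H` and `C` (NA where the covariate does not
#'   vary).
#' @export
sweep_trends <- function(sweep) {
  cor_or_na <- function(x) {
    if (length(unique(x[!is.na(x)])) < 2L) return(NA_real_)
    suppressWarnings(stats::cor(sweep$N_cm, x, method = "spearman",
                                use = "complete.obs"))
  }
  c(k_avg = cor_or_na(sweep$k_avg), gamma = cor_or_na(sweep$gamma),
    H = cor_or_na(sweep$H), C = cor_or_na(sweep$C))
}
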