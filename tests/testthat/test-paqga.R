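test_that("observation collapses amplitudes with probability beta^2", {
  P <- 5
  expect_equal(observe_chain(rep(1, P), rep(0, P)), rep(0L, P))
  expect_equal(observe_chain(rep(0, P), rep(1, P)), rep(1L, P))
  ## balanced superposition: empirical frequency 0.5 within 3 sigma
  set.seed(1)
  n <- 1e4
  bits <- observe_chain(rep(1 / sqrt(2), n), rep(1 / sqrt(2), n))
  expect_lt(abs(mean(bits) - 0.5), 3 * 0.5 / sqrt(n))
})

test_that("crossover probability follows the adaptive formula", {
  m <- 15; p0 <- 0.06
  ## degenerate population: no exponential factor
  expect_equal(crossover_probability(10, 10, 10, 0, m, p0), m * p0)
  ## worst individual: exponent zero
  expect_equal(crossover_probability(20, 20, 10, 0, m, p0), m * p0)
  ## best individual: factor exp(-1)
  expect_equal(crossover_probability(10, 20, 10, 0, m, p0),
               m * p0 * exp(-1))
  ## Q clamps at 1 and scales inversely
  expect_equal(crossover_probability(20, 20, 10, 5, m, p0), (m / 5) * p0)
  ## truncation to 1
  expect_lte(crossover_probability(20, 20, 10, 0, 100, 0.5), 1)
})

test_that("crossover replaces genes towards the incumbent at rate p_c", {
  bits <- rep(0L, 10)
  best <- rep(1L, 10)
  expect_equal(crossover_bits(bits, best, 0), bits)
  expect_equal(crossover_bits(bits, best, 1), best)
  set.seed(2)
  n <- 1e4
  crossed <- crossover_bits(rep(0L, n), rep(1L, n), 0.5)
  expect_lt(abs(mean(crossed) - 0.5), 3 * 0.5 / sqrt(n))
})

test_that("rotation angles follow the adaptive lookup rules", {
  a <- 1 / sqrt(2); b <- 1 / sqrt(2)
  ## agreement: no rotation
  expect_equal(rotation_angle(0L, 0L, 50, 40, a, b), 0)
  expect_equal(rotation_angle(1L, 1L, 50, 40, a, b), 0)
  ## candidate 0, incumbent 1, incumbent fitter, alpha*beta > 0:
  ## theta = +(f_c/f_best) * 0.03 pi (towards bit 1)
  expect_equal(rotation_angle(0L, 1L, 60, 40, a, b), (60 / 40) * 0.03 * pi)
  ## candidate fitter: small magnitude, sign reversed
  expect_equal(rotation_angle(0L, 1L, 30, 40, a, b), -(30 / 40) * 0.01 * pi)
  ## candidate 1, incumbent 0, candidate fitter, alpha*beta > 0: positive
  expect_equal(rotation_angle(1L, 0L, 30, 40, a, b), (30 / 40) * 0.01 * pi)
  ## negative alpha*beta flips the sign
  expect_equal(rotation_angle(0L, 1L, 60, 40, -a, b),
               -(60 / 40) * 0.03 * pi)
  ## magnitude cap: penalty-inflated ratios stay below a quarter turn
  expect_equal(abs(rotation_angle(0L, 1L, 1e5, 40, a, b)), pi / 2)
  ## pole cells: a coin toss where the table says +/-1, zero where frozen
  th <- replicate(50, rotation_angle(1L, 0L, 60, 40, 0, 1))
  expect_true(all(abs(abs(th) - (60 / 40) * 0.03 * pi) < 1e-12))
  expect_true(length(unique(sign(th))) == 2)   # both signs occur
  expect_equal(rotation_angle(0L, 1L, 60, 40, 0, 1), 0)
})

test_that("the Q-gate is an exact rotation", {
  expect_equal(qgate_rotate(0.6, 0.8, 0), list(alpha = 0.6, beta = 0.8))
  r <- qgate_rotate(1, 0, pi / 2)
  expect_equal(r$alpha, 0, tolerance = 1e-12)
  expect_equal(r$beta, 1)
  set.seed(3)
  for (i in 1:20) {
    ang <- runif(1, 0, 2 * pi)
    v <- runif(1, -1, 1); pair <- c(v, sqrt(1 - v^2))
    r <- qgate_rotate(pair[1], pair[2], ang)
    expect_equal(r$alpha^2 + r$beta^2, 1, tolerance = 1e-12)
  }
})

test_that("catastrophe keeps the elite deterministically and resets the rest", {
  set.seed(4)
  m <- 4; P <- 6
  pop <- list(a1 = matrix(runif(m * P), m, P),
              b1 = matrix(runif(m * P), m, P),
              a2 = matrix(runif(m * P), m, P),
              b2 = matrix(runif(m * P), m, P))
  elite <- c(1L, 0L, 1L, 1L, 0L, 0L)
  new <- catastrophe(pop, elite)
  ## elite chromosome re-observes its bits with certainty
  for (k in 1:200) {
    expect_equal(observe_chain(new$a1[1, ], new$b1[1, ]), elite)
    expect_equal(observe_chain(new$a2[1, ], new$b2[1, ]), elite)
  }
  ## every other chromosome is back at the uniform superposition
  expect_true(all(new$a1[-1, ] == 1 / sqrt(2)))
  expect_true(all(new$b2[-1, ] == 1 / sqrt(2)))
})

test_that("optimiser solves degenerate and complete networks", {
  ## A = 0 with diagonal B: every state needs its own input
  net0 <- control_network(matrix(0, 6, 6), diag(runif(6)))
  run <- paqga(net0, paqga_params(maxgen = 30, seed = 1))
  expect_equal(run$n_cm, 6)
  ## complete weighted digraph: a single controller suffices
  netc <- gen_complete(8, seed = 5)
  run <- paqga(netc, paqga_params(seed = 2))
  expect_equal(run$n_cm, 1)
  ## infeasible fully wired network aborts with a diagnostic
  ## one control shared by three independent states cannot separate them
  bad <- control_network(matrix(0, 3, 3), matrix(c(1, 1, 1), 3, 1))
  expect_error(paqga(bad, paqga_params(maxgen = 5, seed = 1)),
               "not\\s+controllable")
})

test_that("optimiser matches the exhaustive oracle on small networks", {
  hits <- 0
  for (s in 1:6) {
    net <- gen_er(10, 10, 2, control_attachment = "identity",
                  seed = 2000 + s)
    ev <- pbh_evaluator(net)
    bf <- brute_force_min_controls(net, evaluator = ev)$n_d
    run <- paqga(net, paqga_params(seed = s), evaluator = ev)
    expect_gte(run$n_cm, bf)
    hits <- hits + (run$n_cm == bf)
  }
  expect_gte(hits, 5)
})

test_that("run history is monotone with a feasible incumbent throughout", {
  net <- gen_er(30, 30, 3, seed = 7)
  run <- paqga(net, paqga_params(seed = 3))
  h <- run$history
  expect_true(all(diff(h$best_f) <= 0))
  expect_true(all(h$penalty == 0))
  expect_equal(h$best_f[nrow(h)], run$f_best)
  expect_equal(run$n_cm, sum(run$scheme$d))
  expect_equal(run$N_cm, run$n_cm / net$N)
  expect_equal(h$best_f[run$convergence_generation], run$f_best)
  if (run$convergence_generation > 1)
    expect_gt(h$best_f[run$convergence_generation - 1], run$f_best)
})

test_that("results are reproducible by seed and invariant to workers", {
  net <- gen_er(15, 15, 2, seed = 8)
  r1 <- paqga(net, paqga_params(maxgen = 20, seed = 5))
  r2 <- paqga(net, paqga_params(maxgen = 20, seed = 5))
  expect_identical(r1$scheme$d, r2$scheme$d)
  expect_identical(r1$history, r2$history)
  r3 <- paqga(net, paqga_params(maxgen = 20, seed = 5, workers = 2L))
  expect_identical(r1$scheme$d, r3$scheme$d)
  expect_identical(r1$history, r3$history)
})

test_that("run serialisation writes JSON and tidy CSV", {
  net <- gen_er(12, 12, 2, seed = 9)
  run <- paqga(net, paqga_params(maxgen = 10, seed = 1))
  js_path <- withr::local_tempfile(fileext = ".json")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_run(run, json = js_path, csv = csv_path)
  js <- jsonlite::fromJSON(js_path)
  expect_equal(js$n_cm, run$n_cm)
  h <- utils::read.csv(csv_path)
  expect_named(h, c("generation", "best_f", "mean_f", "penalty", "n_c"))
  expect_equal(nrow(h), 10)
})
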