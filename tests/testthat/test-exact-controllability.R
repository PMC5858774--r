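test_that("distinct eigenvalues are clustered correctly", {
  expect_equal(distinct_eigenvalues(matrix(0, 3, 3)), as.complex(0),
               ignore_attr = TRUE)
  lam <- distinct_eigenvalues(diag(c(1, 2, 2)))
  expect_equal(sort(Re(lam)), c(1, 2), ignore_attr = TRUE)
  expect_length(lam, 2)
  ## unit-weight 3-cycle: the three cube roots of unity
  A <- matrix(0, 3, 3); A[2, 1] <- 1; A[3, 2] <- 1; A[1, 3] <- 1
  lam <- distinct_eigenvalues(A)
  roots <- exp(2i * pi * (0:2) / 3)
  expect_length(lam, 3)
  for (r in roots) expect_lt(min(Mod(lam - r)), 1e-8)
  expect_error(distinct_eigenvalues(matrix(0, 2, 3)), "square")
})

test_that("pbh_deficiency counts unreachable modes", {
  A0 <- matrix(0, 3, 3)
  expect_equal(pbh_deficiency(A0, diag(3), 0), 0)
  expect_equal(pbh_deficiency(A0, diag(3)[, 1, drop = FALSE], 0), 2)
  ## a single input drives a weighted cycle at every eigenvalue
  A <- matrix(0, 3, 3); A[2, 1] <- 1; A[3, 2] <- 1; A[1, 3] <- 1
  e1 <- diag(3)[, 1, drop = FALSE]
  for (lam in distinct_eigenvalues(A))
    expect_equal(pbh_deficiency(A, e1, lam), 0)
  expect_error(pbh_deficiency(A, diag(4), 0), "N rows")
})

test_that("penalty follows sigma_1 = 10 P with the squared deficiency", {
  ## A = 0, no selected controls: l = 1 (zero eigenvalue), deficiency 3
  net <- control_network(matrix(0, 3, 3), diag(3))
  expect_equal(penalty(net, c(0, 0, 0)), 10 * 3 * 3^2)
  expect_equal(penalty(net, c(1, 1, 1)), 0)
  expect_equal(fitness(net, c(1, 1, 1)), 3)
  ## c > 1 variant: strictly increasing coefficients
  sched <- penalty_schedule(c = 2)
  net2 <- control_network(diag(c(1, 2)), matrix(0, 2, 2))
  ## no controls selected: each of the two eigenvalues deficient by 1
  expect_equal(penalty(net2, c(0, 0), sched), 10 * 2 * 1 + 20 * 2 * 1)
  expect_error(penalty_schedule(c = -1), "positive")
})

test_that("worked fitness example: five controls, one redundancy, penalty 50", {
  net <- worked_example_net()
  expect_equal(fitness(net, c(1, 1, 1, 1, 1)), 5)
  expect_equal(penalty(net, c(1, 1, 1, 1, 1)), 0)
  ## dropping the redundant control still controls the network
  expect_equal(fitness(net, c(1, 1, 1, 1, 0)), 4)
  expect_true(is_fully_controllable(net, c(1, 1, 1, 1, 0)))
  ## removing the essential u4 leaves one unit deficiency: penalty 10P = 50
  expect_equal(penalty(net, c(1, 1, 1, 0, 0)), 50)
  expect_false(is_fully_controllable(net, c(1, 1, 1, 0, 0)))
})

test_that("zero penalty is equivalent to Kalman controllability", {
  ## random sparse instances, including defective (nilpotent) structure
  set.seed(42)
  n_checked <- 0
  for (rep in 1:25) {
    N <- sample(3:7, 1)
    net <- rand_sparse_net(N, sample(2:(N + 3), 1), seed = 500 + rep)
    for (k in 1:4) {
      bits <- rbinom(N, 1, 0.6)
      expect_equal(penalty(net, bits) == 0, kalman_controllable(net, bits),
                   info = sprintf("rep %d bits %s", rep,
                                  paste(bits, collapse = "")))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("cached evaluator agrees with the direct PBH computation", {
  set.seed(9)
  for (rep in 1:10) {
    N <- sample(4:8, 1)
    net <- rand_sparse_net(N, sample(3:(2 * N), 1), seed = 700 + rep)
    ev <- pbh_evaluator(net)
    for (k in 1:5) {
      bits <- rbinom(N, 1, 0.5)
      expect_equal(ev$penalty(bits), penalty(net, bits))
      expect_equal(ev$fitness(bits), fitness(net, bits))
    }
  }
})

test_that("adding a control column never increases any deficiency", {
  set.seed(11)
  for (rep in 1:8) {
    N <- 6
    net <- rand_sparse_net(N, sample(3:10, 1), seed = 800 + rep)
    bits <- rbinom(N, 1, 0.4)
    zeros <- which(bits == 0)
    if (!length(zeros)) next
    bits2 <- bits; bits2[sample(zeros, 1)] <- 1
    ev <- pbh_evaluator(net)
    expect_true(all(ev$deficiencies(bits2) <= ev$deficiencies(bits)))
  }
})

test_that("feasibility is characterised by f(D) <= P and f equals r when feasible", {
  set.seed(13)
  for (rep in 1:10) {
    net <- rand_sparse_net(6, sample(3:9, 1), seed = 900 + rep)
    bits <- rbinom(6, 1, 0.5)
    f <- fitness(net, bits)
    feasible <- is_fully_controllable(net, bits)
    expect_equal(f <= net$P, feasible)
    if (feasible) expect_equal(f, sum(bits))
  }
})

test_that("brute-force minimum with identity B matches maximum multiplicity", {
  ## with B = I the selection constraint is immaterial generically
  set.seed(17)
  agree <- 0; total <- 0
  for (rep in 1:12) {
    N <- sample(4:7, 1)
    net <- gen_er(N, N, 2, control_attachment = "identity",
                  seed = 1000 + rep)
    bf <- brute_force_min_controls(net)$n_d
    mt <- mmt_driver_count(net$A)$n_d
    total <- total + 1
    agree <- agree + (bf == mt)
  }
  expect_gte(agree / total, 0.95)
})

test_that("pbh_report serialises to JSON with re/im eigenvalue pairs", {
  net <- worked_example_net()
  rep <- pbh_report(net, c(1, 1, 1, 0, 0))
  expect_gte(rep$l, 1)
  expect_lte(rep$l, net$N + 1)
  expect_equal(rep$total_penalty, sum(rep$penalties))
  js <- jsonlite::fromJSON(pbh_report_json(rep))
  expect_equal(js$total_penalty, rep$total_penalty)
  expect_named(js$eigenvalues, c("re", "im"))
})
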