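test_that("constructor enforces the one-control-per-state invariant", {
  A <- matrix(0, 3, 3)
  B <- matrix(0, 3, 2)
  B[1, 1] <- 0.5; B[1, 2] <- 0.3       # state 1 fed by two controls
  expect_error(control_network(A, B), "at most one control")
  expect_error(control_network(matrix(0, 2, 3)), "square")
  expect_error(control_network(matrix(c(0, Inf, 0, 0), 2, 2)), "finite")
  net <- control_network(A)            # controls are optional
  expect_equal(net$P, 0L)
})

test_that("scheme_from_bits builds the selector matrix of the worked example", {
  s <- scheme_from_bits(c(1, 1, 1, 0))
  expect_equal(s$r, 3L)
  M_expected <- rbind(diag(3), 0)      # 4 x 3: drops the 4th control
  expect_equal(s$M, M_expected, ignore_attr = TRUE)

  s2 <- scheme_from_bits(c(1, 0, 1))
  expect_equal(s2$r, 2L)
  expect_equal(which(s2$M[, 1] == 1), 1L)
  expect_equal(which(s2$M[, 2] == 1), 3L)

  s0 <- scheme_from_bits(c(0, 0, 0))
  expect_equal(s0$r, 0L)
  expect_equal(dim(s0$M), c(3L, 0L))

  expect_error(scheme_from_bits(c(1, 2, 0)), "binary")
})

test_that("apply_scheme equals B D M and selects columns in control order", {
  net <- example_network_7x3()
  ## all ones: B* is B itself (M is the identity)
  expect_identical(apply_scheme(net, rep(1, 3)), net$B)
  ## subset: matches the matrix-product definition
  for (bits in list(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1), c(0, 0, 0))) {
    s <- control_scheme(bits)
    expect_equal(apply_scheme(net, s),
                 net$B %*% diag(s$d) %*% s$M, ignore_attr = TRUE)
    expect_equal(ncol(apply_scheme(net, s)), s$r)
  }
  expect_equal(ncol(apply_scheme(net, c(0, 0, 0))), 0L)
  expect_error(apply_scheme(net, c(1, 1)), "does not match")
})

test_that("restricting a scheme commutes with applying it", {
  net <- gen_er(12, 6, 2, control_attachment = "uniform", seed = 3)
  d <- c(1, 0, 1, 1, 0, 1)
  d_sub <- c(1, 0, 0, 1, 0, 1)   # d_sub <= d elementwise
  direct <- apply_scheme(net, d_sub)
  via <- apply_scheme(net, d)[, which(d_sub[d == 1] == 1), drop = FALSE]
  expect_equal(direct, via)
})

test_that("edge-list TSV round-trips exactly and validates input", {
  net <- example_network_7x3()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, "tsv")
  back <- read_network(path, "tsv")
  expect_identical(back$A, net$A)
  expect_identical(back$B, net$B)
  ## 9 state edges including the self-loop, 3 control links
  expect_equal(sum(back$A != 0), 9)
  expect_equal(back$A[7, 7] != 0, TRUE)
  expect_equal(sum(back$B != 0), 3)

  ## empty network round-trip
  e <- control_network(matrix(0, 3, 3))
  write_network(e, path, "tsv")
  expect_equal(read_network(path, "tsv")$A, e$A)

  ## a state node linked to two controls is rejected
  writeLines(c("# N 3", "# P 2",
               "4\t1\t0.5\tCS", "5\t1\t0.2\tCS"), path)
  expect_error(read_network(path, "tsv"), "more than one control")

  ## dangling ids are rejected
  writeLines(c("# N 3", "# P 1", "1\t9\t0.5\tSS"), path)
  expect_error(read_network(path, "tsv"), "dangling")

  ## duplicate edges: last occurrence wins, with a warning
  writeLines(c("# N 3", "# P 0",
               "1\t2\t0.5\tSS", "1\t2\t0.9\tSS"), path)
  expect_warning(dup <- read_network(path, "tsv"), "duplicate")
  expect_equal(dup$A[2, 1], 0.9)
})

test_that("Pajek round-trips exactly and symmetrises *Edges sections", {
  net <- example_network_7x3()
  path <- withr::local_tempfile(fileext = ".net")
  write_network(net, path, "pajek")
  back <- read_network(path, "pajek")
  expect_identical(back$A, net$A)
  expect_identical(back$B, net$B)

  writeLines(c("% netctrl N=3 P=0", "*Vertices 3",
               '1 "a"', '2 "b"', '3 "c"',
               "*Edges", "1 2 0.25"), path)
  und <- read_network(path, "pajek")
  expect_equal(und$A[2, 1], 0.25)
  expect_equal(und$A[1, 2], 0.25)
})
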