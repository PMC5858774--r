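## Independent oracles and fixture builders used across the test files.

## Kalman rank test: rank[B*, AB*, ..., A^(N-1)B*] == N.  Independent of the
## package's PBH machinery (QR rank on the real controllability matrix).
kalman_controllable <- function(net, bits) {
  Bs <- apply_scheme(net, bits)
  if (ncol(Bs) == 0L) return(FALSE)
  K <- Bs
  M <- Bs
  for (i in seq_len(net$N - 1L)) {
    M <- net$A %*% M
    K <- cbind(K, M)
  }
  qr(K, tol = 1e-9)$rank == net$N
}

## Plain recursive augmenting-path bipartite matcher (left = out-copies,
## right = in-copies); oracle for mm_driver_count.
matching_size_oracle <- function(A) {
  N <- nrow(A)
  adj <- lapply(seq_len(N), function(j) which(A[, j] != 0))  # out j -> in i
  match_of <- rep(0L, N)   # right vertex -> left vertex
  try_augment <- function(j, seen) {
    for (i in adj[[j]]) {
      if (seen[i]) next
      seen[i] <- TRUE
      if (match_of[i] == 0L) {
        match_of[i] <<- j
        return(TRUE)
      }
      old <- match_of[i]
      match_of[i] <<- j
      if (try_augment(old, seen)) return(TRUE)
      match_of[i] <<- old
    }
    FALSE
  }
  size <- 0L
  for (j in seq_len(N))
    if (try_augment(j, rep(FALSE, N))) size <- size + 1L
  size
}

## The illustrative 7-state / 3-control network: nine state edges
## (x1->x2, x1->x3, x2->x4, x2->x5, x3->x6, x3->x7, x4->x2, x5->x6,
## x7->x7 self-loop) and controls u1->x1, u2->x2, u3->x3.
example_network_7x3 <- function(seed = 1) {
  set.seed(seed)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(3, 6), c(3, 7),
                 c(4, 2), c(5, 6), c(7, 7))
  A <- matrix(0, 7, 7)
  A[cbind(edges[, 2], edges[, 1])] <- runif(nrow(edges))
  B <- matrix(0, 7, 3)
  B[cbind(1:3, 1:3)] <- runif(3)
  control_network(A, B)
}

## Worked fitness example: 7 states, 5 candidate controls.  The state graph
## is two weighted chains (x1->x2->x3, x4->x5) plus two isolated states, so
## the zero eigenvalue has geometric multiplicity 4 and full control needs
## inputs at x1, x4, x6 and x7.  u5 (into the chain interior x5... see B)
## is redundant; u4 is essential.
worked_example_net <- function(seed = 4) {
  set.seed(seed)
  A <- matrix(0, 7, 7)
  A[2, 1] <- runif(1); A[3, 2] <- runif(1)   # x1 -> x2 -> x3
  A[5, 4] <- runif(1)                        # x4 -> x5
  B <- matrix(0, 7, 5)
  B[1, 1] <- runif(1)   # u1 -> x1  (chain head, essential)
  B[4, 2] <- runif(1)   # u2 -> x4  (chain head, essential)
  B[6, 3] <- runif(1)   # u3 -> x6  (isolated, essential)
  B[7, 4] <- runif(1)   # u4 -> x7  (isolated, essential)
  B[2, 5] <- runif(1)   # u5 -> x2  (chain interior, redundant)
  control_network(A, B)
}

## sparse random instance; often contains nilpotent chains (defective zero
## eigenvalue), the numerically hard case
rand_sparse_net <- function(N, n_edges, seed, attachment = "identity") {
  set.seed(seed)
  A <- matrix(0, N, N)
  for (e in seq_len(n_edges)) {
    i <- sample.int(N, 1); j <- sample.int(N, 1)
    if (i != j) A[i, j] <- runif(1)
  }
  B <- diag(runif(N))
  control_network(A, B)
}
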