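#' Distinct eigenvalues of a state matrix
#'
#' Computes the eigenvalues of `A` and merges values whose complex distance
#' is at most `tol_group` into a single representative (the cluster mean).
#' Floating-point eigenvalues of repeated roots scatter, and the PBH test
#' only needs one rank evaluation per distinct value, so a merge rule is
#' required.
#'
#' @param A square numeric matrix.
#' @param tol_group absolute merging tolerance (complex modulus).
#' @return Complex vector of cluster representatives, ordered by real part
#'   then imaginary part.
#' @examples
#' distinct_eigenvalues(diag(c(1, 2, 2)))   # two distinct values
#' @export
distinct_eigenvalues <- function(A, tol_group = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("'A' must be square")
  ev <- eigen(A, only.values = TRUE)$values
  ev <- as.complex(ev)
  ord <- order(Re(ev), Im(ev))
  ev <- ev[ord]
  reps <- complex(0)
  sizes <- integer(0)
  for (v in ev) {
    d <- if (length(reps)) Mod(v - reps) else numeric(0)
    i <- if (length(d)) which.min(d) else 0L
    if (i > 0L && d[i] <= tol_group) {
      reps[i] <- (reps[i] * sizes[i] + v) / (sizes[i] + 1L)  # running mean
      sizes[i] <- sizes[i] + 1L
    } else {
      reps <- c(reps, v)
      sizes <- c(sizes, 1L)
    }
  }
  structure(reps, multiplicity = sizes)
}

## SVD-based numerical rank; threshold follows the usual
## sigma > tol * max(dim) * sigma_max rule with tol at machine-epsilon scale.
num_rank <- function(M, tol_rank = NULL) {
  if (length(M) == 0L) return(0L)
  s <- svd(M, nu = 0, nv = 0)$d
  if (!length(s) || s[1] == 0) return(0L)
  if (is.null(tol_rank)) tol_rank <- .Machine$double.eps
  sum(s > tol_rank * max(dim(M)) * s[1])
}

#' PBH rank deficiency at one eigenvalue
#'
#' Computes \eqn{N - rank([\lambda I_N - A \mid B^*])}: the number of modes
#' at eigenvalue `lambda` left unreachable by the inputs in `Bstar`.  A
#' scheme is fully controllable iff this is zero at every distinct
#' eigenvalue of `A`.
#'
#' @param A square numeric matrix (N x N).
#' @param Bstar reduced input matrix with N rows (may have zero columns).
#' @param lambda a (complex) eigenvalue candidate.
#' @param tol_rank relative singular-value threshold; default
#'   machine-epsilon scale.
#' @return Non-negative integer deficiency.
#' @export
pbh_deficiency <- function(A, Bstar, lambda, tol_rank = NULL) {
  A <- as.matrix(A)
  N <- nrow(A)
  if (ncol(A) != N) stop("'A' must be square")
  Bstar <- as.matrix(Bstar)
  if (nrow(Bstar) != N) stop("'Bstar' must have N rows")
  M <- diag(as.complex(lambda), N) - A
  N - num_rank(cbind(M, Bstar + 0i), tol_rank)
}

## Candidate eigenvalues for the PBH sweep.  Defective zero eigenvalues of
## nilpotent chain structure scatter to O(eps^(1/k)) and are not recovered
## by clustering, so an explicit zero candidate is appended whenever A is
## numerically rank deficient and no candidate is already (near) zero.
pbh_candidates <- function(A, tol_group = 1e-8, tol_rank = NULL) {
  lam <- distinct_eigenvalues(A, tol_group)
  mult <- attr(lam, "multiplicity")
  has_zero <- any(Mod(lam) <= tol_group)
  if (!has_zero && num_rank(A, tol_rank) < nrow(A)) {
    lam <- c(lam, 0 + 0i)
    mult <- c(mult, NA_integer_)
  }
  structure(lam, multiplicity = mult)
}

#' Penalty schedule for infeasible schemes
#'
#' The penalty coefficient of the i-th distinct eigenvalue is
#' \eqn{\sigma_i = 10 P \cdot c^{i-1}}.  The default `c = 1` keeps all
#' coefficients equal to \eqn{10P}, which already guarantees that a scheme
#' has fitness at most P iff it is feasible; `c > 1` gives the strictly
#' increasing variant.
#'
#' @param c positive multiplier between consecutive coefficients.
#' @return Object of class `penalty_schedule`.
#' @export
penalty_schedule <- function(c = 1) {
  if (!is.numeric(c) || c <= 0) stop("'c' must be a positive number")
  structure(list(c = c), class = "penalty_schedule")
}

schedule_sigma <- function(schedule, P, l) {
  10 * P * schedule$c^(seq_len(l) - 1)
}

#' Per-eigenvalue PBH report for a control scheme
#'
#' Evaluates the PBH rank test at every candidate eigenvalue and reports
#' the deficiencies and penalty terms.  Total penalty zero is equivalent to
#' full controllability.
#'
#' @inheritParams apply_scheme
#' @param schedule a [penalty_schedule()].
#' @param tol_group eigenvalue merging tolerance.
#' @param tol_rank rank threshold passed to [pbh_deficiency()].
#' @return Object of class `pbh_report`: list with `eigenvalues`,
#'   `deficiencies`, `l`, `penalties`, `total_penalty` and the selected
#'   count `r`.
#' @export
pbh_report <- function(net, scheme = NULL, schedule = penalty_schedule(),
                       tol_group = 1e-8, tol_rank = NULL) {
  if (is.null(scheme)) scheme <- rep(1L, net$P)
  scheme <- as_scheme(scheme)
  Bstar <- apply_scheme(net, scheme)
  lam <- pbh_candidates(net$A, tol_group, tol_rank)
  defs <- vapply(lam, function(l)
    pbh_deficiency(net$A, Bstar, l, tol_rank), 0)
  sig <- schedule_sigma(schedule, net$P, length(lam))
  pens <- sig * defs^2
  structure(list(eigenvalues = as.complex(lam),
                 deficiencies = as.integer(defs),
                 l = length(lam),
                 penalties = pens,
                 total_penalty = sum(pens),
                 r = scheme$r),
            class = "pbh_report")
}

#' @export
print.pbh_report <- function(x, ...) {
  cat(sprintf("PBH report: %d candidate eigenvalues, total penalty %g\n",
              x$l, x$total_penalty))
  bad <- which(x$deficiencies > 0)
  if (length(bad))
    cat(sprintf("  deficient at %d eigenvalue(s); max deficiency %d\n",
                length(bad), max(x$deficiencies)))
  else cat("  fully controllable under the selected scheme\n")
  invisible(x)
}

#' Serialise a PBH report to JSON
#'
#' Eigenvalues are written as re/im pairs.
#'
#' @param x a [pbh_report()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
pbh_report_json <- function(x, path = NULL) {
  obj <- list(eigenvalues = data.frame(re = Re(x$eigenvalues),
                                       im = Im(x$eigenvalues)),
              deficiencies = x$deficiencies,
              l = x$l,
              penalties = x$penalties,
              total_penalty = x$total_penalty,
              r = x$r)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Penalty and fitness of a control scheme
#'
#' `penalty` is \eqn{Pen(D) = \sum_i \sigma_i \, def_i^2} over the candidate
#' eigenvalues; `fitness` adds the selected-control count,
#' \eqn{f(D) = \sum_j d_j + Pen(D)}.  With \eqn{\sigma_1 = 10P},
#' \eqn{f(D) \le P} iff the scheme is feasible (zero penalty).
#'
#' @inheritParams pbh_report
#' @return A single number.
#' @export
penalty <- function(net, scheme = NULL, schedule = penalty_schedule(),
                    tol_group = 1e-8, tol_rank = NULL) {
  pbh_report(net, scheme, schedule, tol_group, tol_rank)$total_penalty
}

#' @rdname penalty
#' @export
fitness <- function(net, scheme = NULL, schedule = penalty_schedule(),
                    tol_group = 1e-8, tol_rank = NULL) {
  rep <- pbh_report(net, scheme, schedule, tol_group, tol_rank)
  rep$r + rep$total_penalty
}

#' Full-controllability test
#'
#' `TRUE` iff the PBH deficiency is zero at every candidate eigenvalue.
#'
#' @inheritParams pbh_report
#' @export
is_fully_controllable <- function(net, scheme = NULL, tol_group = 1e-8,
                                  tol_rank = NULL) {
  all(pbh_report(net, scheme, tol_group = tol_group,
                 tol_rank = tol_rank)$deficiencies == 0L)
}

#' Cached PBH evaluator
#'
#' Precomputes, per candidate eigenvalue \eqn{\lambda}, the geometric
#' multiplicity \eqn{g = N - rank(\lambda I - A)} and the projection
#' \eqn{C_\lambda = W_\lambda^H B} of the candidate input matrix onto the
#' left null space of \eqn{\lambda I - A}.  The deficiency of a scheme then
#' reduces to \eqn{g - rank} of the \eqn{g \times r} submatrix of selected
#' columns, which makes repeated fitness evaluation (the inner loop of the
#' optimiser and of the exhaustive oracle) cheap.  Simple, well-separated
#' eigenvalues take their left eigenvector from one `eigen(t(A))`
#' decomposition (with a residual check); clustered or ill-conditioned ones
#' fall back to an SVD of \eqn{\lambda I - A}.  Fitness values are memoised
#' by bit pattern.
#'
#' @inheritParams pbh_report
#' @return A list of closures: `fitness(bits)`, `penalty(bits)`,
#'   `deficiencies(bits)`, plus fields `lambdas`, `l` and `N`.
#' @export
pbh_evaluator <- function(net, schedule = penalty_schedule(),
                          tol_group = 1e-8, tol_rank = NULL) {
  A <- net$A; B <- net$B; N <- net$N; P <- net$P
  lam <- pbh_candidates(A, tol_group, tol_rank)
  mult <- attr(lam, "multiplicity")
  l <- length(lam)
  if (is.null(tol_rank)) tol_rank <- .Machine$double.eps
  scaleA <- max(1, sqrt(sum(A^2)))
  scaleB <- max(1, sqrt(sum(B^2)))

  left <- eigen(t(A))
  lv <- left$values

  terms <- vector("list", l)
  for (i in seq_len(l)) {
    li <- lam[i]
    g <- NA_integer_; C <- NULL
    if (!is.na(mult[i]) && mult[i] == 1L) {
      j <- which.min(Mod(lv - li))
      v <- left$vectors[, j]
      v <- v / sqrt(sum(Mod(v)^2))
      resid <- sqrt(sum(Mod(t(A) %*% v - li * v)^2))
      if (Mod(lv[j] - li) <= tol_group && resid <= 1e-10 * scaleA) {
        g <- 1L
        C <- matrix(t(v) %*% B, 1L, P)   # plain transpose: w^T(lambda I - A)=0
      }
    }
    if (is.na(g)) {
      M <- diag(as.complex(li), N) - A
      sv <- svd(M)
      thr0 <- tol_rank * max(N, N + P) * max(sv$d[1], 1)
      r0 <- sum(sv$d > thr0)
      g <- N - r0
      if (g > 0L) {
        W <- sv$u[, (r0 + 1L):N, drop = FALSE]
        C <- Conj(t(W)) %*% B
      } else C <- matrix(0 + 0i, 0L, P)
    }
    thr <- tol_rank * max(N, N + P) * (Mod(li) + scaleA + scaleB)
    terms[[i]] <- list(lambda = li, g = g, C = C, absC = Mod(C), thr = thr)
  }

  ## single-multiplicity eigenvalues collapse to a coverage test:
  ## deficiency 1 iff no selected control projects onto the eigenvector
  g1 <- which(vapply(terms, function(tm) tm$g, 0L) == 1L)
  cover <- NULL
  if (length(g1))
    cover <- do.call(rbind, lapply(terms[g1], function(tm) tm$absC > tm$thr))
  gk <- setdiff(seq_len(l), g1)
  sigma <- schedule_sigma(schedule, P, l)

  memo <- new.env(parent = emptyenv())

  deficiencies <- function(bits) {
    bits <- as.integer(bits)
    sel <- bits == 1L
    defs <- integer(l)
    if (length(g1)) {
      hit <- if (any(sel)) rowSums(cover[, sel, drop = FALSE]) > 0L
             else rep(FALSE, length(g1))
      defs[g1] <- 1L - as.integer(hit)
    }
    for (i in gk) {
      tm <- terms[[i]]
      if (!any(sel)) { defs[i] <- tm$g; next }
      sub <- tm$C[, sel, drop = FALSE]
      s <- svd(sub, nu = 0, nv = 0)$d
      defs[i] <- tm$g - sum(s > tm$thr)
    }
    defs
  }

  penalty_of <- function(bits) sum(sigma * deficiencies(bits)^2)

  fitness_of <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    f <- sum(bits) + penalty_of(bits)
    memo[[key]] <- f
    f
  }

  prime <- function(bits, f) {
    memo[[paste(bits, collapse = "")]] <- f
    invisible(f)
  }

  list(fitness = fitness_of, penalty = penalty_of,
       deficiencies = deficiencies, prime = prime,
       lambdas = as.complex(lam), l = l, N = N, P = P)
}
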