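#' Control schemes: binary selections of candidate control nodes
#'
#' A control scheme is the diagonal of a binary diagonal matrix
#' \eqn{D = diag(d_1, \dots, d_P)}: \eqn{d_j = 1} keeps candidate control
#' node \eqn{u_j}, \eqn{d_j = 0} removes it together with its links.  The
#' index matrix \eqn{M} (\eqn{P \times r}, one column per selected control,
#' each column a unit vector) extracts the nonzero columns of \eqn{D}, so
#' the reduced input matrix is \eqn{B^* = B D M}.
#'
#' @param bits binary vector of length P (0/1, logical accepted).
#' @return An object of class `control_scheme`: list with the binary vector
#'   `d`, the selected count `r` and the index matrix `M`.
#' @examples
#' s <- control_scheme(c(1, 1, 1, 0))
#' s$r
#' s$M   # the 4 x 3 selector matrix
#' @export
control_scheme <- function(bits) {
  if (is.logical(bits)) bits <- as.integer(bits)
  if (!is.numeric(bits) || any(is.na(bits)) || !all(bits %in% c(0, 1)))
    stop("'bits' must be a binary (0/1) vector")
  d <- as.integer(bits)
  P <- length(d)
  sel <- which(d == 1L)
  r <- length(sel)
  M <- matrix(0L, P, r)
  if (r) M[cbind(sel, seq_len(r))] <- 1L
  structure(list(d = d, r = r, M = M), class = "control_scheme")
}

#' @rdname control_scheme
#' @export
scheme_from_bits <- control_scheme

#' @export
print.control_scheme <- function(x, ...) {
  cat(sprintf("control_scheme: %d of %d candidate controls selected\n",
              x$r, length(x$d)))
  if (x$r) cat("  selected:", paste(which(x$d == 1L), collapse = " "), "\n")
  invisible(x)
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "control_scheme")) scheme else control_scheme(scheme)
}

#' Reduced input matrix of a scheme
#'
#' Returns \eqn{B^* = B D M}: the columns of `B` whose control node is
#' selected, in ascending control index order.
#'
#' @param net a [control_network()].
#' @param scheme a [control_scheme()] or a binary vector of length `net$P`.
#' @return Numeric `N x r` matrix.
#' @export
apply_scheme <- function(net, scheme) {
  scheme <- as_scheme(scheme)
  if (length(scheme$d) != net$P)
    stop("scheme length ", length(scheme$d),
         " does not match the number of candidate controls ", net$P)
  net$B[, which(scheme$d == 1L), drop = FALSE]
}
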