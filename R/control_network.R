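#' Directed weighted network with state and candidate control nodes
#'
#' A `control_network` couples an \eqn{N \times N} state matrix `A` with an
#' \eqn{N \times P} candidate input matrix `B`.  The dynamics convention is
#' \eqn{\dot x = A x + B u}: `A[i, j]` is the weight of the directed link
#' from state node \eqn{x_j} to state node \eqn{x_i} (zero means no link),
#' and `B[i, j]` is the weight of the link from candidate control node
#' \eqn{u_j} to state node \eqn{x_i}.  Each state node may listen to at most
#' one control node, so every row of `B` has at most one nonzero entry.
#'
#' @param A numeric N x N matrix of state-to-state coupling weights.
#' @param B numeric N x P matrix of control-to-state weights, or `NULL` for a
#'   network without candidate controls (P = 0).
#' @param labels optional character vector of N state-node names.
#' @return An object of class `control_network`: a list with elements
#'   `A`, `B`, `N`, `P` and `labels`.
#' @examples
#' A <- matrix(0, 3, 3); A[2, 1] <- 0.5; A[3, 2] <- 0.8
#' net <- control_network(A, diag(3))
#' net$N; net$P
#' @export
control_network <- function(A, B = NULL, labels = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A))
    stop("'A' must be square")
  storage.mode(A) <- "double"
  N <- nrow(A)
  if (N < 1L) stop("need at least one state node")
  if (is.null(B)) B <- matrix(0, N, 0L)
  B <- as.matrix(B)
  storage.mode(B) <- "double"
  if (nrow(B) != N)
    stop("'B' must have as many rows as 'A'")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("all stored weights must be finite")
  if (ncol(B) > 0L && any(rowSums(B != 0) > 1L))
    stop("each state node may be linked to at most one control node ",
         "(every row of 'B' must have at most one nonzero entry)")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != N) stop("'labels' must have length N")
  }
  structure(list(A = A, B = B, N = N, P = ncol(B), labels = labels),
            class = "control_network")
}

#' @export
print.control_network <- function(x, ...) {
  cat(sprintf("control_network: %d state nodes, %d candidate control nodes\n",
              x$N, x$P))
  cat(sprintf("  state links:   %d (incl. %d self-loops)\n",
              sum(x$A != 0), sum(diag(x$A) != 0)))
  cat(sprintf("  control links: %d\n", sum(x$B != 0)))
  invisible(x)
}

## edge tables used by the writers and by the statistics module
state_edge_table <- function(net) {
  idx <- which(net$A != 0, arr.ind = TRUE)
  data.frame(source = idx[, 2L], target = idx[, 1L],
             weight = net$A[idx])
}

control_edge_table <- function(net) {
  idx <- which(net$B != 0, arr.ind = TRUE)
  data.frame(control = idx[, 2L], target = idx[, 1L],
             weight = net$B[idx])
}

#' Read or write a control network
#'
#' Two plain-text formats are supported.
#'
#' \describe{
#' \item{`"tsv"`}{A weighted edge list with columns
#'   `source  target  weight  kind`, where `kind` is `SS` (state to state)
#'   or `CS` (control to state).  Node ids follow the convention that
#'   states are `1..N` and controls are `N+1..N+P`; header comment lines
#'   `# N <n>` and `# P <p>` declare the node counts.  Comment lines start
#'   with `#`.}
#' \item{`"pajek"`}{A Pajek `.net` file with `*Vertices` and `*Arcs`
#'   sections; controls are the vertices with id greater than N, declared in
#'   a leading `% N=<n> P=<p>` comment.  An `*Edges` section, if present, is
#'   symmetrised into directed arc pairs on read.}
#' }
#'
#' Duplicate edges are resolved by keeping the last occurrence, with a
#' warning.  A state node linked to two control nodes is rejected.
#' Writing then reading reproduces the stored weights exactly.
#'
#' @param path file path.
#' @param format `"tsv"` or `"pajek"`.
#' @return `read_network` returns a [control_network()]; `write_network`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, format = c("tsv", "pajek")) {
  format <- match.arg(format)
  if (format == "tsv") read_network_tsv(path) else read_network_pajek(path)
}

#' @rdname read_network
#' @param net a [control_network()].
#' @export
write_network <- function(net, path, format = c("tsv", "pajek")) {
  format <- match.arg(format)
  if (format == "tsv") write_network_tsv(net, path) else
    write_network_pajek(net, path)
  invisible(path)
}

fmt_w <- function(w) sprintf("%.17g", w)

write_network_tsv <- function(net, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# netctrl weighted edge list",
               sprintf("# N %d", net$N), sprintf("# P %d", net$P)), con)
  ss <- state_edge_table(net)
  cs <- control_edge_table(net)
  lines <- character(0)
  if (nrow(ss))
    lines <- c(lines, sprintf("%d\t%d\t%s\tSS", ss$source, ss$target,
                              fmt_w(ss$weight)))
  if (nrow(cs))
    lines <- c(lines, sprintf("%d\t%d\t%s\tCS", net$N + cs$control,
                              cs$target, fmt_w(cs$weight)))
  writeLines(lines, con)
}

read_network_tsv <- function(path) {
  raw <- readLines(path)
  hdr <- raw[startsWith(raw, "#")]
  body <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  grab <- function(key) {
    m <- regmatches(hdr, regexec(sprintf("^#\\s*%s\\s+(\\d+)", key), hdr))
    v <- vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_,
                character(1))
    v <- v[!is.na(v)]
    if (length(v)) as.integer(v[[1L]]) else NA_integer_
  }
  N <- grab("N"); P <- grab("P")
  if (!length(body)) {
    if (is.na(N)) stop("empty edge list without '# N' header")
    if (is.na(P)) P <- 0L
    return(control_network(matrix(0, N, N), matrix(0, N, P)))
  }
  parts <- strsplit(body, "\t| +")
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) stop("malformed edge-list row: ", body[which(bad)[1L]])
  src <- as.integer(vapply(parts, `[[`, "", 1L))
  tgt <- as.integer(vapply(parts, `[[`, "", 2L))
  w <- as.numeric(vapply(parts, `[[`, "", 3L))
  kind <- vapply(parts, `[[`, "", 4L)
  if (any(is.na(src)) || any(is.na(tgt)) || any(is.na(w)))
    stop("malformed edge-list row (non-numeric field)")
  if (!all(kind %in% c("SS", "CS"))) stop("edge kind must be SS or CS")
  ss <- kind == "SS"
  if (is.na(N)) N <- max(src[ss], tgt, 0L)
  if (is.na(P)) P <- max(c(src[!ss] - N, 0L))
  build_network_from_edges(N, P, src, tgt, w, ss)
}

build_network_from_edges <- function(N, P, src, tgt, w, ss) {
  if (any(tgt < 1L | tgt > N))
    stop("dangling target node id")
  if (any(src[ss] < 1L | src[ss] > N))
    stop("dangling state source id")
  if (any(src[!ss] <= N | src[!ss] > N + P))
    stop("control source id out of range ", N + 1L, "..", N + P)
  A <- matrix(0, N, N)
  B <- matrix(0, N, P)
  dup_ss <- duplicated(cbind(src, tgt)[ss, , drop = FALSE])
  dup_cs <- duplicated(cbind(src, tgt)[!ss, , drop = FALSE])
  if (any(dup_ss) || any(dup_cs))
    warning("duplicate edges in input; last occurrence wins")
  A[cbind(tgt[ss], src[ss])] <- w[ss]           # assignment order: last wins
  cs_src <- src[!ss] - N; cs_tgt <- tgt[!ss]
  ## reject a state row fed by two distinct controls before building B
  if (length(cs_tgt)) {
    per_state <- tapply(cs_src, cs_tgt, function(v) length(unique(v)))
    if (any(per_state > 1L))
      stop("state node linked to more than one control node")
  }
  B[cbind(cs_tgt, cs_src)] <- w[!ss]
  control_network(A, B)
}

write_network_pajek <- function(net, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%% netctrl N=%d P=%d", net$N, net$P), con)
  writeLines(sprintf("*Vertices %d", net$N + net$P), con)
  lab <- c(if (is.null(net$labels)) paste0("x", seq_len(net$N)) else
             net$labels,
           paste0("u", seq_len(net$P)))
  writeLines(sprintf('%d "%s"', seq_len(net$N + net$P), lab), con)
  writeLines("*Arcs", con)
  ss <- state_edge_table(net)
  cs <- control_edge_table(net)
  if (nrow(ss))
    writeLines(sprintf("%d %d %s", ss$source, ss$target, fmt_w(ss$weight)),
               con)
  if (nrow(cs))
    writeLines(sprintf("%d %d %s", net$N + cs$control, cs$target,
                       fmt_w(cs$weight)), con)
}

read_network_pajek <- function(path) {
  raw <- trimws(readLines(path))
  m <- regmatches(raw, regexec("^%.*N=(\\d+)\\s+P=(\\d+)", raw))
  hit <- which(vapply(m, length, 1L) == 3L)
  vert_ln <- grep("^\\*Vertices", raw, ignore.case = TRUE)
  if (!length(vert_ln)) stop("not a Pajek file: no *Vertices section")
  nv <- as.integer(sub("^\\*Vertices\\s+(\\d+).*", "\\1", raw[vert_ln[1L]],
                       ignore.case = TRUE))
  if (length(hit)) {
    N <- as.integer(m[[hit[1L]]][2L]); P <- as.integer(m[[hit[1L]]][3L])
    if (N + P != nv) stop("vertex count disagrees with N + P header")
  } else { N <- nv; P <- 0L }
  arcs_ln <- grep("^\\*Arcs", raw, ignore.case = TRUE)
  edges_ln <- grep("^\\*Edges", raw, ignore.case = TRUE)
  sect_ln <- sort(c(arcs_ln, edges_ln, length(raw) + 1L))
  parse_block <- function(start) {
    stop_at <- min(sect_ln[sect_ln > start]) - 1L
    if (stop_at < start + 1L) return(NULL)
    lines <- raw[(start + 1L):stop_at]
    lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
    if (!length(lines)) return(NULL)
    parts <- strsplit(lines, "\\s+")
    if (any(vapply(parts, length, 1L) < 3L))
      stop("malformed arc row in Pajek file")
    data.frame(src = as.integer(vapply(parts, `[[`, "", 1L)),
               tgt = as.integer(vapply(parts, `[[`, "", 2L)),
               w = as.numeric(vapply(parts, `[[`, "", 3L)))
  }
  arcs <- do.call(rbind, lapply(arcs_ln, parse_block))
  und <- do.call(rbind, lapply(edges_ln, parse_block))
  if (!is.null(und) && nrow(und)) {
    if (any(und$src > N | und$tgt > N))
      stop("undirected edges may only join state nodes")
    arcs <- rbind(arcs,
                  und,
                  data.frame(src = und$tgt, tgt = und$src, w = und$w))
  }
  if (is.null(arcs) || !nrow(arcs))
    return(control_network(matrix(0, N, N), matrix(0, N, P)))
  ss <- arcs$src <= N
  build_network_from_edges(N, P, arcs$src, arcs$tgt, arcs$w, ss)
}
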