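#' Sample a truncated power-law degree sequence
#'
#' Draws `n` node degrees i.i.d. from the normalized truncated power law
#' \eqn{P(k) = k^{-\lambda} / \sum_{m=k_{min}}^{k_{max}} m^{-\lambda}}.
#' The default support is \eqn{[2, \lfloor\sqrt{n}\rfloor]}: a minimum degree
#' of 2 keeps every agent connected to at least two peers, and the structural
#' cutoff \eqn{\sqrt{n}} is the largest degree an uncorrelated simple
#' scale-free graph can realize without forced degree correlations.  If the
#' drawn sum is odd (a perfect matching of stubs needs an even number), one
#' uniformly chosen entry is redrawn until parity holds.
#'
#' @param n Number of nodes (>= 4).
#' @param lambda_exp Power-law exponent \eqn{\lambda > 1}; 2.2 is typical of
#'   social-media follower networks.
#' @param k_min,k_max Degree support; `k_max = NULL` means the structural
#'   cutoff `floor(sqrt(n))`.
#' @return Integer vector of length `n` with even sum, all entries in
#'   `[k_min, k_max]`.
#' @examples
#' set.seed(1)
#' deg <- sample_degree_sequence(1000, 2.2)
#' sum(deg) %% 2
#' @export
sample_degree_sequence <- function(n, lambda_exp, k_min = 2L, k_max = NULL) {
  if (length(n) != 1L || !is.numeric(n) || n != round(n) || n < 4)
    abort("`n` must be a single integer >= 4.")
  if (length(lambda_exp) != 1L || !is.numeric(lambda_exp) || lambda_exp <= 1)
    abort("`lambda_exp` must be a single number > 1.")
  n <- as.integer(n)
  if (is.null(k_max)) k_max <- floor(sqrt(n))
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_max < k_min || k_max > n - 1L)
    abort("degree support must satisfy 1 <= k_min <= k_max <= n - 1.")
  support <- k_min:k_max
  pmf <- support^(-lambda_exp)
  pmf <- pmf / sum(pmf)
  degrees <- sample(support, n, replace = TRUE, prob = pmf)
  while (sum(degrees) %% 2L != 0L) {
    i <- sample.int(n, 1L)
    degrees[i] <- sample(support, 1L, prob = pmf)
  }
  as.integer(degrees)
}

#' Analytic truncated power-law pmf
#'
#' Direct normalization of \eqn{k^{-\lambda}} over the integer support; used
#' as the closed-form reference for the generator.
#'
#' @inheritParams sample_degree_sequence
#' @param k Integer degrees at which to evaluate the pmf.
#' @return Numeric vector of probabilities (zero outside the support).
#' @export
degree_pmf <- function(k, lambda_exp, k_min = 2L, k_max) {
  support <- k_min:k_max
  z <- sum(support^(-lambda_exp))
  out <- ifelse(k >= k_min & k <= k_max, k^(-lambda_exp) / z, 0)
  as.numeric(out)
}

new_qn_graph <- function(n, ptr, nbr) {
  structure(
    list(n = as.integer(n), ptr = as.integer(ptr), nbr = as.integer(nbr),
         degree = as.integer(diff(ptr))),
    class = "qn_graph")
}

#' Build a simple graph from a degree sequence (Molloy-Reed)
#'
#' Configuration-model stub matching: every node receives as many stubs as
#' its degree; stubs are paired uniformly at random, and pairings that would
#' create a self-loop or a parallel edge are rejected and re-paired so the
#' realized degrees equal the request exactly.  After `max_retries` full
#' restarts without a complete matching the construction fails.
#'
#' @param degrees Integer degree sequence with even sum.
#' @param max_retries Full matching restarts before giving up.
#' @return A `qn_graph`: node count `n`, per-node `degree`, and a compressed
#'   adjacency (`ptr` offsets, sorted 1-based `nbr` ids).
#' @examples
#' g <- build_graph(c(2L, 2L, 2L))  # the triangle
#' g$degree
#' @export
build_graph <- function(degrees, max_retries = 100L) {
  degrees <- as.integer(degrees)
  if (anyNA(degrees) || any(degrees < 1L))
    abort("all degrees must be positive integers.")
  if (sum(degrees) %% 2L != 0L) abort("degree sequence must have even sum.")
  if (any(degrees > length(degrees) - 1L))
    abort("a degree exceeds n - 1: impossible in a simple graph.")
  res <- build_graph_cpp(degrees, as.integer(max_retries))
  if (is.null(res$ptr))
    abort(sprintf("stub matching failed after %d restarts; resample the degree sequence.",
                  max_retries))
  g <- new_qn_graph(length(degrees), res$ptr, res$nbr)
  stopifnot(identical(g$degree, degrees))
  g
}

#' Generate a scale-free network
#'
#' Convenience wrapper: samples a truncated power-law degree sequence and
#' builds the Molloy-Reed graph, resampling the sequence if stub matching
#' fails (rare at the default cutoff).
#'
#' @inheritParams sample_degree_sequence
#' @inheritParams build_graph
#' @param max_resample Fresh degree sequences to try before erroring.
#' @return A `qn_graph`.
#' @export
generate_network <- function(n, lambda_exp, k_min = 2L, k_max = NULL,
                             max_retries = 100L, max_resample = 20L) {
  for (r in seq_len(max_resample)) {
    degrees <- sample_degree_sequence(n, lambda_exp, k_min, k_max)
    g <- tryCatch(build_graph(degrees, max_retries), error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
  abort("could not realize a simple graph after resampling the degree sequence.")
}

#' Neighbors of a node
#'
#' @param graph A `qn_graph`.
#' @param i Node index (1-based).
#' @return Integer vector of neighbor ids.
#' @export
neighbors <- function(graph, i) {
  stopifnot(inherits(graph, "qn_graph"), i >= 1L, i <= graph$n)
  lo <- graph$ptr[i] + 1L
  hi <- graph$ptr[i + 1L]
  if (hi < lo) integer(0) else graph$nbr[lo:hi]
}

#' @export
print.qn_graph <- function(x, ...) {
  cat(sprintf("<qn_graph> %d nodes, %d edges, degree range [%d, %d]\n",
              x$n, length(x$nbr) %/% 2L, min(x$degree), max(x$degree)))
  invisible(x)
}

#' Read / write an undirected edge list
#'
#' Whitespace-separated text, one undirected edge per line, 0-based node ids,
#' no duplicate or self edges.
#'
#' @param graph A `qn_graph`.
#' @param path File path.
#' @return `write_edgelist()` returns `path` invisibly; `read_edgelist()`
#'   returns a `qn_graph`.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "qn_graph"))
  src <- rep.int(seq_len(graph$n), graph$degree)
  dst <- graph$nbr
  keep <- src < dst
  writeLines(paste(src[keep] - 1L, dst[keep] - 1L), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @param n_nodes Optional node count (defaults to max id + 1, so trailing
#'   isolated nodes need it stated).
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  m <- utils::read.table(path, header = FALSE,
                         colClasses = "integer")
  src <- m[[1]] + 1L
  dst <- m[[2]] + 1L
  if (any(src == dst)) abort("edge list contains a self loop.")
  if (is.null(n_nodes)) n_nodes <- max(src, dst)
  key <- pmin(src, dst) * (n_nodes + 1) + pmax(src, dst)
  if (anyDuplicated(key)) abort("edge list contains a duplicate edge.")
  graph_from_edges(n_nodes, cbind(src, dst))
}

# Build a qn_graph from a 1-based edge matrix (internal; also used by fixtures).
graph_from_edges <- function(n, edges) {
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  o <- order(src, dst)
  deg <- tabulate(src, nbins = n)
  new_qn_graph(n, c(0L, cumsum(deg)), dst[o])
}
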