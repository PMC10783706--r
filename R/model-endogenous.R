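#' Influence weight of a neighbor
#'
#' In the goal-function model the opinion of a better-connected neighbor
#' carries more weight: \eqn{A_{ij} = \deg(j)/\deg(i)} is the influence of
#' `j` on `i`, so hubs pull strongly on their low-degree neighbors.
#'
#' @param graph A `qn_graph`.
#' @param i,j Target agent and one of its neighbors.
#' @return `deg(j)/deg(i)`, a positive real.
#' @export
influence_weight <- function(graph, i, j) {
  stopifnot(inherits(graph, "qn_graph"))
  if (!(j %in% neighbors(graph, i)))
    abort(sprintf("node %d is not a neighbor of node %d.", j, i))
  graph$degree[j] / graph$degree[i]
}

#' Number of non-silent neighbors
#'
#' \eqn{m = \sum_{j\in\Gamma_i} |\omega_j|}, the count of neighbors currently
#' expressing a non-null opinion.  This is the normalizer that enters the
#' goal function's social term.
#'
#' @param pop Population tibble.
#' @param graph A `qn_graph`.
#' @param i Agent index.
#' @return A non-negative integer, at most `deg(i)`.
#' @export
expressing_count <- function(pop, graph, i) {
  check_pop_graph(pop, graph)
  sum(abs(pop$omega[neighbors(graph, i)]))
}

# Anchor of the goal function: the value in [-(1+max A), ...] the candidate
# opinion is pulled towards.  Two readings of the typeset formula are kept:
# "social" divides only the social sum by (m + 1); "full" divides the whole
# of sigma*b + social.  With no expressing neighbors both give sigma*b.
goal_anchor <- function(pop, graph, i, parse = c("full", "social")) {
  parse <- match.arg(parse)
  nb <- neighbors(graph, i)
  w <- pop$omega[nb]
  social <- sum(graph$degree[nb] / graph$degree[i] * w)
  m <- sum(abs(w))
  if (parse == "social") pop$sigma[i] * pop$b[i] + social / (m + 1)
  else (pop$sigma[i] * pop$b[i] + social) / (m + 1)
}

#' Evaluate the goal function for candidate opinions
#'
#' The goal (payoff) of expressing \eqn{\omega} is
#' \eqn{G(\omega) = -|v - \omega|} where the anchor \eqn{v} combines the
#' agent's conviction \eqn{\sigma_i b_i} with the degree-weighted opinions
#' of its expressing neighbors, damped by how many of them are speaking
#' (\eqn{m} non-silent neighbors).  The typeset formula admits two readings,
#' both kept behind the `parse` flag: the default `"full"` normalizes the
#' whole sum, \eqn{v = (\sigma_i b_i + \sum_j A_{ij}\omega_j)/(m + 1)};
#' `"social"` normalizes the social term only,
#' \eqn{v = \sigma_i b_i + \sum_j A_{ij}\omega_j/(m + 1)}.  They coincide
#' when no neighbor is expressing.  Payoffs are never positive and vanish
#' only when the candidate hits the anchor exactly.
#'
#' @inheritParams expressing_count
#' @param candidate Candidate opinions, a subset of `c(-1, 0, 1)`.
#' @param parse Which normalization of the anchor to use.
#' @return A tibble with one row per candidate: `candidate`, `anchor`,
#'   `payoff`.
#' @export
goal <- function(pop, graph, i, candidate = c(-1L, 0L, 1L),
                 parse = c("full", "social")) {
  check_pop_graph(pop, graph)
  if (!all(candidate %in% c(-1L, 0L, 1L)))
    abort("candidates must lie in {-1, 0, +1}.")
  v <- goal_anchor(pop, graph, i, parse)
  tibble::tibble(candidate = as.integer(candidate), anchor = v,
                 payoff = -abs(v - candidate))
}

#' Best response of an agent
#'
#' Hard-core agents skip the maximization and always express their belief
#' \eqn{-1}.  Everyone else expresses the candidate in \eqn{\{-1, 0, +1\}}
#' nearest to the anchor (the argmax of the goal function); an anchor exactly
#' half-way between two candidates is resolved by a fair coin.
#'
#' @inheritParams goal
#' @return An integer in `c(-1L, 0L, 1L)`.
#' @export
best_response <- function(pop, graph, i, parse = c("full", "social")) {
  check_pop_graph(pop, graph)
  if (pop$is_hc[i]) return(-1L)
  v <- goal_anchor(pop, graph, i, match.arg(parse))
  eps <- 1e-12
  if (abs(v - 0.5) < eps) return(if (runif(1) < 0.5) 1L else 0L)
  if (abs(v + 0.5) < eps) return(if (runif(1) < 0.5) -1L else 0L)
  if (v > 0.5) 1L else if (v < -0.5) -1L else 0L
}

#' Advance a population by one time unit (endogenous model)
#'
#' Same asynchronous random sequential scheduling as the exogenous model,
#' but each selected agent plays its best response under the goal function.
#'
#' @inheritParams time_unit_exogenous
#' @inheritParams goal
#' @return The updated population tibble.
#' @export
time_unit_endogenous <- function(pop, graph, steps = graph$n,
                                 parse = c("full", "social")) {
  advance(pop, graph, model = "endogenous", steps = steps,
          parse = match.arg(parse))
}

#' Run the endogenous (goal-function) dynamics
#'
#' As [run_exogenous()], with each elementary event replaced by a
#' best-response move that may be silence.
#'
#' @inheritParams run_exogenous
#' @inheritParams goal
#' @return A `qn_trajectory` tibble; see [run_exogenous()].
#' @export
run_endogenous <- function(pop, graph, horizon = 200L, window = 20L,
                           tolerance = 1e-4, parse = c("full", "social")) {
  run_model(pop, graph, model = "endogenous", parse = match.arg(parse),
            horizon = horizon, window = window, tolerance = tolerance)
}
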