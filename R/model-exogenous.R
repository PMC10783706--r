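#' One expression event under the majority-conformity model
#'
#' The selected agent voices its private belief with probability
#' \eqn{\sigma_i}; otherwise it conforms to the sign of the sum of its
#' neighbors' currently expressed opinions.  A zero sum among neighbors that
#' have expressed at some point is resolved by a fair coin; if no neighbor
#' has ever expressed, the agent emits the null opinion \eqn{\omega = 0} and
#' keeps its never-expressed status.
#'
#' This is the plain-R reference for a single elementary step; whole
#' trajectories run through the compiled loop in [run_exogenous()].
#'
#' @param pop Population tibble.
#' @param graph A `qn_graph`.
#' @param i Index of the selected agent.
#' @return The updated population tibble.
#' @export
exogenous_expression <- function(pop, graph, i) {
  check_pop_graph(pop, graph)
  stopifnot(i >= 1L, i <= graph$n)
  if (graph$degree[i] == 0L)
    abort("isolated node: the conformity rule needs at least one neighbor.")
  if (runif(1) < pop$sigma[i]) {
    pop$omega[i] <- pop$b[i]
  } else {
    nb <- neighbors(graph, i)
    s <- sum(pop$omega[nb])
    if (s > 0) pop$omega[i] <- 1L
    else if (s < 0) pop$omega[i] <- -1L
    else if (any(pop$has_expressed[nb]))
      pop$omega[i] <- if (runif(1) < 0.5) 1L else -1L
    else pop$omega[i] <- 0L
  }
  if (pop$omega[i] != 0L) pop$has_expressed[i] <- TRUE
  pop
}

#' Advance a population by one time unit (exogenous model)
#'
#' A time unit is `n` elementary expression events, each on an agent chosen
#' uniformly at random with replacement (asynchronous random sequential
#' update): later events within the unit see the outcomes of earlier ones.
#'
#' @inheritParams exogenous_expression
#' @param steps Number of elementary events; defaults to one time unit.
#' @return The updated population tibble.
#' @export
time_unit_exogenous <- function(pop, graph, steps = graph$n) {
  advance(pop, graph, model = "exogenous", steps = steps)
}

#' Run the exogenous (majority-conformity) dynamics
#'
#' Runs up to `horizon` time units, recording a snapshot per unit, and stops
#' early once the average expressed opinion has moved by less than
#' `tolerance` over the trailing `window` time units.
#'
#' @inheritParams exogenous_expression
#' @param horizon Maximum number of time units.
#' @param window,tolerance Stationarity rule on \eqn{\langle\omega\rangle}.
#' @return A `qn_trajectory` tibble with columns `t`, `mean_omega`, `r`,
#'   `frac_plus`, `frac_minus`, `frac_silent` (row `t = 0` is the initial
#'   all-silent state).  The final population, the constant mean belief and
#'   convergence info ride along as attributes.
#' @examples
#' set.seed(7)
#' g <- generate_network(300, 2.2)
#' pop <- assign_population(g, 3)
#' traj <- run_exogenous(pop, g, horizon = 50)
#' tail(traj, 2)
#' @export
run_exogenous <- function(pop, graph, horizon = 200L, window = 20L,
                          tolerance = 1e-4) {
  run_model(pop, graph, model = "exogenous", parse = "social",
            horizon = horizon, window = window, tolerance = tolerance)
}
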