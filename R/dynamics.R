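model_code <- function(model) match(model, c("exogenous", "endogenous")) - 1L
parse_code <- function(parse) match(parse, c("social", "full")) - 1L

#' Advance a population by a fixed number of elementary events
#'
#' Low-level driver shared by both models: `steps` agents are drawn
#' uniformly at random with replacement and updated sequentially through the
#' compiled step kernel.  Randomness comes from R's RNG, so `set.seed()`
#' makes runs exactly reproducible.
#'
#' @param pop Population tibble.
#' @param graph A `qn_graph`.
#' @param model `"exogenous"` (majority conformity) or `"endogenous"`
#'   (goal-function best response).
#' @param steps Number of elementary events (`graph$n` = one time unit).
#' @param parse Goal-function anchor normalization (endogenous model only).
#' @return The updated population tibble.
#' @export
advance <- function(pop, graph, model = c("exogenous", "endogenous"),
                    steps = graph$n, parse = c("full", "social")) {
  check_pop_graph(pop, graph)
  model <- match.arg(model)
  parse <- match.arg(parse)
  res <- steps_cpp(graph$ptr, graph$nbr, pop$b, pop$sigma, pop$omega,
                   as.integer(pop$has_expressed), as.integer(pop$is_hc),
                   model_code(model), parse_code(parse), as.integer(steps))
  pop$omega <- res$omega
  pop$has_expressed <- as.logical(res$expressed)
  pop
}

run_model <- function(pop, graph, model, parse, horizon, window, tolerance) {
  check_pop_graph(pop, graph)
  if (horizon < 1L) abort("`horizon` must be at least 1 time unit.")
  res <- run_dynamics_cpp(graph$ptr, graph$nbr, pop$b, pop$sigma, pop$omega,
                          as.integer(pop$has_expressed),
                          as.integer(pop$is_hc), model_code(model),
                          parse_code(parse), as.integer(horizon),
                          as.integer(window), tolerance)
  traj <- tibble::as_tibble(res$traj, .name_repair = "minimal")
  names(traj) <- c("t", "mean_omega", "r", "frac_plus", "frac_minus",
                   "frac_silent")
  pop$omega <- res$omega
  pop$has_expressed <- as.logical(res$expressed)
  structure(traj,
            class = c("qn_trajectory", class(traj)),
            final_pop = pop,
            mean_belief = mean(pop$b),
            model = model, parse = parse,
            t_stop = res$t_stop, converged = res$converged)
}

#' Final population of a finished run
#'
#' @param traj A `qn_trajectory` returned by [run_exogenous()] or
#'   [run_endogenous()].
#' @return The population tibble at the last recorded time unit.
#' @export
final_population <- function(traj) {
  stopifnot(inherits(traj, "qn_trajectory"))
  attr(traj, "final_pop")
}

#' Export a trajectory
#'
#' CSV with header `t,mean_omega,r,frac_plus,frac_minus,frac_silent`, one row
#' per time unit including the initial `t = 0` state.
#'
#' @param traj A `qn_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "qn_trajectory"))
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}
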