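#' Assign agents to a network: hard-core minority and conforming majority
#'
#' Every node whose degree equals `k_c` hosts a hard-core (HC) agent: private
#' belief \eqn{b = -1}, maximal strength \eqn{\sigma = 1}, so it always voices
#' its dissent.  Every other node hosts a majority agent with \eqn{b = +1}
#' and strength drawn uniformly on \eqn{(0, 1]}.  All agents start silent
#' (\eqn{\omega = 0}) and are flagged as never having expressed.
#'
#' @param graph A `qn_graph`.
#' @param k_c Degree on which the hard-core minority sits.
#' @return A population tibble with columns `node`, `degree`, `b`, `sigma`,
#'   `omega`, `is_hc`, `has_expressed`.
#' @examples
#' set.seed(1)
#' g <- generate_network(500, 2.2)
#' pop <- assign_population(g, 3)
#' mean(pop$is_hc)
#' @export
assign_population <- function(graph, k_c) {
  stopifnot(inherits(graph, "qn_graph"))
  k_c <- as.integer(k_c)
  is_hc <- graph$degree == k_c
  if (!any(is_hc))
    abort(sprintf("empty hard core: no node has degree %d.", k_c),
          class = "quietnet_empty_hard_core")
  n <- graph$n
  sigma <- 1 - runif(n)            # uniform on (0, 1]: excludes exact 0
  sigma[is_hc] <- 1
  tibble::tibble(
    node = seq_len(n),
    degree = graph$degree,
    b = ifelse(is_hc, -1L, 1L),
    sigma = sigma,
    omega = 0L,
    is_hc = is_hc,
    has_expressed = FALSE)
}

#' Hard-core prevalence
#'
#' Fraction of agents flagged as hard core.
#'
#' @param pop A population tibble.
#' @return A fraction in `[0, 1]`.
#' @export
hc_prevalence <- function(pop) {
  check_population(pop)
  if (nrow(pop) == 0L) abort("empty population.")
  mean(pop$is_hc)
}

#' Export a population table
#'
#' CSV with deterministic column order `node,degree,b,sigma,is_hc`
#' (0-based node ids to match the edge-list format).
#'
#' @param pop A population tibble.
#' @param path File path.
#' @export
write_population <- function(pop, path) {
  check_population(pop)
  out <- tibble::tibble(node = pop$node - 1L, degree = pop$degree,
                        b = pop$b, sigma = pop$sigma, is_hc = pop$is_hc)
  readr::write_csv(out, path)
  invisible(path)
}

check_population <- function(pop) {
  need <- c("node", "degree", "b", "sigma", "omega", "is_hc", "has_expressed")
  if (!is.data.frame(pop) || !all(need %in% names(pop)))
    abort(paste0("`pop` must be a population tibble with columns ",
                 paste(need, collapse = ", "), "."))
  invisible(pop)
}

check_pop_graph <- function(pop, graph) {
  check_population(pop)
  stopifnot(inherits(graph, "qn_graph"))
  if (nrow(pop) != graph$n)
    abort("population and graph sizes differ.")
  invisible(NULL)
}
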