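#' Miniature deterministic fixtures
#'
#' Hand-sized graphs with fully specified agent states, used by the unit
#' tests and the exact-enumeration oracle.  All strengths are hard-coded so
#' every expected number is checkable by hand:
#' \describe{
#'   \item{`triangle`}{3 mutually connected agents, one of them hard core.}
#'   \item{`star5`}{a hub with 4 leaves (\eqn{K_{1,4}}), hub expressing +1.}
#'   \item{`path4`}{a 4-node path; its endpoints have degree 1, below the
#'     generator's minimum, so it exists only as a test graph and is built
#'     directly from its edge list rather than through [build_graph()].}
#'   \item{`two_hubs`}{two degree-4 hubs (one hard core) sharing 3 leaves.}
#' }
#'
#' @param name One of `"triangle"`, `"star5"`, `"path4"`, `"two_hubs"`.
#' @return A `qn_fixture`: list with `name`, `graph`, `pop`.
#' @examples
#' fx <- make_fixture("triangle")
#' fx$pop
#' @export
make_fixture <- function(name = c("triangle", "star5", "path4", "two_hubs")) {
  name <- match.arg(name)
  fixture_pop <- function(degree, b, sigma, omega, is_hc, expressed) {
    tibble::tibble(node = seq_along(b), degree = degree, b = as.integer(b),
                   sigma = sigma, omega = as.integer(omega), is_hc = is_hc,
                   has_expressed = expressed)
  }
  if (name == "triangle") {
    graph <- graph_from_edges(3L, rbind(c(1, 2), c(1, 3), c(2, 3)))
    pop <- fixture_pop(graph$degree,
                       b = c(1, 1, -1), sigma = c(0.7, 0.4, 1),
                       omega = c(1, 0, -1), is_hc = c(FALSE, FALSE, TRUE),
                       expressed = c(TRUE, FALSE, TRUE))
  } else if (name == "star5") {
    graph <- graph_from_edges(5L, cbind(1, 2:5))
    pop <- fixture_pop(graph$degree,
                       b = c(1, 1, 1, 1, 1),
                       sigma = c(0.6, 0.25, 0.5, 0.75, 0.9),
                       omega = c(1, 0, 0, 0, 0), is_hc = rep(FALSE, 5),
                       expressed = c(TRUE, rep(FALSE, 4)))
  } else if (name == "path4") {
    graph <- graph_from_edges(4L, rbind(c(1, 2), c(2, 3), c(3, 4)))
    pop <- fixture_pop(graph$degree,
                       b = c(1, 1, -1, 1), sigma = c(0.3, 0.8, 1, 0.55),
                       omega = c(0, 1, -1, 0),
                       is_hc = c(FALSE, FALSE, TRUE, FALSE),
                       expressed = c(FALSE, TRUE, TRUE, FALSE))
  } else {
    graph <- graph_from_edges(5L, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                                        c(2, 3), c(2, 4), c(2, 5)))
    pop <- fixture_pop(graph$degree,
                       b = c(-1, 1, 1, 1, 1),
                       sigma = c(1, 0.8, 0.2, 0.6, 0.9),
                       omega = c(-1, 1, 0, 0, 0),
                       is_hc = c(TRUE, rep(FALSE, 4)),
                       expressed = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  }
  structure(list(name = name, graph = graph, pop = pop),
            class = "qn_fixture")
}

#' Exact one-step transition distribution
#'
#' Enumerates every outcome of a single elementary event on a small fixture
#' by summing over the uniform agent choice and each branch of the update
#' rule (belief/conformity and the tie coin for the exogenous model; the
#' half-integer-anchor coin for the endogenous one).  Serves as the
#' independent oracle against which simulated one-step frequencies are
#' checked.
#'
#' @param fixture A `qn_fixture` with at most 5 nodes.
#' @param model `"exogenous"` or `"endogenous"`.
#' @param parse Goal-function anchor normalization (endogenous model).
#' @return A tibble with one row per reachable state: `omega` and
#'   `expressed` (comma-separated state strings) and `probability`
#'   (summing to 1).
#' @export
enumerate_one_step <- function(fixture, model = c("exogenous", "endogenous"),
                               parse = c("full", "social")) {
  stopifnot(inherits(fixture, "qn_fixture"))
  model <- match.arg(model)
  parse <- match.arg(parse)
  pop <- fixture$pop
  graph <- fixture$graph
  n <- graph$n
  if (n > 5L) abort("enumeration is limited to fixtures with <= 5 nodes.")

  acc <- new.env(parent = emptyenv())
  add <- function(p, omega, expressed) {
    if (p <= 0) return(invisible())
    key <- paste(paste(omega, collapse = ","),
                 paste(as.integer(expressed), collapse = ","), sep = "|")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  outcome <- function(p, i, w) {
    omega <- pop$omega
    expressed <- pop$has_expressed
    omega[i] <- w
    if (w != 0L) expressed[i] <- TRUE
    add(p, omega, expressed)
  }

  for (i in seq_len(n)) {
    p_i <- 1 / n
    if (model == "exogenous") {
      outcome(p_i * pop$sigma[i], i, pop$b[i])            # belief branch
      pc <- p_i * (1 - pop$sigma[i])                      # conformity branch
      nb <- neighbors(graph, i)
      s <- sum(pop$omega[nb])
      if (s > 0) outcome(pc, i, 1L)
      else if (s < 0) outcome(pc, i, -1L)
      else if (any(pop$has_expressed[nb])) {
        outcome(pc / 2, i, 1L)
        outcome(pc / 2, i, -1L)
      } else outcome(pc, i, 0L)
    } else {
      if (pop$is_hc[i]) {
        outcome(p_i, i, -1L)
      } else {
        v <- goal_anchor(pop, graph, i, parse)
        eps <- 1e-12
        if (abs(v - 0.5) < eps) {
          outcome(p_i / 2, i, 1L); outcome(p_i / 2, i, 0L)
        } else if (abs(v + 0.5) < eps) {
          outcome(p_i / 2, i, -1L); outcome(p_i / 2, i, 0L)
        } else outcome(p_i, i, if (v > 0.5) 1L else if (v < -0.5) -1L else 0L)
      }
    }
  }

  keys <- ls(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  tibble::tibble(
    omega = purrr::map_chr(parts, 1),
    expressed = purrr::map_chr(parts, 2),
    probability = purrr::map_dbl(keys, function(k) acc[[k]])) |>
    dplyr::arrange(.data$omega, .data$expressed)
}
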