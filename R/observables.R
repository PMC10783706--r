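#' Snapshot of the system state
#'
#' The quantities describing one instant of either dynamics:
#' \describe{
#'   \item{`mean_omega`}{average expressed opinion
#'     \eqn{\langle\omega\rangle = \sum_i \omega_i / N} over all agents
#'     (silent agents contribute 0);}
#'   \item{`mean_belief`}{average private belief \eqn{\langle b\rangle},
#'     constant in time;}
#'   \item{`r`}{local opinion climate: the population mean of each agent's
#'     neighborhood average \eqn{\Delta_i = \sum_{j\in\Gamma_i}\omega_j /
#'     \deg(i)} — what agents actually see around themselves;}
#'   \item{`frac_plus`, `frac_minus`, `frac_silent`}{fractions of agents by
#'     expressed state; they sum to one and
#'     `mean_omega = frac_plus - frac_minus`.}
#' }
#'
#' @param pop Population tibble.
#' @param graph A `qn_graph` (every node needs at least one neighbor).
#' @return A one-row tibble.
#' @examples
#' fx <- make_fixture("star5")
#' snapshot(fx$pop, fx$graph)  # r = 0.8 on the star with a +1 center
#' @export
snapshot <- function(pop, graph) {
  check_pop_graph(pop, graph)
  if (any(graph$degree == 0L))
    abort("local climate is undefined for isolated nodes.")
  omega <- pop$omega
  nbr_sum <- as.vector(rowsum(as.numeric(omega[graph$nbr]),
                              rep.int(seq_len(graph$n), graph$degree)))
  tibble::tibble(
    mean_omega = mean(omega),
    mean_belief = mean(pop$b),
    r = mean(nbr_sum / graph$degree),
    frac_plus = mean(omega == 1L),
    frac_minus = mean(omega == -1L),
    frac_silent = mean(omega == 0L))
}

#' Decompose opinion misperception
#'
#' Splits the gap between what the population privately believes and what it
#' locally perceives into its components:
#' private-vs-public mismatch \eqn{\langle b\rangle - \langle\omega\rangle},
#' total misperception \eqn{\langle b\rangle - r}, and the topological
#' contribution \eqn{r - \langle\omega\rangle} (the part due purely to how
#' expressed opinions are arranged on the network).  The three satisfy
#' \eqn{(\langle b\rangle - r) = (\langle b\rangle - \langle\omega\rangle) -
#' (r - \langle\omega\rangle)}.
#'
#' @param snap A one-row snapshot tibble (or any list with `mean_omega` and
#'   `r`).
#' @param mean_belief The constant average belief; defaults to the
#'   snapshot's own `mean_belief` column when present.
#' @return A one-row tibble with `private_public_mismatch`, `misperception`,
#'   `topo_contribution`.
#' @export
misperception <- function(snap, mean_belief = snap$mean_belief) {
  if (is.null(mean_belief))
    abort("supply `mean_belief` when the snapshot lacks it.")
  tibble::tibble(
    private_public_mismatch = mean_belief - snap$mean_omega,
    misperception = mean_belief - snap$r,
    topo_contribution = snap$r - snap$mean_omega)
}

#' Silenced agents per hard-core agent
#'
#' On a final configuration, the number of silent agents (\eqn{\omega = 0},
#' regardless of history) divided by the number of hard-core agents: the
#' leverage of one committed dissenter in muting the majority.
#'
#' @param pop Population tibble with at least one hard-core agent.
#' @return A non-negative real.
#' @export
silenced_per_hc <- function(pop) {
  check_population(pop)
  n_hc <- sum(pop$is_hc)
  if (n_hc == 0L) abort("no hard-core agents in the population.")
  sum(pop$omega == 0L) / n_hc
}

#' Mean number of nearest neighbors of hard-core agents
#'
#' Companion statistic to [silenced_per_hc()]: the average degree of the
#' hard-core agents, i.e. how many agents each one can silence directly.
#'
#' @inheritParams silenced_per_hc
#' @return A positive real.
#' @export
hc_neighbor_count <- function(pop) {
  check_population(pop)
  if (!any(pop$is_hc)) abort("no hard-core agents in the population.")
  mean(pop$degree[pop$is_hc])
}
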