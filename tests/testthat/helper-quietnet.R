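# Shared test utilities: state hashing and simulator-vs-oracle frequency
# comparison for one-step transition distributions.

state_key <- function(omega, expressed) {
  paste(paste(omega, collapse = ","),
        paste(as.integer(expressed), collapse = ","), sep = "|")
}

# Empirical one-step state frequencies from the compiled simulator.
sim_one_step_freq <- function(fixture, model, parse = "full",
                              ntrials = 20000L) {
  g <- fixture$graph
  pop <- fixture$pop
  res <- quietnet:::one_step_trials_cpp(
    g$ptr, g$nbr, pop$b, pop$sigma, pop$omega,
    as.integer(pop$has_expressed), as.integer(pop$is_hc),
    quietnet:::model_code(model), quietnet:::parse_code(parse),
    as.integer(ntrials))
  keys <- vapply(seq_len(ntrials), function(t) {
    state_key(res$omega[t, ], res$expressed[t, ])
  }, character(1))
  tab <- table(keys)
  tibble::tibble(key = names(tab), freq = as.vector(tab) / ntrials)
}

# Assert simulated frequencies agree with the exact enumeration within
# k_sigma multinomial standard errors, and that no unreachable state occurs.
expect_matches_enumeration <- function(fixture, model, parse = "full",
                                       ntrials = 20000L, k_sigma = 4) {
  oracle <- enumerate_one_step(fixture, model, parse)
  oracle$key <- state_key_vec(oracle$omega, oracle$expressed)
  sim <- sim_one_step_freq(fixture, model, parse, ntrials)
  expect_true(all(sim$key %in% oracle$key),
              label = sprintf("%s/%s: simulator reaches only enumerated states",
                              fixture$name, model))
  for (r in seq_len(nrow(oracle))) {
    p <- oracle$probability[r]
    f <- sim$freq[match(oracle$key[r], sim$key)]
    if (is.na(f)) f <- 0
    tol <- k_sigma * sqrt(p * (1 - p) / ntrials) + 1e-12
    expect_lt(abs(f - p), max(tol, 1e-6))
  }
  invisible(NULL)
}

state_key_vec <- function(omega_str, expressed_str) {
  paste(omega_str, expressed_str, sep = "|")
}

# Small custom graph used by the goal-function hand examples: node 1 has
# degree 2 with one degree-4 and one degree-2 neighbor.
hand_graph <- function() {
  quietnet:::graph_from_edges(
    6L, rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(2, 6), c(3, 4)))
}

hand_pop <- function(graph, omega = c(0L, 1L, 0L, 0L, 0L, 0L),
                     sigma = c(0.5, 0.9, 0.3, 0.4, 0.6, 0.7)) {
  tibble::tibble(node = seq_len(graph$n), degree = graph$degree,
                 b = rep(1L, graph$n), sigma = sigma, omega = omega,
                 is_hc = rep(FALSE, graph$n),
                 has_expressed = omega != 0L)
}
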