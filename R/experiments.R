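#' Configuration for ensemble experiments
#'
#' Bundles every knob of a sweep over the hard-core degree \eqn{K_c}:
#' which dynamics to run, the network parameters, the stationarity rule,
#' the number of independent realizations per \eqn{K_c} and the master
#' seed from which per-realization child seeds are derived.
#'
#' @param model `"exogenous"` or `"endogenous"`.
#' @param n Number of agents.
#' @param lambda_exp Degree-distribution exponent.
#' @param kc_list Hard-core degrees to sweep; each must lie within the
#'   degree support `[k_min, k_max]`.
#' @param horizon,window,tolerance Stationarity rule (see [run_exogenous()]).
#' @param realizations Independent realizations per \eqn{K_c} (fresh
#'   network, population and dynamics each time).
#' @param seed Master seed.
#' @param parse Goal-function anchor normalization (endogenous model).
#' @param outputs Optional directory: when set, [sweep_kc()] writes the
#'   ensemble CSV and a JSON manifest there.
#' @param k_min,k_max Degree support (`NULL` = structural cutoff).
#' @return A `qn_config` list.
#' @examples
#' cfg <- model_config("endogenous", n = 500, realizations = 5,
#'                     kc_list = c(2, 3), seed = 42)
#' @export
model_config <- function(model = c("exogenous", "endogenous"), n = 5000L,
                         lambda_exp = 2.2, kc_list = c(2L, 3L, 5L, 10L, 20L),
                         horizon = 200L, window = 20L, tolerance = 1e-4,
                         realizations = 100L, seed = 1L,
                         parse = c("full", "social"), outputs = NULL,
                         k_min = 2L, k_max = NULL) {
  model <- match.arg(model)
  parse <- match.arg(parse)
  if (is.null(k_max)) k_max <- floor(sqrt(n))
  if (realizations < 1L) abort("`realizations` must be >= 1.")
  kc_list <- as.integer(kc_list)
  if (any(kc_list < k_min) || any(kc_list > k_max))
    abort(sprintf("every K_c must lie in the degree support [%d, %d].",
                  k_min, k_max))
  structure(
    list(model = model, n = as.integer(n), lambda_exp = lambda_exp,
         kc_list = kc_list, horizon = as.integer(horizon),
         window = as.integer(window), tolerance = tolerance,
         realizations = as.integer(realizations), seed = as.integer(seed),
         parse = parse, outputs = outputs, k_min = as.integer(k_min),
         k_max = as.integer(k_max)),
    class = "qn_config")
}

# Deterministic child seed: realizations are reproducible piecewise, so an
# ensemble can be recomputed (or parallelized) one realization at a time
# without changing any result.  Kept well below 2^31.
child_seed <- function(seed, k_c, realization, model) {
  m <- if (model == "exogenous") 1 else 2
  as.integer((as.double(seed %% 100003L) * 20011 +
                k_c * 7919 + realization * 104729 + m) %% 2147483587)
}

#' Run a single realization
#'
#' Generates a fresh network (regenerated until at least one node of degree
#' `k_c` exists, counting regenerations), assigns the population, runs the
#' chosen dynamics to stationarity/horizon, and summarizes the final state.
#'
#' @param config A `qn_config`.
#' @param k_c Hard-core degree.
#' @param realization Realization index (drives the child seed).
#' @return A list: `finals` (one-row tibble of final observables),
#'   `trajectory` (the `qn_trajectory`), `regenerations`, `seed`.
#' @export
run_realization <- function(config, k_c, realization = 1L) {
  stopifnot(inherits(config, "qn_config"))
  set.seed(child_seed(config$seed, k_c, realization, config$model))
  regen <- 0L
  repeat {
    g <- generate_network(config$n, config$lambda_exp, config$k_min,
                          config$k_max)
    if (any(g$degree == k_c)) break
    regen <- regen + 1L
    if (regen > 1000L)
      abort(sprintf("no node of degree %d after %d network regenerations.",
                    k_c, regen))
  }
  pop <- assign_population(g, k_c)
  traj <- run_model(pop, g, model = config$model, parse = config$parse,
                    horizon = config$horizon, window = config$window,
                    tolerance = config$tolerance)
  fin <- final_population(traj)
  finals <- dplyr::bind_cols(
    snapshot(fin, g),
    tibble::tibble(silenced_per_hc = silenced_per_hc(fin),
                   hc_fraction = hc_prevalence(fin),
                   hc_neighbors = hc_neighbor_count(fin),
                   t_stop = attr(traj, "t_stop"),
                   converged = attr(traj, "converged")))
  list(finals = finals, trajectory = traj, regenerations = regen,
       seed = child_seed(config$seed, k_c, realization, config$model))
}

#' Ensemble at a single hard-core degree
#'
#' Runs `config$realizations` independent realizations at one \eqn{K_c} and
#' aggregates means and standard errors of the final observables.
#'
#' @inheritParams run_realization
#' @return A one-row tibble with columns `kc`, `n_real`, `mean_b`,
#'   `mean_omega_f`, `se_omega`, `r_f`, `se_r`, `frac_plus`, `frac_minus`,
#'   `frac_silent`, `se_silent`, `silenced_per_hc`, `hc_fraction`,
#'   `hc_neighbors`, `regenerations`.
#' @export
run_ensemble <- function(config, k_c) {
  stopifnot(inherits(config, "qn_config"))
  runs <- purrr::map(seq_len(config$realizations),
                     function(r) run_realization(config, k_c, r))
  finals <- purrr::map_dfr(runs, "finals")
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  tibble::tibble(
    kc = as.integer(k_c),
    n_real = config$realizations,
    mean_b = mean(finals$mean_belief),
    mean_omega_f = mean(finals$mean_omega),
    se_omega = se(finals$mean_omega),
    r_f = mean(finals$r),
    se_r = se(finals$r),
    frac_plus = mean(finals$frac_plus),
    frac_minus = mean(finals$frac_minus),
    frac_silent = mean(finals$frac_silent),
    se_silent = se(finals$frac_silent),
    silenced_per_hc = mean(finals$silenced_per_hc),
    hc_fraction = mean(finals$hc_fraction),
    hc_neighbors = mean(finals$hc_neighbors),
    regenerations = sum(purrr::map_int(runs, "regenerations")))
}

#' Sweep the hard-core degree
#'
#' Runs [run_ensemble()] for every \eqn{K_c} in `config$kc_list`.  When
#' `config$outputs` is set, writes `ensemble.csv` (schema
#' `kc,n_real,mean_b,mean_omega_f,se_omega,r_f,se_r,frac_plus,frac_minus,
#' frac_silent,silenced_per_hc,hc_fraction`) and `manifest.json` (full
#' configuration, seeds, package version, wall time) to that directory.
#'
#' @param config A `qn_config`.
#' @return A `qn_ensemble` tibble, one row per \eqn{K_c}.
#' @examples
#' cfg <- model_config("endogenous", n = 400, realizations = 3,
#'                     kc_list = c(2, 3), seed = 7)
#' sweep_kc(cfg)
#' @export
sweep_kc <- function(config) {
  stopifnot(inherits(config, "qn_config"))
  t0 <- Sys.time()
  out <- purrr::map_dfr(config$kc_list, function(kc) run_ensemble(config, kc))
  out <- structure(out, class = c("qn_ensemble", class(out)),
                   config = config)
  if (!is.null(config$outputs)) {
    dir.create(config$outputs, recursive = TRUE, showWarnings = FALSE)
    cols <- c("kc", "n_real", "mean_b", "mean_omega_f", "se_omega", "r_f",
              "se_r", "frac_plus", "frac_minus", "frac_silent",
              "silenced_per_hc", "hc_fraction")
    readr::write_csv(tibble::as_tibble(out)[, cols],
                     file.path(config$outputs, "ensemble.csv"))
    manifest <- c(unclass(config)[setdiff(names(config), "outputs")],
                  list(package_version = as.character(utils::packageVersion("quietnet")),
                       wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))))
    jsonlite::write_json(manifest, file.path(config$outputs, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Fit the silencing scaling law
#'
#' Regresses the ensemble-mean silenced-per-hard-core counts on \eqn{K_c}
#' on log-log axes; the slope \eqn{\nu} quantifies the superlinear leverage
#' of well-connected dissenters.
#'
#' @param summary A `qn_ensemble` (or any data frame with `kc` and
#'   `silenced_per_hc` columns), with at least 3 rows.
#' @return A `qn_powerlaw_fit`; see [fit_power_law_exponent()].
#' @export
fit_silencing_scaling <- function(summary) {
  if (!all(c("kc", "silenced_per_hc") %in% names(summary)))
    abort("`summary` needs `kc` and `silenced_per_hc` columns.")
  fit_power_law_exponent(summary[, c("kc", "silenced_per_hc")])
}
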