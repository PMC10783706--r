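#' Fit a power-law exponent by log-log least squares
#'
#' Ordinary least squares of \eqn{\log y} on \eqn{\log k_c}: the slope is
#' the scaling exponent \eqn{\nu} of \eqn{y \sim k_c^{\nu}}.  Unweighted OLS
#' over all supplied points is the minimal reproducible choice; the full
#' `lm` fit is kept for inspection via [tidy()] / [glance()].
#'
#' @param data A data frame whose first two columns are \eqn{k_c} and
#'   \eqn{y}, or a numeric vector of \eqn{k_c} values.
#' @param y Numeric responses (all positive) when `data` is a vector.
#' @return A `qn_powerlaw_fit` with elements `exponent`, `intercept` (on the
#'   log scale), `fit` (the `lm` object) and `data` (points plus fitted
#'   values and residuals on the log scale).
#' @examples
#' fit_power_law_exponent(c(2, 3, 5, 10, 20), c(2, 3, 5, 10, 20)^2)
#' @export
fit_power_law_exponent <- function(data, y = NULL) {
  if (is.data.frame(data)) {
    kc <- as.numeric(data[[1]])
    y <- as.numeric(data[[2]])
  } else {
    kc <- as.numeric(data)
    y <- as.numeric(y)
  }
  if (length(kc) != length(y) || length(kc) < 3L)
    abort("need at least 3 (k_c, y) pairs.")
  if (any(!is.finite(kc)) || any(!is.finite(y)) || any(kc <= 0) || any(y <= 0))
    abort("all k_c and y values must be positive and finite.")
  d <- tibble::tibble(log_kc = log(kc), log_y = log(y))
  fit <- lm(log_y ~ log_kc, data = d)
  structure(
    list(exponent = unname(coef(fit)[["log_kc"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         fit = fit,
         data = tibble::tibble(kc = kc, y = y,
                               fitted = exp(stats::fitted(fit)),
                               log_residual = stats::residuals(fit))),
    class = "qn_powerlaw_fit")
}

#' @export
print.qn_powerlaw_fit <- function(x, ...) {
  cat(sprintf("<qn_powerlaw_fit> y ~ k_c^nu, nu = %.3f (log-intercept %.3f, %d points)\n",
              x$exponent, x$intercept, nrow(x$data)))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x A `qn_powerlaw_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient of the log-log regression
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`); the
#'   `log_kc` row is the scaling exponent.
#' @importFrom generics tidy
#' @method tidy qn_powerlaw_fit
#' @export
tidy.qn_powerlaw_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a power-law fit
#'
#' @inheritParams tidy.qn_powerlaw_fit
#' @return A one-row tibble: `exponent`, `intercept`, `r.squared`, `sigma`,
#'   `nobs`.
#' @importFrom generics glance
#' @method glance qn_powerlaw_fit
#' @export
glance.qn_powerlaw_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(exponent = x$exponent, intercept = x$intercept,
                 r.squared = s$r.squared, sigma = s$sigma,
                 nobs = nrow(x$data))
}

#' @export
generics::tidy

#' @export
generics::glance
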