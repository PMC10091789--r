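## day-resolution dates, intervals in years
DAYS_PER_YEAR <- 365.25

years_between <- function(from, to) as.numeric(as.Date(to) - as.Date(from)) / DAYS_PER_YEAR

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided normal p-value for an estimate and its standard error
#' @noRd
z_p <- function(estimate, se) 2 * stats::pnorm(-abs(estimate / se))

#' Wald confidence interval at the conventional 1.96 multiplier
#' @noRd
wald_ci <- function(estimate, se, z = 1.96) c(estimate - z * se, estimate + z * se)

stop_config <- function(...) stop(..., call. = FALSE)

#' Truncated-normal draws by inverse-CDF sampling
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
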