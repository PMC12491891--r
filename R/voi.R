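#' Unit normal loss integral
#'
#' L(z) = phi(z) - z * (1 - Phi(z)), the expected shortfall
#' `E[(T - z)+]` of a standard normal T. This is the kernel of
#' normal-theory expected value of perfect information.
#'
#' @param z Standardized distance (vectorized).
#' @return L(z).
#' @export
#' @examples
#' unit_normal_loss(0) # phi(0) = 0.39894
unit_normal_loss <- function(z) {
  dnorm(z) - z * (1 - pnorm(z))
}

#' Population model for value-of-information totals
#'
#' @param users_per_year Expected new users per year.
#' @param horizon_years Time horizon in years.
#' @param discount_rate Annual discount rate.
#' @param timing `"end"` (users counted at the end of years 1..horizon,
#'   an ordinary annuity) or `"start"` (years 0..horizon-1).
#' @return Object of class `wl_population`.
#' @export
population_model <- function(users_per_year = 988, horizon_years = 5,
                             discount_rate = 0.03,
                             timing = c("end", "start")) {
  timing <- match.arg(timing)
  stopifnot(users_per_year > 0, horizon_years > 0, discount_rate >= 0)
  structure(
    list(
      users_per_year = users_per_year, horizon_years = horizon_years,
      discount_rate = discount_rate, timing = timing
    ),
    class = "wl_population"
  )
}

#' Discounted number of users over the population horizon
#'
#' Sum over the horizon of `users_per_year / (1 + r)^t`, with t = 1..H
#' under end-of-year timing (default) or t = 0..H-1 under start-of-year
#' timing.
#'
#' @param pop A [population_model()].
#' @return Effective (discounted) user count.
#' @export
#' @examples
#' discounted_users(population_model(988, 5, 0.03)) # about 4524.8
discounted_users <- function(pop) {
  stopifnot(inherits(pop, "wl_population"))
  t <- seq_len(pop$horizon_years)
  if (pop$timing == "start") t <- t - 1
  sum(pop$users_per_year / (1 + pop$discount_rate)^t)
}

# Mean and SD of net monetary benefit at threshold lambda.
nb_moments <- function(inc, lambda) {
  mu <- lambda * inc$mean_e - inc$mean_c
  s2 <- lambda^2 * inc$se_e^2 + inc$se_c^2 -
    2 * lambda * inc$rho * inc$se_e * inc$se_c
  c(mu = mu, sigma = sqrt(max(s2, 0)))
}

#' Expected value of perfect information per user
#'
#' The expected opportunity loss of the current adopt/reject decision
#' (made by the sign of expected net benefit) under the bivariate-normal
#' uncertainty: `sigma_NB * L(|mu_NB| / sigma_NB)` with L the
#' [unit_normal_loss()].
#'
#' @param inc A `wl_incremental`.
#' @param lambda Threshold in SEK per QALY (vectorized).
#' @return EVPI per user in SEK.
#' @export
evpi_per_user <- function(inc, lambda) {
  stopifnot(inherits(inc, "wl_incremental"))
  sapply(lambda, function(l) {
    m <- nb_moments(inc, l)
    if (m["sigma"] == 0) {
      return(0)
    }
    unname(m["sigma"] * unit_normal_loss(abs(m["mu"]) / m["sigma"]))
  })
}

#' Expected value of partial perfect information per user
#'
#' EVPI on incremental effectiveness or incremental costs separately.
#' Under bivariate normality the conditional mean net benefit given the
#' learned component X is linear in X with slope
#' `lambda - rho * se_c / se_e` (effect) or
#' `lambda * rho * se_e / se_c - 1` (cost), so
#' `EVPPI = |s| * sd(X) * L(|mu_NB| / (|s| * sd(X)))`, again via the unit
#' normal loss integral; a zero slope gives zero value.
#'
#' @param inc A `wl_incremental` with positive SEs.
#' @param lambda Threshold in SEK per QALY (vectorized).
#' @param component `"effect"` or `"cost"`.
#' @return EVPPI per user in SEK.
#' @export
evppi_per_user <- function(inc, lambda, component = c("effect", "cost")) {
  component <- match.arg(component)
  stopifnot(inherits(inc, "wl_incremental"), inc$se_e > 0, inc$se_c > 0)
  sapply(lambda, function(l) {
    mu <- l * inc$mean_e - inc$mean_c
    s <- if (component == "effect") {
      l - inc$rho * inc$se_c / inc$se_e
    } else {
      l * inc$rho * inc$se_e / inc$se_c - 1
    }
    sx <- if (component == "effect") inc$se_e else inc$se_c
    scale <- abs(s) * sx
    if (scale == 0) {
      return(0)
    }
    scale * unit_normal_loss(abs(mu) / scale)
  })
}

#' Break-even one-off cost of adoption
#'
#' The one-off (e.g. development) cost at which adopting the intervention
#' stops being worthwhile in expectation: per-user expected net monetary
#' benefit at the threshold times the discounted number of users over the
#' population horizon.
#'
#' @param inc A `wl_incremental`.
#' @param lambda Threshold in SEK per QALY.
#' @param pop A [population_model()].
#' @return SEK.
#' @export
breakeven_dev_cost <- function(inc, lambda, pop = population_model()) {
  (lambda * inc$mean_e - inc$mean_c) * discounted_users(pop)
}

#' QALY multiple of reinvested cost savings
#'
#' How many times the QALYs gained by users themselves the health system
#' could produce by reinvesting the cost savings at the threshold:
#' `(-mean_c / lambda) / mean_e`.
#'
#' @param inc A `wl_incremental`.
#' @param lambda Threshold in SEK per QALY.
#' @return Dimensionless multiple.
#' @export
qaly_multiple <- function(inc, lambda) {
  (-inc$mean_c / lambda) / inc$mean_e
}

#' Value-of-information curves over a threshold grid
#'
#' Per-user and population-total EVPI and EVPPI (effect and cost
#' components) at each threshold.
#'
#' @param inc A `wl_incremental`.
#' @param lambdas Threshold grid.
#' @param pop A [population_model()].
#' @return Tibble of class `wl_voi`, one row per threshold.
#' @export
voi_curve <- function(inc, lambdas = analysis_config()$lambda_grid,
                      pop = population_model()) {
  n_eff <- discounted_users(pop)
  evpi <- evpi_per_user(inc, lambdas)
  evppi_e <- evppi_per_user(inc, lambdas, "effect")
  evppi_c <- evppi_per_user(inc, lambdas, "cost")
  out <- tibble::tibble(
    lambda = as.numeric(lambdas),
    evpi_user = evpi,
    evppi_effect_user = evppi_e,
    evppi_cost_user = evppi_c,
    n_discounted = n_eff,
    evpi_total = evpi * n_eff,
    evppi_effect_total = evppi_e * n_eff,
    evppi_cost_total = evppi_c * n_eff
  )
  class(out) <- c("wl_voi", class(out))
  out
}
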