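#' Probability that the intervention is cost-effective
#'
#' Under the bivariate-normal summary of the cost-effectiveness plane the
#' incremental net monetary benefit at threshold lambda,
#' NB = lambda * dE - dC, is normal with mean
#' `lambda * mean_e - mean_c` and variance
#' `lambda^2 se_e^2 + se_c^2 - 2 lambda rho se_e se_c`, so
#' P(cost-effective) = Phi(mu_NB / sigma_NB) in closed form, with no
#' Monte Carlo simulation.
#'
#' @param inc A `wl_incremental` (see [incremental_summary()],
#'   [incremental_from_summaries()]).
#' @param lambda Cost-effectiveness threshold in SEK per QALY (> 0); may
#'   be a vector.
#' @return Probability (vectorized over `lambda`). A degenerate
#'   `sigma_NB = 0` returns 0, 1 or 0.5 by the sign of `mu_NB`.
#' @export
#' @examples
#' inc <- incremental_result(0.0065, -46359, 0.01449, 33335, rho = 0)
#' prob_cost_effective(inc, 5e5)
prob_cost_effective <- function(inc, lambda) {
  stopifnot(inherits(inc, "wl_incremental"), all(lambda > 0))
  mu <- lambda * inc$mean_e - inc$mean_c
  s2 <- lambda^2 * inc$se_e^2 + inc$se_c^2 -
    2 * lambda * inc$rho * inc$se_e * inc$se_c
  s <- sqrt(pmax(s2, 0))
  ifelse(s > 0, pnorm(mu / s), 0.5 * (mu == 0) + (mu > 0))
}

#' Probability that the intervention dominates
#'
#' Orthant probability P(dE > 0, dC < 0) of the bivariate normal: the
#' intervention is both more effective and cost-saving (south-east
#' quadrant of the plane). Computed by one-dimensional quadrature of the
#' conditional normal CDF over the effectiveness margin; with `rho = 0` it
#' reduces to the product of the two marginal probabilities.
#'
#' @param inc A `wl_incremental` with positive standard errors.
#' @return A probability.
#' @export
prob_dominant <- function(inc) {
  stopifnot(inherits(inc, "wl_incremental"))
  if (inc$se_e <= 0 || inc$se_c <= 0) stop("prob_dominant requires positive SEs")
  rho <- inc$rho
  if (rho == 0) {
    return(pnorm(inc$mean_e / inc$se_e) * pnorm(-inc$mean_c / inc$se_c))
  }
  if (abs(rho) >= 1) rho <- sign(rho) * (1 - 1e-12)
  zmin <- -inc$mean_e / inc$se_e
  f <- function(z) {
    cm <- inc$mean_c + rho * inc$se_c * z
    cs <- inc$se_c * sqrt(1 - rho^2)
    dnorm(z) * pnorm(-cm / cs)
  }
  integrate(f, zmin, Inf, rel.tol = 1e-10)$value
}

#' Cost-effectiveness acceptability curve
#'
#' [prob_cost_effective()] evaluated over a threshold grid. As
#' lambda -> 0 the curve approaches Phi(-mean_c / se_c) and as
#' lambda -> Inf it approaches Phi(mean_e / se_e).
#'
#' @param inc A `wl_incremental`.
#' @param lambdas Threshold grid (SEK/QALY, positive).
#' @return Tibble of class `wl_ceac` with `lambda` and `prob_ce`.
#' @export
ceac <- function(inc, lambdas = analysis_config()$lambda_grid) {
  out <- tibble::tibble(
    lambda = as.numeric(lambdas),
    prob_ce = prob_cost_effective(inc, lambdas)
  )
  class(out) <- c("wl_ceac", class(out))
  out
}

#' Confidence ellipse on the cost-effectiveness plane
#'
#' Parameters of the bivariate-normal coverage ellipse: centre, semi-axis
#' lengths and rotation. With zero correlation the ellipse is
#' axis-aligned; zero coverage degenerates to the centre point.
#'
#' @param inc A `wl_incremental`.
#' @param coverage Coverage probability in `[0, 1)`.
#' @param n_points Number of polygon points returned for plotting.
#' @return List with `center`, `radii` (semi-axes), `angle` (radians, first
#'   principal axis vs the effectiveness axis) and a `points` tibble.
#' @export
confidence_ellipse <- function(inc, coverage = 0.9, n_points = 181) {
  stopifnot(coverage >= 0, coverage < 1)
  S <- matrix(c(
    inc$se_e^2, inc$rho * inc$se_e * inc$se_c,
    inc$rho * inc$se_e * inc$se_c, inc$se_c^2
  ), 2, 2)
  ev <- eigen(S, symmetric = TRUE)
  r2 <- qchisq(coverage, df = 2)
  radii <- sqrt(pmax(ev$values, 0) * r2)
  angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  th <- seq(0, 2 * pi, length.out = n_points)
  pts <- cbind(radii[1] * cos(th), radii[2] * sin(th)) %*% t(ev$vectors)
  list(
    center = c(e = inc$mean_e, c = inc$mean_c),
    radii = radii, angle = angle,
    points = tibble::tibble(
      e = inc$mean_e + pts[, 1],
      c = inc$mean_c + pts[, 2]
    )
  )
}
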