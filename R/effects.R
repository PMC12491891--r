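#' Build the analysis outcome matrix
#'
#' Assembles the 16 analysis outcomes per participant-wave: the HRQoL
#' index, the 13 resource-use counts (item-level missingness imputed by
#' LOCF/NOCB unless `impute = FALSE`) and the related/unrelated 3-month
#' drug costs computed from drug entries and prices.
#'
#' @param trial A `wl_trial`.
#' @param tables Validated costing tables (for drug prices).
#' @param impute Run [impute_items()] first (default).
#' @return A tibble of class `wl_outcome_matrix` with columns
#'   `participant_id`, `arm`, `wave`, `responded` and one column per
#'   outcome, in the fixed order of `wl_outcomes()`.
#' @export
build_outcome_matrix <- function(trial, tables = default_costing_tables(),
                                 impute = TRUE) {
  stopifnot(inherits(trial, "wl_trial"))
  if (impute) trial <- impute_items(trial)
  cw <- cost_waves(trial, tables)
  rec <- dplyr::arrange(trial$records, .data$participant_id, .data$wave)
  cw <- dplyr::arrange(cw, .data$participant_id, .data$wave)
  om <- tibble::tibble(
    participant_id = rec$participant_id,
    arm = rec$arm,
    wave = rec$wave,
    responded = rec$responded,
    hrqol = rec$hrqol
  )
  for (j in paste0("use_", 1:13)) om[[j]] <- as.numeric(rec[[j]])
  om$drug_related <- cw$drug_cost_related
  om$drug_unrelated <- cw$drug_cost_unrelated
  class(om) <- c("wl_outcome_matrix", class(om))
  om
}

theta_names <- function() {
  as.vector(outer(
    wl_waves(),
    outer(wl_arms(), wl_outcomes(), function(a, o) paste(o, a, sep = "|")),
    function(w, oa) paste(oa, w, sep = "|")
  )[, , ])
}

# Index into the stacked cell-mean vector (outcome-major, then arm, then
# wave): position of (outcome o, arm a, wave w).
theta_index <- function(o, a, w) {
  oi <- match(o, wl_outcomes())
  ai <- match(a, wl_arms())
  wi <- match(w, wl_waves())
  (oi - 1L) * 8L + (ai - 1L) * 4L + wi
}

#' Jointly estimated arm-by-wave cell means with cluster-robust covariance
#'
#' Fits the saturated cell-means model for all 16 outcomes as one stacked
#' system: each coefficient is the sample mean of an outcome in an
#' arm-by-wave cell, and the joint covariance of all 128 coefficients is
#' the cluster-robust sandwich with participants as clusters (CR1, scaled
#' by G/(G-1) for G clusters). Estimating the outcomes jointly preserves
#' the between-outcome covariance needed for joint hypothesis tests and
#' for the correlation between incremental effectiveness and costs.
#'
#' @param om A `wl_outcome_matrix`.
#' @return Object of class `wl_cells`: `theta` (named vector of cell
#'   means), `vcov` (128 x 128), `cell_n`, `n_clusters`.
#' @export
fit_joint_cell_means <- function(om) {
  outcomes <- wl_outcomes()
  ids <- unique(om$participant_id)
  G <- length(ids)
  pidx <- match(om$participant_id, ids)
  K <- length(outcomes) * 8L
  theta <- rep(NA_real_, K)
  names(theta) <- theta_names()
  cell_n <- integer(K)
  psi <- matrix(0, G, K)
  col0 <- (match(om$arm, wl_arms()) - 1L) * 4L + match(om$wave, wl_waves())
  for (o in seq_along(outcomes)) {
    y <- om[[outcomes[o]]]
    ok <- om$responded & !is.na(y)
    cols <- (o - 1L) * 8L + col0
    for (c0 in 1:8) {
      rows <- which(ok & col0 == c0)
      k <- (o - 1L) * 8L + c0
      nc <- length(rows)
      cell_n[k] <- nc
      if (nc < 2) {
        stop(
          "estimation error: fewer than 2 observations in cell ",
          names(theta)[k]
        )
      }
      m <- mean(y[rows])
      theta[k] <- m
      psi[cbind(pidx[rows], k)] <- (y[rows] - m) / nc
    }
  }
  vcov <- crossprod(psi) * G / (G - 1)
  structure(
    list(
      theta = theta, vcov = vcov, cell_n = cell_n,
      n_clusters = G, outcomes = outcomes
    ),
    class = "wl_cells"
  )
}

# Apply a fixed linear map to cell means with exact covariance propagation.
linear_effects <- function(cells, L, estimator, single_arm = FALSE) {
  d <- as.numeric(L %*% cells$theta)
  V <- L %*% cells$vcov %*% t(L)
  delta <- matrix(d, nrow = 16, ncol = 3, byrow = TRUE,
    dimnames = list(wl_outcomes(), c("3", "6", "9")))
  structure(
    list(
      delta = delta, vcov = V, n_clusters = cells$n_clusters,
      estimator = estimator, single_arm = single_arm, cells = cells
    ),
    class = "wl_effects"
  )
}

# Row order of the 48-vector of effects: outcome-major, horizons 3,6,9.
delta_index <- function(o, h) {
  (match(o, wl_outcomes()) - 1L) * 3L + match(h, c(3, 6, 9))
}

#' Chain waitlist-arm means into counterfactual treatment effects
#'
#' The 3-month effect is the plain intervention-vs-waitlist contrast at
#' wave 3. Beyond the controlled horizon the waitlist arm is itself
#' exposed, so the comparator mean at 6 months is the waitlist wave-6 mean
#' minus the 3-month effect, and likewise at 9 months with the 6-month
#' effect. Algebraically the effect at horizon h is the cumulative sum of
#' per-wave arm contrasts up to h, an exactly linear map of the cell
#' means, so the joint covariance propagates without approximation.
#'
#' @param cells A `wl_cells` fit.
#' @return Object of class `wl_effects` with `delta` (16 outcomes x
#'   horizons 3/6/9) and its 48 x 48 covariance.
#' @export
chain_waitlist_effects <- function(cells) {
  L <- matrix(0, 48, length(cells$theta))
  for (o in wl_outcomes()) {
    for (h in c(3, 6, 9)) {
      r <- delta_index(o, h)
      for (w in c(3, 6, 9)[c(3, 6, 9) <= h]) {
        L[r, theta_index(o, "intervention", w)] <- 1
        L[r, theta_index(o, "waitlist", w)] <- -1
      }
    }
  }
  linear_effects(cells, L, "main")
}

#' Difference-in-differences effects
#'
#' As [chain_waitlist_effects()] but each arm-wave mean is first replaced
#' by its change from baseline, protecting the contrasts against baseline
#' imbalance.
#'
#' @param cells A `wl_cells` fit.
#' @return A `wl_effects` object.
#' @export
estimate_did <- function(cells) {
  L <- matrix(0, 48, length(cells$theta))
  for (o in wl_outcomes()) {
    for (h in c(3, 6, 9)) {
      r <- delta_index(o, h)
      for (w in c(3, 6, 9)[c(3, 6, 9) <= h]) {
        L[r, theta_index(o, "intervention", w)] <- 1
        L[r, theta_index(o, "intervention", 0)] <-
          L[r, theta_index(o, "intervention", 0)] - 1
        L[r, theta_index(o, "waitlist", w)] <- -1
        L[r, theta_index(o, "waitlist", 0)] <-
          L[r, theta_index(o, "waitlist", 0)] + 1
      }
    }
  }
  linear_effects(cells, L, "did")
}

#' Pre-post effects in the intervention arm
#'
#' Single-arm sensitivity estimator: the effect at horizon h is the
#' intervention arm's mean change from baseline to wave h, i.e. it assumes
#' outcomes would have stayed at baseline level without the intervention.
#'
#' @param cells A `wl_cells` fit.
#' @return A `wl_effects` object flagged `single_arm = TRUE`.
#' @export
estimate_prepost <- function(cells) {
  L <- matrix(0, 48, length(cells$theta))
  for (o in wl_outcomes()) {
    for (h in c(3, 6, 9)) {
      r <- delta_index(o, h)
      L[r, theta_index(o, "intervention", h)] <- 1
      L[r, theta_index(o, "intervention", 0)] <- -1
    }
  }
  linear_effects(cells, L, "prepost", single_arm = TRUE)
}

#' Baseline-adjusted (ANCOVA) effects
#'
#' Each outcome's post-baseline equations regress the wave value on an
#' intervention indicator and the participant's baseline value of the same
#' outcome; the chained effect at horizon h is the cumulative sum of
#' adjusted per-wave contrasts. The joint covariance of all 48 effects is
#' cluster-robust, obtained by stacking per-equation influence functions
#' at the participant level.
#'
#' @param om A `wl_outcome_matrix`.
#' @return A `wl_effects` object (`cells` not carried).
#' @export
estimate_ancova <- function(om) {
  outcomes <- wl_outcomes()
  ids <- unique(om$participant_id)
  G <- length(ids)
  base <- om[om$wave == 0, ]
  contrasts <- matrix(NA_real_, 16, 3, dimnames = list(outcomes, c("3", "6", "9")))
  psi <- matrix(0, G, 48) # influence of each cluster on each contrast
  for (o in seq_along(outcomes)) {
    y0 <- base[[outcomes[o]]][match(ids, base$participant_id)]
    for (hi in 1:3) {
      h <- c(3, 6, 9)[hi]
      d <- om[om$wave == h, ]
      y <- d[[outcomes[o]]]
      pid <- match(d$participant_id, ids)
      yb <- y0[pid]
      ok <- d$responded & !is.na(y) & !is.na(yb)
      X <- cbind(1, d$arm[ok] == "intervention", yb[ok])
      yy <- y[ok]
      # a constant (e.g. all-zero) baseline aliases with the intercept;
      # drop aliased columns via the pivoted QR
      beta_full <- qr.coef(qr(X), yy)
      keep <- !is.na(beta_full)
      k <- (o - 1L) * 3L + hi
      if (!keep[2]) { # degenerate: no arm contrast estimable
        contrasts[o, hi] <- 0
        next
      }
      Xk <- X[, keep, drop = FALSE]
      XtXi <- solve(crossprod(Xk))
      bk <- beta_full[keep]
      e <- yy - Xk %*% bk
      pos <- sum(keep[1:2]) # arm column position among kept columns
      infl <- (Xk %*% XtXi)[, pos] * e
      contrasts[o, hi] <- beta_full[2]
      psi[cbind(pid[ok], k)] <- infl
    }
  }
  vcov_c <- crossprod(psi) * G / (G - 1)
  # Chain: cumulative sum of per-wave contrasts within outcome.
  A <- matrix(0, 48, 48)
  for (o in seq_along(outcomes)) {
    for (hi in 1:3) {
      for (wi in 1:hi) A[(o - 1) * 3 + hi, (o - 1) * 3 + wi] <- 1
    }
  }
  dvec <- A %*% as.vector(t(contrasts))
  V <- A %*% vcov_c %*% t(A)
  delta <- matrix(dvec, 16, 3, byrow = TRUE,
    dimnames = list(outcomes, c("3", "6", "9")))
  structure(
    list(
      delta = delta, vcov = V, n_clusters = G,
      estimator = "ancova", single_arm = FALSE, cells = NULL
    ),
    class = "wl_effects"
  )
}

# Discount factor at follow-up month m.
wl_discount <- function(m, rate) (1 + rate)^(-m / 12)

# Linear map from the 48 chained effects to the 16 cumulative effects.
auc_map <- function(config) {
  r <- config$discount_rate
  d <- wl_discount(c(3, 6, 9), r)
  A <- matrix(0, 16, 48, dimnames = list(wl_outcomes(), NULL))
  recall <- wl_recall()
  for (o in wl_outcomes()) {
    ro <- match(o, wl_outcomes())
    cols <- (ro - 1L) * 3L + 1:3
    w <- switch(recall[[o]],
      qaly = if (config$qaly_first_quarter == "ramp") {
        # Trapezoids over months 0-3-6-9 on the year scale, each quarter
        # term discounted at its follow-up month; anchored at zero effect
        # at randomization.
        c(0.125 * (d[1] + d[2]), 0.125 * (d[2] + d[3]), 0.125 * d[3])
      } else {
        # 3-month effect held constant over the first quarter.
        c(0.25 * d[1] + 0.125 * d[2], 0.125 * (d[2] + d[3]), 0.125 * d[3])
      },
      `1mo` = 3 * d, # reported month proxies its quarter
      `3mo` = d # each wave covers its preceding quarter
    )
    A[ro, cols] <- w
  }
  A
}

#' Aggregate chained effects into discounted cumulative effects
#'
#' Converts per-horizon effects to cumulative 9-month quantities: the
#' HRQoL effect becomes QALYs by the trapezoid rule over months 0-3-6-9
#' (on the year scale, anchored at a zero effect at randomization);
#' 3-month-recall outcomes sum their per-wave effects (each wave covers
#' its preceding quarter); 1-month-recall outcomes scale each per-wave
#' effect by 3 so the reported month represents its quarter. Every wave
#' term is discounted at its follow-up month m by (1+r)^(-m/12). The map
#' is linear, so the covariance propagates exactly.
#'
#' @param effects A `wl_effects` object.
#' @param config An [analysis_config()].
#' @return Object of class `wl_auc`: `auc` (named 16-vector), `vcov`
#'   (16 x 16), plus metadata.
#' @export
aggregate_auc <- function(effects, config = analysis_config()) {
  stopifnot(inherits(effects, "wl_effects"))
  A <- auc_map(config)
  dvec <- as.vector(t(effects$delta))
  auc <- setNames(as.numeric(A %*% dvec), wl_outcomes())
  V <- A %*% effects$vcov %*% t(A)
  dimnames(V) <- list(wl_outcomes(), wl_outcomes())
  structure(
    list(
      auc = auc, vcov = V, config = config,
      n_clusters = effects$n_clusters, estimator = effects$estimator,
      single_arm = isTRUE(effects$single_arm)
    ),
    class = "wl_auc"
  )
}

#' Incremental effectiveness and costs
#'
#' Collapses the cumulative effects into the two decision quantities:
#' incremental effectiveness (the QALY AUC) and incremental cost (unit
#' costs applied to the in-scope use-item AUCs, plus the related and
#' unrelated drug-cost AUCs, plus the per-user app cost). Standard errors
#' and the effectiveness-cost correlation come from the joint AUC
#' covariance; 95% CIs are normal-theory (estimate +/- 1.96 SE).
#'
#' @param auc A `wl_auc` object.
#' @param tables Validated costing tables.
#' @param config An [analysis_config()].
#' @param scope Costing scope: `"public"` (main analysis) or `"all"`.
#' @return Object of class `wl_incremental` with `mean_e`, `mean_c`,
#'   `se_e`, `se_c`, `rho`, `ci_e`, `ci_c`.
#' @export
incremental_summary <- function(auc, tables = default_costing_tables(),
                                config = analysis_config(),
                                scope = c("public", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(auc, "wl_auc"))
  uc <- tables$unit_costs[order(tables$unit_costs$item), ]
  w_items <- uc$sek_per_unit
  if (scope == "public") w_items <- w_items * (uc$funding == "public")
  M <- matrix(0, 2, 16, dimnames = list(c("e", "c"), wl_outcomes()))
  M["e", "hrqol"] <- 1
  M["c", paste0("use_", 1:13)] <- w_items
  M["c", c("drug_related", "drug_unrelated")] <- 1
  est <- as.numeric(M %*% auc$auc)
  V <- M %*% auc$vcov %*% t(M)
  mean_e <- est[1]
  mean_c <- est[2] + config$app_cost_per_user
  se_e <- sqrt(V[1, 1])
  se_c <- sqrt(V[2, 2])
  rho <- if (se_e > 0 && se_c > 0) V[1, 2] / (se_e * se_c) else 0
  incremental_result(mean_e, mean_c, se_e, se_c, rho,
    scope = scope, estimator = auc$estimator, n_clusters = auc$n_clusters)
}

#' Construct an incremental result directly
#'
#' The bivariate-normal summary of the cost-effectiveness plane. Use
#' [incremental_from_summaries()] to reconstruct one from published point
#' estimates and confidence intervals.
#'
#' @param mean_e,mean_c Incremental effectiveness (QALYs) and cost (SEK).
#' @param se_e,se_c Standard errors (>= 0).
#' @param rho Correlation between incremental effectiveness and costs.
#' @param scope,estimator,n_clusters Optional metadata.
#' @return Object of class `wl_incremental`.
#' @export
incremental_result <- function(mean_e, mean_c, se_e, se_c, rho = 0,
                               scope = NA_character_,
                               estimator = NA_character_,
                               n_clusters = NA_integer_) {
  stopifnot(se_e >= 0, se_c >= 0)
  if (!is.finite(rho) || abs(rho) > 1) stop("invalid rho: must be in [-1, 1]")
  structure(
    list(
      mean_e = mean_e, mean_c = mean_c, se_e = se_e, se_c = se_c,
      rho = rho,
      ci_e = mean_e + c(-1, 1) * 1.96 * se_e,
      ci_c = mean_c + c(-1, 1) * 1.96 * se_c,
      scope = scope, estimator = estimator, n_clusters = n_clusters
    ),
    class = "wl_incremental"
  )
}

#' @rdname incremental_result
#' @param ci_e,ci_c Published 95% CIs (length-2); converted to SEs via
#'   half-width / 1.96.
#' @export
incremental_from_summaries <- function(mean_e, ci_e, mean_c, ci_c, rho = 0) {
  incremental_result(
    mean_e, mean_c,
    se_e = (ci_e[2] - ci_e[1]) / 2 / 1.96,
    se_c = (ci_c[2] - ci_c[1]) / 2 / 1.96,
    rho = rho, estimator = "summaries"
  )
}

#' @export
print.wl_incremental <- function(x, ...) {
  cat("<wl_incremental>",
    if (!is.na(x$estimator)) paste0("[", x$estimator, "]"), "\n")
  cat(sprintf(
    "  dE = %.4f QALYs (95%% CI %.4f to %.4f)\n",
    x$mean_e, x$ci_e[1], x$ci_e[2]
  ))
  cat(sprintf(
    "  dC = %.0f SEK (95%% CI %.0f to %.0f)\n",
    x$mean_c, x$ci_c[1], x$ci_c[2]
  ))
  cat(sprintf("  corr(dE, dC) = %.3f\n", x$rho))
  invisible(x)
}

#' Joint test that all cumulative effects are zero
#'
#' Wald test of the 16-dimensional null that the intervention changed
#' none of the cumulative outcomes, using the cluster-robust joint
#' covariance. The default reference distribution is F(q, G-1) with G the
#' number of participant clusters (the conventional finite-cluster
#' choice); a chi-square(q) version is available. A rank-deficient
#' covariance is pseudo-inverted with a warning and the rank becomes the
#' degrees of freedom.
#'
#' @param auc A `wl_auc` object.
#' @param method `"F"` (default) or `"chisq"`.
#' @return List with `statistic`, `df`, `p_value`, `method`.
#' @export
joint_null_test <- function(auc, method = c("F", "chisq")) {
  method <- match.arg(method)
  stopifnot(inherits(auc, "wl_auc"))
  a <- auc$auc
  V <- auc$vcov
  qr_v <- qr(V)
  rank <- qr_v$rank
  if (rank < length(a)) {
    warning("rank-deficient covariance (rank ", rank, "); using pseudo-inverse")
    Vi <- MASS::ginv(V)
  } else {
    Vi <- solve(V)
  }
  W <- as.numeric(t(a) %*% Vi %*% a)
  if (method == "F") {
    G <- auc$n_clusters
    stat <- W / rank
    p <- pf(stat, rank, G - 1, lower.tail = FALSE)
    list(statistic = stat, df = c(rank, G - 1), p_value = p, method = "F")
  } else {
    p <- pchisq(W, rank, lower.tail = FALSE)
    list(statistic = W, df = rank, p_value = p, method = "chisq")
  }
}
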