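# Build a wl_cells object by hand (chaining only touches theta and vcov).
manual_cells <- function(hrqol_int, hrqol_wl, vcov = NULL) {
  cells <- fit_joint_cell_means(
    build_outcome_matrix(toy_trial(n_per_arm = 2), impute = FALSE)
  )
  for (k in 1:4) {
    cells$theta[sprintf("hrqol|intervention|%d", c(0, 3, 6, 9)[k])] <- hrqol_int[k]
    cells$theta[sprintf("hrqol|waitlist|%d", c(0, 3, 6, 9)[k])] <- hrqol_wl[k]
  }
  if (!is.null(vcov)) cells$vcov <- vcov
  cells
}

test_that("joint cell means equal per-cell sample means", {
  trial <- toy_trial(
    n_per_arm = 3,
    hrqol_fun = function(arm, wave, i) 0.4 + 0.01 * i + 0.02 * (wave / 3) +
      0.05 * (arm == "intervention")
  )
  om <- build_outcome_matrix(trial, impute = FALSE)
  cells <- fit_joint_cell_means(om)
  r <- trial$records
  for (a in c("intervention", "waitlist")) {
    for (w in c(0, 3, 6, 9)) {
      expect_equal(
        unname(cells$theta[sprintf("hrqol|%s|%d", a, w)]),
        mean(r$hrqol[r$arm == a & r$wave == w])
      )
    }
  }
})

test_that("cluster-robust variance reduces to HC1 with singleton clusters", {
  skip_if_not_installed("sandwich")
  # every participant contributes exactly one record
  set.seed(9)
  grid <- expand.grid(
    i = 1:6, arm = c("intervention", "waitlist"),
    wave = c(0L, 3L, 6L, 9L), stringsAsFactors = FALSE
  )
  om <- tibble::tibble(
    participant_id = sprintf("%s-%d-%d", grid$arm, grid$wave, grid$i),
    arm = grid$arm, wave = grid$wave, responded = TRUE
  )
  for (o in c("hrqol", paste0("use_", 1:13), "drug_related", "drug_unrelated")) {
    om[[o]] <- rnorm(nrow(om))
  }
  cells <- fit_joint_cell_means(om)
  # compare one cell's variance with the HC1 variance of an intercept fit
  y <- om$hrqol[om$arm == "intervention" & om$wave == 3]
  fit <- lm(y ~ 1)
  v_hc1 <- sandwich::vcovHC(fit, type = "HC1")[1, 1]
  k <- which(names(cells$theta) == "hrqol|intervention|3")
  # CR1 factor is G/(G-1) over all clusters; singleton clusters per cell
  # leave only the within-cell scatter, so rescale to the cell's own n
  G <- cells$n_clusters
  n <- length(y)
  v_ours <- cells$vcov[k, k] * (G - 1) / G * n / (n - 1)
  expect_equal(v_ours, v_hc1, tolerance = 1e-10)
})

test_that("joint covariance is calibrated for correlated outcomes", {
  # replicate small trials in which hrqol and drug_related share participant
  # noise; the mean estimated covariance between their wave-3 cell means
  # should match the observed covariance of the estimates
  R <- 300
  est <- matrix(NA_real_, R, 2)
  vc <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(1000 + r)
    n <- 15
    trial <- toy_trial(n_per_arm = n)
    z <- rnorm(nrow(trial$records))
    trial$records$hrqol <- pmin(pmax(0.5 + 0.05 * z, 0), 1)
    om <- build_outcome_matrix(trial, impute = FALSE)
    om$drug_related <- 100 * z + rnorm(nrow(om), 0, 20)
    cells <- fit_joint_cell_means(om)
    i1 <- which(names(cells$theta) == "hrqol|intervention|3")
    i2 <- which(names(cells$theta) == "drug_related|intervention|3")
    est[r, ] <- cells$theta[c(i1, i2)]
    vc[r] <- cells$vcov[i1, i2]
  }
  expect_equal(mean(vc), cov(est[, 1], est[, 2]), tolerance = 0.25)
})

test_that("chaining reproduces the stated arithmetic", {
  cells <- manual_cells(
    hrqol_int = c(0.55, 0.60, 0.62, 0.63),
    hrqol_wl = c(0.55, 0.55, 0.60, 0.62)
  )
  eff <- chain_waitlist_effects(cells)
  expect_equal(unname(eff$delta["hrqol", ]), c(0.05, 0.07, 0.08))
})

test_that("identical arms give zero chained effects", {
  cells <- manual_cells(
    hrqol_int = c(0.5, 0.55, 0.6, 0.6),
    hrqol_wl = c(0.5, 0.55, 0.6, 0.6)
  )
  eff <- chain_waitlist_effects(cells)
  expect_equal(unname(eff$delta["hrqol", ]), c(0, 0, 0))
})

test_that("noiseless simulation with constant effect is recovered exactly", {
  d <- 0.03
  trial <- simulate_trial(noiseless_spec(n_per_arm = 5, effect_hrqol = d), seed = 1)
  om <- build_outcome_matrix(trial)
  eff <- chain_waitlist_effects(fit_joint_cell_means(om))
  # secular recovery trend is shared between arms and must cancel
  expect_equal(unname(eff$delta["hrqol", ]), c(d, d, d), tolerance = 1e-12)
})

test_that("chained effects match direct ITT contrasts from an unexposed control", {
  spec_wait <- noiseless_spec(n_per_arm = 5, effect_hrqol = c(0.02, 0.03, 0.05))
  spec_ctrl <- noiseless_spec(
    n_per_arm = 5, effect_hrqol = c(0.02, 0.03, 0.05),
    control_unexposed = TRUE
  )
  eff_chain <- chain_waitlist_effects(fit_joint_cell_means(
    build_outcome_matrix(simulate_trial(spec_wait, seed = 2))
  ))
  trial_ctrl <- simulate_trial(spec_ctrl, seed = 2)
  r <- trial_ctrl$records
  direct <- sapply(c(3, 6, 9), function(w) {
    mean(r$hrqol[r$arm == "intervention" & r$wave == w]) -
      mean(r$hrqol[r$arm == "waitlist" & r$wave == w])
  })
  expect_equal(unname(eff_chain$delta["hrqol", ]), direct, tolerance = 1e-12)
})

test_that("estimation errors on an empty cell", {
  trial <- toy_trial(n_per_arm = 2)
  om <- build_outcome_matrix(trial, impute = FALSE)
  om <- om[!(om$arm == "waitlist" & om$wave == 9), ]
  expect_error(fit_joint_cell_means(om), "cell hrqol\\|waitlist\\|9")
})

test_that("QALY and cost aggregation match closed forms at zero discounting", {
  d <- 0.0104
  # waitlist means carry the effect from wave 6 (3 months after its
  # delayed exposure), so the chained deltas are exactly (d, d, d)
  cells <- manual_cells(
    hrqol_int = c(0.5, 0.5 + d, 0.5 + d, 0.5 + d),
    hrqol_wl = c(0.5, 0.5, 0.5 + d, 0.5 + d)
  )
  eff <- chain_waitlist_effects(cells)
  cfg0 <- analysis_config(discount_rate = 0)
  auc <- aggregate_auc(eff, cfg0)
  expect_equal(unname(auc$auc["hrqol"]), 0.625 * d)
  # zero deltas elsewhere stay zero
  expect_equal(unname(auc$auc["use_1"]), 0)
})

test_that("discounted aggregation matches hand-computed discount factors", {
  # constant 3-month-recall cost effect of 300 per wave
  trial <- toy_trial(n_per_arm = 2)
  om <- build_outcome_matrix(trial, impute = FALSE)
  cells <- fit_joint_cell_means(om)
  # arm means chosen so the chained deltas are exactly (300, 300, 300)
  cells$theta["drug_related|intervention|3"] <- 300
  cells$theta["drug_related|intervention|6"] <- 300
  cells$theta["drug_related|intervention|9"] <- 300
  cells$theta["drug_related|waitlist|3"] <- 0
  cells$theta["drug_related|waitlist|6"] <- 300
  cells$theta["drug_related|waitlist|9"] <- 300
  eff <- chain_waitlist_effects(cells)
  expect_equal(unname(eff$delta["drug_related", ]), c(300, 300, 300))

  auc0 <- aggregate_auc(eff, analysis_config(discount_rate = 0))
  expect_equal(unname(auc0$auc["drug_related"]), 900)
  auc3 <- aggregate_auc(eff, analysis_config(discount_rate = 0.03))
  hand <- 300 * (1.03^(-3 / 12) + 1.03^(-6 / 12) + 1.03^(-9 / 12))
  expect_equal(unname(auc3$auc["drug_related"]), hand)
  expect_lt(auc3$auc["drug_related"], 900)

  # 1-month-recall outcomes scale each wave by three
  cells$theta[sprintf("use_1|intervention|%d", c(3, 6, 9))] <- c(2, 2, 2)
  cells$theta[sprintf("use_1|waitlist|%d", c(3, 6, 9))] <- c(0, 2, 2)
  eff <- chain_waitlist_effects(cells)
  auc0 <- aggregate_auc(eff, analysis_config(discount_rate = 0))
  expect_equal(unname(auc0$auc["use_1"]), 3 * 2 * 3)
})

test_that("incremental summary applies unit costs, drug costs and app cost", {
  trial <- toy_trial(n_per_arm = 2)
  om <- build_outcome_matrix(trial, impute = FALSE)
  cells <- fit_joint_cell_means(om)
  cells$vcov <- matrix(0, 128, 128)
  eff0 <- chain_waitlist_effects(cells)
  auc0 <- aggregate_auc(eff0, analysis_config(discount_rate = 0))
  inc0 <- incremental_summary(auc0, config = analysis_config(discount_rate = 0))
  expect_equal(inc0$mean_e, 0)
  expect_equal(inc0$mean_c, 12) # app cost floor

  # a cumulative effect of -2 on item 6 at unit cost 1000
  tabs <- default_costing_tables()
  uc <- tabs$unit_costs
  uc$sek_per_unit[uc$item == 6] <- 1000
  tabs <- costing_tables(uc, tabs$drug_prices)
  cells$theta[sprintf("use_6|intervention|%d", c(3, 6, 9))] <- c(-2 / 3, -2 / 3, -2 / 3)
  cells$theta[sprintf("use_6|waitlist|%d", c(3, 6, 9))] <- c(0, -2 / 3, -2 / 3)
  eff <- chain_waitlist_effects(cells)
  auc <- aggregate_auc(eff, analysis_config(discount_rate = 0))
  inc <- incremental_summary(auc, tabs, analysis_config(discount_rate = 0))
  expect_equal(inc$mean_c, -2 * 1000 + 12)
})

test_that("joint null test is exact at the boundary cases", {
  auc0 <- structure(
    list(
      auc = setNames(rep(0, 16), wl_outcomes()),
      vcov = diag(16), n_clusters = 100, estimator = "main"
    ),
    class = "wl_auc"
  )
  expect_equal(joint_null_test(auc0)$p_value, 1)
  auc_huge <- auc0
  auc_huge$auc["hrqol"] <- 50
  expect_lt(joint_null_test(auc_huge)$p_value, 1e-6)
  expect_lt(joint_null_test(auc_huge, method = "chisq")$p_value, 1e-6)
})

test_that("rank-deficient covariance falls back to a pseudo-inverse", {
  V <- diag(16)
  V[16, 16] <- 0
  auc <- structure(
    list(
      auc = setNames(c(rep(0.5, 15), 0), wl_outcomes()),
      vcov = V, n_clusters = 100, estimator = "main"
    ),
    class = "wl_auc"
  )
  expect_warning(res <- joint_null_test(auc), "rank-deficient")
  expect_equal(res$df[1], 15)
})
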