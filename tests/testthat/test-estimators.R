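# Noise-free trial with a baseline imbalance b and constant effect d.
imbalance_trial <- function(b = 0.04, d = 0.02) {
  toy_trial(
    n_per_arm = 3,
    hrqol_fun = function(arm, wave, i) {
      base <- 0.5 + 0.02 * i + b * (arm == "intervention")
      exposed <- (arm == "intervention" && wave >= 3) ||
        (arm == "waitlist" && wave >= 6)
      base + d * exposed
    }
  )
}

test_that("difference in differences removes baseline imbalance", {
  b <- 0.04
  d <- 0.02
  om <- build_outcome_matrix(imbalance_trial(b, d), impute = FALSE)
  cells <- fit_joint_cell_means(om)
  plain <- chain_waitlist_effects(cells)
  did <- estimate_did(cells)
  # at the first horizon the plain contrast absorbs the imbalance
  expect_equal(unname(plain$delta["hrqol", "3"]), d + b, tolerance = 1e-12)
  expect_equal(unname(did$delta["hrqol", "3"]), d, tolerance = 1e-12)
})

test_that("estimators coincide on baseline-balanced noiseless data", {
  om <- build_outcome_matrix(imbalance_trial(b = 0, d = 0.02), impute = FALSE)
  cells <- fit_joint_cell_means(om)
  plain <- chain_waitlist_effects(cells)
  did <- estimate_did(cells)
  anc <- estimate_ancova(om)
  expect_equal(plain$delta, did$delta, tolerance = 1e-10)
  expect_equal(plain$delta, anc$delta, tolerance = 1e-10)
})

test_that("identical arms give zero DiD effects", {
  om <- build_outcome_matrix(
    toy_trial(n_per_arm = 3, hrqol_fun = function(arm, wave, i) 0.5 + 0.01 * i),
    impute = FALSE
  )
  did <- estimate_did(fit_joint_cell_means(om))
  expect_equal(unname(did$delta["hrqol", ]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("pre-post uses intervention-arm changes only", {
  trial <- toy_trial(
    n_per_arm = 2,
    hrqol_fun = function(arm, wave, i) {
      if (arm == "intervention") {
        c(`0` = 0.55, `3` = 0.58, `6` = 0.58, `9` = 0.59)[as.character(wave)]
      } else {
        0.9 - 0.05 * wave / 3 # comparator values must not matter
      }
    }
  )
  om <- build_outcome_matrix(trial, impute = FALSE)
  pp <- estimate_prepost(fit_joint_cell_means(om))
  expect_true(pp$single_arm)
  expect_equal(unname(pp$delta["hrqol", ]), c(0.03, 0.03, 0.04), tolerance = 1e-12)

  flat <- toy_trial(n_per_arm = 2, hrqol_fun = function(arm, wave, i) 0.5)
  pp0 <- estimate_prepost(fit_joint_cell_means(build_outcome_matrix(flat, impute = FALSE)))
  expect_equal(unname(pp0$delta["hrqol", ]), c(0, 0, 0))
})

test_that("baseline adjustment tightens standard errors when baselines predict outcomes", {
  spec <- simulation_spec(
    hrqol_sd_between = 0.08, hrqol_sd_within = 0.03,
    item_missing_rate = 0,
    retention = c(179, 179, 179), complete_cases = 179
  )
  om <- build_outcome_matrix(simulate_trial(spec, seed = 3))
  cells <- fit_joint_cell_means(om)
  plain <- chain_waitlist_effects(cells)
  anc <- estimate_ancova(om)
  i3 <- 1 # hrqol delta at horizon 3 is the first entry of the 48-vector
  expect_lt(sqrt(anc$vcov[i3, i3]), sqrt(plain$vcov[i3, i3]))
})

test_that("attrition scenarios are the identity on fully observed data", {
  spec <- simulation_spec(
    retention = c(179, 179, 179), complete_cases = 179,
    item_missing_rate = 0
  )
  om <- build_outcome_matrix(simulate_trial(spec, seed = 4))
  for (sc in c("best", "worst", "complete_case")) {
    expect_equal(
      as.data.frame(apply_attrition_scenario(om, sc)),
      as.data.frame(om)
    )
  }
})

test_that("worst case imputes tail percentiles computed from observed values", {
  om <- build_outcome_matrix(simulate_trial(simulation_spec(), seed = 5))
  obs_h <- om$hrqol[om$responded & !is.na(om$hrqol)]
  obs_u1 <- om$use_1[om$responded & !is.na(om$use_1)]
  worst <- apply_attrition_scenario(om, "worst")
  miss <- !om$responded
  expect_equal(
    unique(worst$hrqol[miss]),
    quantile(obs_h, 0.05, names = FALSE)
  )
  expect_equal(
    unique(worst$use_1[miss]),
    quantile(obs_u1, 0.95, names = FALSE)
  )
  best <- apply_attrition_scenario(om, "best")
  expect_equal(
    unique(best$hrqol[miss]),
    quantile(obs_h, 0.95, names = FALSE)
  )
  expect_true(all(worst$responded))
})

test_that("complete-case analysis keeps the 104 all-wave responders", {
  om <- build_outcome_matrix(simulate_trial(simulation_spec(), seed = 1))
  cc <- apply_attrition_scenario(om, "complete_case")
  expect_equal(length(unique(cc$participant_id)), 104)
  expect_true(all(cc$responded))
})

test_that("PMM with no missing data returns identical matrices and the plain estimate", {
  spec <- simulation_spec(
    retention = c(179, 179, 179), complete_cases = 179,
    item_missing_rate = 0
  )
  om <- build_outcome_matrix(simulate_trial(spec, seed = 6))
  res <- impute_pmm(om, m = 3, k = 5, seed = 1)
  expect_equal(as.data.frame(res$imputations[[1]]), as.data.frame(om))
  expect_equal(as.data.frame(res$imputations[[2]]), as.data.frame(om))
  plain <- chain_waitlist_effects(fit_joint_cell_means(om))
  expect_equal(res$effects$delta, plain$delta)
  expect_equal(res$effects$vcov, plain$vcov, tolerance = 1e-12)
})

test_that("PMM imputations are drawn from the observed support", {
  om <- build_outcome_matrix(simulate_trial(simulation_spec(), seed = 7))
  res <- impute_pmm(om, m = 2, k = 5, seed = 2)
  for (o in c("hrqol", "use_1", "drug_related")) {
    observed <- om[[o]][om$responded & !is.na(om[[o]])]
    imputed <- res$imputations[[1]][[o]][!om$responded]
    expect_true(all(imputed %in% observed))
  }
})

test_that("PMM recovers the full-data cost estimate under random attrition", {
  spec <- simulation_spec(item_missing_rate = 0)
  full_spec <- simulation_spec(
    retention = c(179, 179, 179), complete_cases = 179,
    item_missing_rate = 0
  )
  # same seed: identical outcomes, only the response pattern differs
  om_miss <- build_outcome_matrix(simulate_trial(spec, seed = 8))
  om_full <- build_outcome_matrix(simulate_trial(full_spec, seed = 8))
  inc_full <- incremental_summary(aggregate_auc(
    chain_waitlist_effects(fit_joint_cell_means(om_full))
  ))
  pooled <- impute_pmm(om_miss, m = 10, k = 5, seed = 3)$effects
  inc_mi <- incremental_summary(aggregate_auc(pooled))
  # agreement within the full-data sampling uncertainty
  expect_lt(abs(inc_mi$mean_c - inc_full$mean_c), 2 * inc_full$se_c)
  expect_lt(abs(inc_mi$mean_e - inc_full$mean_e), 2 * inc_full$se_e)
})
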