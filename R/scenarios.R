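#' Sensitivity-analysis scenario registry
#'
#' Data-driven registry mapping scenario names to an estimator, an
#' outcome-matrix transform, a costing scope and configuration overrides.
#' Adding a scenario needs no change to the core pipeline.
#'
#' @return Named list of scenario definitions.
#' @export
scenario_registry <- function() {
  list(
    main = list(),
    did = list(estimator = "did"),
    ancova = list(estimator = "ancova"),
    prepost = list(estimator = "prepost"),
    complete_cases = list(transform = "complete_case"),
    attrition_negative = list(transform = "worst"),
    attrition_positive = list(transform = "best"),
    multiple_imputation = list(estimator = "mi"),
    include_private = list(scope = "all"),
    more_users = list(config = list(users_per_year = 3586)),
    higher_app_cost = list(config = list(app_cost_per_user = 111))
  )
}

#' Run one sensitivity scenario
#'
#' Dispatches the estimator, attrition transform, costing scope and
#' configuration overrides registered for `name` and returns the standard
#' summary: incremental effectiveness and costs with CIs, the probability
#' of cost-effectiveness at the base-case threshold, the probability of
#' dominance, and total EVPI under the scenario's population model.
#' `more_users` changes only the value-of-information totals;
#' `higher_app_cost` shifts incremental costs by the app-cost difference.
#'
#' @param name Scenario name; see [scenario_registry()].
#' @param trial A `wl_trial`.
#' @param tables Validated costing tables.
#' @param config Base [analysis_config()].
#' @param mi_args Arguments forwarded to [impute_pmm()] for the
#'   `multiple_imputation` scenario.
#' @return Object of class `wl_scenario`.
#' @export
run_scenario <- function(name, trial, tables = default_costing_tables(),
                         config = analysis_config(),
                         mi_args = list(m = 10, k = 5)) {
  reg <- scenario_registry()
  if (!name %in% names(reg)) {
    stop(
      "unknown scenario '", name, "'; valid: ",
      paste(names(reg), collapse = ", ")
    )
  }
  def <- reg[[name]]
  if (!is.null(def$config)) {
    for (nm in names(def$config)) config[[nm]] <- def$config[[nm]]
  }
  om <- build_outcome_matrix(trial, tables)
  if (!is.null(def$transform)) {
    om <- apply_attrition_scenario(om, def$transform)
  }
  estimator <- def$estimator %||% "plain"
  effects <- switch(estimator,
    plain = chain_waitlist_effects(fit_joint_cell_means(om)),
    did = estimate_did(fit_joint_cell_means(om)),
    prepost = estimate_prepost(fit_joint_cell_means(om)),
    ancova = estimate_ancova(om),
    mi = do.call(impute_pmm, c(list(om), mi_args, list(seed = config$seed)))$effects
  )
  auc <- aggregate_auc(effects, config)
  scope <- def$scope %||% "public"
  inc <- incremental_summary(auc, tables, config, scope = scope)
  pop <- population_model(
    config$users_per_year, config$horizon_years, config$discount_rate,
    timing = config$user_discount_timing
  )
  structure(
    list(
      name = name,
      inc = inc,
      auc = auc,
      prob_ce = prob_cost_effective(inc, config$lambda),
      prob_dominant = prob_dominant(inc),
      evpi_total = evpi_per_user(inc, config$lambda) * discounted_users(pop),
      config = config
    ),
    class = "wl_scenario"
  )
}

#' Collate scenario results into a sensitivity table
#'
#' One row per scenario with incremental effectiveness and costs (95%
#' CIs), probability of cost-effectiveness at the base-case threshold and
#' probability of dominance, in stable input order.
#'
#' @param results List of `wl_scenario` objects.
#' @return A tibble.
#' @export
collate_scenarios <- function(results) {
  dplyr::bind_rows(lapply(results, function(s) {
    tibble::tibble(
      scenario = s$name,
      delta_e = s$inc$mean_e,
      delta_e_lo = s$inc$ci_e[1], delta_e_hi = s$inc$ci_e[2],
      delta_c = s$inc$mean_c,
      delta_c_lo = s$inc$ci_c[1], delta_c_hi = s$inc$ci_c[2],
      prob_ce = s$prob_ce,
      prob_dominant = s$prob_dominant,
      evpi_total = s$evpi_total
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
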