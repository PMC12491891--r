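#' Run the full evaluation pipeline
#'
#' Config-driven end-to-end run: simulate (or read) trial data, cost it,
#' estimate chained effects, aggregate to QALYs and costs, compute the
#' acceptability curve, value of information and the sensitivity grid, and
#' write all tables to `out_dir`. Outputs are deterministic given the
#' seed. In summaries mode (config element `summaries` with published
#' point estimates and CIs) the estimation stages are skipped and the
#' cost-effectiveness and VOI layers run standalone.
#'
#' @param config A list, or path to a YAML file, with optional elements:
#'   `seed`, `sim` (overrides for [simulation_spec()]), `analysis`
#'   (overrides for [analysis_config()]), `trial_path` (read data instead
#'   of simulating), `scenarios` (names or `"all"`), `summaries`
#'   (`mean_e`, `ci_e`, `mean_c`, `ci_c`, `rho`), `figures` (logical).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the main objects; files are written to
#'   `out_dir` (`table1.csv`, `table2.csv`, `table3.csv`, `ceac.csv`,
#'   `voi.csv`, `run_log.txt`, data CSVs and optional figures).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  cfg <- do.call(analysis_config, c(config$analysis %||% list(), list(seed = seed)))
  tables <- default_costing_tables()
  log_lines <- c(
    paste("waitcea", as.character(utils::packageVersion("waitcea"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed", seed),
    paste("config_hash", rlang::hash(config))
  )

  if (!is.null(config$summaries)) {
    s <- config$summaries
    inc <- incremental_from_summaries(
      s$mean_e, unlist(s$ci_e), s$mean_c, unlist(s$ci_c),
      rho = s$rho %||% 0
    )
    out <- cea_voi_outputs(inc, cfg, out_dir)
    writeLines(c(log_lines, "mode summaries"), file.path(out_dir, "run_log.txt"))
    return(invisible(c(list(inc = inc), out)))
  }

  if (!is.null(config$trial_path)) {
    trial <- read_trial(config$trial_path)
  } else {
    spec <- do.call(simulation_spec, c(config$sim %||% list(), list(seed = seed)))
    trial <- simulate_trial(spec, seed = seed)
    write_trial(trial, out_dir)
  }

  tab1 <- baseline_summary(trial, tables)
  readr::write_csv(tab1, file.path(out_dir, "table1.csv"))

  om <- build_outcome_matrix(trial, tables)
  effects <- chain_waitlist_effects(fit_joint_cell_means(om))
  auc <- aggregate_auc(effects, cfg)
  inc <- incremental_summary(auc, tables, cfg)
  jt <- joint_null_test(auc)
  tab2 <- tibble::tibble(
    outcome = c("delta_e_qalys", "delta_c_public_sek", names(auc$auc)),
    estimate = c(inc$mean_e, inc$mean_c, unname(auc$auc)),
    ci_lower = c(inc$ci_e[1], inc$ci_c[1],
      unname(auc$auc - 1.96 * sqrt(diag(auc$vcov)))),
    ci_upper = c(inc$ci_e[2], inc$ci_c[2],
      unname(auc$auc + 1.96 * sqrt(diag(auc$vcov))))
  )
  readr::write_csv(tab2, file.path(out_dir, "table2.csv"))

  scen_names <- config$scenarios %||% "all"
  if (identical(scen_names, "all")) scen_names <- names(scenario_registry())
  scens <- lapply(scen_names, run_scenario,
    trial = trial, tables = tables, config = cfg)
  tab3 <- collate_scenarios(scens)
  readr::write_csv(tab3, file.path(out_dir, "table3.csv"))

  out <- cea_voi_outputs(inc, cfg, out_dir)
  if (isTRUE(config$figures)) pipeline_figures(inc, out$ceac, out$voi, out_dir)

  writeLines(
    c(log_lines, "mode estimation",
      sprintf("joint_null_p %.4f", jt$p_value)),
    file.path(out_dir, "run_log.txt")
  )
  invisible(list(
    trial = trial, effects = effects, auc = auc, inc = inc,
    joint_test = jt, scenarios = scens, ceac = out$ceac, voi = out$voi
  ))
}

# CEAC + VOI tables shared by estimation and summaries modes.
cea_voi_outputs <- function(inc, cfg, out_dir) {
  cc <- ceac(inc, cfg$lambda_grid)
  pop <- population_model(
    cfg$users_per_year, cfg$horizon_years, cfg$discount_rate,
    timing = cfg$user_discount_timing
  )
  vv <- voi_curve(inc, cfg$lambda_grid, pop)
  readr::write_csv(cc, file.path(out_dir, "ceac.csv"))
  readr::write_csv(vv, file.path(out_dir, "voi.csv"))
  list(ceac = cc, voi = vv)
}

# Optional figures (CE plane with confidence ellipses, CEAC, VOI curves).
pipeline_figures <- function(inc, cc, vv, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping figures")
    return(invisible(NULL))
  }
  ells <- dplyr::bind_rows(lapply(c(0.9, 0.5, 0.1), function(cv) {
    e <- confidence_ellipse(inc, cv)
    dplyr::mutate(e$points, coverage = factor(cv))
  }))
  p1 <- ggplot2::ggplot(ells, ggplot2::aes(x = .data$e, y = .data$c)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$coverage)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_point(
      data = tibble::tibble(e = inc$mean_e, c = inc$mean_c), size = 2
    ) +
    ggplot2::labs(
      x = "Incremental effectiveness (QALYs)",
      y = "Incremental costs (SEK)"
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "ce_plane.pdf"), p1,
    width = 6, height = 5)
  p2 <- ggplot2::ggplot(cc, ggplot2::aes(.data$lambda, .data$prob_ce)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Threshold (SEK/QALY)", y = "Pr(cost-effective)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "ceac.pdf"), p2, width = 6, height = 4)
  vl <- tidyr::pivot_longer(
    vv[, c("lambda", "evpi_total", "evppi_effect_total", "evppi_cost_total")],
    -"lambda",
    names_to = "quantity", values_to = "sek"
  )
  p3 <- ggplot2::ggplot(vl, ggplot2::aes(.data$lambda, .data$sek,
    linetype = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Threshold (SEK/QALY)", y = "Total value (SEK)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "voi_curves.pdf"), p3,
    width = 6, height = 4)
  invisible(NULL)
}
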