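#' Specification for a synthetic waitlist trial
#'
#' Defines the data-generating process for a two-arm waitlist RCT with
#' assessment waves at 0, 3, 6 and 9 months. The intervention arm is
#' exposed from randomization; the waitlist arm gains access after
#' `waitlist_delay` months, so its outcomes at wave 6 correspond to 3
#' months after exposure. Treatment effects are indexed by time since
#' exposure and switch on only after exposure, which is exactly the
#' identification the chained counterfactual estimator relies on.
#'
#' Resource-use counts follow a hurdle model: any use is Bernoulli with
#' participant-level frailty, and positive use is `1 + NegBin`. HRQoL is
#' generated directly on the index scale with a participant random
#' intercept plus a shared secular recovery trend. Drug costs arise from
#' participant-level user flags per drug class with log-normal quantities.
#'
#' Response patterns are allocated to hit the configured wave response
#' counts *and* the all-wave (complete-case) count exactly; with the
#' defaults that is 179/149/134/118 responses and 104 complete cases,
#' which requires a small number of intermittent returners (participants
#' who miss a wave and come back). Setting `complete_cases` equal to the
#' last retention value gives monotone dropout instead.
#'
#' @param n_intervention,n_waitlist Arm sizes.
#' @param hrqol_baseline_mean Baseline mean of the HRQoL index.
#' @param hrqol_sd_between,hrqol_sd_within Between/within-participant SDs;
#'   their square root of summed squares is the cross-sectional SD
#'   (defaults give about 0.088).
#' @param hrqol_secular Shared (arm-independent) drift of the HRQoL mean
#'   at waves 3, 6, 9, emulating natural recovery.
#' @param treatment_effect_hrqol Additive effect on HRQoL at 3, 6 and 9
#'   months after exposure (recycled if scalar).
#' @param count_models Data frame `item, p_any, mean_given_any, dispersion`
#'   for the 13 use items.
#' @param treatment_effect_counts Multiplicative post-exposure factor on
#'   each item's any-use probability (length 13).
#' @param count_frailty_sd SD of the log-normal participant frailty
#'   multiplying any-use probabilities (capped at 0.95).
#' @param drug_model List with `related` and `unrelated` components, each
#'   `list(p_user, meanlog_units, sdlog_units)`.
#' @param treatment_effect_drug Additive post-exposure SEK shift on
#'   related/unrelated 3-month drug cost (length-2 named vector); applied
#'   on the cost scale and truncated at zero.
#' @param waitlist_delay Months until the waitlist arm is exposed.
#' @param retention Named responses at waves 3, 6, 9 (wave 0 responds in
#'   full); non-increasing.
#' @param complete_cases Number of participants responding at all four
#'   waves.
#' @param item_missing_rate Independent missingness rate for individual
#'   use items within responded waves.
#' @param control_unexposed If `TRUE` the waitlist arm never receives the
#'   intervention (a conventional parallel-arm trial), useful for
#'   validating the chaining estimator against direct contrasts.
#' @param age_mean,age_sd,age_range,p_male Baseline demographics.
#' @param seed Default seed used by [simulate_trial()].
#'
#' @return An object of class `wl_sim_spec`.
#' @export
simulation_spec <- function(n_intervention = 89,
                            n_waitlist = 90,
                            hrqol_baseline_mean = 0.564,
                            hrqol_sd_between = 0.070,
                            hrqol_sd_within = 0.053,
                            hrqol_secular = c(0.004, 0.007, 0.009),
                            treatment_effect_hrqol = 0.0104,
                            count_models = default_count_models(),
                            treatment_effect_counts = default_count_effects(),
                            count_frailty_sd = 0.5,
                            drug_model = default_drug_model(),
                            treatment_effect_drug = c(related = 0, unrelated = 0),
                            waitlist_delay = 3,
                            retention = c(`3` = 149, `6` = 134, `9` = 118),
                            complete_cases = 104,
                            item_missing_rate = 0.0055,
                            control_unexposed = FALSE,
                            age_mean = 42.8, age_sd = 10.9,
                            age_range = c(18, 68), p_male = 0.061,
                            seed = 1L) {
  n <- n_intervention + n_waitlist
  if (length(treatment_effect_hrqol) == 1) {
    treatment_effect_hrqol <- rep(treatment_effect_hrqol, 3)
  }
  stopifnot(
    n_intervention > 0, n_waitlist > 0,
    length(treatment_effect_hrqol) == 3,
    nrow(count_models) == 13,
    length(treatment_effect_counts) == 13,
    all(count_models$p_any >= 0 & count_models$p_any <= 1),
    all(count_models$mean_given_any >= 1),
    item_missing_rate >= 0, item_missing_rate <= 1,
    length(retention) == 3
  )
  retention <- as.integer(retention)
  if (any(diff(c(n, retention)) > 0)) {
    stop("spec error: retention must be non-increasing from n = ", n)
  }
  if (any(retention > n)) stop("spec error: retention target exceeds sample size")
  if (is.null(complete_cases)) complete_cases <- retention[3]
  complete_cases <- as.integer(complete_cases)
  # Feasibility of the response-pattern allocation (see simulate_trial()).
  if (complete_cases > retention[3] || complete_cases > retention[2] ||
    retention[1] < retention[2] ||
    n + complete_cases < retention[1] + retention[3]) {
    stop("spec error: infeasible retention/complete-case combination")
  }
  structure(
    list(
      n_intervention = n_intervention, n_waitlist = n_waitlist,
      hrqol_baseline_mean = hrqol_baseline_mean,
      hrqol_sd_between = hrqol_sd_between,
      hrqol_sd_within = hrqol_sd_within,
      hrqol_secular = hrqol_secular,
      treatment_effect_hrqol = treatment_effect_hrqol,
      count_models = tibble::as_tibble(count_models),
      treatment_effect_counts = treatment_effect_counts,
      count_frailty_sd = count_frailty_sd,
      drug_model = drug_model,
      treatment_effect_drug = treatment_effect_drug,
      waitlist_delay = waitlist_delay,
      retention = retention, complete_cases = complete_cases,
      item_missing_rate = item_missing_rate,
      control_unexposed = control_unexposed,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      p_male = p_male, seed = as.integer(seed)
    ),
    class = "wl_sim_spec"
  )
}

#' Default hurdle-model calibration for the 13 use items
#'
#' Any-use probabilities follow observed baseline any-use proportions;
#' positive-part means and dispersions are calibration choices (only
#' any-use proportions and cost moments are observable targets).
#'
#' @return Tibble with `item`, `p_any`, `mean_given_any`, `dispersion`.
#' @export
default_count_models <- function() {
  tibble::tibble(
    item = 1:13,
    p_any = c(
      0.335, 0.02, 0.045, 0.075, 0.01,
      0.105, 0.23, 0.125, 0.01, 0.06, 0.045, 0.005, 0.065
    ),
    mean_given_any = c(
      1.6, 2.5, 2.5, 2.0, 1.3,
      1.5, 3.5, 2.5, 2.0, 2.5, 2.0, 3.0, 5.0
    ),
    dispersion = rep(1.5, 13)
  )
}

#' @rdname default_count_models
#' @export
default_count_effects <- function() {
  # Post-exposure multiplicative shifts on any-use probability: fewer
  # public consultations and inpatient days, more private mental health
  # care and self-directed care.
  c(0.85, 0.85, 1.60, 0.85, 1.00, 0.90, 1.00, 1.00, 1.00, 1.20, 1.30, 0.90, 0.75)
}

#' @rdname default_count_models
#' @export
default_drug_model <- function() {
  list(
    related = list(p_user = 0.35, meanlog_units = log(60), sdlog_units = 0.8),
    unrelated = list(p_user = 0.38, meanlog_units = log(80), sdlog_units = 1.1)
  )
}

# Allocate response patterns over waves 3/6/9 so that wave margins and the
# all-wave responder count match the spec exactly. Patterns used:
# full {3,6,9}; {3,6}; {3}; {9} (intermittent returners); {} (baseline only).
response_patterns <- function(n, retention, complete_cases) {
  cc <- complete_cases
  a <- retention[2] - cc # respond at 3 and 6, miss 9
  f <- retention[3] - cc # miss 3 and 6, return at 9
  c_ <- retention[1] - retention[2] # respond at 3 only
  g <- n - cc - a - f - c_ # baseline only
  stopifnot(a >= 0, f >= 0, c_ >= 0, g >= 0)
  pat <- rbind(
    matrix(TRUE, cc, 3),
    matrix(rep(c(TRUE, TRUE, FALSE), a), a, 3, byrow = TRUE),
    matrix(rep(c(TRUE, FALSE, FALSE), c_), c_, 3, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, TRUE), f), f, 3, byrow = TRUE),
    matrix(FALSE, g, 3)
  )
  pat[sample.int(n), , drop = FALSE]
}

#' Simulate a waitlist trial
#'
#' Draws a full synthetic dataset from a [simulation_spec()]: one record
#' per participant and wave plus a companion drug-entry table. The output
#' is deterministic given the seed.
#'
#' @param spec A `wl_sim_spec`.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A `wl_trial` object.
#' @export
#' @examples
#' trial <- simulate_trial(simulation_spec(), seed = 1)
#' table(trial$records$wave[trial$records$responded])
simulate_trial <- function(spec = simulation_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "wl_sim_spec"))
  set.seed(seed)
  n <- spec$n_intervention + spec$n_waitlist
  ids <- sprintf("P%03d", seq_len(n))
  arm <- sample(rep(wl_arms(), c(spec$n_intervention, spec$n_waitlist)))
  age <- round(pmin(
    pmax(rnorm(n, spec$age_mean, spec$age_sd), spec$age_range[1]),
    spec$age_range[2]
  ))
  sex <- ifelse(runif(n) < spec$p_male, "male", "female")

  waves <- wl_waves()
  grid <- tibble::tibble(
    participant_id = rep(ids, each = 4),
    arm = rep(arm, each = 4),
    wave = rep(waves, n)
  )
  # Months since exposure: intervention exposed at month 0, waitlist after
  # the delay (never, if control_unexposed).
  expo <- ifelse(grid$arm == "intervention", grid$wave,
    grid$wave - spec$waitlist_delay)
  if (spec$control_unexposed) {
    expo <- ifelse(grid$arm == "intervention", grid$wave, -1)
  }
  eff_idx <- match(expo, c(3, 6, 9)) # NA when unexposed

  # HRQoL: random intercept + secular trend + effect by exposure time.
  b_i <- rnorm(n, 0, spec$hrqol_sd_between)
  secular <- c(0, spec$hrqol_secular)[match(grid$wave, waves)]
  eff_h <- ifelse(is.na(eff_idx), 0, spec$treatment_effect_hrqol[eff_idx])
  hrqol <- spec$hrqol_baseline_mean + b_i[rep(seq_len(n), each = 4)] +
    secular + eff_h + rnorm(4 * n, 0, spec$hrqol_sd_within)
  hrqol <- pmin(pmax(hrqol, 0), 1)

  # Use counts: hurdle with participant frailty on the any-use probability.
  frail <- rlnorm(n, -spec$count_frailty_sd^2 / 2, spec$count_frailty_sd)
  frail_rep <- frail[rep(seq_len(n), each = 4)]
  counts <- matrix(0L, nrow = 4 * n, ncol = 13)
  exposed <- !is.na(eff_idx)
  for (j in 1:13) {
    cm <- spec$count_models[j, ]
    fac <- ifelse(exposed, spec$treatment_effect_counts[j], 1)
    p <- pmin(cm$p_any * frail_rep * fac, 0.95)
    any <- rbinom(4 * n, 1, p)
    pos <- 1L + rnbinom(4 * n, size = cm$dispersion, mu = cm$mean_given_any - 1)
    counts[, j] <- any * pos
  }
  colnames(counts) <- paste0("use_", 1:13)

  rec <- dplyr::bind_cols(grid, tibble::as_tibble(counts))
  rec$age <- age[rep(seq_len(n), each = 4)]
  rec$sex <- sex[rep(seq_len(n), each = 4)]
  rec$hrqol <- hrqol

  # Drug entries: participant-level user flags, one code per class,
  # log-normal quantities per wave; post-exposure additive SEK effect is
  # converted to units via the participant's drug price.
  prices <- default_costing_tables()$drug_prices
  drugs_list <- list()
  for (cl in c("related", "unrelated")) {
    dm <- spec$drug_model[[cl]]
    user <- runif(n) < dm$p_user
    codes_cl <- prices$drug_code[prices$class == cl]
    code_i <- sample(codes_cl, n, replace = TRUE)
    price_i <- prices$sek_per_unit[match(code_i, prices$drug_code)]
    units <- rlnorm(4 * n, dm$meanlog_units, dm$sdlog_units)
    use_row <- user[rep(seq_len(n), each = 4)]
    shift_sek <- ifelse(exposed, spec$treatment_effect_drug[[cl]], 0)
    units_adj <- pmax(
      units + shift_sek / price_i[rep(seq_len(n), each = 4)], 0
    )
    keep <- use_row
    drugs_list[[cl]] <- tibble::tibble(
      participant_id = grid$participant_id[keep],
      wave = grid$wave[keep],
      drug_code = code_i[rep(seq_len(n), each = 4)][keep],
      units = round(units_adj[keep], 1)
    )
  }
  drugs <- dplyr::bind_rows(drugs_list)

  # Response patterns (wave 0 always responds), then blank non-responses.
  pat <- response_patterns(n, spec$retention, spec$complete_cases)
  responded <- rep(TRUE, 4 * n)
  for (k in 1:3) {
    responded[rec$wave == waves[k + 1]] <- pat[, k]
  }
  rec$responded <- responded
  outc <- c("hrqol", paste0("use_", 1:13))
  rec[!responded, outc] <- NA
  drugs <- dplyr::semi_join(
    drugs,
    rec[rec$responded, c("participant_id", "wave")],
    by = c("participant_id", "wave")
  )

  # Item-level missingness within responded waves.
  if (spec$item_missing_rate > 0) {
    for (j in paste0("use_", 1:13)) {
      hit <- responded & (runif(4 * n) < spec$item_missing_rate)
      rec[[j]][hit] <- NA
    }
  }

  rec <- rec[, c(
    "participant_id", "arm", "wave", "responded", "age", "sex",
    "hrqol", paste0("use_", 1:13)
  )]
  wl_trial(rec, drugs)
}

#' Baseline summary by arm
#'
#' Per-arm wave-0 summary: sample size, demographics, HRQoL mean/SD,
#' any-use counts and proportions per item, mean (SD) resource-use costs
#' under the public and all-care scopes split by recall window, and drug
#' any-use and cost summaries.
#'
#' @param trial A `wl_trial`.
#' @param tables Costing tables used for the cost rows.
#' @return A tibble, one row per summary statistic, columns per arm.
#' @export
baseline_summary <- function(trial, tables = default_costing_tables()) {
  stopifnot(inherits(trial, "wl_trial"))
  b <- trial$records[trial$records$wave == 0 & trial$records$responded, ]
  if (nrow(b) == 0) stop("no baseline records")
  arms <- wl_arms()
  if (any(!arms %in% b$arm)) {
    stop("empty arm at baseline: ", setdiff(arms, unique(b$arm)))
  }
  per_arm <- function(a) {
    d <- b[b$arm == a, ]
    cnt <- as.matrix(d[, paste0("use_", 1:13)])
    cnt0 <- cnt
    cnt0[is.na(cnt0)] <- 0L
    costs_pub <- cost_use_matrix(cnt0, tables, scope = "public")
    costs_all <- cost_use_matrix(cnt0, tables, scope = "all")
    dr <- trial$drugs[trial$drugs$wave == 0 &
      trial$drugs$participant_id %in% d$participant_id, ]
    dc <- cost_drugs_by_participant(dr, tables$drug_prices, d$participant_id)
    stats <- c(
      n = nrow(d),
      age_mean = mean(d$age), age_sd = sd(d$age),
      male_prop = mean(d$sex == "male"),
      hrqol_mean = mean(d$hrqol, na.rm = TRUE),
      hrqol_sd = sd(d$hrqol, na.rm = TRUE),
      setNames(colMeans(cnt > 0, na.rm = TRUE), paste0("anyuse_", 1:13)),
      cost_public_1mo_mean = mean(costs_pub[, 1]),
      cost_public_1mo_sd = sd(costs_pub[, 1]),
      cost_public_3mo_mean = mean(costs_pub[, 2]),
      cost_public_3mo_sd = sd(costs_pub[, 2]),
      cost_all_1mo_mean = mean(costs_all[, 1]),
      cost_all_1mo_sd = sd(costs_all[, 1]),
      cost_all_3mo_mean = mean(costs_all[, 2]),
      cost_all_3mo_sd = sd(costs_all[, 2]),
      drug_related_any = mean(dc$related > 0),
      drug_unrelated_any = mean(dc$unrelated > 0),
      drug_related_mean = mean(dc$related),
      drug_related_sd = sd(dc$related),
      drug_unrelated_mean = mean(dc$unrelated),
      drug_unrelated_sd = sd(dc$unrelated)
    )
    stats
  }
  s_int <- per_arm("intervention")
  s_wl <- per_arm("waitlist")
  tibble::tibble(
    statistic = names(s_int),
    intervention = unname(s_int),
    waitlist = unname(s_wl)
  )
}
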