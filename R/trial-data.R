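#' Analysis configuration
#'
#' Bundles the decision-analytic settings used downstream of effect
#' estimation: the willingness-to-pay threshold grid, discounting, the
#' population model for value-of-information totals, and the per-user app
#' cost.
#'
#' @param lambda Base-case cost-effectiveness threshold in SEK per QALY.
#' @param lambda_grid Threshold grid for acceptability and VOI curves
#'   (SEK/QALY, all positive).
#' @param discount_rate Annual discount rate applied to effects, costs and
#'   future users.
#' @param users_per_year Expected number of new app users per year.
#' @param horizon_years Population time horizon in years.
#' @param app_cost_per_user Intervention cost per user in SEK.
#' @param usd_per_sek Exchange rate used only to decorate reports.
#' @param qaly_first_quarter `"ramp"` anchors the HRQoL effect at zero at
#'   randomization and ramps linearly to the 3-month effect; `"flat"`
#'   treats the 3-month effect as constant over the first quarter.
#' @param user_discount_timing `"end"` counts users at the end of years
#'   1..horizon (annuity factor); `"start"` at the start of each year.
#' @param seed Integer seed recorded with pipeline runs.
#'
#' @return An object of class `wl_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$lambda
analysis_config <- function(lambda = 5e5,
                            lambda_grid = c(1, seq(5e4, 1e6, by = 5e4)),
                            discount_rate = 0.03,
                            users_per_year = 988,
                            horizon_years = 5,
                            app_cost_per_user = 12,
                            usd_per_sek = 0.094,
                            qaly_first_quarter = c("ramp", "flat"),
                            user_discount_timing = c("end", "start"),
                            seed = 1L) {
  qaly_first_quarter <- match.arg(qaly_first_quarter)
  user_discount_timing <- match.arg(user_discount_timing)
  stopifnot(
    is.numeric(lambda), length(lambda) == 1, lambda > 0,
    all(lambda_grid > 0),
    discount_rate >= 0,
    users_per_year > 0, horizon_years > 0,
    app_cost_per_user >= 0
  )
  structure(
    list(
      lambda = lambda, lambda_grid = lambda_grid,
      discount_rate = discount_rate,
      users_per_year = users_per_year, horizon_years = horizon_years,
      app_cost_per_user = app_cost_per_user,
      usd_per_sek = usd_per_sek,
      qaly_first_quarter = qaly_first_quarter,
      user_discount_timing = user_discount_timing,
      seed = as.integer(seed)
    ),
    class = "wl_config"
  )
}

#' Per-user app cost from total outlays and download counts
#'
#' The intervention cost per user is total maintenance (and optionally
#' development) cost divided by the number of downloads over the same
#' period.
#'
#' @param total_cost Total cost in SEK.
#' @param downloads Number of downloads (users).
#' @return Cost per user in SEK (not rounded).
#' @export
#' @examples
#' round(app_cost_per_user(24000, 1976)) # maintenance only
#' round(app_cost_per_user(24000 + 194855, 1976)) # incl. development
app_cost_per_user <- function(total_cost, downloads) {
  stopifnot(total_cost >= 0, downloads > 0)
  total_cost / downloads
}

#' Costing tables: unit costs and drug prices
#'
#' @param unit_costs Data frame with columns `item` (1..13),
#'   `sek_per_unit` (>= 0), `funding` (`"public"`/`"private"`) and
#'   `recall` (`"1mo"`/`"3mo"`). Item 13 is inpatient care, costed per day.
#' @param drug_prices Data frame with columns `drug_code`, `sek_per_unit`
#'   (>= 0) and `class` (`"related"`/`"unrelated"`).
#'
#' @return An object of class `wl_costing` containing validated tibbles.
#' @seealso [validate_costing()], [default_costing_tables()]
#' @export
costing_tables <- function(unit_costs, drug_prices) {
  validate_costing(structure(
    list(
      unit_costs = tibble::as_tibble(unit_costs),
      drug_prices = tibble::as_tibble(drug_prices)
    ),
    class = "wl_costing"
  ))
}

#' Validate costing tables
#'
#' Checks that every item 1..13 has a non-negative unit cost, that funding
#' scope matches the main-analysis classification (items 1, 2, 4, 6-9, 12,
#' 13 publicly funded; items 3, 5, 10, 11 private), that recall windows are
#' 1 month for items 1-5 and 3 months for items 6-13, and that drug prices
#' are non-negative with a valid related/unrelated class.
#'
#' @param tables A `wl_costing` object (or plain list with the same
#'   elements).
#' @return The validated `wl_costing` object, invisibly unchanged.
#' @export
validate_costing <- function(tables) {
  uc <- tables$unit_costs
  dp <- tables$drug_prices
  need <- c("item", "sek_per_unit", "funding", "recall")
  if (!all(need %in% names(uc))) {
    stop("unit_costs must have columns: ", paste(need, collapse = ", "))
  }
  missing_items <- setdiff(1:13, uc$item)
  if (length(missing_items) > 0) {
    stop(
      "configuration error: no unit cost for item(s) ",
      paste(missing_items, collapse = ", ")
    )
  }
  if (anyDuplicated(uc$item)) stop("duplicate unit-cost rows per item")
  if (any(uc$sek_per_unit < 0)) stop("unit costs must be >= 0")
  exp_funding <- ifelse(uc$item %in% wl_public_items(), "public", "private")
  bad_f <- uc$item[uc$funding != exp_funding]
  if (length(bad_f) > 0) {
    stop(
      "validation error: funding scope wrong for item(s) ",
      paste(sort(bad_f), collapse = ", "),
      " (public items are ", paste(wl_public_items(), collapse = ","), ")"
    )
  }
  exp_recall <- ifelse(uc$item <= 5, "1mo", "3mo")
  bad_r <- uc$item[uc$recall != exp_recall]
  if (length(bad_r) > 0) {
    stop(
      "validation error: recall window wrong for item(s) ",
      paste(sort(bad_r), collapse = ", ")
    )
  }
  needd <- c("drug_code", "sek_per_unit", "class")
  if (!all(needd %in% names(dp))) {
    stop("drug_prices must have columns: ", paste(needd, collapse = ", "))
  }
  if (any(dp$sek_per_unit < 0)) stop("drug prices must be >= 0")
  if (!all(dp$class %in% c("related", "unrelated"))) {
    stop("drug class must be 'related' or 'unrelated'")
  }
  if (anyDuplicated(dp$drug_code)) stop("duplicate drug price rows")
  if (!inherits(tables, "wl_costing")) class(tables) <- "wl_costing"
  tables
}

#' Default (synthetic) costing tables
#'
#' Plausible Swedish 2023-price-level unit costs per resource-use item and
#' per-unit drug prices. These are synthetic stand-ins for cost-per-patient
#' and pharmacy price lists: realistic in order of magnitude but not actual
#' register extracts, intended for simulation and testing.
#'
#' @return A validated `wl_costing` object.
#' @export
default_costing_tables <- function() {
  unit_costs <- read_unit_costs(
    system.file("extdata", "unit_costs_synthetic.csv", package = "waitcea")
  )
  drug_prices <- read_drug_prices(
    system.file("extdata", "drug_prices_synthetic.csv", package = "waitcea")
  )
  costing_tables(unit_costs, drug_prices)
}

#' Read and write trial record files
#'
#' `read_trial()` reads the long-format trial CSV (one row per
#' participant-wave) and, when present next to it or given explicitly, the
#' companion drug-use CSV keyed by (participant, wave, drug_code). Missing
#' outcome cells are encoded as empty fields. `write_trial()` writes both
#' files.
#'
#' @param path Path to `trial.csv`.
#' @param drugs_path Path to `drugs.csv`; defaults to `drugs.csv` next to
#'   `path`; if that file does not exist an empty drug table is used.
#' @return A `wl_trial` object: list with tibbles `records` and `drugs`.
#' @export
read_trial <- function(path, drugs_path = NULL) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(drugs_path)) {
    cand <- file.path(dirname(path), "drugs.csv")
    drugs_path <- if (file.exists(cand)) cand else NA_character_
  }
  drugs <- if (!is.na(drugs_path)) {
    readr::read_csv(drugs_path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::tibble(
      participant_id = character(), wave = integer(),
      drug_code = character(), units = double()
    )
  }
  wl_trial(rec, drugs)
}

#' @rdname read_trial
#' @param trial A `wl_trial` object.
#' @param dir Output directory (created if needed).
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "wl_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(trial$records, file.path(dir, "trial.csv"), na = "")
  readr::write_csv(trial$drugs, file.path(dir, "drugs.csv"), na = "")
  invisible(file.path(dir, c("trial.csv", "drugs.csv")))
}

#' Construct and validate a trial dataset
#'
#' @param records One row per participant-wave with columns
#'   `participant_id`, `arm`, `wave`, `responded`, optionally `age`, `sex`,
#'   then `hrqol` and `use_1`..`use_13`.
#' @param drugs Drug entries keyed by (participant_id, wave, drug_code)
#'   with consumed `units` over the past 3 months.
#' @return A `wl_trial` object.
#' @export
wl_trial <- function(records, drugs = NULL) {
  rec <- tibble::as_tibble(records)
  need <- c(
    "participant_id", "arm", "wave", "responded",
    "hrqol", paste0("use_", 1:13)
  )
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0) {
    stop("trial records missing column(s): ", paste(miss, collapse = ", "))
  }
  rec$participant_id <- as.character(rec$participant_id)
  rec$wave <- as.integer(rec$wave)
  rec$responded <- as.logical(rec$responded)
  bad_arm <- setdiff(unique(rec$arm), wl_arms())
  if (length(bad_arm) > 0) {
    stop("validation error: unknown arm(s): ", paste(bad_arm, collapse = ", "))
  }
  bad_wave <- setdiff(unique(rec$wave), wl_waves())
  if (length(bad_wave) > 0) {
    stop("validation error: wave must be one of 0,3,6,9; got ",
      paste(bad_wave, collapse = ", "))
  }
  key <- paste(rec$participant_id, rec$wave)
  if (anyDuplicated(key)) {
    stop(
      "validation error: duplicate (participant, wave): ",
      paste(unique(key[duplicated(key)]), collapse = "; ")
    )
  }
  if (any(!is.na(rec$hrqol) & (rec$hrqol < 0 | rec$hrqol > 1))) {
    off <- which(!is.na(rec$hrqol) & (rec$hrqol < 0 | rec$hrqol > 1))
    stop(
      "validation error: hrqol outside [0,1] in row(s) ",
      paste(head(off, 5), collapse = ", ")
    )
  }
  for (j in paste0("use_", 1:13)) {
    v <- rec[[j]]
    if (any(!is.na(v) & v < 0)) {
      stop("validation error: negative counts in ", j)
    }
  }
  nr <- !rec$responded
  outc <- c("hrqol", paste0("use_", 1:13))
  if (any(nr)) {
    present <- rowSums(!is.na(rec[nr, outc, drop = FALSE])) > 0
    if (any(present)) {
      stop(
        "validation error: outcome values present in non-responded ",
        "waves for participant(s) ",
        paste(unique(rec$participant_id[nr][present]), collapse = ", ")
      )
    }
  }
  if (is.null(drugs)) {
    drugs <- tibble::tibble(
      participant_id = character(), wave = integer(),
      drug_code = character(), units = double()
    )
  }
  drugs <- tibble::as_tibble(drugs)
  if (nrow(drugs) > 0) {
    stopifnot(all(c("participant_id", "wave", "drug_code", "units")
      %in% names(drugs)))
    drugs$participant_id <- as.character(drugs$participant_id)
    drugs$wave <- as.integer(drugs$wave)
    if (any(drugs$units < 0)) stop("validation error: negative drug units")
  }
  structure(list(records = rec, drugs = drugs), class = "wl_trial")
}

#' @export
print.wl_trial <- function(x, ...) {
  r <- x$records
  cat(
    "<wl_trial> ", length(unique(r$participant_id)), " participants, ",
    nrow(r), " participant-waves, ", nrow(x$drugs), " drug entries\n",
    sep = ""
  )
  tab <- table(r$arm[r$wave == 0])
  cat("  arms at baseline:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  resp <- tapply(r$responded, r$wave, sum)
  cat("  responses by wave:", paste(names(resp), resp, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Read costing inputs
#'
#' @param path CSV path. `unit_costs.csv` needs columns
#'   `item,label,sek_per_unit,funding,recall`; `drug_prices.csv` needs
#'   `drug_code,sek_per_unit,class`.
#' @return A tibble (not yet validated; see [costing_tables()]).
#' @export
read_unit_costs <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_unit_costs
#' @export
read_drug_prices <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
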