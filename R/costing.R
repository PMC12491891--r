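#' Impute item-level missing resource-use values
#'
#' Fills sporadically missing use items within responded waves by carrying
#' the participant's most recent earlier observation forward (LOCF); a
#' missing baseline takes the next later observation backward (NOCB).
#' Because NOCB runs first, a baseline filled from a later wave then seeds
#' LOCF for intermediate gaps, so consecutive missing waves chain through
#' (disable with `chain = FALSE`, which restricts LOCF to the immediately
#' preceding responded wave). Values in non-responded waves stay absent.
#'
#' @param trial A `wl_trial` (or bare records tibble).
#' @param chain Chain fills across consecutive missing waves (default) or
#'   carry one step only.
#' @return The input with use items imputed; an item missing at every
#'   responded wave of a participant stays `NA` with a warning.
#' @export
impute_items <- function(trial, chain = TRUE) {
  rec <- if (inherits(trial, "wl_trial")) trial$records else tibble::as_tibble(trial)
  rec <- dplyr::arrange(rec, .data$participant_id, .data$wave)
  items <- paste0("use_", 1:13)
  pid <- rec$participant_id
  resp <- rec$responded
  starts <- which(!duplicated(pid))
  ends <- c(starts[-1] - 1, nrow(rec))
  unfillable <- character(0)
  for (j in items) {
    v <- rec[[j]]
    for (g in seq_along(starts)) {
      idx <- starts[g]:ends[g]
      ri <- idx[resp[idx]]
      if (length(ri) == 0) next
      x <- v[ri]
      if (all(is.na(x))) {
        unfillable <- c(unfillable, pid[starts[g]])
        next
      }
      if (!anyNA(x)) next
      # NOCB at baseline: first responded wave takes next observed value.
      if (is.na(x[1])) x[1] <- x[which(!is.na(x))[1]]
      # LOCF forward.
      if (chain) {
        for (k in seq_along(x)[-1]) {
          if (is.na(x[k])) x[k] <- x[k - 1]
        }
      } else {
        filled <- x
        for (k in seq_along(x)[-1]) {
          if (is.na(x[k]) && !is.na(v[ri][k - 1])) filled[k] <- v[ri][k - 1]
        }
        filled[1] <- x[1]
        x <- filled
      }
      v[ri] <- x
    }
    rec[[j]] <- v
  }
  if (length(unfillable) > 0) {
    warning(
      "item missing at every responded wave for participant(s): ",
      paste(unique(unfillable), collapse = ", "), "; left absent"
    )
  }
  if (inherits(trial, "wl_trial")) {
    trial$records <- rec
    trial
  } else {
    rec
  }
}

#' Cost resource use under a funding scope
#'
#' Multiplies item counts by unit costs, keeping the 1-month-recall and
#' 3-month-recall sums separate (they cover different time windows and are
#' aggregated differently over the horizon, so they must never be added
#' directly).
#'
#' @param use_counts Numeric vector of 13 counts (items 1..13).
#' @param tables Validated [costing_tables()].
#' @param scope `"public"` restricts to publicly funded items (the main
#'   analysis); `"all"` costs all 13 items.
#' @return Named numeric vector `c(cost_1mo = , cost_3mo = )` in SEK.
#' @export
#' @examples
#' tabs <- default_costing_tables()
#' counts <- c(1, rep(0, 12)) # one GP visit
#' cost_use(counts, tabs, "public")
cost_use <- function(use_counts, tables, scope = c("public", "all")) {
  scope <- match.arg(scope)
  stopifnot(length(use_counts) == 13, all(use_counts >= 0, na.rm = TRUE))
  m <- cost_use_matrix(matrix(use_counts, nrow = 1), tables, scope)
  setNames(as.numeric(m[1, ]), c("cost_1mo", "cost_3mo"))
}

# Vectorized costing: rows of `counts` are participant-waves, columns
# items 1..13 in order.
cost_use_matrix <- function(counts, tables, scope = c("public", "all")) {
  scope <- match.arg(scope)
  uc <- tables$unit_costs[order(tables$unit_costs$item), ]
  w <- uc$sek_per_unit
  if (scope == "public") w <- w * (uc$funding == "public")
  w1 <- w * (uc$recall == "1mo")
  w3 <- w * (uc$recall == "3mo")
  cbind(
    cost_1mo = as.numeric(counts %*% w1),
    cost_3mo = as.numeric(counts %*% w3)
  )
}

#' Cost drug consumption
#'
#' Sums units times unit price within the related (indicated for
#' posttraumatic stress, depression, anxiety, sleep problems, bipolar
#' disorder or ADHD) and unrelated classes.
#'
#' @param drug_entries Tibble with `drug_code` and `units` (one
#'   participant-wave's entries; may be empty).
#' @param drug_prices Price table with `drug_code`, `sek_per_unit`, `class`.
#' @return Named vector `c(related = , unrelated = )` in SEK.
#' @export
cost_drugs <- function(drug_entries, drug_prices) {
  if (nrow(drug_entries) == 0) {
    return(c(related = 0, unrelated = 0))
  }
  i <- match(drug_entries$drug_code, drug_prices$drug_code)
  if (anyNA(i)) {
    stop(
      "configuration error: unpriced drug code(s): ",
      paste(unique(drug_entries$drug_code[is.na(i)]), collapse = ", ")
    )
  }
  sek <- drug_entries$units * drug_prices$sek_per_unit[i]
  cls <- drug_prices$class[i]
  c(
    related = sum(sek[cls == "related"]),
    unrelated = sum(sek[cls == "unrelated"])
  )
}

# Per-participant drug costs for a fixed wave subset; returns one row per
# id in `ids` (zero when no entries).
cost_drugs_by_participant <- function(drug_entries, drug_prices, ids) {
  out <- tibble::tibble(
    participant_id = ids,
    related = 0, unrelated = 0
  )
  if (nrow(drug_entries) == 0) {
    return(out)
  }
  i <- match(drug_entries$drug_code, drug_prices$drug_code)
  if (anyNA(i)) {
    stop(
      "configuration error: unpriced drug code(s): ",
      paste(unique(drug_entries$drug_code[is.na(i)]), collapse = ", ")
    )
  }
  sek <- drug_entries$units * drug_prices$sek_per_unit[i]
  cls <- drug_prices$class[i]
  for (cl in c("related", "unrelated")) {
    agg <- tapply(sek[cls == cl], drug_entries$participant_id[cls == cl], sum)
    j <- match(names(agg), out$participant_id)
    out[[cl]][j[!is.na(j)]] <- as.numeric(agg)[!is.na(j)]
  }
  out
}

#' Cost every participant-wave
#'
#' Produces the per-wave monetary view of the trial: public and all-care
#' costs by recall window plus related/unrelated drug costs. Non-responded
#' waves yield `NA` costs.
#'
#' @param trial A `wl_trial` (items should be imputed first; see
#'   [impute_items()]).
#' @param tables Validated costing tables.
#' @return Tibble with one row per participant-wave (`CostedWave` layout).
#' @export
cost_waves <- function(trial, tables = default_costing_tables()) {
  stopifnot(inherits(trial, "wl_trial"))
  rec <- trial$records
  cnt <- as.matrix(rec[, paste0("use_", 1:13)])
  cnt0 <- cnt
  cnt0[is.na(cnt0)] <- 0
  pub <- cost_use_matrix(cnt0, tables, "public")
  all_ <- cost_use_matrix(cnt0, tables, "all")
  key <- paste(rec$participant_id, rec$wave)
  dr <- trial$drugs
  drel <- rep(0, nrow(rec))
  dunr <- rep(0, nrow(rec))
  if (nrow(dr) > 0) {
    i <- match(dr$drug_code, tables$drug_prices$drug_code)
    if (anyNA(i)) {
      stop(
        "configuration error: unpriced drug code(s): ",
        paste(unique(dr$drug_code[is.na(i)]), collapse = ", ")
      )
    }
    sek <- dr$units * tables$drug_prices$sek_per_unit[i]
    cls <- tables$drug_prices$class[i]
    dkey <- paste(dr$participant_id, dr$wave)
    for (cl in c("related", "unrelated")) {
      agg <- tapply(sek[cls == cl], dkey[cls == cl], sum)
      j <- match(names(agg), key)
      if (cl == "related") drel[j] <- as.numeric(agg) else dunr[j] <- as.numeric(agg)
    }
  }
  out <- tibble::tibble(
    participant_id = rec$participant_id,
    arm = rec$arm,
    wave = rec$wave,
    responded = rec$responded,
    public_cost_1mo = pub[, 1], public_cost_3mo = pub[, 2],
    all_cost_1mo = all_[, 1], all_cost_3mo = all_[, 2],
    drug_cost_related = drel, drug_cost_unrelated = dunr
  )
  costcols <- setdiff(names(out), c("participant_id", "arm", "wave", "responded"))
  out[!out$responded, costcols] <- NA_real_
  out
}
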