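#' Attrition sensitivity transforms
#'
#' Implements the attrition scenarios: `complete_case` keeps only
#' participants who responded at every wave; `worst` (pessimistic) fills
#' missing observations with the 95th percentile of health-care use and
#' drug costs and the 5th percentile of HRQoL; `best` reverses the
#' percentiles. Percentiles are computed per outcome from observed values
#' pooled across arms and waves. On fully observed data every scenario is
#' the identity.
#'
#' @param om A `wl_outcome_matrix`.
#' @param scenario One of `"best"`, `"worst"`, `"complete_case"`.
#' @return A transformed `wl_outcome_matrix`.
#' @export
apply_attrition_scenario <- function(om,
                                     scenario = c("best", "worst", "complete_case")) {
  scenario <- match.arg(scenario)
  if (scenario == "complete_case") {
    full <- tapply(om$responded, om$participant_id, all)
    keep <- names(full)[full]
    out <- om[om$participant_id %in% keep, ]
    return(out)
  }
  for (o in wl_outcomes()) {
    y <- om[[o]]
    obs <- om$responded & !is.na(y)
    if (all(obs)) next
    # Lower tail is unfavourable for HRQoL, upper tail for use and costs.
    p_bad <- if (o == "hrqol") 0.05 else 0.95
    p <- if (scenario == "worst") p_bad else 1 - p_bad
    fill <- quantile(y[obs], p, names = FALSE, type = 7)
    y[!obs] <- fill
    om[[o]] <- y
  }
  om$responded <- TRUE
  om
}

#' Multiple imputation by predictive mean matching
#'
#' Imputes missing outcome values (whole non-responded waves and residual
#' item gaps) by predictive mean matching: for each outcome a linear
#' prediction from arm, wave and the participant's baseline value is fit
#' on observed post-baseline rows; each missing value takes the observed
#' value of one of the `k` donors nearest in predicted value, drawn
#' uniformly. Missing baseline values are matched within arm first.
#' Chained effects are estimated on each completed dataset and pooled by
#' Rubin's rules (mean of estimates; within- plus between-imputation
#' variance).
#'
#' @param om A `wl_outcome_matrix`.
#' @param m Number of imputations (>= 2).
#' @param k Donor-pool size (reduced with a warning when fewer donors are
#'   observed).
#' @param seed Integer seed.
#' @param estimator Effect estimator applied to each completed dataset:
#'   function of a `wl_cells` object (default [chain_waitlist_effects()]).
#' @return List with `imputations` (list of completed matrices) and
#'   `effects` (pooled `wl_effects`).
#' @export
impute_pmm <- function(om, m = 10, k = 5, seed = 1L,
                       estimator = chain_waitlist_effects) {
  stopifnot(m >= 2, k >= 1)
  set.seed(seed)
  ids <- unique(om$participant_id)
  base <- om[om$wave == 0, ]
  imps <- vector("list", m)
  any_missing <- FALSE
  for (it in seq_len(m)) {
    comp <- om
    for (o in wl_outcomes()) {
      y <- comp[[o]]
      # Baseline gaps: PMM within arm on the arm mean.
      b0 <- comp$wave == 0
      miss0 <- b0 & (!comp$responded | is.na(y))
      if (any(miss0)) {
        any_missing <- TRUE
        for (a in wl_arms()) {
          rows <- which(miss0 & comp$arm == a)
          don <- which(b0 & comp$arm == a & comp$responded & !is.na(y))
          if (length(rows) > 0) {
            y[rows] <- y[sample(don, length(rows), replace = TRUE)]
          }
        }
      }
      # Post-baseline gaps: linear prediction from arm, wave, baseline.
      idx_base <- which(b0)
      yb <- y[idx_base[match(comp$participant_id, comp$participant_id[idx_base])]]
      post <- comp$wave > 0
      obs <- post & comp$responded & !is.na(comp[[o]])
      miss <- post & (!comp$responded | is.na(comp[[o]]))
      if (any(miss)) {
        any_missing <- TRUE
        X <- cbind(
          1, comp$arm == "intervention",
          comp$wave == 6, comp$wave == 9, yb
        )
        beta <- qr.coef(qr(X[obs, , drop = FALSE]), y[obs])
        beta[is.na(beta)] <- 0
        pred <- as.numeric(X %*% beta)
        kk <- min(k, sum(obs))
        if (kk < k) warning("donor pool reduced to ", kk)
        ord_obs <- which(obs)
        for (r in which(miss)) {
          dist <- abs(pred[ord_obs] - pred[r])
          pool <- ord_obs[order(dist)[seq_len(kk)]]
          y[r] <- y[sample(pool, 1)]
        }
      }
      comp[[o]] <- y
    }
    comp$responded <- TRUE
    imps[[it]] <- comp
  }
  fits <- lapply(imps, function(ci) estimator(fit_joint_cell_means(ci)))
  dmat <- sapply(fits, function(f) as.vector(t(f$delta))) # 48 x m
  dbar <- rowMeans(dmat)
  Wbar <- Reduce(`+`, lapply(fits, `[[`, "vcov")) / m
  B <- if (any_missing) cov(t(dmat)) else matrix(0, 48, 48)
  V <- Wbar + (1 + 1 / m) * B
  delta <- matrix(dbar, 16, 3, byrow = TRUE,
    dimnames = list(wl_outcomes(), c("3", "6", "9")))
  pooled <- structure(
    list(
      delta = delta, vcov = V, n_clusters = fits[[1]]$n_clusters,
      estimator = "mi", single_arm = FALSE, cells = NULL
    ),
    class = "wl_effects"
  )
  list(imputations = imps, effects = pooled)
}
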