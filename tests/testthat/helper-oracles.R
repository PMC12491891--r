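# Monte Carlo oracles for the closed-form CEA/VOI layer, plus small
# deterministic fixtures shared across tests.

# Draws from the bivariate-normal (dE, dC) summary.
mc_draws <- function(inc, n, seed) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  e <- inc$mean_e + inc$se_e * z1
  c_ <- inc$mean_c + inc$se_c * (inc$rho * z1 + sqrt(1 - inc$rho^2) * z2)
  list(e = e, c = c_)
}

mc_prob_ce <- function(inc, lambda, n = 1e6, seed = 42) {
  d <- mc_draws(inc, n, seed)
  x <- lambda * d$e - d$c > 0
  list(est = mean(x), se = sd(x) / sqrt(n))
}

mc_prob_dominant <- function(inc, n = 1e6, seed = 42) {
  d <- mc_draws(inc, n, seed)
  x <- d$e > 0 & d$c < 0
  list(est = mean(x), se = sd(x) / sqrt(n))
}

mc_evpi <- function(inc, lambda, n = 1e6, seed = 42) {
  d <- mc_draws(inc, n, seed)
  nb <- lambda * d$e - d$c
  mu <- lambda * inc$mean_e - inc$mean_c
  # Opportunity loss of the expected-net-benefit-maximizing decision.
  loss <- if (mu > 0) pmax(0, -nb) else pmax(0, nb)
  list(est = mean(loss), se = sd(loss) / sqrt(n))
}

# Nested Monte Carlo EVPPI: outer draws of the learned component, inner
# draws of the other component from its conditional normal.
mc_evppi <- function(inc, lambda, component, n_outer = 4000, n_inner = 2000,
                     seed = 42) {
  set.seed(seed)
  mu_nb <- lambda * inc$mean_e - inc$mean_c
  inner_means <- vapply(seq_len(n_outer), function(i) {
    if (component == "effect") {
      x <- rnorm(1, inc$mean_e, inc$se_e)
      cm <- inc$mean_c + inc$rho * inc$se_c * (x - inc$mean_e) / inc$se_e
      cs <- inc$se_c * sqrt(1 - inc$rho^2)
      y <- rnorm(n_inner, cm, cs)
      mean(lambda * x - y)
    } else {
      x <- rnorm(1, inc$mean_c, inc$se_c)
      em <- inc$mean_e + inc$rho * inc$se_e * (x - inc$mean_c) / inc$se_c
      es <- inc$se_e * sqrt(1 - inc$rho^2)
      y <- rnorm(n_inner, em, es)
      mean(lambda * y - x)
    }
  }, numeric(1))
  gain <- pmax(0, inner_means)
  # inner-loop noise biases nested MC upward by at most phi(0) * sd(noise):
  # E[max(0, mu + eps)] - max(0, mu) <= sd(eps) * L(|mu|/sd(eps)) <= phi(0) sd(eps)
  cond_sd_nb <- if (component == "effect") {
    inc$se_c * sqrt(1 - inc$rho^2)
  } else {
    lambda * inc$se_e * sqrt(1 - inc$rho^2)
  }
  list(
    est = mean(gain) - max(0, mu_nb),
    se = sd(gain) / sqrt(n_outer),
    bias_bound = dnorm(0) * cond_sd_nb / sqrt(n_inner)
  )
}

# Incremental summary reconstructed from the published headline estimates
# (point estimates and 95% CIs, zero correlation unless overridden).
published_inc <- function(rho = 0) {
  incremental_from_summaries(
    mean_e = 0.0065, ci_e = c(-0.0219, 0.0349),
    mean_c = -46359, ci_c = c(-111696, 18977),
    rho = rho
  )
}

# Deterministic toy trial: `n_per_arm` participants per arm, all waves
# responded, HRQoL given by `hrqol_fun(arm, wave, i)`, all counts zero
# unless `count_fun` is supplied.
toy_trial <- function(n_per_arm = 2, hrqol_fun = function(arm, wave, i) 0.5,
                      count_fun = NULL) {
  grid <- expand.grid(
    i = seq_len(n_per_arm), arm = c("intervention", "waitlist"),
    wave = c(0L, 3L, 6L, 9L), stringsAsFactors = FALSE
  )
  rec <- tibble::tibble(
    participant_id = paste0(substr(grid$arm, 1, 1), grid$i),
    arm = grid$arm,
    wave = grid$wave,
    responded = TRUE,
    age = 40L,
    sex = "female",
    hrqol = mapply(hrqol_fun, grid$arm, grid$wave, grid$i)
  )
  for (j in 1:13) {
    rec[[paste0("use_", j)]] <- if (is.null(count_fun)) {
      0L
    } else {
      mapply(count_fun, grid$arm, grid$wave, grid$i, j)
    }
  }
  wl_trial(rec)
}

# A noise-free simulation spec: degenerate HRQoL, no counts, no drugs,
# full response. Any treatment effect shows up exactly.
noiseless_spec <- function(n_per_arm = 5, effect_hrqol = 0, ...) {
  cm <- default_count_models()
  cm$p_any <- 0
  dm <- default_drug_model()
  dm$related$p_user <- 0
  dm$unrelated$p_user <- 0
  n <- 2 * n_per_arm
  simulation_spec(
    n_intervention = n_per_arm, n_waitlist = n_per_arm,
    hrqol_sd_between = 0, hrqol_sd_within = 0,
    treatment_effect_hrqol = effect_hrqol,
    count_models = cm, drug_model = dm,
    treatment_effect_counts = rep(1, 13),
    count_frailty_sd = 0,
    retention = c(n, n, n), complete_cases = n,
    item_missing_rate = 0,
    ...
  )
}
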