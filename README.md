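# waitcea

Trial-based cost-effectiveness and value-of-information analysis for
**waitlist randomized controlled trials**, in which the control arm
receives the intervention after a delay and post-delay contrasts need a
constructed counterfactual comparator.

The package was built around the economic evaluation of an app-guided
self-management intervention for posttraumatic stress run alongside a
two-arm waitlist RCT (N = 179, assessments at 0, 3, 6 and 9 months,
3-month delayed access for the waitlist arm), but every stage is generic:
it applies to any two-arm waitlist trial with repeated HRQoL and
resource-use measurement.

## What it computes

**Chained counterfactual effects.** For each of 16 outcomes (an HRQoL
index, 13 resource-use items with mixed 1-month/3-month recall windows,
and related/unrelated drug costs), the treatment effect at 3 months after
exposure is the plain arm contrast, δ₃ = E(3) − W(3). Beyond the
controlled horizon the waitlist arm is itself exposed, so the comparator
mean at 6 months is constructed as W(6) − δ₃, giving
δ₆ = E(6) − (W(6) − δ₃), and similarly δ₉ = E(9) − (W(9) − δ₆). All
outcome equations are estimated jointly as a saturated arm×wave cell-mean
system with a cluster-robust (participant-level) joint covariance, so the
chaining — an exactly linear map — propagates covariance without
approximation.

**Discounted AUC aggregation.** Effects are cumulated over the 9-month
horizon: HRQoL by the trapezoid rule over months 0–3–6–9 on the year
scale (QALYs, anchored at zero effect at randomization), 3-month-recall
items by summing per-wave effects, 1-month-recall items by scaling each
wave by 3; each wave term is discounted at (1+r)^(−m/12), r = 3%/year.

**Cost-effectiveness plane, analytically.** Incremental effectiveness ΔE
(QALYs) and incremental cost ΔC (unit-costed public resource use + drug
costs + per-user app cost, SEK) are summarized as a bivariate normal.
With net monetary benefit NB = λ·ΔE − ΔC, the probability of
cost-effectiveness is Φ(μ_NB/σ_NB) — no Monte Carlo needed — and the
probability of dominance is the south-east orthant probability.

**Value of information.** EVPI per user is σ_NB·L(|μ_NB|/σ_NB) with
L(z) = φ(z) − z(1 − Φ(z)) the unit normal loss integral; EVPPI for the
effect or cost component uses the conditional-linear slope under
bivariate normality. Totals scale by the discounted user stream
Σ_t u/(1+r)^t.

**Sensitivity grid.** Difference-in-differences, baseline adjustment
(ANCOVA), single-arm pre-post, complete cases, best/worst-case attrition
imputation (5th/95th percentiles), multiple imputation by predictive mean
matching, private-care costing scope, more users, higher app cost.

**Synthetic trials.** `simulate_trial()` generates calibrated waitlist
RCT data (hurdle-model use counts, participant random effects, the
trial's exact response pattern 179/149/134/118 with 104 complete cases,
0.55% item-level missingness) so the full pipeline is testable without
microdata.

## Worked example: published summaries mode

The trial microdata are not deposited; the decision layers can be driven
directly from published point estimates and confidence intervals:

```r
library(waitcea)

inc <- incremental_from_summaries(
  mean_e = 0.0065,  ci_e = c(-0.0219, 0.0349),   # QALYs
  mean_c = -46359,  ci_c = c(-111696, 18977)     # SEK
)

prob_cost_effective(inc, 5e5)   # 0.9270613
prob_dominant(inc)              # 0.6178334

pop <- population_model(users_per_year = 988, horizon_years = 5,
                        discount_rate = 0.03)
discounted_users(pop)           # 4524.751
evpi_per_user(inc, 5e5)         # 1108.746 SEK
breakeven_dev_cost(inc, 5e5, pop)  # 224468358 SEK
qaly_multiple(inc, 5e5)         # 14.26431
```

Read: at a threshold of SEK 500,000 per QALY the intervention has a ~93%
probability of being cost-effective and a ~62% probability of dominating
(gaining QALYs *and* saving money); a one-off development cost of about
SEK 224 million would be needed before adoption stopped being worthwhile;
and the expected value of resolving all decision uncertainty is about
SEK 1,109 per user (≈5.0 million SEK over five user cohorts at zero
assumed ΔE–ΔC correlation; a modestly negative correlation raises this —
see the methods vignette).

## Full pipeline on synthetic data

```r
out <- run_pipeline(list(seed = 1), out_dir = "run1")
# writes trial.csv, drugs.csv, table1.csv (baseline), table2.csv
# (cumulative effects), table3.csv (sensitivity grid), ceac.csv, voi.csv,
# run_log.txt — deterministic given the seed
```

## File formats

- `trial.csv` — one row per participant-wave: `participant_id`, `arm`
  (`intervention`/`waitlist`), `wave` (0/3/6/9 months), `responded`,
  `age`, `sex`, `hrqol` (index in [0,1]), `use_1` … `use_13`
  (non-negative counts; items 1–5 past-month recall, 6–13 past-3-month,
  item 13 = inpatient days). Missing outcomes are empty fields.
- `drugs.csv` — `participant_id`, `wave`, `drug_code`, `units` consumed
  in the past 3 months.
- `unit_costs.csv` — `item`, `label`, `sek_per_unit`, `funding`
  (`public`/`private`), `recall` (`1mo`/`3mo`).
- `drug_prices.csv` — `drug_code`, `sek_per_unit`, `class`
  (`related`/`unrelated`).
- Pipeline configs are YAML mirroring `analysis_config()` /
  `simulation_spec()`.

The bundled unit-cost and drug-price tables
(`inst/extdata/*_synthetic.csv`) are synthetic: realistic in magnitude
for 2023 Swedish prices but not register extracts.

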