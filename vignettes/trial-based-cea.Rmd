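---
title: "Trial-based cost-effectiveness analysis for waitlist RCTs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based cost-effectiveness analysis for waitlist RCTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waitcea)
```

## The estimation problem

A waitlist design randomizes participants to immediate exposure
(intervention arm) or delayed exposure after 3 months (waitlist arm),
with outcomes measured at 0, 3, 6 and 9 months. Randomization identifies
the treatment effect at 3 months after exposure directly: the arm
contrast at wave 3, before the waitlist arm gains access. Beyond that
horizon both arms are exposed, so later effects need a constructed
counterfactual.

The chaining estimator rests on one assumption: *the effect of the
intervention at a given time since exposure is the same in both arms*
(guaranteed in expectation by randomization, though not in any finite
sample). Then the waitlist mean at wave 6 — which is 3 months after
*its* exposure — equals the untreated counterfactual mean plus the
3-month effect, so the comparator mean at 6 months is
$W(6) - \delta_3$ and

$$\delta_3 = E(3) - W(3),\qquad
  \delta_6 = E(6) - \big(W(6) - \delta_3\big),\qquad
  \delta_9 = E(9) - \big(W(9) - \delta_6\big).$$

Algebraically $\delta_h = \sum_{w \le h}\big(E(w) - W(w)\big)$: a
cumulative sum of per-wave arm contrasts, i.e. an exactly linear map of
the arm-by-wave cell means. Two consequences the package exploits:

* covariance propagation through the chain is exact (no delta method);
* statistical noise in $\delta_3$ propagates into $\delta_6$ and
  $\delta_9$, which is why chained estimates are less precise than a
  design with an unexposed control would give. This is visible in the
  package's simulations and is a property of the design, not the
  implementation.

Shared secular trends (e.g. natural recovery) cancel in every per-wave
contrast, so the chained effects are robust to them; this is exercised by
the noise-free tests.

## Joint estimation and the cluster-robust covariance

All 16 outcomes — the HRQoL index, 13 resource-use counts and two drug
cost aggregates — are estimated as one stacked, saturated arm×wave
cell-mean system (`fit_joint_cell_means()`). Point estimates are exactly
the per-cell sample means; what the joint system adds is the *joint*
covariance of all 128 coefficients, computed as a cluster-robust sandwich
with participants as clusters and the CR1 scaling $G/(G-1)$ for $G$
clusters. The joint covariance is what permits

* a joint Wald test that all 16 cumulative effects are zero, and
* the correlation between incremental effectiveness and incremental
  costs on the cost-effectiveness plane.

For the joint test the default reference distribution is $F(q, G-1)$
rather than $\chi^2_q$. With $q = 16$ restrictions and 179 clusters of
heavily skewed outcomes, the chi-square reference noticeably over-rejects
(about 9% at the 5% level in the package's null simulations), while the
F reference stays near 7–8%; $F(q, G-1)$ is also the conventional choice
in applied cluster-robust practice. The chi-square version remains
available via `joint_null_test(..., method = "chisq")`. The residual
over-rejection is a finite-cluster property of Wald tests on skewed
hurdle outcomes, documented rather than corrected away.

## From per-horizon effects to QALYs and costs

`aggregate_auc()` cumulates effects over the 9-month horizon
(per-quarter, on the year scale where applicable), with each wave term
discounted at its follow-up month $m$ by $(1+r)^{-m/12}$, $r = 0.03$ per
year by default:

* **HRQoL → QALYs**: trapezoid rule over months 0–3–6–9, anchored at a
  zero effect at randomization (randomization guarantees no effect at
  baseline). With constant effect $d$ and $r = 0$ this gives
  $0.625\,d$ QALYs. An alternative convention that holds $\delta_3$
  constant over the first quarter is available
  (`qaly_first_quarter = "flat"`); the ramp is the default because the
  effect curve starts at exposure.
* **3-month-recall outcomes** (items 6–13, drug costs): each follow-up
  wave reports its preceding quarter, so the cumulative effect is the
  discounted sum of the three per-wave effects.
* **1-month-recall outcomes** (items 1–5): the reported month is taken as
  representative of its quarter, so each per-wave effect is scaled by 3.
  This is the simplest convention consistent with recall windows that
  cannot simply be added; it is isolated in `aggregate_auc()` and the two
  recall classes are never summed directly.

Incremental cost per user is then
$\Delta C = \sum_{j \in \text{scope}} c_j\,\mathrm{AUC}_j +
\mathrm{AUC}_{\text{related}} + \mathrm{AUC}_{\text{unrelated}} +
c_{\text{app}}$, with the public funding scope
$\{1,2,4,6,7,8,9,12,13\}$ in the main analysis and all 13 items in the
private-care sensitivity scenario. The per-user app cost defaults to
SEK 12 (maintenance outlays divided by downloads); the upper bound
including development outlays is SEK 111. Confidence intervals are
normal-theory ($\pm 1.96\,\mathrm{SE}$), consistent with the central
limit theorem assumption the decision layer makes anyway.

## The decision layer

With $(\Delta E, \Delta C)$ bivariate normal, net monetary benefit at
threshold $\lambda$ is univariate normal, so the probability of
cost-effectiveness is $\Phi(\mu_{NB}/\sigma_{NB})$ exactly, the
probability of dominance is an orthant probability (computed by
one-dimensional quadrature of the conditional normal CDF), and the
expected value of perfect information per user is
$\sigma_{NB}\,L(|\mu_{NB}|/\sigma_{NB})$ with
$L(z) = \phi(z) - z\,(1-\Phi(z))$ the unit normal loss integral. EVPPI
for one component uses the conditional-linear slope
($\lambda - \rho\,\sigma_C/\sigma_E$ for the effect,
$\lambda\rho\,\sigma_E/\sigma_C - 1$ for the cost); all closed forms are
verified against seeded Monte Carlo oracles in the test suite. Ties
($\mu_{NB}=0$) return 0.5 by continuity; degenerate $\sigma_{NB}=0$
returns a decision by sign.

Population totals multiply per-user values by the discounted user stream.
Users are counted at the end of years $1..H$ (an ordinary annuity,
$988 \times 4.5797 \approx 4{,}525$ effective users under the defaults);
this convention reproduces the published break-even development cost of
roughly SEK 225 million from the printed inputs, whereas start-of-year
counting gives about 3% more. Both are available
(`population_model(..., timing =)`).

### Reconstruction from published summaries and the role of $\rho$

When only point estimates and confidence intervals are published, SEs are
recovered as CI half-width / 1.96 and the $\Delta E$–$\Delta C$
correlation is unknown. With $\rho = 0$ the reconstruction gives a 92.7%
probability of cost-effectiveness at SEK 500,000/QALY, 61.8% probability
of dominance, and a total EVPI of about SEK 5.0 million. A modestly
negative correlation (around $-0.10$) widens $\sigma_{NB}$, bringing the
probability of cost-effectiveness to just over 92%, flattening the
acceptability curve to within half a point across the entire threshold
range, and raising the EVPI to about SEK 5.4 million — jointly consistent
with a trial whose realized correlation was slightly negative. The
package treats $\rho$ as a free input in summaries mode precisely so this
sensitivity is explicit; when the pipeline is run on microdata, $\rho$ is
propagated from the joint covariance instead.

## Missing data

* **Item-level gaps** (sporadically missing questionnaire items within a
  responded wave, ~0.55% of cells): last observation carried forward,
  with next-observation-carried-backward at baseline. NOCB runs first, so
  a baseline filled from a later wave seeds LOCF for intermediate gaps
  and fills chain across consecutive missing waves; `chain = FALSE`
  restricts carrying to one step. An item missing at every responded wave
  stays absent with a warning.
* **Whole-wave attrition** is handled by scenario: cell means over
  responders (the main analysis, valid under missingness at random),
  complete cases only, best/worst-case imputation with the 5th/95th
  percentiles of the observed pooled distribution (HRQoL and use
  percentiles pointing in opposite directions by construction), or
  multiple imputation by predictive mean matching. Percentiles are pooled
  across arms and waves within outcome; per-wave stratification would be
  an alternative, but pooled percentiles are stable for rare items.
* **PMM** predicts each outcome from arm, wave and the participant's
  baseline value, draws uniformly among the `k = 5` nearest observed
  donors (so imputed values always lie in the observed support), and
  pools chained effects across `m = 10` imputations by Rubin's rules.
  The predictor set and donor count are conventional defaults; both are
  arguments.

## The synthetic trial generator

`simulate_trial()` emulates the study conditions so every stage is
testable without microdata:

* **Arms and waves**: 89/90 participants, waves 0/3/6/9, waitlist exposure
  delayed 3 months. Treatment effects are indexed by *time since
  exposure* and switch on only after exposure — exactly the assumption
  the chaining estimator needs, which makes injected effects recoverable
  end-to-end.
* **HRQoL**: generated directly on the index scale (baseline mean 0.564,
  cross-sectional SD ≈ 0.088 split into between- and within-participant
  components of 0.070 and 0.053), plus a small shared recovery trend.
  The disability-item stage behind the index is bypassed: the published
  mapping from disability items to utilities is external, and the
  analysis consumes only the index. Values are truncated to [0,1]
  (negligible at these parameters).
* **Use counts**: hurdle models per item — any-use Bernoulli (baseline
  probabilities matched to observed baseline any-use proportions, e.g.
  0.335 for general practitioner visits) times $1 + \text{NegBin}$,
  with a log-normal participant frailty (SD 0.5 on the log scale)
  inducing within-participant correlation. Positive-part means and
  dispersions are calibration choices: only any-use proportions and cost
  moments are observable targets, so they are set to plausible visit
  numbers and flagged as such. Treatment acts multiplicatively on the
  any-use probability.
* **Drug costs**: participant-level user flags per class (35%/38%), one
  drug code per user, log-normal quantities per wave; costs are heavy
  tailed like the observed cost SDs.
* **Response structure**: wave responses 179/149/134/118 and exactly 104
  all-wave responders, matched *exactly* by construction. These margins
  are mutually inconsistent with purely monotone dropout (which would
  force 118 complete cases), so the default allocation includes a small
  number of intermittent returners: 104 complete, 30 responding at
  0/3/6, 15 at 0/3, 14 at 0/9, 16 at baseline only. Monotone dropout is
  the special case `complete_cases = ` final retention. Item-level
  missingness is applied independently at 0.55% within responded waves.

What the generator does **not** emulate: informative (outcome-dependent)
dropout, measurement error in self-reported consumption, serial
correlation beyond the participant random effect, seasonal effects, or
the discrete support of the true utility index. Passing tests therefore
show that the estimators recover what this data-generating process
encodes — unbiased chained effects, calibrated covariances under
participant clustering, correct costing arithmetic — not that the
published trial's point estimates are reproducible, which they are not
without the microdata.

## Numerical choices and degenerate inputs

* Orthant probabilities use `stats::integrate` on the conditional-CDF
  integrand at `rel.tol = 1e-10`; $|\rho| = 1$ is nudged inside by
  `1e-12`.
* Rank-deficient joint covariances are pseudo-inverted (`MASS::ginv`)
  with a warning; the Wald degrees of freedom become the rank.
* A constant (e.g. all-zero) baseline covariate in the ANCOVA estimator
  aliases with the intercept and is dropped via the pivoted QR; if the
  arm contrast itself is inestimable the effect is reported as zero.
* Empty arm-wave cells (fewer than two observations) raise an error
  naming the cell rather than silently degrading.
* Simulation determinism: one `set.seed()` per `simulate_trial()` call;
  identical seeds give byte-identical datasets.

## Problem sizes used by the test suite

The suite validates calibration with 200 replicate trials (N = 179) for
parameter recovery and CI coverage, 500 replicates for the size of the
joint null test, Monte Carlo oracles with $10^6$ draws (nested
3000×1500 for EVPPI) on 20 randomized instances, and single large-sample
checks at N = 10,000 for law-of-large-numbers recovery. These sizes give
Monte Carlo error comfortably below the tolerances asserted while keeping
the default test run to a few minutes on one core.

## Known limitations

* The bivariate-normal plane and the normal-theory CIs lean on the CLT;
  with N = 179 and heavy-tailed cost outcomes, simulated CI coverage for
  incremental costs runs slightly under nominal (~93–95%), and the joint
  test is mildly liberal (above).
* Chained effects inherit compounding uncertainty from earlier horizons;
  this is the waitlist design, not a removable artifact.
* EVPI/EVPPI incorporate only the statistical uncertainty summarized by
  the bivariate normal — not structural choices such as the costing
  scope, the AUC conventions or the assumed user stream.
* The costing layer assumes unit costs are already at the analysis price
  level; price-index inflation is a pre-processing step outside the
  package.
* Inpatient care (item 13) is costed per day, the natural unit for a
  "number of inpatient days" item; per-admission costing would require
  admission counts that the instrument does not collect.
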