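---
title: "Methods: the PPI deprescribing cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PPI deprescribing cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppicea)
```

## The decision problem

Long-term PPI use in older adults is frequently inappropriate and carries
excess risks of hypomagnesemia, pneumonia and *Clostridium difficile*
infection (CDI). A pharmacist-led deprescribing service reviews each
regimen and recommends discontinuation, dose reduction, or a switch to an
H2RA; prescribers accept or decline, and accepted deprescribing can
provoke GERD rebound followed by reinstatement of the standard-dose PPI.
`ppicea` evaluates whether such a service is cost-effective against usual
care over one year, per patient evaluated, from the payer perspective.

## Tree structure and assumptions

`decision_cea()` enumerates 88 terminal paths (8 for usual care, 80 for
the deprescribing arm). The structural assumptions are:

* **Adverse events are mutually exclusive within the year.** Each exposure
  class branches over {hypomagnesemia, pneumonia, CDI, none} with
  `p_none = 1 - sum(p_event)`; joint occurrence is second-order at these
  rates. A parameter draw under which some exposure's event probabilities
  sum to ≥ 1 cannot form the tree and is rejected (see below).
* **Exposure mapping.** Usual care, appropriate use, declined
  recommendations and all rebound (reinstated) paths carry standard-dose
  odds ratios for the whole year; dose reduction without rebound carries
  low-dose odds ratios; discontinuation and H2RA switch without rebound
  carry the non-PPI baseline rates (no H2RA-specific odds ratios are
  published). Treating rebound patients as full-year standard exposure is
  justified by the short mean rebound onset (~20 days).
* **Event anatomy.** Hypomagnesemia has a hospitalization branch but no
  attributable mortality; non-hospitalized hypomagnesemia is a terminal
  path with zero cost and zero disutility (no ambulatory management is
  modelled). Pneumonia splits into outpatient care versus hospitalization
  with survive/die branches; all CDI cases are hospitalized with an
  in-hospital mortality branch.
* **Controlled symptoms carry no disutility.** Patients maintained on
  their PPI (either arm) lose no QALYs absent an adverse event; the
  relapse disutilities apply only to rebound episodes (off-medication
  after discontinuation, on-medication after dose reduction or switch),
  accrued over the rebound-onset period. This is one consistent reading of
  inputs labelled "symptomatic relapse"; it affects the absolute, not the
  incremental, QALY scale (see *Known limitations*).

## Payoff accounting

Costs (USD, undiscounted — the horizon is one year):

* medication: 12 × monthly cost of the regimen actually followed; months
  are converted at 30.4375 days/month, so reinstated paths charge the
  deprescribed regimen for `rebound_onset_days` and standard PPI for the
  remaining 365.25 − onset days;
* adverse events: length of stay × daily inpatient fee, or clinic visits ×
  visit fee for outpatient pneumonia; death paths keep the full admission
  cost;
* service: `salary / working_minutes_per_month × minutes_per_case`, once
  for every patient in the deprescribing arm;
* patients who die mid-year are still charged the full-year medication
  cost — a deliberate simplification, second-order at mortality
  probabilities of ~1%.

QALY losses: `disutility × duration/365` per episode. Hospitalized
pneumonia survivors add the ambulatory disutility over the 31-day
convalescence; on death paths the discounted death loss *replaces* any
post-event accrual. Death loses `utility × (1 - (1+r)^-LE) / r`, the
age-specific utility over the discounted annuity of the remaining life
expectancy (undiscounted limit `utility × LE` at r = 0).

## Parameters and run constants

All inputs live in one YAML config (`inst/extdata/hk_defaults.yaml`);
`load_parameters()` validates supports (probabilities and utilities in
[0, 1], costs and durations ≥ 0, `low ≤ base ≤ high`, recommendation mix
summing to 1) and rejects unknown keys by name. Run constants that are not
published as table rows:

| setting | default | why |
|---|---|---|
| `discount_rate_annual` | 0.03 | standard annual rate for the death-loss annuity |
| `wtp_threshold_usd` | 49,023 | 1× Hong Kong GDP per capita (2022), USD at 7.8 HKD/USD |
| `remaining_life_expectancy_years` | 10.1 | sex-averaged remaining life expectancy at the base-case age of 80 from the 2022 Hong Kong life tables (men ≈ 9.0, women ≈ 11.2). The source model reads this from a life table; the value itself is not published, so it is a required config input here |
| `pharmacist_working_minutes_per_month` | 10,560 | 22 working days × 8 h × 60 min; the published inputs give salary and minutes per case but not the divisor |
| `rebound_onset_days` | 20 | mean onset of rebound symptoms after discontinuation |
| `range_sd_divisor` | 3.92 | see distribution calibration |

The patient-age row (triangular, 65–88) is carried and sampled, but
because no life table linking age to remaining life expectancy is
published, age does not propagate to any outcome: it shows zero spread in
the tornado. Supplying region-specific `remaining_life_expectancy_years`
values is the supported route.

## Distribution calibration

The published inputs give base value, range and family only. `ppicea`
treats the range as an approximate central 95% interval: `sd = (high -
low) / 3.92`, then fits beta and gamma by the method of moments with mean
equal to the base value; the divisor is exposed as `range_sd_divisor`.
Triangular families use `(min = low, mode = base, max = high)` directly,
sampled by inverse CDF. Parameters with no published range are fixed in
both one-way and probabilistic analyses. The three recommendation-mix
probabilities are drawn as independent betas and renormalized to sum to 1
— the published table names per-branch beta families, not a Dirichlet —
and the same renormalization is applied at evaluation time so that
one-way variation of a single mix component remains well-defined.

## Numerical choices

* Path probabilities per strategy must sum to 1 within 1e-9 (asserted in
  tests on base and random draws).
* The vectorized rollback used by the sensitivity analyses is verified
  against the brute-force enumerated path sum to a relative 1e-12, and
  against 100 random synthetic chance trees with generation-time
  closed-form expectations (`generate_synthetic_model()`).
* PSA draws violating the adverse-event-sum constraint are rejected and
  resampled; the count is recorded on the result. At the bundled values
  this is essentially never triggered.
* Degenerate inputs are exact: fixed parameters always return the base
  value, and an all-fixed config reproduces the base case bit-identically
  across PSA draws.
* PSA summaries report both the normal-approximation 95% CI of the mean
  and the empirical 2.5/97.5 percentile interval, labelled separately:
  published "95% CI" values of this kind are CIs of the mean and are far
  narrower than the draw distribution.
* The tornado tracks the ICER by default to match the published diagram;
  with a dominant base case the ICER is negative and its spread is harder
  to read, so `tracked = "nmb"` is available and is the stabler choice
  whenever QALYs saved can cross zero inside a range.

## What the synthetic generator does and does not emulate

`generate_synthetic_model()` produces random chance trees (depth ≤ 4,
branching ≤ 3, Dirichlet branch probabilities) with terminal payoffs on
the scales of the real model (costs up to 10⁴ USD, QALY losses up to 10),
plus analytic expectations computed by direct summation at generation
time. It verifies the *expected-value engine* — probability bookkeeping
and rollback — not the clinical content: it contains no exposure logic,
no odds-ratio conversion and no payoff accounting, so passing it says
nothing about the correctness of those layers (they have their own
oracle tests). `perturb_parameters()` jitters base values inside their
sensitivity ranges to emulate region-specific parameter sets and is used
for end-to-end smoke testing.

## Problem sizes

The package's standard runs are: base case and one-way SA, deterministic
and sub-second; PSA at 10,000 draws (vectorized rollback, well under a
second), matching the published simulation count. The test suite uses
smaller draw counts (50–1,600) where only reproducibility or convergence
behaviour is being checked.

## Known limitations

* One-year horizon; no adverse-event recurrence, no Markov extension, no
  parameter covariance, no H2RA-specific adverse-event odds ratios, no
  indirect/productivity costs, no gut-microbiome outcomes.
* **The absolute QALY-loss scale of the published base-case table is not
  reproducible from the published inputs under this accounting.** With
  the bundled inputs this implementation obtains usual-care and
  deprescribing QALY losses of 0.0747 and 0.0660 (saving 0.0088), versus
  the published 0.2397 and 0.2148 (saving 0.0249). Working backwards,
  the published increment would require roughly 19 QALYs lost per death,
  whereas the maximum defensible loss at age 80 (utility 0.81, 3%
  discounting, ~10 remaining years) is about 7; the published absolute
  losses additionally imply a flat per-patient offset that no published
  input generates. The published tree is explicitly simplified and its
  exact QALY accounting is not printed, so this package documents its own
  accounting fully and keeps every choice in config. The *qualitative*
  conclusions — deprescribing dominant, no one-way threshold, ~100%
  probability of cost-effectiveness at the threshold — reproduce, and
  the cost side matches within a few percent.
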