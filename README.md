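# ppicea

Decision-analytic cost-effectiveness model of a **pharmacist-led proton pump
inhibitor (PPI) deprescribing service versus usual care** in older adults
(≥ 65 years) in ambulatory care, from a public healthcare provider
perspective with a one-year horizon.

## Who this is for

Health economists and pharmacy-service planners who want to (re-)evaluate a
PPI deprescribing program with their own regional inputs. Every model input
lives in a plain YAML configuration; the bundled default is a published Hong
Kong parameter set.

## The model

A hypothetical cohort of older PPI users enters a decision tree with two
arms. In the deprescribing arm a pharmacist reviews every regimen: with
probability *p*<sub>inappropriate</sub> the use is inappropriate and one of
three recommendations is made — discontinuation, dose reduction, or switch
to a histamine-2 receptor antagonist (H2RA) — each with its own prescriber
acceptance probability. Accepted deprescribing may trigger GERD rebound,
after which the standard-dose PPI is reinstated. In the usual-care arm all
patients continue standard-dose PPIs.

Each resulting drug exposure (standard PPI, low-dose PPI, H2RA, none)
carries yearly risks of three PPI-associated adverse events —
hypomagnesemia, pneumonia, and *Clostridium difficile* infection (CDI) —
obtained from non-PPI baseline rates *p₀* and odds ratios *OR* via

> p = OR·p₀ / (1 − p₀ + OR·p₀)

with hospitalization and (for hospitalized pneumonia and CDI) mortality
branches.

Per terminal path the model accrues **direct medical cost** (medication,
pro-rata by days; hospitalization days × daily fee; clinic visits; and the
pharmacist's time, salary-valued, once per patient evaluated) and **QALY
loss** (episode disutility × duration/365; plus, on death, the age-specific
utility times the 3 %-discounted annuity of the remaining life expectancy).
Expected values roll back per strategy, and the incremental analysis
reports the incremental cost, QALYs saved, the incremental
cost-effectiveness ratio ICER = ΔCost / ΔQALY with dominance
classification, and the net monetary benefit at a willingness-to-pay
threshold (default: USD 49,023/QALY, 1× Hong Kong GDP per capita).

Uncertainty is handled two ways:

* **One-way sensitivity analysis** over every non-fixed parameter's range,
  with tornado ranking and threshold detection;
* **Probabilistic sensitivity analysis (PSA)**: joint Monte Carlo draws
  from beta/gamma (method-of-moments on base value and range) and
  triangular distributions, common draws across both arms, with
  cost-effectiveness acceptability curves.

## Worked example

```r
library(ppicea)

fit <- decision_cea()          # bundled published parameter set
fit
#> Decision-tree cost-effectiveness analysis: PPI deprescribing vs usual care
#> one-year horizon, 88 terminal paths
#>
#>           strategy cost_usd incremental_cost_usd  qaly_loss  qaly_saved      icer
#>         Usual care 1264.735                   NA 0.07471082          NA        NA
#>  PPI deprescribing 1066.265            -198.4696 0.06595585 0.008754969 -22669.37
#>
#> Verdict: deprescribing is dominant and cost-effective at WTP USD 49,023/QALY
```

Deprescribing costs USD 198 less per patient-year and saves 0.0088 QALYs:
it *dominates* usual care (cheaper **and** more effective), so the negative
ICER is reported only for completeness. The probabilistic analysis:

```r
psa <- simulate(fit, nsim = 10000, seed = 42)
psa
#> Probabilistic sensitivity analysis: 10000 draws (seed 42)
#>   mean QALYs saved:  0.006938 (95% CI of mean 0.006897 to 0.006978; ...)
#>   mean cost saved:   USD 207.8 (95% CI of mean 207.2 to 208.4; ...)
#>   draws saving QALYs: 100.0%; saving cost: 100.0%; cost-effective at WTP 49,023: 100.0%

one_way_sa(default_parameters())
#> One-way sensitivity analysis (tracked outcome: icer)
#> base case: dominant, cost-effective at WTP 49,023
#> no threshold: the verdict is unchanged over every parameter range
#>                  parameter outcome_at_low outcome_at_high  spread
#>   disutil_relapse_off_meds         -21220          -41759 20538.0
#>    disutil_relapse_on_meds         -21633          -34943 13310.0
#>                 or_ppi_cdi         -28114          -19247  8866.9
#>  ...
```

`plot(psa)` draws the cost-effectiveness plane, `ceac(psa, wtp_grid)` the
acceptability curve, and `plot(one_way_sa(...))` the tornado.

## Command line

```sh
Rscript inst/cli/ppicea.R base-case --out-dir results
Rscript inst/cli/ppicea.R psa --n 10000 --seed 42 --out-dir results
Rscript inst/cli/ppicea.R owsa --config my_region.yaml --out-dir results
Rscript inst/cli/ppicea.R validate --config my_region.yaml
```

Each run writes CSV/JSON tables plus a `run_report.json` (config digest,
seed, package version) sufficient to reproduce it.

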