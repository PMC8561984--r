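# equicat

Socioeconomic health-equity analysis for individual-level household surveys:
who uses health services, how unequally use is distributed across living
standards, how much of that inequality is fair (need-driven) versus unfair
(socioeconomic), and who actually captures the money value of subsidized
care. The toolkit was built for refugee/humanitarian health-access surveys —
binary utilization indicators over short recall windows, household
consumption as the living-standards proxy, provider cost ledgers for the
subsidy side — but the estimators are generic.

## What it computes

For an outcome `y` (e.g. "visited a public outpatient facility in the past
month") and the weighted fractional rank `R` of each person in the
equivalized-consumption distribution (`Eq = consumption / size^0.56`):

- **Concentration index** `CI = (2/μ) Cov_w(y, R)`, with the **Wagstaff**
  normalization `CI_W = CI/(1−μ)` and the **Erreygers** correction
  `CI_E = 4μ(1−μ) CI_W` for binary outcomes. Negative = pro-poor,
  positive = pro-rich. Robust standard errors come from the convenient
  regression of `2σ²_R (y/μ)` on `R`.
- **Decomposition** of the CI into per-covariate contributions
  `(β^m_j x̄_j/μ) C_j` using a linear approximation of a probit model
  (marginal effects at means; weighted LPM fallback), with an exact residual
  term `GC_ε/μ`.
- **Horizontal inequity** `HI`: the CI of need-standardized use
  `y − ŷ^need + μ`, where `ŷ^need` predicts use from need factors (age,
  gender, disability, chronic disease) with non-need factors fixed at their
  means. Identically equal to CI minus the summed need contributions.
- **Benefit incidence**: per-service unit costs `c_k = spending_k/units_k`,
  gross benefits `α_k q c_k` and net benefits `α_k max(q c_k − f, 0)`
  (out-of-pocket `f` subtracted, negatives truncated to zero; `α = 13`
  annualizes the 4-week outpatient recall, `α = 1` for the 12-month
  inpatient recall), aggregated into quintile percentage shares with
  benefit concentration indices.
- A **synthetic survey generator** with a documented, margin-calibrated
  generative model (507 households, ~1,870 individuals, log-normal
  consumption, probit utilization) so every estimator is testable against a
  known population truth.

## Worked example

```r
library(equicat)
res <- run_all(list(seed = 1, out_dir = "equity_out"))
res$inequity[, c("outcome", "mean", "ci_wagstaff", "hi_wagstaff")]
```

On the default synthetic world (seed 1) this prints:

```
           outcome   mean ci_wagstaff hi_wagstaff
    use_out_public 0.1282     -0.1401     -0.1240
   use_out_private 0.1873      0.1784      0.1965
    use_inp_public 0.0748      0.0305      0.0387
   use_inp_private 0.0191      0.0698      0.0735
  total_outpatient 0.2717      0.0566      0.0781
   total_inpatient 0.0900      0.0262      0.0350
```

Reading: public outpatient care is *pro-poor* (CI_W = −0.14 — the poorest
quintile uses it at 0.160 vs 0.082 for the richest), private outpatient
care strongly *pro-rich* (CI_W = +0.18). After removing need-driven
differences, inequity (HI) is larger than raw inequality for the pro-rich
services, because need (chronic disease rising with age, concentrated among
the poor) pulls the other way. The decomposition confirms the driver:

```r
group_contributions(res$decomposition_outpatient)
#  consumption contributes +0.0719 of the total CI (0.0412);
#  chronic disease contributes -0.0172 (pro-poor need offset)
```

Benefit incidence (`res$benefits`): with the ledger's 28.6% / 71.4%
outpatient/inpatient subsidy split, public-outpatient gross benefits are
pro-poor (benefit CI −0.12, poorest-quintile share 25.0%), and subtracting
out-of-pocket payments shifts net benefits further (CI −0.16 here; in
worlds with steeper OOP gradients the net distribution turns pro-rich).

The same pipeline runs on real files:

```r
ds <- read_survey("individuals.csv", "households.csv")
ds <- build_weights(ds, read_population("population.yaml"))
ranked <- rank_dataset(ds, theta = 0.56)
inequity_table(ranked)
benefit_shares(individual_benefits(ranked, read_cost_ledger("costs.yaml")),
               ranked)
```

A command-line interface with `simulate` / `equity` / `decompose` /
`inequity` / `bia` / `run` subcommands lives at `inst/cli/equicat.R`.

## Layout

- `R/survey_io.R` — data model, CSV/YAML I/O, post-stratification weights,
  sample-size formula
- `R/living_standards.R` — equivalization, weighted fractional ranks,
  quintiles
- `R/concentration.R` — CI, Wagstaff/Erreygers, robust SEs, quintile tables
- `R/decomposition.R` — probit partial effects at means, additive CI
  decomposition
- `R/inequity.R` — indirect need standardization, horizontal inequity
- `R/bia.R` — unit costs, gross/net benefits, quintile shares
- `R/synthetic_data.R` — generative model + population-truth oracle
- `R/cli_report.R` — descriptive/unadjusted tables, full-pipeline runner
- `vignettes/health-equity-methods.Rmd` — model, assumptions, design choices
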