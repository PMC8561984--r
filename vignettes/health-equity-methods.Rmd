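---
title: "Measuring inequality and inequity in healthcare use: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inequality and inequity in healthcare use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicat)
```

This vignette is the package's own account of the statistics it implements:
the model behind each estimator, the assumptions it leans on, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the places where the design was genuinely open and a choice
had to be made.

## 1. The setting

The pipeline targets cross-sectional household health surveys of the kind
used to monitor healthcare access in displaced populations: households are
sampled (here, stratified by governorate), every member's use of four
service types is recorded as a binary indicator — public and private
outpatient care over a 1-month recall, public and private inpatient care
over 12 months — together with the out-of-pocket (OOP) amount paid per
service, household consumption by expenditure class, and demographic and
socioeconomic covariates. The question is not just *how much* care is used
but *who* uses it along the living-standards gradient, and whether the
money value of subsidized provision reaches the poor.

## 2. Living standards: equivalized consumption and fractional ranks

Consumption proxies living standards (incomes in informal labour markets
are unreliable and volatile). Household economies of scale are damped with
a one-parameter equivalence scale,

\[ Eq = \frac{\text{household consumption}}{(\text{family size})^{\theta}},
\qquad \theta = 0.56 \text{ by default,} \]

an exponent estimated in the literature from dozens of country surveys.
`theta` is exposed everywhere (`rank_dataset(..., theta = )`, `--theta` in
the CLI); `theta = 1` gives per-capita consumption. No other equivalence
scales (OECD, square root) are offered — the exponent spans the practical
range.

Every member carries the household's equivalized consumption. The ranking
variable is the **weighted fractional rank**: sort ascending, then
\(R_i = (\text{cum. weight before } i + w_i/2)/W\). Its weighted mean is
exactly 0.5, which makes two computational routes for the concentration
index agree to machine precision (Section 3).

**Ties.** Tied consumption values share their pooled block's midpoint rank —
the convention that keeps the mean rank at 0.5 and preserves attainable
index bounds. Quintiles, however, are assigned from *individual* midpoint
positions in stable sort order, so that weighted quintile shares are 20%
each up to one observation's weight even when many values tie (e.g. several
members of one household). The consequence, documented and tested: ranks and
all downstream indices are exactly replication-invariant (an integer weight
behaves like that many unit records), while the quintile *label* of a heavy
record can differ from its copies' labels when a block straddles a quintile
boundary. Quintiles are person-weighted, not household-weighted: the
analysis is individual-level, and the survey's published quintile tables are
over individuals.

## 3. The concentration index and its corrections

For outcome \(y\) with weighted mean \(\mu > 0\),

\[ CI = \frac{2}{\mu}\,\mathrm{Cov}_w(y, R) \in [-1, 1], \]

negative when use concentrates among the poor. Weighted covariance uses the
population convention (normalized weights), under which
\(CI = (2/\mu)\sum \tilde w_i y_i R_i - 1\) holds exactly; the test suite
checks both against an \(O(n^2)\) pairwise oracle.

For **binary** outcomes the attainable range shrinks to \(\pm(1-\mu)\), so
two corrections are reported: Wagstaff's \(CI_W = CI/(1-\mu)\) (a
*relative* measure, the default reporting scale) and Erreygers'
\(CI_E = (4\mu/(b-a))\,CI\) (an *absolute* measure), which for binary
outcomes satisfy \(CI_E = 4\mu(1-\mu)\,CI_W\) identically — asserted at
machine precision in the tests. \(\mu = 0\) is an error (no utilization, no
index); \(\mu = 1\) leaves the Wagstaff version undefined (NA).

**Standard errors.** The source analyses report significance stars without
naming a variance estimator, so the package uses the standard "convenient
regression": the WLS slope of \(2\sigma^2_R\, y_i/\mu\) on \(R_i\) equals
the CI, and its heteroskedasticity-robust (HC1-type, effective-sample-size
corrected) standard error is reported, with stars at 0.05/0.01/0.001.
Degenerate outcomes (constant \(y\)) return CI 0 with se 0 and a flag
rather than an error.

## 4. Decomposition

Utilization is modelled as a probit in need factors \(x_j\) (age in years,
gender, disability, chronic disease), non-need factors \(z_k\) (urban,
governorate dummies, household size, head's education, duration of asylum,
service knowledge, head's employment) and the consumption rank. The probit
is **linearized at the means**: working coefficients are the marginal
effects \(\beta^m_j = \phi(\bar x'\hat\theta)\hat\theta_j\), and the
intercept is set so the linear approximation reproduces \(\mu\) at the
means. Then

\[ CI = \sum_j \underbrace{\frac{\beta^m_j \bar x_j}{\mu}}_{\text{elasticity}} C_j
      + \sum_k \frac{\gamma^m_k \bar z_k}{\mu} C_k
      + \frac{GC_\varepsilon}{\mu}, \]

where \(C_j\) is the covariate's own concentration index and
\(GC_\varepsilon\) the generalized CI of the linearization error. Because
every term is a covariance, additivity is *exact by construction* — the
residual computed as \(CI - \sum\) contributions equals \(GC_\varepsilon/\mu\)
to machine precision, for the probit approximation and for the weighted
linear-probability fallback alike (the fallback triggers on
non-convergence or separation, with a warning). This is also why dummy
covariates get continuous marginal effects rather than discrete-change
effects: discrete changes would break the additive identity.

Encoding choices (open in the source material, fixed here): age enters as a
single continuous covariate (the reference tables report one "Age" row);
education as two dummies against the lowest level; duration of asylum as an
ordinal score 1–4 (one reported row implies a scalar); governorate as
dummies against Cairo. Merging dummies into a group sums their
contributions exactly (`group_contributions()`). Sampling weights enter the
probit by default (`use_weights = FALSE` to toggle — whether the original
analysis weighted its probit is unstated). Contributions are computed on the
plain-CI scale; percentage contributions are scale-free, and the table also
carries \(CI_W\) and \(CI_E\) of the total.

## 5. Horizontal inequity

Inequity is inequality not explained by need ("equal treatment for equal
need"). Need-predicted use evaluates the fitted linear approximation at
actual need values with non-need factors at their weighted means; the
standardized outcome is

\[ \check y_i = y_i - \hat y_i^{\text{need}} + \bar{\hat y}, \]

whose weighted mean equals \(\mu\) exactly (the linearization is
mean-preserving). \(HI = CI(\check y)\), Wagstaff-normalized by the *actual*
outcome's \(1 - \mu\). Two routes — the CI of \(\check y\) and
\(CI - \sum\) need contributions — coincide identically for the linear
approximation (both are linear in the same coefficients), a stronger
property than the LPM-only exactness one might expect; the tests assert
agreement to 1e−10 for both model types. Standardized use may leave
\([0,1]\) and is deliberately not clipped: clipping would destroy both mean
preservation and the additive identity. The need set
{age group, gender, disability, chronic disease} is configurable via
`build_design()` for sensitivity runs. Because published inequity tables
cover single services as well as the combined outcomes, a separate model is
fitted per outcome.

## 6. Benefit incidence

Unit cost per service: \(c_k = \) total provider spending / total units.
Per person and service, with \(q\) the utilization quantity, gross benefit
\(= \alpha_k q c_k\) and net benefit \(= \alpha_k \max(q c_k - f, 0)\),
where \(f\) is the person's OOP for that service and \(\alpha_k\)
standardizes recall windows to one year: 13 for outpatient (4-week recall,
52/4), 1 for inpatient. Three deliberate conventions:

- \(q = 1\) per positive any-use report — the survey records whether, not
  how often; benefits are therefore a lower bound on utilization intensity.
- OOP is netted *within* service before annualization
  (\(\alpha_k(q c_k - f)\)), matching the yearly-benefit definition.
- Self-reported OOP exceeding the unit cost would give a negative subsidy;
  following the applied literature the negative is truncated to zero (this
  mutes differences and is flagged as a known bias of net-benefit shares).
- Services without a ledger entry (private providers) get \(c_k = 0\): no
  program subsidy, so private OOP never generates negative program benefit.

Quintile shares are weighted sums normalized to column percentages; each
benefit amount also gets a plain (continuous-variable) concentration index
— no binary normalization applies, and published benefit CIs are not used
as validation targets because their weighting conventions are unstated.
When the ledger is supplied, the per-service "share of total subsidies" row
reproduces the ledger's spending split.

## 7. The synthetic world

`generate_survey(synthetic_config())` draws, by default: 507 households;
household size \(1 + \text{NegBin}\) matched to mean 3.6, sd 2.2 (shifted
so no empty households, overdispersed as real rosters are); governorate,
education, employment, duration and age-group shares set to the survey's
published margins (shares that print to a sum of 100.1% are renormalized);
equivalized consumption log-normal with meanlog 4.4285, sdlog 0.55 —
chosen so the five quintile means land near \$40/\$63/\$82/\$113/\$189
against the published \$40.3–\$182.4 (a two-parameter family cannot hit all
five printed means; the tails match, the second quintile is ~10% low);
chronic disease from a probit rising with age and falling with consumption
rank, calibrated to 20.4% prevalence (this makes its concentration index
negative, as observed); disability at 3.4% independent of rank; and
per-service probit utilization with rank coefficients −0.5 (public
outpatient), +0.8 (private outpatient), +0.1 / +0.3 (inpatient) encoding
the observed pro-poor/pro-rich sign structure. Intercepts are calibrated
once by `scripts/calibrate_coefficients.R` (root-finding on a 400k-person
covariate simulation) so the use means hit 0.13/0.18/0.07/0.02, and are
frozen in the defaults; the script ships so the calibration is
reproducible. The OOP model — price × Beta-distributed fraction whose mean
rises with rank — is a stated assumption of the generator, not a claim
about any real survey (no OOP distribution is published); OOP is drawn only
for users and is capped at the service price.

Members share their household's consumption, so estimators face the
intra-household correlation present in real data. The generator does **not**
emulate: non-response and its correlates, within-household correlation of
utilization beyond shared covariates, measurement error or recall bias in
OOP and use, seasonality, or any joint distribution beyond the documented
margins and gradients. A green test therefore establishes that the
estimators recover a known generative truth under realistic marginal
structure — not that the synthetic world reproduces the real survey's joint
distribution.

`true_concentration_index()` is the recovery oracle: it simulates fresh
individuals directly from the generative model (using exact population
ranks, `plnorm`) and returns the population CI with its Monte-Carlo
standard error; estimator recovery is asserted within 3 combined standard
errors.

## 8. Numerical and edge-case policy

- Sample-size formula: \(n = z^2 p(1-p)/d^2\) with *relative* precision
  \(d = \text{rel} \cdot p\) (the reading under which \(p = 0.5\), 10%,
  \(\alpha = 0.05\) gives the published 384). The raw value is rounded
  half-down (384.16 → 384, 96.04 → 96); plain ceiling would contradict the
  published figure.
- Post-stratification weights are household-level, inherited by members,
  normalized to mean 1; a stratum with population but no sampled households
  warns (weight undefined there).
- Missing OOP with positive use is read as "none reported" → 0 with a
  warning; positive OOP without use is a validation error.
- All analysis is in USD; EGP files convert at load (default 17.6 EGP/USD).
- Chi-square comparisons in the unadjusted table are plain Pearson
  \(\sum (O-E)^2/E\) without continuity correction (matching the generic
  test label); Yates correction is available by flag. Expected cells below
  5 raise a warning annotation.
- Report percentages round half-up to one decimal (`round_half_up()`), the
  convention of the published tables, not banker's rounding.
- Degenerate inputs: empty rank input, zero-mean outcomes, rank-deficient
  designs and zero-unit ledgers with positive spending are all errors that
  name the offending column or service.

## 9. Known limitations

Decomposition results carry no causal interpretation; only one
rank-dependent index family is decomposed (no Erreygers-basis
decomposition); concentration-curve dominance testing and
Taylor-linearized complex-survey variance are out of scope (probability
weights only); and subsidy-per-unit is an imperfect valuation of benefits.
These mirror the acknowledged limits of the underlying methodology.
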