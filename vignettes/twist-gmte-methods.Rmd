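---
title: "Estimating genetically moderated treatment effects from primary-care prescribing records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetically moderated treatment effects from primary-care prescribing records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxtwist)
```

## The problem

Dihydropyridine calcium-channel blockers (dCCBs, e.g. amlodipine) are
first-line antihypertensives. A number of common variants — in genes such as
*RYR3*, *CYP3A5*, *NUMA1*, *APCDD1* and *ADRA1A* — are reported to modify
their effectiveness or adverse-event profile. `pgxtwist` implements the full
analysis chain needed to study such variants in linked primary-care data:

1. **Cohort construction** — turn raw dated prescription and diagnosis
   records into per-patient treatment episodes, incident outcomes and
   covariates;
2. **Association scan** — per-variant Cox proportional-hazards models among
   treated patients, with Benjamini–Hochberg correction;
3. **TWIST triangulation** — estimate the *genetically moderated treatment
   effect* (GMTE) on the additive-hazards scale, combining several
   estimators with different assumptions;
4. **Impact translation** — convert a per-year GMTE into an
   avoidable-diagnosis count and a percent reduction in incidence.

Because the motivating data source is application-controlled, the package
ships a synthetic cohort generator with the same statistical structure, so
every stage is testable end to end without any restricted download.

## The additive-hazards model and the GMTE

Let $T_i \in \{0,1\}$ indicate ever-treated (at least one dCCB
prescription) and $G_i$ the coded genotype (by default the dominant carrier
indicator). The working model is the Lin–Ying additive-hazards model with
time-constant coefficients,

$$\lambda_i(t) = \lambda_0(t) + \beta_T T_i + \beta_G G_i +
  \beta_{GT}\, G_i T_i + \gamma' X_i,$$

where $X_i$ are covariates (age at first prescription, sex, genetic
principal components). The quantity of interest is $\beta_{GT}$, the
**GMTE**: the extra events per carrier per year that occur *because* the
carrier is on treatment. A constant-coefficient model is used because the
estimand is a single per-year risk difference; `lin_ying_fit()` solves the
closed-form least-squares estimating equation over risk sets and reports
robust (sandwich) standard errors. Coefficients are per person-year;
follow-up time is measured in years from the first dCCB prescription
(treated) or study entry (untreated).

The time axis itself models length of exposure — no separate
treatment-duration covariate is used, in either the Cox scan or the
additive-hazards fits.

## The TWIST estimator suite

For one variant and outcome, `run_twist()` computes:

* **GMTE1** — genotype coefficient among treated patients. Unbiased for
  $\beta_{GT}$ if the variant has no direct effect ($\beta_G = 0$).
* **GMTE0** — genotype coefficient among patients never prescribed a dCCB.
  Should be null under the exclusion restriction; it is reported and its
  nullity is flagged, because a non-null GMTE0 invalidates GMTE1 and MR.
* **RGMTE** — `GMTE1 - GMTE0`, variance summed (disjoint subsets). Robust
  to a constant direct genotype effect.
* **MR** — full-sample genotype coefficient divided by the treated
  proportion; valid under the exclusion restriction plus
  genotype-independent treatment assignment.
* **CAT** — difference of adjusted treated-vs-untreated coefficients
  between carrier strata; requires no unmeasured treatment–outcome
  confounding *that differs between genotype strata* (see below).

`combine_ivw()` computes Cochran's $Q$ on candidate sets and, where the
$Q$ p-value exceeds $\alpha = 0.05$, the inverse-variance-weighted mean
with variance $1/\sum w$. The selection rule prefers the largest combinable
set among $\{RGMTE, MR, CAT\}$ (robust estimators first), then pairs in
that order, falling back to RGMTE alone; every component and every pairwise
$Q$ is surfaced so any selection can be audited. Estimates entering the
combination are treated as independent, as the triangulation framework
prescribes. This is exact for RGMTE vs GMTE0-free quantities and a close
approximation otherwise; when the treated and untreated event rates are
equal (as under the null generator) the RGMTE–MR overlap covariance
vanishes, and the combined test's type-I error is checked at the 5% level
in the test suite under exactly that configuration. With a non-null
treatment effect the independence approximation is mildly anticonservative;
the component estimates are always reported alongside the combination.

Two-sided normal p-values and $\pm 1.96\,\mathrm{se}$ Wald intervals are
used throughout.

### A note on CAT and confounding

In a purely additive model with a confounder that is independent of
genotype, the confounding bias of the as-treated contrast is *identical* in
carrier and non-carrier strata and cancels exactly in the CAT difference.
The often-quoted sensitivity of CAT to treatment–outcome confounding
therefore binds only when the confounding differs between genotype strata
(or the model is misspecified, e.g. truly multiplicative hazards). The test
suite demonstrates both facts on the generator: per-stratum as-treated
coefficients are clearly biased under the confounded assignment mode, while
CAT and RGMTE both remain near the generating value.

## Impact translation

Given a per-year GMTE $\hat\beta_{GT}$, the carrier patient-years $PY_c$
accrued by treated carriers in the model, and the total diagnoses $E$ among
treated patients,

$$\text{avoidable count} = \hat\beta_{GT} \times PY_c, \qquad
  \text{percent reduction} = 100 \times
  \frac{\hat\beta_{GT} \times PY_c}{E}.$$

Confidence limits transform through the same linear map. `ci_from_p()`
back-calculates a standard error from a printed estimate/p-value pair so
published intervals can be audited. Counts are reported unrounded and
rounded; because published GMTEs are typically printed at two significant
figures, comparisons against published counts should allow roughly $\pm 2$
diagnoses.

## The synthetic cohort generator

`sim_config()` fixes the data-generating process; the defaults are the
study conditions the pipeline is meant to emulate:

| Parameter | Default | Meaning |
|---|---|---|
| `n_patients`, `p_treated` | 221 000, 0.1406 | ~31 000 treated plus an untreated pool of ~190 000 (the untreated-comparator size is not published; 190 000 is the order of the GP-linked population minus the treated) |
| `variant_mafs` | shipped panel | genotypes drawn Binomial(2, MAF), i.e. Hardy–Weinberg |
| `beta_interact` | 0.00069/y | the true GMTE (study-scale effect) |
| `beta_treat`, `baseline_hazard` | 0.0017/y, calibrated | plumbing: chosen/calibrated so treated non-carrier incidence is 5.4% over follow-up |
| `beta_geno` | 0 | exclusion restriction holds by default |
| entry window | 1990-01-01 to 2011-05-31 | uniform accrual; administrative censoring 2016-05-31 |
| `dropout_rate` | 0.02/y | GP deduction (removal from the register) |
| age, sex | 61.3 (7.7), trunc. [40, 79.3]; 45.6% female | cohort descriptives |
| `rx_per_year_mean` | 9.2 (4.6) | repeat-prescription intensity |
| `episode_years_mean` | 5.9 | *observed* mean episode length; the latent scale is calibrated against dropout, switching and the accrual window |
| `switch_rate` | 0.02/y | switching to another antihypertensive class |

Construction-time validation guarantees every genotype-by-treatment
subgroup hazard is non-negative (an error, never silent truncation), and
identical seeds give byte-identical record bundles.

`sim_config_ryr3_hf()` is the headline fixture: carrier frequency 0.708
among ~31 000 treated, $\beta_{GT} = 0.00069$/y, baseline calibrated in
closed form (`calibrate_hazard()`) so the treated cohort accrues roughly
1 800 outcome events — the scale at which the estimator-recovery studies
run.

What the generator deliberately does **not** emulate: linkage
disequilibrium between panel variants (one causal variant at a time, the
rest null), imputation uncertainty, non-European allele frequencies,
dose/quantity structure, free-text prescriptions, and informative (outcome-
dependent) censoring. Passing tests therefore show the estimators recover
the truth under the model's own assumptions — not that those assumptions
hold in any particular real cohort.

One record-level compromise: repeat prescriptions are laid down at the
configured 9.2/year intensity but with inter-script gaps capped below the
90-day switch-definition gap, so continuing therapy is never mistaken for a
switch; this floors the realized prescriptions-per-year for the slowest
prescribers slightly above the nominal mean.

## Cohort-construction rules

* **Treated cohort**: at least one dCCB prescription
  (`min_prescriptions` configurable); episode = first to last dCCB issue
  date; censoring at GP deduction or the administrative end of prescribing
  data (2016-05-31), whichever is first.
* **Untreated comparators**: patients never prescribed any dCCB; their time
  origin is study entry, taken as the first record date — a choice the
  source analyses leave open, made explicit here.
* **Incident outcomes**: first matching diagnosis strictly after the origin
  and on/before the effective censor date; patients with a diagnosis on or
  before the origin are flagged `prior` and excluded from that outcome's
  incident analysis (the prior-disease subgroup keeps them, by design).
* **Switching**: first issue of a non-dCCB antihypertensive after the first
  dCCB prescription with no further dCCB within `gap_days = 90`. The
  switch rule is nowhere operationalized in the source literature; the
  package adopts this explicit, parameterized definition so results are
  reproducible.
* Dates are day-resolution; intervals convert to years by /365.25.

## Numerical and design choices

* Cox models use Efron tie handling (GP-resolution dates tie heavily);
  robust SEs are optional and off by default.
* BH correction is applied within outcome across the variant panel;
  per-contrast p-values of a genotypic model enter as separate rows.
* The Cox scan runs among treated patients only; genotype effects in the
  untreated belong to TWIST's GMTE0.
* `run_twist()` accepts dominant, additive or recessive codings. The
  genotypic (two-indicator) coding is scan-only: a TWIST decomposition
  needs a single carrier contrast, and analyses of variants with similar
  heterozygote and homozygote effects use the dominant coding.
* Monomorphic variants are skipped with a warning; separation in a Cox fit
  is an error naming the variable; singular additive-hazards designs error
  listing the collinear columns.
* Large recovery studies (~220 000 rows per replicate) adjust for age and
  sex; the ten principal components in the generator are independent noise
  and add nothing but variance at that scale. They are included by default
  in `run_twist()` whenever present in the table.
* Problem sizes in the shipped checks: 20–60 replicates at the full
  ~221 000-patient scale for estimator recovery; 500 replicates of
  4 000-patient cohorts for the type-I-error calibration; file round-trip
  checks at 4 000 patients.

## Known limitations

* The additive-hazards coefficients and Cox hazard ratios are different
  scales; the scan's HRs are not expected to match the additive truth, and
  only direction/calibration are asserted against the generator.
* The IVW combination ignores the (small) finite-sample correlation between
  RGMTE and MR when the treatment effect is non-null (see above).
* The shipped drug-class and diagnosis-code maps are illustrative defaults
  covering the synthetic records; production use on real extracts requires
  the cohort-specific code lists.
* Time-varying GMTE trajectories, multi-variant joint models and
  competing-risks outcomes are out of scope.
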