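---
title: "Methods: code aggregation and the high-dimensional propensity score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: code aggregation and the high-dimensional propensity score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

In claims-based pharmacoepidemiology, the high-dimensional propensity score
(hd-PS) algorithm generates thousands of binary covariates from the codes a
patient accumulates during a baseline window, prioritizes them by confounding
potential, and adjusts the treatment-outcome association through deciles of a
propensity score built from the top-ranked covariates. Medical codes are
hierarchical: drug codes roll up the five ATC levels, and ICD-9 diagnoses roll
up 3/4/5-digit stems or the multi-level CCS groupings. Aggregating codes before
running hd-PS raises covariate prevalence (sub-codes pool into their parent),
which can push an otherwise-invisible confounder past the algorithm's
minimum-frequency screen -- but it can also dilute covariate-exposure and
covariate-outcome associations and therefore lower a covariate's priority.
`hdpsagg` implements the full experimental pipeline needed to study this
trade-off under small cohorts, rare outcomes, and low exposure prevalence,
with a synthetic claims generator standing in for proprietary claims data.

# The synthetic cohort model

Each patient carries independent latent binary confounders $Z_j \sim
\mathrm{Bern}(p_j)$. Exposure follows a logistic model

$$\mathrm{logit}\, P(A=1\mid Z) = \alpha + \sum_j \beta_j Z_j,$$

with $\alpha$ solved numerically (`uniroot` on the cohort-average probability)
so the marginal exposure prevalence hits its target exactly in expectation.
The binary 60-day outcome follows a log-link risk model

$$P(Y=1\mid A,Z) = \pi_0 \cdot RR_t^{A} \cdot \exp\!\Big(\sum_j \gamma_j Z_j\Big),$$

so `true_rr` ($RR_t$) is a marginal risk ratio under no effect modification --
matching the use of risk ratios throughout the analysis stack. Risks at or
above 1 are clipped just below 1 with a warning; if more than 1% of patients
would need clipping the generator aborts with a calibration error rather than
silently distorting the risk model.

Any monotone link would serve for exposure; logistic is the convention. The
baseline window and the 60-day outcome window are collapsed into single binary
flags -- no stage of the pipeline consumes event dates, so simulating them
would add nothing testable.

## Default calibration

The defaults describe one study condition and are not meant to be tuned per
run: 18,829 patients, 38.2% exposed, outcome incidence near 0.6%, $RR_t =
0.50$, and six confounders whose joint effect biases the crude risk ratio to
roughly 1 -- i.e. net upward confounding by indication of about a factor of
two. The confounder set spans a realistic prevalence range (22% down to 1.4%):
common comorbidity-like flags with modest effects, and two rare, strong,
anticoagulant/antiplatelet-like confounders (outcome risk ratios 4-5, exposure
odds ratios ~6). The rarest confounder (prevalence 0.0138, about 260 carriers
at full cohort size) is the designated *sub-threshold split* confounder: with
`sub_threshold_split = TRUE` its pharmacy signal is scattered over sibling
level-5 codes so that every child occurs in fewer than 100 patients while the
common level-4 parent covers all carriers. This reconstructs, by design, the
situation where a confounder is selectable only after aggregation.

Occurrence counts are zero-truncated geometric (success probability 0.55,
mean ~1.8). The distribution of within-patient counts is not documented for
real claims at this granularity; the zero-truncated geometric is the simplest
overdispersed choice that keeps the once/sporadic/frequent recurrence tiers
non-degenerate. Spurious "noise" codes arrive at 6 per patient, spread
uniformly over the five dimensions and a background pool of 12 codes per
dimension. Twelve is a deliberate scaling-down of the thousands of distinct
codes in a real database: it keeps every noise code comfortably past the
100-patient screen (so screening, prioritization and selection all do real
work) while keeping propensity models at a size where a full resampling
experiment runs in minutes. The extended pre-selected covariates are noisy
measurements of the first confounders (sensitivity 0.9, false-positive rate
0.02), so the basic+extended model adjusts partially and the empirical
covariates still have signal to add.

## What the generator does not emulate

Proxy codes are deterministic given carriage (every carrier emits the code),
confounders are mutually independent, and noise codes carry no outcome or
exposure association. Real claims have miscoded and missing proxies,
correlated comorbidity clusters, and weakly informative background codes.
Passing tests therefore demonstrate that the algorithmic machinery behaves as
specified under a known data-generating process -- not that aggregation will
help to any particular degree on real data.

# The covariate engine

For each of the five dimensions (pharmacy, inpatient/outpatient diagnoses,
inpatient/outpatient procedures) the engine:

1. ranks codes by number of distinct patients (ties broken by code text) and
   keeps the top `n_per_dimension` (default 200);
2. computes recurrence cutoffs per code over patients having the code:
   *sporadic* = smallest integer at or above the median count, *frequent* =
   smallest integer at or above the nearest-rank 75th percentile;
3. expands each code into once/sporadic/frequent indicators, dropping
   indicators whose patient set duplicates an already-emitted indicator for
   the same code (nested sets are equal exactly when equal in size; the least
   restrictive label is kept, avoiding perfectly collinear columns);
4. screens out indicators in fewer than `min_patients` patients (default 100,
   boundary inclusive; 0 disables the screen as in the algorithm's later
   revision) and indicators with any structural zero cell in the
   covariate-exposure or covariate-outcome table;
5. prioritizes by the Bross bias multiplier
   $B = \dfrac{p_{c1}(r-1)+1}{p_{c0}(r-1)+1}$ with
   $r = \max(rr_{cd},\, 1/rr_{cd})$, ranking on $|\ln B|$, and keeps the top
   `k_select` (default 500) with deterministic tie-breaks.

Forcing $r \ge 1$ makes ranking by $B$ and by $|\ln B|$ equivalent, which
settles the otherwise ambiguous treatment of protective covariates. The
top-200 prevalence cut is taken *before* recurrence expansion, and recurrence
cutoffs are computed after the aggregation scenario has been applied, with
duplicate (patient, code) rows merged by summing occurrence counts first --
summing (not max) because occurrences are event counts, and merging first so
post-aggregation recurrence tiers remain meaningful. The engine contains no
randomness; identical inputs give identical selections.

# Aggregation scenarios

A scenario pairs a medication setting (`generic`, `atc1`..`atc5`, `none`) with
a diagnosis setting (`icd5`, `icd4`, `icd3`, `ccs1`..`ccs4`, `ccs_universal`,
`none`). ATC aggregation is prefix truncation to widths 1/3/4/5/7; ICD-9
truncation keeps the first 3 or 4 significant characters with V/E prefixes
counting as part of the stem; CCS settings look codes up in a 4-level
cross-map, with `ccs_universal` taking the deepest available level. Codes
absent from the cross-map (or lacking the requested level) pass through
unchanged and are counted in the run report -- dropping them would silently
delete confounder signal, and pass-through keeps aggregation idempotent.
Diagnosis codes are stored without decimal points internally and rendered with
them in reports. Procedure codes always pass through: appropriate procedure
hierarchies are an open problem and out of scope here.

# Models

Five specifications per (sample, scenario): (1) the closed-form crude risk
ratio with the Katz log-scale interval; (2) log-binomial outcome regression on
exposure plus basic covariates (age continuous, sex, index-year indicators --
a single-year cohort drops the year term automatically); (3) plus the
extended flags; (4) exposure plus decile indicators of a propensity score
fitted on basic + selected empirical covariates; (5) as (4) with the extended
flags also inside the propensity model. Putting the predefined covariates
inside the PS (rather than alongside the deciles) follows the convention that
the algorithm "augments" its automatic selection with investigator-defined
covariates.

Log-binomial fits at ~0.6% incidence frequently fail to converge; the
fallback is a modified-Poisson fit with HC0 sandwich variance, flagged
per model so summary tables can report fallback rates. On fixtures where both
converge the two agree within 1% relative. Propensity scores come from
maximum-likelihood logistic regression with constant/duplicate columns pruned
up front and a one-shot drop-and-refit for covariates implicated in
separation. Deciles are cut at the pooled empirical quantiles (type 7); ties
at a boundary all fall to the lower stratum; cut points merged by mass ties
are reported.

# Resampling conditions

Six conditions, each defaulting to 100 replicates: 50%/20% simple random
samples of the whole cohort (conditions 1/2); 50%/20% of the cases kept as
cases with the rest re-coded to non-cases, all records retained (3/4);
50%/20% of the exposed kept, with removed exposed replaced by unexposed
patients drawn with replacement and appended under fresh identifiers, events
copied (5/6). Sample sizes round by `ceiling(fraction x pool)` -- the rule
inferred from the published margins (3,599 = ceiling of 0.5 x 7,197; 1,440 =
ceiling of 0.2 x 7,197; 17,389 unexposed records in condition 6), where floor
and round-half-even both fail. With-replacement replacement draws are the only
consistent reading when every unexposed patient is already retained;
duplicates get new identifiers so downstream stages treat them as distinct
patients. Each (condition, replicate) runs on its own deterministic child
seed, so replicate r is identical across scenarios and any sample can be
regenerated in isolation.

# Evaluation metrics

Replicate risk ratios are summarised by the geometric mean and the 25th/75th
percentiles (linear interpolation; the percentile definition is a documented
choice), with non-finite replicates excluded and counted. Variable coverage
is the percentage of full-cohort-selected covariates -- keyed by (dimension,
code, recurrence level) -- re-selected in a sample. Residual confounding of an
estimate is $|\ln RR - \ln RR_t|$ with $RR_t = 0.50$ by default (a named,
overridable constant; the choice shifts magnitudes but not scenario
rankings). The proportional confounding difference of a scenario against the
base scenario is the relative change in residual confounding, in percent,
computed from *unrounded* geometric means; rounding happens only at render
time. (Computing from 2-decimal rounded inputs shifts the worked example from
-16.3% to about -16.5%; the unrounded convention matches the printed value.)

# Problem sizes used in the shipped tests

The test suite exercises the pipeline at sizes chosen to make Monte-Carlo
checks sharp while keeping a laptop-scale run: parameter-recovery uses 50
replicate cohorts of n = 20,000; the aggregation-mechanism experiment runs the
full 6-condition grid at the default cohort size with 20 replicates per
condition and two scenarios. Both are statements of the package's own testing
design; the functions themselves accept the full 16-scenario, 100-replicate
grid.

# Known limitations

- The generator's independence assumptions (confounders, noise codes) are a
  deliberate simplification; no attempt is made to reproduce any real
  database's covariate distribution.
- No instrumental-variable or collider screening; no zero-cell correction;
  no exposure-only or outcome-only prioritization variants; no PS matching,
  weighting or trimming -- adjustment is by decile indicators only.
- Procedure codes are never aggregated.
- Small samples with rare outcomes can overfit decile outcome models; the
  fallback flags, exclusion counts and error log in the experiment report are
  the intended diagnostics.
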