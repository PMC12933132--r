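---
title: "Methods: Markov-boundary discovery and causal-predictive survival modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov-boundary discovery and causal-predictive survival modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures, the assumptions they lean on, the tunable parameters with
their defaults and rationale, what the synthetic-data generator does and
does not emulate, and the numerical conventions that make runs
bit-reproducible.

## The statistical model

The outcome is binary survival at one or more time horizons (alive = 1,
deceased = 0 at 2, 5, 10 years after baseline). All causal claims are
*local*: we look for the Markov boundary (MB) of the outcome — the
minimal set **M** with *V* ⫫ *T* | **M** for every measured *V* outside
**M** — not for a full causal graph. Three assumptions drive the causal
reading:

1. **Terminal outcome.** Nothing measured is downstream of the survival
   indicator, so the MB contains no effects or spouses; under the
   remaining assumptions it is exactly the set of direct causes.
2. **Causal sufficiency.** No unmeasured common causes of the measured
   variables and the outcome. This is an assumption, not a finding; when
   it fails, intersection variables may be non-causal yet remain
   statistically indispensable predictors.
3. **Faithfulness, up to information equivalence.** Real omics data
   violate faithfulness through duplicated or transformed signals. We do
   not assume the MB is unique; instead the equivalence class of all MBs
   is enumerated, and only its intersection is reported as potential
   direct causes.

## Conditional-independence layer

Mixed data types need more than one test (`testIndependence`):

- `logistic-lrt` (default whenever the dependent variable is the binary
  outcome): likelihood-ratio chi-square comparing `T ~ Z + x` with
  `T ~ Z`. Matches the logistic effect models used downstream.
- `fisher-z` among continuous variables: partial correlation through QR
  residualization, statistic `atanh(r) * sqrt(n - |Z| - 3)`.
- `g2-discrete`: G-test on contingency tables after quantile
  discretization (default 3 bins) of variables with more than 5 distinct
  values. Being rank-based, the discretization makes this test invariant
  to monotone transforms.

**Reliability rule.** A test with fewer than 5 effective samples per
parameter (per degree of freedom for G²) is flagged unreliable and
returns the independence verdict. This is the standard conservatism in
constraint-based discovery: at small *n* relative to |Z|, declaring
dependence would inflate false adjacencies.

**Defaults.** `alpha = 0.05` throughout (configurable); degenerate inputs
(constant variables, aliased predictors) return p = 1; ties in
association ranking break by |statistic| then lexicographic variable id,
so every run is deterministic.

## GLL boundary induction (`gllMB`)

Candidates enter a queue in decreasing marginal association (variables
not associated at `alpha` are excluded immediately with an empty sepset).
After each admission, members are re-tested — newest first, the
semi-interleaved convention — against every conditioning subset of the
other members up to `max_k` (default 3, the "GLL-K-3" configuration),
in increasing subset size then lexicographic order. The first accepting
subset evicts the member and is recorded as its sepset; the sepset is
*not* re-minimized afterwards, so `sepsetReport` stays faithful to the
run. Sweeps repeat until no member can be evicted. Conditioning-set
search order means the recorded sepset is the smallest explanatory set
found first, and identical data + config give byte-identical traces.
CI results are memoized within a run (they are pure functions of the
data), which roughly halves runtime without changing any decision.

The optional OR-symmetry correction (`symmetryCheck`) re-runs discovery
around each member and drops members whose own neighborhood lacks the
outcome. With a terminal outcome it is redundant; it defaults to off, and
when on it never removes silently (every removal is traced).

## Equivalence-class enumeration (`enumerateMBs`)

Generate-and-verify: starting from the boundary on the full data,
removal sets from the union of accepted boundaries are masked in
increasing cardinality (default: all singletons and pairs), the inducer
re-runs on the masked data, and a set-distinct candidate is accepted iff
it verifies on the *original* data. The loop closes when no unprocessed
removal set remains; a hypothesis budget (default 100 re-inductions)
bounds worst-case work, and exhausting it flags the class
`possibly-incomplete`.

**Verification criterion** (left open in the method literature's
supplements; both knobs are exposed):

- `independence` (default): one joint likelihood-ratio test of
  `T ~ candidate + W` vs `T ~ candidate`, with `W` the reference members
  outside the candidate plus a capped deterministic sample of the
  remaining variables. A single joint test rather than per-variable
  marginal tests keeps the false-rejection rate of a genuinely
  equivalent boundary at one test's level; the verification alpha
  defaults to 0.01, deliberately stricter than discovery so that
  discarding an equivalent boundary requires strong evidence.
- `performance-equivalence`: cross-validated logistic AUC of the
  candidate must be non-inferior to the reference on shared stratified
  folds — paired DeLong CI lower bound above −0.02 (configurable margin;
  the margin is a design choice, not an estimate). Degenerate
  single-class folds are refolded with a new derived seed.

A practical limitation follows from the parametric default: invertible
*nonlinear* transforms of a variable are information-equivalent in
principle, but a linear-logistic LRT does not see them as such. The
rank-based `g2-discrete` test does; with the default test, equivalence
enumeration is guaranteed only for linear-equivalent copies (duplicates,
rescalings, exact noisy copies in the infinite-SNR limit).

## Predictive-modeling protocol

`nestedCV` implements stratified repeated nested cross-validation:
model selection by inner-loop mean AUC, performance estimation in the
outer loop, feature selection (including the GLL selector) strictly
inside training folds. Defaults are 10 outer × 10 inner folds × 10
repeats, all configurable; the registered model menu is random forest
(500 trees, mtry ∈ {√p, p/3}) and logistic regression (plain, or ridge
with a 1/n penalty), crossed with the all-features and GLL-K-3
selectors. `fitValidate` fits the final configuration on all training
rows and scores an independent holdout once, with a DeLong-variance
normal 95% CI (2000-replicate bootstrap fallback for degenerate
variance). `compareAUCs` is the paired DeLong test on shared samples;
ties count 0.5 in all AUCs (Mann-Whitney convention, checked against
exhaustive pairwise concordance in the tests). `permutationAudit`
re-runs the *complete* pipeline on wholesale-permuted labels; the
p-value is `(1 + #{permuted ≥ observed}) / (1 + B)`, and a permuted mean
AUC above 0.5 + 2 SE flags estimation bias (leakage).

## Effects and interventions

Per boundary, `estimateEffects` fits the outcome on the boundary members
with continuous predictors z-scored and binary predictors left 0/1 (so a
coefficient is the effect of a category flip, and sign interpretation
survives standardization). Quasi-separation — diverging standardized
coefficients or IRLS failure — triggers a ridge refit (penalty 1/n) and
a `separation` flag; flagged variables are reported, not hidden, and are
excluded from intervention defaults. Box summaries across boundaries use
standard quartiles; the published whisker formulas for this display are
internally inconsistent (left whisker written as min(max(x), Q1 + 1.5
IQR)), so standard Tukey box statistics are implemented and the
discrepancy documented rather than guessed around.

`simulateIntervention` is a do-operation on the inputs: each intervened
variable is set, for every participant, to its 5th (hampers) or 95th
(promotes) percentile computed on the training cohort, and the
*observational* fit is re-evaluated — the model is not refit, which is
the natural reading of a model-based counterfactual. Percentiles use
type-7 (linear interpolation) quantiles. Note a consequence: the few
participants already beyond the target percentile are moved *toward* it,
so per-participant monotonicity holds for all but that tail fraction;
the cohort mean is asserted not to decrease. Fold changes are
`p_post/p_pre` (survival direction) and `(1 − p_pre)/(1 − p_post)`
(death direction), rendered rounded half-up to one decimal; a zero
denominator yields an infinite-fold sentinel, never an error.

Intervention scopes: `smrna-only` = intersection-called molecular
variables; `all-causes` = the union across boundaries.

## Synthetic cohorts: what they emulate, and what they do not

`buildTruthNetwork`/`sampleCohort` generate cohorts whose *structure*
matches the analysis assumptions: a handful of direct causes among many
noise variables; negative-binomial count variables (log link on a latent
Gaussian, dispersion default 5) emulating overdispersed small-RNA
abundances; Gaussian and 4-level ordinal clinical variables; an age-like
variable; engineered equivalence groups (exact duplicates, noisy copies
with configurable SNR that reduce to duplicates as SNR → ∞, invertible
monotone transforms). Outcomes at all horizons share one latent uniform
thresholded per horizon, so (i) each horizon's marginal model is exactly
logistic in the population-standardized causes with the declared
coefficients — making coefficient recovery a sharp test — and (ii)
horizon labels are nested (dead at 2 years ⇒ dead at 5), with intercepts
chosen so survival prevalence declines with horizon (defaults 0.85 /
0.55 / 0.30), reproducing both the class imbalance and the declining
predictivity at longer horizons. Default effect sizes alternate ±0.75,
the magnitude scale of the standardized effects the method reports on
real cohorts. `customTruthNetwork` adds arbitrary DAG structure
(mediator chains, confounders) through linear-Gaussian child nodes.

What the generator does **not** emulate: real marginal distributions of
any particular cohort, platform-specific measurement artifacts or batch
effects, missing data, or the dependence structure among hundreds of
real transcripts (block correlation via latent factors is available but
defaults to off, since no published estimate of that structure exists to
calibrate it). Passing tests on these cohorts therefore demonstrate
correctness of the algorithms under the stated assumptions — not
real-data performance, which requires accession data outside this
package's scope.

Two independent oracles check the pipeline: graphical d-separation
(moralized ancestral graph) for faithful structures, and a brute-force
enumeration of minimal sufficient sets that additionally collapses
exact-equivalence copies onto their source (graphical d-separation alone
cannot see determinism-induced equivalence).

## Reproducibility and problem sizes

All randomness flows from one integer master seed through a
deterministic child-seed derivation; identical config + seed give
byte-identical artifacts (hashed in the run manifest). The test suite
exercises the stated study conditions at desk scale on one CPU:
boundary recovery at n = 4000 over 50 cohort draws (5 causes, 25 noise
variables, F1 ≥ 0.9); equivalence enumeration against the brute-force
oracle on networks of ≤ 8 variables at n = 4000; CI-test calibration on
1000 null replicates at n = 500 per method; nested-CV null calibration
over 20 pure-noise datasets (n = 200, 5 outer folds × 2 repeats);
effect recovery over 25 draws at n = 4000 with intervention means
checked against an independent Monte-Carlo draw at n = 10000. These
sizes are the package's chosen reference conditions; all are arguments,
not constants.

## TMM normalization

`tmmNormalize` implements trimmed-mean-of-M-values scale factors for the
count arm: reference sample by upper-quartile/library-size ratio closest
to the mean; per-pair M and A values on genes nonzero in both samples;
double trim (30% on M, 5% on A); inverse approximate binomial variances
as weights; factors re-centered to geometric mean 1. The unit tests pin
the implementation to the reference implementation in edgeR to 1e-12 and
to a step-by-step hand computation on a toy matrix; identity and
pure-depth cases are exact.

## Known limitations

- Causal conclusions are conditional on causal sufficiency and the
  terminal-outcome argument; neither is testable from the data.
- The default verifier cannot certify nonlinear information equivalence
  (see above).
- Sepsets are reported as mediators-or-confounders without orientation;
  no claim distinguishes the two.
- The permutation audit detects protocol-level optimism; it cannot
  detect biases that survive label permutation (e.g. batch structure
  aligned with splits).
- `runProtocol` keeps each stage's defaults modest; production-scale
  runs should raise the NCV repeats and permutation counts in the
  `RunConfig`.
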