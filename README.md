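# survMB

Local causal discovery and causal-predictive modeling for survival
biomarkers.

## The problem

Cohort studies that profile hundreds of circulating molecular markers
(e.g. small non-coding RNA abundances) alongside clinical variables often
want two different things from the same data: an **unbiased predictive
model** of survival at fixed time horizons, and a short list of
**candidate direct causes** worth validating experimentally. `survMB`
implements both arms for dichotomized survival outcomes:

- **Markov boundary (MB) induction.** The MB of an outcome *T* is the
  non-reducible variable set **M** such that every other variable *V*
  satisfies *V* ⫫ *T* | **M**. When *T* is terminal (nothing downstream of
  death) and there is no unmeasured confounding, the MB is exactly the set
  of direct causes of *T*. The inducer is a generalized-local-learning
  (GLL) algorithm with bounded conditioning (`max_k`, default 3 —
  "GLL-K-3"), interleaving association-ranked admission with subset-search
  elimination, and recording for every excluded variable the **sepset**
  that screened it off (its mediators or confounders).
- **Equivalence-class enumeration (TIE\*-style).** Omics data routinely
  contain information-equivalent variable sets (duplicated signals,
  transformed copies), so the MB need not be unique. A generate-and-verify
  loop masks subsets of discovered boundaries, re-runs the inducer, and
  keeps every candidate that verifies as statistically equivalent on the
  original data. Variables in the **intersection** of all equivalent
  boundaries are the defensible direct-cause calls.
- **Effects and in-silico interventions.** Per boundary, a logistic model
  with standardized predictors yields standardized effect sizes (sES);
  box summaries range each variable's effect across the class. A
  percentile intervention sets each putative cause to its 5th (if it
  hampers survival) or 95th (if it promotes survival) training percentile
  and re-scores the fitted model, reporting survival fold increases and
  death fold reductions (rounded half-up to one decimal).
- **Honest performance estimation.** Stratified repeated nested
  cross-validation (selection strictly inside training folds), double
  holdout external validation with DeLong confidence intervals, paired
  AUC comparisons, and an outcome-label permutation audit that flags
  protocol-level leakage.
- **Synthetic ground truth.** A cohort generator with a known causal DAG
  (terminal outcome, negative-binomial count variables, ordinal/Gaussian
  clinical variables, engineered equivalence groups, nested multi-horizon
  labels) plus graphical d-separation and brute-force
  minimal-sufficient-set oracles, so every stage is testable without any
  external data. TMM (trimmed mean of M-values) normalization is included
  for the count matrix arm.

## Worked example

```r
library(survMB)

## ground truth: 3 direct causes among 20 noise variables, with an exact
## duplicate of X1 engineered into the data
net <- buildTruthNetwork(n_noise_vars = 20, n_direct_causes = 3,
                         effect_sizes = c(-0.75, 0.75, -0.6),
                         equivalence_spec = list(
                           list(source = "X1", mode = "duplicate")),
                         seed = 1)
cohort <- sampleCohort(net, n_samples = 3000, seed = 2)

ec <- enumerateMBs(cohort, "survival_2y", DiscoveryConfig(alpha = 0.05, max_k = 3))
ec
#> EquivalenceClass for 'survival_2y': 2 boundary(ies)
#>   sizes 3-3; intersection {X2, X3}
```

Two equivalent boundaries are found: the duplicated pair `X1`/`X1_eq1`
never co-occurs, each copy appears in half the boundaries, and only the
untouched causes `X2`, `X3` are called potential direct causes:

```r
summarizeClass(ec)
#>   variable frequency in_intersection                                    interpretation
#> 1       X2       1.0            TRUE potential direct cause (given causal sufficiency)
#> 2       X3       1.0            TRUE potential direct cause (given causal sufficiency)
#> 3       X1       0.5           FALSE                          equivalence-class member
#> 4   X1_eq1       0.5           FALSE                          equivalence-class member

eff <- estimateEffects(cohort, ec, "survival_2y")
eff[, c("variable", "presence_frac", "median", "direction")]
#>   variable presence_frac     median direction
#> 1       X1           0.5 -0.8348266   hampers
#> 2   X1_eq1           0.5 -0.8348266   hampers
#> 3       X3           1.0 -0.6559755   hampers
#> 4       X2           1.0  0.6337981  promotes
```

The recovered sES medians match the generative coefficients (−0.75, 0.75,
−0.6) to within sampling error, and the duplicate inherits its source's
effect exactly. An in-silico intervention setting every boundary member to
its favourable percentile:

```r
model <- attr(eff, "fits")[[1]]
iv <- simulateIntervention(model, cohort,
                           mbMembers(mbBoundaries(ec)[[1]]),
                           scope = "all-causes")
iv
#> InterventionResult [all-causes]: mean survival 0.799 -> 0.979
#>   (1.2-fold increase; 9.5-fold death reduction)
```

i.e. the cohort's mean predicted 2-year survival rises from 79.9% to
97.9%, a 9.5-fold reduction in the predicted probability of death
(`foldChange(0.799, 0.979, "death")`).

The full protocol — nested CV, external validation, permutation audit,
boundary enumeration, effects, interventions, sepset report, with a
hashed artifact manifest — runs from one configuration object via
`runProtocol(RunConfig(...), cohort = cohort)`.

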