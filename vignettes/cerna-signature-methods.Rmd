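---
title: "Methods: ceRNA network inference and lncRNA risk signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference and lncRNA risk signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernasig)
```

## The model

`cernasig` operationalizes the competing-endogenous-RNA (ceRNA)
hypothesis as a screening procedure over paired expression profiles. A
lncRNA *l* is called a ceRNA partner of a driver gene *g* when three
conditions hold simultaneously on the same cohort:

1. *g* and *l* are positively co-expressed (Pearson r > 0, two-sided
   t-transform p < α);
2. at least `min_shared` validated miRNAs regulate both *g* and *l*;
3. each such shared miRNA *m* is negatively co-expressed with both *g*
   and *l* (r < 0, and by default p < α on both).

Each surviving (g, m, l) combination is a ceRNA *triple*; the union of
triples defines a tripartite network whose edges are the induced
gene–miRNA and miRNA–lncRNA pairs (gene–lncRNA pairs are evidence, not
edges). The procedure is deliberately simple — raw Pearson correlations,
raw p-values — because that is how such networks are screened in
practice; the package's contribution is making every gate explicit,
deterministic (outputs sorted lexicographically) and testable against a
brute-force enumerator.

The prognostic stage treats the network lncRNAs as candidate biomarkers.
On a 50/50 seeded train/test split:

- univariate Cox proportional-hazards regression keeps candidates with
  Wald p < 0.05;
- bidirectional stepwise selection minimizes the AIC
  (−2 logPL + 2k) over multivariate Cox models, starting from the full
  screened model;
- the selected features are refitted jointly; their coefficients βj and
  the median training risk score define the signature
  `score = Σ βj · EXj`, cutoff = training median.

The cutoff is part of the signature and is *never* re-derived on a new
cohort: high risk means score strictly greater than the stored cutoff.
Expression enters the score untransformed, because a transferred linear
model with a fixed cutoff is only meaningful if the scale it was trained
on travels with it.

## Survival machinery

Cox fitting, Kaplan–Meier estimation and the log-rank test are delegated
to the `survival` package behind a small validated surface (`fit_cox`,
`km_curve`, `logrank_test`). Ties use the Efron approximation by default
(Breslow optional). Choices fixed here:

- Wald 95% intervals use the normal quantile 1.959964;
  `hazard_ratio = exp(coef)` by construction.
- `AIC = -2 logPL + 2k` with k the number of covariates.
- Median survival is defined as the smallest t with S(t) ≤ 0.5 (an
  explicit convention: some software averages across an S = 0.5 plateau)
  and is `NA` when S never reaches 0.5. The 5-year rate is S(1825 days).
- Rows with missing covariates are list-wise dropped per model with a
  logged count; constant or collinear covariates are an error naming the
  columns; non-convergence and monotone likelihoods are reported as
  `converged = FALSE`, not raised.
- Degenerate designs are errors up front: no events, negative times,
  single non-empty group in the log-rank test.

The test suite holds this machinery to independent oracles: a hand-coded
Efron partial likelihood maximized by golden-section search (agreement to
|Δβ| < 1e−4 on n ≤ 20 instances), a hand-tabulated product-limit table,
the exact identity between the Cox score test and the log-rank chi-square
on tie-free binary designs (1e−6), and the zero-censoring identity
between the Kaplan–Meier curve and the empirical survival fraction
(machine precision).

## Stepwise selection

The stepwise search is written out rather than delegated so its move
semantics are fixed: at each step all single-feature removals and
additions are scored; the best move is applied only if it *strictly*
lowers the AIC; ties prefer removal over addition, then lexicographic
feature id; removals never empty the model; failed fits make a move
unavailable rather than aborting. Directions `"backward"` and
`"forward"` are available; the default `"both"` starts from the full
screened model, which mirrors conventional stepwise usage on a screened
candidate set. Greedy search can stop in a local AIC minimum; the test
suite compares it against exhaustive all-subsets enumeration on
5-candidate instances and requires the global optimum to be reached in at
least 80% of them.

## The synthetic-data generator

The generator exists so that every downstream claim can be tested against
planted truth. Its construction: for each planted triple, the miRNA is
standard normal and both targets load on it with weight −a
(`repression_strength`, default 0.8) plus independent Gaussian noise
(`noise_sd`, default 1). This one latent-variable device induces all
three gate conditions at once, with closed forms used directly in tests:

- corr(g, l) = a²/(a² + σ²)  (0.39 at the defaults),
- corr(m, g) = corr(m, l) = −a/√(a² + σ²)  (−0.625).

Survival is exponential with hazard `baseline_hazard · exp(Σ βj xj)` over
the planted prognostic lncRNAs and uniform censoring on
(0, `censor_window`] — the simplest mechanism that satisfies proportional
hazards exactly. Complete response is Bernoulli with
`plogis(cr_intercept + cr_slope · Σ βj xj)`; a negative `cr_slope` makes
low-risk samples respond more often. Mutation status is independent of
everything else.

Defaults were chosen once to resemble a serous ovarian-cancer cohort and
are not tuned: 242 samples; baseline hazard 5e−4/day (median survival on
the order of 1100–1700 days); censoring window 3650 days (≈ 47% censoring
at the defaults); CR intercept 0.5 (≈ 62% responders); CR slope −1;
mutation probability 0.47; age > 60 with probability 0.5, stage III/IV
0.9, grade G3/G4 0.85. Sub-stage RNG streams are derived as
`seed · 10 + stage offset` so that consecutive cohort seeds never share a
stream (naive `seed + k` derivations make statistics correlated across
adjacent seeds, which we observed as over-dispersed rejection rates
before fixing the scheme).

What the generator does **not** emulate: read-count noise models,
library-size or batch effects, correlated miRNA co-regulation beyond the
planted triples, informative censoring, or time-varying effects. Passing
tests therefore demonstrate correctness of the *procedure* under the
stated statistical structure, not robustness to real-data artifacts.

## Design decisions on ambiguous points

- **"More than one same miRNA"** for a candidate pair is read as "at
  least one shared miRNA" (`min_shared = 1`), exposed as a parameter so
  the stricter ≥ 2 reading is one argument away.
- The negative-correlation gate also requires p < α by default
  (`require_negative_p = TRUE`), symmetric with the positive gate;
  sign-only gating is available.
- Correlation p-values are **not** multiple-testing corrected in the
  gates — the screening is defined on raw p < 0.05 — and the package does
  not silently add a correction.
- High risk is score **strictly greater** than the cutoff, which makes
  the training split sizes deterministic (they differ by at most 1).
- The disease-free-survival evaluation reuses the OS-derived risk groups
  and cutoff.
- The co-expression anchor for mRNA ranking is the scalar risk score,
  ranked by |r| with lexicographic tie-breaks.
- Pairwise three-group comparisons are uncorrected by default (a BH flag
  exists); the chi-square test is without Yates correction by default.
- Constant expression features (undefined correlation) are skipped with a
  warning wherever they can occur, never silently dropped.

## Problem sizes in tests and the acceptance script

The suite favors closed forms and planted-truth recovery at sizes where
sampling error is controlled: correlation closed forms averaged over 100
cohorts of n = 200; triple-identification equivalence against brute force
on 100 random instances (≤ 5 genes, ≤ 10 miRNAs, ≤ 30 lncRNAs, n = 100);
planted-triple recovery over 50 cohorts (n = 200, map density 0.1); Cox
hazard-ratio recovery over 100 two-group datasets of n = 1000; log-rank
null calibration over 1000 replicates; all-subsets stepwise oracle over
50 instances; end-to-end signature recovery over 50 planted cohorts
(n = 400, 3 prognostic among 30 candidates, |β| ∈ [0.4, 0.8]) and 500
all-null cohorts. Under the global null the univariate screen sometimes
selects nothing (≈ 20% of seeds at these sizes); the held-out rejection
rate is then computed over the seeds that produce a signature, which is
valid because conditional on any train-selected feature set the held-out
log-rank p remains uniform under the null. `scripts/acceptance.R` re-runs
the same computations at moderately reduced replicate counts and reports
the resulting rates and estimates as JSON.

## Known limitations

- Correlation gates are marginal; no partial correlation or conditioning
  on miRNA abundance is attempted, so dense target maps inflate candidate
  pairs (the false-discovery behaviour is quantified only under the
  generator's assumptions).
- Stepwise AIC is greedy and order-dependent by construction; the
  reported selection path makes this auditable but not optimal.
- The signature transfers raw coefficients and cutoff; cohorts on a
  different expression scale must be harmonized upstream.
- No penalized alternatives (lasso/ridge), time-dependent effects,
  stratified Cox or proportionality diagnostics.
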