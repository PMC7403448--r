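# cernasig

Gene-directed ceRNA network inference and lncRNA prognostic signatures.

## The problem

In BRCA1/2 wild-type ovarian cancer, long non-coding RNAs (lncRNAs) can
modulate the expression of driver genes through the competing endogenous
RNA (ceRNA) mechanism: a lncRNA and a gene that share microRNA (miRNA)
binding sites titrate the same miRNA pool, so their expression rises and
falls together while both move opposite to the shared miRNA. lncRNAs that
sit in such a relationship with DNA-repair drivers are candidate
prognostic and chemo-response biomarkers.

`cernasig` implements that reasoning as a reusable, fully tested analysis
pipeline for anyone with paired expression profiles (driver genes, miRNAs,
lncRNAs), a validated miRNA-target map, and a clinical table:

1. **ceRNA triple identification.** A triple (gene *g*, miRNA *m*,
   lncRNA *l*) is kept when all three screening gates hold:
   - Pearson correlation r(g, l) > 0 with p < α (default 0.05),
   - *m* is a validated regulator of both *g* and *l* (≥ `min_shared`
     shared miRNAs per pair, default 1),
   - r(m, g) < 0 and r(m, l) < 0, both with p < α.
   Triples are assembled into a gene–miRNA–lncRNA network.
2. **Risk signature.** The cohort is split 50/50; network lncRNAs are
   screened by univariate Cox regression (Wald p < 0.05), reduced by
   bidirectional stepwise selection under AIC, and fitted jointly in a
   multivariate Cox model. The signature score for a sample is the linear
   combination `score = Σ βj · EXj` of its lncRNA expression values with
   the multivariate coefficients as weights; the training-cohort median
   score is the risk cutoff, transferred verbatim to held-out cohorts
   (score > cutoff ⇒ high risk).
3. **Evaluation.** Kaplan–Meier curves, log-rank tests, per-group median
   survival and 5-year rates for overall and disease-free survival;
   univariate and multivariate Cox adjustment for age, stage, grade and
   treatment response; complete-response (CR) rates by risk group with a
   chi-square test; binned risk-vs-CR correlation; CR-restricted survival;
   mutant vs risk-stratified wild-type comparison; top risk-correlated
   mRNAs and hypergeometric over-representation analysis.

A synthetic-cohort generator (`sim_config()` / `simulate_cohort()`) plants
known ceRNA triples (via a shared latent miRNA repressor with closed-form
expected correlations), known proportional-hazards lncRNA effects, and a
response variable whose probability depends on risk — so the whole
pipeline is testable end to end without external data.

## Worked example

The package ships a fixed reference three-lncRNA signature,

```
score = (-0.571 · EX_LINC01619) + (-0.26 · EX_DLX6-AS1) + (-0.284 · EX_AC004943.2)
```

with cutoff 0.175. All weights are negative (each lncRNA is protective);
the first weight exponentiates to a hazard ratio of exp(−0.571) ≈ 0.56.

```r
library(cernasig)
sig <- example_signature()
expr <- rbind(s1 = c(1, 0, 0), s2 = c(0, 0, 0), s3 = c(1, 1, 1))
colnames(expr) <- sig$features
risk_score(sig, expr)
#>   sample_id  score group
#> 1        s1 -0.571   low
#> 2        s2  0.000   low
#> 3        s3 -1.115   low
```

A full synthetic run (`run_pipeline()`, or the numbered drivers under
`analysis/`) on the default 242-sample cohort with seed 1 prints:

```
ceRNA network: 10 nodes ( 2 genes, 4 miRNAs, 4 lncRNAs ), 8 edges, 4 triples
screened (univariate p < 0.05): lnc001, lnc002, lnc003
  score = ( 0.805 * lnc001) + (-0.620 * lnc002) + ( 0.563 * lnc003)
  cutoff (training median): 0.0135
test: n(high)=58 n(low)=63 | OS log-rank p=7.34e-08 | medians high 772 low 2365 | 5y high 0.18 low 0.59
CR rate low-risk 77% vs high-risk 52% (chi-square p=5.16e-05)
```

i.e. the network stage recovers exactly the four planted triples, the
signature stage recovers the three planted prognostic lncRNAs with
weights near their true log-hazards (0.6, −0.5, 0.45), the transferred
cutoff separates held-out survival, and low-risk patients achieve CR more
often — the planted direction of the response model.

```sh
Rscript analysis/01_simulate.R --seed 1   # cohort TSVs -> results/cohort/
Rscript analysis/02_network.R             # triples + network
Rscript analysis/03_signature.R --seed 1  # signature + evaluation
Rscript analysis/04_association.R         # chemo-response + enrichment
```

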