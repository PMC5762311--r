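# bccp: driver-activation signatures and Bayesian compound covariate classification

`bccp` is an R package for asking a recurring question in tumor genomics:
*which tumors have a given driver gene switched on, and what does that mean
clinically?* It implements the complete analysis pipeline for
copy-number-anchored driver-activation subtyping — developed around YAP1
activation in head and neck squamous cell carcinoma, but applicable to any
driver whose amplification provides a truth anchor:

1. **Signature derivation** — a dual Pearson correlation screen over paired
   expression/copy-number data: genes correlated with the driver's
   thresholded GISTIC score *and* with its mRNA (both at raw `p < 0.001`,
   `|r| > 0.2`) form the activation signature; the driver itself is
   excluded so the signature captures downstream targets.
2. **Classification** — a Bayesian compound covariate predictor (BCCP).
   With per-gene pooled-variance t-statistics `w_g` (amplified vs
   non-amplified training classes) the compound score of sample *j* is

   ```
   s_j = Σ_g w_g · x_gj
   ```

   over gene-wise standardized expression. Training scores are modelled as
   equal-variance Gaussians per class, giving the posterior probability of
   activation

   ```
   P(active | s) = π_A φ(s; μ_A, σ) / [π_A φ(s; μ_A, σ) + π_I φ(s; μ_I, σ)]
   ```

   Samples with posterior > 0.5 are called activated (YA), the rest
   inactivated (YI). Leave-one-out cross-validation, cross-platform
   application with coverage checks, and a one-vs-rest multi-class
   extension are included.
3. **Clinical and genomic association battery** — Kaplan–Meier / log-rank /
   pooled (optionally cohort-stratified) Cox survival comparisons with
   radiation-subgroup and interaction analyses; per-gene copy-number and
   mutation Fisher screens (amplification = high-level events only,
   deletion = all loss events); differential miRNA filters including a
   staged screen for copy-number-independent activation miRNAs; subtype
   cross-tabulations (e.g. HPV status); and the six-gene interferon-gamma
   composite immune score.
4. **Synthetic multi-omics cohorts** — a fully seeded generator that plants
   a driver with dosage and copy-number-independent activation effects, a
   downstream transcriptional program, subtype-dependent survival, HPV
   anti-association, per-group mutation rates, differential and
   CNI-specific miRNAs, and an interferon-gamma depression — with ground
   truth returned for recovery testing.

## Worked example

```r
library(bccp)

sim   <- simulate_cohort(sim_config(n_tumors = 500, n_genes = 1000,
                                    n_signature_genes = 150, seed = 7))
train <- sim$cohort

sig   <- derive_signature(driver_correlations(train, "YAP1"))
cls   <- training_classes(train, "YAP1")          # GISTIC >= 2 vs rest
expr  <- standardize_genes(train$expression)
fit   <- bccp(expr, cls, genes = sig$signature)
calls <- assign_subtypes(train, fit)

recs  <- survival_records(train$clinical, calls)
logrank_test(recs$time, recs$event, recs$subtype)
ifng_association(ifng_score(train), calls)
```

Output (abridged):

```
Dual correlation screen (p < 0.001 , |r| > 0.2 ):
  copy-number-associated: 152 genes
  mRNA-associated:        157 genes
  signature (intersection, driver excluded): 151 genes
Bayesian compound covariate predictor
  genes: 151  training: 53 active / 447 inactive
  score model: mu_A = 953.732, mu_I = -113.082, sigma = 430.501; priors 0.50/0.50
168 of 500 samples classified YA (33.6%)
LOOCV misclassification: 0.230
log-rank YA vs YI: chisq = 40.1, p = 2.4e-10
5-year survival: YA 16.3%, YI 39.4%
IFNG score: t-test p = 7.3e-56, cor with posterior r = -0.64
HPV association: Fisher p = 2.9e-09
agreement with simulated truth: 97.2%
```

Reading: of 500 simulated tumors, 151 of the 150 planted program genes'
worth of signal survived the dual screen (one null gene slipped in); a
third of tumors were called activated; activated tumors had markedly worse
5-year survival (16% vs 39%), were almost exclusively HPV-negative, and
carried depressed interferon-gamma immune scores — the pattern the pipeline
is designed to detect. The LOOCV rate of 0.23 reflects that the
copy-number training classes deliberately mislabel copy-number-independent
activated tumors as "inactive"; agreement with the simulated latent truth
is 97%.

End-to-end runs are also available through `run_pipeline()` (subcommands
`simulate`, `derive-signature`, `fit`, `classify`, `survival`, `associate`,
`ifng`, `full`) driven by a YAML configuration, or from a shell via
`inst/scripts/run_pipeline.R`.

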