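# pcrscreen

Biomarker analysis for two-arm neoadjuvant trials with a binary
pathologic complete response (pCR) endpoint. The package is aimed at
trial biostatisticians asking the screening questions that arise when an
experimental agent (e.g. a kinase inhibitor) is added to standard
therapy: which expression or phospho-protein endpoints predict response
*to the experimental arm specifically*, where should a continuous
endpoint be dichotomized into "high"/"low", and what pCR rate should be
quoted for the resulting biomarker subgroups?

It implements, as tested reusable functions plus a driver workflow:

- **Pre-specified logistic screens.** Per biomarker *x*, arm-wise models
  `pCR ~ x` within the treated or control arm (and within HER2+, TN,
  HR+HER2− subsets), the interaction model
  `pCR ~ treatment + x + treatment:x`, and the receptor-adjusted form
  `pCR ~ treatment + x + treatment:x + HR + HER2`. All tests are df = 1
  likelihood-ratio (LR) tests; p-values are descriptive, with
  (quasi-)separation handled by a flag plus a tiny ridge refit.
- **Cross-validated cutpoint discovery.** Candidate thresholds are
  midpoints of consecutive distinct values; twofold cross-validation,
  stratified on pCR and repeated 500 times, records the LR p of
  `pCR ~ 1{x > c}` per fold; test-fold p-values are combined per
  candidate by the Mudholkar–George logit method
  (`T = −Σ logit(p_i) · sqrt(3(5k+4)/(kπ²(5k+2)))` referred to a t
  distribution with 5k+4 df); the minimum-combined-p candidate is kept
  only if it was the training-fold argmin in ≥ 10/500 repeats.
- **Bayesian subgroup estimation.** The 8-term logistic model
  `pCR ~ HR + HER2 + biomarker + treatment + treatment:HR +
  treatment:HER2 + treatment:biomarker` under normal(0, 3) priors,
  sampled by a self-contained adaptive Metropolis MCMC with split-R̂ and
  ESS diagnostics; subgroup pCR rates are posterior predictive means
  over each subset's observed covariate mix.
- **RPPA cross-array standardization.** Each array is z-scored
  endpoint-wise using means/SDs averaged over 5000 bootstrap resamples
  whose receptor-subtype mix is held at reference proportions
  (HR+HER2− 0.384, TN 0.368, HR+HER2+ 0.158, HR−HER2+ 0.09).
- **Supporting pieces.** A 2-of-3 variant-caller consensus filter,
  mean-expression signature scores, hypergeometric over-representation
  with BH correction, and a synthetic trial-cohort generator with known
  ground truth that powers all recovery tests.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated
300-patient trial (run the scripts in order from the repository root;
outputs land under `results/`). Script 05 chains cutpoint discovery into
Bayesian subgroup estimation for a simulated phospho-endpoint carrying a
treatment-specific logit jump of 2.4 above a raw-intensity threshold:

```
$ Rscript analysis/05_cutpoint_bayes.R
cutpoint->Bayes chain [FOXO1_S256, all]: ok
  cutpoint -0.211049; 47% of subset classified high
all/FOXO1_S256-high, treated (n=64): posterior pCR 76.1% (95% CrI 65.5% - 85.4%)
all/FOXO1_S256-low, treated (n=86): posterior pCR 25.8% (95% CrI 17.6% - 35.0%)
```

The selected cutpoint (−0.21, in per-array SD units after
standardization) sits at the simulated threshold (the raw threshold is
the endpoint's median, ≈ 0 after z-scoring), 47% of patients are
classified high, and the posterior subgroup means 76% vs 26% recover the
simulated treated-arm rates (≈ 80% above vs ≈ 30% below the threshold).
Script 03 prints the pre-specified dotplot table — the endpoint with the
simulated effect and its block-correlated partner are the only
treated-arm hits — and script 04 shows the transcriptome screen finding
~35/510 genes with the planted 10-gene immune block strongly
over-represented among them.

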