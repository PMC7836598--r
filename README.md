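# hypoxiaSig

Hypoxia gene-signature scoring and prognostic association analysis for
tumor transcriptomics.

Solid tumors — pancreatic cancer in particular — are chronically hypoxic,
and hypoxic tumors tend to be more invasive and carry worse prognosis.
`hypoxiaSig` is for analysts who want to quantify that: it derives a
hypoxia gene signature from tumor-versus-normal expression studies, scores
each sample of a survival cohort by the signature, and tests whether the
score predicts outcome and tracks the epithelial-to-mesenchymal-transition
(EMT) program.

## The method

1. **Signature derivation.** In each tumor/normal study, genes are screened
   by a Welch two-sample t-test on log2 expression with Benjamini–Hochberg
   adjustment; genes with fold change > 2 and adjusted p < 0.05 are called
   upregulated. The signature is the intersection of the upregulated sets
   across studies with the 200-gene hallmark hypoxia set.
2. **Scoring.** For each signature gene *g* and sample *i*,
   *s<sub>gi</sub>* = +1 if the sample is strictly above the cohort median
   of that gene's expression, −1 otherwise; the hypoxia score is
   *S<sub>i</sub>* = Σ<sub>g</sub> *s<sub>gi</sub>*. The EMT score is
   computed identically over the 200-gene hallmark EMT set. Samples are
   dichotomized at the cohort-median score into high/low groups.
3. **Association.** Kaplan–Meier / log-rank for overall and
   progression-free survival by group; univariate Cox per covariate and a
   multivariate Cox built by forward likelihood-ratio selection (Efron
   ties, Wald 95% CIs); Pearson and partial correlation (residualizing on
   stage, grade, residual tumor) between the hypoxia and EMT scores;
   chi-square contingency of group versus stage/grade; and a gene-wise
   Pearson screen for genes correlated with the score.

A synthetic-cohort generator with planted ground truth (a latent per-sample
hypoxia factor that jointly drives signature-gene expression, EMT-gene
expression and event hazard) makes the full pipeline runnable and testable
with no external data.

## Worked example

```r
library(hypoxiaSig)
res <- run_hypoxia_pipeline(synthetic_config(seed = 20210126))
res
#> <hypoxia_pipeline_result> signature of 30 genes (30 planted recovered)
#> <cohort_analysis> 177 samples, score range [-30, 30]
#>   OS log-rank p = 9.695e-06
#>   PFS log-rank p = 1.554e-05
#>   hypoxia-EMT Pearson r = 0.959 (p = 1.81e-97), partial r = 0.957 (p = 9.3e-95)

res$analysis$cox_univariate$os$hypoxia_group
#> Cox PH (OS), n = 177, events = 117
#>               term hazard_ratio ci_low ci_high   p_value
#>  hypoxia_grouphigh        2.258   1.56   3.268 1.588e-05
```

Reading this: the derivation step recovered all 30 genes planted as
tumor-upregulated; the high-hypoxia half of the 177-sample cohort has about
2.3-fold the death hazard of the low half (95% CI 1.56–3.27); and the
hypoxia and EMT scores are strongly positively correlated even after
controlling for stage, grade and residual tumor — the qualitative picture
the pipeline is designed to detect, at the planted effect sizes.

Individual stages are exposed as plain functions (`read_expression`,
`read_gmt`, `read_clinical`, `differential_expression`,
`filter_upregulated`, `intersect_signature`, `signature_score`,
`km_logrank`, `cox_univariate`, `cox_multivariate_forward`,
`partial_correlation`, ...), and `inst/cli/hypoxia_pipeline.R` wraps them
in a file-in/file-out command line (`simulate`, `derive-signature`,
`score`, `associate`, `run-all`). See the methods vignette
(`vignettes/hypoxia-signature-methods.Rmd`) for the model, parameter
defaults and design decisions.

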