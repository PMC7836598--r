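---
title: "Methods: hypoxia signature scoring and prognostic association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hypoxia signature scoring and prognostic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiaSig)
```

# The analysis in one paragraph

Pancreatic tumors are markedly hypoxic, and hypoxia is associated with an
aggressive, mesenchymal phenotype. `hypoxiaSig` implements a transcriptomic
pipeline for quantifying that association: (1) derive a hypoxia gene
signature as the genes of a hallmark hypoxia set that are upregulated in
tumor versus normal tissue in two independent expression studies; (2) score
every sample of a survival cohort by median-dichotomized expression of the
signature genes; (3) test whether the score stratifies survival (log-rank,
Cox), tracks clinical severity (stage/grade contingency), and co-varies with
an epithelial-to-mesenchymal-transition (EMT) score computed the same way.
A synthetic-cohort generator with planted ground truth makes the whole chain
testable without external data.

# The score

For signature gene $g$ and sample $i$ with log-scale expression $x_{gi}$,

$$ s_{gi} = \begin{cases} +1 & x_{gi} > \mathrm{median}_j(x_{gj}) \\ -1 &
\text{otherwise,} \end{cases} \qquad S_i = \sum_{g \in \text{signature}} s_{gi}. $$

The score only sees the rank of a sample within each gene, so it is
invariant under any strictly increasing per-gene transformation (log versus
linear scale, quantile normalisation) — a property the test suite checks on
random matrices. Useful consequences: with an even cohort and no within-gene
ties the scores sum to zero, and each score has the parity of the number of
genes used.

Tie and edge rules are deliberate choices, since "top 50%" does not define
them: strictly-above-median earns +1, so with odd cohort size the median
sample scores −1; a constant gene is uninformative and contributes −1 to
everyone (with a warning). Missing signature genes are dropped, never
imputed, and the score remains a raw sum — comparing scores across
signatures of different sizes is therefore not meaningful.

The high/low dichotomy used downstream is the cohort-median split of the
score, again strictly-above. When every sample has the same score there is
nothing to stratify: `assign_groups()` refuses, and `signature_score()`
returns `NA` groups with a warning (the two-gene worked example in
`?signature_score` is exactly this degenerate case).

# Signature derivation

Each tumor/normal study is screened gene-by-gene with a Welch two-sample
t-test on log2 values — the standard two-group microarray contrast when no
moderated-variance machinery is wanted — with Benjamini–Hochberg adjustment
across all tested genes. The log2 fold change is the difference of group
means, i.e. a ratio of geometric means on the linear scale, which makes the
default filter "fold change > 2" identical to "log2 fold change > 1". Both
filter inequalities are strict. A gene constant within both groups has an
undefined t statistic; it is assigned p = 1 so that an arbitrary mean shift
can never pass a significance filter silently. Studies are treated as
unpaired even when the underlying design was paired; only upregulated genes
are kept, since the signature targets genes over-expressed in tumors. The
derived signature is the intersection of the per-study upregulated sets with
the hallmark hypoxia set, sorted by identifier so the result is independent
of input order.

# Association analyses

* **KM / log-rank** (`km_logrank`): standard two-group log-rank statistic,
  chi-square with 1 df, with KM step functions and per-group medians
  reported. Tested against an independent observed-minus-expected hand
  computation on small instances.
* **Cox models** (`cox_univariate`, `cox_multivariate_forward`): partial
  likelihood with Efron tie handling, Wald 95% CIs. The hypoxia score
  enters as the binary high/low indicator with "low" as reference,
  consistent with reporting a single hazard-ratio row for the score. Stage
  (I reference; II, III/IV) and grade (G1 reference; G2, G3/G4) enter as
  factors. Multivariate selection is forward by likelihood ratio: at each
  step the candidate whose LR test (2·Δ log-likelihood, df = coefficients
  added) has the smallest p enters if p < `forward_entry_p` (default 0.05);
  candidates are pre-screened by univariate significance at the same
  threshold. Degenerate fits — monotone likelihood, NA or extreme
  coefficients, fewer events than coefficients — are flagged, never
  silently returned. No multiplicity correction is applied across the
  endpoint/model combinations.
* **Correlations** (`pearson_cor`, `partial_correlation`): Pearson r with
  the two-sided t-transform p. Partial correlation residualizes both
  scores on the controls by least squares with intercept and correlates the
  residuals, with df = n − 2 − k; ordinal controls (stage, grade) are coded
  as consecutive integers 1..3 via `encode_ordinal`. The residualization
  route is verified against the correlation-matrix-inverse identity
  $-\Omega_{xy}/\sqrt{\Omega_{xx}\Omega_{yy}}$ to 1e−8 on random data.
* **Gene screen** (`correlate_genes_with_score`): gene-wise Pearson r
  against the score. The default keep rule r ≥ 0.05 and p < 0.05 is kept as
  the literal published-style screen although 0.05 is an unusually
  permissive correlation cutoff (plausibly intended as 0.5); it is a config
  parameter precisely so users can tighten it. Note the r cut is one-sided:
  strong negative correlates are excluded by design.
* **Contingency** (`group_contingency`): Pearson chi-square of independence
  without continuity correction; empty levels are dropped with a warning.

# The synthetic cohort

The generator emulates the statistical skeleton of the target study design:
two tumor/normal studies (default 39 vs 39 samples each, matching the larger
of the two microarray studies such a design uses) in which the same
`n_planted = 30` hallmark genes carry a +2 log2 mean shift in tumors over
Gaussian log2 noise (SD 0.5); and a survival cohort (default 177 samples,
the size of the TCGA pancreatic adenocarcinoma cohort) with a standard
normal latent hypoxia factor $z_i$ per sample. Planted genes gain
`factor_loading`·z (default 0.5), all 200 EMT-set genes gain
`emt_loading`·z (default 0.5), and both endpoints get exponential event
times with hazard $h_0 e^{\beta z}$ (OS baseline 0.05, progression baseline
0.08 per time unit, $\beta$ = `log_hr` = 0.6 — chosen to land the
dichotomized hazard ratio near 1.8–2, the magnitude such cohorts report).
Independent exponential censoring at rate 0.025 leaves roughly a third of
OS times censored. Stage and grade come from a proportional-odds logit on z
(slope 0.5, intercepts giving ~10/80/10% stage and ~15/55/30% grade
marginals); residual tumor and gender are independent Bernoulli. All
randomness derives from `seed` (default 20210126), with fixed per-operation
offsets, so identical configurations are bit-identical.

What the generator does **not** emulate: platform/batch effects, probe
summarisation, count-distribution artifacts of RSEM data, correlated noise
between genes, informative censoring, or subtype structure. Passing tests
therefore demonstrate the pipeline's statistical correctness and
calibration, not robustness to those real-data complications.

# Numerical and design choices

* Exponential baseline hazard: the simplest model satisfying proportional
  hazards, making Cox parameter recovery a clean oracle.
* Expression noise Gaussian on log2: matches microarray / log-RSEM
  convention and keeps fold-change arithmetic exact.
* TSV writers emit doubles as shortest exact decimals (`%.17g`), so
  write-then-read round-trips are bit-identical — an invariant the IO tests
  assert.
* Confidence level fixed at 95% everywhere; time units are whatever the
  input uses and are never converted.
* Samples present in expression but not clinical (or vice versa) are
  dropped from joint analyses with a logged count, never imputed.

# Problem sizes used in the test suite

The property tests run at sizes chosen to give stable Monte-Carlo bounds
while keeping the default suite quick: 100 random matrices for the score
invariants; 1000 random vectors for the BH check; 100 random instances plus
one n = 10,000 draw for the partial-correlation oracle; 200 null cohorts of
n = 200 for p-value calibration (Kolmogorov–Smirnov distance < 0.1); 50
seeds at n = 500 for hazard-ratio recovery; and 20 seeds of two 2000-gene,
20 + 20-sample studies for signature recovery (≥ 95% planted genes, ≤ 1%
null pass rate).

# Known limitations

The DE screen is a plain Welch test, not an empirical-Bayes moderated test,
so at very small group sizes its power profile differs from limma-style
pipelines. The score treats genes symmetrically and unweighted; shrinking or
weighting by effect size is out of scope. Forward selection inherits the
usual instabilities of stepwise procedures near the entry threshold — the
package reports the entry path (`entry_steps`) so users can see how firm
each entry was.
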