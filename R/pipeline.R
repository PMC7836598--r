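# End-to-end orchestration: derive the signature from the DE studies, score
# the survival cohort, and run every clinical association. Works on any
# validated inputs; run_hypoxia_pipeline() wires it to the synthetic
# generator for a fully self-contained analysis.

#' Derive a hypoxia signature from tumor/normal studies
#'
#' Runs the differential-expression screen on each study, filters to
#' upregulated genes (fold change and BH-adjusted p thresholds), and
#' intersects across studies and the hallmark hypoxia set.
#'
#' @param studies List of studies, each a list with `expression` (matrix)
#'   and `groups` (per-sample labels with a "tumor" level).
#' @param hallmark Hallmark hypoxia [gene_set].
#' @param config A [pipeline_config()].
#' @return List with `signature` ([gene_set] or NULL), `de_tables` (one per
#'   study) and `upregulated` (per-study gene sets).
#' @export
derive_signature <- function(studies, hallmark, config = pipeline_config()) {
  de_tables <- lapply(studies, function(s)
    differential_expression(s$expression, s$groups))
  upregulated <- lapply(seq_along(de_tables), function(i)
    filter_upregulated(de_tables[[i]],
                       fc_threshold = config$fold_change_threshold,
                       adj_p_threshold = config$adjusted_p_threshold,
                       name = sprintf("upregulated_study%d", i)))
  signature <- intersect_signature(upregulated, hallmark)
  if (!is.null(signature))
    hx_log(sprintf("derive_signature: %d-gene signature", length(signature)))
  list(signature = signature, de_tables = de_tables,
       upregulated = upregulated)
}

#' Score a cohort and run all clinical associations
#'
#' Computes the hypoxia and EMT scores, splits the cohort at the median
#' hypoxia score, and produces: KM/log-rank for OS and PFS, univariate Cox
#' for the score group and the clinical covariates, forward-LR multivariate
#' Cox over the univariately significant candidates, Pearson and partial
#' correlation between the two scores (controls: stage, grade, residual
#' tumor, integer-coded), and group-versus-stage/grade contingency tests.
#'
#' @param expression Cohort expression matrix (log scale).
#' @param clinical Validated clinical table.
#' @param signature Hypoxia signature ([gene_set] or gene ids).
#' @param emt EMT [gene_set] (or NULL to skip EMT-related outputs).
#' @param config A [pipeline_config()].
#' @return List of class `cohort_analysis` with components scores,
#'   emt_scores, logrank (per endpoint), cox_univariate (per endpoint),
#'   cox_multivariate (per endpoint), correlation, contingency.
#' @export
analyze_cohort <- function(expression, clinical, signature, emt = NULL,
                           config = pipeline_config()) {
  aligned <- align_expression_clinical(expression, clinical)
  expression <- aligned$expression
  clinical <- aligned$clinical

  scores <- signature_score(expression, signature)
  clinical$hypoxia_group <- factor(
    align_groups(clinical, scores), levels = c("low", "high"))

  emt_scores <- NULL
  correlation <- NULL
  if (!is.null(emt)) {
    emt_scores <- signature_score(expression, emt)
    hx <- scores$score[match(clinical$sample_id, scores$sample_id)]
    em <- emt_scores$score[match(clinical$sample_id, emt_scores$sample_id)]
    pc <- pearson_cor(hx, em)
    controls <- data.frame(stage = encode_ordinal(clinical$stage),
                           grade = encode_ordinal(clinical$grade),
                           residual = clinical$residual)
    pp <- partial_correlation(hx, em, controls)
    correlation <- list(pearson_r = pc$r, pearson_p = pc$p,
                        partial_r = pp$partial_r, partial_p = pp$p,
                        controls = pp$controls, n = pc$n)
  }

  covariates <- c("hypoxia_group", "stage", "grade", "residual", "gender")
  endpoints <- c("os", "pfs")
  logrank <- lapply(endpoints, function(ep)
    km_logrank(clinical, clinical$hypoxia_group, endpoint = ep))
  names(logrank) <- endpoints
  cox_uni <- lapply(endpoints, function(ep) {
    res <- lapply(covariates, function(cv) cox_univariate(clinical, cv, ep))
    names(res) <- covariates
    res
  })
  names(cox_uni) <- endpoints
  cox_multi <- lapply(endpoints, function(ep) {
    candidates <- covariates[vapply(cox_uni[[ep]], function(r)
      is.finite(r$lr_p) && r$lr_p < config$forward_entry_p, logical(1))]
    if (length(candidates) == 0L) return(NULL)
    cox_multivariate_forward(clinical, candidates, endpoint = ep,
                             entry_p = config$forward_entry_p)
  })
  names(cox_multi) <- endpoints

  contingency <- list(
    stage = group_contingency(clinical$hypoxia_group, clinical$stage),
    grade = group_contingency(clinical$hypoxia_group, clinical$grade))

  structure(list(scores = scores, emt_scores = emt_scores,
                 clinical = clinical, logrank = logrank,
                 cox_univariate = cox_uni, cox_multivariate = cox_multi,
                 correlation = correlation, contingency = contingency),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d samples, score range [%d, %d]\n",
              nrow(x$scores), min(x$scores$score), max(x$scores$score)))
  for (ep in names(x$logrank))
    cat(sprintf("  %s log-rank p = %.4g\n", toupper(ep),
                x$logrank[[ep]]$p_value))
  if (!is.null(x$correlation))
    cat(sprintf("  hypoxia-EMT Pearson r = %.3f (p = %.3g), partial r = %.3f (p = %.3g)\n",
                x$correlation$pearson_r, x$correlation$pearson_p,
                x$correlation$partial_r, x$correlation$partial_p))
  invisible(x)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Chains generation, signature derivation and cohort analysis: simulate the
#' gene sets, DE studies and survival cohort; derive the signature from the
#' studies; score and associate on the cohort. The returned object carries
#' the ground truth so recovery can be checked.
#'
#' @param config A [synthetic_config()].
#' @param pipeline A [pipeline_config()].
#' @return List of class `hypoxia_pipeline_result`: gene_sets, studies,
#'   cohort, derivation (signature + DE tables), analysis
#'   (a `cohort_analysis`), truth.
#' @examples
#' \donttest{
#' res <- run_hypoxia_pipeline(synthetic_config(n_genes = 400,
#'                                              hallmark_size = 40,
#'                                              emt_size = 40,
#'                                              n_planted = 10,
#'                                              cohort_size = 80))
#' res$analysis
#' }
#' @export
run_hypoxia_pipeline <- function(config = synthetic_config(),
                                 pipeline = pipeline_config()) {
  sets <- generate_gene_sets(config)
  studies <- generate_de_studies(config, sets$hypoxia)
  cohort <- generate_survival_cohort(config, sets$hypoxia, sets$emt)
  derivation <- derive_signature(studies, sets$hypoxia, pipeline)
  if (is.null(derivation$signature))
    stop_input("derived signature is empty; nothing to score")
  analysis <- analyze_cohort(cohort$expression, cohort$clinical,
                             derivation$signature, sets$emt, pipeline)
  structure(list(gene_sets = sets, studies = studies, cohort = cohort,
                 derivation = derivation, analysis = analysis,
                 truth = cohort$truth),
            class = "hypoxia_pipeline_result")
}

#' @export
print.hypoxia_pipeline_result <- function(x, ...) {
  sig <- x$derivation$signature
  cat(sprintf("<hypoxia_pipeline_result> signature of %d genes (%d planted recovered)\n",
              length(sig), length(intersect(sig$genes, x$truth$planted))))
  print(x$analysis)
  invisible(x)
}
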