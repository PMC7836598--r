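#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the simulated study design: two tumor/normal
#' differential-expression studies with a planted set of upregulated hallmark
#' hypoxia genes, and a survival cohort in which a latent per-sample hypoxia
#' factor jointly raises signature-gene expression, EMT-gene expression and
#' event hazard. All randomness in the generator flows from `seed` alone, so a
#' given configuration always reproduces the same cohort.
#'
#' Defaults mirror the study design the pipeline targets: 200-gene hallmark
#' hypoxia and EMT sets, a 30-gene planted signature, two 39-vs-39
#' tumor/normal studies, and a 177-sample survival cohort.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_genes Total number of genes in the simulated genome.
#' @param hallmark_size,emt_size Sizes of the simulated hallmark hypoxia and
#'   EMT gene sets (disjoint by construction).
#' @param n_planted Number of hallmark genes truly upregulated in tumors and
#'   loading on the latent hypoxia factor.
#' @param n_tumor,n_normal Per-study group sizes for the two DE studies.
#' @param cohort_size Number of samples in the survival cohort.
#' @param effect_log2fc Mean log2 expression shift of planted genes in tumor
#'   samples of the DE studies.
#' @param factor_loading log2-expression units added to each planted gene per
#'   standard deviation of the latent hypoxia factor.
#' @param emt_loading Same, for every EMT-set gene.
#' @param log_hr Log hazard ratio per unit latent factor (both endpoints).
#' @param noise_sd Residual Gaussian SD of log2 expression.
#' @param baseline_hazard,baseline_hazard_pfs Constant baseline hazards of the
#'   overall-survival and progression endpoints (exponential event times).
#' @param censor_rate Rate of the independent exponential censoring time; 0
#'   disables censoring.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_genes = 500, hallmark_size = 50, emt_size = 50)
#' cfg$n_planted
#' @export
synthetic_config <- function(seed = 20210126,
                             n_genes = 5000,
                             hallmark_size = 200,
                             emt_size = 200,
                             n_planted = 30,
                             n_tumor = 39,
                             n_normal = 39,
                             cohort_size = 177,
                             effect_log2fc = 2,
                             factor_loading = 0.5,
                             emt_loading = 0.5,
                             log_hr = 0.6,
                             noise_sd = 0.5,
                             baseline_hazard = 0.05,
                             baseline_hazard_pfs = 0.08,
                             censor_rate = 0.025) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_genes = check_count(n_genes, "n_genes"),
    hallmark_size = check_count(hallmark_size, "hallmark_size"),
    emt_size = check_count(emt_size, "emt_size"),
    n_planted = check_count(n_planted, "n_planted", min = 0L),
    n_tumor = check_count(n_tumor, "n_tumor", min = 2L),
    n_normal = check_count(n_normal, "n_normal", min = 2L),
    cohort_size = check_count(cohort_size, "cohort_size", min = 2L),
    effect_log2fc = check_number(effect_log2fc, "effect_log2fc", min = 0),
    factor_loading = check_number(factor_loading, "factor_loading", min = 0),
    emt_loading = check_number(emt_loading, "emt_loading", min = 0),
    log_hr = check_number(log_hr, "log_hr"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE),
    baseline_hazard = check_number(baseline_hazard, "baseline_hazard",
                                   min = 0, strict_min = TRUE),
    baseline_hazard_pfs = check_number(baseline_hazard_pfs,
                                       "baseline_hazard_pfs",
                                       min = 0, strict_min = TRUE),
    censor_rate = check_number(censor_rate, "censor_rate", min = 0)
  )
  if (cfg$hallmark_size + cfg$emt_size > cfg$n_genes)
    stop_input("hallmark_size + emt_size (%d) exceeds n_genes (%d)",
               cfg$hallmark_size + cfg$emt_size, cfg$n_genes)
  if (cfg$n_planted > cfg$hallmark_size)
    stop_input("n_planted (%d) exceeds hallmark_size (%d)",
               cfg$n_planted, cfg$hallmark_size)
  structure(cfg, class = "synthetic_config")
}

#' Analysis thresholds for the signature pipeline
#'
#' Holds the screening thresholds used downstream: the differential-expression
#' filter (fold change and BH-adjusted p), the gene-wise score-correlation
#' screen, and the entry p-value of forward likelihood-ratio Cox selection.
#'
#' The default correlation cutoff `gene_corr_r_threshold = 0.05` is the
#' literal screen the pipeline reproduces; it is unusually permissive and is
#' exposed here precisely so users can tighten it.
#'
#' @param fold_change_threshold Keep genes with fold change strictly above
#'   this (default 2; equivalent to log2 fold change > 1).
#' @param adjusted_p_threshold Keep genes with BH-adjusted p strictly below
#'   this (default 0.05).
#' @param gene_corr_r_threshold Minimum Pearson r (one-sided, positive) for
#'   the gene-versus-score screen.
#' @param gene_corr_p_threshold Maximum two-sided p for the same screen.
#' @param forward_entry_p Entry threshold of forward likelihood-ratio Cox
#'   covariate selection.
#' @param log_transform_input If TRUE, expression files are transformed to
#'   log2(x + 1) on read.
#' @param seed Seed for any stochastic analysis step.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fold_change_threshold = 2,
                            adjusted_p_threshold = 0.05,
                            gene_corr_r_threshold = 0.05,
                            gene_corr_p_threshold = 0.05,
                            forward_entry_p = 0.05,
                            log_transform_input = FALSE,
                            seed = 20210126) {
  cfg <- list(
    fold_change_threshold = check_number(fold_change_threshold,
                                         "fold_change_threshold",
                                         min = 0, strict_min = TRUE),
    adjusted_p_threshold = check_number(adjusted_p_threshold,
                                        "adjusted_p_threshold",
                                        min = 0, max = 1,
                                        strict_min = TRUE, strict_max = TRUE),
    gene_corr_r_threshold = check_number(gene_corr_r_threshold,
                                         "gene_corr_r_threshold",
                                         min = -1, max = 1),
    gene_corr_p_threshold = check_number(gene_corr_p_threshold,
                                         "gene_corr_p_threshold",
                                         min = 0, max = 1,
                                         strict_min = TRUE, strict_max = TRUE),
    forward_entry_p = check_number(forward_entry_p, "forward_entry_p",
                                   min = 0, max = 1,
                                   strict_min = TRUE),
    log_transform_input = check_flag(log_transform_input,
                                     "log_transform_input"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "pipeline_config")
}
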