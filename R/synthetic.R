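# Synthetic study generator. Everything downstream can be exercised on these
# cohorts: two tumor/normal expression studies with a planted set of
# upregulated hallmark genes, and a survival cohort driven by a latent
# per-sample hypoxia factor. The planted genes are, by construction, the
# first `n_planted` identifiers of the hallmark set, so DE studies and the
# survival cohort agree on the ground truth.

gene_universe <- function(n_genes) sprintf("G%05d", seq_len(n_genes))

planted_genes <- function(config, hallmark) {
  as_gene_ids(hallmark)[seq_len(config$n_planted)]
}

#' Generate simulated hallmark hypoxia and EMT gene sets
#'
#' Draws two disjoint gene sets from the simulated genome. The hypoxia set's
#' first `n_planted` members are the genes later planted as truly
#' tumor-upregulated and factor-loaded.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `hypoxia` and `emt`, each a [gene_set].
#' @examples
#' sets <- generate_gene_sets(synthetic_config(n_genes = 500,
#'                                             hallmark_size = 40,
#'                                             emt_size = 40))
#' length(sets$hypoxia)
#' @export
generate_gene_sets <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    genome <- gene_universe(config$n_genes)
    picked <- sample(genome, config$hallmark_size + config$emt_size)
    list(
      hypoxia = gene_set("HALLMARK_HYPOXIA_SIM",
                         picked[seq_len(config$hallmark_size)],
                         description = "simulated hallmark hypoxia set"),
      emt = gene_set("HALLMARK_EMT_SIM",
                     picked[config$hallmark_size + seq_len(config$emt_size)],
                     description = "simulated hallmark EMT set")
    )
  })
}

#' Generate two tumor-versus-normal expression studies
#'
#' In both studies the same planted hallmark genes receive a
#' `effect_log2fc` mean shift in tumor samples; every other gene is null.
#' Residual noise is Gaussian on the log2 scale with SD `noise_sd`.
#'
#' @param config A [synthetic_config()].
#' @param hallmark The hypoxia [gene_set] from [generate_gene_sets()].
#' @return A list of two studies, each a list with `expression` (matrix),
#'   `groups` (named character vector, "tumor"/"normal") and `planted`
#'   (character vector of planted gene ids).
#' @export
generate_de_studies <- function(config, hallmark) {
  stopifnot(inherits(config, "synthetic_config"))
  hallmark_genes <- as_gene_ids(hallmark)
  if (config$n_planted > length(hallmark_genes))
    stop_input("n_planted exceeds the hallmark set size")
  planted <- planted_genes(config, hallmark_genes)
  genome <- gene_universe(config$n_genes)
  lapply(1:2, function(study) {
    with_local_seed(config$seed + study, {
      n <- config$n_tumor + config$n_normal
      groups <- c(rep("tumor", config$n_tumor),
                  rep("normal", config$n_normal))
      samples <- sprintf("ST%d_%s%02d", study,
                         ifelse(groups == "tumor", "T", "N"),
                         c(seq_len(config$n_tumor), seq_len(config$n_normal)))
      mu <- rnorm(config$n_genes, mean = 6, sd = 1.5)
      mat <- matrix(rnorm(config$n_genes * n, mean = mu, sd = config$noise_sd),
                    nrow = config$n_genes, ncol = n,
                    dimnames = list(genome, samples))
      mat[planted, groups == "tumor"] <-
        mat[planted, groups == "tumor"] + config$effect_log2fc
      names(groups) <- samples
      list(expression = validate_expression(mat), groups = groups,
           planted = planted)
    })
  })
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times are exponential with hazard `baseline_hazard * exp(linpred)`;
#' an independent exponential censoring time with rate `censor_rate`
#' (disabled when 0) truncates them. Consumes the current RNG stream.
#'
#' @param linpred Per-sample linear predictor (log relative hazard).
#' @param baseline_hazard Constant baseline hazard (> 0).
#' @param censor_rate Exponential censoring rate (>= 0).
#' @return data.frame with columns `time` and `event` (1 = event observed).
#' @export
simulate_survival <- function(linpred, baseline_hazard, censor_rate = 0) {
  check_number(baseline_hazard, "baseline_hazard", min = 0, strict_min = TRUE)
  check_number(censor_rate, "censor_rate", min = 0)
  n <- length(linpred)
  event_time <- rexp(n, rate = baseline_hazard * exp(linpred))
  censor_time <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
  data.frame(time = pmin(event_time, censor_time),
             event = as.integer(event_time <= censor_time))
}

# Ordinal clinical covariate from the latent factor via a cumulative-logit
# (proportional-odds) link: latent y* = slope*z + logistic error, cut at
# fixed thresholds chosen for realistic marginal frequencies at z = 0.
ordinal_from_latent <- function(z, cutpoints, levels, slope = 0.5) {
  ystar <- slope * z + rlogis(length(z))
  factor(levels[findInterval(ystar, cutpoints) + 1L], levels = levels)
}

#' Generate a survival cohort driven by a latent hypoxia factor
#'
#' Each sample carries a standard-normal latent factor z. Planted hallmark
#' genes gain `factor_loading * z` and every EMT gene `emt_loading * z` on
#' the log2 scale; overall-survival and progression hazards are multiplied
#' by `exp(log_hr * z)`; stage and grade odds of the higher category
#' increase with z; residual tumor and gender are independent Bernoulli.
#'
#' @param config A [synthetic_config()].
#' @param hallmark,emt The two [gene_set]s from [generate_gene_sets()].
#' @return An object of class `latent_cohort`: list with `expression`,
#'   `clinical`, `latent_factor` and `truth` (planted genes and the planted
#'   parameters).
#' @export
generate_survival_cohort <- function(config, hallmark, emt) {
  stopifnot(inherits(config, "synthetic_config"))
  hallmark_genes <- as_gene_ids(hallmark)
  emt_genes <- as_gene_ids(emt)
  if (length(intersect(hallmark_genes, emt_genes)) > 0L)
    stop_input("hallmark and EMT sets must be disjoint")
  planted <- planted_genes(config, hallmark_genes)
  genome <- gene_universe(config$n_genes)
  with_local_seed(config$seed + 100L, {
    n <- config$cohort_size
    samples <- sprintf("P%04d", seq_len(n))
    z <- rnorm(n)
    loading <- numeric(config$n_genes)
    names(loading) <- genome
    loading[planted] <- config$factor_loading
    loading[emt_genes] <- config$emt_loading
    mu <- rnorm(config$n_genes, mean = 6, sd = 1.5)
    mat <- matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
                  nrow = config$n_genes, ncol = n,
                  dimnames = list(genome, samples))
    mat <- mat + mu + outer(loading, z)
    os <- simulate_survival(config$log_hr * z, config$baseline_hazard,
                            config$censor_rate)
    pfs <- simulate_survival(config$log_hr * z, config$baseline_hazard_pfs,
                             config$censor_rate)
    clinical <- data.frame(
      sample_id = samples,
      os_time = os$time, os_event = os$event,
      pfs_time = pfs$time, pfs_event = pfs$event,
      stage = ordinal_from_latent(z, cutpoints = qlogis(c(0.10, 0.90)),
                                  levels = .stage_levels),
      grade = ordinal_from_latent(z, cutpoints = qlogis(c(0.15, 0.70)),
                                  levels = .grade_levels),
      residual = rbinom(n, 1L, 0.35),
      gender = rbinom(n, 1L, 0.5),
      stringsAsFactors = FALSE
    )
    structure(list(expression = validate_expression(mat),
                   clinical = validate_clinical(clinical),
                   latent_factor = stats::setNames(z, samples),
                   truth = list(planted = planted,
                                log_hr = config$log_hr,
                                factor_loading = config$factor_loading,
                                emt_loading = config$emt_loading)),
              class = "latent_cohort")
  })
}

#' Write all synthetic pipeline inputs to a directory
#'
#' Produces the standard input files: `study1.tsv`/`study2.tsv` with matching
#' `*.groups.tsv`, `gene_sets.gmt`, `clinical.tsv` and a plain-text
#' `truth.txt` with the planted parameters.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sets <- generate_gene_sets(config)
  studies <- generate_de_studies(config, sets$hypoxia)
  cohort <- generate_survival_cohort(config, sets$hypoxia, sets$emt)
  for (i in seq_along(studies)) {
    write_expression(studies[[i]]$expression,
                     file.path(outdir, sprintf("study%d.tsv", i)))
    groups <- data.frame(sample_id = names(studies[[i]]$groups),
                         group = unname(studies[[i]]$groups))
    data.table::fwrite(groups,
                       file.path(outdir, sprintf("study%d.groups.tsv", i)),
                       sep = "\t", quote = FALSE)
  }
  write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
  write_expression(cohort$expression, file.path(outdir, "cohort.tsv"))
  write_clinical(cohort$clinical, file.path(outdir, "clinical.tsv"))
  truth <- cohort$truth
  writeLines(c(sprintf("log_hr\t%s", truth$log_hr),
               sprintf("factor_loading\t%s", truth$factor_loading),
               sprintf("emt_loading\t%s", truth$emt_loading),
               sprintf("planted\t%s", paste(truth$planted, collapse = ","))),
             file.path(outdir, "truth.txt"))
  hx_log(sprintf("simulate_to_dir: wrote synthetic inputs to %s", outdir))
  invisible(list(sets = sets, studies = studies, cohort = cohort))
}
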