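test_that("gene set generation respects sizes, disjointness and the seed", {
  cfg <- tiny_config()
  sets <- generate_gene_sets(cfg)
  expect_length(sets$hypoxia$genes, cfg$hallmark_size)
  expect_length(sets$emt$genes, cfg$emt_size)
  expect_length(intersect(sets$hypoxia$genes, sets$emt$genes), 0)

  expect_identical(sets, generate_gene_sets(tiny_config()))
  expect_false(identical(sets, generate_gene_sets(tiny_config(seed = 43))))

  expect_error(synthetic_config(n_genes = 4, hallmark_size = 5, emt_size = 2),
               "exceeds n_genes")
  expect_error(synthetic_config(n_genes = 400, hallmark_size = 30,
                                emt_size = 30, n_planted = 31),
               "exceeds hallmark_size")
})

test_that("DE studies plant the configured log2 shift in the same genes", {
  cfg <- tiny_config(effect_log2fc = 2, noise_sd = 0.5,
                     n_tumor = 20, n_normal = 20)
  sets <- generate_gene_sets(cfg)
  studies <- generate_de_studies(cfg, sets$hypoxia)
  expect_length(studies, 2)
  expect_identical(studies[[1]]$planted, studies[[2]]$planted)
  expect_true(all(studies[[1]]$planted %in% sets$hypoxia$genes))

  # empirical tumor-minus-normal mean difference of planted genes within
  # 3 * noise_sd * sqrt(2/n) of the planted shift
  tol <- 3 * cfg$noise_sd * sqrt(2 / cfg$n_tumor)
  for (s in studies) {
    tumor <- s$groups == "tumor"
    diffs <- rowMeans(s$expression[s$planted, tumor]) -
      rowMeans(s$expression[s$planted, !tumor])
    expect_true(all(abs(diffs - cfg$effect_log2fc) < tol))
  }

  expect_identical(studies, generate_de_studies(cfg, sets$hypoxia))
})

test_that("with zero planted effect the t-test is calibrated at the null", {
  cfg <- tiny_config(effect_log2fc = 0, n_genes = 1000, n_tumor = 10,
                     n_normal = 10, hallmark_size = 30, emt_size = 30)
  sets <- generate_gene_sets(cfg)
  s <- generate_de_studies(cfg, sets$hypoxia)[[1]]
  de <- differential_expression(s$expression, s$groups)
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.02)
})

test_that("survival cohort honours censoring, loadings and the latent factor", {
  cfg <- tiny_config(censor_rate = 0, log_hr = 0, cohort_size = 150)
  sets <- generate_gene_sets(cfg)
  cohort <- generate_survival_cohort(cfg, sets$hypoxia, sets$emt)
  expect_true(all(cohort$clinical$os_event == 1))
  expect_true(all(cohort$clinical$pfs_event == 1))
  expect_identical(colnames(cohort$expression), cohort$clinical$sample_id)
  expect_length(cohort$latent_factor, cfg$cohort_size)

  # emt_loading = 0 decouples EMT-set expression from z
  cfg0 <- tiny_config(emt_loading = 0, cohort_size = 400)
  sets0 <- generate_gene_sets(cfg0)
  cohort0 <- generate_survival_cohort(cfg0, sets0$hypoxia, sets0$emt)
  emt_mean <- colMeans(cohort0$expression[sets0$emt$genes, ])
  expect_lt(abs(cor(emt_mean, cohort0$latent_factor)),
            3 / sqrt(cfg0$cohort_size))

  # stage/grade odds increase with z
  cfgz <- tiny_config(cohort_size = 600)
  setsz <- generate_gene_sets(cfgz)
  cohz <- generate_survival_cohort(cfgz, setsz$hypoxia, setsz$emt)
  expect_gt(cor(encode_ordinal(cohz$clinical$stage), cohz$latent_factor), 0)
  expect_gt(cor(encode_ordinal(cohz$clinical$grade), cohz$latent_factor), 0)
})

test_that("planted log hazard ratio on the latent factor is recovered by Cox", {
  cfg <- tiny_config(log_hr = 0.69, cohort_size = 500)
  sets <- generate_gene_sets(cfg)
  cohort <- generate_survival_cohort(cfg, sets$hypoxia, sets$emt)
  clin <- cohort$clinical
  clin$z <- unname(cohort$latent_factor)
  fit <- cox_univariate(clin, "z", endpoint = "os")
  co <- fit$coefficients
  est <- log(co$hazard_ratio)
  se <- (log(co$ci_high) - log(co$ci_low)) / (2 * qnorm(0.975))
  expect_false(fit$flagged)
  expect_lt(abs(est - 0.69), 3 * se)
})

test_that("simulate_to_dir writes inputs that read back into the same objects", {
  cfg <- tiny_config(cohort_size = 30)
  outdir <- withr::local_tempdir()
  objs <- simulate_to_dir(cfg, outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("study1.tsv", "study1.groups.tsv", "study2.tsv", "study2.groups.tsv",
      "gene_sets.gmt", "cohort.tsv", "clinical.tsv", "truth.txt")))))

  expr <- read_expression(file.path(outdir, "cohort.tsv"))
  expect_identical(expr, objs$cohort$expression)
  sets <- read_gmt(file.path(outdir, "gene_sets.gmt"))
  expect_identical(sets$HALLMARK_HYPOXIA_SIM$genes, objs$sets$hypoxia$genes)
  clin <- read_clinical(file.path(outdir, "clinical.tsv"))
  expect_equal(clin, objs$cohort$clinical)
})
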