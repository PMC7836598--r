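make_clin <- function(time, event, n = length(time)) {
  clin <- toy_clinical(n)
  clin$os_time <- time
  clin$os_event <- event
  clin$pfs_time <- time
  clin$pfs_event <- event
  clin
}

test_that("log-rank statistic matches the hand observed-vs-expected oracle", {
  # identical event-time lists in both groups: perfect symmetry
  clin <- make_clin(c(1, 2, 3, 1, 2, 3), rep(1L, 6))
  res <- km_logrank(clin, rep(c("high", "low"), each = 3))
  expect_equal(res$chi_square, 0)

  # fully separated event times, all events
  clin2 <- make_clin(c(1, 2, 3, 4, 5, 6), rep(1L, 6))
  grp2 <- rep(c("high", "low"), each = 3)
  res2 <- km_logrank(clin2, grp2)
  expect_equal(res2$chi_square,
               logrank_oracle(clin2$os_time, clin2$os_event, grp2 == "high"),
               tolerance = 1e-10)

  # random small instances (n <= 8) with censoring and ties
  set.seed(61)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    time <- sample(1:5, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8)
    grp <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    clin_i <- make_clin(time, event, n)
    got <- km_logrank(clin_i, grp)
    expect_equal(got$chi_square,
                 logrank_oracle(time, event, grp == "high"),
                 tolerance = 1e-10)
  }

  # no events anywhere: undefined
  clin0 <- make_clin(c(1, 2, 3, 4), rep(0L, 4))
  expect_error(km_logrank(clin0, c("high", "high", "low", "low")),
               "no events")
})

test_that("KM output carries group sizes, medians and step curves", {
  clin <- make_clin(c(1, 2, 3, 4, 5, 6, 7, 8), rep(1L, 8))
  grp <- rep(c("high", "low"), each = 4)
  res <- km_logrank(clin, grp)
  expect_identical(as.integer(res$group_sizes), c(4L, 4L))
  expect_identical(sort(names(res$median_survival)), c("high", "low"))
  expect_true(all(c("group", "time", "survival") %in% names(res$km_curves)))
  expect_true(all(res$km_curves$survival >= 0 & res$km_curves$survival <= 1))
})

test_that("univariate Cox recovers null and planted binary effects", {
  set.seed(71)
  n <- 500
  z <- rnorm(n)
  grp <- factor(ifelse(z > median(z), "high", "low"),
                levels = c("low", "high"))

  # null: no effect planted
  surv0 <- simulate_survival(rep(0, n), baseline_hazard = 0.05,
                             censor_rate = 0.01)
  clin0 <- data.frame(os_time = surv0$time, os_event = surv0$event,
                      grp = grp)
  fit0 <- cox_univariate(clin0, "grp", "os")
  expect_false(fit0$flagged)
  expect_gt(fit0$coefficients$hazard_ratio, 1 / 1.3)
  expect_lt(fit0$coefficients$hazard_ratio, 1.3)

  # planted log HR 0.69 on the binary group, light censoring
  surv1 <- simulate_survival(0.69 * (grp == "high"), 0.05,
                             censor_rate = 0.01)
  clin1 <- data.frame(os_time = surv1$time, os_event = surv1$event,
                      grp = grp)
  fit1 <- cox_univariate(clin1, "grp", "os")
  co <- fit1$coefficients
  se <- (log(co$ci_high) - log(co$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(log(co$hazard_ratio) - log(2)), 3 * se)

  # degenerate input: two samples, one event -> flagged, not silent
  clin2 <- data.frame(os_time = c(1, 2), os_event = c(1L, 0L),
                      grp = factor(c("low", "high")))
  fit2 <- cox_univariate(clin2, "grp", "os")
  expect_true(fit2$flagged)
})

test_that("forward LR selection keeps planted covariates and honours entry_p", {
  set.seed(81)
  n <- 500
  effect <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  surv <- simulate_survival(0.8 * effect, 0.05, censor_rate = 0.01)
  clin <- data.frame(os_time = surv$time, os_event = surv$event,
                     effect = effect, noise = noise)

  sel <- cox_multivariate_forward(clin, c("effect", "noise"), "os",
                                  entry_p = 0.05)
  expect_identical(sel$retained, "effect")
  expect_false(sel$flagged)
  expect_identical(sel$entry_steps$covariate, "effect")

  # entry_p = 1: everything enters, ordered by LR improvement
  all_in <- cox_multivariate_forward(clin, c("noise", "effect"), "os",
                                     entry_p = 1)
  expect_setequal(all_in$retained, c("effect", "noise"))
  expect_identical(all_in$retained[1], "effect")

  # nothing qualifies at step one: empty model, reported as such
  clin_null <- data.frame(os_time = surv$time, os_event = surv$event,
                          noise = noise)
  empty <- cox_multivariate_forward(clin_null, "noise", "os",
                                    entry_p = 1e-12)
  expect_identical(empty$retained, character(0))
  expect_identical(nrow(empty$coefficients), 0L)
})

test_that("Pearson correlation matches hand computation and guards degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, c(1, 3, 2, 4))$r, 0.8)
  # orthogonal to the centered x
  expect_equal(pearson_cor(x, c(1, -1, -1, 1))$r, 0, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(2, 4)), "zero-variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("partial correlation equals the correlation-matrix-inverse oracle", {
  set.seed(91)
  for (i in 1:30) {
    n <- sample(30:80, 1)
    k <- sample(1:4, 1)
    Z <- matrix(rnorm(n * k), nrow = n)
    colnames(Z) <- paste0("c", seq_len(k))
    x <- rnorm(n) + Z %*% rnorm(k)
    y <- rnorm(n) + Z %*% rnorm(k)
    got <- partial_correlation(as.numeric(x), as.numeric(y),
                               as.data.frame(Z))
    expect_equal(got$partial_r, partial_oracle(x, y, Z), tolerance = 1e-8)
  }

  # no controls reduces exactly to Pearson
  x <- rnorm(40); y <- rnorm(40)
  expect_identical(partial_correlation(x, y)$partial_r, pearson_cor(x, y)$r)
  expect_identical(partial_correlation(x, y)$p, pearson_cor(x, y)$p)

  # y identical to a control: residual variance zero
  z <- rnorm(40)
  expect_error(partial_correlation(x, z, data.frame(z = z)),
               "fully explained")
  # collinear controls named in the error
  expect_error(
    partial_correlation(x, y, data.frame(a = z, b = 2 * z)),
    "collinear.*b")
})

test_that("contingency tables use Pearson chi-square without continuity correction", {
  # identical distributions in both groups
  grp <- rep(c("high", "low"), each = 6)
  cat1 <- rep(c("A", "B", "C"), 4)
  expect_equal(group_contingency(grp, cat1)$chi_square, 0)

  # perfectly separated 2x2: chi-square = n = 20
  grp2 <- rep(c("high", "low"), each = 10)
  cat2 <- rep(c("A", "B"), each = 10)
  res2 <- group_contingency(grp2, cat2)
  expect_equal(res2$chi_square, 20)
  expect_equal(res2$df, 1L)

  # empty level dropped with warning
  cat3 <- factor(cat1, levels = c("A", "B", "C", "D"))
  expect_warning(res3 <- group_contingency(grp, cat3), "dropped")
  expect_identical(res3$dropped_levels, "D")

  # synthetic cohort direction: high-score group enriched for upper stage
  cfg <- tiny_config(cohort_size = 400, factor_loading = 1)
  sets <- generate_gene_sets(cfg)
  cohort <- generate_survival_cohort(cfg, sets$hypoxia, sets$emt)
  st <- signature_score(cohort$expression, cohort$truth$planted)
  tab <- group_contingency(st$group, cohort$clinical$stage)
  expect_gt(tab$proportions["high", "III/IV"],
            tab$proportions["low", "III/IV"])
})
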