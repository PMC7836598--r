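# Clinical association analyses for the score: Kaplan-Meier / log-rank by
# high/low group, univariate and forward likelihood-ratio multivariate Cox
# (Efron ties, Wald CIs at 95%), Pearson and residualization-based partial
# correlation, and chi-square contingency of group versus categorical
# clinical annotations.

endpoint_columns <- function(endpoint) {
  endpoint <- match.arg(tolower(endpoint), c("os", "pfs"))
  list(time = paste0(endpoint, "_time"), event = paste0(endpoint, "_event"))
}

# Groups may come as a score_table, a named vector, or a vector aligned with
# the clinical rows; always returned in clinical order.
align_groups <- function(clinical, groups) {
  if (inherits(groups, "score_table"))
    groups <- stats::setNames(groups$group, groups$sample_id)
  if (!is.null(names(groups))) {
    if (!all(clinical$sample_id %in% names(groups)))
      stop_input("group labels do not cover all clinical samples")
    groups <- groups[clinical$sample_id]
  }
  if (length(groups) != nrow(clinical))
    stop_input("groups must align with the clinical table")
  as.character(groups)
}

#' Two-group log-rank test with Kaplan-Meier estimates
#'
#' Standard log-rank statistic (observed minus expected events at each event
#' time, normalised by the hypergeometric variance), chi-square p with 1 df,
#' plus per-group sizes, median survival and the KM step functions.
#'
#' @param clinical Validated clinical table.
#' @param groups High/low labels: a `score_table`, a named vector, or a
#'   vector aligned with the clinical rows.
#' @param endpoint `"os"` or `"pfs"`.
#' @return List of class `logrank_result`: chi_square, p_value, df,
#'   group_sizes, n_events, median_survival, km_curves (data.frame of the
#'   step functions), endpoint.
#' @export
km_logrank <- function(clinical, groups, endpoint = "os") {
  clinical <- validate_clinical(clinical)
  groups <- align_groups(clinical, groups)
  if (anyNA(groups)) stop_input("group labels contain NA")
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop_input("log-rank needs exactly 2 groups, got %d", length(lev))
  cols <- endpoint_columns(endpoint)
  time <- clinical[[cols$time]]
  event <- clinical[[cols$event]]
  if (sum(event) == 0L)
    stop_input("no events observed in either group; log-rank undefined")
  grp <- factor(groups, levels = sort(lev))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd_fit$chisq)
  p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ grp)
  km_sum <- summary(km, censored = TRUE)
  curves <- data.frame(
    group = sub("^grp=", "", as.character(km_sum$strata)),
    time = km_sum$time, n_risk = km_sum$n.risk,
    n_event = km_sum$n.event, survival = km_sum$surv,
    stringsAsFactors = FALSE)
  med <- summary(km)$table
  median_surv <- stats::setNames(med[, "median"],
                                 sub("^grp=", "", rownames(med)))
  structure(list(chi_square = chisq, p_value = p, df = 1L,
                 group_sizes = table(grp),
                 n_events = tapply(event, grp, sum),
                 median_survival = median_surv,
                 km_curves = curves, endpoint = endpoint),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (%s): chi-square = %.4g, df = %d, p = %.4g\n",
              toupper(x$endpoint), x$chi_square, x$df, x$p_value))
  invisible(x)
}

# Shared coxph fitter with degeneracy flagging. Monotone likelihood /
# non-convergence surfaces as a coxph warning; any NA or wild coefficient,
# or fewer events than coefficients, also flags the fit.
fit_cox <- function(formula, data) {
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = "efron"),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  if (length(coefs) > 0L &&
      (anyNA(coefs) || any(abs(coefs) > 15) || fit$nevent <= length(coefs)))
    flags <- c(flags, "degenerate fit (NA/extreme coefficient or too few events)")
  list(fit = fit, flagged = length(flags) > 0L, flags = flags)
}

cox_result_table <- function(fit) {
  s <- summary(fit, conf.int = 0.95)
  if (is.null(stats::coef(fit)) || length(stats::coef(fit)) == 0L)
    return(data.frame(term = character(0), hazard_ratio = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  data.frame(term = rownames(s$coefficients),
             hazard_ratio = unname(s$conf.int[, "exp(coef)"]),
             ci_low = unname(s$conf.int[, 3L]),
             ci_high = unname(s$conf.int[, 4L]),
             p_value = unname(s$coefficients[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' Univariate Cox proportional-hazards model
#'
#' Partial-likelihood fit (Efron tie handling) of one covariate against the
#' chosen endpoint; hazard ratios with Wald 95% CIs and Wald p per
#' coefficient, plus the likelihood-ratio p of the covariate as a whole
#' (identical for single-coefficient covariates, the factor-level screen
#' otherwise). Degenerate fits (monotone likelihood, too few events) are
#' flagged, never silently returned.
#'
#' @param clinical Clinical table, possibly augmented with extra covariate
#'   columns (e.g. the high/low score group).
#' @param covariate Name of the covariate column.
#' @param endpoint `"os"` or `"pfs"`.
#' @return List of class `cox_result`: coefficients data.frame (term,
#'   hazard_ratio, ci_low, ci_high, p_value), loglik, lr_p, n, n_events,
#'   flagged, flags, retained.
#' @export
cox_univariate <- function(clinical, covariate, endpoint = "os") {
  if (!covariate %in% names(clinical))
    stop_input("covariate '%s' not found in the clinical table", covariate)
  cols <- endpoint_columns(endpoint)
  data <- clinical[stats::complete.cases(clinical[, c(cols$time, cols$event,
                                                      covariate)]), ]
  f <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ `%s`",
                                 cols$time, cols$event, covariate))
  res <- fit_cox(f, data)
  fit <- res$fit
  lr_stat <- 2 * (fit$loglik[2L] - fit$loglik[1L])
  lr_df <- sum(!is.na(stats::coef(fit)))
  structure(list(coefficients = cox_result_table(fit),
                 loglik = fit$loglik[2L],
                 lr_p = stats::pchisq(lr_stat, df = lr_df, lower.tail = FALSE),
                 n = fit$n, n_events = fit$nevent,
                 flagged = res$flagged, flags = res$flags,
                 retained = covariate, endpoint = endpoint),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (%s), n = %d, events = %d%s\n",
              toupper(x$endpoint), x$n, x$n_events,
              if (x$flagged) " [FLAGGED]" else ""))
  if (nrow(x$coefficients) == 0L) cat("  (empty model)\n")
  else print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multivariate Cox model with forward likelihood-ratio selection
#'
#' Stepwise forward entry: at each step every remaining candidate is added
#' to the current model, scored by the likelihood-ratio test
#' (2 * delta log-likelihood, chi-square with df equal to the coefficients
#' it adds), and the candidate with the smallest LR p enters if that p is
#' below `entry_p`; selection stops when no candidate qualifies. An empty
#' model (no candidate entering at step one) is a valid, reported outcome.
#'
#' @param clinical Clinical table, possibly augmented (see
#'   [cox_univariate()]).
#' @param candidates Character vector of candidate covariate columns,
#'   typically pre-screened by univariate significance.
#' @param endpoint `"os"` or `"pfs"`.
#' @param entry_p Entry threshold on the LR p-value (default 0.05).
#' @return A `cox_result` for the final model; `retained` holds the entered
#'   covariates in entry order and `entry_steps` the per-step LR statistics.
#' @export
cox_multivariate_forward <- function(clinical, candidates, endpoint = "os",
                                     entry_p = 0.05) {
  if (length(candidates) < 1L) stop_input("no candidate covariates given")
  missing_cov <- setdiff(candidates, names(clinical))
  if (length(missing_cov) > 0L)
    stop_input("candidate(s) not in the clinical table: %s",
               paste(missing_cov, collapse = ", "))
  check_number(entry_p, "entry_p", min = 0, max = 1, strict_min = TRUE)
  cols <- endpoint_columns(endpoint)
  data <- clinical[stats::complete.cases(
    clinical[, c(cols$time, cols$event, candidates)]), ]
  surv_lhs <- sprintf("survival::Surv(%s, %s)", cols$time, cols$event)
  make_formula <- function(terms) {
    rhs <- if (length(terms) == 0L) "1"
    else paste(sprintf("`%s`", terms), collapse = " + ")
    stats::as.formula(paste(surv_lhs, "~", rhs))
  }

  null_fit <- survival::coxph(make_formula(character(0)), data = data,
                              ties = "efron")
  current_ll <- null_fit$loglik[1L]
  current_df <- 0L
  retained <- character(0)
  remaining <- candidates
  steps <- list()
  final <- NULL

  while (length(remaining) > 0L) {
    trials <- lapply(remaining, function(cand) {
      res <- fit_cox(make_formula(c(retained, cand)), data)
      df_add <- sum(!is.na(stats::coef(res$fit))) - current_df
      lr <- 2 * (res$fit$loglik[2L] - current_ll)
      p <- if (df_add > 0L)
        stats::pchisq(lr, df = df_add, lower.tail = FALSE) else 1
      list(cand = cand, res = res, lr = lr, df = df_add, p = p)
    })
    ps <- vapply(trials, `[[`, numeric(1), "p")
    best <- trials[[which.min(ps)]]
    if (best$p >= entry_p) break
    retained <- c(retained, best$cand)
    remaining <- setdiff(remaining, best$cand)
    current_ll <- best$res$fit$loglik[2L]
    current_df <- current_df + best$df
    final <- best
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, covariate = best$cand,
      lr_statistic = best$lr, df = best$df, lr_p = best$p,
      stringsAsFactors = FALSE)
  }

  if (is.null(final)) {
    hx_log("cox_multivariate_forward: no candidate met the entry threshold; empty model",
           "warn")
    out <- list(coefficients = cox_result_table(null_fit),
                loglik = null_fit$loglik[1L], lr_p = NA_real_,
                n = null_fit$n, n_events = null_fit$nevent,
                flagged = FALSE, flags = character(0))
  } else {
    fit <- final$res$fit
    lr_stat <- 2 * (fit$loglik[2L] - fit$loglik[1L])
    out <- list(coefficients = cox_result_table(fit),
                loglik = fit$loglik[2L],
                lr_p = stats::pchisq(lr_stat, df = current_df,
                                     lower.tail = FALSE),
                n = fit$n, n_events = fit$nevent,
                flagged = final$res$flagged, flags = final$res$flags)
  }
  out$retained <- retained
  out$entry_steps <- if (length(steps) > 0L) do.call(rbind, steps)
  else data.frame(step = integer(0), covariate = character(0),
                  lr_statistic = numeric(0), df = integer(0),
                  lr_p = numeric(0))
  out$endpoint <- endpoint
  structure(out, class = "cox_result")
}

#' Pearson correlation with its t-based p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return List with `r`, `p` (two-sided), `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("Pearson correlation needs n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_input("zero-variance input; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Partial correlation by residualization
#'
#' Regresses x and y on the control variables (least squares with an
#' intercept; factor controls are integer-coded by level order), then takes
#' the Pearson correlation of the residuals. The p-value uses the t
#' transform with n - 2 - k degrees of freedom (k controls). With no
#' controls this reduces exactly to [pearson_cor()].
#'
#' @param x,y Numeric vectors.
#' @param controls NULL, a vector, or a data.frame/list of control
#'   variables.
#' @return List with `partial_r`, `p`, `df`, `n`, `controls` (names used).
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  n <- length(x)
  if (is.null(controls) || (is.list(controls) && length(controls) == 0L)) {
    pc <- pearson_cor(x, y)
    return(list(partial_r = pc$r, p = pc$p, df = n - 2L, n = n,
                controls = character(0)))
  }
  if (!is.data.frame(controls))
    controls <- if (is.list(controls)) as.data.frame(controls)
  else as.data.frame(list(control = controls))
  ctrl_num <- lapply(controls, function(v) {
    if (is.factor(v)) as.integer(v) else as.numeric(v)
  })
  Z <- do.call(cbind, ctrl_num)
  colnames(Z) <- names(controls)
  if (nrow(Z) != n) stop_input("controls must align with x and y")
  k <- ncol(Z)
  if (n <= k + 2L) stop_input("need n > number of controls + 2")
  X <- cbind(`(intercept)` = 1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_input("collinear control variable(s): %s",
               paste(aliased, collapse = ", "))
  }
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  if (stats::var(rx) < .Machine$double.eps * 100 ||
      stats::var(ry) < .Machine$double.eps * 100)
    stop_input("a variable is fully explained by the controls; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(partial_r = r, p = 2 * stats::pt(-abs(tval), df = df),
       df = df, n = n, controls = colnames(Z))
}

#' Contingency of score group against a categorical annotation
#'
#' Counts and within-group proportions per level plus a Pearson chi-square
#' test of independence (no continuity correction). Levels with zero total
#' count are dropped with a warning.
#'
#' @param groups High/low labels (any 2+ level grouping works).
#' @param category Categorical per-sample annotation (factor/character).
#' @return List of class `contingency_result`: counts, proportions (within
#'   group), chi_square, df, p_value, dropped_levels.
#' @export
group_contingency <- function(groups, category) {
  if (length(groups) != length(category))
    stop_input("groups and category must align")
  category <- as.factor(category)
  empty <- levels(category)[table(category) == 0L]
  if (length(empty) > 0L) {
    warning(sprintf("dropped empty category level(s): %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
    category <- droplevels(category)
  }
  if (nlevels(category) < 2L)
    stop_input("need at least 2 category levels with observations")
  tab <- table(group = groups, category = category)
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(counts = tab,
                 proportions = prop.table(tab, margin = 1L),
                 chi_square = unname(test$statistic),
                 df = unname(test$parameter),
                 p_value = test$p.value,
                 dropped_levels = empty),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$counts)
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}
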