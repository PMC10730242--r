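# Association of endotypes with ultrasound outcomes (linear models) and
# with ASCVD (Cox proportional hazards), with the cohort's three nested
# adjustment sets, proportionality and collinearity diagnostics, and
# Kaplan-Meier curves. Endotype 1 is always the reference level. Age, sex
# and systolic blood pressure are deliberately not adjusted for (they are
# constituents of every endotype); an override is available.

#' Covariate sets for the three adjustment models
#'
#' Model 1 adjusts for analytical batch and recruitment centre (the
#' latitude surrogate); Model 2 adds smoking, body-mass index,
#' LDL-cholesterol and diabetes, plus the corresponding baseline ultrasound
#' measure when the outcome is a progression or survival outcome; Model 3
#' adds anti-hypertensive, anti-platelet and lipid-lowering treatment.
#'
#' @param model `"model1"`, `"model2"` or `"model3"`.
#' @param baseline_measure Baseline ultrasound column added by Models 2-3
#'   for progression/survival outcomes (`NULL` for baseline outcomes).
#' @param adjust_age_sex_sbp Override flag: add age, sex and SBP.
#' @return Character vector of covariate names.
#' @export
model_covariates <- function(model = c("model1", "model2", "model3"),
                             baseline_measure = NULL,
                             adjust_age_sex_sbp = FALSE) {
  model <- match.arg(model)
  covs <- c("batch", "center")
  if (model %in% c("model2", "model3")) {
    covs <- c(covs, "smoking", "bmi", "ldl_c", "diabetes", baseline_measure)
  }
  if (model == "model3") {
    covs <- c(covs, "antihypertensive", "antiplatelet", "lipid_lowering")
  }
  if (adjust_age_sex_sbp) covs <- c(covs, "age", "sex", "sbp")
  covs
}

endotype_factor <- function(endotypes, n = NULL) {
  if (inherits(endotypes, "endotype_assignment")) endotypes <- endotypes$endotype
  f <- factor(endotypes)
  if (!is.null(n) && length(f) != n) abort_endo("Endotypes not aligned to table.")
  stats::relevel(f, ref = levels(f)[1])
}

build_formula <- function(response, covariates) {
  rhs <- paste(c("endotype", covariates), collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

#' Linear association of endotypes with an outcome
#'
#' Ordinary least squares with endotype dummy coding (endotype 1 =
#' reference) under one of the three adjustment models.
#'
#' @param table Cohort data frame containing the outcome and covariates.
#' @param outcome Outcome column name.
#' @param endotypes Endotype labels (vector or `endotype_assignment`).
#' @param model Adjustment model (see [model_covariates()]).
#' @param baseline_measure Baseline ultrasound adjustment for progression
#'   outcomes (Models 2-3).
#' @param covariates Explicit covariate override (replaces
#'   [model_covariates()]).
#' @param adjust_age_sex_sbp Add age, sex and SBP to the adjustment set.
#' @return A `regression_result` tibble: `model`, `outcome`, `term`,
#'   `estimate`, `se`, `statistic`, `p_value`, with endotype terms first.
#' @export
fit_linear_models <- function(table, outcome, endotypes, model = "model1",
                              baseline_measure = NULL, covariates = NULL,
                              adjust_age_sex_sbp = FALSE) {
  stopifnot(is.data.frame(table))
  if (!outcome %in% names(table)) abort_endo(paste0("No column `", outcome, "`."))
  covs <- if (is.null(covariates)) {
    model_covariates(model, baseline_measure, adjust_age_sex_sbp)
  } else covariates
  covs <- intersect(covs, names(table))
  df <- as.data.frame(table)
  df$endotype <- endotype_factor(endotypes, nrow(df))
  fit <- stats::lm(build_formula(outcome, covs), data = df)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased) > 0) {
    abort_endo(paste0("Rank-deficient design; aliased term(s): ",
                      paste(aliased, collapse = ", ")),
               class = "endotyper_rank_deficient")
  }
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(
    model = model, outcome = outcome,
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
  out <- out[order(!startsWith(out$term, "endotype")), ]
  attr(out, "fit") <- fit
  class(out) <- c("regression_result", class(out))
  out
}

#' Cox association of endotypes with ASCVD
#'
#' Cox proportional hazards (Efron tie handling) with endotype dummies
#' (endotype 1 = reference) under one of the three adjustment models.
#' Hazard ratios carry Wald 95% confidence intervals
#' `exp(beta +- 1.96 se)`.
#'
#' @param table Cohort data frame with `time` and `event` columns (or
#'   supply `time`/`event` explicitly).
#' @param endotypes Endotype labels.
#' @param model Adjustment model.
#' @param baseline_measure Baseline ultrasound adjustment (Models 2-3; the
#'   ASCVD analysis uses baseline c-IMT_mean-max).
#' @param covariates Explicit covariate override.
#' @param adjust_age_sex_sbp Add age, sex and SBP.
#' @param time,event Optional explicit survival vectors.
#' @return A `regression_result` tibble with `hr`, `ci_lo`, `ci_hi` filled
#'   for each term; the `coxph` fit is attached as attribute `fit` and a
#'   `monotone_likelihood` flag marks non-converged (separated) fits.
#' @export
fit_cox <- function(table, endotypes, model = "model1",
                    baseline_measure = NULL, covariates = NULL,
                    adjust_age_sex_sbp = FALSE, time = NULL, event = NULL) {
  df <- as.data.frame(table)
  if (is.null(time)) time <- df$time
  if (is.null(event)) event <- df$event
  if (is.null(time) || is.null(event)) abort_endo("Need `time` and `event`.")
  if (any(time <= 0)) abort_endo("Survival times must be positive.")
  if (sum(event) < 1) abort_endo("Need at least one event.")
  covs <- if (is.null(covariates)) {
    model_covariates(model, baseline_measure, adjust_age_sex_sbp)
  } else covariates
  covs <- intersect(covs, names(df))
  df$endotype <- endotype_factor(endotypes, nrow(df))
  df$.time <- time; df$.event <- event
  fml <- build_formula("survival::Surv(.time, .event)", covs)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron", model = TRUE),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(is.na(stats::coef(fit)))) {
    abort_endo(paste0("Singular Cox design; aliased/constant term(s): ",
                      paste(names(which(is.na(stats::coef(fit)))),
                            collapse = ", ")),
               class = "endotyper_rank_deficient")
  }
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(
    model = model, outcome = "ascvd",
    term = rownames(sm),
    estimate = unname(sm[, "coef"]),
    se = unname(sm[, "se(coef)"]),
    statistic = unname(sm[, "z"]),
    p_value = unname(sm[, "Pr(>|z|)"]),
    hr = unname(exp(sm[, "coef"])),
    ci_lo = unname(exp(sm[, "coef"] - 1.96 * sm[, "se(coef)"])),
    ci_hi = unname(exp(sm[, "coef"] + 1.96 * sm[, "se(coef)"]))
  )
  out <- out[order(!startsWith(out$term, "endotype")), ]
  attr(out, "fit") <- fit
  attr(out, "monotone_likelihood") <- monotone
  class(out) <- c("regression_result", class(out))
  out
}

#' @method tidy regression_result
#' @export
tidy.regression_result <- function(x, ...) tibble::as_tibble(x)

#' Proportional-hazards diagnostics (scaled Schoenfeld residuals)
#'
#' Correlation test of the scaled Schoenfeld residuals against event-time
#' rank for every covariate, plus the global chi-square test
#' (`survival::cox.zph`, rank transform).
#'
#' @param cox_result A `regression_result` from [fit_cox()] or a `coxph`
#'   fit.
#' @return Tibble with `term`, `chisq`, `df`, `p_value`.
#' @export
check_proportionality <- function(cox_result) {
  fit <- if (inherits(cox_result, "coxph")) cox_result else attr(cox_result, "fit")
  if (is.null(fit)) abort_endo("No Cox fit attached.")
  if (fit$nevent < 2) abort_endo("Need at least 2 events.")
  zp <- survival::cox.zph(fit, transform = "rank")
  tab <- zp$table
  tibble::tibble(term = rownames(tab), chisq = tab[, "chisq"],
                 df = tab[, "df"], p_value = tab[, "p"])
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing covariate j on
#' the remaining covariates. Exact collinearity yields an infinite VIF,
#' which is flagged rather than silently returned.
#'
#' @param design Numeric matrix / data frame of covariates (no intercept
#'   column; factors must be pre-expanded).
#' @return Tibble with `term`, `vif`, `collinear` flag.
#' @export
compute_vif <- function(design) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (ncol(X) < 2) abort_endo("Need >= 2 covariates.")
  if (any(apply(X, 2, stats::sd) == 0)) {
    abort_endo("Zero-variance covariate.", class = "endotyper_zero_variance")
  }
  vif <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  tibble::tibble(term = nm, vif = vif, collinear = !is.finite(vif))
}

#' Kaplan-Meier curves per endotype
#'
#' Product-limit estimator per group, exported as step tables.
#'
#' @param time,event Survival outcome (years, 0/1).
#' @param groups Per-subject group labels (e.g. endotypes).
#' @return Tibble with `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event, groups) {
  if (inherits(groups, "endotype_assignment")) groups <- groups$endotype
  if (any(time <= 0)) abort_endo("Survival times must be positive.")
  g <- factor(groups)
  if (any(table(g) == 0)) abort_endo("Empty group.")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  strata <- if (is.null(fit$strata)) {
    rep(levels(g)[1], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  tibble::tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, survival = fit$surv)
}

#' Kaplan-Meier plot per endotype
#' @param km Output of [km_estimate()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  start <- dplyr::distinct(km, .data$group)
  start$time <- 0; start$survival <- 1
  km2 <- dplyr::bind_rows(start, km[, c("group", "time", "survival")])
  ggplot2::ggplot(km2, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years", y = "event-free survival",
                  colour = "endotype") +
    ggplot2::theme_minimal()
}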