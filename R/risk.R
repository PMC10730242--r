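# SCORE2-style risk scoring, risk categorization, Harrell's C for censored
# outcomes, censoring-adjusted categorical net reclassification improvement
# (Kaplan-Meier within reclassification cells), and percentile bootstrap
# confidence intervals.

#' Load a SCORE2-style coefficient configuration
#'
#' Coefficient/calibration configurations are YAML files with a `terms`
#' list (each term: `variable`, `coefficient`, optional `center`, `scale`,
#' `log`) and a `calibration` block (`baseline_survival`, `scale1`,
#' `scale2`, `horizon`). The configuration shipped with the package
#' (`score2_synthetic.yaml`) is a synthetic, non-clinical stand-in that
#' satisfies the structural properties of the published linear predictors;
#' it is not a clinical SCORE2 implementation.
#'
#' @param path YAML path; default is the shipped synthetic config.
#' @return A `risk_config` list.
#' @export
read_risk_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "score2_synthetic.yaml",
                        package = "endotyper")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$terms) || is.null(cfg$calibration)) {
    abort_endo("Risk config needs `terms` and `calibration`.")
  }
  structure(cfg, class = "risk_config")
}

transform_covariate <- function(x, term) {
  if (isTRUE(term$log)) x <- log(x)
  centre <- term$center %||% 0
  scale <- term$scale %||% 1
  (x - centre) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SCORE2-style linear predictor and calibrated risk
#'
#' `LP = sum coefficient * transformed covariate`; uncalibrated risk
#' `1 - S0^exp(LP)`; calibrated risk
#' `1 - exp(-exp(scale1 + scale2 * ln(-ln(1 - uncalibrated))))`.
#'
#' @param table Data frame of risk factors.
#' @param config A `risk_config` (see [read_risk_config()]).
#' @return Tibble with `lp`, `risk_uncalibrated`, `risk` (calibrated, in
#'   [0, 1]).
#' @export
score2_linear_predictor <- function(table, config = read_risk_config()) {
  stopifnot(is.data.frame(table))
  lp <- rep(0, nrow(table))
  for (term in config$terms) {
    v <- term$variable
    if (!v %in% names(table)) {
      abort_endo(paste0("Missing risk factor: ", v))
    }
    x <- table[[v]]
    if (is.factor(x)) x <- as.numeric(x) - 1
    lp <- lp + term$coefficient * transform_covariate(x, term)
  }
  cal <- config$calibration
  s0 <- cal$baseline_survival
  risk0 <- 1 - s0^exp(lp)
  risk0 <- pmin(pmax(risk0, 1e-12), 1 - 1e-12)
  risk <- 1 - exp(-exp(cal$scale1 + cal$scale2 * log(-log(1 - risk0))))
  if (any(!is.finite(risk)) || any(risk < 0 | risk > 1)) {
    abort_endo("Calibrated risk outside [0, 1].")
  }
  tibble::tibble(lp = lp, risk_uncalibrated = risk0, risk = risk)
}

#' Categorize absolute risk
#'
#' SCORE2 scheme: low < 5%, moderate 5 to < 10%, high >= 10%;
#' SCORE2-OP scheme: low < 7.5%, moderate 7.5 to < 15%, high >= 15%.
#' Boundaries belong to the upper category.
#'
#' @param risk Absolute risk in [0, 1].
#' @param scheme `"score2"` or `"score2_op"`.
#' @return Ordered factor with levels low < moderate < high.
#' @export
categorize_risk <- function(risk, scheme = c("score2", "score2_op")) {
  scheme <- match.arg(scheme)
  if (any(risk < 0, na.rm = TRUE)) abort_endo("Negative risk.")
  if (any(risk > 1, na.rm = TRUE)) abort_endo("Risk above 1.")
  cuts <- if (scheme == "score2") c(0.05, 0.10) else c(0.075, 0.15)
  factor(ifelse(risk < cuts[1], "low",
         ifelse(risk < cuts[2], "moderate", "high")),
         levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Harrell's concordance index for censored survival
#'
#' Usable pairs are anchored at events: subject i with an event at `t_i` is
#' comparable with every j surviving past `t_i` (`t_j > t_i`). A pair is
#' concordant when the event subject has the higher risk; ties in risk
#' count one half.
#'
#' @param time,event Survival outcome.
#' @param risk Per-subject risk score (higher = riskier).
#' @return Concordance in [0, 1].
#' @export
harrell_c <- function(time, event, risk) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  ev <- which(event == 1)
  conc <- 0; comp <- 0
  for (i in ev) {
    j <- which(time > time[i])
    if (length(j) == 0) next
    comp <- comp + length(j)
    conc <- conc + sum(risk[i] > risk[j]) + 0.5 * sum(risk[i] == risk[j])
  }
  if (comp == 0) abort_endo("No comparable pairs.")
  conc / comp
}

# Kaplan-Meier survival probability at a fixed horizon; carries the last
# value forward when follow-up ends before the horizon.
km_surv_at <- function(time, event, horizon) {
  n <- length(time)
  if (n == 0) return(NA_real_)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  s <- 1
  at_risk <- n
  i <- 1
  while (i <= n && time[i] <= horizon) {
    t0 <- time[i]
    d <- sum(time == t0 & event == 1)
    if (d > 0) s <- s * (1 - d / at_risk)
    at_risk <- at_risk - sum(time == t0)
    i <- i + sum(time == t0)
  }
  s
}

#' Censoring-adjusted categorical net reclassification improvement
#'
#' Subjects are cross-classified by old and new risk category. Within each
#' cell, the event probability by `horizon` is estimated by Kaplan-Meier
#' (censoring-adjusted); expected event and non-event masses then replace
#' the event/non-event counts of the classical uncensored NRI, to which the
#' estimator reduces exactly when no record is censored before the horizon.
#' `NRI+ = P(up | event) - P(down | event)`;
#' `NRI- = P(down | non-event) - P(up | non-event)`; total is their sum.
#'
#' @param time,event Survival outcome.
#' @param old_categories,new_categories Ordered risk categories (as from
#'   [categorize_risk()]).
#' @param horizon Evaluation horizon (years).
#' @return An `nri_result`: list with `nri_event`, `nri_nonevent`,
#'   `nri_total`, `horizon`, and the reclassification `cells` tibble.
#' @export
compute_nri <- function(time, event, old_categories, new_categories, horizon) {
  n <- length(time)
  stopifnot(length(old_categories) == n, length(new_categories) == n)
  if (horizon > max(time)) abort_endo("`horizon` exceeds max follow-up.")
  oldc <- as.integer(factor(old_categories,
                            levels = levels(factor(old_categories))))
  if (is.ordered(old_categories)) oldc <- as.integer(old_categories)
  newc <- if (is.ordered(new_categories)) as.integer(new_categories) else
    as.integer(factor(new_categories))
  move <- sign(newc - oldc)

  cells <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(old = oldc, new = newc, move = move,
                                   time = time, event = event),
                    .data$old, .data$new, .data$move),
    n = dplyr::n(),
    p_event = 1 - km_surv_at(.data$time, .data$event, horizon),
    .groups = "drop")

  exp_events <- sum(cells$n * cells$p_event)
  exp_nonevents <- sum(cells$n * (1 - cells$p_event))
  if (exp_events <= 0) abort_endo("Zero estimated events by the horizon.")
  up_e <- sum(cells$n[cells$move > 0] * cells$p_event[cells$move > 0])
  dn_e <- sum(cells$n[cells$move < 0] * cells$p_event[cells$move < 0])
  up_ne <- sum(cells$n[cells$move > 0] * (1 - cells$p_event[cells$move > 0]))
  dn_ne <- sum(cells$n[cells$move < 0] * (1 - cells$p_event[cells$move < 0]))

  structure(list(
    nri_event = (up_e - dn_e) / exp_events,
    nri_nonevent = (dn_ne - up_ne) / exp_nonevents,
    nri_total = (up_e - dn_e) / exp_events + (dn_ne - up_ne) / exp_nonevents,
    horizon = horizon,
    cells = cells
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("<nri_result> horizon %.3g y: NRI+ %.4f, NRI- %.4f, total %.4f\n",
              x$horizon, x$nri_event, x$nri_nonevent, x$nri_total))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI (total): %.4f to %.4f (B = %d)\n",
                x$ci["total", 1], x$ci["total", 2], x$B))
  }
  invisible(x)
}

#' Tidy an NRI result
#' @param x An `nri_result`.
#' @param ... Unused.
#' @return Tibble with one row per component (event, nonevent, total).
#' @method tidy nri_result
#' @export
tidy.nri_result <- function(x, ...) {
  out <- tibble::tibble(
    component = c("event", "nonevent", "total"),
    estimate = c(x$nri_event, x$nri_nonevent, x$nri_total)
  )
  if (!is.null(x$ci)) {
    out$conf_low <- x$ci[, 1]
    out$conf_high <- x$ci[, 2]
  }
  out
}

#' Percentile bootstrap confidence interval
#'
#' Subject-level resampling with replacement; `statistic` receives the
#' resampled data and returns a numeric (possibly named) vector. Resamples
#' on which the statistic fails are skipped and counted; more than 10%
#' failures is an error.
#'
#' @param statistic Function of the data returning a numeric vector.
#' @param data Data frame (rows = subjects).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `ci` (matrix: component x lower/upper), `estimate`,
#'   `n_failed`, `B`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, seed = 1, conf = 0.95) {
  stopifnot(is.data.frame(data), B >= 2)
  est <- statistic(data)
  with_seed(sub_seed(seed, "boot"), {
    n <- nrow(data)
    draws <- matrix(NA_real_, nrow = B, ncol = length(est))
    failed <- 0L
    for (b in seq_len(B)) {
      res <- tryCatch(statistic(data[sample.int(n, n, replace = TRUE), ,
                                     drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(res) || length(res) != length(est) || !all(is.finite(res))) {
        failed <- failed + 1L
      } else {
        draws[b, ] <- res
      }
    }
    if (failed > 0.1 * B) {
      abort_endo(sprintf("Bootstrap failed on %d of %d resamples.", failed, B))
    }
    alpha <- (1 - conf) / 2
    ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                  na.rm = TRUE))
    rownames(ci) <- names(est) %||% paste0("stat", seq_along(est))
    list(ci = ci, estimate = est, n_failed = failed, B = as.integer(B))
  })
}

# Predicted absolute risk at a horizon from a Cox model via the Breslow
# baseline hazard.
cox_risk_at <- function(fit, newdata, horizon) {
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- if (any(bh$time <= horizon)) max(bh$hazard[bh$time <= horizon]) else 0
  lp <- stats::predict(fit, newdata = newdata, type = "lp", reference = "zero")
  1 - exp(-H0 * exp(lp))
}

#' Discrimination and reclassification gain from adding endotypes
#'
#' Fits two Cox models for the ASCVD horizon - the baseline risk score
#' alone, and the score plus endotype dummies - converts both to absolute
#' risks at the horizon, categorizes them under the chosen scheme, and
#' reports Harrell's C for both models plus the censoring-adjusted NRI of
#' the reclassification, with an optional percentile bootstrap CI.
#'
#' @param time,event Survival outcome.
#' @param base_score Baseline continuous risk score (e.g. the SCORE2-style
#'   linear predictor, or c-IMT_mean-max).
#' @param endotypes Endotype labels.
#' @param horizon Evaluation horizon (years).
#' @param scheme Categorization scheme (see [categorize_risk()]).
#' @param B Bootstrap resamples for the NRI CI (0 = skip).
#' @param seed Integer seed for the bootstrap.
#' @return List with `c_base`, `c_new`, `nri` (an `nri_result`, with `ci`
#'   and `B` when bootstrapped).
#' @export
risk_model_comparison <- function(time, event, base_score, endotypes,
                                  horizon = 3, scheme = "score2",
                                  B = 0, seed = 1) {
  if (inherits(endotypes, "endotype_assignment")) endotypes <- endotypes$endotype
  df <- data.frame(time = time, event = event, score = base_score,
                   endotype = factor(endotypes))
  fit_risks <- function(d) {
    f0 <- survival::coxph(survival::Surv(time, event) ~ score, data = d,
                          ties = "efron")
    f1 <- survival::coxph(survival::Surv(time, event) ~ score + endotype,
                          data = d, ties = "efron")
    list(r0 = cox_risk_at(f0, d, horizon), r1 = cox_risk_at(f1, d, horizon))
  }
  r <- fit_risks(df)
  cat0 <- categorize_risk(r$r0, scheme)
  cat1 <- categorize_risk(r$r1, scheme)
  nri <- compute_nri(df$time, df$event, cat0, cat1, horizon)
  if (B > 0) {
    stat <- function(d) {
      rr <- fit_risks(d)
      x <- compute_nri(d$time, d$event,
                       categorize_risk(rr$r0, scheme),
                       categorize_risk(rr$r1, scheme), horizon)
      c(event = x$nri_event, nonevent = x$nri_nonevent, total = x$nri_total)
    }
    bs <- bootstrap_ci(stat, df, B = B, seed = seed)
    nri$ci <- bs$ci
    nri$B <- bs$B
  }
  list(
    c_base = harrell_c(df$time, df$event, r$r0),
    c_new = harrell_c(df$time, df$event, r$r1),
    nri = nri
  )
}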