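# Synthetic cohort generator: latent atherosclerosis classes, correlated
# biomarker blocks, per-segment carotid ultrasound measures and censored
# time-to-ASCVD. The generator is first-class, tested code: every downstream
# stage of the pipeline is exercised against cohorts drawn from it.

#' Default per-class, per-module biomarker mean shifts
#'
#' Rows are latent classes 1..4, columns biomarker co-expression modules.
#' Shifts are in marginal SD units and concentrate on the six modules named
#' in the endotype signatures; the remaining modules carry no class signal.
#' The mildest class (1) sits low on the renin module (m05) and the
#' OPG/GDF15/MMP12/CHI3L1 module (m06) and high on the RAGE/leptin module
#' (m08); class 2 is high on the NEMO/HSP27 module (m03); class 3 mirrors
#' class 1 (high renin, low RAGE/leptin); the most severe class (4) is
#' shifted up +0.8 SD on m06 and down on the IL6RA module (m02).
#'
#' @param n_modules Number of modules (shifts beyond the 17 defaults are 0).
#' @return A 4 x `n_modules` numeric matrix.
#' @export
default_class_module_shifts <- function(n_modules = 17) {
  base <- matrix(0, nrow = 4, ncol = max(n_modules, 8))
  #               m01    m02    m03    m05    m06    m08
  base[1, c(1, 2, 3, 5, 6, 8)] <- c(-1.40,  1.12, -0.56, -1.40, -0.98,  1.40)
  base[2, c(1, 2, 3, 5, 6, 8)] <- c( 1.40,  0.56,  1.40, -0.56, -0.56, -1.40)
  base[3, c(1, 2, 3, 5, 6, 8)] <- c(-0.56, -1.40, -1.40,  1.40,  0.56, -0.56)
  base[4, c(1, 2, 3, 5, 6, 8)] <- c( 1.40, -1.40,  1.40,  0.56,  0.80,  0.56)
  out <- base[, seq_len(n_modules), drop = FALSE]
  colnames(out) <- sprintf("m%02d", seq_len(n_modules))
  rownames(out) <- paste0("class", 1:4)
  out
}

# Module sizes as equal as possible over the biomarker panel; for the default
# 92-biomarker / 17-module panel this gives 7 modules of 6 and 10 of 5.
module_sizes <- function(n_biomarkers, n_modules) {
  base <- n_biomarkers %/% n_modules
  extra <- n_biomarkers %% n_modules
  sizes <- rep(base, n_modules)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  sizes
}

# Biomarker names: the proteins named in the endotype signatures are placed in
# their modules; the remainder of the panel gets generic names.
biomarker_schema <- function(n_biomarkers = 92, n_modules = 17) {
  sizes <- module_sizes(n_biomarkers, n_modules)
  if (any(sizes < 3)) {
    abort_endo("Module sizes must be >= 3; reduce `n_modules` or increase `n_biomarkers`.")
  }
  module <- rep(seq_len(n_modules), sizes)
  named <- list(`2` = "IL6RA", `3` = c("NEMO", "HSP27"), `5` = "REN",
                `6` = c("OPG", "GDF15", "MMP12", "CHI3L1"),
                `8` = c("RAGE", "LEP"))
  nm <- character(n_biomarkers)
  filler <- 0L
  for (m in seq_len(n_modules)) {
    idx <- which(module == m)
    special <- named[[as.character(m)]]
    special <- special[seq_len(min(length(special), length(idx)))]
    for (j in seq_along(idx)) {
      if (j <= length(special)) {
        nm[idx[j]] <- special[j]
      } else {
        filler <- filler + 1L
        nm[idx[j]] <- sprintf("bm%03d", filler)
      }
    }
  }
  tibble::tibble(biomarker = nm, module = module)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a high-risk European cohort of 3121 subjects with four
#' latent atherosclerosis classes: class proportions 1277/783/502/559,
#' per-class mean (SD) composite carotid intima-media thickness
#' (c-IMT_mean-max, mm) of 1.10 (0.20), 1.23 (0.24), 1.39 (0.30), 1.50 (0.33),
#' per-class expected plaque counts 0.89/1.46/2.25/2.64, and class hazard
#' ratios for ASCVD of 1 / 0.97 / 2.43 / 2.85 versus class 1. The baseline
#' hazard is solved numerically so that the marginal 3-year event fraction
#' equals `target_event_rate` (default 5.3%).
#'
#' @param n_subjects Number of subjects.
#' @param class_proportions Four fractions summing to 1.
#' @param class_cimt_means,class_cimt_sds Per-class mean/SD of c-IMT_mean-max (mm).
#' @param class_plaque_rates Per-class Poisson mean plaque count.
#' @param class_log_hazards Per-class log hazard ratio (class 1 = 0).
#' @param baseline_hazard Events per person-year for class 1; if `NULL`,
#'   solved so the marginal event fraction at `admin_censor_time` equals
#'   `target_event_rate`.
#' @param target_event_rate Marginal event fraction used to solve the
#'   baseline hazard when `baseline_hazard` is `NULL`.
#' @param admin_censor_time Administrative censoring time (years).
#' @param event_type_split Probabilities of cardiac / cerebrovascular /
#'   peripheral types given an event.
#' @param n_biomarkers,n_modules Size of the biomarker panel and number of
#'   planted co-expression modules.
#' @param module_within_cor Within-module biomarker correlation in [0, 1).
#' @param class_module_shifts 4 x `n_modules` matrix of per-class module mean
#'   shifts in SD units.
#' @param covariate_effects Named vector of c-IMT effects: `age` (mm/year),
#'   `male` (mm), `sbp` (mm/mmHg). Effects are centred so class marginal
#'   means stay at `class_cimt_means`.
#' @param class_sbp_means,sbp_sd Per-class mean and common SD of systolic
#'   blood pressure (mmHg).
#' @param class_progression_means Per-class mean of the fastest-progressing
#'   segment's annual c-IMT change (mm/year).
#' @param progression_segment_sd Per-segment SD of annual change (mm/year).
#' @param segment_sd Per-segment SD of baseline c-IMT maxima around the
#'   subject-level mean (mm).
#' @param n_segments Carotid segments measured per subject.
#' @param n_centers Number of recruiting centres (latitude/batch surrogate).
#' @param missing_rate Fraction of subjects given at least one missing value
#'   among clinical/biomarker variables (0 = complete data).
#' @param seed Integer seed; every draw of the generator is derived from it.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_subjects = 400, seed = 7)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_config <- function(n_subjects = 3121,
                          class_proportions = c(1277, 783, 502, 559) / 3121,
                          class_cimt_means = c(1.10, 1.23, 1.39, 1.50),
                          class_cimt_sds = c(0.20, 0.24, 0.30, 0.33),
                          class_plaque_rates = c(0.89, 1.46, 2.25, 2.64),
                          class_log_hazards = c(0, log(0.97), log(2.43), log(2.85)),
                          baseline_hazard = NULL,
                          target_event_rate = 0.053,
                          admin_censor_time = 3,
                          event_type_split = c(cardiac = 0.62,
                                               cerebrovascular = 0.34,
                                               peripheral = 0.04),
                          n_biomarkers = 92,
                          n_modules = 17,
                          module_within_cor = 0.6,
                          class_module_shifts = NULL,
                          covariate_effects = c(age = 0.002, male = 0.03, sbp = 0.001),
                          class_sbp_means = c(135, 138, 144, 148),
                          sbp_sd = 15,
                          class_progression_means = c(0.14, 0.16, 0.19, 0.22),
                          progression_segment_sd = 0.12,
                          segment_sd = 0.25,
                          n_segments = 4,
                          n_centers = 7,
                          missing_rate = 0,
                          seed = 1) {
  k <- length(class_proportions)
  if (k != 4L) abort_endo("Exactly four latent classes are supported.")
  if (!all(is.finite(class_proportions)) || any(class_proportions < 0)) {
    abort_endo("`class_proportions` must be finite and non-negative.")
  }
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    abort_endo("`class_proportions` must sum to 1 (tolerance 1e-12).")
  }
  stopifnot(length(class_cimt_means) == k, length(class_cimt_sds) == k,
            length(class_plaque_rates) == k, length(class_log_hazards) == k,
            length(class_sbp_means) == k, length(class_progression_means) == k)
  if (!all(is.finite(class_cimt_means)) || !all(is.finite(class_log_hazards))) {
    abort_endo("Class parameters must be finite.")
  }
  if (any(class_cimt_sds <= 0)) abort_endo("`class_cimt_sds` must be > 0.")
  if (any(class_plaque_rates < 0)) abort_endo("`class_plaque_rates` must be >= 0.")
  check_scalar_number(admin_censor_time, "admin_censor_time")
  if (admin_censor_time <= 0) abort_endo("`admin_censor_time` must be > 0.")
  check_scalar_number(module_within_cor, "module_within_cor", 0, 1 - 1e-9)
  check_scalar_number(missing_rate, "missing_rate", 0, 1)
  check_scalar_number(n_subjects, "n_subjects", 0)
  if (any(module_sizes(n_biomarkers, n_modules) < 3)) {
    abort_endo("Planted module sizes must be >= 3.")
  }
  if (is.null(class_module_shifts)) {
    class_module_shifts <- default_class_module_shifts(n_modules)
  }
  class_module_shifts <- as.matrix(class_module_shifts)
  if (!all(dim(class_module_shifts) == c(k, n_modules)) ||
      !all(is.finite(class_module_shifts))) {
    abort_endo("`class_module_shifts` must be a finite 4 x n_modules matrix.")
  }
  event_type_split <- event_type_split / sum(event_type_split)

  if (is.null(baseline_hazard)) {
    check_scalar_number(target_event_rate, "target_event_rate", 0, 1)
    hr <- exp(class_log_hazards)
    if (target_event_rate == 0) {
      baseline_hazard <- 0
    } else {
      f <- function(l0) {
        sum(class_proportions * (1 - exp(-l0 * hr * admin_censor_time))) -
          target_event_rate
      }
      baseline_hazard <- stats::uniroot(f, c(1e-10, 10), tol = 1e-12)$root
    }
  }
  check_scalar_number(baseline_hazard, "baseline_hazard", 0)
  if (any(exp(class_log_hazards) < 0)) abort_endo("Hazards must be >= 0.")

  structure(list(
    n_subjects = as.integer(n_subjects),
    class_proportions = class_proportions,
    class_cimt_means = class_cimt_means,
    class_cimt_sds = class_cimt_sds,
    class_plaque_rates = class_plaque_rates,
    class_log_hazards = class_log_hazards,
    baseline_hazard = baseline_hazard,
    admin_censor_time = admin_censor_time,
    event_type_split = event_type_split,
    n_biomarkers = as.integer(n_biomarkers),
    n_modules = as.integer(n_modules),
    module_within_cor = module_within_cor,
    class_module_shifts = class_module_shifts,
    covariate_effects = covariate_effects,
    class_sbp_means = class_sbp_means,
    sbp_sd = sbp_sd,
    class_progression_means = class_progression_means,
    progression_segment_sd = progression_segment_sd,
    segment_sd = segment_sd,
    n_segments = as.integer(n_segments),
    n_centers = as.integer(n_centers),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  subjects: %d in %d classes (proportions %s)\n", x$n_subjects,
              length(x$class_proportions),
              paste(signif(x$class_proportions, 3), collapse = "/")))
  cat(sprintf("  biomarkers: %d in %d modules (within-module cor %.2f)\n",
              x$n_biomarkers, x$n_modules, x$module_within_cor))
  cat(sprintf("  baseline hazard: %.4f /py, admin censoring at %.1f y\n",
              x$baseline_hazard, x$admin_censor_time))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Exact class allocation by largest remainder
#'
#' Class counts are a deterministic function of `n` and the proportions:
#' every class receives `floor(n * p)` subjects and remaining seats go to the
#' classes with the largest fractional remainders (ties to the lower index).
#'
#' @param n Number of subjects.
#' @param proportions Class proportions summing to 1.
#' @return Integer vector of length `n` with class labels in blocks.
#' @export
allocate_classes <- function(n, proportions) {
  n <- as.integer(n)
  if (n < 0) abort_endo("`n` must be >= 0.")
  quota <- n * proportions
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    ord <- order(-rem, seq_along(rem))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  rep(seq_along(proportions), times = counts)
}

#' Generate a synthetic cohort
#'
#' Draws one cohort table from a [cohort_config()]: exact largest-remainder
#' class allocation; biomarkers from a block factor model
#' `x = shift[class, module] + sqrt(rho) * f_module + sqrt(1 - rho) * eps`
#' (marginal SD 1, within-module correlation `rho`); per-segment baseline
#' c-IMT maxima drawn so the derived c-IMT_mean-max matches the per-class
#' mean/SD targets after accounting for covariate effects and segment noise;
#' age ~ Uniform(55, 79), sex Bernoulli (52% female), class-shifted systolic
#' blood pressure; Poisson plaque counts; and censored ASCVD survival via
#' [generate_survival()].
#'
#' @param config A [cohort_config()].
#' @return A `cohort_tbl` tibble (one row per subject) with a `roles`
#'   attribute tagging every column (id, truth, center, demographic,
#'   clinical, biomarker, ultrasound_baseline, ultrasound_progression,
#'   outcome) and a `module_truth` attribute with the planted
#'   biomarker-to-module map. `true_class` is generator truth and is never
#'   consumed by analysis stages.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  k <- length(config$class_proportions)
  if (n > 0 && n < k) abort_endo("`n_subjects` must be 0 or >= the number of classes.")
  schema <- biomarker_schema(config$n_biomarkers, config$n_modules)
  classes <- allocate_classes(n, config$class_proportions)
  # Row order carries no information: subjects are shuffled (seeded) so that
  # contiguous subsets are random samples. Class counts stay exact.
  classes <- with_seed(sub_seed(config$seed, "misc"),
                       classes[sample.int(length(classes))])

  out <- with_seed(sub_seed(config$seed, "cohort"), {
    age <- stats::runif(n, 55, 79)
    male <- stats::rbinom(n, 1, 0.48)
    sbp <- config$class_sbp_means[classes] + stats::rnorm(n, 0, config$sbp_sd)
    bmi <- stats::rnorm(n, 27, 4)
    ldl_c <- stats::rnorm(n, 3.6, 0.9)
    smoking <- stats::rbinom(n, 1, 0.30)
    diabetes <- stats::rbinom(n, 1, 0.12)
    antihypertensive <- stats::rbinom(n, 1, 0.35)
    antiplatelet <- stats::rbinom(n, 1, 0.15)
    lipid_lowering <- stats::rbinom(n, 1, 0.25)
    center <- factor(sample.int(config$n_centers, n, replace = TRUE),
                     levels = seq_len(config$n_centers))
    batch <- factor(sample.int(4L, n, replace = TRUE), levels = 1:4)

    # Biomarker block factor model.
    rho <- config$module_within_cor
    bm <- matrix(0, nrow = n, ncol = config$n_biomarkers)
    for (m in seq_len(config$n_modules)) {
      idx <- which(schema$module == m)
      f <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(n * length(idx)), nrow = n)
      shift <- config$class_module_shifts[classes, m]
      bm[, idx] <- shift + sqrt(rho) * f + sqrt(1 - rho) * eps
    }
    colnames(bm) <- schema$biomarker

    # Subject-level c-IMT mean with centred covariate effects, then
    # per-segment maxima whose average (c-IMT_mean-max) hits the class
    # mean/SD targets.
    ce <- config$covariate_effects
    cov_part <- ce[["age"]] * (age - 67) + ce[["male"]] * (male - 0.48) +
      ce[["sbp"]] * (sbp - config$class_sbp_means[classes])
    var_cov <- stats::var(cov_part)
    seg_var <- config$segment_sd^2 / config$n_segments
    subj_sd <- sqrt(pmax(config$class_cimt_sds^2 - var_cov - seg_var, 1e-6))
    t_i <- config$class_cimt_means[classes] + cov_part +
      stats::rnorm(n, 0, subj_sd[classes])
    seg_max <- matrix(stats::rnorm(n * config$n_segments, mean = t_i,
                                   sd = config$segment_sd),
                      nrow = n, ncol = config$n_segments)
    seg_max <- pmax(seg_max, 0.25)
    colnames(seg_max) <- sprintf("cimt_max_seg%d", seq_len(config$n_segments))
    seg_mean <- 0.71 * seg_max + stats::rnorm(n * config$n_segments, 0, 0.05)
    seg_mean <- pmax(pmin(seg_mean, seg_max), 0.15)
    colnames(seg_mean) <- sprintf("cimt_mean_seg%d", seq_len(config$n_segments))

    # Per-segment annual progression; the class target is the mean of the
    # fastest (max) of n_segments iid normal segments.
    e_max <- c(0, 0.5642, 0.8463, 1.0294, 1.1630)[min(config$n_segments, 5)]
    prog_mu <- config$class_progression_means - e_max * config$progression_segment_sd
    prog <- matrix(stats::rnorm(n * config$n_segments,
                                mean = prog_mu[classes],
                                sd = config$progression_segment_sd),
                   nrow = n, ncol = config$n_segments)
    # Segments can regress, but the reporting transform log10(x + 0.1) of the
    # fastest segment requires changes > -0.1 mm/year.
    prog <- pmax(prog, -0.095)
    colnames(prog) <- sprintf("cimt_progr_seg%d", seq_len(config$n_segments))

    n_plaques <- stats::rpois(n, config$class_plaque_rates[classes])

    tab <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(max(n, 0))),
      true_class = as.integer(classes),
      center = center, batch = batch,
      age = age, sex = factor(ifelse(male == 1, "male", "female"),
                              levels = c("female", "male")),
      sbp = sbp, bmi = bmi, ldl_c = ldl_c,
      smoking = smoking, diabetes = diabetes,
      antihypertensive = antihypertensive, antiplatelet = antiplatelet,
      lipid_lowering = lipid_lowering
    )
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(bm),
                            tibble::as_tibble(seg_max),
                            tibble::as_tibble(seg_mean),
                            tibble::as_tibble(prog))
    tab$n_plaques <- n_plaques

    if (config$missing_rate > 0 && n > 0) {
      miss_subj <- which(stats::runif(n) < config$missing_rate)
      maskable <- c("bmi", "ldl_c", schema$biomarker)
      for (i in miss_subj) {
        cols <- sample(maskable, sample.int(3L, 1))
        tab[i, cols] <- NA_real_
      }
    }
    tab
  })

  surv <- generate_survival(classes, config)
  out <- dplyr::bind_cols(out, surv)

  roles <- c(
    subject_id = "id", true_class = "truth", center = "center",
    batch = "center", age = "demographic", sex = "demographic",
    sbp = "clinical", bmi = "clinical", ldl_c = "clinical",
    smoking = "clinical", diabetes = "clinical",
    antihypertensive = "clinical", antiplatelet = "clinical",
    lipid_lowering = "clinical",
    stats::setNames(rep("biomarker", nrow(schema)), schema$biomarker),
    stats::setNames(rep("ultrasound_baseline", 2 * config$n_segments + 1),
                    c(sprintf("cimt_max_seg%d", seq_len(config$n_segments)),
                      sprintf("cimt_mean_seg%d", seq_len(config$n_segments)),
                      "n_plaques")),
    stats::setNames(rep("ultrasound_progression", config$n_segments),
                    sprintf("cimt_progr_seg%d", seq_len(config$n_segments))),
    time = "outcome", event = "outcome", event_type = "outcome"
  )
  # bind_cols ordering: n_plaques was appended after progression segments.
  roles <- roles[names(out)]
  attr(out, "roles") <- roles
  attr(out, "module_truth") <- schema
  attr(out, "config") <- config
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' Column roles of a cohort table
#'
#' @param cohort A cohort table from [generate_cohort()] (or any data frame
#'   carrying a `roles` attribute).
#' @return A tibble with columns `variable` and `role`.
#' @export
cohort_roles <- function(cohort) {
  roles <- attr(cohort, "roles")
  if (is.null(roles)) abort_endo("No `roles` attribute on this table.")
  tibble::tibble(variable = names(roles), role = unname(roles))
}

#' Variables carrying given roles
#'
#' @param cohort A cohort table with a `roles` attribute.
#' @param roles Character vector of roles, e.g.
#'   `c("demographic", "clinical", "biomarker")`.
#' @return Character vector of column names.
#' @export
vars_with_role <- function(cohort, roles) {
  r <- cohort_roles(cohort)
  r$variable[r$role %in% roles]
}

# Default analysis feature set: everything the endotyping model may see.
feature_vars <- function(cohort) {
  vars_with_role(cohort, c("demographic", "clinical", "biomarker"))
}

#' Generate censored ASCVD survival records
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(class_log_hazard)`, administratively censored at
#' `admin_censor_time`. Event types are multinomial among cardiac,
#' cerebrovascular and peripheral with the configured split.
#'
#' @param classes Integer class labels in 1..4.
#' @param config A [cohort_config()].
#' @return Tibble with columns `time` (years), `event` (0/1) and
#'   `event_type` (`none` for censored records).
#' @export
generate_survival <- function(classes, config) {
  stopifnot(inherits(config, "cohort_config"))
  k <- length(config$class_log_hazards)
  if (length(classes) > 0 &&
      (!all(is.finite(classes)) || any(classes < 1 | classes > k))) {
    abort_endo(sprintf("`classes` must be integers in 1..%d.", k))
  }
  n <- length(classes)
  with_seed(sub_seed(config$seed, "survival"), {
    haz <- config$baseline_hazard * exp(config$class_log_hazards[classes])
    t_event <- ifelse(haz > 0, stats::rexp(n, rate = pmax(haz, 1e-300)), Inf)
    event <- as.integer(t_event <= config$admin_censor_time)
    time <- pmin(t_event, config$admin_censor_time)
    types <- names(config$event_type_split)
    event_type <- rep("none", n)
    if (any(event == 1)) {
      event_type[event == 1] <- sample(types, sum(event), replace = TRUE,
                                       prob = config$event_type_split)
    }
    tibble::tibble(
      time = pmax(time, 1e-8),
      event = event,
      event_type = factor(event_type, levels = c(types, "none"))
    )
  })
}

#' Uniform null outcome
#'
#' I.i.d. Uniform(0, 1) draws, independent of every cohort column; used as
#' the random-outcome null control for the representation learner.
#'
#' @param n Number of values.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_null_outcome <- function(n, seed) {
  n <- as.integer(n)
  if (n < 0) abort_endo("`n` must be >= 0.")
  with_seed(sub_seed(seed, "null"), stats::runif(n))
}

#' Write a cohort to delimited text with a role sidecar
#'
#' The table is written as UTF-8 comma-separated text with a header row; the
#' column roles, the truth-column name and the generator seed go to a JSON
#' sidecar next to it; the configuration is written as YAML.
#'
#' @param cohort A `cohort_tbl`.
#' @param path CSV path; the sidecar is `<path>.roles.json` and the config
#'   `<path>.config.yaml`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  roles <- attr(cohort, "roles")
  cfg <- attr(cohort, "config")
  sidecar <- list(roles = as.list(roles), truth_column = "true_class",
                  seed = if (!is.null(cfg)) cfg$seed else NA)
  jsonlite::write_json(sidecar, paste0(path, ".roles.json"), auto_unbox = TRUE)
  if (!is.null(cfg)) {
    yaml::write_yaml(lapply(unclass(cfg), function(x) {
      if (is.matrix(x)) as.data.frame(x) else x
    }), paste0(path, ".config.yaml"))
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path.
#' @return A `cohort_tbl` with restored roles.
#' @export
read_cohort <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  sidecar_path <- paste0(path, ".roles.json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path)
    roles <- unlist(sidecar$roles)
    attr(tab, "roles") <- roles[names(tab)]
  }
  if ("sex" %in% names(tab)) tab$sex <- factor(tab$sex, levels = c("female", "male"))
  if ("center" %in% names(tab)) tab$center <- factor(tab$center)
  if ("batch" %in% names(tab)) tab$batch <- factor(tab$batch)
  if ("event_type" %in% names(tab)) tab$event_type <- factor(tab$event_type)
  class(tab) <- c("cohort_tbl", class(tab))
  tab
}
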