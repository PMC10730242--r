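test_that("class allocation is exact, deterministic and seed-independent", {
  props <- c(1277, 783, 502, 559) / 3121
  cl <- allocate_classes(3121, props)
  expect_equal(as.integer(table(cl)), c(1277L, 783L, 502L, 559L))
  # independent of any RNG state
  set.seed(99); cl2 <- allocate_classes(3121, props)
  expect_identical(cl, cl2)
  # largest-remainder on an awkward n
  cl3 <- allocate_classes(10, c(0.24, 0.24, 0.24, 0.28))
  expect_equal(sum(table(cl3)), 10)
  expect_equal(length(cl3), 10)
  expect_identical(allocate_classes(0, props), integer(0))
})

test_that("generated cohort matches its configured class structure", {
  coh <- add_ultrasound_summaries(generate_cohort(cohort_config(seed = 1)))
  expect_equal(nrow(coh), 3121)
  expect_equal(as.integer(table(coh$true_class)), c(1277L, 783L, 502L, 559L))
  m1 <- mean(coh$cimt_mean_max[coh$true_class == 1])
  expect_lt(abs(m1 - 1.10), 0.02)
  # per-class means within 3 standard errors of targets
  cfg <- attr(coh, "config")
  for (k in 1:4) {
    x <- coh$cimt_mean_max[coh$true_class == k]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - cfg$class_cimt_means[k]), 3 * se)
    np <- coh$n_plaques[coh$true_class == k]
    expect_lt(abs(mean(np) - cfg$class_plaque_rates[k]),
              3 * sd(np) / sqrt(length(np)))
  }
  # biomarker module shifts recovered
  truth <- attr(coh, "module_truth")
  m06 <- truth$biomarker[truth$module == 6]
  z4 <- colMeans(coh[coh$true_class == 4, m06])
  expect_true(all(abs(z4 - 0.80) < 0.2))
})

test_that("empty cohort keeps the full column schema", {
  coh0 <- generate_cohort(cohort_config(n_subjects = 0, seed = 1))
  coh <- generate_cohort(cohort_config(n_subjects = 10, seed = 1))
  expect_equal(nrow(coh0), 0)
  expect_identical(names(coh0), names(coh))
  expect_identical(cohort_roles(coh0), cohort_roles(coh))
})

test_that("roles tag every column exactly once and identify feature sets", {
  coh <- generate_cohort(cohort_config(n_subjects = 50, seed = 2))
  roles <- cohort_roles(coh)
  expect_identical(sort(roles$variable), sort(names(coh)))
  expect_equal(anyDuplicated(roles$variable), 0)
  expect_length(vars_with_role(coh, "biomarker"), 92)
  expect_setequal(vars_with_role(coh, "outcome"), c("time", "event", "event_type"))
})

test_that("survival generation respects hazards and censoring", {
  cfg <- cohort_config(seed = 5)
  cl <- allocate_classes(cfg$n_subjects, cfg$class_proportions)
  sv <- generate_survival(cl, cfg)
  expect_lt(abs(mean(sv$event) - 0.053), 0.01)
  expect_true(all(sv$time <= cfg$admin_censor_time + 1e-12))
  expect_true(all(sv$event_type[sv$event == 0] == "none"))
  expect_true(all(sv$event_type[sv$event == 1] != "none"))

  cfg0 <- cohort_config(n_subjects = 200, baseline_hazard = 0, seed = 5)
  sv0 <- generate_survival(rep(1:4, 50), cfg0)
  expect_true(all(sv0$event == 0))
  expect_true(all(sv0$time == cfg0$admin_censor_time))

  expect_error(generate_survival(c(0, 5), cfg), "1\\.\\.4")
})

test_that("classes with identical log-hazards are exchangeable (log-rank null)", {
  pvals <- vapply(1:60, function(s) {
    cfg <- cohort_config(n_subjects = 400, seed = s,
                         class_log_hazards = c(0, 0, log(2), log(2)),
                         class_proportions = rep(0.25, 4))
    cl <- allocate_classes(400, cfg$class_proportions)
    sv <- generate_survival(cl, cfg)
    keep <- cl %in% c(1, 2)
    sd <- survival::survdiff(
      survival::Surv(sv$time[keep], sv$event[keep]) ~ cl[keep])
    1 - pchisq(sd$chisq, 1)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("null outcome is reproducible, uniform and independent", {
  expect_identical(generate_null_outcome(5, 7), generate_null_outcome(5, 7))
  x <- generate_null_outcome(1e4, 3)
  expect_lt(abs(mean(x) - 0.5), 0.02)
  expect_length(generate_null_outcome(0, 1), 0)
  coh <- generate_cohort(cohort_config(n_subjects = 300, seed = 3))
  y0 <- generate_null_outcome(300, 3)
  expect_lt(abs(cor(y0, coh$sbp)), 0.15)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(class_proportions = c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
  expect_error(cohort_config(class_cimt_sds = c(0, 0.2, 0.3, 0.3)), "> 0")
  expect_error(cohort_config(n_biomarkers = 10, n_modules = 5), ">= 3")
  expect_error(cohort_config(admin_censor_time = 0), "> 0")
  expect_error(cohort_config(class_cimt_means = c(1, NA, 1, 1)), "finite")
  expect_error(generate_cohort(cohort_config(n_subjects = 2)), "classes")
})

test_that("cohort round-trips through delimited text with roles", {
  coh <- generate_cohort(cohort_config(n_subjects = 40, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 40)
  expect_identical(cohort_roles(back), cohort_roles(coh))
  expect_equal(back$cimt_max_seg1, coh$cimt_max_seg1, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".config.yaml")))
  unlink(c(path, paste0(path, ".roles.json"), paste0(path, ".config.yaml")))
})

test_that("missingness lands only in maskable columns at the configured rate", {
  coh <- generate_cohort(cohort_config(n_subjects = 400, seed = 4,
                                       missing_rate = 0.2))
  n_miss <- sum(rowSums(is.na(coh)) > 0)
  expect_gt(n_miss, 40)
  expect_lt(n_miss, 140)
  expect_false(anyNA(coh$cimt_max_seg1))
  expect_false(anyNA(coh$time))
})
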