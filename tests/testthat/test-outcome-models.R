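test_that("linear models use endotype 1 as reference with K-1 dummies", {
  # noiseless two-group contrast: beta = 2, SE = 0
  tab <- tibble::tibble(y = rep(c(0, 2), each = 10))
  res <- suppressWarnings(fit_linear_models(tab, "y", rep(1:2, each = 10),
                                            covariates = character(0)))
  e2 <- res[res$term == "endotype2", ]
  expect_equal(e2$estimate, 2, tolerance = 1e-12)
  expect_lt(e2$se, 1e-12)

  coh <- small_cohort(n = 800, seed = 61)
  res4 <- fit_linear_models(coh, "cimt_mean_max", coh$true_class, "model1")
  endo_terms <- grep("^endotype", res4$term, value = TRUE)
  expect_setequal(endo_terms, c("endotype2", "endotype3", "endotype4"))

  # generator truth: class 4 vs 1 contrast = 1.50 - 1.10 = 0.40
  e4 <- res4[res4$term == "endotype4", ]
  expect_lt(abs(e4$estimate - 0.40), 3 * e4$se)

  # rank deficiency is reported with the aliased terms
  tab2 <- tibble::tibble(y = rnorm(20), a = rnorm(20))
  tab2$b <- tab2$a
  expect_error(fit_linear_models(tab2, "y", rep(1:2, 10),
                                 covariates = c("a", "b")),
               class = "endotyper_rank_deficient")
})

test_that("Cox estimates match a brute-force Efron partial likelihood", {
  # identical event/censoring patterns in both groups -> HR = 1
  time <- rep(c(1, 2, 3, 4, 5), 2)
  event <- rep(c(1, 0, 1, 1, 0), 2)
  grp <- rep(1:2, each = 5)
  res <- fit_cox(tibble::tibble(time = time, event = event), grp,
                 covariates = character(0))
  expect_lt(abs(res$hr[1] - 1), 1e-8)

  # 6-subject toy with tied event times: grid/optimize oracle to 1e-6
  t6 <- c(2, 2, 3, 4, 5, 6)
  e6 <- c(1, 1, 0, 1, 1, 0)
  x6 <- c(1, 0, 1, 1, 0, 0)
  res6 <- fit_cox(tibble::tibble(time = t6, event = e6), x6 + 1,
                  covariates = character(0))
  beta_hat <- res6$estimate[1]
  beta_star <- optimize(function(b) -efron_loglik(b, t6, e6, x6),
                        c(-5, 5), tol = 1e-10)$minimum
  expect_lt(abs(beta_hat - beta_star), 1e-6)

  expect_error(fit_cox(tibble::tibble(time = c(1, 2), event = c(0, 0)),
                       c(1, 2)), "at least one event")
  expect_error(fit_cox(tibble::tibble(time = c(-1, 2), event = c(1, 0)),
                       c(1, 2)), "positive")
})

test_that("planted hazard ratios are recovered on the default cohort", {
  cfg <- cohort_config(seed = 71)
  cl <- allocate_classes(cfg$n_subjects, cfg$class_proportions)
  sv <- generate_survival(cl, cfg)
  res <- fit_cox(sv, cl, covariates = character(0))
  e4 <- res[res$term == "endotype4", ]
  expect_lt(abs(log(e4$hr) - log(2.85)), 3 * e4$se)
  expect_equal(e4$ci_lo, exp(e4$estimate - 1.96 * e4$se), tolerance = 1e-12)
  expect_equal(e4$ci_hi, exp(e4$estimate + 1.96 * e4$se), tolerance = 1e-12)
})

test_that("Schoenfeld test is calibrated under PH and detects violations", {
  sim_ph <- function(seed, flip = FALSE, n = 150) {
    set.seed(seed)
    x <- rbinom(n, 1, 0.5)
    beta <- 1.2
    if (!flip) {
      t_ev <- rexp(n, rate = 0.2 * exp(beta * x))
    } else {
      # effect reverses at t0: piecewise exponential
      t0 <- 2
      t1 <- rexp(n, rate = 0.2 * exp(beta * x))
      t2 <- t0 + rexp(n, rate = 0.2 * exp(-beta * x))
      t_ev <- ifelse(t1 < t0, t1, t2)
    }
    time <- pmin(t_ev, 8)
    event <- as.integer(t_ev <= 8)
    fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron",
                           model = TRUE)
    check_proportionality(fit)$p_value[1]
  }
  p_null <- vapply(1:150, sim_ph, numeric(1))
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  p_tv <- vapply(1:40, sim_ph, numeric(1), flip = TRUE)
  expect_gte(mean(p_tv < 0.05), 0.8)

  expect_error(
    fit_cox(tibble::tibble(time = 1:10, event = rep(1, 10),
                           const = rep(1, 10)),
            rep(1:2, 5), covariates = "const"),
    class = "endotyper_rank_deficient")
})

test_that("VIF equals 1/(1 - R^2) with collinearity flagged", {
  # covariates orthogonal to each other and the intercept -> VIF 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200), 50, 4))))[, 2:5]
  colnames(Q) <- paste0("q", 1:4)
  v <- compute_vif(Q)
  expect_equal(v$vif, rep(1, 4), tolerance = 1e-10)

  # planted R^2 = 0.75 -> VIF = 4
  Z <- qr.Q(qr(cbind(1, matrix(rnorm(80), 40, 2))))[, 2:3]
  x1 <- Z[, 1]
  x2 <- sqrt(0.75) * Z[, 1] + sqrt(0.25) * Z[, 2]
  v2 <- compute_vif(cbind(a = x1, b = x2))
  expect_equal(v2$vif, c(4, 4), tolerance = 1e-8)

  v3 <- compute_vif(cbind(a = x1, b = x1))
  expect_true(all(v3$collinear))
  expect_error(compute_vif(cbind(a = x1)), ">= 2")
  expect_error(compute_vif(cbind(a = x1, b = rep(2, 40))),
               class = "endotyper_zero_variance")
})

test_that("Kaplan-Meier steps match the product-limit estimator", {
  km <- km_estimate(1:4, rep(1, 4), rep(1, 4))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  km2 <- km_estimate(c(2, 4, 6), c(0, 0, 0), rep(1, 3))
  expect_true(all(km2$survival == 1))

  # events at 1 and 3, censoring at 2: S(3) = 0.75 * (1 - 1/2) = 0.375
  km3 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0), rep(1, 4))
  expect_equal(km3$survival[km3$time == 3], 0.375)

  km4 <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1), rep(1:2, each = 2))
  expect_setequal(unique(km4$group), c("1", "2"))
  expect_error(km_estimate(c(0, 1), c(1, 1), c(1, 2)), "positive")
})

test_that("covariate sets follow the three nested adjustment models", {
  m1 <- model_covariates("model1")
  m2 <- model_covariates("model2", baseline_measure = "cimt_mean_max")
  m3 <- model_covariates("model3", baseline_measure = "cimt_mean_max")
  expect_setequal(m1, c("batch", "center"))
  expect_true(all(m1 %in% m2) && all(m2 %in% m3))
  expect_true("cimt_mean_max" %in% m2)
  expect_setequal(setdiff(m3, m2),
                  c("antihypertensive", "antiplatelet", "lipid_lowering"))
  # age/sex/SBP excluded by default, included on override
  expect_false(any(c("age", "sex", "sbp") %in% m3))
  expect_true(all(c("age", "sex", "sbp") %in%
                    model_covariates("model1", adjust_age_sex_sbp = TRUE)))
})
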