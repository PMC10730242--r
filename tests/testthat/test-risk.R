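test_that("the linear predictor is the declared dot product", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(
    "terms:
  - variable: a
    center: 1
    scale: 2
    coefficient: 0.5
  - variable: b
    coefficient: -0.25
  - variable: c
    log: true
    coefficient: 1.0
calibration:
  baseline_survival: 0.95
  scale1: -0.1
  scale2: 1.0
  horizon: 3
", cfg_path)
  cfg <- read_risk_config(cfg_path)
  tab <- tibble::tibble(a = 3, b = 2, c = exp(1.5))
  rs <- score2_linear_predictor(tab, cfg)
  expect_equal(rs$lp, 0.5 * (3 - 1) / 2 - 0.25 * 2 + 1.0 * 1.5,
               tolerance = 1e-12)

  # all transformed covariates zero -> LP 0, risk = calibrated baseline
  tab0 <- tibble::tibble(a = 1, b = 0, c = 1)
  rs0 <- score2_linear_predictor(tab0, cfg)
  expect_equal(rs0$lp, 0, tolerance = 1e-12)
  u0 <- 1 - 0.95
  expect_equal(rs0$risk, 1 - exp(-exp(-0.1 + log(-log(1 - u0)))),
               tolerance = 1e-12)

  # monotone in a positively weighted covariate
  tabm <- tibble::tibble(a = c(1, 2, 5), b = 0, c = 1)
  rsm <- score2_linear_predictor(tabm, cfg)
  expect_true(all(diff(rsm$risk) > 0))

  expect_error(score2_linear_predictor(tibble::tibble(a = 1, b = 1), cfg),
               "Missing risk factor")
  unlink(cfg_path)
})

test_that("risk categories respect the declared thresholds", {
  expect_identical(as.character(categorize_risk(c(0.049, 0.05, 0.10))),
                   c("low", "moderate", "high"))
  expect_identical(as.character(
    categorize_risk(c(0.074, 0.075, 0.149, 0.15), "score2_op")),
    c("low", "moderate", "moderate", "high"))
  expect_error(categorize_risk(-0.01), "Negative")
  expect_true(is.ordered(categorize_risk(0.02)))
})

test_that("Harrell's C matches brute-force pair enumeration", {
  # perfect ranking, no censoring
  time <- c(1, 2, 3, 4, 5)
  expect_equal(harrell_c(time, rep(1, 5), rev(time)), 1.0)

  # censored toy against the enumeration oracle
  t5 <- c(2, 3, 3.5, 5, 7)
  e5 <- c(1, 0, 1, 1, 0)
  r5 <- c(0.9, 0.1, 0.5, 0.5, 0.2)
  expect_equal(harrell_c(t5, e5, r5), harrell_oracle(t5, e5, r5),
               tolerance = 1e-12)

  # uninformative risk: C = 0.5 within Monte-Carlo tolerance
  set.seed(14)
  n <- 2000
  tt <- rexp(n); ee <- rbinom(n, 1, 0.7); rr <- rnorm(n)
  expect_lt(abs(harrell_c(tt, ee, rr) - 0.5), 0.03)

  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)), "comparable")
})

test_that("censoring-adjusted NRI reduces to counting without censoring", {
  # identical categories -> all components zero
  time <- c(rep(1, 10), rep(5, 20))
  event <- c(rep(1, 10), rep(0, 20))
  cats <- categorize_risk(rep(c(0.02, 0.08, 0.2), 10))
  nr0 <- compute_nri(time, event, cats, cats, 3)
  expect_equal(nr0$nri_total, 0)

  # uncensored toy: 10 events (4 up, 1 down), 90 non-events (2 up, 7 down)
  old_cat <- c(rep("low", 4), "moderate", rep("low", 5),      # events
               rep("low", 2), rep("moderate", 7), rep("low", 81))
  new_cat <- c(rep("moderate", 4), "low", rep("low", 5),
               rep("moderate", 2), rep("low", 7), rep("low", 81))
  time2 <- c(rep(1, 10), rep(5, 90))
  event2 <- c(rep(1, 10), rep(0, 90))
  fo <- factor(old_cat, c("low", "moderate", "high"), ordered = TRUE)
  fn <- factor(new_cat, c("low", "moderate", "high"), ordered = TRUE)
  nr <- compute_nri(time2, event2, fo, fn, 3)
  expect_equal(nr$nri_event, 3 / 10, tolerance = 1e-12)
  expect_equal(nr$nri_nonevent, 5 / 90, tolerance = 1e-12)
  expect_equal(nr$nri_total, 3 / 10 + 5 / 90, tolerance = 1e-12)

  expect_error(compute_nri(time2, event2, fo, fn, 99), "horizon")
  expect_error(compute_nri(rep(5, 10), rep(0, 10),
                           fo[1:10], fn[1:10], 3), "Zero estimated events")
})

test_that("censored NRI equals an independent KM-within-cell oracle", {
  set.seed(15)
  n <- 400
  time <- rexp(n, 0.15)
  cens <- runif(n, 0.5, 6)
  event <- as.integer(time <= cens)
  obs <- pmin(time, cens)
  r_old <- runif(n, 0, 0.2)
  r_new <- pmin(pmax(r_old + rnorm(n, 0, 0.04), 0), 1)
  co <- categorize_risk(r_old); cn <- categorize_risk(r_new)
  nr <- compute_nri(obs, event, co, cn, 3)
  orc <- nri_oracle(obs, event, as.character(co), as.character(cn), 3)
  expect_equal(nr$nri_event, unname(orc["event"]), tolerance = 1e-10)
  expect_equal(nr$nri_nonevent, unname(orc["nonevent"]), tolerance = 1e-10)
  # decomposition is exact
  expect_equal(nr$nri_total, nr$nri_event + nr$nri_nonevent, tolerance = 1e-12)
})

test_that("percentile bootstrap is seeded, exact for constants, CLT-consistent", {
  dat <- data.frame(x = rnorm(100))
  cb <- bootstrap_ci(function(d) c(k = 7), dat, B = 50, seed = 1)
  expect_equal(unname(cb$ci["k", ]), c(7, 7))

  set.seed(16)
  dat2 <- data.frame(x = rnorm(1e4))
  bm <- bootstrap_ci(function(d) c(m = mean(d$x)), dat2, B = 300, seed = 2)
  expect_lt(bm$ci["m", 1], 0)
  expect_gt(bm$ci["m", 2], 0)
  width <- diff(unname(bm$ci["m", ]))
  expect_lt(abs(width - 2 * 1.96 / sqrt(1e4)) / (2 * 1.96 / sqrt(1e4)), 0.2)

  b1 <- bootstrap_ci(function(d) c(m = mean(d$x)), dat, B = 40, seed = 9)
  b2 <- bootstrap_ci(function(d) c(m = mean(d$x)), dat, B = 40, seed = 9)
  expect_identical(b1$ci, b2$ci)

  flaky <- function(d) if (runif(1) < 0.5) stop("no") else c(m = mean(d$x))
  expect_error(bootstrap_ci(flaky, dat, B = 40, seed = 3), "failed")
})

test_that("adding endotypes improves discrimination on the synthetic cohort", {
  coh <- small_cohort(n = 1500, seed = 81)
  rs <- score2_linear_predictor(coh)
  cmp <- risk_model_comparison(coh$time, coh$event, rs$lp, coh$true_class,
                               horizon = 3, B = 0)
  expect_gt(cmp$c_new, cmp$c_base)
  expect_equal(cmp$nri$nri_total, cmp$nri$nri_event + cmp$nri$nri_nonevent,
               tolerance = 1e-12)
})
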