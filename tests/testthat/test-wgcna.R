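test_that("topological overlap matches hand-computed values", {
  # three variables, all pairwise |cor| exactly 0.5, beta = 2
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  X <- exact_cor_data(60, S)
  ms <- compute_tom(X, 2)
  expect_equal(unname(ms$adjacency[1, 2]), 0.25, tolerance = 1e-12)
  expect_equal(unname(ms$tom[1, 2]), 0.25, tolerance = 1e-10)

  # perfectly correlated pair: a = 1, TOM = 1
  x1 <- rnorm(50)
  Xp <- cbind(a = x1, b = 2 * x1)
  msp <- compute_tom(Xp, 3)
  expect_equal(unname(msp$tom[1, 2]), 1, tolerance = 1e-12)

  # exactly uncorrelated pair: TOM = 0
  S0 <- diag(2)
  X0 <- exact_cor_data(40, S0)
  ms0 <- compute_tom(X0, 2)
  expect_equal(unname(ms0$tom[1, 2]), 0, tolerance = 1e-12)

  expect_error(compute_tom(cbind(a = rep(1, 20), b = rnorm(20)), 2),
               class = "endotyper_constant_biomarker")
})

test_that("TOM is symmetric with entries in [0, 1] on random panels", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(20:60, 1); p <- sample(4:12, 1)
    X <- matrix(rnorm(n * p), n, p) %*%
      matrix(rnorm(p * p, sd = 0.5), p, p)
    colnames(X) <- paste0("v", seq_len(p))
    tom <- compute_tom(X, sample(1:8, 1))$tom
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_true(all(diag(tom) == 1))
  }
})

test_that("scale-free fit agrees with an independent log-log regression", {
  coh <- small_cohort(n = 400, seed = 41)
  bm <- coh[, vars_with_role(coh, "biomarker")]
  sp <- pick_soft_power(bm, powers = 1:8)
  row <- sp$fit_table[sp$fit_table$power == 3, ]
  # independent re-fit of the binned log-log regression
  a <- abs(cor(as.matrix(bm)))^3; diag(a) <- 0
  k <- rowSums(a)
  brk <- unique(quantile(k, probs = seq(0, 1, length.out = 11)))
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  pk <- as.vector(table(bin)) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- pk > 0 & mk > 0
  ft <- lm(log10(pk[keep]) ~ log10(mk[keep]))
  expect_equal(row$r2, summary(ft)$r.squared, tolerance = 1e-10)
  # mean connectivity is non-increasing in the power
  expect_true(all(diff(sp$fit_table$mean_connectivity) <= 1e-12))
})

test_that("independent noise has no scale-free structure (fallback flagged)", {
  set.seed(3)
  X <- matrix(rnorm(1500 * 30), 1500, 30)
  colnames(X) <- paste0("v", 1:30)
  sp <- pick_soft_power(X)
  expect_true(sp$fallback)
  expect_true(all(sp$fit_table$r2 < 0.8 | sp$fit_table$slope >= 0))
})

test_that("module detection recovers planted blocks and guards small ones", {
  set.seed(21)
  n <- 300
  block <- function(p, rho = 0.9) {
    f <- rnorm(n)
    sqrt(rho) * matrix(f, n, p) + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  }
  X <- cbind(block(5), block(5), matrix(rnorm(n * 2), n, 2))
  colnames(X) <- c(paste0("b1_", 1:5), paste0("b2_", 1:5), "solo1", "solo2")
  ms <- detect_modules(compute_tom(X, 6))
  mp <- tidy(ms)
  m1 <- mp$module[startsWith(mp$biomarker, "b1_")]
  m2 <- mp$module[startsWith(mp$biomarker, "b2_")]
  expect_length(unique(m1), 1)
  expect_length(unique(m2), 1)
  expect_false(unique(m1) == unique(m2))
  expect_true(all(unique(c(m1, m2)) != 0))
  expect_true(all(mp$module[startsWith(mp$biomarker, "solo")] == 0))

  # all-independent panel: everything unassigned
  Xn <- matrix(rnorm(400 * 12), 400, 12)
  colnames(Xn) <- paste0("v", 1:12)
  msn <- detect_modules(compute_tom(Xn, 6))
  expect_true(all(tidy(msn)$module == 0))

  # a planted block of 2 (< min size) stays unassigned
  X2 <- cbind(block(2, rho = 0.95), matrix(rnorm(n * 6), n, 6))
  colnames(X2) <- c("t1", "t2", paste0("v", 1:6))
  ms2 <- detect_modules(compute_tom(X2, 6), min_module_size = 3)
  expect_true(all(tidy(ms2)$module[1:2] == 0))
})

test_that("per-endotype module summary reflects the planted shifts", {
  coh <- small_cohort(n = 1200, seed = 51)
  truth <- attr(coh, "module_truth")
  bm_cols <- truth$biomarker
  z <- z_standardize(coh, bm_cols)
  summ <- endotype_module_summary(z$data[, bm_cols], coh$true_class, truth)
  m06 <- truth$biomarker[truth$module == 6]
  s4 <- summ[summ$biomarker %in% m06 & summ$endotype == 4, ]
  others <- summ[summ$biomarker %in% m06 & summ$endotype != 4, ]
  expect_gt(mean(s4$mean_z), max(tapply(others$mean_z, others$endotype, mean)))

  # a single endotype reproduces the (zero) overall means
  s1 <- endotype_module_summary(z$data[, bm_cols], rep(1, nrow(coh)), truth)
  expect_lt(max(abs(s1$mean_z)), 1e-10)

  expect_error(endotype_module_summary(z$data[, bm_cols],
                                       factor(rep(1, nrow(coh)), levels = 1:2),
                                       truth),
               "Empty endotype")
})
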