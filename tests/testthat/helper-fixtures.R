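# Shared fixtures and independent oracles used across the suite. Everything
# is generated in code; nothing is read from disk.

# Small default-structure cohort (all generator structure, fewer subjects).
small_cohort <- function(n = 600, seed = 11, ...) {
  add_ultrasound_summaries(generate_cohort(
    cohort_config(n_subjects = n, seed = seed, ...)))
}

# Well-separated Gaussian blobs in d dimensions.
make_blobs <- function(k, n_per = 100, d = 8, sep = 5, sd = 0.1, seed = 42) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * d, sd = sep), k, d)
  X <- centers[rep(seq_len(k), each = n_per), ] +
    matrix(stats::rnorm(k * n_per * d, sd = sd), k * n_per, d)
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# Columns with EXACT sample correlation matrix `S`: orthonormalize centred
# Gaussian columns, then mix with chol(S).
exact_cor_data <- function(n, S, seed = 7) {
  set.seed(seed)
  p <- ncol(S)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))              # orthonormal, centred columns
  X <- sqrt(n - 1) * Q %*% chol(S)
  colnames(X) <- paste0("v", seq_len(p))
  X
}

# Brute-force Efron partial log-likelihood for a single covariate.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t0 & event == 1)
    r_idx <- which(time >= t0)
    d <- length(d_idx)
    eta <- beta * x
    sum_r <- sum(exp(eta[r_idx]))
    sum_d <- sum(exp(eta[d_idx]))
    ll <- ll + sum(eta[d_idx])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

# Independent censoring-adjusted NRI oracle: Kaplan-Meier via
# survival::survfit within every reclassification cell.
nri_oracle <- function(time, event, old_cat, new_cat, horizon) {
  oldc <- as.integer(factor(old_cat, levels = c("low", "moderate", "high")))
  newc <- as.integer(factor(new_cat, levels = c("low", "moderate", "high")))
  cell <- interaction(oldc, newc, drop = TRUE)
  p <- n <- mv <- numeric(0)
  for (cl in levels(cell)) {
    ii <- which(cell == cl)
    fit <- survival::survfit(survival::Surv(time[ii], event[ii]) ~ 1)
    s <- summary(fit, times = horizon, extend = TRUE)$surv
    p <- c(p, 1 - s)
    n <- c(n, length(ii))
    mv <- c(mv, sign(newc[ii[1]] - oldc[ii[1]]))
  }
  E <- sum(n * p); NE <- sum(n * (1 - p))
  up <- mv > 0; dn <- mv < 0
  nri_e <- (sum(n[up] * p[up]) - sum(n[dn] * p[dn])) / E
  nri_ne <- (sum(n[dn] * (1 - p[dn])) - sum(n[up] * (1 - p[up]))) / NE
  c(event = nri_e, nonevent = nri_ne, total = nri_e + nri_ne)
}

# Brute-force Harrell concordance by pair enumeration.
harrell_oracle <- function(time, event, risk) {
  conc <- comp <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] > time[i]) {
        comp <- comp + 1
        if (risk[i] > risk[j]) conc <- conc + 1
        else if (risk[i] == risk[j]) conc <- conc + 0.5
      }
    }
  }
  conc / comp
}

# Adjusted Rand index oracle (mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
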