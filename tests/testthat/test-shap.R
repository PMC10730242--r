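test_that("Shapley values of an additive model match the closed form", {
  f_lin <- function(X) cbind(2 * X[, 1] - X[, 2])
  subj <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  at <- shapley_attribution(f_lin, subj, bg, n_permutations = 4, seed = 1)
  expect_equal(unname(at$phi[1, , 1]), c(2, -1), tolerance = 1e-12)

  # nonzero background mean: phi_i = w_i (x_i - mean b_i)
  bg2 <- matrix(rep(c(0.4, -0.3), each = 5), 5, 2,
                dimnames = list(NULL, c("a", "b")))
  at2 <- shapley_attribution(f_lin, subj, bg2, n_permutations = 16, seed = 2)
  expect_equal(unname(at2$phi[1, , 1]),
               c(2 * (1 - 0.4), -1 * (1 + 0.3)), tolerance = 1e-9)
})

test_that("efficiency holds exactly and dummies get zero attribution", {
  f <- function(X) {
    p1 <- plogis(X[, 1] - 0.5 * X[, 2])
    cbind(p1, 1 - p1)
  }
  set.seed(5)
  subj <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("a", "b", "dummy")))
  bg <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "dummy")))
  at <- shapley_attribution(f, subj, bg, n_permutations = 24, seed = 3)
  for (i in 1:3) {
    for (k in 1:2) {
      expect_equal(unname(sum(at$phi[i, , k])),
                   unname(at$prediction[i, k] - at$baseline[k]),
                   tolerance = 1e-12)
    }
  }
  expect_lt(max(abs(at$phi[, "dummy", ])), 0.08)
})

test_that("functionally interchangeable variables share attribution", {
  f <- function(X) cbind(X[, 1] + X[, 2])
  subj <- matrix(c(1, 1, 3), 1, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  set.seed(6)
  bg <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg[, 2] <- bg[, 1]   # identical background marginals
  at <- shapley_attribution(f, subj, bg, n_permutations = 64, seed = 4)
  expect_lt(abs(at$phi[1, "a", 1] - at$phi[1, "b", 1]), 0.05)
})

test_that("variable ranking orders by mean |phi| with declared tie-breaks", {
  at <- structure(list(
    phi = array(0, c(1, 3, 1), dimnames = list("s1", c("v1", "v2", "v3"),
                                               "class1")),
    shap_endotype = matrix(c(0.5, 0.2, 0.9), 3, 1,
                           dimnames = list(c("v1", "v2", "v3"), "class1")),
    global_shap = c(v1 = 0.5, v2 = 0.2, v3 = 0.9)
  ), class = "shap_attribution")
  rk <- rank_variables(at)
  expect_identical(rk$global$variable, c("v3", "v1", "v2"))
  expect_false(rk$degenerate)

  at0 <- at
  at0$global_shap[] <- 0
  at0$shap_endotype[] <- 0
  rk0 <- rank_variables(at0)
  expect_true(rk0$degenerate)
  expect_identical(rk0$global$variable, c("v1", "v2", "v3"))
})

test_that("per-endotype ranking surfaces the dominant variable per class", {
  f <- function(X) {
    z1 <- 2 * X[, 1]; z2 <- 2 * X[, 2]
    den <- exp(z1) + exp(z2)
    cbind(exp(z1) / den, exp(z2) / den)
  }
  set.seed(8)
  subj <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  at <- shapley_attribution(f, subj, bg, n_permutations = 32, seed = 5)
  rk <- rank_variables(at, n_top = 2)
  top1 <- rk$per_endotype$variable[rk$per_endotype$endotype == "class1" &
                                     rk$per_endotype$rank == 1]
  # both classes are driven by the same two symmetric variables; the top
  # variable must carry strictly positive attribution mass
  expect_gt(at$shap_endotype[top1, "class1"], 0)
  expect_error(shapley_attribution(f, subj, bg[0, , drop = FALSE]),
               "non-empty")
})
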