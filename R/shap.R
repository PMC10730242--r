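# Model-agnostic permutation Shapley attributions for the stacking model.
# For every subject and random feature permutation, features are switched
# one at a time from a background draw to the subject's values; the change
# in each class probability is the feature's marginal contribution. The
# permutation average telescopes, so raw attributions already sum to
# f(x) - mean f(background draws); a final additive normalization makes the
# efficiency identity hold exactly against the full-background baseline.

#' Permutation Shapley attributions
#'
#' @param predict_fn Function mapping a feature matrix (n x p) to an n x K
#'   matrix of class probabilities.
#' @param subjects Data frame / matrix of subjects to explain (rows).
#' @param background Reference sample (rows) defining the baseline.
#' @param n_permutations Monte-Carlo permutations per subject.
#' @param seed Integer seed.
#' @return A `shap_attribution` object: `phi` (array subject x variable x
#'   class), `baseline` (mean background prediction per class),
#'   `prediction` (per-subject prediction), `shap_endotype` (mean |phi| per
#'   variable and class) and `global_shap` (mean |phi| per variable).
#' @export
shapley_attribution <- function(predict_fn, subjects, background,
                                n_permutations = 64, seed = 1) {
  Xs <- as.matrix(subjects); storage.mode(Xs) <- "double"
  Xb <- as.matrix(background); storage.mode(Xb) <- "double"
  if (nrow(Xb) == 0) abort_endo("`background` must be non-empty.")
  if (ncol(Xs) != ncol(Xb)) abort_endo("Subject/background schema mismatch.")
  p <- ncol(Xs); n <- nrow(Xs)
  vars <- colnames(Xs)
  if (is.null(vars)) vars <- paste0("x", seq_len(p))

  base_pred <- predict_fn(Xb)
  if (is.null(dim(base_pred))) base_pred <- matrix(base_pred, ncol = 1)
  if (!all(is.finite(base_pred))) abort_endo("Non-finite predictions.")
  K <- ncol(base_pred)
  baseline <- colMeans(base_pred)
  full_pred <- predict_fn(Xs)
  if (is.null(dim(full_pred))) full_pred <- matrix(full_pred, ncol = 1)

  phi <- array(0, dim = c(n, p, K))
  with_seed(sub_seed(seed, "shap"), {
    for (i in seq_len(n)) {
      x <- Xs[i, ]
      # One evaluation batch per subject: n_permutations chains of p+1 rows.
      rows <- matrix(0, nrow = n_permutations * (p + 1L), ncol = p)
      orders <- matrix(0L, nrow = n_permutations, ncol = p)
      for (t in seq_len(n_permutations)) {
        b <- Xb[sample.int(nrow(Xb), 1L), ]
        ord <- sample.int(p)
        orders[t, ] <- ord
        chain <- matrix(rep(b, p + 1L), nrow = p + 1L, byrow = TRUE)
        for (step in seq_len(p)) {
          chain[(step + 1L):(p + 1L), ord[step]] <- x[ord[step]]
        }
        rows[((t - 1L) * (p + 1L) + 1L):(t * (p + 1L)), ] <- chain
      }
      colnames(rows) <- vars
      preds <- predict_fn(rows)
      if (is.null(dim(preds))) preds <- matrix(preds, ncol = 1)
      for (t in seq_len(n_permutations)) {
        block <- preds[((t - 1L) * (p + 1L) + 1L):(t * (p + 1L)), ,
                       drop = FALSE]
        contrib <- block[-1L, , drop = FALSE] - block[-(p + 1L), , drop = FALSE]
        phi[i, orders[t, ], ] <- phi[i, orders[t, ], ] + contrib
      }
      phi[i, , ] <- phi[i, , ] / n_permutations
      # Efficiency normalization against the full-background baseline.
      resid <- full_pred[i, ] - baseline - colSums(matrix(phi[i, , ], nrow = p))
      phi[i, , ] <- phi[i, , ] + matrix(resid / p, nrow = p, ncol = K,
                                        byrow = TRUE)
    }
  })

  dimnames(phi) <- list(rownames(Xs), vars, paste0("class", seq_len(K)))
  shap_endotype <- apply(abs(phi), c(2, 3), mean)
  structure(list(
    phi = phi,
    baseline = baseline,
    prediction = full_pred,
    shap_endotype = shap_endotype,
    global_shap = rowMeans(shap_endotype),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  ), class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<shap_attribution> %d subjects x %d variables x %d classes (%d permutations)\n",
              d[1], d[2], d[3], x$n_permutations))
  invisible(x)
}

#' Long-format Shapley attributions
#' @param x A `shap_attribution`.
#' @param ... Unused.
#' @return Tibble with `subject`, `variable`, `endotype`, `phi`.
#' @method tidy shap_attribution
#' @export
tidy.shap_attribution <- function(x, ...) {
  d <- dim(x$phi)
  dn <- dimnames(x$phi)
  if (is.null(dn[[1]])) dn[[1]] <- as.character(seq_len(d[1]))
  tibble::tibble(
    subject = rep(dn[[1]], times = d[2] * d[3]),
    variable = rep(rep(dn[[2]], each = d[1]), times = d[3]),
    endotype = rep(dn[[3]], each = d[1] * d[2]),
    phi = as.vector(x$phi)
  )
}

#' Rank variables by Shapley attribution
#'
#' Variables are ranked globally by mean |phi| over subjects and endotypes
#' and per endotype by the endotype-wise mean |phi|; ties are broken
#' alphabetically. The per-endotype top lists mirror the usual SHAP summary
#' layout (top 10 per endotype).
#'
#' @param attr A `shap_attribution`.
#' @param n_top Per-endotype list length.
#' @return List with `global` (tibble variable, global_shap, rank),
#'   `per_endotype` (tibble endotype, variable, shap_endotype, rank),
#'   and `degenerate` (TRUE when all attributions are zero).
#' @export
rank_variables <- function(attr, n_top = 10) {
  stopifnot(inherits(attr, "shap_attribution"))
  if (length(attr$global_shap) == 0) abort_endo("Empty attribution matrix.")
  g <- attr$global_shap
  degenerate <- all(g == 0)
  ord <- order(-g, names(g))
  global <- tibble::tibble(variable = names(g)[ord],
                           global_shap = unname(g[ord]),
                           rank = seq_along(g))
  se <- attr$shap_endotype
  per <- dplyr::bind_rows(lapply(colnames(se), function(cl) {
    v <- se[, cl]
    names(v) <- rownames(se)
    o <- order(-v, names(v))[seq_len(min(n_top, length(v)))]
    tibble::tibble(endotype = cl, variable = names(v)[o],
                   shap_endotype = unname(v[o]), rank = seq_along(o))
  }))
  list(global = global, per_endotype = per, degenerate = degenerate)
}

#' Bar plot of top global Shapley attributions
#' @param attr A `shap_attribution`.
#' @param n_top Number of variables shown.
#' @return A ggplot object.
#' @export
plot_shap_ranking <- function(attr, n_top = 15) {
  rk <- rank_variables(attr, n_top = n_top)
  top <- utils::head(rk$global, n_top)
  top$variable <- factor(top$variable, levels = rev(top$variable))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$global_shap, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |SHAP value|", y = NULL) +
    ggplot2::theme_minimal()
}
#' Write attributions as long-format delimited text plus ranking JSON
#'
#' @param attr A `shap_attribution`.
#' @param phi_path CSV path for the long-format tensor
#'   (subject, variable, endotype, phi).
#' @param ranking_path Optional JSON path for the global and per-endotype
#'   rankings.
#' @return `phi_path`, invisibly.
#' @export
write_attributions <- function(attr, phi_path, ranking_path = NULL) {
  utils::write.csv(as.data.frame(tidy.shap_attribution(attr)), phi_path,
                   row.names = FALSE)
  if (!is.null(ranking_path)) {
    rk <- rank_variables(attr)
    jsonlite::write_json(list(global = rk$global,
                              per_endotype = rk$per_endotype,
                              degenerate = rk$degenerate),
                         ranking_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(phi_path)
}
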