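# Weighted correlation network analysis over the biomarker panel: unsigned
# soft-thresholded adjacency, scale-free soft-power selection, topological
# overlap, average-linkage tree cut into modules, and per-endotype module
# summaries (the heatmap source data).

biomarker_matrix <- function(expr) {
  X <- as.matrix(expr)
  storage.mode(X) <- "double"
  if (anyNA(X)) abort_endo("Missing values in the biomarker matrix.")
  sds <- apply(X, 2, stats::sd)
  flat <- colnames(X)[sds == 0]
  if (length(flat) > 0) {
    abort_endo(paste0("Constant biomarker(s): ", paste(flat, collapse = ", ")),
               class = "endotyper_constant_biomarker")
  }
  X
}

#' Scale-free fit of a connectivity distribution
#'
#' Connectivities are binned into `n_bins` equal-count bins; the fit is the
#' R-squared of the linear regression of log10 p(k) on log10 mean(k) over
#' non-empty bins, together with the regression slope (scale-free topology
#' implies a negative slope).
#'
#' @param k Connectivity vector.
#' @param n_bins Number of bins.
#' @return List with `r2` and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  brk <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 3) return(list(r2 = 0, slope = 0))
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  pk <- as.vector(table(bin)) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- pk > 0 & mk > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(mk[keep]))
  list(r2 = suppressWarnings(summary(fit)$r.squared), slope = unname(stats::coef(fit)[2]))
}

#' Pick the soft-thresholding power
#'
#' For each candidate power, the unsigned adjacency `|cor|^power` is formed
#' and the scale-free topology fit of its connectivity distribution is
#' measured. The smallest power whose fit reaches `r2_threshold` (with a
#' negative slope) is returned; when none reaches it - as for designed
#' block structures or independent noise, whose connectivity distributions
#' are not scale-free - the canonical unsigned-network default power
#' (`fallback_power`, 6) is returned and flagged as a fallback.
#'
#' @param expr Subjects x biomarkers matrix / data frame.
#' @param powers Candidate integer powers.
#' @param r2_threshold Scale-free fit acceptance level.
#' @param n_bins Connectivity bins for the fit.
#' @param fallback_power Power used when no candidate reaches the fit bar.
#' @return List with `power`, `fallback` flag and the `fit_table` tibble
#'   (power, r2, slope, mean_connectivity).
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_threshold = 0.8,
                            n_bins = 10, fallback_power = 6) {
  X <- biomarker_matrix(expr)
  if (ncol(X) < 3) abort_endo("Need >= 3 biomarkers.")
  if (nrow(X) < 10) abort_endo("Need >= 10 subjects.")
  ac <- abs(stats::cor(X))
  diag(ac) <- 0
  rows <- lapply(powers, function(b) {
    a <- ac^b
    k <- rowSums(a)
    f <- scale_free_fit(k, n_bins)
    tibble::tibble(power = b, r2 = f$r2, slope = f$slope,
                   mean_connectivity = mean(k))
  })
  fit_table <- dplyr::bind_rows(rows)
  ok <- fit_table$r2 >= r2_threshold & fit_table$slope < 0
  if (any(ok)) {
    power <- fit_table$power[which(ok)[1]]
    fallback <- FALSE
  } else {
    power <- fallback_power
    fallback <- TRUE
  }
  list(power = power, fallback = fallback, fit_table = fit_table)
}

#' Unsigned adjacency and topological overlap
#'
#' Adjacency `a_ij = |cor(x_i, x_j)|^power` (diagonal excluded from
#' connectivity); topological overlap
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j`, and `TOM_ii = 1`.
#'
#' @param expr Subjects x biomarkers matrix / data frame.
#' @param power Soft-thresholding power.
#' @return A `module_set` object with `adjacency`, `tom`, `connectivity`,
#'   `power`; the module map is added by [detect_modules()].
#' @export
compute_tom <- function(expr, power) {
  X <- biomarker_matrix(expr)
  a <- abs(stats::cor(X))^power
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  structure(list(
    power = power,
    adjacency = a,
    connectivity = k,
    tom = tom,
    biomarkers = colnames(X),
    modules = NULL
  ), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d biomarkers, soft power %s", length(x$biomarkers),
              format(x$power)))
  if (!is.null(x$modules)) {
    nm <- sum(unique(x$modules$module) != 0)
    cat(sprintf(", %d modules (+%d unassigned)", nm,
                sum(x$modules$module == 0)))
  }
  cat("\n")
  invisible(x)
}

#' Module map of a `module_set`
#' @param x A `module_set` (after [detect_modules()]).
#' @param ... Unused.
#' @return Tibble with `biomarker` and `module` (0 = unassigned).
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  if (is.null(x$modules)) abort_endo("Run detect_modules() first.")
  x$modules
}

#' Detect co-expression modules by tree cut of the topological overlap
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`,
#' followed by a fixed-height scan: among candidate cut heights, the one
#' producing the largest number of clusters with at least `min_module_size`
#' members is chosen (ties resolved toward the largest height, which leaves
#' the fewest biomarkers unassigned). Members of undersized clusters are
#' unassigned (module 0); modules are numbered by decreasing size.
#'
#' @param moduleset A `module_set` from [compute_tom()].
#' @param min_module_size Minimum module size.
#' @param heights Candidate cut heights.
#' @return The `module_set` with a `modules` tibble (biomarker, module) and
#'   `cut_height` filled in.
#' @export
detect_modules <- function(moduleset, min_module_size = 3,
                           heights = seq(0.05, 0.995, by = 0.005)) {
  stopifnot(inherits(moduleset, "module_set"))
  dss <- stats::as.dist(1 - moduleset$tom)
  tree <- stats::hclust(dss, method = "average")
  best <- NULL
  for (h in heights) {
    labs <- stats::cutree(tree, h = h)
    sizes <- table(labs)
    n_ok <- sum(sizes >= min_module_size)
    if (is.null(best) || n_ok >= best$n_ok) {
      best <- list(h = h, labs = labs, n_ok = n_ok)
    }
  }
  labs <- best$labs
  sizes <- table(labs)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- ifelse(labs %in% keep, labs, 0L)
  # renumber by decreasing size
  kept_sizes <- sort(table(module[module != 0]), decreasing = TRUE)
  remap <- stats::setNames(seq_along(kept_sizes), names(kept_sizes))
  module_new <- ifelse(module == 0L, 0L, remap[as.character(module)])
  moduleset$modules <- tibble::tibble(
    biomarker = moduleset$biomarkers,
    module = as.integer(module_new)
  )
  moduleset$cut_height <- best$h
  moduleset$tree <- tree
  moduleset
}

#' Per-endotype mean Z level of each biomarker, grouped by module
#'
#' The source data of the biomarker heatmap: mean Z-standardized level per
#' (biomarker, endotype), rows ordered by module.
#'
#' @param expr_z Subjects x biomarkers matrix of Z-standardized levels.
#' @param endotypes Per-subject endotype labels (vector or an
#'   `endotype_assignment`).
#' @param modules Module map tibble (`biomarker`, `module`) or a
#'   `module_set` carrying one.
#' @return Tibble with `module`, `biomarker` and one `mean_z` per endotype
#'   (long format: `endotype`, `mean_z`).
#' @export
endotype_module_summary <- function(expr_z, endotypes, modules) {
  if (inherits(endotypes, "endotype_assignment")) endotypes <- endotypes$endotype
  if (inherits(modules, "module_set")) modules <- tidy.module_set(modules)
  X <- as.matrix(expr_z)
  if (nrow(X) != length(endotypes)) abort_endo("Inputs not aligned.")
  lv <- if (is.factor(endotypes)) levels(endotypes) else sort(unique(endotypes))
  if (any(table(factor(endotypes, levels = lv)) == 0)) abort_endo("Empty endotype.")
  out <- dplyr::bind_rows(lapply(lv, function(e) {
    tibble::tibble(endotype = e,
                   biomarker = colnames(X),
                   mean_z = colMeans(X[endotypes == e, , drop = FALSE]))
  }))
  out <- dplyr::left_join(out, modules, by = "biomarker")
  dplyr::arrange(out, .data$module, .data$biomarker, .data$endotype)
}

#' Heatmap of per-endotype biomarker levels grouped by module
#' @param summary_tbl Output of [endotype_module_summary()].
#' @return A ggplot object.
#' @export
plot_module_heatmap <- function(summary_tbl) {
  summary_tbl$biomarker <- factor(summary_tbl$biomarker,
                                  levels = unique(summary_tbl$biomarker))
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = factor(.data$endotype),
                               y = .data$biomarker,
                               fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#67a9cf", mid = "white",
                                  high = "#ef8a62", midpoint = 0) +
    ggplot2::labs(x = "endotype", y = NULL, fill = "mean Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Write a module map / TOM to delimited text
#' @param moduleset A `module_set` with modules detected.
#' @param map_path Two-column CSV for the biomarker-module map.
#' @param tom_path Optional CSV for the dense TOM matrix.
#' @return `map_path`, invisibly.
#' @export
write_modules <- function(moduleset, map_path, tom_path = NULL) {
  utils::write.csv(as.data.frame(tidy.module_set(moduleset)), map_path,
                   row.names = FALSE)
  if (!is.null(tom_path)) {
    utils::write.csv(as.data.frame(moduleset$tom), tom_path, row.names = FALSE)
  }
  invisible(map_path)
}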