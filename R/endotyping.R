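# Endotype discovery: agglomerative clustering of the learned embedding,
# selection of the number of clusters, and severity-ordered relabelling
# (endotype 1 mildest .. endotype K most severe).
#
# The number of clusters is chosen by prediction strength (cluster
# reproducibility across random half-splits): the largest k whose clusters
# can be reproduced from an independent half of the cohort. Mean silhouette
# width is reported alongside and supplies the no-structure guard used by
# the random-outcome null control: quantized embeddings make silhouette
# profiles flat or monotone in k, so reproducibility, not compactness,
# decides k.

embedding_matrix <- function(embedding) {
  X <- as.matrix(embedding)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) abort_endo("Embedding must be finite.")
  X
}

#' Cluster an embedding with Ward-linkage hierarchical clustering
#'
#' Agglomerative clustering with Ward linkage on Euclidean distance
#' (`hclust(method = "ward.D2")`), cut at `k` clusters. With
#' `refine = TRUE` (the default) the cut is polished by Lloyd k-means
#' iterations started from the cut's cluster centroids, which removes the
#' dependence of boundary subjects on the greedy merge order. Deterministic:
#' no random initialization is involved.
#'
#' @param embedding Numeric matrix / data frame (rows = subjects).
#' @param k Number of clusters (>= 2, <= number of subjects).
#' @param tree Optionally, a pre-computed `hclust` tree for the same rows
#'   (avoids recomputing the linkage across a k grid).
#' @param refine Polish the tree cut with centroid-initialized k-means.
#' @return Integer vector of raw cluster labels in 1..k, with the `hclust`
#'   tree attached as attribute `tree`.
#' @export
cluster_embedding <- function(embedding, k, tree = NULL, refine = TRUE) {
  X <- embedding_matrix(embedding)
  n <- nrow(X)
  if (k < 2) abort_endo("`k` must be >= 2.")
  if (k > n) abort_endo("`k` must not exceed the number of subjects.")
  if (all(apply(X, 2, function(col) diff(range(col)) == 0))) {
    abort_endo("degenerate embedding: all points identical",
               class = "endotyper_degenerate")
  }
  if (is.null(tree)) tree <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  if (refine) labels <- refine_labels(X, labels)
  attr(labels, "tree") <- tree
  labels
}

# Lloyd k-means polish started from the current labels' centroids. Keeps k
# fixed; falls back to the input labels if a cluster empties.
refine_labels <- function(X, labels) {
  cent <- rowsum(X, labels) / as.vector(table(labels))
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = cent, iter.max = 30,
                                   algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < length(unique(labels))) {
    return(labels)
  }
  as.integer(km$cluster)
}

mean_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(labels, dist = d)
  mean(sil[, "sil_width"])
}

# Squared Euclidean distances from rows of B to rows of C.
cross_dist2 <- function(B, C) {
  outer(rowSums(B^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(B)), rowSums(C^2)) - 2 * B %*% t(C)
}

#' Prediction strength of a k-clustering
#'
#' Tibshirani-Walther prediction strength: the cohort is split in half,
#' both halves are Ward-clustered at k, and each test-half cluster is scored
#' by the fraction of its within-cluster pairs that are also co-assigned
#' when test subjects are mapped to the nearest training-half centroid. The
#' statistic is the minimum over test clusters, averaged over `n_splits`
#' seeded splits.
#'
#' @param embedding Numeric matrix / data frame.
#' @param ks Integer vector of candidate cluster numbers.
#' @param n_splits Number of random half-splits to average over.
#' @param seed Integer seed for the splits.
#' @return Numeric vector of prediction strengths, one per k.
#' @export
prediction_strength <- function(embedding, ks, n_splits = 5, seed = 1) {
  E <- embedding_matrix(embedding)
  n <- nrow(E)
  if (n < 4) abort_endo("Need at least 4 subjects.")
  with_seed(sub_seed(seed, "misc"), {
    ps_sum <- numeric(length(ks))
    for (split in seq_len(n_splits)) {
      idx <- sample(n, floor(n / 2))
      A <- E[idx, , drop = FALSE]
      B <- E[-idx, , drop = FALSE]
      treeA <- stats::hclust(stats::dist(A), method = "ward.D2")
      treeB <- stats::hclust(stats::dist(B), method = "ward.D2")
      for (j in seq_along(ks)) {
        k <- ks[j]
        labA <- refine_labels(A, stats::cutree(treeA, k))
        labB <- refine_labels(B, stats::cutree(treeB, k))
        centA <- rowsum(A, labA) / as.vector(table(labA))
        predB <- max.col(-cross_dist2(B, centA))
        ps_k <- vapply(seq_len(k), function(g) {
          ii <- which(labB == g)
          if (length(ii) < 2) return(1)
          pp <- predB[ii]
          tab <- table(pp)
          sum(tab * (tab - 1)) / (length(ii) * (length(ii) - 1))
        }, numeric(1))
        ps_sum[j] <- ps_sum[j] + min(ps_k)
      }
    }
    ps_sum / n_splits
  })
}

#' Select the number of clusters
#'
#' Ward-clusters the embedding over a k grid and selects the largest k such
#' that every partition from `kmin` up to k reaches average prediction
#' strength `ps_threshold` (cluster-number selection by reproducibility;
#' the contiguity requirement discards isolated reproducible refinements
#' sitting above an irreproducible one). The mean-silhouette profile is
#' computed alongside: when even the best silhouette falls below
#' `threshold` the embedding is declared unstructured ("no defined
#' cluster"), which is the verdict the random-outcome null control relies
#' on. If no k reaches the prediction-strength bar, the silhouette argmax
#' is used as fallback.
#'
#' @param embedding Numeric matrix / data frame.
#' @param kmin,kmax Grid of candidate cluster numbers.
#' @param threshold No-structure silhouette threshold.
#' @param ps_threshold Prediction-strength acceptance level.
#' @param n_splits Half-splits averaged in the prediction strength.
#' @param seed Seed for the prediction-strength splits.
#' @return List with `k`, `k_silhouette` (silhouette argmax),
#'   `max_silhouette`, `no_structure`, the `profile` tibble (k, mean
#'   silhouette, prediction strength) and the linkage `tree`.
#' @export
select_k <- function(embedding, kmin = 2, kmax = 8, threshold = 0.15,
                     ps_threshold = 0.9, n_splits = 5, seed = 1) {
  X <- embedding_matrix(embedding)
  if (nrow(X) <= kmax) abort_endo("Need more subjects than `kmax`.")
  d <- stats::dist(X)
  tree <- stats::hclust(d, method = "ward.D2")
  ks <- seq.int(kmin, kmax)
  sil <- vapply(ks, function(k) {
    mean_silhouette(stats::cutree(tree, k = k), d)
  }, numeric(1))
  ps <- prediction_strength(X, ks, n_splits = n_splits, seed = seed)
  k_sil <- ks[which.max(sil)]
  run_ok <- cumprod(ps >= ps_threshold) == 1
  k_best <- if (any(run_ok)) ks[max(which(run_ok))] else k_sil
  list(k = k_best,
       k_silhouette = k_sil,
       max_silhouette = max(sil),
       no_structure = max(sil) < threshold,
       profile = tibble::tibble(k = ks, mean_silhouette = sil,
                                prediction_strength = ps),
       tree = tree)
}

#' Order raw clusters into severity-ranked endotypes
#'
#' Bijectively relabels clusters so that the cluster mean of the severity
#' measure (baseline c-IMT_mean-max) is ascending in the label: endotype 1
#' is the mildest, endotype K the most severe. Ties in mean severity are
#' broken by descending cluster size (the larger cluster gets the lower
#' label).
#'
#' @param labels Raw cluster labels.
#' @param severity Per-subject severity measure aligned to `labels`.
#' @param subject_id Optional subject identifiers.
#' @return An `endotype_assignment` tibble with `subject_id` and `endotype`,
#'   plus attributes `k`, `relabel_map` (raw -> ordered) and `tree` when the
#'   labels carry one.
#' @export
order_endotypes <- function(labels, severity, subject_id = NULL) {
  if (length(labels) != length(severity)) {
    abort_endo("`labels` and `severity` must be aligned.")
  }
  raw <- sort(unique(as.integer(labels)))
  sizes <- as.integer(table(factor(labels, levels = raw)))
  if (any(sizes == 0)) abort_endo("Empty cluster.")
  means <- vapply(raw, function(g) mean(severity[labels == g]), numeric(1))
  ord <- order(means, -sizes, raw)
  relabel <- integer(max(raw))
  relabel[raw[ord]] <- seq_along(raw)
  endo <- relabel[as.integer(labels)]
  if (is.null(subject_id)) subject_id <- sprintf("S%05d", seq_along(labels))
  out <- tibble::tibble(subject_id = subject_id, endotype = as.integer(endo))
  attr(out, "k") <- length(raw)
  attr(out, "relabel_map") <- stats::setNames(relabel[raw], raw)
  attr(out, "tree") <- attr(labels, "tree")
  class(out) <- c("endotype_assignment", class(out))
  out
}

#' @export
print.endotype_assignment <- function(x, ...) {
  cat(sprintf("<endotype_assignment> %d subjects, K = %d\n", nrow(x),
              attr(x, "k")))
  print(table(endotype = x$endotype))
  invisible(x)
}

#' Write an endotype assignment as two-column delimited text
#' @param assignment An `endotype_assignment`.
#' @param path Output path (comma separated, header row).
#' @return `path`, invisibly.
#' @export
write_endotypes <- function(assignment, path) {
  utils::write.csv(as.data.frame(assignment[, c("subject_id", "endotype")]),
                   path, row.names = FALSE)
  invisible(path)
}

# Standardized feature matrix for the representation learner: demographic,
# clinical and biomarker columns, sex coded 0/1.
encoder_features <- function(cohort) {
  feats <- feature_vars(cohort)
  tab <- cohort
  tab$sex_male <- as.numeric(tab$sex == "male")
  feats_num <- c(setdiff(feats, "sex"), "sex_male")
  zstd <- z_standardize(tab[, feats_num, drop = FALSE],
                        setdiff(feats_num, "sex_male"))
  list(zstd = zstd, features = feats_num)
}

# Replicate-ensembled embedding: trains `n_replicates` encoders on the same
# data under derived seeds and column-binds their bottleneck codes. Each
# replicate quantizes the outcome-related manifold slightly differently;
# replicate-specific micro-structure decorrelates in the concatenated space
# while the shared endotype structure accumulates.
replicate_embedding <- function(X, y, hparams, seed, n_replicates) {
  models <- lapply(seq_len(n_replicates) - 1L, function(j) {
    train_encoder(X, y, hparams = hparams, seed = seed + j * 100000L)
  })
  emb <- do.call(cbind, lapply(models, function(m) as.matrix(embed(m, X))))
  colnames(emb) <- paste0("dim_", seq_len(ncol(emb)))
  list(models = models, embedding = tibble::as_tibble(emb))
}

#' Run the full endotype-discovery pipeline on a cohort
#'
#' Convenience wrapper: derive ultrasound summaries, Z-standardize the
#' analysis features, train `n_replicates` encoder replicates on
#' standardized c-IMT_mean-max, concatenate their bottleneck codes into the
#' embedding, choose the number of clusters, and order the clusters by mean
#' baseline c-IMT_mean-max.
#'
#' @param cohort A `cohort_tbl` (complete cases).
#' @param seed Integer seed for the encoder replicates and the
#'   cluster-number selection.
#' @param hparams Encoder hyperparameters.
#' @param n_replicates Encoder replicates whose codes form the embedding.
#' @param kmin,kmax Cluster-number grid for [select_k()].
#' @param threshold No-structure silhouette threshold.
#' @return List with `assignment` (an `endotype_assignment`), `models`,
#'   `embedding`, `selection` (the [select_k()] report), `zstd` (feature
#'   standardizer), `features`, and the derived `cohort`.
#' @export
discover_endotypes <- function(cohort, seed = 1, hparams = encoder_hparams(),
                               n_replicates = 3, kmin = 2, kmax = 8,
                               threshold = 0.15) {
  if (!"cimt_mean_max" %in% names(cohort)) cohort <- add_ultrasound_summaries(cohort)
  ef <- encoder_features(cohort)
  X <- as.matrix(ef$zstd$data)
  y <- as.numeric(scale(cohort$cimt_mean_max))
  rep_emb <- replicate_embedding(X, y, hparams, seed, n_replicates)
  sel <- select_k(rep_emb$embedding, kmin = kmin, kmax = kmax,
                  threshold = threshold, seed = seed)
  raw <- cluster_embedding(rep_emb$embedding, sel$k, tree = sel$tree)
  assignment <- order_endotypes(raw, cohort$cimt_mean_max,
                                subject_id = cohort$subject_id)
  list(assignment = assignment, models = rep_emb$models,
       embedding = rep_emb$embedding, selection = sel, zstd = ef$zstd,
       cohort = cohort, features = ef$features)
}

#' Random-outcome null control
#'
#' Re-runs the representation-learning and clustering stages with a
#' Uniform(0, 1) outcome in place of c-IMT_mean-max. With no learnable
#' signal the encoders revert to their untrained state and the embedding
#' should show no cluster structure: the report carries the silhouette and
#' prediction-strength profiles over k and a verdict (`structure` is `TRUE`
#' only when the maximum mean silhouette reaches `threshold`).
#'
#' @param table Numeric feature table (standardized), no missing values.
#' @param seed Integer seed for the null outcome and the encoders.
#' @param hparams Encoder hyperparameters.
#' @param n_replicates Encoder replicates, as in [discover_endotypes()].
#' @param kmin,kmax Cluster-number grid.
#' @param threshold Silhouette level below which the verdict is
#'   "no defined cluster".
#' @return List with `max_silhouette`, `k_best`, `structure`, `verdict` and
#'   the full `profile` tibble.
#' @export
null_control <- function(table, seed = 1, hparams = encoder_hparams(),
                         n_replicates = 3, kmin = 2, kmax = 8,
                         threshold = 0.15) {
  X <- as.matrix(table)
  y0 <- generate_null_outcome(nrow(X), seed)
  y <- if (stats::sd(y0) > 0) (y0 - mean(y0)) / stats::sd(y0) else y0 * 0
  rep_emb <- replicate_embedding(X, y, hparams, seed, n_replicates)
  prof <- select_k(rep_emb$embedding, kmin = kmin, kmax = kmax,
                   threshold = threshold, seed = seed)
  list(max_silhouette = prof$max_silhouette,
       k_best = prof$k,
       structure = !prof$no_structure,
       verdict = if (prof$no_structure) "no defined cluster" else "structure",
       profile = prof$profile)
}

#' Silhouette / prediction-strength profile plot for a k-selection report
#'
#' @param selection A [select_k()] report (or the `selection` element of
#'   [discover_endotypes()]).
#' @return A ggplot object.
#' @export
plot_silhouette_profile <- function(selection) {
  prof <- tidyr::pivot_longer(selection$profile, -"k",
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = NULL) +
    ggplot2::theme_minimal()
}
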