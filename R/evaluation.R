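#' Pair-counting Rand measure between two clusterings
#'
#' Every unordered pair of samples is classified: positive if the test
#' clustering puts the pair in one group, and true if the test agrees with
#' the reference on that pair. R = (TP + TN) / (TP + FP + FN + TN), the
#' fraction of pairs on which the two clusterings agree; label names are
#' irrelevant.
#'
#' @param test_labels,ref_labels Equal-length label vectors (>= 2 samples).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `rand`.
#' @export
rand_index <- function(test_labels, ref_labels) {
  if (length(test_labels) != length(ref_labels)) {
    abort("label vectors must have equal length")
  }
  m <- length(test_labels)
  if (m < 2) abort("need at least 2 samples")
  ct <- table(test_labels, ref_labels)
  tp <- sum(choose(ct, 2))
  p_test <- sum(choose(rowSums(ct), 2))
  p_ref <- sum(choose(colSums(ct), 2))
  pairs <- choose(m, 2)
  fp <- p_test - tp
  fn <- p_ref - tp
  tn <- pairs - tp - fp - fn
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 rand = (tp + tn) / pairs)
}

#' Correlation distance between two expression profiles
#'
#' d_c(x, y) = 1 - cor(x, y), the Pearson correlation distance, in `[0, 2]`.
#'
#' @param x,y Numeric vectors of equal length >= 2; neither constant.
#' @return A single number in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation distance undefined for a constant profile")
  }
  1 - cor(x, y)
}

#' All-pairs correlation distances between samples
#'
#' @param m Expression matrix, genes x samples.
#' @return A `dist` of 1 - Pearson correlation between sample columns.
#' @export
correlation_distance_matrix <- function(m) {
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant sample profile(s): %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  as.dist(1 - cor(m))
}

#' Embed samples in 2D by t-SNE on correlation distances
#'
#' Runs t-SNE on the pairwise correlation-distance matrix between samples,
#' giving the 2D map on which closest-pair identification operates.
#' Deterministic for a given seed.
#'
#' @param m Expression matrix, genes x samples (>= 4 samples).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; must be < (m - 1) / 3. The default 30
#'   is capped at `floor((m - 1) / 3)`.
#' @param ... Passed to [Rtsne::Rtsne()].
#' @return A tibble: `sample_id`, `tsne_1`, `tsne_2`.
#' @export
embed_tsne <- function(m, seed = 1L, perplexity = 30, ...) {
  validate_expression_matrix(m)
  n <- ncol(m)
  if (n < 4) abort("t-SNE needs at least 4 samples")
  cap <- max(1, floor((n - 2) / 3)) # largest perplexity with 3*perplexity < n-1
  if (missing(perplexity)) {
    perplexity <- min(perplexity, cap)
  } else if (perplexity >= (n - 1) / 3) {
    abort(sprintf("perplexity must be < (n - 1)/3 = %.2f; try %d",
                  (n - 1) / 3, cap))
  }
  d <- correlation_distance_matrix(m)
  set.seed(seed)
  fit <- Rtsne::Rtsne(d, is_distance = TRUE, dims = 2,
                      perplexity = perplexity, pca = FALSE, ...)
  tibble::tibble(sample_id = colnames(m),
                 tsne_1 = fit$Y[, 1], tsne_2 = fit$Y[, 2])
}

#' Closest pair of groups by embedded centroid distance
#'
#' Group centroids are the per-group means of the 2D coordinates; the
#' closest pair is the unordered pair with minimal Euclidean centroid
#' distance (ties broken by lexicographically smallest pair of names). In a
#' multi-group study this selects the two hardest-to-separate groups for
#' benchmarking.
#'
#' @param coords Tibble from [embed_tsne()] (columns `sample_id`, `tsne_1`,
#'   `tsne_2`) or a 2-column coordinate matrix.
#' @param group_labels Per-sample group labels, same order as `coords` rows;
#'   every group non-empty.
#' @return A one-row tibble: `group_a`, `group_b`, `distance`.
#' @export
closest_pair <- function(coords, group_labels) {
  xy <- if (is.data.frame(coords)) {
    as.matrix(coords[, c("tsne_1", "tsne_2")])
  } else {
    as.matrix(coords)
  }
  if (nrow(xy) != length(group_labels)) {
    abort("`group_labels` must match the number of embedded samples")
  }
  group_labels <- as.character(group_labels)
  groups <- sort(unique(group_labels))
  if (length(groups) < 2) abort("need at least 2 groups")
  centroids <- vapply(groups,
                      function(g) colMeans(xy[group_labels == g, , drop = FALSE]),
                      numeric(2))
  best <- NULL
  for (i in seq_len(length(groups) - 1)) {
    for (j in seq(i + 1, length(groups))) {
      dd <- sqrt(sum((centroids[, i] - centroids[, j])^2))
      if (is.null(best) || dd < best$distance) {
        best <- tibble::tibble(group_a = groups[i], group_b = groups[j],
                               distance = dd)
      }
    }
  }
  best
}

cluster_once <- function(method, X, coords, run_seed) {
  # X: genes x samples matrix; coords: samples x 2 (or NULL without t-SNE)
  pts <- if (is.null(coords)) t(X) else coords
  switch(method,
    nmf = {
      A <- if (is.null(coords)) X else {
        # NMF needs non-negative input: shift embedded coordinates
        a <- t(coords - min(coords))
        dimnames(a) <- list(paste0("dim", seq_len(nrow(a))), colnames(X))
        a
      }
      assign_clusters(nmf_fit(A, k = 2, seed = run_seed))
    },
    kmeans = {
      set.seed(run_seed)
      kmeans(pts, centers = 2, nstart = 1)$cluster
    },
    hclust_euclidean_complete =
      cutree(hclust(dist(pts), method = "complete"), k = 2),
    hclust_euclidean_ward =
      cutree(hclust(dist(pts), method = "ward.D2"), k = 2),
    hclust_correlation_complete = {
      d <- if (is.null(coords)) correlation_distance_matrix(X) else
        as.dist(1 - cor(t(coords)))
      cutree(hclust(d, method = "complete"), k = 2)
    },
    abort(sprintf("unknown clustering method `%s`", method))
  )
}

#' Benchmark clustering methods against a reference partition
#'
#' Compares consensus-style NMF clustering with K-means and three
#' hierarchical variants (Euclidean + complete, Euclidean + Ward,
#' correlation + complete), each run `n_runs` times (run r seeded
#' `base_seed + r`) and scored by the Rand measure against the reference
#' labels. With `with_tsne = TRUE` every method runs on the 2D correlation
#' t-SNE coordinates of that run (shifted to be non-negative for NMF)
#' instead of the full matrix. Each method's per-run Rand values are tested
#' against the NMF reference arm by a two-sided Welch t-test; a method is
#' flagged significantly worse when p < 0.05 and its mean is below the
#' reference mean.
#'
#' @param m Expression matrix, genes x samples.
#' @param ref_labels Reference partition with exactly 2 groups.
#' @param n_runs Runs per method.
#' @param base_seed Base seed.
#' @param with_tsne Also run the t-SNE-preprocessed arms.
#' @param perplexity Perplexity for the t-SNE arms.
#' @return A tibble: `method`, `tsne`, `mean_rand`, `sd_rand`, `welch_p`,
#'   `significantly_worse`, `rand_values` (list column of per-run values).
#' @export
benchmark_clustering <- function(m, ref_labels, n_runs = 30L, base_seed = 1L,
                                 with_tsne = FALSE, perplexity = 30) {
  validate_expression_matrix(m)
  if (length(ref_labels) != ncol(m)) {
    abort("`ref_labels` must have one label per sample")
  }
  if (length(unique(ref_labels)) != 2) {
    abort("the benchmark compares exactly 2 reference groups")
  }
  methods <- c("nmf", "kmeans", "hclust_euclidean_complete",
               "hclust_euclidean_ward", "hclust_correlation_complete")
  arms <- if (with_tsne) c(FALSE, TRUE) else FALSE

  rand_of <- function(labels) rand_index(labels, ref_labels)$rand
  rows <- list()
  for (tsne in arms) {
    coords_by_run <- if (tsne) {
      lapply(seq_len(n_runs), function(r) {
        as.matrix(embed_tsne(m, seed = base_seed + r,
                             perplexity = min(perplexity, floor((ncol(m) - 2) / 3))
                             )[, c("tsne_1", "tsne_2")])
      })
    } else NULL
    for (method in methods) {
      vals <- vapply(seq_len(n_runs), function(r) {
        coords <- if (tsne) coords_by_run[[r]] else NULL
        rand_of(cluster_once(method, m, coords, base_seed + r))
      }, 0)
      rows[[length(rows) + 1]] <- tibble::tibble(
        method = method, tsne = tsne,
        mean_rand = mean(vals), sd_rand = sd(vals),
        rand_values = list(vals))
    }
  }
  out <- dplyr::bind_rows(rows)
  ref_vals <- out$rand_values[[which(out$method == "nmf" & !out$tsne)]]
  welch <- vapply(seq_len(nrow(out)), function(i) {
    vals <- out$rand_values[[i]]
    if (out$method[i] == "nmf" && !out$tsne[i]) return(NA_real_)
    p <- tryCatch(t.test(vals, ref_vals)$p.value, error = function(e) NA_real_)
    p
  }, 0)
  out$welch_p <- welch
  out$significantly_worse <- !is.na(welch) & welch < 0.05 &
    out$mean_rand < mean(ref_vals)
  out[, c("method", "tsne", "mean_rand", "sd_rand", "welch_p",
          "significantly_worse", "rand_values")]
}
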