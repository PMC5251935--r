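#' Consensus clustering over random-restart NMF runs
#'
#' Runs `n_runs` NMF fits at rank `k` with seeds `base_seed + 1 .. base_seed
#' + n_runs`. Each run assigns samples to their dominant meta-gene; the
#' consensus matrix entry (u, v) is the fraction of runs that co-cluster
#' samples u and v. Final labels cut an average-linkage hierarchical tree on
#' the distance 1 - consensus into k groups, and the cophenetic correlation
#' coefficient (Pearson correlation between those distances and the tree's
#' cophenetic distances) measures how cleanly the consensus is a k-block
#' structure.
#'
#' @inheritParams nmf_fit
#' @param n_runs Number of random restarts (>= 2).
#' @param base_seed Base seed; run r uses seed `base_seed + r`.
#' @param connectivity_stop Stopping rule for the per-run fits; defaults to
#'   the assignment-stability rule (see [nmf_fit()]) since only labels are
#'   consumed here.
#' @param ... Passed on to [nmf_fit()].
#' @return An object of class `nmf_consensus`: `k`, `consensus` (m x m,
#'   symmetric, unit diagonal), `cophenetic`, `labels` (named, 1..k),
#'   `run_labels` (m x n_runs matrix), `n_runs`, `base_seed`.
#' @export
consensus_cluster <- function(A, k, n_runs = 30L, base_seed = 1L,
                              connectivity_stop = TRUE, ...) {
  validate_expression_matrix(A, "A")
  if (n_runs < 2) abort("`n_runs` must be >= 2 (cophenetic undefined otherwise)")
  m <- ncol(A)
  consensus <- matrix(0, m, m)
  run_labels <- matrix(NA_integer_, m, n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_fit(A, k, seed = base_seed + r,
                   connectivity_stop = connectivity_stop, ...)
    lab <- assign_clusters(fit)
    run_labels[, r] <- lab
    consensus <- consensus + outer(lab, lab, "==")
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(A), colnames(A))
  d <- as.dist(1 - consensus)
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = k)
  dv <- as.vector(d)
  cv <- as.vector(cophenetic(tree))
  # a degenerate consensus (all pairwise distances equal) is a perfect tree fit
  cophenetic_coef <- if (sd(dv) == 0 || sd(cv) == 0) 1 else cor(dv, cv)
  structure(list(k = as.integer(k), consensus = consensus,
                 cophenetic = cophenetic_coef,
                 labels = setNames(as.integer(labels), colnames(A)),
                 run_labels = run_labels,
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed)),
            class = "nmf_consensus")
}

#' @export
print.nmf_consensus <- function(x, ...) {
  cat(sprintf("Consensus NMF clustering: k = %d over %d runs (base seed %d)\n",
              x$k, x$n_runs, x$base_seed))
  cat(sprintf("  cophenetic correlation: %.4f\n", x$cophenetic))
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a consensus clustering into per-sample labels
#'
#' @param x An `nmf_consensus`.
#' @param ... Unused.
#' @return `tidy()`: tibble with `sample_id`, `cluster`. `glance()`: one-row
#'   summary with `k`, `cophenetic`, `n_runs`, `base_seed`.
#' @export
tidy.nmf_consensus <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy.nmf_consensus
#' @export
glance.nmf_consensus <- function(x, ...) {
  tibble::tibble(k = x$k, cophenetic = x$cophenetic, n_runs = x$n_runs,
                 base_seed = x$base_seed)
}

#' Choose the factorization rank by cophenetic correlation
#'
#' Runs [consensus_cluster()] for every rank in `k_range` and returns the
#' rank with the highest cophenetic correlation coefficient (ties go to the
#' smallest rank). Ranks 2-5 cover typical subpopulation structure; larger
#' ranks cost proportionally more runs.
#'
#' @inheritParams consensus_cluster
#' @param k_range Candidate ranks (each in 2..min(n, m)).
#' @return An object of class `nmf_rank_selection`: `best_k`, `results`
#'   (named list of `nmf_consensus`), `cophenetic` (tibble with `k`,
#'   `cophenetic`).
#' @export
select_rank <- function(A, k_range = 2:5, n_runs = 30L, base_seed = 1L, ...) {
  if (length(k_range) == 0) abort("`k_range` is empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > min(dim(A))) {
    abort("`k_range` must lie within 2..min(n, m)")
  }
  results <- lapply(k_range, function(k) {
    consensus_cluster(A, k, n_runs = n_runs, base_seed = base_seed, ...)
  })
  names(results) <- as.character(k_range)
  coph <- vapply(results, function(r) r$cophenetic, 0)
  best_k <- k_range[which.max(coph)]
  structure(list(best_k = best_k, results = results,
                 cophenetic = tibble::tibble(k = k_range,
                                             cophenetic = unname(coph))),
            class = "nmf_rank_selection")
}

#' @export
print.nmf_rank_selection <- function(x, ...) {
  cat(sprintf("NMF rank selection: best k = %d\n", x$best_k))
  print(x$cophenetic)
  invisible(x)
}

#' @rdname tidy.nmf_rank_selection
#' @export
glance.nmf_rank_selection <- function(x, ...) {
  best <- x$results[[as.character(x$best_k)]]
  tibble::tibble(best_k = x$best_k, cophenetic = best$cophenetic,
                 n_runs = best$n_runs)
}

#' Tidy a rank selection into the per-rank cophenetic table
#'
#' @param x An `nmf_rank_selection`.
#' @param ... Unused.
#' @return `tidy()`: tibble with `k` and `cophenetic`. `glance()`: one-row
#'   summary of the chosen rank.
#' @export
tidy.nmf_rank_selection <- function(x, ...) {
  x$cophenetic
}
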