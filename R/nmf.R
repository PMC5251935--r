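#' Generalized Kullback-Leibler divergence between a matrix and its
#' reconstruction
#'
#' D(A || WH) = sum_ij A_ij log(A_ij / WH_ij) - A_ij + WH_ij, with the
#' convention 0 log 0 = 0 (a zero data entry contributes just WH_ij).
#' This is the objective the multiplicative updates minimize.
#'
#' @param A Non-negative data matrix.
#' @param WH Non-negative reconstruction, same shape; must be positive
#'   wherever `A` is positive.
#' @param eps Floor applied inside the logarithm's denominator.
#' @return A single non-negative number.
#' @export
kl_divergence <- function(A, WH, eps = 1e-16) {
  if (any(A < 0) || any(WH < 0)) abort("KL divergence requires non-negative matrices")
  if (!all(dim(A) == dim(WH))) abort("`A` and `WH` must have the same shape")
  WH <- pmax(WH, eps)
  pos <- A > 0
  sum(A[pos] * log(A[pos] / WH[pos])) - sum(A[pos]) + sum(WH)
}

#' One multiplicative update of H (KL divergence)
#'
#' `H_au <- H_au * (sum_i W_ia A_iu / (WH)_iu) / (sum_k W_ka)`.
#' Denominators are floored at `eps` to avoid division by zero; the update
#' preserves non-negativity and leaves H unchanged at an exact fixed point
#' A = WH.
#'
#' @param W n x k factor matrix.
#' @param H k x m factor matrix.
#' @param A n x m non-negative data matrix.
#' @param eps Denominator floor.
#' @return The updated H.
#' @export
nmf_update_h <- function(W, H, A, eps = 1e-16) {
  WH <- pmax(W %*% H, eps)
  H * crossprod(W, A / WH) / pmax(colSums(W), eps)
}

#' One multiplicative update of W (KL divergence)
#'
#' `W_ia <- W_ia * (sum_u H_au A_iu / (WH)_iu) / (sum_v H_av)`; the mirror of
#' [nmf_update_h()].
#'
#' @inheritParams nmf_update_h
#' @return The updated W.
#' @export
nmf_update_w <- function(W, H, A, eps = 1e-16) {
  WH <- pmax(W %*% H, eps)
  sweep(W * tcrossprod(A / WH, H), 2, pmax(rowSums(H), eps), "/")
}

#' Fit a rank-k NMF by multiplicative KL updates
#'
#' Factorizes A ~ WH with W (genes x k) and H (k x samples) non-negative,
#' minimizing generalized KL divergence by alternating multiplicative
#' updates (H then W each iteration). W and H are initialized uniformly on
#' (eps, max(A)] from the given seed, so a fit is bitwise reproducible.
#' Convergence is declared when the relative change in KL divergence over
#' `check_every` iterations falls below `tol`.
#'
#' The columns of W are meta-genes: abstracted expression programs over
#' genes. Row i of W holds gene i's loadings on the meta-genes; column u of
#' H holds sample u's usage of them.
#'
#' @param A Non-negative matrix, genes x samples, with dimnames; no all-zero
#'   row or column (filter first).
#' @param k Factorization rank (>= 1; >= 2 for subpopulation discovery).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update iterations.
#' @param tol Relative KL-change convergence tolerance.
#' @param check_every Iterations between convergence checks.
#' @param eps Numerical floor used in initialization and denominators.
#' @param connectivity_stop Also stop once the argmax-of-H sample
#'   assignment has been unchanged for 40 consecutive iterations. This is
#'   the classical stopping rule for consensus clustering, where only the
#'   assignments are consumed; leave `FALSE` when converged loadings
#'   matter (D-score ranking).
#' @return An object of class `nmf_fit`: list with `W`, `H`, `k`, `seed`,
#'   `divergence_trace`, `iterations`, `converged`, `stop_reason`,
#'   `final_kl`.
#' @export
nmf_fit <- function(A, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                    check_every = 10L, eps = 1e-16,
                    connectivity_stop = FALSE) {
  validate_expression_matrix(A, "A")
  n <- nrow(A); m <- ncol(A)
  if (k < 1 || k > min(n, m)) abort("`k` must be in 1..min(n, m)")
  zr <- rowSums(A) == 0
  zc <- colSums(A) == 0
  if (any(zr) || any(zc)) {
    abort(paste("matrix has all-zero rows or columns; apply filter_genes()/",
                "filter_samples() first"))
  }
  set.seed(seed)
  hi <- max(A)
  W0 <- matrix(runif(n * k, eps, hi), n, k)
  H0 <- matrix(runif(k * m, eps, hi), k, m)
  res <- cpp_nmf_kl(A, W0, H0, as.integer(max_iter), tol,
                    as.integer(check_every), eps,
                    if (connectivity_stop) 40L else 0L)
  rownames(res$W) <- rownames(A)
  colnames(res$H) <- colnames(A)
  structure(list(W = res$W, H = res$H, k = as.integer(k),
                 seed = as.integer(seed),
                 divergence_trace = res$trace,
                 iterations = res$iterations,
                 converged = res$converged,
                 stop_reason = res$reason,
                 final_kl = res$final_kl),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("Rank-%d KL-NMF fit: %d genes x %d samples (seed %d)\n",
              x$k, nrow(x$W), ncol(x$H), x$seed))
  cat(sprintf("  %d iterations, converged: %s, final KL divergence: %.6g\n",
              x$iterations, x$converged, x$final_kl))
  invisible(x)
}

#' Assign each sample to its dominant meta-gene
#'
#' The cluster label of sample u is the index a maximizing H_au; ties go to
#' the lowest index.
#'
#' @param x An `nmf_fit` or a non-negative k x m matrix H.
#' @return Named integer vector of labels in 1..k.
#' @export
assign_clusters <- function(x) {
  H <- if (inherits(x, "nmf_fit")) x$H else x
  if (any(H < 0)) abort("H must be non-negative")
  labels <- apply(H, 2, which.max)
  setNames(as.integer(labels), colnames(H))
}

#' @rdname tidy.nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$W), n_samples = ncol(x$H),
                 iterations = x$iterations, converged = x$converged,
                 final_kl = x$final_kl, seed = x$seed)
}

#' Tidy an NMF fit into per-gene loadings
#'
#' @param x An `nmf_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `gene_id` and one `loading_<a>` column per
#'   meta-gene. `glance()`: a one-row fit summary.
#' @export
tidy.nmf_fit <- function(x, ...) {
  W <- x$W
  colnames(W) <- paste0("loading_", seq_len(ncol(W)))
  tibble::as_tibble(W, rownames = "gene_id")
}
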