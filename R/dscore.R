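#' Calibrate the D-score balancing factor
#'
#' The balancing factor lambda is defined by the rule that a gene expressed
#' uniformly across all samples must receive D-score 0. Operationally: the
#' all-ones sample profile is projected onto the row space of H by
#' non-negative least squares, giving loadings (u1, u2) such a gene would
#' carry; lambda = u2 / (u1 + u2) then satisfies
#' lambda * u1 - (1 - lambda) * u2 = 0 exactly.
#'
#' @param H Non-negative 2 x m matrix from a rank-2 factorization.
#' @return lambda in `[0, 1]`.
#' @export
calibrate_lambda <- function(H) {
  if (!is.matrix(H) || nrow(H) != 2) abort("`H` must be a 2 x m matrix")
  if (any(H < 0)) abort("`H` must be non-negative")
  u <- pracma::lsqnonneg(t(H), rep(1, ncol(H)))$x
  if (sum(u) == 0) abort("degenerate H: the uniform profile has zero NNLS loadings")
  u[2] / (u[1] + u[2])
}

#' D-score of a gene from its two meta-gene loadings
#'
#' D_i = | lambda * W_i1 - (1 - lambda) * W_i2 |. Genes loading both
#' meta-genes in the calibrated uniform proportion score 0; genes loading
#' one meta-gene disproportionately score high. Because loadings scale with
#' absolute expression, very lowly expressed genes cannot score high even
#' when their relative change is large.
#'
#' @param loading_1,loading_2 Non-negative loadings (vectorized).
#' @param lambda Balancing factor in `[0, 1]` from [calibrate_lambda()].
#' @return Non-negative D-scores.
#' @export
d_score <- function(loading_1, loading_2, lambda) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1]")
  if (any(loading_1 < 0) || any(loading_2 < 0)) abort("loadings must be >= 0")
  abs(lambda * loading_1 - (1 - lambda) * loading_2)
}

#' Rank genes by D-score from a rank-2 factorization
#'
#' Calibrates lambda once from H, scores every gene, and returns the table
#' sorted by descending D-score (ties broken by gene identifier for
#' determinism). The top `top_n` genes are flagged as feature genes — the
#' genes that best separate the two subpopulations.
#'
#' @param fit An `nmf_fit` with k = 2.
#' @param top_n Number of genes to flag as feature genes.
#' @return A tibble (one row per gene): `gene_id`, `loading_1`, `loading_2`,
#'   `d_score`, `rank`, `is_feature`, `lambda` (constant column).
#' @export
rank_genes <- function(fit, top_n = 500L) {
  if (!inherits(fit, "nmf_fit")) abort("`fit` must be an `nmf_fit`")
  if (fit$k != 2) {
    abort("the D-score is defined for rank-2 factorizations; fit with k = 2")
  }
  lambda <- calibrate_lambda(fit$H)
  tbl <- tibble::tibble(gene_id = rownames(fit$W),
                        loading_1 = fit$W[, 1],
                        loading_2 = fit$W[, 2],
                        d_score = d_score(fit$W[, 1], fit$W[, 2], lambda))
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$d_score), .data$gene_id)
  tbl$rank <- seq_len(nrow(tbl))
  tbl$is_feature <- tbl$rank <= top_n
  tbl$lambda <- lambda
  tbl
}
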