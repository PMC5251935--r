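#' Simulate a single-cell count matrix with planted subpopulations
#'
#' Generates a gene x cell matrix of counts with known ground truth for
#' testing every stage of the workflow. Gene base means are log-normal
#' (log2 means ~ Normal(`mean_log2`, `sd_log2`)); counts are negative
#' binomial with dispersion decreasing with the mean
#' (phi = `phi0` + `phi1` / mu, so lowly expressed genes have higher CV^2);
#' dropout zeroes an observation with probability decreasing logistically
#' with log2 mean expression (midpoint `dropout_midpoint`). Marker genes
#' are drawn from the intermediate range of base expression (the central
#' quantile band) and shifted by +/- `effect_log2fc` log2 units in each
#' non-reference group (half up, half down). Housekeeping genes get high
#' uniform expression and no dropout. Per-cell library scaling is
#' log-normal.
#'
#' @param n_genes Total number of genes (includes markers and housekeeping).
#' @param cells_per_group Cells in each group.
#' @param n_groups Number of cell subpopulations (2 or 3).
#' @param marker_frac Fraction of genes acting as group markers, in (0, 0.5).
#' @param effect_log2fc Marker shift in log2 units (default 2: 4-fold).
#' @param dropout_midpoint log2 mean at which dropout probability is 50%.
#' @param n_housekeeping Number of housekeeping genes.
#' @param mean_log2,sd_log2 Distribution of gene-level log2 base means.
#' @param phi0,phi1 Dispersion model phi(mu) = phi0 + phi1 / mu.
#' @param lib_sd Standard deviation (log scale) of per-cell library factors.
#' @param seed Integer seed; regeneration from the recorded parameters is
#'   bitwise identical.
#' @return An object of class `sc_sim`: `counts` (integer matrix, genes x
#'   cells), `true_labels` (named, 1..n_groups), `marker_genes`,
#'   `housekeeping_genes`, `params` (all arguments incl. seed).
#' @export
simulate_populations <- function(n_genes = 2000L, cells_per_group = 50L,
                                 n_groups = 2L, marker_frac = 0.05,
                                 effect_log2fc = 2, dropout_midpoint = 2,
                                 n_housekeeping = 20L,
                                 mean_log2 = 3, sd_log2 = 1.5,
                                 phi0 = 0.1, phi1 = 2, lib_sd = 0.15,
                                 seed = 1L) {
  if (n_genes < 50 || cells_per_group < 2) abort("simulation too small")
  if (!n_groups %in% 2:3) abort("`n_groups` must be 2 or 3")
  if (marker_frac <= 0 || marker_frac >= 0.5) abort("`marker_frac` must be in (0, 0.5)")
  if (effect_log2fc < 0) abort("`effect_log2fc` must be >= 0")
  params <- list(n_genes = n_genes, cells_per_group = cells_per_group,
                 n_groups = n_groups, marker_frac = marker_frac,
                 effect_log2fc = effect_log2fc,
                 dropout_midpoint = dropout_midpoint,
                 n_housekeeping = n_housekeeping, mean_log2 = mean_log2,
                 sd_log2 = sd_log2, phi0 = phi0, phi1 = phi1,
                 lib_sd = lib_sd, seed = seed)
  set.seed(seed)

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  n_cells <- cells_per_group * n_groups
  cell_ids <- sprintf("cell%03d", seq_len(n_cells))
  labels <- rep(seq_len(n_groups), each = cells_per_group)

  log2_mu <- rnorm(n_genes, mean_log2, sd_log2)

  # housekeeping: high uniform expression, no dropout, never markers
  hk_idx <- utils::tail(order(log2_mu), n_housekeeping)
  log2_mu[hk_idx] <- rnorm(n_housekeeping, mean_log2 + 3, 0.25)

  # markers drawn from the central band of base expression
  n_markers <- round(marker_frac * n_genes)
  candidates <- setdiff(order(abs(log2_mu - median(log2_mu))), hk_idx)
  marker_idx <- sort(sample(head(candidates, max(2 * n_markers, n_markers)),
                            n_markers))
  direction <- rep(c(1, -1), length.out = n_markers)
  # two groups: markers perturb the second group (reference vs shifted);
  # three groups: markers are spread over all groups so the groups are
  # mutually equidistant and no merge is privileged at too-small ranks
  marker_group <- if (n_groups == 2) {
    rep(2L, n_markers)
  } else {
    rep(seq_len(n_groups), length.out = n_markers)
  }

  # per-group log2 means
  group_log2 <- matrix(log2_mu, n_genes, n_groups)
  for (j in seq_len(n_markers)) {
    g <- marker_group[j]
    group_log2[marker_idx[j], g] <-
      group_log2[marker_idx[j], g] + direction[j] * effect_log2fc
  }

  lib <- exp(rnorm(n_cells, 0, lib_sd))
  mu <- 2^group_log2[, labels, drop = FALSE] *
    matrix(lib, n_genes, n_cells, byrow = TRUE)

  phi <- phi0 + phi1 / mu
  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / phi),
                   n_genes, n_cells)

  p_drop <- stats::plogis(-(log2(mu + 1) - dropout_midpoint))
  p_drop[hk_idx, ] <- 0
  keep <- matrix(rbinom(n_genes * n_cells, 1, 1 - p_drop), n_genes, n_cells)
  counts <- counts * keep
  dimnames(counts) <- list(gene_ids, cell_ids)
  storage.mode(counts) <- "integer"

  marker_genes <- gene_ids[marker_idx]
  non_marker <- counts[-marker_idx, , drop = FALSE]
  survive <- mean(rowMeans(non_marker == 0) <= 0.7)
  if (survive < 0.8) {
    warn(sprintf(paste("only %.0f%% of non-marker genes would survive the",
                       "default gene filter; consider a lower dropout",
                       "midpoint"), 100 * survive))
  }

  structure(list(counts = counts,
                 true_labels = setNames(labels, cell_ids),
                 marker_genes = marker_genes,
                 marker_direction = setNames(direction, marker_genes),
                 housekeeping_genes = gene_ids[hk_idx],
                 params = params),
            class = "sc_sim")
}

#' @export
print.sc_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic scRNA-Seq dataset: %d genes x %d cells, %d groups (seed %d)\n",
              nrow(x$counts), ncol(x$counts), p$n_groups, p$seed))
  cat(sprintf("  %d marker genes (|log2FC| = %g), %d housekeeping genes\n",
              length(x$marker_genes), p$effect_log2fc,
              length(x$housekeeping_genes)))
  invisible(x)
}

#' Simulate a PPI network with a planted module
#'
#' Background interactions follow an Erdos-Renyi model; the planted module
#' is a random subset wired with a random spanning tree (guaranteeing
#' connectedness) plus dense extra edges. Vertex names default to the
#' `g%04d` scheme of [simulate_populations()], so the two fixtures share a
#' namespace.
#'
#' @param n_nodes Number of genes in the network.
#' @param edge_prob Background edge probability.
#' @param planted_module_size Size of the planted connected module.
#' @param within_prob Extra edge probability inside the planted module.
#' @param node_names Optional vertex names (length `n_nodes`).
#' @param seed Integer seed.
#' @return A list of class `ppi_sim`: `graph` (igraph), `planted_module`
#'   (character), `params`.
#' @export
simulate_ppi <- function(n_nodes = 200L, edge_prob = 0.02,
                         planted_module_size = 12L, within_prob = 0.4,
                         node_names = NULL, seed = 1L) {
  if (planted_module_size > n_nodes) {
    abort("`planted_module_size` must be <= `n_nodes`")
  }
  params <- list(n_nodes = n_nodes, edge_prob = edge_prob,
                 planted_module_size = planted_module_size,
                 within_prob = within_prob, seed = seed)
  set.seed(seed)
  if (is.null(node_names)) node_names <- sprintf("g%04d", seq_len(n_nodes))
  g <- igraph::sample_gnp(n_nodes, edge_prob, directed = FALSE)
  planted <- sort(sample(n_nodes, planted_module_size))
  # spanning tree over the planted members keeps the module connected
  perm <- sample(planted)
  tree_edges <- cbind(perm[-length(perm)], perm[-1])
  extra <- t(utils::combn(planted, 2))
  extra <- extra[runif(nrow(extra)) < within_prob, , drop = FALSE]
  g <- igraph::add_edges(g, t(rbind(tree_edges, extra)))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- node_names
  structure(list(graph = g, planted_module = node_names[planted],
                 params = params),
            class = "ppi_sim")
}
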