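#' Read a protein-protein interaction network
#'
#' Edge-list input is a two-column TSV of gene identifier pairs (header
#' optional, detected); GraphML input is read as-is. The graph is made
#' simple and undirected: self-loops and duplicate edges are dropped. Gene
#' identifiers must share the expression matrix's namespace; no mapping is
#' performed.
#'
#' @param path Path to a `.graphml` file or an edge-list TSV.
#' @return An undirected simple `igraph` with vertex `name` attributes.
#' @export
read_ppi <- function(path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    first <- readr::read_lines(path, n_max = 1)
    has_header <- !grepl("\t", first) ||
      any(grepl("gene|node|from|to|source|target",
                strsplit(first, "\t")[[1]], ignore.case = TRUE))
    edges <- readr::read_tsv(path, col_names = has_header,
                             show_col_types = FALSE, progress = FALSE)
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  }
  igraph::simplify(igraph::as_undirected(g))
}

#' Per-gene Welch t-statistics between two sample groups
#'
#' Expression is log2(x + 1)-transformed, then each gene gets the Welch
#' unequal-variance t-statistic of (second group - first group), groups
#' taken in sorted label order. Positive t means higher expression in the
#' second group. These statistics weight the network vertices for module
#' detection.
#'
#' @param m Expression matrix, genes x samples.
#' @param labels Two-group label vector, one per sample; each group needs
#'   >= 2 samples.
#' @return A tibble: `gene_id`, `t`.
#' @export
node_statistics <- function(m, labels) {
  validate_expression_matrix(m)
  if (length(labels) != ncol(m)) abort("one label per sample required")
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2) abort("exactly 2 groups required")
  labels <- as.character(labels)
  idx1 <- labels == groups[1]
  idx2 <- labels == groups[2]
  if (sum(idx1) < 2 || sum(idx2) < 2) {
    abort("each group needs at least 2 samples for a Welch t-statistic")
  }
  x <- log2(m + 1)
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  diff <- m2 - m1
  t <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) / 1e-12), diff / se)
  tibble::tibble(gene_id = rownames(m), t = unname(t))
}

# adjacency list of integer neighbor indices, plus node weights |t|
module_graph_context <- function(g, stats) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) abort("the PPI graph must have vertex names")
  t_map <- setNames(stats$t, stats$gene_id)
  t_vec <- unname(t_map[nodes])
  t_vec[is.na(t_vec)] <- 0 # nodes without a statistic carry weight 0
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  list(nodes = nodes, adj = adj, abst = abs(t_vec), t = t_vec)
}

# greedy expansion maximizing s(M) = sum(|t| in M) / sqrt(|M|)
grow_module <- function(adj, abst, seed_idx, max_size) {
  n <- length(adj)
  in_mod <- logical(n)
  in_mod[seed_idx] <- TRUE
  members <- seed_idx
  sum_t <- abst[seed_idx]
  score <- sum_t
  boundary <- setdiff(adj[[seed_idx]], seed_idx)
  while (length(members) < max_size && length(boundary) > 0) {
    best <- boundary[which.max(abst[boundary])]
    new_score <- (sum_t + abst[best]) / sqrt(length(members) + 1)
    if (new_score <= score) break
    in_mod[best] <- TRUE
    members <- c(members, best)
    sum_t <- sum_t + abst[best]
    score <- new_score
    boundary <- boundary[boundary != best]
    nb <- adj[[best]]
    boundary <- union(boundary, nb[!in_mod[nb]])
  }
  list(members = members, score = score)
}

#' Grow a module around a seed gene by greedy expansion
#'
#' Starting from the seed, the neighbor maximizing the module score
#' s(M) = (sum of member |t|) / sqrt(|M|) is added repeatedly; growth stops
#' when no neighbor strictly increases the score or the module reaches
#' `max_size`. The result is connected by construction and contains the
#' seed. Nodes missing from `stats` carry weight 0.
#'
#' @param g Undirected `igraph` with vertex names.
#' @param stats Tibble from [node_statistics()] (`gene_id`, `t`).
#' @param seed_gene Seed gene identifier; must be a graph vertex.
#' @param max_size Upper bound on module size.
#' @return A list of class `ppi_module`: `seed_gene`, `members`, `score`,
#'   `p_value` (`NA` until [module_pvalue()]), `hub`.
#' @export
seeded_module_search <- function(g, stats, seed_gene, max_size = 50L) {
  ctx <- module_graph_context(g, stats)
  seed_idx <- match(seed_gene, ctx$nodes)
  if (is.na(seed_idx)) {
    near <- ctx$nodes[startsWith(tolower(ctx$nodes),
                                 tolower(substr(seed_gene, 1, 3)))]
    abort(sprintf("seed gene `%s` is not in the graph%s", seed_gene,
                  if (length(near) > 0)
                    sprintf(" (nearest matches: %s)",
                            paste(head(near, 3), collapse = ", "))
                  else ""))
  }
  grown <- grow_module(ctx$adj, ctx$abst, seed_idx, max_size)
  finalize_module(g, ctx, grown, seed_gene)
}

finalize_module <- function(g, ctx, grown, seed_gene) {
  members <- ctx$nodes[grown$members]
  sub <- igraph::induced_subgraph(g, members)
  deg <- igraph::degree(sub)
  hub <- igraph::V(sub)$name[which.max(deg)]
  structure(list(seed_gene = seed_gene, members = members,
                 score = grown$score, p_value = NA_real_, hub = hub),
            class = "ppi_module")
}

#' @export
print.ppi_module <- function(x, ...) {
  cat(sprintf("PPI module seeded at %s: %d genes, score %.3f, hub %s",
              x$seed_gene, length(x$members), x$score, x$hub))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Monte Carlo permutation p-value for a module
#'
#' The null distribution re-grows a module from the same seed after each of
#' `n_perm` random permutations of the t-statistics across all nodes; the
#' p-value is (1 + #\{null score >= observed score\}) / (n_perm + 1), so it is
#' never below 1 / (n_perm + 1).
#'
#' @inheritParams seeded_module_search
#' @param module A `ppi_module` from [seeded_module_search()].
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed for the permutations.
#' @return The module with its `p_value` filled in.
#' @export
module_pvalue <- function(g, stats, module, n_perm = 1000L, seed = 1L,
                          max_size = 50L) {
  ctx <- module_graph_context(g, stats)
  seed_idx <- match(module$seed_gene, ctx$nodes)
  if (is.na(seed_idx)) abort("module seed gene not in graph")
  set.seed(seed)
  null_ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(ctx$abst)
    null_score <- grow_module(ctx$adj, perm, seed_idx, max_size)$score
    if (null_score >= module$score) null_ge <- null_ge + 1L
  }
  module$p_value <- (1 + null_ge) / (n_perm + 1)
  module
}

#' Detect differentially expressed PPI modules from seed genes
#'
#' Grows one module per seed gene present in the graph, scores each by
#' Monte Carlo permutation, deduplicates modules sharing more than half of
#' the smaller module's members (keeping the lower p-value), and returns
#' the `n_top` modules by ascending p-value (ties by descending score).
#' Feature genes from [rank_genes()] are the intended seeds.
#'
#' @inheritParams module_pvalue
#' @param seed_genes Character vector of seed gene identifiers (e.g. the
#'   top-500 feature genes); seeds absent from the graph are skipped.
#' @param n_top Number of modules to return.
#' @return An object of class `module_set`: a list of `ppi_module`s plus
#'   attributes; use [tidy.module_set()] for the summary table and
#'   [module_members()] for per-gene rows.
#' @export
detect_modules <- function(g, stats, seed_genes, n_top = 5L, n_perm = 1000L,
                           seed = 1L, max_size = 50L) {
  if (length(seed_genes) == 0) abort("`seed_genes` is empty")
  ctx <- module_graph_context(g, stats)
  present <- seed_genes[seed_genes %in% ctx$nodes]
  if (length(present) == 0) abort("no seed gene is present in the graph")

  grown <- lapply(present, function(sg) {
    grow_module(ctx$adj, ctx$abst, match(sg, ctx$nodes), max_size)
  })
  keys <- vapply(grown, function(x) paste(sort(x$members), collapse = ","), "")
  first <- !duplicated(keys)
  modules <- purrr::map2(grown[first], present[first],
                         function(gr, sg) finalize_module(g, ctx, gr, sg))

  modules <- purrr::imap(modules, function(mod, i) {
    module_pvalue(g, stats, mod, n_perm = n_perm, seed = seed + i,
                  max_size = max_size)
  })

  ord <- order(vapply(modules, function(x) x$p_value, 0),
               -vapply(modules, function(x) x$score, 0))
  modules <- modules[ord]
  kept <- list()
  for (mod in modules) {
    overlaps <- any(vapply(kept, function(k) {
      shared <- length(intersect(k$members, mod$members))
      shared > 0.5 * min(length(k$members), length(mod$members))
    }, TRUE))
    if (!overlaps) kept[[length(kept) + 1]] <- mod
  }
  kept <- head(kept, n_top)
  structure(kept, class = "module_set",
            stats = stats, n_perm = as.integer(n_perm),
            seed = as.integer(seed))
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("%d PPI module(s):\n", length(x)))
  print(tidy(x))
  invisible(x)
}

#' Summarize a set of detected modules
#'
#' @param x A `module_set` from [detect_modules()].
#' @param ... Unused.
#' @return A tibble: `seed_gene`, `size`, `score`, `p_value`, `hub`.
#' @export
tidy.module_set <- function(x, ...) {
  purrr::map_dfr(x, function(mod) {
    tibble::tibble(seed_gene = mod$seed_gene, size = length(mod$members),
                   score = mod$score, p_value = mod$p_value, hub = mod$hub)
  })
}

#' Per-gene membership table for detected modules
#'
#' @param x A `module_set`.
#' @return A tibble: `module` (index), `seed_gene`, `gene_id`, `t`,
#'   `is_seed`, `is_hub`.
#' @export
module_members <- function(x) {
  stats <- attr(x, "stats")
  t_map <- setNames(stats$t, stats$gene_id)
  purrr::imap_dfr(x, function(mod, i) {
    tibble::tibble(module = i, seed_gene = mod$seed_gene,
                   gene_id = mod$members,
                   t = unname(t_map[mod$members]),
                   is_seed = mod$members == mod$seed_gene,
                   is_hub = mod$members == mod$hub)
  })
}
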