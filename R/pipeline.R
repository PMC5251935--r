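pipeline_defaults <- function() {
  list(counts = NULL, row_ids = NULL, col_ids = NULL,
       lengths = NULL, housekeeping = NULL,
       hk_threshold = 4, max_zero_fraction = 0.7, normalize = TRUE,
       k = NULL, k_range = 2:5, n_runs = 30L, seed = 1L,
       top_n = 500L,
       graph = NULL, n_top = 5L, n_perm = 1000L, max_size = 50L,
       tsne_perplexity = 30,
       out_dir = NULL, quiet = FALSE)
}

read_lines_if_path <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    readr::read_lines(x)
  } else {
    x
  }
}

#' Run the full heterogeneity-detection pipeline
#'
#' Executes preprocess -> consensus NMF clustering (fixed `k`, or rank
#' selection over `k_range`) -> D-score feature ranking -> optional seeded
#' PPI module detection, and writes results plus a JSON run manifest
#' recording every parameter, seed and input digest, so a run can be
#' replayed bitwise via [replay_manifest()]. When more than two
#' subpopulations are found, the two with the closest centroids on the
#' correlation t-SNE map are selected for ranking and module detection.
#'
#' @param config Named list overriding the defaults in the pipeline
#'   configuration (see Details), or a path to a YAML file of the same.
#'   Required: `counts` (path or matrix). Optional: `lengths`,
#'   `housekeeping`, `k`/`k_range`, `n_runs`, `seed`, `top_n`, `graph`,
#'   `n_perm`, `n_top`, `out_dir`, ...
#' @return A list of class `scnmf_run`: `matrix`, `preprocess_log`,
#'   `clustering`, `rank_selection` (or NULL), `dscores`, `pair` (groups
#'   compared), `modules` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml_load_config(config)
  }
  unknown <- setdiff(names(config), names(pipeline_defaults()))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(pipeline_defaults(), config)
  if (is.null(cfg$counts)) abort("config must name a counts matrix")
  say <- function(stage, ...) {
    if (!isTRUE(cfg$quiet)) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  digests <- list()
  for (f in c("counts", "lengths", "graph", "housekeeping")) {
    if (is.character(cfg[[f]]) && length(cfg[[f]]) == 1 && file.exists(cfg[[f]])) {
      digests[[f]] <- unname(tools::md5sum(cfg[[f]]))
    }
  }

  # --- preprocess -----------------------------------------------------
  counts <- if (is.matrix(cfg$counts)) cfg$counts else
    read_expression(cfg$counts, cfg$row_ids, cfg$col_ids)
  lengths <- if (is.character(cfg$lengths)) read_gene_lengths(cfg$lengths)
             else cfg$lengths
  housekeeping <- read_lines_if_path(cfg$housekeeping)
  pre <- clock("preprocess", preprocess_counts(
    counts, lengths = lengths, housekeeping = housekeeping,
    hk_threshold = cfg$hk_threshold,
    max_zero_fraction = cfg$max_zero_fraction, normalize = cfg$normalize))
  A <- pre$values
  say("preprocess", "%d genes x %d samples retained", nrow(A), ncol(A))

  # --- clustering -----------------------------------------------------
  rank_sel <- NULL
  if (is.null(cfg$k)) {
    rank_sel <- clock("cluster", select_rank(A, k_range = cfg$k_range,
                                             n_runs = cfg$n_runs,
                                             base_seed = cfg$seed))
    clustering <- rank_sel$results[[as.character(rank_sel$best_k)]]
    say("cluster", "chose k = %d (cophenetic %.3f)", rank_sel$best_k,
        clustering$cophenetic)
  } else {
    clustering <- clock("cluster", consensus_cluster(A, cfg$k,
                                                     n_runs = cfg$n_runs,
                                                     base_seed = cfg$seed))
    say("cluster", "k = %d, cophenetic %.3f", cfg$k, clustering$cophenetic)
  }
  labels <- clustering$labels

  # --- closest pair + feature ranking --------------------------------
  if (clustering$k > 2) {
    coords <- embed_tsne(A, seed = cfg$seed,
                         perplexity = min(cfg$tsne_perplexity,
                                          floor((ncol(A) - 2) / 3)))
    pair_tbl <- closest_pair(coords, labels)
    pair <- c(pair_tbl$group_a, pair_tbl$group_b)
    say("rank", "closest pair of groups: %s vs %s", pair[1], pair[2])
  } else {
    pair <- c("1", "2")
  }
  in_pair <- labels %in% as.integer(pair)
  A2 <- A[, in_pair, drop = FALSE]
  A2 <- A2[rowSums(A2) > 0, , drop = FALSE]
  pair_labels <- labels[in_pair]
  fit2 <- clock("rank", nmf_fit(A2, k = 2, seed = cfg$seed))
  dscores <- rank_genes(fit2, top_n = cfg$top_n)
  say("rank", "lambda = %.3f; top gene %s", dscores$lambda[1],
      dscores$gene_id[1])

  # --- module detection ----------------------------------------------
  modules <- NULL
  if (!is.null(cfg$graph)) {
    g <- if (is.character(cfg$graph)) read_ppi(cfg$graph) else cfg$graph
    stats <- node_statistics(A2, pair_labels)
    seeds <- dscores$gene_id[dscores$is_feature]
    modules <- clock("modules", detect_modules(
      g, stats, seeds, n_top = cfg$n_top, n_perm = cfg$n_perm,
      seed = cfg$seed, max_size = cfg$max_size))
    say("modules", "%d module(s), best p = %.4g", length(modules),
        min(tidy(modules)$p_value))
  }

  serializable <- !vapply(cfg, is.null, TRUE) &
    !vapply(cfg, is.matrix, TRUE) &
    !vapply(cfg, inherits, TRUE, "igraph")
  manifest <- list(
    tool = "scnmf", version = as.character(packageVersion("scnmf")),
    config = cfg[serializable],
    seed = cfg$seed, input_digests = digests, timings = as.list(timings))

  run <- structure(list(matrix = A, preprocess_log = pre$log,
                        clustering = clustering, rank_selection = rank_sel,
                        dscores = dscores, pair = pair, modules = modules,
                        manifest = manifest),
                   class = "scnmf_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_expression(run$matrix, p("matrix.tsv"))
  readr::write_tsv(tidy(run$clustering), p("labels.tsv"), progress = FALSE)
  write_expression(run$clustering$consensus, p("consensus.tsv"))
  if (!is.null(run$rank_selection)) {
    readr::write_tsv(tidy(run$rank_selection), p("cophenetic.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(run$dscores, p("dscores.tsv"), progress = FALSE)
  if (!is.null(run$modules)) {
    readr::write_tsv(tidy(run$modules), p("modules.tsv"), progress = FALSE)
    readr::write_tsv(module_members(run$modules), p("module_members.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with the configuration recorded in a
#' `manifest.json`; with unchanged inputs the outputs are bitwise
#' identical.
#'
#' @param manifest_path Path to a `manifest.json` written by [run_pipeline()].
#' @param out_dir Output directory for the replay (defaults to the
#'   manifest's).
#' @return The `scnmf_run` of the replay.
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg$k_range <- as.integer(cfg$k_range)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(cfg)
}

yaml_load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading a YAML configuration requires the yaml package")
  }
  yaml::read_yaml(path)
}

#' @export
print.scnmf_run <- function(x, ...) {
  cat("scnmf pipeline run\n")
  print(x$preprocess_log)
  print(x$clustering)
  cat(sprintf("  compared groups: %s vs %s\n", x$pair[1], x$pair[2]))
  cat(sprintf("  top feature gene: %s (D = %.3f)\n",
              x$dscores$gene_id[1], x$dscores$d_score[1]))
  if (!is.null(x$modules)) print(x$modules)
  invisible(x)
}
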