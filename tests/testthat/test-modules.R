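make_stats <- function(nodes, t) tibble::tibble(gene_id = nodes, t = t)

star_graph <- function() {
  igraph::graph_from_edgelist(
    cbind("hub", paste0("leaf", 1:4)), directed = FALSE)
}

test_that("node statistics are Welch t-statistics on log2(x + 1)", {
  m <- named_matrix(rep(c(2, 2, 2, 2), each = 3), 3, 4)
  labs <- c(1, 1, 2, 2)
  expect_equal(node_statistics(m, labs)$t, rep(0, 3))

  m2 <- named_matrix(0, 2, 6)
  m2[1, 4:6] <- c(8, 9, 10) # expressed only in group 2
  m2[2, ] <- c(5, 6, 7, 5, 6, 7)
  t2 <- node_statistics(m2, rep(1:2, each = 3))$t
  expect_gt(t2[1], 0)

  set.seed(3)
  m3 <- named_matrix(rpois(60, 20), 5, 12)
  storage.mode(m3) <- "double"
  labs3 <- rep(c("a", "b"), each = 6)
  ours <- node_statistics(m3, labs3)$t
  oracle <- vapply(seq_len(5), function(i) {
    x <- log2(m3[i, ] + 1)
    unname(t.test(x[labs3 == "b"], x[labs3 == "a"])$statistic)
  }, 0)
  expect_equal(ours, oracle, tolerance = 1e-10)

  expect_error(node_statistics(m3, rep(c("a", "b"), times = c(1, 11))),
               "at least 2")
})

test_that("greedy expansion follows the size-normalized score", {
  g <- star_graph()
  nodes <- igraph::V(g)$name
  stats <- make_stats(nodes, c(2, 5, 0, 0, 0)) # hub t=2, leaf1 t=5
  mod <- seeded_module_search(g, stats, "hub")
  # adding leaf1: (2+5)/sqrt(2) = 4.95 > 2; further zero leaves only dilute
  expect_setequal(mod$members, c("hub", "leaf1"))
  expect_equal(mod$score, 7 / sqrt(2))
  expect_equal(mod$hub, "hub")

  zero <- make_stats(nodes, rep(0, 5))
  expect_equal(seeded_module_search(g, zero, "hub")$members, "hub")

  expect_error(seeded_module_search(g, stats, "nothere"), "not in the graph")
})

test_that("module scores ignore the sign of the t-statistics", {
  sim <- simulate_ppi(n_nodes = 60, edge_prob = 0.05, planted_module_size = 8,
                      seed = 2)
  set.seed(4)
  t_vals <- rnorm(60)
  s1 <- seeded_module_search(sim$graph, make_stats(igraph::V(sim$graph)$name, t_vals),
                             sim$planted_module[1])
  s2 <- seeded_module_search(sim$graph, make_stats(igraph::V(sim$graph)$name, -t_vals),
                             sim$planted_module[1])
  expect_identical(s1$members, s2$members)
  expect_equal(s1$score, s2$score)
})

test_that("permutation p-values respect the add-one bound and null", {
  g <- star_graph()
  nodes <- igraph::V(g)$name
  flat <- make_stats(nodes, rep(1, 5))
  mod <- seeded_module_search(g, flat, "hub")
  mod <- module_pvalue(g, flat, mod, n_perm = 200, seed = 1)
  expect_gt(mod$p_value, 0.5) # exchangeable weights: observed is typical
  expect_gte(mod$p_value, 1 / 201)
})

test_that("an extreme planted module is recovered at the minimal p-value", {
  sim <- simulate_ppi(n_nodes = 120, edge_prob = 0.03,
                      planted_module_size = 10, seed = 6)
  nodes <- igraph::V(sim$graph)$name
  t_vals <- setNames(rnorm(length(nodes), 0, 0.3), nodes)
  t_vals[sim$planted_module] <- 12 + rnorm(10, 0, 0.5)
  stats <- make_stats(nodes, unname(t_vals[nodes]))

  mods <- detect_modules(sim$graph, stats, seed_genes = sim$planted_module,
                         n_top = 3, n_perm = 99, seed = 3)
  best <- mods[[1]]
  overlap <- length(intersect(best$members, sim$planted_module)) /
    length(sim$planted_module)
  expect_gte(overlap, 0.8)
  expect_equal(best$p_value, 1 / 100)

  # every reported module is connected and contains its seed
  for (mod in mods) {
    sub <- igraph::induced_subgraph(sim$graph, mod$members)
    expect_true(igraph::is_connected(sub))
    expect_true(mod$seed_gene %in% mod$members)
  }
})

test_that("detect_modules returns what it finds, deterministically", {
  sim <- simulate_ppi(n_nodes = 50, edge_prob = 0.04,
                      planted_module_size = 6, seed = 9)
  nodes <- igraph::V(sim$graph)$name
  set.seed(10)
  stats <- make_stats(nodes, rnorm(50))
  m1 <- detect_modules(sim$graph, stats, seed_genes = nodes[1:8],
                       n_top = 20, n_perm = 49, seed = 7)
  expect_lte(length(m1), 8) # no padding beyond distinct modules
  m2 <- detect_modules(sim$graph, stats, seed_genes = nodes[1:8],
                       n_top = 20, n_perm = 49, seed = 7)
  expect_identical(tidy(m1), tidy(m2))
  expect_error(detect_modules(sim$graph, stats, "absent"), "seed gene")

  members <- module_members(m1)
  expect_true(all(c("module", "gene_id", "t", "is_seed", "is_hub") %in%
                  names(members)))
})

test_that("PPI fixtures are reproducible and honor edge_prob = 0", {
  s1 <- simulate_ppi(seed = 5)
  s2 <- simulate_ppi(seed = 5)
  expect_true(igraph::identical_graphs(s1$graph, s2$graph))

  s0 <- simulate_ppi(n_nodes = 30, edge_prob = 0, planted_module_size = 5,
                     seed = 3)
  deg <- igraph::degree(s0$graph)
  expect_true(all(deg[setdiff(igraph::V(s0$graph)$name,
                              s0$planted_module)] == 0))
  sub <- igraph::induced_subgraph(s0$graph, s0$planted_module)
  expect_true(igraph::is_connected(sub))
})

test_that("edge lists round-trip through read_ppi", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(from = c("a", "b", "a", "a"),
                                  to = c("b", "c", "a", "b")), path)
  g <- read_ppi(path)
  expect_equal(sort(igraph::V(g)$name), c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 2) # self-loop and duplicate dropped
})
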