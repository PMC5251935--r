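test_that("gene lengths are the union of merged exon intervals", {
  exons <- tibble::tibble(
    gene_id = c("a", "a", "b", "b", "c"),
    start = c(1, 201, 1, 51, 10),
    end = c(100, 300, 100, 150, 10))
  len <- gene_lengths_from_exons(exons)
  expect_equal(len$length[len$gene_id == "a"], 200L) # disjoint exons sum
  expect_equal(len$length[len$gene_id == "b"], 150L) # overlap counted once
  expect_equal(len$length[len$gene_id == "c"], 1L)   # 1-based inclusive

  expect_error(gene_lengths_from_exons(
    tibble::tibble(gene_id = "a", start = 10, end = 5)), "reversed")
  expect_error(gene_lengths_from_exons(exons, genes = c("a", "zz")), "zz")
})

test_that("FPKM follows counts * 1e9 / (length * sample total)", {
  counts <- named_matrix(c(10, 0), 2, 1)
  counts[2, 1] <- 1e6 - 10 # sample total 1e6
  lengths <- setNames(c(1000, 1000), rownames(counts))
  fpkm <- compute_fpkm(counts, lengths)
  expect_equal(fpkm[1, 1], 10)
  expect_equal(compute_fpkm(named_matrix(c(0, 5, 3, 2), 2, 2),
                            setNames(c(100, 200), c("g001", "g002")))[1, 1], 0)

  # 2x2 case frozen from hand evaluation of the formula
  counts2 <- named_matrix(c(10, 30, 20, 40), 2, 2)
  lengths2 <- setNames(c(500, 2000), rownames(counts2))
  fpkm2 <- compute_fpkm(counts2, lengths2)
  expect_equal(unname(fpkm2),
               matrix(c(10e9 / (500 * 40), 30e9 / (2000 * 40),
                        20e9 / (500 * 60), 40e9 / (2000 * 60)), 2, 2))

  zero_col <- named_matrix(c(1, 1, 0, 0), 2, 2)
  expect_error(compute_fpkm(zero_col, lengths2), "s002")
  expect_error(compute_fpkm(counts2, setNames(500, "g001")), "g002")
})

test_that("FPKM is equivariant under gene/sample permutation", {
  counts <- random_positive_matrix(8, 5, seed = 11)
  storage.mode(counts) <- "double"
  lengths <- setNames(sample(200:2000, 8), rownames(counts))
  fpkm <- compute_fpkm(counts, lengths)
  pg <- sample(nrow(counts)); ps <- sample(ncol(counts))
  fpkm_perm <- compute_fpkm(counts[pg, ps], lengths)
  expect_equal(fpkm_perm, fpkm[pg, ps])
})

test_that("size factors are median-of-ratios with geometric mean 1", {
  m1 <- named_matrix(c(1, 2, 3, 2, 4, 6), 3, 2)
  norm1 <- normalize_size_factors(m1)
  expect_equal(unname(norm1$size_factors), c(1 / sqrt(2), sqrt(2)))

  m2 <- named_matrix(rep(c(1, 5, 9), 3), 3, 3)
  norm2 <- normalize_size_factors(m2)
  expect_equal(unname(norm2$size_factors), rep(1, 3))
  expect_equal(norm2$values, m2)

  m3 <- random_positive_matrix(9, 4, seed = 5)
  expect_equal(unname(normalize_size_factors(m3)$size_factors),
               unname(size_factor_oracle(m3)))

  # cross-check against DESeq2 (equal up to its missing geomean-1 rescale)
  skip_if_not_installed("DESeq2")
  counts <- random_positive_matrix(50, 6, seed = 9)
  counts[] <- round(counts * 10)
  counts[counts == 0] <- 1
  ours <- normalize_size_factors(counts)$size_factors
  deseq <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(deseq / exp(mean(log(deseq)))),
               tolerance = 1e-10)
})

test_that("renormalizing an already normalized matrix gives unit factors", {
  m <- random_positive_matrix(20, 6, seed = 3)
  norm <- normalize_size_factors(m)
  again <- normalize_size_factors(norm$values)
  expect_equal(unname(again$size_factors), rep(1, 6), tolerance = 1e-10)
})

test_that("size factors require a gene positive in all samples", {
  m <- named_matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(normalize_size_factors(m), "pseudocount")
})

test_that("housekeeping sample filter applies the geometric-mean rule", {
  m <- named_matrix(c(4, 4, 2, 8, 5, 0, 1, 1), 2, 4)
  rownames(m) <- c("hk1", "hk2")
  kept <- filter_samples(m, c("hk1", "hk2"), threshold = 4)
  # geomeans: 4 (boundary, kept), 4 = sqrt(2*8) (kept), 0 (zero), 1
  expect_equal(colnames(kept), c("s001", "s002"))
  expect_error(filter_samples(m, "absent"), "housekeeping")
  expect_error(filter_samples(m, "hk1", threshold = -1), ">= 0")
})

test_that("gene filter drops genes unexpressed in over 70% of cells", {
  m <- named_matrix(1, 3, 10)
  m[1, 1:7] <- 0  # 0.70 exactly: kept
  m[2, 1:8] <- 0  # 0.80: removed
  kept <- filter_genes(m)
  expect_equal(rownames(kept), c("g001", "g003"))

  m4 <- named_matrix(1, 1, 4)
  m4[1, 1:3] <- 0 # 0.75 > 0.7: removed
  expect_warning(res <- filter_genes(m4), "every gene")
  expect_equal(nrow(res), 0)
})

test_that("filter survivors match a brute-force scan and are a fixed point", {
  sim <- small_sim(seed = 21)
  m <- sim$counts
  storage.mode(m) <- "double"
  f1 <- filter_genes(filter_samples(m, sim$housekeeping_genes))
  keep_samples <- vapply(seq_len(ncol(m)), function(j) {
    geometric_mean(m[sim$housekeeping_genes, j]) >= 4
  }, TRUE)
  ms <- m[, keep_samples, drop = FALSE]
  keep_genes <- vapply(seq_len(nrow(ms)), function(i) {
    sum(ms[i, ] == 0) / ncol(ms) <= 0.7
  }, TRUE)
  expect_equal(dim(f1), c(sum(keep_genes), sum(keep_samples)))

  f2 <- filter_genes(filter_samples(f1, sim$housekeeping_genes))
  expect_identical(f1, f2)
})

test_that("preprocess_counts logs stage dimensions consistently", {
  sim <- small_sim(seed = 4)
  pre <- preprocess_counts(sim$counts, housekeeping = sim$housekeeping_genes)
  expect_equal(pre$log$stage,
               c("input", "sample_filter", "gene_filter", "normalized"))
  expect_equal(dim(pre$values),
               c(pre$log$n_genes[4], pre$log$n_samples[4]),
               ignore_attr = TRUE)
  expect_equal(exp(mean(log(pre$size_factors))), 1, tolerance = 1e-12)
})
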