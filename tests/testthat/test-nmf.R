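test_that("KL divergence matches its closed form and conventions", {
  A <- random_positive_matrix(6, 4, seed = 1)
  expect_equal(kl_divergence(A, A), 0)
  expect_equal(kl_divergence(matrix(1), matrix(exp(1))), exp(1) - 2)

  # zero data entry contributes just the reconstruction term
  A0 <- matrix(c(0, 2), 1, 2)
  WH <- matrix(c(3, 2), 1, 2)
  expect_equal(kl_divergence(A0, WH), 3)

  expect_error(kl_divergence(matrix(-1), matrix(1)), "non-negative")
})

test_that("multiplicative updates have A = WH as a fixed point", {
  set.seed(42)
  W <- matrix(runif(12, 0.5, 2), 6, 2)
  H <- matrix(runif(8, 0.5, 2), 2, 4)
  A <- W %*% H
  expect_equal(nmf_update_h(W, H, A), H, tolerance = 1e-12)
  expect_equal(nmf_update_w(W, H, A), W, tolerance = 1e-12)
})

test_that("scalar updates reproduce the hand-evaluated 1x1 case", {
  A <- matrix(2); W <- matrix(1); H <- matrix(1)
  expect_equal(nmf_update_h(W, H, A), matrix(2))
  expect_equal(nmf_update_w(W, H, A), matrix(2))
})

test_that("alternating updates never increase the KL divergence", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:40, 1); m <- sample(5:15, 1); k <- sample(2:3, 1)
    A <- matrix(runif(n * m, 0.05, 5), n, m)
    W <- matrix(runif(n * k, 0.1, 1), n, k)
    H <- matrix(runif(k * m, 0.1, 1), k, m)
    kl <- kl_divergence(A, W %*% H)
    for (it in 1:40) {
      H <- nmf_update_h(W, H, A)
      W <- nmf_update_w(W, H, A)
      kl_new <- kl_divergence(A, W %*% H)
      expect_lte(kl_new, kl + 1e-8)
      kl <- kl_new
    }
    expect_true(all(W >= 0) && all(H >= 0))
  }
})

test_that("updates are equivariant under scaling of the data", {
  set.seed(7)
  A <- matrix(runif(50, 0.2, 4), 10, 5)
  W1 <- matrix(runif(20, 0.1, 1), 10, 2); H1 <- matrix(runif(10, 0.1, 1), 2, 5)
  W2 <- W1; H2 <- 3 * H1
  for (it in 1:20) {
    H1 <- nmf_update_h(W1, H1, A); W1 <- nmf_update_w(W1, H1, A)
    H2 <- nmf_update_h(W2, H2, 3 * A); W2 <- nmf_update_w(W2, H2, 3 * A)
  }
  expect_equal(W2 %*% H2, 3 * (W1 %*% H1), tolerance = 1e-9)
})

test_that("the compiled fit matches composing the R reference updates", {
  A <- random_positive_matrix(30, 8, seed = 13)
  fit <- nmf_fit(A, k = 2, seed = 5, max_iter = 25, tol = 0)
  set.seed(5)
  hi <- max(A)
  W <- matrix(runif(30 * 2, 1e-16, hi), 30, 2)
  H <- matrix(runif(2 * 8, 1e-16, hi), 2, 8)
  for (it in 1:25) {
    H <- nmf_update_h(W, H, A)
    W <- nmf_update_w(W, H, A)
  }
  expect_equal(unname(fit$W), unname(W), tolerance = 1e-10)
  expect_equal(unname(fit$H), unname(H), tolerance = 1e-10)
})

test_that("a rank-1 matrix is reconstructed essentially exactly", {
  set.seed(2)
  A <- outer(runif(20, 0.5, 2), runif(6, 0.5, 2))
  dimnames(A) <- list(sprintf("g%03d", 1:20), sprintf("s%03d", 1:6))
  fit <- nmf_fit(A, k = 1, seed = 3)
  expect_lt(fit$final_kl / sum(A), 1e-6)
})

test_that("fits are bitwise reproducible from the seed", {
  A <- random_positive_matrix(25, 10, seed = 8)
  f1 <- nmf_fit(A, k = 2, seed = 99)
  f2 <- nmf_fit(A, k = 2, seed = 99)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$divergence_trace, f2$divergence_trace)
})

test_that("the divergence trace is non-increasing", {
  A <- random_positive_matrix(40, 12, seed = 4)
  fit <- nmf_fit(A, k = 3, seed = 1)
  expect_true(all(diff(fit$divergence_trace) <= 1e-8))
})

test_that("fitting rejects all-zero rows and bad ranks", {
  A <- random_positive_matrix(10, 5, seed = 1)
  A[3, ] <- 0
  expect_error(nmf_fit(A, k = 2, seed = 1), "filter_genes")
  B <- random_positive_matrix(10, 5, seed = 2)
  expect_error(nmf_fit(B, k = 6, seed = 1), "min")
})

test_that("cluster assignment is the argmax of H with low-index ties", {
  H <- matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8), 2, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(assign_clusters(H), c(a = 1L, b = 1L, c = 2L))

  set.seed(31)
  Hr <- matrix(runif(40), 4, 10, dimnames = list(NULL, letters[1:10]))
  expect_equal(unname(assign_clusters(Hr)),
               vapply(seq_len(10), function(u) which.max(Hr[, u]), 0L))
})

test_that("tidy and glance expose loadings and fit statistics", {
  A <- random_positive_matrix(15, 6, seed = 6)
  fit <- nmf_fit(A, k = 2, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("gene_id", "loading_1", "loading_2"))
  expect_equal(td$loading_1, unname(fit$W[, 1]))
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_true(gl$final_kl >= 0)
})
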