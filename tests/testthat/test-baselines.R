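# Consensus clustering baseline, CDF-area selection, PCA embedding.

test_that("consensus matrix is block {0,1} on perfectly separated data", {
  fx <- make_separable_expr(n_genes = 10, n_per = 10, shift = 8, seed = 1)
  cr <- consensus_cluster(fx$x, k_range = 2:3, reps = 100, p_item = 0.8,
                          base = "kmeans", seed = 1)
  m2 <- cr$consensus[["k2"]]
  same <- outer(fx$labels, fx$labels, "==")
  expect_true(all(m2[same] == 1))
  expect_true(all(m2[!same] == 0))
  expect_equal(m2, t(m2))
  expect_true(all(diag(m2) == 1))
  expect_true(all(m2 >= 0 & m2 <= 1))
  expect_equal(concordance(cr$assignments[["k2"]], fx$labels)$ari, 1)
})

test_that("a single full-sample rep reproduces one k-means partition", {
  fx <- make_separable_expr(n_genes = 8, n_per = 8, shift = 6, seed = 2)
  cr <- consensus_cluster(fx$x, k_range = 2:3, reps = 1, p_item = 1,
                          base = "kmeans", seed = 3)
  m2 <- cr$consensus[["k2"]]
  expect_true(all(m2 %in% c(0, 1)))
  km <- kmeans_cluster(t(fx$x), 2, seed = 99)
  expect_equal(m2, outer(km, km, function(a, b) (a == b) + 0),
               ignore_attr = TRUE)
})

test_that("the hclust-Pearson base also resolves clean structure", {
  # Pearson distance is location-free per sample, so the groups must
  # differ in expression *pattern*: disjoint up-regulated gene blocks
  set.seed(4)
  x <- matrix(rnorm(16 * 20, sd = 0.5), 16, 20)
  labels <- rep(1:2, each = 10)
  x[1:8, labels == 1] <- x[1:8, labels == 1] + 8
  x[9:16, labels == 2] <- x[9:16, labels == 2] + 8
  dimnames(x) <- list(paste0("g", 1:16), sprintf("S%02d", 1:20))
  cr <- consensus_cluster(x, k_range = 2:4, reps = 50, p_item = 0.8,
                          base = "hclust", seed = 1)
  expect_equal(concordance(cr$assignments[["k2"]], labels)$ari, 1)
})

test_that("consensus input validation", {
  fx <- make_separable_expr(n_genes = 5, n_per = 5, seed = 5)
  expect_error(consensus_cluster(fx$x, 2:3, reps = 0), "at least 1")
  expect_error(consensus_cluster(fx$x, 2:6, reps = 10, p_item = 0.3),
               "p_item too small")
  expect_error(consensus_cluster(fx$x, c(3, 2), reps = 10),
               "strictly increasing")
})

test_that("CDF areas match closed forms", {
  # fabricate consensus results with known value distributions
  fake <- function(values_by_k, n) {
    consensus <- lapply(values_by_k, function(v) {
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- v
      m <- m + t(m)
      diag(m) <- 1
      m
    })
    names(consensus) <- paste0("k", seq_along(consensus) + 1L)
    structure(list(k_range = seq_along(consensus) + 1L,
                   consensus = consensus),
              class = "consensus_result")
  }
  n <- 9; npair <- choose(n, 2)  # 36 pairs
  zeros_ones <- rep(c(1, 0), c(9, 27))       # fraction p = 0.25 ones
  halves <- rep(0.5, npair)
  cr <- fake(list(zeros_ones, halves), n)
  area <- suppressWarnings(cdf_area(cr))
  expect_equal(area$areas[1], 0.75)   # 1 - p
  expect_equal(area$areas[2], 0.5)    # single step at 0.5
})

test_that("the CDF-area rule picks the true k on a 4-blob cohort", {
  set.seed(10)
  k <- 4; n_per <- 12; n_genes <- 30
  mu <- matrix(rnorm(n_genes * k, sd = 4), n_genes, k)
  x <- mu[, rep(1:k, each = n_per)] +
    matrix(rnorm(n_genes * k * n_per, sd = 0.5), n_genes)
  dimnames(x) <- list(paste0("g", 1:n_genes),
                      sprintf("S%02d", 1:(k * n_per)))
  cr <- consensus_cluster(x, k_range = 2:6, reps = 100, p_item = 0.8,
                          base = "kmeans", seed = 1)
  area <- cdf_area(cr)
  expect_identical(area$chosen_k, 4L)
  expect_true(all(area$deltas[area$k_values > 4] < 0.1))
  # areas of nested stable clusterings are non-decreasing up to the truth
  expect_true(all(diff(area$areas[area$k_values <= 4]) > -1e-8))
})

test_that("PCA embedding matches an independent SVD up to sign", {
  x <- rand_expr(10, 6, seed = 1)
  emb <- pca_embed(x, 3)
  xc <- x - rowMeans(x)
  sv <- svd(t(xc))
  oracle <- sv$u %*% diag(sv$d)
  for (j in 1:3) {
    expect_true(
      max(abs(emb[, j] - oracle[, j])) < 1e-8 ||
      max(abs(emb[, j] + oracle[, j])) < 1e-8
    )
  }
  # deterministic sign convention
  expect_identical(emb, pca_embed(x, 3))
})

test_that("PCA variance accounting is exact", {
  # rank-1 data: all variance on component 1
  base <- rand_expr(6, 5, seed = 2)[, 1]
  x <- outer(base, seq(1, 3, length.out = 5))
  colnames(x) <- paste0("s", 1:5)
  ev <- attr(pca_embed(x, 2), "explained_variance")
  expect_lt(ev[2] / ev[1], 1e-20)

  y <- rand_expr(8, 5, seed = 3)
  ev2 <- attr(pca_embed(y, 4), "explained_variance")
  total <- sum(apply(t(y), 2, var))
  expect_equal(sum(ev2), total, tolerance = 1e-10)
  expect_error(pca_embed(y, 0), "at least 1")
})
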