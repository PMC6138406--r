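# SigClust, survival association, concordance, signature scores.

test_that("SigClust rejects on strongly separated clouds", {
  set.seed(1)
  x <- rbind(matrix(rnorm(20 * 5), 20, 5),
             matrix(rnorm(20 * 5, mean = 50), 20, 5))
  res <- sigclust_pair(x, nsim = 100, seed = 1)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$ci, 0)
  expect_lte(res$ci, 1)
  expect_length(res$null_ci, 100)
  expect_true(all(res$null_ci > 0 & res$null_ci <= 1))
  expect_error(sigclust_pair(x, nsim = 10), "unstable")
  expect_error(sigclust_pair(x[1:3, ]), "at least 4")
})

test_that("SigClust is valid (never anti-conservative) under the null", {
  # the hard eigenvalue floor inflates the null total variance, so under a
  # single Gaussian the test errs on the conservative side: the rejection
  # rate must not exceed the nominal level (binomial slack for 60 runs)
  rejections <- vapply(1:60, function(s) {
    set.seed(s + 9000)
    x <- matrix(rnorm(30 * 8), 30, 8)
    sigclust_pair(x, nsim = 60, seed = s)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 60))
})

test_that("pairwise SigClust covers all class pairs", {
  blobs <- make_blobs(10, rbind(c(0, 0, 0), c(30, 0, 0),
                                c(0, 30, 0), c(0, 0, 30)),
                      sd = 0.5, seed = 2)
  res2 <- pairwise_sigclust(blobs$x[blobs$labels <= 2, ],
                            blobs$labels[blobs$labels <= 2],
                            nsim = 40, seed = 1)
  expect_identical(nrow(res2$pairs), 1L)
  res4 <- pairwise_sigclust(blobs$x, blobs$labels, nsim = 40, seed = 1)
  expect_identical(nrow(res4$pairs), 6L)
  expect_identical(res4$n_significant, 6L)

  # undersized classes are skipped with a warning
  lab <- rep(1L, nrow(blobs$x))
  lab[1] <- 2L
  expect_warning(r <- pairwise_sigclust(blobs$x, lab, nsim = 40, seed = 1),
                 "< 2 members")
  expect_true(anyNA(r$pairs$p_value))
})

test_that("log-rank equals the hand-computed O-E oracle", {
  # groups A: events at 1, 2; B: events at 3, 4.
  # t=1: O_A=1 E_A=1/2 V=1*3*2*2/(16*3)=1/4
  # t=2: O_A=1 E_A=1/3 V=1*2*1*2/(9*2)=2/9
  # => U = 7/6, V = 1/4 + 2/9 = 17/36, chi2 = U^2/V = 49/17
  lr <- logrank_test(time = c(1, 2, 3, 4), event = rep(1, 4),
                     group = c("A", "A", "B", "B"))
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-8)
  expect_identical(lr$df, 1L)

  # identical groups: no difference, p = 1
  same <- logrank_test(time = rep(c(1, 2, 5), 2), event = rep(c(1, 1, 0), 2),
                       group = rep(c("A", "B"), each = 3))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  four <- logrank_test(time = 1:8, event = rep(1, 8), group = rep(1:4, 2))
  expect_identical(four$df, 3L)

  expect_error(logrank_test(1:4, rep(0, 4), rep(1:2, 2)), "no events")
  expect_error(logrank_test(1:4, rep(1, 4), rep(1, 4)), "2 groups")
})

test_that("log-rank p agrees with a permutation reference", {
  set.seed(5)
  time <- rexp(24, rate = rep(c(0.1, 0.4), each = 12))
  event <- rbinom(24, 1, 0.8)
  group <- rep(1:2, each = 12)
  lr <- logrank_test(time, event, group)
  perm_chi2 <- replicate(1500, {
    g <- sample(group)
    logrank_test(time, event, g)$chi2
  })
  p_perm <- mean(perm_chi2 >= lr$chi2)
  expect_lt(abs(p_perm - lr$p_value),
            0.03 + 3 * sqrt(lr$p_value * (1 - lr$p_value) / 1500))
})

test_that("Kaplan-Meier estimates follow the product-limit form", {
  km <- km_estimate(time = c(1, 2), event = c(1, 1))
  expect_equal(km$surv, c(0.5, 0))

  none <- km_estimate(time = c(2, 4, 6), event = c(0, 0, 0))
  expect_true(all(none$surv == 1))

  # censored-only tail leaves the curve flat; curve is non-increasing
  mixed <- km_estimate(time = c(1, 2, 3, 8, 9), event = c(1, 1, 1, 0, 0))
  expect_equal(min(mixed$surv), mixed$surv[mixed$time == 3])
  expect_true(all(diff(mixed$surv) <= 1e-12))
})

test_that("concordance: ARI and hypergeometric overlaps", {
  a <- rep(1:4, each = 5)
  expect_equal(concordance(a, a)$ari, 1)
  relabeled <- c(3L, 1L, 4L, 2L)[a]
  expect_equal(concordance(a, relabeled)$ari, 1)

  # overlap of 5 between two size-5 classes out of 20: p = 1/C(20,5)
  b <- rep(c(9, 8, 7, 6), each = 5)
  p <- concordance(a, b)$p_overlap
  expect_equal(p["1", "9"], 1 / choose(20, 5), tolerance = 1e-12)

  expect_error(
    concordance(stats::setNames(a, paste0("x", 1:20)),
                stats::setNames(a, paste0("y", 1:20))),
    "disjoint")
})

test_that("ARI is centred at zero for independent labelings", {
  set.seed(9)
  aris <- replicate(60, {
    concordance(sample(4, 200, replace = TRUE),
                sample(4, 200, replace = TRUE))$ari
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("ARI agrees with mclust's implementation", {
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:20) {
    a <- sample(4, 50, replace = TRUE)
    b <- sample(3, 50, replace = TRUE)
    expect_equal(concordance(a, b)$ari,
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("signature scores average the found genes", {
  x <- matrix(c(2, 4, 1, 6), 2, 2,
              dimnames = list(c("CDKN1A", "MDM2"), c("s1", "s2")))
  expect_equal(unname(signature_score(x, c("CDKN1A", "MDM2"))),
               c(3, 3.5))
  expect_equal(signature_score(x, "MDM2"), x["MDM2", ])
  expect_warning(s <- signature_score(x, c("CDKN1A", "NOPE")), "NOPE")
  expect_equal(unname(s), unname(x["CDKN1A", ]))
  expect_error(signature_score(x, "ABSENT"), "none of the signature genes")
})
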