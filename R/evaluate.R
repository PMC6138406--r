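# Statistical evaluation of clusterings: SigClust significance, survival
# association, concordance with external labelings, and simple expression
# signature scores.

#' SigClust: Monte-Carlo significance of a two-cluster split
#'
#' Tests whether the data support two clusters against the null of a
#' single multivariate Gaussian. The test statistic is the cluster index
#' `CI = (best 2-means within-cluster SS) / (total SS about the grand
#' mean)`. The null covariance is estimated by hard-thresholded
#' eigenvalues: `lambda_i~ = max(lambda_i, sigma_N^2)` with background
#' noise variance `sigma_N^2 = (MAD of all mean-centered entries /
#' 0.6745)^2`; `nsim` datasets are simulated from
#' `N(0, diag(lambda~))`, the CI recomputed for each, and the p-value is
#' the add-one Monte-Carlo proportion of null CIs at or below the
#' observed one (so p is never exactly 0).
#'
#' @param x Samples x features numeric matrix of the two putative
#'   clusters pooled together (`nrow >= 4`).
#' @param nsim Number of null simulations (default 100, minimum 20).
#' @param seed Integer seed.
#' @param n_init k-means restarts used for every CI computation.
#' @return Object of class `"sigclust_result"`: list with `ci`,
#'   `null_ci` (length nsim), `p_value`, `eigenvalue_floor`
#'   (`sigma_N^2`), `nsim`.
#' @references Liu, Hayes, Nobel, Marron (2008) JASA 103:1281-1293.
#' @export
sigclust_pair <- function(x, nsim = 100, seed = 1, n_init = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 4L) stop("need at least 4 samples")
  if (nsim < 20L) stop("nsim below 20 gives unstable p-values")

  cluster_index <- function(z) {
    tot <- sum(sweep(z, 2L, colMeans(z))^2)
    if (tot == 0) return(1)
    kmeans_best(z, 2L, n_init = as.integer(n_init))$tot.withinss / tot
  }

  set.seed(seed)
  ci <- cluster_index(x)
  xc <- sweep(x, 2L, colMeans(x))
  sigma2 <- (stats::mad(as.vector(xc), constant = 1) / 0.6745)^2
  sv <- svd(xc, nu = 0, nv = 0)$d
  lambda <- rep(0, d)
  lambda[seq_along(sv)] <- sv^2 / (n - 1)
  lambda <- pmax(lambda, sigma2)

  null_ci <- vapply(seq_len(nsim), function(b) {
    z <- matrix(stats::rnorm(n * d), n, d)
    z <- sweep(z, 2L, sqrt(lambda), "*")
    cluster_index(z)
  }, numeric(1))

  structure(
    list(ci = ci, null_ci = null_ci,
         p_value = (1 + sum(null_ci <= ci)) / (1 + nsim),
         eigenvalue_floor = sigma2, nsim = as.integer(nsim)),
    class = "sigclust_result"
  )
}

#' @export
print.sigclust_result <- function(x, ...) {
  cat("SigClust: CI = ", format(x$ci, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      " (", x$nsim, " null simulations, noise floor ",
      format(x$eigenvalue_floor, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Pairwise SigClust across all subtype pairs
#'
#' Runs [sigclust_pair()] on every unordered pair of classes, on the data
#' space supplied (typically the same preprocessed expression matrix used
#' for clustering, restricted per pair to the two classes). Pairs in
#' which a class has fewer than 2 members are skipped with a warning.
#'
#' @param x Samples x features matrix (rows in the order of `labels`), or
#'   a genes x samples expression matrix with `genes_in_rows = TRUE`.
#' @param labels Integer class labels in `1..k`, `k >= 2`.
#' @param nsim,seed,n_init Passed to [sigclust_pair()].
#' @param genes_in_rows Set `TRUE` when `x` is an expression matrix
#'   (genes x samples); it is transposed internally.
#' @param alpha Significance level used for the reported count.
#' @return List with `pairs` (data.frame: `a`, `b`, `ci`, `p_value`),
#'   `n_significant` (count of pairs with p < `alpha`), `alpha`.
#' @export
pairwise_sigclust <- function(x, labels, nsim = 100, seed = 1,
                              genes_in_rows = FALSE, n_init = 10,
                              alpha = 0.05) {
  x <- as.matrix(x)
  if (genes_in_rows) x <- t(x)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) stop("one label per sample required")
  k <- max(labels)
  if (k < 2L) stop("need at least 2 classes")
  combos <- utils::combn(sort(unique(labels)), 2L)
  rows <- lapply(seq_len(ncol(combos)), function(j) {
    a <- combos[1L, j]; b <- combos[2L, j]
    sel <- labels %in% c(a, b)
    if (sum(labels == a) < 2L || sum(labels == b) < 2L) {
      warning("skipping pair (", a, ",", b, "): class with < 2 members")
      return(data.frame(a = a, b = b, ci = NA_real_, p_value = NA_real_))
    }
    res <- sigclust_pair(x[sel, , drop = FALSE], nsim = nsim,
                         seed = derive_seed(seed, "sigclust") + j,
                         n_init = n_init)
    data.frame(a = a, b = b, ci = res$ci, p_value = res$p_value)
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       n_significant = sum(pairs$p_value < alpha, na.rm = TRUE),
       alpha = alpha)
}

#' Log-rank test of survival differences between subtypes
#'
#' Standard (unweighted) g-group log-rank test: at each distinct event
#' time, observed versus expected events per group under the
#' hypergeometric model; the chi-square statistic has `g - 1` degrees of
#' freedom. Delegates to [survival::survdiff()].
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event observed, 0 = censored).
#' @param group Group labels (at least 2 distinct values, at least 1
#'   event overall).
#' @return List with `chi2`, `df`, `p_value`, `n` (per-group sizes).
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  if (sum(event) < 1) stop("no events observed")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survdiff(survival::Surv(time, event) ~ g,
                            data = data.frame(time = time, event = event,
                                              g = factor(group)))
  df <- length(fit$n) - 1L
  list(chi2 = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n = as.vector(fit$n))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate for one group of subjects; right-censored
#' records reduce the risk set only. Delegates to
#' [survival::survfit()].
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Data.frame step function: `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

# Adjusted Rand index from the contingency table (permutation-model
# chance correction).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Concordance between a subtyping and a reference labeling
#'
#' Quantifies agreement of two partitions of the same samples by the
#' adjusted Rand index and, per (class, reference-class) pair, the
#' hypergeometric upper-tail probability of the observed overlap given
#' the class sizes — the test used to match de-novo subtypes to
#' previously characterized ones.
#'
#' @param labels Integer subtype labels (named by sample, or aligned with
#'   `reference`).
#' @param reference Reference labels for the same samples; if both
#'   vectors are named, samples are matched by name.
#' @return List with `ari` and `p_overlap` (matrix, rows = subtype
#'   classes, columns = reference classes, hypergeometric upper-tail p of
#'   each overlap).
#' @export
concordance <- function(labels, reference) {
  if (!is.null(names(labels)) && !is.null(names(reference))) {
    shared <- intersect(names(labels), names(reference))
    if (length(shared) == 0L) stop("disjoint sample sets")
    labels <- labels[shared]
    reference <- reference[shared]
  } else if (length(labels) != length(reference)) {
    stop("labelings cover different sample sets")
  }
  tab <- table(labels, reference)
  n <- sum(tab)
  p <- tab
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      # P(overlap >= observed) drawing |class i| samples from an urn with
      # |ref j| marked among n
      p[i, j] <- stats::phyper(tab[i, j] - 1, colSums(tab)[j],
                               n - colSums(tab)[j], rowSums(tab)[i],
                               lower.tail = FALSE)
    }
  }
  list(ari = adjusted_rand_index(labels, reference),
       p_overlap = unclass(p))
}

#' Mean-expression signature score
#'
#' Per-sample unweighted mean expression over a gene list — e.g. the
#' two-gene TP53 activity score over CDKN1A and MDM2 used to separate
#' TP53-intact from TP53-deficient tumors. Genes absent from the matrix
#' are reported by warning; at least one must be present.
#'
#' @param x Genes x samples expression matrix.
#' @param genes Character vector of gene symbols.
#' @return Named numeric vector, one score per sample.
#' @export
signature_score <- function(x, genes) {
  found <- intersect(genes, rownames(x))
  if (length(found) == 0L) {
    stop("none of the signature genes are present in the matrix")
  }
  absent <- setdiff(genes, found)
  if (length(absent)) {
    warning("signature genes absent from the matrix: ",
            paste(absent, collapse = ", "))
  }
  colMeans(x[found, , drop = FALSE])
}
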