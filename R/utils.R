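# Internal numerical helpers shared across modules.

# Moore-Penrose pseudoinverse via SVD; singular values below tol * max(d)
# are treated as zero (rank-revealing, stable for n_hidden ~ N).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Activation functions by tag.
activation_fun <- function(tag) {
  switch(tag,
    linear  = identity,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    hardlim = function(z) (z >= 0) + 0,
    stop("unknown activation: ", tag)
  )
}

# Deterministic per-component seed derived from a master seed, kept
# within 32-bit integer range so stages can be re-run independently.
derive_seed <- function(seed, stream) {
  offsets <- c(
    weights = 104729L, kmeans = 15485863L, gap = 32452843L,
    consensus = 49979687L, sigclust = 67867967L, simulate = 86028121L,
    classifier = 2038074743L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) + off) %% .Machine$integer.max)
}

# k-means++ seeding: first center uniform, later centers with
# probability proportional to squared distance to the nearest chosen one.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
    for (j in 2L:k) {
      if (all(d2 == 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
    }
  }
  # jitter exact duplicates so stats::kmeans accepts the center matrix
  if (anyDuplicated(centers)) {
    dup <- duplicated(centers)
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      stats::rnorm(sum(dup) * ncol(x), sd = 1e-8)
  }
  centers
}

# Best-of-restarts k-means used by clustering, gap statistic and SigClust.
# Restarts on empty-cluster failures; errors after n_init consecutive failures.
kmeans_best <- function(x, k, n_init = 25L, iter_max = 300L) {
  x <- as.matrix(x)
  if (k == 1L) {
    centers <- matrix(colMeans(x), 1L)
    ss <- sum(sweep(x, 2L, centers[1L, ])^2)
    return(list(cluster = rep(1L, nrow(x)), centers = centers,
                tot.withinss = ss))
  }
  best <- NULL
  failures <- 0L
  tries <- 0L
  while (tries < n_init) {
    tries <- tries + 1L
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = kmeanspp_init(x, k), iter.max = iter_max)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || length(unique(fit$cluster)) < k) {
      failures <- failures + 1L
      if (failures >= n_init) {
        stop("k-means produced an empty cluster in ", n_init, " restarts")
      }
      tries <- tries - 1L  # failed restart does not consume a draw
      next
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# Renumber cluster labels canonically: 1..k by decreasing cluster size,
# ties broken by the smallest member index.
canonical_labels <- function(labels) {
  labels <- as.integer(labels)
  ids <- sort(unique(labels))
  size <- tabulate(match(labels, ids))
  first <- vapply(ids, function(g) min(which(labels == g)), integer(1))
  ord <- order(-size, first)
  out <- match(labels, ids[ord])
  attr(out, "k") <- length(ids)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
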