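# Clustering of the feature space and selection of the number of clusters.

#' k-means clustering with canonical label numbering
#'
#' Partitions the rows of a feature matrix by k-means (Euclidean,
#' best of `n_init` k-means++-seeded restarts, up to 300 Lloyd/Hartigan
#' iterations) and renumbers the labels canonically: clusters are labeled
#' 1..k by decreasing size, ties broken by the smallest member index, so
#' repeated runs are comparable.
#'
#' @param f Samples x features numeric matrix (e.g. from
#'   [elm_features()] or [pca_embed()]).
#' @param k Number of clusters, `1 <= k <= nrow(f)`.
#' @param n_init Number of seeded restarts (default 25); the restart with
#'   the lowest within-cluster sum of squares is kept.
#' @param seed Integer seed.
#' @return Named integer vector of labels in `1..k` with attributes `"k"`
#'   and `"tot_withinss"`.
#' @export
kmeans_cluster <- function(f, k, n_init = 25, seed = 1) {
  f <- as.matrix(f)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(f)) stop("k = ", k, " exceeds the sample count ", nrow(f))
  set.seed(seed)
  fit <- kmeans_best(f, as.integer(k), n_init = as.integer(n_init))
  labels <- canonical_labels(fit$cluster)
  names(labels) <- rownames(f)
  attr(labels, "tot_withinss") <- fit$tot.withinss
  labels
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the log within-cluster dispersion `log(W_k)` of k-means
#' partitions against its expectation under `B` reference datasets drawn
#' uniformly over the observed per-feature range:
#' `Gap(k) = mean_b log(W*_kb) - log(W_k)`, with simulation standard
#' error `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`. `W_k` is the total
#' within-cluster sum of squares about the centroids. The chosen k is
#' either the global maximum of the gap curve (default, the "peak") or
#' Tibshirani's 1-SE rule (smallest k with
#' `Gap(k) >= Gap(k+1) - s_(k+1)`).
#'
#' @param f Samples x features matrix.
#' @param k_range Strictly increasing integer vector of candidate k.
#' @param B Number of uniform reference datasets (default 50, minimum 10).
#' @param seed Integer seed.
#' @param rule `"global_max"` (default) or `"tibshirani_1se"`.
#' @param n_init k-means restarts per fit (default 25).
#' @return An object of class `"gap_result"`: data.frame-backed list with
#'   `k_values`, `log_Wk`, `gap`, `s_k`, `chosen_k`, `B`, `rule`.
#' @examples
#' set.seed(1)
#' f <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 8), 30))
#' gap_statistic(f, 1:4, B = 20, seed = 1)$chosen_k
#' @export
gap_statistic <- function(f, k_range, B = 50, seed = 1,
                          rule = c("global_max", "tibshirani_1se"),
                          n_init = 25) {
  rule <- match.arg(rule)
  f <- as.matrix(f)
  k_range <- as.integer(k_range)
  if (length(k_range) < 1L || any(diff(k_range) <= 0L)) {
    stop("k_range must be strictly increasing")
  }
  if (max(k_range) > nrow(f) - 1L) stop("max(k_range) must be at most N - 1")
  if (B < 10L) stop("B must be at least 10")
  set.seed(seed)
  wk <- function(x, k) kmeans_best(x, k, n_init = as.integer(n_init))$tot.withinss

  log_wk <- vapply(k_range, function(k) log(wk(f, k)), numeric(1))
  lo <- apply(f, 2L, min)
  hi <- apply(f, 2L, max)
  n <- nrow(f)
  log_wk_ref <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    ref <- vapply(seq_along(lo),
                  function(j) stats::runif(n, lo[j], hi[j]),
                  numeric(n))
    log_wk_ref[b, ] <- vapply(k_range, function(k) log(wk(ref, k)),
                              numeric(1))
  }
  gap <- colMeans(log_wk_ref) - log_wk
  s_k <- apply(log_wk_ref, 2L, stats::sd) * sqrt(1 + 1 / B)

  chosen <- if (rule == "global_max") {
    k_range[which.max(gap)]
  } else {
    idx <- length(k_range)  # last k qualifies vacuously
    for (i in seq_len(length(k_range) - 1L)) {
      if (gap[i] >= gap[i + 1L] - s_k[i + 1L]) { idx <- i; break }
    }
    k_range[idx]
  }
  structure(
    list(k_values = k_range, log_Wk = log_wk, gap = gap, s_k = s_k,
         chosen_k = chosen, B = as.integer(B), rule = rule),
    class = "gap_result"
  )
}

#' @export
print.gap_result <- function(x, ...) {
  cat("Gap statistic over k = ", paste(range(x$k_values), collapse = ".."),
      " (B = ", x$B, " uniform references, rule = ", x$rule, ")\n", sep = "")
  print(data.frame(k = x$k_values, logW = x$log_Wk, gap = x$gap,
                   se = x$s_k), row.names = FALSE, digits = 4)
  cat("chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' @export
plot.gap_result <- function(x, ...) {
  graphics::plot(x$k_values, x$gap, type = "b", pch = 19,
                 xlab = "number of clusters k", ylab = "Gap(k)", ...)
  graphics::arrows(x$k_values, x$gap - x$s_k, x$k_values, x$gap + x$s_k,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(v = x$chosen_k, lty = 2, col = "grey40")
  invisible(x)
}

#' Silhouette widths of a clustering
#'
#' Per-sample silhouette width `s(i) = (b(i) - a(i)) / max(a(i), b(i))`
#' with `a(i)` the mean Euclidean distance to the sample's own cluster and
#' `b(i)` the smallest mean distance to another cluster; singletons score
#' 0. Computed via [cluster::silhouette()].
#'
#' @param f Samples x features matrix (the space the clustering lives in).
#' @param labels Integer cluster labels, `k >= 2`, every cluster nonempty.
#' @return List with `widths` (per-sample, named) and `average`
#'   (unweighted mean).
#' @export
silhouette_width <- function(f, labels) {
  f <- as.matrix(f)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("silhouette requires k >= 2")
  sil <- cluster::silhouette(labels, stats::dist(f))
  widths <- sil[, "sil_width"]
  names(widths) <- rownames(f)
  list(widths = widths, average = mean(widths))
}
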