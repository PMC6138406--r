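# Baseline machinery: Monti-style consensus clustering with CDF-area model
# selection, and PCA embedding of samples.

#' Consensus clustering by subsampling
#'
#' The classical subtyping baseline: repeatedly subsample the cohort,
#' cluster each subsample with a conventional algorithm, and record for
#' every sample pair the proportion of runs in which they land in the same
#' cluster out of the runs in which both were drawn. The consensus matrix
#' `M_k` (one per candidate k) summarizes clustering stability; the final
#' per-k assignment is average-linkage hierarchical clustering of
#' `1 - M_k` cut at k.
#'
#' Each rep draws one subsample of `round(p_item * N)` samples (without
#' replacement) and clusters it at every k, with a per-rep seed derived
#' from the master seed so stages are reproducible. The default base
#' algorithm is average-linkage hierarchical clustering on Pearson
#' distance (1 - correlation across genes), mirroring the usual default of
#' consensus-clustering software; `"kmeans"` uses Euclidean k-means on the
#' sample profiles.
#'
#' @param x Genes x samples expression matrix (samples are clustered).
#' @param k_range Strictly increasing candidate cluster counts.
#' @param reps Number of subsampling repetitions (default 1000; >= 10).
#' @param p_item Fraction of samples drawn per rep (default 0.8).
#' @param base `"hclust"` (Pearson distance, average linkage; default) or
#'   `"kmeans"`.
#' @param seed Integer master seed.
#' @return Object of class `"consensus_result"`: list with `k_range`,
#'   `consensus` (list of N x N matrices in `[0,1]`, unit diagonal),
#'   `assignments` (list of canonical label vectors per k),
#'   `co_sampled` (pair count matrix), `reps`, `p_item`, `base`.
#' @export
consensus_cluster <- function(x, k_range = 2:6, reps = 1000, p_item = 0.8,
                              base = c("hclust", "kmeans"), seed = 1) {
  base <- match.arg(base)
  x <- as.matrix(x)
  n <- ncol(x)
  k_range <- as.integer(k_range)
  if (any(diff(k_range) <= 0L)) stop("k_range must be strictly increasing")
  if (reps < 1L) stop("reps must be at least 1")
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]")
  m_draw <- round(p_item * n)
  if (m_draw < max(k_range)) {
    stop("p_item too small: subsamples of ", m_draw,
         " cannot hold ", max(k_range), " clusters")
  }

  d_full <- if (base == "hclust") 1 - stats::cor(x) else NULL
  co_clust <- lapply(k_range, function(k) matrix(0, n, n))
  co_samp <- matrix(0, n, n)

  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, "consensus") + r)
    idx <- sort(sample.int(n, m_draw))
    co_samp[idx, idx] <- co_samp[idx, idx] + 1
    labels_at <- if (base == "hclust") {
      hc <- stats::hclust(stats::as.dist(d_full[idx, idx]), method = "average")
      lapply(k_range, function(k) stats::cutree(hc, k))
    } else {
      sub <- t(x[, idx, drop = FALSE])
      lapply(k_range, function(k) kmeans_best(sub, k, n_init = 3L)$cluster)
    }
    for (i in seq_along(k_range)) {
      same <- outer(labels_at[[i]], labels_at[[i]], "==") + 0
      co_clust[[i]][idx, idx] <- co_clust[[i]][idx, idx] + same
    }
  }

  if (any(co_samp[upper.tri(co_samp)] == 0)) {
    warning("some sample pairs were never co-sampled; their consensus is 0")
  }

  ids <- colnames(x)
  consensus <- lapply(co_clust, function(cc) {
    m <- ifelse(co_samp > 0, cc / pmax(co_samp, 1), 0)
    diag(m) <- 1
    dimnames(m) <- list(ids, ids)
    m
  })
  assignments <- lapply(seq_along(k_range), function(i) {
    hc <- stats::hclust(stats::as.dist(1 - consensus[[i]]), method = "average")
    labels <- canonical_labels(stats::cutree(hc, k_range[i]))
    names(labels) <- ids
    labels
  })
  names(consensus) <- names(assignments) <- paste0("k", k_range)
  structure(
    list(k_range = k_range, consensus = consensus,
         assignments = assignments, co_sampled = co_samp,
         reps = as.integer(reps), p_item = p_item, base = base,
         seed = seed),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering: ", ncol(x$co_sampled), " samples, k = ",
      paste(range(x$k_range), collapse = ".."), ", ", x$reps,
      " reps (p_item = ", x$p_item, ", base = ", x$base, ")\n", sep = "")
  invisible(x)
}

#' CDF areas and the consensus model-selection rule
#'
#' For each k, the empirical cumulative distribution of the
#' upper-triangle consensus values is integrated over `[0, 1]` to give the
#' area `A(k)`; a stable clustering pushes consensus values toward 0/1 and
#' enlarges the area. The relative increase
#' `Delta(k) = (A(k) - A(k-1)) / A(k-1)` (and `A(k)` itself for the
#' smallest k) drives the selection rule: the optimal k is the largest k
#' whose relative increase is still substantial (>= 0.1); when the area
#' stops increasing substantially from k to k+1 clusters, k is chosen.
#'
#' @param cr A [consensus_cluster()] result with at least 2 k values.
#' @return List with `k_values`, `areas`, `deltas`, `chosen_k`.
#' @export
cdf_area <- function(cr) {
  stopifnot(inherits(cr, "consensus_result"))
  if (length(cr$k_range) < 2L) stop("need at least 2 k values")
  areas <- vapply(cr$consensus, function(m) {
    v <- sort(m[upper.tri(m)])
    # integral of the ECDF step function over [0, 1]
    sum(diff(c(v, 1)) * seq_along(v) / length(v))
  }, numeric(1))
  deltas <- c(areas[1L],
              diff(areas) / utils::head(areas, -1L))
  ok <- deltas >= 0.1
  chosen <- if (any(ok)) {
    cr$k_range[max(which(ok))]
  } else {
    warning("no k shows a substantial (>= 0.1) relative CDF-area increase; ",
            "returning the smallest k")
    cr$k_range[1L]
  }
  list(k_values = cr$k_range, areas = unname(areas),
       deltas = unname(deltas), chosen_k = chosen)
}

#' PCA embedding of samples
#'
#' Projects samples onto the top principal components of the gene-centered
#' expression matrix — the visualization counterpart of the ELM feature
#' space. The sign of each component is fixed so its largest-magnitude
#' gene loading is positive, making the embedding deterministic.
#'
#' @param x Genes x samples matrix.
#' @param n_components Number of components,
#'   `1 <= n_components <= min(n_genes, N)`.
#' @return Samples x n_components matrix (colnames `PC1..`), with
#'   attribute `"explained_variance"` (variances of all components).
#' @export
pca_embed <- function(x, n_components = 3) {
  x <- as.matrix(x)
  if (n_components < 1L) stop("n_components must be at least 1")
  if (n_components > min(dim(x))) {
    stop("n_components exceeds min(n_genes, n_samples)")
  }
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pr$x, 2L, flip, "*")[, seq_len(n_components), drop = FALSE]
  attr(scores, "explained_variance") <- unname(pr$sdev^2)
  scores
}
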