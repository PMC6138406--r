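# The central model: ELM-CC molecular subtyping. A random single-hidden-
# layer network projects each sample's expression profile onto a small
# hidden feature space; k-means on those features defines the subtypes.

#' Fit an ELM-CC molecular subtyping model
#'
#' Runs the full subtyping procedure on a preprocessed (log-scale,
#' normalized) genes x samples expression matrix:
#'
#' 1. optional variance filtering by [mad_filter()];
#' 2. random input weights for a single-hidden-layer network with
#'    `n_hidden` nodes ([elm_weights()]);
#' 3. the least-squares autoencoding fit of the network
#'    ([elm_regression()]) and extraction of the hidden feature matrix
#'    `F[j, i] = w_i . x_j + b_i` ([elm_features()]) — a random affine
#'    projection of each sample onto `n_hidden` dimensions;
#' 4. k-means partitioning of the feature space into `k` subtypes
#'    ([kmeans_cluster()]);
#' 5. silhouette widths of the result ([silhouette_width()]).
#'
#' `n_hidden = 3` (the default) both reduces thousands of genes to a
#' clusterable space and makes the cohort directly visualizable.
#'
#' @param x Genes x samples numeric expression matrix with dimnames.
#' @param k Number of subtypes (default 4).
#' @param n_hidden Hidden nodes = feature-space dimension (default 3).
#' @param seed Master seed; weights and k-means restarts derive from it.
#' @param mad_threshold If non-NULL, apply [mad_filter()] at this cutoff
#'   first.
#' @param activation Hidden-layer activation for the feature matrix:
#'   `"linear"` (pre-activation, default) or `"sigmoid"`.
#' @param distribution Input-weight distribution, see [elm_weights()].
#' @param n_init k-means restarts (default 25).
#' @return Object of class `"elmcc"`: list with `features` (N x n_hidden),
#'   `cluster` (named integer labels 1..k), `k`, `n_hidden`, `weights`,
#'   `model` (the autoencoding [elm_regression()] fit), `silhouette`
#'   (per-sample widths and average), `x` (the filtered training matrix,
#'   kept for cross-cohort classification), `filter_report`, `call`.
#' @examples
#' cohort <- simulate_cohort(n_samples = 60, n_noise = 200, seed = 1)
#' fit <- elmcc(cohort$expression, k = 4, mad_threshold = 0.5, seed = 1)
#' fit
#' table(fitted(fit), cohort$labels)
#' @seealso [predict.elmcc()], [gap_statistic()], [consensus_cluster()]
#' @export
elmcc <- function(x, k = 4, n_hidden = 3, seed = 1, mad_threshold = NULL,
                  activation = c("linear", "sigmoid"),
                  distribution = c("uniform", "gaussian"),
                  n_init = 25) {
  activation <- match.arg(activation)
  distribution <- match.arg(distribution)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("x needs gene rownames and sample colnames")
  }
  filter_report <- NULL
  if (!is.null(mad_threshold)) {
    x <- mad_filter(x, mad_threshold)
    filter_report <- attr(x, "filter_report")
    if (nrow(x) == 0L) stop("MAD filter removed every gene")
  }
  w <- elm_weights(nrow(x), n_hidden, derive_seed(seed, "weights"),
                   distribution)
  model <- elm_regression(w, x, activation = activation)
  feats <- elm_features(w, x, activation = activation)
  labels <- kmeans_cluster(feats, k, n_init = n_init,
                           seed = derive_seed(seed, "kmeans"))
  sil <- if (k >= 2L) silhouette_width(feats, labels) else NULL
  structure(
    list(
      features = feats, cluster = labels, k = as.integer(k),
      n_hidden = as.integer(n_hidden), weights = w, model = model,
      silhouette = sil, activation = activation, seed = seed,
      x = x, filter_report = filter_report, call = match.call()
    ),
    class = "elmcc"
  )
}

#' @export
print.elmcc <- function(x, ...) {
  cat("ELM-CC subtyping\n")
  cat("  ", ncol(x$x), " samples, ", nrow(x$x), " genes -> ",
      x$n_hidden, " hidden features (", x$activation,
      "), k = ", x$k, "\n", sep = "")
  cat("  cluster sizes:",
      paste(tabulate(x$cluster, x$k), collapse = " / "), "\n")
  if (!is.null(x$silhouette)) {
    cat("  average silhouette width:",
        format(x$silhouette$average, digits = 3), "\n")
  }
  invisible(x)
}

#' Summarize an ELM-CC fit
#'
#' @param object An [elmcc()] object.
#' @param ... Unused.
#' @return Object of class `"summary.elmcc"` with cluster sizes,
#'   per-cluster and overall average silhouette widths, filter report and
#'   reconstruction RMSE.
#' @export
summary.elmcc <- function(object, ...) {
  sizes <- tabulate(object$cluster, object$k)
  per_cluster <- if (!is.null(object$silhouette)) {
    tapply(object$silhouette$widths, object$cluster, mean)
  } else NULL
  structure(
    list(
      k = object$k, n_hidden = object$n_hidden,
      n_samples = ncol(object$x), n_genes = nrow(object$x),
      sizes = sizes, silhouette_by_cluster = per_cluster,
      silhouette_average = object$silhouette$average %||% NA_real_,
      rmse = object$model$rmse, filter_report = object$filter_report
    ),
    class = "summary.elmcc"
  )
}

#' @export
print.summary.elmcc <- function(x, ...) {
  cat("ELM-CC subtyping of", x$n_samples, "samples\n")
  if (!is.null(x$filter_report)) {
    cat("  MAD filter: ", x$filter_report$n_out, "/", x$filter_report$n_in,
        " genes kept (threshold ", x$filter_report$threshold, ")\n",
        sep = "")
  }
  cat("  feature space:", x$n_hidden, "hidden nodes; reconstruction RMSE",
      format(x$rmse, digits = 4), "\n")
  tab <- data.frame(cluster = seq_len(x$k), size = x$sizes,
                    mean_silhouette = as.vector(x$silhouette_by_cluster))
  print(tab, row.names = FALSE, digits = 3)
  cat("  average silhouette width:",
      format(x$silhouette_average, digits = 3), "\n")
  invisible(x)
}

#' @export
fitted.elmcc <- function(object, ...) object$cluster

#' @export
coef.elmcc <- function(object, ...) {
  list(W = object$weights$W, b = object$weights$b,
       beta = object$model$beta)
}

#' Plot the ELM feature space colored by subtype
#'
#' Pairwise scatter of the hidden features (or a single panel when
#' `n_hidden == 2`), colored by cluster — the flat analogue of the 3-D
#' feature-space views used to inspect subtype separation.
#'
#' @param x An [elmcc()] object.
#' @param ... Passed to [graphics::pairs()] / [graphics::plot()].
#' @export
plot.elmcc <- function(x, ...) {
  cols <- x$cluster
  if (ncol(x$features) >= 3L) {
    graphics::pairs(x$features, col = cols, pch = 19,
                    main = "ELM feature space", ...)
  } else if (ncol(x$features) == 2L) {
    graphics::plot(x$features, col = cols, pch = 19,
                   main = "ELM feature space", ...)
  } else {
    graphics::stripchart(x$features[, 1L] ~ cols, method = "jitter",
                         vertical = TRUE, pch = 19,
                         xlab = "cluster", ylab = "F1", ...)
  }
  invisible(x)
}

#' Classify an independent cohort with a fitted ELM-CC model
#'
#' Transfers the discovered subtypes to a validation cohort: both cohorts
#' are harmonized to their shared gene space (z-scored per cohort by
#' default), a hard-limit ELM classifier is trained on the training
#' samples with the fitted subtype labels as targets, and the validation
#' samples are classified.
#'
#' @param object An [elmcc()] fit.
#' @param newdata Genes x samples expression matrix of the independent
#'   cohort.
#' @param n_hidden Hidden nodes of the classifier (default 50).
#' @param standardize Z-score each gene within each cohort before
#'   training (default `TRUE`).
#' @param seed Seed for the classifier's random weights (defaults to the
#'   fit's master seed).
#' @param ... Unused.
#' @return Named integer vector of predicted subtype labels for the
#'   columns of `newdata`; the trained classifier is attached as
#'   attribute `"classifier"`.
#' @export
predict.elmcc <- function(object, newdata, n_hidden = 50,
                          standardize = TRUE, seed = object$seed, ...) {
  h <- harmonize_cohorts(object$x, as.matrix(newdata),
                         standardize = standardize)
  clf <- elm_classifier(h$train, object$cluster, n_hidden = n_hidden,
                        seed = derive_seed(seed, "classifier"))
  out <- predict(clf, h$test)
  attr(out, "classifier") <- clf
  out
}
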