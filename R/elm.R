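# Extreme learning machine core: random single-hidden-layer feedforward
# network. Input weights W (n_hidden x n_genes) and biases b are random and
# fixed; only the output weights beta are fit, by a Moore-Penrose
# least-squares solve. The hidden-layer observations
# F[j, i] = w_i . x_j + b_i are the low-dimensional embedding clustered
# downstream.

#' Draw random ELM input weights and biases
#'
#' Input weights and biases of an extreme learning machine are never
#' trained: they are drawn once from a fixed distribution (uniform on
#' \[-1, 1\] by convention, or standard Gaussian) and define a random
#' projection of the input space.
#'
#' @param n_input Input dimension (number of genes).
#' @param n_hidden Number of hidden nodes = dimension of the feature space.
#' @param seed Integer seed; weights are reproducible from
#'   `(seed, n_hidden, n_input, distribution)`.
#' @param distribution `"uniform"` for U(-1, 1) (default) or `"gaussian"`
#'   for N(0, 1).
#' @return An object of class `"elm_weights"`: list with `W`
#'   (n_hidden x n_input), `b` (length n_hidden), `seed`, `distribution`.
#' @examples
#' w <- elm_weights(10, 3, seed = 1)
#' dim(w$W)
#' @export
elm_weights <- function(n_input, n_hidden, seed,
                        distribution = c("uniform", "gaussian")) {
  distribution <- match.arg(distribution)
  if (n_hidden < 1L) stop("n_hidden must be at least 1")
  if (n_input < 1L) stop("n_input must be at least 1")
  set.seed(seed)
  draw <- switch(distribution,
    uniform  = function(n) stats::runif(n, -1, 1),
    gaussian = function(n) stats::rnorm(n)
  )
  structure(
    list(
      W = matrix(draw(n_hidden * n_input), n_hidden, n_input),
      b = draw(n_hidden),
      seed = seed,
      distribution = distribution
    ),
    class = "elm_weights"
  )
}

#' @export
print.elm_weights <- function(x, ...) {
  cat("ELM input weights: ", nrow(x$W), " hidden nodes x ", ncol(x$W),
      " inputs, ", x$distribution, " draws (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Hidden-layer feature matrix of an ELM
#'
#' Evaluates the hidden layer for every sample (column) of an expression
#' matrix: `F[j, i] = w_i . x_j + b_i`. By default the literal
#' pre-activation values are returned — the feature matrix is then a pure
#' random affine projection; `activation = "sigmoid"` applies the
#' conventional ELM squashing instead.
#'
#' @param weights An [elm_weights()] object with `n_input` equal to the
#'   gene count of `x`.
#' @param x Genes x samples expression matrix.
#' @param activation `"linear"` (default, pre-activation), `"sigmoid"`, or
#'   `"hardlim"`.
#' @return Samples x n_hidden numeric matrix; rownames are sample IDs,
#'   colnames `F1..Fd`.
#' @export
elm_features <- function(weights, x,
                         activation = c("linear", "sigmoid", "hardlim")) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  if (ncol(weights$W) != nrow(x)) {
    stop("weight/input dimension mismatch: weights expect ", ncol(weights$W),
         " genes, matrix has ", nrow(x))
  }
  f <- t(x) %*% t(weights$W)
  f <- sweep(f, 2L, weights$b, "+")
  f <- activation_fun(activation)(f)
  dimnames(f) <- list(colnames(x), paste0("F", seq_len(nrow(weights$W))))
  f
}

#' Train the ELM regression (autoencoding) model
#'
#' Fits the output weights of the single-hidden-layer network by least
#' squares with the inputs as their own targets: `beta = pinv(H) %*% T`
#' where `H` is the samples x n_hidden hidden-output matrix under the
#' chosen activation, `T = t(x)`, and `pinv` is the Moore-Penrose
#' pseudoinverse (singular values below `1e-10 * s_max` zeroed). When
#' `n_hidden >= N` and `H` has full row rank the fit is exact.
#'
#' @inheritParams elm_features
#' @param activation Activation of the hidden layer during training
#'   (default `"linear"`, matching the feature definition).
#' @return An object of class `"elm_model"`: list with `weights`, `beta`
#'   (n_hidden x n_genes), `activation`, `n_output`, and the training
#'   reconstruction `rmse`.
#' @export
elm_regression <- function(weights, x,
                           activation = c("linear", "sigmoid")) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  h <- elm_features(weights, x, activation = activation)
  if (any(!is.finite(h))) {
    stop("non-finite hidden outputs; rescale the input expression values")
  }
  targets <- t(x)
  beta <- pinv(h) %*% targets
  resid <- h %*% beta - targets
  structure(
    list(
      weights = weights,
      beta = beta,
      activation = activation,
      n_output = ncol(targets),
      rmse = sqrt(mean(resid^2))
    ),
    class = "elm_model"
  )
}

#' @export
print.elm_model <- function(x, ...) {
  cat("ELM model: ", nrow(x$beta), " hidden nodes -> ", x$n_output,
      " outputs (", x$activation, " hidden activation)\n", sep = "")
  cat("training reconstruction RMSE:", format(x$rmse, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.elm_model <- function(object, ...) object$beta

#' Train a hard-limit ELM classifier
#'
#' Trains an ELM for classification: the hidden layer uses the hard-limit
#' step activation `g(z) = 1 if z >= 0 else 0`, there is one output node
#' per subtype, targets are one-hot rows, and the output weights are the
#' least-squares solution `beta = pinv(H) %*% T`. Used to transfer
#' subtypes discovered on a training cohort to an independent cohort.
#'
#' @param x Genes x samples training expression matrix (typically the
#'   harmonized, per-cohort standardized shared gene space; see
#'   [harmonize_cohorts()]).
#' @param labels Integer subtype labels in `1..k`, one per sample; every
#'   class must be represented.
#' @param n_hidden Number of hidden nodes (default 50).
#' @param seed Seed for the random input weights.
#' @param distribution Input weight distribution, see [elm_weights()].
#' @return An object of class `c("elm_classifier", "elm_model")` storing
#'   the weights, `beta`, `k`, the gene list, and training accuracy.
#' @seealso [predict.elm_classifier()]
#' @export
elm_classifier <- function(x, labels, n_hidden = 50, seed = 1,
                           distribution = c("uniform", "gaussian")) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != ncol(x)) stop("one label per sample required")
  k <- max(labels)
  if (k < 2L) stop("need at least 2 classes")
  counts <- tabulate(labels, nbins = k)
  if (any(counts == 0L)) {
    stop("class with zero members: ", paste(which(counts == 0L), collapse = ", "))
  }
  w <- elm_weights(nrow(x), n_hidden, seed, match.arg(distribution))
  h <- elm_features(w, x, activation = "hardlim")
  targets <- matrix(0, ncol(x), k)
  targets[cbind(seq_len(ncol(x)), labels)] <- 1
  beta <- pinv(h) %*% targets
  model <- structure(
    list(
      weights = w, beta = beta, activation = "hardlim",
      n_output = k, k = k, genes = rownames(x),
      rmse = sqrt(mean((h %*% beta - targets)^2))
    ),
    class = c("elm_classifier", "elm_model")
  )
  model$train_accuracy <-
    mean(predict(model, x) == labels)
  model
}

#' Predict subtype labels with a trained ELM classifier
#'
#' Evaluates the hard-limit hidden layer on each sample, multiplies by the
#' trained output weights, and assigns the class of the maximal output
#' node; ties go to the smallest class index.
#'
#' @param object An [elm_classifier()] model.
#' @param newdata Genes x samples matrix. If it carries rownames and the
#'   model stores a gene list, rows are matched by gene symbol (all model
#'   genes must be present); otherwise the gene dimension must match.
#' @param ... Unused.
#' @return Named integer vector of class labels in `1..k`.
#' @export
predict.elm_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$genes) && !is.null(rownames(newdata))) {
    miss <- setdiff(object$genes, rownames(newdata))
    if (length(miss)) {
      stop("newdata is missing ", length(miss), " model genes (e.g. ",
           miss[1L], ")")
    }
    newdata <- newdata[object$genes, , drop = FALSE]
  } else if (nrow(newdata) != ncol(object$weights$W)) {
    stop("dimension mismatch: model expects ", ncol(object$weights$W),
         " genes, newdata has ", nrow(newdata))
  }
  h <- elm_features(object$weights, newdata, activation = "hardlim")
  scores <- h %*% object$beta
  out <- max.col(scores, ties.method = "first")
  names(out) <- colnames(newdata)
  out
}

#' @export
print.elm_classifier <- function(x, ...) {
  cat("Hard-limit ELM classifier: ", nrow(x$beta), " hidden nodes, ",
      x$k, " classes, ", length(x$genes), " genes\n", sep = "")
  cat("training accuracy:", format(x$train_accuracy, digits = 4), "\n")
  invisible(x)
}

#' Serialize / restore an ELM model as JSON
#'
#' Writes seed, distribution, `W`, `b`, `beta`, activation, gene list and
#' class count to a JSON file so a trained classifier is portable across
#' cohorts and sessions.
#'
#' @param model An `"elm_model"` or `"elm_classifier"`.
#' @param path Output (input) JSON path.
#' @return `write_elm_model`: `path` invisibly. `read_elm_model`: the
#'   restored model.
#' @export
write_elm_model <- function(model, path) {
  payload <- list(
    class = class(model),
    seed = model$weights$seed,
    distribution = model$weights$distribution,
    n_hidden = nrow(model$weights$W),
    n_input = ncol(model$weights$W),
    W = as.vector(t(model$weights$W)),
    b = model$weights$b,
    beta = as.vector(t(model$beta)),
    n_output = model$n_output,
    activation = model$activation,
    genes = model$genes,
    k = model$k
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- structure(
    list(
      W = matrix(p$W, p$n_hidden, p$n_input, byrow = TRUE),
      b = p$b, seed = p$seed, distribution = p$distribution
    ),
    class = "elm_weights"
  )
  structure(
    list(
      weights = w,
      beta = matrix(p$beta, p$n_hidden, p$n_output, byrow = TRUE),
      activation = p$activation,
      n_output = p$n_output,
      k = p$k,
      genes = p$genes
    ),
    class = p$class
  )
}
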