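# Fixtures built in code: small expression matrices, Gaussian blobs, and
# brute-force oracles used to check the package's implementations.

# samples x d Gaussian blobs around the given centers
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  d <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(c) {
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[c, ], n_per, d, byrow = TRUE)
  }))
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# genes x samples expression matrix with two well-separated sample groups
make_separable_expr <- function(n_genes = 20, n_per = 20, shift = 5,
                                sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per
  m <- matrix(rnorm(n_genes * n, sd = sd), n_genes, n)
  m[, seq_len(n_per)] <- m[, seq_len(n_per)] + shift
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n)))
  list(x = m, labels = rep(1:2, each = n_per))
}

rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# independent double-loop silhouette oracle
brute_silhouette <- function(f, labels) {
  d <- as.matrix(dist(f))
  n <- nrow(f)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# run the installed CLI script; returns list(status, stdout, stderr)
run_cli <- function(...) {
  script <- system.file("cli", "elmcc-cli.R", package = "elmcc")
  stopifnot(nzchar(script))
  out <- tempfile(); err <- tempfile()
  status <- system2(file.path(R.home("bin"), "Rscript"),
                    c(script, vapply(list(...), as.character, character(1))),
                    stdout = out, stderr = err,
                    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
  list(status = status,
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
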