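# Expression matrix and clinical table input/output, filtering and
# cross-cohort harmonization.
#
# The package's universal currency is a plain numeric matrix with genes in
# rows (unique rownames = gene symbols) and samples in columns (unique
# colnames = sample IDs), on a log scale (log2-TPM or normalized microarray
# intensity).

#' Read a gene expression matrix from delimited text
#'
#' Reads a TSV/CSV expression table into the canonical genes x samples
#' matrix. The file must have a header row and an ID column (column 1).
#' Files written in either orientation are supported; the result is always
#' genes in rows. Duplicate gene symbols are collapsed by keeping the row
#' with the highest scaled median absolute deviation (the most informative
#' probe/transcript); duplicate sample IDs are an error. Lines starting
#' with `#` are ignored, so provenance headers written by
#' [write_expression()] round-trip.
#'
#' @param path Path to the delimited text file.
#' @param orientation `"genes_in_rows"` (default) if rows are genes and the
#'   header holds sample IDs, `"samples_in_rows"` for the transpose.
#' @param sep Field delimiter (default tab).
#' @param na_action `"error"` (default) refuses matrices with missing
#'   values; `"drop"` removes genes with any missing entry and reports the
#'   count.
#' @return A numeric matrix, genes x samples, with unique dimnames. If
#'   genes were dropped or collapsed, attributes `"n_dropped_na"` /
#'   `"n_collapsed"` record the counts.
#' @seealso [write_expression()], [mad_filter()]
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            sep = "\t",
                            na_action = c("error", "drop")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 2L) stop("expected an ID column plus at least one data column")
  ids <- as.character(df[[1L]])
  cn <- colnames(df)[-1L]  # data.frame subsetting would mangle duplicates
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))[1L]
      stop("non-numeric value in column '", cn[j],
           "', row '", ids[if (is.na(bad)) 1L else bad], "'")
    }
  }
  m <- as.matrix(body)
  dimnames(m) <- list(ids, cn)
  if (orientation == "samples_in_rows") m <- t(m)

  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }

  n_dropped <- 0L
  if (anyNA(m)) {
    if (na_action == "error") {
      stop("matrix contains missing values; use na_action = \"drop\" to ",
           "remove incomplete genes")
    }
    bad <- apply(m, 1L, anyNA)
    n_dropped <- sum(bad)
    message("dropped ", n_dropped, " genes with missing values")
    m <- m[!bad, , drop = FALSE]
  }

  n_collapsed <- 0L
  if (anyDuplicated(rownames(m))) {
    mads <- apply(m, 1L, stats::mad)
    keep <- rep(TRUE, nrow(m))
    for (g in unique(rownames(m)[duplicated(rownames(m))])) {
      rows <- which(rownames(m) == g)
      keep[rows] <- FALSE
      keep[rows[which.max(mads[rows])]] <- TRUE
      n_collapsed <- n_collapsed + length(rows) - 1L
    }
    message("collapsed ", n_collapsed,
            " duplicate gene rows (kept highest-MAD row)")
    m <- m[keep, , drop = FALSE]
  }
  if (n_dropped > 0L) attr(m, "n_dropped_na") <- n_dropped
  if (n_collapsed > 0L) attr(m, "n_collapsed") <- n_collapsed
  m
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: writes genes x samples with the gene
#' symbol in column 1 and sample IDs in the header. Optional comment
#' lines (prefixed `#`) carry provenance and are skipped on re-read.
#'
#' @param m Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param header Optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, sep = "\t", header = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = sep), con)
  body <- apply(m, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = sep))
  writeLines(paste(rownames(m), body, sep = sep), con)
  invisible(path)
}

#' Read a clinical table
#'
#' Reads a TSV with mandatory columns `sample_id`, `time`, `event`
#' (additional covariate columns are kept). Times must be non-negative,
#' events coded 0/1.
#'
#' @param path Path to the TSV file.
#' @param sep Field delimiter.
#' @return A data.frame with at least `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$time < 0)) stop("negative survival times")
  if (!all(df$event %in% c(0, 1))) stop("event must be coded 0/1")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Convert RSEM scaled estimates to log2-TPM
#'
#' TCGA level-3 RSEM gene files report scaled estimates in `[0, 1]`;
#' abundance in transcripts per million is the scaled estimate times 1e6,
#' which is then log2-transformed after adding a pseudocount.
#'
#' @param m Genes x samples matrix of RSEM scaled estimates (non-negative).
#' @param pseudocount Positive offset added before the log (default 1, so
#'   zero abundance maps to 0).
#' @return `log2(m * 1e6 + pseudocount)`, same shape and dimnames.
#' @export
rsem_to_log2tpm <- function(m, pseudocount = 1) {
  if (any(m < 0)) stop("RSEM scaled estimates must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  log2(m * 1e6 + pseudocount)
}

#' Filter genes by median absolute deviation
#'
#' Removes low-variability genes before subtyping: a gene is retained when
#' its MAD across samples exceeds `threshold`. By default the MAD carries
#' the usual consistency constant 1.4826 (so it estimates the standard
#' deviation under normality, matching [stats::mad()]); set
#' `constant = 1` for the raw median absolute deviation.
#'
#' @param m Genes x samples matrix.
#' @param threshold Positive cutoff; genes with scaled MAD > threshold are
#'   kept.
#' @param constant Consistency constant multiplying the raw MAD
#'   (default 1.4826).
#' @return The filtered matrix; attribute `"filter_report"` records
#'   `n_in`, `n_out`, `threshold` and `constant`.
#' @examples
#' x <- matrix(rnorm(200, sd = rep(c(0.1, 2), each = 10)), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' dim(mad_filter(x, 1))
#' @export
mad_filter <- function(m, threshold, constant = 1.4826) {
  if (threshold <= 0) stop("threshold must be positive")
  if (nrow(m) < 1L || ncol(m) < 2L) {
    stop("need at least one gene and two samples")
  }
  mads <- apply(m, 1L, stats::mad, constant = constant)
  out <- m[mads > threshold, , drop = FALSE]
  attr(out, "filter_report") <- list(
    n_in = nrow(m), n_out = nrow(out),
    threshold = threshold, constant = constant
  )
  out
}

#' Harmonize two cohorts to a shared gene space
#'
#' Restricts a training and a validation expression matrix to the
#' intersection of their gene symbols (in the training cohort's order) so
#' a classifier trained on one cohort can be applied to the other.
#' Optionally z-scores each gene within its own cohort, which absorbs
#' platform-level location/scale differences; genes with zero variance in
#' either cohort are then dropped from both.
#'
#' @param train,test Genes x samples matrices.
#' @param standardize If `TRUE`, z-score each gene row per cohort.
#' @return A list with elements `train`, `test` (equal gene lists, equal
#'   order) and `dropped` (genes removed for zero variance).
#' @export
harmonize_cohorts <- function(train, test, standardize = FALSE) {
  shared <- intersect(rownames(train), rownames(test))
  if (length(shared) < 2L) stop("fewer than 2 shared gene IDs between cohorts")
  tr <- train[shared, , drop = FALSE]
  te <- test[shared, , drop = FALSE]
  dropped <- character(0)
  if (standardize) {
    sd_tr <- apply(tr, 1L, stats::sd)
    sd_te <- apply(te, 1L, stats::sd)
    bad <- sd_tr == 0 | sd_te == 0
    if (any(bad)) {
      dropped <- shared[bad]
      message("dropped ", sum(bad), " zero-variance genes during harmonization")
      tr <- tr[!bad, , drop = FALSE]
      te <- te[!bad, , drop = FALSE]
    }
    zscore <- function(x) t(scale(t(x)))[, , drop = FALSE]
    tr <- zscore(tr)
    te <- zscore(te)
  }
  list(train = tr, test = te, dropped = dropped)
}
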