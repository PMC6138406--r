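# Expression I/O, transformation, filtering, harmonization.

test_that("read/write round-trips and handles both orientations", {
  m <- rand_expr(3, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path)
  expect_identical(dim(back), c(3L, 2L))
  expect_equal(back, m, tolerance = 1e-12)

  # transposed file read with samples_in_rows gives the identical matrix
  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("sample_id", rownames(m)), collapse = "\t"),
               sapply(seq_len(ncol(m)), function(j)
                 paste(c(colnames(m)[j], format(m[, j], digits = 15)),
                       collapse = "\t"))), tpath)
  back_t <- read_expression(tpath, orientation = "samples_in_rows")
  expect_equal(back_t, m, tolerance = 1e-10)

  # provenance comment headers are skipped on re-read
  hpath <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, hpath, header = c("tool v1", "config: x=1"))
  expect_equal(read_expression(hpath), m, tolerance = 1e-12)
})

test_that("duplicate gene rows collapse to the highest-MAD row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  low  <- c(1.0, 1.1, 1.0, 0.9)   # raw MAD ~ 0.05
  high <- c(1.0, 3.0, 6.0, 0.5)   # raw MAD ~ 2
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               paste(c("TP53", low), collapse = "\t"),
               paste(c("TP53", high), collapse = "\t"),
               paste(c("EGFR", 1:4), collapse = "\t")), path)
  suppressMessages(m <- read_expression(path))
  expect_identical(nrow(m), 2L)
  expect_equal(unname(m["TP53", ]), high)
})

test_that("malformed inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\toops", "g2\t3\t4"), path)
  expect_error(read_expression(path), "non-numeric")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts1", "g1\t1\t2"), dup)
  expect_error(read_expression(dup), "duplicate sample")

  nap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\tNA", "g2\t3\t4"), nap)
  expect_error(read_expression(nap), "missing values")
  suppressMessages(m <- read_expression(nap, na_action = "drop"))
  expect_identical(rownames(m), "g2")
  expect_identical(attr(m, "n_dropped_na"), 1L)
})

test_that("RSEM scaled estimates convert to log2-TPM", {
  m <- matrix(c(1e-6, 0, 1e-5, 0.5), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out0 <- rsem_to_log2tpm(m, pseudocount = 0)
  expect_equal(out0["a", "s1"], 0)          # log2(1)
  out1 <- rsem_to_log2tpm(m, pseudocount = 1)
  expect_equal(out1["b", "s1"], 0)          # log2(0 + 1)
  expect_equal(out1["a", "s2"], log2(11), tolerance = 1e-12)
  expect_equal(out1["a", "s2"], 3.4594, tolerance = 1e-4)
  expect_identical(dimnames(out1), dimnames(m))
  expect_error(rsem_to_log2tpm(-m), "non-negative")
})

test_that("MAD filter keeps exactly the genes above threshold", {
  m <- rbind(const = rep(5, 5), ramp = 1:5, spread = c(0, 10, 20, 30, 40))
  colnames(m) <- paste0("s", 1:5)
  out <- mad_filter(m, 1)
  # constant gene has MAD 0; ramp has scaled MAD exactly 1.4826 > 1
  expect_setequal(rownames(out), c("ramp", "spread"))
  rep <- attr(out, "filter_report")
  expect_identical(rep$n_in, 3L)
  expect_identical(rep$n_out, 2L)
  # raw (unscaled) MAD of the ramp is exactly 1, not > 1
  expect_identical(rownames(mad_filter(m, 1, constant = 1)), "spread")
  expect_error(mad_filter(m, 0), "positive")
})

test_that("MAD filter is idempotent and sample-order invariant", {
  m <- rand_expr(50, 12, seed = 3) * rep(runif(50, 0.1, 3), 12)
  f1 <- mad_filter(m, 1)
  f2 <- mad_filter(f1, 1)
  expect_equal(dim(f2), dim(f1))
  expect_equal(unclass(f2), unclass(f1), ignore_attr = TRUE)
  perm <- sample(ncol(m))
  expect_setequal(rownames(mad_filter(m[, perm], 1)), rownames(f1))
})

test_that("cohort harmonization intersects genes and optionally z-scores", {
  train <- rand_expr(4, 6, seed = 1)
  rownames(train) <- c("A", "B", "C", "Z")
  test <- rand_expr(4, 5, seed = 2)
  rownames(test) <- c("B", "C", "D", "Z")
  h <- harmonize_cohorts(train, test)
  expect_identical(rownames(h$train), c("B", "C", "Z"))
  expect_identical(rownames(h$train), rownames(h$test))
  expect_equal(h$train, train[c("B", "C", "Z"), ])

  hz <- harmonize_cohorts(train, test, standardize = TRUE)
  expect_lt(max(abs(rowMeans(hz$train))), 1e-10)
  expect_lt(max(abs(apply(hz$test, 1, sd) - 1)), 1e-10)

  same <- harmonize_cohorts(train, train)
  expect_equal(same$test, train)
  rownames(test) <- paste0("X", 1:4)
  expect_error(harmonize_cohorts(train, test), "shared gene")
})
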