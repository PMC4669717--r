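test_that("expression_matrix validates ids, labels and finiteness", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(m, c(s1 = "case", s2 = "control")),
               "duplicate probe id.*a")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(m2, c(s1 = "case")), "unlabelled.*s2")
  expect_error(expression_matrix(m2, c(s1 = "case", s2 = "tumor")),
               "case.*control")
  m2[1, 1] <- NA
  expect_error(expression_matrix(m2, c(s1 = "case", s2 = "control")),
               "finite")
})

test_that("TSV and GCT round trips reproduce the matrix exactly", {
  x <- tiny_matrix()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gct <- withr::local_tempfile(fileext = ".gct")
  write_expression_matrix(x, tsv, "tsv")
  write_expression_matrix(x, gct, "gct")

  from_tsv <- read_expression_matrix(tsv, paste0(tsv, ".labels"))
  from_gct <- read_expression_matrix(gct, x$labels, format = "auto")
  expect_identical(from_tsv$values, x$values)
  expect_identical(from_tsv$labels, x$labels)
  expect_identical(from_gct$values, from_tsv$values)
  expect_equal(sum(from_tsv$labels == "case"), 2)

  # full precision survives for irrational values too
  y <- x
  y$values[] <- x$values * pi
  write_expression_matrix(y, tsv, "tsv")
  expect_identical(read_expression_matrix(tsv, y$labels)$values, y$values)
})

test_that("malformed inputs are rejected with coordinates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "a\t1\t2", "a\t3\t4"), tsv)
  expect_error(read_expression_matrix(tsv, c(s1 = "case", s2 = "control")),
               "duplicate probe id.*a")
  writeLines(c("gene\ts1", "a\t1"), tsv)
  expect_error(read_expression_matrix(tsv, c(s1 = "case")),
               "malformed TSV header")
  gct <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t1", "NAME\tDescription\ts1", "a\tna\t1"), gct)
  expect_error(read_expression_matrix(gct, c(s1 = "case"), format = "gct"),
               "size line says 2 x 1")
})

test_that("quantile normalization equalizes column distributions", {
  x <- tiny_matrix()
  qn <- quantile_normalize_log2(x)
  sorted <- apply(qn$values, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  # hand-derived two-column case
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  out <- quantile_normalize_log2(expression_matrix(
    m, c(s1 = "case", s2 = "control")))
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))
  # identical columns are a fixed point
  m2 <- matrix(rep(c(5, 1, 3), 2), 3, 2,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  x2 <- expression_matrix(m2, c(s1 = "case", s2 = "control"))
  expect_equal(quantile_normalize_log2(x2)$values, x2$values)
})

test_that("quantile normalization is idempotent and matches limma", {
  set.seed(42)
  m <- matrix(rnorm(200, 8, 2), 50, 4,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:4)))
  x <- expression_matrix(m, setNames(rep(c("case", "control"), each = 2),
                                     colnames(m)))
  once <- quantile_normalize_log2(x)
  twice <- quantile_normalize_log2(once)
  expect_equal(twice$values, once$values)
  expect_equal(once$values,
               limma::normalizeQuantiles(m, ties = TRUE),
               ignore_attr = TRUE)
})

test_that("log2 transform is applied when requested, positivity enforced", {
  m <- matrix(c(2, 4, 8, 16), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  x <- expression_matrix(m, c(s1 = "case", s2 = "control"))
  out <- quantile_normalize_log2(x, already_log2 = FALSE)
  expect_equal(sort(out$values[, 1]), sort(out$values[, 2]))
  expect_true(all(out$values <= 4))
  m[1, 1] <- -1
  xneg <- expression_matrix(m, c(s1 = "case", s2 = "control"))
  expect_error(quantile_normalize_log2(xneg, already_log2 = FALSE),
               "strictly positive")
})

test_that("restrict_to_platform intersects, preserves order, is idempotent", {
  x <- tiny_matrix()  # probes p1 p2 p3
  r <- restrict_to_platform(x, c("p3", "p2", "zz"))
  expect_identical(probe_ids(r), c("p2", "p3"))
  expect_identical(sample_ids(r), sample_ids(x))
  expect_identical(restrict_to_platform(r, c("p3", "p2", "zz"))$values,
                   r$values)
  expect_identical(restrict_to_platform(x, c("p1", "p2", "p3", "p4"))$values,
                   x$values)
  expect_error(restrict_to_platform(x, c("q1", "q2")), "no matrix probes")
  # commutes with sample subsetting
  a <- subset_samples(restrict_to_platform(x, c("p1", "p3")), c("s1", "s3"))
  b <- restrict_to_platform(subset_samples(x, c("s1", "s3")), c("p1", "p3"))
  expect_identical(a$values, b$values)
})

test_that("probe lists read with comments and duplicate rejection", {
  f <- withr::local_tempfile()
  writeLines(c("# platform", "p1", "", "p2"), f)
  expect_identical(read_probe_list(f), c("p1", "p2"))
  writeLines(c("p1", "p1"), f)
  expect_error(read_probe_list(f), "duplicate")
})
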