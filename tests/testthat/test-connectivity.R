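test_that("ks_tag_score reproduces hand-derived and analytic cases", {
  expect_equal(ks_tag_score(c(1, 2), 10), 0.8)
  expect_equal(ks_tag_score(c(9, 10), 10), -0.9)
  for (n in c(3, 7, 10))
    expect_equal(ks_tag_score(seq_len(n), n), -1 / n)
  expect_error(ks_tag_score(integer(0), 10), "empty")
  expect_error(ks_tag_score(c(1, 1), 10), "distinct")
  expect_error(ks_tag_score(c(0, 5), 10), "distinct integers")
  expect_error(ks_tag_score(c(5, 11), 10), "distinct integers")
})

test_that("ks_tag_score agrees with the brute-force oracle on random cases", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(2:40, 1)
    t <- sample.int(n, 1)
    v <- sort(sample.int(n, t))
    expect_equal(ks_tag_score(v, n), ks_oracle(v, n))
  }
})

test_that("vectorized KS matches the scalar path and reversal antisymmetry", {
  set.seed(13)
  n <- 25
  pos <- t(replicate(50, sample.int(n, 4)))
  vec <- sigreverse:::ks_tag_score_matrix(pos, n)
  scal <- apply(pos, 1, ks_tag_score, n = n)
  expect_equal(vec, scal)
  # rank reversal swaps the top-excess and bottom-excess maxima exactly
  # (a' = b - 1/n, b' = a + 1/n), so scores negate up to the 2/n
  # discreteness of the rank grid
  ab <- function(v) {
    t <- length(v); j <- seq_len(t)
    c(a = max(j / t - v / n), b = max(v / n - (j - 1) / t))
  }
  for (i in 1:50) {
    v <- sort(pos[i, ])
    rev_v <- sort(n + 1 - v)
    x <- ab(v)
    expect_equal(ab(rev_v)[["a"]], x[["b"]] - 1 / n)
    expect_equal(ab(rev_v)[["b"]], x[["a"]] + 1 / n)
    s <- ks_tag_score(v, n); r <- ks_tag_score(rev_v, n)
    if (x[["a"]] > x[["b"]] || x[["b"]] - x[["a"]] > 2 / n) {
      expect_equal(s + r, -1 / n)
    } else {
      # a/b near-tie: the negative branch wins on both sides
      expect_lte(s, 0); expect_lte(r, 0)
    }
  }
})

test_that("instance_es combines the two tag sets per the sign rule", {
  sig <- signature_from_tags(c("p01", "p02"), c("p09", "p10"))
  ranks <- named_ranks(1:10)
  r <- instance_es(sig, ranks)
  expect_equal(r$ks_up, 0.8)
  expect_equal(r$ks_down, -0.9)
  expect_equal(r$es, 1.7)
  expect_equal(r$n_dropped, 0)

  # reversed profile: up tags at bottom, down tags at top
  rev <- named_ranks(10:1)
  expect_equal(instance_es(sig, rev)$es, -1.7)

  # same-sign rule: both tag sets near the top
  sig2 <- signature_from_tags(c("p01", "p02"), c("p03", "p04"))
  expect_equal(instance_es(sig2, ranks)$es, 0)

  # one-sided signatures use the surviving side
  expect_equal(instance_es(signature_from_tags(c("p01", "p02"),
                                               character(0)), ranks)$es, 0.8)
  expect_equal(instance_es(signature_from_tags(character(0),
                                               c("p09", "p10")), ranks)$es,
               0.9)

  # missing tags are dropped and counted; a fully absent side errors
  sig3 <- signature_from_tags(c("p01", "zz"), c("p10", "qq"))
  r3 <- instance_es(sig3, ranks)
  expect_equal(r3$n_dropped, 2)
  expect_error(instance_es(signature_from_tags(c("zz"), c("p10")), ranks),
               "absent from the profile universe")
})

test_that("scale_scores maps extremes to +/-1 and keeps zeros", {
  expect_equal(scale_scores(c(0.8, -0.4, 0.2)), c(1.0, -1.0, 0.25))
  expect_equal(scale_scores(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(scale_scores(c(0.5, 0.25)), c(1.0, 0.5))
  set.seed(7)
  x <- rnorm(100)
  s <- scale_scores(x)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(max(s), 1)
  expect_equal(min(s), -1)
  expect_error(scale_scores(numeric(0)), "at least one")
})

test_that("drug_enrichment scores member positions in the ordering", {
  ids <- sprintf("i%02d", 1:10)
  expect_equal(drug_enrichment(ids, ids[1:2]), 0.8)
  expect_equal(drug_enrichment(ids, ids[9:10]), -0.9)
  expect_equal(drug_enrichment(ids, ids), -1 / 10)
  expect_error(drug_enrichment(ids, character(0)), "zero instances")
  expect_error(drug_enrichment(ids, "nope"), "missing from the ordering")
})

test_that("exact drug p-values enumerate the null; permutation agrees", {
  expect_equal(drug_p_value(-0.9, 10, 2, "exact"), 1 / 45)
  # an observed 0 scored against a symmetric null sits at its center
  # (the enumerated KS null itself is skewed: a zero score is impossible)
  sym_null <- c(seq(0.05, 1, by = 0.05), -seq(0.05, 1, by = 0.05))
  expect_gte(drug_p_value(0, 10, 2, "permutation", null_scores = sym_null),
             0.5)
  mc <- drug_p_value(-0.9, 10, 2, "permutation", n_perm = 4400, seed = 21)
  expect_lt(abs(mc - 1 / 45), 0.01)
  expect_error(drug_p_value(-0.9, 10, 2, "permutation", n_perm = 50),
               ">= 100")
  expect_error(drug_p_value(-0.5, 50, 10, "exact"), "choose")
  # permutation mode is reproducible from its seed
  expect_identical(
    drug_p_value(-0.5, 30, 3, "permutation", n_perm = 500, seed = 5),
    drug_p_value(-0.5, 30, 3, "permutation", n_perm = 500, seed = 5))
})

test_that("query flags planted reversers and little else", {
  tr <- cohort_truth(seed = 1)
  ct <- compendium_truth(seed = 7)
  comp <- make_compendium(tr, ct)
  sig <- signature_from_tags(tr$planted_up, tr$planted_down)
  res <- query_compendium(sig, comp, seed = 7)
  hits <- res$drugs$drug[res$drugs$hit]
  expect_true(all(names(ct$reversers) %in% hits))
  expect_lte(length(setdiff(hits, names(ct$reversers))), 4)
  expect_true(all(res$instances$score >= -1 & res$instances$score <= 1))
  expect_true(all(abs(res$instances$es) <= 2))
  expect_true(all(res$drugs$hit == (res$drugs$enrichment < 0 &
                                      res$drugs$p_value < 0.05)))
})

test_that("query is invariant to instance order in the input compendium", {
  tr <- cohort_truth(n_up = 20L, n_down = 20L, seed = 3)
  ct <- compendium_truth(n_drugs = 8L, instances_per_drug = 3L,
                         reversers = c(drug_02 = 2.0), seed = 9)
  comp <- make_compendium(tr, ct, n_probes = 300L)
  sig <- signature_from_tags(tr$planted_up, tr$planted_down)
  res1 <- query_compendium(sig, comp, n_perm = 1000, seed = 2)

  set.seed(31)
  perm <- sample(ncol(comp$ranks))
  shuffled <- reference_compendium(comp$ranks[, perm],
                                   comp$instances[perm, ])
  res2 <- query_compendium(sig, shuffled, n_perm = 1000, seed = 2)
  expect_equal(res2$drugs, res1$drugs)
  expect_equal(res2$instances, res1$instances, ignore_attr = TRUE)
})

test_that("degenerate compendia behave per contract", {
  tr <- cohort_truth(n_up = 5L, n_down = 5L, seed = 2)
  ct <- compendium_truth(n_drugs = 1L, instances_per_drug = 4L,
                         reversers = numeric(0), seed = 3)
  comp <- make_compendium(tr, ct, n_probes = 50L)
  sig <- signature_from_tags(tr$planted_up, tr$planted_down)
  res <- query_compendium(sig, comp, seed = 1)
  expect_equal(res$drugs$enrichment, -1 / 4)
  expect_false(res$drugs$hit)

  disjoint <- signature_from_tags("xx", "yy")
  expect_error(query_compendium(disjoint, comp), "absent")
})

test_that("compendium round-trips through ranks/instances TSV and GMT", {
  tr <- cohort_truth(n_up = 3L, n_down = 3L, seed = 6)
  ct <- compendium_truth(n_drugs = 3L, instances_per_drug = 2L,
                         reversers = c(drug_01 = 1.5), seed = 4)
  comp <- make_compendium(tr, ct, n_probes = 30L)
  dir <- withr::local_tempdir()
  write_compendium(comp, dir, "c")
  back <- read_compendium(file.path(dir, "c_ranks.tsv"),
                          file.path(dir, "c_instances.tsv"))
  expect_identical(back$ranks, comp$ranks)
  expect_identical(back$instances, comp$instances)
  gmt <- file.path(dir, "c.gmt")
  write_drug_gmt(comp, gmt)
  lines <- strsplit(readLines(gmt), "\t")
  expect_length(lines, 3)
  expect_equal(vapply(lines, length, integer(1)), rep(4L, 3))
})
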