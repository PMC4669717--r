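# Independent brute-force KS oracle: evaluates the two empirical-CDF
# differences at every rank position of the universe (not the max-over-j
# closed form used by ks_tag_score).
ks_oracle <- function(v, n) {
  v <- sort(v)
  t <- length(v)
  a <- max(vapply(0:n, function(i) sum(v <= i) / t - i / n, numeric(1)))
  b <- max(vapply(1:n, function(i) i / n - sum(v <= i - 1) / t, numeric(1)))
  if (a > b) a else -b
}

# Small labelled matrix fixture: 3 probes x 4 samples, values chosen so no
# two are equal (round-trip and normalization tests stay tie-free).
tiny_matrix <- function() {
  vals <- matrix(c(1.5, 2.25, 3.125,
                   4.0625, 5.5, 6.75,
                   7.875, 8.25, 9.5,
                   10.125, 11.0625, 12.375),
                 nrow = 3, ncol = 4,
                 dimnames = list(c("p1", "p2", "p3"),
                                 c("s1", "s2", "s3", "s4")))
  expression_matrix(vals, c(s1 = "case", s2 = "case",
                            s3 = "control", s4 = "control"))
}

# Rank profile as a named vector: probes p01..p<n>, given their ranks.
named_ranks <- function(ranks) {
  stats::setNames(ranks, sprintf("p%02d", seq_along(ranks)))
}
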