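#' Kolmogorov-Smirnov tag enrichment score
#'
#' The Connectivity-Map-style KS statistic for a tag set inside a ranked
#' list. With tag positions `V(1) < ... < V(t)` in a universe of size `n`,
#' let `a = max_j [ j/t - V(j)/n ]` and `b = max_j [ V(j)/n - (j-1)/t ]`;
#' the score is `a` when `a > b`, else `-b`. Positive scores mean the tags
#' cluster near the top (rank 1 = most up-regulated by treatment), negative
#' scores near the bottom; the value is always in `[-1, 1]`.
#'
#' @param tag_positions integer vector of tag ranks; must be distinct values
#'   in `1..n` (any order; sorted internally).
#' @param n size of the ranked universe.
#' @return the signed KS score, a scalar in `[-1, 1]`.
#' @export
#' @examples
#' ks_tag_score(c(1, 2), 10)   # +0.8 : tags at the very top
#' ks_tag_score(c(9, 10), 10)  # -0.9 : tags at the very bottom
ks_tag_score <- function(tag_positions, n) {
  t <- length(tag_positions)
  if (t == 0L) stop("empty tag set", call. = FALSE)
  v <- sort.int(as.numeric(tag_positions))
  if (anyDuplicated(v) || v[1L] < 1 || v[t] > n || any(v != floor(v)))
    stop("tag positions must be distinct integers in 1..n", call. = FALSE)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

# KS scores for many equal-sized position subsets at once: `pos` is an
# m x t matrix of distinct positions (rows need not be sorted). Used by the
# permutation null and exact enumeration.
ks_tag_score_matrix <- function(pos, n) {
  if (!is.matrix(pos)) pos <- matrix(pos, nrow = 1L)
  t <- ncol(pos)
  v <- matrix(pos[order(row(pos), pos)], nrow(pos), t, byrow = TRUE)
  jt <- matrix(seq_len(t) / t, nrow(pos), t, byrow = TRUE)
  a <- apply(jt - v / n, 1L, max)
  b <- apply(v / n - (jt - 1 / t), 1L, max)
  ifelse(a > b, a, -b)
}

#' Instance-level enrichment of a signature in one rank profile
#'
#' Scores the up-tag and down-tag sets separately with [ks_tag_score()] and
#' combines them: when the two KS scores disagree in sign,
#' `es = ks_up - ks_down` (so a profile that pushes up-tags down and
#' down-tags up scores strongly negative, i.e. reverses the signature);
#' when they agree in sign the combined score is 0. One-sided signatures
#' use the surviving side alone (`es = ks_up` or `es = -ks_down`). Tags
#' absent from the profile's universe are dropped and counted.
#'
#' @param sig a `Signature`.
#' @param ranks named integer vector: rank of every universe probe in this
#'   instance (1 = most up-regulated by treatment).
#' @return list with `ks_up`, `ks_down` (NA for an absent side), `es`, and
#'   `n_dropped` (tags not found in the universe).
#' @export
instance_es <- function(sig, ranks) {
  stopifnot(inherits(sig, "Signature"))
  n <- length(ranks)
  up_pos <- unname(ranks[stats::na.omit(match(sig$up_tags, names(ranks)))])
  dn_pos <- unname(ranks[stats::na.omit(match(sig$down_tags, names(ranks)))])
  dropped <- (length(sig$up_tags) - length(up_pos)) +
             (length(sig$down_tags) - length(dn_pos))
  has_up <- length(sig$up_tags) > 0L
  has_dn <- length(sig$down_tags) > 0L
  if ((has_up && !length(up_pos)) || (has_dn && !length(dn_pos)))
    stop("all tags on one required side are absent from the profile universe",
         call. = FALSE)
  if (!has_up && !has_dn)
    stop("signature has no tags", call. = FALSE)
  ks_up <- if (has_up) ks_tag_score(up_pos, n) else NA_real_
  ks_dn <- if (has_dn) ks_tag_score(dn_pos, n) else NA_real_
  es <- if (!has_dn) ks_up
        else if (!has_up) -ks_dn
        else if (sign(ks_up) != sign(ks_dn)) ks_up - ks_dn
        else 0
  list(ks_up = ks_up, ks_down = ks_dn, es = es, n_dropped = dropped)
}

#' Scale instance enrichment scores to [-1, 1]
#'
#' Divides positive scores by the maximum positive score `p` and negative
#' scores by the magnitude `q` of the minimum negative score, so the most
#' extreme instance on each present side lands exactly at +1 or -1. Zeros
#' stay zero.
#'
#' @param es numeric vector of instance ES values.
#' @return numeric vector of the same length, in `[-1, 1]`.
#' @export
scale_scores <- function(es) {
  if (!length(es)) stop("need at least one instance", call. = FALSE)
  out <- numeric(length(es))
  pos <- es > 0; neg <- es < 0
  if (any(pos)) out[pos] <- es[pos] / max(es[pos])
  if (any(neg)) out[neg] <- es[neg] / abs(min(es[neg]))
  out
}

#' Drug-level enrichment across the ordered instance list
#'
#' With all instances ordered by scaled score (descending, ties by instance
#' id), a drug's enrichment is the [ks_tag_score()] of its instances'
#' positions in that ordering. Negative values mean the drug's instances
#' cluster at the reversal end of the list.
#'
#' @param ordered_ids character vector: all instance ids, best score first.
#' @param member_ids the drug's instance ids (subset of `ordered_ids`).
#' @return signed KS enrichment in `[-1, 1]`.
#' @export
drug_enrichment <- function(ordered_ids, member_ids) {
  if (!length(member_ids)) stop("drug has zero instances", call. = FALSE)
  pos <- match(member_ids, ordered_ids)
  if (anyNA(pos))
    stop("member instance(s) missing from the ordering: ",
         paste(member_ids[is.na(pos)], collapse = ", "), call. = FALSE)
  ks_tag_score(pos, length(ordered_ids))
}

#' P-value for a drug-level enrichment score
#'
#' Null model: the drug's `t` instances occupy a uniformly random size-`t`
#' subset of the `n` ordered positions. The p-value is one-sided in the
#' observed direction (the retention rule conditions on a negative sign
#' first). Exact mode enumerates all `choose(n, t)` subsets (allowed up to
#' 1e6) and counts those at least as extreme, observed included; permutation
#' mode uses `(1 + #extreme) / (n_perm + 1)` with a seeded sample.
#'
#' @param observed the drug's enrichment score.
#' @param n total instance count.
#' @param t the drug's instance count.
#' @param mode `"exact"` or `"permutation"`.
#' @param n_perm permutation count (>= 100).
#' @param seed RNG seed for permutation mode.
#' @param null_scores optional pre-computed null KS sample for permutation
#'   mode (recycled across drugs sharing `(n, t)`); overrides `n_perm`/`seed`.
#' @return p-value in `(0, 1]`.
#' @export
drug_p_value <- function(observed, n, t, mode = c("exact", "permutation"),
                         n_perm = 10000L, seed = 1L, null_scores = NULL) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    if (choose(n, t) > 1e6)
      stop("exact mode needs choose(n, t) <= 1e6; use permutation mode",
           call. = FALSE)
    null <- ks_tag_score_matrix(t(utils::combn(n, t)), n)
    extreme <- if (observed >= 0) null >= observed else null <= observed
    return(sum(extreme) / length(null))
  }
  if (is.null(null_scores)) {
    if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
    null_scores <- with_local_seed(seed, sample_null_ks(n, t, n_perm))
  }
  extreme <- if (observed >= 0) null_scores >= observed
             else null_scores <= observed
  (1 + sum(extreme)) / (length(null_scores) + 1)
}

sample_null_ks <- function(n, t, n_perm) {
  pos <- matrix(0L, n_perm, t)
  for (i in seq_len(n_perm)) pos[i, ] <- sample.int(n, t)
  ks_tag_score_matrix(pos, n)
}

#' Query a reference compendium with a disease signature
#'
#' Runs the full connectivity screen: per-instance ES ([instance_es()]),
#' scaling ([scale_scores()]), the score-ordered instance list (ties broken
#' by instance id), per-drug enrichment ([drug_enrichment()]) with a
#' p-value ([drug_p_value()]), and the retention rule — a drug is a hit
#' when its enrichment is negative and its p-value is below `p_threshold`.
#'
#' @param sig a `Signature` whose tags overlap the compendium universe.
#' @param comp a [reference_compendium()].
#' @param n_perm permutations for the drug-level null (default 10000).
#' @param seed RNG seed for the permutation null.
#' @param p_threshold drug retention p cutoff (default 0.05).
#' @param p_mode `"auto"` (exact when `choose(n, t) <= 1e6`, else
#'   permutation), `"exact"`, or `"permutation"`.
#' @return an object of class `ConnectivityResult`: list with `instances`
#'   (data.frame: instance_id, drug, ks_up, ks_down, es, score),
#'   `drugs` (data.frame: drug, n_instances, enrichment, p_value, hit),
#'   `n_dropped_tags`, `n_permutations`, `seed`.
#' @export
query_compendium <- function(sig, comp, n_perm = 10000L, seed = 1L,
                             p_threshold = 0.05,
                             p_mode = c("auto", "exact", "permutation")) {
  stopifnot(inherits(sig, "Signature"), inherits(comp, "ReferenceCompendium"))
  p_mode <- match.arg(p_mode)
  inst <- comp$instances
  scored <- lapply(seq_len(nrow(inst)), function(i)
    instance_es(sig, comp$ranks[, i]))
  es <- vapply(scored, `[[`, numeric(1), "es")
  instances <- data.frame(
    instance_id = inst$instance_id,
    drug = inst$drug,
    ks_up = vapply(scored, `[[`, numeric(1), "ks_up"),
    ks_down = vapply(scored, `[[`, numeric(1), "ks_down"),
    es = es,
    score = scale_scores(es),
    stringsAsFactors = FALSE)
  # Ties in scaled score (common: the same-sign rule zeroes about half of
  # all null instances) are broken by a seeded random key assigned to
  # instance ids in lexicographic order. A lexicographic tie-break would
  # cluster tied instances of the same drug and wreck the drug-level null;
  # the random key keeps tied instances exchangeable while the result stays
  # deterministic in `seed` and invariant to input instance order.
  sorted_ids <- sort(instances$instance_id)
  tie_key <- with_local_seed(seed + 999983L,
                             stats::runif(length(sorted_ids)))
  ord <- order(-instances$score,
               tie_key[match(instances$instance_id, sorted_ids)])
  ordered_ids <- instances$instance_id[ord]
  n <- length(ordered_ids)

  drugs <- sort(unique(inst$drug))
  null_cache <- new.env(parent = emptyenv())
  res <- lapply(drugs, function(d) {
    members <- inst$instance_id[inst$drug == d]
    t <- length(members)
    enr <- drug_enrichment(ordered_ids, members)
    mode <- if (p_mode == "auto") {
      if (choose(n, t) <= 1e6) "exact" else "permutation"
    } else p_mode
    if (mode == "exact") {
      p <- drug_p_value(enr, n, t, "exact")
    } else {
      key <- paste0("t", t)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- with_local_seed(
          seed + t, sample_null_ks(n, t, n_perm))
      p <- drug_p_value(enr, n, t, "permutation",
                        null_scores = null_cache[[key]])
    }
    data.frame(drug = d, n_instances = t, enrichment = enr, p_value = p,
               hit = enr < 0 & p < p_threshold, stringsAsFactors = FALSE)
  })
  drugs_df <- do.call(rbind, res)
  structure(list(instances = instances[ord, ], drugs = drugs_df,
                 n_dropped_tags = scored[[1L]]$n_dropped,
                 n_permutations = n_perm, seed = seed,
                 p_threshold = p_threshold),
            class = "ConnectivityResult")
}

#' @export
print.ConnectivityResult <- function(x, ...) {
  cat(sprintf("ConnectivityResult: %d instances, %d drugs, %d hit(s)\n",
              nrow(x$instances), nrow(x$drugs), sum(x$drugs$hit)))
  invisible(x)
}

#' Write connectivity reports as TSV
#'
#' Writes `<name>_instances.tsv` (instance_id, drug, ks_up, ks_down, es,
#' score) and `<name>_drugs.tsv` (drug, n_instances, enrichment, p_value,
#' hit), full precision.
#'
#' @param res a `ConnectivityResult`.
#' @param dir output directory.
#' @param name file stem.
#' @return written paths, invisibly.
#' @export
write_connectivity <- function(res, dir, name) {
  stopifnot(inherits(res, "ConnectivityResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ipath <- file.path(dir, paste0(name, "_instances.tsv"))
  dpath <- file.path(dir, paste0(name, "_drugs.tsv"))
  inst <- res$instances
  for (col in c("ks_up", "ks_down", "es", "score"))
    inst[[col]] <- sprintf("%.17g", inst[[col]])
  utils::write.table(inst, ipath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  drugs <- res$drugs
  for (col in c("enrichment", "p_value"))
    drugs[[col]] <- sprintf("%.17g", drugs[[col]])
  utils::write.table(drugs, dpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ipath, dpath))
}
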