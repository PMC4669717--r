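#' Pooled-variance two-sample t-test
#'
#' Classic Student t with pooled variance and `df = n1 + n2 - 2`, the test
#' behind volcano selection of differentially expressed probes. Degenerate
#' inputs where both groups have zero variance are resolved by convention:
#' equal means give `t = 0, p = 1`; different means give `p = 0` with
#' `degenerate = TRUE` (the separation is infinitely many pooled SDs wide).
#'
#' @param case_values,control_values numeric vectors, each of length >= 2.
#' @return list with `t_stat`, `p_value`, `df`, `degenerate`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))
two_sample_t <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  m1 <- mean(case_values); m2 <- mean(control_values)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * stats::var(case_values) +
          (n2 - 1L) * stats::var(control_values)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2)
      return(list(t_stat = 0, p_value = 1, df = df, degenerate = FALSE))
    return(list(t_stat = sign(m1 - m2) * Inf, p_value = 0, df = df,
                degenerate = TRUE))
  }
  t <- (m1 - m2) / se
  list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df), df = df,
       degenerate = FALSE)
}

# Row-wise pooled t over a probes x samples matrix; returns a data.frame of
# per-probe statistics. Vectorized so 100-seed null simulations stay cheap.
row_pooled_t <- function(values, labels) {
  case <- values[, labels == "case", drop = FALSE]
  ctrl <- values[, labels == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1L)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1L)
  df <- n1 + n2 - 2L
  se <- sqrt((((n1 - 1L) * v1 + (n2 - 1L) * v2) / df) * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0 & m1 != m2
  t[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 0,
                       sign(m1[se == 0] - m2[se == 0]) * Inf)
  p[se == 0] <- ifelse(degen[se == 0], 0, 1)
  data.frame(probe_id = rownames(values), mean_case = m1, mean_control = m2,
             delta_log2 = m1 - m2, t_stat = t, p_value = p,
             degenerate = degen, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fold-change threshold on the log2 scale
#'
#' A probe passes when its absolute log2 mean difference reaches
#' `log2(fold_threshold)`; the boundary is included by default ("at least
#' fourfold"), with `inclusive = FALSE` giving the strict reading.
#'
#' @param delta_log2 log2 fold change(s) (case mean minus control mean).
#' @param fold_threshold linear fold threshold, > 1 (default 4).
#' @param inclusive include the boundary?
#' @return logical vector.
#' @export
passes_fold <- function(delta_log2, fold_threshold = 4, inclusive = TRUE) {
  if (fold_threshold <= 1)
    stop("fold_threshold must be > 1", call. = FALSE)
  cut <- log2(fold_threshold)
  if (inclusive) abs(delta_log2) >= cut else abs(delta_log2) > cut
}

#' Extract an up/down probe signature by volcano selection
#'
#' Tests every probe with the pooled two-sample t-test and keeps probes that
#' pass both the p-value threshold and the fold-change threshold: up-tags
#' have case mean at least `log2(fold_threshold)` above control, down-tags
#' the mirror image. Tag lists are ordered by `|t|` descending (ties by
#' probe id) — a reporting convention only, since the KS connectivity
#' statistic ignores tag order.
#'
#' @param x a labelled [expression_matrix()] with >= 2 samples per group.
#' @param p_threshold raw p-value cutoff (default 1e-4; no multiplicity
#'   correction, matching the screen's design).
#' @param fold_threshold linear fold-change cutoff (default 4).
#' @param inclusive boundary handling, see [passes_fold()].
#' @return an object of class `Signature`: list with `up_tags`, `down_tags`
#'   (character vectors), `stats` (per-probe data.frame), `thresholds`, and
#'   `empty` flag.
#' @export
select_signature <- function(x, p_threshold = 1e-4, fold_threshold = 4,
                             inclusive = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be in (0, 1]", call. = FALSE)
  stats <- row_pooled_t(x$values, x$labels)
  sig_p <- stats$p_value < p_threshold
  fold <- passes_fold(stats$delta_log2, fold_threshold, inclusive)
  up <- stats[sig_p & fold & stats$delta_log2 > 0, ]
  dn <- stats[sig_p & fold & stats$delta_log2 < 0, ]
  order_tags <- function(df)
    df$probe_id[order(-abs(df$t_stat), df$probe_id)]
  sig <- new_signature(order_tags(up), order_tags(dn), stats,
                       p_threshold, fold_threshold)
  if (sig$empty)
    warning("no probes pass the signature thresholds; signature is empty",
            call. = FALSE)
  sig
}

new_signature <- function(up_tags, down_tags, stats, p_threshold,
                          fold_threshold) {
  if (length(intersect(up_tags, down_tags)))
    stop("up and down tags must be disjoint", call. = FALSE)
  structure(list(up_tags = as.character(up_tags),
                 down_tags = as.character(down_tags),
                 stats = stats,
                 thresholds = c(p_threshold = p_threshold,
                                fold_threshold = fold_threshold),
                 empty = length(up_tags) + length(down_tags) == 0L),
            class = "Signature")
}

#' Build a signature from explicit tag lists
#'
#' Wraps externally supplied up/down probe lists (e.g. GRP files from
#' another tool) in the container [query_compendium()] expects. No
#' statistics are attached.
#'
#' @param up_tags,down_tags character vectors of probe ids (disjoint).
#' @return a `Signature`.
#' @export
signature_from_tags <- function(up_tags, down_tags) {
  new_signature(up_tags, down_tags, stats = NULL, p_threshold = NA_real_,
                fold_threshold = NA_real_)
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature: %d up-tags, %d down-tags (p < %g, fold >= %g)\n",
              length(x$up_tags), length(x$down_tags),
              x$thresholds[["p_threshold"]], x$thresholds[["fold_threshold"]]))
  invisible(x)
}

#' Write a signature as GRP tag lists plus a stats table
#'
#' Writes `<name>_up.grp` and `<name>_dn.grp` (one probe id per line) and,
#' when statistics are present, `<name>_stats.tsv` with columns probe_id,
#' mean_case, mean_control, delta_log2, t, p.
#'
#' @param sig a `Signature`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return character vector of written paths, invisibly.
#' @export
write_signature <- function(sig, dir, name) {
  stopifnot(inherits(sig, "Signature"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  up <- file.path(dir, paste0(name, "_up.grp"))
  dn <- file.path(dir, paste0(name, "_dn.grp"))
  writeLines(sig$up_tags, up)
  writeLines(sig$down_tags, dn)
  paths <- c(up, dn)
  if (!is.null(sig$stats)) {
    st <- file.path(dir, paste0(name, "_stats.tsv"))
    out <- data.frame(probe_id = sig$stats$probe_id,
                      mean_case = sprintf("%.17g", sig$stats$mean_case),
                      mean_control = sprintf("%.17g", sig$stats$mean_control),
                      delta_log2 = sprintf("%.17g", sig$stats$delta_log2),
                      t = sprintf("%.17g", sig$stats$t_stat),
                      p = sprintf("%.17g", sig$stats$p_value))
    utils::write.table(out, st, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, st)
  }
  invisible(paths)
}

#' Read a GRP tag list
#'
#' @param path GRP file: one id per line, `#` comments ignored.
#' @return character vector of probe ids.
#' @export
read_grp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ids <- trimws(readLines(path))
  ids[nzchar(ids) & !startsWith(ids, "#")]
}
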