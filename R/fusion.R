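#' Per-cohort hit list
#'
#' @param cohort_id cohort identifier.
#' @param hits character vector of drug ids with negative enrichment at
#'   p < 0.05 in this cohort. Names are normalized (lower-cased, trimmed)
#'   before set operations.
#' @return list of class `CohortHits`.
#' @export
cohort_hits <- function(cohort_id, hits) {
  hits <- normalize_drug(hits)
  if (anyDuplicated(hits))
    stop("duplicate drug(s) in cohort ", cohort_id, ": ",
         paste(unique(hits[duplicated(hits)]), collapse = ", "),
         call. = FALSE)
  structure(list(cohort_id = as.character(cohort_id), hits = hits),
            class = "CohortHits")
}

normalize_drug <- function(x) tolower(trimws(as.character(x)))

#' Fuse per-cohort hit lists across cohorts
#'
#' The multi-cohort "fusion" is the union of the per-cohort hit lists —
#' a drug found by any cohort is retained — together with per-drug support
#' counts (how many cohorts hit it) and exact-membership Venn region sizes
#' over all non-empty cohort subsets.
#'
#' @param hit_lists list of [cohort_hits()] with distinct cohort ids.
#' @return object of class `FusionResult`: list with `cohort_ids`,
#'   `union_drugs` (sorted), `support` (named integer vector), and
#'   `venn_regions` (data.frame: subset label `id1&id2...`, count —
#'   all `2^k - 1` regions, zeros included).
#' @export
fuse <- function(hit_lists) {
  if (!length(hit_lists)) stop("need at least one cohort", call. = FALSE)
  stopifnot(all(vapply(hit_lists, inherits, logical(1), "CohortHits")))
  ids <- vapply(hit_lists, `[[`, character(1), "cohort_id")
  if (anyDuplicated(ids))
    stop("duplicate cohort id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sets <- lapply(hit_lists, `[[`, "hits")
  union_drugs <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) union_drugs %in% s,
                   logical(length(union_drugs)))
  if (!is.matrix(member)) member <- matrix(member, nrow = length(union_drugs))
  support <- stats::setNames(as.integer(rowSums(member)), union_drugs)
  k <- length(ids)
  subsets <- lapply(seq_len(2^k - 1L), function(m)
    which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L))
  labels <- vapply(subsets, function(s) paste(ids[s], collapse = "&"),
                   character(1))
  region_of <- apply(member, 1L, function(row) sum(2^(which(row) - 1L)))
  counts <- vapply(seq_along(subsets), function(m)
    sum(region_of == m), integer(1))
  structure(list(cohort_ids = ids, union_drugs = union_drugs,
                 support = support,
                 venn_regions = data.frame(subset = labels, count = counts,
                                           stringsAsFactors = FALSE)),
            class = "FusionResult")
}

#' @export
print.FusionResult <- function(x, ...) {
  cat(sprintf("FusionResult: %d cohorts, %d drugs in the union\n",
              length(x$cohort_ids), length(x$union_drugs)))
  invisible(x)
}

#' Functional category map for drugs
#'
#' A total mapping drug -> functional category; drugs absent from the map
#' resolve to `"unknown"`. The packaged default
#' (`inst/extdata/drug_categories.tsv`) carries the six-group
#' classification of the screen's experimentally validated drugs
#' (anti-inflammation, antibiotics, antipsychotics, cardiovascular,
#' chemotherapeutic, others).
#'
#' @param path two-column TSV (drug, category); default the packaged map.
#' @return named character vector (names normalized drug ids).
#' @export
read_category_map <- function(path = system.file("extdata",
                                                 "drug_categories.tsv",
                                                 package = "sigreverse")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#",
                          quote = "")
  allowed <- c("anti-inflammation", "antibiotics", "antipsychotics",
               "cardiovascular", "chemotherapeutic", "others", "unknown")
  bad <- setdiff(unique(df$category), allowed)
  if (length(bad))
    stop("unknown categor(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stats::setNames(df$category, normalize_drug(df$drug))
}

#' Annotate a fusion result with drug categories
#'
#' @param fusion a [fuse()] result.
#' @param categories a named drug -> category vector
#'   ([read_category_map()]); missing drugs get `"unknown"`.
#' @return data.frame (drug, support, category) sorted by support
#'   descending, then drug id.
#' @export
annotate_fusion <- function(fusion, categories = read_category_map()) {
  stopifnot(inherits(fusion, "FusionResult"))
  drugs <- fusion$union_drugs
  cat <- unname(categories[drugs])
  cat[is.na(cat)] <- "unknown"
  out <- data.frame(drug = drugs, support = unname(fusion$support[drugs]),
                    category = cat, stringsAsFactors = FALSE)
  out[order(-out$support, out$drug), , drop = FALSE]
}

#' Write fusion reports as TSV
#'
#' `<stem>_fusion.tsv` (drug, support, category) and `<stem>_venn.tsv`
#' (subset, count).
#'
#' @param fusion a `FusionResult`.
#' @param dir output directory.
#' @param stem file stem.
#' @param categories category map passed to [annotate_fusion()].
#' @return written paths, invisibly.
#' @export
write_fusion <- function(fusion, dir, stem = "screen",
                         categories = read_category_map()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- file.path(dir, paste0(stem, "_fusion.tsv"))
  vpath <- file.path(dir, paste0(stem, "_venn.tsv"))
  utils::write.table(annotate_fusion(fusion, categories), fpath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fusion$venn_regions, vpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fpath, vpath))
}
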