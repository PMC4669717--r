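#' Reference compendium of drug-treatment rank profiles
#'
#' A compendium holds one complete rank profile per treatment instance over
#' a shared probe universe (rank 1 = most up-regulated by the treatment),
#' plus instance-to-drug metadata. This is the stand-in for the Connectivity
#' Map database of drug-treatment expression profiles.
#'
#' @param ranks integer matrix, probes x instances: `ranks[p, i]` is the
#'   rank of probe `p` in instance `i`; every column must be a permutation
#'   of `1..n_probes`. Rownames are the probe universe, colnames the
#'   instance ids.
#' @param instances data.frame with columns `instance_id` and `drug`
#'   (one row per rank column, same order).
#' @return an object of class `ReferenceCompendium`.
#' @export
reference_compendium <- function(ranks, instances) {
  if (!is.matrix(ranks) || is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("`ranks` must be a matrix with probe rownames and instance colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(ranks)) || anyDuplicated(colnames(ranks)))
    stop("duplicate probe or instance ids in rank matrix", call. = FALSE)
  n <- nrow(ranks)
  ok <- apply(ranks, 2L, function(col) identical(sort.int(as.integer(col)),
                                                 seq_len(n)))
  if (!all(ok))
    stop("instance(s) not a complete permutation of the probe universe: ",
         paste(colnames(ranks)[!ok], collapse = ", "), call. = FALSE)
  req <- c("instance_id", "drug")
  if (!is.data.frame(instances) || !all(req %in% names(instances)))
    stop("`instances` needs columns instance_id and drug", call. = FALSE)
  if (!identical(as.character(instances$instance_id), colnames(ranks)))
    stop("instance metadata must match rank columns in order", call. = FALSE)
  instances$instance_id <- as.character(instances$instance_id)
  instances$drug <- as.character(instances$drug)
  structure(list(probe_universe = rownames(ranks),
                 ranks = ranks,
                 instances = instances),
            class = "ReferenceCompendium")
}

#' @export
print.ReferenceCompendium <- function(x, ...) {
  cat(sprintf("ReferenceCompendium: %d probes, %d instances, %d drugs\n",
              nrow(x$ranks), ncol(x$ranks), length(unique(x$instances$drug))))
  invisible(x)
}

#' Write a compendium as ranks + instances TSV
#'
#' `<stem>_ranks.tsv` has a `probe_id` column plus one integer rank column
#' per instance; `<stem>_instances.tsv` has columns instance_id, drug.
#'
#' @param comp a `ReferenceCompendium`.
#' @param dir output directory.
#' @param stem file stem.
#' @return written paths, invisibly.
#' @export
write_compendium <- function(comp, dir, stem = "compendium") {
  stopifnot(inherits(comp, "ReferenceCompendium"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rpath <- file.path(dir, paste0(stem, "_ranks.tsv"))
  ipath <- file.path(dir, paste0(stem, "_instances.tsv"))
  df <- data.frame(probe_id = rownames(comp$ranks), comp$ranks,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, rpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comp$instances, ipath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(rpath, ipath))
}

#' Read a compendium from ranks + instances TSV
#'
#' @param ranks_path,instances_path files written by [write_compendium()].
#' @return a `ReferenceCompendium`.
#' @export
read_compendium <- function(ranks_path, instances_path) {
  for (p in c(ranks_path, instances_path))
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  df <- utils::read.table(ranks_path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "", quote = "")
  ranks <- as.matrix(df[-1L])
  storage.mode(ranks) <- "integer"
  rownames(ranks) <- df[[1L]]
  inst <- utils::read.table(instances_path, sep = "\t", header = TRUE,
                            colClasses = "character", comment.char = "",
                            quote = "")
  reference_compendium(ranks, inst)
}

#' Export per-drug instance sets as GMT
#'
#' One line per drug: `drug<TAB>na<TAB>instance ids...`.
#'
#' @param comp a `ReferenceCompendium`.
#' @param path output GMT file.
#' @return `path`, invisibly.
#' @export
write_drug_gmt <- function(comp, path) {
  stopifnot(inherits(comp, "ReferenceCompendium"))
  sets <- split(comp$instances$instance_id, comp$instances$drug)
  lines <- vapply(names(sets), function(d)
    paste(c(d, "na", sets[[d]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
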