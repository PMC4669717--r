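#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect is UTF-8, tab-delimited, first column header `probe_id`,
#' one column per sample; sample group labels come from a companion
#' two-column file (`sample_id<TAB>group`, group in case/control) given as
#' `labels`. The GCT dialect is v1.2: a `#1.2` first line, a
#' `<n_probes><TAB><n_samples>` second line, then a header
#' `NAME<TAB>Description<TAB><samples...>`; the Description column is
#' ignored on read.
#'
#' @param path path to the matrix file.
#' @param labels either a named character vector of case/control labels or a
#'   path to a label TSV.
#' @param format `"tsv"`, `"gct"`, or `"auto"` (sniff the `#1.2` magic).
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, labels, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (identical(first, "#1.2")) "gct" else "tsv"
  }
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
    labels <- read_labels(labels)
  if (format == "gct") read_gct(path, labels) else read_tsv_matrix(path, labels)
}

read_labels <- function(path) {
  if (!file.exists(path)) stop("no such label file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2)
    stop("label file must have columns sample_id, group: ", path,
         call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

read_tsv_matrix <- function(path, labels) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "probe_id")
    stop("malformed TSV header (expected first column 'probe_id'): ", path,
         call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c("character", rep("numeric",
                                                          length(header) - 1L)),
                          comment.char = "", quote = "")
  build_matrix(df[[1L]], header[-1L], as.matrix(df[-1L]), labels, path)
}

read_gct <- function(path, labels) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1L] != "#1.2")
    stop("malformed GCT (missing '#1.2' version line): ", path, call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("malformed GCT size line: ", path, call. = FALSE)
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L)
    stop("malformed GCT header: ", path, call. = FALSE)
  con <- textConnection(lines[-(1:2)])
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c("character", "character",
                                         rep("numeric", length(header) - 2L)),
                          comment.char = "", quote = "")
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
    stop(sprintf("GCT size line says %d x %d but body is %d x %d: %s",
                 dims[1L], dims[2L], nrow(df), ncol(df) - 2L, path),
         call. = FALSE)
  build_matrix(df[[1L]], header[-(1:2)], as.matrix(df[-(1:2)]), labels, path)
}

build_matrix <- function(pids, sids, values, labels, path) {
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or non-finite value at probe '%s', sample '%s' in %s",
                 pids[bad[1L, 1L]], sids[bad[1L, 2L]], path), call. = FALSE)
  dimnames(values) <- list(pids, sids)
  expression_matrix(values, labels)
}

#' Write an expression matrix to TSV or GCT
#'
#' Values are written with 17 significant digits so that a read/write round
#' trip reproduces them exactly. The TSV dialect also writes a companion
#' label file at `paste0(path, ".labels")` unless `label_path` is given.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file.
#' @param format `"tsv"` or `"gct"`.
#' @param label_path where to write the two-column label file (TSV format
#'   only); `NULL` for `<path>.labels`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, format = c("tsv", "gct"),
                                    label_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  format <- match.arg(format)
  vals <- apply(x$values, 2L, sprintf, fmt = "%.17g")
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(x$values))
  if (format == "tsv") {
    body <- cbind(probe_ids(x), vals)
    lines <- c(paste(c("probe_id", sample_ids(x)), collapse = "\t"),
               apply(body, 1L, paste, collapse = "\t"))
    writeLines(lines, path)
    if (is.null(label_path)) label_path <- paste0(path, ".labels")
    writeLines(c("sample_id\tgroup",
                 paste(sample_ids(x), x$labels, sep = "\t")), label_path)
  } else {
    body <- cbind(probe_ids(x), "na", vals)
    lines <- c("#1.2",
               paste(nrow(x$values), ncol(x$values), sep = "\t"),
               paste(c("NAME", "Description", sample_ids(x)), collapse = "\t"),
               apply(body, 1L, paste, collapse = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a platform probe list
#'
#' One probe id per line; blank lines and lines starting with `#` are
#' ignored. Emulates restricting query signatures to the HG-U133A probe
#' universe.
#'
#' @param path file with one probe id per line.
#' @return character vector of unique probe ids, in file order.
#' @export
read_probe_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) stop("empty probe list: ", path, call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate probe id(s) in platform list: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ids
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample column to share the same value distribution: the
#' column-wise mean of the sorted columns. When `already_log2 = FALSE` the
#' values are log2-transformed first (they must then be strictly positive).
#' Ties within a column receive the mean of the target values across the
#' tied rank span. This is the packaged substitute for full RMA
#' preprocessing; it reproduces RMA's quantile step only.
#'
#' @param x an `ExpressionMatrix`.
#' @param already_log2 are the values already on the log2 scale?
#' @return an `ExpressionMatrix` with identical per-column sorted values.
#' @export
quantile_normalize_log2 <- function(x, already_log2 = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!already_log2) {
    if (any(v <= 0))
      stop("values must be strictly positive when already_log2 = FALSE",
           call. = FALSE)
    v <- log2(v)
  }
  n <- nrow(v)
  target <- rowMeans(apply(v, 2L, sort.int, method = "quick"))
  csum <- c(0, cumsum(target))
  out <- apply(v, 2L, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = n)
  dimnames(out) <- dimnames(x$values)
  expression_matrix(out, x$labels)
}

#' Restrict an expression matrix to a platform probe universe
#'
#' Keeps the probes shared by the matrix and the platform list (matrix row
#' order preserved), mirroring the restriction of Plus-2.0 cohorts to the
#' HG-U133A probe sets used by the reference compendium.
#'
#' @param x an `ExpressionMatrix`.
#' @param platform character vector of platform probe ids (see
#'   [read_probe_list()]).
#' @return an `ExpressionMatrix` over the intersection.
#' @export
restrict_to_platform <- function(x, platform) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep <- probe_ids(x) %in% platform
  if (!any(keep))
    stop("no matrix probes belong to the platform list", call. = FALSE)
  expression_matrix(x$values[keep, , drop = FALSE], x$labels)
}
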