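#' Labelled expression matrix
#'
#' An `ExpressionMatrix` holds log2-scale expression values as a numeric
#' matrix (probes in rows, samples in columns) together with a case/control
#' label for every sample. It is the container consumed by
#' [quantile_normalize_log2()], [restrict_to_platform()] and
#' [select_signature()].
#'
#' @param values numeric matrix with unique rownames (probe ids) and unique
#'   colnames (sample ids); all entries must be finite.
#' @param labels named character vector mapping every sample id to
#'   `"case"` or `"control"`. Order need not match the columns.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `labels` (character vector aligned to the
#'   columns of `values`).
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' expression_matrix(m, c(s1 = "case", s2 = "control"))
expression_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop("`values` must carry probe rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(pid))
    stop("duplicate probe id(s): ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("all expression values must be finite", call. = FALSE)
  labels <- validate_labels(labels, sid)
  structure(list(values = values, labels = labels),
            class = "ExpressionMatrix")
}

validate_labels <- function(labels, sample_ids) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.null(names(labels)))
    stop("`labels` must be named by sample id", call. = FALSE)
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("unlabelled sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  labels <- labels[sample_ids]
  bad <- !labels %in% c("case", "control")
  if (any(bad))
    stop("labels must be 'case' or 'control'; offending sample(s): ",
         paste(sample_ids[bad], collapse = ", "), call. = FALSE)
  labels
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset the samples of an expression matrix
#'
#' @param x an `ExpressionMatrix`.
#' @param samples character vector of sample ids to keep (order respected).
#' @return an `ExpressionMatrix` over the requested samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  expression_matrix(x$values[, samples, drop = FALSE], x$labels[samples])
}
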