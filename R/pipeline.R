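#' Read and validate a pipeline configuration
#'
#' The config is a JSON object with fields: `cohorts` (array of
#' `{id, matrix, labels}`; paths resolved relative to the config file),
#' `platform` (probe list path, optional), `compendium`
#' (`{ranks, instances}`), `thresholds`
#' (`{p_signature = 1e-4, fold = 4, p_drug = 0.05}`, all defaulting to the
#' screen's published cutoffs), `n_permutations` (default 10000), `seed`,
#' and `out_dir`.
#'
#' @param path config JSON file.
#' @return validated config list with absolute paths (class
#'   `PipelineConfig`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  if (!length(cfg$cohorts)) stop("config has no cohorts", call. = FALSE)
  cfg$cohorts <- lapply(cfg$cohorts, function(co) {
    for (f in c("id", "matrix", "labels"))
      if (is.null(co[[f]]))
        stop("cohort entry missing field '", f, "'", call. = FALSE)
    co$matrix <- resolve(co$matrix)
    co$labels <- resolve(co$labels)
    co
  })
  ids <- vapply(cfg$cohorts, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate cohort id(s) in config", call. = FALSE)
  cfg$platform <- resolve(cfg$platform)
  if (is.null(cfg$compendium$ranks) || is.null(cfg$compendium$instances))
    stop("config needs compendium$ranks and compendium$instances",
         call. = FALSE)
  cfg$compendium$ranks <- resolve(cfg$compendium$ranks)
  cfg$compendium$instances <- resolve(cfg$compendium$instances)
  thr <- cfg$thresholds
  cfg$thresholds <- list(
    p_signature = thr$p_signature %||% 1e-4,
    fold = thr$fold %||% 4,
    p_drug = thr$p_drug %||% 0.05)
  if (cfg$thresholds$p_signature <= 0 || cfg$thresholds$p_signature > 1 ||
      cfg$thresholds$fold <= 1 ||
      cfg$thresholds$p_drug < 0 || cfg$thresholds$p_drug > 1)
    stop("thresholds out of range", call. = FALSE)
  cfg$n_permutations <- as.integer(cfg$n_permutations %||% 10000L)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- resolve(cfg$out_dir %||% "results")
  structure(cfg, class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full repositioning screen
#'
#' For every cohort: read the expression matrix, quantile-normalize,
#' restrict to the platform universe (when a platform list is configured),
#' extract the volcano signature, query the compendium, and write the
#' signature GRP/TSV and connectivity reports. Then fuse the per-cohort hit
#' lists, write the fusion/Venn/annotated tables, and a `manifest.json`
#' recording the config, seed, package version and per-stage counts. All
#' outputs are deterministic functions of the config and seed — no
#' timestamps — so re-runs are byte-identical.
#'
#' @param config a [read_pipeline_config()] result or a config file path.
#' @param quiet suppress per-stage messages?
#' @return the `FusionResult`, invisibly; side effect: report files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message(...)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  platform <- if (!is.null(config$platform))
    read_probe_list(config$platform)
  comp <- tryCatch(
    read_compendium(config$compendium$ranks, config$compendium$instances),
    error = function(e) stop("[compendium] ", conditionMessage(e),
                             call. = FALSE))

  hit_lists <- list()
  counts <- list()
  for (co in config$cohorts) {
    stage <- sprintf("[cohort %s] ", co$id)
    res <- tryCatch({
      mat <- read_expression_matrix(co$matrix, co$labels)
      n_raw <- nrow(mat$values)
      mat <- quantile_normalize_log2(mat, already_log2 = TRUE)
      if (!is.null(platform)) mat <- restrict_to_platform(mat, platform)
      say(stage, n_raw, " probes, ", nrow(mat$values),
          " after platform restriction")
      sig <- withCallingHandlers(
        select_signature(mat, config$thresholds$p_signature,
                         config$thresholds$fold),
        warning = function(w) {
          say(stage, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      say(stage, length(sig$up_tags), " up-tags, ",
          length(sig$down_tags), " down-tags")
      write_signature(sig, out, co$id)
      conn <- if (sig$empty) NULL
              else query_compendium(sig, comp,
                                    n_perm = config$n_permutations,
                                    seed = child_seed(config$seed, "query"),
                                    p_threshold = config$thresholds$p_drug)
      hits <- if (is.null(conn)) character(0)
              else conn$drugs$drug[conn$drugs$hit]
      if (!is.null(conn)) {
        write_connectivity(conn, out, co$id)
        say(stage, length(hits), " hit drug(s); ",
            conn$n_dropped_tags, " tag(s) dropped at the compendium")
      }
      list(hits = hits,
           counts = list(probes_tested = nrow(mat$values),
                         up_tags = length(sig$up_tags),
                         down_tags = length(sig$down_tags),
                         hits = length(hits)))
    }, error = function(e) stop(stage, conditionMessage(e), call. = FALSE))
    hit_lists[[co$id]] <- cohort_hits(co$id, res$hits)
    counts[[co$id]] <- res$counts
  }

  fusion <- fuse(unname(hit_lists))
  write_fusion(fusion, out, "screen")
  say("[fusion] ", length(fusion$union_drugs), " drug(s) in the union")

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    package = "sigreverse",
    version = as.character(utils::packageVersion("sigreverse")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stage_counts = counts,
    n_union_drugs = length(fusion$union_drugs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fusion)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic screen), `signature`
#' (extract one cohort's signature), `query` (score a signature against a
#' compendium), `fuse` (combine hits TSVs), `run` (full pipeline from a
#' config). Invoked by the `exec/sigreverse` script; callable from R with a
#' character vector of arguments for testing.
#'
#' @param args character vector, e.g. `c("run", "--config", "cfg.json")`.
#' @return exit status (0 on success), invisibly.
#' @export
sigreverse_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sigreverse <command> [options]",
    "  simulate  --out DIR [--seed N] [--n-probes N] [--n-cohorts N]",
    "  signature --matrix TSV --labels TSV --out DIR --name STEM",
    "            [--p N] [--fold N] [--platform FILE]",
    "  query     --up GRP --down GRP --ranks TSV --instances TSV --out DIR",
    "            --name STEM [--seed N] [--n-perm N] [--exact-p|--mc-p]",
    "  fuse      --out DIR --hits ID=TSV [--hits ID=TSV ...]",
    "  run       --config JSON [--seed N] [--out DIR]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- parse_cli_args(args[-1L])
  status <- tryCatch({
    switch(cmd,
      simulate = {
        simulate_screen(req(opt, "out"),
                        n_cohorts = as.integer(opt[["n-cohorts"]] %||% 5L),
                        n_probes = as.integer(opt[["n-probes"]] %||% 2000L),
                        seed = as.integer(opt[["seed"]] %||% 11L))
      },
      signature = {
        mat <- read_expression_matrix(req(opt, "matrix"),
                                      req(opt, "labels"))
        mat <- quantile_normalize_log2(mat)
        if (!is.null(opt[["platform"]]))
          mat <- restrict_to_platform(mat, read_probe_list(opt[["platform"]]))
        sig <- select_signature(mat,
                                as.numeric(opt[["p"]] %||% 1e-4),
                                as.numeric(opt[["fold"]] %||% 4))
        write_signature(sig, req(opt, "out"), req(opt, "name"))
      },
      query = {
        sig <- signature_from_tags(read_grp(req(opt, "up")),
                                   read_grp(req(opt, "down")))
        comp <- read_compendium(req(opt, "ranks"), req(opt, "instances"))
        mode <- if (isTRUE(opt[["exact-p"]])) "exact"
                else if (isTRUE(opt[["mc-p"]])) "permutation" else "auto"
        conn <- query_compendium(sig, comp,
                                 n_perm = as.integer(opt[["n-perm"]] %||% 10000L),
                                 seed = as.integer(opt[["seed"]] %||% 1L),
                                 p_mode = mode)
        write_connectivity(conn, req(opt, "out"), req(opt, "name"))
      },
      fuse = {
        specs <- opt[["hits"]]
        if (is.null(specs)) stop("fuse needs at least one --hits ID=TSV")
        lists <- lapply(specs, function(s) {
          kv <- strsplit(s, "=", fixed = TRUE)[[1L]]
          if (length(kv) != 2L) stop("--hits must look like ID=TSV")
          df <- utils::read.table(kv[2L], sep = "\t", header = TRUE,
                                  colClasses = "character")
          hits <- if ("hit" %in% names(df))
            df$drug[df$hit %in% c("TRUE", "true", "1")] else df$drug
          cohort_hits(kv[1L], hits)
        })
        write_fusion(fuse(lists), req(opt, "out"), "screen")
      },
      run = {
        cfg <- read_pipeline_config(req(opt, "config"))
        if (!is.null(opt[["seed"]])) cfg$seed <- as.integer(opt[["seed"]])
        if (!is.null(opt[["out"]])) cfg$out_dir <- opt[["out"]]
        run_pipeline(cfg)
      },
      stop("unknown command: ", cmd, "\n", usage))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

req <- function(opt, name) {
  if (is.null(opt[[name]])) stop("missing required --", name, call. = FALSE)
  opt[[name]]
}

# --key value / --key=value / bare --flag parser; repeated --hits accumulate.
parse_cli_args <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    a <- substring(a, 3L)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
      key <- kv[1L]; val <- paste(kv[-1L], collapse = "=")
    } else if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      key <- a; val <- args[i + 1L]; i <- i + 1L
    } else {
      key <- a; val <- TRUE
    }
    if (key == "hits") opt[["hits"]] <- c(opt[["hits"]], val)
    else opt[[key]] <- val
    i <- i + 1L
  }
  opt
}
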