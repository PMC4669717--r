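#' Ground truth for a synthetic case/control cohort
#'
#' Describes the planted world behind [make_cohort()]: which probes carry a
#' differential effect, how large it is on the log2 scale, the per-probe
#' noise SD, and the group sizes. Defaults follow the desk-scale cohort the
#' pipeline is tested on: 100 up + 100 down planted probes out of 2000,
#' a 3.0 log2 effect (8-fold, comfortably past the 4-fold cutoff), sigma
#' 0.3 (typical replicate noise on a log2 intensity scale), and 20 case /
#' 10 control samples (the roughly 2:1 tumor:normal imbalance of the real
#' cohorts at desk scale).
#'
#' @param planted_up,planted_down character vectors of probe ids (disjoint);
#'   `NULL` with `n_up`/`n_down` plants the first probes of the universe.
#' @param n_up,n_down plant counts used when explicit ids are not given.
#' @param effect_log2 planted effect size, log2 units, >= 0.
#' @param sigma log2 noise SD, > 0.
#' @param n_case,n_control group sizes.
#' @param seed RNG seed; the cohort is a pure function of it.
#' @return list of class `CohortTruth`.
#' @export
cohort_truth <- function(planted_up = NULL, planted_down = NULL,
                         n_up = 100L, n_down = 100L, effect_log2 = 3.0,
                         sigma = 0.3, n_case = 20L, n_control = 10L,
                         seed = 1L) {
  if (effect_log2 < 0) stop("effect_log2 must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (is.null(planted_up)) planted_up <- synthetic_probe_ids(n_up)
  if (is.null(planted_down))
    planted_down <- synthetic_probe_ids(n_up + n_down)[-seq_len(n_up)]
  if (length(intersect(planted_up, planted_down)))
    stop("planted up/down sets must be disjoint", call. = FALSE)
  structure(list(planted_up = planted_up, planted_down = planted_down,
                 effect_log2 = effect_log2, sigma = sigma,
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 seed = as.integer(seed)),
            class = "CohortTruth")
}

synthetic_probe_ids <- function(n) sprintf("probe_%04d", seq_len(n))

#' Simulate a labelled case/control expression cohort
#'
#' Each probe gets a baseline log2 level drawn once from Uniform(4, 12)
#' (the usual dynamic range of log2 microarray intensities); every sample
#' value is baseline plus Normal(0, sigma) noise, and case samples
#' additionally get `+effect_log2` on planted up probes and `-effect_log2`
#' on planted down probes. Fully reproducible from `truth$seed`.
#'
#' @param truth a [cohort_truth()].
#' @param n_probes universe size (default 2000); planted ids must fall in
#'   the first `n_probes` synthetic ids when defaults are used.
#' @return an [expression_matrix()] with samples `case_01..`, `ctrl_01..`.
#' @export
make_cohort <- function(truth, n_probes = 2000L) {
  stopifnot(inherits(truth, "CohortTruth"))
  probes <- synthetic_probe_ids(n_probes)
  missing <- setdiff(c(truth$planted_up, truth$planted_down), probes)
  if (length(missing))
    stop("planted probe(s) outside the universe: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  n_s <- truth$n_case + truth$n_control
  with_local_seed(truth$seed, {
    baseline <- stats::runif(n_probes, 4, 12)
    vals <- baseline + matrix(stats::rnorm(n_probes * n_s, 0, truth$sigma),
                              n_probes, n_s)
    up <- match(truth$planted_up, probes)
    dn <- match(truth$planted_down, probes)
    case_cols <- seq_len(truth$n_case)
    vals[up, case_cols] <- vals[up, case_cols] + truth$effect_log2
    vals[dn, case_cols] <- vals[dn, case_cols] - truth$effect_log2
    samples <- c(sprintf("case_%02d", seq_len(truth$n_case)),
                 sprintf("ctrl_%02d", seq_len(truth$n_control)))
    dimnames(vals) <- list(probes, samples)
    labels <- stats::setNames(rep(c("case", "control"),
                                  c(truth$n_case, truth$n_control)), samples)
    expression_matrix(vals, labels)
  })
}

#' Ground truth for a synthetic reference compendium
#'
#' Declares which drugs are reversers (their instances displace planted up
#' probes toward the bottom of the rank profile and planted down probes
#' toward the top — the profile a therapeutic candidate shows) and which
#' are mimickers (the opposite), with a latent-shift strength each.
#' Defaults: 40 drugs x 5 instances with the first 4 drugs as reversers at
#' strength 2.0 and no mimickers, the desk-scale version of "up to 7000
#' profiles ... 1309 drugs".
#'
#' @param n_drugs,instances_per_drug compendium shape.
#' @param reversers named numeric vector drug -> strength (> 0); default
#'   first 4 drugs at 2.0. Use `numeric(0)` for a null compendium.
#' @param mimickers named numeric vector drug -> strength; default none.
#' @param seed RNG seed.
#' @return list of class `CompendiumTruth`.
#' @export
compendium_truth <- function(n_drugs = 40L, instances_per_drug = 5L,
                             reversers = NULL, mimickers = numeric(0),
                             seed = 7L) {
  drugs <- sprintf("drug_%02d", seq_len(n_drugs))
  if (is.null(reversers))
    reversers <- stats::setNames(rep(2.0, 4L), drugs[1:4])
  check_named_strengths(reversers, "reversers", drugs)
  check_named_strengths(mimickers, "mimickers", drugs)
  if (length(intersect(names(reversers), names(mimickers))))
    stop("reverser and mimicker sets must be disjoint", call. = FALSE)
  structure(list(drugs = drugs,
                 n_drugs = as.integer(n_drugs),
                 instances_per_drug = as.integer(instances_per_drug),
                 reversers = reversers, mimickers = mimickers,
                 seed = as.integer(seed)),
            class = "CompendiumTruth")
}

check_named_strengths <- function(x, what, drugs) {
  if (!length(x)) return(invisible(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named drug -> strength vector", call. = FALSE)
  if (any(x <= 0)) stop(what, " strengths must be > 0", call. = FALSE)
  unknown <- setdiff(names(x), drugs)
  if (length(unknown))
    stop("unknown drug(s) in ", what, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Simulate a reference compendium with planted reversers/mimickers
#'
#' Each instance draws a latent Normal(0, 1) value per probe; reverser
#' instances subtract their strength on the cohort's planted up probes and
#' add it on planted down probes (mimickers do the opposite). The rank
#' profile is the descending order of the latent values, so reverser
#' instances systematically push the disease's up genes toward the bottom.
#' Only ranks are generated — the connectivity stage consumes nothing else.
#'
#' @param cohort_truth the [cohort_truth()] whose plants the drugs act on.
#' @param comp_truth a [compendium_truth()].
#' @param n_probes universe size (must cover the planted probes).
#' @return a [reference_compendium()] with instance ids
#'   `<drug>_i<k>`.
#' @export
make_compendium <- function(cohort_truth, comp_truth, n_probes = 2000L) {
  stopifnot(inherits(cohort_truth, "CohortTruth"),
            inherits(comp_truth, "CompendiumTruth"))
  probes <- synthetic_probe_ids(n_probes)
  up <- match(cohort_truth$planted_up, probes)
  dn <- match(cohort_truth$planted_down, probes)
  if (anyNA(up) || anyNA(dn))
    stop("planted probes outside the compendium universe", call. = FALSE)
  drugs <- rep(comp_truth$drugs, each = comp_truth$instances_per_drug)
  inst_ids <- paste0(drugs, "_i",
                     rep(seq_len(comp_truth$instances_per_drug),
                         comp_truth$n_drugs))
  n_inst <- length(inst_ids)
  shift <- stats::setNames(numeric(comp_truth$n_drugs), comp_truth$drugs)
  shift[names(comp_truth$reversers)] <- comp_truth$reversers
  shift[names(comp_truth$mimickers)] <- -comp_truth$mimickers
  ranks <- with_local_seed(comp_truth$seed, {
    z <- matrix(stats::rnorm(n_probes * n_inst), n_probes, n_inst)
    s <- shift[drugs]
    z[up, ] <- sweep(z[up, , drop = FALSE], 2L, s, `-`)
    z[dn, ] <- sweep(z[dn, , drop = FALSE], 2L, s, `+`)
    apply(-z, 2L, rank, ties.method = "first")
  })
  storage.mode(ranks) <- "integer"
  dimnames(ranks) <- list(probes, inst_ids)
  reference_compendium(ranks,
                       data.frame(instance_id = inst_ids, drug = drugs,
                                  stringsAsFactors = FALSE))
}

#' Write a full synthetic screen to disk
#'
#' Materializes `n_cohorts` cohorts sharing one planted truth (per-cohort
#' child seeds), the compendium, a platform probe list covering the
#' universe, and a `truth.json` manifest — everything `run_pipeline()`
#' needs, in the package's TSV/GRP formats.
#'
#' @param dir output directory.
#' @param n_cohorts number of cohorts (default 5, as in the real screen).
#' @param n_probes universe size.
#' @param seed base seed; cohorts and the compendium use [child_seed()]
#'   streams derived from it.
#' @param cohort_template a [cohort_truth()] supplying everything but the
#'   per-cohort seed.
#' @param comp_truth a [compendium_truth()]; its seed is overridden by the
#'   compendium child seed.
#' @return path of the written config JSON, invisibly.
#' @export
simulate_screen <- function(dir, n_cohorts = 5L, n_probes = 2000L, seed = 11L,
                            cohort_template = cohort_truth(),
                            comp_truth = compendium_truth()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_entries <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    tr <- cohort_template
    tr$seed <- child_seed(seed, "cohort", i)
    mat <- make_cohort(tr, n_probes)
    id <- sprintf("cohort_%d", i)
    mpath <- file.path(dir, paste0(id, ".tsv"))
    write_expression_matrix(mat, mpath, "tsv")
    cohort_entries[[i]] <- list(id = id, matrix = paste0(id, ".tsv"),
                                labels = paste0(id, ".tsv.labels"))
  }
  ct <- comp_truth
  ct$seed <- child_seed(seed, "compendium")
  comp <- make_compendium(cohort_template, ct, n_probes)
  write_compendium(comp, dir, "compendium")
  writeLines(c("# synthetic platform probe universe",
               synthetic_probe_ids(n_probes)),
             file.path(dir, "platform.txt"))
  truth <- list(planted_up = cohort_template$planted_up,
                planted_down = cohort_template$planted_down,
                effect_log2 = cohort_template$effect_log2,
                sigma = cohort_template$sigma,
                reversers = as.list(ct$reversers),
                mimickers = as.list(ct$mimickers),
                seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config <- list(cohorts = cohort_entries,
                 platform = "platform.txt",
                 compendium = list(ranks = "compendium_ranks.tsv",
                                   instances = "compendium_instances.tsv"),
                 thresholds = list(p_signature = 1e-4, fold = 4,
                                   p_drug = 0.05),
                 n_permutations = 10000L,
                 seed = seed,
                 out_dir = "results")
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg_path)
}
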