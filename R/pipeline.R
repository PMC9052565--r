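#' Pipeline configuration
#'
#' Bundles the stage configurations for a full run: cohort source,
#' one analysis configuration per alpha level (both 0.05 and 0.01 by
#' default, mirroring the two-threshold design), consensus clustering,
#' and the survival subgroups.
#'
#' @param cohort A `cohort_config` (simulate) or a path to a cohort CSV
#'   written by [write_cohort()] (its sidecar dictionary JSON must sit
#'   next to it).
#' @param alphas Numeric vector of alpha levels.
#' @param iterations,min_count,max_cond_size Passed to
#'   [analysis_config()] (with `min_count` scaled to `iterations` when
#'   left `NULL`, preserving the strict more-than-half rule).
#' @param resample `"bootstrap"` or `"refresh"` — iteration regime for
#'   [stability_run()]; `"refresh"` requires a simulated cohort.
#' @param consensus A [consensus_config()].
#' @param subgroups Subgroup list for [subgroup_analysis()].
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   file output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = default_config(),
                            alphas = c(0.05, 0.01),
                            iterations = 1000L, min_count = NULL,
                            max_cond_size = 3L,
                            resample = c("bootstrap", "refresh"),
                            consensus = consensus_config(),
                            subgroups = default_subgroups(),
                            seed = 1L, out_dir = NULL) {
  resample <- match.arg(resample)
  if (length(alphas) < 1) stop("at least one alpha level is required")
  if (is.null(min_count)) min_count <- as.integer(iterations %/% 2L)
  structure(list(cohort = cohort, alphas = alphas,
                 iterations = as.integer(iterations),
                 min_count = as.integer(min_count),
                 max_cond_size = as.integer(max_cond_size),
                 resample = resample, consensus = consensus,
                 subgroups = subgroups, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> encode -> stability selection per alpha ->
#' association graph -> seven-model consensus clustering -> Kaplan-Meier
#' subgroup analysis -> recovery scoring against the planted truth (when
#' ground truth exists). Stages are isolated: a stage error is recorded
#' in the report, its dependent stages are skipped, and independent
#' stages (e.g. the survival analysis) still run. Deterministic given
#' the configuration seeds.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: `per_alpha` (named by alpha: `stability`,
#'   `edges`, `graph`, `partitions`, `consensus`, `associated`),
#'   `subgroups`, `recovery` (per alpha, when truth exists), `meta`
#'   (encoding log), `errors`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  errors <- list()
  note_err <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  ## cohort ------------------------------------------------------------
  if (inherits(config$cohort, "cohort_config")) {
    sim <- generate_cohort(config$cohort, seed = config$seed)
    cohort <- sim$cohort; dictionary <- sim$dictionary; truth <- sim$graph
  } else if (is.character(config$cohort)) {
    sim <- read_cohort(config$cohort) # validates before any stage runs
    cohort <- sim$cohort; dictionary <- sim$dictionary; truth <- NULL
    if (config$resample == "refresh")
      stop("the refresh regime requires a simulated cohort")
  } else stop("config$cohort must be a cohort_config or a CSV path")

  enc <- encode_table(cohort, dictionary)
  X <- enc$matrix

  refresh_fn <- NULL
  if (config$resample == "refresh") {
    cohort_cfg <- config$cohort
    cols <- colnames(X)
    refresh_fn <- function(seed) {
      cc <- generate_cohort(cohort_cfg, seed = seed)
      m <- encode_table(cc$cohort, cc$dictionary)$matrix
      m[, cols, drop = FALSE]
    }
  }

  ## per-alpha network stages -------------------------------------------
  per_alpha <- list()
  recovery <- list()
  for (a in config$alphas) {
    key <- format(a)
    acfg <- analysis_config(alpha = a, iterations = config$iterations,
                            min_count = config$min_count,
                            max_cond_size = config$max_cond_size,
                            seed = config$seed)
    res <- tryCatch(stability_run(X, acfg, refresh = refresh_fn),
                    error = function(e) note_err(paste0("gm_", key), e))
    if (is.null(res)) next
    edges <- select_stable_edges(res, acfg)
    stage <- list(stability = res, edges = edges)
    graph <- tryCatch(
      suppressWarnings(build_association_graph(res, acfg)),
      error = function(e) note_err(paste0("graph_", key), e))
    if (!is.null(graph) && igraph::vcount(graph) > 0) {
      stage$graph <- graph
      parts <- tryCatch(partition_all(graph, config$consensus),
                        error = function(e)
                          note_err(paste0("cluster_", key), e))
      if (!is.null(parts)) {
        responses <- intersect(c("OS", "TTF"), names(parts[[1]]))
        # a response variable may itself be a factor for the other response
        factors <- names(parts[[1]])
        tab <- cocluster_counts(parts, factors, responses)
        stage$partitions <- parts
        stage$consensus <- tab
        stage$associated <- consensus_factors(tab, config$consensus)
      }
    }
    if (!is.null(truth))
      recovery[[key]] <- recovery_metrics(edges, truth)
    per_alpha[[key]] <- stage
  }

  ## survival subgroups (independent of the network stages) -------------
  subgroups <- tryCatch(
    suppressWarnings(subgroup_analysis(cohort, config$subgroups)),
    error = function(e) note_err("subgroups", e))

  report <- structure(list(
    per_alpha = per_alpha, subgroups = subgroups, recovery = recovery,
    meta = enc$meta, errors = errors,
    provenance = list(seed = config$seed, alphas = config$alphas,
                      iterations = config$iterations,
                      min_count = config$min_count,
                      resample = config$resample,
                      package = as.character(utils::packageVersion("crpcnet")),
                      r_version = R.version.string)),
    class = "run_report")

  if (!is.null(config$out_dir))
    write_run_report(report, cohort, dictionary, truth, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> alphas:", paste(names(x$per_alpha), collapse = ", "),
      "\n")
  for (key in names(x$per_alpha)) {
    st <- x$per_alpha[[key]]
    cat("  alpha ", key, ": ", nrow(st$edges), " stable edges",
        sep = "")
    if (!is.null(st$associated))
      cat("; ", nrow(st$associated), " consensus factor-response pairs",
          sep = "")
    cat("\n")
  }
  if (length(x$recovery))
    for (key in names(x$recovery)) {
      r <- x$recovery[[key]]
      cat("  recovery (alpha ", key, "): precision ",
          round(r$precision, 3), ", recall ", round(r$recall, 3),
          ", sign accuracy ", round(r$sign_accuracy, 3), "\n", sep = "")
    }
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
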