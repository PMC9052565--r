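#' Write a cohort to CSV with a sidecar JSON dictionary
#'
#' One row per patient, header row of variable names, empty fields for
#' missing values; the variable dictionary goes to `<stem>_dictionary.json`.
#'
#' @param cohort Cohort data frame.
#' @param dictionary Variable dictionary.
#' @param path CSV path (the dictionary path is derived from it).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, dictionary, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  jsonlite::write_json(dictionary, dictionary_path(path), dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort CSV and its sidecar dictionary
#'
#' Validates the pair before any analysis: the file must parse as CSV,
#' the dictionary must exist and cover every column, and column names
#' must be unique.
#'
#' @param path Cohort CSV path.
#' @return List with `cohort` and `dictionary`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop("malformed cohort CSV: ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(cohort) < 2 || nrow(cohort) < 1)
    stop("malformed cohort CSV: needs a header row and at least one patient")
  if (anyDuplicated(names(cohort)))
    stop("malformed cohort CSV: duplicate column names")
  dpath <- dictionary_path(path)
  if (!file.exists(dpath)) stop("dictionary not found: ", dpath)
  dictionary <- as.data.frame(jsonlite::read_json(dpath, simplifyVector = TRUE))
  missing <- setdiff(names(cohort), dictionary$name)
  if (length(missing))
    stop("dictionary does not cover column(s): ",
         paste(missing, collapse = ", "))
  list(cohort = cohort, dictionary = dictionary)
}

#' Sidecar dictionary path for a cohort CSV
#'
#' @param path Cohort CSV path.
#' @return The path of the JSON dictionary written next to it.
#' @export
dictionary_path <- function(path)
  paste0(sub("\\.csv$", "", path), "_dictionary.json")

#' Write a planted graph as edge-list TSV and GraphML
#'
#' @param graph A `planted_graph` data frame.
#' @param stem Output path without extension; writes `<stem>.tsv` and
#'   `<stem>.graphml`.
#' @return `stem`, invisibly.
#' @export
write_planted_graph <- function(graph, stem) {
  utils::write.table(graph, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  g <- igraph::graph_from_data_frame(graph, directed = FALSE)
  igraph::write_graph(g, paste0(stem, ".graphml"), format = "graphml")
  invisible(stem)
}

#' Export a stability result as TSV
#'
#' One row per unordered pair with a non-zero selection count:
#' pair, count, B, frequency, positive fraction — the machine twin of a
#' published stability table.
#'
#' @param result A `stability_result`.
#' @param path Output TSV path.
#' @return The exported data frame, invisibly.
#' @export
write_stability_tsv <- function(result, path) {
  cnt <- result$selection_count
  keep <- which(cnt > 0 & upper.tri(cnt), arr.ind = TRUE)
  df <- data.frame(
    var1 = result$nodes[keep[, 1]], var2 = result$nodes[keep[, 2]],
    selection_count = cnt[keep], B = result$B,
    frequency = cnt[keep] / result$B,
    positive_fraction = ifelse(cnt[keep] > 0,
                               result$positive_sign_count[keep] / cnt[keep],
                               NA_real_))
  df <- df[order(-df$frequency, df$var1, df$var2), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}

# Internal: write every artifact of a pipeline run under out_dir.
write_run_report <- function(report, cohort, dictionary, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_cohort(cohort, dictionary, fp("cohort.csv"))
  if (!is.null(truth)) write_planted_graph(truth, fp("planted_graph"))
  for (key in names(report$per_alpha)) {
    st <- report$per_alpha[[key]]
    tag <- gsub("\\.", "", key)
    write_stability_tsv(st$stability, fp(sprintf("stability_a%s.tsv", tag)))
    utils::write.table(st$edges, fp(sprintf("edges_a%s.tsv", tag)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(st$graph))
      igraph::write_graph(st$graph, fp(sprintf("graph_a%s.graphml", tag)),
                          format = "graphml")
    if (!is.null(st$partitions))
      jsonlite::write_json(lapply(st$partitions, as.list),
                           fp(sprintf("partitions_a%s.json", tag)),
                           auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(st$consensus))
      utils::write.table(st$consensus, fp(sprintf("consensus_a%s.tsv", tag)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (length(report$subgroups)) {
    sub_tab <- do.call(rbind, lapply(report$subgroups, function(s) {
      hr <- s$hazard_ratio
      data.frame(subgroup = s$subgroup, contrast = s$contrast,
                 logrank_chisq = s$logrank$statistic,
                 logrank_p = s$logrank$p_value,
                 hr = if (is.null(hr)) NA_real_ else hr$hr,
                 hr_lcl = if (is.null(hr)) NA_real_ else hr$ci[1],
                 hr_ucl = if (is.null(hr)) NA_real_ else hr$ci[2])
    }))
    utils::write.table(sub_tab, fp("subgroups.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  keep <- report[c("recovery", "meta", "errors", "provenance")]
  jsonlite::write_json(keep, fp("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, digits = NA)
  invisible(out_dir)
}
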