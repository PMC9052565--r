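#' Marginal summary of a cohort table
#'
#' The machine twin of a study's baseline/outcome tables: medians with
#' min-max for continuous variables, incidence percentages for binary
#' variables, and Kaplan-Meier medians (with 95% CI) for overall survival
#' and time-to-treatment-failure when the corresponding columns are
#' present. Used by the calibration tests and the acceptance script.
#'
#' @param cohort A non-empty cohort data frame (see [generate_cohort()]).
#' @return A list with components `n`, `continuous` (data frame: variable,
#'   median, min, max), `binary` (variable, n, percent; computed over
#'   non-missing values) and `km` (endpoint, events, median, lcl, ucl).
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("summarize_cohort() requires a non-empty cohort table")
  special <- c("os_days", "os_event", "ttf_days", "ttf_event",
               "observation_days")
  is_binary <- vapply(cohort, function(x) {
    v <- unique(x[!is.na(x)])
    length(v) > 0 && all(v %in% c(0, 1))
  }, logical(1))
  is_num <- vapply(cohort, is.numeric, logical(1))

  cont_vars <- setdiff(names(cohort)[is_num & !is_binary], special)
  continuous <- do.call(rbind, lapply(cont_vars, function(v) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    data.frame(variable = v, median = stats::median(x),
               min = min(x), max = max(x))
  }))

  bin_vars <- setdiff(names(cohort)[is_binary], special)
  binary <- do.call(rbind, lapply(bin_vars, function(v) {
    x <- cohort[[v]][!is.na(cohort[[v]])]
    data.frame(variable = v, n = sum(x), percent = 100 * mean(x))
  }))

  km <- NULL
  for (ep in list(c("OS", "os_days", "os_event"),
                  c("TTF", "ttf_days", "ttf_event"))) {
    if (all(ep[2:3] %in% names(cohort))) {
      cv <- km_curve(cohort[[ep[2]]], cohort[[ep[3]]])
      km <- rbind(km, data.frame(
        endpoint = ep[1], events = sum(cohort[[ep[3]]]),
        median = cv$median, lcl = cv$median_ci[1], ucl = cv$median_ci[2]))
    }
  }
  list(n = nrow(cohort), continuous = continuous, binary = binary, km = km)
}

#' Score a selected edge set against the planted truth
#'
#' Edges are compared as unordered node pairs. Precision is the fraction
#' of selected edges that are planted; recall the fraction of planted
#' edges selected; sign accuracy the fraction of the intersection whose
#' called sign matches the planted sign (an `indeterminate` call counts
#' as a mismatch).
#'
#' @param selected An edge selection: data frame with columns
#'   `var1`/`var2` (or `source`/`target`) and optionally `sign`.
#' @param truth A `planted_graph` (columns `source`, `target`, `sign`).
#' @return List: `precision`, `recall`, `sign_accuracy`, `n_selected`,
#'   `n_truth`, `n_intersection`, and `flags` (character vector noting
#'   undefined quantities, e.g. empty selection or empty truth).
#' @export
recovery_metrics <- function(selected, truth) {
  pick <- function(df, a, b) if (a %in% names(df)) df[[a]] else df[[b]]
  norm_sign <- function(s) {
    s <- as.character(s)
    s[s %in% c("+", "positive")] <- "+"
    s[s %in% c("-", "negative")] <- "-"
    s
  }
  flags <- character()
  if (is.null(truth) || nrow(truth) == 0) {
    flags <- c(flags, "empty truth graph: recall undefined")
    tkey <- character(0); tsign <- character(0)
  } else {
    tkey <- edge_keys(truth$source, truth$target)
    tsign <- truth$sign
  }
  if (is.null(selected) || nrow(selected) == 0) {
    flags <- c(flags, "empty selection: precision undefined")
    skey <- character(0); ssign <- character(0)
  } else {
    skey <- edge_keys(pick(selected, "var1", "source"),
                      pick(selected, "var2", "target"))
    ssign <- if ("sign" %in% names(selected)) selected$sign
             else rep(NA_character_, nrow(selected))
  }
  inter <- intersect(skey, tkey)
  precision <- if (length(skey)) length(inter) / length(skey) else NA_real_
  recall <- if (length(tkey)) length(inter) / length(tkey) else NA_real_
  sign_accuracy <- if (length(inter)) {
    mean(norm_sign(ssign[match(inter, skey)]) ==
           norm_sign(tsign[match(inter, tkey)]), na.rm = FALSE)
  } else NA_real_
  list(precision = precision, recall = recall,
       sign_accuracy = sign_accuracy,
       n_selected = length(skey), n_truth = length(tkey),
       n_intersection = length(inter), flags = flags)
}
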