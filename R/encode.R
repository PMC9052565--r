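#' Encode a cohort table for network analysis
#'
#' Maps a raw cohort table to the numeric matrix analysed by the
#' graphical-Markov stage: binary variables to 0/1, ordinal variables to
#' integers, continuous variables standardised to mean 0 / SD 1. The
#' censor flags are emitted as their own nodes (`OS_censoring = 1 -
#' os_event`, `TTF_censoring = 1 - ttf_event`), survival durations as
#' `OS` / `TTF`, the follow-up window as `observation_period`, and PSA
#' response as `PSA_response`. Rows missing any response value are
#' dropped (count logged); missing explanatory values are mean-imputed
#' (continuous) or mode-imputed (binary/ordinal/count), with logged
#' counts. Constant columns are flagged and excluded from the matrix.
#'
#' @param cohort Cohort data frame.
#' @param dictionary Variable dictionary covering every column
#'   (see [cohort_dictionary()]).
#' @return List: `matrix` (numeric, named columns), `meta` (list:
#'   `n_dropped_rows`, `imputed` named counts, `excluded` constant
#'   columns, `roles` data frame mapping encoded names to roles).
#' @export
encode_table <- function(cohort, dictionary) {
  missing_cols <- setdiff(names(cohort), dictionary$name)
  if (length(missing_cols))
    stop("dictionary does not cover column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_kind <- setdiff(dictionary$kind,
                      c("binary", "ordinal", "continuous", "count"))
  if (length(bad_kind)) {
    off <- dictionary$name[dictionary$kind %in% bad_kind]
    stop("unknown kind for column(s): ", paste(off, collapse = ", "))
  }
  dict <- dictionary[match(names(cohort), dictionary$name), ]

  rename <- c(os_days = "OS", ttf_days = "TTF", psa_response = "PSA_response",
              observation_days = "observation_period",
              os_event = "OS_censoring", ttf_event = "TTF_censoring")

  resp_cols <- dict$name[dict$role == "response"]
  drop_row <- rep(FALSE, nrow(cohort))
  for (v in resp_cols) drop_row <- drop_row | is.na(cohort[[v]])
  n_dropped <- sum(drop_row)
  tab <- cohort[!drop_row, , drop = FALSE]

  imputed <- integer()
  cols <- list()
  roles <- character()
  for (k in seq_len(ncol(tab))) {
    v <- dict$name[k]; kind <- dict$kind[k]
    x <- tab[[v]]
    x <- switch(kind,
      binary = encode_binary(x, v),
      ordinal = as.numeric(x),
      count = as.numeric(x),
      continuous = as.numeric(x))
    nmiss <- sum(is.na(x))
    if (nmiss > 0) {
      fill <- if (kind == "continuous") mean(x, na.rm = TRUE)
              else stat_mode(x)
      x[is.na(x)] <- fill
      imputed[v] <- nmiss
    }
    if (v %in% c("os_event", "ttf_event")) x <- 1 - x
    if (kind == "continuous") {
      s <- stats::sd(x)
      if (is.finite(s) && s > 0) x <- (x - mean(x)) / s
    }
    enc_name <- if (v %in% names(rename)) rename[[v]] else v
    cols[[enc_name]] <- x
    roles[enc_name] <- dict$role[k]
  }
  M <- do.call(cbind, cols)
  colnames(M) <- names(cols)
  const <- .colSds(M) <= 0 | !is.finite(.colSds(M))
  excluded <- colnames(M)[const]
  if (length(excluded))
    message("excluding constant column(s) from network analysis: ",
            paste(excluded, collapse = ", "))
  M <- M[, !const, drop = FALSE]
  list(matrix = M,
       meta = list(n_dropped_rows = n_dropped, imputed = imputed,
                   excluded = excluded,
                   roles = data.frame(name = colnames(M),
                                      role = unname(roles[colnames(M)]),
                                      stringsAsFactors = FALSE)))
}

encode_binary <- function(x, name) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    v <- unique(x[!is.na(x)])
    if (!all(v %in% c(0, 1)))
      stop("binary column '", name, "' has values outside {0, 1}")
    return(as.numeric(x))
  }
  x <- as.character(x)
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) > 2)
    stop("binary column '", name, "' has more than two levels")
  as.numeric(match(x, lev) - 1L)
}

stat_mode <- function(x) {
  x <- x[!is.na(x)]
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}
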