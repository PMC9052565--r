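#' Stability selection over resampled or re-simulated skeletons
#'
#' Runs the PC skeleton `config$iterations` times and counts, for every
#' unordered variable pair, how often the edge is present and how often
#' its final partial correlation is positive. Two iteration regimes are
#' supported:
#'
#' * **bootstrap** (default, `refresh = NULL`): each iteration analyses a
#'   patient-level nonparametric bootstrap resample (same `n`, with
#'   replacement) of `data`. This is the only option when a single fixed
#'   dataset is all there is. Note that resampling one dataset cannot
#'   remove dataset-level sampling noise: a null pair whose *observed*
#'   p-value is below `alpha` will be re-detected in most resamples, so
#'   the long-run rate of falsely stable edges is governed by `alpha`,
#'   not by the stability threshold (see the methods vignette).
#' * **refresh** (`refresh` a `function(seed)` returning a numeric matrix
#'   with the same columns as `data`): each iteration analyses an
#'   independently re-simulated dataset, e.g. a fresh synthetic cohort.
#'   Under this regime false-edge frequencies concentrate near `alpha`
#'   (binomially), and the stability threshold is an effective filter.
#'   Used for planted-graph recovery and null-calibration studies.
#'
#' An iteration that fails entirely is logged and counted as "no edges";
#' the run never aborts. Results are deterministic given `config$seed`.
#'
#' @param data Numeric matrix of encoded variables (see [encode_table()]).
#' @param config An [analysis_config()].
#' @param refresh Optional `function(seed)` supplying a fresh dataset per
#'   iteration (the re-simulation regime).
#' @return A `stability_result`: `nodes`, `alpha`, `B`, integer matrices
#'   `selection_count` and `positive_sign_count`, `failures` (character
#'   log), `n_isolated_total`.
#' @export
stability_run <- function(data, config = analysis_config(), refresh = NULL) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("data must be a numeric encoded matrix")
  n <- nrow(X); p <- ncol(X)
  nodes <- colnames(X)
  if (is.null(nodes)) stop("data must have column names")
  B <- config$iterations

  counts <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  poscounts <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  failures <- character()
  n_isolated <- 0L

  set.seed(config$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, B)
  for (b in seq_len(B)) {
    sk <- tryCatch({
      if (is.null(refresh)) {
        set.seed(iter_seeds[b])
        Xb <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
      } else {
        Xb <- refresh(iter_seeds[b])
        if (!identical(colnames(Xb), nodes))
          stop("refresh() returned mismatching columns")
      }
      pc_skeleton(Xb, config, warn = FALSE)
    }, error = function(e) e)
    if (inherits(sk, "error")) {
      failures <- c(failures,
                    sprintf("iteration %d: %s", b, conditionMessage(sk)))
      next
    }
    n_isolated <- n_isolated + length(sk$isolated)
    counts <- counts + sk$adjacency
    pos <- sk$adjacency & !is.na(sk$last_pcor) & sk$last_pcor > 0
    poscounts <- poscounts + pos
  }
  structure(list(nodes = nodes, alpha = config$alpha, B = B,
                 selection_count = counts,
                 positive_sign_count = poscounts,
                 failures = failures, n_isolated_total = n_isolated),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  sel <- sum(x$selection_count[upper.tri(x$selection_count)] > x$B / 2)
  cat("<stability_result> ", length(x$nodes), " nodes, B = ", x$B,
      ", alpha = ", x$alpha, "\n", sep = "")
  cat("  pairs with frequency > 0.5: ", sel,
      "; failed iterations: ", length(x$failures), "\n", sep = "")
  invisible(x)
}

#' Stable-edge selection with sign calls
#'
#' Retains pairs selected in strictly more than `config$min_count` of the
#' `B` iterations (a pair at exactly the threshold is *not* retained).
#' The causality sign is `positive` when the positive-sign fraction
#' strictly exceeds `sign_threshold`, `negative` when strictly below
#' `1 - sign_threshold`, and `indeterminate` otherwise (including ties at
#' the threshold).
#'
#' @param result A `stability_result`.
#' @param config The [analysis_config()] used for the run
#'   (`result$B` must equal `config$iterations`).
#' @return An `edge_selection` data frame: `var1`, `var2`,
#'   `selection_count`, `frequency`, `positive_fraction`, `sign`, sorted
#'   by frequency (descending) then by name. Honours the config's
#'   `restrict_to` filter if set.
#' @export
select_stable_edges <- function(result, config) {
  stopifnot(inherits(result, "stability_result"))
  if (result$B != config$iterations)
    stop("result$B does not match config$iterations")
  cnt <- result$selection_count
  keep <- which(cnt > config$min_count & upper.tri(cnt), arr.ind = TRUE)
  nodes <- result$nodes
  sel <- data.frame(
    var1 = nodes[keep[, 1L]], var2 = nodes[keep[, 2L]],
    selection_count = cnt[keep],
    frequency = cnt[keep] / result$B,
    positive_fraction = ifelse(cnt[keep] > 0,
                               result$positive_sign_count[keep] / cnt[keep],
                               NA_real_),
    stringsAsFactors = FALSE)
  st <- config$sign_threshold
  sel$sign <- ifelse(sel$positive_fraction > st, "positive",
                     ifelse(sel$positive_fraction < 1 - st, "negative",
                            "indeterminate"))
  if (!is.null(config$restrict_to))
    sel <- sel[sel$var1 %in% config$restrict_to |
                 sel$var2 %in% config$restrict_to, ]
  sel <- sel[order(-sel$frequency, sel$var1, sel$var2), ]
  rownames(sel) <- NULL
  class(sel) <- c("edge_selection", "data.frame")
  sel
}
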