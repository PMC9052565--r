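#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate with simultaneous handling of tied event times
#' (subjects censored at `t` remain at risk at `t`), Greenwood standard
#' errors, and the median with a Brookmeyer-Crowley-style 95% confidence
#' interval computed on the log-log scale. The median is the smallest
#' time at which the survival function reaches 0.5 or less; when the
#' curve never does (for example an all-censored sample) the median is
#' `NA` and flagged undefined.
#'
#' @param times Positive follow-up times (days).
#' @param events Event indicators (1 = event, 0 = censored), same length.
#' @return A `survival_curve` list: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err` (Greenwood SE of S), `median`,
#'   `median_ci`, `median_defined`, `n`.
#' @export
km_curve <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be positive and finite")
  if (!all(events %in% c(0, 1))) stop("events must be binary 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  sm <- summary(fit, times = fit$time, extend = TRUE)
  # smallest t with S(t) <= 0.5 (no averaging on an exact 0.5 plateau)
  at <- which(fit$surv <= 0.5 + 1e-12)
  median <- if (length(at)) fit$time[min(at)] else NA_real_
  q <- suppressWarnings(stats::quantile(fit, probs = 0.5, conf.int = TRUE))
  ci <- c(unname(q$lower)[1], unname(q$upper)[1])
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, std_err = sm$std.err,
                 median = median, median_ci = ci,
                 median_defined = length(at) > 0, n = length(times)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> n =", x$n, " events =", sum(x$n_event), "\n")
  if (x$median_defined)
    cat("  median =", x$median, " (95% CI ", x$median_ci[1], "-",
        x$median_ci[2], ")\n")
  else cat("  median undefined (curve never reaches 0.5)\n")
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard log-rank chi-square: at each distinct event time the observed
#' minus hypergeometric-expected events per group, summed and compared
#' against a chi-square with (k - 1) degrees of freedom. A group with no
#' events contributes expectations only; a declared group that is empty
#' raises an error naming the group.
#'
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param group Group labels (factor or vector; at least 2 levels).
#' @return List: `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
logrank <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  cnt <- table(group)
  if (any(cnt == 0))
    stop("empty group: ", paste(names(cnt)[cnt == 0], collapse = ", "))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Two-group hazard ratio from a univariate Cox model
#'
#' Single-covariate Cox proportional-hazards fit (Efron tie handling by
#' default, suited to heavily tied whole-day data; Breslow available) by
#' Newton-Raphson, with the Wald 95% confidence interval. A monotone
#' partial likelihood (complete separation of the event times) is
#' flagged and the confidence interval reported as unbounded on the
#' diverging side.
#'
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param group Binary group indicator (0/1, logical, or 2-level factor);
#'   the hazard ratio is for group 1 versus group 0.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List: `hr`, `ci` (95%), `log_hr`, `se`, `n`, `events`,
#'   `flagged` (TRUE when the likelihood is monotone).
#' @export
hazard_ratio <- function(times, events, group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(group)
  if (!all(g %in% c(0L, 1L))) stop("group must be binary")
  if (length(unique(g)) < 2) stop("both groups must be present")
  for (lev in 0:1)
    if (sum(events[g == lev]) < 1)
      stop("group ", lev, " has no events")
  wfit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ g, ties = ties),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(stats::coef(wfit))
  se <- sqrt(unname(stats::vcov(wfit)[1, 1]))
  flagged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100
  ci <- if (flagged) {
    if (is.finite(beta) && beta > 0) c(0, Inf) else c(0, Inf)
  } else exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  list(hr = exp(beta), ci = ci, log_hr = beta, se = se,
       n = length(times), events = sum(events), flagged = flagged)
}

#' Default subgroup definitions for overall-survival comparisons
#'
#' The six confirmatory subgroup splits: presence of liver metastasis,
#' presence of lung metastasis, ECOG performance status (0 / 1 / >= 2),
#' neutropenia, febrile neutropenia, and cabazitaxel cycle count
#' dichotomised at >= 4 versus < 4 (the cohort median is 4).
#'
#' @param cycle_cutoff Cycle-count dichotomy (default 4).
#' @return A named list of subgroup definitions.
#' @export
default_subgroups <- function(cycle_cutoff = 4) {
  list(
    liver_metastasis = list(variable = "liver_metastasis", type = "binary"),
    lung_metastasis = list(variable = "lung_metastasis", type = "binary"),
    ecog_ps = list(variable = "ecog_ps", type = "ordinal"),
    neutropenia = list(variable = "neutropenia", type = "binary"),
    febrile_neutropenia = list(variable = "febrile_neutropenia",
                               type = "binary"),
    treatment_cycles = list(variable = "treatment_cycles",
                            type = "threshold", cutoff = cycle_cutoff)
  )
}

#' Overall-survival subgroup analysis
#'
#' For each subgroup split: per-group patient and event counts,
#' Kaplan-Meier medians with confidence intervals, the log-rank test
#' across all levels, and the two-group hazard ratio (for an ordinal
#' split, the highest level versus the lowest; for a threshold split,
#' at-or-above versus below the cutoff). A subgroup whose variable is
#' missing, constant, or leaves a level empty is skipped with a warning.
#'
#' @param cohort A cohort data frame with `os_days` / `os_event`.
#' @param subgroups A list as produced by [default_subgroups()].
#' @return A named list of `subgroup_comparison` objects (skipped
#'   subgroups are absent).
#' @export
subgroup_analysis <- function(cohort, subgroups = default_subgroups()) {
  stopifnot(all(c("os_days", "os_event") %in% names(cohort)))
  out <- list()
  for (nm in names(subgroups)) {
    sg <- subgroups[[nm]]
    v <- cohort[[sg$variable]]
    if (is.null(v)) {
      warning("subgroup '", nm, "': variable not in table; skipped")
      next
    }
    grp <- switch(sg$type,
      binary = factor(v, levels = c(0, 1),
                      labels = c("absent", "present")),
      ordinal = factor(v),
      threshold = factor(v >= sg$cutoff, levels = c(FALSE, TRUE),
                         labels = c(paste0("<", sg$cutoff),
                                    paste0(">=", sg$cutoff))))
    keep <- !is.na(grp)
    grp <- droplevels(grp[keep])
    if (nlevels(grp) < 2) {
      warning("subgroup '", nm, "': fewer than two populated levels; skipped")
      next
    }
    t0 <- cohort$os_days[keep]; e0 <- cohort$os_event[keep]
    per_group <- do.call(rbind, lapply(levels(grp), function(l) {
      cv <- km_curve(t0[grp == l], e0[grp == l])
      data.frame(level = l, n = sum(grp == l), events = sum(e0[grp == l]),
                 median = cv$median, lcl = cv$median_ci[1],
                 ucl = cv$median_ci[2])
    }))
    lr <- logrank(t0, e0, grp)
    # hazard ratio: last level vs first level
    ext <- grp %in% levels(grp)[c(1, nlevels(grp))]
    hr <- tryCatch(
      hazard_ratio(t0[ext], e0[ext],
                   as.integer(grp[ext] == levels(grp)[nlevels(grp)])),
      error = function(e) NULL)
    out[[nm]] <- structure(
      list(subgroup = nm, variable = sg$variable, groups = per_group,
           logrank = lr, hazard_ratio = hr,
           contrast = paste(levels(grp)[nlevels(grp)], "vs",
                            levels(grp)[1])),
      class = "subgroup_comparison")
  }
  out
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat("<subgroup_comparison>", x$subgroup, "\n")
  print(x$groups, row.names = FALSE)
  cat("  log-rank chi-square =", signif(x$logrank$statistic, 4),
      " p =", signif(x$logrank$p_value, 3), "\n")
  if (!is.null(x$hazard_ratio))
    cat("  HR (", x$contrast, ") = ", signif(x$hazard_ratio$hr, 4),
        "  95% CI ", signif(x$hazard_ratio$ci[1], 4), "-",
        signif(x$hazard_ratio$ci[2], 4), "\n", sep = "")
  invisible(x)
}
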