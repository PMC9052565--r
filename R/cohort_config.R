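#' Default synthetic-cohort configuration
#'
#' Returns the full parameterisation of the default synthetic CRPC cohort:
#' 660 patients, 91 explanatory variables, one-year (365-day) administrative
#' censoring, and marginal distributions calibrated to a post-marketing
#' surveillance population of docetaxel-refractory CRPC patients treated with
#' cabazitaxel (median age 70, median overall survival 319 days, median
#' time-to-treatment-failure 116 days, 57.9% neutropenia-associated events,
#' and so on).
#'
#' Survival outcomes are Weibull proportional-hazards models. The overall
#' survival (OS) hazard is raised by liver metastasis, lung metastasis and
#' ECOG performance status, and lowered by longer treatment exposure
#' (time-to-treatment-failure, TTF) and by the occurrence of neutropenia.
#' The TTF hazard is raised by relative dose intensity (RDI), so higher RDI
#' shortens treatment duration. Neutropenia follows a logistic model in
#' dose, cycle count and RDI; Grade >= 3 and febrile neutropenia are nested
#' within it. Cycle counts are derived from treatment duration and a
#' patient-specific realized cycle length. The implied dependency structure
#' is returned by [default_planted_graph()].
#'
#' All scale parameters are in days, doses in mg/m2, RDI in percent. The
#' `scales` entry holds the fixed centring/scaling constants used inside the
#' hazard and logit linear predictors (they are part of the model definition,
#' not estimated from data).
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()], [default_planted_graph()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$n_patients
#' cfg$psa_response_rule$threshold
default_config <- function() {
  structure(list(
    n_patients = 660L,
    n_explanatory = 91L,
    followup_days = 365,
    age = list(median = 70, sd = 9, min = 43, max = 91),
    covariate_prevalences = c(
      gleason_8_10               = 0.782,
      prior_docetaxel            = 0.979,
      prior_enzalutamide         = 0.799,
      prior_abiraterone          = 0.550,
      prior_radiation            = 0.299,
      bone_metastasis            = 0.880,
      prostate_lesion            = 0.706,
      regional_node_metastasis   = 0.403,
      distant_node_metastasis    = 0.277,
      liver_metastasis           = 0.133,
      seminal_vesicle_metastasis = 0.118,
      lung_metastasis            = 0.106,
      bladder_metastasis         = 0.099,
      other_metastasis           = 0.055,
      diarrhea                   = 0.100,
      anemia                     = 0.142,
      bone_marrow_suppression    = 0.698,
      severe_infection           = 0.045,
      peripheral_neuropathy      = 0.015
    ),
    ecog_ps_probs = c(`0` = 0.625, `1` = 0.295, `2` = 0.080),
    dose_distribution = list(
      breaks = c(10, 15, 20, 25, 26.3),
      probs  = c(0.023, 0.177, 0.496, 0.302)
    ),
    rdi = list(mean = 68, sd = 16.4, min = 17.8, max = 101),
    cycle_length = list(base_days = 16.5, delay_exponent = 1.7,
                        lognorm_sd = 0.40, max_cycles = 18L),
    ttf_model = list(shape = 0.95, scale = 228,
                     loghr = c(rdi = 0.35)),
    os_model = list(shape = 1.05, scale = 366,
                    loghr = c(liver_metastasis    = 1.15,
                              lung_metastasis     = 1.15,
                              ecog_ps             = 0.70,
                              ttf                 = -0.70,
                              neutropenia         = -0.95,
                              febrile_neutropenia = -0.35)),
    ae_model = list(
      neutropenia = list(intercept = 0.02,
                         coef = c(dose = 0.60, cycles = 0.55, rdi = 0.50)),
      grade3_given_neutropenia = 0.85,
      febrile_given_grade3     = 0.366
    ),
    dropout = list(rate = 0.05, min_day = 30),
    psa_response_rule = list(threshold = 0.30, baseline_floor = 5),
    psa_model = list(meanlog = log(40), sdlog = 1.2,
                     intercept = -0.3, ttf_slope = 0.9,
                     missing_rate = 0.11),
    # fixed standardisation constants for the linear predictors
    scales = list(dose = c(20.8, 3.4), rdi = c(68, 16.4),
                  cycles = c(4.5, 3.0), ttf = c(130, 110)),
    discontinuation_probs = c(pd = 0.564, ae = 0.428, other = 0.433)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  patients:", x$n_patients,
      " explanatory variables:", x$n_explanatory,
      " follow-up:", x$followup_days, "days\n")
  cat("  OS model:    Weibull(shape =", x$os_model$shape,
      ", scale =", x$os_model$scale, "days),",
      length(x$os_model$loghr), "covariate effects\n")
  cat("  TTF model:   Weibull(shape =", x$ttf_model$shape,
      ", scale =", x$ttf_model$scale, "days),",
      length(x$ttf_model$loghr), "covariate effects\n")
  cat("  dropout:", x$dropout$rate * 100, "%  PSA response rule: >=",
      x$psa_response_rule$threshold * 100, "% decline, baseline >=",
      x$psa_response_rule$baseline_floor, "ng/mL\n")
  invisible(x)
}

# Named structural explanatory variables, in generation order.
structural_variables <- function() {
  c("age", "gleason_8_10", "ecog_ps",
    "prior_docetaxel", "prior_enzalutamide", "prior_abiraterone",
    "prior_radiation",
    "bone_metastasis", "prostate_lesion", "regional_node_metastasis",
    "distant_node_metastasis", "liver_metastasis",
    "seminal_vesicle_metastasis", "lung_metastasis", "bladder_metastasis",
    "other_metastasis",
    "dose", "rdi", "treatment_cycles",
    "discontinued_ae", "discontinued_pd", "discontinued_other",
    "neutropenia", "grade3_neutropenia", "febrile_neutropenia",
    "diarrhea", "anemia", "bone_marrow_suppression", "severe_infection",
    "peripheral_neuropathy", "psa_baseline")
}

#' Validate a cohort configuration
#'
#' Checks field types, probability ranges and positivity constraints.
#' Raises a configuration error naming the offending field.
#'
#' @param config A `cohort_config` list.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(field, msg)
    stop(sprintf("configuration error in field '%s': %s", field, msg),
         call. = FALSE)
  if (!is.numeric(config$n_patients) || config$n_patients < 1)
    fail("n_patients", "must be a positive count")
  n_struct <- length(structural_variables())
  if (!is.numeric(config$n_explanatory) || config$n_explanatory < n_struct)
    fail("n_explanatory",
         sprintf("must be >= %d (the number of named structural variables)",
                 n_struct))
  if (!is.numeric(config$followup_days) || config$followup_days <= 0)
    fail("followup_days", "must be positive")
  pr <- config$covariate_prevalences
  if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
    fail("covariate_prevalences", "all probabilities must lie in [0, 1]")
  if (abs(sum(config$ecog_ps_probs) - 1) > 1e-8)
    fail("ecog_ps_probs", "must sum to 1")
  for (m in c("os_model", "ttf_model")) {
    if (config[[m]]$shape <= 0 || config[[m]]$scale <= 0)
      fail(m, "Weibull shape and scale must be > 0")
  }
  dd <- config$dose_distribution
  # printed category percentages carry rounding; tolerate it
  if (abs(sum(dd$probs) - 1) > 0.01 ||
      length(dd$breaks) != length(dd$probs) + 1)
    fail("dose_distribution", "probs must sum to 1 and match the breaks")
  if (config$dropout$rate < 0 || config$dropout$rate > 1)
    fail("dropout", "rate must lie in [0, 1]")
  psa <- config$psa_response_rule
  if (psa$threshold <= 0 || psa$threshold >= 1)
    fail("psa_response_rule", "threshold must lie in (0, 1)")
  invisible(config)
}

#' Planted dependency graph of a cohort configuration
#'
#' The ground-truth edge list implied by a configuration: one undirected
#' edge per direct dependency created by the generator, in the *encoded*
#' variable space used by the network analysis (see [encode_table()]),
#' where `OS` / `TTF` are survival durations in days, so a hazard-raising
#' covariate carries a negative expected correlation sign.
#'
#' Edges fall into two groups: *effect* edges, present only when the
#' corresponding configuration coefficient is non-zero (for example liver
#' metastasis on the OS hazard), and *mechanical* edges created by the
#' bookkeeping of the design regardless of coefficients (censor flags,
#' the observation window, cycle counts derived from treatment duration,
#' nesting of the neutropenia grades).
#'
#' @param config A `cohort_config`.
#' @return A `planted_graph`: data frame with columns `source`, `target`,
#'   `sign` (`"+"` or `"-"`, the expected correlation sign) and
#'   `effect_size` (log-hazard or log-odds coefficient; 1 for
#'   deterministic/mechanical couplings).
#' @export
default_planted_graph <- function(config = default_config()) {
  edges <- list()
  add <- function(a, b, effect) {
    if (!is.finite(effect) || effect == 0) return()
    edges[[length(edges) + 1L]] <<- data.frame(
      source = a, target = b,
      sign = if (effect > 0) "+" else "-",
      effect_size = effect, stringsAsFactors = FALSE)
  }
  os <- config$os_model$loghr
  # positive log-hazard-ratio => shorter survival => negative correlation
  add("OS", "liver_metastasis",    -os[["liver_metastasis"]])
  add("OS", "lung_metastasis",     -os[["lung_metastasis"]])
  add("OS", "ecog_ps",             -os[["ecog_ps"]])
  add("OS", "TTF",                 -os[["ttf"]])
  add("OS", "neutropenia",         -os[["neutropenia"]])
  add("OS", "febrile_neutropenia", -os[["febrile_neutropenia"]])
  add("TTF", "rdi", -config$ttf_model$loghr[["rdi"]])
  ne <- config$ae_model$neutropenia$coef
  add("neutropenia", "dose",             ne[["dose"]])
  add("neutropenia", "treatment_cycles", ne[["cycles"]])
  add("neutropenia", "rdi",              ne[["rdi"]])
  add("TTF", "PSA_response", config$psa_model$ttf_slope)
  # mechanical couplings (always present)
  add("OS", "OS_censoring", 1)
  add("TTF", "TTF_censoring", 1)
  add("OS", "observation_period", 1)
  add("TTF", "treatment_cycles", 1)
  add("rdi", "treatment_cycles", 1)
  add("neutropenia", "grade3_neutropenia", 1)
  add("grade3_neutropenia", "febrile_neutropenia", 1)
  add("TTF_censoring", "discontinued_ae", -1)
  add("TTF_censoring", "discontinued_pd", -1)
  add("TTF_censoring", "discontinued_other", -1)
  add("TTF_censoring", "observation_period", -1)
  g <- do.call(rbind, edges)
  rownames(g) <- NULL
  stopifnot(all(g$source != g$target), all(g$effect_size != 0))
  class(g) <- c("planted_graph", "data.frame")
  g
}

# Canonical unordered-pair keys for edge comparison.
edge_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
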