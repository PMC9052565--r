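#' Generate a synthetic CRPC cohort with a known dependency structure
#'
#' Draws a patient-level cohort from the generative model described by a
#' [default_config()]-style configuration: baseline covariates, dosing,
#' latent Weibull treatment-failure and death times with planted
#' proportional-hazards effects, adverse events, PSA response, a small
#' random early-dropout process, and administrative censoring at
#' `config$followup_days`. Identical `(config, seed)` pairs reproduce the
#' table exactly.
#'
#' Generation order (a directed acyclic graph): baseline covariates and
#' dosing; latent treatment-failure time `T` (hazard raised by RDI); the
#' observation window (dropout or the full year); planned cycle count and
#' the neutropenia cascade (logistic in dose, cycles, RDI, with Grade >= 3
#' and febrile neutropenia nested); latent death time `D` (hazard raised by
#' liver/lung metastasis and ECOG PS, lowered by treatment exposure and by
#' neutropenia); then realized outcomes `os_days = min(D, window)` and
#' `ttf_days = min(T, D, window)` (any discontinuation reason, including
#' death, counts as a TTF event), recorded cycle counts, discontinuation
#' reasons, and PSA response coupled to treatment exposure with
#' missingness for PSA-ineligible patients.
#'
#' @param config A `cohort_config`; validated before use.
#' @param seed Integer seed; every random draw derives from it.
#' @return A list with components:
#'   * `cohort`: data frame, one row per patient: `os_days`, `os_event`,
#'     `ttf_days`, `ttf_event`, `psa_response`, `observation_days`, and
#'     `config$n_explanatory` explanatory columns;
#'   * `graph`: the planted ground-truth graph ([default_planted_graph()]);
#'   * `dictionary`: the variable dictionary (name, role, kind, units).
#' @export
#' @examples
#' cc <- generate_cohort(default_config(), seed = 1)
#' dim(cc$cohort)
generate_cohort <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  set.seed(seed)
  n   <- as.integer(config$n_patients)
  fup <- config$followup_days

  ## --- baseline characteristics -------------------------------------
  ag <- config$age
  u_lo <- stats::pnorm(ag$min, ag$median, ag$sd)
  u_hi <- stats::pnorm(ag$max, ag$median, ag$sd)
  age <- round(stats::qnorm(stats::runif(n, u_lo, u_hi), ag$median, ag$sd))

  prev <- config$covariate_prevalences
  bin <- sapply(names(prev), function(v) stats::rbinom(n, 1L, prev[[v]]))
  colnames(bin) <- names(prev)

  ps_levels <- as.integer(names(config$ecog_ps_probs))
  ecog_ps <- sample(ps_levels, n, replace = TRUE, prob = config$ecog_ps_probs)

  ## --- dosing --------------------------------------------------------
  dd <- config$dose_distribution
  cat_idx <- sample.int(length(dd$probs), n, replace = TRUE, prob = dd$probs)
  lo <- dd$breaks[cat_idx]; hi <- dd$breaks[cat_idx + 1L]
  # skew the within-category draw low: clinical dosing clusters at the
  # reduced end of each band
  dose <- lo + (hi - lo) * stats::rbeta(n, 1, 2)

  rr <- config$rdi
  u_lo <- stats::pnorm(rr$min, rr$mean, rr$sd)
  u_hi <- stats::pnorm(rr$max, rr$mean, rr$sd)
  rdi <- stats::qnorm(stats::runif(n, u_lo, u_hi), rr$mean, rr$sd)

  sc <- config$scales
  z_dose <- (dose - sc$dose[1]) / sc$dose[2]
  z_rdi  <- (rdi  - sc$rdi[1])  / sc$rdi[2]

  ## --- latent treatment failure and observation window ----------------
  tm <- config$ttf_model
  lp_t <- tm$loghr[["rdi"]] * z_rdi
  T_lat <- rweibull_ph(n, tm$shape, tm$scale, lp_t)

  drop <- stats::rbinom(n, 1L, config$dropout$rate) == 1L
  u_drop <- ifelse(drop, stats::runif(n, config$dropout$min_day, fup), Inf)
  window <- pmin(u_drop, fup)

  ## --- treatment exposure, cycles, neutropenia cascade ----------------
  cl <- config$cycle_length
  # realized per-patient cycle length: the protocol interval stretched
  # super-proportionally at low delivered dose intensity (low RDI reflects
  # both dose reductions and cycle delays), with an independent lognormal
  # delay factor
  cyc_len <- cl$base_days * (100 / rdi)^cl$delay_exponent *
    exp(stats::rnorm(n, 0, cl$lognorm_sd))
  exposure <- pmin(T_lat, window)
  cycles_planned <- clamp_cycles(exposure / cyc_len, cl$max_cycles)

  z_cyc <- (cycles_planned - sc$cycles[1]) / sc$cycles[2]
  nm <- config$ae_model$neutropenia
  p_neut <- stats::plogis(nm$intercept + nm$coef[["dose"]] * z_dose +
                          nm$coef[["cycles"]] * z_cyc +
                          nm$coef[["rdi"]] * z_rdi)
  neutropenia <- stats::rbinom(n, 1L, p_neut)
  grade3 <- neutropenia *
    stats::rbinom(n, 1L, config$ae_model$grade3_given_neutropenia)
  febrile <- grade3 *
    stats::rbinom(n, 1L, config$ae_model$febrile_given_grade3)

  ## --- death ----------------------------------------------------------
  om <- config$os_model
  z_ttf <- (pmin(T_lat, fup) - sc$ttf[1]) / sc$ttf[2]
  lp_o <- om$loghr[["liver_metastasis"]] * bin[, "liver_metastasis"] +
    om$loghr[["lung_metastasis"]] * bin[, "lung_metastasis"] +
    om$loghr[["ecog_ps"]] * ecog_ps +
    om$loghr[["ttf"]] * z_ttf +
    om$loghr[["neutropenia"]] * neutropenia +
    om$loghr[["febrile_neutropenia"]] * febrile
  # centre the linear predictor at its design expectation so the baseline
  # scale parameter stays interpretable as the median-patient scale
  lp_o <- lp_o - expected_os_lp(config)
  D_lat <- rweibull_ph(n, om$shape, om$scale, lp_o)

  ## --- realized outcomes ----------------------------------------------
  os_days  <- pmin(D_lat, window)
  os_event <- as.integer(D_lat <= window)
  ttf_days  <- pmin(T_lat, D_lat, window)
  ttf_event <- as.integer(pmin(T_lat, D_lat) <= window)
  observation_days <- window
  # whole-day recording
  os_days  <- pmax(1, round(os_days))
  ttf_days <- pmax(1, round(ttf_days))
  observation_days <- pmax(1, round(observation_days))
  ttf_days <- pmin(ttf_days, observation_days)
  os_days  <- pmin(os_days, observation_days)

  treatment_cycles <- clamp_cycles(ttf_days / cyc_len, cl$max_cycles)

  ## --- discontinuation reasons (multiple allowed) ----------------------
  # reasons are recorded only for observed failures; none, one or several
  # may be ticked (an event can go without a recorded reason, as in
  # registry practice)
  dp <- config$discontinuation_probs
  disc_pd    <- stats::rbinom(n, 1L, dp[["pd"]]) * ttf_event
  disc_ae    <- stats::rbinom(n, 1L, dp[["ae"]]) * ttf_event
  disc_other <- stats::rbinom(n, 1L, dp[["other"]]) * ttf_event

  ## --- PSA ------------------------------------------------------------
  pm <- config$psa_model
  psa_baseline <- exp(stats::rnorm(n, pm$meanlog, pm$sdlog))
  eligible <- psa_baseline >= config$psa_response_rule$baseline_floor
  p_resp <- stats::plogis(pm$intercept + pm$ttf_slope * z_ttf)
  psa_response <- stats::rbinom(n, 1L, p_resp)
  missing <- !eligible | stats::runif(n) < pm$missing_rate
  psa_response[missing] <- NA_integer_

  ## --- noise padding ---------------------------------------------------
  n_noise <- config$n_explanatory - length(structural_variables())
  n_bin  <- n_noise %/% 2L
  n_cont <- n_noise - n_bin
  noise_prev <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), length.out = n_bin)
  noise_b <- matrix(0L, n, n_bin)
  for (k in seq_len(n_bin)) noise_b[, k] <- stats::rbinom(n, 1L, noise_prev[k])
  noise_c <- matrix(stats::rnorm(n * n_cont), n, n_cont)
  colnames(noise_b) <- sprintf("noise_bin_%02d", seq_len(n_bin))
  colnames(noise_c) <- sprintf("noise_cont_%02d", seq_len(n_cont))

  cohort <- data.frame(
    os_days = os_days, os_event = os_event,
    ttf_days = ttf_days, ttf_event = ttf_event,
    psa_response = psa_response,
    observation_days = observation_days,
    age = age,
    gleason_8_10 = bin[, "gleason_8_10"],
    ecog_ps = ecog_ps,
    prior_docetaxel = bin[, "prior_docetaxel"],
    prior_enzalutamide = bin[, "prior_enzalutamide"],
    prior_abiraterone = bin[, "prior_abiraterone"],
    prior_radiation = bin[, "prior_radiation"],
    bone_metastasis = bin[, "bone_metastasis"],
    prostate_lesion = bin[, "prostate_lesion"],
    regional_node_metastasis = bin[, "regional_node_metastasis"],
    distant_node_metastasis = bin[, "distant_node_metastasis"],
    liver_metastasis = bin[, "liver_metastasis"],
    seminal_vesicle_metastasis = bin[, "seminal_vesicle_metastasis"],
    lung_metastasis = bin[, "lung_metastasis"],
    bladder_metastasis = bin[, "bladder_metastasis"],
    other_metastasis = bin[, "other_metastasis"],
    dose = dose, rdi = rdi,
    treatment_cycles = treatment_cycles,
    discontinued_ae = disc_ae, discontinued_pd = disc_pd,
    discontinued_other = disc_other,
    neutropenia = neutropenia, grade3_neutropenia = grade3,
    febrile_neutropenia = febrile,
    diarrhea = bin[, "diarrhea"], anemia = bin[, "anemia"],
    bone_marrow_suppression = bin[, "bone_marrow_suppression"],
    severe_infection = bin[, "severe_infection"],
    peripheral_neuropathy = bin[, "peripheral_neuropathy"],
    psa_baseline = psa_baseline)
  cohort <- cbind(cohort, as.data.frame(noise_b), as.data.frame(noise_c))

  list(cohort = cohort,
       graph = default_planted_graph(config),
       dictionary = cohort_dictionary(cohort))
}

# Weibull proportional-hazards draw: S(t) = exp(-(t/scale)^shape * e^lp).
rweibull_ph <- function(n, shape, scale, lp) {
  u <- stats::runif(n)
  scale * (-log(u) * exp(-lp))^(1 / shape)
}

# a started cycle counts as delivered
clamp_cycles <- function(x, max_cycles) {
  pmin(pmax(1L, as.integer(ceiling(x))), as.integer(max_cycles))
}

# Design expectation of the OS linear predictor under the default marginals.
expected_os_lp <- function(config) {
  om <- config$os_model$loghr
  prev <- config$covariate_prevalences
  ps_mean <- sum(as.integer(names(config$ecog_ps_probs)) *
                   config$ecog_ps_probs)
  om[["liver_metastasis"]] * prev[["liver_metastasis"]] +
    om[["lung_metastasis"]] * prev[["lung_metastasis"]] +
    om[["ecog_ps"]] * ps_mean +
    om[["ttf"]] * 0 +          # exposure z-score is approximately centred
    om[["neutropenia"]] * 0.58 +         # design neutropenia incidence
    om[["febrile_neutropenia"]] * 0.18   # design febrile incidence
}

#' Variable dictionary for a cohort table
#'
#' One row per column: name, role (`response`, `explanatory`,
#' `bookkeeping`), kind (`binary`, `ordinal`, `continuous`, `count`) and
#' units. Exactly three columns carry the `response` role: OS, TTF and
#' PSA response; censor flags and the observation window are bookkeeping.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @return A data frame with columns `name`, `role`, `kind`, `units`.
#' @export
cohort_dictionary <- function(cohort) {
  spec1 <- function(name, role, kind, units = "")
    data.frame(name = name, role = role, kind = kind, units = units,
               stringsAsFactors = FALSE)
  fixed <- rbind(
    spec1("os_days", "response", "continuous", "days"),
    spec1("os_event", "bookkeeping", "binary", "1 = death observed"),
    spec1("ttf_days", "response", "continuous", "days"),
    spec1("ttf_event", "bookkeeping", "binary", "1 = failure observed"),
    spec1("psa_response", "response", "binary", ">=30% PSA decline"),
    spec1("observation_days", "bookkeeping", "continuous", "days"),
    spec1("age", "explanatory", "continuous", "years"),
    spec1("ecog_ps", "explanatory", "ordinal", "0/1/>=2"),
    spec1("dose", "explanatory", "continuous", "mg/m2"),
    spec1("rdi", "explanatory", "continuous", "percent"),
    spec1("treatment_cycles", "explanatory", "count", "cycles"),
    spec1("psa_baseline", "explanatory", "continuous", "ng/mL"))
  rest <- setdiff(names(cohort), fixed$name)
  kind <- ifelse(grepl("^noise_cont", rest), "continuous", "binary")
  dict <- rbind(fixed, spec1(rest, "explanatory", kind))
  dict <- dict[match(names(cohort), dict$name), ]
  rownames(dict) <- NULL
  stopifnot(!anyNA(dict$name))
  dict
}
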