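test_that("default configuration carries the study design constants", {
  cfg <- default_config()
  expect_identical(cfg$n_patients, 660L)
  expect_identical(cfg$n_explanatory, 91L)
  expect_equal(cfg$followup_days, 365)
  expect_equal(cfg$psa_response_rule$threshold, 0.30)
  expect_equal(cfg$psa_response_rule$baseline_floor, 5)
  expect_silent(validate_config(cfg))
})

test_that("configuration errors name the offending field", {
  cfg <- default_config()
  cfg$n_patients <- -5
  expect_error(validate_config(cfg), "n_patients")
  cfg <- default_config()
  cfg$covariate_prevalences[["liver_metastasis"]] <- 1.4
  expect_error(validate_config(cfg), "covariate_prevalences")
  cfg <- default_config()
  cfg$os_model$shape <- 0
  expect_error(generate_cohort(cfg, 1), "os_model")
  cfg <- default_config()
  cfg$n_explanatory <- 5L
  expect_error(validate_config(cfg), "n_explanatory")
})

test_that("identical (config, seed) pairs reproduce the cohort exactly", {
  cfg <- default_config()
  a <- generate_cohort(cfg, 11)
  b <- generate_cohort(cfg, 11)
  expect_identical(a$cohort, b$cohort)
  c <- generate_cohort(cfg, 12)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("cohort tables satisfy the structural invariants", {
  cc <- generate_cohort(default_config(), 21)
  tab <- cc$cohort
  expect_identical(nrow(tab), 660L)
  # 91 explanatory + 5 response + 1 bookkeeping column
  expect_identical(ncol(tab), 97L)
  expect_false(anyDuplicated(names(tab)) > 0)
  expect_true(all(tab$ttf_days <= tab$observation_days))
  expect_true(all(tab$os_days <= 365 & tab$os_days > 0))
  expect_true(all(tab$os_event %in% 0:1), all(tab$ttf_event %in% 0:1))
  # administrative-censoring consistency: a full-follow-up survivor is
  # censored unless death falls on the boundary day itself
  full <- tab$os_days == 365 & tab$os_event == 1
  expect_lt(mean(full), 0.01)
  dict <- cc$dictionary
  expect_identical(sum(dict$role == "response"), 3L)
  expect_setequal(dict$name, names(tab))
})

test_that("planted graph is well-formed and lives in the encoded name space", {
  cc <- generate_cohort(default_config(), 3)
  g <- cc$graph
  expect_true(all(g$source != g$target))
  expect_true(all(g$effect_size != 0))
  expect_true(all(g$sign %in% c("+", "-")))
  enc <- encode_table(cc$cohort, cc$dictionary)
  expect_true(all(unique(c(g$source, g$target)) %in% colnames(enc$matrix)))
  # zeroing every coefficient leaves only the mechanical couplings
  g0 <- default_planted_graph(zero_effect_config())
  expect_lt(nrow(g0), nrow(g))
  expect_true(all(abs(g0$effect_size) == 1))
})

test_that("with zero planted effects, explanatory-outcome correlations vanish", {
  cc <- generate_cohort(zero_effect_config(), 31)
  enc <- encode_table(cc$cohort, cc$dictionary)$matrix
  resp <- c("OS", "TTF", "PSA_response")
  expl <- setdiff(colnames(enc),
                  c(resp, "OS_censoring", "TTF_censoring",
                    "observation_period"))
  r <- stats::cor(enc[, resp], enc[, expl])
  expect_gte(mean(abs(r) < 3 / sqrt(nrow(enc))), 0.95)
})

test_that("summarize_cohort reports incidences and hand-checked KM medians", {
  tab <- data.frame(os_days = c(100, 200, 300, 360),
                    os_event = c(1, 1, 1, 1),
                    flag = c(1, 1, 1, 1))
  s <- summarize_cohort(tab)
  expect_equal(s$binary$percent[s$binary$variable == "flag"], 100)
  # hand product-limit: S = 0.75, 0.50, 0.25, 0 -> first time S <= 0.5 is 200
  expect_equal(s$km$median[s$km$endpoint == "OS"], 200)
  expect_error(summarize_cohort(data.frame()), "non-empty")
})

test_that("recovery metrics handle perfect, empty and partial selections", {
  truth <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      sign = c("+", "-"), effect_size = c(1, -1))
  perfect <- data.frame(var1 = c("b", "c"), var2 = c("a", "b"),
                        sign = c("positive", "negative"))
  m <- recovery_metrics(perfect, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$sign_accuracy, 1)

  m0 <- recovery_metrics(perfect[0, ], truth)
  expect_true(is.na(m0$precision))
  expect_equal(m0$recall, 0)
  expect_match(paste(m0$flags, collapse = " "), "precision undefined")

  mt <- recovery_metrics(perfect, truth[0, ])
  expect_true(is.na(mt$recall))
  expect_match(paste(mt$flags, collapse = " "), "empty truth")

  half <- data.frame(var1 = c("a", "a"), var2 = c("b", "c"),
                     sign = c("negative", "positive"))
  mh <- recovery_metrics(half, truth)
  expect_equal(mh$precision, 0.5)
  expect_equal(mh$recall, 0.5)
  expect_equal(mh$sign_accuracy, 0) # wrong sign on the one matched edge
})
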