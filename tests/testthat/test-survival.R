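test_that("Kaplan-Meier estimates match hand product-limit computations", {
  cv <- km_curve(c(10, 20), c(1, 0))
  expect_equal(cv$surv[cv$time == 10], 0.5)
  expect_equal(cv$surv[cv$time == 20], 0.5) # flat after the censoring

  # four deaths: S = .75, .50, .25, 0; median = first time S <= 0.5
  cv4 <- km_curve(c(100, 200, 300, 360), rep(1, 4))
  expect_equal(cv4$median, 200)

  # the classic 21-subject remission toy (9 events, 12 censored)
  times <- c(6, 6, 6, 7, 10, 13, 16, 22, 23,
             6, 9, 10, 11, 17, 19, 20, 25, 32, 32, 34, 35)
  events <- c(rep(1, 9), rep(0, 12))
  cv21 <- km_curve(times, events)
  hand <- km_oracle(times, events)
  got <- cv21$surv[match(hand$time, cv21$time)]
  expect_equal(got, hand$surv, tolerance = 1e-10)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(51)
  t <- rexp(400, 0.01) + 1
  cv <- km_curve(t, rep(1, 400))
  emp <- vapply(cv$time, function(u) mean(t > u), numeric(1))
  expect_equal(cv$surv, emp, tolerance = 1e-12)
})

test_that("an all-censored sample flags the median as undefined", {
  cv <- km_curve(c(50, 80, 120), c(0, 0, 0))
  expect_false(cv$median_defined)
  expect_true(is.na(cv$median))
  expect_error(km_curve(c(-1, 5), c(1, 1)), "positive")
  expect_error(km_curve(c(1, 5), c(1, 2)), "binary")
})

test_that("median confidence interval brackets the median when defined", {
  set.seed(52)
  t <- round(rweibull(300, 1.2, 200)) + 1
  e <- as.integer(t < 365); t <- pmin(t, 365)
  cv <- km_curve(t, e)
  expect_true(cv$median_defined)
  expect_true(is.na(cv$median_ci[1]) || cv$median_ci[1] <= cv$median)
  expect_true(is.na(cv$median_ci[2]) || cv$median_ci[2] >= cv$median)
})

test_that("log-rank matches the direct hypergeometric oracle", {
  # all group-1 events precede all group-2 events
  times <- c(1, 2, 3, 4, 5, 6, 101, 102, 103, 104, 105, 106)
  events <- rep(1, 12)
  grp <- rep(c(1, 2), each = 6)
  lr <- logrank(times, events, grp)
  expect_equal(lr$statistic, logrank_oracle(times, events, grp),
               tolerance = 1e-10)
  expect_identical(lr$df, 1)

  # identical groups: no signal
  t2 <- rep(c(5, 9, 13, 20), 2); e2 <- rep(c(1, 0, 1, 1), 2)
  lr2 <- logrank(t2, e2, rep(c("a", "b"), each = 4))
  expect_lt(lr2$statistic, 1e-10)
  expect_gt(lr2$p_value, 0.999)

  expect_error(logrank(t2, e2, factor(rep("a", 8), levels = c("a", "b"))),
               "empty group: b")
})

test_that("log-rank equals the Cox score test at beta = 0", {
  # exact identity requires untied event times: survdiff applies the
  # hypergeometric ties correction that the Breslow score omits
  set.seed(53)
  t <- rexp(160, 0.02)
  e <- rbinom(160, 1, 0.8)
  g <- rbinom(160, 1, 0.5)
  lr <- logrank(t, e, g)
  cox <- survival::coxph(survival::Surv(t, e) ~ g, ties = "breslow")
  expect_equal(lr$statistic, unname(cox$score), tolerance = 1e-6)
})

test_that("hazard ratios are symmetric under label swap and near 1 for null groups", {
  set.seed(54)
  t <- round(rexp(300, 0.01)) + 1
  e <- rbinom(300, 1, 0.85)
  g <- rbinom(300, 1, 0.5)
  h1 <- hazard_ratio(t, e, g)
  h2 <- hazard_ratio(t, e, 1 - g)
  expect_equal(h1$hr, 1 / h2$hr, tolerance = 1e-10)
  expect_lt(abs(h1$log_hr), 0.35)
  expect_false(h1$flagged)
  expect_error(hazard_ratio(t, e, rep(0, 300)), "both groups")
  expect_error(hazard_ratio(c(1, 2, 3, 4), c(1, 1, 0, 0), c(0, 0, 1, 1)),
               "no events")
})

test_that("complete separation of event times is flagged with an unbounded CI", {
  t <- c(1:8, 101:108)
  e <- rep(1, 16)
  g <- rep(c(1, 0), each = 8)
  h <- hazard_ratio(t, e, g)
  expect_true(h$flagged)
  expect_true(is.infinite(h$ci[2]))
})

test_that("subgroup analysis skips degenerate splits and keeps directions", {
  cc <- generate_cohort(default_config(), 2)
  tab <- cc$cohort
  sg <- suppressWarnings(subgroup_analysis(tab))
  expect_setequal(names(sg), names(default_subgroups()))
  expect_gt(sg$liver_metastasis$hazard_ratio$hr, 1)
  expect_lt(sg$neutropenia$hazard_ratio$hr, 1)
  expect_lt(sg$treatment_cycles$hazard_ratio$hr, 1)
  # per-group counts add up to the analysed patients
  expect_identical(sum(sg$liver_metastasis$groups$n), nrow(tab))

  tab$liver_metastasis <- 0
  expect_warning(sg2 <- subgroup_analysis(tab), "fewer than two")
  expect_false("liver_metastasis" %in% names(sg2))
  expect_warning(
    subgroup_analysis(tab, list(gone = list(variable = "nope",
                                            type = "binary"))),
    "not in table")
})
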