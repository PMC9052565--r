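test_that("single-iteration stability counts are 0 or 1 and runs are seeded", {
  set.seed(41)
  X <- cbind(a = rnorm(120), b = rnorm(120), c = rnorm(120))
  cfg <- analysis_config(alpha = 0.05, iterations = 1L, min_count = 0L,
                         seed = 5)
  res <- stability_run(X, cfg)
  expect_true(all(res$selection_count %in% 0:1))
  cfg20 <- analysis_config(iterations = 20L, min_count = 10L, seed = 9)
  r1 <- stability_run(X, cfg20)
  r2 <- stability_run(X, cfg20)
  expect_identical(r1$selection_count, r2$selection_count)
  expect_identical(r1$positive_sign_count, r2$positive_sign_count)
})

test_that("strong chain edges are stably selected under the bootstrap", {
  X <- make_structure("chain", 300, seed = 43)
  cfg <- analysis_config(alpha = 0.05, iterations = 50L, min_count = 25L,
                         seed = 3)
  res <- stability_run(X, cfg)
  sel <- select_stable_edges(res, cfg)
  got <- pair_key(sel$var1, sel$var2)
  expect_true(all(c("X Y", "Y Z") %in% got))
  expect_true(all(sel$sign[match(c("X Y", "Y Z"), got)] == "positive"))
  expect_true(res$selection_count["X", "Y"] <= res$B)
  expect_true(all(res$positive_sign_count <= res$selection_count))
})

test_that("re-simulated iterations keep false-edge frequencies near alpha", {
  # under the refresh regime a null pair's selection count is binomial
  # around alpha, so no false edge approaches the majority threshold
  p <- 8; n <- 200
  cols <- paste0("v", seq_len(p))
  refresh <- function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, cols))
    m
  }
  X <- refresh(1)
  cfg <- analysis_config(alpha = 0.05, iterations = 60L, min_count = 30L,
                         seed = 13)
  res <- stability_run(X, cfg, refresh = refresh)
  freq <- res$selection_count[upper.tri(res$selection_count)] / res$B
  expect_lte(mean(freq), 0.10)
  expect_true(all(freq <= 0.5))
  expect_identical(nrow(select_stable_edges(res, cfg)), 0L)
})

test_that("failed iterations are logged and never abort the run", {
  n <- 100
  cols <- c("a", "b")
  k <- 0
  refresh <- function(seed) {
    k <<- k + 1
    if (k %% 3 == 0) stop("simulated outage")
    set.seed(seed)
    matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, cols))
  }
  cfg <- analysis_config(iterations = 9L, min_count = 4L, seed = 2)
  res <- stability_run(matrix(rnorm(200), 100, 2,
                              dimnames = list(NULL, cols)),
                       cfg, refresh = refresh)
  expect_length(res$failures, 3L)
  expect_true(all(res$selection_count <= 6))
})

test_that("edge retention uses a strict majority and strict sign thresholds", {
  nodes <- c("u", "v", "w")
  cnt <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  pos <- cnt
  cnt["u", "v"] <- cnt["v", "u"] <- 500L  # exactly at threshold: dropped
  cnt["u", "w"] <- cnt["w", "u"] <- 501L  # strictly above: retained
  cnt["v", "w"] <- cnt["w", "v"] <- 760L
  pos["u", "w"] <- pos["w", "u"] <- 501L
  pos["v", "w"] <- pos["w", "v"] <- 380L  # exactly half: indeterminate
  res <- manual_stability_result(nodes, cnt, pos, B = 1000L)
  cfg <- analysis_config(alpha = 0.05, iterations = 1000L, min_count = 500L)
  sel <- select_stable_edges(res, cfg)
  got <- pair_key(sel$var1, sel$var2)
  expect_false("u v" %in% got)
  expect_setequal(got, c("u w", "v w"))
  expect_identical(sel$sign[match("u w", got)], "positive")
  expect_identical(sel$sign[match("v w", got)], "indeterminate")
  # a positive fraction strictly below 1 - threshold is negative
  pos["v", "w"] <- pos["w", "v"] <- 100L
  res2 <- manual_stability_result(nodes, cnt, pos, B = 1000L)
  sel2 <- select_stable_edges(res2, cfg)
  expect_identical(sel2$sign[pair_key(sel2$var1, sel2$var2) == "v w"],
                   "negative")
  expect_error(select_stable_edges(res, analysis_config(iterations = 200L,
                                                        min_count = 100L)),
               "does not match")
})

test_that("selection can be restricted to response-incident pairs", {
  nodes <- c("OS", "x1", "x2")
  cnt <- matrix(900L, 3, 3, dimnames = list(nodes, nodes))
  diag(cnt) <- 0L
  res <- manual_stability_result(nodes, cnt, cnt, B = 1000L)
  cfg <- analysis_config(iterations = 1000L, min_count = 500L,
                         restrict_to = "OS")
  sel <- select_stable_edges(res, cfg)
  expect_true(all(sel$var1 == "OS" | sel$var2 == "OS"))
  expect_identical(nrow(sel), 2L)
})
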