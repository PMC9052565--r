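test_that("association graphs carry stability frequencies as weights", {
  nodes <- c("OS", "liver", "x")
  cnt <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  cnt["OS", "liver"] <- cnt["liver", "OS"] <- 760L
  res <- manual_stability_result(nodes, cnt, cnt, B = 1000L)
  g <- build_association_graph(res)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.76)

  cnt["OS", "liver"] <- cnt["liver", "OS"] <- 500L # frequency 0.5: excluded
  res2 <- manual_stability_result(nodes, cnt, cnt, B = 1000L)
  expect_warning(g2 <- build_association_graph(res2), "empty")
  expect_equal(igraph::vcount(g2), 0)

  cnt3 <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  cnt3["OS", "liver"] <- cnt3["liver", "OS"] <- 900L
  cnt3["OS", "x"] <- cnt3["x", "OS"] <- 800L
  cnt3["liver", "x"] <- cnt3["x", "liver"] <- 700L
  res3 <- manual_stability_result(nodes, cnt3, cnt3, B = 1000L)
  g3 <- build_association_graph(res3)
  expect_equal(igraph::ecount(g3), 3)
  expect_setequal(igraph::E(g3)$weight, c(0.9, 0.8, 0.7))
})

test_that("all seven models split two disconnected triangles", {
  parts <- partition_all(two_triangles(), consensus_config(seed = 4))
  expect_length(parts, 7L)
  expect_setequal(names(parts), consensus_model_names())
  tab <- cocluster_counts(parts, factors = c("a2", "a3", "b2", "b3"),
                          responses = c("a1", "b1"))
  within <- tab$count[(tab$factor %in% c("a2", "a3") & tab$response == "a1") |
                      (tab$factor %in% c("b2", "b3") & tab$response == "b1")]
  across <- tab$count[(tab$factor %in% c("a2", "a3") & tab$response == "b1") |
                      (tab$factor %in% c("b2", "b3") & tab$response == "a1")]
  expect_true(all(within == 7L))
  expect_true(all(across == 0L))
})

test_that("a complete equal-weight graph collapses to one community", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- c("p", "q", "r", "s")
  igraph::E(g)$weight <- 0.8
  parts <- partition_all(g, consensus_config(seed = 1))
  for (m in names(parts))
    expect_identical(length(unique(parts[[m]])), 1L, info = m)
  tab <- cocluster_counts(parts, factors = c("q", "r", "s"), responses = "p")
  expect_true(all(tab$count == 7L))
})

test_that("at least six of seven models recover a planted two-block split", {
  g <- planted_two_block()
  parts <- partition_all(g, consensus_config(seed = 11))
  truth <- rep(1:2, each = 10)
  hits <- vapply(parts, function(m) {
    m <- m[sprintf("n%02d", 1:20)]
    length(unique(m)) == 2 &&
      (all(m[1:10] == m[1]) && all(m[11:20] == m[11]) && m[1] != m[11])
  }, logical(1))
  expect_gte(sum(hits), 6L)
})

test_that("co-clustering counts are invariant to node input order", {
  g <- planted_two_block()
  perm <- sample(seq_len(igraph::vcount(g)))
  g2 <- igraph::permute(g, perm)
  p1 <- partition_all(g, consensus_config(seed = 21))
  p2 <- partition_all(g2, consensus_config(seed = 21))
  f <- sprintf("n%02d", 2:10)
  t1 <- cocluster_counts(p1, f, "n01")
  t2 <- cocluster_counts(p2, f, "n01")
  expect_identical(t1$count, t2$count)
  # and rerunning with the same seed is identical
  p3 <- partition_all(g, consensus_config(seed = 21))
  expect_identical(p1, p3)
})

test_that("absent factors count zero and are noted", {
  parts <- partition_all(two_triangles(), consensus_config())
  tab <- cocluster_counts(parts, factors = c("a2", "ghost"),
                          responses = "a1")
  expect_identical(tab$count[tab$factor == "ghost"], 0L)
  expect_match(paste(attr(tab, "notes"), collapse = " "), "ghost")
})

test_that("consensus reporting uses the count-at-least-four rule", {
  tab <- data.frame(factor = c("f1", "f2", "f3", "f4"),
                    response = "OS", count = c(7L, 4L, 3L, 0L))
  class(tab) <- c("consensus_table", "data.frame")
  out <- consensus_factors(tab, consensus_config(min_models = 4))
  expect_setequal(out$factor, c("f1", "f2"))
  expect_identical(out$factor[1], "f1") # ordered by count descending
  strict <- consensus_factors(tab, consensus_config(min_models = 5))
  expect_identical(strict$factor, "f1")
})

test_that("causality calls use an inclusive 80% boundary", {
  cfg <- consensus_config()
  expect_identical(causality_call(0.85, cfg), "positive")
  expect_identical(causality_call(0.80, cfg), "positive")
  expect_identical(causality_call(0.5, cfg), "not-positive")
  expect_error(causality_call(1.2, cfg))
})
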