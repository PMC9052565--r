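# Independent oracles and small fixtures, built in code at test time.

# Regression-residual oracle for the partial correlation: correlate the
# residuals of least-squares regressions of columns i and j on S.
pcor_residual_oracle <- function(data, i, j, S) {
  X <- as.matrix(data)
  if (length(S) == 0) return(stats::cor(X[, i], X[, j]))
  Z <- X[, S, drop = FALSE]
  ri <- stats::lm.fit(cbind(1, Z), X[, i])$residuals
  rj <- stats::lm.fit(cbind(1, Z), X[, j])$residuals
  stats::cor(ri, rj)
}

# Hand product-limit estimator over the distinct event times.
km_oracle <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (k in seq_along(tt)) {
    d <- sum(times == tt[k] & events == 1)
    r <- sum(times >= tt[k])
    s <- s * (1 - d / r)
    out[k] <- s
  }
  data.frame(time = tt, surv = out)
}

# Direct two-group log-rank statistic: hypergeometric observed-minus-
# expected sums over the distinct event times.
logrank_oracle <- function(times, events, group) {
  g <- as.integer(as.factor(group)) - 1L
  tt <- sort(unique(times[events == 1]))
  o_e <- 0; v <- 0
  for (t in tt) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_e)^2 / v
}

# Gaussian structure toys (chain, fork, collider) with strong effects.
make_structure <- function(kind, n, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  if (kind == "chain") {
    y <- x + stats::rnorm(n); z <- y + stats::rnorm(n)
  } else if (kind == "fork") {
    y <- stats::rnorm(n); x <- y + stats::rnorm(n); z <- y + stats::rnorm(n)
  } else if (kind == "collider") {
    y <- stats::rnorm(n); z <- x + y + stats::rnorm(n)
  } else stop("unknown kind")
  cbind(X = x, Y = y, Z = z)
}

true_skeleton <- function(kind) {
  switch(kind,
         chain = rbind(c("X", "Y"), c("Y", "Z")),
         fork = rbind(c("X", "Y"), c("Y", "Z")),
         collider = rbind(c("X", "Z"), c("Y", "Z")))
}

skeleton_pairs <- function(sk) {
  A <- sk$adjacency
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  sort(paste(pmin(sk$nodes[idx[, 1]], sk$nodes[idx[, 2]]),
             pmax(sk$nodes[idx[, 1]], sk$nodes[idx[, 2]])))
}

pairs_of <- function(a, b) sort(paste(pmin(a, b), pmax(a, b)))
# unsorted variant for row-aligned lookups
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Columns with exact sample correlations: u1, u2 orthonormal and centred,
# y = r * u1 + sqrt(1 - r^2) * u2 has exact sample correlation r with u1.
exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  b <- scale(matrix(stats::rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(b))
  u1 <- q[, 1]; u2 <- q[, 2]; u3 <- q[, 3]
  cbind(x = u1, y = r * u1 + sqrt(1 - r^2) * u2, s = u3)
}

# A cohort configuration with every planted coefficient set to zero
# (mechanical couplings remain).
zero_effect_config <- function() {
  cfg <- default_config()
  cfg$os_model$loghr[] <- 0
  cfg$ttf_model$loghr[] <- 0
  cfg$ae_model$neutropenia$coef[] <- 0
  cfg$psa_model$ttf_slope <- 0
  cfg
}

# Small stability_result built by hand for threshold-semantics tests.
manual_stability_result <- function(nodes, counts, poscounts, B, alpha = 0.05) {
  structure(list(nodes = nodes, alpha = alpha, B = B,
                 selection_count = counts,
                 positive_sign_count = poscounts,
                 failures = character(), n_isolated_total = 0L),
            class = "stability_result")
}

# Weighted graph helpers for the consensus tests.
two_triangles <- function() {
  el <- rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
              c("b1", "b2"), c("b2", "b3"), c("b1", "b3"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- 0.9
  g
}

planted_two_block <- function(block_size = 10, w_in = 0.9, w_bridge = 0.05) {
  n <- 2 * block_size
  nodes <- sprintf("n%02d", seq_len(n))
  el <- NULL; w <- NULL
  for (b in 0:1) {
    ids <- nodes[seq_len(block_size) + b * block_size]
    cmb <- utils::combn(ids, 2)
    el <- cbind(el, cmb); w <- c(w, rep(w_in, ncol(cmb)))
  }
  el <- cbind(el, c(nodes[1], nodes[block_size + 1]))
  w <- c(w, w_bridge)
  g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
  igraph::E(g)$weight <- w
  g
}
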