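#' Analysis configuration for the graphical-Markov stage
#'
#' @param alpha Per-test significance level for the conditional
#'   independence tests (the study design uses 0.05 and 0.01).
#' @param iterations Number of stability iterations `B` (design: 1000).
#' @param min_count Strict selection threshold: an edge is retained when
#'   present in *more than* `min_count` of the `B` iterations (design:
#'   500 of 1000).
#' @param max_cond_size Largest conditioning-set size tried by the PC
#'   skeleton search.
#' @param sign_threshold An edge's causality sign is called positive when
#'   its positive-sign fraction strictly exceeds this value, negative
#'   when strictly below `1 - sign_threshold`, else indeterminate.
#' @param ridge Ridge added to ill-conditioned correlation submatrices.
#' @param kappa_max Condition-number cap triggering the ridge.
#' @param seed Seed for the resampling stream.
#' @param restrict_to Optional character vector of node names; when set,
#'   [select_stable_edges()] reports only pairs with at least one
#'   endpoint in this set (e.g. the response variables). Estimation
#'   always uses the full graph.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, iterations = 1000L,
                            min_count = 500L, max_cond_size = 3L,
                            sign_threshold = 0.5, ridge = 1e-4,
                            kappa_max = 1e8, seed = 1L,
                            restrict_to = NULL) {
  stopifnot(alpha > 0, alpha < 1, min_count < iterations,
            max_cond_size >= 0, sign_threshold >= 0, sign_threshold <= 1)
  structure(list(alpha = alpha, iterations = as.integer(iterations),
                 min_count = as.integer(min_count),
                 max_cond_size = as.integer(max_cond_size),
                 sign_threshold = sign_threshold, ridge = ridge,
                 kappa_max = kappa_max, seed = as.integer(seed),
                 restrict_to = restrict_to),
            class = "analysis_config")
}

#' PC-style skeleton of a numeric data matrix
#'
#' Standard PC skeleton search ("stable" variant: within each
#' conditioning-set size the adjacency sets are those at the start of the
#' stage, so the result does not depend on edge processing order): start
#' from the complete graph and remove the edge `i - j` as soon as some
#' conditioning set `S` drawn from `adj(i) \\ {j}` or `adj(j) \\ {i}` with
#' `|S| <= max_cond_size` yields a Fisher-z p-value above `alpha`.
#' Conditioning sets are enumerated in increasing size and
#' lexicographically within a size. A test that is incomputable
#' (degenerate correlation submatrix, insufficient sample) is skipped —
#' the edge is retained for that set — so a pathological submatrix never
#' interrupts the analysis. Zero-variance columns are isolated up front.
#'
#' @param data Numeric matrix (rows = observations, named columns).
#' @param config An [analysis_config()].
#' @param warn Warn about zero-variance columns (default `TRUE`;
#'   [stability_run()] silences this and collects the log instead).
#' @return A `pc_skeleton` list: `nodes`, logical `adjacency` matrix,
#'   `last_pcor` (the partial correlation of each surviving edge in its
#'   last surviving conditioning context, marginal if never conditioned),
#'   `isolated` (names of zero-variance columns), `n`.
#' @export
pc_skeleton <- function(data, config = analysis_config(), warn = TRUE) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("data must be numeric")
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 columns")
  if (n < config$max_cond_size + 3)
    stop("need at least max_cond_size + 3 rows")
  nodes <- colnames(X)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  alpha <- config$alpha

  sds <- .colSds(X)
  ok <- is.finite(sds) & sds > 0
  isolated <- nodes[!ok]
  if (length(isolated) && warn)
    warning("isolating zero-variance column(s): ",
            paste(isolated, collapse = ", "))

  C <- matrix(NA_real_, p, p)
  if (sum(ok) >= 2)
    C[ok, ok] <- suppressWarnings(stats::cor(X[, ok, drop = FALSE]))

  # order 0: marginal screen, vectorised
  z <- atanh(clamp1(C) * (1 - 1e-15))
  pv <- 2 * stats::pnorm(-sqrt(max(n - 3, 1)) * abs(z))
  A <- !is.na(pv) & pv <= alpha
  A[!ok, ] <- FALSE; A[, !ok] <- FALSE
  diag(A) <- FALSE
  lastr <- C
  lastr[!A] <- NA_real_

  ord <- 0L
  while (ord < config$max_cond_size) {
    ord <- ord + 1L
    if (n - ord - 3 <= 0) break
    A_ref <- A # PC-stable adjacency snapshot
    deg <- rowSums(A_ref)
    eidx <- which(A & upper.tri(A), arr.ind = TRUE)
    if (nrow(eidx) == 0) break
    any_tested <- FALSE
    for (e in seq_len(nrow(eidx))) {
      i <- eidx[e, 1L]; j <- eidx[e, 2L]
      if (deg[i] - 1L < ord && deg[j] - 1L < ord) next
      sets <- cond_sets(A_ref, i, j, ord)
      if (is.null(sets)) next
      any_tested <- TRUE
      if (ord == 1L) {
        ks <- sets[1L, ]
        rij <- C[i, j]; rik <- C[i, ks]; rjk <- C[j, ks]
        den <- (1 - rik^2) * (1 - rjk^2)
        r1 <- ifelse(den > 1e-12, (rij - rik * rjk) / sqrt(pmax(den, 1e-300)),
                     NA_real_)
        # degenerate conditioners go through the ridge path one by one
        for (d in which(!is.finite(r1)))
          r1[d] <- pcor_from_cor(C, i, j, ks[d], config$ridge,
                                 config$kappa_max)
        r1 <- clamp1(r1)
        pvs <- ifelse(is.na(r1), NA_real_,
                      ifelse(abs(r1) >= 1, 0,
                             2 * stats::pnorm(-sqrt(n - 4) * abs(atanh(
                               r1 * (1 - 1e-15))))))
        hit <- which(!is.na(pvs) & pvs > alpha)
        if (length(hit)) {
          A[i, j] <- A[j, i] <- FALSE
          lastr[i, j] <- lastr[j, i] <- NA_real_
        } else {
          keep <- which(!is.na(r1))
          if (length(keep))
            lastr[i, j] <- lastr[j, i] <- r1[max(keep)]
        }
      } else {
        for (s in seq_len(ncol(sets))) {
          S <- sets[, s]
          r <- pcor_from_cor(C, i, j, S, config$ridge, config$kappa_max)
          pvs <- fisher_z_p(r, n, ord)
          if (is.na(pvs)) next # incomputable: edge retained for this S
          if (pvs > alpha) {
            A[i, j] <- A[j, i] <- FALSE
            lastr[i, j] <- lastr[j, i] <- NA_real_
            break
          }
          lastr[i, j] <- lastr[j, i] <- r
        }
      }
    }
    if (!any_tested) break
  }
  structure(list(nodes = nodes, adjacency = A, last_pcor = lastr,
                 isolated = isolated, n = n),
            class = "pc_skeleton")
}

.colSds <- function(X) {
  m <- colMeans(X)
  sqrt(pmax(colMeans(X * X) - m * m, 0))
}

# Conditioning sets of size `ord` drawn from adj(i)\{j} or adj(j)\{i}
# (snapshot adjacency), deduplicated, lexicographic. Returns an
# `ord` x nsets matrix or NULL.
cond_sets <- function(A_ref, i, j, ord) {
  ni <- setdiff(which(A_ref[i, ]), j)
  nj <- setdiff(which(A_ref[j, ]), i)
  # combn(x, m) with scalar x would enumerate seq_len(x): index instead
  subsets <- function(v, m) {
    if (length(v) < m) return(NULL)
    idx <- utils::combn(seq_along(v), m)
    matrix(v[idx], nrow = m)
  }
  out <- cbind(subsets(ni, ord), subsets(nj, ord))
  if (is.null(out) || ncol(out) == 0) return(NULL)
  # pack each (ascending) set into one number: radix order of the packed
  # key equals lexicographic order of the set
  base <- nrow(A_ref) + 1
  keys <- as.numeric(base^((ord - 1):0) %*% out)
  dup <- duplicated(keys)
  out <- out[, !dup, drop = FALSE]
  out[, order(keys[!dup]), drop = FALSE]
}
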