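#' Partial correlation of two columns given a conditioning set
#'
#' Computes the partial correlation of columns `i` and `j` of a numeric
#' matrix given the columns in `S`, from the inverse of the correlation
#' submatrix of `c(i, j, S)`. Equals the Pearson correlation when `S` is
#' empty. When the submatrix is ill-conditioned (reciprocal condition
#' number below `1/kappa_max`) a ridge `ridge` is added to its diagonal
#' before inversion; when the computation is irrecoverably degenerate
#' (zero-variance column, non-finite correlations) the function returns
#' `NA_real_` as an "incomputable" signal rather than throwing, so that
#' callers can apply a fallback instead of aborting a whole analysis.
#'
#' @param data Numeric matrix or data frame (rows = observations).
#' @param i,j Column indices or names; distinct and not in `S`.
#' @param S Conditioning set: column indices or names (possibly empty).
#' @param ridge Ridge added to an ill-conditioned correlation submatrix.
#' @param kappa_max Condition-number cap triggering the ridge.
#' @return A correlation in `[-1, 1]`, or `NA_real_` if incomputable.
#' @export
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' partial_correlation(x, 1, 2)             # Pearson r
#' partial_correlation(x, 1, 2, S = 3)
partial_correlation <- function(data, i, j, S = integer(),
                                ridge = 1e-4, kappa_max = 1e8) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("data must be numeric")
  idx <- resolve_columns(X, c(i, j, S))
  if (anyDuplicated(idx)) stop("i, j and S must name distinct columns")
  if (nrow(X) < length(S) + 3)
    stop("need at least |S| + 3 rows")
  C <- suppressWarnings(stats::cor(X[, idx, drop = FALSE]))
  pcor_from_cor(C, 1L, 2L, seq_along(S) + 2L, ridge = ridge,
                kappa_max = kappa_max)
}

resolve_columns <- function(X, cols) {
  if (is.character(cols)) {
    idx <- match(cols, colnames(X))
    if (anyNA(idx)) stop("unknown column(s): ",
                         paste(cols[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(cols)
}

# Partial correlation from a precomputed correlation matrix. The whole
# skeleton search runs off one correlation matrix per dataset, so this is
# the inner loop; sizes are |S| + 2 <= 5 by default.
pcor_from_cor <- function(C, i, j, S = integer(),
                          ridge = 1e-4, kappa_max = 1e8) {
  if (length(S) == 0L) return(C[i, j])
  if (length(S) == 1L) {
    rij <- C[i, j]; rik <- C[i, S]; rjk <- C[j, S]
    if (!is.finite(rij) || !is.finite(rik) || !is.finite(rjk))
      return(NA_real_)
    den <- (1 - rik^2) * (1 - rjk^2)
    if (den > 1e-12) {
      r <- (rij - rik * rjk) / sqrt(den)
      return(if (r > 1) 1 else if (r < -1) -1 else r)
    }
    # near-collinear conditioner: fall through to the ridge path
  }
  idx <- c(i, j, S)
  M <- C[idx, idx]
  if (anyNA(M)) return(NA_real_)
  d <- length(idx)
  # correlation submatrices are PSD: Cholesky inversion, with a ridge
  # retry when the matrix is ill-conditioned (cheap bound: for |M| <= 1,
  # kappa_1 <= d^2 max|M^-1|) or numerically non-PD
  P <- tryCatch({
    P0 <- chol2inv(chol(M))
    if (max(abs(P0)) * d * d > kappa_max)
      chol2inv(chol(M + diag(ridge, d)))
    else P0
  }, error = function(e)
    tryCatch(chol2inv(chol(M + diag(ridge, d))),
             error = function(e2) NULL))
  if (is.null(P) || !all(is.finite(P))) return(NA_real_)
  dd <- P[1, 1] * P[2, 2]
  if (dd <= 0) return(NA_real_)
  r <- -P[1, 2] / sqrt(dd)
  if (r > 1) 1 else if (r < -1) -1 else r
}

clamp1 <- function(r) pmin(pmax(r, -1), 1)

#' Conditional-independence test from a partial correlation
#'
#' Fisher-z test: `z = atanh(r)`, statistic `sqrt(n - |S| - 3) * |z|`,
#' two-sided standard-normal tail. Returns `p = 1` when `r` is exactly 0
#' and `p = 0` when `|r| = 1`. Degeneracies propagate as `NA`
#' ("incomputable"): a sample too small (`n - |S| - 3 <= 0`) or an
#' incomputable partial correlation.
#'
#' @inheritParams partial_correlation
#' @return A p-value in `[0, 1]`, or `NA_real_` if incomputable.
#' @export
ci_test <- function(data, i, j, S = integer(),
                    ridge = 1e-4, kappa_max = 1e8) {
  r <- partial_correlation(data, i, j, S, ridge = ridge,
                           kappa_max = kappa_max)
  fisher_z_p(r, nrow(as.matrix(data)), length(S))
}

fisher_z_p <- function(r, n, s) {
  df <- n - s - 3
  if (df <= 0) return(NA_real_)
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  2 * stats::pnorm(-sqrt(df) * abs(atanh(r)))
}
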