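#' Hellinger transform of a community table
#'
#' Square root of within-site relative abundance: entry `sqrt(y / rowsum)`.
#' Rows with zero total stay zero and are flagged in attribute
#' `empty_rows`.
#'
#' @param counts Nonnegative site-by-species matrix.
#' @return Transformed matrix; nonzero rows have unit sum of squares.
#' @export
hellinger <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  rs <- rowSums(counts)
  out <- sqrt(counts / ifelse(rs > 0, rs, 1))
  attr(out, "empty_rows") <- which(rs == 0)
  out
}

#' Orthogonal environmental polynomials
#'
#' Centred, mutually orthonormal polynomial predictors of degree 1..`degree`
#' of the environmental gradient, used to model unimodal species responses.
#'
#' @param E Environmental values (at least 3 distinct).
#' @param degree Polynomial degree, default 2.
#' @return Matrix with columns `E1`, `E2`, ... (orthonormal, centred).
#' @export
ortho_env <- function(E, degree = 2) {
  if (length(unique(E)) < 3) stop("need at least 3 distinct environmental values")
  P <- stats::poly(E, degree = degree)
  colnames(P) <- paste0("E", seq_len(degree))
  unclass(P)[, , drop = FALSE]
}

#' (Partial) redundancy analysis
#'
#' Multi-response least squares of a (transformed, then centred) community
#' table on a predictor set, optionally after removing the effect of a
#' conditioning set: with `Z` given, both `Y` and `X` are residualized on
#' `(1, Z)` first and `R2` is the semipartial fraction of the conditioned
#' total. Collinear predictor columns are dropped by pivoted QR.
#'
#' @param Y Response matrix (sites x species); centred internally.
#' @param X Predictor matrix.
#' @param Z Optional conditioning matrix.
#' @return List of class `nn_rda`: `R2`, `adj_R2`, `fitted`, `residuals`,
#'   `scores` (canonical linear-combination site scores, scaling 1),
#'   `eig` (canonical eigenvalues), `rank`, `n`, `p` (predictors used),
#'   `dropped` (names of dropped collinear columns).
#' @export
rda_fit <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X must have the same number of rows")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    qz <- qr(cbind(1, Z))
    Yc <- qr.resid(qz, Yc)
    X <- qr.resid(qz, X)
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  qx <- qr(X, tol = 1e-8)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, keep, drop = FALSE]
    qx <- qr(X, tol = 1e-8)
  }
  fitted <- qr.fitted(qx, Yc)
  ss_tot <- sum(Yc^2)
  ss_fit <- sum(fitted^2)
  R2 <- if (ss_tot > 0) ss_fit / ss_tot else 0
  p <- qx$rank
  sv <- svd(fitted)
  pos <- sv$d > max(sv$d[1], 0) * 1e-8
  scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  adj <- if (n > p + 1) adj_r2(R2, n, p) else NA_real_
  structure(list(R2 = R2, adj_R2 = adj, fitted = fitted,
                 residuals = Yc - fitted, response = Yc, scores = scores,
                 eig = sv$d[pos]^2 / (n - 1), rank = sum(pos), n = n, p = p,
                 dropped = dropped),
            class = "nn_rda")
}

#' @export
print.nn_rda <- function(x, ...) {
  cat(sprintf("rda: n = %d, p = %d, R2 = %.4f, adj R2 = %.4f\n",
              x$n, x$p, x$R2, x$adj_R2))
  invisible(x)
}

#' Ezekiel adjusted coefficient of determination
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`; may be negative.
#'
#' @param R2 Unadjusted fraction.
#' @param n Number of sites.
#' @param p Number of predictors.
#' @export
adj_r2 <- function(R2, n, p) {
  if (n <= p + 1) stop("need n > p + 1")
  1 - (1 - R2) * (n - 1) / (n - p - 1)
}

# pseudo-F for a (partial) RDA; q = conditioning rank. A numerically zero
# residual (saturated fit) maps to +Inf rather than a sign-unstable ratio.
pseudo_f <- function(ss_fit, ss_res, p, n, q = 0) {
  if (ss_res <= 1e-12 * ss_fit) return(Inf)
  (ss_fit / p) / (ss_res / (n - p - q - 1))
}

#' Permutation test for a (partial) RDA
#'
#' Without conditioning, rows of `Y` are freely permuted. With a
#' conditioning set, the reduced-model residual scheme is used: `Y` is
#' replaced by `fitted(Y ~ Z) + permuted residuals(Y ~ Z)` and the partial
#' statistic recomputed. The statistic is the pseudo-F; the p-value is
#' `(1 + #(F* >= F)) / (1 + n_perm)`, one-tailed in the upper tail.
#'
#' @param Y Response matrix.
#' @param X Predictors under test.
#' @param Z Optional conditioning predictors.
#' @param n_perm Number of permutations (>= 99 recommended).
#' @param seed Optional seed.
#' @return List: `statistic` (pseudo-F), `R2` (semipartial), `p_value`.
#' @export
permutation_test <- function(Y, X, Z = NULL, n_perm = 999, seed = NULL) {
  if (n_perm < 99) warning("n_perm < 99: p-value unreliable")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (is.null(Z)) {
    qx <- qr(scale(X, center = TRUE, scale = FALSE), tol = 1e-8)
    p <- qx$rank
    stat_of <- function(Yp) {
      f <- qr.fitted(qx, Yp)
      ssf <- sum(f^2)
      pseudo_f(ssf, sum(Yp^2) - ssf, p, n)
    }
    r2_of <- function(Yp) { f <- qr.fitted(qx, Yp); sum(f^2) / sum(Yp^2) }
    obs <- stat_of(Yc)
    R2 <- r2_of(Yc)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      Yp <- scale(Yp, center = TRUE, scale = FALSE)  # unchanged by row perm
      if (stat_of(Yp) >= obs) ge <- ge + 1L
    }
  } else {
    Z <- as.matrix(Z)
    qz <- qr(cbind(1, Z))
    qcond <- qz$rank - 1L
    Yres <- qr.resid(qz, Yc)
    Yfit_z <- Yc - Yres
    Xr <- qr.resid(qz, X)
    qx <- qr(Xr, tol = 1e-8)
    p <- qx$rank
    stat_of <- function(Yr) {
      f <- qr.fitted(qx, Yr)
      ssf <- sum(f^2)
      pseudo_f(ssf, sum(Yr^2) - ssf, p, n, q = qcond)
    }
    obs <- stat_of(Yres)
    R2 <- { f <- qr.fitted(qx, Yres); sum(f^2) / sum(Yres^2) }
    ge <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- Yfit_z + Yres[sample.int(n), , drop = FALSE]
      Ypr <- qr.resid(qz, Yp)
      if (stat_of(Ypr) >= obs) ge <- ge + 1L
    }
  }
  list(statistic = obs, R2 = R2, p_value = (1 + ge) / (1 + n_perm))
}

#' Forward selection of predictors for RDA
#'
#' The classical alpha-only forward selection: a global permutation test on
#' the full candidate set must pass at `alpha` first; then candidates are
#' added greedily by largest gain in R2, each admission gated by the
#' partial permutation test of the candidate conditioned on the already
#' selected set. Stops when no candidate is admitted. The Blanchet
#' adjusted-R2 second stopping rule is available via `r2_stop`.
#'
#' @param Y Response matrix.
#' @param candidates Matrix of candidate predictor columns (named).
#' @param alpha Admission level (default 0.05).
#' @param n_perm Permutations per test (default 999).
#' @param r2_stop Optional global adjusted-R2 ceiling (Blanchet rule);
#'   `NULL` (default) disables it.
#' @param seed Optional seed.
#' @return List: `selected` (column names, possibly empty), `X` (selected
#'   matrix or NULL), `global_p`, `p_values` (per admitted candidate).
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 999,
                           r2_stop = NULL, seed = NULL) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("V", seq_len(ncol(candidates)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  glob <- permutation_test(Y, candidates, n_perm = n_perm)
  if (glob$p_value > alpha)
    return(list(selected = character(0), X = NULL, global_p = glob$p_value,
                p_values = numeric(0)))
  sel <- integer(0); pvals <- numeric(0)
  remaining <- seq_len(ncol(candidates))
  repeat {
    if (!length(remaining)) break
    # candidate with the largest added R2 given the current selection
    gains <- vapply(remaining, function(j) {
      rda_fit(Y, candidates[, c(sel, j), drop = FALSE])$R2
    }, numeric(1))
    j <- remaining[which.max(gains)]
    Z <- if (length(sel)) candidates[, sel, drop = FALSE] else NULL
    pt <- permutation_test(Y, candidates[, j, drop = FALSE], Z = Z,
                           n_perm = n_perm)
    if (pt$p_value > alpha) break
    if (!is.null(r2_stop) &&
        rda_fit(Y, candidates[, c(sel, j), drop = FALSE])$adj_R2 > r2_stop)
      break
    sel <- c(sel, j)
    pvals <- c(pvals, pt$p_value)
    remaining <- setdiff(remaining, j)
  }
  list(selected = colnames(candidates)[sel],
       X = if (length(sel)) candidates[, sel, drop = FALSE] else NULL,
       global_p = glob$p_value, p_values = pvals)
}
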