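test_that("Hellinger transform matches the definition and vegan's oracle", {
  expect_equal(hellinger(matrix(c(1, 0), 1)), matrix(c(1, 0), 1),
               ignore_attr = TRUE)
  expect_equal(hellinger(matrix(c(4, 1), 1)), matrix(c(2, 1) / sqrt(5), 1),
               ignore_attr = TRUE)
  set.seed(8)
  m <- matrix(rpois(60, 4), 10, 6)
  h <- hellinger(m)
  expect_equal(h, vegan::decostand(m, "hellinger"),
               ignore_attr = TRUE, tolerance = 1e-12)
  rs <- rowSums(m)
  expect_equal(unname(rowSums(h^2))[rs > 0], rep(1, sum(rs > 0)))
  m[3, ] <- 0
  expect_equal(attr(hellinger(m), "empty_rows"), 3L)
  expect_error(hellinger(matrix(-1)), "nonnegative")
})

test_that("orthogonal environmental polynomials are centred and orthonormal", {
  E <- runif(30)
  P <- ortho_env(E, 2)
  expect_equal(colnames(P), c("E1", "E2"))
  expect_equal(unname(colSums(P)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(crossprod(P)), diag(2), tolerance = 1e-10)
  # classical equally spaced case: degree 1 proportional to (-2,-1,0,1,2)
  P5 <- ortho_env(1:5, 2)
  expect_equal(unname(P5[, 1] / P5[5, 1]), c(-2, -1, 0, 1, 2) / 2,
               tolerance = 1e-12)
  # symmetric ladder: degree-2 column is even around the centre
  expect_equal(unname(P5[, 2]), unname(rev(P5[, 2])), tolerance = 1e-12)
  expect_error(ortho_env(rep(1, 10)), "distinct")
})

# brute-force multi-response least squares via normal equations
brute_rda <- function(Y, X, Z = NULL) {
  Yc <- scale(Y, scale = FALSE)
  if (!is.null(Z)) {
    PZ <- cbind(1, Z) %*% solve(crossprod(cbind(1, Z))) %*% t(cbind(1, Z))
    Yc <- Yc - PZ %*% Yc
    X <- X - PZ %*% X
  } else X <- scale(X, scale = FALSE)
  B <- solve(crossprod(X)) %*% crossprod(X, Yc)
  fit <- X %*% B
  list(fitted = fit, R2 = sum(fit^2) / sum(Yc^2))
}

test_that("RDA reproduces the brute-force projection oracle", {
  set.seed(13)
  for (k in 1:5) {
    Y <- matrix(rnorm(12 * 8), 12, 8)
    X <- matrix(rnorm(12 * 3), 12, 3)
    Z <- matrix(rnorm(12 * 2), 12, 2)
    f1 <- rda_fit(Y, X)
    o1 <- brute_rda(Y, X)
    expect_equal(f1$fitted, o1$fitted, ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(f1$R2, o1$R2, tolerance = 1e-10)
    f2 <- rda_fit(Y, X, Z)
    o2 <- brute_rda(Y, X, Z)
    expect_equal(f2$fitted, o2$fitted, ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(f2$R2, o2$R2, tolerance = 1e-10)
    # variance decomposition
    expect_equal(sum(f1$fitted^2) + sum(f1$residuals^2), sum(f1$response^2),
                 tolerance = 1e-9)
  }
})

test_that("RDA limits: saturated basis gives R2 = 1, orthogonal predictors 0", {
  set.seed(14)
  Y <- matrix(rnorm(6 * 4), 6, 4)
  X_sat <- stats::model.matrix(~ factor(1:6))[, -1]
  expect_equal(rda_fit(Y, X_sat)$R2, 1, tolerance = 1e-10)
  # predictor orthogonal to Y's centred column space
  Yc <- scale(Y, scale = FALSE)
  x_orth <- qr.resid(qr(Yc), rnorm(6))
  expect_lt(rda_fit(Y, x_orth)$R2, 1e-12)
  # collinear columns are dropped with a recorded name
  Xc <- cbind(a = rnorm(6), b = rnorm(6))
  Xc <- cbind(Xc, c = Xc[, 1] + Xc[, 2])
  f <- rda_fit(Y, Xc)
  expect_equal(f$p, 2)
  expect_length(f$dropped, 1)
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adj_r2(0.5, 100, 9), 1 - 0.5 * 99 / 90)
  expect_equal(adj_r2(0.5, 100, 9), 0.45)
  expect_equal(adj_r2(0.37, 50, 0), 0.37)
  expect_lte(adj_r2(0, 30, 5), 0)
  expect_error(adj_r2(0.5, 10, 9))
})

test_that("permutation test is extreme for strong signal and valid in form", {
  set.seed(15)
  X <- matrix(rnorm(20), 20, 1)
  Y <- cbind(2 * X + rnorm(20, sd = 0.01), -X + rnorm(20, sd = 0.01))
  pt <- permutation_test(Y, X, n_perm = 199)
  expect_equal(pt$p_value, 1 / 200)
  # null: p in (0, 1], no conditioning
  Y0 <- matrix(rnorm(40), 20, 2)
  p0 <- permutation_test(Y0, X, n_perm = 99)$p_value
  expect_gt(p0, 0); expect_lte(p0, 1)
  # with conditioning: residual scheme still valid in form
  Z <- matrix(rnorm(20), 20, 1)
  pz <- permutation_test(Y0, X, Z = Z, n_perm = 99)$p_value
  expect_gt(pz, 0); expect_lte(pz, 1)
  expect_warning(permutation_test(Y0, X, n_perm = 50), "unreliable")
})

test_that("forward selection admits true predictors and rejects pure noise", {
  set.seed(16)
  n <- 30
  cand <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, paste0("V", 1:6)))
  # single strong predictor among noise
  hits <- 0L
  for (r in 1:20) {
    Y <- cbind(3 * cand[, 4] + rnorm(n, sd = 0.2),
               -2 * cand[, 4] + rnorm(n, sd = 0.2))
    fs <- forward_select(Y, cand, n_perm = 99)
    if (length(fs$selected) && fs$selected[1] == "V4") hits <- hits + 1L
  }
  expect_gte(hits, 19)   # >= 95% of strong-effect draws

  # saturated case: the response's own basis is fully selected
  Yb <- cand[, 1:2] %*% matrix(c(1, 0.5, -1, 2), 2, 2)
  fsb <- forward_select(Yb, cand[, 1:2], n_perm = 99)
  expect_setequal(fsb$selected, c("V1", "V2"))

  # null tables: empty set in >= 90% of draws (global pre-test gate)
  empty <- 0L
  for (r in 1:60) {
    Y0 <- matrix(rnorm(n * 3), n, 3)
    fs0 <- forward_select(Y0, cand, n_perm = 99)
    if (!length(fs0$selected)) empty <- empty + 1L
  }
  expect_gte(empty / 60, 0.9)
})
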