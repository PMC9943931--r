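# planted community: two guilds sorted along a binary habitat split of a
# 6 x 6 window, with per-guild species counts; strong filter, mild noise
planted_community <- function(seed = 1, n_sp_per_guild = 4, noise = 0.2) {
  set.seed(seed)
  xy <- expand.grid(x = 0:5, y = 0:5)
  E <- ifelse(xy$x < 3, 0.25, 0.75) + runif(36, -0.05, 0.05)
  S <- 2 * n_sp_per_guild
  comm <- matrix(0, 36, S)
  for (j in seq_len(S)) {
    guild <- if (j <= n_sp_per_guild) 1 else 2
    pref <- if (guild == 1) xy$x < 3 else xy$x >= 3
    lam <- ifelse(pref, 6, noise)
    comm[, j] <- rpois(36, lam)
  }
  list(comm = comm, E = E, d = as.matrix(dist(xy)), xy = as.matrix(xy),
       guild = rep(1:2, each = n_sp_per_guild))
}

test_that("variation partitioning recovers planted environmental structure", {
  pc <- planted_community(seed = 2)
  vp <- variation_partition(pc$comm, pc$E, d = pc$d, n_perm = 199, seed = 9)
  f <- vp$fractions
  # arithmetic identities on the adjusted scale
  expect_equal(unname(f["pure_env"] + f["shared"] + f["pure_spatial"] +
                        f["residual"]), 1, tolerance = 1e-9)
  expect_equal(unname(f["env"] + f["pure_spatial"]), unname(f["total"]),
               tolerance = 1e-9)
  expect_equal(unname(f["spatial"] + f["pure_env"]), unname(f["total"]),
               tolerance = 1e-9)
  # the planted signal is environmental and significant
  expect_true("E1" %in% vp$selected$env)
  expect_gt(f["env"], 0.3)
  expect_lte(vp$p_values["pure_env"], 0.05)
})

test_that("null communities yield near-zero adjusted fractions on average", {
  set.seed(30)
  fr <- replicate(30, {
    comm <- matrix(rpois(36 * 5, 5), 36, 5)
    E <- runif(36)
    xy <- expand.grid(x = 0:5, y = 0:5)
    vp <- variation_partition(comm, E, d = as.matrix(dist(xy)),
                              n_perm = 99)
    vp$fractions["total"]
  })
  expect_lt(abs(mean(fr)), 0.05)
})

test_that("component classification follows the guild-count-dependent rules", {
  vp_stub <- function(p) {
    structure(list(p_values = p, alpha = 0.05), class = "nn_varpart")
  }
  p1 <- c(env = 0.3, pure_env = 0.20, spatial = 0.001, pure_spatial = 0.001)
  expect_equal(classify_components(vp_stub(p1), 1), "true spatial")
  p2 <- c(env = 0.04, pure_env = 0.01, spatial = 0.2, pure_spatial = 0.4)
  expect_equal(classify_components(vp_stub(p2), 1), "false environmental")
  p3 <- c(env = 0.01, pure_env = 0.01, spatial = 0.001, pure_spatial = 0.001)
  expect_setequal(classify_components(vp_stub(p3), 3),
                  c("true environmental", "spatial"))
  # single guild never yields "true environmental"
  expect_false("true environmental" %in% classify_components(vp_stub(p3), 1))
  # no significant components -> empty labels
  p4 <- c(env = 0.5, pure_env = 0.5, spatial = 0.5, pure_spatial = 0.5)
  expect_length(classify_components(vp_stub(p4), 2), 0)
})

test_that("guild structure recovers a planted partition", {
  # two planted habitats: the partition is always significant and pure
  # (every k-means cluster nests inside one true habitat); the SSI flat-
  # profile behaviour means exact k = 2 is only a majority outcome
  res <- lapply(1:10, function(s) {
    pc <- planted_community(seed = s)
    gs <- guild_structure(pc$comm, ortho_env(pc$E, 2), n_perm = 99, seed = s)
    truth <- pc$xy[, "x"] < 3
    pure <- all(vapply(split(truth, gs$habitat),
                       function(v) length(unique(v)) == 1L, logical(1)))
    c(sig = gs$significant, pure = pure, k2 = gs$k == 2)
  })
  res <- do.call(rbind, res)
  expect_true(all(res[, "sig"]))
  expect_gte(mean(res[, "pure"]), 0.9)
  expect_gte(mean(res[, "k2"]), 0.6)

  # three well-separated habitats: SSI profile peaks and k = 3 is recovered
  k3 <- vapply(1:8, function(s) {
    set.seed(s)
    xy <- expand.grid(x = 0:5, y = 0:5)
    hab <- cut(xy$x, c(-1, 1, 3, 5), labels = FALSE)
    E <- c(0.15, 0.5, 0.85)[hab] + runif(36, -0.02, 0.02)
    comm <- matrix(0, 36, 9)
    for (j in 1:9) {
      g <- (j - 1) %/% 3 + 1
      comm[, j] <- rpois(36, ifelse(hab == g, 30, 0.1))
    }
    guild_structure(comm, ortho_env(E, 2), n_perm = 99, seed = s)$k
  }, integer(1))
  expect_true(all(k3 == 3))
})

test_that("hierarchical model handles the degenerate single-habitat case", {
  pc <- planted_community(seed = 4)
  win <- list(xy = pc$xy, dist = pc$d)
  hm <- hierarchical_model(pc$comm, rep(1L, 36), win, n_perm = 99, seed = 1)
  # single habitat: no among component, W is the plain window PCNM
  expect_length(hm$selected$among, 0)
  expect_equal(unname(hm$fractions["habitat"]), 0)
})

test_that("hierarchical model splits habitat and spatial structure", {
  pc <- planted_community(seed = 5)
  win <- list(xy = pc$xy, dist = pc$d)
  habitat <- ifelse(pc$xy[, "x"] < 3, 1L, 2L)
  hm <- hierarchical_model(pc$comm, habitat, win, n_perm = 99, seed = 2)
  # the habitat dummies capture the guild-separable fraction
  expect_gt(hm$fractions["habitat"], 0.3)
  expect_true(all(hm$fractions <= 1 + 1e-9))
  # totals are consistent: habitat + pure spatial = total
  expect_equal(unname(hm$fractions["habitat"] + hm$fractions["pure_spatial"]),
               unname(hm$fractions["total"]), tolerance = 1e-9)
})

test_that("autocorrelation analysis flags degenerate and detects planted structure", {
  pc <- planted_community(seed = 6)
  # all species share one spatial pattern -> degenerate, flagged
  base <- pcnm(pc$d)$vectors[, 1]
  same <- vapply(1:4, function(j) base, numeric(36))
  a0 <- autocorrelation_analysis(same, pc$d, n_perm = 99)
  expect_true(!is.na(a0$flag) || is.na(a0$r))

  # two guilds with contrasting spatial scales: within-guild pairs are
  # positively correlated with near-identical correlograms, across-guild
  # pairs uncorrelated with distant correlograms -> negative Mantel r
  V <- pcnm(pc$d)$vectors
  broad <- V[, 1]; fine <- V[, ncol(V)]
  neg <- vapply(1:10, function(s) {
    set.seed(s)
    f <- cbind(vapply(1:4, function(j) broad * runif(1, 0.8, 1.2) +
                        rnorm(36, sd = 0.02), numeric(36)),
               vapply(1:4, function(j) fine * runif(1, 0.8, 1.2) +
                        rnorm(36, sd = 0.02), numeric(36)))
    a <- autocorrelation_analysis(f, pc$d, n_perm = 99, seed = s)
    !is.na(a$r) && a$r < 0 && a$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(neg), 0.9)

  # constant species are dropped with a record
  f2 <- cbind(base, rep(1, 36), -base, base + rnorm(36, sd = 0.1))
  colnames(f2) <- paste0("s", 1:4)
  a2 <- autocorrelation_analysis(f2, pc$d, n_perm = 99, seed = 1)
  expect_equal(a2$dropped, "s2")
})
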