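test_that("habitat weights follow the row-max-scaled Gaussian niche", {
  gu <- data.frame(guild = 1:2, optimum = c(0.5, 0.7), tolerance = c(0.1, 0.1))
  ha <- habitat_weights(0.5, gu)
  # the best-matched guild attains the row maximum of 1
  expect_equal(ha[1, 1], 1)
  # Gaussian ratio at 2 sigma from the optimum
  expect_equal(ha[1, 2] / ha[1, 1], exp(-2), tolerance = 1e-12)

  # flat filter: huge tolerances make every association ~ 1
  guf <- data.frame(guild = 1:3, optimum = c(0.1, 0.5, 0.9),
                    tolerance = rep(1e3, 3))
  haf <- habitat_weights(seq(0, 1, 0.25), guf)
  expect_true(all(abs(haf - 1) < 1e-5))
  expect_true(all(apply(habitat_weights(runif(10), draw_guilds(5, seed = 1)),
                        1, max) == 1))
  expect_error(habitat_weights(0.5, data.frame(guild = 1, optimum = 0.5,
                                               tolerance = 0)), "> 0")
})

test_that("per-site parent probabilities are normalized and label-free", {
  L <- preset_world("linear")
  gu <- draw_guilds(4, seed = 2)
  sz <- draw_guild_sizes(L$JM, 4, seed = 3)
  set.seed(7)
  st <- initialize_population(L, gu, sz, "monodominance")
  ha <- habitat_weights(L$E, gu)
  keep <- which(runif(L$JM) > 0.01)
  n_s <- tabulate(st$site[keep], nbins = L$n_sites)
  keepL <- split(keep, factor(st$site[keep], levels = seq_len(L$n_sites)))
  for (s in c(1, 17, 64)) {
    pp <- nnc:::site_parent_probs(s, 0.09, keepL, n_s, L$nb, ha, st$guild)
    expect_equal(sum(pp$pr), 1, tolerance = 1e-12)
    expect_true(all(pp$pr > 0))
  }
  # row-max rescaling of HA cancels: arbitrary positive per-row rescaling
  # leaves the parent probabilities unchanged
  ha2 <- ha * runif(nrow(ha), 0.1, 10)
  p1 <- nnc:::site_parent_probs(5, 0.81, keepL, n_s, L$nb, ha, st$guild)
  p2 <- nnc:::site_parent_probs(5, 0.81, keepL, n_s, L$nb, ha2, st$guild)
  expect_equal(p1$pr, p2$pr, tolerance = 1e-12)

  # neutral reduction: with a flat filter the immigrant weights reduce to
  # the row-normalized immigration field w(s,s')/n_s', independent of E
  haflat <- matrix(1, L$n_sites, 4)
  pf <- nnc:::site_parent_probs(5, 1, keepL, n_s, L$nb, haflat, st$guild)
  nbs <- L$nb[5, ]
  exp_w <- rep(0.125 / n_s[nbs], lengths(keepL[nbs]))
  expect_equal(pf$pr, exp_w / sum(exp_w), tolerance = 1e-12)
})

test_that("a step conserves individuals, guilds never increase, speciation is Binomial", {
  L <- preset_world("humps")
  gu <- draw_guilds(8, seed = 4)
  sz <- draw_guild_sizes(L$JM, 8, seed = 5)
  p <- simulation_params(m = 0.09, nu = 0.01)
  set.seed(21)
  st <- initialize_population(L, gu, sz, "monodominance")
  ha <- habitat_weights(L$E, gu)
  n_guilds <- length(unique(st$guild))
  n_new <- 0L
  n_steps <- 150
  for (t in seq_len(n_steps)) {
    before <- if (is.null(st$pool$n)) length(st$pool$guild) else st$pool$n
    st <- nn_step(st, p, ha)
    n_new <- n_new + (st$pool$n - before)
    g_now <- length(unique(st$guild))
    expect_lte(g_now, n_guilds)
    n_guilds <- g_now
  }
  expect_equal(length(st$species), L$JM)
  expect_equal(unname(tabulate(st$site)), rep(8L, 64))
  # speciation count ~ Binomial(JM * n_steps, nu): within 3 standard errors
  mu <- L$JM * n_steps * p$nu
  se <- sqrt(L$JM * n_steps * p$nu * (1 - p$nu))
  expect_lt(abs(n_new - mu), 3 * se)
})

test_that("nu = 0 with a single species is absorbing", {
  L <- tiny_world(4, 4, J = 4)
  st <- initialize_population(L, one_guild(), 64L, "monodominance", seed = 2)
  p <- simulation_params(m = 0.5, nu = 0)
  st2 <- simulate_steps(st, p, 20)
  expect_equal(unique(st2$species), 1L)
  expect_equal(length(st2$species), 64L)
})

test_that("neutral fixation probability equals initial frequency (voter martingale)", {
  L <- tiny_world(4, 4, J = 4)
  gu <- one_guild()
  p <- simulation_params(m = 0.3, nu = 0, max_steps = 1e5)
  fix_b <- vapply(1:400, function(seed) {
    set.seed(seed)
    st <- initialize_population(L, gu, 64L, "monodominance")
    st$species[sample(64, 16)] <- 2L   # species B at frequency 1/4
    st$pool <- list(guild = c(1L, 1L), code = c("A", "B"),
                    birth_step = c(0L, 0L), is_t0 = c(TRUE, TRUE), n = 2L)
    st <- simulate_steps(st, p, 5000, stop_when_single_species = TRUE)
    unique(st$species) == 2L
  }, logical(1))
  # scaled from the spec's 2000 replicates to 400; 4 sigma binomial band
  expect_lt(abs(mean(fix_b) - 0.25), 4 * sqrt(0.25 * 0.75 / 400))
})

test_that("runs converge by coalescence or annihilation and report timing", {
  L <- preset_world("random", env_seed = 8)
  gu <- draw_guilds(4, seed = 6)
  sz <- draw_guild_sizes(L$JM, 4, seed = 7)
  p <- simulation_params(m = 0.09, nu = 0.01, max_steps = 20000, seed = 31)
  r <- run_to_convergence(L, gu, sz, p)
  expect_true(r$converged)
  expect_lte(r$t_guild_stationary, r$t_convergence)
  expect_true(all(diff(r$trajectory$n_guilds) <= 0))
  expect_equal(nrow(r$trajectory), r$t_convergence)
  # at convergence: every guild's initial-species survivors share a founder
  st <- r$state
  t0 <- st$pool$is_t0[st$species]
  if (any(t0)) {
    per_guild <- tapply(st$founder[t0], st$guild[t0],
                        function(f) length(unique(f)))
    expect_true(all(per_guild == 1L))
  }
  # max_steps exhaustion flags non-convergence
  p2 <- simulation_params(m = 0.09, nu = 0.01, max_steps = 3, seed = 31)
  r2 <- run_to_convergence(L, gu, sz, p2)
  expect_false(r2$converged)
})

test_that("coupled monodominance / infinite-diversity runs agree after convergence", {
  L <- preset_world("linear", env_seed = 2)
  gu <- draw_guilds(3, seed = 9)
  sz <- draw_guild_sizes(L$JM, 3, seed = 10)
  p <- simulation_params(m = 0.81, nu = 0.01, max_steps = 20000, seed = 41)
  cp <- coupled_pair_check(L, gu, sz, p)
  expect_true(cp$converged)
  expect_true(cp$agree)
  expect_true(cp$coarsening_ok)
  expect_true(cp$guilds_monotone)
  expect_true(cp$abundance_ok)
})
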