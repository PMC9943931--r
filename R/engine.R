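#' Simulation parameters
#'
#' @param m Dispersal rate: probability that a replacement individual is an
#'   immigrant from the eight nearest neighbouring communities (design
#'   levels 0.01, 0.09, 0.81).
#' @param nu Point-mutation speciation probability per individual per time
#'   step (default 0.001).
#' @param max_steps Safety bound on the number of steps.
#' @param seed Integer seed for the run's random stream.
#' @return An object of class `nn_params`.
#' @export
simulation_params <- function(m, nu = 0.001, max_steps = 100000L, seed = NULL) {
  if (nu < 0 || nu > 1 || m < 0 || m > 1) stop("require 0 <= nu, m <= 1")
  structure(list(m = m, nu = nu, max_steps = as.integer(max_steps),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "nn_params")
}

#' Habitat association weights
#'
#' The habitat association of a guild (and of each of its individuals and
#' species) to a site is the Gaussian density of the site's environment `E`
#' at the guild's optimum `mu` with standard deviation `sigma`, rescaled by
#' the row maximum so that every site's best-matched guild has weight 1.
#' The row rescaling cancels in the immigration-probability normalization of
#' the engine, and is kept for fidelity to the matrix formulation.
#'
#' @param E Environmental values per site.
#' @param guilds An `nn_guilds` table (all tolerances > 0).
#' @return Matrix `length(E) x nrow(guilds)` with values in (0, 1\].
#' @export
habitat_weights <- function(E, guilds) {
  if (any(guilds$tolerance <= 0)) stop("all tolerances must be > 0")
  ha <- vapply(seq_len(nrow(guilds)),
               function(k) stats::dnorm(E, guilds$optimum[k], guilds$tolerance[k]),
               numeric(length(E)))
  ha <- matrix(ha, nrow = length(E))
  ha / apply(ha, 1, max)
}

# Per-site parent candidate weights. Returns candidate individual indices
# and their sampling probabilities for site s: the local-birth term gives
# each non-speciating local individual (1 - m)/n_s; the immigrant term gives
# each non-speciating individual at neighbour s' the weight
# m * (1/8) * (1/n_s') * HA(s, guild) renormalized over all neighbour
# individuals (the matrix formulation's EF row). Weights depend on sites and
# guilds only, never on species labels: this is the coupling contract.
site_parent_probs <- function(s, m, keepL, n_s, nb, ha, guild) {
  loc <- keepL[[s]]
  nbs <- nb[s, ]
  lens <- lengths(keepL[nbs])
  nbi <- unlist(keepL[nbs], use.names = FALSE)
  status <- "ok"
  if (length(nbi)) {
    wnb <- rep.int(0.125 / n_s[nbs], lens)   # n_s > 0 wherever lens > 0
    haw <- ha[s, guild[nbi]] * wnb
    Z <- sum(haw)
  } else Z <- 0
  nloc <- length(loc)
  if (m >= 1 && Z > 0) {            # pure immigration: no local term
    cand <- nbi; pr <- haw / Z
  } else if (m <= 0 && nloc > 0L) { # pure local birth: no immigrant term
    cand <- loc; pr <- rep.int(1 / nloc, nloc)
  } else if (nloc > 0L && Z > 0) {
    cand <- c(loc, nbi)
    pr <- c(rep.int((1 - m) / nloc, nloc), (m / Z) * haw)
  } else if (nloc > 0L) {
    cand <- loc; pr <- rep.int(1 / nloc, nloc); status <- "no_immigrants"
  } else if (Z > 0) {
    cand <- nbi; pr <- haw / Z; status <- "no_local_parents"
  } else {
    return(NULL)
  }
  list(cand = cand, pr = pr, status = status)
}

# grow pool arrays in amortized O(1)
grow_pool <- function(pool, extra) {
  n <- pool$n; cap <- length(pool$guild)
  if (n + extra > cap) {
    newcap <- max(2L * cap, n + extra)
    length(pool$guild) <- newcap
    length(pool$code) <- newcap
    length(pool$birth_step) <- newcap
    length(pool$is_t0) <- newcap
  }
  pool
}

#' Advance the population by one time step
#'
#' Synchronous non-overlapping generations. In canonical order: (1) a
#' speciation mask is drawn over all `JM` slots (row-major sites, slots
#' ascending) — each individual is removed and replaced by a brand-new
#' species with probability `nu`, the new species inheriting its ancestor's
#' guild (niche conservatism) and being coded by the ancestor slot and time
#' step; (2) for each site in row-major order, the remaining slots are
#' filled i.i.d. from the parent probability vector
#' `m * EF_s + (1 - m) * RA_s`, where `RA_s` is the local relative
#' abundance of the non-speciating parent pool and `EF_s` the
#' environment-filtered immigration field over the eight neighbouring
#' communities; offspring adopt their parent's species, guild and founder
#' lineage. Parent draws resolve to individual slot indices, so two runs
#' with identical seeds and identical (site, guild, founder) configurations
#' make identical choices regardless of species labelling.
#'
#' Degenerate sites (all local parents speciated, or a zero immigration
#' field) drop the affected term and renormalize; counts are accumulated in
#' `state$degenerate`.
#'
#' @param state An `nn_state`.
#' @param params An `nn_params`.
#' @param ha Optional precomputed [habitat_weights()] matrix.
#' @return The advanced `nn_state`.
#' @export
nn_step <- function(state, params, ha = NULL) {
  ls <- state$landscape
  J <- ls$J; n_sites <- ls$n_sites; JM <- n_sites * J
  if (is.null(ha)) ha <- habitat_weights(ls$E, state$guilds)
  nb <- ls$nb
  m <- params$m
  step <- state$step + 1L

  spec_mask <- stats::runif(JM) < params$nu
  keep <- which(!spec_mask)
  site <- state$site
  n_s <- tabulate(site[keep], nbins = n_sites)
  keepL <- split(keep, factor(site[keep], levels = seq_len(n_sites)))

  new_species <- state$species
  new_guild <- state$guild
  new_founder <- state$founder

  pool <- state$pool
  if (is.null(pool$n)) pool$n <- length(pool$guild)
  n_new <- sum(spec_mask)
  pool <- grow_pool(pool, n_new)
  if (n_new) {
    slots <- which(spec_mask)
    ids <- pool$n + seq_len(n_new)
    pool$guild[ids] <- state$guild[slots]
    pool$code[ids] <- sprintf("i%d.t%d", slots, step)
    pool$birth_step[ids] <- step
    pool$is_t0[ids] <- FALSE
    pool$n <- pool$n + n_new
    new_species[slots] <- ids
    # guild and founder lineage of the replaced individual are retained
  }

  degen <- state$degenerate %||% c(no_local_parents = 0L, no_immigrants = 0L)
  for (s in seq_len(n_sites)) {
    slots <- ((s - 1L) * J + 1L):(s * J)
    offspring <- slots[!spec_mask[slots]]
    need <- length(offspring)
    if (!need) next
    pp <- site_parent_probs(s, m, keepL, n_s, nb, ha, state$guild)
    if (is.null(pp))
      stop("no parent candidates at site ", s, " (all neighbours speciated)")
    if (pp$status != "ok") degen[pp$status] <- degen[pp$status] + 1L
    par <- pp$cand[sample.int(length(pp$cand), need, replace = TRUE, prob = pp$pr)]
    new_species[offspring] <- state$species[par]
    new_guild[offspring] <- state$guild[par]
    new_founder[offspring] <- state$founder[par]
  }

  state$species <- new_species
  state$guild <- new_guild
  state$founder <- new_founder
  state$pool <- pool
  state$step <- step
  state$degenerate <- degen
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convergence criterion: for every guild, the extant individuals whose
# species was founded at initialization descend from at most one founder
# code ("coalesced"); vacuously true when no initial-species individuals
# remain ("annihilated").
lineages_converged <- function(state) {
  t0 <- state$pool$is_t0[state$species]
  if (!any(t0)) return(TRUE)
  f <- state$founder[t0]; g <- state$guild[t0]
  all(vapply(split(f, g), function(v) length(unique(v)) == 1L, logical(1)))
}

#' Run a simulation to its dynamic-equilibrium convergence time
#'
#' Runs the monodominance initialization (by default) until the
#' lineage-based convergence criterion first holds: for every guild, the
#' surviving individuals of initial species descend from at most one
#' founder, i.e. all initial lineages per guild have coalesced or been
#' annihilated. By the duality of the neutral model this is exactly the
#' time from which the run is indistinguishable (up to species labels) from
#' the paired infinite-diversity run with the same seed.
#'
#' @param landscape An `nn_landscape`.
#' @param guilds,sizes Guild table and guild sizes (see
#'   [initialize_population()]).
#' @param params An `nn_params`; `params$seed` seeds the whole run.
#' @param mode Initialization mode.
#' @param record Keep the per-step guild/species counts (default TRUE).
#' @return A list of class `nn_run`: `state` at convergence, `converged`
#'   flag, `t_convergence`, `t_guild_stationary` (step of the last guild
#'   extinction, 0 if none), and `trajectory` (data frame `step`,
#'   `n_guilds`, `n_species`).
#' @export
run_to_convergence <- function(landscape, guilds, sizes, params,
                               mode = "monodominance", record = TRUE) {
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- initialize_population(landscape, guilds, sizes, mode = mode)
  ha <- habitat_weights(landscape$E, guilds)
  n_guilds <- length(unique(state$guild))
  traj_g <- integer(0); traj_s <- integer(0)
  t_stationary <- 0L; converged <- FALSE; t_conv <- NA_integer_
  for (t in seq_len(params$max_steps)) {
    state <- nn_step(state, params, ha)
    g_now <- length(unique(state$guild))
    if (g_now < n_guilds) t_stationary <- state$step
    n_guilds <- g_now
    if (record) {
      traj_g <- c(traj_g, g_now)
      traj_s <- c(traj_s, length(unique(state$species)))
    }
    if (lineages_converged(state)) { converged <- TRUE; t_conv <- state$step; break }
  }
  structure(list(state = state, converged = converged,
                 t_convergence = t_conv, t_guild_stationary = t_stationary,
                 trajectory = if (record)
                   data.frame(step = seq_along(traj_g), n_guilds = traj_g,
                              n_species = traj_s)),
            class = "nn_run")
}

#' @export
print.nn_run <- function(x, ...) {
  cat(sprintf("run: %s at step %s; guilds stationary at %d; %d species extant\n",
              if (x$converged) "converged" else "NOT converged",
              x$t_convergence, x$t_guild_stationary,
              length(unique(x$state$species))))
  invisible(x)
}

#' Advance an existing state by a fixed number of steps
#'
#' @param state An `nn_state`.
#' @param params An `nn_params` (its `seed` is ignored here; seed the
#'   stream yourself for reproducibility).
#' @param n_steps Number of steps to run.
#' @param stop_when_single_species Stop early on global fixation.
#' @return The advanced state.
#' @export
simulate_steps <- function(state, params, n_steps,
                           stop_when_single_species = FALSE) {
  ha <- habitat_weights(state$landscape$E, state$guilds)
  for (t in seq_len(n_steps)) {
    state <- nn_step(state, params, ha)
    if (stop_when_single_species &&
        length(unique(state$species)) == 1L) break
  }
  state
}

# one-to-one correspondence of slot-aligned species labelings
label_bijection <- function(sp_a, sp_b) {
  u <- unique(cbind(sp_a, sp_b))
  !anyDuplicated(u[, 1]) && !anyDuplicated(u[, 2])
}

#' Coupled monodominance / infinite-diversity convergence check
#'
#' Runs both initializations on shared randomness (same seed, identical
#' draw order) and verifies that from the lineage-based convergence time of
#' the monodominance run onward the two site-by-species compositions are
#' identical up to a bijection of species labels. This is the package's
#' operational test of the duality argument: the neutral genealogy is a
#' system of coalescing random walkers, so once every guild's initial
#' lineages have coalesced or been annihilated the initial labelling no
#' longer matters.
#'
#' @inheritParams run_to_convergence
#' @param extra_steps Additional post-convergence steps to verify (default 3).
#' @return List: `agree` (TRUE when compositions match up to a label
#'   bijection at the convergence time and for `extra_steps` steps after),
#'   `converged`, `t_convergence`, `coarsening_ok` (TRUE when the
#'   monodominance species count never exceeded the infinite-diversity
#'   count before convergence), `guilds_monotone` and `abundance_ok`
#'   (per-step invariant checks over the whole coupled run).
#' @export
coupled_pair_check <- function(landscape, guilds, sizes, params,
                               extra_steps = 3L) {
  seed <- params$seed %||% stop("coupled_pair_check requires params$seed")
  set.seed(seed)
  st_m <- initialize_population(landscape, guilds, sizes, mode = "monodominance")
  set.seed(seed)
  st_i <- initialize_population(landscape, guilds, sizes,
                                mode = "infinite_diversity")
  ha <- habitat_weights(landscape$E, guilds)
  # one sub-seed per step keeps the two chains on shared randomness while
  # they are advanced alternately
  set.seed(seed)
  step_seeds <- sample.int(.Machine$integer.max - 1L,
                           params$max_steps + extra_steps)
  coarsening_ok <- TRUE
  guilds_monotone <- TRUE; abundance_ok <- TRUE
  n_guilds_prev <- length(unique(st_m$guild))
  t_conv <- NA_integer_; agree <- NA
  for (t in seq_len(params$max_steps)) {
    set.seed(step_seeds[t]); st_m <- nn_step(st_m, params, ha)
    set.seed(step_seeds[t]); st_i <- nn_step(st_i, params, ha)
    g_now <- length(unique(st_m$guild))
    guilds_monotone <- guilds_monotone && g_now <= n_guilds_prev
    n_guilds_prev <- g_now
    abundance_ok <- abundance_ok &&
      length(st_m$species) == landscape$JM &&
      length(st_i$species) == landscape$JM
    if (is.na(t_conv)) {
      coarsening_ok <- coarsening_ok &&
        length(unique(st_m$species)) <= length(unique(st_i$species))
      if (lineages_converged(st_m)) {
        t_conv <- t
        agree <- label_bijection(st_m$species, st_i$species) &&
          identical(st_m$guild, st_i$guild) &&
          identical(st_m$founder, st_i$founder)
        for (k in seq_len(extra_steps)) {
          set.seed(step_seeds[t + k]); st_m <- nn_step(st_m, params, ha)
          set.seed(step_seeds[t + k]); st_i <- nn_step(st_i, params, ha)
          agree <- agree && label_bijection(st_m$species, st_i$species)
        }
        break
      }
    }
  }
  list(agree = agree, converged = !is.na(t_conv), t_convergence = t_conv,
       coarsening_ok = coarsening_ok, guilds_monotone = guilds_monotone,
       abundance_ok = abundance_ok)
}
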