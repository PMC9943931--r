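#' Draw guild niches
#'
#' Each guild has a Gaussian environmental niche: an optimum `mu` drawn
#' uniformly on \[0, 1\] and a tolerance `sigma` drawn uniformly on (0, 10\].
#' Scenarios whose narrowest tolerance falls below `exclude_below` (default
#' 0.0052, the empirical exclusion threshold of the full design) are flagged
#' but not rejected.
#'
#' @param g Number of guilds (>= 1).
#' @param seed Integer seed.
#' @param exclude_below Tolerance threshold for the exclusion flag.
#' @return A data frame of class `nn_guilds` with columns `guild`,
#'   `optimum`, `tolerance`, and attribute `excluded` (logical).
#' @export
draw_guilds <- function(g, seed = NULL, exclude_below = 0.0052) {
  g <- as.integer(g)
  if (is.na(g) || g < 1L) stop("g must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- stats::runif(g)
  sigma <- stats::runif(g, 0, 10)        # P(sigma == 0) = 0: open at 0
  out <- data.frame(guild = seq_len(g), optimum = mu, tolerance = sigma)
  attr(out, "excluded") <- min(sigma) < exclude_below
  class(out) <- c("nn_guilds", "data.frame")
  out
}

#' Guild sizes from sorted cutpoints
#'
#' Splits `JM` into `g` parts as the successive differences of
#' `(0, sorted cutpoints, JM)`.
#'
#' @param cutpoints Sorted (or sortable) integer cutpoints in `1..JM-1`,
#'   distinct.
#' @param JM Total number of individuals.
#' @return Integer vector of sizes summing to `JM`.
#' @examples
#' sizes_from_cutpoints(c(3, 7), 10)   # 3 4 3
#' @export
sizes_from_cutpoints <- function(cutpoints, JM) {
  cp <- sort(as.integer(cutpoints))
  if (anyDuplicated(cp)) stop("cutpoints must be distinct")
  if (length(cp) && (cp[1] < 1L || cp[length(cp)] > JM - 1L))
    stop("cutpoints must lie in 1..JM-1")
  diff(c(0L, cp, as.integer(JM)))
}

#' Draw initial guild population sizes
#'
#' `JM` is split at `g - 1` points sampled uniformly without replacement
#' from `1..JM-1` and sorted; guild sizes are the successive differences.
#' Sampling without replacement guarantees every guild size is at least 1.
#'
#' @param JM System size (total individuals).
#' @param g Number of guilds (`1 <= g <= JM`).
#' @param seed Integer seed.
#' @return Integer vector of length `g` summing to `JM`.
#' @export
draw_guild_sizes <- function(JM, g, seed = NULL) {
  JM <- as.integer(JM); g <- as.integer(g)
  if (g < 1L || g > JM) stop("require 1 <= g <= JM")
  if (g == 1L) return(JM)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sizes_from_cutpoints(sample(JM - 1L, g - 1L), JM)
}

#' Quadruple a species pool for the large system
#'
#' The large (40 x 40) system starts from the small-system pool with the
#' same guild niches and every guild population size multiplied by four.
#'
#' @param guilds An `nn_guilds` table.
#' @param sizes Small-system guild sizes.
#' @return List with the unchanged `guilds` and `sizes * 4`.
#' @export
quadruple_pool <- function(guilds, sizes) {
  list(guilds = guilds, sizes = as.integer(sizes) * 4L)
}

#' Initialize the population of a landscape
#'
#' Individuals (one per site-slot; slots are `J` per site) are assigned to
#' guilds by a uniform random permutation of the `JM` site-slots. Every
#' individual carries a unique founder code (its initial site-slot index).
#' Species labels depend on the mode:
#' \describe{
#'   \item{`monodominance`}{all individuals of a guild form one species
#'     (species count at t0 = g);}
#'   \item{`infinite_diversity`}{every individual is its own species
#'     (species count at t0 = JM).}
#' }
#' The slot assignment and founder codes are identical for both modes at the
#' same seed: the two initial states differ only in the species-labelling
#' map. This shared-randomness contract is what makes the coupled
#' convergence test of the engine exact.
#'
#' @param landscape An `nn_landscape`.
#' @param guilds An `nn_guilds` table.
#' @param sizes Guild sizes summing to the landscape's `JM`.
#' @param mode `"monodominance"` or `"infinite_diversity"`.
#' @param seed Integer seed.
#' @return An `nn_state` (see [nn_state()]).
#' @export
initialize_population <- function(landscape, guilds, sizes,
                                  mode = c("monodominance", "infinite_diversity"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  sizes <- as.integer(sizes)
  if (sum(sizes) != landscape$JM)
    stop("guild sizes must sum to the landscape JM")
  if (any(sizes < 1L)) stop("guild sizes must be >= 1")
  if (length(sizes) != nrow(guilds)) stop("one size per guild required")
  if (!is.null(seed)) set.seed(as.integer(seed))
  JM <- landscape$JM
  # slot i belongs to site (i-1) %/% J + 1; a uniform permutation places the
  # guild blocks over slots
  perm <- sample.int(JM)
  guild_of_slot <- integer(JM)
  guild_of_slot[perm] <- rep.int(seq_len(nrow(guilds)), sizes)
  founder <- seq_len(JM)
  if (mode == "monodominance") {
    species <- guild_of_slot
    pool_guild <- guilds$guild
    pool_code <- sprintf("g%d.t0", guilds$guild)
  } else {
    species <- founder
    pool_guild <- guild_of_slot
    pool_code <- sprintf("f%d.t0", founder)
  }
  nn_state(landscape, guilds, species = species, guild = guild_of_slot,
           founder = founder, pool_guild = pool_guild, pool_code = pool_code,
           mode = mode)
}

#' Population state container
#'
#' Low-level constructor for the engine state. Individuals are stored in
#' fixed site-slot order (slot `i` lives at site `(i - 1) %/% J + 1`), with
#' parallel vectors for species id, guild id and founder code, plus a
#' species registry (`pool`).
#'
#' @param landscape,guilds See [initialize_population()].
#' @param species,guild,founder Integer vectors of length `JM`.
#' @param pool_guild Guild of each registered species.
#' @param pool_code Printable code of each registered species.
#' @param mode Initialization mode label.
#' @return An object of class `nn_state`.
#' @keywords internal
nn_state <- function(landscape, guilds, species, guild, founder,
                     pool_guild, pool_code, mode) {
  n_sp <- length(pool_guild)
  structure(list(
    landscape = landscape, guilds = guilds,
    site = rep(seq_len(landscape$n_sites), each = landscape$J),
    species = as.integer(species), guild = as.integer(guild),
    founder = as.integer(founder),
    pool = list(guild = as.integer(pool_guild), code = pool_code,
                birth_step = integer(n_sp),
                is_t0 = rep(TRUE, n_sp)),
    step = 0L, mode = mode), class = "nn_state")
}

#' @export
print.nn_state <- function(x, ...) {
  cat(sprintf("population state: step %d, %d individuals, %d species, %d guilds (%s)\n",
              x$step, length(x$species), length(unique(x$species)),
              length(unique(x$guild)), x$mode))
  invisible(x)
}

#' Site-by-species abundance view of a state
#'
#' @param state An `nn_state`.
#' @param sites Optional site subset (e.g. a window's `sites`).
#' @return Integer matrix sites x species; columns named by species code and
#'   restricted to species present in the subset.
#' @export
site_species_table <- function(state, sites = NULL) {
  keep <- if (is.null(sites)) TRUE else state$site %in% sites
  site <- state$site[keep]; sp <- state$species[keep]
  usite <- if (is.null(sites)) sort(unique(state$site)) else sites
  usp <- sort(unique(sp))
  i <- match(site, usite); j <- match(sp, usp)
  m <- matrix(tabulate((j - 1L) * length(usite) + i,
                       nbins = length(usite) * length(usp)),
              length(usite), length(usp),
              dimnames = list(as.character(usite), state$pool$code[usp]))
  attr(m, "species_id") <- usp
  attr(m, "guild") <- state$pool$guild[usp]
  m
}

#' Export the species pool and population tables
#'
#' Pool CSV: `species,guild,optimum,tolerance,birth_step`; population CSV:
#' `site,slot,species,guild,founder`.
#'
#' @param state An `nn_state`.
#' @param pool_file,pop_file Paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the data frames written.
#' @export
write_population <- function(state, pool_file = NULL, pop_file = NULL) {
  sp_ids <- sort(unique(state$species))
  pool <- data.frame(species = state$pool$code[sp_ids],
                     guild = state$pool$guild[sp_ids],
                     optimum = state$guilds$optimum[state$pool$guild[sp_ids]],
                     tolerance = state$guilds$tolerance[state$pool$guild[sp_ids]],
                     birth_step = state$pool$birth_step[sp_ids])
  pop <- data.frame(site = state$site,
                    slot = ((seq_along(state$site) - 1L) %% state$landscape$J) + 1L,
                    species = state$pool$code[state$species],
                    guild = state$guild, founder = state$founder)
  if (!is.null(pool_file)) utils::write.csv(pool, pool_file, row.names = FALSE, quote = FALSE)
  if (!is.null(pop_file)) utils::write.csv(pop, pop_file, row.names = FALSE, quote = FALSE)
  invisible(list(pool = pool, population = pop))
}
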