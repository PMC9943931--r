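# deterministic 31-bit seed derived from a master seed and a tag path;
# keeps every stochastic stage traceable to (master, scenario, stage)
derive_seed <- function(master, ...) {
  s <- paste(c(master, ...), collapse = "/")
  h <- as.double(master %% 2147483647L)
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

#' Workbench configuration presets
#'
#' `paper_full` is the full-scale design: small system 20 x 20, large
#' 40 x 40, `J = 16`, `nu = 0.001`, 10 x 10 central window. `reduced` is a
#' scaled-down analogue that runs on one CPU in minutes: an 8 x 8 grid with
#' `J = 8`, `nu = 0.01`, a 6 x 6 central window, triangle-wave period 8 and
#' bump period 4 (so the hump structure keeps (width/period)^2 maxima), and
#' lighter permutation counts.
#'
#' @param preset `"paper_full"` or `"reduced"`.
#' @return A named list of class `nn_config`.
#' @export
nn_config <- function(preset = c("paper_full", "reduced")) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper_full") {
    list(small = list(width = 20L, height = 20L),
         large = list(width = 40L, height = 40L),
         J = 16L, nu = 0.001, window = 10L,
         linear_period = 20, hump_period = 5,
         m_small = c(0.01, 0.09), m_large = 0.81,
         g_levels = c(1L, 8L, 40L, 160L, 500L),
         n_niche = 5L, n_size = 5L, n_niche_single = 25L,
         max_steps = 1000000L, n_perm = 999L, alpha = 0.05,
         tolerance_exclude = 0.0052)
  } else {
    list(small = list(width = 8L, height = 8L),
         large = list(width = 8L, height = 8L),
         J = 8L, nu = 0.01, window = 6L,
         linear_period = 8, hump_period = 4,
         m_small = c(0.01, 0.09), m_large = 0.81,
         g_levels = c(1L, 8L, 40L), g_levels_large = 8L,
         n_niche = 1L, n_size = 1L, n_niche_single = 1L,
         max_steps = 20000L, n_perm = 199L, alpha = 0.05,
         tolerance_exclude = 0.0052)
  }
  cfg$preset <- preset
  structure(cfg, class = "nn_config")
}

#' Enumerate the experimental design
#'
#' Full design: in the small system, every combination of two dispersal
#' rates, three environmental structures, four multi-guild levels, five
#' niche draws and five guild-size draws (2 x 3 x 4 x 5 x 5 = 600) plus 25
#' single-guild niche draws per (m, structure) cell (2 x 3 x 25 = 150); in
#' the large system one size draw for all five guild levels and five niche
#' draws (1 x 3 x 5 x 5 = 75). 825 scenarios in total, 125 per small-system
#' cell. Niche and size draws are shared across cells within a guild level,
#' as in the design. The reduced preset keeps one replicate per stratum
#' with guild levels {1, 8, 40} (small) and 8 (large): 21 scenarios.
#'
#' @param config An `nn_config` (or preset name).
#' @param master_seed Master seed from which all scenario seeds derive.
#' @return Data frame of class `nn_manifest`: `id, system, m, structure, g,
#'   niche_rep, size_rep` and the derived `env_seed, niche_seed, size_seed,
#'   run_seed`.
#' @export
enumerate_scenarios <- function(config = nn_config("paper_full"),
                                master_seed = 1L) {
  if (is.character(config)) config <- nn_config(config)
  structures <- c("random", "linear", "humps")
  rows <- list()
  add <- function(system, m, structure, g, niche_rep, size_rep) {
    rows[[length(rows) + 1L]] <<- data.frame(
      system = system, m = m, structure = structure, g = g,
      niche_rep = niche_rep, size_rep = size_rep)
  }
  g_multi <- setdiff(config$g_levels, 1L)
  for (m in config$m_small) for (st in structures) {
    for (g in g_multi)
      for (nr in seq_len(config$n_niche))
        for (sr in seq_len(config$n_size))
          add("small", m, st, g, nr, sr)
    if (1L %in% config$g_levels)
      for (nr in seq_len(config$n_niche_single))
        add("small", m, st, 1L, nr, 1L)
  }
  g_large <- config$g_levels_large %||% config$g_levels
  for (st in structures)
    for (g in g_large)
      for (nr in seq_len(config$n_niche))
        add("large", config$m_large, st, g, nr, 1L)
  man <- do.call(rbind, rows)
  man$id <- seq_len(nrow(man))
  # shared niche/size draws across cells within a guild level, per design
  man$env_seed <- mapply(function(sys, st) derive_seed(master_seed, "env", sys, st),
                         man$system, man$structure)
  man$niche_seed <- mapply(function(g, nr) derive_seed(master_seed, "niche", g, nr),
                           man$g, man$niche_rep)
  man$size_seed <- mapply(function(g, sr) derive_seed(master_seed, "size", g, sr),
                          man$g, man$size_rep)
  man$run_seed <- vapply(man$id, function(i) derive_seed(master_seed, "run", i),
                         integer(1))
  man <- man[, c("id", "system", "m", "structure", "g", "niche_rep",
                 "size_rep", "env_seed", "niche_seed", "size_seed",
                 "run_seed")]
  attr(man, "master_seed") <- master_seed
  attr(man, "config") <- config
  class(man) <- c("nn_manifest", "data.frame")
  man
}

#' Flag scenarios whose narrowest guild tolerance falls below a threshold
#'
#' The full design excluded the six scenarios whose minimum environmental
#' tolerance was below 0.0052; the threshold is configurable.
#'
#' @param manifest An `nn_manifest`.
#' @param threshold Tolerance threshold (default from the manifest config,
#'   0.0052).
#' @return The manifest with a logical `excluded` column.
#' @export
exclusion_filter <- function(manifest, threshold = NULL) {
  cfg <- attr(manifest, "config")
  if (is.null(threshold)) threshold <- cfg$tolerance_exclude %||% 0.0052
  key <- paste(manifest$g, manifest$niche_seed)
  mins <- vapply(split(seq_len(nrow(manifest)), key)[unique(key)], function(idx) {
    r <- manifest[idx[1], ]
    min(draw_guilds(r$g, seed = r$niche_seed)$tolerance)
  }, numeric(1))
  manifest$excluded <- mins[match(key, unique(key))] < threshold
  manifest
}

# assemble the inputs of one scenario (landscape, guilds, sizes, params)
scenario_inputs <- function(scn, config) {
  sys <- config[[scn$system]]
  grid <- grid_spec(sys$width, sys$height, J = config$J)
  land <- build_landscape(grid, scn$structure, seed = scn$env_seed,
                          linear_period = config$linear_period,
                          hump_period = config$hump_period)
  guilds <- draw_guilds(scn$g, seed = scn$niche_seed,
                        exclude_below = config$tolerance_exclude)
  JM_small <- config$small$width * config$small$height * config$J
  sizes <- draw_guild_sizes(JM_small, scn$g, seed = scn$size_seed)
  scaleup <- grid$JM / JM_small
  if (scaleup != 1) sizes <- as.integer(sizes * scaleup)
  params <- simulation_params(m = scn$m, nu = config$nu,
                              max_steps = config$max_steps,
                              seed = scn$run_seed)
  list(landscape = land, guilds = guilds, sizes = sizes, params = params,
       window = extract_window(land, config$window))
}

#' Run one scenario end to end
#'
#' Landscape, pool, forward simulation to convergence, then the full
#' diagnostic battery on the central window: diversity metrics, variation
#' partitioning with component classification, guild structure and the
#' hierarchical spatial model when eligible, and the autocorrelation
#' analysis of the classified components. Non-converged runs are flagged
#' and returned without statistics.
#'
#' @param scn One row of an `nn_manifest` (data frame or list).
#' @param config The `nn_config` used to build the manifest.
#' @param keep_state Keep the full final `nn_state` in the record
#'   (default FALSE; it is large).
#' @return A list of class `nn_record`.
#' @export
run_scenario <- function(scn, config, keep_state = FALSE) {
  inp <- scenario_inputs(scn, config)
  run <- run_to_convergence(inp$landscape, inp$guilds, inp$sizes, inp$params,
                            record = FALSE)
  rec <- list(id = scn$id, system = scn$system, m = scn$m,
              structure = scn$structure, g = scn$g,
              niche_rep = scn$niche_rep, size_rep = scn$size_rep,
              seeds = list(env = scn$env_seed, niche = scn$niche_seed,
                           size = scn$size_seed, run = scn$run_seed),
              excluded = isTRUE(attr(inp$guilds, "excluded")),
              converged = run$converged,
              t_convergence = run$t_convergence,
              t_guild_stationary = run$t_guild_stationary)
  if (!run$converged) {
    rec$flag <- "not converged within max_steps; statistics skipped"
    class(rec) <- "nn_record"
    return(rec)
  }
  win <- inp$window
  comm <- site_species_table(run$state, win$sites)
  rec$n_guilds_window <- length(unique(attr(comm, "guild")))
  rec$metrics <- diversity_metrics(comm, inp$guilds, sizes = inp$sizes)
  vp_seed <- derive_seed(scn$run_seed, "varpart")
  vp <- variation_partition(comm, win$E, d = win$dist,
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = vp_seed)
  rec$varpart <- list(fractions = vp$fractions, p_values = vp$p_values,
                      relative = vp$relative, selected = vp$selected)
  rec$components <- classify_components(vp, rec$n_guilds_window)
  alpha <- config$alpha

  # autocorrelation targets per the component classification
  ac <- list()
  Y <- vp$Y
  if (rec$n_guilds_window <= 1) {
    if ("false environmental" %in% rec$components && !is.null(vp$env_X))
      ac$false_environmental <- rda_fit(Y, vp$env_X)$fitted
    if ("true spatial" %in% rec$components && !is.null(vp$spatial_X))
      ac$true_spatial <- rda_fit(Y, vp$spatial_X)$fitted
  } else if ("true environmental" %in% rec$components && !is.null(vp$env_X)) {
    ac$true_environmental <- rda_fit(Y, vp$env_X)$fitted
  }
  rec$autocorr <- lapply(names(ac), function(nm) {
    a <- autocorrelation_analysis(ac[[nm]], win$dist,
                                  n_perm = config$n_perm,
                                  seed = derive_seed(scn$run_seed, "ac", nm),
                                  component = nm)
    list(component = nm, r = a$r, p_value = a$p_value, flag = a$flag)
  })

  # hierarchical habitat structure for eligible multi-guild communities
  if (rec$n_guilds_window >= 2 && !is.na(vp$p_values["pure_env"]) &&
      vp$p_values["pure_env"] <= alpha && !is.null(vp$env_X)) {
    gs <- try(guild_structure(comm, vp$env_X, n_perm = config$n_perm,
                              alpha = alpha,
                              seed = derive_seed(scn$run_seed, "guildstruct")),
              silent = TRUE)
    if (!inherits(gs, "try-error")) {
      rec$guild_structure <- list(k = gs$k, p_value = gs$p_value,
                                  significant = gs$significant,
                                  habitat = gs$habitat)
      if (gs$significant) {
        hm <- try(hierarchical_model(comm, gs, win, n_perm = config$n_perm,
                                     alpha = alpha,
                                     seed = derive_seed(scn$run_seed, "hier")),
                  silent = TRUE)
        if (!inherits(hm, "try-error")) {
          rec$hierarchical <- list(fractions = hm$fractions,
                                   relative = hm$relative,
                                   selected = hm$selected,
                                   p_values = hm$p_values, flags = hm$flags)
          rec$autocorr_contexts <- context_autocorr(
            Y, gs$habitat, hm, win, config, scn$run_seed)
        }
      }
    }
  }
  if (keep_state) rec$state <- run$state
  class(rec) <- "nn_record"
  rec
}

# per-environmental-context autocorrelation: within each habitat type with
# selected within-block spatial structure, 3 distance classes when the
# context has >= 45 site pairs, else 2
context_autocorr <- function(Y, habitat, hm, win, config, run_seed) {
  out <- list()
  for (h in sort(unique(habitat))) {
    sel <- grep(sprintf("^W%d\\.", h), unlist(hm$selected), value = TRUE)
    if (!length(sel) || is.null(hm$spatial_X)) next
    idx <- which(habitat == h)
    if (length(idx) < 4) next
    Wh <- hm$spatial_X[idx, intersect(sel, colnames(hm$spatial_X)),
                       drop = FALSE]
    if (!ncol(Wh)) next
    Yh <- Y[idx, , drop = FALSE]
    Yh <- Yh[, apply(Yh, 2, stats::var) > 0, drop = FALSE]
    if (ncol(Yh) < 3) next
    fit <- rda_fit(Yh, Wh)
    ncl <- if (length(idx) * (length(idx) - 1) / 2 >= 45) 3L else 2L
    a <- try(autocorrelation_analysis(fit$fitted, win$dist[idx, idx],
                                      n_classes = ncl,
                                      n_perm = config$n_perm,
                                      seed = derive_seed(run_seed, "ctx", h),
                                      component = sprintf("context %d", h)),
             silent = TRUE)
    if (!inherits(a, "try-error"))
      out[[as.character(h)]] <- list(habitat = h, r = a$r,
                                     p_value = a$p_value, flag = a$flag)
  }
  out
}

#' @export
print.nn_record <- function(x, ...) {
  cat(sprintf("scenario %s: %s/%s m=%g g=%d — %s\n", x$id, x$system,
              x$structure, x$m, x$g,
              if (isTRUE(x$converged))
                sprintf("converged at %d", x$t_convergence)
              else "not converged"))
  invisible(x)
}

#' Summarize a batch of scenario records
#'
#' Flattens records into one row per scenario (time ratio to stationary
#' guild number, diversity metrics, adjusted fractions, relative
#' proportions, test outcomes) for stratum-level comparison.
#'
#' @param records List of `nn_record` objects.
#' @return Data frame, one row per record.
#' @export
summarize_records <- function(records) {
  rows <- lapply(records, function(r) {
    base <- data.frame(id = r$id, system = r$system, m = r$m,
                       structure = r$structure, g = r$g,
                       converged = isTRUE(r$converged),
                       excluded = isTRUE(r$excluded),
                       t_convergence = r$t_convergence %||% NA_integer_,
                       t_guild_stationary = r$t_guild_stationary %||% NA_integer_)
    base$t_ratio <- with(base, ifelse(converged & t_convergence > 0,
                                      t_guild_stationary / t_convergence,
                                      NA_real_))
    if (!is.null(r$metrics)) base <- cbind(base, r$metrics)
    if (!is.null(r$varpart)) {
      f <- r$varpart$fractions; p <- r$varpart$p_values
      base$frac_env <- f[["env"]]; base$frac_spatial <- f[["spatial"]]
      base$frac_pure_env <- f[["pure_env"]]
      base$frac_pure_spatial <- f[["pure_spatial"]]
      base$frac_total <- f[["total"]]
      base$rel_env <- r$varpart$relative[["env"]]
      base$p_env <- p[["env"]]; base$p_pure_env <- p[["pure_env"]]
      base$p_spatial <- p[["spatial"]]; base$p_pure_spatial <- p[["pure_spatial"]]
      base$components <- paste(r$components, collapse = "; ")
    }
    base
  })
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
  do.call(rbind, rows)
}

#' Run a whole manifest
#'
#' @param manifest An `nn_manifest`.
#' @param config Matching `nn_config`.
#' @param progress Print one line per scenario.
#' @return List of `nn_record`s.
#' @export
run_batch <- function(manifest, config, progress = FALSE) {
  lapply(seq_len(nrow(manifest)), function(i) {
    rec <- run_scenario(manifest[i, ], config)
    if (progress) print(rec)
    rec
  })
}

#' Serialize / restore a scenario record
#'
#' JSON round-trip via jsonlite; matrices and the trajectory are kept as
#' nested arrays.
#'
#' @param record An `nn_record` (or any list).
#' @param file Path.
#' @return `read_record()` returns the restored list.
#' @export
write_record <- function(record, file) {
  jsonlite::write_json(unclass(record), file, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(file)
}

#' @rdname write_record
#' @export
read_record <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
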