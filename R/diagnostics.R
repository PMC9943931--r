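#' Variation partitioning of a model-community table
#'
#' Partitions the Hellinger-transformed species abundance variation of the
#' window into environmental and spatial components by (partial) redundancy
#' analysis. Environmental candidates are the first- and second-order
#' orthogonal polynomials of `E`; spatial candidates are the positive PCNM
#' eigenfunctions of the window distances. Each set passes through forward
#' selection before partitioning. Fractions are adjusted (Ezekiel): env
#' `[a+b]`, spatial `[b+c]`, pure env `[a]`, pure spatial `[c]`, shared
#' `[b]`, residual `[d]`; `[a]+[b]+[c]+[d] = 1`. Statistical claims about
#' species-environment relationships use the pure environmental fraction,
#' whose test conditions on the selected spatial set (environmental tests
#' are biased when both species and environment are spatially structured).
#'
#' @param comm Site-by-species abundance matrix over the window.
#' @param E Environmental values of the window sites.
#' @param d Distance matrix of the window sites (or an `nn_pcnm` /
#'   precomputed spatial candidate matrix via `spatial`).
#' @param spatial Optional precomputed spatial candidate matrix.
#' @param n_perm Permutations per test (default 999).
#' @param alpha Selection and test level (default 0.05).
#' @param seed Optional seed.
#' @return List of class `nn_varpart`: `fractions` (named numeric:
#'   `env, spatial, pure_env, pure_spatial, shared, residual, total`),
#'   `p_values` (`env, pure_env, spatial, pure_spatial`), `selected`
#'   (per-set names), `relative` (`env, pure_spatial` over total), `Y`,
#'   `env_X`, `spatial_X`, `flag`.
#' @export
variation_partition <- function(comm, E, d = NULL, spatial = NULL,
                                n_perm = 999, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  Y <- hellinger(comm)
  keep <- apply(Y, 2, stats::var) > 0
  if (sum(keep) < 2) stop("need >= 2 species with nonzero variance")
  Y <- Y[, keep, drop = FALSE]
  env_cand <- ortho_env(E, 2)
  if (is.null(spatial)) {
    if (is.null(d)) stop("supply either d or spatial")
    spatial <- pcnm(d)$vectors
  } else if (inherits(spatial, "nn_pcnm")) spatial <- spatial$vectors

  fse <- forward_select(Y, env_cand, alpha = alpha, n_perm = n_perm)
  fss <- forward_select(Y, spatial, alpha = alpha, n_perm = n_perm)
  Xe <- fse$X; Xs <- fss$X
  n <- nrow(Y)

  ab <- if (is.null(Xe)) 0 else rda_fit(Y, Xe)$adj_R2
  bc <- if (is.null(Xs)) 0 else rda_fit(Y, Xs)$adj_R2
  abc <- if (is.null(Xe) && is.null(Xs)) 0
         else rda_fit(Y, cbind(Xe, Xs))$adj_R2
  a <- abc - bc; cfrac <- abc - ab; b <- ab + bc - abc
  fractions <- c(env = ab, spatial = bc, pure_env = a, pure_spatial = cfrac,
                 shared = b, residual = 1 - abc, total = abc)

  pv <- c(env = NA_real_, pure_env = NA_real_, spatial = NA_real_,
          pure_spatial = NA_real_)
  if (!is.null(Xe)) {
    pv["env"] <- permutation_test(Y, Xe, n_perm = n_perm)$p_value
    pv["pure_env"] <- permutation_test(Y, Xe, Z = Xs, n_perm = n_perm)$p_value
  }
  if (!is.null(Xs)) {
    pv["spatial"] <- permutation_test(Y, Xs, n_perm = n_perm)$p_value
    pv["pure_spatial"] <- permutation_test(Y, Xs, Z = Xe, n_perm = n_perm)$p_value
  }
  total <- abc
  rel <- c(env = if (total > 0) ab / total else NA_real_,
           pure_spatial = if (total > 0) cfrac / total else NA_real_)
  structure(list(fractions = fractions, p_values = pv,
                 selected = list(env = fse$selected, spatial = fss$selected),
                 global_p = c(env = fse$global_p, spatial = fss$global_p),
                 relative = rel, Y = Y, env_X = Xe, spatial_X = Xs,
                 alpha = alpha,
                 flag = if (is.null(Xe) && is.null(Xs)) "no_predictors_selected"
                        else NA_character_),
            class = "nn_varpart")
}

#' @export
print.nn_varpart <- function(x, ...) {
  f <- x$fractions
  cat(sprintf(paste0("variation partitioning (adjusted): env [a+b] = %.3f,",
                     " spatial [b+c] = %.3f\n  [a] = %.3f  [b] = %.3f",
                     "  [c] = %.3f  [d] = %.3f\n"),
              f["env"], f["spatial"], f["pure_env"], f["shared"],
              f["pure_spatial"], f["residual"]))
  print(round(x$p_values, 4))
  invisible(x)
}

#' Classify significant components of a variation partitioning
#'
#' Single-guild communities have no real species-environment structure, so
#' a significant purely environmental component is a *false environmental*
#' component, and significant spatial structure without any environmental
#' signal is a *true spatial* component. In multi-guild communities a
#' significant purely environmental component is a *true environmental*
#' component; significant spatial structure is labelled *spatial*.
#'
#' @param vp An `nn_varpart`.
#' @param n_guilds Number of guilds present in the community.
#' @param alpha Test level (default the partitioning's own).
#' @return Character vector of applicable component labels (possibly
#'   empty).
#' @export
classify_components <- function(vp, n_guilds, alpha = vp$alpha) {
  p <- vp$p_values
  sig <- function(k) !is.na(p[k]) && p[k] <= alpha
  out <- character(0)
  if (n_guilds <= 1) {
    if (sig("pure_env")) out <- c(out, "false environmental")
    if ((sig("spatial") || sig("pure_spatial")) &&
        !(sig("env") || sig("pure_env")))
      out <- c(out, "true spatial")
  } else {
    if (sig("pure_env")) out <- c(out, "true environmental")
    if (sig("spatial") || sig("pure_spatial")) out <- c(out, "spatial")
  }
  out
}

#' Hierarchical guild (habitat) structure of the window
#'
#' k-means partitioning of the canonical linear-combination site scores
#' (scaling 1) of the environmental RDA, with the number of habitat types
#' chosen by the simple structure index (SSI) over `k = 2..k_max`
#' (cascaded k-means). Significance is a permutation RDA of the
#' habitat-type dummy variables against the community table; because the
#' clusters are derived from the response itself this test is circular and
#' is reported as such in the output metadata.
#'
#' @param comm Site-by-species abundances of the window.
#' @param env_X Selected environmental predictor matrix (from
#'   [variation_partition()]).
#' @param k_max Largest k to try; default `min(10, floor(n/5))`.
#' @param ssi_tol Parsimony guard: the smallest k whose SSI reaches
#'   `ssi_tol` times the maximum is chosen (SSI profiles are nearly flat
#'   when tight clusters are over-split; default 0.9).
#' @param n_perm,alpha,seed Test controls.
#' @return List of class `nn_guild_structure`: `habitat` (integer
#'   assignment per site), `k`, `ssi` (profile over k), `p_value`,
#'   `significant`, `note`.
#' @export
guild_structure <- function(comm, env_X, k_max = NULL, ssi_tol = 0.9,
                            n_perm = 999, alpha = 0.05, seed = NULL) {
  if (is.null(env_X)) stop("guild structure requires a selected environmental model")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Y <- hellinger(comm)
  fit <- rda_fit(Y, env_X)
  sc <- fit$scores
  if (!ncol(sc) || max(abs(sc)) < 1e-12) stop("degenerate canonical scores")
  # cluster only the informative canonical axes: near-noise axes (< 5% of
  # the canonical variance) destabilize the simple structure index
  keep_ax <- fit$eig / sum(fit$eig) >= 0.05
  keep_ax[1] <- TRUE
  sc <- sc[, keep_ax, drop = FALSE]
  n <- nrow(Y)
  if (is.null(k_max)) k_max <- max(2L, min(10L, n %/% 5L))
  ck <- vegan::cascadeKM(sc, inf.gr = 2, sup.gr = k_max, criterion = "ssi")
  ssi <- ck$results["ssi", ]
  kbest <- as.integer(sub(" groups", "",
                          names(which(ssi >= ssi_tol * max(ssi)))[1]))
  habitat <- as.integer(ck$partition[, paste(kbest, "groups")])
  H <- stats::model.matrix(~ factor(habitat))[, -1, drop = FALSE]
  colnames(H) <- paste0("H", seq_len(ncol(H)))
  pt <- permutation_test(Y, H, n_perm = n_perm)
  structure(list(habitat = habitat, k = kbest, ssi = ssi,
                 p_value = pt$p_value, significant = pt$p_value <= alpha,
                 H = H,
                 note = "habitat types derived from the response; test is circular"),
            class = "nn_guild_structure")
}

# habitat dummy matrix from an assignment vector
habitat_dummies <- function(habitat) {
  H <- stats::model.matrix(~ factor(habitat))[, -1, drop = FALSE]
  colnames(H) <- paste0("H", seq_len(ncol(H)))
  H
}

#' Hierarchical spatial model within and among patchy habitats
#'
#' Given a significant habitat structure, models the residual variation of
#' the community (after the habitat-type dummies `H`) with two spatial
#' predictor sets: `A`, among-habitat structure — PCNM eigenfunctions of
#' the habitat-centroid distances expanded to member sites; and `W`,
#' within-habitat structure — block-diagonal PCNMs computed per habitat
#' type (zero outside the block). Both sets pass through forward selection
#' on the residuals of `Y | H`.
#'
#' @param comm Site-by-species abundances.
#' @param structure An `nn_guild_structure` (or an integer habitat vector).
#' @param window An `nn_window` (for site coordinates/distances).
#' @param n_perm,alpha,seed Test controls.
#' @return List of class `nn_hierarchical`: `fractions` (`habitat`,
#'   `spatial` = selected A+W given H, `total`), `relative`
#'   (env-analogue and pure-spatial proportions of total), `selected`,
#'   `p_values` (A and W given H), `flags` (habitats too small for a
#'   within block), `H`, `spatial_X`.
#' @export
hierarchical_model <- function(comm, structure, window, n_perm = 999,
                               alpha = 0.05, seed = NULL) {
  habitat <- if (inherits(structure, "nn_guild_structure"))
    structure$habitat else as.integer(structure)
  if (!is.null(seed)) set.seed(as.integer(seed))
  Y <- hellinger(comm)
  n <- nrow(Y)
  xy <- window$xy
  kh <- sort(unique(habitat))
  H <- if (length(kh) > 1) habitat_dummies(habitat) else NULL
  flags <- character(0)

  # A: among-habitat PCNMs on centroid distances, expanded by membership
  A <- NULL
  if (length(kh) >= 3) {
    cent <- t(vapply(kh, function(h) colMeans(xy[habitat == h, , drop = FALSE]),
                     numeric(2)))
    pa <- try(pcnm(as.matrix(stats::dist(cent))), silent = TRUE)
    if (!inherits(pa, "try-error")) {
      A <- pa$vectors[match(habitat, kh), , drop = FALSE]
      colnames(A) <- paste0("A.", colnames(pa$vectors))
    }
  }
  # W: block PCNM per habitat with >= 3 sites
  Wlist <- list()
  for (h in kh) {
    idx <- which(habitat == h)
    if (length(idx) < 3) {
      flags <- c(flags, sprintf("habitat %d has < 3 sites: no within block", h))
      next
    }
    dh <- as.matrix(stats::dist(xy[idx, , drop = FALSE]))
    if (max(dh) == 0) { flags <- c(flags, sprintf("habitat %d degenerate", h)); next }
    pw <- pcnm(dh)
    wb <- matrix(0, n, ncol(pw$vectors))
    wb[idx, ] <- pw$vectors
    colnames(wb) <- paste0("W", h, ".", colnames(pw$vectors))
    Wlist[[as.character(h)]] <- wb
  }
  W <- if (length(Wlist)) do.call(cbind, Wlist) else NULL
  if (is.null(A) && is.null(W))
    stop("no spatial candidates could be built for this habitat partition")

  Yres <- if (is.null(H)) scale(Y, scale = FALSE) else qr.resid(qr(cbind(1, H)), Y)
  fsA <- if (!is.null(A)) forward_select(Yres, A, alpha = alpha, n_perm = n_perm)
         else list(selected = character(0), X = NULL)
  fsW <- if (!is.null(W)) forward_select(Yres, W, alpha = alpha, n_perm = n_perm)
         else list(selected = character(0), X = NULL)
  S <- cbind(fsA$X, fsW$X)

  hab_frac <- if (is.null(H)) 0 else rda_fit(Y, H)$adj_R2
  total <- if (is.null(S) && is.null(H)) 0
           else rda_fit(Y, cbind(H, S))$adj_R2
  pure_spatial <- total - hab_frac
  pv <- c(among = NA_real_, within = NA_real_)
  if (!is.null(fsA$X))
    pv["among"] <- permutation_test(Y, fsA$X, Z = H, n_perm = n_perm)$p_value
  if (!is.null(fsW$X))
    pv["within"] <- permutation_test(Y, fsW$X, Z = H, n_perm = n_perm)$p_value
  structure(list(
    fractions = c(habitat = hab_frac, pure_spatial = pure_spatial,
                  total = total),
    relative = c(env = if (total > 0) hab_frac / total else NA_real_,
                 pure_spatial = if (total > 0) pure_spatial / total else NA_real_),
    selected = list(among = fsA$selected, within = fsW$selected),
    p_values = pv, flags = flags, H = H, spatial_X = S),
    class = "nn_hierarchical")
}

#' Diniz-Filho autocorrelation analysis of a fitted component
#'
#' Under neutral dynamics the species abundances are mutually uncorrelated
#' and their short-distance autocorrelation patterns are alike, so the
#' Mantel correlation between the species-pair correlation table and the
#' table of distances between species' Moran's I correlograms is near
#' zero. Niche structure makes ecologically-equivalent species positively
#' correlated *and* similar in their correlograms, driving that Mantel
#' correlation negative; the test is one-tailed in the lower tail.
#'
#' @param fitted Site-by-species fitted values of a component (an RDA's
#'   `fitted`, or raw abundances).
#' @param d Site distance matrix.
#' @param n_classes Distance classes for the correlograms; default Sturges
#'   on the pair count (use 3 or 2 for per-environmental-context runs).
#' @param n_perm,seed Mantel controls.
#' @param component Optional component label carried into the result.
#' @return List of class `nn_autocorr`: `r`, `p_value`, `correlation`
#'   (species-pair correlations), `correlogram_distance`, `I` (species x
#'   class Moran's I), `dropped` (constant species), `component`, `flag`.
#' @export
autocorrelation_analysis <- function(fitted, d, n_classes = NULL,
                                     n_perm = 999, seed = NULL,
                                     component = NA_character_) {
  fitted <- as.matrix(fitted)
  vars <- apply(fitted, 2, stats::var)
  dropped <- colnames(fitted)[vars <= 1e-12]
  fitted <- fitted[, vars > 1e-12, drop = FALSE]
  if (ncol(fitted) < 3)
    return(structure(list(r = NA_real_, p_value = NA_real_,
                          dropped = dropped, component = component,
                          flag = "fewer than 3 variable species"),
                     class = "nn_autocorr"))
  n <- nrow(fitted)
  if (is.null(n_classes)) n_classes <- sturges_classes(n * (n - 1) / 2)
  cg <- lapply(seq_len(ncol(fitted)),
               function(j) morans_correlogram(fitted[, j], d, n_classes))
  # all correlograms share the class breaks (they depend on d only)
  Imat <- t(vapply(cg, function(g) g$I, numeric(nrow(cg[[1]]))))
  rownames(Imat) <- colnames(fitted)
  cgd <- as.matrix(stats::dist(Imat))
  cors <- stats::cor(fitted)
  flag <- NA_character_
  mt <- list(r = NA_real_, p_value = NA_real_)
  ut <- upper.tri(cors)
  if (stats::sd(cors[ut]) == 0 || stats::sd(cgd[ut]) == 0) {
    flag <- "degenerate: identical spatial patterns across species"
  } else {
    mt <- mantel(cors, cgd, n_perm = n_perm, tail = "lower", seed = seed)
  }
  structure(list(r = mt$r, p_value = mt$p_value, correlation = cors,
                 correlogram_distance = cgd, I = Imat, dropped = dropped,
                 component = component, flag = flag),
            class = "nn_autocorr")
}
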