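#' Overlap of two Gaussian niches
#'
#' Functional similarity between two species is the overlapping area of
#' their Gaussian niche densities, `integral of min(phi1, phi2)` over the
#' real line, a number in \[0, 1\]. Equal-variance pairs have the closed
#' form `2 * pnorm(-|mu1 - mu2| / (2 * sigma))`; unequal variances are
#' handled by solving the density crossing points analytically.
#'
#' @param mu1,sigma1,mu2,sigma2 Niche optima and tolerances (`sigma > 0`).
#' @return Similarity in \[0, 1\].
#' @examples
#' gaussian_overlap(0.5, 0.1, 0.7, 0.1)   # 2 * pnorm(-1) = 0.3173
#' @export
gaussian_overlap <- function(mu1, sigma1, mu2, sigma2) {
  if (sigma1 <= 0 || sigma2 <= 0) stop("tolerances must be > 0")
  if (mu1 == mu2 && sigma1 == sigma2) return(1)
  if (sigma1 == sigma2) {
    return(2 * stats::pnorm(-abs(mu1 - mu2) / (2 * sigma1)))
  }
  # order so sigma1 < sigma2; crossing points are the roots of the
  # log-density difference, a quadratic in x
  if (sigma1 > sigma2) {
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    tmp <- sigma1; sigma1 <- sigma2; sigma2 <- tmp
  }
  a <- 1 / sigma1^2 - 1 / sigma2^2
  b <- -2 * (mu1 / sigma1^2 - mu2 / sigma2^2)
  cc <- mu1^2 / sigma1^2 - mu2^2 / sigma2^2 + 2 * log(sigma1 / sigma2)
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) {
    # the narrow density dominates nowhere (numerically): overlap is the
    # mass of the smaller density, i.e. 1 for nested identical means
    return(min(1, stats::integrate(function(x)
      pmin(stats::dnorm(x, mu1, sigma1), stats::dnorm(x, mu2, sigma2)),
      -Inf, Inf, rel.tol = 1e-9)$value))
  }
  r <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  # between the roots the narrow (sigma1) density is the larger one
  ov <- (stats::pnorm(r[1], mu1, sigma1) + 1 - stats::pnorm(r[2], mu1, sigma1)) +
        (stats::pnorm(r[2], mu2, sigma2) - stats::pnorm(r[1], mu2, sigma2))
  min(max(ov, 0), 1)
}

#' Species-by-species Gaussian-overlap similarity table
#'
#' Species of the same guild share a niche, so within-guild similarity is
#' exactly 1; the dissimilarity used by the functional-diversity statistics
#' is `1 - similarity`.
#'
#' @param guild Guild id of each species.
#' @param guilds An `nn_guilds` table.
#' @return List with `similarity` and `dissimilarity` matrices.
#' @export
similarity_table <- function(guild, guilds) {
  ug <- sort(unique(guild))
  gsim <- diag(length(ug))
  if (length(ug) > 1) {
    for (i in seq_along(ug)[-length(ug)]) for (j in (i + 1):length(ug)) {
      s <- gaussian_overlap(guilds$optimum[ug[i]], guilds$tolerance[ug[i]],
                            guilds$optimum[ug[j]], guilds$tolerance[ug[j]])
      gsim[i, j] <- gsim[j, i] <- s
    }
  }
  sim <- gsim[match(guild, ug), match(guild, ug), drop = FALSE]
  dimnames(sim) <- NULL
  list(similarity = sim, dissimilarity = 1 - sim)
}

#' Simpson diversity and its effective number of species
#'
#' @param abund Pooled species abundances (or relative abundances).
#' @return List: `D` = `1 - sum(p^2)`, `effective` = `1 / sum(p^2)`.
#' @export
simpson <- function(abund) {
  if (length(abund) == 0 || sum(abund) <= 0) stop("empty abundance vector")
  p <- abund / sum(abund)
  s2 <- sum(p^2)
  list(D = 1 - s2, effective = 1 / s2)
}

#' Rao's quadratic entropy and its effective number
#'
#' `Q = sum_ij p_i p_j d_ij` with a functional dissimilarity in \[0, 1\];
#' the effective number uses the inverse-Simpson analogue `1 / (1 - Q)`.
#'
#' @param abund Pooled species abundances.
#' @param d Symmetric dissimilarity matrix, zero diagonal, entries \[0, 1\].
#' @return List: `Q`, `effective`.
#' @export
rao_q <- function(abund, d) {
  if (length(abund) != nrow(d) || nrow(d) != ncol(d))
    stop("dimension mismatch between abundances and dissimilarity")
  p <- abund / sum(abund)
  Q <- as.numeric(t(p) %*% d %*% p)
  list(Q = Q, effective = 1 / (1 - Q))
}

#' Functional uniqueness and redundancy
#'
#' Uniqueness `U = Q / D` relates Rao's quadratic entropy to Simpson
#' diversity; redundancy is `R = 1 - U`. A community whose species all
#' belong to one guild has `Q = 0`, hence `U = 0` and `R = 1`. A
#' single-species community leaves `U` undefined; it is reported as 0 with
#' the `undefined` flag set.
#'
#' @inheritParams rao_q
#' @return List: `U`, `R`, `Q`, `D`, `undefined`.
#' @export
uniqueness_redundancy <- function(abund, d) {
  D <- simpson(abund)$D
  if (D <= 0)
    return(list(U = 0, R = 1, Q = 0, D = D, undefined = TRUE))
  Q <- rao_q(abund, d)$Q
  U <- Q / D
  list(U = U, R = 1 - U, Q = Q, D = D, undefined = FALSE)
}

#' Initial Rao's quadratic diversity of a species pool
#'
#' The t0 functional diversity of the system, treating each guild as a
#' single species with relative abundance `size / JM` and pairwise
#' dissimilarity `1 - gaussian_overlap`.
#'
#' @param sizes Initial guild sizes.
#' @param guilds An `nn_guilds` table.
#' @return `Q0` (numeric).
#' @export
initial_rao <- function(sizes, guilds) {
  g <- nrow(guilds)
  if (length(sizes) != g) stop("one size per guild required")
  if (g == 1) return(0)
  st <- similarity_table(seq_len(g), guilds)
  rao_q(as.numeric(sizes), st$dissimilarity)$Q
}

#' Diversity metrics of a converged model-community window
#'
#' Pools abundances over the window sites and computes the one-row metrics
#' record used by the scenario workbench.
#'
#' @param comm Site-by-species abundance matrix (attributes `guild` as set
#'   by [site_species_table()], or pass `guild`).
#' @param guilds An `nn_guilds` table.
#' @param guild Optional explicit guild vector per species column.
#' @param sizes Optional initial guild sizes for `Q0`.
#' @return One-row data frame: `D_eff, Q, Q_eff, U, R, Q0, n_species,
#'   n_guilds`.
#' @export
diversity_metrics <- function(comm, guilds, guild = attr(comm, "guild"),
                              sizes = NULL) {
  ab <- colSums(comm)
  pres <- ab > 0
  ab <- ab[pres]; guild <- guild[pres]
  st <- similarity_table(guild, guilds)
  si <- simpson(ab)
  ur <- uniqueness_redundancy(ab, st$dissimilarity)
  data.frame(D_eff = si$effective, Q = ur$Q,
             Q_eff = 1 / (1 - ur$Q), U = ur$U, R = ur$R,
             Q0 = if (is.null(sizes)) NA_real_ else initial_rao(sizes, guilds),
             n_species = sum(pres), n_guilds = length(unique(guild)))
}
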