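#' Grid specification for a torus metacommunity
#'
#' Defines a rectangular lattice of local communities with periodic
#' boundaries. Each site (local community) holds exactly `J` individuals, so
#' the system size is `JM = width * height * J`.
#'
#' @param width,height Lattice dimensions in sites (integers, at least 3).
#' @param J Local community size (individuals per site), default 16.
#' @return An object of class `nn_grid` with fields `width`, `height`, `J`,
#'   `n_sites` and `JM`.
#' @examples
#' grid_spec(20, 20)          # small system: 400 sites, JM = 6400
#' grid_spec(40, 40)$JM       # large system: 25600
#' @export
grid_spec <- function(width, height = width, J = 16L) {
  width <- as.integer(width); height <- as.integer(height); J <- as.integer(J)
  if (is.na(width) || is.na(height) || width < 3L || height < 3L)
    stop("grid must be at least 3x3 (Moore neighbourhoods overlap self otherwise)")
  if (is.na(J) || J < 1L) stop("J must be a positive integer")
  structure(list(width = width, height = height, J = J,
                 n_sites = width * height, JM = width * height * J),
            class = "nn_grid")
}

#' @export
print.nn_grid <- function(x, ...) {
  cat(sprintf("torus grid: %d x %d sites, J = %d, JM = %d\n",
              x$width, x$height, x$J, x$JM))
  invisible(x)
}

# Site order is row-major with y slowest: site = y*width + x + 1, 0-based x,y.
site_xy <- function(grid) {
  s <- seq_len(grid$n_sites) - 1L
  cbind(x = s %% grid$width, y = s %/% grid$width)
}

xy_site <- function(grid, x, y) {
  (y %% grid$height) * grid$width + (x %% grid$width) + 1L
}

#' Moore neighbour index table on the torus
#'
#' For each site, the indices of its eight nearest neighbouring sites
#' (rook + diagonal) under periodic wrap. Used internally by the engine;
#' [build_torus_weights()] exposes the same structure as a sparse weight
#' matrix.
#'
#' @param grid An `nn_grid`.
#' @return Integer matrix `n_sites x 8`.
#' @keywords internal
neighbor_index <- function(grid) {
  xy <- site_xy(grid)
  off <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
               dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))
  nb <- matrix(0L, grid$n_sites, 8L)
  for (k in 1:8)
    nb[, k] <- xy_site(grid, xy[, "x"] + off[k, "dx"], xy[, "y"] + off[k, "dy"])
  nb
}

#' Torus dispersal weights (spatial weight 1/8 to each Moore neighbour)
#'
#' Builds the row-stochastic site-by-site dispersal weight matrix: each site
#' gives weight 1/8 to each of its eight nearest neighbouring communities on
#' the torus and weight 0 to itself.
#'
#' @param grid An `nn_grid`.
#' @return A sparse `dgCMatrix` (`n_sites x n_sites`); rows sum to 1.
#' @examples
#' w <- build_torus_weights(grid_spec(5, 5))
#' Matrix::rowSums(w)   # all 1
#' @export
build_torus_weights <- function(grid) {
  if (!inherits(grid, "nn_grid")) stop("grid must be an nn_grid")
  nb <- neighbor_index(grid)
  if (any(apply(nb, 1, anyDuplicated) > 0) || any(nb == row(nb)))
    stop("grid too small: neighbourhood wraps onto duplicate sites")
  Matrix::sparseMatrix(i = rep(seq_len(grid$n_sites), 8L),
                       j = as.vector(nb),
                       x = 1 / 8,
                       dims = c(grid$n_sites, grid$n_sites))
}

# Triangle wave with period P, phase-shifted half a step so the sampled
# values form an exact uniform ladder (each level hit twice per period).
tri_wave <- function(x, period) {
  t <- ((x + 0.5) / period) %% 1
  1 - abs(2 * t - 1)
}

#' Generate an environmental gradient on the torus
#'
#' Environmental values `E` per site, bounded in \[0, 1\], with every value
#' represented by (approximately) the same number of local communities and,
#' for the structured gradients, continuous across the opposite sides of the
#' lattice.
#'
#' Structures:
#' \describe{
#'   \item{`random`}{an equally spaced ladder of `n_sites` values on
#'     \[0, 1\], randomly permuted over sites: exactly uniform representation
#'     and no spatial correlation.}
#'   \item{`linear`}{a triangle wave along `x` (constant in `y`) with one
#'     full period per `linear_period` columns (default 20: one wave on the
#'     20 x 20 system, two on the 40 x 40).}
#'   \item{`humps`}{a periodic isotropic bump field
#'     `cos(2*pi*x/P) + cos(2*pi*y/P)` with period `hump_period` (default 5)
#'     in both axes, rank-transformed to the uniform ladder. The field has
#'     exactly `(width/P)*(height/P)` strict local maxima: 16 on the small
#'     system, 64 on the large.}
#' }
#'
#' @param grid An `nn_grid`.
#' @param structure One of `"random"`, `"linear"`, `"humps"`.
#' @param seed Integer seed; required for `random` (and used to break rank
#'   ties reproducibly for `humps`).
#' @param linear_period Columns per triangle-wave period (default 20).
#' @param hump_period Sites per bump period in each axis (default 5).
#' @return Numeric vector of length `n_sites` with attribute `structure`.
#' @examples
#' E <- generate_environment(grid_spec(20, 20), "humps", seed = 1)
#' count_local_maxima(grid_spec(20, 20), E)   # 16
#' @export
generate_environment <- function(grid, structure = c("random", "linear", "humps"),
                                 seed = NULL, linear_period = 20,
                                 hump_period = 5) {
  structure <- match.arg(structure)
  n <- grid$n_sites
  ladder <- seq(0, 1, length.out = n)
  xy <- site_xy(grid)
  E <- switch(structure,
    random = {
      if (is.null(seed)) stop("seed is required for the random structure")
      set.seed(as.integer(seed))
      sample(ladder)
    },
    linear = tri_wave(xy[, "x"], linear_period),
    humps = {
      P <- hump_period
      B <- cos(2 * pi * xy[, "x"] / P) + cos(2 * pi * xy[, "y"] / P)
      # smooth torus-periodic secondary field breaks the symmetry ties so the
      # rank ladder varies continuously within former tie classes
      B2 <- cos(2 * pi * xy[, "x"] / grid$width + 0.7) +
            cos(2 * pi * xy[, "y"] / grid$height + 1.3)
      if (!is.null(seed)) set.seed(as.integer(seed))
      ladder[order(order(B, B2, stats::runif(n)))]
    })
  attr(E, "structure") <- structure
  E
}

#' Count strict local maxima of a site field on the torus
#'
#' A site is a strict local maximum when its value exceeds the values at all
#' eight Moore neighbours (with periodic wrap).
#'
#' @param grid An `nn_grid`.
#' @param E Numeric site field (length `n_sites`).
#' @return Integer count.
#' @export
count_local_maxima <- function(grid, E) {
  stopifnot(length(E) == grid$n_sites)
  nb <- neighbor_index(grid)
  nbmax <- apply(matrix(E[nb], nrow = grid$n_sites), 1, max)
  sum(E > nbmax)
}

#' Assemble a landscape (grid + environment + dispersal structure)
#'
#' Convenience constructor bundling everything the engine needs.
#'
#' @inheritParams generate_environment
#' @param grid An `nn_grid`.
#' @return An object of class `nn_landscape`: the grid fields plus `E`,
#'   `structure`, `xy` (0-based coordinates) and the neighbour index table.
#' @export
build_landscape <- function(grid, structure = "random", seed = NULL,
                            linear_period = 20, hump_period = 5) {
  E <- generate_environment(grid, structure, seed = seed,
                            linear_period = linear_period,
                            hump_period = hump_period)
  structure(list(grid = grid, width = grid$width, height = grid$height,
                 J = grid$J, n_sites = grid$n_sites, JM = grid$JM,
                 xy = site_xy(grid), E = as.numeric(E),
                 structure = attr(E, "structure"),
                 nb = neighbor_index(grid)),
            class = "nn_landscape")
}

#' @export
print.nn_landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d torus, J = %d, environment '%s'\n",
              x$width, x$height, x$J, x$structure))
  invisible(x)
}

#' Central observation window of model communities
#'
#' The model communities analysed by all statistics are a square block of
#' sites in the centre of the system (10 x 10 in the full designs). Window
#' distances are plain Euclidean, not toroidal: the window represents an
#' area sampled from a larger system, so edge wrapping is invisible to the
#' analyst.
#'
#' @param landscape An `nn_landscape` (or `nn_grid`).
#' @param size Window side length in sites, default 10.
#' @return An object of class `nn_window`: `sites` (site ids), `xy` (local
#'   0-based coordinates), `E`, and `dist` (Euclidean distance matrix).
#' @export
extract_window <- function(landscape, size = 10L) {
  size <- as.integer(size)
  w <- landscape$width; h <- landscape$height
  if (w < size || h < size) stop("grid too small for the requested window")
  x0 <- (w - size) %/% 2L; y0 <- (h - size) %/% 2L
  loc <- expand.grid(x = 0:(size - 1L), y = 0:(size - 1L))
  gr <- if (inherits(landscape, "nn_grid")) landscape else landscape$grid
  sites <- xy_site(gr, x0 + loc$x, y0 + loc$y)
  out <- list(sites = sites, xy = as.matrix(loc), size = size,
              offset = c(x0, y0),
              dist = as.matrix(stats::dist(loc)))
  if (!is.null(landscape$E)) out$E <- landscape$E[sites]
  structure(out, class = "nn_window")
}

#' Approximate scale of an independent biogeographic unit
#'
#' The characteristic number of lattice steps an individual's lineage
#' diffuses before speciation under nearest-neighbour dispersal, taken as
#' the integer part of `sqrt(m / nu)`. With `nu = 0.001` this reproduces the
#' three design scales: 3 (`m = 0.01`), 9 (`m = 0.09`) and 28 (`m = 0.81`).
#'
#' @param m Dispersal rate, in (0, 1\].
#' @param nu Speciation rate, in (0, m\].
#' @return Integer number of sites.
#' @examples
#' approximate_scale(0.81, 0.001)   # 28
#' @export
approximate_scale <- function(m, nu) {
  if (any(nu <= 0)) stop("nu must be positive")
  if (any(m < nu) || any(m > 1)) stop("require 0 < nu <= m <= 1")
  as.integer(floor(sqrt(m / nu)))
}

#' Export / import a landscape table
#'
#' Plain CSV with header `site,x,y,E`, one row per local community in
#' deterministic row-major order (y slowest).
#'
#' @param landscape An `nn_landscape`.
#' @param file Path to write to / read from.
#' @return `write_landscape()` returns `file` invisibly; `read_landscape()`
#'   returns a data frame with columns `site`, `x`, `y`, `E`.
#' @export
write_landscape <- function(landscape, file) {
  d <- data.frame(site = seq_len(landscape$n_sites),
                  x = landscape$xy[, "x"], y = landscape$xy[, "y"],
                  E = landscape$E)
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(file) {
  d <- utils::read.csv(file)
  stopifnot(identical(names(d), c("site", "x", "y", "E")))
  d
}
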