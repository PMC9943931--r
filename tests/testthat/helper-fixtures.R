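# shared fixtures, built in code

# tiny neutral landscape + single guild for engine tests
tiny_world <- function(width = 4, height = 4, J = 4, structure = "random",
                       seed = 1) {
  build_landscape(grid_spec(width, height, J = J), structure, seed = seed,
                  linear_period = width, hump_period = 4)
}

one_guild <- function(optimum = 0.5, tolerance = 5) {
  g <- data.frame(guild = 1L, optimum = optimum, tolerance = tolerance)
  class(g) <- c("nn_guilds", "data.frame")
  g
}

# the reduced-preset engine configuration used by the coupling and trend
# tests (8x8, J = 8, nu = 0.01)
preset_world <- function(structure = "humps", env_seed = 3) {
  build_landscape(grid_spec(8, 8, J = 8), structure, seed = env_seed,
                  linear_period = 8, hump_period = 4)
}

# wrap-around vs interior E-steps over the 8-neighbour graph
seam_steps <- function(landscape) {
  nb <- nnc:::neighbor_index(landscape$grid)
  n <- landscape$n_sites
  from <- rep(seq_len(n), 8)
  to <- as.vector(nb)
  dx <- abs(landscape$xy[to, 1] - landscape$xy[from, 1])
  dy <- abs(landscape$xy[to, 2] - landscape$xy[from, 2])
  wrap <- dx > 1 | dy > 1
  d <- abs(landscape$E[to] - landscape$E[from])
  list(wrap = max(d[wrap]), interior = max(d[!wrap]))
}

decile_counts <- function(E) {
  tabulate(pmin(findInterval(E, seq(0, 1, 0.1), rightmost.closed = TRUE), 10),
           nbins = 10)
}
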