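# Shared fixtures: small phantoms and discretized lattices built in code.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(16L, 16L, 6L), voxel_spacing = c(1, 1, 2),
               tumor_radius = 5, ...)
}

# A random discretized lattice with levels 1..ng everywhere in a central
# blob mask (0 outside), seeded.
random_lattice <- function(dims = c(8L, 8L, 3L), ng = 4L, seed = 1) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
  border <- array(FALSE, dim = dims)
  lev[border] <- 0L
  lev
}

# 1D lattice helper.
lat1d <- function(v) array(as.integer(v), dim = c(length(v), 1L, 1L))

derive_seed_pub <- radscore:::derive_seed
with_seed_pub <- radscore:::with_seed

skew_sample <- function(x) {
  m2 <- mean((x - mean(x))^2)
  mean((x - mean(x))^3) / m2^1.5
}
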