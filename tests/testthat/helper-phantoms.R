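# Shared fixtures and independent oracles, built in code at test time.

# uniform-cost edge field for a given grid
uniform_costs <- function(grid, cost = 1L) {
  grid <- as.integer(grid)
  mk <- function(d) array(cost, dim = pmax(d, 0L))
  edge_field(mk(c(grid[1] - 1L, grid[2], grid[3])),
             mk(c(grid[1], grid[2] - 1L, grid[3])),
             mk(c(grid[1], grid[2], grid[3] - 1L)), kind = "cost")
}

# small smooth 3D truth: separable cosine ramp scaled to a target number
# of cycles end-to-end, then capped so 6-neighbour steps stay below
# `max_step` (benign, exactly recoverable input)
smooth_truth <- function(grid, cycles = 3, max_step = 2.8) {
  u <- lapply(grid, function(n) seq(0, 1, length.out = n))
  f <- (sin(pi * u[[1]]) %o% sin(pi * u[[2]]) %o% sin(pi * u[[3]])) +
    0.5 * (u[[1]] %o% rep(1, grid[2]) %o% rep(1, grid[3]))
  f <- f - min(f)
  f <- f / max(f) * 2 * pi * cycles
  worst <- 0
  for (ax in 1:3) {
    if (grid[ax] < 2) next
    ep <- phasetree:::edge_endpoints(f, ax)
    if (length(ep$i)) worst <- max(worst, max(abs(ep$i - ep$j)))
  }
  if (worst > max_step) f <- f * (max_step / worst)
  f
}

# read a NIfTI back as a bare array (no header/pointer attributes)
nifti_array <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(as.vector(a), dim = dim(a))
}

# oracle 1: sequential cumulative rewrap along a 1D line
cumulative_unwrap_1d <- function(phi) {
  th <- phi
  for (i in seq_along(phi)[-1]) {
    th[i] <- phi[i] - 2 * pi * round((phi[i] - th[i - 1]) / (2 * pi))
  }
  th
}

# oracle 2: Prim by exhaustive edge scan (no bucket queue), independent of
# the compiled path. `costs` is an edge_field; returns unwrapped theta
# anchored at the given seed's wrapped value.
exhaustive_mst_unwrap <- function(phase, costs, seed = 1L) {
  g <- dim(phase)
  nvox <- prod(g)
  # enumerate edges: matrix of (a, b, cost), linear voxel indices
  edges <- NULL
  lin <- array(seq_len(nvox), dim = g)
  axes <- list(costs$x, costs$y, costs$z)
  for (ax in 1:3) {
    n <- g[ax]
    if (n < 2L) next
    idx1 <- idx2 <- rep(list(quote(expr = )), 3L)
    idx1[[ax]] <- 1:(n - 1L); idx2[[ax]] <- 2:n
    a <- as.vector(do.call(`[`, c(list(lin), idx1, list(drop = FALSE))))
    b <- as.vector(do.call(`[`, c(list(lin), idx2, list(drop = FALSE))))
    edges <- rbind(edges, cbind(a, b, as.vector(axes[[ax]])))
  }
  edges <- edges[edges[, 3] > 0, , drop = FALSE]
  th <- as.vector(phase)
  visited <- rep(FALSE, nvox)
  visited[seed] <- TRUE
  for (step in seq_len(nvox - 1L)) {
    frontier <- xor(visited[edges[, 1]], visited[edges[, 2]])
    if (!any(frontier)) break
    cand <- edges[frontier, , drop = FALSE]
    e <- cand[which.min(cand[, 3]), ]
    new <- if (visited[e[1]]) e[2] else e[1]
    ref <- if (visited[e[1]]) e[1] else e[2]
    th[new] <- th[new] - 2 * pi * round((th[new] - th[ref]) / (2 * pi))
    visited[new] <- TRUE
  }
  array(th, dim = g)
}

# congruence residual: distance of (theta - phase) from the 2*pi lattice
congruence_residual <- function(theta, phase) {
  d <- (theta - phase) / (2 * pi)
  max(abs(d - round(d)))
}

# equality up to one global 2*pi*k over a region
expect_equal_mod_2pi <- function(a, b, mask = NULL, tol = 1e-8) {
  d <- a - b
  if (!is.null(mask)) d <- d[mask]
  k <- round(median(d) / (2 * pi))
  expect_lt(max(abs(d - 2 * pi * k)), tol)
}

# tiny default phantom used by several files
tiny_phantom <- function(grid = c(16, 16, 16), amplitude_hz = 150,
                         noise_fraction = 0, seed = 1, ...) {
  f <- make_topography(grid, amplitude_hz = amplitude_hz, rng_seed = seed)
  simulate_echoes(f, noise_fraction = noise_fraction, rng_seed = seed, ...)
}
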