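# Shared fixtures: small lattices and populations built in code.

# memoized small lattices (built once per test run)
.fixture_env <- new.env()

fixture_lattice <- function(n = 8L, spacing = 16.8, jitter = 0.25,
                            seed = 1L) {
  key <- paste(n, spacing, jitter, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_lattice(n, spacing, jitter, seed = seed)
  .fixture_env[[key]]
}

# population occupying an explicit set of sites, all cycling at stage 0
fixture_population <- function(lattice, sites, cycle = cycle_params()) {
  pop <- new_population(lattice, 1L, cycle, seed = 1L)
  # reset and occupy the requested sites
  pop$occupancy[] <- 0L
  n <- length(sites)
  pop$state <- rep(CELL_CYCLING, max(64L, 2L * n))
  pop$M <- rep(0L, max(64L, 2L * n))
  pop$site1 <- c(sites, rep(0L, max(64L, 2L * n) - n))
  pop$site2 <- rep(0L, max(64L, 2L * n))
  pop$n_exp <- rep(0, max(64L, 2L * n))
  pop$t_birth <- rep(0, max(64L, 2L * n))
  pop$n_cells <- n
  pop$occupancy[sites] <- seq_len(n)
  pop$births <- 0L; pop$deaths <- 0L; pop$lyses <- 0L
  pop
}

# all interior (non-boundary) sites within `radius_sites` hops-equivalent
# euclidean distance of the box center: a compact ball
ball_sites <- function(lattice, radius_sites) {
  ctr <- colMeans(lattice$box)
  d <- sqrt(colSums((t(lattice$positions) - ctr)^2))
  which(d <= radius_sites * lattice$spacing & !lattice$boundary)
}

# default simulation context for direct calls of the cell operations
fixture_ctx <- function(lattice, spec = model_spec(variant = 2),
                        ecm_ok = NULL, push_cap = 15L) {
  list(spec = spec,
       ecm_ok = ecm_ok %||% rep(TRUE, lattice$n_sites),
       push_cap = push_cap, p_re_scale = 1, t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
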