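#' Nutrient conditions of the growth experiments
#'
#' The four glucose/oxygen medium combinations: I (1 mM / 0.28 mM,
#' hyponourished), II (5 / 0.28, physiological), III (25 / 0.28,
#' hypernourished), IV (25 / 0.07, hypoxic).
#' @param name `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return named vector `c(G =, O =)` in mM.
#' @export
nutrient_condition <- function(name) {
  tbl <- list(I = c(G = 1, O = 0.28), II = c(G = 5, O = 0.28),
              III = c(G = 25, O = 0.28), IV = c(G = 25, O = 0.07))
  if (!name %in% names(tbl)) stop("unknown condition: ", name)
  tbl[[name]]
}

#' Assemble a simulation configuration
#'
#' Collects every tunable of a run: the nutrient condition, the growth
#' control variant with its thresholds, cell-cycle, metabolic and diffusion
#' parameters, the lattice and field-grid geometry, time stepping and seed.
#' `k_div_max` of the model spec is tied to the cycle time `1/tau`.
#'
#' @param condition one of `"I"`..`"IV"`, or `NULL` when `medium` is given.
#' @param medium named vector `c(G =, O =)` (mM); overrides `condition`.
#' @param variant growth-control variant 1-4.
#' @param model a [model_spec()]; built from `variant` by default.
#' @param cycle a [cycle_params()].
#' @param metabolic a [metabolic_params()].
#' @param diffusion a [diffusion_params()].
#' @param n_initial initial cell count (desk-scale default 500; the
#'   reference experiments start from ~10000 cells).
#' @param t_end simulated time (h).
#' @param dt_field field-update interval (h); the molecular fields are
#'   relaxed to steady state this often and all rates refreshed.
#' @param output_every growth-curve sampling interval (h).
#' @param profile_times times (h) at which radial profiles are recorded.
#' @param lattice list with `n_per_dim`, `spacing`, `jitter`.
#' @param grid_factor field-grid spacing in units of the lattice spacing.
#' @param push_cap maximal pushing distance (hops).
#' @param migration list `rate` (1/h), `mode` (`"unbiased"`/`"biased"`),
#'   `J`, `FT`.
#' @param solver list `tol`, `max_iter` for the field solves.
#' @param seed integer seed (lattice, initial stages and event stream).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(condition = "III", medium = NULL,
                              variant = 4L, model = NULL,
                              cycle = cycle_params(),
                              metabolic = metabolic_params(),
                              diffusion = diffusion_params(),
                              n_initial = 800L, t_end = 216,
                              dt_field = 0.1, output_every = 6,
                              profile_times = numeric(0),
                              lattice = list(n_per_dim = 34L,
                                             spacing = 16.8, jitter = 0.25),
                              grid_factor = 1, push_cap = 15L,
                              migration = list(rate = 0, mode = "unbiased",
                                               J = 0, FT = 1),
                              solver = list(tol = 1e-8, max_iter = 200L),
                              seed = 1L) {
  if (is.null(medium)) medium <- nutrient_condition(condition)
  if (is.null(model)) model <- model_spec(variant = variant,
                                          k_div_max = cycle$k_div_max)
  else model$k_div_max <- cycle$k_div_max
  if (t_end <= 0) stop("t_end must be positive")
  if (dt_field <= 0) stop("dt_field must be positive")
  structure(list(condition = condition, medium = medium, model = model,
                 cycle = cycle, metabolic = metabolic,
                 diffusion = diffusion, n_initial = as.integer(n_initial),
                 t_end = t_end, dt_field = dt_field,
                 output_every = output_every, profile_times = profile_times,
                 lattice = lattice, grid_factor = grid_factor,
                 push_cap = as.integer(push_cap), migration = migration,
                 solver = solver, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Set up lattice, population and fields for a run
#'
#' Builds the lattice, seeds a compact desynchronized ball of cycling cells
#' at its center and initializes all fields at their medium/boundary values
#' (the first field update of [run_simulation()] replaces them by the
#' steady state).
#'
#' @param config a [simulation_config()].
#' @return list with `lattice`, `pop`, `grid`, `state`.
#' @export
initialize_simulation <- function(config) {
  lat <- build_lattice(config$lattice$n_per_dim, config$lattice$spacing,
                       config$lattice$jitter, seed = config$seed)
  pop <- new_population(lat, config$n_initial, config$cycle,
                        seed = config$seed + 1L)
  grid <- field_grid(lat, factor = config$grid_factor,
                     medium = config$medium)
  z <- array(0, grid$dims)
  state <- structure(list(G = array(config$medium[["G"]], grid$dims),
                          O = array(config$medium[["O"]], grid$dims),
                          L = z, ECM = z, W = z, sigma = z, sigma_d = z,
                          phi = z, phi_d = z,
                          mask = array(FALSE, grid$dims)),
                     class = "field_state")
  list(lattice = lat, pop = pop, grid = grid, state = state)
}

# per-site context for one field window: division/death rates, ECM gate and
# exposure flag evaluated at every lattice site by trilinear interpolation
make_site_context <- function(lattice, grid, state, config) {
  if (is.null(grid$cache$site_stencil))
    grid$cache$site_stencil <- interp_stencil(grid, lattice$positions)
  loc <- interp_fields(grid, state, lattice$positions,
                       stencil = grid$cache$site_stencil)
  p_atp <- atp_production(loc$G, loc$O, config$metabolic)
  spec <- config$model
  list(spec = spec,
       kdiv_site = k_div(loc, p_atp, spec),
       knec_site = k_nec(loc, p_atp, spec),
       ecm_ok = loc$ECM >= spec$ECM_min,
       exp_flag = as.numeric(1 - heaviside(spec$W_max - loc$W) *
                               heaviside(loc$O - spec$O_min)),
       push_cap = config$push_cap,
       p_re_scale = config$cycle$p_re,
       t = NA_real_)
}

# total event rate of one cell under the current site context
cell_rate <- function(pop, lattice, id, ctx, cycle, mig) {
  st <- pop$state[id]
  if (is.na(st) || st == CELL_LYSED) return(0)
  if (st == CELL_DYING) return(cycle$k_lys)
  s <- pop$site1[id]
  r <- ctx$knec_site[s] + cycle$k_apt
  if (st == CELL_CYCLING) r <- r + cycle$m_d * ctx$kdiv_site[s]
  if (st == CELL_QUIESCENT && cycle$k_re * cycle$p_re > 0)
    r <- r + cycle$k_re
  if (mig$rate > 0 && pop$site2[id] == 0L)
    r <- r + migration_rate(pop, lattice, id, mig)
  r
}

#' Total migration rate of a one-site cell
#'
#' Unbiased mode: `lambda * n_free / n`; biased mode: the sum over free
#' neighbors of `lambda / n * exp(-dE / F_T)` with the adhesion energy
#' change `dE` of the hop.  Used both by the event loop and as the
#' generator of the migration master equation in tests.
#' @param pop,lattice population and lattice.
#' @param id cell id (one site).
#' @param mig migration settings (list `rate`, `mode`, `J`, `FT`).
#' @export
migration_rate <- function(pop, lattice, id, mig) {
  s <- pop$site1[id]
  nb <- neighbors(lattice, s)
  free_nb <- nb[pop$occupancy[nb] == 0L & !lattice$boundary[nb]]
  if (length(free_nb) == 0L) return(0)
  base <- mig$rate / length(nb)
  if (identical(mig$mode, "biased") && mig$J != 0) {
    contacts <- function(site) {
      nb2 <- neighbors(lattice, site)
      sum(pop$occupancy[nb2] != 0L & pop$occupancy[nb2] != id)
    }
    e_now <- -mig$J * contacts(s)
    base * sum(vapply(free_nb, function(tg)
      exp(-(-mig$J * contacts(tg) - e_now) / mig$FT), numeric(1)))
  } else {
    base * length(free_nb)
  }
}

# vectorized initial rate computation for all cells
all_cell_rates <- function(pop, lattice, ctx, cycle, mig) {
  n <- pop$n_cells
  r <- numeric(length(pop$state))
  st <- pop$state[seq_len(n)]
  s1 <- pop$site1[seq_len(n)]
  live <- !is.na(st) & st != CELL_LYSED
  dy <- which(live & st == CELL_DYING)
  vi <- live & st != CELL_DYING
  r[dy] <- cycle$k_lys
  idx <- which(vi)
  r[idx] <- ctx$knec_site[s1[idx]] + cycle$k_apt
  cyc <- which(vi & st == CELL_CYCLING)
  r[cyc] <- r[cyc] + cycle$m_d * ctx$kdiv_site[s1[cyc]]
  if (cycle$k_re * cycle$p_re > 0) {
    qui <- which(vi & st == CELL_QUIESCENT)
    r[qui] <- r[qui] + cycle$k_re
  }
  if (mig$rate > 0) {
    one <- which(vi & pop$site2[seq_len(n)] == 0L)
    for (i in one) r[i] <- r[i] + migration_rate(pop, lattice, i, mig)
  }
  r
}

# process stochastic events within one field window [t0, t1); rates frozen
# at the window-start context except for state/site changes of the cells
# themselves. Returns updated time and bookkeeping.
simulate_window <- function(pop, lattice, ctx, cycle, mig, t0, t1,
                            counters) {
  rates <- all_cell_rates(pop, lattice, ctx, cycle, mig)
  total <- sum(rates)
  t <- t0
  refresh <- function(ids) {
    for (i in ids) {
      old <- rates[i]
      new <- cell_rate(pop, lattice, i, ctx, cycle, mig)
      rates[i] <<- new
      total <<- total + (new - old)
    }
  }
  neighbors_of_sites <- function(sites) {
    occ <- unique(unlist(lapply(sites, function(s)
      pop$occupancy[neighbors(lattice, s)])))
    occ[occ != 0L]
  }
  while (TRUE) {
    if (total <= 1e-12) break
    dt <- rexp(1L, total)
    if (t + dt > t1) break
    t <- t + dt
    counters$events <- counters$events + 1L
    n <- pop$n_cells
    i <- sample.int(n, 1L, prob = rates[seq_len(n)])
    st <- pop$state[i]
    s <- pop$site1[i]
    u <- runif(1L) * rates[i]
    affected_sites <- integer(0)
    if (st == CELL_DYING) {
      freed <- c(s, pop$site2[i])
      lyse_cell(pop, i)
      affected_sites <- freed[freed != 0L]
      refresh(i)
    } else {
      acc <- ctx$knec_site[s] + cycle$k_apt
      if (u < acc) {                      # death (necrosis or apoptosis)
        die_cell(pop, i)
        refresh(i)
      } else {
        stage_rate <- if (st == CELL_CYCLING)
          cycle$m_d * ctx$kdiv_site[s] else 0
        if (st == CELL_CYCLING && u < acc + stage_rate) {
          # one stage transition; a full cycle is exactly m_d transitions
          # (growth is a side-effect of reaching stage m_g, retried while
          # no free site is reachable)
          M <- pop$M[i]
          try_grow <- function() {
            okg <- grow_cell(pop, lattice, i, ctx$push_cap)
            if (isTRUE(c(okg))) {
              moved <- attr(okg, "moved_sites")
              affected_sites <<- moved
              pushed <- unique(pop$occupancy[moved])
              refresh(unique(c(i, pushed[pushed != 0L & pushed != i])))
              TRUE
            } else FALSE
          }
          if (M == cycle$m_d - 1L) {
            if (pop$site2[i] == 0L) try_grow()   # only when m_g == m_d
            if (pop$site2[i] != 0L) {
              ctx$t <- t
              kids <- divide_cell(pop, lattice, i, ctx)
              if (length(rates) < length(pop$state))
                rates <- c(rates,
                           numeric(length(pop$state) - length(rates)))
              refresh(kids)
            }
          } else if (M + 1L == cycle$m_g && pop$site2[i] == 0L) {
            if (try_grow()) pop$M[i] <- cycle$m_g
          } else {
            pop$M[i] <- M + 1L
            refresh(i)
          }
        } else if (st == CELL_QUIESCENT) {  # re-entry probe
          reenter_quiescent(pop, lattice, i, ctx)
          refresh(i)
        } else {                            # migration
          old_site <- s
          tgt <- migrate_cell(pop, lattice, i, mode = mig$mode,
                              J = mig$J, FT = mig$FT)
          if (!is.na(tgt)) {
            affected_sites <- c(old_site, tgt)
            refresh(i)
          }
        }
      }
    }
    if (mig$rate > 0 && length(affected_sites)) {
      affected_sites <- affected_sites[affected_sites != 0L]
      refresh(setdiff(neighbors_of_sites(affected_sites), i))
    }
    if (isTRUE(getOption("spheroidsim.audit_events")))
      check_occupancy(pop, t)
  }
  # audit: recompute every cell's rate from scratch and compare with the
  # incrementally maintained total
  fresh <- sum(all_cell_rates(pop, lattice, ctx, cycle, mig))
  audit <- abs(fresh - total) / max(fresh, .Machine$double.eps)
  counters$audit_max <- max(counters$audit_max, audit)
  check_occupancy(pop, t1)
  invisible(t1)
}

# occupancy exclusivity / ownership audit; cheap enough to run per window
check_occupancy <- function(pop, t) {
  n <- pop$n_cells
  st <- pop$state[seq_len(n)]
  live <- which(st != CELL_LYSED)
  claimed <- c(pop$site1[live], pop$site2[live])
  claimed <- claimed[claimed > 0L]
  occ_sites <- which(pop$occupancy != 0L)
  owners1 <- pop$occupancy[pop$site1[live]]
  ok <- anyDuplicated(claimed) == 0L &&
    length(claimed) == length(occ_sites) &&
    all(owners1 == live)
  if (!ok)
    stop(sprintf(
      "occupancy bookkeeping violated at t = %.3f h (%d claims, %d occupied, %d orphans)",
      t, length(claimed), length(occ_sites), sum(owners1 != live)))
  invisible(TRUE)
}

#' Run a full spheroid growth simulation
#'
#' Alternates exact stochastic cell events within each field window with a
#' steady-state refresh of all molecular fields at the window boundaries
#' (operator splitting: cellular dynamics are orders of magnitude slower
#' than molecular relaxation).  Per-cell rates are frozen at the
#' window-start field values and refreshed whenever a cell's own state or
#' sites change.  Fully reproducible given the seed.
#'
#' @param config a [simulation_config()].
#' @param verbose print a summary line per output interval.
#' @return object of class `spheroid_run`: `curve` (data.frame time,
#'   counts, radius, diagnostics), `profiles` (named list of
#'   [radial_profile()]s), final `pop`, `state`, `lattice`, `grid`,
#'   `counters` and `provenance`.
#' @export
run_simulation <- function(config, verbose = FALSE) {
  ini <- initialize_simulation(config)
  lat <- ini$lattice; pop <- ini$pop; grid <- ini$grid
  capacity <- sum(!lat$boundary)
  counters <- new.env(parent = emptyenv())
  counters$events <- 0L
  counters$audit_max <- 0
  set.seed(config$seed + 2L)
  state <- update_fields(grid, ini$state, pop, lat, config$metabolic,
                         config$diffusion, config$solver$tol,
                         config$solver$max_iter)
  ctx <- make_site_context(lat, grid, state, config)
  mig <- config$migration
  curve <- list()
  profiles <- list()
  record <- function(t) {
    cc <- population_counts(pop)
    curve[[length(curve) + 1L]] <<- data.frame(
      time = t, n_cycling = cc[["cycling"]],
      n_quiescent = cc[["quiescent"]], n_dying = cc[["dying"]],
      n_lysed = cc[["lysed"]],
      radius = spheroid_radius(pop, lat),
      min_O = min(state$O), max_L = max(state$L),
      max_W = max(state$W),
      solver_iterations = state$iterations %||% NA_integer_)
    if (verbose) {
      r <- curve[[length(curve)]]
      message(sprintf(
        "t=%6.1f h  N=%5d (cyc %4d qui %4d dyi %4d lys %4d)  r=%6.1f um  minO=%.4f  maxL=%.2f",
        t, sum(cc) - cc[["lysed"]], cc[["cycling"]], cc[["quiescent"]],
        cc[["dying"]], cc[["lysed"]], r$radius, r$min_O, r$max_L))
    }
  }
  record(0)
  next_output <- config$output_every
  pending_profiles <- sort(config$profile_times)
  t <- 0
  while (t < config$t_end - 1e-9) {
    t1 <- min(t + config$dt_field, config$t_end)
    simulate_window(pop, lat, ctx, config$cycle, mig, t, t1, counters)
    t <- t1
    # cumulative waste/hypoxia exposure, in nominal cell-cycle units
    n <- pop$n_cells
    viable <- which(pop$state[seq_len(n)] %in% c(CELL_CYCLING,
                                                 CELL_QUIESCENT))
    if (length(viable)) {
      fl <- ctx$exp_flag[pop$site1[viable]]
      racc <- if (config$model$exposure_clock == "local")
        ctx$kdiv_site[pop$site1[viable]] else 1 / config$cycle$tau
      pop$n_exp[viable] <- pop$n_exp[viable] + fl * racc * config$dt_field
    }
    occ_n <- sum(pop$occupancy != 0L)
    if (occ_n > 0.95 * capacity)
      stop(sprintf(
        "lattice capacity overflow at t=%.1f h: %d of %d interior sites occupied",
        t, occ_n, capacity))
    state <- update_fields(grid, state, pop, lat, config$metabolic,
                           config$diffusion, config$solver$tol,
                           config$solver$max_iter)
    ctx <- make_site_context(lat, grid, state, config)
    if (t >= next_output - 1e-9) {
      record(t)
      next_output <- next_output + config$output_every
    }
    while (length(pending_profiles) && t >= pending_profiles[1L] - 1e-9) {
      profiles[[sprintf("%g", pending_profiles[1L])]] <-
        radial_profile(pop, lat, grid, state)
      pending_profiles <- pending_profiles[-1L]
    }
  }
  structure(list(
    config = config, lattice = lat, grid = grid, pop = pop, state = state,
    curve = do.call(rbind, curve), profiles = profiles,
    counters = list(events = counters$events,
                    audit_max = counters$audit_max,
                    births = pop$births, deaths = pop$deaths,
                    lyses = pop$lyses),
    provenance = list(seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("spheroidsim")),
                      r_version = R.version.string,
                      condition = config$condition,
                      variant = config$model$variant,
                      n_initial = config$n_initial,
                      t_end = config$t_end)),
    class = "spheroid_run")
}

#' @export
print.spheroid_run <- function(x, ...) {
  cc <- population_counts(x$pop)
  cat(sprintf(
    "spheroid_run: variant %d, condition %s, %g h, %d events\n",
    x$config$model$variant, x$config$condition %||% "custom",
    x$config$t_end, x$counters$events))
  cat(sprintf("  final: %d viable cells, radius %.1f um\n",
              cc[["cycling"]] + cc[["quiescent"]],
              tail(x$curve$radius, 1L)))
  invisible(x)
}

#' Number of fitted parameters attributed to a model variant
#'
#' Used for the AIC penalty; the differences between variants (0, +2, +9
#' going from the ATP model to the lactate and waste extensions) mirror the
#' nesting structure of the variants, which is all that matters for model
#' ordering.
#' @param spec a [model_spec()].
#' @export
model_k <- function(spec) {
  switch(spec$variant, 8L, 8L, 10L, 17L)
}

#' Score a run against reference growth curves
#'
#' Interpolates the simulated radius curve onto the reference time points
#' and evaluates the Gaussian log-likelihood and AIC.
#' @param result a `spheroid_run`.
#' @param reference data.frame with columns `x` (time, h), `mu` (radius,
#'   um), `sigma` (> 0).
#' @return a [fit_result()].
#' @export
compare_runs <- function(result, reference) {
  if (is.null(reference$x) || is.null(reference$mu) ||
      is.null(reference$sigma))
    stop("reference must have columns x, mu, sigma")
  score_against_reference(
    curves = list(radius = data.frame(x = result$curve$time,
                                      value = result$curve$radius)),
    references = list(radius = reference),
    k = model_k(result$config$model))
}
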