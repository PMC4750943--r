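#' Cell state codes
#'
#' Integer codes used in the population vectors: cycling (1), quiescent
#' (2), dying (3), lysed (4).
#' @name cell_states
#' @export
CELL_CYCLING <- 1L
#' @rdname cell_states
#' @export
CELL_QUIESCENT <- 2L
#' @rdname cell_states
#' @export
CELL_DYING <- 3L
#' @rdname cell_states
#' @export
CELL_LYSED <- 4L

#' Cell-cycle parameters
#'
#' The cell cycle is split into `m_d` Poisson stages, each advancing at rate
#' `m_d * k_div`, so the total cycle time is Erlang(`m_d`) with mean
#' `tau = 1/k_div` and coefficient of variation `1/sqrt(m_d)`.  Growth to
#' two lattice sites happens at stage `m_g`; division back to two one-site
#' daughters at the `m_d`-th transition.
#'
#' @param m_d number of cycle stages.
#' @param m_g growth stage (1 <= m_g <= m_d).
#' @param tau expected cycle time (h) under permissive conditions.
#' @param k_re,p_re quiescence exit probing rate (1/h) and probability;
#'   their product is 0 by default (quiescence permanent).
#' @param k_apt apoptosis rate (1/h); 0 by default (negligible for this
#'   system).
#' @param k_lys lysis rate of dying cells (1/h); in vitro value ~0.01/h (no
#'   macrophages to clear debris).
#' @return object of class `cycle_params`.
#' @export
cycle_params <- function(m_d = 10L, m_g = 5L, tau = 24, k_re = 0, p_re = 0,
                         k_apt = 0, k_lys = 0.01) {
  m_d <- as.integer(m_d); m_g <- as.integer(m_g)
  if (m_g < 1L || m_g > m_d) stop("need 1 <= m_g <= m_d")
  if (tau <= 0) stop("tau must be positive")
  if (any(c(k_re, p_re, k_apt, k_lys) < 0)) stop("rates must be >= 0")
  structure(list(m_d = m_d, m_g = m_g, tau = tau, k_div_max = 1 / tau,
                 k_re = k_re, p_re = p_re, k_apt = k_apt, k_lys = k_lys),
            class = "cycle_params")
}

#' Create a cell population
#'
#' Populations are environments (modified in place by the event operations,
#' which is what an event loop needs).  `new_population()` seeds a compact
#' ball of `n_init` cycling cells around the box center, with cycle stages
#' drawn uniformly (a desynchronized population, as after spheroid
#' formation).  Boundary (medium) sites are never occupied.
#'
#' @param lattice a `spheroid_lattice`.
#' @param n_init initial cell count.
#' @param cycle a [cycle_params()].
#' @param seed integer seed for the stage randomization.
#' @return object of class `cell_population` (an environment with vectors
#'   `state`, `M`, `site1`, `site2`, `n_exp`, `t_birth`, the site
#'   `occupancy` map and the census counters).
#' @export
new_population <- function(lattice, n_init, cycle = cycle_params(),
                           seed = 1L) {
  ok <- which(!lattice$boundary)
  if (n_init > length(ok)) stop("initial population exceeds lattice capacity")
  ctr <- colMeans(lattice$box)
  d2 <- colSums((t(lattice$positions[ok, , drop = FALSE]) - ctr)^2)
  sites <- ok[order(d2)[seq_len(n_init)]]
  pop <- new.env(parent = emptyenv())
  cap <- max(64L, 2L * n_init)
  pop$state <- rep(NA_integer_, cap)
  pop$M <- rep(NA_integer_, cap)
  pop$site1 <- rep(0L, cap)
  pop$site2 <- rep(0L, cap)
  pop$n_exp <- rep(NA_real_, cap)
  pop$t_birth <- rep(NA_real_, cap)
  n <- length(sites)
  pop$state[seq_len(n)] <- CELL_CYCLING
  pop$M[seq_len(n)] <- with_seed(seed, {
    sample.int(cycle$m_d, n, replace = TRUE) - 1L
  })
  pop$site1[seq_len(n)] <- sites
  pop$n_exp[seq_len(n)] <- 0
  pop$t_birth[seq_len(n)] <- 0
  pop$n_cells <- n
  pop$occupancy <- integer(lattice$n_sites)
  pop$occupancy[sites] <- seq_len(n)
  pop$births <- 0L
  pop$deaths <- 0L
  pop$lyses <- 0L
  class(pop) <- "cell_population"
  pop
}

grow_capacity <- function(pop, need) {
  cap <- length(pop$state)
  if (need <= cap) return(invisible(pop))
  new_cap <- max(need, 2L * cap)
  pad_i <- rep(NA_integer_, new_cap - cap)
  pad_d <- rep(NA_real_, new_cap - cap)
  pop$state <- c(pop$state, pad_i)
  pop$M <- c(pop$M, pad_i)
  pop$site1 <- c(pop$site1, rep(0L, new_cap - cap))
  pop$site2 <- c(pop$site2, rep(0L, new_cap - cap))
  pop$n_exp <- c(pop$n_exp, pad_d)
  pop$t_birth <- c(pop$t_birth, pad_d)
  invisible(pop)
}

#' @export
print.cell_population <- function(x, ...) {
  cc <- population_counts(x)
  cat("cell_population:", x$n_cells, "cells (",
      paste(names(cc), cc, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Census of a population by state
#' @param pop a `cell_population`.
#' @return named integer vector (cycling, quiescent, dying, lysed).
#' @export
population_counts <- function(pop) {
  st <- pop$state[seq_len(pop$n_cells)]
  c(cycling = sum(st == CELL_CYCLING), quiescent = sum(st == CELL_QUIESCENT),
    dying = sum(st == CELL_DYING), lysed = sum(st == CELL_LYSED))
}

#' Cell table of a population
#' @param x a `cell_population`.
#' @param ... unused.
#' @export
as.data.frame.cell_population <- function(x, ...) {
  n <- x$n_cells
  data.frame(id = seq_len(n),
             state = c("cycling", "quiescent", "dying",
                       "lysed")[x$state[seq_len(n)]],
             M = x$M[seq_len(n)], site1 = x$site1[seq_len(n)],
             site2 = x$site2[seq_len(n)], n_exp = x$n_exp[seq_len(n)],
             t_birth = x$t_birth[seq_len(n)])
}

#' One draw of the stochastic simulation algorithm
#'
#' Given the per-event rates, draws the exponential waiting time
#' `dt ~ Exp(sum(rates))` and the event index with probability proportional
#' to its rate.  Returns `NULL` when no event is enabled (total rate zero):
#' the simulation halt signal.
#'
#' @param rates non-negative numeric vector of event rates (1/h).
#' @return `list(index, dt)` or `NULL`.
#' @export
gillespie_step <- function(rates) {
  if (any(rates < 0)) stop("rates must be non-negative")
  total <- sum(rates)
  if (total <= 0) return(NULL)
  list(index = sample.int(length(rates), 1L, prob = rates),
       dt = rexp(1L, total))
}

#' Grow a cell to two lattice sites, pushing neighbors if needed
#'
#' At its growth stage a cell occupies an adjacent site.  If all neighbors
#' are occupied, the chain of cells along the (deterministic, smallest-index
#' tie-broken) shortest path to the nearest free interior site is shifted
#' outward by one site each, and the freed neighbor is taken.  Returns
#' `FALSE` (growth deferred) when no free site is reachable within
#' `push_cap` hops; occupancy exclusivity is preserved in all cases.
#'
#' @param pop a `cell_population`.
#' @param lattice the lattice.
#' @param id cell id (cycling, one site).
#' @param push_cap maximal pushing distance (hops).
#' @return logical success flag; on success the set of sites whose occupant
#'   changed is attached as attribute `"moved_sites"`.
#' @export
grow_cell <- function(pop, lattice, id, push_cap = 15L) {
  if (pop$state[id] != CELL_CYCLING) stop("grow: cell is not cycling")
  if (pop$site2[id] != 0L) stop("grow: cell already occupies two sites")
  s <- pop$site1[id]
  nb <- neighbors(lattice, s)
  free_nb <- nb[pop$occupancy[nb] == 0L & !lattice$boundary[nb]]
  if (length(free_nb) > 0L) {
    tgt <- if (length(free_nb) == 1L) free_nb
           else free_nb[sample.int(length(free_nb), 1L)]
    pop$site2[id] <- tgt
    pop$occupancy[tgt] <- id
    return(structure(TRUE, moved_sites = tgt))
  }
  res <- nearest_free_path(lattice, pop$occupancy, s, push_cap,
                           target_ok = !lattice$boundary)
  if (res$dist < 0) return(FALSE)
  path <- res$path   # s, ..., free site
  touched <- path[-1L]
  # shift occupants outward, starting from the free end
  for (k in seq.int(length(path) - 1L, 2L)) {
    mover <- pop$occupancy[path[k]]
    dest <- path[k + 1L]
    if (pop$site1[mover] == path[k]) pop$site1[mover] <- dest
    else pop$site2[mover] <- dest
    pop$occupancy[dest] <- mover
  }
  pop$site2[id] <- path[2L]
  pop$occupancy[path[2L]] <- id
  structure(TRUE, moved_sites = touched)
}

#' Divide a two-site cell into two daughters
#'
#' Each daughter keeps one of the parent sites and decides independently,
#' with probability `p_div` evaluated at its own site, whether to re-enter
#' the cycle (stage 0) or become quiescent.  The parent record becomes
#' daughter A; daughter B is appended.  The exposure counter is inherited.
#'
#' @param pop a `cell_population`.
#' @param lattice the lattice.
#' @param id dividing cell (at stage `m_d`, two sites).
#' @param ctx simulation context: list with `spec` (a [model_spec()]),
#'   `ecm_ok` (logical per site), `push_cap`, and time `t`.
#' @return integer vector with the two daughter ids.
#' @export
divide_cell <- function(pop, lattice, id, ctx) {
  if (pop$site2[id] == 0L) stop("divide: cell occupies a single site")
  grow_capacity(pop, pop$n_cells + 1L)
  sA <- pop$site1[id]; sB <- pop$site2[id]
  idB <- pop$n_cells + 1L
  pop$n_cells <- idB
  pop$births <- pop$births + 1L
  pop$site1[idB] <- sB
  pop$site2[idB] <- 0L
  pop$site2[id] <- 0L
  pop$occupancy[sB] <- idB
  pop$n_exp[idB] <- pop$n_exp[id]
  pop$t_birth[id] <- ctx$t %||% 0
  pop$t_birth[idB] <- ctx$t %||% 0
  for (dd in c(id, idB)) {
    s <- pop$site1[dd]
    # pushing distance: a cell with a free neighbor pushes nobody (L = 0)
    L <- distance_to_nearest_free(lattice, pop$occupancy, s,
                                  ctx$push_cap %||% 15L) - 1
    p <- p_div(L, ECM = if (ctx$ecm_ok[s]) 1 else 0,
               n_exp = pop$n_exp[dd], spec = ctx$spec)
    if (runif(1L) < p) {
      pop$state[dd] <- CELL_CYCLING
    } else {
      pop$state[dd] <- CELL_QUIESCENT
    }
    pop$M[dd] <- 0L
  }
  c(id, idB)
}

#' Cell death and lysis
#'
#' `die_cell()` moves a viable cell to the dying state (it keeps its sites
#' and becomes TUNEL-positive); `lyse_cell()` removes a dying cell,
#' freeing its lattice sites for reuse.
#' @param pop a `cell_population`.
#' @param id cell id.
#' @export
die_cell <- function(pop, id) {
  if (!pop$state[id] %in% c(CELL_CYCLING, CELL_QUIESCENT))
    stop("die: cell is not viable")
  pop$state[id] <- CELL_DYING
  pop$deaths <- pop$deaths + 1L
  invisible(pop)
}

#' @rdname die_cell
#' @export
lyse_cell <- function(pop, id) {
  if (pop$state[id] != CELL_DYING) stop("lyse: cell is not dying")
  for (s in c(pop$site1[id], pop$site2[id])) {
    if (s > 0L) pop$occupancy[s] <- 0L
  }
  pop$site1[id] <- 0L
  pop$site2[id] <- 0L
  pop$state[id] <- CELL_LYSED
  pop$lyses <- pop$lyses + 1L
  invisible(pop)
}

#' Re-entry of a quiescent cell into the cycle
#'
#' Applied when the quiescence-exit probe (rate `k_re`) fires: with
#' probability `p_re` -- same functional form as the division-entry
#' probability -- the cell returns to stage 0 of the cycle.  Disabled by
#' default (`p_re * k_re = 0`).
#'
#' @inheritParams divide_cell
#' @return logical: did the cell re-enter?
#' @export
reenter_quiescent <- function(pop, lattice, id, ctx) {
  if (pop$state[id] != CELL_QUIESCENT) stop("reenter: cell is not quiescent")
  s <- pop$site1[id]
  L <- distance_to_nearest_free(lattice, pop$occupancy, s,
                                ctx$push_cap %||% 15L) - 1
  p <- (ctx$p_re_scale %||% 1) *
    p_div(L, ECM = if (ctx$ecm_ok[s]) 1 else 0, n_exp = pop$n_exp[id],
          spec = ctx$spec)
  if (runif(1L) < p) {
    pop$state[id] <- CELL_CYCLING
    pop$M[id] <- 0L
    TRUE
  } else FALSE
}

#' Migrate a one-site cell to a free neighbor site
#'
#' Unbiased mode: a uniformly chosen free neighbor (the per-neighbor rate
#' `lambda/n` of a lattice random walk with `lambda = 6 D / l^2`).  Biased
#' mode: free neighbors are weighted by `exp(-dE / F_T)` where `dE` is the
#' change in adhesion energy `-J * (number of cell-cell contacts)` incurred
#' by the hop.
#'
#' @param pop a `cell_population`.
#' @param lattice the lattice.
#' @param id cell id (viable, one site).
#' @param mode `"unbiased"` or `"biased"`.
#' @param J adhesion energy per cell-cell contact (biased mode).
#' @param FT fluctuation energy scale (biased mode).
#' @return the new site index, or `NA_integer_` if no free neighbor exists
#'   (event disabled, not an error).
#' @export
migrate_cell <- function(pop, lattice, id, mode = c("unbiased", "biased"),
                         J = 0, FT = 1) {
  mode <- match.arg(mode)
  if (pop$site2[id] != 0L) stop("migrate: cell occupies two sites")
  s <- pop$site1[id]
  nb <- neighbors(lattice, s)
  free_nb <- nb[pop$occupancy[nb] == 0L & !lattice$boundary[nb]]
  if (length(free_nb) == 0L) return(NA_integer_)
  if (mode == "unbiased") {
    tgt <- if (length(free_nb) == 1L) free_nb
           else free_nb[sample.int(length(free_nb), 1L)]
  } else {
    contacts <- function(site, exclude) {
      nb2 <- neighbors(lattice, site)
      sum(pop$occupancy[nb2] != 0L & pop$occupancy[nb2] != exclude)
    }
    e_now <- -J * contacts(s, id)
    w <- vapply(free_nb, function(tg) {
      exp(-(-J * contacts(tg, id) - e_now) / FT)
    }, numeric(1))
    tgt <- if (length(free_nb) == 1L) free_nb
           else free_nb[sample.int(length(free_nb), 1L, prob = w)]
  }
  pop$occupancy[s] <- 0L
  pop$occupancy[tgt] <- id
  pop$site1[id] <- tgt
  tgt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
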