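# Agent dynamics: SSA kernel, cycle statistics, growth/pushing, division,
# death/lysis, migration.

test_that("gillespie_step: event weights, waiting times, halt signal", {
  set.seed(1)
  draws <- replicate(4000, gillespie_step(c(a = 1, b = 3))$index)
  expect_equal(mean(draws == 2L), 0.75, tolerance = 0.03)
  dts <- replicate(4000, gillespie_step(c(a = 1, b = 3))$dt)
  expect_equal(mean(dts), 0.25, tolerance = 0.02)
  # single-rate waiting times are exponential (KS test)
  set.seed(2)
  w <- replicate(10000, gillespie_step(c(r = 0.7))$dt)
  ks <- suppressWarnings(stats::ks.test(w, "pexp", rate = 0.7))
  expect_gt(ks$p.value, 0.01)
  expect_null(gillespie_step(c(0, 0)))
  expect_error(gillespie_step(c(-1, 2)), "non-negative")
  # determinism given the RNG state
  set.seed(3); s1 <- gillespie_step(c(1, 2, 3))
  set.seed(3); s2 <- gillespie_step(c(1, 2, 3))
  expect_identical(s1, s2)
})

# drive one cell through full cycles with the package event machinery and
# collect division times
sample_cycle_times <- function(n_cells, m_d, tau, seed) {
  lat <- fixture_lattice(5, seed = 1)
  cyc <- cycle_params(m_d = m_d, m_g = min(5L, m_d), tau = tau)
  ctr <- ball_sites(lat, 0.9)[1]
  times <- numeric(n_cells)
  set.seed(seed)
  ctx <- fixture_ctx(lat)
  for (i in seq_len(n_cells)) {
    pop <- fixture_population(lat, ctr, cyc)
    t <- 0
    repeat {
      # per-stage rate m_d * k_div; one stage transition per event
      t <- t + rexp(1, cyc$m_d / tau)
      M <- pop$M[1L]
      if (M == cyc$m_d - 1L) {
        if (pop$site2[1L] == 0L) grow_cell(pop, lat, 1L)
        if (pop$site2[1L] != 0L) break      # division fires here
      } else if (M + 1L == cyc$m_g && pop$site2[1L] == 0L) {
        ok <- grow_cell(pop, lat, 1L)
        if (isTRUE(c(ok))) pop$M[1L] <- cyc$m_g
      } else {
        pop$M[1L] <- M + 1L
      }
    }
    times[i] <- t
  }
  times
}

test_that("cycle times are Erlang(m_d) with mean tau and CV 1/sqrt(m_d)", {
  tau <- 24
  for (m_d in c(1L, 10L)) {
    tt <- sample_cycle_times(4000, m_d, tau, seed = 10 + m_d)
    expect_equal(mean(tt), tau, tolerance = 0.03)
    cv <- stats::sd(tt) / mean(tt)
    expect_equal(cv, 1 / sqrt(m_d), tolerance = 0.05)
  }
  # m_d = 1: exponential (CV 1 and KS against the exponential law)
  tt1 <- sample_cycle_times(3000, 1L, tau, seed = 31)
  ks <- suppressWarnings(stats::ks.test(tt1, "pexp", rate = 1 / tau))
  expect_gt(ks$p.value, 0.01)
})

test_that("growth: direct occupation, pushing chain, occupancy exclusivity", {
  lat <- build_lattice(9, 16.8, jitter = 0, seed = 1)
  ctr_site <- ball_sites(lat, 0.9)[1]
  # free neighbor exists: direct occupation
  pop <- fixture_population(lat, ctr_site)
  set.seed(5)
  ok <- grow_cell(pop, lat, 1L)
  expect_true(c(ok))
  expect_true(pop$site2[1L] %in% neighbors(lat, ctr_site))
  expect_equal(pop$occupancy[pop$site2[1L]], 1L)
  # full shell of thickness 2: pushing shifts cells along one path
  shell <- ball_sites(lat, 2.5)
  pop2 <- fixture_population(lat, shell)
  ctr2 <- shell[which.min(colSums((t(lat$positions[shell, ]) -
                                   colMeans(lat$box))^2))]
  id <- pop2$occupancy[ctr2]
  n_occ_before <- sum(pop2$occupancy != 0L)
  ok2 <- grow_cell(pop2, lat, id)
  expect_true(c(ok2))
  # total occupancy grows by exactly one site
  expect_equal(sum(pop2$occupancy != 0L), n_occ_before + 1L)
  # exclusivity: every site has at most one occupant and bookkeeping agrees
  occ_sites <- which(pop2$occupancy != 0L)
  claimed <- c(pop2$site1[seq_len(pop2$n_cells)],
               pop2$site2[seq_len(pop2$n_cells)])
  claimed <- claimed[claimed > 0L]
  expect_equal(sort(claimed), sort(occ_sites))
  expect_equal(anyDuplicated(claimed), 0L)
  # growth defers (returns FALSE) when no free site is reachable
  pop3 <- fixture_population(lat, shell)
  expect_false(c(grow_cell(pop3, lat, pop3$occupancy[ctr2],
                           push_cap = 1L)))
  expect_equal(pop3$site2[pop3$occupancy[ctr2]], 0L)
})

test_that("division: daughter states follow p_div, errors on 1-site cells", {
  lat <- fixture_lattice(6, seed = 2)
  site <- ball_sites(lat, 0.9)[1]
  ctx <- fixture_ctx(lat)
  # p_div = 1 at the border with ECM ok: both daughters cycling
  set.seed(6)
  pop <- fixture_population(lat, site)
  grow_cell(pop, lat, 1L)
  pop$M[1L] <- ctx$spec$variant   # value irrelevant to divide_cell
  kids <- divide_cell(pop, lat, 1L, ctx)
  expect_equal(length(kids), 2L)
  expect_true(all(pop$state[kids] == CELL_CYCLING))
  expect_true(all(pop$M[kids] == 0L))
  # ECM below the gate: both daughters quiescent
  pop2 <- fixture_population(lat, site)
  grow_cell(pop2, lat, 1L)
  ctx0 <- fixture_ctx(lat, ecm_ok = rep(FALSE, lat$n_sites))
  kids2 <- divide_cell(pop2, lat, 1L, ctx0)
  expect_true(all(pop2$state[kids2] == CELL_QUIESCENT))
  # dividing a one-site cell is a contract violation
  pop3 <- fixture_population(lat, site)
  expect_error(divide_cell(pop3, lat, 1L, ctx), "single site")
})

test_that("division entry frequencies follow the binomial of p_div", {
  # a dividing cell buried inside a solid ball: its daughters see an
  # intermediate p_div determined by their own pushing distances
  lat <- fixture_lattice(9, seed = 3)
  spec <- model_spec(variant = 2, dL = 5)
  ctx <- fixture_ctx(lat, spec = spec)
  sites <- ball_sites(lat, 3.2)
  ctr <- colMeans(lat$box)
  depth2 <- sites[order(abs(colSums((t(lat$positions[sites, ]) - ctr)^2) -
                            (1.5 * 16.8)^2))[1:2]]
  build <- function() {
    pop <- fixture_population(lat, setdiff(sites, depth2[2]))
    id <- pop$occupancy[depth2[1]]
    ok <- grow_cell(pop, lat, id, push_cap = 3L)
    stopifnot(isTRUE(c(ok)))
    list(pop = pop, id = id)
  }
  set.seed(7)
  bp <- build()
  La <- distance_to_nearest_free(lat, bp$pop$occupancy,
                                 bp$pop$site1[bp$id]) - 1
  Lb <- distance_to_nearest_free(lat, bp$pop$occupancy,
                                 bp$pop$site2[bp$id]) - 1
  expected <- (exp(-La / spec$dL) + exp(-Lb / spec$dL)) / 2
  expect_gt(expected, 0.05)
  expect_lt(expected, 0.999)
  n <- 2500
  cycling <- 0L
  for (k in seq_len(n)) {
    bp <- build()
    kids <- divide_cell(bp$pop, lat, bp$id, ctx)
    cycling <- cycling + sum(bp$pop$state[kids] == CELL_CYCLING)
  }
  frac <- cycling / (2 * n)
  expect_equal(frac, expected, tolerance = 0.05)
})

test_that("death and lysis transitions free sites and keep books", {
  lat <- fixture_lattice(6, seed = 4)
  sites <- ball_sites(lat, 1.4)
  pop <- fixture_population(lat, sites)
  id <- 1L
  expect_error(lyse_cell(pop, id), "not dying")
  die_cell(pop, id)
  expect_equal(pop$state[id], CELL_DYING)
  expect_error(die_cell(pop, id), "not viable")   # already dying
  s <- pop$site1[id]
  lyse_cell(pop, id)
  expect_equal(pop$state[id], CELL_LYSED)
  expect_equal(pop$occupancy[s], 0L)
  expect_equal(pop$site1[id], 0L)
  # freed site immediately reusable by a neighbor's growth
  nb_cells <- pop$occupancy[neighbors(lat, s)]
  nb_cells <- nb_cells[nb_cells != 0L]
  if (length(nb_cells)) {
    set.seed(8)
    ok <- grow_cell(pop, lat, nb_cells[1L], push_cap = 2L)
    expect_true(c(ok))
  }
  expect_equal(pop$deaths, 1L)
  expect_equal(pop$lyses, 1L)
})

test_that("unbiased migration MSD grows like 6 D t", {
  lat <- build_lattice(14, 16.8, 0.2, seed = 5)
  l <- mean_adjacent_distance(lat)   # the hop length scale of the walk
  D <- 100                       # um^2/h
  lambda <- 6 * D / l^2
  T_end <- 2
  set.seed(9)
  start <- ball_sites(lat, 0.9)[1]
  n_walk <- 1200
  disp2 <- numeric(n_walk)
  for (w in seq_len(n_walk)) {
    pop <- fixture_population(lat, start)
    t <- 0
    repeat {
      nb <- neighbors(lat, pop$site1[1L])
      rate <- lambda * sum(pop$occupancy[nb] == 0L &
                           !lat$boundary[nb]) / length(nb)
      dt <- rexp(1, rate)
      if (t + dt > T_end) break
      t <- t + dt
      migrate_cell(pop, lat, 1L, mode = "unbiased")
    }
    disp2[w] <- sum((lat$positions[pop$site1[1L], ] -
                     lat$positions[start, ])^2)
  }
  expect_equal(mean(disp2), 6 * D * T_end, tolerance = 0.10)
})

test_that("biased migration matches the enumerated master-equation equilibrium", {
  # two cells on a small lattice with adhesion: compare the long-run
  # fraction of time the mobile cell spends adjacent to the fixed cell
  # against the stationary distribution of the exactly enumerated chain
  lat <- build_lattice(4, 16.8, jitter = 0, seed = 1)
  interior <- which(!lat$boundary)
  expect_equal(length(interior), 8L)
  fixed <- interior[1L]
  J <- 1; FT <- 1
  mig <- list(rate = 1, mode = "biased", J = J, FT = FT)
  # exact stationary distribution over the mobile cell's positions
  free_sites <- setdiff(interior, fixed)
  nstates <- length(free_sites)
  Q <- matrix(0, nstates, nstates)
  for (a in seq_len(nstates)) {
    pop <- fixture_population(lat, c(fixed, free_sites[a]))
    s <- free_sites[a]
    nb <- neighbors(lat, s)
    tgt <- nb[pop$occupancy[nb] == 0L & !lat$boundary[nb]]
    contacts <- function(site, exclude_site) {
      nn <- neighbors(lat, site)
      sum(nn == fixed)
    }
    e_now <- -J * contacts(s)
    for (tg in tgt) {
      b <- match(tg, free_sites)
      Q[a, b] <- mig$rate / length(nb) * exp(-(-J * contacts(tg) - e_now) / FT)
    }
    Q[a, a] <- -sum(Q[a, -a])
  }
  ei <- eigen(t(Q))
  pi_exact <- abs(Re(ei$vectors[, which.min(abs(Re(ei$values)))]))
  pi_exact <- pi_exact / sum(pi_exact)
  adj_states <- vapply(free_sites, function(s) fixed %in% neighbors(lat, s),
                       logical(1))
  p_adj_exact <- sum(pi_exact[adj_states])
  # simulate the same chain with migrate_cell
  set.seed(11)
  pop <- fixture_population(lat, c(fixed, free_sites[1L]))
  t_adj <- 0; t_tot <- 0
  for (step in 1:4000) {
    s <- pop$site1[2L]
    rate <- migration_rate(pop, lat, 2L, mig)
    dt <- rexp(1, rate)
    t_tot <- t_tot + dt
    if (fixed %in% neighbors(lat, s)) t_adj <- t_adj + dt
    migrate_cell(pop, lat, 2L, mode = "biased", J = J, FT = FT)
  }
  expect_equal(t_adj / t_tot, p_adj_exact, tolerance = 0.08)
})

test_that("quiescence re-entry: disabled by default, exponential when on", {
  cyc <- cycle_params()
  expect_equal(cyc$k_re * cyc$p_re, 0)
  # with p_re = 1 and an isolated cell (pushing distance 0), each probe
  # succeeds: re-entry times are the probe times, exponential mean 1/k_re
  lat <- fixture_lattice(6, seed = 6)
  site <- ball_sites(lat, 0.9)[1]
  ctx <- fixture_ctx(lat)
  set.seed(12)
  n <- 2000
  k_re <- 0.001 / 2.4
  times <- numeric(n)
  for (i in seq_len(n)) {
    pop <- fixture_population(lat, site)
    pop$state[1L] <- CELL_QUIESCENT
    t <- 0
    repeat {
      t <- t + rexp(1, k_re)
      if (reenter_quiescent(pop, lat, 1L, ctx)) break
    }
    times[i] <- t
  }
  expect_equal(mean(times), 2400, tolerance = 0.06)
  expect_error(reenter_quiescent(pop, lat, 1L, ctx), "not quiescent")
})

test_that("population bookkeeping: births - lyses equals occupancy change", {
  lat <- fixture_lattice(8, seed = 7)
  pop <- new_population(lat, 40, cycle_params(), seed = 3)
  expect_equal(sum(population_counts(pop)), 40L)
  df <- as.data.frame(pop)
  expect_equal(nrow(df), 40L)
  expect_true(all(df$state == "cycling"))
  expect_true(all(pop$M[1:40] >= 0 & pop$M[1:40] < cycle_params()$m_d))
  expect_error(new_population(lat, 10000, cycle_params()), "capacity")
})
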