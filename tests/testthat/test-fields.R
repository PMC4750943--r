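# Steady-state reaction-diffusion solves against closed forms and a
# radial shooting oracle.

all_faces <- c("xlo", "xhi", "ylo", "yhi", "zlo", "zhi")

grid_box <- function(dims, spacing, G = 25, O = 0.28) {
  field_grid(dims = dims, spacing = spacing, bc = list(
    G = list(value = G, dirichlet_faces = all_faces),
    O = list(value = O, dirichlet_faces = all_faces),
    L = list(value = 0, dirichlet_faces = all_faces),
    ECM = list(value = 0, dirichlet_faces = all_faces),
    W = list(value = 0, dirichlet_faces = all_faces)))
}

test_that("no sink: fields equal the boundary value everywhere", {
  g <- grid_box(c(7, 7, 7), 20)
  phi <- array(0, g$dims)
  res <- solve_steady_glucose_oxygen(g, NULL, phi, array(FALSE, g$dims))
  expect_equal(max(abs(res$G - 25)), 0, tolerance = 1e-10)
  expect_equal(max(abs(res$O - 0.28)), 0, tolerance = 1e-10)
})

test_that("1D slab with constant uptake matches the closed-form parabola", {
  # D = 1, q = 8, X = 1, c0 = 2 at both ends: c(x) = 2 - 4 x (1 - x)
  g <- field_grid(dims = c(41, 3, 3), spacing = 1 / 40,
                  bc = list(G = list(value = 2,
                                     dirichlet_faces = c("xlo", "xhi"))))
  sol <- spheroidsim:::solve_linear_field(
    g, D = array(1, g$dims), sink = array(0, g$dims),
    source = array(-8, g$dims), bc_value = 2,
    dirichlet_faces = c("xlo", "xhi"))
  x <- (0:40) / 40
  expect_equal(sol[, 2, 2], 2 - 4 * x * (1 - x), tolerance = 1e-10)
  expect_equal(sol[21, 2, 2], 1, tolerance = 1e-10)
})

test_that("well-mixed limit: ECM approaches k_gen * phi / k_deg", {
  g <- grid_box(c(9, 9, 9), 15)
  dp <- diffusion_params(D_tum = c(G = 3.6e5, O = 3.6e6, L = 3.6e5,
                                   W = 1e5, ECM = 1e12),
                         k_gen_ECM = 0.002, k_deg_ECM = 0.05)
  phi <- array(0.5, g$dims)
  # with enormous D the interior is flattened toward a uniform balance
  # (the Dirichlet rim still pins the faces to zero, so compare the
  # volume-averaged reaction balance instead of the plateau)
  ecm <- solve_steady_linear("ECM", g, phi = phi,
                             mask = array(TRUE, g$dims), diffusion = dp)
  expect_true(max(ecm) <= 0.002 * 0.5 / 0.05 + 1e-9)
  # moderate diffusion, large box: center reaches the plateau
  g2 <- grid_box(c(17, 17, 17), 50)
  dp2 <- diffusion_params(D_tum = c(G = 3.6e5, O = 3.6e6, L = 3.6e5,
                                    W = 1e5, ECM = 10),
                          k_gen_ECM = 0.002, k_deg_ECM = 0.05)
  ecm2 <- solve_steady_linear("ECM", g2, phi = array(0.5, g2$dims),
                              mask = array(TRUE, g2$dims), diffusion = dp2)
  expect_equal(ecm2[9, 9, 9], 0.002 * 0.5 / 0.05, tolerance = 1e-3)
})

test_that("singular operator (no Dirichlet, no decay) fails explicitly", {
  g <- field_grid(dims = c(5, 5, 5), spacing = 10,
                  bc = list(L = list(value = 0,
                                     dirichlet_faces = character(0))))
  expect_error(
    spheroidsim:::solve_linear_field(g, array(1, g$dims),
                                     array(0, g$dims), array(1, g$dims),
                                     0, character(0)),
    "singular")
})

test_that("discrete maximum principle holds on randomized sink fields", {
  set.seed(4)
  g <- grid_box(c(9, 9, 9), 20)
  for (k in 1:5) {
    phi <- array(runif(prod(g$dims), 0, 0.6), g$dims)
    mask <- array(runif(prod(g$dims)) < 0.5, g$dims)
    res <- solve_steady_glucose_oxygen(g, NULL, phi, mask)
    expect_true(all(res$G <= 25 + 1e-9))
    expect_true(all(res$O <= 0.28 + 1e-9))
    expect_true(all(res$G >= -1e-9))
    expect_true(all(res$O >= -1e-9))
    expect_lt(res$residual, 1e-8)
  }
})

test_that("warm restarts and cached-factor CG agree with fresh direct solves", {
  # same problem solved with and without the cached-preconditioner path
  g <- grid_box(c(11, 11, 11), 20)
  set.seed(13)
  phi <- array(runif(11^3, 0, 0.6), g$dims)
  mask <- array(runif(11^3) < 0.5, g$dims)
  r1 <- solve_steady_glucose_oxygen(g, NULL, phi, mask)      # cold cache
  r2 <- solve_steady_glucose_oxygen(g, r1, phi, mask)        # warm + PCG
  expect_equal(r2$G, r1$G, tolerance = 1e-8)
  expect_equal(r2$O, r1$O, tolerance = 1e-8)
})

# The spherically-symmetric shooting-oracle comparison of the coupled
# G/O solve lives in test-acceptance.R (solver-oracle criterion).
test_that("rasterization conserves cell mass and splits states", {
  lat <- fixture_lattice(8, seed = 5)
  g <- field_grid(lat, factor = 2)
  sites <- ball_sites(lat, 2.5)
  pop <- fixture_population(lat, sites)
  ras <- rasterize_cells(pop, lat, g)
  vn <- g$spacing^3
  expect_equal(sum(ras$sigma) * vn, length(sites))
  expect_equal(sum(ras$sigma_d), 0)
  # one dying cell moves mass between the two densities
  die_cell(pop, 1L)
  ras2 <- rasterize_cells(pop, lat, g)
  expect_equal(sum(ras2$sigma) * vn, length(sites) - 1)
  expect_equal(sum(ras2$sigma_d) * vn, 1)
  # empty population: zero fields
  pop$occupancy[] <- 0L
  pop$n_cells <- 0L
  ras0 <- rasterize_cells(pop, lat, g)
  expect_true(all(ras0$sigma == 0))
})

test_that("field update is idempotent for an unchanged population", {
  lat <- fixture_lattice(8, seed = 6)
  g <- field_grid(lat, factor = 2, medium = nutrient_condition("II"))
  pop <- fixture_population(lat, ball_sites(lat, 2.5))
  st1 <- update_fields(g, NULL, pop, lat)
  st2 <- update_fields(g, st1, pop, lat)
  expect_equal(st2$G, st1$G, tolerance = 1e-7)
  expect_equal(st2$O, st1$O, tolerance = 1e-7)
  expect_equal(st2$L, st1$L, tolerance = 1e-7)
  expect_true(all(st1$ECM >= 0 & st1$ECM <= 1))
  expect_true(all(st1$G >= 0 & st1$O >= 0 & st1$L >= 0 & st1$W >= 0))
})

test_that("trilinear interpolation is exact for affine fields", {
  g <- grid_box(c(6, 5, 4), 12)
  co <- spheroidsim:::node_coords(g)
  f <- array(2 + 0.3 * co[, 1] - 0.1 * co[, 2] + 0.05 * co[, 3], g$dims)
  set.seed(9)
  p <- cbind(runif(50, 0, 5 * 12), runif(50, 0, 4 * 12),
             runif(50, 0, 3 * 12))
  expect_equal(interp_field(g, f, p),
               2 + 0.3 * p[, 1] - 0.1 * p[, 2] + 0.05 * p[, 3],
               tolerance = 1e-10)
})
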