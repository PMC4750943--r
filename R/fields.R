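#' Regular grid for the molecular fields
#'
#' The concentration fields (glucose G, oxygen O, lactate L, extracellular
#' matrix ECM, waste W) live on a regular node grid covering the lattice
#' bounding box.  Boundary conditions idealize a hanging drop with medium
#' renewal: Dirichlet values equal to the medium concentrations for G and O
#' on all box faces, zero Dirichlet for L, ECM and W.  Individual faces can
#' be switched to zero-flux (Neumann) per species, which is used by the
#' one-dimensional verification problems.
#'
#' @param lattice a `spheroid_lattice` (or `NULL` when `dims`/`origin` are
#'   given directly).
#' @param factor grid coarsening factor: node spacing is
#'   `factor * lattice$spacing`.
#' @param medium named vector with medium concentrations `G`, `O` (mM).
#' @param dims,spacing,origin direct grid geometry (used when `lattice` is
#'   `NULL`).
#' @param bc optional boundary specification: named list per species,
#'   each `list(value =, dirichlet_faces =)` with faces among
#'   `"xlo","xhi","ylo","yhi","zlo","zhi"`; non-listed faces are zero-flux.
#' @return object of class `field_grid`.
#' @export
field_grid <- function(lattice = NULL, factor = 1,
                       medium = c(G = 25, O = 0.28),
                       dims = NULL, spacing = NULL, origin = c(0, 0, 0),
                       bc = NULL) {
  all_faces <- c("xlo", "xhi", "ylo", "yhi", "zlo", "zhi")
  if (!is.null(lattice)) {
    spacing <- factor * lattice$spacing
    len <- lattice$box["hi", ] - lattice$box["lo", ]
    dims <- as.integer(round(len / spacing)) + 1L
    origin <- lattice$box["lo", ]
  }
  if (is.null(dims) || is.null(spacing))
    stop("either a lattice or dims + spacing must be given")
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(bc)) {
    bc <- list(G = list(value = unname(medium["G"]),
                        dirichlet_faces = all_faces),
               O = list(value = unname(medium["O"]),
                        dirichlet_faces = all_faces),
               L = list(value = 0, dirichlet_faces = all_faces),
               ECM = list(value = 0, dirichlet_faces = all_faces),
               W = list(value = 0, dirichlet_faces = all_faces))
  }
  for (s in names(bc)) {
    if (bc[[s]]$value < 0) stop("boundary values must be non-negative")
  }
  structure(list(dims = as.integer(dims), spacing = spacing,
                 origin = as.numeric(origin), bc = bc,
                 cache = new.env(parent = emptyenv())),
            class = "field_grid")
}

# memoized assembly skeleton of the 7-point operator for one set of
# Dirichlet faces: edge lists, unknown numbering and scatter matrices for
# the diagonal and the boundary right-hand side
operator_skeleton <- function(grid, dirichlet_faces) {
  key <- paste0("sk_", paste(sort(dirichlet_faces), collapse = ","))
  cache <- grid$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  d <- grid$dims
  N <- prod(d)
  idx <- array(seq_len(N), d)
  ea <- integer(0); eb <- integer(0)
  for (ax in 1:3) {
    sl_a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sl_b <- sl_a
    sl_a[[ax]] <- seq_len(d[ax] - 1L)
    sl_b[[ax]] <- 2:d[ax]
    ea <- c(ea, as.vector(do.call(`[`, c(list(idx), sl_a))))
    eb <- c(eb, as.vector(do.call(`[`, c(list(idx), sl_b))))
  }
  dir <- face_nodes(grid, dirichlet_faces)
  unk <- which(!dir)
  nu <- length(unk)
  unkmap <- integer(N)
  unkmap[unk] <- seq_len(nu)
  ua <- unkmap[ea]; ub <- unkmap[eb]
  both <- ua > 0L & ub > 0L
  E <- length(ea)
  Sdiag <- Matrix::sparseMatrix(
    i = c(ua[ua > 0L], ub[ub > 0L]),
    j = c(which(ua > 0L), which(ub > 0L)),
    x = 1, dims = c(nu, E))
  adir <- ua > 0L & ub == 0L
  bdir <- ub > 0L & ua == 0L
  Srhs <- Matrix::sparseMatrix(
    i = c(ua[adir], ub[bdir]), j = c(which(adir), which(bdir)),
    x = 1, dims = c(nu, E))
  sk <- list(ea = ea, eb = eb, both = both,
             iup = pmin(ua[both], ub[both]),
             jup = pmax(ua[both], ub[both]),
             Sdiag = Sdiag, Srhs = Srhs, unk = unk, nu = nu,
             any_dir = any(dir))
  cache[[key]] <- sk
  sk
}

n_nodes <- function(grid) prod(grid$dims)

node_volume <- function(grid) grid$spacing^3

# n x 3 matrix of node coordinates, x fastest
node_coords <- function(grid) {
  d <- grid$dims
  h <- grid$spacing
  cbind(rep(grid$origin[1] + (seq_len(d[1]) - 1) * h, times = d[2] * d[3]),
        rep(rep(grid$origin[2] + (seq_len(d[2]) - 1) * h, each = d[1]),
            times = d[3]),
        rep(grid$origin[3] + (seq_len(d[3]) - 1) * h, each = d[1] * d[2]))
}

# logical vector marking nodes on the given faces
face_nodes <- function(grid, faces) {
  d <- grid$dims
  idx <- array(FALSE, d)
  if ("xlo" %in% faces) idx[1, , ] <- TRUE
  if ("xhi" %in% faces) idx[d[1], , ] <- TRUE
  if ("ylo" %in% faces) idx[, 1, ] <- TRUE
  if ("yhi" %in% faces) idx[, d[2], ] <- TRUE
  if ("zlo" %in% faces) idx[, , 1] <- TRUE
  if ("zhi" %in% faces) idx[, , d[3]] <- TRUE
  as.vector(idx)
}

#' Diffusion and production parameters of the molecular fields
#'
#' Tumor-tissue diffusion coefficients are literature-typical values
#' (um^2/h); in the surrounding medium diffusion is faster by `med_ratio`
#' (default 30) for the freely diffusing species G, O, L, W.  ECM is a
#' deposited macromolecular network: it diffuses slowly and identically
#' everywhere.  Generation/degradation rates are expressed per unit cell
#' volume fraction, so a dense viable region approaches a plateau of order
#' `k_gen_ECM / k_deg_ECM * phi` (~0.01), about three times the cycle gate
#' `ECM_min` = 0.003, which places the gate crossing in the outermost cell
#' layer (see vignette).
#'
#' @param D_tum named vector of tumor diffusion coefficients (um^2/h) for
#'   G, O, L, W, ECM.
#' @param med_ratio medium/tumor diffusivity ratio for G, O, L, W.
#' @param k_gen_ECM,k_deg_ECM ECM generation (per volume fraction, 1/h) and
#'   degradation (1/h) rates.
#' @param k_gen_W,k_upt_W waste release (per dead volume fraction, 1/h) and
#'   uptake (per viable volume fraction, 1/h) rates.
#' @return object of class `diffusion_params`.
#' @export
diffusion_params <- function(D_tum = c(G = 3.6e5, O = 3.6e6, L = 3.6e5,
                                       W = 1e5, ECM = 50),
                             med_ratio = 30,
                             k_gen_ECM = 8e-4, k_deg_ECM = 0.05,
                             k_gen_W = 0.05, k_upt_W = 0.02) {
  if (any(D_tum < 0) || med_ratio <= 0 ||
      any(c(k_gen_ECM, k_deg_ECM, k_gen_W, k_upt_W) < 0))
    stop("diffusion parameters must be non-negative")
  structure(list(D_tum = D_tum, med_ratio = med_ratio,
                 k_gen_ECM = k_gen_ECM, k_deg_ECM = k_deg_ECM,
                 k_gen_W = k_gen_W, k_upt_W = k_upt_W),
            class = "diffusion_params")
}

#' Rasterize a cell population onto the field grid
#'
#' Every cell contributes `1 / node volume` to the grid node nearest to the
#' centroid of its occupied sites: viable cells (cycling and quiescent) to
#' the density `sigma`, dying-not-yet-lysed cells to `sigma_d`.  Total mass
#' is conserved: `sum(sigma) * node_volume` equals the viable cell count.
#'
#' @param pop a `cell_population`.
#' @param lattice the `spheroid_lattice` the population lives on.
#' @param grid a [field_grid()] covering the lattice box.
#' @return list with arrays `sigma`, `sigma_d` (cells/um^3) of dim
#'   `grid$dims`.
#' @export
rasterize_cells <- function(pop, lattice, grid) {
  st <- pop$state[seq_len(pop$n_cells)]
  live <- which(st == CELL_CYCLING | st == CELL_QUIESCENT)
  dying <- which(st == CELL_DYING)
  vn <- node_volume(grid)
  acc <- function(cells) {
    a <- array(0, grid$dims)
    if (length(cells) == 0L) return(a)
    p1 <- lattice$positions[pop$site1[cells], , drop = FALSE]
    s2 <- pop$site2[cells]
    p <- p1
    two <- which(s2 > 0L)
    if (length(two))
      p[two, ] <- 0.5 * (p1[two, , drop = FALSE] +
                         lattice$positions[s2[two], , drop = FALSE])
    ijk <- sweep(p, 2L, grid$origin) / grid$spacing
    ijk <- round(ijk) + 1
    if (any(ijk < 1) || any(sweep(ijk, 2L, grid$dims) > 0))
      stop("cell position outside the field grid")
    lin <- ijk[, 1] + grid$dims[1] * (ijk[, 2] - 1) +
      grid$dims[1] * grid$dims[2] * (ijk[, 3] - 1)
    cnt <- tabulate(lin, nbins = n_nodes(grid))
    array(cnt / vn, grid$dims)
  }
  list(sigma = acc(live), sigma_d = acc(dying))
}

# binary closing (6-neighborhood dilate then erode) of a 3D logical array
close3d <- function(mask) {
  shift_or <- function(m, red) {
    out <- m
    d <- dim(m)
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    for (ax in 1:3) {
      for (s in c(-1L, 1L)) {
        src <- ix; dst <- ix
        if (s == 1L) { src[[ax]] <- 1:(d[ax] - 1); dst[[ax]] <- 2:d[ax] }
        else { src[[ax]] <- 2:d[ax]; dst[[ax]] <- 1:(d[ax] - 1) }
        piece <- do.call(`[`, c(list(m), src))
        cur <- do.call(`[`, c(list(out), dst))
        out <- do.call(`[<-`, c(list(out), dst,
                                list(if (red) cur & piece else cur | piece)))
      }
    }
    out
  }
  shift_or(shift_or(mask, red = FALSE), red = TRUE)
}

# Assemble the 7-point finite-volume operator -div(D grad u) + sink*u and
# solve against `source` with the given Dirichlet boundary.  Face
# conductances use the harmonic mean of the nodal D (flux continuity at the
# tumor/medium interface).  Returns the full solution array.
solve_linear_field <- function(grid, D, sink, source, bc_value,
                               dirichlet_faces, cache_key = NULL) {
  h2 <- grid$spacing^2
  D <- as.vector(D)
  sink <- as.vector(sink)
  source <- as.vector(source)
  sk <- operator_skeleton(grid, dirichlet_faces)
  if (!sk$any_dir && all(sink == 0))
    stop("singular steady-state operator: no Dirichlet face and no decay")
  w <- 2 * D[sk$ea] * D[sk$eb] /
    pmax(D[sk$ea] + D[sk$eb], .Machine$double.xmin) / h2
  diagv <- as.vector(sk$Sdiag %*% w) + sink[sk$unk]
  wb <- w[sk$both]
  A <- Matrix::sparseMatrix(i = c(sk$iup, seq_len(sk$nu)),
                            j = c(sk$jup, seq_len(sk$nu)),
                            x = c(-wb, diagv),
                            dims = c(sk$nu, sk$nu), symmetric = TRUE)
  rhs <- source[sk$unk] + bc_value * as.vector(sk$Srhs %*% w)
  u <- rep(bc_value, prod(grid$dims))
  u[sk$unk] <- chol_pcg_solve(grid, cache_key, A, rhs)
  array(u, grid$dims)
}

# Solve the SPD system A x = b.  Within a run the operator changes only
# through its diagonal (uptake linearization, slow drift of the tumor
# mask), so a cached Cholesky factor of an earlier operator is used as the
# preconditioner of a conjugate-gradient iteration; the factorization is
# redone only when CG stops converging quickly.  Solutions are exact to a
# 1e-12 relative residual, so the direct and iterative paths agree far
# below the field tolerances.
chol_pcg_solve <- function(grid, cache_key, A, b, tol = 1e-12,
                           max_cg = 8L) {
  fresh <- function() {
    ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
    if (!is.null(cache_key))
      grid$cache[[paste0("chol_", cache_key)]] <- ch
    as.vector(Matrix::solve(ch, b))
  }
  if (is.null(cache_key)) return(fresh())
  ch <- grid$cache[[paste0("chol_", cache_key)]]
  if (is.null(ch)) return(fresh())
  x <- as.vector(Matrix::solve(ch, b))
  r <- b - as.vector(A %*% x)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(x)
  z <- as.vector(Matrix::solve(ch, r))
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_cg)) {
    if (sqrt(sum(r * r)) <= tol * bnorm) return(x)
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- as.vector(Matrix::solve(ch, r))
    rz2 <- sum(r * z)
    p <- z + rz2 / rz * p
    rz <- rz2
  }
  fresh()   # preconditioner too stale: refactorize and store
}

#' Steady state of the coupled glucose/oxygen problem
#'
#' Solves `div(D_u grad u) = q_u(G, O) * phi` for u in (G, O) with Dirichlet
#' medium values, where `phi` is the viable cell volume fraction and the
#' uptake is the cross-inhibited Michaelis-Menten model.  A semi-implicit
#' Picard iteration freezes the nonlinearity at the previous iterate: the
#' uptake is linearized as `q_u = [V_max(other)/(u_prev + k)] * u`, which
#' keeps the operator an M-matrix (hence non-negative solutions), and the
#' two linearized diffusion problems are solved together in each sweep.
#' Damping is halved when the nonlinear residual oscillates.
#'
#' @param grid a [field_grid()].
#' @param state previous `field_state` (warm start) or `NULL`.
#' @param phi viable volume-fraction array (dim `grid$dims`).
#' @param mask logical array: `TRUE` inside tumor tissue (selects `D_tum`
#'   over `D_med`).
#' @param metabolic a [metabolic_params()].
#' @param diffusion a [diffusion_params()].
#' @param tol relative nonlinear residual tolerance.
#' @param max_iter maximal Picard sweeps.
#' @return list with arrays `G`, `O`, and `iterations`, `residual`.
#' @export
solve_steady_glucose_oxygen <- function(grid, state, phi, mask,
                                        metabolic = metabolic_params(),
                                        diffusion = diffusion_params(),
                                        tol = 1e-8, max_iter = 200L) {
  DG <- ifelse(mask, diffusion$D_tum[["G"]],
               diffusion$D_tum[["G"]] * diffusion$med_ratio)
  DO <- ifelse(mask, diffusion$D_tum[["O"]],
               diffusion$D_tum[["O"]] * diffusion$med_ratio)
  bcG <- grid$bc$G$value; bcO <- grid$bc$O$value
  G <- if (!is.null(state$G) && all(dim(state$G) == grid$dims)) state$G
       else array(bcG, grid$dims)
  O <- if (!is.null(state$O) && all(dim(state$O) == grid$dims)) state$O
       else array(bcO, grid$dims)
  phi <- as.vector(phi)
  unkG <- !face_nodes(grid, grid$bc$G$dirichlet_faces)
  unkO <- !face_nodes(grid, grid$bc$O$dirichlet_faces)

  # relative nonlinear residual || -div(D grad u) + phi q_u(G,O) ||
  rel_resid <- function(G, O) {
    qg <- phi * glucose_uptake(pmax(as.vector(G), 0), pmax(as.vector(O), 0),
                               metabolic)
    qo <- phi * oxygen_uptake(pmax(as.vector(G), 0), pmax(as.vector(O), 0),
                              metabolic)
    rg <- apply_diff_op(grid, DG, G)[unkG] + qg[unkG]
    ro <- apply_diff_op(grid, DO, O)[unkO] + qo[unkO]
    max(sqrt(sum(rg^2)) / max(sqrt(sum(qg^2)), .Machine$double.eps),
        sqrt(sum(ro^2)) / max(sqrt(sum(qo^2)), .Machine$double.eps))
  }

  omega <- 1
  res_prev <- Inf
  res <- NA_real_
  for (it in seq_len(max_iter)) {
    gv <- pmax(as.vector(G), 0)
    ov <- pmax(as.vector(O), 0)
    vg <- metabolic$q_G_max *
      (1 - (1 - metabolic$q_G_min / metabolic$q_G_max) *
         ov / (ov + metabolic$k_G_O2))
    vo <- metabolic$q_O2_max *
      (1 - (1 - metabolic$q_O2_min / metabolic$q_O2_max) *
         gv / (gv + metabolic$k_O2_G))
    # Newton linearization of the Michaelis-Menten sink around the
    # previous iterate: q(u) ~ q' u + (q - q' u); the derivative term goes
    # on the diagonal (keeping the operator an M-matrix), the remainder to
    # the right-hand side
    dG <- vg * metabolic$k_G_G / (gv + metabolic$k_G_G)^2
    dO <- vo * metabolic$k_O2_O2 / (ov + metabolic$k_O2_O2)^2
    srcG <- -phi * vg * gv^2 / (gv + metabolic$k_G_G)^2
    srcO <- -phi * vo * ov^2 / (ov + metabolic$k_O2_O2)^2
    Gn <- solve_linear_field(grid, DG, phi * dG, srcG, bcG,
                             grid$bc$G$dirichlet_faces, cache_key = "G")
    On <- solve_linear_field(grid, DO, phi * dO, srcO, bcO,
                             grid$bc$O$dirichlet_faces, cache_key = "O")
    G <- (1 - omega) * G + omega * Gn
    O <- (1 - omega) * O + omega * On
    res <- rel_resid(G, O)
    if (all(phi == 0)) res <- 0   # no sink: the single solve is exact
    if (res < tol) {
      G[G < 0 & G > -tol * bcG] <- 0
      O[O < 0 & O > -tol * bcO] <- 0
      return(list(G = G, O = O, iterations = it, residual = res))
    }
    if (res > res_prev) omega <- max(omega / 2, 1 / 16)
    else omega <- min(1, omega * 1.25)
    res_prev <- res
  }
  stop(sprintf(
    "glucose/oxygen steady state did not converge: residual %.3e after %d iterations",
    res, max_iter))
}

# apply -div(D grad u) with harmonic face conductances (natural boundary);
# values at Dirichlet nodes are not meaningful and must be masked by caller
apply_diff_op <- function(grid, D, u) {
  d <- grid$dims
  h2 <- grid$spacing^2
  D <- array(as.vector(D), d)
  u <- array(as.vector(u), d)
  r <- array(0, d)
  for (ax in 1:3) {
    sl_a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sl_b <- sl_a
    sl_a[[ax]] <- seq_len(d[ax] - 1L)
    sl_b[[ax]] <- 2:d[ax]
    Da <- do.call(`[`, c(list(D), sl_a, drop = FALSE))
    Db <- do.call(`[`, c(list(D), sl_b, drop = FALSE))
    w <- 2 * Da * Db / pmax(Da + Db, .Machine$double.xmin) / h2
    ua <- do.call(`[`, c(list(u), sl_a, drop = FALSE))
    ub <- do.call(`[`, c(list(u), sl_b, drop = FALSE))
    flux <- w * (ua - ub)
    ra <- do.call(`[`, c(list(r), sl_a, drop = FALSE)) + flux
    r <- do.call(`[<-`, c(list(r), sl_a, list(ra)))
    rb <- do.call(`[`, c(list(r), sl_b, drop = FALSE)) - flux
    r <- do.call(`[<-`, c(list(r), sl_b, list(rb)))
  }
  as.vector(r)
}

#' Steady state of a linear field (lactate, ECM or waste)
#'
#' Single sparse solve of the linear reaction-diffusion balance with the
#' sources frozen at the current cell configuration and glucose/oxygen
#' fields: lactate is produced at `phi * p_L(G, O)` and only removed by
#' diffusion; ECM is generated by viable cells and degrades at `k_deg_ECM`;
#' waste is released by dead (not yet lysed) cells and taken up by viable
#' cells.
#'
#' @param species one of `"L"`, `"ECM"`, `"W"`.
#' @param grid a [field_grid()].
#' @param G,O current glucose/oxygen arrays (needed for `"L"`).
#' @param phi,phi_d viable and dead volume-fraction arrays.
#' @param mask tumor mask (logical array).
#' @param metabolic a [metabolic_params()].
#' @param diffusion a [diffusion_params()].
#' @return solution array of dim `grid$dims`.
#' @export
solve_steady_linear <- function(species, grid, G = NULL, O = NULL,
                                phi, phi_d = NULL, mask,
                                metabolic = metabolic_params(),
                                diffusion = diffusion_params()) {
  N <- n_nodes(grid)
  phi <- as.vector(phi)
  Dmix <- function(sp) ifelse(as.vector(mask), diffusion$D_tum[[sp]],
                              diffusion$D_tum[[sp]] * diffusion$med_ratio)
  switch(species,
    L = {
      if (is.null(G) || is.null(O))
        stop("lactate needs the glucose/oxygen fields")
      src <- phi * lactate_production(pmax(as.vector(G), 0),
                                      pmax(as.vector(O), 0), metabolic)
      solve_linear_field(grid, Dmix("L"), rep(0, N), src,
                         grid$bc$L$value, grid$bc$L$dirichlet_faces,
                         cache_key = "L")
    },
    ECM = {
      src <- diffusion$k_gen_ECM * phi
      solve_linear_field(grid, rep(diffusion$D_tum[["ECM"]], N),
                         rep(diffusion$k_deg_ECM, N), src,
                         grid$bc$ECM$value, grid$bc$ECM$dirichlet_faces,
                         cache_key = "ECM")
    },
    W = {
      if (is.null(phi_d)) stop("waste needs the dead-cell density")
      src <- diffusion$k_gen_W * as.vector(phi_d)
      # debris diffuses slowly everywhere (aggregates, no medium boost)
      solve_linear_field(grid, rep(diffusion$D_tum[["W"]], N),
                         diffusion$k_upt_W * phi, src,
                         grid$bc$W$value, grid$bc$W$dirichlet_faces,
                         cache_key = "W")
    },
    stop("unknown species: ", species))
}

#' Refresh all molecular fields to their steady state
#'
#' The full field update performed after every field-update interval:
#' rasterize the population, rebuild the tumor mask (occupied nodes,
#' morphologically closed), solve the coupled G/O problem, then lactate,
#' ECM and waste.  Because every species is relaxed to steady state, two
#' consecutive updates with an unchanged population give identical fields.
#'
#' @param grid a [field_grid()].
#' @param state previous `field_state` (warm start) or `NULL`.
#' @param pop,lattice the population and its lattice.
#' @param metabolic,diffusion parameter objects.
#' @param tol,max_iter forwarded to [solve_steady_glucose_oxygen()].
#' @return object of class `field_state`: arrays `G`, `O`, `L`, `ECM`,
#'   `W`, `sigma`, `sigma_d`, `phi`, `phi_d`, logical `mask`, and solver
#'   diagnostics.
#' @export
update_fields <- function(grid, state, pop, lattice,
                          metabolic = metabolic_params(),
                          diffusion = diffusion_params(),
                          tol = 1e-8, max_iter = 200L) {
  ras <- rasterize_cells(pop, lattice, grid)
  # volume fraction occupied by (reference-volume) cells at each node
  phi <- ras$sigma * metabolic$cell_volume
  phi_d <- ras$sigma_d * metabolic$cell_volume
  mask <- close3d((ras$sigma + ras$sigma_d) > 0)
  go <- solve_steady_glucose_oxygen(grid, state, phi, mask, metabolic,
                                    diffusion, tol, max_iter)
  L <- solve_steady_linear("L", grid, go$G, go$O, phi, NULL, mask,
                           metabolic, diffusion)
  ECM <- solve_steady_linear("ECM", grid, phi = phi, mask = mask,
                             metabolic = metabolic, diffusion = diffusion)
  W <- solve_steady_linear("W", grid, phi = phi, phi_d = phi_d, mask = mask,
                           metabolic = metabolic, diffusion = diffusion)
  structure(list(G = go$G, O = go$O, L = L, ECM = pmin(ECM, 1), W = W,
                 sigma = ras$sigma, sigma_d = ras$sigma_d,
                 phi = phi, phi_d = phi_d, mask = mask,
                 iterations = go$iterations, residual = go$residual),
            class = "field_state")
}

#' Trilinear interpolation of a field at arbitrary positions
#'
#' @param grid a [field_grid()].
#' @param field array of dim `grid$dims`.
#' @param positions n x 3 matrix (um).
#' @return numeric vector of interpolated values.
#' @export
interp_field <- function(grid, field, positions) {
  d <- grid$dims
  t <- sweep(positions, 2L, grid$origin) / grid$spacing
  t <- pmin(pmax(t, 0), matrix(rep(d - 1L, each = nrow(positions)),
                               ncol = 3L) - 1e-9)
  i0 <- floor(t)
  fr <- t - i0
  i0 <- i0 + 1L   # 1-based lower corner
  out <- numeric(nrow(positions))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (i0[, 1] + dx) + d[1] * (i0[, 2] + dy - 1) +
      d[1] * d[2] * (i0[, 3] + dz - 1)
    out <- out + w * field[lin]
  }
  out
}

#' Interpolate all fields at cell or site positions
#'
#' @param grid a [field_grid()].
#' @param state a `field_state`.
#' @param positions n x 3 matrix (um).
#' @param stencil optional precomputed trilinear stencil (internal
#'   `interp_stencil`) for these positions.
#' @return data.frame with columns G, O, L, ECM, W.
#' @export
interp_fields <- function(grid, state, positions, stencil = NULL) {
  if (is.null(stencil)) stencil <- interp_stencil(grid, positions)
  ap <- function(field) pmax(apply_stencil(stencil, field), 0)
  data.frame(G = ap(state$G), O = ap(state$O), L = ap(state$L),
             ECM = ap(state$ECM), W = ap(state$W))
}

# precomputed trilinear corner indices and weights for fixed positions
interp_stencil <- function(grid, positions) {
  d <- grid$dims
  t <- sweep(positions, 2L, grid$origin) / grid$spacing
  t <- pmin(pmax(t, 0), matrix(rep(d - 1L, each = nrow(positions)),
                               ncol = 3L) - 1e-9)
  i0 <- floor(t)
  fr <- t - i0
  i0 <- i0 + 1L
  n <- nrow(positions)
  idx <- matrix(0L, n, 8L)
  w <- matrix(0, n, 8L)
  k <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    k <- k + 1L
    w[, k] <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    idx[, k] <- (i0[, 1] + dx) + d[1] * (i0[, 2] + dy - 1) +
      d[1] * d[2] * (i0[, 3] + dz - 1)
  }
  list(idx = idx, w = w)
}

apply_stencil <- function(stencil, field) {
  out <- numeric(nrow(stencil$idx))
  for (k in 1:8) out <- out + stencil$w[, k] * field[stencil$idx[, k]]
  out
}

#' Write a field snapshot as plain-text CSV
#'
#' Long-format node table (one row per node: indices, coordinates, species
#' values and densities); the inverse reader reconstructs the arrays.
#' @param state a `field_state`.
#' @param grid the [field_grid()] it lives on.
#' @param path output file.
#' @export
write_fields_csv <- function(state, grid, path) {
  xyz <- node_coords(grid)
  df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   G = as.vector(state$G), O = as.vector(state$O),
                   L = as.vector(state$L), ECM = as.vector(state$ECM),
                   W = as.vector(state$W), sigma = as.vector(state$sigma),
                   sigma_d = as.vector(state$sigma_d))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
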