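#' Build an unstructured 3D cell lattice
#'
#' Constructs the site graph that cells populate: a regular cubic grid of
#' `n_per_dim^3` points with mean spacing `spacing`, jittered uniformly by up
#' to `jitter * spacing` in each coordinate, with the neighbor relation given
#' by the Gabriel graph of the jittered points (an edge exists iff the sphere
#' having the two sites as diameter contains no third site).  The Gabriel
#' graph is a subgraph of the Delaunay tessellation that contains the
#' Euclidean minimum spanning tree, so the lattice is always connected, and
#' exact co-spherical ties are excluded so that `jitter = 0` reproduces the
#' 6-neighbor face adjacency of the cubic grid.
#'
#' The default spacing of 16.8 um is the estimated cell diameter, so one site
#' holds one cell and the site volume (`spacing^3` = 4742 um^3 for the cube;
#' per-site share of the box) is commensurate with the reference cell volume
#' of 2700 um^3 for jittered packings.  Sites of the outermost grid layer are
#' flagged as `boundary`: they belong to the growth medium, are never
#' occupied by cells, but count as free space for distance queries.
#'
#' After jittering, a few soft-sphere relaxation sweeps push apart pairs
#' closer than `spacing`, restoring the mean nearest-neighbor distance to
#' within a few percent of `spacing` while keeping the packing disordered
#' (a plain jittered grid underestimates the nearest-neighbor distance
#' considerably, because the minimum over many neighbors is biased
#' downward).
#'
#' @param n_per_dim integer >= 3, sites per box edge.
#' @param spacing target mean inter-site distance (um).
#' @param jitter jitter amplitude as a fraction of `spacing`, in [0, 0.5).
#' @param relax_sweeps soft-sphere relaxation sweeps after jittering.
#' @param seed integer seed; lattices are reproducible given the seed.
#' @return An object of class `spheroid_lattice`: a list with `positions`
#'   (n x 3 matrix, um), CSR adjacency (`adj_ptr`, `adj_idx`), `spacing`,
#'   `jitter`, `seed`, `box` (2 x 3 bounding box), `boundary` (logical),
#'   `n_sites`.
#' @export
build_lattice <- function(n_per_dim, spacing = 16.8, jitter = 0.25,
                          relax_sweeps = 8L, seed = 1L) {
  if (n_per_dim < 3) stop("n_per_dim must be >= 3")
  if (jitter < 0 || jitter >= 0.5) stop("jitter must be in [0, 0.5)")
  if (spacing <= 0) stop("spacing must be positive")
  n <- as.integer(n_per_dim)
  N <- n^3
  g <- (seq_len(n) - 0.5) * spacing
  pos <- as.matrix(expand.grid(x = g, y = g, z = g))
  dimnames(pos) <- NULL
  ijk <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n),
                               k = seq_len(n)))
  boundary <- apply(ijk == 1L | ijk == n, 1L, any)

  if (jitter > 0) {
    pos <- pos + with_seed(seed, {
      matrix(runif(3L * N, -jitter * spacing, jitter * spacing), ncol = 3L)
    })
    pos <- relax_positions(pos, spacing, relax_sweeps)
  }
  # jitter < 0.5 keeps points distinct; still guard against degeneracy
  if (qr(sweep(pos, 2L, colMeans(pos)))$rank < 3L)
    stop("degenerate (coplanar) site set")

  ed <- gabriel_edges_cpp(pos, bin_size = spacing, r_max = 2.5 * spacing,
                          tol = 1e-9 * spacing^2)
  adj <- edges_to_csr(ed$i, ed$j, N)

  structure(
    list(positions = pos, adj_ptr = adj$ptr, adj_idx = adj$idx,
         spacing = spacing, jitter = jitter, seed = as.integer(seed),
         box = rbind(lo = c(0, 0, 0), hi = rep(n * spacing, 3L)),
         boundary = boundary, n_sites = N, n_per_dim = n),
    class = "spheroid_lattice")
}

# soft-sphere relaxation: push apart point pairs closer than `spacing`
# (half the overlap, split between the two ends) for a few sweeps
relax_positions <- function(pos, spacing, sweeps, kappa = 0.5) {
  for (s in seq_len(sweeps)) {
    cp <- close_pairs_cpp(pos, spacing, spacing)
    if (length(cp$i) == 0L) break
    f <- kappa * (spacing - cp$d) / pmax(cp$d, 1e-6 * spacing) / 2
    dvec <- (pos[cp$j, , drop = FALSE] - pos[cp$i, , drop = FALSE]) * f
    grp <- c(cp$i, cp$j)
    for (cc in 1:3) {
      acc <- rowsum(c(-dvec[, cc], dvec[, cc]), grp)
      idx <- as.integer(rownames(acc))
      pos[idx, cc] <- pos[idx, cc] + acc[, 1L]
    }
  }
  pos
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# symmetric edge list -> compressed sparse row adjacency with sorted rows
edges_to_csr <- function(i, j, n) {
  from <- c(i, j)
  to <- c(j, i)
  o <- order(from, to)
  from <- from[o]
  to <- to[o]
  counts <- tabulate(from, nbins = n)
  list(ptr = as.integer(c(0L, cumsum(counts))), idx = as.integer(to))
}

#' @export
print.spheroid_lattice <- function(x, ...) {
  deg <- diff(x$adj_ptr)
  cat("spheroid_lattice:", x$n_sites, "sites,",
      sprintf("spacing %.2f um, jitter %.2f, seed %d\n",
              x$spacing, x$jitter, x$seed))
  cat(sprintf("  degree: min %d / mean %.2f / max %d; boundary sites: %d\n",
              min(deg), mean(deg), max(deg), sum(x$boundary)))
  invisible(x)
}

#' Neighbor sites of a lattice site
#' @param lattice a `spheroid_lattice`.
#' @param site site index.
#' @return integer vector of adjacent site indices (sorted).
#' @export
neighbors <- function(lattice, site) {
  stopifnot(site >= 1, site <= lattice$n_sites)
  lattice$adj_idx[seq.int(lattice$adj_ptr[site] + 1L,
                          length.out = lattice$adj_ptr[site + 1L] -
                            lattice$adj_ptr[site])]
}

#' Mean nearest-neighbor distance of a lattice
#'
#' The nearest neighbor of every site is one of its Gabriel neighbors, so the
#' minimum adjacent edge length per site is the exact nearest-neighbor
#' distance.
#' @param lattice a `spheroid_lattice`.
#' @return mean over sites of the distance to the nearest other site (um).
#' @export
mean_nn_distance <- function(lattice) {
  pos <- lattice$positions
  row <- rep.int(seq_len(lattice$n_sites), diff(lattice$adj_ptr))
  d <- sqrt(rowSums((pos[row, , drop = FALSE] -
                     pos[lattice$adj_idx, , drop = FALSE])^2))
  mean(tapply(d, row, min))
}

#' Mean distance between adjacent lattice sites
#'
#' The average edge length of the neighbor graph: the length scale `l`
#' entering the migration rate `lambda = 6 D / l^2` of a lattice random
#' walk.  On a Gabriel-graph lattice this exceeds the grid pitch by
#' ~15% (diagonal-like edges).
#' @param lattice a `spheroid_lattice`.
#' @export
mean_adjacent_distance <- function(lattice) {
  row <- rep.int(seq_len(lattice$n_sites), diff(lattice$adj_ptr))
  mean(sqrt(rowSums((lattice$positions[row, , drop = FALSE] -
                     lattice$positions[lattice$adj_idx, , drop = FALSE])^2)))
}

#' Graph distance to the closest free lattice site
#'
#' Breadth-first hop distance from an occupied site to the nearest
#' unoccupied site, capped at `max_radius` hops.  This is the pushing
#' distance L entering the cycle-entry probability `exp(-L / dL)`.
#'
#' @param lattice a `spheroid_lattice`.
#' @param occupancy integer vector over sites; 0 = free, otherwise cell id.
#' @param site occupied query site.
#' @param max_radius search cap (hops).
#' @return integer hop count, or `Inf` if no free site within the cap.
#' @export
distance_to_nearest_free <- function(lattice, occupancy, site,
                                     max_radius = 15L) {
  if (occupancy[site] == 0L)
    stop("query site is not occupied (contract violation)")
  res <- bfs_nearest_cpp(lattice$adj_ptr, lattice$adj_idx,
                         occupancy == 0L, as.integer(site),
                         as.integer(max_radius), FALSE, logical(0))
  if (res$dist < 0) Inf else res$dist
}

# nearest free site plus the shortest pushing chain to it (ties: smallest
# site index).  A pushing chain transmits through cells, so only occupied
# sites are traversable; free sites terminate the search, and `target_ok`
# restricts which free sites qualify as destinations (the permanently-free
# medium boundary never does).
nearest_free_path <- function(lattice, occupancy, site, max_radius,
                              target_ok = NULL) {
  free <- occupancy == 0L
  targets <- if (is.null(target_ok)) free else free & target_ok
  bfs_nearest_cpp(lattice$adj_ptr, lattice$adj_idx, targets,
                  as.integer(site), as.integer(max_radius), TRUE,
                  !free)
}

#' Border sites of a cell population
#'
#' A site belongs to the spheroid border when it is occupied and has at
#' least one free neighbor connected to the exterior growth medium.  Free
#' sites fully enclosed by the spheroid (a lysed necrotic region) are
#' interior holes: sites adjacent to them are not border sites, matching
#' the image-analysis convention where the lumen is hole-filled before the
#' border is extracted.
#' @param lattice a `spheroid_lattice`.
#' @param occupancy integer vector over sites; 0 = free.
#' @return integer vector of border site indices.
#' @export
border_sites <- function(lattice, occupancy) {
  free <- occupancy == 0L
  ext <- exterior_free_cpp(lattice$adj_ptr, lattice$adj_idx, free,
                           which(lattice$boundary))
  row <- rep.int(seq_len(lattice$n_sites), diff(lattice$adj_ptr))
  next_to_ext <- rowsum(as.numeric(ext[lattice$adj_idx]), row,
                        reorder = TRUE)[, 1L] > 0
  which(occupancy != 0L & next_to_ext)
}

#' Euclidean distance from a site to the spheroid border
#'
#' Distance (um) from an occupied site to the nearest border site.  Radial
#' statistics are taken against this border distance rather than the distance
#' to the center of mass, which keeps profiles meaningful for ellipsoidal
#' spheroids.
#' @inheritParams border_sites
#' @param site occupied query site.
#' @export
distance_to_border <- function(lattice, occupancy, site) {
  if (all(occupancy == 0L)) stop("empty population")
  if (occupancy[site] == 0L) stop("query site is not occupied")
  bs <- border_sites(lattice, occupancy)
  if (length(bs) == 0L) stop("population has no border (full lattice?)")
  p <- lattice$positions[site, ]
  sqrt(min(colSums((t(lattice$positions[bs, , drop = FALSE]) - p)^2)))
}

#' Write / read a lattice as a plain-text site table
#'
#' One row per site: index, coordinates, boundary flag and the
#' semicolon-separated neighbor list; lattice metadata in `#`-prefixed
#' header lines.
#' @param lattice a `spheroid_lattice`.
#' @param path file path.
#' @export
write_lattice_csv <- function(lattice, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spheroid_lattice n_per_dim=%d spacing=%.10g jitter=%.10g seed=%d",
                     lattice$n_per_dim, lattice$spacing, lattice$jitter,
                     lattice$seed), con)
  nb <- vapply(seq_len(lattice$n_sites), function(i)
    paste(neighbors(lattice, i), collapse = ";"), character(1))
  df <- data.frame(site = seq_len(lattice$n_sites),
                   x = lattice$positions[, 1L], y = lattice$positions[, 2L],
                   z = lattice$positions[, 3L],
                   boundary = as.integer(lattice$boundary),
                   neighbors = nb)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lattice_csv
#' @export
read_lattice_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.eE+-]+", hdr))[[1L]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                   vapply(kv, `[`, "", 1L))
  df <- read.csv(path, comment.char = "#")
  N <- nrow(df)
  nbl <- strsplit(as.character(df$neighbors), ";", fixed = TRUE)
  i <- rep.int(df$site, lengths(nbl))
  j <- as.integer(unlist(nbl))
  keep <- i < j
  adj <- edges_to_csr(i[keep], j[keep], N)
  n <- as.integer(vals[["n_per_dim"]])
  structure(
    list(positions = cbind(df$x, df$y, df$z), adj_ptr = adj$ptr,
         adj_idx = adj$idx, spacing = vals[["spacing"]],
         jitter = vals[["jitter"]], seed = as.integer(vals[["seed"]]),
         box = rbind(lo = c(0, 0, 0), hi = rep(n * vals[["spacing"]], 3L)),
         boundary = df$boundary == 1L, n_sites = N, n_per_dim = n),
    class = "spheroid_lattice")
}

#' Per-site share of the simulation box volume
#' @param lattice a `spheroid_lattice`.
#' @return volume per site (um^3).
#' @export
site_volume <- function(lattice) {
  prod(lattice$box["hi", ] - lattice$box["lo", ]) / lattice$n_sites
}
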