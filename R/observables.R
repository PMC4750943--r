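#' Volume-equivalent spheroid radius
#'
#' Default estimator: the radius of the sphere whose volume equals the
#' number of occupied (non-lysed) sites times the per-cell volume,
#' `(3 N V / (4 pi))^(1/3)`.  The alternative `"border"` estimator is
#' the mean distance of border sites from the occupied-site centroid.
#'
#' @param pop a `cell_population`.
#' @param lattice the lattice.
#' @param method `"volume"` (default) or `"border"`.
#' @param cell_volume volume attributed to one occupied site (um^3);
#'   defaults to the per-site share of the box, [site_volume()], which makes
#'   a solid ball of radius R sites measure R times the lattice spacing.
#' @return radius in um.
#' @export
spheroid_radius <- function(pop, lattice, method = c("volume", "border"),
                            cell_volume = NULL) {
  method <- match.arg(method)
  occ_sites <- which(pop$occupancy != 0L)
  if (length(occ_sites) == 0L) stop("empty population")
  if (method == "volume") {
    v <- cell_volume %||% site_volume(lattice)
    (3 * length(occ_sites) * v / (4 * pi))^(1 / 3)
  } else {
    bs <- border_sites(lattice, pop$occupancy)
    ctr <- colMeans(lattice$positions[occ_sites, , drop = FALSE])
    mean(sqrt(colSums((t(lattice$positions[bs, , drop = FALSE]) - ctr)^2)))
  }
}

#' Border-distance radial profile of cell states and ECM
#'
#' For every non-lysed cell, the Euclidean distance from its site to the
#' nearest border site (occupied site with a free neighbor) is computed and
#' binned into contiguous intervals `[i h, (i+1) h)`.  Per bin the fraction
#' of cycling cells (the Ki67-positive analogue), of dying cells (the
#' TUNEL-positive analogue) and the mean local ECM intensity are reported.
#' Bins without cells carry count 0 and `NA` fractions (sparse interior
#' bins are flagged rather than zero-filled).
#'
#' @param pop a `cell_population`.
#' @param lattice the lattice.
#' @param grid,state optional [field_grid()] and `field_state` for the ECM
#'   column (`NA` otherwise).
#' @param h bin width (um); default one cell layer (the lattice spacing).
#' @return data.frame of class `radial_profile` with columns `bin_lo`,
#'   `bin_mid`, `n`, `n_cycling`, `n_dying`, `f_cycling`, `f_dying`, `ecm`.
#' @export
radial_profile <- function(pop, lattice, grid = NULL, state = NULL,
                           h = lattice$spacing) {
  if (h <= 0) stop("bin width must be positive")
  n <- pop$n_cells
  st <- pop$state[seq_len(n)]
  alive <- which(st != CELL_LYSED)
  if (length(alive) == 0L) stop("empty population")
  bs <- border_sites(lattice, pop$occupancy)
  bpos <- lattice$positions[bs, , drop = FALSE]
  cpos <- lattice$positions[pop$site1[alive], , drop = FALSE]
  # distance to nearest border site, chunked to bound memory
  dist <- numeric(length(alive))
  step <- max(1L, floor(2e6 / max(nrow(bpos), 1L)))
  for (from in seq(1L, length(alive), by = step)) {
    to <- min(from + step - 1L, length(alive))
    dd <- outer(rowSums(cpos[from:to, , drop = FALSE]^2),
                rowSums(bpos^2), `+`) -
      2 * cpos[from:to, , drop = FALSE] %*% t(bpos)
    dist[from:to] <- sqrt(pmax(apply(dd, 1L, min), 0))
  }
  bin <- floor(dist / h)
  bins <- 0:max(bin)
  cnt <- tabulate(bin + 1L, nbins = length(bins))
  cyc <- tabulate((bin + 1L)[st[alive] == CELL_CYCLING],
                  nbins = length(bins))
  dyg <- tabulate((bin + 1L)[st[alive] == CELL_DYING], nbins = length(bins))
  ecm <- rep(NA_real_, length(bins))
  if (!is.null(grid) && !is.null(state)) {
    ev <- interp_field(grid, state$ECM, cpos)
    sums <- tabulate_weighted(bin + 1L, ev, length(bins))
    ecm <- ifelse(cnt > 0, sums / cnt, NA_real_)
  }
  out <- data.frame(bin_lo = bins * h, bin_mid = (bins + 0.5) * h, n = cnt,
                    n_cycling = cyc, n_dying = dyg,
                    f_cycling = ifelse(cnt > 0, cyc / cnt, NA_real_),
                    f_dying = ifelse(cnt > 0, dyg / cnt, NA_real_),
                    ecm = ecm)
  class(out) <- c("radial_profile", "data.frame")
  out
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Gaussian log-likelihood of model values against measured means
#'
#' `lnL = sum_i [ -log(sqrt(2 pi sigma_i^2)) - (x_i - mu_i)^2 / (2 sigma_i^2) ]`:
#' the log of the product of independent normal densities; points with
#' large measurement uncertainty are weighted less.
#'
#' @param x model values.
#' @param mu measured means (same length).
#' @param sigma measured standard deviations (> 0).
#' @return the log-likelihood (scalar).
#' @export
gaussian_loglik <- function(x, mu, sigma) {
  if (length(x) != length(mu) || length(mu) != length(sigma))
    stop("x, mu and sigma must have equal length")
  if (any(sigma <= 0))
    stop("sigma must be positive (first offending index: ",
         which(sigma <= 0)[1L], ")")
  sum(-0.5 * log(2 * pi * sigma^2) - (x - mu)^2 / (2 * sigma^2))
}

#' Akaike information criterion
#'
#' `AIC = 2 k - 2 lnL`; `delta_aic(A, B)` is `AIC(A) - AIC(B)` (negative
#' when A is preferred) and is antisymmetric.
#' @param lnL log-likelihood.
#' @param k number of free parameters.
#' @export
aic <- function(lnL, k) 2 * k - 2 * lnL

#' @rdname aic
#' @param fitA,fitB `fit_result` objects (or lists with `lnL` and `k`).
#' @export
delta_aic <- function(fitA, fitB) {
  aic(fitA$lnL, fitA$k) - aic(fitB$lnL, fitB$k)
}

#' Bundle a likelihood evaluation into a fit result
#'
#' @param lnL total log-likelihood.
#' @param k parameter count.
#' @param breakdown optional data.frame with per-curve log-likelihoods.
#' @return object of class `fit_result` with `lnL`, `k`, `AIC`,
#'   `breakdown`.
#' @export
fit_result <- function(lnL, k, breakdown = NULL) {
  structure(list(lnL = lnL, k = k, AIC = aic(lnL, k),
                 breakdown = breakdown), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: lnL = %.6g, k = %d, AIC = %.6g\n",
              x$lnL, x$k, x$AIC))
  if (!is.null(x$breakdown)) print(x$breakdown)
  invisible(x)
}

#' Score simulated curves against reference curves
#'
#' Linearly interpolates each simulated curve onto the reference abscissae
#' and accumulates the Gaussian log-likelihood; one reference table per
#' curve with columns `x`, `mu`, `sigma`.
#'
#' @param curves named list of data.frames with columns `x`, `value`
#'   (simulation output).
#' @param references named list (same names) of data.frames with columns
#'   `x`, `mu`, `sigma`.
#' @param k parameter count of the generating model.
#' @return a [fit_result()] with a per-curve breakdown.
#' @export
score_against_reference <- function(curves, references, k) {
  if (!all(names(references) %in% names(curves)))
    stop("missing curves: ",
         paste(setdiff(names(references), names(curves)), collapse = ", "))
  rows <- lapply(names(references), function(nm) {
    ref <- references[[nm]]
    if (nrow(ref) == 0L) stop("empty reference for curve ", nm)
    sim <- curves[[nm]]
    xi <- approx(sim$x, sim$value, xout = ref$x, rule = 2)$y
    data.frame(curve = nm, n = nrow(ref),
               lnL = gaussian_loglik(xi, ref$mu, ref$sigma))
  })
  breakdown <- do.call(rbind, rows)
  fit_result(sum(breakdown$lnL), k, breakdown)
}

#' Write growth curves and profiles in tidy CSV form
#'
#' @param result a `spheroid_run` (see [run_simulation()]).
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_run_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$curve, file.path(dir, "growth_curve.csv"),
            row.names = FALSE)
  if (length(result$profiles)) {
    prof <- do.call(rbind, lapply(names(result$profiles), function(tm) {
      cbind(time = as.numeric(tm), result$profiles[[tm]])
    }))
    write.csv(prof, file.path(dir, "radial_profiles.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(result$provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
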