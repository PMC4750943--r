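#' Default image-processing thresholds
#'
#' Intensity and fractional thresholds of the staining classification:
#' `I_HOECHST` gates the nuclei channel before watershed segmentation;
#' `I_TUNEL`/`I_Ki67` decide pixel positivity in the marker channels and
#' `phi_TUNEL`/`phi_Ki67` the fraction of positive pixels required for a
#' nucleus to be called positive.
#' @param I_HOECHST,I_TUNEL,phi_TUNEL,I_Ki67,phi_Ki67 thresholds in \[0, 1\].
#' @return object of class `image_params`.
#' @export
image_params <- function(I_HOECHST = 0.15, I_TUNEL = 0.45, phi_TUNEL = 0.20,
                         I_Ki67 = 0.35, phi_Ki67 = 0.05) {
  v <- c(I_HOECHST = I_HOECHST, I_TUNEL = I_TUNEL, phi_TUNEL = phi_TUNEL,
         I_Ki67 = I_Ki67, phi_Ki67 = phi_Ki67)
  if (any(v < 0 | v > 1)) stop("image thresholds must lie in [0, 1]")
  structure(as.list(v), class = "image_params")
}

#' Median filter with reflective edge padding
#'
#' Each pixel is replaced by the median over its `n x n` window (Eq-style
#' impulse response of an edge-preserving smoother); edges are handled by
#' reflective padding.  For the common 3 x 3 case a vectorized
#' median-selection network is used.
#'
#' @param img numeric matrix (intensities).
#' @param n odd window size >= 3.
#' @return filtered matrix of the same shape.
#' @export
median_filter <- function(img, n = 3L) {
  if (n %% 2L != 1L || n < 3L) stop("window size must be odd and >= 3")
  a <- (n - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ridx <- reflect_index(nr, a)
  cidx <- reflect_index(nc, a)
  pad <- img[ridx, cidx, drop = FALSE]
  stack <- matrix(0, nr * nc, n * n)
  k <- 0L
  for (dy in 0:(n - 1L)) for (dx in 0:(n - 1L)) {
    k <- k + 1L
    stack[, k] <- as.vector(pad[dx + seq_len(nr), dy + seq_len(nc)])
  }
  med <- if (n == 3L) median9(stack) else apply(stack, 1L, median)
  matrix(med, nr, nc)
}

reflect_index <- function(len, a) {
  # reflective (mirror-without-repeat) padding indices 1..len with margin a
  idx <- c(seq.int(a + 1L, 2L, by = -1L), seq_len(len),
           seq.int(len - 1L, len - a, by = -1L))
  idx[idx < 1L] <- 1L
  idx[idx > len] <- len
  idx
}

# exact median of 9 per row using only pmin/pmax: sort each triple, then
# median9 = med3(max of minima, med3 of medians, min of maxima)
median9 <- function(m) {
  med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
  sw <- function(i, j) {
    lo <- pmin(m[, i], m[, j]); hi <- pmax(m[, i], m[, j])
    m[, i] <<- lo; m[, j] <<- hi
  }
  for (base in c(0L, 3L, 6L)) {
    sw(base + 1, base + 2); sw(base + 2, base + 3); sw(base + 1, base + 2)
  }
  med3(pmax(m[, 1], pmax(m[, 4], m[, 7])),
       med3(m[, 2], m[, 5], m[, 8]),
       pmin(m[, 3], pmin(m[, 6], m[, 9])))
}

#' Four-pass 3x3 median smoothing of a nuclei channel
#'
#' The preprocessing applied before nuclei segmentation: a short series of
#' small median filters removes noise while preserving nuclear edges (a
#' larger kernel would blur adjacent nuclei together).
#' @param img numeric matrix.
#' @param passes number of 3x3 passes.
#' @export
smooth_nuclei <- function(img, passes = 4L) {
  for (k in seq_len(passes)) img <- median_filter(img, 3L)
  img
}

#' Watershed segmentation of a thresholded nuclei channel
#'
#' Pixels above `I_thresh` form the foreground; the inverted intensity
#' landscape `1 - I` is flooded so that every catchment basin (one per
#' intensity peak) becomes one nucleus label.  Basins whose peak is less
#' than `tolerance` above the separating ridge are merged, which suppresses
#' over-segmentation from residual noise.
#'
#' @param img numeric matrix, intensities in \[0, 1).
#' @param I_thresh foreground threshold (default `I_HOECHST`).
#' @param tolerance minimum peak-to-ridge height difference.
#' @return object of class `segmentation`: list with the integer `labels`
#'   matrix (0 = background) and the nucleus count `n`.
#' @export
watershed_segment <- function(img, I_thresh = image_params()$I_HOECHST,
                              tolerance = 0.05) {
  if (any(img < 0 | img >= 1 + 1e-12)) stop("intensities must lie in [0, 1)")
  fg <- img > I_thresh
  x <- img
  x[!fg] <- 0
  labels <- EBImage::imageData(EBImage::watershed(x, tolerance = tolerance,
                                                  ext = 1))
  labels[!fg] <- 0L
  structure(list(labels = labels, n = max(labels)), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("segmentation:", x$n, "nuclei,",
      sum(x$labels > 0), "foreground pixels\n")
  invisible(x)
}

#' Per-nucleus centroids and sizes
#' @param seg a `segmentation`.
#' @return data.frame with id, x, y (pixel coordinates) and area (pixels).
#' @export
nuclei_table <- function(seg) {
  lab <- seg$labels
  px <- which(lab > 0)
  id <- lab[px]
  xi <- (px - 1) %% nrow(lab) + 1
  yi <- (px - 1) %/% nrow(lab) + 1
  data.frame(id = sort(unique(id)),
             x = as.vector(tapply(xi, id, mean)),
             y = as.vector(tapply(yi, id, mean)),
             area = as.vector(table(id)))
}

#' Classify nuclei by a marker channel
#'
#' A pixel is marker-positive when its intensity reaches `I_thresh`; a
#' nucleus is positive when the fraction of its positive pixels reaches
#' `phi_thresh`.
#'
#' @param seg a `segmentation`.
#' @param marker numeric matrix (same shape as the segmented channel).
#' @param I_thresh pixel intensity threshold.
#' @param phi_thresh fractional threshold.
#' @return logical vector of length `seg$n` (nucleus positivity).
#' @export
classify_nuclei <- function(seg, marker, I_thresh, phi_thresh) {
  if (!all(dim(marker) == dim(seg$labels)))
    stop("marker channel shape mismatch")
  if (I_thresh < 0 || I_thresh > 1 || phi_thresh < 0 || phi_thresh > 1)
    stop("thresholds must lie in [0, 1]")
  if (seg$n == 0L) return(logical(0))
  px <- which(seg$labels > 0)
  id <- seg$labels[px]
  pos <- as.numeric(marker[px] >= I_thresh)
  frac <- rowsum(pos, id)[, 1L] / as.vector(table(id))
  out <- logical(seg$n)
  out[sort(unique(id))] <- frac >= phi_thresh
  out
}

#' Confusion-matrix metrics of a nucleus classification
#'
#' Sensitivity `TPR = TP/(TP+FN)`, specificity `TNR = TN/(TN+FP)` and the
#' classification error `epsilon = (FP+FN)/(TP+FP+TN+FN)` against a gold
#' standard.
#'
#' @param flags logical vector (automated classification).
#' @param truth logical vector (gold standard, same length).
#' @return object of class `classification_metrics` with counts and ratios.
#' @export
compute_metrics <- function(flags, truth) {
  if (length(flags) != length(truth))
    stop("classification and gold standard cover different object sets")
  TP <- sum(flags & truth); FP <- sum(flags & !truth)
  TN <- sum(!flags & !truth); FN <- sum(!flags & truth)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 TNR = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
                 epsilon = (FP + FN) / max(TP + FP + TN + FN, 1L)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "TP %d FP %d TN %d FN %d | TPR %.3f TNR %.3f epsilon %.3f\n",
    x$TP, x$FP, x$TN, x$FN, x$TPR, x$TNR, x$epsilon))
  invisible(x)
}

#' Estimate the spheroid lumen and border from segmented nuclei
#'
#' The nuclei mask is inflated by a series of 3x3 dilations (a coarse
#' approximation of the cell bodies around the nuclei), holes (necrotic
#' areas) are filled, and the border is the set of lumen pixels adjacent to
#' the background.
#'
#' @param seg a `segmentation` with at least one nucleus.
#' @param dilations number of 3x3 dilation passes.
#' @return list with logical matrices `lumen` and `border`.
#' @export
estimate_lumen_and_border <- function(seg, dilations = 3L) {
  if (seg$n < 1L) stop("no nuclei to estimate a lumen from")
  brush <- EBImage::makeBrush(3L, shape = "box")
  m <- seg$labels > 0
  for (k in seq_len(dilations)) m <- EBImage::dilate(m, brush) > 0
  m <- EBImage::fillHull(m) > 0
  er <- EBImage::erode(m, brush) > 0
  list(lumen = m, border = m & !er)
}

#' Per-cell equivalent diameters from a discrete Voronoi tessellation
#'
#' Every raster pixel (clipped to the lumen when one is supplied) is
#' assigned to its nearest nucleus centroid; the pixel count of each
#' Voronoi region, times the pixel area, estimates the projected cell area
#' and the equivalent diameter is `2 sqrt(area / pi)`.  Cells whose region
#' touches the raster (or lumen) boundary are unbounded and excluded from
#' the `interior` flag.
#'
#' @param centroids n x 2 matrix of nucleus centers (um).
#' @param lumen optional logical matrix restricting the tessellated region.
#' @param pixel_size raster pixel edge length (um).
#' @param box optional c(xmin, xmax, ymin, ymax) tessellation window (um);
#'   defaults to the centroid bounding box padded by two mean spacings.
#' @return data.frame with id, x, y, area (um^2), diameter (um), interior.
#' @export
voronoi_cell_diameter <- function(centroids, lumen = NULL, pixel_size = 1,
                                  box = NULL) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 4L) stop("need at least 4 centroids")
  if (qr(sweep(centroids, 2L, colMeans(centroids)))$rank < 2L)
    stop("degenerate (collinear) centroids")
  if (!is.null(lumen)) {
    nr <- nrow(lumen); nc <- ncol(lumen)
    xs <- (seq_len(nr) - 0.5) * pixel_size
    ys <- (seq_len(nc) - 0.5) * pixel_size
    inside <- which(lumen)
    ri <- (inside - 1) %% nr + 1
    ci <- (inside - 1) %/% nr + 1
    px <- cbind(xs[ri], ys[ci])
    # rim pixels: on the raster edge or 4-adjacent to non-lumen pixels
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- lumen
    at <- function(dr, dc) pad[cbind(ri + 1L + dr, ci + 1L + dc)]
    edge_pix <- !(at(-1, 0) & at(1, 0) & at(0, -1) & at(0, 1))
  } else {
    if (is.null(box)) {
      spacing_guess <- sqrt(prod(apply(centroids, 2L, function(v)
        diff(range(v)))) / nrow(centroids))
      box <- c(range(centroids[, 1]) + c(-2, 2) * spacing_guess,
               range(centroids[, 2]) + c(-2, 2) * spacing_guess)
    }
    xs <- seq(box[1] + pixel_size / 2, box[2], by = pixel_size)
    ys <- seq(box[3] + pixel_size / 2, box[4], by = pixel_size)
    px <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    edge_pix <- px[, 1] %in% xs[c(1, length(xs))] |
      px[, 2] %in% ys[c(1, length(ys))]
  }
  n <- nrow(centroids)
  nearest <- integer(nrow(px))
  best <- rep(Inf, nrow(px))
  for (i in seq_len(n)) {
    d2 <- (px[, 1] - centroids[i, 1])^2 + (px[, 2] - centroids[i, 2])^2
    upd <- d2 < best
    nearest[upd] <- i
    best[upd] <- d2[upd]
  }
  counts <- tabulate(nearest, nbins = n)
  area <- counts * pixel_size^2
  touches_edge <- rep(FALSE, n)
  te <- unique(nearest[edge_pix])
  touches_edge[te] <- TRUE
  data.frame(id = seq_len(n), x = centroids[, 1], y = centroids[, 2],
             area = area, diameter = 2 * sqrt(area / pi),
             interior = !touches_edge & counts > 0)
}

#' Half-open radial binning of objects by border distance
#'
#' An object with distance `d` enters bin `floor(d / h)` (bin `i` covers
#' `[i h, (i+1) h)`); per-bin counts and, for each supplied logical column,
#' positive counts and fractions are returned.  Profiles from several
#' images are averaged bin-wise with [average_profiles()].
#'
#' @param distance numeric vector of border distances (um).
#' @param flags optional data.frame / named list of logical vectors.
#' @param h bin width (um).
#' @return data.frame with bin_lo, bin_mid, n and per-flag columns.
#' @export
radial_binning <- function(distance, flags = NULL, h = 1) {
  if (h <= 0) stop("bin width must be positive")
  if (any(distance < 0)) stop("distances must be non-negative")
  bin <- floor(distance / h)
  nb <- max(bin) + 1L
  out <- data.frame(bin_lo = (seq_len(nb) - 1L) * h,
                    bin_mid = (seq_len(nb) - 0.5) * h,
                    n = tabulate(bin + 1L, nbins = nb))
  for (nm in names(flags)) {
    pos <- tabulate((bin + 1L)[flags[[nm]]], nbins = nb)
    out[[paste0("n_", nm)]] <- pos
    out[[paste0("f_", nm)]] <- ifelse(out$n > 0, pos / out$n, NA_real_)
  }
  out
}

#' @rdname radial_binning
#' @param profiles list of data.frames from [radial_binning()] with equal
#'   bin widths; bin-wise arithmetic means of the fraction columns are
#'   returned over the images in which the bin is populated.
#' @export
average_profiles <- function(profiles) {
  nb <- max(vapply(profiles, nrow, 1L))
  template <- profiles[[which.max(vapply(profiles, nrow, 1L))]]
  out <- template[, c("bin_lo", "bin_mid")]
  fcols <- grep("^f_", names(template), value = TRUE)
  for (fc in fcols) {
    acc <- matrix(NA_real_, nb, length(profiles))
    for (k in seq_along(profiles)) {
      v <- profiles[[k]][[fc]]
      acc[seq_along(v), k] <- v
    }
    out[[fc]] <- rowMeans(acc, na.rm = TRUE)
    out[[paste0("sd_", sub("^f_", "", fc))]] <-
      apply(acc, 1L, stats::sd, na.rm = TRUE)
  }
  out$n_images <- rowSums(!is.na(
    vapply(profiles, function(p) {
      v <- rep(NA_real_, nb)
      v[seq_len(nrow(p))] <- p$n
      v
    }, numeric(nb))))
  out
}

#' Generate a synthetic stained spheroid section with ground truth
#'
#' Renders a multichannel section image emulating a stained cryosection:
#' nuclei as Gaussian blobs in the blue channel, a configurable fraction of
#' marker-positive nuclei in the red channel, and a radially increasing ECM
#' intensity in the green channel; additive Gaussian noise and a constant
#' background are optional.  Centers are placed on a jittered triangular
#' packing inside a disc, so nucleus spacing is controlled and collisions
#' cannot exceed the packing limit.
#'
#' @param n_nuclei requested nucleus count.
#' @param size image side length (pixels).
#' @param pixel_size um per pixel.
#' @param spacing center-to-center spacing of the packing (um).
#' @param nucleus_radius Gaussian blob radius parameter (um).
#' @param positive_fraction fraction of marker-positive nuclei.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param background constant background intensity.
#' @param fill if `TRUE`, every packing position inside the disc carries a
#'   nucleus (`n_nuclei` is ignored): a vacancy-free section whose cell
#'   areas equal the packing cell area, used to benchmark the Voronoi
#'   sizing.
#' @param seed integer seed.
#' @return list with `channels` (list of matrices red, green, blue),
#'   `truth` (data.frame x, y in pixels, positive flag), `pixel_size`.
#' @export
generate_synthetic_section <- function(n_nuclei = 120L, size = 192L,
                                       pixel_size = 1, spacing = 14,
                                       nucleus_radius = 3.5,
                                       positive_fraction = 0.3,
                                       noise_sd = 0.01, background = 0.02,
                                       fill = FALSE, seed = 1L) {
  if (spacing < 3 * nucleus_radius / 1.5)
    stop("nuclei too dense: spacing below the packing limit")
  with_seed(seed, {
    ctr <- size * pixel_size / 2
    rad <- 0.42 * size * pixel_size
    # jittered triangular packing inside a disc
    xs <- seq(spacing / 2, size * pixel_size, by = spacing)
    ys <- seq(spacing / 2, size * pixel_size, by = spacing * sqrt(3) / 2)
    pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
      off <- if (r %% 2 == 0) spacing / 2 else 0
      cbind(xs + off, ys[r])
    }))
    pts <- pts + matrix(runif(length(pts), -0.15, 0.15) * spacing,
                        ncol = 2L)
    keep <- sqrt((pts[, 1] - ctr)^2 + (pts[, 2] - ctr)^2) < rad
    pts <- pts[keep, , drop = FALSE]
    if (!fill) {
      if (nrow(pts) < n_nuclei)
        stop("disc too small for the requested nucleus count")
      pts <- pts[sample.int(nrow(pts), n_nuclei), , drop = FALSE]
    }
    n_nuclei <- nrow(pts)
    positive <- rep(FALSE, n_nuclei)
    positive[sample.int(n_nuclei, round(positive_fraction * n_nuclei))] <-
      TRUE

    xpix <- (seq_len(size) - 0.5) * pixel_size
    blob <- function(which_idx, amp) {
      img <- matrix(0, size, size)
      for (i in which_idx) {
        dx2 <- (xpix - pts[i, 1])^2
        dy2 <- (xpix - pts[i, 2])^2
        sub <- outer(dx2, dy2, `+`)
        img <- img + amp[i] * exp(-sub / (2 * nucleus_radius^2))
      }
      img
    }
    amp <- runif(n_nuclei, 0.75, 0.95)
    blue <- blob(seq_len(n_nuclei), amp)
    red <- blob(which(positive), amp)
    xg <- outer((xpix - ctr)^2, (xpix - ctr)^2, `+`)
    green <- 0.5 * pmax(1 - sqrt(xg) / rad, 0)   # matrix first: keep dims
    clipw <- function(img) {
      img <- img + background + rnorm(length(img), 0, noise_sd)
      pmin(pmax(img, 0), 1 - 1e-6)
    }
    list(channels = list(red = clipw(red), green = clipw(green),
                         blue = clipw(blue)),
         truth = data.frame(x = pts[, 1] / pixel_size,
                            y = pts[, 2] / pixel_size,
                            positive = positive),
         pixel_size = pixel_size)
  })
}

#' Match segmented nuclei to ground-truth centers
#'
#' Assigns each true center to the label of the pixel it falls on (or the
#' nearest labeled pixel within `max_dist`).
#' @param seg a `segmentation`.
#' @param truth data.frame with x, y in pixel coordinates.
#' @param max_dist maximal center-to-label distance (pixels).
#' @return integer vector of labels (NA where unmatched).
#' @export
match_nuclei <- function(seg, truth, max_dist = 5) {
  lab <- seg$labels
  nt <- nuclei_table(seg)
  out <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    xi <- round(truth$x[i]); yi <- round(truth$y[i])
    xi <- min(max(xi, 1L), nrow(lab)); yi <- min(max(yi, 1L), ncol(lab))
    l <- lab[xi, yi]
    if (l == 0L) {
      d2 <- (nt$x - truth$x[i])^2 + (nt$y - truth$y[i])^2
      j <- which.min(d2)
      l <- if (sqrt(d2[j]) <= max_dist) nt$id[j] else NA_integer_
    }
    out[i] <- l
  }
  out
}

#' Read and write section images as TIFF or PNG
#'
#' Thin wrappers around [EBImage::readImage()] / [EBImage::writeImage()]
#' returning plain channel matrices.
#' @param path image file.
#' @export
read_section_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) return(list(gray = d))
  list(red = d[, , 1], green = d[, , 2], blue = d[, , 3])
}

#' @rdname read_section_image
#' @param channels list with matrices red, green, blue.
#' @export
write_section_image <- function(channels, path) {
  arr <- simplify2array(channels[c("red", "green", "blue")])
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}
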