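# Section-image analysis: filtering, segmentation, classification,
# lumen/border, Voronoi sizing, radial binning, synthetic generator.

test_that("median filter: constants, impulse removal, brute-force oracle", {
  img <- matrix(0.4, 20, 20)
  expect_equal(median_filter(img, 3), img)
  # single bright pixel in zeros disappears
  img2 <- matrix(0, 15, 15)
  img2[8, 8] <- 1
  expect_true(all(median_filter(img2, 3) == 0))
  # random integer image vs an exhaustive sort-based oracle (both 3x3 with
  # the vectorized network and 5x5 with the generic path)
  set.seed(1)
  img3 <- matrix(sample(0:9, 12 * 11, replace = TRUE) / 10, 12, 11)
  for (n in c(3L, 5L)) {
    a <- (n - 1L) %/% 2L
    oracle <- matrix(0, 12, 11)
    for (x in 1:12) for (y in 1:11) {
      xs <- pmin(pmax(x + (-a:a), 1), 12)
      # reflective padding oracle
      rx <- x + (-a:a); rx[rx < 1] <- 2 - rx[rx < 1]
      rx[rx > 12] <- 2 * 12 - rx[rx > 12]
      ry <- y + (-a:a); ry[ry < 1] <- 2 - ry[ry < 1]
      ry[ry > 11] <- 2 * 11 - ry[ry > 11]
      oracle[x, y] <- median(img3[rx, ry])
    }
    expect_equal(median_filter(img3, n), oracle)
  }
  expect_error(median_filter(img3, 4), "odd")
})

test_that("median filter is idempotent on piecewise-constant plateaus", {
  img <- matrix(0, 24, 24)
  img[6:18, 6:18] <- 0.8
  once <- smooth_nuclei(img, passes = 4)
  again <- median_filter(once, 3)
  expect_equal(again, once)
})

test_that("watershed finds the generated nuclei, background below threshold", {
  # two well-separated Gaussian blobs
  xs <- 1:64
  blob <- function(cx, cy) outer(exp(-(xs - cx)^2 / 18),
                                 exp(-(xs - cy)^2 / 18)) * 0.9
  img <- pmin(blob(20, 20) + blob(45, 45), 0.999)
  seg <- watershed_segment(img, I_thresh = 0.15)
  expect_equal(seg$n, 2L)
  # all pixels below threshold: no nuclei
  expect_equal(watershed_segment(matrix(0.05, 32, 32), 0.15)$n, 0L)
  # labels invariant under a monotone intensity rescaling that preserves
  # the threshold crossing
  resc <- function(v) 0.15 + (v > 0.15) * (v - 0.15) * 0.5
  seg2 <- watershed_segment(resc(img) + (img <= 0.15) * (img - 0.15) * 0.2,
                            I_thresh = 0.15)
  expect_equal(seg2$n, 2L)
  expect_true(all((seg$labels > 0) == (seg2$labels > 0)))
})

test_that("nucleus classification follows the pixel and fraction thresholds", {
  lab <- matrix(0L, 10, 10)
  lab[1:2, 1:5] <- 1L   # nucleus of 10 pixels
  seg <- list(labels = lab, n = 1L)
  class(seg) <- "segmentation"
  marker <- matrix(0, 10, 10)
  marker[1, 1] <- 0.9    # exactly one positive pixel
  # 1/10 positive pixels < phi = 0.2 -> negative
  expect_false(classify_nuclei(seg, marker, I_thresh = 0.5,
                               phi_thresh = 0.2))
  # phi = 0.1 -> positive
  expect_true(classify_nuclei(seg, marker, I_thresh = 0.5,
                              phi_thresh = 0.1))
  # saturated nucleus is positive at any thresholds
  expect_true(classify_nuclei(seg, matrix(1, 10, 10), 1, 1))
  expect_error(classify_nuclei(seg, matrix(1, 5, 5), 0.5, 0.5),
               "mismatch")
})

test_that("confusion metrics are exact on toy matrices", {
  perfect <- compute_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$TPR, 1)
  expect_equal(perfect$TNR, 1)
  expect_equal(perfect$epsilon, 0)
  # TP=45 FP=5 TN=40 FN=10
  flags <- c(rep(TRUE, 45), rep(TRUE, 5), rep(FALSE, 40), rep(FALSE, 10))
  truth <- c(rep(TRUE, 45), rep(FALSE, 5), rep(FALSE, 40), rep(TRUE, 10))
  m <- compute_metrics(flags, truth)
  expect_equal(m$TPR, 45 / 55)
  expect_equal(m$TNR, 40 / 45)
  expect_equal(m$epsilon, 0.15)
  flipped <- compute_metrics(!truth, truth)
  expect_equal(flipped$TPR, 0)
  expect_equal(flipped$TNR, 0)
  expect_equal(flipped$epsilon, 1)
  expect_error(compute_metrics(TRUE, c(TRUE, FALSE)), "different")
})

test_that("lumen estimation: dilated disc, merging, hole filling", {
  lab <- matrix(0L, 40, 40)
  lab[18:22, 18:22] <- 1L
  seg <- structure(list(labels = lab, n = 1L), class = "segmentation")
  lb <- estimate_lumen_and_border(seg, dilations = 3)
  expect_true(all(lb$lumen[which(lab > 0)]))
  expect_gt(sum(lb$lumen), sum(lab > 0))
  expect_true(all(lb$border | !lb$lumen | EBImage::erode(
    lb$lumen, EBImage::makeBrush(3, "box")) > 0))
  # two overlapping dilated discs become one connected lumen
  lab2 <- matrix(0L, 40, 40)
  lab2[15:18, 18:21] <- 1L
  lab2[24:27, 18:21] <- 2L
  seg2 <- structure(list(labels = lab2, n = 2L), class = "segmentation")
  lb2 <- estimate_lumen_and_border(seg2, dilations = 3)
  cc <- EBImage::bwlabel(lb2$lumen)
  expect_equal(max(cc), 1)
  # a hole strictly inside the lumen is filled
  ring <- matrix(0L, 40, 40)
  ring[12:28, 12:28] <- 1L
  ring[18:22, 18:22] <- 0L
  seg3 <- structure(list(labels = ring, n = 1L), class = "segmentation")
  lb3 <- estimate_lumen_and_border(seg3, dilations = 1)
  expect_true(all(lb3$lumen[18:22, 18:22]))
  expect_error(estimate_lumen_and_border(
    structure(list(labels = matrix(0L, 4, 4), n = 0L),
              class = "segmentation")), "no nuclei")
})

test_that("discrete Voronoi diameters recover lattice closed forms", {
  # square grid spacing s: every interior cell has area s^2
  s <- 10
  pts <- as.matrix(expand.grid(x = seq(5, 95, by = s),
                               y = seq(5, 95, by = s)))
  vd <- voronoi_cell_diameter(pts, pixel_size = 0.5,
                              box = c(-5, 105, -5, 105))
  interior <- vd$interior &
    pts[, 1] > 10 & pts[, 1] < 90 & pts[, 2] > 10 & pts[, 2] < 90
  expect_gt(sum(interior), 10)
  expect_equal(mean(vd$diameter[interior]), 2 * sqrt(s^2 / pi),
               tolerance = 0.01)
  # translation invariance
  vd2 <- voronoi_cell_diameter(pts + 3, pixel_size = 0.5,
                               box = c(-5, 105, -5, 105) + 3)
  expect_equal(vd2$diameter[interior], vd$diameter[interior],
               tolerance = 1e-10)
  # hexagonal packing spacing s: cell area sqrt(3)/2 s^2
  hx <- do.call(rbind, lapply(0:12, function(r)
    cbind(seq(0, 120, by = s) + (r %% 2) * s / 2, r * s * sqrt(3) / 2)))
  vh <- voronoi_cell_diameter(hx, pixel_size = 0.5,
                              box = c(-10, 135, -10, 120))
  ih <- vh$interior & hx[, 1] > 20 & hx[, 1] < 100 &
    hx[, 2] > 20 & hx[, 2] < 85
  expect_equal(mean(vh$diameter[ih]), 2 * sqrt(sqrt(3) / 2 * s^2 / pi),
               tolerance = 0.01)
  expect_error(voronoi_cell_diameter(pts[1:3, ]), "at least 4")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(voronoi_cell_diameter(line), "collinear")
})

test_that("radial binning: half-open edges, conservation, averaging", {
  d <- c(0, 0.999, 1, 1.5, 2, 5)
  rb <- radial_binning(d, h = 1)
  expect_equal(rb$n[1], 2L)   # 0 and 0.999
  expect_equal(rb$n[2], 2L)   # 1 (edge -> bin 1) and 1.5
  expect_equal(rb$n[3], 1L)
  expect_equal(sum(rb$n), length(d))
  # flags produce counts and fractions
  rb2 <- radial_binning(d, flags = list(pos = c(TRUE, FALSE, TRUE, TRUE,
                                                FALSE, FALSE)), h = 1)
  expect_equal(rb2$f_pos[1], 0.5)
  expect_equal(rb2$f_pos[2], 1.0)
  # two-image average equals the arithmetic mean per bin
  p1 <- radial_binning(c(0.5, 1.5), flags = list(pos = c(TRUE, FALSE)),
                       h = 1)
  p2 <- radial_binning(c(0.4, 1.6), flags = list(pos = c(FALSE, FALSE)),
                       h = 1)
  avg <- average_profiles(list(p1, p2))
  expect_equal(avg$f_pos, c(0.5, 0))
  expect_error(radial_binning(c(-1, 2)), "non-negative")
})

test_that("synthetic sections: reproducible, segmentable, classifiable", {
  sec <- generate_synthetic_section(n_nuclei = 60, size = 160,
                                    positive_fraction = 0.3,
                                    noise_sd = 0.005, seed = 42)
  sec_rep <- generate_synthetic_section(n_nuclei = 60, size = 160,
                                        positive_fraction = 0.3,
                                        noise_sd = 0.005, seed = 42)
  expect_identical(sec$channels$blue, sec_rep$channels$blue)
  expect_identical(sec$truth, sec_rep$truth)
  expect_equal(nrow(sec$truth), 60L)
  expect_true(all(sec$channels$blue >= 0 & sec$channels$blue < 1))
  # low-noise segmentation recovers the nucleus count exactly
  sm <- smooth_nuclei(sec$channels$blue)
  seg <- watershed_segment(sm, I_thresh = 0.15, tolerance = 0.1)
  expect_equal(seg$n, 60L)
  # known positive fraction recovered by classification at the default
  # marker thresholds
  lab_of_truth <- match_nuclei(seg, sec$truth)
  expect_true(all(!is.na(lab_of_truth)))
  flags <- classify_nuclei(seg, sec$channels$red, I_thresh = 0.35,
                           phi_thresh = 0.05)
  recovered <- flags[lab_of_truth]
  m <- compute_metrics(recovered, sec$truth$positive)
  expect_lt(m$epsilon, 0.05)
  # density above the packing limit is rejected
  expect_error(generate_synthetic_section(n_nuclei = 50, size = 64,
                                          spacing = 4,
                                          nucleus_radius = 3.5),
               "packing")
})
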