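truth_centers <- function(series) {
  as.matrix(series$truth[, c("x_mm", "y_mm")])
}

test_that("edge detection: constant image yields no edges, discs yield rings", {
  expect_equal(sum(detect_edges(matrix(5, 64, 64))), 0L)

  # one sharp disc: edge-pixel centroid within 1 pixel of the disc center
  n <- 128
  cx <- 70.3; cy <- 52.8
  img <- matrix(0, n, n)
  idx <- which(outer((1:n - cy)^2, (1:n - cx)^2, "+") <= 15^2)
  img[idx] <- 1
  e <- detect_edges(img)
  pos <- which(e, arr.ind = TRUE)
  expect_lt(abs(mean(pos[, 2]) - cx), 1)
  expect_lt(abs(mean(pos[, 1]) - cy), 1)
})

test_that("edges of the rendered phantom ring every sphere boundary", {
  l <- layout_3t()
  s <- ir_series_clean()
  e <- detect_edges(s$images[[1]])
  pos <- which(e, arr.ind = TRUE)
  n <- s$protocol$matrix_size
  p <- s$protocol$pixel_mm
  ex <- ((pos[, 2] - 1) - (n - 1) / 2) * p
  ey <- ((pos[, 1] - 1) - (n - 1) / 2) * p
  for (sp in 1:14) {
    d <- sqrt((ex - l$sphere_centers_mm[sp, 1])^2 +
                (ey - l$sphere_centers_mm[sp, 2])^2)
    on_ring <- sum(abs(d - l$inner_radius_mm) <= 1.5 * p)
    expect_gte(on_ring, 8)
  }
})

test_that("rigid registration recovers applied transforms within 0.5 mm / 0.5 deg", {
  l <- layout_3t()
  cases <- list(c(0, 0, 0), c(6, -4, 5), c(-9, 7, -10))
  for (cs in cases) {
    s <- render_series(l, acquisition_protocol("ir"),
                       translation_mm = cs[1:2], rotation_deg = cs[3])
    tf <- fit_rigid_transform(detect_edges(s$images[[1]]), l)
    expect_lt(max(abs(tf$translation_mm - cs[1:2])), 0.5)
    expect_lt(abs(tf$rotation_deg - cs[3]), 0.5)
  }
})

test_that("registration fails on empty or pure-noise edge maps", {
  l <- layout_3t()
  expect_error(fit_rigid_transform(matrix(FALSE, 256, 256), l), "no edges")
  set.seed(7)
  noise_edges <- matrix(runif(256^2) < 0.02, 256, 256)
  expect_error(fit_rigid_transform(noise_edges, l), "registration failed")
})

test_that("center refinement reaches the true centers on clean data", {
  s <- ir_series_clean()
  rois <- rois_clean()
  err_px <- sqrt((rois$centers$x_mm - s$truth$x_mm)^2 +
                   (rois$centers$y_mm - s$truth$y_mm)^2) / 0.98
  expect_lt(max(err_px), 0.25)
  expect_false(any(rois$centers$flagged))
})

test_that("per-sphere refinement reduces center error under geometric distortion", {
  # distort the true sphere positions by ~1 mm, but register/refine against
  # the undistorted template
  set.seed(21)
  l <- layout_3t()
  ldist <- l
  jitter <- matrix(runif(28, -1, 1), 14, 2)
  ldist$sphere_centers_mm <- l$sphere_centers_mm + jitter
  s <- render_series(ldist, acquisition_protocol("ir"))
  img <- s$images[[1]]
  tf <- fit_rigid_transform(detect_edges(img), l)
  init <- t1phantom:::transform_points(l$sphere_centers_mm, tf$rotation_deg,
                                       tf$translation_mm)
  refined <- refine_centers(img, tf, l)
  truth <- truth_centers(s)
  err_init <- mean(sqrt(rowSums((init - truth)^2)))
  err_refined <- mean(sqrt(rowSums(
    (cbind(refined$x_mm, refined$y_mm) - truth)^2)))
  expect_lt(err_refined, err_init)
  expect_lt(err_refined, 0.25)   # mm
})

test_that("a sphere whose window diverges is flagged and kept at its initialisation", {
  l <- layout_3t()
  s <- ir_series_clean()
  # deliberately misplace the whole template near the edge of the water disc
  bad_tf <- structure(list(translation_mm = c(0, 18), rotation_deg = 0,
                           objective = NA, coverage = NA),
                      class = "rigid_transform")
  expect_warning(
    centers <- refine_centers(s$images[[1]], bad_tf, l),
    "diverged")
  init <- t1phantom:::transform_points(l$sphere_centers_mm, 0, c(0, 18))
  flagged <- centers$flagged
  expect_true(any(flagged))
  expect_equal(cbind(centers$x_mm, centers$y_mm)[flagged, , drop = FALSE],
               init[flagged, , drop = FALSE], ignore_attr = TRUE)
})

test_that("ROI masks have the expected lattice pixel counts at 0.98 mm pixels", {
  centers0 <- tibble::tibble(sphere = 1L, x_mm = 0, y_mm = 0)
  # center exactly on a pixel center (odd matrix puts a pixel at the origin)
  roi <- extract_rois(centers0, matrix_size = 255, radius_mm = 4.0)
  expect_identical(lengths(roi$masks), 49L)
  # tiny radius keeps only the center pixel
  roi1 <- extract_rois(centers0, matrix_size = 255, radius_mm = 0.1)
  expect_identical(lengths(roi1$masks), 1L)
  # radius touching the sphere boundary is refused
  expect_error(extract_rois(centers0, 255, radius_mm = 7.5), "inner radius")

  # over random subpixel placements the count stays within the lattice bounds
  set.seed(5)
  counts <- replicate(300, {
    cen <- tibble::tibble(sphere = 1L,
                          x_mm = runif(1, -0.49, 0.49),
                          y_mm = runif(1, -0.49, 0.49))
    lengths(extract_rois(cen, 255, radius_mm = 4.0)$masks)
  })
  expect_true(all(counts >= 45 & counts <= 59))
})

test_that("ROI masks are pairwise disjoint and within 4 mm of their centers", {
  rois <- rois_clean()
  all_idx <- unlist(rois$masks)
  expect_identical(anyDuplicated(all_idx), 0L)
  n <- rois$matrix_size
  coords <- ((1:n - 1) - (n - 1) / 2) * rois$pixel_mm
  for (sp in 1:14) {
    pos <- arrayInd(rois$masks[[sp]], c(n, n))
    d <- sqrt((coords[pos[, 2]] - rois$centers$x_mm[sp])^2 +
                (coords[pos[, 1]] - rois$centers$y_mm[sp])^2)
    expect_true(all(d <= rois$radius_mm))
  }
})

test_that("ROI means are exact on noise-free data and linear in intensity", {
  l <- layout_3t()
  s <- ir_series_clean()
  rois <- rois_clean()
  m <- roi_means(s, rois)
  expected <- tidyr::expand_grid(sphere = 1:14, ti = s$series_values) |>
    dplyr::mutate(sig = ir_signal_full(ti, l$reference_t1_ms[sphere], 1, 4500))
  joined <- dplyr::left_join(m, expected,
                             by = c(sphere = "sphere", series_value = "ti"))
  expect_equal(joined$mean_signal, joined$sig)

  s2 <- s
  s2$images <- lapply(s$images, function(x) 3.5 * x)
  m2 <- roi_means(s2, rois)
  expect_equal(m2$mean_signal, 3.5 * m$mean_signal)
})

test_that("ROI-mean noise scales as sigma over sqrt(mask size)", {
  l <- layout_3t()
  sigma <- 0.02
  vals <- sapply(1:40, function(seed) {
    p <- acquisition_protocol("ir", ti_list_ms = c(35, 100, 500, 3000),
                              noise_sigma = sigma, rng_seed = seed)
    s <- render_series(l, p)
    m <- roi_means(s, rois_clean())
    m$mean_signal[m$sphere == 1 & m$series_value == 3000]
  })
  npix <- lengths(rois_clean()$masks)[1]
  # high-SNR magnitude noise is approximately Gaussian with sd sigma
  expect_equal(sd(vals), sigma / sqrt(npix), tolerance = 0.4)
})

test_that("integer-pixel image shifts shift the recovered centers equivariantly", {
  l <- layout_3t()
  s <- ir_series_clean()
  img <- s$images[[1]]
  di <- 3L; dj <- -4L   # rows (y), cols (x)
  n <- nrow(img)
  shifted <- matrix(0, n, n)
  shifted[(1 + max(di, 0)):(n + min(di, 0)),
          (1 + max(dj, 0)):(n + min(dj, 0))] <-
    img[(1 - min(di, 0)):(n - max(di, 0)),
        (1 - min(dj, 0)):(n - max(dj, 0))]

  segment_raw <- function(im) {
    tf <- fit_rigid_transform(detect_edges(im), l)
    refine_centers(im, tf, l)
  }
  c0 <- segment_raw(img)
  c1 <- segment_raw(shifted)
  p <- s$protocol$pixel_mm
  expect_equal(c1$x_mm, c0$x_mm + dj * p, tolerance = 1e-3)
  expect_equal(c1$y_mm, c0$y_mm + di * p, tolerance = 1e-3)
})

test_that("geometry mismatch between series and ROIs is rejected", {
  s <- ir_series_clean()
  rois <- rois_clean()
  rois$pixel_mm <- 1.0
  expect_error(roi_means(s, rois), "geometry")
})
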