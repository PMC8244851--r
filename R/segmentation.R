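# Sphere localisation: gradient edges -> rigid template registration ->
# per-sphere center refinement -> 4 mm ROI extraction.

#' Detect region edges by gradient filtering and thresholding
#'
#' Central-difference gradient magnitude, thresholded to keep the
#' highest-gradient pixels (top 4% by default, enough to retain the faint
#' boundaries of the longest-T1 spheres alongside the strong water/air
#' boundary), producing the binary edge map that drives template
#' registration.
#'
#' @param image 2D nonnegative matrix.
#' @param threshold_quantile Quantile of the gradient magnitude above which a
#'   pixel counts as an edge.
#' @return Logical matrix of edge pixels.
#' @export
detect_edges <- function(image, threshold_quantile = 0.96) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stop("image must be nonnegative")
  n <- nrow(image); m <- ncol(image)
  gx <- matrix(0, n, m)
  gy <- matrix(0, n, m)
  gx[, 2:(m - 1)] <- (image[, 3:m] - image[, 1:(m - 2)]) / 2
  gy[2:(n - 1), ] <- (image[3:n, ] - image[1:(n - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  thr <- stats::quantile(mag, threshold_quantile, names = FALSE)
  mag > thr
}

# continuous registration objective: mean bilinearly interpolated distance
# (px) from transformed template boundary points to the nearest edge pixel
template_boundary_mm <- function(layout, n_boundary) {
  phi <- 2 * pi * (seq_len(n_boundary) - 1) / n_boundary
  ring <- cbind(cos(phi), sin(phi)) * layout$inner_radius_mm
  do.call(rbind, lapply(1:14, function(s) {
    sweep(ring, 2, layout$sphere_centers_mm[s, ], "+")
  }))
}

bilinear_at <- function(D, row, col) {
  nr <- nrow(D); nc <- ncol(D)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1); c0 <- pmin(floor(col), nc - 1)
  fr <- row - r0; fc <- col - c0
  D[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    D[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    D[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    D[cbind(r0 + 1, c0 + 1)] * fr * fc
}

transform_points <- function(pts, rotation_deg, translation_mm) {
  th <- rotation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(pts %*% t(rot), 2, translation_mm, "+")
}

#' Register the known sphere template to an edge map
#'
#' Finds the in-plane rigid transformation (translation + rotation) placing
#' the 14 template sphere boundaries onto the detected edge pixels. A coarse
#' grid over translation and rotation minimises the mean distance from
#' transformed boundary points to the nearest edge pixel (precomputed exact
#' Euclidean distance transform, capped at `distance_cap_px` so that a few
#' missing boundary segments cannot dominate the score); a Nelder-Mead
#' refinement then polishes the optimum. Coverage (fraction of boundary
#' points within 1.5 px of an edge) is reported for quality control and
#' gates failure.
#'
#' @param edges Logical edge matrix from [detect_edges()].
#' @param layout Phantom layout providing template centers and radius.
#' @param pixel_mm Pixel size of the edge image.
#' @param translation_range_mm,translation_step_mm Coarse grid extent/step for
#'   both translation axes.
#' @param rotation_range_deg,rotation_step_deg Coarse grid extent/step for
#'   rotation.
#' @param n_boundary Boundary points sampled per template circle.
#' @param distance_cap_px Cap (pixels) on per-point distances entering the
#'   registration score.
#' @param coverage_floor Minimum acceptable coverage; below it registration
#'   is declared failed.
#' @return A `rigid_transform`: list with `translation_mm`, `rotation_deg`
#'   (normalized to (-180, 180]), `objective` (mean boundary-to-edge distance
#'   in px) and `coverage`.
#' @export
fit_rigid_transform <- function(edges, layout, pixel_mm = 0.98,
                                translation_range_mm = 20,
                                translation_step_mm = 1,
                                rotation_range_deg = 15,
                                rotation_step_deg = 1,
                                n_boundary = 36,
                                distance_cap_px = 3,
                                coverage_floor = 0.5) {
  stopifnot(is.matrix(edges))
  if (!any(edges)) stop("no edges detected")
  D <- pmin(.distance_transform_cpp(edges), distance_cap_px)
  rots <- seq(-rotation_range_deg, rotation_range_deg, by = rotation_step_deg)
  txs <- seq(-translation_range_mm, translation_range_mm,
             by = translation_step_mm)
  scores <- .rigid_score_grid_cpp(D, layout$sphere_centers_mm,
                                  layout$inner_radius_mm, as.integer(n_boundary),
                                  pixel_mm, rots, txs, txs)
  idx <- arrayInd(which.min(scores), dim(scores))
  init <- c(rots[idx[1]], txs[idx[2]], txs[idx[3]])

  tmpl <- template_boundary_mm(layout, n_boundary)
  n <- nrow(D)
  obj <- function(p) {
    pts <- transform_points(tmpl, p[1], p[2:3])
    col <- pts[, 1] / pixel_mm + (n - 1) / 2 + 1
    row <- pts[, 2] / pixel_mm + (n - 1) / 2 + 1
    mean(bilinear_at(D, row, col))
  }
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  p <- opt$par
  pts <- transform_points(tmpl, p[1], p[2:3])
  dvals <- bilinear_at(D, pts[, 2] / pixel_mm + (n - 1) / 2 + 1,
                       pts[, 1] / pixel_mm + (n - 1) / 2 + 1)
  coverage <- mean(dvals <= 1.5)
  if (coverage < coverage_floor) {
    stop("registration failed: boundary coverage ", signif(coverage, 3),
         " below floor ", coverage_floor)
  }
  rot <- ((p[1] + 180) %% 360) - 180
  if (rot == -180) rot <- 180
  structure(
    list(translation_mm = c(p[2], p[3]), rotation_deg = rot,
         objective = opt$value, coverage = coverage),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> translation (",
      paste(signif(x$translation_mm, 4), collapse = ", "),
      ") mm, rotation ", signif(x$rotation_deg, 4), " deg; coverage ",
      signif(x$coverage, 3), "\n", sep = "")
  invisible(x)
}

#' Refine each sphere center individually
#'
#' Starting from the rigid-transform positions, iterates an
#' intensity-weighted centroid of the inverted image (spheres are dark in the
#' shortest-TI image) within a local window around each sphere until the
#' update falls below tolerance. Per-sphere refinement accommodates smooth
#' geometric distortion. A sphere whose refined center drifts more than half
#' the inner radius from its initialisation is flagged and kept at the
#' initialised position.
#'
#' @param image The image used for segmentation (shortest-TI IR image).
#' @param transform A `rigid_transform` from [fit_rigid_transform()].
#' @param layout Phantom layout.
#' @param pixel_mm Pixel size.
#' @param window_factor Window half-width as a multiple of the inner radius.
#' @param tol_px Convergence tolerance on the center update (pixels).
#' @param max_iter Maximum centroid iterations per sphere.
#' @return Tibble with columns `sphere`, `x_mm`, `y_mm`, `flagged`.
#' @export
refine_centers <- function(image, transform, layout, pixel_mm = 0.98,
                           window_factor = 1.5, tol_px = 0.01,
                           max_iter = 50) {
  n <- nrow(image)
  init <- transform_points(layout$sphere_centers_mm, transform$rotation_deg,
                           transform$translation_mm)
  hw <- round(window_factor * layout$inner_radius_mm / pixel_mm)
  coords <- pixel_coords_mm(n, pixel_mm)

  r_window <- window_factor * layout$inner_radius_mm
  r_core <- layout$inner_radius_mm / 2
  refine_one <- function(c0) {
    cc <- c0
    dark <- TRUE
    for (it in seq_len(max_iter)) {
      col0 <- round(cc[1] / pixel_mm + (n - 1) / 2 + 1)
      row0 <- round(cc[2] / pixel_mm + (n - 1) / 2 + 1)
      rows <- max(1, row0 - hw):min(n, row0 + hw)
      cols <- max(1, col0 - hw):min(n, col0 + hw)
      sub <- image[rows, cols, drop = FALSE]
      xw <- matrix(coords[cols], length(rows), length(cols), byrow = TRUE)
      yw <- matrix(coords[rows], length(rows), length(cols))
      # circular window: keeps the weights clear of unrelated structure
      d2 <- (xw - cc[1])^2 + (yw - cc[2])^2
      inside <- d2 <= r_window^2
      if (it == 1) {
        # weight polarity: pull toward the sphere whether it is darker or
        # brighter than its immediate surroundings (fixed after iteration 1
        # so the target cannot flip while the centroid moves)
        core <- d2 <= r_core^2
        ring <- inside & d2 > layout$inner_radius_mm^2
        dark <- !any(ring) || mean(sub[core]) <= mean(sub[ring])
      }
      w <- if (dark) (max(sub[inside]) - sub) * inside
           else (sub - min(sub[inside])) * inside
      sw <- sum(w)
      if (sw == 0) break
      new <- c(sum(w * xw), sum(w * yw)) / sw
      moved <- sqrt(sum((new - cc)^2)) / pixel_mm
      cc <- new
      if (moved < tol_px) break
    }
    cc
  }

  out <- t(apply(init, 1, refine_one))
  drift <- sqrt(rowSums((out - init)^2))
  flagged <- drift > layout$inner_radius_mm / 2
  if (any(flagged)) {
    warning(sum(flagged), " sphere center(s) diverged during refinement; ",
            "keeping rigid-transform positions for sphere(s) ",
            paste(which(flagged), collapse = ", "))
    out[flagged, ] <- init[flagged, ]
  }
  tibble::tibble(sphere = 1:14, x_mm = out[, 1], y_mm = out[, 2],
                 flagged = flagged)
}

#' Extract circular ROI masks around refined centers
#'
#' A pixel belongs to a sphere's ROI when its center lies within `radius_mm`
#' of the refined sphere center (pixel-center membership; at 0.98 mm pixels
#' and 4 mm radius this yields about 52 pixels per ROI).
#'
#' @param centers Tibble with `sphere`, `x_mm`, `y_mm` (from
#'   [refine_centers()]).
#' @param matrix_size Image matrix size.
#' @param pixel_mm Pixel size.
#' @param radius_mm ROI radius; must be smaller than the sphere inner radius.
#' @param inner_radius_mm Sphere inner radius used for the validity check.
#' @return A `roi_set`: list with `centers`, `masks` (per-sphere integer
#'   pixel-index vectors), `matrix_size`, `pixel_mm`, `radius_mm`.
#' @export
extract_rois <- function(centers, matrix_size, pixel_mm = 0.98,
                         radius_mm = 4.0, inner_radius_mm = 7.5) {
  if (radius_mm >= inner_radius_mm) {
    stop("ROI radius must be smaller than the sphere inner radius")
  }
  n <- matrix_size
  coords <- pixel_coords_mm(n, pixel_mm)
  xmat <- matrix(coords, n, n, byrow = TRUE)
  ymat <- matrix(coords, n, n)
  half_fov <- n * pixel_mm / 2
  masks <- purrr::map2(centers$x_mm, centers$y_mm, function(cx, cy) {
    if (abs(cx) > half_fov || abs(cy) > half_fov) {
      stop("sphere center outside the image")
    }
    which((xmat - cx)^2 + (ymat - cy)^2 <= radius_mm^2)
  })
  structure(
    list(centers = centers, masks = masks, matrix_size = as.integer(n),
         pixel_mm = pixel_mm, radius_mm = radius_mm),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>", length(x$masks), "ROIs of radius", x$radius_mm,
      "mm;", round(mean(lengths(x$masks)), 1), "pixels per ROI on average\n")
  invisible(x)
}

#' Mean ROI signal per series point
#'
#' Averages pixel intensities inside each ROI mask for every image of the
#' series, producing the tidy signal table consumed by the fitters. ROIs are
#' determined on the shortest-TI IR image and reused unchanged for the VFA
#' series of the same session.
#'
#' @param series An `image_series`.
#' @param rois A `roi_set` with matching geometry.
#' @return Tibble with columns `sphere`, `series_value`, `mean_signal`.
#' @export
roi_means <- function(series, rois) {
  stopifnot(inherits(series, "image_series"), inherits(rois, "roi_set"))
  if (nrow(series$images[[1]]) != rois$matrix_size ||
      abs(series$protocol$pixel_mm - rois$pixel_mm) > 1e-9) {
    stop("ROI geometry does not match the image series")
  }
  out <- purrr::map2_dfr(series$images, series$series_values, function(img, v) {
    tibble::tibble(
      sphere = rois$centers$sphere,
      series_value = v,
      mean_signal = purrr::map_dbl(rois$masks, ~ mean(img[.x]))
    )
  })
  if (anyNA(out$mean_signal)) stop("ROI mean produced NaN (empty mask?)")
  out
}

#' Segment an image series end to end
#'
#' Runs edge detection, rigid template registration, per-sphere center
#' refinement and ROI extraction on the segmentation image of a series (the
#' shortest-TI image of an IR stack; the first image otherwise).
#'
#' @param series An `image_series` (IR recommended).
#' @param layout The phantom layout used as template.
#' @param radius_mm ROI radius in mm.
#' @param ... Passed to [fit_rigid_transform()].
#' @return A `roi_set`.
#' @export
segment_series <- function(series, layout, radius_mm = 4.0, ...) {
  stopifnot(inherits(series, "image_series"))
  img <- if (series$protocol$modality == "ir") {
    # shortest inversion time: long-T1 background is strongly suppressed
    series$images[[which.min(series$series_values)]]
  } else {
    # largest flip angle: spheres are brightest relative to the saturated
    # long-T1 background, giving the strongest edge contrast
    series$images[[which.max(series$series_values)]]
  }
  edges <- detect_edges(img)
  tf <- fit_rigid_transform(edges, layout,
                            pixel_mm = series$protocol$pixel_mm, ...)
  centers <- refine_centers(img, tf, layout,
                            pixel_mm = series$protocol$pixel_mm)
  extract_rois(centers, series$protocol$matrix_size,
               pixel_mm = series$protocol$pixel_mm, radius_mm = radius_mm,
               inner_radius_mm = layout$inner_radius_mm)
}
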