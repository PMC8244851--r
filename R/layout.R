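# NiCl2 array geometry and NMR reference T1 values.

# Reference T1 (ms) of the 14 NiCl2 spheres, NMR measurement service values,
# sphere 1 = longest T1. Keyed by static field strength in tesla.
.reference_t1 <- list(
  `1.5` = c(1955, 1454, 985, 704, 496, 352, 246, 174, 126, 88, 62, 44, 30, 22),
  `3`   = c(2033, 1489, 1012, 731, 514, 368, 260, 185, 133, 93, 65, 46, 32, 23)
)

#' Build the 14-sphere NiCl2 array layout
#'
#' Constructs the planar geometry of the system phantom's T1 reference array:
#' ten spheres evenly spaced on an outer circle and the four shortest-T1
#' spheres on a central square grid, together with the NMR-traceable reference
#' T1 value of each sphere at the requested field strength.
#'
#' @param field_tesla Static field strength; one of 1.5 or 3.0.
#' @param outer_radius_mm Radius of the circle carrying spheres 1-10 (mm).
#' @param grid_spacing_mm Side length of the central square carrying spheres
#'   11-14 (mm).
#' @param inner_radius_mm Inner radius of each sphere (mm); the liquid volume
#'   whose T1 is certified.
#' @param background_signal_level Relative equilibrium signal of the water
#'   background (sphere contents have level 1); the default leaves every
#'   sphere darker than the background in the shortest-inversion-time image.
#'
#' @return An object of class `phantom_layout`: a list with `sphere_centers_mm`
#'   (14 x 2 matrix, x/y in mm relative to the array center), `inner_radius_mm`,
#'   `reference_t1_ms` (length-14, strictly decreasing), `field_tesla`, and
#'   `background_signal_level`.
#' @examples
#' layout <- build_layout(3.0)
#' layout$reference_t1_ms[1]   # 2033
#' @export
build_layout <- function(field_tesla,
                         outer_radius_mm = 45,
                         grid_spacing_mm = 20,
                         inner_radius_mm = 7.5,
                         background_signal_level = 1.5) {
  key <- as.character(field_tesla)
  if (key == "3.0") key <- "3"
  if (!key %in% names(.reference_t1)) {
    stop("unsupported field strength: ", field_tesla, " T (supported: 1.5, 3.0)")
  }
  # spheres 1-10 on the outer circle, starting at the top, clockwise
  ang <- pi / 2 - 2 * pi * (0:9) / 10
  outer <- cbind(outer_radius_mm * cos(ang), outer_radius_mm * sin(ang))
  h <- grid_spacing_mm / 2
  inner <- rbind(c(-h, h), c(h, h), c(-h, -h), c(h, -h))
  centers <- rbind(outer, inner)
  colnames(centers) <- c("x_mm", "y_mm")

  layout <- structure(
    list(
      sphere_centers_mm = centers,
      inner_radius_mm = inner_radius_mm,
      reference_t1_ms = .reference_t1[[key]],
      field_tesla = as.numeric(field_tesla),
      background_signal_level = background_signal_level
    ),
    class = "phantom_layout"
  )
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  stopifnot(nrow(layout$sphere_centers_mm) == 14L,
            length(layout$reference_t1_ms) == 14L)
  if (any(diff(layout$reference_t1_ms) >= 0)) {
    stop("reference T1 values must be strictly decreasing with sphere index")
  }
  d <- as.matrix(stats::dist(layout$sphere_centers_mm))
  diag(d) <- Inf
  if (any(d <= 2 * layout$inner_radius_mm)) {
    stop("sphere layout has overlapping spheres")
  }
  invisible(layout)
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat("<phantom_layout> 14-sphere NiCl2 T1 array at", x$field_tesla, "T\n")
  cat("  inner radius:", x$inner_radius_mm, "mm; reference T1",
      max(x$reference_t1_ms), "-", min(x$reference_t1_ms), "ms\n")
  invisible(x)
}

#' Tidy the sphere table of a phantom layout
#'
#' @param x A `phantom_layout`.
#' @param ... Unused.
#' @return A tibble with one row per sphere: index, center coordinates and
#'   reference T1.
#' @export
tidy.phantom_layout <- function(x, ...) {
  tibble::tibble(
    sphere = 1:14,
    x_mm = x$sphere_centers_mm[, 1],
    y_mm = x$sphere_centers_mm[, 2],
    t1_nmr_ms = x$reference_t1_ms
  )
}
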