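#' Equivalent-circle radius of the head cross-section, in pixels
#'
#' The pixel count of the segmented head area is taken as the head's
#' cross-section; the equivalent-circle radius is `sqrt(area / pi)`. Using
#' the area rather than a fitted outline is deliberately robust to partial
#' leaf occlusion of the head rim.
#'
#' @param head_mask An [instance_mask] of class `head`.
#' @return Radius in pixels.
#' @export
head_radius_px <- function(head_mask) {
  area <- sum(head_mask$raster)
  if (area < 1L) {
    stop("degenerate mask: empty head mask", call. = FALSE)
  }
  sqrt(area / pi)
}

#' Camera-to-equator distance of the cabbage head
#'
#' The camera sees the top of the head, but the cross-section that the
#' segmented area represents lies at the head's equator, one radius below
#' the apex. With apex distance `Z0` (a robust minimum of the in-mask
#' depths) the coupled system "equator distance = apex distance + metric
#' radius" and the pinhole conversion at the equator has the closed-form
#' solution `r_mm = r_px * Z0 / (f - r_px)`, hence `H = Z0 + r_mm`.
#'
#' @param head_mask An [instance_mask].
#' @param depth A [depth_raster].
#' @param camera A [camera_model].
#' @param r_px Equivalent-circle radius in pixels (see [head_radius_px]).
#' @param apex_percentile Quantile of in-mask depths used as the apex
#'   distance; default 0.05 for robustness to depth speckle.
#' @return Camera-to-equator distance H in mm.
#' @export
cross_section_distance <- function(head_mask, depth, camera, r_px,
                                   apex_percentile = 0.05) {
  d <- unclass(depth)[head_mask$raster]
  d <- d[!is.na(d)]
  if (length(d) == 0L) {
    stop("missing depth: no valid depth pixel inside head mask",
         call. = FALSE)
  }
  f <- camera$focal_length
  if (r_px >= f) {
    stop("geometry error: r_px >= focal length", call. = FALSE)
  }
  z0 <- as.numeric(stats::quantile(d, apex_percentile))
  r_mm <- r_px * z0 / (f - r_px)
  z0 + r_mm
}

#' Convert a pixel radius to millimetres
#'
#' Default pinhole reading: `r_mm = r_px * H / f` — an object at distance H
#' spans `H / f` millimetres per pixel. A literal mode `r_mm = r_px * k / H`
#' (with `k = 1 / f`) is selectable for sensitivity experiments; it inverts
#' the distance dependence and is physically implausible, but kept for
#' auditability of the conversion-rule choice.
#'
#' @param r_px Radius in pixels.
#' @param H Camera-to-cross-section distance in mm (> 0).
#' @param camera A [camera_model].
#' @param mode `"pinhole"` (default) or `"literal"`.
#' @return Radius in mm.
#' @export
px_to_mm <- function(r_px, H, camera, mode = c("pinhole", "literal")) {
  mode <- match.arg(mode)
  if (H <= 0) {
    stop("domain error: H must be positive", call. = FALSE)
  }
  if (mode == "pinhole") {
    r_px * H / camera$focal_length
  } else {
    r_px * (1 / camera$focal_length) / H
  }
}

#' Sphere volume from a radius in millimetres
#'
#' @param radius Radius in mm (>= 0).
#' @return Volume in m^3: `(4/3) pi (radius/1000)^3`.
#' @export
sphere_volume <- function(radius) {
  if (any(radius < 0)) {
    stop("domain error: negative radius", call. = FALSE)
  }
  (4 / 3) * pi * (radius / 1000)^3
}

#' Head volume from a measured circumference
#'
#' Ground-truth helper: the harvested head's circumference tape measure is
#' converted to an equivalent sphere volume (`radius = circumference /
#' (2 pi)`). The sphere assumption is an approximation of a real cabbage
#' head, adequate for round storage cultivars.
#'
#' @param circumference Circumference in mm (> 0).
#' @return Volume in m^3.
#' @export
volume_from_circumference <- function(circumference) {
  if (any(circumference <= 0)) {
    stop("domain error: circumference must be positive", call. = FALSE)
  }
  sphere_volume(circumference / (2 * pi))
}

#' Millimetre-per-pixel scale from a reference object
#'
#' A reference object of known physical size placed on the imaged plane
#' calibrates the scale used to convert scanned ground-truth leaf masks to
#' metric area (each pixel contributes scale^2 mm^2).
#'
#' @param reference_mask An [instance_mask] of the reference object.
#' @param known_size Physical extent in mm along the chosen axis.
#' @param axis `"width"` (column extent, default) or `"height"`.
#' @return mm per pixel.
#' @export
reference_scale <- function(reference_mask, known_size,
                            axis = c("width", "height")) {
  axis <- match.arg(axis)
  idx <- which(reference_mask$raster, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("degenerate mask: empty reference mask", call. = FALSE)
  }
  extent <- if (axis == "width") diff(range(idx[, 2])) + 1
            else diff(range(idx[, 1])) + 1
  known_size / extent
}

#' Combine reference scales from several markers
#'
#' @param scales Numeric vector of mm-per-pixel estimates.
#' @param tolerance Maximum allowed relative spread before an inconsistency
#'   warning; default 0.01.
#' @return The mean scale; warns when the spread exceeds `tolerance`.
#' @export
combine_reference_scales <- function(scales, tolerance = 0.01) {
  m <- mean(scales)
  if (length(scales) > 1 && (max(scales) - min(scales)) / m > tolerance) {
    warning(sprintf("inconsistent reference scales (spread %.2f%%)",
                    100 * (max(scales) - min(scales)) / m), call. = FALSE)
  }
  m
}

#' Measure a cabbage head: radius and sphere volume
#'
#' Composition of [head_radius_px], [cross_section_distance], [px_to_mm]
#' and [sphere_volume].
#'
#' @param head_mask An [instance_mask] of class `head`.
#' @param depth A [depth_raster].
#' @param camera A [camera_model].
#' @param apex_percentile Passed to [cross_section_distance].
#' @param mode Conversion mode for [px_to_mm].
#' @return Object of class `head_measure`: `radius_px`, `radius_mm`,
#'   `cross_section_distance` (mm) and `volume` (m^3).
#' @export
measure_head <- function(head_mask, depth, camera, apex_percentile = 0.05,
                         mode = "pinhole") {
  r_px <- head_radius_px(head_mask)
  H <- cross_section_distance(head_mask, depth, camera, r_px,
                              apex_percentile)
  r_mm <- px_to_mm(r_px, H, camera, mode)
  structure(list(radius_px = r_px, cross_section_distance = H,
                 radius_mm = r_mm, volume = sphere_volume(r_mm)),
            class = "head_measure")
}

#' @export
print.head_measure <- function(x, ...) {
  cat(sprintf(
    "<head_measure> r = %.1f px -> %.1f mm at H = %.0f mm, volume %.5f m^3\n",
    x$radius_px, x$radius_mm, x$cross_section_distance, x$volume))
  invisible(x)
}
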