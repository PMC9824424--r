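#' Intersection points of leaf-plane triples
#'
#' Three planes in general position meet in a single point. For every
#' unordered triple of per-leaf planes the 3x3 linear system
#' `z = a_i x + b_i y + c_i` is solved; a solution is kept when (i) the
#' system is well conditioned (absolute determinant of the row-normalised
#' matrix at least `det_threshold` — near-parallel leaf planes otherwise
#' produce wild far-away points), (ii) its projection into the image falls
#' inside the plant mask, and (iii) its height lies within the plausibility
#' bounds `z_bounds` (by default between the ground plane and the camera).
#'
#' @param planes List of `leaf_plane` objects (>= 3).
#' @param plant_mask Optional [instance_mask] of the whole plant; `NULL`
#'   disables the in-mask filter (useful for analytic tests).
#' @param camera A [camera_model]; required when `plant_mask` is given, and
#'   used for the default `z_bounds`.
#' @param det_threshold Conditioning threshold on the normalised
#'   determinant.
#' @param z_bounds Numeric `(z_min, z_max)` in mm; default
#'   `c(0, camera_height)` when a camera is supplied, otherwise no bound.
#' @return Numeric matrix (columns x, y, z) of surviving intersection
#'   points; zero rows raises a no-support error in [attachment_point].
#' @export
triple_intersections <- function(planes, plant_mask = NULL, camera = NULL,
                                 det_threshold = 1e-6, z_bounds = NULL) {
  if (length(planes) < 3L) {
    stop("insufficient planes: need at least 3", call. = FALSE)
  }
  if (is.null(z_bounds)) {
    z_bounds <- if (!is.null(camera)) c(0, camera$camera_height)
                else c(-Inf, Inf)
  }
  triples <- utils::combn(length(planes), 3)
  pts <- matrix(numeric(0), ncol = 3)
  for (k in seq_len(ncol(triples))) {
    tri <- planes[triples[, k]]
    # rows of a x + b y - z = -c, normalised to unit gradient
    A <- t(vapply(tri, function(p) c(p$a, p$b, -1), numeric(3)))
    rhs <- -vapply(tri, function(p) p$c, numeric(1))
    norms <- sqrt(rowSums(A^2))
    An <- A / norms
    if (abs(det(An)) < det_threshold) next
    sol <- solve(A, rhs)
    if (sol[3] < z_bounds[1] || sol[3] > z_bounds[2]) next
    if (!is.null(plant_mask)) {
      if (is.null(camera)) {
        stop("camera required for the in-mask filter", call. = FALSE)
      }
      d <- camera$camera_height - sol[3]
      if (d <= 0) next
      col0 <- round(sol[1] * camera$focal_length / d +
                      camera$principal_point[1])
      row0 <- round(sol[2] * camera$focal_length / d +
                      camera$principal_point[2])
      if (col0 < 0 || row0 < 0 ||
          col0 >= camera$image_size[1] || row0 >= camera$image_size[2]) next
      if (!plant_mask$raster[row0 + 1, col0 + 1]) next
    }
    pts <- rbind(pts, sol)
  }
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  pts
}

#' Average intersection points into the leaf-attachment point
#'
#' The attachment point — the hidden point at the stem centre where the
#' leaves converge — is the arithmetic mean of the surviving plane
#' intersection points. A median aggregate is available for robustness
#' experiments.
#'
#' @param intersections Numeric matrix (columns x, y, z), >= 1 row.
#' @param aggregate `"mean"` (default) or `"median"` (component-wise).
#' @return An object of class `attachment_point`: `position` (x, y, z mm),
#'   `support` (number of points), `dispersion` (RMS distance of the points
#'   from the position, mm).
#' @export
attachment_point <- function(intersections, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(intersections))) {
    intersections <- matrix(intersections, ncol = 3)
  }
  if (nrow(intersections) < 1L) {
    stop("no support: empty intersection set", call. = FALSE)
  }
  position <- if (aggregate == "mean") colMeans(intersections)
              else apply(intersections, 2, stats::median)
  d2 <- rowSums(sweep(intersections, 2, position)^2)
  structure(list(position = stats::setNames(as.numeric(position),
                                            c("x", "y", "z")),
                 support = nrow(intersections),
                 dispersion = sqrt(mean(d2))),
            class = "attachment_point")
}

#' @export
print.attachment_point <- function(x, ...) {
  cat(sprintf(
    "<attachment_point> (%.1f, %.1f, %.1f) mm, support %d, dispersion %.2f mm\n",
    x$position[1], x$position[2], x$position[3], x$support, x$dispersion))
  invisible(x)
}

#' Locate the stem (leaf-attachment point) of one plant
#'
#' Full composition: each leaf cloud is MSAC-filtered and a regression
#' plane fitted to its inliers; all plane triples are intersected, filtered
#' to the segmented plant area and plausibility bounds, and averaged.
#'
#' @param leaf_clouds List of [leaf_cloud]s (>= 3 usable leaves).
#' @param plant_mask Optional [instance_mask] of the whole plant.
#' @param camera A [camera_model].
#' @param config An [msac_config].
#' @param det_threshold,z_bounds,aggregate Passed to
#'   [triple_intersections] and [attachment_point].
#' @return An `attachment_point`; the fitted per-leaf planes are attached
#'   as attribute `planes`.
#' @export
locate_stem <- function(leaf_clouds, plant_mask = NULL, camera = NULL,
                        config = msac_config(), det_threshold = 1e-6,
                        z_bounds = NULL, aggregate = "mean") {
  usable <- Filter(function(cl) nrow(cl) >= 3L, leaf_clouds)
  if (length(usable) < 3L) {
    stop("insufficient planes: need at least 3 leaves with >= 3 points",
         call. = FALSE)
  }
  planes <- lapply(usable, function(cl) {
    fit_plane_lsq(msac_filter(cl, config))
  })
  pts <- triple_intersections(planes, plant_mask, camera,
                              det_threshold = det_threshold,
                              z_bounds = z_bounds)
  if (nrow(pts) == 0L) {
    stop("no support: no plane-triple intersection survived the filters",
         call. = FALSE)
  }
  ap <- attachment_point(pts, aggregate = aggregate)
  attr(ap, "planes") <- planes
  ap
}
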