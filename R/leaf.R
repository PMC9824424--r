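#' Assign leaf masks to plant masks
#'
#' A leaf belongs to a plant when more than `threshold` (default 80%) of
#' its segmented area lies inside the plant's segmented area. If several
#' plants exceed the threshold the largest overlap fraction wins (ties go
#' to the lower plant id); leaves exceeding it for no plant stay
#' unassigned.
#'
#' @param leaf_masks List of leaf [instance_mask]s.
#' @param plant_masks List of plant [instance_mask]s on the same grid.
#' @param threshold Overlap fraction that must be exceeded; default 0.8.
#' @return Data frame with columns `leaf_id`, `plant_id` (`NA` when
#'   unassigned) and `overlap` (the winning fraction).
#' @export
assign_leaves <- function(leaf_masks, plant_masks, threshold = 0.8) {
  plant_ids <- vapply(plant_masks, function(m) m$instance_id, integer(1))
  res <- lapply(leaf_masks, function(leaf) {
    area <- sum(leaf$raster)
    fracs <- vapply(plant_masks, function(plant) {
      sum(leaf$raster & plant$raster) / area
    }, numeric(1))
    ok <- which(fracs > threshold)
    if (length(ok) == 0L) {
      data.frame(leaf_id = leaf$instance_id, plant_id = NA_integer_,
                 overlap = if (length(fracs)) max(fracs) else 0)
    } else {
      # largest fraction wins; order() breaks exact ties by lower plant id
      best <- ok[order(-fracs[ok], plant_ids[ok])][1]
      data.frame(leaf_id = leaf$instance_id, plant_id = plant_ids[best],
                 overlap = fracs[best])
    }
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Leaf endpoint: farthest cloud point from the attachment point
#'
#' @param cloud A [leaf_cloud] (or n x 3 matrix).
#' @param p An `attachment_point` or numeric (x, y, z).
#' @return Numeric (x, y, z) of the point with the greatest 3D Euclidean
#'   distance to `p`; ties broken by first occurrence in scan order.
#' @export
leaf_endpoint <- function(cloud, p) {
  pts <- unclass(cloud)
  if (nrow(pts) < 1L) {
    stop("degenerate cloud: empty", call. = FALSE)
  }
  pos <- if (inherits(p, "attachment_point")) p$position else p
  d2 <- (pts[, 1] - pos[1])^2 + (pts[, 2] - pos[2])^2 + (pts[, 3] - pos[3])^2
  stats::setNames(as.numeric(pts[which.max(d2), ]), c("x", "y", "z"))
}

#' 3D leaf length
#'
#' Straight-line Euclidean distance between the leaf base (attachment
#' point) and the leaf endpoint; leaf curvature is deliberately not
#' followed.
#'
#' @param p Attachment point (`attachment_point` or numeric xyz).
#' @param q Leaf endpoint (numeric xyz).
#' @return Length in mm.
#' @export
leaf_length <- function(p, q) {
  pos <- if (inherits(p, "attachment_point")) p$position else p
  sqrt(sum((as.numeric(q) - as.numeric(pos))^2))
}

#' Leaf areas from lengths (length-based allometry)
#'
#' Each leaf's area is its length times the plant's mean leaf length times
#' a dimensionless shape factor (default 2.7): `area_i = Lbar * L_i * 2.7`,
#' converted from mm^2 to m^2. The mean length and the factor stand in for
#' the leaf width, which a nadir camera cannot see. The total over n leaves
#' satisfies the closed form `total = 2.7 * n * Lbar^2`.
#'
#' @param lengths Numeric vector of leaf lengths in mm (> 0, >= 1 leaf).
#' @param shape_factor Allometric shape factor; default 2.7.
#' @return List with `areas` (m^2, per leaf), `total` (m^2) and
#'   `mean_length` (mm).
#' @export
leaf_areas <- function(lengths, shape_factor = 2.7) {
  if (length(lengths) < 1L) {
    stop("empty plant: no leaf lengths", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("invalid measure: leaf lengths must be positive", call. = FALSE)
  }
  lbar <- mean(lengths)
  areas <- lbar * lengths * shape_factor * 1e-6   # mm^2 -> m^2
  list(areas = areas, total = sum(areas), mean_length = lbar)
}

#' Measure all leaves of one plant
#'
#' For each leaf cloud: endpoint (farthest point from the attachment
#' point), 3D length, then areas via the length allometry.
#'
#' @param leaf_clouds List of [leaf_cloud]s (>= 1).
#' @param attachment An `attachment_point`.
#' @param shape_factor Allometric factor; default 2.7.
#' @return List with `leaves` (data frame: leaf_id, endpoint coordinates,
#'   length_mm, area_m2), `mean_leaf_length` (mm) and `total_leaf_area`
#'   (m^2).
#' @export
measure_plant_leaves <- function(leaf_clouds, attachment, shape_factor = 2.7) {
  if (length(leaf_clouds) < 1L) {
    stop("empty plant: no leaf clouds", call. = FALSE)
  }
  ends <- t(vapply(leaf_clouds, leaf_endpoint, numeric(3), p = attachment))
  lengths <- vapply(seq_len(nrow(ends)), function(i) {
    leaf_length(attachment, ends[i, ])
  }, numeric(1))
  la <- leaf_areas(lengths, shape_factor)
  ids <- vapply(leaf_clouds, function(cl) {
    id <- attr(cl, "leaf_id")
    if (is.null(id)) NA_integer_ else id
  }, integer(1))
  list(
    leaves = data.frame(leaf_id = ids,
                        end_x = ends[, 1], end_y = ends[, 2], end_z = ends[, 3],
                        length_mm = lengths, area_m2 = la$areas),
    mean_leaf_length = la$mean_length,
    total_leaf_area = la$total)
}
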