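#' Pinhole camera model for a nadir view
#'
#' Describes the camera that produced the co-registered image and depth
#' raster: a pinhole model looking straight down at the canopy from a fixed
#' height above the ground plane.
#'
#' Image coordinates are 0-based `(col, row)` with the origin at the top-left
#' pixel. The world frame has its origin on the ground plane directly below
#' the principal point, `z` pointing up, `x` along increasing column and `y`
#' along increasing row. Depth values are camera-to-surface distances along
#' the optical axis, so surface height is `camera_height - depth`.
#'
#' @param focal_length Focal length in pixels (> 0).
#' @param principal_point Numeric `(cx, cy)` in 0-based pixel coordinates;
#'   defaults to the image centre.
#' @param camera_height Camera height above the ground plane in mm (> 0).
#'   The default 900 mm matches a boom-mounted survey rig driven over the
#'   crop rows.
#' @param image_size Integer `(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(focal_length = 1000, image_size = c(1024, 1024))
#' cam
#' @export
camera_model <- function(focal_length = 1000,
                         principal_point = NULL,
                         camera_height = 900,
                         image_size = c(1024L, 1024L)) {
  stopifnot(is.numeric(focal_length), length(focal_length) == 1L,
            is.finite(focal_length), focal_length > 0,
            is.numeric(camera_height), length(camera_height) == 1L,
            is.finite(camera_height), camera_height > 0,
            length(image_size) == 2L, all(image_size >= 1))
  image_size <- as.integer(image_size)
  if (is.null(principal_point)) {
    principal_point <- (image_size - 1) / 2
  }
  stopifnot(length(principal_point) == 2L, all(is.finite(principal_point)))
  if (principal_point[1] < 0 || principal_point[1] > image_size[1] - 1 ||
      principal_point[2] < 0 || principal_point[2] > image_size[2] - 1) {
    stop("principal_point must lie inside the image bounds", call. = FALSE)
  }
  structure(
    list(focal_length = focal_length,
         principal_point = as.numeric(principal_point),
         camera_height = camera_height,
         image_size = image_size),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> f = %g px, principal point (%g, %g), %d x %d px, height %g mm\n",
              x$focal_length, x$principal_point[1], x$principal_point[2],
              x$image_size[1], x$image_size[2], x$camera_height))
  invisible(x)
}

#' Depth raster
#'
#' A per-pixel grid of camera-to-surface distances in millimetres. Invalid
#' (no-data) pixels are stored as `NA`.
#'
#' @param values Numeric matrix `[height, width]` of distances in mm; `NA`
#'   marks no-data pixels. All non-`NA` values must be finite and > 0.
#' @return An object of class `depth_raster` (a matrix with class attribute).
#' @export
depth_raster <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  v <- values[!is.na(values)]
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("depth values must be finite and positive (use NA for no-data)",
         call. = FALSE)
  }
  structure(values, class = c("depth_raster", "matrix"))
}

#' @export
print.depth_raster <- function(x, ...) {
  v <- x[!is.na(x)]
  cat(sprintf("<depth_raster> %d x %d px, %d valid (%.1f%%), range [%g, %g] mm\n",
              nrow(x), ncol(x), length(v), 100 * length(v) / length(x),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

mask_classes <- c("plant", "head", "leaf")

#' Instance segmentation mask
#'
#' One binary raster together with its class label (`plant`, `head` or
#' `leaf`), an integer instance id, and an optional detection confidence.
#' `head` is the crop class: the forming cabbage head.
#'
#' @param raster Logical matrix `[height, width]` with at least one `TRUE`
#'   pixel.
#' @param class_label One of `"plant"`, `"head"`, `"leaf"`.
#' @param instance_id Integer id, unique within its class for a scene.
#' @param score Optional confidence in `[0, 1]` (`NA` for ground truth).
#' @return An object of class `instance_mask`.
#' @export
instance_mask <- function(raster, class_label, instance_id, score = NA_real_) {
  stopifnot(is.matrix(raster))
  if (!is.logical(raster)) {
    storage.mode(raster) <- "logical"
  }
  if (!any(raster)) {
    stop("instance mask must contain at least one true pixel", call. = FALSE)
  }
  class_label <- match.arg(class_label, mask_classes)
  if (!is.na(score) && (score < 0 || score > 1)) {
    stop("score must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(raster = raster, class_label = class_label,
         instance_id = as.integer(instance_id), score = as.numeric(score)),
    class = "instance_mask")
}

#' @export
print.instance_mask <- function(x, ...) {
  cat(sprintf("<instance_mask> class %s, id %d, %d px%s\n",
              x$class_label, x$instance_id, sum(x$raster),
              if (is.na(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

#' Leaf point cloud
#'
#' Back-projected 3D points of one segmented leaf, in the world frame
#' (mm, z up from the ground plane).
#'
#' @param points Numeric matrix with columns `x`, `y`, `z` (mm) and at least
#'   3 rows.
#' @param leaf_id Integer leaf instance id.
#' @param plant_id Optional integer plant id.
#' @return An object of class `leaf_cloud` (numeric matrix with attributes).
#' @export
leaf_cloud <- function(points, leaf_id = NA_integer_, plant_id = NA_integer_) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 3L) {
    stop("degenerate cloud: fewer than 3 points", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("cloud coordinates must be finite", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(points, class = c("leaf_cloud", "matrix"),
            leaf_id = as.integer(leaf_id), plant_id = as.integer(plant_id))
}

#' @export
print.leaf_cloud <- function(x, ...) {
  cat(sprintf("<leaf_cloud> leaf %s, %d points\n",
              attr(x, "leaf_id"), nrow(x)))
  invisible(x)
}

# Internal: run expr with a private RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
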