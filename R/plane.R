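#' MSAC configuration
#'
#' Parameters for M-estimator sample consensus outlier rejection on leaf
#' point clouds. MSAC scores a candidate plane by the sum of truncated
#' squared orthogonal residuals, `sum(pmin(r^2, tol^2))`, so (unlike plain
#' RANSAC) residuals below the tolerance still discriminate between
#' candidates.
#'
#' @param distance_tolerance Inlier tolerance in mm (> 0). Default 10 mm,
#'   of the order of leaf thickness plus photogrammetric depth noise.
#' @param max_iterations Number of random 3-point samples (>= 1). When the
#'   cloud is small enough that all 3-point subsets number at most
#'   `max_iterations`, every subset is tried instead of sampling.
#' @param min_inlier_fraction Support below this fraction flags the result
#'   with a `low_support` attribute and a warning.
#' @param rng_seed Integer seed making the sampling deterministic.
#' @return An object of class `msac_config`.
#' @export
msac_config <- function(distance_tolerance = 10, max_iterations = 500L,
                        min_inlier_fraction = 0.5, rng_seed = 1L) {
  stopifnot(distance_tolerance > 0, max_iterations >= 1,
            min_inlier_fraction > 0, min_inlier_fraction <= 1)
  structure(list(distance_tolerance = distance_tolerance,
                 max_iterations = as.integer(max_iterations),
                 min_inlier_fraction = min_inlier_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "msac_config")
}

# Plane through 3 points as unit normal + offset; NULL when collinear.
plane_from_triplet <- function(p1, p2, p3) {
  v1 <- p2 - p1
  v2 <- p3 - p1
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(n^2))
  scale <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
  if (nn < 1e-9 * scale^2) return(NULL)
  list(normal = n / nn, offset = sum(n / nn * p1))
}

#' Remove point-cloud outliers with MSAC
#'
#' Robustly identifies the dominant plane in a leaf point cloud and returns
#' only the points within the distance tolerance of it. Candidate planes are
#' spanned by random 3-point samples and scored by the truncated squared
#' orthogonal residual sum; the minimum-score plane wins. Deterministic for
#' a given `rng_seed`.
#'
#' @param cloud A [leaf_cloud] (or n x 3 matrix) with at least 3
#'   non-collinear points.
#' @param config An [msac_config].
#' @return A [leaf_cloud] containing the inlier subset, in input order. If
#'   the inlier fraction falls below `min_inlier_fraction` the result
#'   carries attribute `low_support = TRUE` and a warning is raised.
#' @export
msac_filter <- function(cloud, config = msac_config()) {
  pts <- unclass(cloud)
  n <- nrow(pts)
  stopifnot(n >= 3L)
  tol <- config$distance_tolerance
  n_triples <- choose(n, 3)
  if (n_triples <= config$max_iterations) {
    samples <- utils::combn(n, 3)
  } else {
    samples <- with_seed(config$rng_seed, {
      replicate(config$max_iterations, sample.int(n, 3L))
    })
  }
  best_score <- Inf
  best_plane <- NULL
  for (k in seq_len(ncol(samples))) {
    s <- samples[, k]
    pl <- plane_from_triplet(pts[s[1], ], pts[s[2], ], pts[s[3], ])
    if (is.null(pl)) next
    r2 <- (pts %*% pl$normal - pl$offset)^2
    score <- sum(pmin(r2, tol^2))
    if (score < best_score) {
      best_score <- score
      best_plane <- pl
    }
  }
  if (is.null(best_plane)) {
    stop("degenerate geometry: all candidate samples collinear",
         call. = FALSE)
  }
  keep <- abs(pts %*% best_plane$normal - best_plane$offset) <= tol
  out <- leaf_cloud(pts[keep, , drop = FALSE],
                    leaf_id = attr(cloud, "leaf_id"),
                    plant_id = attr(cloud, "plant_id"))
  frac <- sum(keep) / n
  if (frac < config$min_inlier_fraction) {
    attr(out, "low_support") <- TRUE
    warning(sprintf("low support: inlier fraction %.2f below %.2f",
                    frac, config$min_inlier_fraction), call. = FALSE)
  }
  out
}

#' Fit a regression plane to a point cloud
#'
#' Least-squares multiple linear regression of z on x and y: minimises the
#' vertical residual sum `sum((z - a x - b y - c)^2)`. For a leaf this plane
#' carries the leaf's orientation inward, towards the hidden attachment
#' point at the stem.
#'
#' @param cloud A [leaf_cloud] (or n x 3 matrix), at least 3 points with
#'   non-collinear (x, y).
#' @return An object of class `leaf_plane`: list with slopes `a`, `b`
#'   (mm/mm), offset `c` (mm) of `z = a x + b y + c`, and `inlier_count`.
#' @export
fit_plane_lsq <- function(cloud) {
  pts <- unclass(cloud)
  stopifnot(nrow(pts) >= 3L)
  X <- cbind(pts[, 1], pts[, 2], 1)
  qr_x <- qr(X)
  if (qr_x$rank < 3L) {
    stop("degenerate geometry: collinear x,y support", call. = FALSE)
  }
  coefs <- qr.coef(qr_x, pts[, 3])
  structure(list(a = coefs[[1]], b = coefs[[2]], c = coefs[[3]],
                 inlier_count = nrow(pts),
                 leaf_id = attr(cloud, "leaf_id")),
            class = "leaf_plane")
}

#' @export
print.leaf_plane <- function(x, ...) {
  cat(sprintf("<leaf_plane> z = %.4g x + %.4g y + %.4g  (%d points)\n",
              x$a, x$b, x$c, x$inlier_count))
  invisible(x)
}

#' Residual of points to a plane
#'
#' @param plane A `leaf_plane` (graph form `z = a x + b y + c`).
#' @param points Numeric vector (length 3) or n x 3 matrix.
#' @param mode `"vertical"`: `|z - a x - b y - c|`; `"orthogonal"`: the
#'   vertical residual divided by `sqrt(a^2 + b^2 + 1)` (true point-plane
#'   distance).
#' @return Residual(s) in mm.
#' @export
plane_residual <- function(plane, points, mode = c("vertical", "orthogonal")) {
  mode <- match.arg(mode)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- abs(points[, 3] - plane$a * points[, 1] - plane$b * points[, 2] -
             plane$c)
  if (mode == "orthogonal") {
    r <- r / sqrt(plane$a^2 + plane$b^2 + 1)
  }
  as.numeric(r)
}
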