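## Parametric generator of top-down cabbage scenes: funnel-shaped plants of
## planar elliptical leaves radiating from a common attachment point at the
## stem, plus an optional spherical head tangent to the attachment height.
## Rendering is a pinhole z-buffer producing a depth raster and per-class
## label maps, with known ground truth for every instance.

#' Specification of one synthetic cabbage plant
#'
#' Leaves are planar elliptical patches whose inner tip touches the
#' attachment point, tilted upward-and-outward by the elevation angle so
#' the plant forms a funnel; azimuths are equally spaced with optional
#' jitter. The head, when present, is a sphere tangent from above to the
#' attachment height (head-less mode mirrors the earliest growth stage,
#' where no head has formed yet).
#'
#' @param stem_xy World (x, y) of the stem in mm.
#' @param attachment_z Height of the leaf-attachment point in mm.
#' @param n_leaves Number of leaves (>= 3 for stem-recovery scenes).
#' @param leaf_lengths Either a vector of `n_leaves` lengths (mm) or a
#'   range `c(min, max)` sampled uniformly at scene build. Default
#'   `c(150, 350)`.
#' @param leaf_widths Vector of widths (mm) or `NULL` for the default
#'   0.6 * length (widths are capped at the length so the far tip is the
#'   farthest point from the base).
#' @param elevation_angle Funnel steepness in degrees above horizontal.
#' @param azimuth_jitter Uniform azimuth perturbation, degrees.
#' @param head_radius Head radius in mm, or `NA` for no head.
#' @param head_center_z Head centre height in mm; default
#'   `attachment_z + head_radius` (sphere tangent to the attachment point).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(stem_xy = c(0, 0), attachment_z = 50, n_leaves = 12L,
                       leaf_lengths = c(150, 350), leaf_widths = NULL,
                       elevation_angle = 25, azimuth_jitter = 5,
                       head_radius = NA_real_, head_center_z = NULL) {
  stopifnot(n_leaves >= 1, all(leaf_lengths > 0),
            elevation_angle >= 0, elevation_angle < 90)
  if (!is.na(head_radius)) stopifnot(head_radius >= 0)
  if (is.null(head_center_z) && !is.na(head_radius)) {
    head_center_z <- attachment_z + head_radius
  }
  structure(list(stem_xy = as.numeric(stem_xy),
                 attachment_z = attachment_z,
                 n_leaves = as.integer(n_leaves),
                 leaf_lengths = leaf_lengths, leaf_widths = leaf_widths,
                 elevation_angle = elevation_angle,
                 azimuth_jitter = azimuth_jitter,
                 head_radius = head_radius, head_center_z = head_center_z),
            class = "plant_spec")
}

# Planar elliptical patch: centre, orthonormal in-plane axes (unit), semi
# axes, and the graph-form plane z = a x + b y + c it lies in.
make_patch <- function(center, u_axis, w_axis, semi_u, semi_w) {
  n <- c(u_axis[2] * w_axis[3] - u_axis[3] * w_axis[2],
         u_axis[3] * w_axis[1] - u_axis[1] * w_axis[3],
         u_axis[1] * w_axis[2] - u_axis[2] * w_axis[1])
  stopifnot(abs(n[3]) > 1e-9)          # patch must be a graph over (x, y)
  a <- -n[1] / n[3]
  b <- -n[2] / n[3]
  cc <- center[3] - a * center[1] - b * center[2]
  list(center = center, u = u_axis, w = w_axis,
       semi_u = semi_u, semi_w = semi_w, a = a, b = b, c = cc)
}

#' Build a synthetic scene with ground truth
#'
#' Resolves the plant specifications into concrete leaf and head geometry.
#' Deterministic for a given seed.
#'
#' @param specs A [plant_spec] or list of them.
#' @param camera A [camera_model].
#' @param seed Integer seed for length sampling and azimuth jitter.
#' @param min_spacing Minimum stem-to-stem distance in mm (layout check);
#'   default 300.
#' @return An object of class `cabbage_scene` holding per-plant geometry
#'   and the `truth` record: attachment points, per-leaf true lengths and
#'   elliptical areas, head radii and sphere volumes.
#' @export
build_scene <- function(specs, camera = camera_model(), seed = 1L,
                        min_spacing = 300) {
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  stems <- t(vapply(specs, function(s) s$stem_xy, numeric(2)))
  if (nrow(stems) > 1) {
    dmin <- min(stats::dist(stems))
    if (dmin < min_spacing) {
      stop(sprintf("layout error: stems %.0f mm apart (< %.0f)", dmin,
                   min_spacing), call. = FALSE)
    }
  }
  leaf_id <- 0L
  plants <- vector("list", length(specs))
  leaf_truth <- list()
  head_truth <- list()
  with_seed(seed, {
    for (pid in seq_along(specs)) {
      s <- specs[[pid]]
      n <- s$n_leaves
      lengths <- if (length(s$leaf_lengths) == n) {
        s$leaf_lengths                      # per-leaf lengths as given
      } else if (length(s$leaf_lengths) == 2L) {
        stats::runif(n, s$leaf_lengths[1], s$leaf_lengths[2])
      } else {
        stop("leaf_lengths must be a range c(min, max) or one value per leaf",
             call. = FALSE)
      }
      widths <- if (is.null(s$leaf_widths)) pmin(0.6 * lengths, lengths)
                else rep_len(s$leaf_widths, n)
      az <- 2 * pi * (seq_len(n) - 1) / n +
        (stats::runif(n) * 2 - 1) * s$azimuth_jitter * pi / 180
      e <- s$elevation_angle * pi / 180
      tip <- c(s$stem_xy, s$attachment_z)
      leaves <- vector("list", n)
      for (li in seq_len(n)) {
        leaf_id <- leaf_id + 1L
        u_axis <- c(cos(az[li]) * cos(e), sin(az[li]) * cos(e), sin(e))
        w_axis <- c(-sin(az[li]), cos(az[li]), 0)
        center <- tip + (lengths[li] / 2) * u_axis
        patch <- make_patch(center, u_axis, w_axis,
                            lengths[li] / 2, widths[li] / 2)
        patch$leaf_id <- leaf_id
        patch$plant_id <- pid
        patch$occluder <- FALSE
        leaves[[li]] <- patch
        leaf_truth[[leaf_id]] <- data.frame(
          plant_id = pid, leaf_id = leaf_id, length_mm = lengths[li],
          width_mm = widths[li],
          area_m2 = pi_ellipse_area(lengths[li], widths[li]),
          azimuth = az[li], occluder = FALSE)
      }
      head <- NULL
      if (!is.na(s$head_radius) && s$head_radius > 0) {
        head <- list(center = c(s$stem_xy, s$head_center_z),
                     radius = s$head_radius, head_id = pid, plant_id = pid)
        head_truth[[length(head_truth) + 1L]] <- data.frame(
          plant_id = pid, head_id = pid, radius_mm = s$head_radius,
          center_z = s$head_center_z,
          volume_m3 = sphere_volume(s$head_radius),
          low_visibility = FALSE)
      }
      plants[[pid]] <- list(spec = s, plant_id = pid,
                           attachment = tip, leaves = leaves, head = head)
    }
  })
  structure(list(plants = plants, camera = camera, seed = as.integer(seed),
                 truth = list(
                   attachment = t(vapply(plants, function(p) p$attachment,
                                         numeric(3))),
                   leaves = do.call(rbind, leaf_truth),
                   heads = if (length(head_truth)) do.call(rbind, head_truth)
                           else NULL)),
            class = "cabbage_scene")
}

pi_ellipse_area <- function(length_mm, width_mm) {
  pi * (length_mm / 2) * (width_mm / 2) * 1e-6
}

#' @export
print.cabbage_scene <- function(x, ...) {
  nh <- if (is.null(x$truth$heads)) 0L else nrow(x$truth$heads)
  cat(sprintf("<cabbage_scene> %d plant(s), %d leaves, %d head(s), seed %d\n",
              length(x$plants), nrow(x$truth$leaves), nh, x$seed))
  invisible(x)
}

# Depth of a patch surface over an image window, Inf where missed.
# U, V are matrices of (col - cx)/f and (row - cy)/f for the window.
patch_depth <- function(patch, U, V, camera_height) {
  denom <- 1 + patch$a * U + patch$b * V
  d <- (camera_height - patch$c) / denom
  d[denom <= 1e-9 | d <= 0] <- Inf
  x <- U * d; y <- V * d; z <- camera_height - d
  rx <- x - patch$center[1]; ry <- y - patch$center[2]
  rz <- z - patch$center[3]
  su <- (rx * patch$u[1] + ry * patch$u[2] + rz * patch$u[3]) / patch$semi_u
  sw <- (rx * patch$w[1] + ry * patch$w[2] + rz * patch$w[3]) / patch$semi_w
  d[!is.finite(d) | su^2 + sw^2 > 1] <- Inf
  d
}

sphere_depth <- function(head, U, V, camera_height) {
  cx <- head$center[1]; cy <- head$center[2]
  dz <- camera_height - head$center[3]
  A <- U^2 + V^2 + 1
  B <- -2 * (U * cx + V * cy + dz)
  C <- cx^2 + cy^2 + dz^2 - head$radius^2
  disc <- B^2 - 4 * A * C
  d <- matrix(Inf, nrow(U), ncol(U))
  hit <- disc >= 0
  d[hit] <- (-B[hit] - sqrt(disc[hit])) / (2 * A[hit])
  d[d <= 0] <- Inf
  d
}

# Conservative image-window (1-based row/col ranges) for a surface.
surface_window <- function(surf, camera, margin = 3L) {
  ch <- camera$camera_height
  if (!is.null(surf$radius)) {                       # sphere
    th <- seq(0, 2 * pi, length.out = 33)
    pts <- cbind(surf$center[1] + surf$radius * cos(th),
                 surf$center[2] + surf$radius * sin(th),
                 surf$center[3])
    pts <- rbind(pts, c(surf$center[1], surf$center[2],
                        surf$center[3] + surf$radius))
  } else {                                           # patch boundary
    th <- seq(0, 2 * pi, length.out = 49)
    pts <- t(surf$center + outer(surf$u * surf$semi_u, cos(th)) +
               outer(surf$w * surf$semi_w, sin(th)))
  }
  d <- ch - pts[, 3]
  d[d < 1] <- 1
  col0 <- pts[, 1] * camera$focal_length / d + camera$principal_point[1]
  row0 <- pts[, 2] * camera$focal_length / d + camera$principal_point[2]
  # widen spheres: the outline is outside the equator's projection
  extra <- if (!is.null(surf$radius)) ceiling(0.3 * diff(range(col0)) + margin)
           else margin
  list(rows = max(1L, floor(min(row0)) + 1L - extra):
         min(camera$image_size[2], ceiling(max(row0)) + 1L + extra),
       cols = max(1L, floor(min(col0)) + 1L - extra):
         min(camera$image_size[1], ceiling(max(col0)) + 1L + extra))
}

#' Render a scene to a depth raster and label maps
#'
#' Pinhole z-buffer rasterization: per pixel the nearest surface wins.
#' Label maps are derived from the winning surface — the leaf map carries
#' leaf instance ids, the head map head ids, and the plant map the plant id
#' over the union of that plant's parts. Gaussian depth noise and uniform
#' outlier replacement emulate photogrammetric depth defects; the
#' background is the ground plane. The per-leaf occlusion fraction (share
#' of a leaf's projected footprint hidden by nearer surfaces) is recorded
#' in the returned truth.
#'
#' @param scene A [build_scene] result.
#' @param noise_sd Depth noise standard deviation in mm; default 2, a
#'   plausible close-range photogrammetry figure.
#' @param outlier_fraction Fraction of pixels replaced by uniform gross
#'   outliers; default 0.
#' @param seed Seed for noise; defaults to `scene$seed + 1` so a scene
#'   renders reproducibly.
#' @return A list of class `cabbage_render`: `depth` ([depth_raster]),
#'   `leaf_map`, `head_map`, `plant_map` (integer matrices), mask lists
#'   `leaf_masks`, `head_masks`, `plant_masks`, the updated `truth`, and
#'   the `camera`. `head_masks` are visibility-clipped (what a detector
#'   would see); `head_masks_full` cover each head's full projected
#'   outline, emulating ground-truth annotation of a partially covered
#'   head.
#' @export
render <- function(scene, noise_sd = 2, outlier_fraction = 0, seed = NULL) {
  camera <- scene$camera
  if (is.null(seed)) seed <- scene$seed + 1L
  W <- camera$image_size[1]; H <- camera$image_size[2]
  f <- camera$focal_length; ch <- camera$camera_height
  ucol <- ((0:(W - 1)) - camera$principal_point[1]) / f
  vrow <- ((0:(H - 1)) - camera$principal_point[2]) / f
  best_d <- matrix(ch, H, W)            # ground plane everywhere
  leaf_map <- matrix(0L, H, W)
  head_map <- matrix(0L, H, W)
  plant_map <- matrix(0L, H, W)
  surfaces <- list()
  for (p in scene$plants) {
    for (lf in p$leaves) surfaces[[length(surfaces) + 1L]] <- lf
    if (!is.null(p$head)) surfaces[[length(surfaces) + 1L]] <- p$head
  }
  solo <- numeric(length(surfaces))
  head_full <- list()
  # first pass: z-buffer
  for (si in seq_along(surfaces)) {
    surf <- surfaces[[si]]
    win <- surface_window(surf, camera)
    U <- matrix(ucol[win$cols], length(win$rows), length(win$cols),
                byrow = TRUE)
    V <- matrix(vrow[win$rows], length(win$rows), length(win$cols))
    d <- if (!is.null(surf$radius)) sphere_depth(surf, U, V, ch)
         else patch_depth(surf, U, V, ch)
    solo[si] <- sum(is.finite(d))
    if (!is.null(surf$radius)) {
      # full projected outline, as an annotator would trace it under cover
      full <- matrix(FALSE, H, W)
      full[win$rows, win$cols] <- is.finite(d)
      head_full[[length(head_full) + 1L]] <-
        instance_mask(full, "head", surf$head_id)
    }
    sub <- best_d[win$rows, win$cols]
    upd <- is.finite(d) & d < sub
    sub[upd] <- d[upd]
    best_d[win$rows, win$cols] <- sub
    is_head <- !is.null(surf$radius)
    lm <- leaf_map[win$rows, win$cols]
    hm <- head_map[win$rows, win$cols]
    pm <- plant_map[win$rows, win$cols]
    if (is_head) {
      hm[upd] <- surf$head_id
      lm[upd] <- 0L
    } else {
      lm[upd] <- surf$leaf_id
      hm[upd] <- 0L
    }
    pm[upd] <- surf$plant_id
    leaf_map[win$rows, win$cols] <- lm
    head_map[win$rows, win$cols] <- hm
    plant_map[win$rows, win$cols] <- pm
  }
  # occlusion fractions from the final winner map
  truth <- scene$truth
  vis_leaf <- tabulate(leaf_map[leaf_map > 0L],
                       nbins = max(1L, max(truth$leaves$leaf_id)))
  occl <- rep(NA_real_, nrow(truth$leaves))
  for (si in seq_along(surfaces)) {
    surf <- surfaces[[si]]
    if (is.null(surf$radius) && solo[si] > 0) {
      row <- match(surf$leaf_id, truth$leaves$leaf_id)
      occl[row] <- 1 - vis_leaf[surf$leaf_id] / solo[si]
    }
  }
  truth$leaves$occlusion <- occl
  if (!is.null(truth$heads)) {
    vis_head <- vapply(seq_len(nrow(truth$heads)), function(i) {
      sum(head_map == truth$heads$head_id[i])
    }, numeric(1))
    head_solo <- vapply(seq_along(surfaces), function(si) {
      if (!is.null(surfaces[[si]]$radius)) solo[si] else NA_real_
    }, numeric(1))
    head_solo <- head_solo[!is.na(head_solo)]
    truth$heads$occlusion <- 1 - vis_head / head_solo
  }
  # depth defects
  depth_vals <- with_seed(seed, {
    v <- best_d
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
    if (outlier_fraction > 0) {
      n_out <- round(outlier_fraction * length(v))
      idx <- sample.int(length(v), n_out)
      v[idx] <- stats::runif(n_out, 0.4 * ch, ch)
    }
    pmax(v, 1)
  })
  structure(list(
    depth = depth_raster(depth_vals),
    leaf_map = leaf_map, head_map = head_map, plant_map = plant_map,
    leaf_masks = label_map_to_masks(leaf_map, "leaf"),
    head_masks = label_map_to_masks(head_map, "head"),
    head_masks_full = head_full,
    plant_masks = label_map_to_masks(plant_map, "plant"),
    truth = truth, camera = camera), class = "cabbage_render")
}

#' @export
print.cabbage_render <- function(x, ...) {
  cat(sprintf("<cabbage_render> %d x %d px; %d leaf, %d head, %d plant mask(s)\n",
              nrow(x$depth), ncol(x$depth), length(x$leaf_masks),
              length(x$head_masks), length(x$plant_masks)))
  invisible(x)
}

#' Plot a rendered scene
#'
#' @param x A `cabbage_render`.
#' @param what `"depth"`, `"leaf"`, `"head"` or `"plant"`.
#' @param ... Passed to [graphics::image].
#' @export
plot.cabbage_render <- function(x, what = c("depth", "leaf", "head", "plant"),
                                ...) {
  what <- match.arg(what)
  m <- switch(what, depth = unclass(x$depth), leaf = x$leaf_map,
              head = x$head_map, plant = x$plant_map)
  graphics::image(t(m)[, nrow(m):1], useRaster = TRUE, axes = FALSE,
                  main = what, ...)
  invisible(x)
}

#' Occlude a plant's head with leaf patches
#'
#' Adds horizontal elliptical patches just above the head apex until
#' approximately `cover_fraction` of the head's image disc is hidden
#' (measured in image space on the head's window). The truth keeps the
#' true head radius; patches are flagged as occluders in the leaf truth so
#' morphometry tests can exclude them. Coverage of 0.95 or more flags the
#' head record `low_visibility`.
#'
#' @param scene A `cabbage_scene` whose target plant has a head.
#' @param cover_fraction Fraction in `[0, 1)` of the head disc to cover.
#' @param plant_id Which plant's head; default 1.
#' @param seed Seed for patch placement; default `scene$seed + 2`.
#' @return The modified scene.
#' @export
occlude_head <- function(scene, cover_fraction, plant_id = 1L, seed = NULL) {
  if (cover_fraction >= 1) {
    stop("domain error: cover_fraction must be < 1", call. = FALSE)
  }
  if (cover_fraction < 0) {
    stop("domain error: cover_fraction must be >= 0", call. = FALSE)
  }
  p <- scene$plants[[plant_id]]
  if (is.null(p$head)) {
    stop("plant has no head to occlude", call. = FALSE)
  }
  if (cover_fraction == 0) return(scene)
  camera <- scene$camera
  ch <- camera$camera_height
  head <- p$head
  win <- surface_window(head, camera)
  ucol <- ((0:(camera$image_size[1] - 1)) - camera$principal_point[1]) /
    camera$focal_length
  vrow <- ((0:(camera$image_size[2] - 1)) - camera$principal_point[2]) /
    camera$focal_length
  U <- matrix(ucol[win$cols], length(win$rows), length(win$cols),
              byrow = TRUE)
  V <- matrix(vrow[win$rows], length(win$rows), length(win$cols))
  head_px <- is.finite(sphere_depth(head, U, V, ch))
  apex_z <- head$center[3] + head$radius
  r <- head$radius
  covered <- matrix(FALSE, nrow(U), ncol(U))
  patches <- list()
  if (is.null(seed)) seed <- scene$seed + 2L
  with_seed(seed, {
    for (k in 1:300) {
      cov <- sum(covered & head_px) / sum(head_px)
      if (cov >= cover_fraction) break
      rad <- r * sqrt(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      rot <- stats::runif(1, 0, 2 * pi)
      center <- c(head$center[1] + rad * cos(ang),
                  head$center[2] + rad * sin(ang), apex_z + 5)
      patch <- make_patch(center,
                          c(cos(rot), sin(rot), 0),
                          c(-sin(rot), cos(rot), 0),
                          0.28 * r, 0.182 * r)
      covered <- covered | is.finite(patch_depth(patch, U, V, ch))
      patches[[length(patches) + 1L]] <- patch
    }
  })
  next_leaf_id <- max(scene$truth$leaves$leaf_id)
  for (patch in patches) {
    next_leaf_id <- next_leaf_id + 1L
    patch$leaf_id <- next_leaf_id
    patch$plant_id <- p$plant_id
    patch$occluder <- TRUE
    scene$plants[[plant_id]]$leaves <-
      c(scene$plants[[plant_id]]$leaves, list(patch))
    scene$truth$leaves <- rbind(scene$truth$leaves, data.frame(
      plant_id = p$plant_id, leaf_id = next_leaf_id,
      length_mm = 2 * patch$semi_u, width_mm = 2 * patch$semi_w,
      area_m2 = pi_ellipse_area(2 * patch$semi_u, 2 * patch$semi_w),
      azimuth = NA_real_, occluder = TRUE))
  }
  if (!is.null(scene$truth$heads) && cover_fraction >= 0.95) {
    hr <- scene$truth$heads$plant_id == p$plant_id
    scene$truth$heads$low_visibility[hr] <- TRUE
  }
  scene
}
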