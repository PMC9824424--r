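#' Intersection over union of two masks
#'
#' @param a,b Co-registered [instance_mask]s (or logical matrices).
#' @return `|a intersect b| / |a union b|`.
#' @export
mask_iou <- function(a, b) {
  ra <- if (inherits(a, "instance_mask")) a$raster else a
  rb <- if (inherits(b, "instance_mask")) b$raster else b
  if (!identical(dim(ra), dim(rb))) {
    stop("registration error: mask shapes differ", call. = FALSE)
  }
  sum(ra & rb) / sum(ra | rb)
}

#' Match detected instances to ground truth at one IoU threshold
#'
#' Detections are sorted by descending score and each is greedily matched
#' to the not-yet-matched truth with the highest IoU, provided that IoU
#' reaches the threshold (a true positive); otherwise it is a false
#' positive. Truths left unmatched are false negatives. Cumulative
#' precision/recall down the ranked list form the PR curve.
#'
#' @param detections List of [instance_mask]s carrying scores.
#' @param truths List of ground-truth [instance_mask]s of the same class.
#' @param iou_threshold Minimum IoU for a match.
#' @return List with counts `tp`, `fp`, `fn`, the threshold, and vectors
#'   `precision`/`recall` (one point per ranked detection).
#' @export
match_instances <- function(detections, truths, iou_threshold = 0.5) {
  scores <- vapply(detections, function(d) {
    if (is.na(d$score)) 1 else d$score
  }, numeric(1))
  ord <- order(-scores)
  matched <- logical(length(truths))
  is_tp <- logical(length(detections))
  for (i in ord) {
    if (length(truths) == 0L) break
    ious <- vapply(truths, function(tr) mask_iou(detections[[i]], tr),
                   numeric(1))
    ious[matched] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) {
      matched[j] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  tp_cum <- cumsum(is_tp[ord])
  k <- seq_along(ord)
  list(tp = sum(is_tp), fp = sum(!is_tp[seq_along(detections)]),
       fn = sum(!matched), iou_threshold = iou_threshold,
       precision = if (length(ord)) tp_cum / k else numeric(0),
       recall = if (length(truths)) tp_cum / length(truths)
                else rep(0, length(ord)))
}

#' Average precision of a PR curve (101-point interpolation)
#'
#' Area under the precision envelope: for each recall level on the grid
#' 0, 0.01, ..., 1 the maximum precision at or beyond that recall is taken
#' and the 101 values averaged (the COCO convention).
#'
#' @param pr A list with `precision` and `recall` vectors, as returned by
#'   [match_instances].
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pr) {
  if (length(pr$precision) == 0L) return(0)
  grid <- seq(0, 1, by = 0.01)
  vapply(grid, function(r) {
    sel <- pr$recall >= r - 1e-12
    if (any(sel)) max(pr$precision[sel]) else 0
  }, numeric(1)) |> mean()
}

#' Mean average precision over IoU thresholds 0.50-0.95
#'
#' @param detections,truths As in [match_instances].
#' @param thresholds IoU threshold grid; default `seq(0.5, 0.95, 0.05)`.
#' @return List with `ap` (named vector, one AP per threshold) and `map`
#'   (their mean).
#' @export
map_range <- function(detections, truths,
                      thresholds = seq(0.5, 0.95, by = 0.05)) {
  ap <- vapply(thresholds, function(t) {
    average_precision(match_instances(detections, truths, t))
  }, numeric(1))
  names(ap) <- sprintf("AP@%.2f", thresholds)
  list(ap = ap, map = mean(ap))
}

#' Mean accuracy of estimates against reference values
#'
#' Per item: `100 * (1 - |estimate - reference| / reference)`, floored at
#' 0; the mean over items is returned. This is one natural reading of a
#' "mean accuracy" between a measured and an estimated column; it is the
#' complement of the mean relative error in percent.
#'
#' @param reference Positive reference values.
#' @param estimate Estimates, same length.
#' @return Mean accuracy in percent.
#' @export
accuracy_stats <- function(reference, estimate) {
  if (length(reference) != length(estimate)) {
    stop("pairing error: lengths differ", call. = FALSE)
  }
  stopifnot(all(reference > 0))
  mean(pmax(0, 100 * (1 - abs(estimate - reference) / reference)))
}

#' Mean, population SD and relative SD of a measure column
#'
#' The standard deviation uses the population formula (divisor n), the
#' convention of the bundled reference tables; `sd_percent` is
#' `100 * sd / mean`.
#'
#' @param values Numeric vector, length >= 2.
#' @return List with `mean`, `sd`, `sd_percent`.
#' @export
column_stats <- function(values) {
  if (length(values) < 2L) {
    stop("insufficient data: need at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  list(mean = m, sd = s, sd_percent = 100 * s / m)
}
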