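#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the measurement pipeline,
#' grouped by stage. Override individual entries by passing a partial list
#' to [measure_scene]; unnamed stages keep their defaults.
#'
#' @param ... Named stage overrides (`msac`, `stem`, `leafarea`, `assign`,
#'   `head`), each a named list of keys to replace.
#' @return Nested configuration list.
#' @examples
#' cfg <- cabbage_config(msac = list(tolerance_mm = 5))
#' cfg$msac$tolerance_mm
#' @export
cabbage_config <- function(...) {
  cfg <- list(
    msac = list(tolerance_mm = 10, max_iterations = 500L,
                min_inlier_fraction = 0.5, seed = 1L),
    stem = list(det_threshold = 1e-6, z_min_mm = 0, z_max_mm = NULL,
                aggregate = "mean"),
    leafarea = list(shape_factor = 2.7),
    assign = list(threshold = 0.8),
    head = list(apex_percentile = 0.05, eq5_mode = "pinhole"))
  over <- list(...)
  for (stage in names(over)) {
    stopifnot(stage %in% names(cfg))
    for (key in names(over[[stage]])) {
      cfg[[stage]][[key]] <- over[[stage]][[key]]
    }
  }
  cfg
}

#' Measure every plant in a scene
#'
#' End-to-end orchestration: leaves are assigned to plants by the 80%
#' overlap rule; per plant, the leaf clouds are back-projected, the
#' attachment point located by robust plane intersection, leaf lengths and
#' allometric areas computed, and — when a head instance overlaps the
#' plant — the head radius and sphere volume measured. A plant whose stem
#' location fails yields an error record instead of silently disappearing.
#'
#' @param leaf_masks,plant_masks,head_masks Lists of [instance_mask]s on a
#'   common grid (`head_masks` may be empty for early growth stages).
#' @param depth A [depth_raster].
#' @param camera A [camera_model].
#' @param config A [cabbage_config] list.
#' @return Object of class `scene_measures`: `plants` (list of
#'   `plant_measure`), `unassigned` (leaf ids failing the overlap rule),
#'   `skipped` (leaf ids with too little valid depth to back-project),
#'   `errors` (per-plant failure records) and the `assignment` table.
#' @export
measure_scene <- function(leaf_masks, plant_masks, head_masks = list(),
                          depth, camera, config = cabbage_config()) {
  assignment <- if (length(leaf_masks)) {
    assign_leaves(leaf_masks, plant_masks, config$assign$threshold)
  } else {
    data.frame(leaf_id = integer(), plant_id = integer(),
               overlap = numeric())
  }
  leaf_ids <- vapply(leaf_masks, function(m) m$instance_id, integer(1))
  msac_cfg <- msac_config(config$msac$tolerance_mm,
                          config$msac$max_iterations,
                          config$msac$min_inlier_fraction,
                          config$msac$seed)
  z_bounds <- c(config$stem$z_min_mm,
                if (is.null(config$stem$z_max_mm)) camera$camera_height
                else config$stem$z_max_mm)
  results <- list()
  errors <- list()
  skipped <- list()
  for (plant in plant_masks) {
    pid <- plant$instance_id
    lids <- assignment$leaf_id[!is.na(assignment$plant_id) &
                                 assignment$plant_id == pid]
    res <- tryCatch({
      clouds <- list()
      for (lmask in leaf_masks[match(lids, leaf_ids)]) {
        cl <- tryCatch(backproject(lmask, depth, camera),
                       error = function(e) NULL)
        if (is.null(cl)) {
          # too little valid depth under the mask (border sliver, no-data)
          skipped[[length(skipped) + 1L]] <- lmask$instance_id
        } else {
          clouds[[length(clouds) + 1L]] <- cl
        }
      }
      # MSAC-clean every leaf cloud once: both the plane fits and the
      # endpoint search must see outlier-free depth
      clouds <- lapply(clouds, function(cl) {
        tryCatch(suppressWarnings(msac_filter(cl, msac_cfg)),
                 error = function(e) cl)
      })
      ap <- locate_stem(clouds, plant, camera, msac_cfg,
                        det_threshold = config$stem$det_threshold,
                        z_bounds = z_bounds,
                        aggregate = config$stem$aggregate)
      lm <- measure_plant_leaves(clouds, ap, config$leafarea$shape_factor)
      head <- NULL
      for (hm in head_masks) {
        ov <- sum(hm$raster & plant$raster) / sum(hm$raster)
        if (ov > 0.5) {
          head <- measure_head(hm, depth, camera,
                               config$head$apex_percentile,
                               config$head$eq5_mode)
          break
        }
      }
      structure(list(plant_id = pid, attachment = ap,
                     leaves = lm$leaves,
                     mean_leaf_length = lm$mean_leaf_length,
                     total_leaf_area = lm$total_leaf_area,
                     n_leaves = nrow(lm$leaves), head = head),
                class = "plant_measure")
    }, error = function(e) {
      structure(list(plant_id = pid, error = conditionMessage(e)),
                class = "plant_error")
    })
    if (inherits(res, "plant_error")) {
      errors[[length(errors) + 1L]] <- res
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  structure(list(plants = results,
                 unassigned = assignment$leaf_id[is.na(assignment$plant_id)],
                 skipped = as.integer(unlist(skipped)),
                 errors = errors, assignment = assignment),
            class = "scene_measures")
}

#' @export
print.plant_measure <- function(x, ...) {
  cat(sprintf("<plant_measure> plant %d: %d leaves, mean length %.1f mm, LA %.3f m^2",
              x$plant_id, x$n_leaves, x$mean_leaf_length, x$total_leaf_area))
  if (!is.null(x$head)) {
    cat(sprintf(", head %.1f mm / %.5f m^3", x$head$radius_mm,
                x$head$volume))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.scene_measures <- function(x, ...) {
  cat(sprintf("<scene_measures> %d plant(s), %d unassigned leaf(s), %d error(s)\n",
              length(x$plants), length(x$unassigned), length(x$errors)))
  for (p in x$plants) print(p)
  for (e in x$errors) {
    cat(sprintf("  plant %d failed: %s\n", e$plant_id, e$error))
  }
  invisible(x)
}

#' @export
summary.scene_measures <- function(object, ...) {
  df <- do.call(rbind, lapply(object$plants, function(p) {
    data.frame(plant_id = p$plant_id, n_leaves = p$n_leaves,
               mean_leaf_length_mm = p$mean_leaf_length,
               total_leaf_area_m2 = p$total_leaf_area,
               head_radius_mm = if (is.null(p$head)) NA_real_
                                else p$head$radius_mm,
               head_volume_m3 = if (is.null(p$head)) NA_real_
                                else p$head$volume)
  }))
  df
}

## ---- Bundled reference tables ---------------------------------------------

#' Load the bundled field-validation reference tables
#'
#' Per-plant tables from a destructive field validation of 30 storage
#' cabbage plants (cv. Storidor, 10 plants at each of the BBCH 41, 45 and
#' 48 head-development stages): hand-measured head volume and visible leaf
#' area next to the image-based estimates computed once from ground-truth
#' segmentation masks ("calculated") and once from detected masks
#' ("detected").
#'
#' @return Named list of data frames: `volume_bbch48`, `volume_bbch45`,
#'   `leafarea_bbch48`, `leafarea_bbch45`, `leafarea_bbch41`, and
#'   `printed_summaries` (the summary rows printed in the source tables).
#' @export
cabbage_tables <- function() {
  dir <- system.file("extdata", package = "cabbagemorph")
  read <- function(f) utils::read.csv(file.path(dir, f))
  list(volume_bbch48 = read("volume_bbch48.csv"),
       volume_bbch45 = read("volume_bbch45.csv"),
       leafarea_bbch48 = read("leafarea_bbch48.csv"),
       leafarea_bbch45 = read("leafarea_bbch45.csv"),
       leafarea_bbch41 = read("leafarea_bbch41.csv"),
       printed_summaries = read("printed_summaries.csv"))
}

#' Recompute the reference tables' summary statistics
#'
#' Computes column means, relative population standard deviations and
#' cross-column mean accuracies from the bundled per-plant tables and lays
#' them side by side with the printed summary rows.
#'
#' @return Data frame with columns `table`, `quantity`, `computed`,
#'   `printed`, `note`.
#' @export
reproduce_tables <- function() {
  tabs <- cabbage_tables()
  rows <- list()
  add <- function(table, quantity, computed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      table = table, quantity = quantity, computed = computed)
  }
  for (tb in c("volume_bbch48", "volume_bbch45")) {
    d <- tabs[[tb]]
    for (col in c("measured_m3", "calculated_m3", "detected_m3")) {
      cs <- column_stats(d[[col]])
      add(tb, paste0("mean_", sub("_m3", "", col)), cs$mean)
      add(tb, paste0("sd_pct_", sub("_m3", "", col)), cs$sd_percent)
    }
    add(tb, "accuracy_calculated",
        accuracy_stats(d$measured_m3, d$calculated_m3))
    add(tb, "accuracy_detected",
        accuracy_stats(d$calculated_m3, d$detected_m3))
  }
  for (tb in c("leafarea_bbch48", "leafarea_bbch45", "leafarea_bbch41")) {
    d <- tabs[[tb]]
    cols <- c(leaves_visible = "mean_leaves_visible",
              measured_la_m2 = "mean_measured_la",
              calculated_la_m2 = "mean_calculated_la",
              leaves_detected = "mean_leaves_detected",
              detected_la_m2 = "mean_detected_la")
    for (col in names(cols)) {
      cs <- column_stats(d[[col]])
      add(tb, cols[[col]], cs$mean)
      add(tb, sub("mean_", "sd_pct_", cols[[col]]), cs$sd_percent)
    }
    add(tb, "accuracy_calculated",
        accuracy_stats(d$measured_la_m2, d$calculated_la_m2))
    add(tb, "accuracy_detected",
        accuracy_stats(d$calculated_la_m2, d$detected_la_m2))
    add(tb, "area_per_leaf_measured",
        mean(d$measured_la_m2) / mean(d$leaves_visible))
  }
  out <- do.call(rbind, rows)
  ps <- tabs$printed_summaries
  out <- merge(out, ps, by = c("table", "quantity"), all.x = TRUE,
               sort = FALSE)
  out[order(match(out$table, names(tabs)), match(out$quantity, unique(out$quantity))), ]
}
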