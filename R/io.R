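## Raster, annotation and point-cloud IO, plus mask back-projection.
##
## Supported raster dialects:
##   * PNG, 8- or 16-bit single channel (read; written at 8 bit only, so
##     label maps with ids > 255 and depth maps are written as TIFF/PGM)
##   * TIFF, 16-bit integer or float single channel
##   * PGM (plain ASCII "P2"), the text dialect used for bundled fixtures
## Stored integer values are instance ids for label maps and millimetres
## (times unit_scale) for depth; stored 0 in integer depth is no-data.

read_raster_values <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (length(dim(img)) == 3L) {
      stop("format error: expected a single-channel raster, got ",
           dim(img)[3], " channels: ", path, call. = FALSE)
    }
    depth_bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    img * (2^depth_bits - 1)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(raw)) == 3L) {
      stop("format error: expected a single-channel raster, got ",
           dim(raw)[3], " channels: ", path, call. = FALSE)
    }
    bits <- attr(raw, "bits.per.sample")
    # integer samples come back as stored values under as.is; float samples
    # come back as reinterpreted garbage, so fall back to the plain read,
    # which returns float samples unchanged
    ok_int <- all(is.finite(raw)) && all(raw == round(raw)) &&
      all(raw >= 0) && (is.null(bits) || max(raw) < 2^bits)
    v <- if (ok_int) raw else tiff::readTIFF(path)
    attributes(v) <- list(dim = dim(v))
    v
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    stop("unsupported raster format: ", ext, call. = FALSE)
  }
}

write_raster_values <- function(values, path, maxval = 65535L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(values / 65535, path, bits.per.sample = 16L,
                    compression = "none", reduce = FALSE)
  } else if (ext == "pgm") {
    write_pgm(values, path, maxval = maxval)
  } else if (ext == "png") {
    if (max(values) > 255) {
      stop("PNG output is 8-bit; values exceed 255 (use TIFF or PGM)",
           call. = FALSE)
    }
    png::writePNG(values / 255, path)
  } else {
    stop("unsupported raster format: ", ext, call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = txt, what = character(), quiet = TRUE)
  if (length(tok) < 4L || tok[1] != "P2") {
    stop("format error: not a plain (P2) PGM file: ", path, call. = FALSE)
  }
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) {
    stop("format error: PGM pixel count mismatch in ", path, call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(values, path, maxval = 65535L) {
  stopifnot(all(values >= 0), all(values <= maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(values), nrow(values)),
               as.character(maxval)), con)
  apply_rows <- apply(round(values), 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

#' Read a label map into instance masks
#'
#' A label map is a single-channel integer raster where 0 is background and
#' each distinct positive value marks the pixels of one instance.
#'
#' @param path PNG (8/16-bit), TIFF or ASCII PGM file.
#' @param class_label Class to assign to every instance in the file:
#'   `"plant"`, `"head"` or `"leaf"`.
#' @return A list of [instance_mask] objects, one per distinct positive
#'   label value, with `instance_id` preserved. An all-zero raster gives an
#'   empty list.
#' @export
read_label_map <- function(path, class_label) {
  values <- read_raster_values(path)
  if (max(abs(values - round(values))) > 1e-6) {
    stop("format error: label map must be integer-valued: ", path,
         call. = FALSE)
  }
  values <- round(values)
  label_map_to_masks(values, class_label)
}

#' Convert an in-memory label map to instance masks
#'
#' @param values Integer matrix; 0 background, positive values instance ids.
#' @param class_label Class for all masks.
#' @return List of [instance_mask] objects.
#' @export
label_map_to_masks <- function(values, class_label) {
  ids <- sort(unique(values[values > 0]))
  lapply(ids, function(id) {
    instance_mask(values == id, class_label, id)
  })
}

#' Collapse instance masks back into a label map
#'
#' Inverse of [label_map_to_masks] for non-overlapping masks; where masks
#' overlap, the later mask in the list wins.
#'
#' @param masks List of [instance_mask] objects on a common grid.
#' @param dim Grid dimension `c(height, width)`; taken from the first mask
#'   when omitted.
#' @return Integer matrix of instance ids.
#' @export
masks_to_label_map <- function(masks, dim = NULL) {
  if (length(masks) == 0L) {
    stopifnot(!is.null(dim))
    return(matrix(0L, dim[1], dim[2]))
  }
  if (is.null(dim)) dim <- base::dim(masks[[1]]$raster)
  out <- matrix(0L, dim[1], dim[2])
  for (m in masks) out[m$raster] <- m$instance_id
  out
}

#' Write a label map raster
#'
#' @param values Integer matrix of instance ids (0 = background).
#' @param path Output path; extension selects the dialect (`.tif`, `.pgm`,
#'   or `.png` for ids up to 255).
#' @export
write_label_map <- function(values, path) {
  write_raster_values(values, path)
}

#' Read a depth raster
#'
#' @param path Single-channel 16-bit PNG/TIFF (integer) or float TIFF, or
#'   ASCII PGM. Stored 0 in integer rasters is the no-data sentinel.
#' @param unit_scale Millimetres per stored unit (e.g. 1000 for a float
#'   raster in metres). Default 1.
#' @return A [depth_raster] in mm with `NA` at no-data pixels.
#' @export
read_depth_raster <- function(path, unit_scale = 1) {
  values <- read_raster_values(path)
  if (any(values < 0)) {
    stop("format error: negative depth values in ", path, call. = FALSE)
  }
  integerish <- max(abs(values - round(values))) < 1e-9
  if (integerish) {
    values[values == 0] <- NA
  }
  depth_raster(values * unit_scale)
}

#' Write a depth raster
#'
#' Depth is stored as integer millimetres (after dividing by `unit_scale`);
#' `NA` pixels are written as the 0 sentinel.
#'
#' @param depth A [depth_raster].
#' @param path Output `.tif` or `.pgm` path.
#' @param unit_scale Millimetres per stored unit.
#' @export
write_depth_raster <- function(depth, path, unit_scale = 1) {
  values <- unclass(depth) / unit_scale
  values[is.na(values)] <- 0
  write_raster_values(round(values), path)
}

## ---- COCO-style annotations ------------------------------------------------

coco_category_map <- c(plant = "plant", head = "head", crop = "head",
                       leaf = "leaf")

#' Read COCO-style instance annotations
#'
#' Reads an instance-annotation JSON file (polygon or uncompressed-RLE
#' segmentations) and rasterizes every annotation to the image size.
#' Category names are mapped to the classes `plant`, `head` (accepting the
#' alias `crop`) and `leaf`.
#'
#' @param path COCO instance JSON file.
#' @return A named list, one element per image (by file name), each a list
#'   of [instance_mask] objects. Annotation ids become instance ids.
#' @export
read_coco_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cats <- list()
  for (ct in doc$categories) {
    nm <- tolower(ct$name)
    if (!nm %in% names(coco_category_map)) {
      stop("mapping error: unknown category name '", ct$name, "'",
           call. = FALSE)
    }
    cats[[as.character(ct$id)]] <- coco_category_map[[nm]]
  }
  imgs <- list()
  for (im in doc$images) {
    imgs[[as.character(im$id)]] <- im
  }
  out <- stats::setNames(vector("list", length(imgs)),
                         vapply(imgs, function(im) im$file_name, ""))
  for (ann in doc$annotations) {
    im <- imgs[[as.character(ann$image_id)]]
    raster <- rasterize_segmentation(ann$segmentation, im$height, im$width)
    if (!any(raster)) next
    m <- instance_mask(raster, cats[[as.character(ann$category_id)]],
                       ann$id,
                       score = if (is.null(ann$score)) NA_real_ else ann$score)
    key <- im$file_name
    out[[key]] <- c(out[[key]], list(m))
  }
  out
}

rasterize_segmentation <- function(seg, height, width) {
  if (!is.null(seg$counts)) {
    decode_rle(seg, height, width)
  } else {
    raster <- matrix(FALSE, height, width)
    for (poly in seg) {
      raster <- xor(raster, rasterize_polygon(unlist(poly), height, width))
    }
    raster
  }
}

# Uncompressed COCO RLE: column-major runs starting with background.
decode_rle <- function(seg, height, width) {
  counts <- as.integer(unlist(seg$counts))
  if (!is.null(seg$size)) {
    height <- seg$size[[1]]; width <- seg$size[[2]]
  }
  stopifnot(sum(counts) == height * width)
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
  matrix(vals, nrow = height, ncol = width)
}

# Even-odd scanline fill of a flat [x1,y1,x2,y2,...] polygon; pixel (c,r) is
# filled when its centre (c + 0.5, r + 0.5) lies inside the polygon.
rasterize_polygon <- function(xy, height, width) {
  px <- xy[seq(1, length(xy), 2)]
  py <- xy[seq(2, length(xy), 2)]
  n <- length(px)
  raster <- matrix(FALSE, height, width)
  if (n < 3) return(raster)
  for (row in seq_len(height)) {
    yc <- row - 0.5
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((py[i] > yc) != (py[j] > yc)) {
        xs <- c(xs, px[i] + (yc - py[i]) / (py[j] - py[i]) * (px[j] - px[i]))
      }
      j <- i
    }
    if (length(xs) < 2) next
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- ceiling(xs[k] - 0.5) + 1       # first pixel with centre > xs[k]
      c1 <- floor(xs[k + 1] - 0.5 + 1e-9) + 1
      if (c1 >= c0) {
        c0 <- max(c0, 1L); c1 <- min(c1, width)
        if (c1 >= c0) raster[row, c0:c1] <- TRUE
      }
    }
  }
  raster
}

## ---- Back-projection -------------------------------------------------------

#' Back-project a mask into a 3D point cloud
#'
#' Reads the depth under every true mask pixel and lifts it to world
#' coordinates. Under the default pinhole model a pixel at 0-based `(col,
#' row)` with depth `d` maps to `x = (col - cx) d / f`, `y = (row - cy) d /
#' f`, `z = camera_height - d`. The orthographic mode instead uses a fixed
#' ground-sampling distance: `x = col * gsd`, `y = row * gsd` — convenient
#' for analytically constructed test scenes.
#'
#' @param mask An [instance_mask].
#' @param depth A [depth_raster] co-registered with the mask.
#' @param camera A [camera_model].
#' @param mode `"pinhole"` (default) or `"ortho"`.
#' @param ground_sampling mm per pixel for the orthographic mode.
#' @return A [leaf_cloud]; no-data depth pixels are skipped.
#' @export
backproject <- function(mask, depth, camera, mode = c("pinhole", "ortho"),
                        ground_sampling = 1) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(mask$raster), dim(depth)))
  h <- nrow(depth)
  idx <- which(mask$raster & !is.na(unclass(depth)))
  if (length(idx) < 3L) {
    stop("degenerate cloud: fewer than 3 valid depth pixels under mask",
         call. = FALSE)
  }
  row0 <- (idx - 1L) %% h          # 0-based row
  col0 <- (idx - 1L) %/% h         # 0-based col
  d <- unclass(depth)[idx]
  z <- camera$camera_height - d
  if (mode == "pinhole") {
    f <- camera$focal_length
    x <- (col0 - camera$principal_point[1]) * d / f
    y <- (row0 - camera$principal_point[2]) * d / f
  } else {
    x <- col0 * ground_sampling
    y <- row0 * ground_sampling
  }
  leaf_cloud(cbind(x = x, y = y, z = z), leaf_id = mask$instance_id)
}

## ---- Point clouds and measure tables ---------------------------------------

#' Write a point cloud as ASCII PLY
#'
#' @param cloud A [leaf_cloud] (or any n x 3 matrix).
#' @param path Output path.
#' @export
write_ply <- function(cloud, path) {
  pts <- unclass(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(apply(format(pts, trim = TRUE, scientific = FALSE), 1L,
                   paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PLY vertex list
#'
#' @param path PLY file written by [write_ply] (vertex-list dialect).
#' @return Numeric matrix with columns x, y, z.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  vals <- scan(text = lines[(end + 1):(end + nv)], quiet = TRUE)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write plant measures to CSV
#'
#' One row per plant (leaf_id `NA`, holding the plant-level totals) and one
#' row per leaf. Columns: `plant_id, leaf_id, length_mm, area_m2,
#' head_radius_mm, head_volume_m3`.
#'
#' @param measures A list of `plant_measure` objects (see [measure_scene]).
#' @param path Output CSV path.
#' @return The table written, invisibly.
#' @export
write_measures <- function(measures, path) {
  rows <- lapply(measures, function(pm) {
    plant_rows <- data.frame(
      plant_id = pm$plant_id, leaf_id = NA_integer_,
      length_mm = pm$mean_leaf_length, area_m2 = pm$total_leaf_area,
      head_radius_mm = if (is.null(pm$head)) NA_real_ else pm$head$radius_mm,
      head_volume_m3 = if (is.null(pm$head)) NA_real_ else pm$head$volume)
    if (!is.null(pm$leaves) && nrow(pm$leaves)) {
      leaf_rows <- data.frame(
        plant_id = pm$plant_id, leaf_id = pm$leaves$leaf_id,
        length_mm = pm$leaves$length_mm, area_m2 = pm$leaves$area_m2,
        head_radius_mm = NA_real_, head_volume_m3 = NA_real_)
      rbind(plant_rows, leaf_rows)
    } else plant_rows
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plant_id = integer(), leaf_id = integer(),
               length_mm = numeric(), area_m2 = numeric(),
               head_radius_mm = numeric(), head_volume_m3 = numeric())
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read a measures CSV written by [write_measures]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_measures <- function(path) {
  utils::read.csv(path, colClasses = c(
    plant_id = "integer", leaf_id = "integer", length_mm = "numeric",
    area_m2 = "numeric", head_radius_mm = "numeric",
    head_volume_m3 = "numeric"))
}

#' Encode a binary mask as uncompressed COCO RLE
#'
#' Column-major run-length encoding with runs alternating background /
#' foreground, starting at background. Inverse of the RLE branch of
#' [read_coco_annotations]'s decoder.
#'
#' @param raster Logical matrix.
#' @return A list with `size = c(height, width)` and integer `counts`.
#' @export
encode_rle <- function(raster) {
  v <- as.logical(raster)
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1]) counts <- c(0L, counts)
  list(size = c(nrow(raster), ncol(raster)), counts = as.integer(counts))
}

#' Write instance masks as a COCO-style annotation file
#'
#' Masks are stored as uncompressed RLE segmentations with the package's
#' class names as categories; the inverse of [read_coco_annotations] for
#' files this package writes.
#'
#' @param masks List of [instance_mask]s for one image.
#' @param path Output JSON path.
#' @param file_name Image file name recorded in the annotation.
#' @return The path, invisibly.
#' @export
write_coco_annotations <- function(masks, path, file_name = "scene.png") {
  if (length(masks)) {
    dims <- dim(masks[[1]]$raster)
  } else {
    dims <- c(0L, 0L)
  }
  cats <- list(list(id = 1L, name = "plant"),
               list(id = 2L, name = "head"),
               list(id = 3L, name = "leaf"))
  cat_id <- c(plant = 1L, head = 2L, leaf = 3L)
  anns <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    ann <- list(id = m$instance_id, image_id = 1L,
                category_id = cat_id[[m$class_label]],
                segmentation = encode_rle(m$raster),
                area = sum(m$raster), iscrowd = 0L)
    if (!is.na(m$score)) ann$score <- m$score
    ann
  })
  doc <- list(images = list(list(id = 1L, file_name = file_name,
                                 height = dims[1], width = dims[2])),
              categories = cats, annotations = anns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
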