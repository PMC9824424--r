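# Shared fixtures, built in code.

# Coarse camera for geometry tests where rasterization accuracy is not at
# stake (footprint +/- 540 mm at ground level).
small_camera <- function() {
  camera_model(focal_length = 300, camera_height = 900,
               image_size = c(360L, 360L))
}

# Funnel plant with fixed leaf lengths, rendered at the study camera.
funnel_scene <- function(n_leaves = 12L, lengths = NULL, head_radius = NA,
                         camera = camera_model(), seed = 11L, ...) {
  if (is.null(lengths)) {
    lengths <- seq(150, 350, length.out = n_leaves)
  }
  build_scene(plant_spec(n_leaves = n_leaves, leaf_lengths = lengths,
                         head_radius = head_radius, ...),
              camera = camera, seed = seed)
}

# Points sampled on the plane z = a x + b y + c over [-r, r]^2.
plane_points <- function(n, a, b, c, r = 100, seed = 1) {
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  with_seed(seed, {
    x <- runif(n, -r, r); y <- runif(n, -r, r)
    cbind(x = x, y = y, z = a * x + b * y + c)
  })
}

# Disc mask of radius r_px centred at (row0, col0), 1-based centre.
disc_mask <- function(dim, center, r_px, class_label = "head", id = 1L) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  instance_mask((rows - center[1])^2 + (cols - center[2])^2 <= r_px^2,
                class_label, id)
}

# Rectangular mask helper on a small grid.
rect_mask <- function(dim, rows, cols, class_label = "leaf", id = 1L,
                      score = NA_real_) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, cols] <- TRUE
  instance_mask(m, class_label, id, score)
}
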