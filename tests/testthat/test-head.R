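test_that("equivalent-circle radius inverts the disc area", {
  dim <- c(300L, 300L)
  big <- disc_mask(dim, c(150, 150), 100)
  expect_equal(head_radius_px(big), 100, tolerance = 1e-3)

  one <- rect_mask(dim, 5, 5, "head", 1L)
  expect_equal(head_radius_px(one), 1 / sqrt(pi))

  fifty <- disc_mask(dim, c(150, 150), 50)
  expect_equal(head_radius_px(fifty), 50, tolerance = 0.01)
})

test_that("equator distance solves the coupled apex system in closed form", {
  cam <- camera_model(focal_length = 1000, camera_height = 900,
                      image_size = c(300L, 300L))
  mask <- disc_mask(c(300L, 300L), c(150, 150), 40)
  depth600 <- depth_raster(matrix(600, 300, 300))

  # hand-checked closed form: r_mm = 100*600/900, H = Z0 + r_mm
  H <- cross_section_distance(mask, depth600, cam, r_px = 100)
  expect_equal(H, 600 + 100 * 600 / 900, tolerance = 1e-9)

  # zero-radius limit: H -> apex distance
  expect_equal(cross_section_distance(mask, depth600, cam, r_px = 0), 600)

  expect_error(cross_section_distance(mask, depth600, cam, r_px = 1000),
               "geometry error")
  empty_depth <- matrix(NA_real_, 300, 300)
  empty_depth[1, 1] <- 500               # valid pixel outside the mask
  expect_error(cross_section_distance(mask, depth_raster(empty_depth), cam,
                                      50), "missing depth")
})

test_that("pixel-to-mm conversion is pinhole by default, literal by flag", {
  cam <- camera_model(focal_length = 1000)
  expect_equal(px_to_mm(100, 900, cam), 90)
  expect_equal(px_to_mm(0, 900, cam), 0)
  expect_equal(px_to_mm(100, 1800, cam), 2 * px_to_mm(100, 900, cam))
  expect_equal(px_to_mm(100, 900, cam, "literal"), 100 * (1 / 1000) / 900)
  expect_error(px_to_mm(100, -1, cam), "domain error")
})

test_that("sphere volume and the circumference helper are consistent", {
  expect_equal(sphere_volume(100), 0.00419, tolerance = 1e-3)
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(200), 8 * sphere_volume(100))   # cubic law
  # radius implied by a 0.00289 m^3 head
  expect_equal(sphere_volume(88.4), 0.00289, tolerance = 1e-2)
  expect_error(sphere_volume(-1), "domain error")

  expect_equal(volume_from_circumference(2 * pi * 100), sphere_volume(100))
  expect_equal(volume_from_circumference(555.2), 0.00289, tolerance = 1e-2)
  expect_equal(volume_from_circumference(200) * 8,
               volume_from_circumference(400))
  expect_error(volume_from_circumference(0), "domain error")
})

test_that("reference objects calibrate the mm-per-pixel scale", {
  dim <- c(200L, 200L)
  marker <- rect_mask(dim, 10:29, 50:149, "plant", 1L)   # 100 px wide
  expect_equal(reference_scale(marker, 50), 0.5)

  # 40000-px leaf at 0.5 mm/px is 0.01 m^2
  leaf <- rect_mask(dim, 1:200, 1:200, "leaf", 1L)
  expect_equal(sum(leaf$raster) * 0.5^2 * 1e-6, 0.01)

  expect_silent(s <- combine_reference_scales(c(0.500, 0.501)))
  expect_equal(s, 0.5005)
  expect_warning(combine_reference_scales(c(0.5, 0.6)), "inconsistent")
})

test_that("synthetic sphere renders recover head volume", {
  cam <- camera_model()
  errs <- vapply(c(60, 75, 90, 120), function(r) {
    sc <- build_scene(plant_spec(n_leaves = 3, leaf_lengths = c(150, 200),
                                 head_radius = r), cam, seed = 3)
    rd <- render(sc, noise_sd = 0)
    hm <- measure_head(rd$head_masks_full[[1]], rd$depth, cam)
    hm$volume / sc$truth$heads$volume_m3 - 1
  }, numeric(1))
  # The mask is the sphere's outline (wider than the equator's projection)
  # and the percentile apex sits slightly beyond the true apex, so the
  # estimate carries a small positive geometric bias that grows with r/Z.
  expect_lt(max(abs(errs)), 0.08)
  expect_lt(max(abs(errs[1:2])), 0.03)   # small heads: within 3%

  # H within 2% of the true camera-to-equator distance
  sc <- build_scene(plant_spec(n_leaves = 3, leaf_lengths = c(150, 200),
                               head_radius = 90), cam, seed = 3)
  rd <- render(sc, noise_sd = 0)
  r_px <- head_radius_px(rd$head_masks_full[[1]])
  H <- cross_section_distance(rd$head_masks_full[[1]], rd$depth, cam, r_px)
  H_true <- cam$camera_height - sc$truth$heads$center_z
  expect_lt(abs(H - H_true) / H_true, 0.02)

  # up to 30% leaf cover of the disc, measured on the annotated full mask
  sc_occ <- occlude_head(sc, 0.3)
  rd_occ <- render(sc_occ, noise_sd = 0)
  hm_occ <- measure_head(rd_occ$head_masks_full[[1]], rd_occ$depth, cam)
  expect_lt(abs(hm_occ$volume / sc$truth$heads$volume_m3 - 1), 0.15)
})

test_that("projection and conversion invert each other for flat discs", {
  # a disc of known metric radius at known depth, forward-projected and
  # converted back with the pinhole rule, returns its radius within 1%
  cam <- camera_model(focal_length = 1000, camera_height = 900,
                      image_size = c(600L, 600L))
  r_mm <- 80; depth_mm <- 700
  r_px_true <- r_mm * cam$focal_length / depth_mm
  mask <- disc_mask(c(600L, 600L), c(300, 300), r_px_true)
  r_back <- px_to_mm(head_radius_px(mask), depth_mm, cam)
  expect_lt(abs(r_back - r_mm) / r_mm, 0.01)
})
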