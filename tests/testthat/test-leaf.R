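test_that("leaves are assigned to plants by the 80% overlap rule", {
  dim <- c(10L, 10L)
  plant <- rect_mask(dim, 1:10, 1:10, "plant", 1L)
  inside <- rect_mask(dim, 2:4, 2:4, "leaf", 1L)
  a <- assign_leaves(list(inside), list(plant))
  expect_equal(a$plant_id, 1L)

  # exactly 50% overlap stays below the "more than 80%" rule
  half_plant <- rect_mask(dim, 1:10, 1:5, "plant", 1L)
  leaf <- rect_mask(dim, 3:4, 4:7, "leaf", 2L)       # half in, half out
  a2 <- assign_leaves(list(leaf), list(half_plant))
  expect_true(is.na(a2$plant_id))
  expect_equal(a2$overlap, 0.5)

  # 85% in plant A, 90% in plant B -> B wins (enumerated on a toy grid)
  leaf20 <- rect_mask(c(10L, 20L), 1:2, 1:10, "leaf", 3L)   # 20 px
  ma <- matrix(FALSE, 10, 20); ma[1:2, 1:9] <- TRUE; ma[1, 1] <- FALSE
  pa <- instance_mask(ma, "plant", 1L)                      # covers 17 px
  pb <- rect_mask(c(10L, 20L), 1:2, 1:9, "plant", 2L)       # covers 18 px
  expect_equal(sum(leaf20$raster & pa$raster) / 20, 0.85)
  expect_equal(sum(leaf20$raster & pb$raster) / 20, 0.90)
  a3 <- assign_leaves(list(leaf20), list(pa, pb))
  expect_equal(a3$plant_id, 2L)

  # exact tie on overlap fraction goes to the lower plant id
  p1 <- rect_mask(dim, 1:9, 1:10, "plant", 4L)
  p2 <- rect_mask(dim, 2:10, 1:10, "plant", 2L)
  mid <- rect_mask(dim, 2:9, 1:10, "leaf", 9L)       # fully inside both
  a4 <- assign_leaves(list(mid), list(p1, p2))
  expect_equal(a4$plant_id, 2L)
})

test_that("leaf endpoint is the farthest cloud point (exhaustive oracle)", {
  cl <- leaf_cloud(rbind(c(1, 0, 0), c(3, 0, 0), c(2, 0, 0)), 1L)
  expect_equal(as.numeric(leaf_endpoint(cl, c(0, 0, 0))), c(3, 0, 0))

  set.seed(31)
  big <- matrix(runif(3e4, -500, 500), ncol = 3)
  p <- c(10, -20, 30)
  q <- leaf_endpoint(leaf_cloud(big, 1L), p)
  d2 <- rowSums(sweep(big, 2, p)^2)                  # brute-force scan
  expect_equal(as.numeric(q), as.numeric(big[which.max(d2), ]))

  # ties break to the first occurrence in scan order
  tie <- leaf_cloud(rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0)), 1L)
  expect_equal(as.numeric(leaf_endpoint(tie, c(0, 0, 0))), c(5, 0, 0))
})

test_that("leaf length is the 3D Euclidean distance", {
  expect_equal(leaf_length(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(leaf_length(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(leaf_length(c(1, 1, 1), c(2, 3, 6)), sqrt(30))
})

test_that("length allometry follows area_i = Lbar * L_i * factor", {
  one <- leaf_areas(100)
  expect_equal(one$areas, 0.027)                     # 0.1 * 0.1 * 2.7
  expect_equal(one$total, 0.027)

  two <- leaf_areas(c(200, 400))
  expect_equal(two$mean_length, 300)
  expect_equal(two$areas, c(0.162, 0.324))
  expect_equal(two$total, 0.486)

  # closed form: n equal leaves of length L -> total = 2.7 n L^2
  for (n in c(1, 5, 13)) {
    eq <- leaf_areas(rep(250, n))
    expect_equal(eq$total, 2.7 * n * 0.25^2)
  }

  # identity total = factor * n * Lbar^2 on random inputs
  set.seed(8)
  for (k in 1:20) {
    L <- runif(sample(1:25, 1), 50, 400)
    la <- leaf_areas(L, shape_factor = 2.7)
    expect_equal(la$total, 2.7 * length(L) * (mean(L) / 1000)^2,
                 tolerance = 1e-12)
  }

  # adding a leaf of exactly mean length adds factor * Lbar^2
  L <- c(150, 250, 350)
  before <- leaf_areas(L)
  after <- leaf_areas(c(L, mean(L)))
  expect_equal(after$mean_length, before$mean_length)
  expect_equal(after$total - before$total, 2.7 * (mean(L) / 1000)^2)

  expect_error(leaf_areas(numeric(0)), "empty plant")
  expect_error(leaf_areas(c(100, -5)), "invalid measure")
})

test_that("lengths scale linearly and areas quadratically", {
  set.seed(4)
  clouds <- lapply(1:4, function(i) {
    leaf_cloud(matrix(runif(30, -300, 300), ncol = 3), i)
  })
  ap <- attachment_point(c(0, 0, 50))
  base <- measure_plant_leaves(clouds, ap)
  s <- 2.5
  scaled <- measure_plant_leaves(
    lapply(clouds, function(cl) leaf_cloud(unclass(cl) * s,
                                           attr(cl, "leaf_id"))),
    attachment_point(c(0, 0, 50) * s))
  expect_equal(scaled$leaves$length_mm, base$leaves$length_mm * s)
  expect_equal(scaled$leaves$area_m2, base$leaves$area_m2 * s^2)
  expect_equal(scaled$total_leaf_area, base$total_leaf_area * s^2)
})

test_that("plant leaf measurement recovers synthetic lengths", {
  cam <- camera_model()
  sc <- funnel_scene(12, camera = cam, seed = 23)
  rd <- render(sc, noise_sd = 0, outlier_fraction = 0)
  clouds <- lapply(rd$leaf_masks, backproject, depth = rd$depth,
                   camera = cam)
  ap <- attachment_point(matrix(sc$truth$attachment[1, ], ncol = 3))
  m <- measure_plant_leaves(clouds, ap)
  truth <- sc$truth$leaves[match(m$leaves$leaf_id,
                                 sc$truth$leaves$leaf_id), ]
  rel <- abs(m$leaves$length_mm - truth$length_mm) / truth$length_mm
  expect_lt(max(rel), 0.02)                          # every leaf within 2%

  # permuting leaf order leaves the totals unchanged
  m2 <- measure_plant_leaves(rev(clouds), ap)
  expect_equal(m2$total_leaf_area, m$total_leaf_area)
  expect_equal(m2$mean_leaf_length, m$mean_leaf_length)

  # an occluded leaf tip can only shorten the measured length
  sc_occ <- occlude_head(funnel_scene(8, camera = cam, seed = 25,
                                      head_radius = 90,
                                      head_center_z = 300),
                         0.5)            # raised head occludes inner leaves
  rd_occ <- render(sc_occ, noise_sd = 0)
  ids <- vapply(rd_occ$leaf_masks, function(m) m$instance_id, integer(1))
  occl <- rd_occ$truth$leaves$occlusion[match(ids,
                                              rd_occ$truth$leaves$leaf_id)]
  real <- !rd_occ$truth$leaves$occluder[match(ids,
                                              rd_occ$truth$leaves$leaf_id)]
  pick <- which(real & occl > 0.2)
  if (length(pick)) {
    cl <- backproject(rd_occ$leaf_masks[[pick[1]]], rd_occ$depth, cam)
    tl <- rd_occ$truth$leaves$length_mm[
      rd_occ$truth$leaves$leaf_id == ids[pick[1]]]
    est <- leaf_length(attachment_point(matrix(sc_occ$truth$attachment[1, ],
                                               ncol = 3)),
                       leaf_endpoint(cl, sc_occ$truth$attachment[1, ]))
    expect_lte(est, tl * 1.01)           # directional: never overestimates
  }
})
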