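test_that("mask IoU counts intersection over union", {
  dim <- c(20L, 20L)
  a <- rect_mask(dim, 1:10, 1:10)
  expect_equal(mask_iou(a, a), 1)
  b <- rect_mask(dim, 11:20, 11:20)
  expect_equal(mask_iou(a, b), 0)
  # two 10x10 squares overlapping in a 10x5 strip: 50 / 150
  c_ <- rect_mask(dim, 1:10, 6:15)
  expect_equal(mask_iou(a, c_), 1 / 3)
  expect_error(mask_iou(a, rect_mask(c(10L, 10L), 1:5, 1:5)),
               "registration error")
  # symmetry and the intersection bound on random masks
  set.seed(2)
  for (k in 1:5) {
    m1 <- instance_mask(matrix(runif(400) < 0.4, 20, 20), "leaf", 1L)
    m2 <- instance_mask(matrix(runif(400) < 0.4, 20, 20), "leaf", 2L)
    expect_equal(mask_iou(m1, m2), mask_iou(m2, m1))
    expect_lte(sum(m1$raster & m2$raster),
               min(sum(m1$raster), sum(m2$raster)))
  }
})

test_that("instance matching reproduces greedy counts and PR identities", {
  dim <- c(30L, 30L)
  t1 <- rect_mask(dim, 1:10, 1:10, "leaf", 1L)
  d1 <- rect_mask(dim, 1:10, 1:10, "leaf", 1L, score = 0.9)
  r <- match_instances(list(d1), list(t1), 0.5)
  expect_equal(c(r$tp, r$fp, r$fn), c(1, 0, 0))
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)

  none <- match_instances(list(), list(t1, rect_mask(dim, 20:25, 20:25,
                                                     "leaf", 2L)), 0.5)
  expect_equal(c(none$tp, none$fp, none$fn), c(0, 0, 2))

  # 3 detections / 2 truths vs an independent greedy oracle
  t2 <- rect_mask(dim, 15:24, 15:24, "leaf", 2L)
  d2 <- rect_mask(dim, 1:10, 3:12, "leaf", 2L, score = 0.8)   # iou 8/12 w t1
  d3 <- rect_mask(dim, 15:24, 16:24, "leaf", 3L, score = 0.7) # vs t2
  dets <- list(d1, d2, d3)
  truths <- list(t1, t2)
  oracle_greedy <- function(dets, truths, thr) {
    ord <- order(-vapply(dets, function(d) d$score, numeric(1)))
    used <- rep(FALSE, length(truths)); tp <- 0
    for (i in ord) {
      io <- vapply(seq_along(truths), function(j) {
        if (used[j]) -1 else mask_iou(dets[[i]], truths[[j]])
      }, numeric(1))
      if (max(io) >= thr) { used[which.max(io)] <- TRUE; tp <- tp + 1 }
    }
    c(tp = tp, fp = length(dets) - tp, fn = sum(!used))
  }
  for (thr in c(0.3, 0.5, 0.8)) {
    got <- match_instances(dets, truths, thr)
    want <- oracle_greedy(dets, truths, thr)
    expect_equal(c(got$tp, got$fp, got$fn), unname(want))
    # counting identities hold at every threshold
    expect_equal(got$tp + got$fn, length(truths))
    expect_equal(got$tp + got$fp, length(dets))
  }
})

test_that("average precision follows the 101-point COCO convention", {
  dim <- c(40L, 40L)
  truths <- list(rect_mask(dim, 1:10, 1:10, "leaf", 1L),
                 rect_mask(dim, 20:29, 20:29, "leaf", 2L))
  perfect <- list(rect_mask(dim, 1:10, 1:10, "leaf", 1L, 0.9),
                  rect_mask(dim, 20:29, 20:29, "leaf", 2L, 0.8))
  res <- map_range(perfect, truths)
  expect_true(all(res$ap == 1))
  expect_equal(res$map, 1)

  # every detection has IoU 0.7 with its truth: passes 5 of 10 thresholds.
  # 25x34-px truths, detections shifted so overlap 700 / union 1000 = 0.7.
  t1 <- rect_mask(dim, 1:25, 1:34, "leaf", 1L)
  d1 <- rect_mask(dim, 1:25, 7:40, "leaf", 1L, 0.9)
  expect_equal(mask_iou(t1, d1), 0.7)
  res7 <- map_range(list(d1), list(t1))
  expect_equal(unname(res7$ap[1:5]), rep(1, 5))
  expect_equal(unname(res7$ap[6:10]), rep(0, 5))
  expect_equal(res7$map, 0.5)

  # a lone false positive has AP 0
  fp_only <- match_instances(list(rect_mask(dim, 30:35, 1:5, "leaf", 9L,
                                            0.5)), list(t1), 0.5)
  expect_equal(average_precision(fp_only), 0)

  # mAP cannot increase when the threshold grid shifts upward
  low <- map_range(list(d1), list(t1), thresholds = seq(0.4, 0.85, 0.05))
  expect_gte(low$map, res7$map)
})

test_that("mean accuracy and column statistics match hand arithmetic", {
  expect_equal(accuracy_stats(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(accuracy_stats(100, 90), 90)
  expect_equal(accuracy_stats(100, 300), 0)          # floored at 0
  expect_error(accuracy_stats(1:3, 1:2), "pairing error")

  expect_equal(column_stats(c(1, 1, 1))$sd, 0)
  cs <- column_stats(c(2, 4))
  expect_equal(cs$mean, 3)
  expect_equal(cs$sd, 1)                             # population sd
  expect_equal(cs$sd_percent, 100 / 3)
  expect_error(column_stats(5), "insufficient data")
})

test_that("bundled volume table reproduces its printed summary statistics", {
  tabs <- cabbage_tables()
  v48 <- tabs$volume_bbch48
  cs <- column_stats(v48$measured_m3)
  expect_equal(round(cs$mean, 4), 0.0029)
  # population sd reproduces the printed 0.00057; the sample sd does not
  expect_equal(round(cs$sd, 5), 0.00057)
  expect_false(round(stats::sd(v48$measured_m3), 5) == 0.00057)
  # mean relative accuracy on the rounded columns: ~86.6 (printed: 87.2;
  # the source's accuracy formula is undocumented)
  expect_equal(accuracy_stats(v48$measured_m3, v48$calculated_m3), 86.57,
               tolerance = 0.005)
})
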