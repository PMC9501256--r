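test_that("single-object area estimate is median-robust", {
  expect_equal(estimate_single_area(rep(40, 6)), 40)
  expect_equal(estimate_single_area(c(rep(40, 9), 400)), 40)
  expect_error(estimate_single_area(numeric(0)), "defer")
  # within 10% of the rendered spot area on a synthetic fixture
  img <- render_spots(c(60, 200), c(20, 35, 45), c(40, 100, 160),
                      rep(180, 3), 2)
  det <- detect_objects(img + 0)
  est <- estimate_single_area(det$area_px)
  expect_lt(abs(est - det$area_px[1]) / det$area_px[1], 0.1)
})

test_that("frame differencing counts movers, not scenery", {
  f <- render_spots(c(50, 80), 25, 30, 180, 2)
  expect_identical(diff_movers(f, f)$count, 0L)
  f2 <- render_spots(c(50, 80), 25, 35, 180, 2)
  expect_identical(diff_movers(f2, f)$count, 1L)
  # two independent movers, far apart
  g1 <- render_spots(c(60, 120), c(15, 45), c(30, 90), c(180, 180), 2)
  g2 <- render_spots(c(60, 120), c(15, 45), c(35, 95), c(180, 180), 2)
  expect_identical(diff_movers(g2, g1)$count, 2L)
  expect_error(diff_movers(f, matrix(0, 2, 2)), "shape")
})

test_that("aggregate division rounds half away from zero, floor one", {
  expect_identical(count_aggregate(40, 40), 1L)
  expect_identical(count_aggregate(200, 40), 5L)
  expect_identical(count_aggregate(100, 40), 3L)   # 2.5 -> 3
  expect_identical(count_aggregate(10, 40), 1L)
  expect_identical(count_aggregate(c(40, 100), 40), c(1L, 3L))
  expect_error(count_aggregate(0, 40), "positive")
  expect_error(count_aggregate(40, 0), "positive")
})

test_that("fused discs decompose to k within 1 for k up to 6", {
  # k identical discs in a row at spacing that fuses their contours
  rad <- 6
  single <- disk_mask(40, 40, 20, 20, rad)
  a1 <- region_area(find_contours(single, 1)[[1]])
  for (k in 2:6) {
    w <- 40 + 12 * k
    m <- matrix(FALSE, 40, w)
    for (i in seq_len(k))
      m <- m | disk_mask(40, w, 20, 8 + (i - 1) * (2 * rad - 1), rad)
    cts <- find_contours(m, 1)
    expect_length(cts, 1L)
    est <- count_aggregate(region_area(cts[[1]]), a1)
    expect_lte(abs(est - k), 1)
  }
})

test_that("tracking links drifting and parallel objects correctly", {
  # one object drifting at constant velocity: one track spanning all
  det <- data.frame(frame = 1:12, row = 20, col = 5 + 3 * (1:12))
  tr <- track_centroids(det)
  expect_identical(unique(tr$track_id), 1L)
  # two objects beyond the link radius: two disjoint tracks
  det2 <- rbind(det, data.frame(frame = 1:12, row = 60,
                                col = 5 + 3 * (1:12)))
  tr2 <- track_centroids(det2)
  expect_identical(sort(unique(tr2$track_id)), c(1L, 2L))
  # non-crossing synthetic trajectories: track count = object count
  withr::with_seed(31, {
    rows <- seq(10, 90, by = 16)
    det3 <- do.call(rbind, lapply(seq_along(rows), function(i)
      data.frame(frame = 1:15, row = rows[i] + rnorm(15, 0, 0.2),
                 col = 4 * (1:15) + runif(1, 0, 4))))
    tr3 <- track_centroids(det3[order(det3$frame), ])
    expect_identical(length(unique(tr3$track_id)), length(rows))
  })
  # a static object is flagged stuck
  det4 <- data.frame(frame = 1:10, row = 30, col = 50)
  st <- attr(track_centroids(det4), "status")
  expect_identical(st$status, "stuck")
})

test_that("counting a blank video yields all zeros", {
  blank <- array(0, dim = c(40, 60, 4))
  rep <- count_video(blank)
  expect_true(all(rep$per_frame$movers == 0))
  expect_true(all(rep$per_frame$zone_equivalents == 0))
  expect_identical(rep$cumulative_accumulated, 0L)
})

test_that("well-separated bright movers are counted exactly", {
  cf <- scene_config(n_objects = 6L, n_frames = 25L, faint_fraction = 0,
                     pair_fraction = 0, aggregation_enabled = FALSE,
                     magnet_zone = NULL, noise_sd = 2, seed = 5)
  vid <- render_video(cf)
  rep <- count_video(vid, scene_count_config(cf))
  tf <- vid$truth$frames
  for (f in 2:25) {
    rec <- tf[tf$frame == f, ]
    # skip frames where a spot straddles the frame border (it is
    # neither fully in truth nor fully out of the image)
    if (any(rec$col > 292 & rec$col < 308)) next
    truth_n <- sum(rec$visible)
    expect_identical(rep$per_frame$out_equivalents[f], truth_n)
  }
  acc <- evaluate_accuracy(rep, vid$truth)
  expect_equal(acc$fraction, 1.0)
})

test_that("end-to-end counts are invariant to integer frame shifts", {
  # noiseless spots with compact support, kept well inside the frame
  # in both the original and the shifted stack
  rows <- c(20, 45, 32)
  cols0 <- c(15, 30, 55)
  stack <- function(dr, dc) {
    arr <- array(0, dim = c(80, 160, 10))
    for (f in 1:10)
      arr[, , f] <- render_spots(c(80, 160), rows + dr,
                                 cols0 + 3 * (f - 1) + dc,
                                 rep(180, 3), 2)
    arr
  }
  a <- count_video(stack(0, 0), count_config())
  b <- count_video(stack(7, 12), count_config())
  expect_identical(a$per_frame$out_equivalents,
                   b$per_frame$out_equivalents)
  expect_identical(a$per_frame$movers, b$per_frame$movers)
  expect_equal(b$detections$row - a$detections$row,
               rep(7, nrow(a$detections)), tolerance = 1e-9)
})
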