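test_that("an empty scene renders pure noise with zero totals", {
  cf <- scene_config(n_objects = 0L, n_frames = 5L, seed = 2)
  vid <- render_video(cf)
  expect_equal(dim(vid$frames), c(120, 300, 5))
  expect_true(all(vid$truth$totals[, c("spawned", "moving", "stuck",
                                       "exited")] == 0))
  expect_identical(vid$truth$final_stuck, 0L)
})

test_that("a noiseless object renders its amplitude at its position", {
  cf <- scene_config(n_objects = 1L, n_frames = 3L, noise_sd = 0,
                     faint_fraction = 0, pair_fraction = 0,
                     aggregation_enabled = FALSE, magnet_zone = NULL,
                     seed = 4)
  vid <- render_video(cf)
  tf <- vid$truth$frames
  sp <- tf[tf$frame == vid$truth$objects$spawn_frame[1], ]
  f <- vid$frames[, , sp$frame]
  peak <- which(f == max(f), arr.ind = TRUE)[1, ]
  expect_equal(max(f), 180)            # spawn positions are integers
  expect_equal(as.numeric(peak), c(sp$row, sp$col))
})

test_that("render_spots is photometrically additive", {
  one <- render_spots(c(30, 30), 10, 12, 100, 2)
  two <- render_spots(c(30, 30), 22, 20, 150, 2)
  both <- render_spots(c(30, 30), c(10, 22), c(12, 20), c(100, 150), 2)
  expect_equal(both, one + two, tolerance = 1e-12)
})

test_that("certain sticking makes the cumulative stuck count exact", {
  cf <- scene_config(n_objects = 20L, n_frames = 120L,
                     stick_probability = 1,
                     magnet_zone = list(r0 = 1, r1 = 120,
                                        c0 = 140, c1 = 170),
                     pair_fraction = 0, faint_fraction = 0, seed = 6)
  vid <- render_video(cf)
  tf <- vid$truth$frames
  # every object observed moving inside the zone must end up stuck
  entered <- unique(tf$object_id[tf$status == "moving" &
                                   tf$col >= 140 & tf$col <= 170])
  stuck_ids <- unique(tf$object_id[tf$status == "stuck"])
  expect_true(all(entered %in% stuck_ids))
  expect_identical(vid$truth$final_stuck, length(stuck_ids))
  expect_gt(vid$truth$final_stuck, 0L)
  # stuck objects never move again
  for (o in unique(tf$object_id[tf$status == "stuck"])) {
    rec <- tf[tf$object_id == o & tf$status == "stuck", ]
    expect_lt(max(rec$row) - min(rec$row), 1e-9)
    expect_lt(max(rec$col) - min(rec$col), 1e-9)
  }
})

test_that("ground truth conserves objects every frame", {
  vid <- render_video(scene_config(seed = 12))
  tt <- vid$truth$totals
  expect_true(all(tt$moving + tt$stuck + tt$exited == tt$spawned))
  # visible positions stay inside the frame
  tf <- vid$truth$frames
  vis <- tf[tf$visible, ]
  expect_true(all(vis$row >= 1 & vis$row <= 120 &
                    vis$col >= 1 & vis$col <= 300))
})

test_that("rendering is bit-exact under a fixed seed", {
  a <- render_video(scene_config(n_frames = 15L, seed = 33))
  b <- render_video(scene_config(n_frames = 15L, seed = 33))
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth$frames, b$truth$frames)
  c <- render_video(scene_config(n_frames = 15L, seed = 34))
  expect_false(identical(a$frames, c$frames))
})

test_that("the benchmark suite restricts each case as labelled", {
  bm <- standard_benchmarks(seed = 1)
  expect_named(bm, c("separated_movers", "aggregates", "faint",
                     "overlap_traces", "mixed"))
  # case one: bright, never sticking
  t1 <- bm$separated_movers$truth
  expect_true(all(t1$objects$class == "bright"))
  expect_identical(t1$final_stuck, 0L)
  # case two: aggregates of two or more stuck objects exist at the end
  t2 <- bm$aggregates$truth
  expect_gt(t2$final_stuck, 1L)
  agg <- t2$objects$aggregate_id
  expect_gt(max(table(agg[!is.na(agg)])), 1L)
  # case three: all faint
  expect_true(all(bm$faint$truth$objects$class == "faint"))
  # mixed: totals add up
  tm <- bm$mixed$truth$totals
  expect_true(all(tm$moving + tm$stuck + tm$exited == tm$spawned))
})

test_that("video IO round-trips through TIFF", {
  vid <- render_video(scene_config(n_objects = 3L, n_frames = 4L,
                                   frame_shape = c(40L, 60L),
                                   magnet_zone = NULL, seed = 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_video(vid, path)
  back <- read_video(path)
  expect_equal(dim(back), dim(vid$frames))
  sc <- max(vid$frames)
  expect_lt(max(abs(back * sc - vid$frames)), sc / 2^15)
})

test_that("trajectory renderings carry capture verdicts into truth", {
  env <- fluid_env(5e-3)
  m <- magnet_model()
  spec <- capsule_spec(2.7, 0, n_freeze_cycles = 3)
  # far streamline: no capture
  far <- integrate_trajectory(spec, env, m,
                              start = list(position = c(0, 2.2e-4)))
  cf0 <- scene_config(frame_shape = c(60L, 410L), n_frames = 30L,
                      pixel_size_um = 5, noise_sd = 1,
                      magnet_zone = list(r0 = 40, r1 = 60,
                                         c0 = 180, c1 = 220), seed = 2)
  v0 <- render_from_trajectories(list(far), env, cf0)
  expect_identical(v0$truth$final_stuck, 0L)
  # several captured capsules at separated stops
  heights <- c(1.5e-5, 2.5e-5, 3.5e-5)
  caps <- lapply(heights, function(y)
    integrate_trajectory(spec, env, m,
                         start = list(position = c(0, y))))
  expect_true(all(vapply(caps, `[[`, logical(1), "captured")))
  v1 <- render_from_trajectories(caps, env, cf0)
  expect_identical(v1$truth$final_stuck, 3L)
})

test_that("counting a rendering of separated captures closes the loop", {
  # three capsules trapped at three pole positions: stops are far
  # apart, so the counting module's cumulative estimate is exact
  env <- fluid_env(5e-3)
  spec <- capsule_spec(2.7, 0, n_freeze_cycles = 3)
  caps <- lapply(c(400, 1000, 1600), function(x)
    integrate_trajectory(spec, env, magnet_model(x_um = x),
                         start = list(position = c(0, 2e-5))))
  expect_true(all(vapply(caps, `[[`, logical(1), "captured")))
  cf <- scene_config(frame_shape = c(60L, 410L), n_frames = 40L,
                     pixel_size_um = 5, noise_sd = 1,
                     magnet_zone = list(r0 = 45, r1 = 60,
                                        c0 = 1, c1 = 410), seed = 3)
  vid <- render_from_trajectories(caps, env, cf)
  rep <- count_video(vid, scene_count_config(cf))
  expect_identical(rep$cumulative_accumulated, 3L)
})
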