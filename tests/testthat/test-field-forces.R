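test_that("Stokes drag is linear, antiparallel and matches hand values", {
  expect_equal(drag_force(1e-6, c(0, 0), 1e-3), c(0, 0))
  # hand evaluation: R = 1.35 um, eta = 1e-3, |v| = 5 mm/s
  f <- drag_force(1.35e-6, c(5e-3, 0), 1e-3)
  expect_equal(f, c(-6 * pi * 1e-3 * 1.35e-6 * 5e-3, 0))
  # cell/capsule fold ratio 13 / 2.7
  r <- drag_force(13e-6 / 2, c(1, 0), 1e-3)[1] /
       drag_force(2.7e-6 / 2, c(1, 0), 1e-3)[1]
  expect_equal(r, 13 / 2.7)
  # linearity in R and |v| over grids
  for (R in c(0.5, 2, 5) * 1e-6) for (v in c(1, 10) * 1e-3) {
    expect_equal(drag_force(R, c(v, 0), 1e-3),
                 R / 1e-6 * v / 1e-3 * drag_force(1e-6, c(1e-3, 0), 1e-3))
  }
  expect_error(drag_force(0, c(1, 0), 1e-3), "positive")
  expect_error(drag_force(1e-6, c(1, 0), 0), "positive")
})

test_that("field model calibrates at the channel edge and decays", {
  m <- magnet_model(B_edge = 0.3, standoff_um = 100, x_um = 1000)
  edge <- c(1000e-6, 0)
  B <- field_at(m, edge)$B
  expect_equal(sqrt(sum(B^2)), 0.3, tolerance = 1e-9)
  expect_lt(B[2], 0)   # points toward the pole below the wall
  # inverse-square decay by construction
  p1 <- c(1000e-6, 100e-6)   # distance 2 r_edge
  expect_equal(sqrt(sum(field_at(m, p1)$B^2)), 0.3 / 4)
  # monotone decrease along a ray
  d <- seq(50, 400, by = 25) * 1e-6
  mag <- vapply(d, function(y) sqrt(sum(field_at(m, c(1000e-6, y))$B^2)),
                numeric(1))
  expect_true(all(diff(mag) < 0))
  expect_error(field_at(m, m$pole_position), "singularity")
})

test_that("analytic field gradient matches central finite differences", {
  m <- magnet_model(B_edge = 0.3, standoff_um = 100, x_um = 1000,
                    pole_exponent = 2)
  withr::with_seed(11, {
    for (i in 1:10) {
      p <- c(runif(1, 0, 2e-3), runif(1, 1e-5, 2.5e-4))
      g <- field_at(m, p)$gradB
      h <- 1e-9
      fd <- vapply(1:2, function(j) {
        e <- c(0, 0); e[j] <- h
        (field_at(m, p + e)$B - field_at(m, p - e)$B) / (2 * h)
      }, numeric(2))
      expect_lt(max(abs(fd - g)) / max(abs(fd)), 1e-4)
      expect_equal(g[1, 2], g[2, 1], tolerance = 1e-6 * max(abs(g)))
    }
  })
})

test_that("induced magnetic moment is linear in volume and payload", {
  k <- make_constants()
  s <- capsule_spec(2.7, 0, n_freeze_cycles = 1, constants = k)
  expect_equal(magnetic_moment(s, c(0, 0), k), c(0, 0))
  B <- c(0.1, 0.05)
  m1 <- magnetic_moment(s, B, k)
  expect_equal(m1, s$volume_m3 * s$chi_cap / k$mu0 * B)
  s2 <- capsule_spec(2.7 * 2^(1 / 3), 0, n_freeze_cycles = 1,
                     constants = k)
  expect_equal(magnetic_moment(s2, B, k), 2 * m1, tolerance = 1e-12)
  # 3-cycle vs 1-cycle payload at identical size and field: ratio 4
  s3 <- capsule_spec(2.7, 0, mnp_mass_fraction = 0.064, rho = s$rho,
                     constants = k)
  s1 <- capsule_spec(2.7, 0, mnp_mass_fraction = 0.016, rho = s$rho,
                     constants = k)
  expect_equal(magnetic_moment(s3, B, k) / magnetic_moment(s1, B, k),
               c(4, 4))
})

test_that("magnetic force needs a gradient and a magnetic payload", {
  m <- magnet_model()
  s0 <- capsule_spec(2.7, 0, mnp_mass_fraction = 0)
  expect_equal(magnetic_force(s0, m, c(1e-3, 1e-4)), c(0, 0))
  # force on a loaded capsule points toward the pole
  s <- capsule_spec(2.7, 0, n_freeze_cycles = 3)
  pos <- c(1000e-6, 1e-4)
  f <- magnetic_force(s, m, pos)
  dirn <- (m$pole_position - pos) / sqrt(sum((m$pole_position - pos)^2))
  expect_equal(f / sqrt(sum(f * f)), dirn, tolerance = 1e-9)
})

test_that("induced force equals the magnetostatic energy gradient", {
  # for the curl-free tip field, (B . grad) B = grad(|B|^2 / 2), so
  # F = (V chi / mu0) grad(|B|^2 / 2); check against numerical
  # differentiation of the energy density term
  k <- make_constants()
  m <- magnet_model(B_edge = 0.3, standoff_um = 120, x_um = 800)
  s <- capsule_spec(2.7, 0, n_freeze_cycles = 3, constants = k)
  u <- function(p) {
    B <- field_at(m, p)$B
    s$volume_m3 * s$chi_cap / (2 * k$mu0) * sum(B * B)
  }
  withr::with_seed(21, {
    for (i in 1:5) {
      p <- c(runif(1, 2e-4, 1.6e-3), runif(1, 2e-5, 2e-4))
      f <- magnetic_force(s, m, p, k)
      h <- 1e-10
      fn <- c((u(p + c(h, 0)) - u(p - c(h, 0))) / (2 * h),
              (u(p + c(0, h)) - u(p - c(0, h))) / (2 * h))
      expect_lt(sqrt(sum((f - fn)^2)) / sqrt(sum(fn * fn)), 1e-3)
    }
  })
})

test_that("net force is the exact sum of drag and magnetic parts", {
  env <- quiet_env(5)
  m <- magnet_model()
  s <- capsule_spec(2.7, 0, n_freeze_cycles = 2)
  st <- list(position = c(900e-6, 8e-5), velocity = c(2e-3, -1e-4))
  v_rel <- st$velocity - c(flow_velocity(env, st$position[2]), 0)
  expect_equal(net_force(s, env, m, st),
               drag_force(s$radius_m, v_rel, env$eta) +
                 magnetic_force(s, m, st$position))
  # co-moving with the flow far from the magnet: essentially force-free
  far <- list(position = c(0, 2e-4),
              velocity = c(flow_velocity(env, 2e-4), 0))
  f <- net_force(s, env, m, far)
  expect_lt(sqrt(sum(f * f)), 1e-13)   # ~1e3 x below any trapping force
})

test_that("parabolic profile peaks at 1.5x mean with no-slip walls", {
  env <- fluid_env(10e-3, channel_height = 200e-6)
  expect_equal(flow_velocity(env, 100e-6), 1.5 * 10e-3)
  expect_equal(flow_velocity(env, 0), 0)
  expect_equal(flow_velocity(env, 200e-6), 0)
  plug <- fluid_env(10e-3, profile = "plug")
  expect_equal(flow_velocity(plug, 5e-5), 10e-3)
})
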