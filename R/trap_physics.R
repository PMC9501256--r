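#' Flow-cell environment
#'
#' Two-dimensional channel: `x` runs along the flow (0 at the inlet),
#' `y` across the channel (0 at the magnet-side wall, `channel_height`
#' at the far wall).  The magnet sits below the `y = 0` wall.
#'
#' @param mean_velocity Mean flow velocity (m/s).
#' @param eta Dynamic viscosity (Pa s).
#' @param channel_height Channel height (m).
#' @param channel_length Simulated channel length (m).
#' @param profile `"parabolic"` (plane Poiseuille, no-slip walls, peak
#'   1.5 x mean) or `"plug"` (uniform, mainly for closed-form checks).
#' @return An object of class `fluid_env`.
#' @export
fluid_env <- function(mean_velocity, eta = 1.0e-3,
                      channel_height = 250e-6, channel_length = 2e-3,
                      profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  stopifnot(eta > 0, channel_height > 0, channel_length > 0,
            mean_velocity >= 0)
  structure(list(eta = eta, channel_height = channel_height,
                 channel_length = channel_length,
                 mean_velocity = mean_velocity, profile = profile),
            class = "fluid_env")
}

#' Local axial flow velocity
#'
#' @param env A [fluid_env()].
#' @param y Wall-normal coordinate(s), m.
#' @return Axial fluid velocity at height `y` (m/s); zero outside the
#'   channel.
#' @export
flow_velocity <- function(env, y) {
  H <- env$channel_height
  v <- switch(env$profile,
              parabolic = 6 * env$mean_velocity * y * (H - y) / H^2,
              plug = rep(env$mean_velocity, length(y)))
  v[y < 0 | y > H] <- 0
  v
}

#' Permanent-magnet field model
#'
#' Monopole-like tip field of a conical concentrator: the field points
#' toward the pole with magnitude `B_edge * (r_edge / r)^pole_exponent`,
#' where `r` is the distance from the pole and `r_edge` the pole-to-wall
#' standoff.  `B_edge` is therefore the calibrated magnitude at the
#' nearest point of the channel edge (directly above the pole), and the
#' magnitude strictly decreases away from the pole.
#'
#' @param B_edge Field magnitude at the channel-edge calibration point
#'   (T); default 0.3.
#' @param standoff_um Pole-to-wall distance (micrometres).
#' @param x_um Axial pole position (micrometres from the inlet).
#' @param pole_exponent Radial decay exponent of the field magnitude;
#'   2 is the monopole-tip approximation.
#' @return An object of class `magnet_model` with fields
#'   `pole_position` (m, `y < 0`), `r_edge`, `B_edge`, `pole_exponent`.
#' @export
magnet_model <- function(B_edge = 0.3, standoff_um = 100, x_um = 1000,
                         pole_exponent = 2) {
  stopifnot(B_edge >= 0, standoff_um > 0, pole_exponent > 0)
  structure(list(pole_position = c(x_um, -standoff_um) * 1e-6,
                 r_edge = standoff_um * 1e-6,
                 B_edge = B_edge,
                 pole_exponent = pole_exponent),
            class = "magnet_model")
}

#' Magnetic field and gradient at a point
#'
#' Analytic field vector and Jacobian of the monopole-tip model.  The
#' Jacobian `gradB[i, j] = dB_i/dx_j` is symmetric (the model field is
#' curl-free), so `(B . grad) B` equals the gradient of the magnetostatic
#' energy density term `|B|^2 / 2`.
#'
#' @param magnet A [magnet_model()].
#' @param position Position vector (m), length 2.
#' @return List with `B` (length-2 vector, T) and `gradB` (2 x 2 matrix,
#'   T/m).
#' @export
field_at <- function(magnet, position) {
  u <- as.numeric(position) - magnet$pole_position
  r2 <- sum(u * u)
  if (r2 == 0) stop("field evaluated at the pole singularity",
                    call. = FALSE)
  r <- sqrt(r2)
  p <- magnet$pole_exponent
  a <- magnet$B_edge * magnet$r_edge^p     # B = -a * u / r^(p+1)
  rp1 <- r^(p + 1)
  B <- -a * u / rp1
  gradB <- -a * (diag(2) / rp1 - (p + 1) * tcrossprod(u) / (rp1 * r2))
  list(B = B, gradB = gradB)
}

#' Stokes drag force
#'
#' `F_D = -6 pi eta R v_rel`, the creeping-flow drag on a sphere moving
#' at `v_rel` relative to the local fluid.
#'
#' @param radius Sphere radius (m), > 0.
#' @param velocity_rel Velocity relative to the local fluid (m/s),
#'   length 2.
#' @param eta Dynamic viscosity (Pa s), > 0.
#' @return Force vector (N), antiparallel to `velocity_rel`.
#' @export
drag_force <- function(radius, velocity_rel, eta) {
  if (radius <= 0 || eta <= 0)
    stop("radius and eta must be positive", call. = FALSE)
  -6 * pi * eta * radius * as.numeric(velocity_rel)
}

#' Magnetic force on a capsule
#'
#' `F_M = rho V (M0 . grad) B + (V chi_cap / mu0) (B . grad) B`: the
#' remanence term plus the induced term.  With zero remanence and the
#' monopole-tip field the force points toward the pole.
#'
#' @param spec A [capsule_spec()].
#' @param magnet A [magnet_model()].
#' @param position Position (m), length 2.
#' @param constants A [physical_constants()] object.
#' @return Force vector (N), length 2.
#' @export
magnetic_force <- function(spec, magnet, position,
                           constants = physical_constants()) {
  f <- field_at(magnet, position)
  a <- spec$rho * spec$volume_m3 * spec$M0 +
    spec$volume_m3 * spec$chi_cap / constants$mu0 * f$B
  as.numeric(f$gradB %*% a)
}

#' Net force on a capsule in the flow
#'
#' Sum of Stokes drag (computed from the velocity relative to the local
#' flow profile) and the magnetic force.
#'
#' @param spec A [capsule_spec()].
#' @param env A [fluid_env()].
#' @param magnet A [magnet_model()].
#' @param state List with `position` and `velocity` (length-2, m and
#'   m/s).
#' @param constants A [physical_constants()] object.
#' @return Force vector (N), length 2.
#' @export
net_force <- function(spec, env, magnet, state,
                      constants = physical_constants()) {
  v_rel <- state$velocity -
    c(flow_velocity(env, state$position[2]), 0)
  drag_force(spec$radius_m, v_rel, env$eta) +
    magnetic_force(spec, magnet, state$position, constants)
}

#' Integrate a capsule trajectory and decide capture
#'
#' Advances a capsule from an inlet state until it is captured, exits
#' the channel, or the time budget runs out.  A capsule is captured when
#' it rests on the magnet-side wall (centre within one radius of the
#' wall), the wall-normal magnetic force presses it against the wall,
#' and its residual speed does not exceed `eps_v`.
#'
#' Two integration modes are available.  `"overdamped"` uses the
#' zero-inertia force balance `v = v_flow + F_M / (6 pi eta R)` with an
#' explicit step whose displacement is bounded by 0.1 capsule radius
#' near the pole (growing with distance from it).  `"inertial"` solves
#' `m dv/dt = F_D + F_M` with an exponential integrator that is exact
#' for piecewise-constant force and flow, hence unconditionally stable
#' at the microsecond velocity-relaxation scale of micron-sized spheres.
#'
#' @param spec A [capsule_spec()].
#' @param env A [fluid_env()].
#' @param magnet A [magnet_model()].
#' @param start List with `position` (m, length 2) and optionally
#'   `velocity` (m/s; default co-moving with the flow) and `t` (s).
#' @param dt_max Maximum time step (s); defaults to
#'   `max(5e-4, t_max / 2e4)` so that slow creeping scenarios remain
#'   inside the step budget.
#' @param t_max Time budget (s); default 5 channel transit times.
#' @param mode `"overdamped"` or `"inertial"`.
#' @param eps_v Capture speed tolerance (m/s); default 1e-6 (1 um/s).
#' @param external_force Constant extra force (N), length 2; default
#'   zero.  Useful for closed-form integrator checks.
#' @param record Keep the trajectory (downsampled) in the result.
#' @param max_steps Step budget guard.
#' @param constants A [physical_constants()] object.
#' @return An object of class `capture_result`: list with `captured`,
#'   `stop_position` (or `NULL`), `time`, `exit_reason` and, if
#'   requested, a `trajectory` data.frame (`t, x, y, vx, vy`).
#' @export
integrate_trajectory <- function(spec, env, magnet, start,
                                 dt_max = NULL, t_max = NULL,
                                 mode = c("overdamped", "inertial"),
                                 eps_v = 1e-6,
                                 external_force = c(0, 0),
                                 record = TRUE, max_steps = 2e5,
                                 constants = physical_constants()) {
  mode <- match.arg(mode)
  R <- spec$radius_m
  H <- env$channel_height
  L <- env$channel_length
  gam <- 6 * pi * env$eta * R
  chiV <- spec$volume_m3 * spec$chi_cap / constants$mu0
  m0V <- spec$rho * spec$volume_m3 * spec$M0
  mass <- spec$mass_kg
  pole <- magnet$pole_position
  pexp <- magnet$pole_exponent
  amag <- magnet$B_edge * magnet$r_edge^pexp
  re <- magnet$r_edge

  pos <- as.numeric(start$position)
  if (pos[2] < R) pos[2] <- R
  if (pos[2] > H - R) pos[2] <- H - R
  vel <- if (!is.null(start$velocity)) as.numeric(start$velocity)
         else c(flow_velocity(env, pos[2]), 0)
  t <- start$t %||% 0
  if (is.null(t_max))
    t_max <- if (env$mean_velocity > 0) 5 * L / env$mean_velocity else 60
  if (is.null(dt_max)) dt_max <- max(5e-4, t_max / 2e4)

  fmag <- function(p) {
    u <- p - pole
    r2 <- sum(u * u)
    r <- sqrt(r2)
    rp1 <- r^(pexp + 1)
    B <- -amag * u / rp1
    gB <- -amag * (diag(2) / rp1 - (pexp + 1) * tcrossprod(u) / (rp1 * r2))
    as.numeric(gB %*% (m0V + chiV * B))
  }

  traj <- if (record) vector("list", 512L) else NULL
  n_rec <- 0L
  rec_every <- 20L
  push <- function(i) {
    n_rec <<- n_rec + 1L
    if (record && n_rec > length(traj))
      length(traj) <<- 2L * length(traj)
    if (record) traj[[n_rec]] <<- c(t, pos, vel)
  }

  captured <- FALSE
  exit_reason <- "t_max"
  step <- 0L
  if (record) push(0L)

  while (step < max_steps) {
    step <- step + 1L
    FM <- fmag(pos) + external_force
    at_wall <- pos[2] <= R + 1e-12
    vflow <- flow_velocity(env, pos[2])

    if (mode == "overdamped") {
      v <- c(vflow, 0) + FM / gam
      if (at_wall && FM[2] < 0) {
        # pressed against the wall: wall-normal motion cancelled
        if (v[1] <= eps_v) {           # flow no longer wins: capture
          captured <- TRUE
          vel <- c(0, 0)
          exit_reason <- "captured"
          break
        }
        v[2] <- 0
      }
      vel <- v
      sp <- sqrt(sum(v * v))
      if (sp <= eps_v && at_wall && FM[2] < 0) {
        captured <- TRUE
        exit_reason <- "captured"
        break
      }
      r_pole <- sqrt(sum((pos - pole)^2))
      ds <- max(0.1 * R, min(2e-6, 0.25 * (r_pole - re)))
      dt <- if (sp > 0) min(dt_max, ds / sp) else dt_max
      if (dt <= 0 || !is.finite(dt))
        stop("integration step underflow", call. = FALSE)
      pos <- pos + v * dt
      t <- t + dt
    } else {
      # exponential integrator on m dv/dt = -gam (v - v*) with
      # v* = v_flow + FM/gam frozen over the step
      vstar <- c(vflow, 0) + FM / gam
      tau <- mass / gam
      sp <- max(sqrt(sum(vstar * vstar)), sqrt(sum(vel * vel)))
      r_pole <- sqrt(sum((pos - pole)^2))
      ds <- max(0.1 * R, min(2e-6, 0.25 * (r_pole - re)))
      dt <- if (sp > 0) min(dt_max, ds / sp) else dt_max
      if (dt <= 0 || !is.finite(dt))
        stop("integration step underflow", call. = FALSE)
      ee <- exp(-dt / tau)
      dv <- vel - vstar
      pos_new <- pos + vstar * dt + dv * tau * (1 - ee)
      vel <- vstar + dv * ee
      pos <- pos_new
      t <- t + dt
      if (pos[2] <= R && FM[2] < 0) {
        pos[2] <- R
        if (vel[2] < 0) vel[2] <- 0
        if (abs(vel[1]) <= eps_v ||
            (vel[1] <= eps_v && vstar[1] <= eps_v)) {
          captured <- TRUE
          exit_reason <- "captured"
          break
        }
      }
    }

    # wall clamping
    if (pos[2] < R) pos[2] <- R
    if (pos[2] > H - R) pos[2] <- H - R

    if (record && step %% rec_every == 0L) push(step)
    if (pos[1] > L) { exit_reason <- "exited"; break }
    if (t >= t_max) { exit_reason <- "t_max"; break }
  }
  if (step >= max_steps) exit_reason <- "max_steps"
  if (record) push(step)

  trajectory <- NULL
  if (record) {
    m <- do.call(rbind, traj[seq_len(n_rec)])
    trajectory <- data.frame(t = m[, 1], x = m[, 2], y = m[, 3],
                             vx = m[, 4], vy = m[, 5])
  }
  structure(list(captured = captured,
                 stop_position = if (captured) pos else NULL,
                 time = t, exit_reason = exit_reason,
                 final_position = pos, final_velocity = vel,
                 trajectory = trajectory),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  if (x$captured)
    cat(sprintf("<capture_result> captured at x = %.1f um after %.3g s\n",
                1e6 * x$stop_position[1], x$time))
  else
    cat(sprintf("<capture_result> not captured (%s) after %.3g s\n",
                x$exit_reason, x$time))
  invisible(x)
}

#' Capture-efficiency sweep over size, payload and flow velocity
#'
#' For every combination of capsule size class, number of loading cycles
#' and mean flow velocity, releases `n_per_cell` capsules with random
#' diameters (truncated normal, the class dispersion) and random inlet
#' heights (uniform across the channel) and records the fraction
#' captured.  A single integer seed makes the whole sweep reproducible.
#'
#' The `n_per_cell` draws of one size class are shared across all its
#' cycles x velocity cells (common random numbers), so within a size
#' class the comparison between payloads and velocities is paired: the
#' same physical capsule is re-released under each condition.
#'
#' @param sizes Named list of [capsule_spec()] templates (e.g.
#'   [capsule_presets()]); the payload of each is overridden per cycles
#'   value.
#' @param cycles Integer vector of freezing/thawing cycle counts.
#' @param velocities_mm_s Mean flow velocities to test (mm/s).
#' @param n_per_cell Capsules per grid cell (>= 1).
#' @param env A [fluid_env()] (its `mean_velocity` is overridden).
#' @param magnet A [magnet_model()].
#' @param seed Integer seed.
#' @param mode Integration mode, see [integrate_trajectory()].
#' @param constants A [physical_constants()] object.
#' @return A data.frame of class `efficiency_grid` with columns
#'   `diameter_class_um`, `cycles`, `velocity_mm_s`, `n`, `captured`,
#'   `fraction`.
#' @export
capture_efficiency_sweep <- function(sizes = capsule_presets(),
                                     cycles = 1:3,
                                     velocities_mm_s = c(5, 10, 20, 50, 100),
                                     n_per_cell = 20,
                                     env = fluid_env(5e-3),
                                     magnet = magnet_model(),
                                     seed = 1,
                                     mode = "overdamped",
                                     constants = physical_constants()) {
  if (n_per_cell < 1) stop("n_per_cell must be >= 1", call. = FALSE)
  # one draw of (diameter, inlet height) per size class, shared by all
  # of that class's cells
  draws <- withr::with_seed(seed, lapply(sizes, function(base) {
    list(d = rtruncnorm_pos(n_per_cell, base$mean_diameter_um,
                            base$diameter_sd_um,
                            lower = 0.1 * base$mean_diameter_um),
         h = stats::runif(n_per_cell))
  }))
  grid <- expand.grid(size = names(sizes), cycles = cycles,
                      velocity_mm_s = velocities_mm_s,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    base <- sizes[[grid$size[i]]]
    spec <- capsule_spec(base$mean_diameter_um, base$diameter_sd_um,
                         n_freeze_cycles = grid$cycles[i],
                         shell_label = base$shell_label,
                         constants = constants)
    envi <- env
    envi$mean_velocity <- grid$velocity_mm_s[i] * 1e-3
    dr <- draws[[grid$size[i]]]
    cap <- vapply(seq_len(n_per_cell), function(j) {
      sj <- set_diameter(spec, dr$d[j])
      y0 <- sj$radius_m +
        dr$h[j] * (env$channel_height - 2 * sj$radius_m)
      integrate_trajectory(sj, envi, magnet,
                           start = list(position = c(0, y0)),
                           mode = mode, record = FALSE,
                           constants = constants)$captured
    }, logical(1))
    sum(cap)
  })
  grid$diameter_class_um <- vapply(sizes[grid$size],
                                   function(s) s$mean_diameter_um,
                                   numeric(1))
  out <- data.frame(diameter_class_um = grid$diameter_class_um,
                    cycles = grid$cycles,
                    velocity_mm_s = grid$velocity_mm_s,
                    n = n_per_cell,
                    captured = unlist(res))
  out$fraction <- out$captured / out$n
  class(out) <- c("efficiency_grid", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Minimal number of internalised capsules for cell capture
#'
#' Increments the capsule count `k` of a cell released at a reference
#' inlet height until the trajectory integrator reports capture, and
#' returns the smallest capturing `k`.  Returns `NA` (with a warning) if
#' even `k_max` capsules do not suffice.
#'
#' @param cell A [cell_spec()]; its `internalized_capsules` field is
#'   ignored and swept.
#' @param env A [fluid_env()].
#' @param magnet A [magnet_model()].
#' @param velocity_mm_s Mean flow velocity (mm/s); overrides `env`.
#' @param start_height_frac Inlet height as a fraction of the channel
#'   height (default 0.5, the centreline).
#' @param k_max Upper bound on the search.
#' @param constants A [physical_constants()] object.
#' @return Integer `k`, or `NA_integer_` if not capturable below
#'   `k_max`.
#' @export
min_capsules_for_capture <- function(cell, env, magnet, velocity_mm_s,
                                     start_height_frac = 0.5,
                                     k_max = 200,
                                     constants = physical_constants()) {
  stopifnot(inherits(cell, "cell_spec"))
  if (cell$capsule$chi_cap <= 0 && all(cell$capsule$M0 == 0))
    stop("capsule payload must be magnetic", call. = FALSE)
  envi <- env
  envi$mean_velocity <- velocity_mm_s * 1e-3
  y0 <- start_height_frac * env$channel_height
  for (k in seq_len(k_max)) {
    eq <- cell_as_capsule(cell_spec(k, cell$capsule, cell$diameter_um),
                          constants)
    y0k <- min(max(y0, eq$radius_m), env$channel_height - eq$radius_m)
    res <- integrate_trajectory(eq, envi, magnet,
                                start = list(position = c(0, y0k)),
                                mode = "overdamped", record = FALSE,
                                constants = constants)
    if (res$captured) return(k)
  }
  warning("not capturable below k_max = ", k_max)
  NA_integer_
}
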