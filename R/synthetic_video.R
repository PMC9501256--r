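#' Scene configuration for the synthetic flow-video generator
#'
#' Parameterises the four phenomena seen in fluorescence videos of
#' magnetic capture in flow: (1) well-separated bright movers advected
#' along the channel, (2) growing bright aggregates at the magnet
#' position, (3) weakly fluorescent objects (near the far cuvette wall),
#' and (4) overlapping light traces of objects converging before
#' aggregation.
#'
#' @param frame_shape Integer `c(rows, cols)` of each frame.
#' @param n_frames Number of frames.
#' @param n_objects Total objects spawned over the clip.
#' @param pixel_size_um Physical pixel pitch (micrometres), metadata
#'   only.
#' @param spot_sigma_px Gaussian point-spread sigma (px).
#' @param base_intensity Peak amplitude of a bright object (arbitrary
#'   camera units).
#' @param faint_fraction Fraction of objects rendered faint.
#' @param faint_intensity_factor Amplitude factor for faint objects
#'   (default 0.2).
#' @param advection_px_per_frame Mean rightward drift per frame (px).
#' @param magnet_zone List `(r0, r1, c0, c1)` region at the magnet wall,
#'   or `NULL` for no zone.
#' @param stick_probability Per-frame sticking probability while inside
#'   the zone (requires `aggregation_enabled`).
#' @param aggregation_enabled Allow sticking/aggregation.
#' @param pair_fraction Fraction of objects spawned as converging pairs
#'   whose traces superimpose (case 4).
#' @param noise_sd Gaussian read-noise standard deviation per pixel.
#' @param row_jitter_px Per-frame cross-flow jitter sd (px).
#' @param spawn_sep_px Minimum centre separation enforced between a
#'   newly spawned object and the objects already in flight (converging
#'   pair partners are exempt from each other); spawning errors out if
#'   the frame cannot accommodate the requested density.
#' @param stick_excl_px Volume-exclusion distance between stuck
#'   objects: an object sticking closer than this to an already stuck
#'   one attaches at contact distance instead of superposing, the way
#'   capsules pile up at a magnet rather than occupying the same spot.
#' @param seed Integer seed; fixes the whole stack bit-exactly.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(frame_shape = c(120L, 300L), n_frames = 200L,
                         n_objects = 50L, pixel_size_um = 1,
                         spot_sigma_px = 2, base_intensity = 180,
                         faint_fraction = 0.15,
                         faint_intensity_factor = 0.2,
                         advection_px_per_frame = 3,
                         magnet_zone = list(r0 = 85, r1 = 116,
                                            c0 = 130, c1 = 185),
                         stick_probability = 0.25,
                         aggregation_enabled = TRUE,
                         pair_fraction = 0.2,
                         noise_sd = 3, row_jitter_px = 0.3,
                         spawn_sep_px = 4 * spot_sigma_px,
                         stick_excl_px = 4.5 * spot_sigma_px,
                         seed = 1L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 8),
            n_frames >= 1, n_objects >= 0,
            faint_fraction >= 0, faint_fraction <= 1,
            pair_fraction >= 0, pair_fraction <= 1,
            stick_probability >= 0, stick_probability <= 1,
            spot_sigma_px > 0, noise_sd >= 0)
  structure(as.list(environment()), class = "scene_config")
}

#' Render Gaussian spots onto a blank frame
#'
#' Photometrically additive: the rendering of several spots is the
#' pixel-wise sum of their individual renderings.
#'
#' @param shape `c(rows, cols)`.
#' @param rows,cols Spot centre coordinates (px, may be fractional).
#' @param amplitudes Peak amplitudes.
#' @param sigma_px Gaussian sigma (px).
#' @return Numeric matrix.
#' @export
render_spots <- function(shape, rows, cols, amplitudes, sigma_px) {
  img <- matrix(0, shape[1], shape[2])
  if (!length(rows)) return(img)
  w <- ceiling(4 * sigma_px)
  for (i in seq_along(rows)) {
    r0 <- max(1L, floor(rows[i] - w)); r1 <- min(shape[1], ceiling(rows[i] + w))
    c0 <- max(1L, floor(cols[i] - w)); c1 <- min(shape[2], ceiling(cols[i] + w))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    gr <- exp(-(rr - rows[i])^2 / (2 * sigma_px^2))
    gc <- exp(-(cc - cols[i])^2 / (2 * sigma_px^2))
    img[rr, cc] <- img[rr, cc] + amplitudes[i] * outer(gr, gc)
  }
  img
}

#' Generate a synthetic flow video with ground truth
#'
#' Objects spawn at integer positions (some present from the first
#' frame, the rest entering at the left edge), drift rightward with
#' small jitter, and -- inside the magnet zone, when aggregation is
#' enabled -- stick in place with a per-frame probability.  Stuck
#' objects never move again; their Gaussian intensities sum where they
#' overlap, forming aggregates.  Gaussian read noise is added per
#' pixel.  The same seed reproduces the stack bit-exactly.
#'
#' @param config A [scene_config()].
#' @return A list of class `video_stream` with `frames` (array
#'   `[rows, cols, n_frames]`), `truth` (class `ground_truth`: `objects`
#'   data.frame, `frames` per-object per-frame records, `totals` per
#'   frame, `final_stuck`), and `config`.
#' @export
render_video <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, render_video_impl(config))
}

render_video_impl <- function(cf) {
  nr <- cf$frame_shape[1]; nc <- cf$frame_shape[2]
  nf <- cf$n_frames
  n <- cf$n_objects
  zone <- cf$magnet_zone

  # --- object roster -------------------------------------------------
  n_pair <- if (n >= 2) 2L * floor(cf$pair_fraction * n / 2) else 0L
  is_pair_member <- rep(FALSE, n)
  if (n_pair > 0) is_pair_member[seq_len(n_pair)] <- TRUE
  class_faint <- stats::runif(n) < cf$faint_fraction
  margin <- ceiling(4 * cf$spot_sigma_px)

  due_frame <- integer(n); preplaced <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (is_pair_member[i]) {
      due_frame[i] <- due_frame[i + 1L] <-
        sample.int(max(1L, floor(0.6 * nf)), 1L)
      i <- i + 2L
    } else {
      preplaced[i] <- stats::runif(1) < 0.35
      due_frame[i] <- if (preplaced[i]) 1L else
        sample.int(max(1L, floor(0.75 * nf)), 1L)
      i <- i + 1L
    }
  }

  # --- frame-major kinematics with spawn separation and stick
  #     volume exclusion --------------------------------------------
  rowp <- matrix(NA_real_, n, nf); colp <- matrix(NA_real_, n, nf)
  status <- matrix("unspawned", n, nf)
  spawn_frame <- rep(NA_integer_, n)
  cur_r <- rep(NA_real_, n); cur_c <- rep(NA_real_, n)
  alive <- function(o, excl = integer(0)) {
    s <- which(!is.na(spawn_frame) & cur_c <= nc + margin)
    setdiff(s, c(o, excl))
  }
  clear_of <- function(r, c, others) {
    !length(others) ||
      min((cur_r[others] - r)^2 + (cur_c[others] - c)^2) >=
        cf$spawn_sep_px^2
  }
  pair_drift <- ifelse(is_pair_member,
                       ifelse(seq_len(n) %% 2 == 1L, 0.45, -0.45), 0)
  stuck <- rep(FALSE, n)
  for (f in seq_len(nf)) {
    # advance objects already in flight
    for (o in which(!is.na(spawn_frame))) {
      if (stuck[o]) next
      cur_c[o] <- cur_c[o] + cf$advection_px_per_frame +
        stats::rnorm(1, 0, 0.15 * cf$advection_px_per_frame)
      cur_r[o] <- cur_r[o] + stats::rnorm(1, 0, cf$row_jitter_px) +
        pair_drift[o]
      if (pair_drift[o] != 0 && f - spawn_frame[o] >= 10)
        pair_drift[o] <- 0
    }
    # spawn objects that are due, enforcing separation
    for (o in which(is.na(spawn_frame) & due_frame <= f)) {
      if (is_pair_member[o] && o %% 2 == 0L) next  # placed with partner
      if (is_pair_member[o]) {
        placed <- FALSE
        for (try in 1:40) {
          r <- sample(seq(margin + 4L, nr - margin - 4L), 1L)
          if (clear_of(r - 4, margin, alive(o, o + 1L)) &&
              clear_of(r + 4, margin, alive(o, o + 1L))) {
            spawn_frame[c(o, o + 1L)] <- f
            cur_r[o] <- r - 4; cur_r[o + 1L] <- r + 4
            cur_c[o] <- cur_c[o + 1L] <- margin
            placed <- TRUE
            break
          }
        }
        if (!placed) due_frame[c(o, o + 1L)] <- f + 1L
      } else {
        placed <- FALSE
        for (try in 1:40) {
          r <- sample(seq(margin, nr - margin), 1L)
          c <- if (preplaced[o] && f == 1L)
            sample(seq(margin, nc - margin), 1L) else margin
          if (clear_of(r, c, alive(o))) {
            spawn_frame[o] <- f
            cur_r[o] <- r; cur_c[o] <- c
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          if (preplaced[o] && f == 1L)
            stop("cannot place initial objects without overlap; ",
                 "reduce n_objects or spawn_sep_px", call. = FALSE)
          due_frame[o] <- f + 1L
        }
      }
    }
    # sticking inside the magnet zone, with volume exclusion
    for (o in which(!is.na(spawn_frame))) {
      if (stuck[o] || !cf$aggregation_enabled || is.null(zone)) next
      r <- cur_r[o]; c <- cur_c[o]
      if (r >= zone$r0 && r <= zone$r1 && c >= zone$c0 &&
          c <= zone$c1 && stats::runif(1) < cf$stick_probability) {
        others <- which(stuck)
        if (length(others)) {
          d2 <- (cur_r[others] - r)^2 + (cur_c[others] - c)^2
          jmin <- others[which.min(d2)]
          if (min(d2) < cf$stick_excl_px^2) {
            # attach at contact with the nearest stuck object
            dr <- r - cur_r[jmin]; dc <- c - cur_c[jmin]
            nrm <- sqrt(dr * dr + dc * dc)
            if (nrm < 1e-9) { dr <- -1; dc <- 0; nrm <- 1 }
            cur_r[o] <- cur_r[jmin] + dr / nrm * cf$stick_excl_px
            cur_c[o] <- cur_c[jmin] + dc / nrm * cf$stick_excl_px
          }
        }
        stuck[o] <- TRUE
      }
    }
    live <- which(!is.na(spawn_frame))
    rowp[live, f] <- cur_r[live]; colp[live, f] <- cur_c[live]
    status[live, f] <- ifelse(stuck[live], "stuck",
                              ifelse(cur_c[live] > nc + margin,
                                     "exited", "moving"))
  }
  spawn_frame[is.na(spawn_frame)] <- nf + 1L

  # --- ground-truth records ------------------------------------------
  recs <- vector("list", nf)
  for (f in seq_len(nf)) {
    sp <- which(spawn_frame <= f)
    if (!length(sp)) next
    st <- status[sp, f]
    recs[[f]] <- data.frame(
      object_id = sp, frame = f,
      row = rowp[sp, f], col = colp[sp, f],
      class = ifelse(class_faint[sp], "faint", "bright"),
      status = st,
      visible = st != "exited" &
        rowp[sp, f] >= 1 & rowp[sp, f] <= nr &
        colp[sp, f] >= 1 & colp[sp, f] <= nc)
  }
  tf <- do.call(rbind, recs)

  totals <- data.frame(frame = seq_len(nf))
  totals$spawned <- vapply(seq_len(nf), function(f)
    sum(spawn_frame <= f), integer(1))
  for (s in c("moving", "stuck", "exited"))
    totals[[s]] <- vapply(seq_len(nf), function(f)
      sum(status[, f] == s), integer(1))

  # aggregate grouping of stuck objects by footprint overlap
  stuck_final <- which(status[, nf] == "stuck")
  agg_id <- rep(NA_integer_, n)
  if (length(stuck_final) > 1) {
    pos <- cbind(rowp[stuck_final, nf], colp[stuck_final, nf])
    d <- as.matrix(stats::dist(pos))
    parent <- seq_along(stuck_final)
    find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
    thr <- max(4 * cf$spot_sigma_px, 1.2 * cf$stick_excl_px)
    for (a in seq_along(stuck_final)) for (b in seq_len(a - 1L))
      if (d[a, b] < thr) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    agg_id[stuck_final] <- vapply(seq_along(stuck_final), find, integer(1))
  } else if (length(stuck_final) == 1) {
    agg_id[stuck_final] <- 1L
  }

  objects <- data.frame(object_id = seq_len(n),
                        class = ifelse(class_faint, "faint", "bright"),
                        spawn_frame = spawn_frame,
                        aggregate_id = agg_id)

  truth <- structure(list(objects = objects, frames = tf,
                          totals = totals,
                          final_stuck = length(stuck_final)),
                     class = "ground_truth")

  # --- rendering -----------------------------------------------------
  amp <- ifelse(class_faint, cf$faint_intensity_factor, 1) *
    cf$base_intensity
  frames <- array(0, dim = c(nr, nc, nf))
  for (f in seq_len(nf)) {
    live <- which(spawn_frame <= f & status[, f] != "exited")
    img <- render_spots(c(nr, nc), rowp[live, f], colp[live, f],
                        amp[live], cf$spot_sigma_px)
    if (cf$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, cf$noise_sd), nr, nc)
    frames[, , f] <- pmax(img, 0)
  }

  structure(list(frames = frames, truth = truth, config = cf),
            class = "video_stream")
}

#' @export
print.video_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stream> %d x %d px, %d frames, %d true objects\n",
              d[1], d[2], d[3],
              if (!is.null(x$truth)) nrow(x$truth$objects) else NA))
  invisible(x)
}

#' Counting configuration matched to a scene
#'
#' Convenience: a [count_config()] whose magnet zone equals the scene's.
#'
#' @param config A [scene_config()].
#' @param ... Overrides passed to [count_config()].
#' @return A `count_config`.
#' @export
scene_count_config <- function(config, ...) {
  count_config(magnet_zone = config$magnet_zone, ...)
}

#' Render a video from simulated capsule trajectories
#'
#' Bridges the physics and counting modules: physical trajectories are
#' mapped to pixel coordinates (the magnet-side wall at the bottom row)
#' and rendered as bright spots; captured capsules become stuck objects
#' at their stop positions.  Positions outside the frame are recorded
#' as not visible (clipped), never an error.
#'
#' @param results List of `capture_result`s with recorded trajectories.
#' @param env The [fluid_env()] used for the simulation.
#' @param config A [scene_config()]; `pixel_size_um` sets the
#'   micrometre-to-pixel mapping and `n_frames` the temporal sampling.
#' @return A `video_stream` whose ground truth carries the capture
#'   verdicts (`status` `"stuck"` for captured capsules after their
#'   stop time).
#' @export
render_from_trajectories <- function(results, env,
                                     config = scene_config()) {
  stopifnot(length(results) >= 1)
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  nf <- config$n_frames
  px <- config$pixel_size_um * 1e-6
  t_end <- max(vapply(results, function(r) max(r$trajectory$t),
                      numeric(1)))
  times <- seq(0, t_end, length.out = nf)
  n <- length(results)
  rowp <- matrix(NA_real_, n, nf); colp <- matrix(NA_real_, n, nf)
  status <- matrix("moving", n, nf)
  for (o in seq_len(n)) {
    tr <- results[[o]]$trajectory
    tr <- tr[!duplicated(tr$t), , drop = FALSE]
    xi <- stats::approx(tr$t, tr$x, xout = times, rule = 2)$y
    yi <- stats::approx(tr$t, tr$y, xout = times, rule = 2)$y
    rowp[o, ] <- nr - yi / px
    colp[o, ] <- xi / px + 1
    if (results[[o]]$captured) {
      status[o, times >= results[[o]]$time] <- "stuck"
    } else {
      status[o, times >= max(tr$t)] <- "exited"
    }
  }
  tfr <- do.call(rbind, lapply(seq_len(nf), function(f)
    data.frame(object_id = seq_len(n), frame = f,
               row = rowp[, f], col = colp[, f],
               class = "bright", status = status[, f],
               visible = status[, f] != "exited" &
                 rowp[, f] >= 1 & rowp[, f] <= nr &
                 colp[, f] >= 1 & colp[, f] <= nc)))
  totals <- data.frame(
    frame = seq_len(nf), spawned = n,
    moving = colSums(status == "moving"),
    stuck = colSums(status == "stuck"),
    exited = colSums(status == "exited"))
  truth <- structure(list(
    objects = data.frame(object_id = seq_len(n), class = "bright",
                         spawn_frame = 1L,
                         captured = vapply(results, `[[`, logical(1),
                                           "captured")),
    frames = tfr, totals = totals,
    final_stuck = sum(status[, nf] == "stuck")),
    class = "ground_truth")
  frames <- withr::with_seed(config$seed, {
    arr <- array(0, dim = c(nr, nc, nf))
    for (f in seq_len(nf)) {
      live <- which(status[, f] != "exited")
      img <- render_spots(c(nr, nc), rowp[live, f], colp[live, f],
                          rep(config$base_intensity, length(live)),
                          config$spot_sigma_px)
      if (config$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, config$noise_sd),
                            nr, nc)
      arr[, , f] <- pmax(img, 0)
    }
    arr
  })
  structure(list(frames = frames, truth = truth, config = config),
            class = "video_stream")
}

#' Standard benchmark suite
#'
#' Five fixed fixtures mirroring the video phenomenology: the four
#' single-case clips (separated movers, magnet-zone aggregates, faint
#' objects, overlapping traces) and one mixed clip combining all four.
#'
#' @param seed Integer seed shared (with fixed offsets) by the
#'   fixtures.
#' @return Named list of `video_stream` objects.
#' @export
standard_benchmarks <- function(seed = 1L) {
  list(
    separated_movers = render_video(scene_config(
      n_objects = 12L, n_frames = 60L, faint_fraction = 0,
      pair_fraction = 0, aggregation_enabled = FALSE,
      magnet_zone = NULL, seed = seed)),
    aggregates = render_video(scene_config(
      n_objects = 30L, n_frames = 120L, faint_fraction = 0,
      pair_fraction = 0, stick_probability = 0.8,
      magnet_zone = list(r0 = 60, r1 = 116, c0 = 140, c1 = 160),
      seed = seed + 1L)),
    faint = render_video(scene_config(
      n_objects = 15L, n_frames = 80L, faint_fraction = 1,
      pair_fraction = 0, aggregation_enabled = FALSE,
      magnet_zone = NULL, seed = seed + 2L)),
    overlap_traces = render_video(scene_config(
      n_objects = 16L, n_frames = 80L, faint_fraction = 0,
      pair_fraction = 1, aggregation_enabled = FALSE,
      magnet_zone = NULL, seed = seed + 3L)),
    mixed = render_video(scene_config(seed = seed + 4L)))
}

#' Write a video stream as a multi-page TIFF (plus ground truth)
#'
#' @param stream A `video_stream` or 3-d array.
#' @param path Output TIFF path.
#' @param truth_path Optional JSON path for the ground truth.
#' @param bits 8 or 16 bit quantisation.
#' @return `path`, invisibly.
#' @export
write_video <- function(stream, path, truth_path = NULL, bits = 16) {
  frames <- as_frame_array(stream)
  mx <- max(frames, 1)
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(f) frames[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  if (!is.null(truth_path) && inherits(stream, "video_stream"))
    jsonlite::write_json(stream$truth$frames, truth_path,
                         dataframe = "columns", digits = NA)
  invisible(path)
}

#' Read a grayscale video stack
#'
#' Accepts a multi-page TIFF or a directory of numbered PNG frames.
#'
#' @param path TIFF file or PNG directory.
#' @return 3-d array `[rows, cols, frames]` on the original intensity
#'   scale of the file (0..1 for normalised TIFF/PNG).
#' @export
read_video <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$",
                             full.names = TRUE))
    if (!length(files)) stop("no PNG frames in ", path, call. = FALSE)
    pages <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(m) {
      if (length(dim(m)) == 3) m[, , 1] else m
    })
  }
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
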