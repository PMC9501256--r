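# Orchestration: reproducible runs tying the physics, generator and
# counting modules together, with YAML configuration and CSV/JSON
# artifacts.  Plots are convenience artifacts; all downstream reading
# is from the CSV/JSON outputs.

#' Read and validate a run configuration
#'
#' Top-level YAML keys: `mode` (sweep | count | benchmark | closure),
#' `seed`, plus one optional section per module (`capsule`, `fluid`,
#' `magnet`, `scene`, `counting`, `sweep`).  Unknown keys anywhere are
#' rejected.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  top <- c("mode", "seed", "capsule", "fluid", "magnet", "scene",
           "counting", "sweep")
  bad <- setdiff(names(cfg), top)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$mode) &&
      !cfg$mode %in% c("sweep", "count", "benchmark", "closure"))
    stop("mode must be one of sweep, count, benchmark, closure",
         call. = FALSE)
  sections <- list(
    fluid = names(formals(fluid_env)),
    magnet = names(formals(magnet_model)),
    scene = names(formals(scene_config)),
    counting = names(formals(count_config)),
    sweep = c("cycles", "velocities_mm_s", "n_per_cell", "sizes_um"),
    capsule = c("diameter_um", "diameter_sd_um", "cycles",
                "mnp_mass_fraction", "rho_override", "shell_label"))
  for (s in names(sections)) {
    bad <- setdiff(names(cfg[[s]]), sections[[s]])
    if (length(bad))
      stop(sprintf("unknown keys in section '%s': %s", s,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

write_manifest <- function(out_dir, seed, config = NULL, extra = list()) {
  man <- c(list(
    package_version = as.character(utils::packageVersion("magtrap")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config), extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

build_env <- function(cfg) do.call(fluid_env, c(list(
  mean_velocity = 5e-3), cfg$fluid %||% list()))

build_magnet <- function(cfg) do.call(magnet_model, cfg$magnet %||% list())

#' Run a capture-efficiency sweep and write its artifacts
#'
#' Produces `sweep.csv` (columns `diameter_class_um, cycles,
#' velocity_mm_s, n, captured, fraction`), an efficiency-versus-velocity
#' plot per size x cycles cell, and a JSON manifest.
#'
#' @param config A [read_run_config()] list (or `NULL` for defaults).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed.
#' @return The efficiency grid data.frame, invisibly.
#' @export
run_sweep <- function(config = NULL, out_dir = tempfile("sweep"),
                      seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sw <- config$sweep %||% list()
  sizes <- capsule_presets()
  if (!is.null(sw$sizes_um))
    sizes <- sizes[vapply(sizes, function(s)
      s$mean_diameter_um %in% sw$sizes_um, logical(1))]
  grid <- capture_efficiency_sweep(
    sizes = sizes,
    cycles = sw$cycles %||% 1:3,
    velocities_mm_s = sw$velocities_mm_s %||% c(5, 10, 20, 50, 100),
    n_per_cell = sw$n_per_cell %||% 20,
    env = build_env(config), magnet = build_magnet(config),
    seed = seed)
  utils::write.csv(grid, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE)
  p <- ggplot2::ggplot(grid,
         ggplot2::aes(x = velocity_mm_s, y = fraction,
                      colour = factor(cycles))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~diameter_class_um, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "mean flow velocity (mm/s)",
                  y = "capture fraction", colour = "cycles")
  ggplot2::ggsave(file.path(out_dir, "sweep.png"), p,
                  width = 8, height = 3.2, dpi = 120)
  write_manifest(out_dir, seed, config,
                 list(outputs = c("sweep.csv", "sweep.png")))
  invisible(grid)
}

#' Count a video file and write the report
#'
#' @param video Path to a multi-page TIFF or PNG directory, or a
#'   `video_stream`/array.
#' @param config A [read_run_config()] list (its `counting` section
#'   feeds [count_config()]).
#' @param out_dir Output directory.
#' @param seed Recorded in the manifest (the counter is deterministic).
#' @return The `count_report`, invisibly.
#' @export
run_count <- function(video, config = NULL, out_dir = tempfile("count"),
                      seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stream <- if (is.character(video)) read_video(video) else video
  cc <- do.call(count_config, config$counting %||% list())
  rep <- count_video(stream, cc)
  utils::write.csv(rep$per_frame, file.path(out_dir, "per_frame.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(avg_single_area_px = rep$avg_single_area_px,
         cumulative_accumulated = rep$cumulative_accumulated),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, seed, config,
                 list(outputs = c("per_frame.csv", "report.json")))
  invisible(rep)
}

#' Run the counting-accuracy benchmark
#'
#' Generates the mixed four-case synthetic benchmark for a ladder of
#' seeds, counts each clip, evaluates the recovered fraction against
#' ground truth and writes a per-seed and mean accuracy table.
#'
#' @param config A [read_run_config()] list; its `scene` section
#'   overrides the generator defaults and `counting` the counter.
#' @param out_dir Output directory.
#' @param seed Base seed; clips use `seed + 0:(n_seeds - 1)`.
#' @param n_seeds Number of benchmark clips.
#' @return Data.frame (`seed`, `true_total`, `matched`, `fraction`),
#'   with the mean fraction as attribute `mean_fraction`, invisibly.
#' @export
run_benchmark <- function(config = NULL, out_dir = tempfile("bench"),
                          seed = 1, n_seeds = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_seeds) - 1L, function(k) {
    sc <- do.call(scene_config,
                  c(list(seed = seed + k), config$scene %||% list()))
    vid <- render_video(sc)
    cc <- do.call(scene_count_config,
                  c(list(config = sc), config$counting %||% list()))
    acc <- evaluate_accuracy(count_video(vid, cc), vid$truth)
    data.frame(seed = seed + k, true_total = acc$true_total,
               matched = acc$matched, fraction = acc$fraction)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "benchmark.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, seed, config,
                 list(mean_fraction = mean(tab$fraction)))
  attr(tab, "mean_fraction") <- mean(tab$fraction)
  invisible(tab)
}

#' End-to-end closure run: physics to rendering to counting
#'
#' Simulates a batch of capsules through the flow cell, renders the
#' trajectories as a fluorescence video, counts the video, and compares
#' the counting module's cumulative accumulated estimate with the
#' simulator's true captured count.
#'
#' @param config A [read_run_config()] list.
#' @param out_dir Output directory.
#' @param seed Integer seed (governs capsule sampling and rendering
#'   noise).
#' @param n_capsules Number of simulated capsules.
#' @return List with `true_captured`, `counted`, `relative_error`,
#'   invisibly.
#' @export
run_closure <- function(config = NULL, out_dir = tempfile("closure"),
                        seed = 1, n_capsules = 15) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- build_env(config)
  magnet <- build_magnet(config)
  cap <- if (!is.null(config$capsule))
    capsule_spec(config$capsule$diameter_um,
                 config$capsule$diameter_sd_um %||% 0,
                 n_freeze_cycles = config$capsule$cycles,
                 mnp_mass_fraction = config$capsule$mnp_mass_fraction)
  else capsule_spec(2.7, 0.4, n_freeze_cycles = 3)
  results <- withr::with_seed(seed, {
    pop <- rtruncnorm_pos(n_capsules, cap$mean_diameter_um,
                          cap$diameter_sd_um,
                          0.1 * cap$mean_diameter_um)
    hgt <- stats::runif(n_capsules)
    lapply(seq_len(n_capsules), function(j) {
      sj <- set_diameter(cap, pop[j])
      y0 <- sj$radius_m + hgt[j] * (env$channel_height - 2 * sj$radius_m)
      integrate_trajectory(sj, env, magnet,
                           start = list(position = c(0, y0)),
                           mode = "overdamped")
    })
  })
  px_um <- ceiling(env$channel_height * 1e6 / 110)
  nrows <- ceiling(env$channel_height * 1e6 / px_um) + 4
  ncols <- ceiling(env$channel_length * 1e6 / px_um) + 4
  zone_c <- (magnet$pole_position[1] * 1e6 / px_um) + 1
  sc <- do.call(scene_config, c(
    list(frame_shape = c(nrows, ncols), n_frames = 120L,
         pixel_size_um = px_um, seed = seed,
         magnet_zone = list(r0 = nrows - 30, r1 = nrows,
                            c0 = zone_c - 25, c1 = zone_c + 25)),
    config$scene %||% list()))
  vid <- render_from_trajectories(results, env, sc)
  rep <- count_video(vid, scene_count_config(sc))
  true_k <- sum(vapply(results, `[[`, logical(1), "captured"))
  counted <- rep$cumulative_accumulated
  rel <- if (true_k > 0) abs(counted - true_k) / true_k
         else as.numeric(counted > 0)
  out <- list(true_captured = true_k, counted = counted,
              relative_error = rel)
  jsonlite::write_json(out, file.path(out_dir, "closure.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, seed, config)
  invisible(out)
}
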