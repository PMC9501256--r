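#' Configuration of the video-counting pipeline
#'
#' @param threshold_k Segmentation threshold multiplier, see
#'   [segment_frame()].
#' @param min_area_px Minimum component size kept by [find_contours()].
#' @param aggregate_factor A detection whose area exceeds
#'   `aggregate_factor` x the single-object area is decomposed as an
#'   aggregate; also gates the robust single-area estimate.
#' @param link_radius_px Maximum per-frame centroid displacement when
#'   linking detections into tracks and when pairing appear/disappear
#'   blobs in frame differencing.
#' @param match_radius_px Centroid matching radius used by
#'   [evaluate_accuracy()].
#' @param magnet_zone `NULL`, or a list `(r0, r1, c0, c1)` giving the
#'   rectangular region of interest at the magnet wall inside which
#'   static bright spots are decomposed into accumulated objects.
#' @param faint_rel Detections whose peak intensity falls below
#'   `faint_rel` x the median bright peak are classed `faint`.
#' @param enhance Run segmentation on the Sobel-enhanced image
#'   (default) rather than on raw intensity.
#' @param stuck_eps_px,stuck_frames A track whose centroid moves less
#'   than `stuck_eps_px` for `stuck_frames` consecutive frames is
#'   flagged stuck.
#' @return A list of class `count_config`.
#' @export
count_config <- function(threshold_k = 22, min_area_px = 8,
                         aggregate_factor = 1.6, link_radius_px = 12,
                         match_radius_px = 6, magnet_zone = NULL,
                         faint_rel = 0.5, enhance = TRUE,
                         stuck_eps_px = 1, stuck_frames = 5) {
  structure(list(threshold_k = threshold_k, min_area_px = min_area_px,
                 aggregate_factor = aggregate_factor,
                 link_radius_px = link_radius_px,
                 match_radius_px = match_radius_px,
                 magnet_zone = magnet_zone, faint_rel = faint_rel,
                 enhance = enhance, stuck_eps_px = stuck_eps_px,
                 stuck_frames = stuck_frames),
            class = "count_config")
}

in_zone <- function(r, c, zone) {
  if (is.null(zone)) rep(FALSE, length(r))
  else r >= zone$r0 & r <= zone$r1 & c >= zone$c0 & c <= zone$c1
}

#' Detect bright objects in one frame
#'
#' Segments the frame, extracts contours and summarises each component.
#'
#' @param frame Numeric matrix.
#' @param config A [count_config()].
#' @return A data.frame with one row per detection: `row`, `col`
#'   (centroid), `area_px` (filled region area), `n_px`,
#'   `mean_intensity`, `peak_intensity`, the contour bounding box
#'   (`bb_r0`, `bb_r1`, `bb_c0`, `bb_c1`), and `in_zone` (centroid
#'   inside, or bounding box intersecting, the magnet zone).
#' @export
detect_objects <- function(frame, config = count_config()) {
  mask <- segment_frame(frame, config$threshold_k,
                        enhance = config$enhance)
  ctrs <- find_contours(mask, config$min_area_px)
  if (!length(ctrs))
    return(data.frame(row = numeric(0), col = numeric(0),
                      area_px = numeric(0), n_px = integer(0),
                      mean_intensity = numeric(0),
                      peak_intensity = numeric(0),
                      bb_r0 = numeric(0), bb_r1 = numeric(0),
                      bb_c0 = numeric(0), bb_c1 = numeric(0),
                      in_zone = logical(0)))
  rows <- vapply(ctrs, function(ct) mean(ct[, 1]), numeric(1))
  cols <- vapply(ctrs, function(ct) mean(ct[, 2]), numeric(1))
  area <- vapply(ctrs, region_area, numeric(1))
  npx <- vapply(ctrs, function(ct) attr(ct, "n_px"), numeric(1))
  bb <- t(vapply(ctrs, function(ct)
    c(min(ct[, 1]), max(ct[, 1]), min(ct[, 2]), max(ct[, 2])),
    numeric(4)))
  # intensity summarised over the filled bounding box of the contour
  mi <- numeric(length(ctrs)); pk <- numeric(length(ctrs))
  for (i in seq_along(ctrs)) {
    rr <- max(1, bb[i, 1]):min(nrow(frame), bb[i, 2])
    cc <- max(1, bb[i, 3]):min(ncol(frame), bb[i, 4])
    patch <- frame[rr, cc, drop = FALSE]
    mi[i] <- mean(patch)
    pk[i] <- max(patch)
  }
  zone <- config$magnet_zone
  touch <- if (is.null(zone)) rep(FALSE, length(rows)) else
    bb[, 2] >= zone$r0 & bb[, 1] <= zone$r1 &
    bb[, 4] >= zone$c0 & bb[, 3] <= zone$c1
  data.frame(row = rows, col = cols, area_px = area, n_px = npx,
             mean_intensity = mi, peak_intensity = pk,
             bb_r0 = bb[, 1], bb_r1 = bb[, 2],
             bb_c0 = bb[, 3], bb_c1 = bb[, 4],
             in_zone = in_zone(rows, cols, config$magnet_zone) | touch)
}

#' Robust single-object area estimate
#'
#' Median of the areas after discarding values above the aggregate gate
#' (`aggregate_factor` x the median of all areas), so a minority of
#' aggregates cannot inflate the estimate.
#'
#' @param areas Numeric vector of detection areas (>= 1 value).
#' @param aggregate_factor Gate multiplier.
#' @return Estimated area of a single object, px.
#' @export
estimate_single_area <- function(areas, aggregate_factor = 1.6) {
  areas <- areas[is.finite(areas) & areas > 0]
  if (!length(areas))
    stop("no areas to estimate from; defer until objects are detected",
         call. = FALSE)
  med <- stats::median(areas)
  kept <- areas[areas < aggregate_factor * med]
  if (!length(kept)) kept <- areas
  stats::median(kept)
}

#' Count moving objects between two frames
#'
#' Segments the absolute difference of adjacent frames and counts one
#' moving object per edge blob, merging paired appear/disappear blobs
#' that lie within `link_radius_px` of each other.
#'
#' @param frame_t,frame_prev Numeric matrices of identical shape.
#' @param config A [count_config()].
#' @return List with `count` and the detection data.frame `blobs`.
#' @export
diff_movers <- function(frame_t, frame_prev, config = count_config()) {
  if (!all(dim(frame_t) == dim(frame_prev)))
    stop("frames must share the same shape", call. = FALSE)
  d <- abs(frame_t - frame_prev)
  blobs <- detect_objects(d, config)
  n <- nrow(blobs)
  if (n <= 1) return(list(count = n, blobs = blobs))
  # greedily pair blobs closer than link_radius: one object that moved
  # far enough to leave two difference blobs
  dm <- as.matrix(stats::dist(blobs[, c("row", "col")]))
  diag(dm) <- Inf
  paired <- rep(FALSE, n)
  pairs <- 0L
  repeat {
    ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    if (!is.finite(dm[ij[1], ij[2]]) ||
        dm[ij[1], ij[2]] > config$link_radius_px) break
    pairs <- pairs + 1L
    paired[ij] <- TRUE
    dm[ij, ] <- Inf; dm[, ij] <- Inf
  }
  list(count = n - pairs, blobs = blobs)
}

#' Number of objects in a fused bright spot
#'
#' Divides the spot area by the average single-object area, rounding
#' half away from zero, with a minimum of one.
#'
#' @param spot_area_px Area of the bright spot (> 0).
#' @param avg_single_area_px Average single-object area (> 0).
#' @return Positive integer count.
#' @export
count_aggregate <- function(spot_area_px, avg_single_area_px) {
  if (any(spot_area_px <= 0) || any(avg_single_area_px <= 0))
    stop("areas must be positive", call. = FALSE)
  pmax(1L, as.integer(floor(spot_area_px / avg_single_area_px + 0.5)))
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking: each detection in frame `t` is
#' joined to the closest track head predicted within `link_radius_px`;
#' unmatched detections open new tracks.  A head that misses a frame
#' coasts along its last observed velocity for up to `coast_frames`
#' frames (so an object whose contour temporarily fuses with another is
#' not lost) and is closed afterwards.  Tracks whose centroid moves
#' less than `stuck_eps_px` for `stuck_frames` consecutive frames are
#' flagged `stuck`.
#'
#' @param detections A data.frame with columns `frame`, `row`, `col`
#'   (one row per detection), frames in increasing order.
#' @param config A [count_config()].
#' @param coast_frames Frames an unmatched head keeps moving before its
#'   track is closed.
#' @param n_frames Total frames of the stream (defaults to the last
#'   frame seen).
#' @return A data.frame with columns `frame`, `row`, `col`, `track_id`
#'   (one row per detection, in input order).  Attributes: `summary`, a
#'   per-track data.frame (`track_id`, `start_frame`, `end_frame`,
#'   `end_row`, `end_col` -- the last *matched* position --, `stuck`,
#'   `stuck_frame`, `closed`); `status`, the (`track_id`, `status`)
#'   moving/stuck table; `heads`, the per-frame positions of all live
#'   heads (`frame`, `track_id`, `row`, `col`, `coasting`).
#' @export
track_centroids <- function(detections, config = count_config(),
                            coast_frames = 12L, n_frames = NULL) {
  empty <- data.frame(frame = integer(0), row = numeric(0),
                      col = numeric(0), track_id = integer(0))
  if (!nrow(detections)) {
    attr(empty, "summary") <- data.frame(
      track_id = integer(0), start_frame = integer(0),
      end_frame = integer(0), end_row = numeric(0),
      end_col = numeric(0), stuck = logical(0),
      stuck_frame = integer(0), closed = logical(0))
    attr(empty, "status") <- data.frame(track_id = integer(0),
                                        status = character(0))
    attr(empty, "heads") <- data.frame(
      frame = integer(0), track_id = integer(0), row = numeric(0),
      col = numeric(0), coasting = logical(0))
    return(empty)
  }
  if (is.null(n_frames)) n_frames <- max(detections$frame)
  heads <- list()      # live heads, each: list(id, r, c, vr, vc,
                       #   last_r, last_c, start, end, still, miss,
                       #   stuck_frame)
  done <- list()       # closed tracks
  assigned_all <- rep(NA_integer_, nrow(detections))
  head_rows <- vector("list", n_frames)
  next_id <- 1L
  for (f in seq_len(n_frames)) {
    sel <- which(detections$frame == f)
    det <- detections[sel, , drop = FALSE]
    # predicted positions
    if (length(heads)) {
      pr <- vapply(heads, function(h) h$r + h$vr, numeric(1))
      pc <- vapply(heads, function(h) h$c + h$vc, numeric(1))
    } else pr <- pc <- numeric(0)
    assigned <- rep(NA_integer_, nrow(det))
    matched_head <- rep(FALSE, length(heads))
    if (length(heads) && nrow(det)) {
      dm <- sqrt(outer(det$row, pr, "-")^2 + outer(det$col, pc, "-")^2)
      dm[dm > config$link_radius_px] <- Inf
      while (any(is.finite(dm))) {
        ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        i <- ij[1]; j <- ij[2]
        h <- heads[[j]]
        moved <- sqrt((det$row[i] - h$last_r)^2 +
                      (det$col[i] - h$last_c)^2)
        h$still <- if (moved < config$stuck_eps_px) h$still + 1L else 0L
        if (h$still >= config$stuck_frames && is.na(h$stuck_frame))
          h$stuck_frame <- f
        gap <- f - h$end
        h$vr <- (det$row[i] - h$last_r) / gap
        h$vc <- (det$col[i] - h$last_c) / gap
        if (!is.na(h$stuck_frame)) { h$vr <- 0; h$vc <- 0 }
        h$r <- h$last_r <- det$row[i]
        h$c <- h$last_c <- det$col[i]
        h$end <- f
        h$miss <- 0L
        heads[[j]] <- h
        assigned[i] <- h$id
        matched_head[j] <- TRUE
        dm[i, ] <- Inf; dm[, j] <- Inf
      }
    }
    for (i in which(is.na(assigned))) {
      assigned[i] <- next_id
      heads[[length(heads) + 1L]] <-
        list(id = next_id, r = det$row[i], c = det$col[i],
             vr = 0, vc = 0, last_r = det$row[i], last_c = det$col[i],
             start = f, start_r = det$row[i], start_c = det$col[i],
             end = f, still = 0L, miss = 0L,
             stuck_frame = NA_integer_)
      matched_head <- c(matched_head, TRUE)
      next_id <- next_id + 1L
    }
    assigned_all[sel] <- assigned
    # coast or close unmatched heads
    keep <- rep(TRUE, length(heads))
    for (j in seq_along(heads)) {
      if (matched_head[j]) next
      h <- heads[[j]]
      h$miss <- h$miss + 1L
      if (h$miss > coast_frames) {
        done[[length(done) + 1L]] <- h
        keep[j] <- FALSE
      } else {
        h$r <- h$r + h$vr; h$c <- h$c + h$vc
        heads[[j]] <- h
      }
    }
    heads <- heads[keep]
    if (length(heads))
      head_rows[[f]] <- data.frame(
        frame = f,
        track_id = vapply(heads, `[[`, integer(1), "id"),
        row = vapply(heads, `[[`, numeric(1), "r"),
        col = vapply(heads, `[[`, numeric(1), "c"),
        coasting = vapply(heads, function(h) h$miss > 0L, logical(1)))
  }
  all_tracks <- c(heads, done)
  summarise <- function(h, closed)
    data.frame(track_id = h$id, start_frame = h$start,
               start_row = h$start_r, start_col = h$start_c,
               end_frame = h$end, end_row = h$last_r,
               end_col = h$last_c, stuck = !is.na(h$stuck_frame),
               stuck_frame = h$stuck_frame, closed = closed)
  summary <- do.call(rbind, c(
    lapply(heads, summarise, closed = FALSE),
    lapply(done, summarise, closed = TRUE)))
  summary <- summary[order(summary$track_id), , drop = FALSE]
  out <- data.frame(frame = detections$frame, row = detections$row,
                    col = detections$col, track_id = assigned_all)
  attr(out, "summary") <- summary
  attr(out, "status") <- data.frame(
    track_id = summary$track_id,
    status = ifelse(summary$stuck, "stuck", "moving"))
  attr(out, "heads") <- do.call(rbind, head_rows)
  out
}

#' Count fluorescent objects through a video stream
#'
#' Runs the full counting pipeline over a frame stack: Sobel-enhanced
#' segmentation and contour detection per frame, a robust single-object
#' area estimate, frame differencing for movers, area division for
#' bright aggregates in the magnet zone, and centroid tracking of the
#' remaining detections.  The cumulative accumulated-object estimate is
#' the aggregate-equivalent count inside the magnet zone of the final
#' frame.
#'
#' @param stream A 3-d array `[rows, cols, frames]` (or a
#'   `video_stream` from [render_video()]), at least 2 frames.
#' @param config A [count_config()].
#' @return An object of class `count_report`: list with `per_frame`
#'   (data.frame `frame`, `movers`, `faint`, `zone_equivalents`,
#'   `out_equivalents`), `avg_single_area_px`, `cumulative_accumulated`,
#'   `detections`, `tracks`, `config`.
#' @export
count_video <- function(stream, config = count_config()) {
  frames <- as_frame_array(stream)
  nf <- dim(frames)[3]
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)

  det_list <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- detect_objects(frames[, , f], config)
    if (nrow(d)) d$frame <- f else d$frame <- integer(0)
    det_list[[f]] <- d
  }
  det <- do.call(rbind, det_list)

  # single-object area from out-of-zone detections of the early frames
  pool <- det$area_px[!det$in_zone]
  avg_single <- if (length(pool)) {
    n_use <- max(20L, sum(det$frame[!det$in_zone] <= 10))
    estimate_single_area(utils::head(pool, n_use),
                         config$aggregate_factor)
  } else NA_real_

  bright_ref <- if (nrow(det)) stats::median(det$peak_intensity) else NA

  # centroid tracking over all detections: resolves superimposed
  # traces of movers and records arrivals into the magnet zone
  tracks <- track_centroids(det, config, n_frames = nf)
  det$track_id <- tracks$track_id
  tsum <- attr(tracks, "summary")
  heads <- attr(tracks, "heads")

  # arrival events: a track that became static inside the zone, or
  # whose contour was absorbed by a zone blob (track closed with its
  # last matched position inside the zone rectangle or within the
  # footprint of a zone detection, which can protrude past the
  # rectangle as the aggregate grows)
  zone <- config$magnet_zone
  events <- NULL
  if (!is.null(zone) && !is.null(tsum) && nrow(tsum)) {
    m <- config$link_radius_px
    near_zone_blob <- function(r, c, f) {
      d <- det_list[[min(f, nf)]]
      if (!nrow(d)) return(FALSE)
      d <- d[in_zone(d$row, d$col, zone), , drop = FALSE]
      if (!nrow(d)) return(FALSE)
      any(r >= d$bb_r0 - m & r <= d$bb_r1 + m &
          c >= d$bb_c0 - m & c <= d$bb_c1 + m)
    }
    absorbed <- vapply(seq_len(nrow(tsum)), function(i)
      in_zone(tsum$end_row[i], tsum$end_col[i], zone) ||
        near_zone_blob(tsum$end_row[i], tsum$end_col[i],
                       tsum$end_frame[i]), logical(1))
    ev_stuck <- tsum$stuck & absorbed
    ev_lost <- !tsum$stuck & tsum$closed & absorbed
    events <- data.frame(
      frame = ifelse(ev_stuck, tsum$stuck_frame, tsum$end_frame),
      row = tsum$end_row, col = tsum$end_col,
      sign = 1L)[ev_stuck | ev_lost, , drop = FALSE]
    # an object whose contour separates again from a zone blob (a
    # mover crossing over the aggregate) re-emerges as a new track
    # born inside the blob footprint; it debits one arrival
    emerged <- tsum$start_frame > 1L &
      vapply(seq_len(nrow(tsum)), function(i)
        near_zone_blob(tsum$start_row[i], tsum$start_col[i],
                       tsum$start_frame[i]), logical(1))
    if (any(emerged))
      events <- rbind(events, data.frame(
        frame = tsum$start_frame[emerged],
        row = tsum$start_row[emerged],
        col = tsum$start_col[emerged], sign = -1L))
  }

  # per-detection equivalent counts: area division, raised where
  # tracking proves more members (coasting heads inside a mover blob,
  # accumulated arrivals inside a zone blob)
  det$equivalents <- if (is.na(avg_single)) rep(1L, nrow(det))
                     else count_aggregate(det$area_px, avg_single)
  per <- data.frame(frame = seq_len(nf), movers = 0L, faint = 0L,
                    zone_equivalents = 0L, out_equivalents = 0L)
  for (f in 2:nf) {
    per$movers[f] <- diff_movers(frames[, , f], frames[, , f - 1],
                                 config)$count
  }
  mrg <- config$link_radius_px
  for (f in seq_len(nf)) {
    sel <- which(det$frame == f)
    if (!length(sel)) next
    d <- det[sel, , drop = FALSE]
    eq <- d$equivalents
    hf <- if (!is.null(heads)) heads[heads$frame == f, , drop = FALSE]
          else NULL
    for (i in seq_len(nrow(d))) {
      if (d$in_zone[i]) {
        if (!is.null(events) && nrow(events)) {
          inside <- events$row >= d$bb_r0[i] - mrg &
            events$row <= d$bb_r1[i] + mrg &
            events$col >= d$bb_c0[i] - mrg &
            events$col <= d$bb_c1[i] + mrg
          eq[i] <- max(eq[i],
                       sum(events$sign[inside & events$frame <= f]))
        }
      } else if (!is.null(hf) && nrow(hf)) {
        near <- sum(hf$row >= d$bb_r0[i] - 1 & hf$row <= d$bb_r1[i] + 1 &
                    hf$col >= d$bb_c0[i] - 1 & hf$col <= d$bb_c1[i] + 1)
        eq[i] <- max(eq[i], near)
      }
    }
    det$equivalents[sel] <- eq
    per$zone_equivalents[f] <- sum(eq[d$in_zone])
    per$out_equivalents[f] <- sum(eq[!d$in_zone])
    per$faint[f] <- sum(!d$in_zone &
                          d$peak_intensity < config$faint_rel * bright_ref)
  }

  structure(list(per_frame = per,
                 avg_single_area_px = avg_single,
                 cumulative_accumulated = per$zone_equivalents[nf],
                 detections = det, tracks = tracks, config = config),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf(
    "<count_report> %d frames, avg single area %.1f px, %d accumulated\n",
    nrow(x$per_frame), x$avg_single_area_px, x$cumulative_accumulated))
  invisible(x)
}

#' Fraction of ground-truth objects recovered by a count report
#'
#' Per frame, every detection offers a capacity equal to its
#' aggregate-equivalent count; each true object is matched greedily to
#' the nearest detection with remaining capacity whose centroid lies
#' within `match_radius_px` (enlarged by the detection's equivalent
#' radius, so members of an aggregate are matched by count within its
#' footprint).  The accuracy is total matches over total true objects
#' across frames; overcounting is reported separately and does not
#' raise the fraction.
#'
#' @param report A [count_video()] report.
#' @param truth A `ground_truth` object (see [render_video()]).
#' @return List with `fraction`, `matched`, `true_total`,
#'   `overcount_fraction`.
#' @export
evaluate_accuracy <- function(report, truth) {
  config <- report$config
  det <- report$detections
  avg <- report$avg_single_area_px
  tf <- truth$frames
  matched <- 0L; true_total <- 0L; spare <- 0L
  for (f in unique(tf$frame)) {
    tr <- tf[tf$frame == f & tf$visible, , drop = FALSE]
    true_total <- true_total + nrow(tr)
    if (!nrow(tr)) next
    d <- det[det$frame == f, , drop = FALSE]
    if (!nrow(d)) next
    capacity <- if (!is.null(d$equivalents)) d$equivalents
                else if (is.na(avg)) rep(1L, nrow(d))
                else count_aggregate(d$area_px, avg)
    mr <- config$match_radius_px
    for (i in seq_len(nrow(tr))) {
      dist <- sqrt((d$row - tr$row[i])^2 + (d$col - tr$col[i])^2)
      in_fp <- if (!is.null(d$bb_r0))
        tr$row[i] >= d$bb_r0 - mr / 2 & tr$row[i] <= d$bb_r1 + mr / 2 &
        tr$col[i] >= d$bb_c0 - mr / 2 & tr$col[i] <= d$bb_c1 + mr / 2
      else dist <= mr + sqrt(d$area_px / pi)
      ok <- which(capacity > 0L & (dist <= mr | in_fp))
      if (length(ok)) {
        j <- ok[which.min(dist[ok])]
        capacity[j] <- capacity[j] - 1L
        matched <- matched + 1L
      }
    }
    spare <- spare + sum(capacity)
  }
  list(fraction = if (true_total) matched / true_total else 1,
       matched = matched, true_total = true_total,
       overcount_fraction = if (true_total) spare / true_total else 0)
}

# coerce video_stream / list of matrices / array to [r, c, f] array
as_frame_array <- function(stream) {
  if (inherits(stream, "video_stream")) return(stream$frames)
  if (is.list(stream))
    return(array(unlist(stream),
                 dim = c(dim(stream[[1]]), length(stream))))
  if (is.array(stream) && length(dim(stream)) == 3) return(stream)
  stop("stream must be a 3-d array, list of matrices or video_stream",
       call. = FALSE)
}
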