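#' Default synthetic arena
#'
#' A circular dish filling a 640x480 frame: radius 42.5 mm (85 mm inside
#' diameter) at 0.2 mm per pixel = 212.5 px, centred in the frame.
#'
#' @return A [circle_roi()] in pixel coordinates.
#' @export
synth_arena <- function() circle_roi(c(319.5, 239.5), 212.5)

#' Guide paths for the synthetic worm
#'
#' A guide path is a smooth planar curve, parameterised by arc length in
#' mm, along which the simulated worm's body lies. `guide_arc` is a gentle
#' circular arc well inside the dish (the default crawling path);
#' `guide_coil` is a tight circle whose circumference is shorter than the
#' worm, forcing the body to overlap itself (a scenario where skeleton
#' tracking is expected to fail, used to probe failure modes).
#'
#' @param center_mm `c(x, y)` path centre in mm (image frame, y down).
#' @param radius_mm Path radius in mm.
#' @param start_angle Angle (radians) of arc-length 0.
#' @param direction `1` (counter-clockwise in image coordinates) or `-1`.
#' @return An object of class `guide_path`: a function of arc length
#'   returning mm coordinates.
#' @export
guide_arc <- function(center_mm = c(63.9, 47.9), radius_mm = 32,
                      start_angle = 0, direction = 1) {
  force(center_mm); force(radius_mm); force(start_angle); force(direction)
  structure(list(
    fn = function(s_mm) {
      a <- start_angle + direction * s_mm / radius_mm
      cbind(x = center_mm[1] + radius_mm * cos(a),
            y = center_mm[2] + radius_mm * sin(a))
    },
    kind = "arc", radius_mm = radius_mm),
    class = "guide_path")
}

#' @rdname guide_arc
#' @export
guide_coil <- function(center_mm = c(63.9, 47.9), radius_mm = 12,
                       start_angle = 0, direction = 1) {
  p <- guide_arc(center_mm, radius_mm, start_angle, direction)
  p$kind <- "coil"
  p
}

#' Elastic worm model
#'
#' A peristaltic worm: its tip-to-tip body length oscillates as
#' `L(t) = rest_length * (1 + stretch_amplitude * sin(2 * pi * t /
#' stretch_period))`, emulating the stretch/contract cycle of earthworm
#' locomotion (body stretch up to 1.5x rest length at amplitude 0.5), while
#' the head end advances along the guide path at `speed_mm_s`. The body is
#' a capsule: a tube of radius `half_width_mm` around a centerline laid
#' backward along the path, with round caps, so the centerline core spans
#' `L - 2 * half_width_mm`.
#'
#' @param rest_length_mm Rest (default) body length, tip to tip.
#' @param stretch_amplitude Fractional length oscillation in `[0, 0.5]`.
#' @param stretch_period_s Oscillation period in seconds.
#' @param speed_mm_s Head travel speed along the guide path.
#' @param half_width_mm Body half-width (tube radius).
#' @param guide A [guide_arc()]-style `guide_path`.
#' @param start_offset_mm Arc-length position of the head tip at t = 0.
#' @return An object of class `worm_model`.
#' @export
worm_model <- function(rest_length_mm = 100, stretch_amplitude = 0.25,
                       stretch_period_s = 20, speed_mm_s = 2,
                       half_width_mm = 1.5, guide = guide_arc(),
                       start_offset_mm = rest_length_mm * 1.6) {
  if (rest_length_mm <= 0) stop("'rest_length_mm' must be > 0")
  if (stretch_amplitude < 0 || stretch_amplitude > 0.5)
    stop("'stretch_amplitude' must be in [0, 0.5]")
  if (stretch_period_s <= 0) stop("'stretch_period_s' must be > 0")
  if (speed_mm_s < 0) stop("'speed_mm_s' must be >= 0")
  if (half_width_mm <= 0) stop("'half_width_mm' must be > 0")
  stopifnot(inherits(guide, "guide_path"))
  structure(list(rest_length_mm = rest_length_mm,
                 stretch_amplitude = stretch_amplitude,
                 stretch_period_s = stretch_period_s,
                 speed_mm_s = speed_mm_s, half_width_mm = half_width_mm,
                 guide = guide, start_offset_mm = start_offset_mm),
            class = "worm_model")
}

#' Simulate the worm's pose at a time point
#'
#' Evaluates the stretch model and lays the body backward along the guide
#' path. Ground-truth feature points are on the centerline core (the
#' capsule's medial axis): head at arc position `s_head - half_width`, tail
#' at `s_head - L + half_width`, center at the true arc-length midpoint
#' `s_head - L / 2`. An error is raised if any part of the body (centerline
#' plus half-width) would leave the arena.
#'
#' @param model A [worm_model()].
#' @param t Time in seconds (>= 0).
#' @param arena A [circle_roi()] in pixels used for the containment check.
#' @param cal A [calibration()] (pixel size for the containment check and
#'   pixel-coordinate ground truth).
#' @param step_mm Centerline sampling step.
#' @return An object of class `worm_pose`: centerline (n x 2, px), arc
#'   length `length_mm` = L(t), and `head`, `center`, `tail` ground-truth
#'   pixel coordinates.
#' @export
simulate_pose <- function(model, t, arena = synth_arena(),
                          cal = calibration(), step_mm = 0.1) {
  stopifnot(inherits(model, "worm_model"), t >= 0)
  L <- model$rest_length_mm *
    (1 + model$stretch_amplitude * sin(2 * pi * t / model$stretch_period_s))
  s_head <- model$start_offset_mm + model$speed_mm_s * t
  hw <- model$half_width_mm
  if (L <= 2 * hw) stop("body length below twice the half-width")
  s <- seq(s_head - L + hw, s_head - hw, by = step_mm)
  if (s[length(s)] < s_head - hw) s <- c(s, s_head - hw)
  pts_mm <- model$guide$fn(s)
  mmpx <- cal$mm_per_pixel
  ctr_mm <- arena$center * mmpx
  rad_mm <- arena$radius * mmpx
  rr <- sqrt((pts_mm[, 1] - ctr_mm[1])^2 + (pts_mm[, 2] - ctr_mm[2])^2)
  if (any(rr + hw > rad_mm))
    stop_mimizu("worm out of arena", "mimizu_out_of_arena")
  structure(list(
    centerline = pts_mm / mmpx,
    length_mm = L,
    head = as.numeric(model$guide$fn(s_head - hw) / mmpx),
    center = as.numeric(model$guide$fn(s_head - L / 2) / mmpx),
    tail = as.numeric(model$guide$fn(s_head - L + hw) / mmpx),
    t = t, half_width_px = hw / mmpx),
    class = "worm_pose")
}

#' Speck-noise parameters for rendering
#'
#' Small dark specks (tape glints, debris) scattered over the arena; their
#' count per frame is Poisson with mean `rate`, each a disk with radius
#' drawn uniformly from `radius_px`. Default radii keep every speck's area
#' below the default 50 px fragment-removal threshold.
#'
#' @param rate Mean specks per frame (0 disables noise).
#' @param radius_px `c(min, max)` speck radius in px.
#' @param value Speck red-channel value (dark, like the worm).
#' @return A list of class `speck_noise`.
#' @export
speck_noise <- function(rate = 3, radius_px = c(1, 3), value = 60) {
  structure(list(rate = rate, radius_px = radius_px, value = value),
            class = "speck_noise")
}

stamp_disks <- function(mask, centers_rc, radius) {
  dm <- dim(mask)
  rw <- ceiling(radius + 0.5)
  # offsets of a disk footprint around a pixel, reused for every center
  og <- expand.grid(dr = -rw:rw, dc = -rw:rw)
  og <- og[og$dr^2 + og$dc^2 <= (radius + 0.5)^2, ]  # superset, refined below
  r0 <- centers_rc[, 1]; c0 <- centers_rc[, 2]
  rr <- rep(round(r0), each = nrow(og)) + og$dr
  cc <- rep(round(c0), each = nrow(og)) + og$dc
  dr <- rr - rep(r0, each = nrow(og)); dc <- cc - rep(c0, each = nrow(og))
  ok <- dr * dr + dc * dc <= radius^2 &
    rr >= 1 & rr <= dm[1] & cc >= 1 & cc <= dm[2]
  mask[(cc[ok] - 1) * dm[1] + rr[ok]] <- TRUE
  mask
}

#' Render a synthetic frame
#'
#' Red-channel contrast mirrors the recording setup: light dish background
#' (red 210) inside the arena, black outside, dark worm (red 60); green and
#' blue carry deliberately lower contrast. The worm is stamped as disks of
#' the body half-width along the centerline. Speck noise is reproducible
#' for a fixed `seed`.
#'
#' @param pose A [simulate_pose()] result.
#' @param arena A [circle_roi()] in pixels.
#' @param noise A [speck_noise()]; `NULL` disables noise.
#' @param seed Integer seed for the speck draw (`NULL` = use current RNG
#'   state).
#' @param width,height Frame size in px.
#' @return A `[row, col, 3]` array of 0-255 values.
#' @export
render_frame <- function(pose, arena = synth_arena(), noise = speck_noise(),
                         seed = NULL, width = 640, height = 480) {
  stopifnot(inherits(pose, "worm_pose"))
  if (pose$half_width_px < 1.5)
    stop("body half-width must be at least 1.5 px at this calibration")
  dm <- c(height, width)
  x <- matrix(rep(seq_len(width) - 1, each = height), height, width)
  y <- matrix(rep(seq_len(height) - 1, times = width), height, width)
  inside <- (x - arena$center[1])^2 + (y - arena$center[2])^2 <=
    arena$radius^2
  worm <- matrix(FALSE, height, width)
  ctr_rc <- cbind(pose$centerline[, 2] + 1, pose$centerline[, 1] + 1)
  worm <- stamp_disks(worm, ctr_rc, pose$half_width_px)
  specks <- matrix(FALSE, height, width)
  if (!is.null(noise) && noise$rate > 0) {
    draw <- function() {
      k <- rpois(1, noise$rate)
      if (k > 0) {
        ang <- runif(k, 0, 2 * pi)
        rad <- arena$radius * sqrt(runif(k))
        sr <- runif(k, noise$radius_px[1], noise$radius_px[2])
        px <- arena$center[1] + rad * cos(ang)
        py <- arena$center[2] + rad * sin(ang)
        for (i in seq_len(k))
          specks <<- stamp_disks(specks, cbind(py[i] + 1, px[i] + 1), sr[i])
      }
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  dark <- worm | specks
  ch <- function(bg, fg) {
    m <- matrix(0, height, width)
    m[inside] <- bg
    m[dark & inside] <- fg
    m
  }
  out <- array(0, dim = c(height, width, 3))
  out[, , 1] <- ch(210, 60)   # red: highest contrast
  out[, , 2] <- ch(170, 110)
  out[, , 3] <- ch(165, 120)
  out
}

#' Generate a synthetic frame sequence with ground truth
#'
#' Writes zero-padded image frames, a ground-truth CSV in the trajectory
#' dialect (true head/center/tail pixel coordinates and true body length
#' L(t) per frame) and a run-configuration file consumable by the `track`
#' command. Fully reproducible from `seed`.
#'
#' @param model A [worm_model()].
#' @param n_frames Number of frames (>= 1).
#' @param interval Seconds between frames.
#' @param arena A [circle_roi()].
#' @param noise A [speck_noise()] or `NULL`.
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed); `NULL` keeps frames in
#'   memory only.
#' @param format `"png"` (lossless, default) or `"jpeg"`.
#' @param cal A [calibration()].
#' @return Invisibly, a list with `frames` (a `worm_frames` sequence),
#'   `ground_truth` (a `worm_trajectory`), `config` (named list), and the
#'   output `dir` (or `NULL`).
#' @export
generate_sequence <- function(model, n_frames, interval = 1,
                              arena = synth_arena(), noise = speck_noise(),
                              seed = 1, dir = NULL,
                              format = c("png", "jpeg"),
                              cal = calibration(frame_interval = interval)) {
  stopifnot(inherits(model, "worm_model"), n_frames >= 1)
  format <- match.arg(format)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  frames <- vector("list", n_frames)
  gt <- vector("list", n_frames)
  files <- character(n_frames)
  for (i in seq_len(n_frames)) {
    t_s <- (i - 1) * interval
    pose <- simulate_pose(model, t_s, arena, cal)
    fr <- render_frame(pose, arena, noise,
                       seed = (seed + 7919L * (i - 1L)) %% 2147483647L)
    gt[[i]] <- list(head = pose$head, center = pose$center,
                    tail = pose$tail, length_mm = pose$length_mm)
    if (is.null(dir)) {
      frames[[i]] <- fr
    } else {
      files[i] <- file.path(dir, sprintf("frame_%04d.%s", i - 1,
                                         if (format == "png") "png" else "jpg"))
      write_raster(fr, files[i])
    }
  }
  fs <- if (is.null(dir)) frame_sequence(frames, interval)
        else load_frames(dir, interval)
  gt_traj <- trajectory(
    frame = seq_len(n_frames) - 1L,
    time_s = (seq_len(n_frames) - 1) * interval,
    head = t(vapply(gt, function(g) round(g$head, 3), numeric(2))),
    center = t(vapply(gt, function(g) round(g$center, 3), numeric(2))),
    tail = t(vapply(gt, function(g) round(g$tail, 3), numeric(2))),
    length_mm = round(vapply(gt, `[[`, numeric(1), "length_mm"), 3),
    status = rep("ok", n_frames))
  config <- list(
    roi = sprintf("%.10g,%.10g,%.10g", arena$center[1], arena$center[2],
                  arena$radius),
    threshold = "auto", polarity = "dark_object",
    min_fragment_area = 50, min_spur = 5,
    mm_per_pixel = cal$mm_per_pixel, frame_interval = interval,
    tail_seed_x = round(gt_traj$tail_x[1]),
    tail_seed_y = round(gt_traj$tail_y[1]))
  if (!is.null(dir)) {
    write_trajectory_csv(gt_traj, file.path(dir, "ground_truth.csv"))
    write_run_config(config, file.path(dir, "track_config.txt"))
  }
  invisible(list(frames = fs, ground_truth = gt_traj, config = config,
                 dir = dir))
}

#' Synthetic scenario presets
#'
#' Named worm scenarios used by the CLI and the test-bench:
#' * `static`: no motion, constant length; the degenerate baseline.
#' * `crawl`: gentle peristaltic crawling along an arc (speed 0.6 mm/s,
#'   amplitude 0.1, period 45 s); parameters keep every endpoint's
#'   per-frame displacement below 10 px (2 mm at the default calibration)
#'   so that nearest-endpoint association is unambiguous.
#' * `stretch`: anchored head with maximal length oscillation (amplitude
#'   0.5, period 20 s), exercising the elastic-length measurement across
#'   the full 0.5x-1.5x range.
#' * `coil`: the worm wraps over itself on a tight coil path; skeleton
#'   topology breaks down and the tracker is expected to degrade (kept for
#'   failure-mode studies).
#'
#' @param name Preset name.
#' @return A [worm_model()].
#' @export
synth_preset <- function(name = c("crawl", "static", "stretch", "coil")) {
  name <- match.arg(name)
  switch(name,
    static = worm_model(rest_length_mm = 100, stretch_amplitude = 0,
                        speed_mm_s = 0),
    crawl = worm_model(rest_length_mm = 100, stretch_amplitude = 0.1,
                       stretch_period_s = 45, speed_mm_s = 0.6),
    stretch = worm_model(rest_length_mm = 100, stretch_amplitude = 0.5,
                         stretch_period_s = 20, speed_mm_s = 0),
    coil = worm_model(rest_length_mm = 100, stretch_amplitude = 0,
                      speed_mm_s = 0.5, guide = guide_coil()))
}
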