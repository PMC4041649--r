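#' Body length along the skeleton
#'
#' Geodesic tail-to-head distance on the skeleton's pixel graph (axial step
#' 1 px, diagonal step sqrt(2)) scaled by the calibration. This measures
#' length along the bent body, so it is invariant to posture, translation
#' and rotation.
#'
#' @param skel A `worm_skeleton`.
#' @param tail,head `c(x, y)` skeleton pixels; `head` must be reachable
#'   from `tail`.
#' @param cal A [calibration()].
#' @return Body length in mm.
#' @export
body_length <- function(skel, tail, head, cal = calibration()) {
  stopifnot(inherits(cal, "worm_calibration"))
  gmap <- geodesic_map(skel, tail)
  pos <- match(pt_to_lin(head, skel$dim), skel$idx)
  if (is.na(pos) || !is.finite(gmap$dist[pos]))
    stop("head is not reachable from tail on the skeleton")
  gmap$dist[pos] * cal$mm_per_pixel
}

#' Per-point velocity series
#'
#' Speed of one tracked point per frame transition: Euclidean pixel
#' displacement times `mm_per_pixel`, divided by the frame interval.
#' Forward differences at the native frame rate, no smoothing. Transitions
#' touching a `lost` or `carried_forward` record are `NA` (the point was
#' not observed, so its displacement is undefined).
#'
#' @param traj A `worm_trajectory` with at least two rows.
#' @param point `"head"`, `"center"` or `"tail"`.
#' @param cal A [calibration()].
#' @param window Optional odd integer; when > 1, a centred moving average
#'   of that many transitions is applied to the speeds (default off).
#' @return A data.frame of class `velocity_series` with columns `time_s`
#'   (time of the transition end) and `speed_mm_s`.
#' @export
velocities <- function(traj, point = c("head", "center", "tail"),
                       cal = calibration(), window = 1L) {
  point <- match.arg(point)
  if (NROW(traj) < 2) stop("need at least two records to compute velocity")
  stopifnot(inherits(cal, "worm_calibration"))
  x <- traj[[paste0(point, "_x")]]
  y <- traj[[paste0(point, "_y")]]
  dt <- diff(traj$time_s)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  sp <- sqrt(diff(x)^2 + diff(y)^2) * cal$mm_per_pixel / dt
  present <- traj$status %in% c("ok", "seeded")
  sp[!(present[-length(present)] & present[-1])] <- NA_real_
  if (window > 1) {
    if (window %% 2 == 0) stop("'window' must be odd")
    k <- rep(1 / window, window)
    sm <- stats::filter(sp, k, sides = 2)
    sp <- as.numeric(sm)
  }
  structure(data.frame(time_s = traj$time_s[-1], speed_mm_s = sp),
            class = c("velocity_series", "data.frame"), point = point)
}

#' Summary statistics of a series
#'
#' Arithmetic mean, standard deviation over time (sample, n-1), maximum and
#' minimum of the present (non-`NA`) values.
#'
#' @param x Numeric vector, or a `velocity_series`, or a `worm_trajectory`
#'   (whose `length_mm` column is summarised).
#' @return Named numeric vector `c(mean, sd, max, min)`.
#' @export
summarize_series <- function(x) {
  if (inherits(x, "velocity_series")) x <- x$speed_mm_s
  if (inherits(x, "worm_trajectory") || (is.data.frame(x) &&
      "length_mm" %in% names(x))) x <- x$length_mm
  x <- x[!is.na(x)]
  if (!length(x)) stop("no present values to summarise")
  c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
    max = max(x), min = min(x))
}

#' Body-length summary with stretch range
#'
#' Mean, sd, max, min of per-frame body length plus the stretch
#' (max - min), the range the elastic body covered over the recording.
#'
#' @param x A `worm_trajectory` or numeric vector of lengths (mm).
#' @return A one-row data.frame with `mean_mm`, `sd_mm`, `max_mm`,
#'   `min_mm`, `stretch_mm`.
#' @export
summarize_lengths <- function(x) {
  s <- summarize_series(x)
  data.frame(mean_mm = s[["mean"]], sd_mm = s[["sd"]], max_mm = s[["max"]],
             min_mm = s[["min"]],
             stretch_mm = stretch_mm(s[["max"]], s[["min"]]))
}

#' Stretch range from extreme body lengths
#'
#' The distance from minimum to maximum body length, i.e. how far the worm
#' stretched beyond its most contracted state.
#'
#' @param max_mm,min_mm Extreme body lengths in mm.
#' @return `max_mm - min_mm`.
#' @export
stretch_mm <- function(max_mm, min_mm) {
  if (any(max_mm < min_mm)) stop("max_mm must be >= min_mm")
  max_mm - min_mm
}

#' Compare an automatic trajectory against a reference
#'
#' Standard bivariate correlation of the coordinate series per axis
#' (Pearson r on raw pixel coordinates), plus mean and sd of the
#' per-transition velocity differences (automatic minus reference), for
#' each tracked point present in both tables. The reference is typically a
#' manually tracked trajectory; a two-point reference (head/tail only)
#' restricts the comparison to those points.
#'
#' @param auto,reference `worm_trajectory` tables covering the same frame
#'   indices.
#' @param cal A [calibration()] used for the velocity differences.
#' @return A data.frame with one row per point and columns `point`,
#'   `pearson_r_x`, `pearson_r_y`, `mean_velocity_diff`,
#'   `sd_velocity_diff`.
#' @export
compare_trajectories <- function(auto, reference, cal = calibration()) {
  missing_in_ref <- setdiff(auto$frame, reference$frame)
  missing_in_auto <- setdiff(reference$frame, auto$frame)
  if (length(missing_in_ref) || length(missing_in_auto))
    stop("frame mismatch between trajectories; missing in reference: [",
         paste(missing_in_ref, collapse = ", "),
         "]; missing in automatic: [",
         paste(missing_in_auto, collapse = ", "), "]")
  auto <- auto[order(auto$frame), ]
  reference <- reference[order(reference$frame), ]
  pts <- c("head", "center", "tail")
  pts <- pts[vapply(pts, function(p) {
    !all(is.na(auto[[paste0(p, "_x")]])) &&
      !all(is.na(reference[[paste0(p, "_x")]]))
  }, logical(1))]
  # r is undefined (NA) when either series is constant
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }
  rows <- lapply(pts, function(p) {
    ax <- auto[[paste0(p, "_x")]]; ay <- auto[[paste0(p, "_y")]]
    rx <- reference[[paste0(p, "_x")]]; ry <- reference[[paste0(p, "_y")]]
    va <- velocities(auto, p, cal)$speed_mm_s
    vr <- velocities(reference, p, cal)$speed_mm_s
    dv <- va - vr
    data.frame(point = p,
               pearson_r_x = safe_cor(ax, rx),
               pearson_r_y = safe_cor(ay, ry),
               mean_velocity_diff = mean(dv, na.rm = TRUE),
               sd_velocity_diff = if (sum(!is.na(dv)) > 1)
                 sd(dv, na.rm = TRUE) else 0)
  })
  do.call(rbind, rows)
}
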