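#' Feature points of one frame
#'
#' Head, center and tail pixel coordinates on a frame's skeleton, plus a
#' status flag: `seeded` (from user initialization), `ok` (tracked),
#' `carried_forward` (worm not found, coordinates repeated from the
#' previous frame) or `lost`.
#'
#' @param head,center,tail `c(x, y)` pixel coordinates.
#' @param frame_index Integer frame index (0-based, matching the CSV).
#' @param status One of `"seeded"`, `"ok"`, `"lost"`, `"carried_forward"`.
#' @param length_mm Optional body length in mm.
#' @return An object of class `feature_points`.
#' @export
feature_points <- function(head, center, tail, frame_index = 0L,
                           status = c("seeded", "ok", "lost",
                                      "carried_forward"),
                           length_mm = NA_real_) {
  status <- match.arg(status)
  structure(list(head = as.numeric(head), center = as.numeric(center),
                 tail = as.numeric(tail),
                 frame_index = as.integer(frame_index), status = status,
                 length_mm = length_mm),
            class = "feature_points")
}

#' @export
print.feature_points <- function(x, ...) {
  cat(sprintf(
    "feature_points[frame %d, %s]: head (%g, %g) center (%g, %g) tail (%g, %g)\n",
    x$frame_index, x$status, x$head[1], x$head[2],
    x$center[1], x$center[2], x$tail[1], x$tail[2]))
  invisible(x)
}

nearest_endpoint <- function(eps, pt) {
  d2 <- (eps[, 1] - pt[1])^2 + (eps[, 2] - pt[2])^2
  # ties towards the endpoint listed first (endpoints are (row, col)-sorted)
  eps[which.min(d2), ]
}

#' Initialize feature points from a tail seed
#'
#' The tail is the skeleton endpoint nearest (Euclidean) to the
#' user-supplied seed, which may lie off the skeleton; the head is the
#' geodesically farthest skeleton pixel from the tail; the center is the
#' midpoint of the tail-to-head path.
#'
#' @param skel A `worm_skeleton` (pruned).
#' @param tail_seed `c(x, y)` approximate tail position, supplied by the
#'   user for the first frame.
#' @param frame_index Frame index stored in the result.
#' @return A [feature_points()] object with status `"seeded"`.
#' @export
init_feature_points <- function(skel, tail_seed, frame_index = 0L) {
  stopifnot(inherits(skel, "worm_skeleton"))
  if (!length(skel$idx)) stop("cannot initialize on an empty skeleton")
  eps <- find_endpoints(skel)
  tail <- nearest_endpoint(eps, tail_seed)
  gmap <- geodesic_map(skel, tail)
  head <- farthest_point(gmap)$point
  center <- midpoint_on_path(gmap, head)
  feature_points(head, center, tail, frame_index, "seeded")
}

#' Track feature points into the next frame
#'
#' The tail moves slowest, so it is matched first: the new tail is the
#' endpoint with the shortest Euclidean distance to the previous tail. The
#' new head is the endpoint (tail excluded) nearest the previous head; with
#' more than two endpoints, head candidates are all remaining endpoints and
#' distance ties are broken towards the candidate farthest along the body
#' from the tail. If the skeleton has a single endpoint (partly coiled
#' body), the head falls back to the geodesically farthest pixel from the
#' tail. The center is re-derived as the tail-to-head path midpoint by
#' default, or matched to the nearest skeleton pixel with
#' `center_mode = "match"`.
#'
#' @param prev [feature_points()] of the previous frame.
#' @param skel The current frame's `worm_skeleton`, or `NULL` if no worm
#'   was found (coordinates are then carried forward).
#' @param frame_index Frame index stored in the result.
#' @param center_mode `"geodesic"` (recompute midpoint) or `"match"`
#'   (nearest skeleton pixel to the previous center).
#' @return A [feature_points()] object.
#' @export
track_step <- function(prev, skel, frame_index = prev$frame_index + 1L,
                       center_mode = c("geodesic", "match")) {
  stopifnot(inherits(prev, "feature_points"))
  center_mode <- match.arg(center_mode)
  if (is.null(skel) || !length(skel$idx))
    return(feature_points(prev$head, prev$center, prev$tail, frame_index,
                          "carried_forward"))
  eps <- find_endpoints(skel)
  tail <- nearest_endpoint(eps, prev$tail)
  rest <- eps[!(eps[, 1] == tail[1] & eps[, 2] == tail[2]), , drop = FALSE]
  gmap <- geodesic_map(skel, tail)
  if (nrow(rest) == 0) {
    head <- farthest_point(gmap)$point
  } else {
    d2 <- (rest[, 1] - prev$head[1])^2 + (rest[, 2] - prev$head[2])^2
    near <- which(d2 <= min(d2) + 1e-9)
    if (length(near) > 1) {
      # break ties by maximal geodesic separation from the tail
      gd <- vapply(near, function(i) {
        pos <- match(pt_to_lin(rest[i, ], skel$dim), skel$idx)
        gmap$dist[pos]
      }, numeric(1))
      near <- near[order(-gd)[1]]
    }
    head <- rest[near[1], ]
  }
  if (!is.finite(gmap$dist[match(pt_to_lin(head, skel$dim), skel$idx)]))
    head <- farthest_point(gmap)$point  # disconnected remnant: stay on body
  center <- if (center_mode == "geodesic") {
    midpoint_on_path(gmap, head)
  } else {
    pts <- skeleton_points(skel)
    d2 <- (pts[, 1] - prev$center[1])^2 + (pts[, 2] - prev$center[2])^2
    pts[which.min(d2), ]
  }
  feature_points(head, center, tail, frame_index, "ok")
}

#' Tracking configuration
#'
#' Bundles the preprocessing, skeletonization and calibration settings used
#' by [track_sequence()].
#'
#' @param roi A [circle_roi()] delimiting the dish interior, or `NULL` to
#'   process the full frame.
#' @param threshold Intensity threshold in 0-255, or `"auto"` for per-frame
#'   Otsu over in-ROI pixels.
#' @param polarity `"dark_object"` (default) or `"bright_object"`.
#' @param min_fragment_area Minimum component area kept (px).
#' @param min_spur Spur-pruning length (px).
#' @param cal A [calibration()].
#' @param center_mode `"geodesic"` or `"match"` (see [track_step()]).
#' @return A list of class `track_config`.
#' @export
track_config <- function(roi = NULL, threshold = "auto",
                         polarity = "dark_object", min_fragment_area = 50,
                         min_spur = 5, cal = calibration(),
                         center_mode = "geodesic") {
  structure(list(roi = roi, threshold = threshold, polarity = polarity,
                 min_fragment_area = min_fragment_area, min_spur = min_spur,
                 cal = cal, center_mode = center_mode),
            class = "track_config")
}

# One frame: raw raster -> pruned skeleton (NULL when no worm found).
segment_frame <- function(frame, config) {
  ch <- if (length(dim(frame)) == 3) red_channel(frame) else frame
  if (!is.null(config$roi)) ch <- apply_roi(ch, config$roi)
  mask <- binarize(ch, config$threshold, config$polarity, roi = config$roi)
  mask <- remove_small_fragments(mask, config$min_fragment_area)
  worm <- tryCatch(largest_component(mask),
                   mimizu_no_worm = function(e) NULL)
  if (is.null(worm)) return(NULL)
  prune_spurs(hilditch_thin(worm), config$min_spur)
}

#' Track a worm through a frame sequence
#'
#' Runs the full pipeline per frame -- ROI masking, red channel,
#' thresholding, fragment removal, largest component, Hilditch thinning,
#' spur pruning -- then initializes feature points from the tail seed on the
#' first frame and propagates them with [track_step()]. Frames where no
#' worm is segmented repeat the last coordinates with status
#' `carried_forward`; tracking resumes on the next segmentable frame.
#'
#' @param frames A `worm_frames` sequence.
#' @param config A [track_config()].
#' @param tail_seed `c(x, y)` tail position on the first frame.
#' @param verbose Emit a per-frame status message.
#' @return A `worm_trajectory` data.frame with one row per frame, body
#'   length in mm (geodesic tail-to-head distance times the calibration)
#'   and per-frame status.
#' @export
track_sequence <- function(frames, config = track_config(), tail_seed,
                           verbose = FALSE) {
  stopifnot(inherits(frames, "worm_frames"), inherits(config, "track_config"))
  if (missing(tail_seed)) stop("'tail_seed' is required")
  n <- frames$n
  recs <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    skel <- segment_frame(get_frame(frames, i), config)
    if (i == 1) {
      if (is.null(skel))
        stop("cannot initialize: no worm found in the first frame")
      fp <- init_feature_points(skel, tail_seed, frame_index = 0L)
    } else {
      fp <- track_step(prev, skel, frame_index = i - 1L,
                       center_mode = config$center_mode)
    }
    fp$length_mm <- if (!is.null(skel)) {
      round(body_length(skel, fp$tail, fp$head, config$cal), 3)
    } else prev$length_mm
    if (verbose)
      message(sprintf("frame %d: %s", i - 1L, fp$status))
    recs[[i]] <- fp
    prev <- fp
  }
  trajectory(
    frame = vapply(recs, `[[`, integer(1), "frame_index"),
    time_s = frames$times,
    head = t(vapply(recs, `[[`, numeric(2), "head")),
    center = t(vapply(recs, `[[`, numeric(2), "center")),
    tail = t(vapply(recs, `[[`, numeric(2), "tail")),
    length_mm = vapply(recs, `[[`, numeric(1), "length_mm"),
    status = vapply(recs, `[[`, character(1), "status"))
}

#' Write a skeleton overlay image for debugging
#'
#' @param frame Original frame (matrix or 3-channel array).
#' @param skel The frame's `worm_skeleton`.
#' @param fp Optional [feature_points()] to mark (head/center/tail).
#' @param file Output image path (PNG recommended).
#' @return `file`, invisibly.
#' @export
write_overlay <- function(frame, skel, fp = NULL, file) {
  d <- dim(frame)
  arr <- if (length(d) == 2) {
    array(rep(frame, 3), dim = c(d[1], d[2], 3))
  } else frame
  green <- arr[, , 2]
  green[skel$idx] <- 255
  arr[, , 2] <- green
  if (!is.null(fp)) {
    mark <- function(arr, pt, channel) {
      rc <- pt_to_rc(pt)
      rr <- pmax(1, rc[1] - 2):pmin(d[1], rc[1] + 2)
      cc <- pmax(1, rc[2] - 2):pmin(d[2], rc[2] + 2)
      for (ch in 1:3) arr[rr, cc, ch] <- if (ch == channel) 255 else 0
      arr
    }
    arr <- mark(arr, fp$head, 1)    # head red
    arr <- mark(arr, fp$center, 3)  # center blue
    arr <- mark(arr, fp$tail, 2)    # tail green
  }
  write_raster(arr, file)
}
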