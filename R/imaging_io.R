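#' Pixel-size and frame-interval calibration
#'
#' Length scale and timing of the recording. The reference recording setup
#' digitised the dish at 0.2 mm per pixel with one frame per second, which
#' are the defaults.
#'
#' @param mm_per_pixel Length of one pixel side in millimetres (> 0).
#' @param frame_interval Seconds between consecutive frames (> 0).
#' @return An object of class `worm_calibration`.
#' @examples
#' calibration()            # 0.2 mm/px, 1 s
#' calibration(0.1, 0.5)
#' @export
calibration <- function(mm_per_pixel = 0.2, frame_interval = 1) {
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1 ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("'mm_per_pixel' must be a single positive number")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be a single positive number")
  structure(list(mm_per_pixel = mm_per_pixel,
                 frame_interval = frame_interval),
            class = "worm_calibration")
}

#' Build a frame sequence from in-memory rasters
#'
#' @param frames List of 2D matrices or `[row, col, 3]` arrays with 8-bit
#'   intensities (0-255). All frames must share dimensions.
#' @param interval Seconds between frames; frame `i` is at time
#'   `(i - 1) * interval`.
#' @param files Optional character vector of source paths (used by
#'   [load_frames()]; frames are then read lazily).
#' @return An object of class `worm_frames` with elements `n`, `times`,
#'   `width`, `height`.
#' @seealso [load_frames()], [get_frame()]
#' @export
frame_sequence <- function(frames = NULL, interval = 1, files = NULL) {
  if (is.null(frames) && is.null(files))
    stop_mimizu("empty sequence", "mimizu_empty_sequence")
  if (!is.null(frames)) {
    if (length(frames) == 0)
      stop_mimizu("empty sequence", "mimizu_empty_sequence")
    dims <- lapply(frames, function(f) dim(f)[1:2])
    for (i in seq_along(dims))
      if (!identical(dims[[i]], dims[[1]]))
        stop(sprintf("frame %d dimensions (%s) differ from frame 1 (%s)",
                     i, paste(dims[[i]], collapse = "x"),
                     paste(dims[[1]], collapse = "x")))
    n <- length(frames)
    h <- dims[[1]][1]; w <- dims[[1]][2]
  } else {
    n <- length(files)
    h <- w <- NA_integer_  # filled by load_frames
  }
  if (!is.numeric(interval) || interval <= 0)
    stop("'interval' must be positive")
  structure(list(frames = frames, files = files, n = n,
                 times = (seq_len(n) - 1) * interval,
                 width = w, height = h, interval = interval),
            class = "worm_frames")
}

#' Load an ordered frame sequence from image files
#'
#' Frames are ordered by lexicographic filename sort, so sequences should use
#' zero-padded names (`frame_0001.png`, ...). Times are assigned as
#' `index * interval` starting at 0. All images must share dimensions; pixel
#' data are read lazily by [get_frame()].
#'
#' @param path A directory containing image files, or a glob pattern
#'   (e.g. `"frames/*.png"`).
#' @param interval Seconds between frames.
#' @param pattern Filename regular expression used when `path` is a
#'   directory (default: JPEG/PNG/TIFF extensions).
#' @return A `worm_frames` object.
#' @export
load_frames <- function(path, interval = 1,
                        pattern = "\\.(jpe?g|png|tiff?)$") {
  if (length(path) != 1 || !is.character(path))
    stop("'path' must be a single directory or glob pattern")
  if (dir.exists(path)) {
    files <- list.files(path, pattern = pattern, full.names = TRUE,
                        ignore.case = TRUE)
  } else {
    files <- Sys.glob(path)
  }
  files <- sort(files, method = "radix")
  if (length(files) == 0)
    stop_mimizu("empty sequence", "mimizu_empty_sequence")
  fs <- frame_sequence(files = files, interval = interval)
  dims <- NULL
  for (i in seq_along(files)) {
    d <- dim(read_raster(files[i]))[1:2]
    if (is.null(dims)) dims <- d
    else if (!identical(d, dims))
      stop(sprintf("dimension mismatch: '%s' is %dx%d, expected %dx%d",
                   basename(files[i]), d[2], d[1], dims[2], dims[1]))
  }
  fs$height <- dims[1]; fs$width <- dims[2]
  fs
}

# Read one image file into [row, col(, channel)] 0-255 numerics.
# EBImage stores images as (x, y[, c]); transpose to matrix convention.
read_raster <- function(file) {
  img <- EBImage::readImage(file)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) {
    t(a) * 255
  } else {
    aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
  }
}

write_raster <- function(raster, file, quality = 95) {
  a <- if (length(dim(raster)) == 2) {
    EBImage::Image(t(raster) / 255)
  } else {
    EBImage::Image(aperm(raster, c(2, 1, 3)) / 255, colormode = "Color")
  }
  EBImage::writeImage(a, file, quality = quality)
  invisible(file)
}

#' Extract one frame from a sequence
#'
#' @param fs A `worm_frames` object.
#' @param i Frame index (1-based).
#' @return A matrix or `[row, col, 3]` array of 0-255 intensities.
#' @export
get_frame <- function(fs, i) {
  stopifnot(inherits(fs, "worm_frames"))
  if (i < 1 || i > fs$n) stop(sprintf("frame index %d out of range", i))
  if (!is.null(fs$frames)) fs$frames[[i]] else read_raster(fs$files[i])
}

#' @export
print.worm_frames <- function(x, ...) {
  cat(sprintf("worm_frames: %d frame(s), %sx%s px, interval %g s%s\n",
              x$n, x$width, x$height, x$interval,
              if (is.null(x$frames)) " (on disk)" else ""))
  invisible(x)
}

trajectory_columns <- c("frame", "time_s", "head_x", "head_y", "center_x",
                        "center_y", "tail_x", "tail_y", "length_mm", "status")
trajectory_statuses <- c("ok", "seeded", "lost", "carried_forward")

#' Assemble a trajectory table
#'
#' One row per frame with head/center/tail pixel coordinates (x = column,
#' y = row, 0-based), body length in mm and a status flag (`ok`, `seeded`,
#' `lost` or `carried_forward`). Coordinates may be `NA` when `status` is
#' `"lost"` or when the center point is absent (two-point reference data).
#'
#' @param frame Integer frame indices.
#' @param time_s Times in seconds.
#' @param head,center,tail Two-column matrices (or vectors for one record)
#'   of x, y coordinates.
#' @param length_mm Body lengths in mm (>= 0, or NA).
#' @param status Character vector of status flags.
#' @return A `data.frame` of class `worm_trajectory`.
#' @export
trajectory <- function(frame, time_s, head, center, tail, length_mm, status) {
  as_m <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = FALSE)
    p
  }
  head <- as_m(head); center <- as_m(center); tail <- as_m(tail)
  df <- data.frame(frame = as.integer(frame), time_s = as.numeric(time_s),
                   head_x = head[, 1], head_y = head[, 2],
                   center_x = center[, 1], center_y = center[, 2],
                   tail_x = tail[, 1], tail_y = tail[, 2],
                   length_mm = as.numeric(length_mm),
                   status = as.character(status))
  validate_trajectory(df)
  class(df) <- c("worm_trajectory", "data.frame")
  df
}

validate_trajectory <- function(df) {
  bad <- setdiff(df$status, trajectory_statuses)
  if (length(bad))
    stop("invalid status value(s): ", paste(unique(bad), collapse = ", "))
  ln <- df$length_mm[!is.na(df$length_mm)]
  if (any(ln < 0)) stop("length_mm must be >= 0")
  invisible(df)
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "",
         ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
                sub("0+$", "", sprintf(paste0("%.", digits, "f"), x))))
}

#' Write a trajectory to CSV
#'
#' Comma-separated, '.' decimal, UTF-8, LF line endings, with the fixed
#' header `frame,time_s,head_x,head_y,center_x,center_y,tail_x,tail_y,`
#' `length_mm,status`. Written files round-trip through
#' [read_trajectory_csv()].
#'
#' @param traj A `worm_trajectory` (or conforming data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (NROW(traj) == 0) stop("cannot write an empty trajectory")
  validate_trajectory(traj)
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  lines <- paste(sapply(seq_len(nrow(traj)), function(i) {
    paste(c(sprintf("%d", traj$frame[i]),
            sprintf("%.10g", traj$time_s[i]),
            fmt_num(c(traj$head_x[i], traj$head_y[i], traj$center_x[i],
                      traj$center_y[i], traj$tail_x[i], traj$tail_y[i])),
            fmt_num(traj$length_mm[i]),
            traj$status[i]), collapse = ",")
  }))
  writeLines(c(paste(trajectory_columns, collapse = ","), lines), con,
             sep = "\n")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Accepts the ten-column dialect written by [write_trajectory_csv()] and a
#' two-point dialect lacking the `center_x`/`center_y` columns (as produced
#' by manual head/tail tracking); missing centers are returned as `NA`.
#'
#' @param path File to read.
#' @return A `worm_trajectory` data.frame, in frame order.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("malformed trajectory file: empty")
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  two_point <- identical(hdr, setdiff(trajectory_columns,
                                      c("center_x", "center_y")))
  if (!two_point && !identical(hdr, trajectory_columns))
    stop("unrecognised trajectory header: ", lines[1])
  ncol_exp <- length(hdr)
  rows <- lapply(seq_along(lines)[-1], function(ln) {
    if (!nzchar(lines[ln])) return(NULL)
    f <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    if (length(f) != ncol_exp)
      stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                   ln, ncol_exp, length(f)))
    num <- f[-length(f)]
    num[num == ""] <- NA
    v <- suppressWarnings(as.numeric(num))
    if (any(is.na(v) & !is.na(num)))
      stop(sprintf("non-numeric value at line %d: '%s'",
                   ln, num[which(is.na(v) & !is.na(num))[1]]))
    c(v, NA)  # placeholder for status slot
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  status <- vapply(seq_along(lines)[-1][nzchar(lines[-1])], function(ln) {
    f <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    f[length(f)]
  }, character(1))
  if (!length(rows)) {
    df <- data.frame(matrix(numeric(0), ncol = 9))
    names(df) <- trajectory_columns[1:9]
    df$status <- character(0)
    class(df) <- c("worm_trajectory", "data.frame")
    return(df)
  }
  m <- do.call(rbind, rows)
  if (two_point) {
    df <- data.frame(frame = as.integer(m[, 1]), time_s = m[, 2],
                     head_x = m[, 3], head_y = m[, 4],
                     center_x = NA_real_, center_y = NA_real_,
                     tail_x = m[, 5], tail_y = m[, 6],
                     length_mm = m[, 7], status = status)
  } else {
    df <- data.frame(frame = as.integer(m[, 1]), time_s = m[, 2],
                     head_x = m[, 3], head_y = m[, 4],
                     center_x = m[, 5], center_y = m[, 6],
                     tail_x = m[, 7], tail_y = m[, 8],
                     length_mm = m[, 9], status = status)
  }
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  validate_trajectory(df)
  class(df) <- c("worm_trajectory", "data.frame")
  df
}

#' Read/write a flat key=value run configuration
#'
#' Understands `key = value` and `key: value` lines; `#` starts a comment.
#' Values for the keys `mm_per_pixel`, `frame_interval`, `min_fragment_area`,
#' `min_spur` are numeric; `threshold` is numeric or `"auto"`; `roi` is
#' either `"cx,cy,r"` or three `x,y` marks separated by `;`.
#'
#' @param path File to read or write.
#' @return `read_run_config`: a named list. `write_run_config`: `path`,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$",
                                ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num) && key != "roi") num else val
  }
  out
}

#' @param config Named list of scalar values to serialise.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k,
            if (is.numeric(v)) sprintf("%.10g", v) else as.character(v))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
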