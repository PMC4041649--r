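#' Circular region of interest
#'
#' The dish interior. Either construct directly from a center and radius, or
#' derive it from three rim marks with [circle_from_marks()].
#'
#' @param center `c(x, y)` pixel coordinates of the circle center (0-based
#'   pixel-center convention).
#' @param radius Radius in pixels (> 0).
#' @return An object of class `circle_roi`.
#' @export
circle_roi <- function(center, radius) {
  if (length(center) != 2 || !all(is.finite(center)))
    stop("'center' must be finite c(x, y)")
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop("'radius' must be a single positive number")
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "circle_roi")
}

#' @export
print.circle_roi <- function(x, ...) {
  cat(sprintf("circle_roi: center (%.2f, %.2f), radius %.2f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Circumcircle through three rim marks
#'
#' The dish outline is marked at three positions on its rim; the ROI is the
#' circle through those marks (their circumcircle).
#'
#' @param p1,p2,p3 `c(x, y)` pixel coordinates of the marks; must be
#'   distinct and non-collinear.
#' @return A [circle_roi()].
#' @examples
#' circle_from_marks(c(0, 1), c(1, 0), c(0, -1))  # unit circle at origin
#' @export
circle_from_marks <- function(p1, p2, p3) {
  P <- rbind(p1, p2, p3)
  if (nrow(unique(P)) != 3)
    stop_mimizu("degenerate marks: points must be distinct",
                "mimizu_degenerate_marks")
  # Perpendicular-bisector system: 2(p2-p1).c = |p2|^2-|p1|^2, likewise p3.
  A <- 2 * rbind(P[2, ] - P[1, ], P[3, ] - P[1, ])
  b <- c(sum(P[2, ]^2) - sum(P[1, ]^2), sum(P[3, ]^2) - sum(P[1, ]^2))
  scale <- max(abs(A))
  if (abs(det(A)) < 1e-9 * scale^2)
    stop_mimizu("degenerate marks: points are collinear",
                "mimizu_degenerate_marks")
  ctr <- solve(A, b)
  circle_roi(ctr, sqrt(sum((P[1, ] - ctr)^2)))
}

#' Mask a frame to the circular ROI
#'
#' Pixels whose centers lie outside the circle are set to 0 (background);
#' pixels inside are unchanged. Works on 2D rasters and 3-channel arrays.
#' Idempotent.
#'
#' @param frame Matrix or `[row, col, 3]` array of intensities.
#' @param roi A [circle_roi()].
#' @return The masked raster, same shape as `frame`.
#' @export
apply_roi <- function(frame, roi) {
  stopifnot(inherits(roi, "circle_roi"))
  d <- dim(frame)
  x <- matrix(rep(seq_len(d[2]) - 1, each = d[1]), d[1], d[2])
  y <- matrix(rep(seq_len(d[1]) - 1, times = d[2]), d[1], d[2])
  outside <- (x - roi$center[1])^2 + (y - roi$center[2])^2 > roi$radius^2
  if (length(d) == 2) {
    frame[outside] <- 0
  } else {
    for (ch in seq_len(d[3])) {
      plane <- frame[, , ch]
      plane[outside] <- 0
      frame[, , ch] <- plane
    }
  }
  frame
}

#' Extract the red channel
#'
#' Worm/background contrast is highest in the red channel under the
#' reference lighting, so segmentation operates on it alone. A 2D
#' (grayscale) input passes through unchanged with a message.
#'
#' @param frame `[row, col, 3]` array (R, G, B) or a 2D matrix.
#' @return A 2D matrix of intensities.
#' @export
red_channel <- function(frame) {
  d <- dim(frame)
  if (length(d) == 2) {
    message("red_channel: grayscale input passed through unchanged")
    return(frame)
  }
  if (d[3] < 3) stop("'frame' must have 3 channels")
  frame[, , 1]
}

#' Otsu's threshold over a set of intensities
#'
#' Maximises the between-class variance over all 256 candidate thresholds
#' using the cumulative-moment formulation. The returned value `t` splits
#' classes as `{v < t}` and `{v >= t}`; ties take the smallest `t`.
#'
#' @param values Numeric vector of intensities in 0-255.
#' @return Integer threshold in 1-255.
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("cannot compute a threshold from no pixels")
  h <- tabulate(pmin(pmax(floor(values), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)                     # mass of {v <= k}, k = 0..255
  m0 <- cumsum(p * levels)            # first moment of {v <= k}
  mt <- m0[256]
  # candidate thresholds t = k+1 split at {v < t} = {v <= k}
  w1 <- 1 - w0
  sigma2 <- (mt * w0 - m0)^2 / (w0 * w1)
  sigma2[!is.finite(sigma2)] <- -Inf
  k <- which.max(sigma2[1:255])       # which.max takes the first maximum
  as.integer(k)                       # threshold t = k (splitting v < k)
}

#' Threshold a channel into a binary worm mask
#'
#' With the default `dark_object` polarity, pixels strictly below the
#' threshold become foreground (the worm is darker than the lit dish).
#' `threshold = "auto"` computes Otsu's threshold, restricted to pixels
#' inside `roi` when one is given.
#'
#' @param channel 2D matrix of intensities (0-255).
#' @param threshold Numeric threshold in 0-255, or `"auto"`.
#' @param polarity `"dark_object"` (foreground below threshold) or
#'   `"bright_object"` (foreground above threshold).
#' @param roi Optional [circle_roi()]; with `"auto"`, Otsu is computed over
#'   in-ROI pixels only, and pixels outside are always background.
#' @return Logical matrix, `TRUE` = worm.
#' @export
binarize <- function(channel, threshold = "auto",
                     polarity = c("dark_object", "bright_object"),
                     roi = NULL) {
  polarity <- match.arg(polarity)
  d <- dim(channel)
  inside <- NULL
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "circle_roi"))
    x <- matrix(rep(seq_len(d[2]) - 1, each = d[1]), d[1], d[2])
    y <- matrix(rep(seq_len(d[1]) - 1, times = d[2]), d[1], d[2])
    inside <- (x - roi$center[1])^2 + (y - roi$center[2])^2 <= roi$radius^2
    if (!any(inside)) stop("empty ROI: no pixels inside the circle")
  }
  if (identical(threshold, "auto")) {
    vals <- if (is.null(inside)) channel else channel[inside]
    threshold <- otsu_threshold(vals)
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
    stop("'threshold' must be in [0, 255] or \"auto\"")
  mask <- if (polarity == "dark_object") channel < threshold
          else channel > threshold
  if (!is.null(inside)) mask <- mask & inside
  mask
}

# 8-connected component labelling on a logical mask via the pixel adjacency
# graph. Returns a list(labels = integer matrix (0 = background),
# sizes = per-label pixel counts, min_pixel = per-label smallest (row, col)).
label_components <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0)
    return(list(labels = matrix(0L, dm[1], dm[2]), sizes = integer(0),
                min_pixel = NULL))
  rc <- lin_to_rc(idx, dm)
  pos <- match  # position of a linear index within idx
  edges <- NULL
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rc[, "r"] + d[1]; c2 <- rc[, "c"] + d[2]
    ok <- r2 >= 1L & r2 <= dm[1] & c2 >= 1L & c2 <= dm[2]
    j <- pos(rc_to_lin(r2[ok], c2[ok], dm), idx)
    keep <- !is.na(j)
    edges <- rbind(edges, cbind(which(ok)[keep], j[keep]))
  }
  if (is.null(edges) || nrow(edges) == 0) {
    comp <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n)
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)$membership
  }
  labels <- matrix(0L, dm[1], dm[2])
  labels[idx] <- comp
  sizes <- tabulate(comp)
  ord <- order(comp, rc[, "r"], rc[, "c"])
  first <- ord[!duplicated(comp[ord])]
  min_pixel <- rc[first, , drop = FALSE][order(comp[first]), , drop = FALSE]
  list(labels = labels, sizes = sizes, min_pixel = min_pixel)
}

#' Remove small foreground fragments
#'
#' Deletes every 8-connected foreground component whose area is strictly
#' below `min_area` pixels; components of exactly `min_area` survive.
#' Intended to clear tape glints and other specks before thinning.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @param min_area Minimum surviving component area in pixels (>= 1). The
#'   default of 50 px corresponds to about 2 mm^2 at 0.2 mm/px, well below
#'   any adult worm cross-section.
#' @return Logical matrix.
#' @export
remove_small_fragments <- function(mask, min_area = 50) {
  if (!is.numeric(min_area) || min_area < 1)
    stop("'min_area' must be >= 1")
  lab <- label_components(mask)
  if (!length(lab$sizes)) return(mask)
  keep <- which(lab$sizes >= min_area)
  mask & matrix(lab$labels %in% keep, nrow(mask), ncol(mask))
}

#' Keep only the largest foreground component
#'
#' Guarantees a single worm blob before thinning (one worm per dish). Ties
#' in area are broken towards the component whose minimal (row, col) pixel
#' is smallest.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with exactly one 8-connected component.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!length(lab$sizes))
    stop_mimizu("no worm found: mask has no foreground", "mimizu_no_worm")
  best <- which(lab$sizes == max(lab$sizes))
  if (length(best) > 1) {
    mp <- lab$min_pixel[best, , drop = FALSE]
    best <- best[order(mp[, 1], mp[, 2])[1]]
  }
  lab$labels == best
}
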