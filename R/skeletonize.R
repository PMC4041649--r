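#' Hilditch thinning of a binary worm mask
#'
#' Iteratively peels boundary pixels until the foreground is a one-pixel-wide
#' centerline (the skeleton), preserving 8-connectivity. A pixel `p` with
#' 8-neighbours `n1..n8` (clockwise from north) is deletable when all of
#' Hilditch's tests hold:
#'
#' 1. `2 <= B(p) <= 6`, where `B` counts foreground neighbours;
#' 2. the crossing number `A(p) = 1`, where `A` counts 0-to-1 transitions in
#'    the cyclic neighbour sequence;
#' 3. `n1 * n3 * n7 = 0` or `A(n1) != 1` (north/east/west test);
#' 4. `n1 * n3 * n5 = 0` or `A(n3) != 1` (north/east/south test).
#'
#' Each pass selects its candidates on the start-of-pass image using all
#' four tests, then deletes them sequentially in raster order (row-major;
#' reversed on every second pass to balance the scan's directional erosion
#' bias), re-verifying tests 1-2 on the current image before each deletion. The
#' re-verification makes every deletion a simple-point deletion, so the
#' number of 8-connected components is invariant; fixing the candidate set
#' at the start of the pass stops deletions from cascading along a two-pixel
#' wide limb within a single pass, which would otherwise erode it
#' end-to-end. Passes repeat until nothing is deleted; the result is a fixed
#' point of the operator (thinning is idempotent).
#'
#' @param mask Logical matrix, `TRUE` = worm; must contain at least one
#'   foreground pixel.
#' @return An object of class `worm_skeleton`: the skeleton pixel set (a
#'   subset of the mask foreground) with its 8-neighbourhood adjacency
#'   implied by pixel positions.
#' @export
hilditch_thin <- function(mask) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop("'mask' must be a logical matrix")
  if (!any(mask)) stop("cannot thin an empty mask")
  dm <- dim(mask)
  nrp <- dm[1] + 2L
  P <- matrix(0L, nrp, dm[2] + 2L)
  P[2:(dm[1] + 1), 2:(dm[2] + 1)] <- as.integer(mask)
  # padded linear-index offsets, clockwise from north
  ring <- c(-1L, nrp - 1L, nrp, nrp + 1L, 1L, -nrp + 1L, -nrp, -nrp - 1L)
  oN <- ring[1]; oE <- ring[3]; oS <- ring[5]; oW <- ring[7]
  crossings <- function(S, at) {
    V <- matrix(0L, length(at), 8L)
    for (k in 1:8) V[, k] <- S[at + ring[k]]
    rowSums(V == 0L & cbind(V[, -1, drop = FALSE], V[, 1]) == 1L)
  }
  pass <- 0L
  repeat {
    pass <- pass + 1L
    S0 <- P
    fg <- which(S0 == 1L)
    if (!length(fg)) break
    B0 <- S0[fg + oN] + S0[fg + ring[2]] + S0[fg + oE] + S0[fg + ring[4]] +
          S0[fg + oS] + S0[fg + ring[6]] + S0[fg + oW] + S0[fg + ring[8]]
    cand <- fg[B0 >= 2L & B0 <= 6L]
    if (length(cand)) cand <- cand[crossings(S0, cand) == 1L]
    if (length(cand)) {
      n1 <- S0[cand + oN]; n3 <- S0[cand + oE]
      n5 <- S0[cand + oS]; n7 <- S0[cand + oW]
      c3 <- (n1 * n3 * n7 == 0L) | (crossings(S0, cand + oN) != 1L)
      c4 <- (n1 * n3 * n5 == 0L) | (crossings(S0, cand + oE) != 1L)
      cand <- cand[c3 & c4]
    }
    if (!length(cand)) break
    rc <- cbind((cand - 1L) %% nrp, (cand - 1L) %/% nrp)
    ord <- order(rc[, 1], rc[, 2])
    if (pass %% 2L == 0L) ord <- rev(ord)  # alternate scan direction
    cand <- cand[ord]
    deleted <- FALSE
    for (i in cand) {
      v <- P[i + ring]
      B <- sum(v)
      if (B < 2L || B > 6L) next
      if (sum(v == 0L & c(v[-1], v[1]) == 1L) != 1L) next
      P[i] <- 0L
      deleted <- TRUE
    }
    if (!deleted) break
  }
  new_skeleton(which(P[2:(dm[1] + 1), 2:(dm[2] + 1)] == 1L), dm)
}

new_skeleton <- function(idx, dm) {
  structure(list(idx = sort(as.integer(idx)), dim = as.integer(dm)),
            class = "worm_skeleton")
}

#' @export
print.worm_skeleton <- function(x, ...) {
  cat(sprintf("worm_skeleton: %d pixel(s) in a %dx%d frame\n",
              length(x$idx), x$dim[2], x$dim[1]))
  invisible(x)
}

#' Skeleton pixels as coordinates
#'
#' @param skel A `worm_skeleton`.
#' @return Two-column matrix of `x`, `y` pixel coordinates (0-based),
#'   ordered by (row, col).
#' @export
skeleton_points <- function(skel) {
  stopifnot(inherits(skel, "worm_skeleton"))
  rc <- lin_to_rc(skel$idx, skel$dim)
  pts <- cbind(x = rc[, "c"] - 1, y = rc[, "r"] - 1)
  pts[order(rc[, "r"], rc[, "c"]), , drop = FALSE]
}

#' Convert a skeleton back to a logical mask
#'
#' @param x A `worm_skeleton`.
#' @param ... Unused.
#' @return Logical matrix of the skeleton's frame dimensions.
#' @export
as.matrix.worm_skeleton <- function(x, ...) {
  m <- matrix(FALSE, x$dim[1], x$dim[2])
  m[x$idx] <- TRUE
  m
}

# Degree of each skeleton pixel in the 8-neighbourhood (ordered as skel$idx).
skeleton_degree <- function(skel) {
  dm <- skel$dim
  m <- as.matrix.worm_skeleton(skel)
  P <- matrix(0L, dm[1] + 2L, dm[2] + 2L)
  P[2:(dm[1] + 1), 2:(dm[2] + 1)] <- as.integer(m)
  nrp <- dm[1] + 2L
  ring <- c(-1L, nrp - 1L, nrp, nrp + 1L, 1L, -nrp + 1L, -nrp, -nrp - 1L)
  rc <- lin_to_rc(skel$idx, dm)
  at <- rc_to_lin(rc[, "r"] + 1L, rc[, "c"] + 1L, c(nrp, dm[2] + 2L))
  deg <- integer(length(at))
  for (k in 1:8) deg <- deg + P[at + ring[k]]
  deg
}

# Weighted 8-neighbour adjacency of the skeleton as an igraph object.
# Vertices are positions in skel$idx; axial edges weigh 1, diagonal sqrt(2).
# With metric = "manhattan" a diagonal step counts 2 (a literal four-neighbour
# path metric, available for comparison).
skeleton_graph <- function(skel, metric = c("chamfer", "manhattan")) {
  metric <- match.arg(metric)
  dm <- skel$dim
  idx <- skel$idx
  rc <- lin_to_rc(idx, dm)
  diagw <- if (metric == "chamfer") sqrt(2) else 2
  edges <- NULL; w <- NULL
  steps <- list(list(c(0L, 1L), 1), list(c(1L, 0L), 1),
                list(c(1L, 1L), diagw), list(c(-1L, 1L), diagw))
  for (s in steps) {
    r2 <- rc[, "r"] + s[[1]][1]; c2 <- rc[, "c"] + s[[1]][2]
    ok <- r2 >= 1L & r2 <= dm[1] & c2 >= 1L & c2 <= dm[2]
    j <- match(rc_to_lin(r2[ok], c2[ok], dm), idx)
    keep <- !is.na(j)
    edges <- rbind(edges, cbind(which(ok)[keep], j[keep]))
    w <- c(w, rep(s[[2]], sum(keep)))
  }
  n <- length(idx)
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n)
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::E(g)$weight <- w
  }
  g
}

#' Skeleton endpoints
#'
#' Endpoints are skeleton pixels with at most one skeleton 8-neighbour; for
#' a clean worm skeleton these are the head and tail candidates.
#'
#' @param skel A `worm_skeleton`.
#' @return Two-column matrix of `x`, `y` coordinates, sorted by (row, col).
#' @export
find_endpoints <- function(skel) {
  stopifnot(inherits(skel, "worm_skeleton"))
  if (!length(skel$idx)) stop("empty skeleton")
  deg <- skeleton_degree(skel)
  rc <- lin_to_rc(skel$idx[deg <= 1L], skel$dim)
  rc <- rc[order(rc[, "r"], rc[, "c"]), , drop = FALSE]
  cbind(x = rc[, "c"] - 1, y = rc[, "r"] - 1)
}

#' Geodesic distance map along the skeleton
#'
#' Single-source shortest paths on the skeleton's 8-neighbour pixel graph,
#' with axial steps weighing 1 pixel and diagonal steps `sqrt(2)` (the
#' default chamfer metric). Distances are along the body, not straight-line:
#' on a U-shaped worm the far tip is geodesically distant even if the two
#' tips are Euclidean-close. Pixels in other components are `Inf`.
#'
#' @param skel A `worm_skeleton`.
#' @param source `c(x, y)` of a skeleton pixel.
#' @param metric `"chamfer"` (1 / sqrt(2), default) or `"manhattan"` (a
#'   literal four-neighbour metric where a diagonal step counts 2).
#' @return An object of class `geodesic_map` with per-pixel distances and
#'   predecessor links for path reconstruction.
#' @export
geodesic_map <- function(skel, source, metric = c("chamfer", "manhattan")) {
  stopifnot(inherits(skel, "worm_skeleton"))
  metric <- match.arg(metric)
  src <- match(pt_to_lin(source, skel$dim), skel$idx)
  if (is.na(src))
    stop(sprintf("source (%g, %g) is not a skeleton pixel",
                 source[1], source[2]))
  g <- skeleton_graph(skel, metric)
  dist <- as.numeric(igraph::distances(g, v = src))
  # predecessor links recovered from the distance field: u precedes v when
  # dist[u] + w(u,v) = dist[v]; ties resolved to the smallest (row, col) u
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  u <- c(el[, 1], el[, 2]); v <- c(el[, 2], el[, 1]); w2 <- c(w, w)
  ok <- is.finite(dist[u]) & abs(dist[u] + w2 - dist[v]) < 1e-9
  u <- u[ok]; v <- v[ok]
  rc <- lin_to_rc(skel$idx, skel$dim)
  ord <- order(v, rc[u, 1], rc[u, 2])
  u <- u[ord]; v <- v[ord]
  pred <- rep(NA_integer_, length(dist))
  first <- !duplicated(v)
  pred[v[first]] <- u[first]
  pred[src] <- NA_integer_
  pred[!is.finite(dist)] <- NA_integer_
  structure(list(skel = skel, source = src, dist = dist, pred = pred,
                 metric = metric),
            class = "geodesic_map")
}

#' @export
print.geodesic_map <- function(x, ...) {
  cat(sprintf(
    "geodesic_map: source (%g, %g), %d/%d pixels reachable, max %.2f px\n",
    skel_xy(x$skel, x$source)[1], skel_xy(x$skel, x$source)[2],
    sum(is.finite(x$dist)), length(x$dist),
    max(x$dist[is.finite(x$dist)])))
  invisible(x)
}

skel_xy <- function(skel, pos) {
  rc <- lin_to_rc(skel$idx[pos], skel$dim)
  unname(c(rc[, "c"] - 1, rc[, "r"] - 1))
}

#' Farthest skeleton pixel from the map source
#'
#' With the source at the tail, the geodesically farthest pixel defines the
#' head. Ties are broken towards the smallest (row, col).
#'
#' @param gmap A [geodesic_map()].
#' @return List with `point` (`c(x, y)`) and `distance` (pixels).
#' @export
farthest_point <- function(gmap) {
  stopifnot(inherits(gmap, "geodesic_map"))
  fin <- which(is.finite(gmap$dist))
  if (!length(fin)) stop("geodesic map has no finite distances")
  dmax <- max(gmap$dist[fin])
  at <- fin[gmap$dist[fin] >= dmax - 1e-9]
  rc <- lin_to_rc(gmap$skel$idx[at], gmap$skel$dim)
  best <- at[order(rc[, "r"], rc[, "c"])[1]]
  list(point = skel_xy(gmap$skel, best), distance = dmax)
}

# Reconstruct source -> target as positions in skel$idx.
reconstruct_path <- function(gmap, target_pos) {
  path <- target_pos
  while (!is.na(gmap$pred[path[1]])) path <- c(gmap$pred[path[1]], path)
  if (path[1] != gmap$source)
    stop("target is not reachable from the geodesic source")
  path
}

#' Midpoint of the geodesic path to a target
#'
#' Reconstructs the source-to-target path and returns the path pixel whose
#' cumulative distance is closest to half the total; exact ties go to the
#' pixel nearer the source. With source = tail and target = head this is the
#' body's center point.
#'
#' @param gmap A [geodesic_map()].
#' @param target `c(x, y)` of a reachable skeleton pixel.
#' @return `c(x, y)` of the midpoint pixel.
#' @export
midpoint_on_path <- function(gmap, target) {
  stopifnot(inherits(gmap, "geodesic_map"))
  tpos <- match(pt_to_lin(target, gmap$skel$dim), gmap$skel$idx)
  if (is.na(tpos) || !is.finite(gmap$dist[tpos]))
    stop(sprintf("target (%g, %g) is not reachable on the skeleton",
                 target[1], target[2]))
  path <- reconstruct_path(gmap, tpos)
  cum <- gmap$dist[path]
  half <- cum[length(cum)] / 2
  dev <- abs(cum - half)
  best <- which(dev <= min(dev) + 1e-9)[1]  # first = nearer the source
  skel_xy(gmap$skel, path[best])
}

#' Prune short spur branches from a skeleton
#'
#' Thinning leaves short side branches ("spurs") where the mask boundary is
#' rough; a spur from an endpoint to the nearest junction shorter than
#' `min_spur` pixels (geodesic length) is noise rather than a head or tail
#' segment. Spurs are removed iteratively, shortest first, until none
#' remain; the two endpoints of the longest endpoint-to-endpoint path are
#' never pruned, so the main body axis always survives.
#'
#' @param skel A `worm_skeleton`.
#' @param min_spur Minimum branch length (pixels) to keep; `0` is the
#'   identity. Default 5 px: shorter than any plausible head or tail
#'   segment at 0.2 mm/px, longer than typical thinning artifacts.
#' @return A pruned `worm_skeleton`.
#' @export
prune_spurs <- function(skel, min_spur = 5) {
  stopifnot(inherits(skel, "worm_skeleton"))
  if (min_spur < 0) stop("'min_spur' must be >= 0")
  if (min_spur == 0) return(skel)
  repeat {
    n <- length(skel$idx)
    if (n <= 2) return(skel)
    deg <- skeleton_degree(skel)
    eps <- which(deg <= 1L)
    if (length(eps) <= 2) return(skel)
    g <- skeleton_graph(skel)
    # protect the two tips of the longest endpoint-to-endpoint geodesic
    dmat <- igraph::distances(g, v = eps, to = eps)
    dmat[!is.finite(dmat)] <- -1
    far <- arrayInd(which.max(dmat), dim(dmat))
    protected <- c(eps[far[1]], eps[far[2]])
    rc <- lin_to_rc(skel$idx, skel$dim)
    spur <- NULL  # list(len, pixels)
    for (e in setdiff(eps, protected)) {
      path <- e; cur <- e; prev <- 0L; len <- 0
      repeat {
        nbrs <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (!length(nbrs)) { cur <- NA; break }       # isolated branch
        nxt <- nbrs[1]
        step <- if (sum(abs(rc[cur, ] - rc[nxt, ])) == 2L) sqrt(2) else 1
        len <- len + step
        if (deg[nxt] >= 3L) break                      # reached a junction
        if (deg[nxt] <= 1L) { cur <- NA; break }       # endpoint-to-endpoint
        path <- c(path, nxt); prev <- cur; cur <- nxt
      }
      if (is.na(cur[1])) next
      if (len < min_spur && (is.null(spur) || len < spur$len))
        spur <- list(len = len, pixels = path)
    }
    if (is.null(spur)) return(skel)
    skel <- new_skeleton(skel$idx[-spur$pixels], skel$dim)
  }
}
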