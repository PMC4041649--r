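# Independent oracles, deliberately written along different routes than the
# package implementations they check.

# 8-connected labelling by explicit stack-based flood fill.
oracle_flood_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (i in which(mask)) {
    r0 <- (i - 1L) %% nr + 1L; c0 <- (i - 1L) %/% nr + 1L
    if (lab[r0, c0] > 0L) next
    k <- k + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

oracle_component_count <- function(mask) max(oracle_flood_label(mask), 0L)

# Small-fragment filter by flood fill + per-label area tally.
oracle_fragment_filter <- function(mask, min_area) {
  lab <- oracle_flood_label(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Otsu by the naive definition: for every threshold t, split the raw values
# into {v < t} and {v >= t} and compute the between-class variance from the
# class means directly.
oracle_otsu <- function(values) {
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 1:255) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Single-source geodesic distances on a skeleton mask by label-correcting
# iteration (no priority queue): relax every 8-neighbour edge until no
# distance changes.
oracle_geodesic <- function(mask, source_rc) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  dist[source_rc[1], source_rc[2]] <- 0
  repeat {
    changed <- FALSE
    for (i in which(mask)) {
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      if (!is.finite(dist[r, c])) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !mask[r2, c2]) next
        w <- if (abs(dr) + abs(dc) == 2L) sqrt(2) else 1
        if (dist[r, c] + w < dist[r2, c2] - 1e-12) {
          dist[r2, c2] <- dist[r, c] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist
}

oracle_polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}
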