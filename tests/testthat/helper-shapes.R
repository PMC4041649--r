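# Small fixtures built in code.

mask_from_rc <- function(nr, nc, rc) {
  m <- matrix(FALSE, nr, nc)
  m[rc] <- TRUE
  m
}

hline_mask <- function(len = 20, nr = 5, row = 3, from = 3) {
  m <- matrix(FALSE, nr, from + len + 2)
  m[row, from:(from + len - 1)] <- TRUE
  m
}

diag_mask <- function(len = 11, pad = 2) {
  n <- len + 2 * pad
  m <- matrix(FALSE, n, n)
  for (i in seq_len(len)) m[pad + i, pad + i] <- TRUE
  m
}

# Random union-of-disks blob on a small grid (seed controlled by caller).
blob_mask <- function(nr = 45, nc = 45, n_disks = NULL) {
  m <- matrix(FALSE, nr, nc)
  if (is.null(n_disks)) n_disks <- sample(1:4, 1)
  for (b in seq_len(n_disks)) {
    r0 <- runif(1, 8, nr - 8); c0 <- runif(1, 8, nc - 8)
    rad <- runif(1, 2, 7)
    m[which(outer(seq_len(nr) - r0, seq_len(nc) - c0,
                  function(a, b) a^2 + b^2) <= rad^2)] <- TRUE
  }
  m
}

# Grayscale test frame: light background, dark capsule worm along a polyline
# given in (x, y) pixel coordinates.
worm_frame <- function(nr, nc, path_xy, half_width = 3,
                       bg = 200, fg = 50) {
  m <- matrix(FALSE, nr, nc)
  # densify the polyline to sub-pixel steps
  pts <- path_xy
  dense <- pts[1, , drop = FALSE]
  for (i in seq_len(nrow(pts) - 1)) {
    seg <- pts[i + 1, ] - pts[i, ]
    n <- max(2, ceiling(sqrt(sum(seg^2)) / 0.5))
    dense <- rbind(dense,
                   cbind(pts[i, 1] + seg[1] * seq_len(n) / n,
                         pts[i, 2] + seg[2] * seq_len(n) / n))
  }
  m <- mimizutrack:::stamp_disks(m, cbind(dense[, 2] + 1, dense[, 1] + 1),
                                 half_width)
  fr <- matrix(bg, nr, nc)
  fr[m] <- fg
  fr
}

# A short in-memory worm sequence: `offset` translates every frame by a
# constant; `drift` moves the worm by that much per frame.
static_sequence <- function(n = 10, nr = 120, nc = 160, offset = c(0, 0),
                            drift = c(0, 0)) {
  path <- cbind(x = seq(30, 120, length.out = 10),
                y = 40 + 25 * sin(seq(0, pi, length.out = 10)))
  frames <- lapply(seq_len(n) - 1, function(i) {
    worm_frame(nr, nc, sweep(path, 2, offset + i * drift, "+"))
  })
  frame_sequence(frames, interval = 1)
}

expect_same_skeleton <- function(a, b) {
  expect_identical(a$idx, b$idx)
  expect_identical(a$dim, b$dim)
}
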