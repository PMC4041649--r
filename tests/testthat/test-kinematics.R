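test_that("body_length converts geodesic pixels to mm", {
  skel <- hilditch_thin(hline_mask(101, nr = 5, row = 3, from = 3))
  cal <- calibration(0.2, 1)
  expect_equal(body_length(skel, c(2, 2), c(102, 2), cal), 20.0)
  dsk <- hilditch_thin(diag_mask(11))
  pts <- skeleton_points(dsk)
  expect_equal(body_length(dsk, pts[1, ], pts[nrow(pts), ], cal),
               10 * sqrt(2) * 0.2)
  # doubling the calibration doubles the length
  expect_equal(body_length(skel, c(2, 2), c(102, 2), calibration(0.4, 1)),
               40.0)
})

test_that("body_length is invariant under translation and rotation", {
  m <- matrix(FALSE, 30, 30)
  m[5, 4:14] <- TRUE; m[6:12, 14] <- TRUE        # an L-shaped body
  skel <- mimizutrack:::new_skeleton(which(m), dim(m))
  cal <- calibration()
  l0 <- body_length(skel, c(3, 4), c(13, 11), cal)
  mt <- matrix(FALSE, 30, 30)
  mt[15, 10:20] <- TRUE; mt[16:22, 20] <- TRUE   # translated by (6, 10)
  skt <- mimizutrack:::new_skeleton(which(mt), dim(mt))
  expect_equal(body_length(skt, c(9, 14), c(19, 21), cal), l0)
  mr <- matrix(FALSE, 30, 30)                    # rotated 90 degrees
  mr[4:14, 5] <- TRUE; mr[14, 6:12] <- TRUE
  skr <- mimizutrack:::new_skeleton(which(mr), dim(mr))
  expect_equal(body_length(skr, c(4, 3), c(11, 13), cal), l0)
  expect_error(body_length(skel, c(3, 4), c(25, 25), cal), "reachable")
})

test_that("velocities use Euclidean displacement over the frame interval", {
  tr <- trajectory(frame = 0:1, time_s = c(0, 1),
                   head = rbind(c(0, 0), c(3, 4)),
                   center = rbind(c(0, 0), c(0, 0)),
                   tail = rbind(c(5, 5), c(5, 5)),
                   length_mm = c(10, 10), status = c("seeded", "ok"))
  v <- velocities(tr, "head", calibration(0.2, 1))
  expect_equal(v$speed_mm_s, 1.0)           # 3-4-5 triangle: 5 px * 0.2 mm
  expect_equal(velocities(tr, "tail", calibration(0.2, 1))$speed_mm_s, 0)
  # doubling mm/px doubles speed; halving the frame spacing doubles it too
  expect_equal(velocities(tr, "head", calibration(0.4, 1))$speed_mm_s, 2.0)
  tr_fast <- tr
  tr_fast$time_s <- c(0, 0.5)
  expect_equal(velocities(tr_fast, "head", calibration(0.2, 0.5))$speed_mm_s,
               2.0)
  expect_error(velocities(tr[1, ], "head"), "at least two")
})

test_that("transitions touching unobserved frames are absent", {
  tr <- trajectory(frame = 0:3, time_s = 0:3,
                   head = cbind(c(0, 1, 1, 2), 0),
                   center = cbind(0, 0), tail = cbind(9, 9),
                   length_mm = 10,
                   status = c("seeded", "ok", "carried_forward", "ok"))
  v <- velocities(tr, "head", calibration(1, 1))
  expect_equal(is.na(v$speed_mm_s), c(FALSE, TRUE, TRUE))
  expect_equal(v$speed_mm_s[1], 1)
})

test_that("velocity of a reversed sequence is the reversed series", {
  withr::local_seed(21)
  n <- 15
  tr <- trajectory(frame = 0:(n - 1), time_s = 0:(n - 1),
                   head = cbind(cumsum(sample(-3:3, n, TRUE)),
                                cumsum(sample(-3:3, n, TRUE))),
                   center = cbind(0, 0), tail = cbind(0, 0),
                   length_mm = 10, status = c("seeded", rep("ok", n - 1)))
  fwd <- velocities(tr, "head")$speed_mm_s
  rev_tr <- tr
  rev_tr$head_x <- rev(tr$head_x); rev_tr$head_y <- rev(tr$head_y)
  rev_tr$status <- rep("ok", n)
  bwd <- velocities(rev_tr, "head")$speed_mm_s
  expect_equal(bwd, rev(fwd))
})

test_that("summarize_series computes mean, sample sd, max, min", {
  s <- summarize_series(c(1, 2, 3))
  expect_equal(unname(s), c(2, 1, 3, 1))
  s1 <- summarize_series(5)
  expect_equal(unname(s1), c(5, 0, 5, 5))
  expect_error(summarize_series(c(NA_real_, NA_real_)), "no present values")
  withr::local_seed(31)
  draws <- rnorm(1000, mean = 4.2, sd = 1.3)
  s2 <- summarize_series(draws)
  expect_lt(abs(s2[["mean"]] - 4.2), 3 * 1.3 / sqrt(1000))
  expect_lt(abs(s2[["sd"]] - 1.3), 3 * 1.3 / sqrt(2 * 999))
})

test_that("summarize_lengths reports the stretch range", {
  ls <- summarize_lengths(c(131.44, 150, 190.73, 160))
  expect_equal(ls$max_mm, 190.73)
  expect_equal(ls$min_mm, 131.44)
  expect_equal(ls$stretch_mm, 190.73 - 131.44)
  expect_equal(stretch_mm(220.38, 145.33), 75.05)
  expect_error(stretch_mm(1, 2), ">=")
})

test_that("compare_trajectories matches the textbook correlation formula", {
  mk <- function(hx, hy) trajectory(
    frame = seq_along(hx) - 1L, time_s = seq_along(hx) - 1,
    head = cbind(hx, hy), center = cbind(0, 0), tail = cbind(1, 1),
    length_mm = 10, status = c("seeded", rep("ok", length(hx) - 1)))
  a <- mk(c(3, 7, 2, 9, 5), c(1, 4, 2, 8, 6))
  # identical trajectories: r = 1 on both axes, zero velocity difference
  cmp <- compare_trajectories(a, a)
  h <- cmp[cmp$point == "head", ]
  expect_equal(h$pearson_r_x, 1.0)
  expect_equal(h$pearson_r_y, 1.0)
  expect_equal(h$mean_velocity_diff, 0.0)
  expect_equal(h$sd_velocity_diff, 0.0)
  # negated, mean-shifted x: r = -1
  b <- mk(20 - c(3, 7, 2, 9, 5), c(1, 4, 2, 8, 6))
  expect_equal(compare_trajectories(a, b)[1, "pearson_r_x"], -1.0)
  # direct covariance/sd formula on a small pair of series
  cset <- mk(c(2, 4, 3, 8, 7), c(5, 2, 6, 1, 9))
  got <- compare_trajectories(a, cset)[1, ]
  rx <- cov(a$head_x, cset$head_x) / (sd(a$head_x) * sd(cset$head_x))
  ry <- cov(a$head_y, cset$head_y) / (sd(a$head_y) * sd(cset$head_y))
  expect_equal(got$pearson_r_x, rx)
  expect_equal(got$pearson_r_y, ry)
})

test_that("compare_trajectories reports missing frames", {
  mk <- function(fr) trajectory(
    frame = fr, time_s = fr, head = cbind(fr, fr), center = cbind(0, 0),
    tail = cbind(1, 1), length_mm = 10,
    status = rep("ok", length(fr)))
  expect_error(compare_trajectories(mk(0:4), mk(0:3)), "4")
  expect_error(compare_trajectories(mk(0:2), mk(0:4)), "3, 4")
})

test_that("two-point references restrict the comparison to head and tail", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,time_s,head_x,head_y,tail_x,tail_y,length_mm,status",
               "0,0,0,0,9,9,,ok", "1,1,3,4,9,9,,ok", "2,2,5,8,8,9,,ok"), f)
  ref <- read_trajectory_csv(f)
  auto <- trajectory(frame = 0:2, time_s = 0:2,
                     head = rbind(c(0, 0), c(3, 4), c(5, 8)),
                     center = rbind(c(1, 1), c(2, 2), c(3, 3)),
                     tail = rbind(c(9, 9), c(9, 9), c(8, 9)),
                     length_mm = 10, status = c("seeded", "ok", "ok"))
  cmp <- compare_trajectories(auto, ref)
  expect_setequal(cmp$point, c("head", "tail"))
  expect_equal(cmp$pearson_r_x[cmp$point == "head"], 1.0)
})
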