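test_that("a one-pixel line is a fixed point of thinning", {
  m <- hline_mask(20)
  expect_identical(as.matrix(hilditch_thin(m)), m)
  d <- diag_mask(11)
  expect_identical(as.matrix(hilditch_thin(d)), d)
})

test_that("a filled 3x9 rectangle thins to its long-axis centerline", {
  m <- matrix(FALSE, 7, 13)
  m[3:5, 3:11] <- TRUE
  skel <- hilditch_thin(m)
  # frozen from an independent step-by-step execution of the deletion rules
  # on this instance: the middle row survives, retracted one pixel per end
  expected <- cbind(row = rep(4L, 7), col = 4:10)
  got <- which(as.matrix(skel), arr.ind = TRUE)
  expect_equal(unname(got[order(got[, 1], got[, 2]), ]), unname(expected))
})

test_that("a filled disk thins to a near-point skeleton, one component", {
  m <- matrix(FALSE, 17, 17)
  m[outer(1:17 - 9, 1:17 - 9, function(a, b) a^2 + b^2) <= 36] <- TRUE
  skel <- hilditch_thin(m)
  sm <- as.matrix(skel)
  expect_true(all(m[sm]))                       # subset of the disk
  expect_equal(oracle_component_count(sm), 1L)  # same as the input's
  deg <- mimizutrack:::skeleton_degree(skel)
  expect_lte(sum(deg > 2), 3)                   # at most a small central hub
})

test_that("thinning is idempotent, subset and component-preserving on blobs", {
  withr::local_seed(7)
  for (k in 1:25) {
    m <- blob_mask()
    if (!any(m)) next
    skel <- hilditch_thin(m)
    sm <- as.matrix(skel)
    expect_true(all(m[sm]))
    expect_same_skeleton(hilditch_thin(sm), skel)
    expect_equal(oracle_component_count(sm), oracle_component_count(m))
  }
  expect_error(hilditch_thin(matrix(FALSE, 3, 3)), "empty")
})

test_that("find_endpoints identifies line ends, isolated pixels and T-junctions", {
  line <- hline_mask(10, from = 3)
  eps <- find_endpoints(hilditch_thin(line))
  expect_equal(nrow(eps), 2)
  expect_equal(eps[, "x"], c(2, 11))  # 0-based extremes
  single <- mimizutrack:::new_skeleton(which(mask_from_rc(5, 5, cbind(3, 3))),
                                       c(5L, 5L))
  expect_equal(nrow(find_endpoints(single)), 1)
  # T-shape: two 7-px strokes crossing
  tm <- matrix(FALSE, 11, 11)
  tm[3, 3:9] <- TRUE
  tm[3:9, 6] <- TRUE
  tsk <- mimizutrack:::new_skeleton(which(tm), dim(tm))
  te <- find_endpoints(tsk)
  expect_equal(nrow(te), 3)
  # results sorted by (row, col)
  expect_true(!is.unsorted(te[, "y"]))
})

test_that("geodesic distances use 1/sqrt(2) weights", {
  line <- hline_mask(11, from = 3)
  skel <- hilditch_thin(line)
  g <- geodesic_map(skel, c(2, 2))   # left end (x=2, y=2)
  fp <- farthest_point(g)
  expect_equal(fp$distance, 10)
  expect_equal(fp$point, c(12, 2))
  dsk <- hilditch_thin(diag_mask(11))
  gd <- geodesic_map(dsk, skeleton_points(dsk)[1, ])
  expect_equal(farthest_point(gd)$distance, 10 * sqrt(2))
  # literal four-neighbour metric counts a diagonal step as 2
  gm <- geodesic_map(dsk, skeleton_points(dsk)[1, ], metric = "manhattan")
  expect_equal(farthest_point(gm)$distance, 20)
  expect_error(geodesic_map(skel, c(0, 0)), "not a skeleton pixel")
})

test_that("geodesic map matches the brute-force relaxation oracle", {
  # L-shaped skeleton: 6 axial + right-angle turn + 6 axial
  lm <- matrix(FALSE, 12, 12)
  lm[2, 2:7] <- TRUE
  lm[3:7, 7] <- TRUE
  skel <- mimizutrack:::new_skeleton(which(lm), dim(lm))
  g <- geodesic_map(skel, c(1, 1))  # (x=1, y=1) = [row 2, col 2]
  od <- oracle_geodesic(lm, c(2, 2))
  pts <- mimizutrack:::lin_to_rc(skel$idx, skel$dim)
  for (i in seq_along(skel$idx))
    expect_equal(g$dist[i], od[pts[i, "r"], pts[i, "c"]])
  # random blob skeletons vs oracle (also checks farthest_point's max)
  withr::local_seed(13)
  for (k in 1:6) {
    m <- blob_mask(35, 35, n_disks = 2)
    if (!any(m)) next
    skel <- hilditch_thin(m)
    src <- skeleton_points(skel)[1, ]
    g <- geodesic_map(skel, src)
    od <- oracle_geodesic(as.matrix(skel), c(src[2] + 1, src[1] + 1))
    pts <- mimizutrack:::lin_to_rc(skel$idx, skel$dim)
    for (i in seq_along(skel$idx))
      expect_equal(g$dist[i], od[pts[i, "r"], pts[i, "c"]])
    expect_equal(farthest_point(g)$distance,
                 max(od[is.finite(od) & as.matrix(skel)]))
  }
})

test_that("farthest_point breaks ties towards the smallest (row, col)", {
  line <- hline_mask(11, from = 3)          # x = 2..12 at y = 2
  skel <- hilditch_thin(line)
  g <- geodesic_map(skel, c(7, 2))          # source mid-line
  fp <- farthest_point(g)
  expect_equal(fp$distance, 5)
  expect_equal(fp$point, c(2, 2))           # left end wins the tie
})

test_that("midpoint_on_path halves the path with source-side ties", {
  line <- hline_mask(11, from = 3)
  skel <- hilditch_thin(line)
  g <- geodesic_map(skel, c(2, 2))
  expect_equal(midpoint_on_path(g, c(12, 2)), c(7, 2))  # 6th pixel, cum 5/10
  # 2-pixel skeleton: tie at half = 0.5 resolves to the source
  two <- mimizutrack:::new_skeleton(which(mask_from_rc(3, 4, rbind(c(2, 2), c(2, 3)))),
                                    c(3L, 4L))
  g2 <- geodesic_map(two, c(1, 1))
  expect_equal(midpoint_on_path(g2, c(2, 1)), c(1, 1))
  # L-shaped path, walked by hand: the shortest path cuts the corner with a
  # diagonal step, (1,1)..(5,1) then (6,2)..(6,6): total 4 + sqrt(2) + 4 =
  # 9.414. Half is 4.707; cumulative 4 at (5,1) and 5.414 at (6,2) tie in
  # deviation (0.707 each), so the source-side pixel (5,1) wins.
  lm <- matrix(FALSE, 12, 12)
  lm[2, 2:7] <- TRUE
  lm[3:7, 7] <- TRUE
  skel <- mimizutrack:::new_skeleton(which(lm), dim(lm))
  g3 <- geodesic_map(skel, c(1, 1))
  expect_equal(g3$dist[match(mimizutrack:::pt_to_lin(c(6, 6), skel$dim),
                             skel$idx)], 8 + sqrt(2))
  expect_equal(midpoint_on_path(g3, c(6, 6)), c(5, 1))
  expect_error(midpoint_on_path(g3, c(11, 11)), "not reachable")
})

test_that("prune_spurs removes short branches but never the main axis", {
  line <- hline_mask(50, nr = 20, row = 10, from = 3)
  skel <- hilditch_thin(line)
  expect_same_skeleton(prune_spurs(skel, 5), skel)     # clean: identity
  expect_same_skeleton(prune_spurs(skel, 1000), skel)  # protected main path
  # 50-px main path with a 3-px spur
  m <- line
  m[6:9, 20] <- TRUE  # vertical spur meeting the line's junction at [9, 20]
  spurred <- mimizutrack:::new_skeleton(which(m), dim(m))
  expect_equal(nrow(find_endpoints(spurred)), 3)
  pruned <- prune_spurs(spurred, 5)
  expect_equal(nrow(find_endpoints(pruned)), 2)
  expect_true(all(pruned$idx %in% spurred$idx))
  expect_true(all(skel$idx %in% pruned$idx))            # main axis intact
  expect_lte(length(pruned$idx), length(skel$idx) + 1)  # junction stub only
  expect_same_skeleton(prune_spurs(spurred, 0), spurred)  # min_spur 0
  # a branch at least min_spur long is kept
  keep <- prune_spurs(spurred, 2)
  expect_equal(nrow(find_endpoints(keep)), 3)
})
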