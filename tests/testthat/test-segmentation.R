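test_that("connected_regions partitions the above-threshold voxels", {
  for (seed in c(3, 17)) {
    m <- random_map(c(10, 10, 10), seed)
    thr <- 0.8
    regs <- connected_regions(m, thr)
    all_idx <- unlist(lapply(regs, `[[`, "idx"))
    # disjoint and covering: exhaustive voxel audit
    expect_false(any(duplicated(all_idx)))
    expect_setequal(all_idx, which(as.vector(m$values) > thr) - 1L)
    # regions come in descending order of their maximum density
    maxima <- vapply(regs, `[[`, numeric(1), "max_density")
    expect_true(all(diff(maxima) <= 0))
  }
  # empty result below any density
  z <- density_map(array(0, dim = c(4, 4, 4)))
  expect_length(connected_regions(z, 0.5), 0)
})

test_that("connected_regions matches a brute-force flood fill", {
  for (seed in c(5, 23, 41)) {
    m <- random_map(c(12, 12, 12), seed)
    for (thr in c(0.6, 0.85)) {
      regs <- connected_regions(m, thr)
      lab <- oracle_flood_fill(m$values, thr)
      # same number of components and identical membership partition
      expect_equal(length(regs), max(lab))
      got <- lapply(regs, function(r) sort(r$idx))
      want <- lapply(seq_len(max(lab)), function(l)
        sort(which(as.vector(lab) == l) - 1L))
      expect_setequal(
        vapply(got, paste, character(1), collapse = ","),
        vapply(want, paste, character(1), collapse = ","))
    }
  }
  # 6-connectivity differs from 26 where only diagonals touch
  v <- array(0, dim = c(3, 3, 1))
  v[1, 1, 1] <- 1; v[2, 2, 1] <- 1
  m <- density_map(v)
  expect_length(connected_regions(m, 0.5, connectivity = 26), 1)
  expect_length(connected_regions(m, 0.5, connectivity = 6), 2)
})

test_that("region count flips 2 -> 1 exactly at the two-Gaussian saddle", {
  d <- 6; res <- 8; sigma <- 0.225 * res       # sigma = 1.8 A
  m <- synthesize_map(two_blob_model(d), resolution = res, voxel_size = 0.5)
  saddle <- 2 * exp(-d^2 / (8 * sigma^2))      # closed form at x = d/2
  eps <- 0.02 * saddle
  above <- connected_regions(m, saddle + eps, min_points = 3)
  below <- connected_regions(m, saddle - eps, min_points = 3)
  expect_length(above, 2)
  expect_length(below, 1)
  # the merged region contains both peaks
  peaks <- rbind(xyz_to_grid(m, c(0, 0, 0)), xyz_to_grid(m, c(d, 0, 0)))
  peaks_lin <- apply(round(peaks), 1, ijk_to_lin_test, dims = dim(m$values))
  expect_true(all(peaks_lin %in% below[[1]]$idx))
})

test_that("lowering the threshold only merges regions, never splits", {
  # 6 A apart at sigma = 1.35 A: the saddle (~0.17 of peak) falls inside
  # the scanned threshold range, so the merge is observed
  m <- synthesize_map(two_blob_model(6), resolution = 6, voxel_size = 0.5)
  thresholds <- seq(0.9, 0.05, by = -0.05) * max(m$values)
  counts <- vapply(thresholds, function(t)
    length(connected_regions(m, t, min_points = 3)), integer(1))
  # each region at a lower level contains every higher-level region it
  # overlaps (no splits): verified via membership nesting on a pair
  r_hi <- connected_regions(m, thresholds[3], min_points = 3)
  r_lo <- connected_regions(m, thresholds[length(thresholds)],
                            min_points = 3)
  for (rh in r_hi) {
    containing <- Filter(function(rl) any(rh$idx %in% rl$idx), r_lo)
    expect_length(containing, 1)
    expect_true(all(rh$idx %in% containing[[1]]$idx))
  }
  # counts change only by merges and births: once down to 1, stays 1
  first1 <- which(counts == 1)[1]
  expect_true(all(counts[first1:length(counts)] == 1))
})

test_that("branch detection separates short stubs from long arms", {
  short <- tube_map(tube_with_arm_model(24, arm_len = 6))
  reg_s <- connected_regions(short, 0.35 * max(short$values))[[1]]
  reg_s <- detect_branching(reg_s, short, segmentation_params())
  expect_false(reg_s$is_branched)
  expect_equal(max(reg_s$branch_lengths), 6, tolerance = 2)

  long <- tube_map(tube_with_arm_model(24, arm_len = 15))
  reg_l <- connected_regions(long, 0.35 * max(long$values))[[1]]
  reg_l <- detect_branching(reg_l, long, segmentation_params())
  expect_true(reg_l$is_branched)
  expect_equal(max(reg_l$branch_lengths), 15, tolerance = 2)

  # plain tube: every off-path voxel is within the tube's own radius
  plain <- tube_map(tube_model(24))
  reg_p <- connected_regions(plain, 0.35 * max(plain$values))[[1]]
  reg_p <- detect_branching(reg_p, plain, segmentation_params())
  expect_false(reg_p$is_branched)
  expect_lt(max(c(0, reg_p$branch_lengths)), 4)

  # degenerate single-point region
  v <- array(0, dim = c(3, 3, 3)); v[2, 2, 2] <- 1
  reg_1 <- connected_regions(density_map(v), 0.5)[[1]]
  reg_1 <- detect_branching(reg_1, density_map(v), segmentation_params())
  expect_false(reg_1$is_branched)
  expect_length(reg_1$branch_lengths, 0)
})

test_that("grow_segments isolates continuous chains with ground truth", {
  # single blob: one region centred on the atom
  blob <- single_blob_map(resolution = 3)
  st <- grow_segments(blob, segmentation_params())
  expect_length(st$regions, 1)
  ctr <- colMeans(grid_to_xyz(blob, lin_to_ijk_matrix(st$regions[[1]]$idx,
                                                      dim(blob$values))))
  expect_lt(max(abs(ctr)), 0.75)

  # helix-loop-helix: one region whose envelope covers the true trace
  truth <- make_test_model("helix_loop_helix", 30)
  m <- synthesize_map(truth, resolution = 3)
  st2 <- grow_segments(m, segmentation_params())
  expect_length(st2$regions, 1)
  r <- st2$regions[[1]]
  rxyz <- grid_to_xyz(m, lin_to_ijk_matrix(r$idx, dim(m$values)))
  tc <- as.matrix(truth[truth$atom == "CA", c("x", "y", "z")])
  # >= 90% of the above-contour grid points within 2 A of the true trace
  # belong to the region (points below the final contour are outside any
  # region by definition)
  vox <- all_voxel_xyz(m)
  floor_t <- mean(m$values) + stats::sd(as.vector(m$values))
  near_trace <- which(min_d2_to_points(vox, tc) <= 4 &
                        as.vector(m$values) > floor_t) - 1L
  covered <- mean(near_trace %in% r$idx)
  expect_gte(covered, 0.9)
  # and no part of the chain is missed
  rxyz <- grid_to_xyz(m, lin_to_ijk_matrix(r$idx, dim(m$values)))
  expect_lt(max(sqrt(min_d2_to_points(tc, rxyz))), 2)
  expect_false(r$is_branched)

  # never accepts a branched region
  expect_true(all(!vapply(st2$regions, `[[`, logical(1), "is_branched")))

  # all-below-floor map: no regions
  flat <- density_map(array(0.01, dim = c(8, 8, 8)))
  expect_length(grow_segments(flat, segmentation_params())$regions, 0)
})

test_that("branch rejection keeps touching chains apart", {
  tcc <- make_test_model("two_chain_contact", 20, contact_distance = 3)
  m <- synthesize_map(tcc, resolution = 3)
  st <- grow_segments(m, segmentation_params())
  expect_length(st$regions, 2)
  for (ri in seq_along(st$regions)) {
    rxyz <- grid_to_xyz(m, lin_to_ijk_matrix(st$regions[[ri]]$idx,
                                             dim(m$values)))
    hits <- vapply(c("A", "B"), function(ch) {
      ca <- as.matrix(tcc[tcc$atom == "CA" & tcc$chain_id == ch,
                          c("x", "y", "z")])
      sum(vapply(seq_len(nrow(ca)), function(i)
        min(colSums((t(rxyz) - ca[i, ])^2)) < 1, logical(1)))
    }, numeric(1))
    # a region contains one chain's axis, never points of both
    expect_true(min(hits) == 0 && max(hits) > 0)
  }
})

test_that("masking removes a region but keeps its end caps", {
  mod <- tube_model(16)
  m <- tube_map(mod)
  st <- grow_segments(m, segmentation_params())
  r <- st$regions[[1]]
  expect_gt(length(r$end_caps), 0)
  st2 <- st
  st2$working_map <- m          # fresh copy to exercise mask_region alone
  st2 <- mask_region(st2, r)
  # the region body is gone at its threshold...
  regs_after <- connected_regions(st2$working_map, r$threshold)
  body <- setdiff(r$idx, r$end_caps)
  for (ra in regs_after) expect_false(any(body %in% ra$idx))
  # ...but end caps keep their original density
  expect_identical(st2$working_map$values[r$end_caps + 1L],
                   m$values[r$end_caps + 1L])
  # masking twice is idempotent
  st3 <- mask_region(st2, r)
  expect_identical(st3$working_map$values, st2$working_map$values)
})

test_that("fragment seeds are honoured and reconciled with the contour", {
  truth <- make_test_model("helix_loop_helix", 30)
  m <- synthesize_map(truth, resolution = 3)
  frag <- truth[truth$residue_index <= 8 & truth$atom == "CA", ]
  seeds <- seed_regions_from_fragments(m, list(frag),
                                       segmentation_params())
  expect_length(seeds, 1)
  # seed points all within 3 A of fragment atoms and above the floor
  sxyz <- grid_to_xyz(m, lin_to_ijk_matrix(seeds[[1]]$idx, dim(m$values)))
  fxyz <- as.matrix(frag[, c("x", "y", "z")])
  dmin <- vapply(seq_len(nrow(sxyz)), function(i)
    sqrt(min(colSums((t(fxyz) - sxyz[i, ])^2))), numeric(1))
  expect_true(all(dmin <= 3 + 1e-9))
  # seeded growth still converges to the same single region
  st <- grow_segments(m, segmentation_params(), seeds = seeds)
  expect_length(st$regions, 1)
  expect_false(st$regions[[1]]$is_branched)
})
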