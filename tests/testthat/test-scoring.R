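test_that("secondary structure is recognized from Calpha geometry", {
  # ideal 10-residue helix: all residues helical, pairs (i, i+4)
  hel <- helix_ca_model(10)
  ss <- assign_ss_from_ca(hel)
  expect_true(all(ss$labels$label == "helix"))
  expect_equal(nrow(ss$pairs), 6)           # n - 4 on the fixture
  expect_equal(ss$pairs$res_j - ss$pairs$res_i, rep(4L, 6))
  expect_true(all(ss$pairs$est_distance <= 3.5))

  # a lone extended strand has no ladder partner: zero pairs
  str <- make_test_model("extended_strand", 8)
  m_str <- atoms_to_ca_model_test(str)
  ss_str <- assign_ss_from_ca(m_str)
  expect_equal(nrow(ss_str$pairs), 0)
  expect_true(any(ss_str$labels$label == "strand"))

  # two antiparallel strands 4.8 A apart pair along the ladder
  a <- make_test_model("extended_strand", 6)
  b <- make_test_model("extended_strand", 6)
  b$z <- b$z + 4.8
  b$chain_id <- "B"
  two <- atoms_to_ca_model_test(dplyr::bind_rows(a, b))
  ss2 <- assign_ss_from_ca(two)
  sheet <- ss2$pairs[ss2$pairs$type == "sheet", ]
  expect_gt(nrow(sheet), 0)
  expect_true(all(sheet$est_distance <= 3.5))

  # too-short model: all loop, no partners
  tiny <- ca_model(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)))
  ss3 <- assign_ss_from_ca(tiny)
  expect_true(all(ss3$labels$label == "loop"))
  expect_equal(nrow(ss3$pairs), 0)
})

test_that("H-bond score counts good bonds fully and poor ones half", {
  hel <- helix_ca_model(10)
  expect_equal(hbond_score(hel), 6)
  # uniform 15% stretch keeps the helical arrangement but pushes every
  # bond past 3.5 A: each then counts half
  stretched <- helix_ca_model(10, scale = 1.15)
  sss <- assign_ss_from_ca(stretched)
  expect_equal(nrow(sss$pairs), 6)
  expect_true(all(sss$pairs$est_distance > 3.5 &
                    sss$pairs$est_distance <= 5.0))
  expect_equal(hbond_score(stretched), 3)
  # loop-only model scores zero
  loopy <- ca_model(cbind((0:6) * 3.8, c(0, 2, 0, -2, 0, 2, 0), 0))
  expect_equal(hbond_score(loopy), 0)
})

test_that("map-model correlation behaves like a correlation", {
  truth <- make_test_model("ideal_helix", 10)
  map <- synthesize_map(truth, resolution = 3)
  model <- atoms_to_ca_model_test(truth)
  cc <- map_model_cc(model, map)
  expect_gt(cc, 0.99)
  # linear rescaling of the map leaves CC unchanged
  map2 <- map
  map2$values <- 3.7 * map$values + 0.2
  expect_equal(map_model_cc(model, map2), cc, tolerance = 1e-9)
  # a model in pure noise decorrelates across seeds
  ccs <- vapply(1:5, function(s) {
    set.seed(s)
    nm <- density_map(array(stats::rnorm(24^3), dim = c(24, 24, 24)),
                      origin = c(-12, -12, -6), resolution_hint = 3)
    map_model_cc(model, nm)
  }, numeric(1))
  expect_lt(max(abs(ccs)), 0.1)
  # zero-variance mask errors
  flat <- density_map(array(1, dim = c(24, 24, 24)),
                      origin = c(-12, -12, -6), resolution_hint = 3)
  expect_error(map_model_cc(model, flat), "variance")
})

test_that("density-fit and combined scores follow their formulas", {
  expect_equal(density_fit_score(0.5, 7), 0)
  expect_equal(density_fit_score(0.5, 10000), 0)
  expect_equal(density_fit_score(0.6, 100), 10)
  expect_equal(density_fit_score(1.0, 4), 10)
  # strictly increasing in N above 0.5, decreasing below
  for (cc in c(0.6, 0.9)) {
    u <- density_fit_score(cc, c(1, 4, 16, 64))
    expect_true(all(diff(u) > 0))
  }
  for (cc in c(0.1, 0.4)) {
    u <- density_fit_score(cc, c(1, 4, 16, 64))
    expect_true(all(diff(u) < 0))
  }
  expect_equal(combined_score(0, 0, 10), 0)
  expect_equal(combined_score(5, 0.8, 25), 9)
  expect_equal(combined_score(2.5, 0.5, 100), 7.5)
  # breakdown internal consistency: T recomputed from stored parts
  truth <- make_test_model("ideal_helix", 10)
  map <- synthesize_map(truth, resolution = 3)
  br <- score_breakdown(atoms_to_ca_model_test(truth), map,
                        s_likelihood = 1.25)
  expect_equal(br$combined_T,
               combined_score(1.25, br$cc, br$n_residues),
               tolerance = 1e-9)
  expect_equal(br$density_fit_U, density_fit_score(br$cc, br$n_atoms),
               tolerance = 1e-9)
})

test_that("direction choice keeps the better-scoring chain", {
  truth <- make_test_model("ideal_helix", 10)
  map <- synthesize_map(truth, resolution = 3)
  fwd <- atoms_to_ca_model_test(truth)
  # identical models tie -> forward kept
  tie <- choose_direction(fwd, fwd, map)
  expect_equal(attr(tie, "direction"), "forward")
  # degraded H-bond geometry loses
  worse <- helix_ca_model(10, scale = 1.15)
  win <- choose_direction(fwd, worse, map)
  expect_equal(attr(win, "direction"), "forward")
  win2 <- choose_direction(worse, fwd, map)
  expect_equal(attr(win2, "direction"), "reverse")
  # antisymmetry: the same underlying model wins either way
  expect_equal(ca_xyz_test(win), ca_xyz_test(win2))
  # a copy shifted out of density loses on fit
  shifted <- fwd
  shifted$x <- shifted$x + 8
  expect_equal(attr(choose_direction(fwd, shifted, map), "direction"),
               "forward")
})

test_that("combine_models removes overlap and is idempotent", {
  truth <- make_test_model("helix_loop_helix", 20)
  map <- synthesize_map(truth, resolution = 3)
  full <- atoms_to_ca_model_test(truth)

  # single candidate passes through unchanged (up to chain lettering)
  one <- combine_models(list(full), map)
  expect_length(one, 1)
  expect_equal(ca_xyz_test(one[[1]]), ca_xyz_test(full))

  # exact duplicates collapse to one survivor
  dup <- combine_models(list(full, full), map)
  expect_length(dup, 1)

  # a short chain overlapping the middle of the long one is consumed
  short <- full[8:12, ]
  class(short) <- class(full)
  both <- combine_models(list(full, short), map)
  expect_equal(sum(vapply(both, nrow, integer(1))), nrow(full))

  # a lower-ranked chain overlapping at one end keeps only its
  # non-overlapping run if long enough
  tail8 <- full[13:20, ]
  tail8$x <- tail8$x + 0.5   # slightly worse fit, still overlapping
  class(tail8) <- class(full)
  res <- combine_models(list(full, tail8), map)
  expect_equal(sum(vapply(res, nrow, integer(1))), nrow(full))

  # idempotence: combining the output changes nothing
  again <- combine_models(both, map)
  expect_equal(lapply(again, ca_xyz_test), lapply(both, ca_xyz_test))

  # all output chains pairwise non-overlapping under the 2 A criterion
  if (length(res) > 1) {
    for (i in seq_along(res)) for (j in seq_along(res)) {
      if (i >= j) next
      d2 <- min_d2_to_points(ca_xyz_test(res[[i]]), ca_xyz_test(res[[j]]))
      expect_gt(min(d2), 4)
    }
  }
})

test_that("mean chain length averages residue counts", {
  m10 <- ca_model(cbind((0:9) * 3.8, 0, 0))
  m30 <- ca_model(cbind((0:29) * 3.8, 0, 0))
  expect_equal(mean_chain_length(list(m10, m30)), 20)
  m7 <- ca_model(cbind((0:6) * 3.8, 0, 0))
  expect_equal(mean_chain_length(list(m7)), 7)
  m16 <- ca_model(cbind((0:15) * 3.8, 0, 0))
  expect_equal(mean_chain_length(list(m16, m16, m16)), 16)
  expect_error(mean_chain_length(list()), "chains")
})
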