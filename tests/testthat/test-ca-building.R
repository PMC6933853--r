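# shared fixture: straight chain with Cbeta stubs every 3.8 A alternating
# up/down (as in an extended chain); each stub carries a short second
# side-chain atom so its density ridge extends clear of the main chain.
# Termini are glycine-like (no stub) so the chain ends are unambiguous.
poly_ala_fixture <- function(n_res = 8) {
  stub <- 2:(n_res - 1)
  side <- (-1)^stub
  ca <- tibble::tibble(atom = "CA", residue_index = seq_len(n_res),
                       chain_id = "A",
                       x = (seq_len(n_res) - 1) * 3.8, y = 0, z = 0)
  cb <- tibble::tibble(atom = "CB", residue_index = stub,
                       chain_id = "A",
                       x = ca$x[stub], y = side * 1.53, z = 0)
  cg <- tibble::tibble(atom = "CG", residue_index = stub,
                       chain_id = "A",
                       x = ca$x[stub], y = side * 2.9, z = 0)
  model <- dplyr::bind_rows(ca, cb, cg)
  map <- synthesize_map(model, resolution = 3, voxel_size = 0.5)
  reg <- connected_regions(map, 0.35 * max(map$values))[[1]]
  ep <- region_endpoints(reg, map)
  bones <- extract_bones(map, reg)
  path <- morph_path(ep$path, bones)
  list(model = model, map = map, region = reg, path = path, bones = bones,
       true_ca = as.matrix(ca[, c("x", "y", "z")]),
       true_cb = as.matrix(cb[, c("x", "y", "z")]))
}

test_that("side-chain bones are the bones away from the path", {
  fx <- poly_ala_fixture()
  side <- side_chain_bones(fx$bones, fx$path)
  d_path <- nearest_path_distance_test(as.matrix(side[, c("x", "y", "z")]),
                                       fx$path)
  expect_true(all(d_path > 1.5))
  # stub-tip bones survive
  d_tip <- min_d2_to_points(as.matrix(side[, c("x", "y", "z")]),
                            fx$true_cb)
  expect_lt(sqrt(min(d_tip)), 1.0)
  # exclusion radius 0 returns the input unchanged
  p0 <- ca_build_params(bones_path_exclusion = 0)
  expect_identical(side_chain_bones(fx$bones, fx$path, p0), fx$bones)
  # bones all on the path -> empty set
  axis_bones <- fx$bones[nearest_path_distance_test(
    as.matrix(fx$bones[, c("x", "y", "z")]), fx$path) < 1.0, ]
  expect_equal(nrow(side_chain_bones(axis_bones, fx$path)), 0)
})

test_that("Cbeta candidates recover the stub positions", {
  fx <- poly_ala_fixture()
  side <- side_chain_bones(fx$bones, fx$path)
  cb <- cbeta_candidates(fx$path, side)
  # one candidate per stub, each within 1.5 A of its true Cbeta
  expect_gte(nrow(cb), nrow(fx$true_cb) - 1)
  expect_lte(nrow(cb), nrow(fx$true_cb) + 1)
  d <- sqrt(min_d2_to_points(cb, fx$true_cb))
  expect_true(all(d < 1.5))
  # and every stub is represented by some candidate
  d_rev <- sqrt(min_d2_to_points(fx$true_cb, cb))
  expect_true(all(d_rev < 1.5))
  # no side bones -> no candidates
  empty <- side[0, ]
  expect_equal(nrow(cbeta_candidates(fx$path, empty)), 0)
})

test_that("distinct stubs give distinct candidates", {
  # two stubs 7.6 A apart on a plain tube
  ca <- tibble::tibble(atom = "CA", residue_index = 1:9, chain_id = "A",
                       x = (0:8) * 3.8 / 2, y = 0, z = 0)
  stub_x <- c(2 * 3.8 / 2, 6 * 3.8 / 2)
  cb <- tibble::tibble(atom = "CB", residue_index = c(3L, 7L),
                       chain_id = "A", x = stub_x, y = 1.53, z = 0)
  cg <- tibble::tibble(atom = "CG", residue_index = c(3L, 7L),
                       chain_id = "A", x = stub_x, y = 2.9, z = 0)
  mod <- dplyr::bind_rows(ca, cb, cg)
  map <- synthesize_map(mod, resolution = 3, voxel_size = 0.5)
  reg <- connected_regions(map, 0.3 * max(map$values))[[1]]
  ep <- region_endpoints(reg, map)
  bones <- extract_bones(map, reg)
  path <- morph_path(ep$path, bones)
  cands <- cbeta_candidates(path, side_chain_bones(bones, path))
  expect_equal(nrow(cands), 2)
  expect_gt(stats::dist(cands)[1], 2)
})

test_that("initial placement spaces Calphas at the target distance", {
  # straight 38 A path, no Cbeta: 11 sites at 3.8 +/- 0.2
  p38 <- straight_path(38, step = 0.2)
  m <- place_initial_ca(p38, params = ca_build_params())
  expect_equal(nrow(m), 11)
  d <- sqrt(rowSums(diff(as.matrix(m[, c("x", "y", "z")]))^2))
  expect_true(all(abs(d - 3.8) <= 0.2))
  # 3.8 A path: two sites at the ends
  p1 <- straight_path(3.8, step = 0.2)
  m1 <- place_initial_ca(p1)
  expect_equal(nrow(m1), 2)
  expect_equal(sqrt(sum((ca_xyz_test(m1)[2, ] - ca_xyz_test(m1)[1, ])^2)),
               3.8, tolerance = 0.25)
  # shorter than one spacing: single site
  expect_equal(nrow(place_initial_ca(straight_path(1.2, step = 0.2))), 1)
  # with Cbeta candidates every candidate ends up adjacent to a site: the
  # candidate centroid sits mid-arm (~2.2 A off the chain on this
  # fixture), so adjacency means < 3 A overall and in register (< 1 A
  # along the chain axis)
  fx <- poly_ala_fixture()
  cands <- cbeta_candidates(fx$path, side_chain_bones(fx$bones, fx$path))
  mq <- place_initial_ca(fx$path, cands)
  d_cb <- sqrt(min_d2_to_points(cands, ca_xyz_test(mq)))
  expect_true(all(d_cb < 3))
  dx <- vapply(seq_len(nrow(cands)), function(j)
    min(abs(ca_xyz_test(mq)[, 1] - cands[j, 1])), numeric(1))
  expect_true(all(dx < 1))
})

test_that("placement score is the stated weighted sum of squares", {
  flatmap <- density_map(array(1, dim = c(20, 10, 10)),
                         origin = c(-2, -2, -2))
  path <- straight_path(15, step = 0.25)
  # weights (1,0,0,0), two sites 4.8 A apart: score exactly 1
  m2 <- ca_model(rbind(c(0, 0, 0), c(4.8, 0, 0)))
  p1000 <- ca_build_params(score_weights = c(1, 0, 0, 0))
  expect_equal(ca_placement_score(m2, flatmap, path, params = p1000), 1.0)
  # ideal spacing on a flat map with adjacent Cbetas scores ~0
  n <- 5
  ideal <- ca_model(cbind((0:(n - 1)) * 3.8, 0, 0))
  cbs <- cbind((0:(n - 1)) * 3.8, 0.9, 0)
  sc0 <- ca_placement_score(ideal, flatmap, path, cbs)
  expect_lt(sc0, 0.05)
  # displacing one site along the path strictly increases the score
  shifted <- ideal
  shifted$x[3] <- shifted$x[3] + 1
  expect_gt(ca_placement_score(shifted, flatmap, path, cbs), sc0)
  # rigid-body invariance: rotate model, path and cbetas together
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(x) x %*% t(R)
  m_rot <- ca_model(rot(ca_xyz_test(ideal)))
  path_rot <- path_from_points(rot(path$points))
  sc_rot <- ca_placement_score(m_rot, flatmap, path_rot, rot(cbs))
  expect_equal(sc_rot, sc0, tolerance = 1e-6)
})

test_that("discrete optimization inserts, deletes and stops at optima", {
  fx <- poly_ala_fixture()
  cands <- cbeta_candidates(fx$path, side_chain_bones(fx$bones, fx$path))
  m0 <- place_initial_ca(fx$path, cands)
  # drop an interior residue: the insertion move must restore it
  gap <- m0[-4, ]
  class(gap) <- class(m0)
  opt <- optimize_ca(gap, fx$map, fx$path, cands, seed = 3)
  expect_equal(nrow(opt), nrow(m0))
  s_gap <- ca_placement_score(gap, fx$map, fx$path, cands)
  s_opt <- ca_placement_score(opt, fx$map, fx$path, cands)
  expect_lt(s_opt, s_gap)
  # a model the optimizer cannot improve is returned unchanged
  again <- optimize_ca(opt, fx$map, fx$path, cands, seed = 17)
  expect_equal(ca_xyz_test(again), ca_xyz_test(opt))
})

test_that("refinement honours its composite target", {
  # two residues at 4.2 A with zero density weight move toward 3.8
  m42 <- ca_model(rbind(c(0, 0, 0), c(4.2, 0, 0)))
  p_geo <- ca_build_params(refine_weights = c(start = 0.1, dist = 1,
                                              density = 0))
  flat <- density_map(array(1, dim = c(12, 8, 8)), origin = c(-2, -2, -2))
  ref <- refine_ca(m42, flat, p_geo)
  d_new <- sqrt(sum((ca_xyz_test(ref)[2, ] - ca_xyz_test(ref)[1, ])^2))
  expect_lt(abs(d_new - 3.8), abs(4.2 - 3.8))
  expect_equal(nrow(ref), 2)
  # a model at the target minimum stays put
  m38 <- ca_model(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  ref38 <- refine_ca(m38, flat, p_geo)
  expect_equal(ca_xyz_test(ref38), ca_xyz_test(m38), tolerance = 1e-4)
  # the density term pulls an offset model toward the tube axis
  tube <- tube_map(tube_model(20))
  n <- 5
  off_model <- ca_model(cbind(2 + (0:(n - 1)) * 3.8, 0.5, 0))
  refT <- refine_ca(off_model, tube, ca_build_params())
  expect_lt(mean(abs(ca_xyz_test(refT)[, 2])), 0.5)
  # no residue moves more than the cap
  shift <- sqrt(rowSums((ca_xyz_test(refT) - ca_xyz_test(off_model))^2))
  expect_true(all(shift <= ca_build_params()$max_refine_shift + 1e-9))
})

test_that("splicing replaces overlapping runs and only those", {
  n <- 20
  base <- ca_model(cbind((0:(n - 1)) * 3.8, 0, 0))
  # fragment coincident with residues 5-14, jittered well under the cut
  frag_ca <- ca_xyz_test(base)[5:14, ] +
    matrix(c(0.2, -0.1, 0.15), 10, 3, byrow = TRUE)
  frag <- tibble::tibble(atom = "CA", residue_index = 1:10,
                         chain_id = "H",
                         x = frag_ca[, 1], y = frag_ca[, 2],
                         z = frag_ca[, 3])
  sp <- splice_ss(base, list(frag))
  expect_equal(nrow(sp), n)
  expect_true(all(sp$spliced[5:14]))
  expect_false(any(sp$spliced[c(1:4, 15:20)]))
  expect_equal(ca_xyz_test(sp)[5:14, ], frag_ca, tolerance = 1e-9)
  # junction spacing stays physical
  d <- sqrt(rowSums(diff(ca_xyz_test(sp))^2))
  expect_true(all(d < 4.8))

  # fragment far away: nothing happens
  far <- frag
  far$y <- far$y + 50
  expect_equal(splice_ss(base, list(far)), base)

  # single-residue overlap is not a crossover
  one <- frag[5, ]
  expect_equal(splice_ss(base, list(one)), base)

  # a reversed fragment still splices (direction-agnostic overlap)
  rev_frag <- frag[10:1, ]
  rev_frag$residue_index <- 1:10
  sp_rev <- splice_ss(base, list(rev_frag))
  expect_true(any(sp_rev$spliced))
})

test_that("helix template search finds helices and ignores noise", {
  h <- make_test_model("ideal_helix", 12)
  hmap <- synthesize_map(h, resolution = 3)
  fr <- find_helices(hmap, 3)
  expect_length(fr, 1)
  fca <- as.matrix(fr[[1]][fr[[1]]$atom == "CA", c("x", "y", "z")])
  # axis recovered: all placed Calphas close to the true spiral, and the
  # centroid sits on the true axis (x = y = 0) within 1 A
  tc <- as.matrix(h[h$atom == "CA", c("x", "y", "z")])
  expect_lt(max(sqrt(min_d2_to_points(fca, tc))), 1.5)
  expect_lt(sqrt(sum(colMeans(fca)[1:2]^2)), 1)

  # seeded pure-noise map: nothing above the cutoff
  set.seed(31)
  nm <- density_map(array(stats::rnorm(27000), dim = c(30, 30, 30)),
                    resolution_hint = 3)
  expect_length(find_helices(nm, 3), 0)

  # two parallel helices 10 A apart are found separately
  h2 <- make_test_model("ideal_helix", 12)
  h2$x <- h2$x + 10
  bmap <- synthesize_map(dplyr::bind_rows(
    h, dplyr::mutate(h2, chain_id = "B")), resolution = 3)
  fr2 <- find_helices(bmap, 3)
  expect_length(fr2, 2)
  ctrs <- t(vapply(fr2, function(f)
    colMeans(as.matrix(f[f$atom == "CA", c("x", "y", "z")])), numeric(3)))
  expect_equal(unname(abs(ctrs[1, 1] - ctrs[2, 1])), 10, tolerance = 1.5)
})

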