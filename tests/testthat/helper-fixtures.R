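# Synthetic fixtures with known geometry, built in code at test time.

# a straight tube of density along +x: closely spaced pseudo-atoms give a
# smooth cylinder whose axis (y = z = 0 at the given offset) is known
tube_model <- function(length_A = 20, spacing = 1, origin = c(0, 0, 0),
                       chain_id = "T") {
  n <- floor(length_A / spacing) + 1
  tibble::tibble(atom = "CA", residue_index = seq_len(n),
                 chain_id = chain_id,
                 x = origin[1] + (seq_len(n) - 1) * spacing,
                 y = origin[2], z = origin[3])
}

# tube along +x with one perpendicular arm (along +y) of the given length
# attached at its midpoint
tube_with_arm_model <- function(tube_len = 24, arm_len = 6, spacing = 1) {
  tube <- tube_model(tube_len, spacing, chain_id = "T")
  mid <- tube_len / 2
  n_arm <- floor(arm_len / spacing)
  arm <- tibble::tibble(atom = "CA", residue_index = seq_len(n_arm),
                        chain_id = "S",
                        x = mid, y = seq_len(n_arm) * spacing, z = 0)
  dplyr::bind_rows(tube, arm)
}

tube_map <- function(model, resolution = 3, voxel = 1, padding = 5) {
  synthesize_map(model, resolution = resolution, voxel_size = voxel,
                 padding = padding)
}

# two isolated Gaussian blobs d apart along x (non-consecutive residues, so
# no backbone interpolation links them)
two_blob_model <- function(d = 10) {
  tibble::tibble(atom = "CA", residue_index = c(1L, 5L),
                 chain_id = c("A", "B"),
                 x = c(0, d), y = 0, z = 0)
}

single_blob_map <- function(resolution = 3, voxel = 1) {
  m <- tibble::tibble(atom = "CA", residue_index = 1L, chain_id = "A",
                      x = 0, y = 0, z = 0)
  synthesize_map(m, resolution = resolution, voxel_size = voxel)
}

# straight trace_path through the given points (n x 3 matrix)
path_from_points <- function(pts) {
  structure(list(points = pts, ijk = NULL, region_id = NA_integer_,
                 weight = NA_real_,
                 unweighted_length = if (nrow(pts) > 1)
                   sum(sqrt(rowSums(diff(pts)^2))) else 0),
            class = "trace_path")
}

straight_path <- function(length_A, step = 0.5, origin = c(0, 0, 0)) {
  s <- seq(0, length_A, by = step)
  if (s[length(s)] < length_A) s <- c(s, length_A)
  path_from_points(cbind(origin[1] + s, origin[2], origin[3]))
}

# seeded random small map for oracle comparisons
random_map <- function(dims, seed, positive = TRUE) {
  set.seed(seed)
  v <- array(stats::runif(prod(dims)), dim = dims)
  density_map(v, voxel_size = 1, origin = c(0, 0, 0), resolution_hint = 3)
}

# the whole grid as one region (for path oracles on small maps)
whole_grid_region <- function(map) {
  n <- length(map$values)
  connected_regions(map, min(map$values) - 1, min_points = 1)[[1]]
}

# distances between consecutive CA atoms of one chain in an atom tibble
consecutive_ca_dist <- function(atoms, chain = NULL) {
  ca <- atoms[atoms$atom == "CA", ]
  if (!is.null(chain)) ca <- ca[ca$chain_id == chain, ]
  ca <- ca[order(ca$residue_index), ]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  sqrt(rowSums(diff(xyz)^2))
}

# ideal helix ca_model (for scoring tests), optionally uniformly scaled
helix_ca_model <- function(n, scale = 1) {
  atoms <- make_test_model("ideal_helix", n)
  ca <- as.matrix(atoms[atoms$atom == "CA", c("x", "y", "z")]) * scale
  ca_model(ca)
}

# 0-based linear index <-> 0-based (i,j,k), mirroring the package convention
ijk_to_lin_test <- function(ijk, dims) {
  as.integer(ijk[1] + dims[1] * (ijk[2] + dims[2] * ijk[3]))
}
lin_to_ijk_test <- function(lin, dims) {
  c(lin %% dims[1], (lin %/% dims[1]) %% dims[2], lin %/% (dims[1] * dims[2]))
}

# matrix version of the 0-based linear -> (i,j,k) conversion
lin_to_ijk_matrix <- function(lin, dims) {
  cbind(lin %% dims[1], (lin %/% dims[1]) %% dims[2],
        lin %/% (dims[1] * dims[2]))
}

# minimum squared distance from each row of P to the point set Q
min_d2_to_points <- function(P, Q) {
  out <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(Q))) {
    d2 <- (P[, 1] - Q[i, 1])^2 + (P[, 2] - Q[i, 2])^2 +
      (P[, 3] - Q[i, 3])^2
    out <- pmin(out, d2)
  }
  out
}

# Angstrom coordinates of every voxel of a map (0-based grid order)
all_voxel_xyz <- function(map) {
  d <- dim(map$values)
  grid <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  grid_to_xyz(map, grid)
}

# local aliases for quantities the tests recompute from public structures
ca_xyz_test <- function(m) as.matrix(m[, c("x", "y", "z")])
nearest_path_distance_test <- function(pts, path) {
  pp <- path$points
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((pp[, 1] - pts[i, 1])^2 + (pp[, 2] - pts[i, 2])^2 +
               (pp[, 3] - pts[i, 3])^2))
  }, numeric(1))
}

# atom tibble (CA/CB rows, possibly several chains) -> one ca_model tibble
atoms_to_ca_model_test <- function(atoms) {
  ca <- atoms[atoms$atom == "CA", ]
  ca <- ca[order(ca$chain_id, ca$residue_index), ]
  cb <- atoms[atoms$atom == "CB", ]
  m <- ca_model(as.matrix(ca[, c("x", "y", "z")]), chain_id = ca$chain_id)
  j <- match(paste(ca$chain_id, ca$residue_index),
             paste(cb$chain_id, cb$residue_index))
  m$cb_x <- cb$x[j]; m$cb_y <- cb$y[j]; m$cb_z <- cb$z[j]
  m
}
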