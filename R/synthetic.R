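#' Generate ground-truth test models
#'
#' Builds small Calpha/Cbeta coordinate sets with known geometry for
#' validating every downstream stage without experimental data. Consecutive
#' Calpha-Calpha distances are 3.8 A by construction.
#'
#' Kinds:
#' * `ideal_helix`: canonical alpha-helix Calpha geometry (1.5 A rise,
#'   100 degree twist per residue; radius solved so the Calpha-Calpha
#'   distance is exactly 3.8 A), Cbeta pointing outward.
#' * `extended_strand`: pleated extended chain (3.3 A rise, alternating
#'   pleat), Cbeta alternating up/down.
#' * `helix_loop_helix`: two antiparallel helices joined by a circular-arc
#'   loop of six residues with exact 3.8 A chords; helix axes end up roughly
#'   10-11 A apart, typical of packed helices.
#' * `two_chain_contact`: two extended chains whose Cbeta atoms face each
#'   other and approach to `contact_distance`, to exercise branch rejection.
#'
#' @param kind One of `"ideal_helix"`, `"extended_strand"`,
#'   `"helix_loop_helix"`, `"two_chain_contact"`.
#' @param n_residues Total number of residues (>= 3; split across chains for
#'   `two_chain_contact`).
#' @param seed Integer seed (the constructions are deterministic; the seed is
#'   part of the interface so callers can treat all fixtures uniformly).
#' @param contact_distance Cbeta-tip separation in Angstroms for
#'   `two_chain_contact`.
#' @return A tibble of atom records: `atom` ("CA"/"CB"), `residue_index`,
#'   `chain_id`, `x`, `y`, `z` (Angstroms).
#' @export
make_test_model <- function(kind, n_residues, seed = 1L,
                            contact_distance = 3) {
  if (n_residues < 3) stop("n_residues must be >= 3", call. = FALSE)
  kind <- match.arg(kind, c("ideal_helix", "extended_strand",
                            "helix_loop_helix", "two_chain_contact"))
  switch(kind,
    ideal_helix = helix_atoms(n_residues),
    extended_strand = strand_atoms(n_residues, chain_id = "A"),
    helix_loop_helix = hlh_atoms(n_residues),
    two_chain_contact = two_chain_atoms(n_residues, contact_distance)
  )
}

CA_CA <- 3.8
HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
# radius giving an exact 3.8 A Calpha step at the canonical rise and twist
HELIX_RADIUS <- sqrt(CA_CA^2 - HELIX_RISE^2) / (2 * sin(HELIX_TWIST / 2))

helix_ca <- function(n, phase0 = 0) {
  i <- seq_len(n) - 1
  phi <- phase0 + i * HELIX_TWIST
  cbind(HELIX_RADIUS * cos(phi), HELIX_RADIUS * sin(phi), HELIX_RISE * i)
}

atoms_tibble <- function(ca, cb = NULL, chain_id = "A", start_resno = 1L) {
  n <- nrow(ca)
  resno <- start_resno + seq_len(n) - 1L
  out <- tibble::tibble(atom = "CA", residue_index = as.integer(resno),
                        chain_id = chain_id,
                        x = ca[, 1], y = ca[, 2], z = ca[, 3])
  if (!is.null(cb)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      atom = "CB", residue_index = as.integer(resno), chain_id = chain_id,
      x = cb[, 1], y = cb[, 2], z = cb[, 3]))
  }
  dplyr::arrange(out, .data$chain_id, .data$residue_index,
                 .data$atom)
}

helix_atoms <- function(n) {
  ca <- helix_ca(n)
  radial <- ca
  radial[, 3] <- 0
  radial <- radial / sqrt(rowSums(radial^2))
  # Cbeta points outward from the axis, tilted slightly toward N-term
  dir <- radial
  dir[, 3] <- -0.44
  dir <- dir / sqrt(rowSums(dir^2))
  atoms_tibble(ca, ca + 1.53 * dir)
}

strand_ca <- function(n, origin = c(0, 0, 0), direction = 1) {
  rise <- 3.3
  pleat <- sqrt(CA_CA^2 - rise^2) / 2
  i <- seq_len(n) - 1
  cbind(origin[1] + direction * rise * i,
        origin[2] + pleat * (-1)^i,
        origin[3] + 0)
}

strand_atoms <- function(n, chain_id = "A", origin = c(0, 0, 0),
                         direction = 1, cb_dir = c(0, 0, 1)) {
  ca <- strand_ca(n, origin, direction)
  i <- seq_len(n) - 1
  cb <- ca + outer((-1)^i, 1.53 * cb_dir / sqrt(sum(cb_dir^2)))
  atoms_tibble(ca, cb, chain_id = chain_id)
}

hlh_atoms <- function(n) {
  n_loop <- if (n >= 14) 6L else max(3L, n - 8L)
  n1 <- (n - n_loop) %/% 2
  n2 <- n - n_loop - n1
  k <- n_loop - 1L                       # arc steps within the loop
  theta <- pi / k                        # loop spans a semicircle
  R <- CA_CA / (2 * sin(theta / 2))      # exact 3.8 A chords on the arc

  h1 <- helix_ca(n1)
  last1 <- h1[n1, ]
  centre <- last1 + c(R, 0, CA_CA)
  alpha <- pi - theta * (0:k)
  loop <- cbind(centre[1] + R * cos(alpha),
                centre[2],
                centre[3] + R * sin(alpha))
  l_end <- loop[k + 1, ]
  # second helix descends; first Calpha placed 3.8 A below the loop end
  h2 <- helix_ca(n2)
  h2[, 3] <- -h2[, 3]
  h2 <- sweep(h2, 2, c(l_end[1] - HELIX_RADIUS, l_end[2], l_end[3] - CA_CA),
              `+`)
  ca <- rbind(h1, loop, h2)

  # Cbeta: outward from the local chain using a smoothed normal
  cb <- ca_pseudo_cb(ca)
  atoms_tibble(ca, cb)
}

# Cbeta stub direction from local Calpha geometry: perpendicular to the
# chain tangent, away from the local centre of curvature.
ca_pseudo_cb <- function(ca) {
  n <- nrow(ca)
  cb <- ca
  for (i in seq_len(n)) {
    p <- ca[max(1, i - 1), ]; q <- ca[i, ]; r <- ca[min(n, i + 1), ]
    t_vec <- r - p
    bis <- (p - q) + (r - q)            # toward the centre of curvature
    perp <- bis - t_vec * sum(bis * t_vec) / max(sum(t_vec^2), 1e-9)
    if (sqrt(sum(perp^2)) < 1e-6) {     # straight stretch: any normal
      perp <- c(-t_vec[2], t_vec[1], 0)
      if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
    }
    perp <- perp / sqrt(sum(perp^2))
    cb[i, ] <- q - 1.53 * perp          # away from curvature centre
  }
  cb
}

two_chain_atoms <- function(n, contact_distance) {
  na <- n %/% 2
  nb <- n - na
  gap <- 2 * 1.53 + contact_distance    # Calpha-plane separation in z
  a <- strand_atoms(na, chain_id = "A", origin = c(0, 0, 0),
                    cb_dir = c(0, 0, 1))
  # B mirrored above A so that +z-facing stubs of A meet -z-facing stubs of
  # B head-on at exactly contact_distance
  b <- strand_atoms(nb, chain_id = "B", origin = c(0, 0, gap),
                    cb_dir = c(0, 0, -1))
  out <- dplyr::bind_rows(a, b)
  out$residue_index <- as.integer(out$residue_index)
  out
}

#' Synthesize a cryo-EM-like density map from a model
#'
#' Each atom contributes an isotropic Gaussian of standard deviation
#' `sigma_factor * resolution` (default factor 0.225, approximating the
#' point-spread of a map truncated at the stated resolution) with equal
#' amplitude per atom. Optional i.i.d. Gaussian noise with standard deviation
#' `noise_sigma` times the peak noise-free density is added afterwards,
#' generated from `seed`. Deterministic given its arguments; with
#' `noise_sigma = 0` the output is seed-independent.
#'
#' @param model Atom tibble as from [make_test_model()] (any atom names).
#' @param resolution Nominal resolution in Angstroms (> 0).
#' @param voxel_size Grid spacing in Angstroms.
#' @param noise_sigma Noise level as a fraction of the peak noise-free
#'   density (>= 0).
#' @param seed Integer seed for the noise stream.
#' @param padding Angstroms of empty border around the model.
#' @param sigma_factor Gaussian width as a fraction of `resolution`.
#' @param backbone_interp Insert pseudo-atoms along consecutive
#'   Calpha-Calpha bonds (two per bond, emulating the intervening N/C/O
#'   main-chain atoms) so backbone density is continuous, as it is in
#'   experimental maps. Bonds are interpolated only between residues with
#'   consecutive indices in the same chain.
#' @return A [density_map()] with `resolution_hint = resolution`.
#' @export
synthesize_map <- function(model, resolution, voxel_size = 1,
                           noise_sigma = 0, seed = 1L, padding = 5,
                           sigma_factor = 0.225, backbone_interp = TRUE) {
  stopifnot(nrow(model) > 0, resolution > 0, noise_sigma >= 0, padding >= 0)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  if (backbone_interp && all(c("atom", "chain_id", "residue_index") %in%
                               names(model))) {
    xyz <- rbind(xyz, backbone_fill_points(model))
  }
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  origin <- lo
  sigma <- sigma_factor * resolution
  cutoff <- 4 * sigma
  values <- array(0, dim = dims)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * voxel_size)
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    rng <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - p[a]) <= cutoff)
    })
    if (any(lengths(rng) == 0)) next
    gx <- exp(-(ax[[1]][rng[[1]]] - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - p[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - p[3])^2 / (2 * sigma^2))
    values[rng[[1]], rng[[2]], rng[[3]]] <-
      values[rng[[1]], rng[[2]], rng[[3]]] + outer(gx, outer(gy, gz))
  }
  if (noise_sigma > 0) {
    peak <- max(values)
    noise <- with_local_seed(seed, {
      stats::rnorm(prod(dims), sd = noise_sigma * peak)
    })
    values <- values + array(noise, dim = dims)
  }
  density_map(values, voxel_size = voxel_size, origin = origin,
              resolution_hint = resolution)
}

# interpolated points along consecutive CA-CA bonds within each chain
backbone_fill_points <- function(model, k = 2L) {
  ca <- model[model$atom == "CA", , drop = FALSE]
  out <- list()
  for (ch in split(ca, ca$chain_id)) {
    ch <- ch[order(ch$residue_index), , drop = FALSE]
    if (nrow(ch) < 2) next
    consec <- which(diff(ch$residue_index) == 1L)
    for (i in consec) {
      p <- c(ch$x[i], ch$y[i], ch$z[i])
      q <- c(ch$x[i + 1], ch$y[i + 1], ch$z[i + 1])
      for (f in seq_len(k) / (k + 1)) {
        out[[length(out) + 1L]] <- (1 - f) * p + f * q
      }
    }
  }
  if (length(out) == 0) matrix(numeric(0), 0, 3) else do.call(rbind, out)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Write a Calpha/Cbeta model as PDB
#'
#' Emits standard ATOM records (CA, and CB where present), one chain per
#' traced segment, residues numbered sequentially within each chain. Accepts
#' either an atom tibble (as from [make_test_model()]) or a `ca_model`
#' (as from [trace_and_build()]).
#'
#' @param model Atom tibble or `ca_model` tibble.
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_ca_model <- function(model, path) {
  atoms <- if (inherits(model, "ca_model")) ca_model_to_atoms(model) else model
  atoms <- dplyr::arrange(atoms, .data$chain_id, .data$residue_index,
                          .data$atom)
  n <- nrow(atoms)
  if (n == 0) stop("empty model", call. = FALSE)
  # residue name must be consistent within a residue: ALA where a CB exists
  key <- paste(atoms$chain_id, atoms$residue_index)
  has_cb <- tapply(atoms$atom == "CB", key, any)[key]
  resid <- ifelse(has_cb, "ALA", "GLY")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$residue_index,
                   chain = atoms$chain_id,
                   resid = resid,
                   elety = atoms$atom,
                   eleno = seq_len(n))
  invisible(path)
}

#' Read a Calpha/Cbeta model from PDB
#'
#' Keeps CA and CB ATOM records only.
#'
#' @param path PDB file path.
#' @return Atom tibble with columns `atom`, `residue_index`, `chain_id`,
#'   `x`, `y`, `z`.
#' @export
read_ca_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$elety %in% c("CA", "CB") & at$type == "ATOM", , drop = FALSE]
  tibble::tibble(atom = at$elety,
                 residue_index = as.integer(at$resno),
                 chain_id = ifelse(is.na(at$chain), "A", at$chain),
                 x = at$x, y = at$y, z = at$z)
}
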