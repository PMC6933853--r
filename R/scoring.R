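#' Hydrogen-bond scoring parameters
#'
#' @param good_cutoff Heavy-atom distance up to which an H-bond counts as
#'   good, Angstroms (default 3.5).
#' @param poor_weight Weight of poor H-bonds (partners in a helical or
#'   sheet arrangement but beyond `good_cutoff`; default 0.5).
#' @param poor_max Upper distance bound for a poor H-bond, Angstroms.
#' @return An `hbond_params` list.
#' @export
hbond_params <- function(good_cutoff = 3.5, poor_weight = 0.5,
                         poor_max = 5.0) {
  stopifnot(good_cutoff > 0, poor_max >= good_cutoff)
  structure(list(good_cutoff = good_cutoff, poor_weight = poor_weight,
                 poor_max = poor_max), class = "hbond_params")
}

#' Secondary structure and H-bond partners from Calpha geometry
#'
#' Labels each residue helix, strand or loop from Calpha-only geometry and
#' lists candidate main-chain H-bond partner pairs. A residue window is
#' helical when the Calpha(i)-Calpha(i+3) and Calpha(i)-Calpha(i+4)
#' distances match the helical pattern (windows are deliberately tolerant —
#' 4.6-6.4 A and 5.6-7.8 A — so that distorted or stretched helices are
#' still recognized as a helical arrangement; whether a bond is good or
#' poor is judged later from the estimated donor-acceptor distance).
#' Strands are extended stretches (Calpha(i)-Calpha(i+3) > 9 A) and pair
#' into ladders with strand residues of another run at 4.0-5.5 A.
#'
#' H-bond heavy-atom (O...N) distances are estimated from Calpha geometry:
#' for a helical pair (i, i+4), the distance between the peptide midpoints
#' `m_i = (Calpha_i + Calpha_{i+1})/2` and `m_{i+3}` minus 1.8 A (the C=O
#' bond plus the N offset along the bond direction); for a ladder pair, the
#' Calpha-Calpha distance minus 2.0 A.
#'
#' @param model A `ca_model` (>= 5 residues for any non-loop labels).
#' @return List with `labels` (tibble: `chain_id`, `residue_index`,
#'   `label`) and `pairs` (tibble: `chain_i`, `res_i`, `chain_j`, `res_j`,
#'   `type`, `est_distance`).
#' @export
assign_ss_from_ca <- function(model) {
  labels <- tibble::tibble(chain_id = model$chain_id,
                           residue_index = model$residue_index,
                           label = "loop")
  pairs <- tibble::tibble(chain_i = character(0), res_i = integer(0),
                          chain_j = character(0), res_j = integer(0),
                          type = character(0), est_distance = numeric(0))
  if (nrow(model) < 5) return(list(labels = labels, pairs = pairs))

  chains <- split(seq_len(nrow(model)), model$chain_id)
  lab <- labels$label
  strand_rows <- integer(0)
  strand_run <- integer(0)   # run id per strand row
  run_counter <- 0L

  for (rows in chains) {
    ca <- ca_xyz(model[rows, ])
    n <- nrow(ca)
    if (n < 4) next
    d13 <- if (n >= 4) sqrt(rowSums((ca[seq_len(n - 3), , drop = FALSE] -
                                       ca[4:n, , drop = FALSE])^2)) else numeric(0)
    d14 <- if (n >= 5) sqrt(rowSums((ca[seq_len(n - 4), , drop = FALSE] -
                                       ca[5:n, , drop = FALSE])^2)) else numeric(0)
    helical_win <- which(seq_len(max(n - 4, 0)) > 0 &
                           d13[seq_len(max(n - 4, 0))] >= 4.6 &
                           d13[seq_len(max(n - 4, 0))] <= 6.4 &
                           d14 >= 5.6 & d14 <= 7.8)
    for (i in helical_win) lab[rows[i:(i + 4)]] <- "helix"

    ext_win <- which(d13 > 9.0)
    ext_res <- sort(unique(unlist(lapply(ext_win, function(i) i:(i + 3)))))
    # strand runs of >= 3 consecutive extended residues
    if (length(ext_res) > 0) {
      runs <- split(ext_res, cumsum(c(1, diff(ext_res) != 1)))
      for (rn in runs) {
        if (length(rn) >= 3) {
          run_counter <- run_counter + 1L
          pick <- rows[rn][lab[rows[rn]] != "helix"]
          lab[pick] <- "strand"
          strand_rows <- c(strand_rows, pick)
          strand_run <- c(strand_run, rep(run_counter, length(pick)))
        }
      }
    }

    # helical H-bond pairs (i, i+4) with both residues helical
    mids <- (ca[-1, , drop = FALSE] + ca[-n, , drop = FALSE]) / 2
    for (i in helical_win) {
      est <- sqrt(sum((mids[i + 3, ] - mids[i, ])^2)) - 1.8
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        chain_i = model$chain_id[rows[i]],
        res_i = model$residue_index[rows[i]],
        chain_j = model$chain_id[rows[i + 4]],
        res_j = model$residue_index[rows[i + 4]],
        type = "helix", est_distance = est))
    }
  }

  # sheet ladders: strand residues of different runs within 4.0-5.5 A
  if (length(strand_rows) >= 2) {
    sxyz <- ca_xyz(model[strand_rows, ])
    for (a in seq_along(strand_rows)) {
      d2 <- (sxyz[, 1] - sxyz[a, 1])^2 + (sxyz[, 2] - sxyz[a, 2])^2 +
        (sxyz[, 3] - sxyz[a, 3])^2
      ok <- which(strand_run != strand_run[a] & d2 >= 4.0^2 & d2 <= 5.5^2)
      if (length(ok) == 0) next
      b <- ok[which.min(d2[ok])]
      if (b <= a) next                      # each unordered pair once
      ra <- strand_rows[a]; rb <- strand_rows[b]
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        chain_i = model$chain_id[ra], res_i = model$residue_index[ra],
        chain_j = model$chain_id[rb], res_j = model$residue_index[rb],
        type = "sheet", est_distance = sqrt(d2[b]) - 2.0))
    }
  }
  labels$label <- lab
  list(labels = labels, pairs = pairs)
}

#' H-bond score of a model
#'
#' Number of good hydrogen bonds (estimated heavy-atom distance within
#' `good_cutoff`) plus `poor_weight` times the number of poor ones
#' (helical/sheet arrangement but between `good_cutoff` and `poor_max`).
#'
#' @param model A `ca_model`.
#' @param params An [hbond_params()].
#' @return Scalar score (0 for loop-only or too-short models).
#' @export
hbond_score <- function(model, params = hbond_params()) {
  ss <- assign_ss_from_ca(model)
  if (nrow(ss$pairs) == 0) return(0)
  d <- ss$pairs$est_distance
  good <- sum(d <= params$good_cutoff)
  poor <- sum(d > params$good_cutoff & d <= params$poor_max)
  good + params$poor_weight * poor
}

# model-based density on the map's grid, same forward model as
# synthesize_map
model_density_on_grid <- function(map, xyz, sigma) {
  dims <- dim(map$values)
  values <- array(0, dim = dims)
  cutoff <- 4 * sigma
  ax <- lapply(1:3, function(a)
    map$origin[a] + (seq_len(dims[a]) - 1) * map$voxel_size[a])
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    rng <- lapply(1:3, function(a) which(abs(ax[[a]] - p[a]) <= cutoff))
    if (any(lengths(rng) == 0)) next
    gx <- exp(-(ax[[1]][rng[[1]]] - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - p[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - p[3])^2 / (2 * sigma^2))
    values[rng[[1]], rng[[2]], rng[[3]]] <-
      values[rng[[1]], rng[[2]], rng[[3]]] + outer(gx, outer(gy, gz))
  }
  values
}

#' Map-model correlation
#'
#' Pearson correlation between the map and model-based density (same
#' Gaussian forward model as [synthesize_map()]) over the grid points
#' within `mask_radius` of any model atom.
#'
#' @param model A `ca_model` or atom tibble.
#' @param map A [density_map()].
#' @param mask_radius Mask radius around model atoms, Angstroms.
#' @param sigma_factor Gaussian width as a fraction of the map's
#'   `resolution_hint` (a 3 A width is assumed if the hint is missing).
#' @return Correlation in `[-1, 1]`.
#' @export
map_model_cc <- function(model, map, mask_radius = 3,
                         sigma_factor = 0.225) {
  atoms <- if (inherits(model, "ca_model")) ca_model_to_atoms(model) else model
  stopifnot(nrow(atoms) > 0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  res <- if (is.finite(map$resolution_hint)) map$resolution_hint else 3
  sigma <- sigma_factor * res
  # same forward model as synthesize_map, including backbone continuity
  synth_xyz <- xyz
  if (all(c("atom", "chain_id", "residue_index") %in% names(atoms)))
    synth_xyz <- rbind(synth_xyz, backbone_fill_points(atoms))
  synth <- model_density_on_grid(map, synth_xyz, sigma)

  dims <- dim(map$values)
  mask <- array(FALSE, dim = dims)
  ax <- lapply(1:3, function(a)
    map$origin[a] + (seq_len(dims[a]) - 1) * map$voxel_size[a])
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(a)
      which(abs(ax[[a]] - xyz[i, a]) <= mask_radius))
    if (any(lengths(rng) == 0)) next
    sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    pts <- cbind(ax[[1]][sub[, 1]], ax[[2]][sub[, 2]], ax[[3]][sub[, 3]])
    d2 <- (pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
      (pts[, 3] - xyz[i, 3])^2
    inside <- sub[d2 <= mask_radius^2, , drop = FALSE]
    mask[inside] <- TRUE
  }
  a <- as.vector(map$values)[as.vector(mask)]
  b <- as.vector(synth)[as.vector(mask)]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance density within the model mask", call. = FALSE)
  stats::cor(a, b)
}

#' Density-fit score
#'
#' `U = 10 * (CC - 0.5) * sqrt(N)`: positive correlation above 0.5 rewards
#' larger models, correlation below 0.5 penalizes them, and the score is
#' independent of size exactly at CC = 0.5.
#'
#' @param cc Map-model correlation.
#' @param n_atoms Number of atoms in the scored model (>= 0).
#' @return Scalar U.
#' @export
density_fit_score <- function(cc, n_atoms) {
  stopifnot(n_atoms >= 0)
  10 * (cc - 0.5) * sqrt(n_atoms)
}

#' Combined model score
#'
#' `T = S + CC * sqrt(N)`, where `S` is an externally supplied sequence-fit
#' likelihood score (its computation is outside this package's scope), `CC`
#' the map-model correlation and `N` the number of residues built.
#'
#' @param s_likelihood Sequence-to-density likelihood score S.
#' @param cc Map-model correlation.
#' @param n_residues Number of residues built (>= 0).
#' @return Scalar T.
#' @export
combined_score <- function(s_likelihood, cc, n_residues) {
  stopifnot(n_residues >= 0)
  s_likelihood + cc * sqrt(n_residues)
}

#' Score breakdown for one chain
#'
#' @param model A `ca_model`.
#' @param map A [density_map()].
#' @param s_likelihood Externally supplied likelihood score S (default 0).
#' @param params An [hbond_params()].
#' @return One-row tibble: `n_residues`, `n_atoms`, `cc`, `hbond_score`,
#'   `density_fit_U`, `combined_T`.
#' @export
score_breakdown <- function(model, map, s_likelihood = 0,
                            params = hbond_params()) {
  cc <- map_model_cc(model, map)
  n_res <- nrow(model)
  n_atoms <- nrow(ca_model_to_atoms(model))
  tibble::tibble(
    n_residues = n_res, n_atoms = n_atoms, cc = cc,
    hbond_score = hbond_score(model, params),
    density_fit_U = density_fit_score(cc, n_atoms),
    combined_T = combined_score(s_likelihood, cc, n_res))
}

#' Choose the chain direction
#'
#' Scores each direction as H-bond score plus density-fit score U and keeps
#' the higher-scoring one; an exact tie keeps the forward model. With
#' side-chain fitting out of scope, the side-chain contribution to the fit
#' reduces to the Cbeta atoms.
#'
#' @param model_forward,model_reverse `ca_model`s spanning the same trace.
#' @param map A [density_map()].
#' @param params An [hbond_params()].
#' @return The winning `ca_model`, with attribute `direction` ("forward" or
#'   "reverse") and `direction_score`.
#' @export
choose_direction <- function(model_forward, model_reverse, map,
                             params = hbond_params()) {
  score_of <- function(m) {
    cc <- tryCatch(map_model_cc(m, map), error = function(e) 0)
    hbond_score(m, params) +
      density_fit_score(cc, nrow(ca_model_to_atoms(m)))
  }
  sf <- score_of(model_forward)
  sr <- score_of(model_reverse)
  out <- if (sr > sf) model_reverse else model_forward
  attr(out, "direction") <- if (sr > sf) "reverse" else "forward"
  attr(out, "direction_score") <- max(sf, sr)
  out
}

#' Combine candidate chains, removing overlaps
#'
#' Ranks candidates by density-fit score U (then by length) and removes
#' from lower-ranked chains any residue whose Calpha lies within
#' `overlap_radius` of a retained higher-ranked Calpha; remaining fragments
#' shorter than `min_fragment` residues are dropped. The output is
#' idempotent under re-combination.
#'
#' @param candidates List of `ca_model`s.
#' @param map A [density_map()].
#' @param overlap_radius Overlap criterion, Angstroms (default 2).
#' @param min_fragment Shortest surviving fragment, residues (default 3).
#' @return List of pairwise non-overlapping `ca_model`s, re-lettered
#'   A, B, C, ...
#' @export
combine_models <- function(candidates, map, overlap_radius = 2,
                           min_fragment = 3) {
  candidates <- Filter(function(m) nrow(m) > 0, candidates)
  if (length(candidates) == 0) return(list())
  u <- vapply(candidates, function(m) {
    cc <- tryCatch(map_model_cc(m, map), error = function(e) 0)
    density_fit_score(cc, nrow(ca_model_to_atoms(m)))
  }, numeric(1))
  len <- vapply(candidates, nrow, integer(1))
  ord <- order(-u, -len)
  kept <- list()
  kept_ca <- matrix(numeric(0), 0, 3)
  for (ci in ord) {
    m <- candidates[[ci]]
    ca <- ca_xyz(m)
    if (nrow(kept_ca) > 0) {
      near <- vapply(seq_len(nrow(ca)), function(i) {
        min((kept_ca[, 1] - ca[i, 1])^2 + (kept_ca[, 2] - ca[i, 2])^2 +
              (kept_ca[, 3] - ca[i, 3])^2) <= overlap_radius^2
      }, logical(1))
    } else near <- rep(FALSE, nrow(ca))
    keep_rows <- which(!near)
    if (length(keep_rows) == 0) next
    runs <- split(keep_rows, cumsum(c(1, diff(keep_rows) != 1)))
    for (rn in runs) {
      if (length(rn) < min_fragment) next
      frag <- m[rn, ]
      frag$residue_index <- seq_len(nrow(frag))
      class(frag) <- class(m)
      kept[[length(kept) + 1L]] <- frag
      kept_ca <- rbind(kept_ca, ca[rn, , drop = FALSE])
    }
  }
  for (i in seq_along(kept)) kept[[i]]$chain_id <- chain_letter(i)
  kept
}

chain_letter <- function(i) {
  letters_pool <- c(LETTERS, letters, as.character(0:9))
  letters_pool[((i - 1) %% length(letters_pool)) + 1]
}

#' Mean chain length
#'
#' Arithmetic mean of per-chain residue counts (the length of segments
#' between breaks in the chain).
#'
#' @param models List of `ca_model`s (non-empty).
#' @return Mean residues per chain.
#' @export
mean_chain_length <- function(models) {
  if (length(models) == 0) stop("no chains", call. = FALSE)
  mean(vapply(models, nrow, integer(1)))
}
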