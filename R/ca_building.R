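#' Calpha model-building parameters
#'
#' @param target_ca_ca Target consecutive Calpha-Calpha distance, Angstroms.
#' @param bones_path_exclusion Bones points closer than this to the path are
#'   treated as main-chain and removed before Cbeta identification.
#' @param cbeta_seed_radius Radius around each path point within which
#'   side-chain bones points are averaged into a centroid.
#' @param cluster_linkage_cut Single-linkage cut height for clustering the
#'   centroids into Cbeta candidates (Cbetas of neighbouring residues are
#'   ~5 A apart in an extended chain, so 2 A separates clusters cleanly).
#' @param score_weights Weights of the four placement-score terms
#'   (Calpha-Calpha distance, Cbeta proximity, midpoint density, midpoint
#'   distance to path), each term normalized by its own count.
#' @param refine_weights Named weights of the refinement target terms:
#'   `start` (deviation from the starting coordinates), `dist`
#'   (Calpha-Calpha distance), `density` (density at Calpha, Cbeta and
#'   midpoint positions).
#' @param crossover_fraction Fraction of `target_ca_ca` within which a
#'   fragment Calpha and a model Calpha count as overlapping for splicing.
#' @param cb_dead_zone Cbeta-proximity deviations smaller than this
#'   (Angstroms) do not contribute to the placement score.
#' @param cb_attach_max A Cbeta candidate within this distance of a Calpha
#'   is attached to it in the output model.
#' @param cbeta_min_path_distance Cluster centres closer than this to the
#'   path are discarded as main-chain contamination rather than side-chain
#'   take-offs (a genuine Cbeta centroid sits off the path by roughly the
#'   Calpha-Cbeta bond length).
#' @param splice_min_density_ratio A detected fragment is only eligible for
#'   splicing when the mean map density at its Calpha positions is at least
#'   this fraction of the mean density at the traced model's Calphas; a
#'   misregistered rigid template sits in the valleys between backbone
#'   density peaks and fails this gate.
#' @param max_refine_shift Cap on how far refinement may move a Calpha from
#'   its starting position, Angstroms.
#' @return A `ca_build_params` list.
#' @export
ca_build_params <- function(target_ca_ca = 3.8, bones_path_exclusion = 1.5,
                            cbeta_seed_radius = 3, cluster_linkage_cut = 2.0,
                            score_weights = c(1, 1, 1, 1),
                            refine_weights = c(start = 0.1, dist = 1,
                                               density = 1),
                            crossover_fraction = 0.75, cb_dead_zone = 1.0,
                            cb_attach_max = 2.5, max_refine_shift = 2,
                            splice_min_density_ratio = 0.8,
                            cbeta_min_path_distance = 1.0) {
  stopifnot(target_ca_ca > 0, bones_path_exclusion >= 0,
            cbeta_seed_radius > 0, cluster_linkage_cut > 0,
            length(score_weights) == 4, all(score_weights >= 0),
            crossover_fraction > 0, max_refine_shift > 0)
  structure(list(target_ca_ca = target_ca_ca,
                 bones_path_exclusion = bones_path_exclusion,
                 cbeta_seed_radius = cbeta_seed_radius,
                 cluster_linkage_cut = cluster_linkage_cut,
                 score_weights = score_weights,
                 refine_weights = refine_weights,
                 crossover_fraction = crossover_fraction,
                 cb_dead_zone = cb_dead_zone,
                 cb_attach_max = cb_attach_max,
                 max_refine_shift = max_refine_shift,
                 splice_min_density_ratio = splice_min_density_ratio,
                 cbeta_min_path_distance = cbeta_min_path_distance),
            class = "ca_build_params")
}

#' Calpha model container
#'
#' A `ca_model` is a tibble with one row per residue: `chain_id`,
#' `residue_index`, Calpha coordinates `x`, `y`, `z`, optional Cbeta
#' coordinates `cb_x`, `cb_y`, `cb_z` (`NA` when absent), and a `spliced`
#' flag marking residues replaced by a secondary-structure fragment.
#'
#' @param ca n x 3 matrix of Calpha positions (Angstroms).
#' @param cb Optional n x 3 matrix of Cbeta positions (`NA` rows allowed).
#' @param chain_id Chain identifier.
#' @param spliced Logical vector (recycled).
#' @return A `ca_model` tibble.
#' @export
ca_model <- function(ca, cb = NULL, chain_id = "A", spliced = FALSE) {
  ca <- rbind_vec(ca)
  n <- nrow(ca)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3) else cb <- rbind_vec(cb)
  out <- tibble::tibble(chain_id = chain_id,
                        residue_index = seq_len(n),
                        x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
                        spliced = rep_len(spliced, n))
  class(out) <- c("ca_model", class(out))
  out
}

ca_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])
cb_xyz <- function(model) {
  m <- as.matrix(model[, c("cb_x", "cb_y", "cb_z")])
  m[stats::complete.cases(m), , drop = FALSE]
}

ca_model_to_atoms <- function(model) {
  ca <- tibble::tibble(atom = "CA", residue_index = model$residue_index,
                       chain_id = model$chain_id,
                       x = model$x, y = model$y, z = model$z)
  has_cb <- stats::complete.cases(model[, c("cb_x", "cb_y", "cb_z")])
  cb <- tibble::tibble(atom = "CB",
                       residue_index = model$residue_index[has_cb],
                       chain_id = model$chain_id[has_cb],
                       x = model$cb_x[has_cb], y = model$cb_y[has_cb],
                       z = model$cb_z[has_cb])
  dplyr::bind_rows(ca, cb)
}

atoms_to_ca_model <- function(atoms) {
  models <- lapply(split(atoms, atoms$chain_id), function(ch) {
    ca <- ch[ch$atom == "CA", ]
    ca <- ca[order(ca$residue_index), ]
    cb <- ch[ch$atom == "CB", ]
    m <- ca_model(as.matrix(ca[, c("x", "y", "z")]),
                  chain_id = ca$chain_id[1])
    j <- match(ca$residue_index, cb$residue_index)
    m$cb_x <- cb$x[j]; m$cb_y <- cb$y[j]; m$cb_z <- cb$z[j]
    m$residue_index <- ca$residue_index
    m
  })
  unname(models)
}

# ---------------------------------------------------------------------------
# path geometry helpers
# ---------------------------------------------------------------------------

path_arc <- function(path) {
  pts <- path$points
  n <- nrow(pts)
  if (n < 2) return(list(s = 0, pts = pts))
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-n, , drop = FALSE])^2))
  list(s = c(0, cumsum(seg)), pts = pts)
}

# point on the path polyline at arc position s (clamped)
path_point_at <- function(arc, s) {
  ss <- pmin(pmax(s, 0), max(arc$s))
  out <- matrix(0, length(ss), 3)
  for (k in seq_along(ss)) {
    i <- findInterval(ss[k], arc$s, all.inside = TRUE)
    t0 <- arc$s[i]; t1 <- arc$s[i + 1]
    f <- if (t1 > t0) (ss[k] - t0) / (t1 - t0) else 0
    out[k, ] <- (1 - f) * arc$pts[i, ] + f * arc$pts[i + 1, ]
  }
  out
}

nearest_path_distance <- function(pts, path) {
  pp <- path$points
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((pp[, 1] - pts[i, 1])^2 + (pp[, 2] - pts[i, 2])^2 +
               (pp[, 3] - pts[i, 3])^2))
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Cbeta identification
# ---------------------------------------------------------------------------

#' Side-chain bones points
#'
#' Removes bones points lying within `bones_path_exclusion` of any path
#' point; what remains essentially marks the side chains.
#'
#' @param bones A `bones_set`.
#' @param path A `trace_path`.
#' @param params A [ca_build_params()].
#' @return The filtered `bones_set`.
#' @export
side_chain_bones <- function(bones, path, params = ca_build_params()) {
  if (nrow(bones) == 0L || params$bones_path_exclusion == 0) return(bones)
  d <- nearest_path_distance(as.matrix(bones[, c("x", "y", "z")]), path)
  bones[d > params$bones_path_exclusion, ]
}

#' Candidate Cbeta positions
#'
#' Each path point seeds the centroid of all side-chain bones points within
#' `cbeta_seed_radius`; the centroids are clustered (single linkage, cut at
#' `cluster_linkage_cut`) and the cluster centres returned as candidate
#' Cbeta positions.
#'
#' @param path A `trace_path`.
#' @param side_bones A `bones_set` from [side_chain_bones()].
#' @param params A [ca_build_params()].
#' @return Matrix (k x 3) of candidate Cbeta positions (0 rows when there
#'   are no side bones).
#' @export
cbeta_candidates <- function(path, side_bones, params = ca_build_params()) {
  if (nrow(side_bones) == 0L) return(matrix(numeric(0), 0, 3))
  bx <- as.matrix(side_bones[, c("x", "y", "z")])
  pp <- path$points
  cent <- list()
  for (i in seq_len(nrow(pp))) {
    d2 <- (bx[, 1] - pp[i, 1])^2 + (bx[, 2] - pp[i, 2])^2 +
      (bx[, 3] - pp[i, 3])^2
    sel <- d2 <= params$cbeta_seed_radius^2
    if (any(sel)) cent[[length(cent) + 1L]] <-
        colMeans(bx[sel, , drop = FALSE])
  }
  if (length(cent) == 0L) return(matrix(numeric(0), 0, 3))
  cent <- do.call(rbind, cent)
  if (nrow(cent) == 1L) {
    keep <- nearest_path_distance(cent, path) >=
      params$cbeta_min_path_distance
    return(cent[keep, , drop = FALSE])
  }
  cl <- stats::cutree(stats::hclust(stats::dist(cent), method = "single"),
                      h = params$cluster_linkage_cut)
  out <- t(vapply(split(seq_len(nrow(cent)), cl),
                  function(ix) colMeans(cent[ix, , drop = FALSE]),
                  numeric(3)))
  # centres that fall back onto the path are main-chain contamination
  keep <- nearest_path_distance(out, path) >= params$cbeta_min_path_distance
  out <- out[keep, , drop = FALSE]
  unname(out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Calpha placement, scoring, optimization, refinement
# ---------------------------------------------------------------------------

#' Initial Calpha placement along a path
#'
#' The residue count follows from the path length divided by the target
#' Calpha-Calpha distance; positions lie on the path, spaced approximately
#' one target distance apart in arc length and registered against the
#' identified Cbeta candidates where possible. The register is found by a
#' dynamic program over discretized arc positions: consecutive sites may be
#' 2.8-4.8 A apart with a quadratic penalty away from the target spacing,
#' and a site close to a Cbeta candidate is rewarded when its distance to
#' the candidate matches an ideal Calpha-Cbeta bond (1.53 A).
#'
#' @param path A (morphed) `trace_path`.
#' @param cbetas Matrix of candidate Cbeta positions (possibly 0 rows).
#' @param params A [ca_build_params()].
#' @return A `ca_model` (single Calpha when the path is shorter than one
#'   spacing).
#' @export
place_initial_ca <- function(path, cbetas = matrix(numeric(0), 0, 3),
                             params = ca_build_params()) {
  arc <- path_arc(path)
  L <- max(arc$s)
  tgt <- params$target_ca_ca
  if (round(L / tgt) < 1) return(ca_model(path_point_at(arc, L / 2)))

  ds <- 0.2                                  # arc discretization, Angstroms
  s_grid <- seq(0, L, by = ds)
  if (s_grid[length(s_grid)] < L) s_grid <- c(s_grid, L)
  pts <- path_point_at(arc, s_grid)

  # unary term: each Cbeta candidate projects onto the path and digs a
  # Gaussian reward well at that arc position, anchoring the register
  # (sites want to sit where a side chain takes off); stretches without
  # Cbeta evidence carry no per-site cost
  unary <- numeric(length(s_grid))
  if (nrow(cbetas) > 0) {
    anchors <- numeric(0)
    for (j in seq_len(nrow(cbetas))) {
      d2 <- (pts[, 1] - cbetas[j, 1])^2 + (pts[, 2] - cbetas[j, 2])^2 +
        (pts[, 3] - cbetas[j, 3])^2
      k <- which.min(d2)
      if (sqrt(d2[k]) <= 3.5) anchors <- c(anchors, s_grid[k])
    }
    if (length(anchors) > 0) {
      dnear <- vapply(s_grid, function(s) min(abs(s - anchors)), numeric(1))
      unary <- -exp(-dnear^2 / (2 * 0.6^2))
    }
  }

  lo <- max(1L, as.integer(floor(2.8 / ds)))
  hi <- as.integer(ceiling(4.8 / ds))
  m <- length(s_grid)
  end_slack <- min(tgt / 2, L / 4)
  starts <- which(s_grid <= end_slack)
  ends <- which(s_grid >= L - end_slack)

  best <- rep(Inf, m)
  prev <- rep(NA_integer_, m)
  best[starts] <- unary[starts] + 0.05 * s_grid[starts]^2  # prefer full span
  for (i in seq_len(m)) {
    if (!is.finite(best[i]) || i + lo > m) next
    jr <- (i + lo):min(i + hi, m)
    step <- s_grid[jr] - s_grid[i]
    cost <- best[i] + (step - tgt)^2 + unary[jr]
    upd <- cost < best[jr]
    best[jr][upd] <- cost[upd]
    prev[jr][upd] <- i
  }
  fin <- best[ends] + 0.05 * (L - s_grid[ends])^2
  if (all(!is.finite(fin))) return(ca_model(path_point_at(arc, L / 2)))
  cur <- ends[which.min(fin)]
  sel <- integer(0)
  while (!is.na(cur)) {
    sel <- c(cur, sel)
    cur <- prev[cur]
  }
  ca_model(pts[sel, , drop = FALSE])
}

#' Placement score of a Calpha arrangement
#'
#' Weighted sum of four sum-of-squares terms (lower is better): deviation of
#' consecutive Calpha-Calpha distances from the target; distance from each
#' Cbeta candidate to its nearest Calpha beyond a dead zone; normalized
#' density shortfall at Calpha-Calpha midpoints relative to the densest
#' point on the path; and distance from those midpoints to the path. Each
#' term is divided by its own count.
#'
#' @param model A `ca_model` with at least 2 residues.
#' @param map A [density_map()].
#' @param path The region's `trace_path`.
#' @param cbetas Matrix of Cbeta candidates.
#' @param params A [ca_build_params()].
#' @return Scalar score (>= 0).
#' @export
ca_placement_score <- function(model, map, path,
                               cbetas = matrix(numeric(0), 0, 3),
                               params = ca_build_params()) {
  ca <- ca_xyz(model)
  n <- nrow(ca)
  stopifnot(n >= 2)
  w <- params$score_weights
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  term1 <- sum((d - params$target_ca_ca)^2) / (n - 1)

  term2 <- 0
  if (nrow(cbetas) > 0 && w[2] > 0) {
    dd <- vapply(seq_len(nrow(cbetas)), function(j) {
      sqrt(min((ca[, 1] - cbetas[j, 1])^2 + (ca[, 2] - cbetas[j, 2])^2 +
                 (ca[, 3] - cbetas[j, 3])^2))
    }, numeric(1))
    term2 <- sum(pmax(0, dd - params$cb_dead_zone)^2) / nrow(cbetas)
  }

  mids <- (ca[-1, , drop = FALSE] + ca[-n, , drop = FALSE]) / 2
  term3 <- 0
  if (w[3] > 0) {
    rho_ref <- max(interp_density(map, path$points))
    if (rho_ref > 0) {
      short <- pmax(0, 1 - interp_density(map, mids) / rho_ref)
      term3 <- sum(short^2) / (n - 1)
    }
  }
  term4 <- if (w[4] > 0)
    sum(nearest_path_distance(mids, path)^2) / (n - 1) else 0

  w[1] * term1 + w[2] * term2 + w[3] * term3 + w[4] * term4
}

#' Discrete optimization of the Calpha arrangement
#'
#' Greedy first-improvement search over the move set insert-between,
#' delete, and extend-at-either-end, scored with [ca_placement_score()];
#' stops when no move improves the score. The seed only shuffles the order
#' in which moves are tried, so the result is deterministic given the seed.
#'
#' @inheritParams ca_placement_score
#' @param seed Integer seed for move-order shuffling.
#' @param max_moves Safety cap on accepted moves.
#' @return The optimized `ca_model`.
#' @export
optimize_ca <- function(model, map, path,
                        cbetas = matrix(numeric(0), 0, 3),
                        params = ca_build_params(), seed = 1L,
                        max_moves = 200L) {
  if (nrow(model) < 2) return(model)
  arc <- path_arc(path)
  L <- max(arc$s)
  ca <- ca_xyz(model)
  score <- function(m) ca_placement_score(ca_model(m), map, path, cbetas,
                                          params)
  cur <- score(ca)
  snap_to_path <- function(p) {
    pp <- arc$pts
    d2 <- (pp[, 1] - p[1])^2 + (pp[, 2] - p[2])^2 + (pp[, 3] - p[3])^2
    pp[which.min(d2), ]
  }
  moves_done <- 0L
  pass <- 0L
  repeat {
    pass <- pass + 1L
    n <- nrow(ca)
    moves <- list()
    for (i in seq_len(n - 1))
      moves[[length(moves) + 1L]] <- list(kind = "insert", i = i)
    if (n > 2) for (i in seq_len(n))
      moves[[length(moves) + 1L]] <- list(kind = "delete", i = i)
    moves[[length(moves) + 1L]] <- list(kind = "prepend")
    moves[[length(moves) + 1L]] <- list(kind = "append")
    ord <- with_local_seed(seed + pass, sample.int(length(moves)))
    improved <- FALSE
    for (mi in ord) {
      mv <- moves[[mi]]
      cand <- switch(mv$kind,
        insert = {
          p <- snap_to_path((ca[mv$i, ] + ca[mv$i + 1, ]) / 2)
          rbind(ca[seq_len(mv$i), , drop = FALSE], p,
                ca[(mv$i + 1):n, , drop = FALSE])
        },
        delete = ca[-mv$i, , drop = FALSE],
        prepend = {
          p <- snap_to_path(2 * ca[1, ] - ca[2, ])
          rbind(p, ca)
        },
        append = {
          p <- snap_to_path(2 * ca[n, ] - ca[n - 1, ])
          rbind(ca, p)
        })
      if (nrow(cand) < 2) next
      # degenerate end moves (snapping back onto an existing site) skipped
      dmin <- min(sqrt(rowSums((cand[-1, , drop = FALSE] -
                                  cand[-nrow(cand), , drop = FALSE])^2)))
      if (mv$kind %in% c("prepend", "append", "insert") && dmin < 1e-6) next
      sc <- score(cand)
      if (sc < cur - 1e-9) {
        ca <- cand
        cur <- sc
        improved <- TRUE
        moves_done <- moves_done + 1L
        break
      }
    }
    if (!improved || moves_done >= max_moves) break
  }
  out <- ca_model(ca, chain_id = model$chain_id[1])
  out
}

#' Coordinate refinement of a Calpha model
#'
#' Local minimization of a composite target with terms for deviation from
#' the starting coordinates, deviation of consecutive Calpha-Calpha
#' distances from the target, and (normalized) density at Calpha, Cbeta and
#' midpoint positions. Residue count is unchanged and each Calpha moves at
#' most `max_refine_shift` from its start. Cbetas, when present, ride
#' rigidly on their Calpha.
#'
#' @param model A `ca_model` (>= 2 residues).
#' @param map A [density_map()].
#' @param params A [ca_build_params()].
#' @return The refined `ca_model`, with attribute `refine_converged`.
#' @export
refine_ca <- function(model, map, params = ca_build_params()) {
  n <- nrow(model)
  if (n < 2) return(model)
  x0 <- ca_xyz(model)
  cb0 <- as.matrix(model[, c("cb_x", "cb_y", "cb_z")])
  has_cb <- stats::complete.cases(cb0)
  cb_off <- cb0 - x0
  w <- params$refine_weights
  rho_ref <- max(c(interp_density(map, x0), 1e-12))

  target <- function(par) {
    ca <- matrix(par, n, 3)
    val <- w[["start"]] * sum((ca - x0)^2) / n
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    val <- val + w[["dist"]] * sum((d - params$target_ca_ca)^2) / (n - 1)
    if (w[["density"]] > 0) {
      mids <- (ca[-1, , drop = FALSE] + ca[-n, , drop = FALSE]) / 2
      pts <- rbind(ca, mids)
      if (any(has_cb)) pts <- rbind(pts, (ca + cb_off)[has_cb, , drop = FALSE])
      short <- pmax(0, 1 - interp_density(map, pts) / rho_ref)
      val <- val + w[["density"]] * sum(short^2) / nrow(pts)
    }
    val
  }
  cap <- params$max_refine_shift
  fit <- stats::optim(as.vector(x0), target, method = "L-BFGS-B",
                      lower = as.vector(x0) - cap,
                      upper = as.vector(x0) + cap,
                      control = list(maxit = 400, factr = 1e8))
  ca <- matrix(fit$par, n, 3)
  # enforce the per-atom Euclidean cap (box bounds allow slightly more)
  shift <- ca - x0
  nr <- sqrt(rowSums(shift^2))
  over <- nr > cap
  if (any(over)) ca[over, ] <- x0[over, ] + shift[over, , drop = FALSE] *
      (cap / nr[over])
  out <- model
  out$x <- ca[, 1]; out$y <- ca[, 2]; out$z <- ca[, 3]
  cb <- ca + cb_off
  out$cb_x <- ifelse(has_cb, cb[, 1], NA_real_)
  out$cb_y <- ifelse(has_cb, cb[, 2], NA_real_)
  out$cb_z <- ifelse(has_cb, cb[, 3], NA_real_)
  # best-so-far is returned either way; the flag records non-convergence
  attr(out, "refine_converged") <- fit$convergence == 0
  out
}

#' Splice secondary-structure fragments into a Calpha model
#'
#' Where a run of fragment Calphas overlaps a run of model Calphas (pairs
#' within `crossover_fraction * target_ca_ca`, 2.85 A at defaults, with
#' crossovers at both ends of the run), the intervening model residues are
#' replaced by the fragment coordinates, which are typically more accurate.
#' A single-residue overlap does not splice. Overlapping fragments are
#' applied best-overlap-first; later fragments cannot touch already-spliced
#' residues.
#'
#' @param model A `ca_model`.
#' @param fragments List of fragments: atom tibbles or n x 3 Calpha
#'   matrices.
#' @param params A [ca_build_params()].
#' @return The spliced `ca_model` (`spliced` flags set).
#' @export
splice_ss <- function(model, fragments, params = ca_build_params()) {
  if (length(fragments) == 0L || nrow(model) == 0L) return(model)
  cut <- params$crossover_fraction * params$target_ca_ca
  frag_ca <- lapply(fragments, function(f) {
    if (is.matrix(f)) f else {
      fca <- f[f$atom == "CA", ]
      as.matrix(fca[order(fca$residue_index), c("x", "y", "z")])
    }
  })
  # candidate splices: (fragment, model range, fragment range, mean overlap)
  plan <- list()
  ca <- ca_xyz(model)
  for (fi in seq_along(frag_ca)) {
    fc <- frag_ca[[fi]]
    for (rev in c(FALSE, TRUE)) {
      fm <- if (rev) fc[rev(seq_len(nrow(fc))), , drop = FALSE] else fc
      # nearest model residue for each fragment residue
      nearest <- t(vapply(seq_len(nrow(fm)), function(j) {
        d2 <- (ca[, 1] - fm[j, 1])^2 + (ca[, 2] - fm[j, 2])^2 +
          (ca[, 3] - fm[j, 3])^2
        k <- which.min(d2)
        c(k, sqrt(d2[k]))
      }, numeric(2)))
      hit <- which(nearest[, 2] <= cut)
      if (length(hit) < 2) next
      j1 <- min(hit); j2 <- max(hit)
      i1 <- nearest[j1, 1]; i2 <- nearest[j2, 1]
      if (i2 <= i1) next
      # a valid crossover maps fragment residues onto model residues
      # one-to-one: the mapping must be monotone, cover the run densely,
      # and preserve the residue count to within one
      if (any(diff(nearest[hit, 1]) < 0)) next
      if (length(hit) < 0.7 * (j2 - j1 + 1)) next
      if (abs((j2 - j1) - (i2 - i1)) > 1) next
      plan[[length(plan) + 1L]] <- list(fi = fi, fm = fm, j1 = j1, j2 = j2,
                                        i1 = i1, i2 = i2,
                                        quality = -mean(nearest[hit, 2]))
    }
  }
  if (length(plan) == 0L) return(model)
  # choose non-conflicting splices best-overlap-first, in the original
  # residue numbering, then apply from the end backwards so earlier
  # indices stay valid when a splice changes the residue count
  plan <- plan[order(vapply(plan, function(p) -p$quality, numeric(1)))]
  used_frag <- logical(length(frag_ca))
  claimed <- model$spliced
  chosen <- list()
  for (p in plan) {
    if (used_frag[p$fi] || any(claimed[p$i1:p$i2])) next
    claimed[p$i1:p$i2] <- TRUE
    used_frag[p$fi] <- TRUE
    chosen[[length(chosen) + 1L]] <- p
  }
  if (length(chosen) == 0L) return(model)
  chosen <- chosen[order(-vapply(chosen, function(p) p$i1, numeric(1)))]
  out <- model
  for (p in chosen) {
    repl <- p$fm[p$j1:p$j2, , drop = FALSE]
    before <- out[seq_len(p$i1 - 1), ]
    after <- if (p$i2 < nrow(out)) out[(p$i2 + 1):nrow(out), ] else out[0, ]
    mid <- ca_model(repl, chain_id = out$chain_id[1], spliced = TRUE)
    new <- dplyr::bind_rows(before, mid, after)
    new$residue_index <- seq_len(nrow(new))
    class(new) <- class(model)
    out <- new
  }
  out
}

# ---------------------------------------------------------------------------
# helix template search
# ---------------------------------------------------------------------------

#' Find helices by density template matching
#'
#' Rotation/translation search of an ideal alpha-helix density template
#' against the map, in two stages. First the helix axis is located: for
#' each of the strongest local density maxima, orientations from a
#' Fibonacci hemisphere are scored by the Pearson correlation between map
#' density and an azimuthally averaged helix profile (a tube peaking at the
#' backbone radius) sampled on a cylindrical lattice; the best placements
#' are shifted onto the axis and refined by local optimization of tilt and
#' position. Second, the helical phase (spin about the axis and axial
#' shift) is fitted by maximizing the map density summed over the placed
#' Calpha/Cbeta template atoms. Placements above `cor_cutoff` are accepted
#' non-overlapping.
#'
#' @param map A [density_map()] with resolution_hint <= 5 A (or supply
#'   `resolution`).
#' @param resolution Nominal resolution, Angstroms.
#' @param n_residues Template length (residues).
#' @param cor_cutoff Minimum map-template correlation for a hit.
#' @param max_hits Maximum number of placements returned.
#' @param n_centres Number of candidate centres examined.
#' @return List of fragments (atom tibbles of the placed template Calphas,
#'   with attribute `kind = "helix"` and `cor` the placement correlation).
#' @export
find_helices <- function(map, resolution = map$resolution_hint,
                         n_residues = 8, cor_cutoff = 0.5, max_hits = 10,
                         n_centres = 25) {
  stopifnot(is.finite(resolution), resolution > 0)
  sigma <- 0.225 * resolution
  half_len <- (n_residues - 1) * HELIX_RISE / 2

  # template Calpha/Cbeta atoms in the axis frame (axis = z through origin)
  tmpl <- helix_atoms(n_residues)
  tz <- as.matrix(tmpl[, c("x", "y", "z")])
  tz[, 3] <- tz[, 3] - half_len
  t_is_ca <- tmpl$atom == "CA"
  t_fill <- backbone_fill_points(dplyr::mutate(tmpl, z = .data$z - half_len))

  # azimuthally averaged comparison: the map is sampled on rings around the
  # trial axis and ring means are correlated with the azimuthal average of
  # the helix template density, which makes the score independent of the
  # (unknown) helical phase
  r_g <- seq(0, 4.5, by = 0.75)
  z_g <- seq(-(half_len + 1.5), half_len + 1.5, by = 0.75)
  az <- seq(0, 2 * pi, length.out = 11)[-11]
  cell <- as.matrix(expand.grid(r = r_g, z = z_g))
  ring_pts <- do.call(rbind, lapply(az, function(a)
    cbind(cell[, 1] * cos(a), cell[, 1] * sin(a), cell[, 2])))
  profile <- rowMeans(matrix(
    gaussian_density_at(ring_pts, rbind(tz, t_fill), sigma),
    nrow = nrow(cell)))

  cyl_cor_parts <- function(R, ctr) {
    pts <- sweep(ring_pts %*% t(R), 2, ctr, `+`)
    ringmean <- rowMeans(matrix(interp_density(map, pts),
                                nrow = nrow(cell)))
    lo <- cell[, 2] <= 0
    cc <- function(a, b) {
      v <- suppressWarnings(stats::cor(a, b))
      if (is.finite(v)) v else -1
    }
    # dense-core statistic: at these resolutions a helix images as a
    # solid rod, so the axis carries substantial density along its whole
    # length, whereas a template lying across a chain has empty axis ends
    core_cells <- cell[, 1] == 0 & abs(cell[, 2]) <= half_len
    core <- (mean(ringmean[core_cells]) - min(ringmean)) /
      max(max(ringmean) - min(ringmean), 1e-12)
    c(full = cc(ringmean, profile),
      lo = cc(ringmean[lo], profile[lo]),
      hi = cc(ringmean[!lo], profile[!lo]),
      core = core)
  }
  cyl_cor <- function(R, ctr) cyl_cor_parts(R, ctr)[["full"]]

  # signal-amplitude gate: a real helix stands far above the map noise
  # floor after azimuthal averaging, random fluctuations do not
  map_mean <- mean(map$values)
  map_sd <- stats::sd(as.vector(map$values))
  contrast_of <- function(R, ctr) {
    pts <- sweep(ring_pts %*% t(R), 2, ctr, `+`)
    ringmean <- rowMeans(matrix(interp_density(map, pts),
                                nrow = nrow(cell)))
    (max(ringmean) - map_mean) / map_sd
  }

  cand <- local_maxima_xyz(map, n_centres)
  if (nrow(cand) == 0L) return(list())
  dirs <- fibonacci_hemisphere(40)

  placements <- list()
  for (ci in seq_len(nrow(cand))) {
    best <- list(cor = -Inf)
    for (di in seq_len(nrow(dirs))) {
      R <- rotation_to_z(dirs[di, ])
      cc <- cyl_cor(R, cand[ci, ])
      if (cc > best$cor) best <- list(cor = cc, R = R, centre = cand[ci, ])
    }
    if (best$cor < cor_cutoff - 0.25) next
    if (contrast_of(best$R, best$centre) < 2) next
    # the candidate maximum sits on the backbone spiral, ~one backbone
    # radius off the axis: cross-search transverse offsets to centre it,
    # then refine tilt and position; two rounds, since centring and tilt
    # are coupled
    offs <- as.matrix(expand.grid(a = seq(-2.3, 2.3, by = 1.15),
                                  b = seq(-2.3, 2.3, by = 1.15)))
    for (round in 1:2) {
      u <- best$R[, 1]; v <- best$R[, 2]
      for (k in seq_len(nrow(offs))) {
        ctr <- best$centre + offs[k, 1] * u + offs[k, 2] * v
        cc <- cyl_cor(best$R, ctr)
        if (cc > best$cor) { best$cor <- cc; best$centre <- ctr }
      }
      R0 <- best$R; c0 <- best$centre
      obj <- function(par) {
        -cyl_cor(R0 %*% small_rotation(par[1], par[2]), c0 + par[3:5])
      }
      fit <- stats::optim(rep(0, 5), obj, method = "Nelder-Mead",
                          control = list(maxit = 400,
                                         parscale = c(0.2, 0.2, 1, 1, 1)))
      if (-fit$value > best$cor) {
        best$R <- R0 %*% small_rotation(fit$par[1], fit$par[2])
        best$centre <- c0 + fit$par[3:5]
        best$cor <- -fit$value
      }
    }
    # accept only placements supported along the whole axis: a template
    # lying across a chain rather than along it correlates in one axial
    # half only
    parts <- cyl_cor_parts(best$R, best$centre)
    if (best$cor >= cor_cutoff &&
        min(parts[["lo"]], parts[["hi"]]) >= cor_cutoff - 0.2 &&
        parts[["core"]] >= 0.3 &&
        contrast_of(best$R, best$centre) >= 2)
      placements[[length(placements) + 1L]] <- best
  }
  if (length(placements) == 0L) return(list())
  placements <- placements[order(-vapply(placements, `[[`, numeric(1),
                                         "cor"))]

  out <- list()
  kept_axes <- list()
  for (p in placements) {
    # duplicate suppression on the axis segment itself: two placements on
    # the same helix have nearly coincident axis segments even when one
    # is slightly tilted or shifted along the axis
    axis_dir <- p$R %*% c(0, 0, 1)
    seg <- list(a = p$centre - half_len * as.vector(axis_dir),
                b = p$centre + half_len * as.vector(axis_dir))
    if (length(kept_axes) > 0) {
      dmin <- min(vapply(kept_axes, function(k)
        segment_segment_distance(seg$a, seg$b, k$a, k$b), numeric(1)))
      if (dmin < 4) next
    }
    # fit the helical phase: spin about the axis and axial shift
    best_ph <- list(val = -Inf, spin = 0, dz = 0)
    for (sp in seq(0, 2 * pi, length.out = 25)[-25]) {
      for (dz in seq(-0.75, 0.75, by = 0.375)) {
        atoms <- rbind(tz, t_fill) %*% t(spin_z(sp))
        atoms[, 3] <- atoms[, 3] + dz
        pts <- sweep(atoms %*% t(p$R), 2, p$centre, `+`)
        val <- mean(interp_density(map, pts))
        if (val > best_ph$val) best_ph <- list(val = val, spin = sp, dz = dz)
      }
    }
    atoms <- tz %*% t(spin_z(best_ph$spin))
    atoms[, 3] <- atoms[, 3] + best_ph$dz
    placed <- sweep(atoms %*% t(p$R), 2, p$centre, `+`)
    ca_placed <- placed[t_is_ca, , drop = FALSE]
    frag <- atoms_tibble(ca_placed, placed[!t_is_ca, , drop = FALSE],
                         chain_id = "H")
    attr(frag, "kind") <- "helix"
    attr(frag, "cor") <- p$cor
    out[[length(out) + 1L]] <- frag
    kept_axes[[length(kept_axes) + 1L]] <- seg
    if (length(out) >= max_hits) break
  }
  out
}

# minimum distance between two 3-D line segments (a1-b1, a2-b2)
segment_segment_distance <- function(a1, b1, a2, b2) {
  d1 <- b1 - a1; d2 <- b2 - a2; r <- a1 - a2
  A <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  tiny <- 1e-12
  if (A <= tiny && e <= tiny) return(sqrt(sum(r * r)))
  if (A <= tiny) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= tiny) {
      t <- 0; s <- min(max(-c_ / A, 0), 1)
    } else {
      b <- sum(d1 * d2)
      denom <- A * e - b * b
      s <- if (denom > tiny) min(max((b * f - c_ * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / A, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / A, 0), 1) }
    }
  }
  p1 <- a1 + s * d1; p2 <- a2 + t * d2
  sqrt(sum((p1 - p2)^2))
}

gaussian_density_at <- function(pts, atoms, sigma) {
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(atoms))) {
    d2 <- (pts[, 1] - atoms[i, 1])^2 + (pts[, 2] - atoms[i, 2])^2 +
      (pts[, 3] - atoms[i, 3])^2
    out <- out + exp(-d2 / (2 * sigma^2))
  }
  out
}

local_maxima_xyz <- function(map, n_top) {
  v <- map$values
  d <- dim(v)
  if (any(d < 3)) return(matrix(numeric(0), 0, 3))
  core <- v[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  ismax <- array(TRUE, dim = dim(core))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- v[(2 + dx):(d[1] - 1 + dx), (2 + dy):(d[2] - 1 + dy),
            (2 + dz):(d[3] - 1 + dz)]
    ismax <- ismax & core >= nb
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  vals <- core[idx]
  keep <- vals > mean(v) + stats::sd(as.vector(v))
  idx <- idx[keep, , drop = FALSE]
  vals <- vals[keep]
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  ord <- order(-vals)[seq_len(min(n_top, length(vals)))]
  grid_to_xyz(map, idx[ord, , drop = FALSE])   # idx is 1-based core => 0-based full grid offset +1-1
}

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - i / n)                # upper hemisphere only
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

rotation_to_z <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  z <- c(0, 0, 1)
  vcross <- c(z[2] * dir[3] - z[3] * dir[2],
              z[3] * dir[1] - z[1] * dir[3],
              z[1] * dir[2] - z[2] * dir[1])
  cc <- sum(z * dir)
  if (sum(vcross^2) < 1e-12)
    return(if (cc > 0) diag(3) else diag(c(1, -1, -1)))
  vx <- matrix(c(0, vcross[3], -vcross[2],
                 -vcross[3], 0, vcross[1],
                 vcross[2], -vcross[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cc)
}

spin_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

small_rotation <- function(ax, ay) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rx %*% Ry
}
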