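#' Morphing parameters
#'
#' @param window_halfwidth Number of path points considered on either side
#'   of the point being moved (default 5, i.e. an 11-point window).
#' @param max_shift Cap on the shift applied per iteration, Angstroms
#'   (prevents a path jumping between parallel ridges).
#' @param n_iterations Number of morph passes.
#' @return A `morph_params` list.
#' @export
morph_params <- function(window_halfwidth = 5, max_shift = 2,
                         n_iterations = 3) {
  stopifnot(window_halfwidth >= 0, max_shift > 0, n_iterations >= 1)
  structure(list(window_halfwidth = as.integer(window_halfwidth),
                 max_shift = max_shift,
                 n_iterations = as.integer(n_iterations)),
            class = "morph_params")
}

#' Extract ridgeline ("bones") marker points from a region
#'
#' Places unordered off-grid marker points at the highest-density points
#' along ridgelines of the region: for each region voxel with a full 3x3x3
#' neighbourhood, a quadratic is fitted to the 27 neighbouring densities;
#' the local ridge direction is the Hessian eigenvector with the largest
#' eigenvalue, and the point is kept when the density is a local maximum in
#' the two transverse directions (both transverse eigenvalues negative),
#' refined by the Newton shift within the transverse plane (clamped to one
#' voxel). Points closer than half a voxel to a higher-density marker are
#' thinned away. Both main-chain and side-chain ridges are captured;
#' connectivity is deliberately not defined.
#'
#' @param map A [density_map()].
#' @param region A `map_region`.
#' @return A tibble of class `bones_set`: columns `x`, `y`, `z`, `density`.
#' @export
extract_bones <- function(map, region) {
  dims <- dim(map$values)
  vs <- map$voxel_size
  ijk <- lin_to_ijk(region$idx, dims)
  interior <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] - 2 &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] - 2 &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3] - 2
  ijk <- ijk[interior, , drop = FALSE]
  if (nrow(ijk) == 0L) return(empty_bones())

  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offA <- sweep(off, 2, vs, `*`)   # offsets in Angstroms
  X <- cbind(1, offA[, 1], offA[, 2], offA[, 3],
             offA[, 1]^2, offA[, 2]^2, offA[, 3]^2,
             offA[, 1] * offA[, 2], offA[, 1] * offA[, 3],
             offA[, 2] * offA[, 3])
  pinv <- solve(crossprod(X), t(X))   # fixed design, one factorization

  # gather the 27 neighbour values for every candidate voxel
  nbr <- matrix(0, nrow(ijk), 27L)
  for (k in seq_len(27L)) {
    nbr[, k] <- map$values[cbind(ijk[, 1] + off[k, 1] + 1L,
                                 ijk[, 2] + off[k, 2] + 1L,
                                 ijk[, 3] + off[k, 3] + 1L)]
  }
  coef <- nbr %*% t(pinv)             # n x 10 quadratic coefficients

  centres <- grid_to_xyz(map, ijk)
  clamp <- min(vs)
  keep <- logical(nrow(ijk))
  pos <- centres
  for (i in seq_len(nrow(ijk))) {
    a <- coef[i, ]
    H <- matrix(c(2 * a[5], a[8], a[9],
                  a[8], 2 * a[6], a[10],
                  a[9], a[10], 2 * a[7]), 3, 3)
    b <- a[2:4]
    eg <- eigen(H, symmetric = TRUE)
    lam <- eg$values                  # descending
    if (!(lam[2] < 0 && lam[3] < 0)) next
    Vt <- eg$vectors[, 2:3, drop = FALSE]
    s <- -Vt %*% ((t(Vt) %*% b) / lam[2:3])
    ns <- sqrt(sum(s^2))
    if (ns > clamp) s <- s * clamp / ns
    keep[i] <- TRUE
    pos[i, ] <- centres[i, ] + as.vector(s)
  }
  if (!any(keep)) return(empty_bones())
  pos <- pos[keep, , drop = FALSE]
  dens <- interp_density(map, pos)

  # thin: drop points within half a voxel of a denser retained point
  ord <- order(-dens, pos[, 1], pos[, 2], pos[, 3])
  pos <- pos[ord, , drop = FALSE]
  dens <- dens[ord]
  r2 <- (0.5 * min(vs))^2
  kept <- integer(0)
  for (i in seq_len(nrow(pos))) {
    if (length(kept) > 0) {
      d2 <- (pos[kept, 1] - pos[i, 1])^2 + (pos[kept, 2] - pos[i, 2])^2 +
        (pos[kept, 3] - pos[i, 3])^2
      if (any(d2 < r2)) next
    }
    kept <- c(kept, i)
  }
  out <- tibble::tibble(x = pos[kept, 1], y = pos[kept, 2],
                        z = pos[kept, 3], density = dens[kept])
  class(out) <- c("bones_set", class(out))
  out
}

empty_bones <- function() {
  out <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                        density = numeric(0))
  class(out) <- c("bones_set", class(out))
  out
}

# index of the nearest bones point for each row of pts (n x 3)
nearest_bones_index <- function(pts, bones) {
  bx <- as.matrix(bones[, c("x", "y", "z")])
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (bx[, 1] - pts[i, 1])^2 + (bx[, 2] - pts[i, 2])^2 +
      (bx[, 3] - pts[i, 3])^2
    which.min(d2)
  }, integer(1))
}

#' Morph a trace path onto the ridgeline markers
#'
#' For each path point, the points up to `window_halfwidth` positions on
#' either side are gathered; each is assigned the shift that would move it
#' onto its nearest bones point, and the average of those shifts (clamped to
#' `max_shift`) is applied to the central point. All points move
#' simultaneously within one iteration, and the procedure is repeated
#' `n_iterations` times. The output has the same number of points in the
#' same order; an empty bones set returns the path unchanged.
#'
#' @param path A `trace_path`.
#' @param bones A `bones_set` from [extract_bones()].
#' @param params A [morph_params()].
#' @return The morphed `trace_path`.
#' @export
morph_path <- function(path, bones, params = morph_params()) {
  if (nrow(bones) == 0L || nrow(path$points) == 0L) return(path)
  pts <- path$points
  n <- nrow(pts)
  w <- params$window_halfwidth
  bx <- as.matrix(bones[, c("x", "y", "z")])
  for (it in seq_len(params$n_iterations)) {
    ni <- nearest_bones_index(pts, bones)
    shifts <- bx[ni, , drop = FALSE] - pts
    newpts <- pts
    for (i in seq_len(n)) {
      win <- max(1, i - w):min(n, i + w)
      s <- colMeans(shifts[win, , drop = FALSE])
      ns <- sqrt(sum(s^2))
      if (ns > params$max_shift) s <- s * params$max_shift / ns
      newpts[i, ] <- pts[i, ] + s
    }
    pts <- newpts
  }
  path$points <- pts
  path$ijk <- NULL                      # off-grid after morphing
  path$unweighted_length <- if (n > 1)
    sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                        pts[-n, , drop = FALSE])^2))) else 0
  path
}
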