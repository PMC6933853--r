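#' Segmentation parameters
#'
#' Controls the iterative contour-lowering segmentation. Regions grow as the
#' contour level walks down a descending threshold schedule; a region that
#' would become branched (a side arm longer than `branch_cutoff`, usually
#' merged side-chain density between adjacent chains) is frozen at its last
#' unbranched level and masked out of the working map except for its end
#' caps, which are retained so later connections can still be made.
#'
#' @param branch_cutoff Maximum allowed branch length in Angstroms
#'   (default 10).
#' @param connectivity Voxel neighbourhood, 26 (default) or 6.
#' @param n_levels Number of contour levels in the default schedule.
#' @param min_region_points Smallest voxel count for a region to be born.
#' @param floor_threshold Density level at which growth stops; `NULL` means
#'   mean + 1 SD of the map values.
#' @param top_quantile Quantile of map values at which the schedule starts.
#' @param schedule Optional explicit strictly-decreasing threshold vector
#'   (overrides `n_levels`/`top_quantile`).
#' @param path_params A [path_weight_params()] used for branch measurement.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(branch_cutoff = 10, connectivity = 26,
                                n_levels = 40, min_region_points = 5,
                                floor_threshold = NULL,
                                top_quantile = 0.999, schedule = NULL,
                                path_params = path_weight_params()) {
  stopifnot(branch_cutoff > 0, connectivity %in% c(6, 26), n_levels >= 2)
  if (!is.null(schedule) && any(diff(schedule) >= 0))
    stop("threshold schedule must be strictly decreasing", call. = FALSE)
  structure(list(branch_cutoff = branch_cutoff,
                 connectivity = as.integer(connectivity),
                 n_levels = as.integer(n_levels),
                 min_region_points = as.integer(min_region_points),
                 floor_threshold = floor_threshold,
                 top_quantile = top_quantile, schedule = schedule,
                 path_params = path_params),
            class = "segmentation_params")
}

seg_floor <- function(map, params) {
  if (!is.null(params$floor_threshold)) return(params$floor_threshold)
  v <- as.vector(map$values)
  mean(v) + stats::sd(v)
}

# Descending schedule between the top quantile and the floor; geometric when
# both ends are positive (density spans orders of magnitude near peaks),
# linear otherwise.
seg_schedule <- function(map, params) {
  if (!is.null(params$schedule)) return(params$schedule)
  v <- as.vector(map$values)
  top <- stats::quantile(v, params$top_quantile, names = FALSE)
  floor_t <- seg_floor(map, params)
  if (top <= floor_t) return(floor_t)
  if (floor_t > 0) {
    exp(seq(log(top), log(floor_t), length.out = params$n_levels))
  } else {
    seq(top, floor_t, length.out = params$n_levels)
  }
}

new_region <- function(idx, threshold, map, id = NA_integer_) {
  v <- as.vector(map$values)[idx + 1L]
  structure(list(id = id, idx = as.integer(idx), threshold = threshold,
                 max_density = max(v), n_points = length(idx),
                 is_branched = NA, branch_lengths = numeric(0),
                 end_caps = integer(0), path = NULL),
            class = "map_region")
}

#' @export
print.map_region <- function(x, ...) {
  cat(sprintf(
    "<map_region> %d voxels at threshold %.4g (max density %.4g)%s\n",
    x$n_points, x$threshold, x$max_density,
    if (isTRUE(x$is_branched)) ", branched"
    else if (isFALSE(x$is_branched)) ", unbranched" else ""))
  invisible(x)
}

#' Connected regions above a contour level
#'
#' Identifies the maximal sets of grid points with density above `threshold`
#' that are mutually connected through the chosen voxel neighbourhood. Every
#' above-threshold point belongs to exactly one region; regions smaller than
#' `min_points` are dropped.
#'
#' @param map A [density_map()].
#' @param threshold Contour level (finite).
#' @param min_points Minimum voxel count per returned region.
#' @param connectivity Voxel neighbourhood, 26 (default) or 6.
#' @return List of `map_region` objects in descending order of their maximum
#'   density.
#' @export
connected_regions <- function(map, threshold, min_points = 1,
                              connectivity = 26) {
  stopifnot(is.finite(threshold))
  dims <- dim(map$values)
  labels <- cpp_label_components(as.vector(map$values), as.integer(dims),
                                 threshold, as.integer(connectivity))
  if (all(labels == 0L)) return(list())
  keep <- labels != 0L
  idx_by_label <- split((which(keep) - 1L), labels[keep])
  regions <- lapply(idx_by_label, new_region, threshold = threshold,
                    map = map)
  regions <- regions[lengths(lapply(regions, `[[`, "idx")) >= min_points]
  ord <- order(-vapply(regions, `[[`, numeric(1), "max_density"),
               vapply(regions, function(r) r$idx[1], integer(1)))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$id <- i
  unname(regions)
}

#' Detect branching of a region
#'
#' Computes the region's main path (between the end points B and C of
#' [region_endpoints()]), assigns off-path voxels to connected side branches,
#' and measures each branch as the unweighted Angstrom length of its longest
#' minimum-weight path back to the main path. The region is branched when
#' any branch exceeds `branch_cutoff`.
#'
#' @param region A `map_region`.
#' @param map The source [density_map()].
#' @param params A [segmentation_params()].
#' @return The region with `is_branched`, `branch_lengths`, `path` and
#'   `end_caps` filled in.
#' @export
detect_branching <- function(region, map, params = segmentation_params()) {
  dims <- dim(map$values)
  if (region$n_points <= 1L) {
    region$is_branched <- FALSE
    region$branch_lengths <- numeric(0)
    ep <- region_endpoints(region, map, params$path_params)
    region$path <- ep$path
    region$end_caps <- region$idx
    return(region)
  }
  ep <- region_endpoints(region, map, params$path_params)
  region$path <- ep$path
  path_lin <- ijk_to_lin(ep$path$ijk, dims)
  region$end_caps <- end_cap_voxels(region, path_lin, dims)
  off <- setdiff(region$idx, path_lin)
  if (length(off) == 0L) {
    region$is_branched <- FALSE
    region$branch_lengths <- numeric(0)
    return(region)
  }
  dj <- region_dijkstra(region, map, path_lin, params$path_params)
  # group off-path voxels into connected branches
  ind <- numeric(length(map$values))
  ind[off + 1L] <- 1
  blab <- cpp_label_components(ind, as.integer(dims), 0.5,
                               params$connectivity)
  lens <- tapply(dj$udist[off + 1L], blab[off + 1L], max)
  lens <- as.numeric(lens[is.finite(lens)])
  region$branch_lengths <- sort(lens, decreasing = TRUE)
  region$is_branched <- any(region$branch_lengths > params$branch_cutoff)
  region
}

# voxels within one voxel (26-neighbourhood) of either path end
end_cap_voxels <- function(region, path_lin, dims) {
  ends <- lin_to_ijk(c(path_lin[1], path_lin[length(path_lin)]), dims)
  ijk <- lin_to_ijk(region$idx, dims)
  near <- rep(FALSE, nrow(ijk))
  for (e in seq_len(nrow(ends))) {
    d <- pmax(abs(ijk[, 1] - ends[e, 1]), abs(ijk[, 2] - ends[e, 2]),
              abs(ijk[, 3] - ends[e, 3]))
    near <- near | d <= 1
  }
  region$idx[near]
}

#' Mask an accepted region out of the working map
#'
#' Sets the region's voxels (except its end caps) to the masking sentinel,
#' one map standard deviation below the floor threshold, so the region is no
#' longer considered while later, weaker connections can still attach at the
#' retained end caps. Masking is idempotent.
#'
#' @param state A `segmentation_state` (see [grow_segments()]).
#' @param region A `map_region` with `end_caps` filled in.
#' @return The updated `segmentation_state`.
#' @export
mask_region <- function(state, region) {
  to_mask <- setdiff(region$idx, region$end_caps)
  state$working_map$values[to_mask + 1L] <- state$sentinel
  state
}

#' Iterative contour-lowering segmentation
#'
#' Walks a descending threshold schedule. At each level, connected regions
#' of the working map are identified; a region that would become branched is
#' frozen at its last unbranched level and masked (except end caps); when
#' two accepted regions first become connected they are merged into a single
#' region replacing both, unless the merge itself is branched, in which case
#' the merge is reverted and the parents are frozen. Growth stops at the
#' floor threshold.
#'
#' @param map A [density_map()].
#' @param params A [segmentation_params()].
#' @param seeds Optional list of `map_region` to start from (e.g. from
#'   [seed_regions_from_fragments()]); by default the highest-density
#'   regions of the map seed themselves as the schedule descends.
#' @return A `segmentation_state` list: `working_map` (masked map),
#'   `regions` (accepted `map_region`s, descending max density),
#'   `current_threshold`, `sentinel`, `floor_threshold`.
#' @export
grow_segments <- function(map, params = segmentation_params(),
                          seeds = NULL) {
  dims <- dim(map$values)
  v0 <- as.vector(map$values)
  floor_t <- seg_floor(map, params)
  sched <- seg_schedule(map, params)
  sentinel <- floor_t - stats::sd(v0)
  state <- list(working_map = map, regions = list(),
                current_threshold = Inf, sentinel = sentinel,
                floor_threshold = floor_t)
  class(state) <- "segmentation_state"

  regions <- list()           # all regions ever accepted, by id
  status <- character(0)      # "active" / "frozen" / "consumed"
  claim <- integer(length(v0))  # voxel -> region id (active: all points;
                                # frozen: end caps only)
  failed_merges <- character(0)
  next_id <- 0L

  for (s in seeds %||% list()) {
    if (is.null(s) || length(s$idx) == 0L) next
    cand <- new_region(s$idx, sched[1], map)
    cand <- detect_branching(cand, map, params)
    next_id <- next_id + 1L
    cand$id <- next_id
    regions[[next_id]] <- cand
    status[next_id] <- "active"
  }
  for (id in seq_len(next_id)) {
    claim[regions[[id]]$idx + 1L] <- id
  }

  claim_region <- function(claim, r, st) {
    claim[claim == r$id] <- 0L
    if (st == "active") claim[r$idx + 1L] <- r$id
    else claim[r$end_caps + 1L] <- r$id
    claim
  }

  # mask a frozen region plus its one-voxel shell (minus end caps and
  # voxels claimed by other regions), so the thin low-density sleeve
  # around a masked chain does not respawn as spurious regions
  freeze_mask <- function(state, r) {
    state <- mask_region(state, r)
    shell <- setdiff(dilate_idx(r$idx, dims), r$idx)
    shell <- shell[claim[shell + 1L] == 0L]
    shell <- setdiff(shell, r$end_caps)
    state$working_map$values[shell + 1L] <- state$sentinel
    state
  }

  for (t in sched) {
    state$current_threshold <- t
    wv <- as.vector(state$working_map$values)
    labels <- cpp_label_components(wv, as.integer(dims), t,
                                   params$connectivity)
    if (all(labels == 0L)) next
    keep <- labels != 0L
    comps <- split(which(keep) - 1L, labels[keep])
    # deterministic order: by descending component max original density
    cmax <- vapply(comps, function(ix) max(v0[ix + 1L]), numeric(1))
    comps <- comps[order(-cmax, vapply(comps, min, numeric(1)))]

    for (comp in comps) {
      touched <- unique(claim[comp + 1L])
      touched <- touched[touched != 0L]
      touched <- touched[status[touched] != "consumed"]

      if (length(touched) == 0L) {
        if (length(comp) < params$min_region_points) next
        cand <- new_region(comp, t, map)
        cand <- detect_branching(cand, map, params)
        if (!cand$is_branched) {
          next_id <- next_id + 1L
          cand$id <- next_id
          regions[[next_id]] <- cand
          status[next_id] <- "active"
          claim <- claim_region(claim, cand, "active")
        }
      } else if (length(touched) == 1L && status[touched] == "active") {
        r <- regions[[touched]]
        # unchanged at this level -> nothing to re-test; otherwise the
        # region becomes the overlapping component (this also reconciles
        # seed regions, whose initial point sets are not contour-derived)
        if (length(comp) == r$n_points && all(comp == r$idx)) next
        cand <- new_region(comp, t, map, id = r$id)
        cand <- detect_branching(cand, map, params)
        if (cand$is_branched) {
          status[r$id] <- "frozen"
          claim <- claim_region(claim, r, "frozen")
          state <- freeze_mask(state, r)
        } else {
          regions[[r$id]] <- cand
          claim <- claim_region(claim, cand, "active")
        }
      } else if (length(touched) >= 2L ||
                 (length(touched) == 1L && status[touched] == "frozen")) {
        # a merge that branched stays branched at lower contours (density
        # only accretes), so a failed parent set need not be retried
        key <- paste(sort(touched), collapse = "-")
        if (key %in% failed_merges) next
        parents <- regions[touched]
        # parents' points are restricted to the current contour so the
        # child is contour-consistent (only matters for seed regions,
        # whose initial point sets are geometric, not contour-derived)
        par_idx <- unlist(lapply(parents, `[[`, "idx"))
        par_idx <- par_idx[v0[par_idx + 1L] > t]
        union_idx <- sort(unique(c(comp, par_idx)))
        cand <- new_region(union_idx, t, map)
        # candidate must be evaluated on unmasked density
        cand <- detect_branching(cand, map, params)
        if (cand$is_branched) {
          failed_merges <- c(failed_merges, key)
          for (r in parents) {
            if (status[r$id] == "active") {
              status[r$id] <- "frozen"
              claim <- claim_region(claim, r, "frozen")
              state <- freeze_mask(state, r)
            }
          }
        } else {
          # merge consumes the parents; restore their masked density so the
          # child keeps growing as one region
          for (r in parents) {
            if (status[r$id] == "frozen") {
              masked <- setdiff(r$idx, r$end_caps)
              state$working_map$values[masked + 1L] <- v0[masked + 1L]
            }
            status[r$id] <- "consumed"
            claim[claim == r$id] <- 0L
          }
          next_id <- next_id + 1L
          cand$id <- next_id
          regions[[next_id]] <- cand
          status[next_id] <- "active"
          claim <- claim_region(claim, cand, "active")
        }
      }
    }
  }

  alive <- which(status %in% c("active", "frozen"))
  out <- regions[alive]
  ord <- order(-vapply(out, `[[`, numeric(1), "max_density"),
               vapply(out, function(r) r$idx[1], integer(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- i
  state$regions <- unname(out)
  state
}

#' Seed regions from secondary-structure fragments
#'
#' Converts fragments (atom tibbles) into initial regions: all grid points
#' within `radius` Angstroms of any fragment atom and above the floor
#' threshold.
#'
#' @param map A [density_map()].
#' @param fragments List of atom tibbles (columns `x`, `y`, `z`).
#' @param params A [segmentation_params()].
#' @param radius Inclusion radius in Angstroms (default 3).
#' @return List of `map_region` seeds (possibly empty).
#' @export
seed_regions_from_fragments <- function(map, fragments,
                                        params = segmentation_params(),
                                        radius = 3) {
  dims <- dim(map$values)
  floor_t <- seg_floor(map, params)
  lapply(seq_along(fragments), function(i) {
    fr <- fragments[[i]]
    xyz <- as.matrix(fr[, c("x", "y", "z")])
    g <- xyz_to_grid(map, xyz)
    rad_vox <- ceiling(radius / min(map$voxel_size))
    lo <- pmax(floor(apply(g, 2, min)) - rad_vox, 0)
    hi <- pmin(ceiling(apply(g, 2, max)) + rad_vox, dims - 1)
    grid <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    pts <- grid_to_xyz(map, grid)
    keep <- rep(FALSE, nrow(pts))
    for (k in seq_len(nrow(xyz))) {
      d2 <- (pts[, 1] - xyz[k, 1])^2 + (pts[, 2] - xyz[k, 2])^2 +
        (pts[, 3] - xyz[k, 3])^2
      keep <- keep | d2 <= radius^2
    }
    idx <- ijk_to_lin(grid[keep, , drop = FALSE], dims)
    idx <- idx[as.vector(map$values)[idx + 1L] > floor_t]
    if (length(idx) == 0L) return(NULL)
    new_region(sort(idx), floor_t, map, id = i)
  }) |> Filter(f = Negate(is.null))
}

# all voxels within one step (26-neighbourhood) of the given 0-based
# linear indices, clipped to the grid
dilate_idx <- function(idx, dims) {
  ijk <- lin_to_ijk(idx, dims)
  out <- idx
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    s <- cbind(ijk[, 1] + dx, ijk[, 2] + dy, ijk[, 3] + dz)
    ok <- s[, 1] >= 0 & s[, 1] < dims[1] & s[, 2] >= 0 &
      s[, 2] < dims[2] & s[, 3] >= 0 & s[, 3] < dims[3]
    out <- c(out, ijk_to_lin(s[ok, , drop = FALSE], dims))
  }
  sort(unique(out))
}
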