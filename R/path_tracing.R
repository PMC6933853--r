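#' Path-weighting parameters
#'
#' Controls the density-derived edge weights used for chain tracing. A step
#' entering a voxel of density `rho` costs
#' `w = ((rho_max - rho) / (rho_max - rho_min))^exponent_a`, so steps through
#' density near the region maximum are nearly free and steps through the
#' lowest density in the region cost about one; the minimum-weight path is
#' therefore the route with the highest minimum density.
#'
#' By default each step uses the mean of the two endpoint voxel weights
#' (`symmetric = TRUE`), which makes path cost independent of traversal
#' direction; `symmetric = FALSE` weights by the entered voxel only. Diagonal
#' steps scale the weight by the Euclidean step length in voxels so the cost
#' approximates a line integral.
#'
#' @param exponent_a Weight exponent (> 0; default 2).
#' @param rho_min,rho_max Density range of the region; left `NULL`, they are
#'   taken from the region's voxels at call time.
#' @param symmetric Use direction-independent (mean-of-endpoints) weights.
#' @param connectivity Voxel neighbourhood: 26 (default) or 6.
#' @return A `path_weight_params` list.
#' @export
path_weight_params <- function(exponent_a = 2, rho_min = NULL,
                               rho_max = NULL, symmetric = TRUE,
                               connectivity = 26) {
  stopifnot(exponent_a > 0, connectivity %in% c(6, 26))
  if (!is.null(rho_min) && !is.null(rho_max) && !(rho_max > rho_min) &&
      !(rho_max == rho_min))
    stop("rho_max must be >= rho_min", call. = FALSE)
  structure(list(exponent_a = exponent_a, rho_min = rho_min,
                 rho_max = rho_max, symmetric = symmetric,
                 connectivity = as.integer(connectivity)),
            class = "path_weight_params")
}

#' Density-to-weight transform for path tracing
#'
#' @param rho Density value(s); clamped into `[rho_min, rho_max]`.
#' @param params A [path_weight_params()] with `rho_min`/`rho_max` set.
#' @return Weight(s) in `[0, 1]`, monotone decreasing in `rho`. A degenerate
#'   flat region (`rho_max == rho_min`) gives weight 0 everywhere.
#' @export
edge_weight <- function(rho, params) {
  lo <- params$rho_min
  hi <- params$rho_max
  if (is.null(lo) || is.null(hi))
    stop("edge_weight needs rho_min and rho_max in params", call. = FALSE)
  if (hi == lo) return(rep(0, length(rho)))
  t <- (hi - pmin(pmax(rho, lo), hi)) / (hi - lo)
  t^params$exponent_a
}

region_rho_range <- function(region, map, params) {
  if (!is.null(params$rho_min) && !is.null(params$rho_max))
    return(c(params$rho_min, params$rho_max))
  v <- as.vector(map$values)[region$idx + 1L]
  range(v)
}

# Weighted Dijkstra over a region from one or more 0-based linear sources.
region_dijkstra <- function(region, map, sources_lin, params) {
  dims <- dim(map$values)
  rr <- region_rho_range(region, map, params)
  mask <- logical(length(map$values))
  mask[region$idx + 1L] <- TRUE
  cpp_dijkstra(as.vector(map$values), mask, as.integer(dims),
               map$voxel_size, as.integer(sources_lin),
               rr[1], rr[2], params$exponent_a, params$symmetric,
               params$connectivity)
}

# reconstruct 0-based linear path from Dijkstra parents, source -> target
walk_parents <- function(parent, target_lin) {
  path <- integer(0)
  cur <- target_lin
  repeat {
    path <- c(cur, path)
    nxt <- parent[cur + 1L]
    if (nxt < 0) break
    cur <- nxt
  }
  path
}

new_trace_path <- function(ijk, map, region_id = NA_integer_,
                           weight = NA_real_) {
  pts <- grid_to_xyz(map, ijk)
  ulen <- if (nrow(pts) > 1)
    sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])^2))) else 0
  structure(list(points = pts, ijk = ijk, region_id = region_id,
                 weight = weight, unweighted_length = ulen),
            class = "trace_path")
}

#' @export
print.trace_path <- function(x, ...) {
  cat(sprintf("<trace_path> %d points, %.2f A unweighted length\n",
              nrow(x$points), x$unweighted_length))
  invisible(x)
}

#' @export
as.data.frame.trace_path <- function(x, ...) {
  as.data.frame(stats::setNames(as.data.frame(x$points),
                                c("x", "y", "z")))
}

#' Minimum-weight path between two voxels of a region
#'
#' Traces the route through the region that minimizes the summed
#' density-derived step weights (see [path_weight_params()]) — i.e. the path
#' with the highest minimum density. Ties are broken deterministically by
#' lexicographic voxel order.
#'
#' @param region A region, as from [connected_regions()].
#' @param map The [density_map()] the region was derived from.
#' @param start,end 0-based grid index triples, both inside the region.
#' @param params A [path_weight_params()].
#' @return A `trace_path`: ordered Angstrom points (grid-neighbour steps),
#'   with total `weight` and `unweighted_length` attached.
#' @export
min_weight_path <- function(region, map, start, end,
                            params = path_weight_params()) {
  dims <- dim(map$values)
  s <- ijk_to_lin(start, dims)
  e <- ijk_to_lin(end, dims)
  if (!(s %in% region$idx) || !(e %in% region$idx))
    stop("start and end must lie inside the region", call. = FALSE)
  dj <- region_dijkstra(region, map, s, params)
  if (!is.finite(dj$dist[e + 1L]))
    stop("start and end are not connected within the region", call. = FALSE)
  lin_path <- walk_parents(dj$parent, e)
  new_trace_path(lin_to_ijk(lin_path, dims), map,
                 region_id = region$id %||% NA_integer_,
                 weight = dj$dist[e + 1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End points and main path of a region
#'
#' Starting from the region's maximum-density voxel A (ties broken by
#' lexicographic grid order), finds the voxel B at the largest weighted-path
#' distance from A, then the voxel C at the largest weighted-path distance
#' from B. The unweighted Angstrom length of the B-C path is the region's
#' length.
#'
#' @inheritParams min_weight_path
#' @return List with `B`, `C` (0-based grid index triples), `path` (the B-C
#'   `trace_path`) and `length` (Angstroms).
#' @export
region_endpoints <- function(region, map, params = path_weight_params()) {
  dims <- dim(map$values)
  v <- as.vector(map$values)[region$idx + 1L]
  a_lin <- region$idx[order(-v, region$idx)[1]]
  if (length(region$idx) == 1L) {
    ijk <- lin_to_ijk(a_lin, dims)
    return(list(B = ijk[1, ], C = ijk[1, ],
                path = new_trace_path(ijk, map,
                                      region_id = region$id %||% NA_integer_,
                                      weight = 0),
                length = 0))
  }
  # "furthest" = largest unweighted length of the minimum-weight path (the
  # same measure that defines the region length); the weighted distance
  # itself is degenerate along high-density ridges where weights are ~0
  furthest <- function(dj) {
    d <- dj$udist[region$idx + 1L]
    d[!is.finite(d)] <- -Inf
    region$idx[order(-d, region$idx)[1]]
  }
  b_lin <- furthest(region_dijkstra(region, map, a_lin, params))
  dj_b <- region_dijkstra(region, map, b_lin, params)
  c_lin <- furthest(dj_b)
  lin_path <- walk_parents(dj_b$parent, c_lin)
  path <- new_trace_path(lin_to_ijk(lin_path, dims), map,
                         region_id = region$id %||% NA_integer_,
                         weight = dj_b$dist[c_lin + 1L])
  list(B = lin_to_ijk(b_lin, dims)[1, ], C = lin_to_ijk(c_lin, dims)[1, ],
       path = path, length = path$unweighted_length)
}

#' Length of a side branch
#'
#' The unweighted Angstrom length of the minimum-weight path from
#' `branch_point` to its attachment on the main path; 0 for a point on the
#' path itself.
#'
#' @inheritParams min_weight_path
#' @param main_path The region's B-C `trace_path`.
#' @param branch_point 0-based grid index triple inside the region.
#' @return Length in Angstroms.
#' @export
branch_length <- function(region, map, main_path, branch_point,
                          params = path_weight_params()) {
  dims <- dim(map$values)
  bp <- ijk_to_lin(branch_point, dims)
  path_lin <- ijk_to_lin(main_path$ijk, dims)
  if (bp %in% path_lin) return(0)
  dj <- region_dijkstra(region, map, path_lin, params)
  u <- dj$udist[bp + 1L]
  if (!is.finite(u))
    stop("branch_point is not connected to the main path within the region",
         call. = FALSE)
  u
}
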