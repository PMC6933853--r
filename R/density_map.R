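#' Density map objects
#'
#' A `density_map` is a regular 3-D scalar grid with a physical voxel size and
#' an origin, the object a tracing run interprets. Values are stored in an R
#' array laid out x-fastest; grid indices are 0-based throughout the package,
#' and the Angstrom position of grid index `(i, j, k)` is
#' `origin + c(i, j, k) * voxel_size`.
#'
#' @param values 3-D numeric array of density values (arbitrary units).
#' @param voxel_size Angstroms per grid step along each axis; a scalar is
#'   recycled to all three axes.
#' @param origin Angstrom position of grid index `(0, 0, 0)` (length 3).
#' @param resolution_hint Nominal map resolution in Angstroms, or `NA`.
#'
#' @return An object of class `density_map`: a list with elements `values`,
#'   `voxel_size`, `origin` and `resolution_hint`.
#' @export
density_map <- function(values, voxel_size = 1, origin = c(0, 0, 0),
                        resolution_hint = NA_real_) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size components must be finite and > 0", call. = FALSE)
  if (any(!is.finite(values)))
    stop("density values must all be finite", call. = FALSE)
  if (any(!is.finite(origin)))
    stop("origin must be finite", call. = FALSE)
  structure(
    list(values = values, voxel_size = voxel_size, origin = origin,
         resolution_hint = as.numeric(resolution_hint)[1]),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d grid, voxel %s A, origin (%s) A\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  values: min %.4g, max %.4g, mean %.4g, sd %.4g",
              min(x$values), max(x$values), mean(x$values),
              stats::sd(as.vector(x$values))))
  if (is.finite(x$resolution_hint))
    cat(sprintf("; nominal resolution %.2f A", x$resolution_hint))
  cat("\n")
  invisible(x)
}

#' Convert between 0-based grid indices and Angstrom coordinates
#'
#' @param map A [density_map()].
#' @param ijk Integer matrix (n x 3) of 0-based grid indices, or a length-3
#'   vector.
#' @param xyz Numeric matrix (n x 3) of Angstrom positions, or a length-3
#'   vector.
#' @return `grid_to_xyz()` returns an n x 3 matrix of Angstrom positions;
#'   `xyz_to_grid()` the fractional (real-valued) 0-based grid coordinates.
#' @export
grid_to_xyz <- function(map, ijk) {
  ijk <- rbind_vec(ijk)
  sweep(sweep(ijk, 2, map$voxel_size, `*`), 2, map$origin, `+`)
}

#' @rdname grid_to_xyz
#' @export
xyz_to_grid <- function(map, xyz) {
  xyz <- rbind_vec(xyz)
  sweep(sweep(xyz, 2, map$origin, `-`), 2, map$voxel_size, `/`)
}

rbind_vec <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else
    matrix(as.numeric(x), ncol = ncol(x), dimnames = NULL)
}

# linear (0-based) voxel index <-> 0-based (i,j,k); x fastest
lin_to_ijk <- function(lin, dims) {
  cbind(lin %% dims[1],
        (lin %/% dims[1]) %% dims[2],
        lin %/% (dims[1] * dims[2]))
}

ijk_to_lin <- function(ijk, dims) {
  ijk <- rbind_vec(ijk)
  as.integer(ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]))
}

#' Trilinear interpolation of map density at Angstrom positions
#'
#' Positions outside the grid are clamped to the boundary voxel centres.
#'
#' @inheritParams grid_to_xyz
#' @return Numeric vector of interpolated density values.
#' @export
interp_density <- function(map, xyz) {
  g <- xyz_to_grid(map, xyz)
  d <- dim(map$values)
  for (a in 1:3) g[, a] <- pmin(pmax(g[, a], 0), d[a] - 1)
  g0 <- floor(g)
  # keep the upper corner in range on the boundary
  for (a in 1:3) g0[, a] <- pmin(g0[, a], d[a] - 2)
  g0 <- pmax(g0, 0)
  f <- g - g0
  out <- numeric(nrow(g))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
         (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
         (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    idx <- cbind(g0[, 1] + cx, g0[, 2] + cy, g0[, 3] + cz) + 1
    out <- out + w * map$values[idx]
  }
  out
}

# ---------------------------------------------------------------------------
# MRC / CCP4 map format (modes 0, 1, 2 read; mode 2 write).
# 1024-byte header of 56 4-byte words plus 10 80-char labels; data follow,
# stored with the MAPC axis fastest. On read the data are permuted to the
# package's internal x-fastest layout.
# ---------------------------------------------------------------------------

#' Read an MRC/CCP4 density map
#'
#' Axis order is normalized at read time to the internal x-fastest layout
#' regardless of the header's axis permutation (`MAPC/MAPR/MAPS`). The origin
#' is taken from the MRC2014 `ORIGIN` record when set, otherwise from the
#' CCP4-style `NXSTART/NYSTART/NZSTART` offsets.
#'
#' @param path Path to an MRC/CCP4 file (mode 0, 1 or 2).
#' @param resolution_hint Optional nominal resolution to attach, Angstroms.
#' @return A [density_map()].
#' @export
read_map <- function(path, resolution_hint = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L)
    stop("truncated MRC file: header shorter than 1024 bytes", call. = FALSE)

  parse_header <- function(endian) {
    ints <- readBin(hdr_raw, "integer", n = 256L, size = 4L, endian = endian)
    flts <- readBin(hdr_raw, "double", n = 256L, size = 4L, endian = endian)
    list(nc = ints[1], nr = ints[2], ns = ints[3], mode = ints[4],
         nstart = ints[5:7], m = ints[8:10], cella = flts[11:13],
         mapcrs = ints[17:19], nsymbt = ints[24],
         origin = flts[50:52], endian = endian)
  }
  h <- parse_header("little")
  plausible <- function(h) {
    h$mode %in% c(0L, 1L, 2L) && all(c(h$nc, h$nr, h$ns) > 0) &&
      all(c(h$nc, h$nr, h$ns) < 1e6)
  }
  if (!plausible(h)) {
    h <- parse_header("big")
    if (!plausible(h))
      stop("not a readable MRC/CCP4 map (unsupported mode or corrupt header)",
           call. = FALSE)
  }
  if (any(h$mapcrs < 1 | h$mapcrs > 3) || anyDuplicated(h$mapcrs))
    stop("invalid MAPC/MAPR/MAPS axis permutation in MRC header",
         call. = FALSE)
  if (h$nsymbt > 0) readBin(con, "raw", n = h$nsymbt)

  n_vox <- as.numeric(h$nc) * h$nr * h$ns
  data <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = n_vox, size = 1L,
                             signed = TRUE, endian = h$endian)),
    "1" = as.numeric(readBin(con, "integer", n = n_vox, size = 2L,
                             signed = TRUE, endian = h$endian)),
    "2" = readBin(con, "double", n = n_vox, size = 4L, endian = h$endian))
  if (length(data) < n_vox)
    stop("truncated MRC file: fewer data values than header promises",
         call. = FALSE)

  # data axes are (column, row, section) = map axes mapcrs
  arr <- array(data, dim = c(h$nc, h$nr, h$ns))
  perm <- match(1:3, h$mapcrs)   # where x, y, z live among (c, r, s)
  arr <- aperm(arr, perm)
  m <- ifelse(h$m > 0, h$m, dim(arr))
  cella <- ifelse(h$cella > 0, h$cella, m)
  voxel <- cella / m
  nstart_xyz <- h$nstart[perm]
  origin <- if (any(h$origin != 0)) h$origin else nstart_xyz * voxel
  density_map(arr, voxel_size = voxel, origin = origin,
              resolution_hint = resolution_hint)
}

#' Write a density map as MRC (mode 2)
#'
#' @param map A [density_map()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  v <- as.vector(map$values)
  wi(d)                      # NX NY NZ (columns fastest = x)
  wi(2L)                     # MODE 2 = float32
  wi(c(0L, 0L, 0L))          # NSTART
  wi(d)                      # MX MY MZ
  wf(d * map$voxel_size)     # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(c(1L, 2L, 3L))          # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))              # ISPG, NSYMBT
  wi(rep(0L, 25L))           # EXTRA (words 26-49 in 1-based numbering)
  wf(map$origin)             # ORIGIN (MRC2014)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))           # RMS
  wi(1L)                     # NLABL
  lab <- sprintf("%-80s", "catrace density map")
  writeBin(charToRaw(lab), con)
  writeBin(raw(800L - 80L), con)
  wf(v)
  invisible(path)
}
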