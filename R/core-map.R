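#' Construct a density map
#'
#' A `density_map` is a 3-D scalar grid in canonical `(x, y, z)` index
#' order together with the voxel spacing per axis and the Cartesian
#' position of grid index `(1, 1, 1)`.
#'
#' @param grid 3-D numeric array, at least 2 voxels per axis, indexed
#'   `grid[x, y, z]`.
#' @param voxel voxel spacing in Angstrom; scalar or length-3 vector.
#' @param origin position of the first voxel (Angstrom), length 3.
#' @param normalized whether values have been rescaled to unit maximum.
#' @return object of class `density_map`.
#' @export
density_map <- function(grid, voxel, origin = c(0, 0, 0),
                        normalized = FALSE) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3-D array")
  if (any(dim(grid) < 2L)) stop("grid needs >= 2 voxels per axis")
  voxel <- rep_len(as.numeric(voxel), 3L)
  if (any(voxel <= 0)) stop("voxel spacing must be positive")
  stopifnot(length(origin) == 3L)
  out <- list(grid = grid, voxel = voxel, origin = as.numeric(origin),
              normalized = isTRUE(normalized))
  class(out) <- "density_map"
  out
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s voxels, spacing (%.3g, %.3g, %.3g) A\n",
              paste(dim(x$grid), collapse = "x"),
              x$voxel[1], x$voxel[2], x$voxel[3]))
  invisible(x)
}

#' Read a CCP4/MRC 2014 density map
#'
#' Reads mode-2 (32-bit float) maps. The grid is normalised to canonical
#' `(x, y, z)` axis order regardless of the header's MAPC/MAPR/MAPS
#' permutation; voxel spacing comes from the cell dimensions divided by
#' the sampling, and the origin combines the ORIGIN header fields with
#' the start offsets. Only orthogonal cells are supported. Little-endian
#' byte order is assumed (the MRC2014 default on current hardware).
#'
#' @param path file path.
#' @return a [density_map()].
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h_int1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg_nsym <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  extra <- readBin(con, "integer", n = 25, size = 4, endian = "little")
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  magic <- readBin(con, "raw", n = 4)
  if (!identical(magic, charToRaw("MAP ")))
    stop("not an MRC/CCP4 map: bad magic word")
  readBin(con, "integer", n = 1, size = 4)          # machine stamp
  readBin(con, "numeric", n = 1, size = 4)          # rms
  readBin(con, "integer", n = 1, size = 4)          # nlabl
  readBin(con, "raw", n = 800)                      # labels
  nxyz <- h_int1[1:3]
  mode <- h_int1[4]
  nstart <- h_int1[5:7]
  mxyz <- h_int1[8:10]
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2)")
  if (any(abs(cellb - 90) > 1e-4))
    stop("non-orthogonal cell is not supported")
  if (!setequal(mapcrs, 1:3)) stop("invalid MAPC/MAPR/MAPS permutation")
  nvox <- prod(nxyz)
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(vals) != nvox) stop("truncated map data")
  stored <- array(vals, dim = nxyz)                 # (cols, rows, sections)
  grid <- aperm(stored, match(1:3, mapcrs))         # -> (x, y, z)
  # cell/sampling are stated along crystallographic x,y,z already
  voxel <- ifelse(mxyz > 0, cella / mxyz, 1)
  start_axis <- numeric(3)
  start_axis[mapcrs] <- nstart
  density_map(grid, voxel = voxel,
              origin = origin + start_axis * voxel)
}

#' Write a CCP4/MRC 2014 density map
#'
#' Writes a mode-2 (32-bit float) little-endian map. By default the
#' canonical axis order is used; `axis_order` permutes MAPC/MAPR/MAPS
#' (mainly to exercise readers against permuted files).
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @param axis_order integer permutation of `1:3` giving the axes mapped
#'   to columns, rows and sections.
#' @return the path, invisibly.
#' @export
write_map <- function(map, path, axis_order = 1:3) {
  stopifnot(inherits(map, "density_map"), setequal(axis_order, 1:3))
  grid <- map$grid
  stored <- aperm(grid, axis_order)
  nxyz <- dim(stored)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(nxyz); wi(2L)                       # NX NY NZ, MODE
  wi(c(0L, 0L, 0L))                      # N*START
  wi(dim(grid))                          # MX MY MZ (sampling along x,y,z)
  wf(dim(grid) * map$voxel)              # CELLA
  wf(c(90, 90, 90))                      # CELLB
  wi(axis_order)                         # MAPC MAPR MAPS
  wf(c(min(grid), max(grid), mean(grid)))
  wi(c(1L, 0L))                          # ISPG, NSYMBT
  wi(integer(25))                        # extra
  wf(map$origin)                         # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machine stamp (LE)
  wf(stats::sd(grid))
  wi(0L)
  writeChar(strrep(" ", 800), con, nchars = 800, eos = NULL)
  wf(as.numeric(stored))
  invisible(path)
}

#' Parse a plain-text distance-restraint table
#'
#' Each non-comment line holds one upper-bound distance restraint:
#' `chainA resA atomA chainB resB atomB upper`, whitespace-delimited.
#' Lines starting with `#` are skipped. This simple format is a stand-in
#' for program-specific restraint dialects (e.g. Xplor `.tbl` files),
#' which are not parsed here.
#'
#' @param text character scalar, vector of lines, or file path.
#' @return object of class `restraint_set`: a data.frame with columns
#'   `chain_a`, `res_a`, `atom_a`, `chain_b`, `res_b`, `atom_b`, `upper`.
#' @export
parse_restraints <- function(text) {
  lines <- .as_lines(text)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  entries <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 7L)
      stop("expected 7 fields, got ", length(f), " at line ", i)
    upper <- suppressWarnings(as.numeric(f[7]))
    res_a <- suppressWarnings(as.integer(f[2]))
    res_b <- suppressWarnings(as.integer(f[5]))
    if (is.na(upper) || is.na(res_a) || is.na(res_b))
      stop("malformed numeric field at line ", i)
    if (upper <= 0) stop("non-positive upper bound at line ", i)
    entries[[k]] <- data.frame(chain_a = f[1], res_a = res_a, atom_a = f[3],
                               chain_b = f[4], res_b = res_b, atom_b = f[6],
                               upper = upper)
  }
  out <- if (length(entries)) do.call(rbind, entries) else
    data.frame(chain_a = character(), res_a = integer(),
               atom_a = character(), chain_b = character(),
               res_b = integer(), atom_b = character(), upper = numeric())
  class(out) <- c("restraint_set", "data.frame")
  out
}
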