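#' Density volume
#'
#' A 3D scalar voxel grid with physical voxel size and origin, the carrier of
#' a particle's EM density. All geometry inside the package is in nm; MRC
#' headers (in Angstrom) are converted at the file boundary. Voxel centers
#' sit at `origin + (index - 0.5) * voxel_size` for 1-based indices.
#'
#' @param values 3D numeric array.
#' @param voxel_size voxel edge length in nm (> 0).
#' @param origin nm offset of the grid corner (length 3).
#' @param provenance optional list describing how the volume was produced.
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(values, voxel_size, origin = c(0, 0, 0),
                           provenance = list()) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!is.finite(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be positive")
  }
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin), provenance = provenance),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_volume: %d x %d x %d voxels, %.3f nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

# physical coordinates (nm) of voxel centers given 1-based indices (n x 3)
voxel_centers <- function(volume, ijk) {
  sweep((ijk - 0.5) * volume$voxel_size, 2L, volume$origin, "+")
}

#' Read an MRC density volume
#'
#' Parses the 1024-byte MRC2014 header and the data block. Modes 0 (int8),
#' 1 (int16) and 2 (float32) are accepted; voxel size is taken from the cell
#' dimensions (Angstrom) divided by the grid size and converted to nm.
#' Little-endian files only (the standard for EMDB depositions).
#'
#' @param path path to an .mrc file.
#' @return a `density_volume` (values, voxel_size in nm, origin in nm).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) {
    stop("malformed MRC header: file shorter than 1024 bytes")
  }
  int_at <- function(word) {
    readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)], "integer",
            size = 4L, endian = "little")
  }
  float_at <- function(word) {
    readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)], "numeric",
            size = 4L, endian = "little")
  }
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(float_at(11), float_at(12), float_at(13))
  map_tag <- rawToChar(hdr_raw[209:212])
  if (!grepl("^MAP", map_tag)) {
    # legacy files may omit the tag; sanity-check dimensions instead
    if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5)) {
      stop("malformed MRC header: bad dimension fields nx/ny/nz")
    }
  }
  if (!mode %in% c(0L, 1L, 2L)) {
    stop(sprintf("malformed MRC header: unsupported mode %d", mode))
  }
  if (any(c(mx, my, mz) <= 0)) {
    stop("malformed MRC header: non-positive sampling fields mx/my/mz")
  }
  origin_ang <- c(float_at(50), float_at(51), float_at(52))
  n_vox <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n_vox, size = 1L, signed = TRUE),
    "1" = readBin(con, "integer", n = n_vox, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n_vox, size = 4L, endian = "little"))
  if (length(vals) < n_vox) {
    stop(sprintf("truncated MRC data block: expected %.0f voxels, read %d",
                 n_vox, length(vals)))
  }
  vx <- cella / c(mx, my, mz) / 10 # Angstrom -> nm
  if (any(!is.finite(vx)) || any(vx <= 0)) {
    stop("malformed MRC header: non-positive cell dimensions (cella)")
  }
  if (max(vx) - min(vx) > 1e-4 * mean(vx)) {
    warning("anisotropic voxel size in MRC header; using the mean")
  }
  arr <- array(as.numeric(vals), dim = c(nx, ny, nz))
  density_volume(arr, voxel_size = mean(vx), origin = origin_ang / 10,
                 provenance = list(source = path, mrc_mode = mode))
}

#' Write a density volume as MRC (mode 2, float32)
#'
#' @param volume a `density_volume`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_mrc <- function(volume, path) {
  d <- dim(volume$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  vx_ang <- volume$voxel_size * 10
  wi(d[1]); wi(d[2]); wi(d[3])        # nx ny nz
  wi(2L)                              # mode 2: float32
  wi(0L); wi(0L); wi(0L)              # nxstart nystart nzstart
  wi(d[1]); wi(d[2]); wi(d[3])        # mx my mz
  wf(d[1] * vx_ang); wf(d[2] * vx_ang); wf(d[3] * vx_ang) # cella (Angstrom)
  wf(90); wf(90); wf(90)              # cellb
  wi(1L); wi(2L); wi(3L)              # mapc mapr maps
  v <- volume$values
  wf(min(v)); wf(max(v)); wf(mean(v)) # dmin dmax dmean
  wi(0L)                              # ispg
  wi(0L)                              # nsymbt
  for (i in 25:49) wi(0L)             # extra
  wf(volume$origin * 10)              # origin x y z (Angstrom), words 50-52
  writeBin(charToRaw("MAP "), con)    # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # machst: little-endian
  wf(stats::sd(as.numeric(v)))        # rms
  wi(0L)                              # nlabl
  writeBin(raw(800), con)             # labels
  wf(as.numeric(v))
  invisible(path)
}
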