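#' Voxel clouds
#'
#' A `voxel_cloud` is the set of value-1 voxels of a binarised segmented
#' structure: an n x 3 matrix of zero-based integer indices `(i, j, k)`, an
#' anisotropic voxel size (micrometres per axis), and a world origin. The
#' world coordinate of a voxel is its *center*,
#' `origin + (index + 1/2) * voxel_size`.
#'
#' @param index integer matrix (n x 3) of zero-based voxel indices.
#' @param voxel_size numeric length-3, micrometres per voxel along x, y, z.
#' @param origin numeric length-3 world position of the grid corner
#'   (micrometres).
#' @return An object of class `voxel_cloud`.
#' @export
voxel_cloud <- function(index, voxel_size, origin = c(0, 0, 0)) {
  index <- as.matrix(index)
  if (length(index) == 0L) index <- matrix(integer(0), 0, 3)
  if (ncol(index) != 3L) stop("index must have 3 columns")
  storage.mode(index) <- "integer"
  dimnames(index) <- NULL
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(index = index, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_cloud")
}

#' @export
print.voxel_cloud <- function(x, ...) {
  cat(sprintf("voxel_cloud: %d voxels, voxel size %s um, volume %.6g um^3\n",
              nrow(x$index),
              paste(signif(x$voxel_size, 4), collapse = " x "),
              cloud_volume(x)))
  invisible(x)
}

#' Voxel-count volume of a cloud
#'
#' Volume is exactly `count x sx*sy*sz`, the voxel-count volumetry used for
#' all synthetic structures.
#'
#' @param cloud a [voxel_cloud].
#' @return volume in cubic micrometres.
#' @export
cloud_volume <- function(cloud) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  nrow(cloud$index) * prod(cloud$voxel_size)
}

#' World coordinates of voxel centers
#'
#' @param cloud a [voxel_cloud].
#' @return numeric matrix (n x 3) of voxel-center positions in micrometres.
#' @export
voxel_centers <- function(cloud) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  sweep(sweep(cloud$index + 0.5, 2, cloud$voxel_size, "*"),
        2, cloud$origin, "+")
}

#' Center of mass of a voxel cloud
#'
#' Mean voxel-center position, the point used for soma position and
#' mitochondrion compartment assignment.
#'
#' @param cloud a non-empty [voxel_cloud].
#' @return numeric length-3 position (micrometres).
#' @export
cloud_com <- function(cloud) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  if (nrow(cloud$index) == 0L) stop("data error: empty voxel cloud")
  colMeans(voxel_centers(cloud))
}

# ---- raster IO ------------------------------------------------------------

# Minimal MRC (CCP-EM 2014 layout) mask IO. Only what a binarised mask needs:
# modes 0 (int8), 1 (int16), 2 (float32); the 1024-byte header's nx/ny/nz,
# mode, mx/my/mz and cella fields; little-endian. Values > 0 are mask.

#' Read a binary mask from an MRC file
#'
#' Accepts modes 0 (int8), 1 (int16) and 2 (float32); any voxel value > 0 is
#' treated as inside the mask. Voxel size is taken from the header cell
#' dimensions (`cella / m`) and is interpreted as micrometres unless
#' `angstrom = TRUE`, in which case it is converted.
#'
#' @param path MRC file path.
#' @param angstrom is the header cell size in Angstrom (the crystallographic
#'   convention)?
#' @return a [voxel_cloud] with origin `c(0, 0, 0)`.
#' @export
read_mask_mrc <- function(path, angstrom = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 3, size = 4, endian = "little")      # nstart
  m <- readBin(con, "integer", 3, size = 4, endian = "little") # mx,my,mz
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024)
  n <- prod(dims)
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop(sprintf("unsupported MRC mode %d (expected 0, 1 or 2)", mode)))
  if (length(vals) != n) stop("truncated MRC data block")
  keep <- which(vals > 0) - 1L
  idx <- cbind(keep %% dims[1],
               (keep %/% dims[1]) %% dims[2],
               keep %/% (dims[1] * dims[2]))
  vs <- cella / pmax(m, 1L)
  if (angstrom) vs <- vs * 1e-4
  voxel_cloud(idx, voxel_size = vs)
}

#' Write a voxel cloud as an MRC mask
#'
#' Writes mode-0 (int8) masks with the cloud's voxel size in the header cell
#' fields (micrometres). The grid spans from index 0 to the cloud's maximum
#' index per axis unless `dims` is given.
#'
#' @param cloud a [voxel_cloud].
#' @param path output path.
#' @param dims optional integer length-3 grid dimensions.
#' @return `path`, invisibly.
#' @export
write_mask_mrc <- function(cloud, path, dims = NULL) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  if (is.null(dims)) {
    dims <- if (nrow(cloud$index)) apply(cloud$index, 2, max) + 1L else
      c(1L, 1L, 1L)
  }
  dims <- as.integer(dims)
  arr <- raw(prod(dims))
  if (nrow(cloud$index)) {
    pos <- cloud$index[, 1] + dims[1] * (cloud$index[, 2] +
                                           dims[2] * cloud$index[, 3])
    arr[pos + 1L] <- as.raw(1L)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(dims, con, size = 4, endian = "little")              # nx ny nz
  writeBin(0L, con, size = 4, endian = "little")                # mode 0
  writeBin(c(0L, 0L, 0L), con, size = 4, endian = "little")     # nstart
  writeBin(dims, con, size = 4, endian = "little")              # mx my mz
  writeBin(dims * cloud$voxel_size, con, size = 4, endian = "little") # cella
  writeBin(rep(90, 3), con, size = 4, endian = "little")        # cellb
  writeBin(1:3, con, size = 4, endian = "little")               # mapc/r/s
  pad <- 1024L - (4L * (3 + 1 + 3 + 3 + 3 + 3 + 3))
  writeBin(raw(pad), con)
  writeBin(arr, con)
  invisible(path)
}

#' Read a binary mask from a multi-page TIFF
#'
#' Each page is one z-slice; any pixel value > 0 is inside the mask. TIFF
#' stores no physical voxel size, so it must be supplied.
#'
#' @param path TIFF file path.
#' @param voxel_size numeric length-3 voxel size in micrometres (required).
#' @return a [voxel_cloud].
#' @export
read_mask_tiff <- function(path, voxel_size) {
  if (missing(voxel_size))
    stop("configuration error: voxel_size is required for TIFF masks")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  idx <- vector("list", length(pages))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    w <- which(pg > 0, arr.ind = TRUE)  # row = y index, col = x index
    if (nrow(w))
      idx[[k]] <- cbind(w[, 2] - 1L, w[, 1] - 1L, k - 1L)
  }
  voxel_cloud(do.call(rbind, idx[!vapply(idx, is.null, logical(1))]),
              voxel_size = voxel_size)
}

#' Write a voxel cloud as a multi-page TIFF mask
#'
#' @param cloud a [voxel_cloud].
#' @param path output path.
#' @param dims optional integer length-3 grid dimensions.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(cloud, path, dims = NULL) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  if (is.null(dims)) {
    dims <- if (nrow(cloud$index)) apply(cloud$index, 2, max) + 1L else
      c(1L, 1L, 1L)
  }
  dims <- as.integer(dims)
  pages <- vector("list", dims[3])
  for (k in seq_len(dims[3])) {
    pg <- matrix(0, nrow = dims[2], ncol = dims[1])  # rows = y, cols = x
    sel <- cloud$index[, 3] == (k - 1L)
    if (any(sel))
      pg[cbind(cloud$index[sel, 2] + 1L, cloud$index[sel, 1] + 1L)] <- 1
    pages[[k]] <- pg
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Merge voxel clouds on a shared grid
#'
#' Pools instances (e.g. all mitochondria of one axon) into a single cloud.
#' All clouds must share voxel size and origin.
#'
#' @param clouds list of [voxel_cloud]s.
#' @return a [voxel_cloud] with the union of the voxels.
#' @export
merge_clouds <- function(clouds) {
  stopifnot(length(clouds) >= 1,
            all(vapply(clouds, inherits, logical(1), "voxel_cloud")))
  vs <- clouds[[1]]$voxel_size
  or <- clouds[[1]]$origin
  for (cl in clouds[-1]) {
    if (max(abs(cl$voxel_size - vs)) > 0 || max(abs(cl$origin - or)) > 0)
      stop("consistency error: clouds are not on the same grid")
  }
  idx <- unique(do.call(rbind, lapply(clouds, `[[`, "index")))
  voxel_cloud(idx, vs, or)
}
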