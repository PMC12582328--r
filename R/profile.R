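#' Project a voxel cloud onto a skeleton
#'
#' Orthogonally projects every voxel center onto the nearest location along
#' the skeleton's profiling path and returns the normalised arc-length
#' position of each projection on a 0-1 scale (0 = path start, 1 = path end;
#' points beyond either end clamp to the ends).
#'
#' @param cloud a [voxel_cloud].
#' @param skel a [skeleton] with a path of at least 2 nodes.
#' @return numeric vector of normalised positions, one per voxel.
#' @export
project_cloud <- function(cloud, skel) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  if (nrow(cloud$index) == 0L) return(numeric(0))
  pr <- project_points(skel, voxel_centers(cloud))
  pr$s / path_length(skel)
}

#' Axial cross-sectional-area profile
#'
#' Bins normalised positions into a histogram over `[0, 1]` (half-open bins,
#' position 1 assigned to the last bin), rescales the x axis to physical
#' micrometres by the structure length, and rescales the y axis so that the
#' rectangle-rule integral of the curve over micrometres equals the structure
#' volume. Each bin value is then the local cross-sectional area in square
#' micrometres.
#'
#' @param t_norm numeric vector of normalised positions in `[0, 1]` (from
#'   [project_cloud()]).
#' @param length_um physical path length in micrometres (> 0).
#' @param volume_um3 structure volume in cubic micrometres (>= 0), e.g. from
#'   [cloud_volume()].
#' @param bin_width normalised histogram bin width (default 0.001).
#' @return an object of class `axial_profile`: list with `position_um` (bin
#'   centers), `area_raw_um2`, `area_smooth_um2` (`NULL` until
#'   [smooth_profile()]), `bin_width_norm`, `bin_um`, `total_length_um`,
#'   `total_volume_um3`.
#' @export
area_profile <- function(t_norm, length_um, volume_um3, bin_width = 0.001) {
  if (!is.numeric(length_um) || length_um <= 0)
    stop("domain error: length_um must be positive")
  if (volume_um3 < 0) stop("domain error: volume_um3 must be non-negative")
  stopifnot(bin_width > 0, bin_width <= 1)
  if (length(t_norm) && (min(t_norm) < 0 || max(t_norm) > 1))
    stop("t_norm values must lie in [0, 1]")
  nbin <- as.integer(round(1 / bin_width))
  bin <- pmin(floor(t_norm / bin_width) + 1L, nbin)   # [lo, hi); t = 1 -> last
  counts <- tabulate(bin, nbins = nbin)
  bin_um <- bin_width * length_um
  total <- sum(counts)
  area <- if (total > 0) counts / total / bin_um * volume_um3 else
    numeric(nbin)
  structure(
    list(position_um = (seq_len(nbin) - 0.5) * bin_um,
         area_raw_um2 = area, area_smooth_um2 = NULL,
         bin_width_norm = bin_width, bin_um = bin_um,
         total_length_um = length_um, total_volume_um3 = volume_um3,
         smooth_sigma_bins = NULL),
    class = "axial_profile")
}

#' Build an axial profile directly from a cloud and skeleton
#'
#' Convenience wrapper: projection, histogram, physical rescaling and
#' Gaussian smoothing in one call.
#'
#' @param cloud a [voxel_cloud].
#' @param skel a [skeleton].
#' @param bin_width normalised bin width (default 0.001).
#' @param sigma_bins Gaussian smoothing sigma in bins (default 5); `NULL`
#'   skips smoothing.
#' @return an `axial_profile`.
#' @export
profile_structure <- function(cloud, skel, bin_width = 0.001,
                              sigma_bins = 5) {
  pf <- area_profile(project_cloud(cloud, skel), path_length(skel),
                     cloud_volume(cloud), bin_width)
  if (!is.null(sigma_bins)) pf <- smooth_profile(pf, sigma_bins)
  pf
}

#' Gaussian-smooth an axial profile
#'
#' Discrete Gaussian convolution of the raw area curve (kernel truncated at
#' four sigma, normalised to unit mass) with reflective boundary padding,
#' which conserves the curve's integral. `sigma_bins = 0` copies the raw
#' curve unchanged.
#'
#' @param profile an `axial_profile`.
#' @param sigma_bins kernel standard deviation in bins (>= 0).
#' @return the profile with `area_smooth_um2` filled in.
#' @export
smooth_profile <- function(profile, sigma_bins = 5) {
  stopifnot(inherits(profile, "axial_profile"))
  if (!is.numeric(sigma_bins) || sigma_bins < 0)
    stop("domain error: sigma_bins must be non-negative")
  y <- profile$area_raw_um2
  profile$area_smooth_um2 <- gauss_smooth(y, sigma_bins)
  profile$smooth_sigma_bins <- sigma_bins
  profile
}

# Gaussian filter with 'reflect' boundary handling (d c b a | a b c d ...)
gauss_smooth <- function(y, sigma) {
  n <- length(y)
  if (sigma == 0 || n == 0L) return(y)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  if (r >= n) stop("smoothing kernel wider than the profile")
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- c(y[r:1], y, y[n:(n - r + 1L)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf(
    "axial_profile: %d bins (%.4g um each), length %.4g um, volume %.6g um^3%s\n",
    length(x$area_raw_um2), x$bin_um, x$total_length_um, x$total_volume_um3,
    if (is.null(x$area_smooth_um2)) " (unsmoothed)" else
      sprintf(", smoothed (sigma %.3g bins)", x$smooth_sigma_bins)))
  invisible(x)
}

#' @export
plot.axial_profile <- function(x, ...) {
  graphics::plot(x$position_um, x$area_raw_um2, type = "h", col = "grey70",
                 xlab = "position along skeleton (um)",
                 ylab = expression(paste("cross-sectional area (", mu,
                                         m^2, ")")), ...)
  if (!is.null(x$area_smooth_um2))
    graphics::lines(x$position_um, x$area_smooth_um2, col = "navy", lwd = 2)
  invisible(x)
}

#' Write an axial profile as CSV
#'
#' Columns `position_um, area_raw_um2, area_smooth_um2`.
#'
#' @param profile an `axial_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "axial_profile"))
  df <- data.frame(position_um = profile$position_um,
                   area_raw_um2 = profile$area_raw_um2,
                   area_smooth_um2 = if (is.null(profile$area_smooth_um2))
                     NA_real_ else profile$area_smooth_um2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an axial profile from CSV
#'
#' Inverse of [write_profile_csv()]; length and volume are reconstructed from
#' the bin grid and the rectangle-rule integral.
#'
#' @param path CSV path written by [write_profile_csv()].
#' @return an `axial_profile`.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  n <- nrow(df)
  bin_um <- if (n > 1) df$position_um[2] - df$position_um[1] else
    2 * df$position_um[1]
  length_um <- n * bin_um
  pf <- structure(
    list(position_um = df$position_um, area_raw_um2 = df$area_raw_um2,
         area_smooth_um2 = if (all(is.na(df$area_smooth_um2))) NULL else
           df$area_smooth_um2,
         bin_width_norm = 1 / n, bin_um = bin_um,
         total_length_um = length_um,
         total_volume_um3 = sum(df$area_raw_um2) * bin_um,
         smooth_sigma_bins = NA_real_),
    class = "axial_profile")
  pf
}
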