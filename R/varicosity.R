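# ---- peak primitives ------------------------------------------------------

# indices of local maxima; plateaus contribute their (floor) midpoint
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# topographic prominence of each peak plus its flanking bases: extend from the
# peak in each direction until a strictly higher sample or the signal edge;
# the base on each side is the minimum over that range, and prominence is the
# peak height above the higher of the two bases.
peak_prominence <- function(y, peaks) {
  n <- length(y)
  out <- data.frame(peak = peaks, prominence = NA_real_,
                    left_base = NA_integer_, right_base = NA_integer_)
  for (r in seq_along(peaks)) {
    p <- peaks[r]
    i <- p
    lmin <- y[p]; lpos <- p
    while (i > 1L && y[i - 1L] <= y[p]) {
      i <- i - 1L
      if (y[i] < lmin) { lmin <- y[i]; lpos <- i }
    }
    i <- p
    rmin <- y[p]; rpos <- p
    while (i < n && y[i + 1L] <= y[p]) {
      i <- i + 1L
      if (y[i] < rmin) { rmin <- y[i]; rpos <- i }
    }
    out$prominence[r] <- y[p] - max(lmin, rmin)
    out$left_base[r] <- lpos
    out$right_base[r] <- rpos
  }
  out
}

# width of a peak at the given absolute height, searched within its bases;
# returns fractional bin indices of the two crossings (linear interpolation)
peak_width_at <- function(y, peak, height, left_base, right_base) {
  i <- peak
  while (i > left_base && y[i - 1L] > height) i <- i - 1L
  left_ip <- if (i > left_base && y[i] > y[i - 1L])
    (i - 1L) + (height - y[i - 1L]) / (y[i] - y[i - 1L]) else i
  j <- peak
  while (j < right_base && y[j + 1L] > height) j <- j + 1L
  right_ip <- if (j < right_base && y[j] > y[j + 1L])
    j + (y[j] - height) / (y[j] - y[j + 1L]) else j
  c(left_ip, right_ip)
}

# ---- varicosity calling ---------------------------------------------------

#' Detect axonal varicosities in a smoothed axial profile
#'
#' Local maxima of the smoothed cross-sectional-area curve are called
#' varicosities when their topographic prominence reaches `prominence_frac`
#' of the curve's outlier-excluded maximum (the `outlier_quantile` quantile
#' of the smoothed curve). Varicosity length is the full width of the peak at
#' half height: by default at `peak - prominence/2` (width at half relative
#' height); `height = "half_max"` instead uses half the absolute peak height.
#' Crossings are linearly interpolated between bins.
#'
#' @param profile a smoothed `axial_profile` (see [smooth_profile()]).
#' @param prominence_frac minimum prominence as a fraction of the reference
#'   maximum (default 0.30).
#' @param outlier_quantile quantile of the smoothed curve used as the
#'   outlier-excluded reference maximum (default 0.995).
#' @param height FWHM convention: `"half_prominence"` (default) or
#'   `"half_max"`.
#' @return a data frame of class `varicosity_calls` with one row per call:
#'   `center_um`, `peak_area_um2`, `prominence_um2`, `fwhm_um`, `start_um`,
#'   `end_um`. Attributes carry the axon length and detection parameters.
#' @export
detect_varicosities <- function(profile, prominence_frac = 0.30,
                                outlier_quantile = 0.995,
                                height = c("half_prominence", "half_max")) {
  stopifnot(inherits(profile, "axial_profile"))
  height <- match.arg(height)
  if (!(prominence_frac > 0 && prominence_frac <= 1))
    stop("prominence_frac must be in (0, 1]")
  y <- profile$area_smooth_um2
  if (is.null(y))
    stop("profile must be smoothed first (see smooth_profile)")
  empty <- data.frame(center_um = numeric(0), peak_area_um2 = numeric(0),
                      prominence_um2 = numeric(0), fwhm_um = numeric(0),
                      start_um = numeric(0), end_um = numeric(0))
  mk <- function(df) {
    structure(df, class = c("varicosity_calls", "data.frame"),
              axon_length_um = profile$total_length_um,
              prominence_frac = prominence_frac,
              outlier_quantile = outlier_quantile, height = height)
  }
  if (length(y) == 0L || all(y == 0)) return(mk(empty))
  peaks <- local_maxima(y)
  if (length(peaks) == 0L) return(mk(empty))
  pr <- peak_prominence(y, peaks)
  ref <- stats::quantile(y, outlier_quantile, names = FALSE)
  keep <- pr$prominence >= prominence_frac * ref
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0L) return(mk(empty))
  bin_um <- profile$bin_um
  to_um <- function(ip) (ip - 0.5) * bin_um   # fractional bin -> um
  res <- empty
  for (r in seq_len(nrow(pr))) {
    p <- pr$peak[r]
    h <- if (height == "half_prominence") y[p] - 0.5 * pr$prominence[r] else
      0.5 * y[p]
    w <- peak_width_at(y, p, h, pr$left_base[r], pr$right_base[r])
    res <- rbind(res, data.frame(
      center_um = to_um(p), peak_area_um2 = y[p],
      prominence_um2 = pr$prominence[r],
      fwhm_um = (w[2] - w[1]) * bin_um,
      start_um = to_um(w[1]), end_um = to_um(w[2])))
  }
  mk(res[order(res$center_um), , drop = FALSE])
}

#' Define connectors between varicosities
#'
#' Connectors are the complement of the varicosity intervals within
#' `[0, axon length]`, including the terminal stretches before the first and
#' after the last varicosity. Each connector carries the mean smoothed
#' cross-sectional area over its interval. Together, varicosity and connector
#' intervals tile the axon without overlap.
#'
#' @param profile the smoothed `axial_profile` the calls came from.
#' @param calls a `varicosity_calls` data frame (sorted, non-overlapping).
#' @return data frame with `start_um`, `end_um`, `mean_area_um2`.
#' @export
define_connectors <- function(profile, calls) {
  stopifnot(inherits(profile, "axial_profile"))
  L <- profile$total_length_um
  y <- profile$area_smooth_um2
  if (is.null(y)) stop("profile must be smoothed first")
  calls <- as.data.frame(calls)
  if (nrow(calls) > 1L) {
    o <- order(calls$start_um)
    calls <- calls[o, , drop = FALSE]
    if (any(calls$end_um[-nrow(calls)] > calls$start_um[-1L]))
      stop("consistency error: varicosity intervals overlap")
  }
  bounds_lo <- c(0, pmin(pmax(calls$end_um, 0), L))
  bounds_hi <- c(pmin(pmax(calls$start_um, 0), L), L)
  keep <- bounds_hi > bounds_lo
  bounds_lo <- bounds_lo[keep]
  bounds_hi <- bounds_hi[keep]
  mean_area <- vapply(seq_along(bounds_lo), function(i) {
    sel <- profile$position_um >= bounds_lo[i] &
      profile$position_um < bounds_hi[i]
    if (any(sel)) mean(y[sel]) else {
      mid <- (bounds_lo[i] + bounds_hi[i]) / 2
      stats::approx(profile$position_um, y, xout = mid, rule = 2)$y
    }
  }, numeric(1))
  data.frame(start_um = bounds_lo, end_um = bounds_hi,
             mean_area_um2 = mean_area)
}

#' Varicosity density
#'
#' Number of varicosity calls per micrometre of axon.
#'
#' @param calls a `varicosity_calls` data frame (or anything with one row per
#'   call).
#' @param axon_length_um axon length in micrometres (> 0).
#' @return density in calls per micrometre.
#' @export
varicosity_density <- function(calls, axon_length_um) {
  if (!is.numeric(axon_length_um) || axon_length_um <= 0)
    stop("domain error: axon_length_um must be positive")
  nrow(as.data.frame(calls)) / axon_length_um
}

#' Mitochondrial occupancy profile
#'
#' Elementwise ratio of the smoothed mitochondrial cross-sectional-area curve
#' to the smoothed axonal curve, on a shared bin grid. Bins where the axon
#' area falls below `area_floor` report occupancy 0 and are flagged.
#'
#' @param mito_profile smoothed `axial_profile` of the pooled mitochondria.
#' @param axon_profile smoothed `axial_profile` of the axon, same skeleton
#'   and binning.
#' @param area_floor axon area (square micrometres) below which the ratio is
#'   not evaluated (default 1e-6).
#' @return data frame of class `occupancy_profile`: `position_um`,
#'   `occupancy`, `low_axon` (logical flag).
#' @export
occupancy <- function(mito_profile, axon_profile, area_floor = 1e-6) {
  stopifnot(inherits(mito_profile, "axial_profile"),
            inherits(axon_profile, "axial_profile"))
  if (length(mito_profile$position_um) != length(axon_profile$position_um) ||
      max(abs(mito_profile$position_um - axon_profile$position_um)) > 1e-9)
    stop("consistency error: profiles must share the same binning")
  ym <- mito_profile$area_smooth_um2
  ya <- axon_profile$area_smooth_um2
  if (is.null(ym) || is.null(ya)) stop("profiles must be smoothed first")
  low <- ya < area_floor
  occ <- ifelse(low, 0, ym / ya)
  structure(data.frame(position_um = axon_profile$position_um,
                       occupancy = occ, low_axon = low),
            class = c("occupancy_profile", "data.frame"))
}

#' Assign mitochondria to varicosities or connectors
#'
#' Each mitochondrion instance is projected by its center of mass onto the
#' axon skeleton; it is "in varicosity" when the projected arc-length
#' position falls inside any varicosity FWHM interval and "in connector"
#' otherwise. The two counts partition the instances.
#'
#' @param mito_instances list of [voxel_cloud]s, one connected mitochondrion
#'   each.
#' @param skel the axon [skeleton].
#' @param calls a `varicosity_calls` data frame.
#' @return list with `in_varicosity`, `in_connector` (counts) and `labels`
#'   (character vector per instance).
#' @export
assign_mitochondria <- function(mito_instances, skel, calls) {
  calls <- as.data.frame(calls)
  labels <- vapply(mito_instances, function(cl) {
    if (!inherits(cl, "voxel_cloud") || nrow(cl$index) == 0L)
      stop("data error: mitochondrion instance with empty voxel set")
    s <- project_point(skel, cloud_com(cl))$s_um
    if (nrow(calls) &&
        any(calls$start_um <= s & s <= calls$end_um)) "varicosity" else
          "connector"
  }, character(1))
  list(in_varicosity = sum(labels == "varicosity"),
       in_connector = sum(labels == "connector"),
       labels = labels)
}

#' Write varicosity and connector calls as CSV
#'
#' One row per feature with a `type` column (`varicosity`/`connector`);
#' columns absent for a feature type are NA.
#'
#' @param calls `varicosity_calls` data frame.
#' @param connectors connector data frame from [define_connectors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_csv <- function(calls, connectors, path) {
  calls <- as.data.frame(calls)
  a <- if (nrow(calls)) data.frame(
    type = "varicosity", start_um = calls$start_um, end_um = calls$end_um,
    center_um = calls$center_um, fwhm_um = calls$fwhm_um,
    prominence_um2 = calls$prominence_um2, mean_area_um2 = NA_real_) else NULL
  b <- if (nrow(connectors)) data.frame(
    type = "connector", start_um = connectors$start_um,
    end_um = connectors$end_um, center_um = NA_real_, fwhm_um = NA_real_,
    prominence_um2 = NA_real_,
    mean_area_um2 = connectors$mean_area_um2) else NULL
  out <- rbind(a, b)
  out <- out[order(out$start_um), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
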