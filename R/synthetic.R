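# run fn with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Synthetic pearls-on-a-string axon
#'
#' Generates a straight axon along the x axis with radius profile
#' `r(s) = base_r_um + sum_i bump_peak_r_um * exp(-(s - c_i)^2 / (2 sigma^2))`
#' (varicosities as Gaussian radial bumps over a thin baseline), voxelises it
#' as a solid of revolution on an anisotropic grid (voxel-center-in-solid
#' test), and attaches analytic ground truth. Bump centers can optionally be
#' jittered (`center_jitter_um`, seeded); the recorded truth uses the
#' realised centers.
#'
#' @param length_um total axon length (micrometres).
#' @param centers_um varicosity center positions along the axon.
#' @param bump_peak_r_um radial bump amplitude above baseline.
#' @param bump_sigma_um Gaussian bump sigma (micrometres).
#' @param base_r_um baseline (connector) radius, > 0.
#' @param voxel_um voxel size, length-3 (micrometres per axis).
#' @param seed integer seed (used only when `center_jitter_um > 0`).
#' @param center_jitter_um sd of optional Gaussian jitter on bump centers.
#' @param node_spacing_um skeleton node spacing (default 0.5).
#' @return list with `skeleton`, `cloud` ([voxel_cloud]) and `truth` (centers,
#'   amplitudes, widths, baseline, analytic volume, radius function, bump
#'   FWHM intervals, merged-peak flag).
#' @export
make_axon <- function(length_um = 50, centers_um = seq(2.5, 47.5, by = 5),
                      bump_peak_r_um = 0.5, bump_sigma_um = 0.4,
                      base_r_um = 0.15, voxel_um = c(0.04, 0.04, 0.04),
                      seed = 1L, center_jitter_um = 0,
                      node_spacing_um = 0.5) {
  stopifnot(base_r_um > 0, length_um > 0, bump_sigma_um > 0)
  if (length(centers_um) &&
      (min(centers_um) < 0 || max(centers_um) > length_um))
    stop("bump centers must lie within [0, length_um]")
  if (any(voxel_um > bump_sigma_um / 4))
    warning("voxel pitch exceeds bump_sigma/4; bumps may be undersampled")
  centers <- centers_um
  if (center_jitter_um > 0 && length(centers)) {
    centers <- with_seed(seed, function()
      sort(centers + stats::rnorm(length(centers), 0, center_jitter_um)))
  }
  rfun <- function(s) {
    r <- rep(base_r_um, length(s))
    for (c in centers)
      r <- r + bump_peak_r_um * exp(-(s - c)^2 / (2 * bump_sigma_um^2))
    r
  }
  # merged peaks: neighbouring bumps closer than ~2.5 sigma have no dip
  merged <- length(centers) > 1 &&
    any(diff(sort(centers)) < 2.5 * bump_sigma_um)

  sk_x <- seq(0, length_um, by = node_spacing_um)
  if (sk_x[length(sk_x)] < length_um) sk_x <- c(sk_x, length_um)
  skel <- skeleton(cbind(sk_x, 0, 0))

  cloud <- voxelize_revolution(rfun, length_um, voxel_um)

  # analytic solid-of-revolution volume by fine quadrature
  svol <- stats::integrate(function(s) pi * rfun(s)^2, 0, length_um,
                           subdivisions = 2000L, rel.tol = 1e-9)$value
  half <- bump_sigma_um * sqrt(2 * log(2))
  truth <- list(length_um = length_um, centers_um = centers,
                bump_peak_r_um = bump_peak_r_um,
                bump_sigma_um = bump_sigma_um, base_r_um = base_r_um,
                voxel_um = voxel_um, seed = seed,
                analytic_volume_um3 = svol, radius_fun = rfun,
                bump_intervals = if (length(centers))
                  cbind(start_um = centers - half, end_um = centers + half)
                else cbind(start_um = numeric(0), end_um = numeric(0)),
                merged_peaks = merged)
  list(skeleton = skel, cloud = cloud, truth = truth)
}

# voxelise {(x, y, z): 0 <= x <= L, y^2 + z^2 <= rfun(x)^2} slice by slice;
# grid is centered on the axis with origin recorded so voxel centers are
# world-exact
voxelize_revolution <- function(rfun, length_um, voxel_um,
                                rmax = NULL) {
  nx <- as.integer(ceiling(length_um / voxel_um[1]))
  xc <- (seq_len(nx) - 0.5) * voxel_um[1]
  r_slice <- rfun(xc)
  if (is.null(rmax)) rmax <- max(r_slice)
  ny <- 2L * as.integer(ceiling((rmax + 2 * voxel_um[2]) / voxel_um[2]))
  nz <- 2L * as.integer(ceiling((rmax + 2 * voxel_um[3]) / voxel_um[3]))
  y0 <- -ny / 2 * voxel_um[2]
  z0 <- -nz / 2 * voxel_um[3]
  ycp <- y0 + (seq_len(ny) - 0.5) * voxel_um[2]
  zcp <- z0 + (seq_len(nz) - 0.5) * voxel_um[3]
  d2 <- outer(ycp^2, zcp^2, "+")          # ny x nz radial distances squared
  out <- vector("list", nx)
  for (i in seq_len(nx)) {
    w <- which(d2 <= r_slice[i]^2, arr.ind = TRUE)
    if (nrow(w))
      out[[i]] <- cbind(i - 1L, w[, 1] - 1L, w[, 2] - 1L)
  }
  idx <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  voxel_cloud(if (is.null(idx)) matrix(integer(0), 0, 3) else idx,
              voxel_size = voxel_um, origin = c(0, y0, z0))
}

#' Synthetic intra-axonal mitochondria
#'
#' Places coaxial capsule-shaped mitochondria inside a synthetic axon:
#' centers spaced `spacing_um` apart starting at `spacing_um / 2`, each a
#' cylinder of radius `occupancy_radius_frac` times the local axon radius
#' with quarter-circle tapered caps. Instances are voxelised on the axon's
#' grid; ground-truth compartment labels come from the generator's own bump
#' FWHM intervals (an instance is "varicosity" when its center lies inside
#' one).
#'
#' @param truth the `truth` element returned by [make_axon()].
#' @param occupancy_radius_frac mitochondrial radius as a fraction of the
#'   local axon radius, in (0, 1).
#' @param spacing_um center-to-center spacing of instances.
#' @param seed integer seed (used only when `center_jitter_um > 0`).
#' @param capsule_len_um total axial length of each capsule (default
#'   `spacing_um / 2`).
#' @param center_jitter_um sd of optional Gaussian jitter on capsule centers.
#' @return list with `clouds` (list of [voxel_cloud]), `labels`
#'   (ground-truth compartments), `centers_um` and `analytic_volumes_um3`
#'   (per-instance quadrature volumes).
#' @export
make_mitochondria <- function(truth, occupancy_radius_frac, spacing_um = 5,
                              seed = 1L, capsule_len_um = spacing_um / 2,
                              center_jitter_um = 0) {
  stopifnot(occupancy_radius_frac > 0, occupancy_radius_frac < 1)
  L <- truth$length_um
  centers <- seq(spacing_um / 2, L - spacing_um / 4, by = spacing_um)
  if (center_jitter_um > 0) {
    centers <- with_seed(seed, function()
      sort(centers + stats::rnorm(length(centers), 0, center_jitter_um)))
  }
  rfun <- truth$radius_fun
  frac <- occupancy_radius_frac
  half <- capsule_len_um / 2
  clouds <- vector("list", length(centers))
  vols <- numeric(length(centers))
  cap <- min(half / 2, frac * max(rfun(centers)))  # axial cap extent
  for (k in seq_along(centers)) {
    c0 <- centers[k]
    reff <- function(s) {
      a <- abs(s - c0)
      base <- frac * rfun(s)
      taper <- ifelse(a <= half - cap, 1,
                      ifelse(a >= half, 0,
                             sqrt(pmax(0, 1 - ((a - (half - cap)) / cap)^2))))
      base * taper
    }
    clouds[[k]] <- voxelize_revolution(reff, L, truth$voxel_um,
                                       rmax = frac * max(rfun(seq(0, L,
                                                                  by = 0.01))))
    vols[k] <- stats::integrate(function(s) pi * reff(s)^2,
                                max(0, c0 - half), min(L, c0 + half),
                                subdivisions = 2000L, rel.tol = 1e-9)$value
  }
  labels <- vapply(centers, function(c0) {
    bi <- truth$bump_intervals
    if (nrow(bi) && any(bi[, 1] <= c0 & c0 <= bi[, 2])) "varicosity" else
      "connector"
  }, character(1))
  list(clouds = clouds, labels = labels, centers_um = centers,
       analytic_volumes_um3 = vols)
}

#' Synthetic sensillum geometry with known truth
#'
#' Builds a straight cuticle center-line of length `L_um` along the z axis,
#' places the soma center of mass on the (extrapolated) cuticle axis at
#' proportion `soma_C`, and a straight outer-dendrite skeleton (node order
#' tip to ciliary constriction) with the cuticle base point at a stated
#' axial distance from the constriction and a stated lateral offset.
#' Analytic ground truth (C, D, encapsulated fraction) is attached.
#'
#' @param L_um cuticle length.
#' @param soma_C true cuticle proportion of the soma COM (<= 1; negative =
#'   below the base).
#' @param dendrite_len_um outer-dendrite length.
#' @param base_offset_from_constriction_um axial distance of the cuticle
#'   base point from the ciliary constriction, toward the tip.
#' @param lateral_offset_um perpendicular offset of the cuticle base point
#'   from the dendrite axis.
#' @param n_nodes nodes per skeleton (default 11).
#' @return list with `geometry` (a [sensillum_geometry]) and `truth`
#'   (`C`, `D_um`, `encapsulated`).
#' @export
make_sensillum <- function(L_um = 12.98, soma_C = -0.4607,
                           dendrite_len_um = 10,
                           base_offset_from_constriction_um = 1.8,
                           lateral_offset_um = 0.2, n_nodes = 11L) {
  stopifnot(L_um > 0, dendrite_len_um > 0, soma_C <= 1)
  off <- base_offset_from_constriction_um
  # dendrite along z: constriction at z = 0, tip at z = dendrite_len
  dz <- seq(dendrite_len_um, 0, length.out = n_nodes)   # tip -> constriction
  dendrite <- skeleton(cbind(0, 0, dz))
  # cuticle base sits off-axis at axial height `off`, cuticle rises along z
  base_pt <- c(lateral_offset_um, 0, off)
  cz <- seq(off, off + L_um, length.out = n_nodes)
  cuticle <- skeleton(cbind(lateral_offset_um, 0, cz))
  soma <- c(lateral_offset_um, 0, off + soma_C * L_um)
  geom <- sensillum_geometry(cuticle, soma, dendrite,
                             dendrite_orientation = "tip_to_constriction",
                             cuticle_base_point = base_pt)
  truth <- list(C = soma_C, D_um = -soma_C * L_um,
                encapsulated = min(1, max(0, 1 - off / dendrite_len_um)))
  list(geometry = geom, truth = truth)
}

#' Simulate allometry data from the generative model
#'
#' Forward-samples the hierarchical regression: for each of the four
#' species x neuron-type groups, `y = alpha_g + beta_g x + N(0, sigma_obs)`
#' with `beta_g = beta_overall + delta_s + gamma_g` and x drawn uniformly
#' over `x_range` (log10 outer-dendritic surface area).
#'
#' @param n_per_group observations per group.
#' @param seed integer seed.
#' @param alpha numeric length-4 group intercepts (order: Aedes.CO2,
#'   Aedes.odor, Drosophila.CO2, Drosophila.odor).
#' @param beta_overall overall slope.
#' @param delta numeric length-2 species slope deviations (Aedes,
#'   Drosophila).
#' @param gamma numeric length-4 group slope deviations, same order as
#'   `alpha`.
#' @param sigma_obs observation noise sd (>= 0).
#' @param x_range range of the predictor (default `c(0.5, 2.5)`).
#' @return data frame with `x`, `y`, `species`, `neuron_type`; the true group
#'   parameters are attached as attribute `truth`.
#' @export
simulate_allometry <- function(n_per_group = 20, seed = 1L,
                               alpha = c(0.6, 0.4, 0.5, 0.3),
                               beta_overall = 1.5, delta = c(0, 0),
                               gamma = c(0, 0, 0, 0), sigma_obs = 0.15,
                               x_range = c(0.5, 2.5)) {
  if (sigma_obs < 0) stop("domain error: sigma_obs must be non-negative")
  species <- c("Aedes", "Aedes", "Drosophila", "Drosophila")
  type <- c("CO2", "odor", "CO2", "odor")
  beta_g <- beta_overall + delta[c(1, 1, 2, 2)] + gamma
  with_seed(seed, function() {
    rows <- lapply(1:4, function(g) {
      x <- stats::runif(n_per_group, x_range[1], x_range[2])
      y <- alpha[g] + beta_g[g] * x +
        if (sigma_obs > 0) stats::rnorm(n_per_group, 0, sigma_obs) else 0
      data.frame(x = x, y = y, species = species[g], neuron_type = type[g])
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(alpha = alpha, beta = beta_g,
                               beta_overall = beta_overall, delta = delta,
                               gamma = gamma, sigma_obs = sigma_obs)
    out
  })
}

#' Voxelised sphere
#'
#' Sphere of the given radius voxelised on an isotropic grid by the
#' voxel-center-in-sphere test, for voxel-count volumetry.
#'
#' @param radius_um sphere radius (micrometres).
#' @param voxel_um isotropic voxel pitch (default 0.02, i.e. 20 nm).
#' @return a [voxel_cloud].
#' @export
make_sphere <- function(radius_um, voxel_um = 0.02) {
  stopifnot(radius_um > 0, voxel_um > 0)
  n <- as.integer(ceiling(radius_um / voxel_um)) + 1L
  cc <- (seq(-n, n - 1) + 0.5) * voxel_um  # voxel centers, symmetric about 0
  r2 <- radius_um^2
  out <- vector("list", length(cc))
  d2yz <- outer(cc^2, cc^2, "+")
  for (i in seq_along(cc)) {
    w <- which(d2yz <= r2 - cc[i]^2, arr.ind = TRUE)
    if (nrow(w)) out[[i]] <- cbind(i - 1L, w[, 1] - 1L, w[, 2] - 1L)
  }
  idx <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  voxel_cloud(idx, rep(voxel_um, 3), origin = rep(-n * voxel_um, 3))
}
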