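# shared fixtures and small oracles, all built in code at test time

# random rigid transform (proper rotation + translation)
random_rigid <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 5))
}

apply_rigid <- function(tr, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(tr$R), 2, tr$t, "+")
}

# build an axial_profile directly from an area curve sampled at bin centers
profile_from_curve <- function(area, length_um) {
  n <- length(area)
  bin_um <- length_um / n
  structure(
    list(position_um = (seq_len(n) - 0.5) * bin_um, area_raw_um2 = area,
         area_smooth_um2 = NULL, bin_width_norm = 1 / n, bin_um = bin_um,
         total_length_um = length_um,
         total_volume_um3 = sum(area) * bin_um, smooth_sigma_bins = NULL),
    class = "axial_profile")
}

# small fast MCMC settings for tests that need many fits
quick_fit <- function(df, ...) {
  suppressWarnings(allometry_fit(df, chains = 2, warmup = 500,
                                 samples = 500, thin = 3, ...))
}

# brute-force LOO by refitting without each observation
brute_force_loo <- function(df, model, seed, ...) {
  vapply(seq_len(nrow(df)), function(i) {
    f <- suppressWarnings(allometry_fit(df[-i, ], model = model,
                                        seed = seed, ...))
    gi <- match(paste(df$species[i], df$neuron_type[i], sep = "."),
                f$group_table$group)
    mu <- f$alpha_g[, gi] + f$beta_g[, gi] * df$x[i]
    ll <- dnorm(df$y[i], mu, f$sigma_obs, log = TRUE)
    m <- max(ll)
    m + log(mean(exp(ll - m)))
  }, numeric(1))
}
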