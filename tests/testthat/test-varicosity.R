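test_that("flat profiles yield no varicosity calls", {
  pf <- smooth_profile(profile_from_curve(rep(0.3, 1000), 50), 5)
  calls <- detect_varicosities(pf)
  expect_equal(nrow(calls), 0L)
  conn <- define_connectors(pf, calls)
  expect_equal(nrow(conn), 1L)
  expect_equal(c(conn$start_um, conn$end_um), c(0, 50))
  expect_equal(conn$mean_area_um2, 0.3, tolerance = 1e-9)
})

test_that("a single Gaussian bump is called with an oracle-checked FWHM", {
  L <- 20
  s <- (seq_len(1000) - 0.5) * (L / 1000)
  base <- 0.07
  y <- base + 1.2 * exp(-(s - 10)^2 / (2 * 0.4^2))
  pf <- smooth_profile(profile_from_curve(y, L), 2)
  calls <- detect_varicosities(pf)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$center_um - 10), 0.05)

  # direct half-height scan oracle on the smoothed curve
  ys <- pf$area_smooth_um2
  p <- which.max(ys)
  height <- ys[p] - 0.5 * (ys[p] - min(ys))
  left <- max(which(ys[1:p] < height))
  right <- p - 1 + min(which(ys[p:1000] < height))
  interp <- function(i, j) i + (height - ys[i]) / (ys[j] - ys[i])
  w_oracle <- (interp(right - 1, right) - interp(left + 1, left)) *
    pf$bin_um
  expect_lt(abs(calls$fwhm_um / w_oracle - 1), 0.10)
})

test_that("two equal bumps five micrometres apart give two centred calls", {
  L <- 20
  s <- (seq_len(1000) - 0.5) * (L / 1000)
  y <- 0.07 + exp(-(s - 7.5)^2 / 0.32) + exp(-(s - 12.5)^2 / 0.32)
  pf <- smooth_profile(profile_from_curve(y, L), 2)
  calls <- detect_varicosities(pf)
  expect_equal(nrow(calls), 2L)
  expect_lt(max(abs(calls$center_um - c(7.5, 12.5))), pf$bin_um + 1e-12)
})

test_that("raising the prominence threshold never adds calls", {
  ax <- make_axon(length_um = 20, centers_um = c(3, 8, 13, 18),
                  bump_peak_r_um = 0.4, voxel_um = rep(0.04, 3))
  pf <- profile_structure(ax$cloud, ax$skeleton)
  counts <- vapply(seq(0.05, 1, by = 0.05), function(fr)
    nrow(detect_varicosities(pf, prominence_frac = fr)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection on clean generated axons is exact (precision = recall = 1)", {
  ax <- make_axon()   # 10 bumps every 5 um on a 50 um axon
  pf <- profile_structure(ax$cloud, ax$skeleton)
  calls <- detect_varicosities(pf)
  expect_equal(nrow(calls), 10L)
  # every detected center within one bin of a true center, and vice versa
  expect_lt(max(abs(calls$center_um - ax$truth$centers_um)), pf$bin_um + 1e-12)
})

test_that("varicosities and connectors tile the axon exactly", {
  ax <- make_axon(length_um = 25, centers_um = c(5, 10, 15, 20),
                  voxel_um = rep(0.04, 3))
  pf <- profile_structure(ax$cloud, ax$skeleton)
  calls <- detect_varicosities(pf)
  conn <- define_connectors(pf, calls)
  expect_equal(nrow(conn), nrow(calls) + 1L)
  ivals <- rbind(data.frame(s = calls$start_um, e = calls$end_um),
                 data.frame(s = conn$start_um, e = conn$end_um))
  ivals <- ivals[order(ivals$s), ]
  expect_equal(ivals$s[1], 0)
  expect_equal(ivals$e[nrow(ivals)], pf$total_length_um)
  expect_equal(ivals$s[-1], ivals$e[-nrow(ivals)], tolerance = 1e-12)

  bad <- calls
  bad$start_um[2] <- bad$end_um[1] - 0.2
  expect_error(define_connectors(pf, bad), "overlap")
})

test_that("connector mean area over a constant region equals the constant", {
  pf <- smooth_profile(profile_from_curve(rep(0.42, 800), 40), 4)
  calls <- detect_varicosities(pf)   # none on a flat curve
  conn <- define_connectors(pf, calls)
  expect_equal(conn$mean_area_um2, 0.42, tolerance = 1e-9)
})

test_that("varicosity density is count per unit length", {
  calls <- data.frame(center_um = seq(2.5, 47.5, 5))
  expect_equal(varicosity_density(calls, 50), 0.2)
  expect_equal(varicosity_density(calls[0, , drop = FALSE], 50), 0)
  expect_equal(varicosity_density(calls, 25), 2 * varicosity_density(calls, 50))
  expect_error(varicosity_density(calls, 0), "domain error")
})

test_that("occupancy is an elementwise ratio with exact special cases", {
  ax <- make_axon(length_um = 10, centers_um = c(3, 7),
                  voxel_um = rep(0.04, 3))
  apf <- profile_structure(ax$cloud, ax$skeleton)
  # mitochondria identical to the axon: occupancy 1 everywhere interior
  occ_self <- occupancy(apf, apf)
  expect_equal(occ_self$occupancy, rep(1, 1000), tolerance = 1e-6)

  # empty numerator: all zeros
  empty <- voxel_cloud(matrix(integer(0), 0, 3), ax$cloud$voxel_size,
                       ax$cloud$origin)
  mpf0 <- smooth_profile(area_profile(project_cloud(empty, ax$skeleton),
                                      10, 0), 5)
  expect_equal(occupancy(mpf0, apf)$occupancy, rep(0, 1000))

  # mismatched binning is a consistency error
  pf_coarse <- smooth_profile(area_profile(project_cloud(ax$cloud,
                                                         ax$skeleton),
                                           10, cloud_volume(ax$cloud),
                                           bin_width = 0.002), 5)
  expect_error(occupancy(pf_coarse, apf), "consistency error")
})

test_that("nested coaxial mitochondria recover the analytic area ratio", {
  # capsule centers (2.5, 7.5, ...) coincide with the varicosity centers
  ax <- make_axon(length_um = 20, centers_um = c(2.5, 7.5, 12.5, 17.5),
                  voxel_um = rep(0.04, 3))
  mt <- make_mitochondria(ax$truth, occupancy_radius_frac = 0.837,
                          spacing_um = 5)
  apf <- profile_structure(ax$cloud, ax$skeleton)
  mpf <- profile_structure(merge_clouds(mt$clouds), ax$skeleton)
  occ <- occupancy(mpf, apf)
  expect_lt(abs(max(occ$occupancy) - 0.70), 0.01)
  # geometric nesting bounds occupancy everywhere
  expect_lt(max(occ$occupancy), 1.05)
})

test_that("mitochondria are assigned to compartments by center of mass", {
  ax <- make_axon(length_um = 20, centers_um = c(5, 10, 15),
                  voxel_um = rep(0.04, 3))
  pf <- profile_structure(ax$cloud, ax$skeleton)
  calls <- detect_varicosities(pf)

  vox_at <- function(x_um) {
    # single voxel whose center projects to x_um on the axis
    i <- as.integer(round(x_um / 0.04 - 0.5))
    voxel_cloud(cbind(i, 0L, 0L), rep(0.04, 3),
                origin = c(0, -0.02, -0.02))
  }
  at_center <- vox_at(10)
  between <- vox_at(12.5)
  res <- assign_mitochondria(list(at_center, between), ax$skeleton, calls)
  expect_equal(res$labels, c("varicosity", "connector"))
  expect_equal(res$in_varicosity, 1L)
  expect_equal(res$in_connector, 1L)

  # brute-force interval membership oracle on random placements
  set.seed(31)
  xs <- runif(40, 0.5, 19.5)
  clouds <- lapply(xs, vox_at)
  res2 <- assign_mitochondria(clouds, ax$skeleton, calls)
  oracle <- vapply(xs, function(x) {
    s <- x - 0.02   # voxel center snaps to the grid
    s <- (as.integer(round(x / 0.04 - 0.5)) + 0.5) * 0.04
    if (any(calls$start_um <= s & s <= calls$end_um)) "varicosity" else
      "connector"
  }, character(1))
  expect_equal(res2$labels, oracle)

  expect_error(assign_mitochondria(list(voxel_cloud(matrix(integer(0), 0, 3),
                                                    rep(0.04, 3))),
                                   ax$skeleton, calls), "data error")
})

test_that("call tables export varicosities and connectors as one CSV", {
  ax <- make_axon(length_um = 15, centers_um = c(5, 10),
                  voxel_um = rep(0.04, 3))
  pf <- profile_structure(ax$cloud, ax$skeleton)
  calls <- detect_varicosities(pf)
  conn <- define_connectors(pf, calls)
  f <- withr::local_tempfile(fileext = ".csv")
  write_calls_csv(calls, conn, f)
  tab <- read.csv(f)
  expect_equal(sum(tab$type == "varicosity"), nrow(calls))
  expect_equal(sum(tab$type == "connector"), nrow(conn))
  expect_false(is.unsorted(tab$start_um))
})
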