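test_that("slice drift is removed to sub-pixel residuals", {
  g <- gen_sted_chromatid(list(type = "straight", length_nm = 2000),
                          spot_spacing_nm = 100, seed = 3)
  a <- g$protein$data + g$dna$data * 50
  nz <- dim(a)[3]
  b <- a
  for (z in 2:nz) {  # inject a cumulative 40-nm (2 px) shift per slice
    sh <- 2 * (z - 1)
    b[, , z] <- 0
    b[(1 + sh):dim(a)[1], , z] <- a[1:(dim(a)[1] - sh), , z]
  }
  pp <- preprocess_stack(image_stack(b, c(20, 20, 140)),
                         smooth_sigma = 0, interpolate_z = FALSE)
  dr <- attr(pp, "drift_px")
  resid <- dr[, 1] - (seq_len(nz) - 1) * 2
  resid <- resid - mean(resid)
  expect_lt(max(abs(resid)) * 20, 5)  # < 5 nm residual
})

test_that("z interpolation is identity on isotropic input and smoothing
           leaves constants unchanged", {
  a <- array(runif(20 * 20 * 20), c(20, 20, 20))
  st <- image_stack(a, c(20, 20, 20))
  pp <- preprocess_stack(st, drift_correct = FALSE, smooth_sigma = 0)
  expect_identical(pp$data, a)
  cst <- image_stack(array(7, c(16, 16, 8)), c(20, 20, 20))
  pp2 <- preprocess_stack(cst, drift_correct = FALSE, smooth_sigma = 0.5)
  expect_equal(pp2$data, cst$data, tolerance = 1e-12)
  expect_warning(preprocess_stack(image_stack(array(runif(64), c(8, 8, 1)),
                                              c(20, 20, 140))),
                 "single-slice")
})

test_that("straight tubes trace to their known length", {
  tb <- make_gaussian_tube(sigma_nm = 100, length_nm = 2000)
  ax <- trace_axis(tb$mask, tb$stack$voxel_size_nm, end_trim_nm = 0)
  expect_equal(ax$length_nm, tb$truth_length_nm, tolerance = 20 / 2000)
  expect_equal(ax$cum_s_nm[length(ax$cum_s_nm)], ax$length_nm)
  # end trim removes the requested length from both ends
  ax2 <- trace_axis(tb$mask, tb$stack$voxel_size_nm, end_trim_nm = 200)
  expect_lt(ax2$length_nm, ax$length_nm - 350)
})

test_that("quarter-circle arcs trace to within 3% of pi*r/2", {
  arc <- make_arc_tube_mask(radius_nm = 2000)
  ax <- trace_axis(arc$mask, arc$vox_nm, end_trim_nm = 0)
  expect_equal(ax$length_nm, arc$truth_length_nm, tolerance = 0.03)
})

test_that("isotropic blobs are rejected for lack of a dominant axis", {
  expect_error(trace_axis(array(TRUE, c(12, 12, 12)), c(20, 20, 20)),
               "aspect ratio")
})

test_that("axis length is invariant under 45-degree rotation", {
  vox <- 20
  n <- 160
  cc <- (seq_len(n) - 0.5) * vox
  czn <- 31
  cz <- (seq_len(czn) - 0.5) * vox - czn * vox / 2
  mk <- function(theta) {
    d <- c(cos(theta), sin(theta))
    m <- array(FALSE, c(n, n, czn))
    p0 <- c(400, 400)
    for (z in seq_len(czn)) {
      # distance from the line segment p0 + t*d, t in [0, 2000]
      rx <- outer(cc - p0[1], rep(1, n)); ry <- outer(rep(1, n), cc - p0[2])
      tt <- pmin(pmax(rx * d[1] + ry * d[2], 0), 2000)
      dist2 <- (rx - tt * d[1])^2 + (ry - tt * d[2])^2 + cz[z]^2
      m[, , z] <- dist2 <= 100^2
    }
    m
  }
  l0 <- trace_axis(mk(0), rep(vox, 3), end_trim_nm = 0)$length_nm
  l45 <- trace_axis(mk(pi / 4), rep(vox, 3), end_trim_nm = 0)$length_nm
  expect_equal(l45, l0, tolerance = 0.02)
})

test_that("Gaussian tube FWHM matches 2*sqrt(2 ln 2)*sigma", {
  # render wider than the sampled profile so constant offsets stay
  # constant across the whole lateral extent
  tb <- make_gaussian_tube(sigma_nm = 100, length_nm = 4000,
                           lateral_halfwidth_nm = 1100)
  ax <- trace_axis(tb$mask, tb$stack$voxel_size_nm, end_trim_nm = 0)
  wp <- compute_fwhm_profile(tb$stack, ax)
  expect_equal(wp$mean_fwhm_nm, 2 * sqrt(2 * log(2)) * 100,
               tolerance = 0.02)
  # scale invariance of the FWHM
  st2 <- tb$stack; st2$data <- st2$data * 7
  wp2 <- compute_fwhm_profile(st2, ax)
  expect_equal(wp2$mean_fwhm_nm, wp$mean_fwhm_nm, tolerance = 1e-9)
  # background offsets below 10% of peak do not move the FWHM
  st3 <- tb$stack; st3$data <- st3$data + 0.08
  wp3 <- compute_fwhm_profile(st3, ax)
  expect_equal(wp3$mean_fwhm_nm, wp$mean_fwhm_nm, tolerance = 0.02)
  expect_error(compute_fwhm_profile(tb$stack, ax, window_nm = 5000),
               "shorter than one window")
})

test_that("two-width synthetic recovers the truth FWHM ratio within 5%", {
  tb1 <- make_gaussian_tube(sigma_nm = 100, length_nm = 3000)
  tb2 <- make_gaussian_tube(sigma_nm = 150, length_nm = 3000,
                            lateral_halfwidth_nm = 1000)
  ax1 <- trace_axis(tb1$mask, tb1$stack$voxel_size_nm, end_trim_nm = 0)
  ax2 <- trace_axis(tb2$mask, tb2$stack$voxel_size_nm, end_trim_nm = 0)
  r <- compute_fwhm_profile(tb2$stack, ax2)$mean_fwhm_nm /
       compute_fwhm_profile(tb1$stack, ax1)$mean_fwhm_nm
  expect_equal(r, 1.5, tolerance = 0.05)
})

test_that("radial profile containment matches the 2D Gaussian oracle", {
  tb <- make_gaussian_tube(sigma_nm = 170, length_nm = 3000,
                           lateral_halfwidth_nm = 1000,
                           axial_halfwidth_nm = 800)
  ax <- trace_axis(tb$mask, tb$stack$voxel_size_nm, end_trim_nm = 0)
  rp <- compute_radial_profile(tb$stack, ax, chromatid_width_nm = 1400)
  expect_equal(rp$intensity[1], 1)
  # oracle: radial mass of a symmetric 2D Gaussian truncated at 700 nm
  R <- 700; s <- 170
  r90 <- sqrt(-2 * s^2 * log(1 - 0.9 * (1 - exp(-R^2 / (2 * s^2)))))
  expect_equal(unname(rp$containment_radius_nm["0.9"]), r90,
               tolerance = 25 / r90)  # within the sampling pitch
  expect_true(all(diff(rp$containment_radius_nm) >= 0))
  # symmetric input: symmetrization is the identity on either half
  expect_true(all(rp$intensity <= 1 + 1e-9))
  expect_error(compute_radial_profile(tb$stack, ax, chromatid_width_nm = 1e5),
               "window")
})

test_that("a broad peripheral population adds shoulder mass over a
           single Gaussian", {
  tb_n <- make_gaussian_tube(sigma_nm = 120, length_nm = 2500,
                             lateral_halfwidth_nm = 1000,
                             axial_halfwidth_nm = 700)
  tb_b <- make_gaussian_tube(sigma_nm = 350, length_nm = 2500,
                             lateral_halfwidth_nm = 1000,
                             axial_halfwidth_nm = 700, amplitude = 0.35)
  st <- tb_n$stack; st$data <- st$data + tb_b$stack$data
  ax <- trace_axis(tb_n$mask, st$voxel_size_nm, end_trim_nm = 0)
  rp <- compute_radial_profile(st, ax, chromatid_width_nm = 1400)
  # least-squares single-Gaussian fit to the symmetrized profile; the
  # two-population mixture must carry more shoulder mass than the fit
  r <- rp$radius_nm; y <- rp$intensity
  ls_fit <- optim(c(1, 150), function(p)
    sum((p[1] * exp(-r^2 / (2 * p[2]^2)) - y)^2))$par
  gfit <- ls_fit[1] * exp(-r^2 / (2 * ls_fit[2]^2))
  tail_idx <- r > 300
  expect_gt(sum(y[tail_idx]), sum(gfit[tail_idx]) * 1.05)
})
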