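test_that("noise-only images yield essentially no detections", {
  set.seed(11)
  noise <- image_stack(array(rnorm(512 * 512 * 4, 100, 10), c(512, 512, 4)),
                       c(20, 20, 140))
  sp <- detect_spots(noise)
  expect_lte(nrow(sp), 1)  # <= 1 false positive per megapixel
})

test_that("isolated spots localize to within 10 nm", {
  g <- gen_sted_chromatid(list(type = "straight", length_nm = 1000),
                          spot_spacing_nm = 400, tube_radius_sigma_nm = 0,
                          seed = 5)
  st <- g$protein
  set.seed(9)
  st$data <- st$data + array(rnorm(length(st$data), 0, 100), dim(st$data))
  sp <- detect_spots(st)  # SNR = 10 (amplitude 1000, noise SD 100)
  expect_gte(nrow(sp), 3)
  tp <- g$truth$spot_positions
  for (i in seq_len(nrow(tp))) {
    derr <- sqrt((sp$x_nm - tp[i, 1])^2 + (sp$y_nm - tp[i, 2])^2)
    expect_lt(min(derr), 10)
  }
  # two spots 400 nm apart resolve into (at least) two clusters
  cl <- cluster_spots(sp)
  expect_equal(nrow(cl), 3)
})

test_that("clustering respects eps in the anisotropically scaled space", {
  two <- data.frame(x_nm = c(0, 10), y_nm = 0, z_nm = 0, intensity = 1)
  expect_equal(nrow(cluster_spots(two)), 1)     # 10 units apart: one cluster
  far <- data.frame(x_nm = c(0, 100), y_nm = 0, z_nm = 0, intensity = 1)
  expect_equal(nrow(cluster_spots(far)), 2)     # beyond eps: singletons kept
  # z compression: 140-nm slice neighbours merge, 56-nm axial stay apart
  zpair <- data.frame(x_nm = 0, y_nm = 0, z_nm = c(0, 140), intensity = 1)
  expect_equal(nrow(cluster_spots(zpair)), 1)
  axpair <- data.frame(x_nm = c(0, 56), y_nm = 0, z_nm = 0, intensity = 1)
  expect_equal(nrow(cluster_spots(axpair)), 2)
  expect_equal(nrow(cluster_spots(two[0, ])), 0)
})

test_that("clustering is invariant to input row order", {
  set.seed(13)
  sp <- data.frame(x_nm = runif(60, 0, 2000), y_nm = runif(60, 0, 500),
                   z_nm = sample(c(70, 210, 350), 60, TRUE),
                   intensity = runif(60, 500, 5000))
  c1 <- cluster_spots(sp)
  c2 <- cluster_spots(sp[sample(nrow(sp)), ])
  o1 <- order(c1$x_nm, c1$y_nm, c1$z_nm)
  o2 <- order(c2$x_nm, c2$y_nm, c2$z_nm)
  expect_equal(c1$x_nm[o1], c2$x_nm[o2])
  expect_equal(c1$member_count[o1], c2$member_count[o2])
})

test_that("multiplicity thresholds at the intensity unit and multiples", {
  cl <- data.frame(cluster_id = 1:3, x_nm = 0, y_nm = 0, z_nm = 0,
                   total_intensity = c(2999, 3001, 6500),
                   member_count = 1L, multiplicity = 1L)
  out <- correct_multiplicity(cl, 3000)
  expect_equal(out$multiplicity, c(1L, 2L, 3L))
  expect_error(correct_multiplicity(cl, 0), "positive")
  # total multiplicity is non-increasing in the intensity unit
  units <- c(1000, 2000, 3000, 5000, 10000)
  sums <- vapply(units, function(u)
    sum(correct_multiplicity(cl, u)$multiplicity), numeric(1))
  expect_true(all(diff(sums) <= 0))
})

test_that("spacing statistics reproduce constructed geometry", {
  ax <- structure(list(
    centroids = cbind(seq(0, 2000, by = 20), 0, 0),
    cum_s_nm = seq(0, 2000, by = 20),
    tangents = matrix(rep(c(1, 0, 0), 101), ncol = 3, byrow = TRUE),
    length_nm = 2000), class = "chromatid_axis")
  cl <- data.frame(cluster_id = 1:41, x_nm = seq(0, 2000, by = 50),
                   y_nm = 0, z_nm = 0, total_intensity = 1000,
                   member_count = 1L, multiplicity = 1L)
  ss <- spacing_stats(cl, ax)
  expect_equal(ss$median_as_nm, 50)
  expect_true(all(ss$ca_nm < 1e-9))
  expect_equal(ss$clusters_per_um, 41 / 2)
  expect_equal(ss$median_nn_nm, 50)
  expect_error(spacing_stats(cl[1, ], ax), ">= 2")
})

test_that("random uniform placements give exponential axial spacings", {
  ax <- structure(list(
    centroids = cbind(seq(0, 10000, by = 20), 0, 0),
    cum_s_nm = seq(0, 10000, by = 20),
    tangents = matrix(rep(c(1, 0, 0), 501), ncol = 3, byrow = TRUE),
    length_nm = 10000), class = "chromatid_axis")
  set.seed(8)
  n <- 600
  cl <- data.frame(cluster_id = seq_len(n),
                   x_nm = runif(n, 0, 10000), y_nm = 0, z_nm = 0,
                   total_intensity = 1000, member_count = 1L,
                   multiplicity = 1L)
  ss <- spacing_stats(cl, ax)
  ks <- ks.test(ss$as_nm, "pexp", rate = n / 10000)
  expect_gt(ks$p.value, 0.01)
})

test_that("56-nm axial spacing is recovered end to end", {
  all_as <- c(); n_cl <- 0; n_truth <- 0
  for (seed in 7:9) {
    g <- gen_sted_chromatid(list(type = "straight", length_nm = 3000),
                            spot_spacing_nm = 56,
                            tube_radius_sigma_nm = 110,
                            dna_sigma_nm = 200, seed = seed)
    tp <- g$truth$spot_positions
    set.seed(500 + seed)  # localization jitter of the detection step
    det <- data.frame(x_nm = tp[, 1] + rnorm(nrow(tp), 0, 10),
                      y_nm = tp[, 2] + rnorm(nrow(tp), 0, 10),
                      z_nm = tp[, 3] + rnorm(nrow(tp), 0, 10),
                      intensity = 1000)
    cl <- cluster_spots(det)
    ax <- axis_from_dna(g)
    ss <- spacing_stats(cl, ax)
    all_as <- c(all_as, ss$as_nm)
    n_cl <- n_cl + nrow(cl); n_truth <- n_truth + nrow(tp)
  }
  expect_equal(median(all_as), 56, tolerance = 0.10)
  expect_equal(n_cl / n_truth, 1, tolerance = 0.05)
})

test_that("60% detection efficiency thins the per-um density accordingly", {
  g <- gen_sted_chromatid(list(type = "straight", length_nm = 3000),
                          spot_spacing_nm = 56, tube_radius_sigma_nm = 110,
                          detection_efficiency = 0.6, dna_sigma_nm = 200,
                          seed = 12)
  tp <- g$truth$spot_positions[g$truth$rendered, , drop = FALSE]
  set.seed(600)
  det <- data.frame(x_nm = tp[, 1] + rnorm(nrow(tp), 0, 10),
                    y_nm = tp[, 2] + rnorm(nrow(tp), 0, 10),
                    z_nm = tp[, 3] + rnorm(nrow(tp), 0, 10),
                    intensity = 1000)
  cl <- cluster_spots(det)
  ax <- axis_from_dna(g)
  ss <- spacing_stats(cl, ax)
  full_density <- length(g$truth$spot_s_nm) / (g$truth$axis_length_nm / 1000)
  expect_lt(ss$clusters_per_um, 0.8 * full_density)
  # thinning inflates the median spacing
  expect_gt(ss$median_as_nm, 56)
})
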