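test_that("calibration fit recovers an exact line and resists outliers", {
  I <- seq(20, 200, length.out = 30)
  f <- suppressWarnings(  # rlm convergence warning on an exact line
    fit_calibration(data.frame(intensity = I,
                               concentration_nM = 2 * (I - 10))))
  expect_equal(f$slope, 2, tolerance = 1e-8)
  expect_equal(f$background_intensity, 10, tolerance = 1e-6)

  set.seed(1)
  I2 <- runif(50, 20, 200)
  pairs <- rbind(data.frame(intensity = I2, concentration_nM = 2 * (I2 - 10)),
                 data.frame(intensity = runif(5, 20, 200),
                            concentration_nM = 2500))
  # oracle: least squares on the 50 inliers alone
  oracle <- unname(coef(lm(concentration_nM ~ intensity, pairs[1:50, ]))[2])
  f2 <- fit_calibration(pairs)
  expect_equal(f2$slope, oracle, tolerance = 0.05)

  expect_error(fit_calibration(data.frame(intensity = rep(5, 10),
                                          concentration_nM = 1:10)),
               "singular")
})

test_that("intensity-to-concentration transform is affine with flooring", {
  curve <- fit_calibration(data.frame(intensity = c(10, 110),
                                      concentration_nM = c(0, 200)))
  st <- image_stack(array(10, c(4, 4, 2)), c(250, 250, 500))
  expect_true(all(intensity_to_concentration(st, curve)$data == 0))
  st2 <- image_stack(array(110, c(4, 4, 2)), c(250, 250, 500))
  expect_true(all(intensity_to_concentration(st2, curve)$data == 200))
  st3 <- image_stack(array(5, c(4, 4, 2)), c(250, 250, 500))  # below bg
  expect_true(all(intensity_to_concentration(st3, curve)$data == 0))
})

test_that("noise-free synthetic cell round-trips through the pipeline", {
  cal <- list(slope = 2, offset = 100)
  g <- gen_confocal_cell(250000, 150, calibration = cal, seed = 1)
  curve <- fit_calibration(data.frame(intensity = c(100, 200, 300),
                                      concentration_nM = c(0, 200, 400)))
  cm <- intensity_to_concentration(g$stack, curve)
  q <- quantify_compartments(cm, g$truth$cell_mask, g$truth$chromatin_mask)
  expect_equal(q$conc_Chr, g$truth$bound_concentration + 150, tolerance = 1e-3)
  expect_equal(q$conc_Cyt, 150, tolerance = 1e-6)
  qc <- correct_bound_fraction(q, "NEBD_to_anaphase")
  expect_equal(qc$N_Chr_bound, 250000, tolerance = 5e-3)
  # conservation: bound + soluble partition the whole-cell pool
  expect_equal(qc$N_Chr_bound + qc$N_Cyt, q$N_total, tolerance = 1e-8)
})

test_that("uniform concentration gives equal compartment means and zero bound", {
  g <- gen_confocal_cell(0, 100, seed = 1)
  cm <- image_stack(array(100 * g$truth$cell_mask, dim(g$truth$cell_mask)),
                    g$stack$voxel_size_nm)
  q <- quantify_compartments(cm, g$truth$cell_mask, g$truth$chromatin_mask)
  expect_equal(q$conc_Chr, 100)
  expect_equal(q$conc_Cyt, 100)
  qc <- correct_bound_fraction(q, "NEBD_to_anaphase")
  expect_equal(qc$conc_Chr_bound, 0)
  expect_equal(qc$N_Chr_bound, 0)
})

test_that("prophase equilibrium correction applies the Kd partition", {
  q <- structure(list(V_Chr = 100, V_Cyt = 900, conc_Chr = 400,
                      conc_Cyt = 50, N_total = NA), class = "compartment_quant")
  qc <- correct_bound_fraction(q, "prophase", Kd = 1)
  expect_equal(qc$conc_Chr_bound, 200)       # [Chr]/(1+Kd), Kd = 1
  expect_equal(qc$conc_Chr_bg, 200)
  # worked example from the metaphase concentrations ~520/~190 nM
  Kd <- kd_from_metaphase(520, 190)
  expect_equal(Kd, 190 / 330, tolerance = 1e-12)
  expect_equal(Kd, 0.576, tolerance = 1e-3)
  qc2 <- correct_bound_fraction(q, "prophase", Kd = Kd)
  expect_equal(qc2$conc_Chr_bound, 400 / (1 + Kd))
  expect_equal(400 / (1 + Kd), 253.8, tolerance = 1e-3)
  expect_error(correct_bound_fraction(q, "prophase"), "Kd")
})

test_that("negative bound concentrations floor at zero with a flag", {
  q <- structure(list(V_Chr = 100, V_Cyt = 900, conc_Chr = 80,
                      conc_Cyt = 100, N_total = NA), class = "compartment_quant")
  expect_warning(qc <- correct_bound_fraction(q, "NEBD_to_anaphase"),
                 "floored")
  expect_equal(qc$conc_Chr_bound, 0)
  expect_true(qc$floored)
})

test_that("bound-count recovery is accurate and monotone across cells", {
  counts <- round(seq(5e4, 5e5, length.out = 8))
  curve <- fit_calibration(data.frame(intensity = c(100, 200, 300),
                                      concentration_nM = c(0, 200, 400)))
  noise <- list(photons_per_intensity = 20, read_sd = 1)
  rec <- function(n, nm, seed) {
    g <- gen_confocal_cell(n, 120, noise_model = nm, seed = seed)
    cm <- intensity_to_concentration(g$stack, curve)
    q <- quantify_compartments(cm, g$truth$cell_mask, g$truth$chromatin_mask)
    correct_bound_fraction(q, "NEBD_to_anaphase")$N_Chr_bound
  }
  clean <- vapply(counts, rec, numeric(1), nm = NULL, seed = 1)
  expect_true(all(abs(clean / counts - 1) < 0.01))
  noisy <- vapply(seq_along(counts), function(i)
    rec(counts[i], noise, seed = i), numeric(1))
  expect_true(all(abs(noisy / counts - 1) < 0.05))
  expect_true(all(diff(clean) > 0))  # monotone in the true bound count
})

test_that("unit conversion constant is the Avogadro product", {
  expect_equal(molecules_from_conc(1, 1), 0.602214076, tolerance = 1e-12)
  expect_equal(molecules_from_conc(518.92, 800), 250000, tolerance = 1e-4)
})
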