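#' Simulate a calibrated confocal cell with known bound and free pools
#'
#' Builds a two-compartment cell — a chromatin ellipsoid nested inside a
#' cell ellipsoid — on a voxel grid, fills it with a freely diffusing
#' protein pool of known concentration plus a chromatin-bound pool of a
#' known total copy number, and renders fluorescence intensity through an
#' affine calibration (intensity = background + concentration / slope)
#' with optional Poisson photon noise and Gaussian read noise.
#'
#' @param bound_count total number of chromatin-bound molecules
#' @param free_conc_nM concentration of the freely diffusing pool (nM),
#'   present throughout the cell volume (chromatin included)
#' @param geometry list with `dim` (voxels, length 3), `voxel_size_nm`,
#'   `cell_semiaxes_nm`, `chromatin_semiaxes_nm` (both length 3, centered)
#' @param noise_model `NULL` for noise-free, else list with
#'   `photons_per_intensity` (Poisson scaling, 0 disables) and `read_sd`
#'   (Gaussian read noise, intensity units)
#' @param calibration list with `slope` (nM per intensity unit) and
#'   `offset` (background intensity)
#' @param seed integer seed; fixed seed gives bit-identical output
#' @return list with `stack` (an [image_stack()]) and `truth` (a
#'   `synthetic_cell_truth`: masks, bound count, free concentration,
#'   calibration and the implied bound concentration)
#' @export
gen_confocal_cell <- function(bound_count, free_conc_nM,
                              geometry = list(),
                              noise_model = NULL,
                              calibration = list(slope = 2, offset = 100),
                              seed = 1L) {
  g <- utils::modifyList(list(
    dim = c(48L, 48L, 24L),
    voxel_size_nm = c(250, 250, 500),
    cell_semiaxes_nm = c(5500, 5500, 5200),
    chromatin_semiaxes_nm = c(3200, 3200, 2800)), geometry)
  stopifnot(bound_count >= 0, free_conc_nM >= 0, calibration$slope > 0)
  if (any(g$chromatin_semiaxes_nm >= g$cell_semiaxes_nm))
    stop("chromatin ellipsoid must be strictly nested inside the cell ellipsoid")

  vox <- g$voxel_size_nm
  ctr <- g$dim * vox / 2
  ax <- (seq_len(g$dim[1]) - 0.5) * vox[1] - ctr[1]
  ay <- (seq_len(g$dim[2]) - 0.5) * vox[2] - ctr[2]
  az <- (seq_len(g$dim[3]) - 0.5) * vox[3] - ctr[3]
  ell <- function(semi) {
    r2 <- outer(outer((ax / semi[1])^2, (ay / semi[2])^2, `+`),
                (az / semi[3])^2, `+`)
    r2 <= 1
  }
  cell_mask <- ell(g$cell_semiaxes_nm)
  chromatin_mask <- ell(g$chromatin_semiaxes_nm)
  if (!all(chromatin_mask[chromatin_mask] & cell_mask[chromatin_mask]))
    stop("geometry not nested")

  vvol <- prod(vox) * 1e-9
  v_chr <- sum(chromatin_mask) * vvol
  bound_conc <- if (bound_count > 0) bound_count / (v_chr * NM_UM3_TO_MOLECULES) else 0

  conc <- array(0, g$dim)
  conc[cell_mask] <- free_conc_nM
  conc[chromatin_mask] <- conc[chromatin_mask] + bound_conc

  intensity <- calibration$offset + conc / calibration$slope
  if (!is.null(noise_model)) {
    set.seed(as.integer(seed))
    ppi <- noise_model$photons_per_intensity %||% 0
    if (ppi > 0)
      intensity <- array(rpois(length(intensity), intensity * ppi) / ppi,
                         dim(intensity))
    rsd <- noise_model$read_sd %||% 0
    if (rsd > 0)
      intensity <- intensity + array(rnorm(length(intensity), 0, rsd),
                                     dim(intensity))
  }

  truth <- structure(list(
    bound_count = bound_count,
    free_concentration = free_conc_nM,
    bound_concentration = bound_conc,
    chromatin_mask = chromatin_mask,
    cell_mask = cell_mask,
    chromatin_volume_um3 = v_chr,
    cell_volume_um3 = sum(cell_mask) * vvol,
    calibration_slope = calibration$slope,
    calibration_offset = calibration$offset),
    class = "synthetic_cell_truth")
  list(stack = image_stack(intensity, vox, "protein"), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a normalized FRAP difference trajectory
#'
#' The normalized difference between unbleached and bleached chromatin
#' halves follows the two-state exchange model
#' \eqn{a + (1 - a) e^{-(\kappa + k_{off}) t}} where `a` is the immobile
#' fraction and the combined rate \eqn{\kappa + k_{off}} is the inverse
#' residence time. Gaussian noise of standard deviation `noise_sd` is
#' added independently per frame; the value at t = 0 is 1 by
#' construction of the model (noise is still added for t = 0 frames when
#' `noise_sd > 0`, as in a real measurement).
#'
#' @param immobile_a immobile fraction in `[0, 1]`
#' @param rate_per_min combined exchange rate (per minute), > 0
#' @param n_frames number of frames (default 40; acquisitions of 30-45
#'   frames at 20-s intervals are typical)
#' @param dt_s frame interval in seconds (> 0)
#' @param noise_sd per-frame Gaussian noise SD on the normalized scale
#' @param seed integer seed
#' @return list with `series` (a `frap_series`: `t_s`, `norm_diff`) and
#'   `truth` (`a`, `rate_per_min`, `tau_min`)
#' @export
gen_frap_series <- function(immobile_a, rate_per_min, n_frames = 40L,
                            dt_s = 20, noise_sd = 0, seed = 1L) {
  stopifnot(immobile_a >= 0, immobile_a <= 1, rate_per_min > 0)
  if (dt_s <= 0) stop("dt_s must be positive")
  t_s <- (seq_len(n_frames) - 1L) * dt_s
  nd <- immobile_a + (1 - immobile_a) * exp(-rate_per_min * t_s / 60)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    nd <- nd + rnorm(n_frames, 0, noise_sd)
  }
  series <- structure(list(t_s = t_s, norm_diff = nd), class = "frap_series")
  list(series = series,
       truth = list(a = immobile_a, rate_per_min = rate_per_min,
                    tau_min = 1 / rate_per_min))
}
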