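#' Fit an FCS calibration curve by robust linear regression
#'
#' Relates measured fluorescence intensity to absolute concentration via
#' the linear model `concentration = slope * (intensity - background)`.
#' The line is fitted by iteratively reweighted robust regression
#' ([MASS::rlm()], M-estimation), so a minority of gross outliers among
#' the calibration measurements does not bias the factor.
#'
#' @param pairs data frame (or matrix) with columns `intensity` and
#'   `concentration_nM`; at least 2 distinct intensities required
#' @return a `calibration_curve`: `slope` (nM per intensity unit),
#'   `background_intensity`, `fit_residual_scale`, `n_points`
#' @export
fit_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("intensity", "concentration_nM") %in% names(pairs)))
  if (length(unique(pairs$intensity)) < 2)
    stop("calibration fit is singular: need >= 2 distinct intensities")
  # M-estimation degenerates when the points are exactly collinear
  # (zero residual scale); ordinary least squares is exact there
  fit <- tryCatch(MASS::rlm(concentration_nM ~ intensity, data = pairs,
                            maxit = 50),
                  error = function(e)
                    stats::lm(concentration_nM ~ intensity, data = pairs))
  if (!all(is.finite(coef(fit))))
    fit <- stats::lm(concentration_nM ~ intensity, data = pairs)
  slope <- unname(coef(fit)["intensity"])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive; got ", slope)
  structure(list(
    slope = slope,
    background_intensity = -unname(coef(fit)["(Intercept)"]) / slope,
    fit_residual_scale = fit$s,
    n_points = nrow(pairs)),
    class = "calibration_curve")
}

#' Convert a fluorescence stack into a concentration map
#'
#' Applies the affine calibration voxelwise:
#' `conc = slope * (intensity - background)`. Negative values (noise
#' below background) are floored at 0.
#'
#' @param stack single-channel [image_stack()] with voxel-size metadata
#' @param curve a `calibration_curve` from [fit_calibration()]
#' @return [image_stack()] of concentrations (nM)
#' @export
intensity_to_concentration <- function(stack, curve) {
  stopifnot(inherits(stack, "image_stack"), inherits(curve, "calibration_curve"))
  if (is.null(stack$voxel_size_nm) || any(!is.finite(stack$voxel_size_nm)))
    stop("stack is missing voxel-size metadata")
  conc <- curve$slope * (stack$data - curve$background_intensity)
  conc[conc < 0] <- 0
  image_stack(conc, stack$voxel_size_nm, "concentration_nM")
}

#' Per-compartment volumes, concentrations and total copy number
#'
#' The cytoplasmic region is the cell mask minus the chromatin mask (XOR
#' of the nested masks). Volumes come from voxel counts times the voxel
#' volume; compartment concentrations are means of the concentration map
#' over each region; the total cellular copy number integrates the map
#' over the cell mask.
#'
#' @param conc_map concentration [image_stack()] (nM)
#' @param cell_mask,chromatin_mask logical arrays, `chromatin_mask`
#'   nested inside `cell_mask`
#' @return a `compartment_quant` with `V_Chr`, `V_Cyt` (um^3),
#'   `conc_Chr`, `conc_Cyt` (nM) and `N_total` (molecules)
#' @export
quantify_compartments <- function(conc_map, cell_mask, chromatin_mask) {
  stopifnot(inherits(conc_map, "image_stack"))
  if (!any(cell_mask) || !any(chromatin_mask)) stop("empty mask")
  if (any(chromatin_mask & !cell_mask))
    stop("chromatin mask must be nested inside the cell mask")
  cyt_mask <- cell_mask & !chromatin_mask
  vvol <- voxel_volume_um3(conc_map)
  v_chr <- sum(chromatin_mask) * vvol
  v_cyt <- sum(cyt_mask) * vvol
  conc_chr <- mean(conc_map$data[chromatin_mask])
  conc_cyt <- mean(conc_map$data[cyt_mask])
  n_total <- sum(conc_map$data[cell_mask]) * vvol * NM_UM3_TO_MOLECULES
  structure(list(V_Chr = v_chr, V_Cyt = v_cyt,
                 conc_Chr = conc_chr, conc_Cyt = conc_cyt,
                 N_total = n_total),
            class = "compartment_quant")
}

#' Split compartment quantities into chromatin-bound and soluble pools
#'
#' Between nuclear envelope breakdown and the end of anaphase the
#' nuclear envelope is open, so the freely diffusing pool inside the
#' chromatin region has the cytoplasmic concentration: the bound
#' concentration is `[Chr]c = [Chr] - [Cyt]`, the bound copy number is
#' `N_Chr_bound = [Chr]c * V_Chr * N_A`, and the soluble count adds the
#' free pool inside the chromatin volume,
#' `N_Cyt = ([Cyt] V_Cyt + [Cyt] V_Chr) * N_A`. In prophase the envelope
#' is closed and a binding equilibrium is assumed instead: with
#' `Kd = [Cyt](meta) / [Chr]c(meta)` estimated from a metaphase cell of
#' the same experiment, the free nuclear concentration is
#' `[Chr]bg = Kd/(1 + Kd) [Chr]` and the bound concentration
#' `[Chr]c = [Chr]/(1 + Kd)`. After nuclear envelope reformation no
#' equilibrium constant is measurable and only the total nuclear count
#' is reported.
#'
#' @param quant a `compartment_quant` from [quantify_compartments()]
#' @param phase_label one of `"prophase"`, `"NEBD_to_anaphase"`,
#'   `"post_reformation"`
#' @param Kd dissociation-equilibrium ratio from metaphase; required for
#'   `"prophase"`
#' @return the input with added fields `conc_Chr_bound`, `conc_Chr_bg`,
#'   `N_Chr_bound`, `N_Cyt`, `Kd`, `phase_label`, `floored` (TRUE when a
#'   negative bound concentration was clipped to 0)
#' @export
correct_bound_fraction <- function(quant, phase_label, Kd = NULL) {
  stopifnot(inherits(quant, "compartment_quant"))
  phase_label <- match.arg(phase_label,
    c("prophase", "NEBD_to_anaphase", "post_reformation"))
  q <- quant
  q$phase_label <- phase_label
  q$floored <- FALSE
  if (phase_label == "NEBD_to_anaphase") {
    cb <- q$conc_Chr - q$conc_Cyt
    if (cb < 0) {
      warning("cytoplasmic concentration exceeds chromatin concentration; ",
              "bound concentration floored at 0")
      cb <- 0; q$floored <- TRUE
    }
    q$conc_Chr_bg <- q$conc_Cyt
    q$conc_Chr_bound <- cb
    q$N_Chr_bound <- molecules_from_conc(cb, q$V_Chr)
    q$N_Cyt <- molecules_from_conc(q$conc_Cyt, q$V_Cyt + q$V_Chr)
    q$Kd <- NA_real_
  } else if (phase_label == "prophase") {
    if (is.null(Kd)) stop("prophase correction needs Kd from a metaphase cell")
    q$Kd <- Kd
    q$conc_Chr_bg <- Kd / (1 + Kd) * q$conc_Chr
    q$conc_Chr_bound <- q$conc_Chr / (1 + Kd)
    q$N_Chr_bound <- molecules_from_conc(q$conc_Chr_bound, q$V_Chr)
    q$N_Cyt <- molecules_from_conc(q$conc_Cyt, q$V_Cyt) +
      molecules_from_conc(q$conc_Chr_bg, q$V_Chr)
  } else {
    q$conc_Chr_bound <- NA_real_
    q$conc_Chr_bg <- NA_real_
    q$N_Chr_bound <- NA_real_
    q$N_Cyt <- NA_real_
    q$Kd <- NA_real_
    q$N_nuclear <- molecules_from_conc(q$conc_Chr, q$V_Chr)
  }
  q
}

#' Estimate the binding-equilibrium ratio from a metaphase cell
#'
#' `Kd = [Cyt](meta) / [Chr]c(meta)` with
#' `[Chr]c(meta) = [Chr](meta) - [Cyt](meta)`.
#'
#' @param conc_Chr_meta,conc_Cyt_meta metaphase chromatin and
#'   cytoplasmic mean concentrations (nM)
#' @return dimensionless Kd
#' @export
kd_from_metaphase <- function(conc_Chr_meta, conc_Cyt_meta) {
  cb <- conc_Chr_meta - conc_Cyt_meta
  if (cb <= 0) stop("metaphase bound concentration must be positive")
  conc_Cyt_meta / cb
}
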