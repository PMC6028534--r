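#' Extract bleached/unbleached profiles and the normalized difference
#'
#' Projects the DNA-weighted protein intensity onto the major 2D axis of
#' the chromatin mask (principal axis of the mask's second moments),
#' splits the profile at the bleach boundary, excludes a central gap of
#' `gap_px` pixels around the boundary to avoid edge effects, and forms
#' the DNA-weighted means of the protein signal in the bleached (`F_b`)
#' and unbleached (`F_ub`) halves:
#' \deqn{F(t) = \sum_x P(x,t) D(x,t) / \sum_x D(x,t).}
#' The readout is the normalized difference: the per-frame contrast
#' `(F_ub(t) - F_b(t)) / (F_ub(t) + F_b(t))` anchored to 1 at t = 0.
#' Dividing by the per-frame sum makes any multiplicative
#' photobleaching factor common to both halves cancel exactly, which is
#' the rationale for fitting the pure exchange model to this readout;
#' without photobleaching it coincides with dividing by the initial
#' difference alone.
#'
#' @param protein_stacks,dna_stacks lists of per-timepoint
#'   [image_stack()]s (protein and DNA channels, same grids)
#' @param bleach_side which side of the major axis was bleached:
#'   `"low"` (smaller axis coordinate) or `"high"`
#' @param gap_px half-gap excluded on each side of the bleach boundary,
#'   in pixels along the major axis (default 14)
#' @param dna_threshold fraction of the DNA-channel maximum used to
#'   segment the chromatin mask (default 0.2)
#' @param prefilter_sigma_px Gaussian prefilter applied in-plane to both
#'   channels before profile extraction (0 disables)
#' @param t_s acquisition times in seconds (default frame index * 20 s)
#' @return a `frap_series` with `t_s`, `F_b`, `F_ub`, `norm_diff`
#' @export
extract_frap_profiles <- function(protein_stacks, dna_stacks,
                                  bleach_side = c("low", "high"),
                                  gap_px = 14L,
                                  dna_threshold = 0.2,
                                  prefilter_sigma_px = 1,
                                  t_s = NULL) {
  bleach_side <- match.arg(bleach_side)
  n <- length(protein_stacks)
  stopifnot(n == length(dna_stacks), n >= 1)
  if (is.null(t_s)) t_s <- (seq_len(n) - 1) * 20

  # chromatin mask and major axis from the first (prebleach) DNA frame
  d0 <- dna_stacks[[1]]$data
  mask <- d0 >= dna_threshold * max(d0)
  idx <- which(apply(mask, c(1, 2), any), arr.ind = TRUE)  # in-plane voxels
  if (nrow(idx) < 2) stop("chromatin mask too small for axis extraction")
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  if (ev[which.max(abs(ev))] < 0) ev <- -ev  # deterministic orientation

  F_b <- F_ub <- numeric(n)
  for (i in seq_len(n)) {
    p <- protein_stacks[[i]]$data
    d <- dna_stacks[[i]]$data
    if (prefilter_sigma_px > 0) {
      p <- gaussian_smooth3(p, c(prefilter_sigma_px, prefilter_sigma_px, 0))
      d <- gaussian_smooth3(d, c(prefilter_sigma_px, prefilter_sigma_px, 0))
    }
    # project chromatin voxels (all z) onto the in-plane major axis
    vox <- which(array(mask, dim(d)), arr.ind = TRUE)
    s <- (vox[, 1] - ctr[1]) * ev[1] + (vox[, 2] - ctr[2]) * ev[2]
    pw <- p[vox]; dw <- d[vox]
    keep <- abs(s) > gap_px / 2
    s <- s[keep]; pw <- pw[keep]; dw <- dw[keep]
    lo <- s < 0
    side_b <- if (bleach_side == "low") lo else !lo
    F_b[i] <- sum(pw[side_b] * dw[side_b]) / sum(dw[side_b])
    F_ub[i] <- sum(pw[!side_b] * dw[!side_b]) / sum(dw[!side_b])
  }
  contrast <- (F_ub - F_b) / (F_ub + F_b)
  if (!is.finite(contrast[1]) || abs(contrast[1]) < .Machine$double.eps * 100)
    stop("normalization undefined: no intensity difference at t = 0")
  structure(list(t_s = t_s, F_b = F_b, F_ub = F_ub,
                 norm_diff = contrast / contrast[1]),
            class = "frap_series")
}

#' Fit the two-state exchange model to a FRAP difference curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM()])
#' fit of \eqn{a + (1 - a) e^{-(\kappa + k_{off}) t}} to the normalized
#' difference trajectory. `a` is the immobile fraction; the combined
#' rate \eqn{\kappa + k_{off}} (with \eqn{\kappa = k_{on} B}) sets the
#' residence time \eqn{\tau = 1/(\kappa + k_{off})}. Only the combined
#' rate is identifiable from this experiment.
#'
#' @param series a `frap_series` (needs `t_s` and `norm_diff`)
#' @param start optional list with starting values `a`, `rate_per_min`
#' @return a `frap_fit`: `a`, `rate_per_min`, `tau_min`, `clipped`
#'   (TRUE if `a` was clipped into `[0, 1]`), `fit` (the nls object)
#' @export
fit_recovery <- function(series, start = list(a = 0.5, rate_per_min = 1)) {
  stopifnot(!is.null(series$t_s), !is.null(series$norm_diff))
  if (length(series$t_s) < 10) stop("need >= 10 frames to fit the model")
  df <- data.frame(t_min = series$t_s / 60, nd = series$norm_diff)
  fit <- tryCatch(
    minpack.lm::nlsLM(nd ~ a + (1 - a) * exp(-rate * t_min), data = df,
                      start = list(a = start$a, rate = start$rate_per_min),
                      lower = c(a = -0.5, rate = 1e-6),
                      upper = c(a = 1.5, rate = 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("FRAP fit did not converge: ",
                             conditionMessage(e)))
  a <- unname(coef(fit)["a"]); rate <- unname(coef(fit)["rate"])
  clipped <- a < 0 || a > 1
  if (clipped) {
    warning("fitted immobile fraction ", signif(a, 3),
            " outside [0, 1]; clipped")
    a <- min(max(a, 0), 1)
  }
  structure(list(a = a, rate_per_min = rate, tau_min = 1 / rate,
                 clipped = clipped, fit = fit),
            class = "frap_fit")
}

#' Fraction of the mobile pool exchanged by time T
#'
#' Closed form under the exchange model:
#' `(1 - a) * (1 - exp(-rate * T))`.
#'
#' @param fit a `frap_fit` (or list with `a`, `rate_per_min`)
#' @param T_min time in minutes
#' @return exchanged fraction of the chromosome-bound pool
#' @export
exchanged_fraction <- function(fit, T_min) {
  (1 - fit$a) * (1 - exp(-fit$rate_per_min * T_min))
}

#' Bootstrap the exchange-model parameters over cells
#'
#' Resamples cells with replacement `n` times; for each resample the
#' model is fitted to the pooled (t, normalized difference) data of the
#' sampled cells. Failed fits are recorded and excluded.
#'
#' @param series_collection list of `frap_series` (>= 3 cells)
#' @param n number of bootstrap resamples (default 300)
#' @param seed integer seed
#' @return a `frap_bootstrap`: vectors `boot_a`, `boot_rate`, `boot_tau`,
#'   medians and interquartile ranges of each, and `n_failed`
#' @export
bootstrap_fit <- function(series_collection, n = 300L, seed = 1L) {
  m <- length(series_collection)
  if (m < 3) stop("need >= 3 cells to bootstrap")
  set.seed(as.integer(seed))
  boot_a <- boot_rate <- rep(NA_real_, n)
  n_failed <- 0L
  for (b in seq_len(n)) {
    pick <- sample.int(m, m, replace = TRUE)
    t_all <- unlist(lapply(series_collection[pick], `[[`, "t_s"))
    nd_all <- unlist(lapply(series_collection[pick], `[[`, "norm_diff"))
    f <- tryCatch(
      suppressWarnings(fit_recovery(list(t_s = t_all, norm_diff = nd_all))),
      error = function(e) NULL)
    if (is.null(f)) { n_failed <- n_failed + 1L; next }
    boot_a[b] <- f$a; boot_rate[b] <- f$rate_per_min
  }
  ok <- !is.na(boot_a)
  summ <- function(v) c(median = median(v), iqr_lo = unname(quantile(v, 0.25)),
                        iqr_hi = unname(quantile(v, 0.75)))
  structure(list(boot_a = boot_a[ok], boot_rate = boot_rate[ok],
                 boot_tau = 1 / boot_rate[ok],
                 a = summ(boot_a[ok]), rate = summ(boot_rate[ok]),
                 tau = summ(1 / boot_rate[ok]),
                 n_failed = n_failed, n = n),
            class = "frap_bootstrap")
}
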