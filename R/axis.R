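# --- slice drift estimation --------------------------------------------

# translation (px) aligning slice b onto slice a, by exhaustive integer
# cross-correlation with parabolic sub-pixel refinement
estimate_shift2d <- function(a, b, max_shift = 6L) {
  score <- matrix(-Inf, 2 * max_shift + 1, 2 * max_shift + 1)
  d <- dim(a)
  for (sx in -max_shift:max_shift) for (sy in -max_shift:max_shift) {
    ax <- max(1, 1 + sx):min(d[1], d[1] + sx)
    ay <- max(1, 1 + sy):min(d[2], d[2] + sy)
    bx <- ax - sx; by <- ay - sy
    va <- a[ax, ay]; vb <- b[bx, by]
    score[sx + max_shift + 1, sy + max_shift + 1] <-
      sum(va * vb) / sqrt(sum(va^2) * sum(vb^2) + 1e-300)
  }
  pk <- which(score == max(score), arr.ind = TRUE)[1, ]
  refine <- function(m, i, j, along) {
    if (along == 1 && (i == 1 || i == nrow(m))) return(0)
    if (along == 2 && (j == 1 || j == ncol(m))) return(0)
    y0 <- m[i, j]
    ym <- if (along == 1) m[i - 1, j] else m[i, j - 1]
    yp <- if (along == 1) m[i + 1, j] else m[i, j + 1]
    den <- ym - 2 * y0 + yp
    if (abs(den) < 1e-12) 0 else 0.5 * (ym - yp) / den
  }
  # score peaks at sx = -s when b's content is a's shifted by +s;
  # negate so the return value is the content shift of b relative to a
  -c(pk[1] - max_shift - 1 + refine(score, pk[1], pk[2], 1),
     pk[2] - max_shift - 1 + refine(score, pk[1], pk[2], 2))
}

# shift a 2D slice by (sx, sy) pixels with bilinear interpolation
shift_slice <- function(a, s) {
  d <- dim(a)
  px <- seq_len(d[1]) - s[1]; py <- seq_len(d[2]) - s[2]
  x0 <- floor(px); fx <- px - x0
  y0 <- floor(py); fy <- py - y0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  a00 <- a[cl(x0, d[1]), cl(y0, d[2])]
  a10 <- a[cl(x0 + 1, d[1]), cl(y0, d[2])]
  a01 <- a[cl(x0, d[1]), cl(y0 + 1, d[2])]
  a11 <- a[cl(x0 + 1, d[1]), cl(y0 + 1, d[2])]
  wx <- matrix(fx, d[1], d[2]); wy <- matrix(fy, d[1], d[2], byrow = TRUE)
  a00 * (1 - wx) * (1 - wy) + a10 * wx * (1 - wy) +
    a01 * (1 - wx) * wy + a11 * wx * wy
}

#' Preprocess a STED z stack for axis analysis
#'
#' Three steps: (1) slice-to-slice drift correction — the lateral
#' translation between consecutive z slices is estimated by normalized
#' cross-correlation with sub-pixel refinement and removed cumulatively;
#' (2) linear interpolation along z to an isotropic voxel size matching
#' the lateral pixel size; (3) Gaussian smoothing (sigma in voxels) of
#' the resulting stack.
#'
#' @param stack an [image_stack()] (native grid, e.g. 20 nm xy / 140 nm z)
#' @param drift_correct logical; skipped with a warning for single-slice
#'   stacks
#' @param interpolate_z logical; identity if the stack is already
#'   isotropic
#' @param smooth_sigma Gaussian sigma in voxels (default 0.5; 0 disables)
#' @param max_shift_px drift search radius in pixels
#' @return preprocessed [image_stack()] (isotropic if requested); the
#'   per-slice cumulative shifts applied are attached as attribute
#'   `"drift_px"`
#' @export
preprocess_stack <- function(stack, drift_correct = TRUE,
                             interpolate_z = TRUE, smooth_sigma = 0.5,
                             max_shift_px = 6L) {
  a <- stack$data
  vox <- stack$voxel_size_nm
  nz <- dim(a)[3]
  drift <- matrix(0, nz, 2)
  if (drift_correct) {
    if (nz < 2) {
      warning("single-slice stack: drift correction skipped")
    } else {
      for (z in 2:nz)
        drift[z, ] <- drift[z - 1, ] +
          estimate_shift2d(a[, , z - 1], a[, , z], max_shift_px)
      drift <- sweep(drift, 2, colMeans(drift))
      for (z in seq_len(nz))
        a[, , z] <- shift_slice(a[, , z], -drift[z, ])
    }
  }
  if (interpolate_z && nz >= 2 && abs(vox[3] - vox[1]) > 1e-9) {
    zc_old <- (seq_len(nz) - 0.5) * vox[3]
    nz_new <- max(2L, floor((nz * vox[3]) / vox[1]))
    zc_new <- (seq_len(nz_new) - 0.5) * vox[1]
    zc_new <- zc_new[zc_new >= zc_old[1] & zc_new <= zc_old[nz]]
    b <- array(0, c(dim(a)[1:2], length(zc_new)))
    i <- findInterval(zc_new, zc_old, rightmost.closed = TRUE)
    i <- pmin(i, nz - 1L)
    f <- (zc_new - zc_old[i]) / (zc_old[i + 1L] - zc_old[i])
    for (k in seq_along(zc_new))
      b[, , k] <- a[, , i[k]] * (1 - f[k]) + a[, , i[k] + 1L] * f[k]
    a <- b
    vox <- c(vox[1], vox[2], vox[1])
  }
  if (smooth_sigma > 0) a <- gaussian_smooth3(a, rep(smooth_sigma, 3))
  out <- image_stack(a, vox, stack$channel)
  attr(out, "drift_px") <- drift
  out
}

# --- axis tracing -------------------------------------------------------

#' Trace the 3D chromatid/Condensin axis from a segmented volume
#'
#' Two-pass centerline extraction. First the segmented voxel cloud is
#' cut into cross sections orthogonal to its principal eigenvector at
#' `coarse_step_nm` spacing; their centroids give a coarse polyline.
#' Second, the polyline is resampled at `fine_step_nm` and each point is
#' re-centered on the centroid of the voxels in a thin slab orthogonal
#' to the local tangent, so the slicing follows the local curvature. A
#' configurable trim is excluded from both chromatid ends.
#'
#' @param mask logical 3D array (single tube-like component) or an
#'   [image_stack()] holding one
#' @param voxel_size_nm voxel size (taken from the stack if given)
#' @param coarse_step_nm first-pass slice spacing (default 100)
#' @param fine_step_nm second-pass spacing (default 20)
#' @param end_trim_nm length excluded from each end of the traced axis
#' @param lateral_max_nm maximum lateral distance of slab voxels from
#'   the current center (guards against grabbing distant mask parts)
#' @return a `chromatid_axis`: `centroids` (n x 3, nm), `cum_s_nm`,
#'   `tangents`, `length_nm`
#' @export
trace_axis <- function(mask, voxel_size_nm = NULL, coarse_step_nm = 100,
                       fine_step_nm = 20, end_trim_nm = 0,
                       lateral_max_nm = 1500) {
  if (inherits(mask, "image_stack")) {
    voxel_size_nm <- mask$voxel_size_nm
    mask <- mask$data > 0
  }
  stopifnot(!is.null(voxel_size_nm))
  pts <- voxel_coords_nm(mask, voxel_size_nm)
  if (nrow(pts) < 10) stop("mask too small to trace")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (sqrt(eg$values[1] / max(eg$values[2], 1e-12)) < 2)
    stop("no dominant axis: mask aspect ratio < 2")
  e1 <- eg$vectors[, 1]

  # pass 1: coarse slicing orthogonal to the principal eigenvector
  tproj <- cc %*% e1
  br <- seq(min(tproj) - 1e-9, max(tproj) + coarse_step_nm, by = coarse_step_nm)
  bin <- findInterval(tproj, br)
  coarse <- do.call(rbind, lapply(sort(unique(bin)), function(b)
    colMeans(pts[bin == b, , drop = FALSE])))
  # terminal bins cut the tube obliquely and are clipped by the volume
  # ends, biasing their centroids off-axis; drop them and let the
  # end-walk below recover the tips along the correct local tangent
  if (nrow(coarse) > 4) coarse <- coarse[2:(nrow(coarse) - 1), , drop = FALSE]

  # pass 2: resample at fine spacing, re-center in local orthogonal slabs
  cum <- polyline_cumlen(coarse)
  L0 <- cum[length(cum)]
  s_fine <- seq(0, L0, by = fine_step_nm)
  fine <- polyline_point(coarse, cum, s_fine)
  centro <- matrix(NA_real_, length(s_fine), 3)
  for (i in seq_along(s_fine)) {
    tg <- polyline_point(coarse, cum, min(s_fine[i] + coarse_step_nm, L0)) -
          polyline_point(coarse, cum, max(s_fine[i] - coarse_step_nm, 0))
    tg <- tg / sqrt(sum(tg^2))
    rel <- sweep(pts, 2, fine[i, ])
    d_ax <- rel %*% t(tg)
    inslab <- abs(d_ax) <= fine_step_nm / 2
    if (!any(inslab)) next
    lat2 <- rowSums(rel[inslab, , drop = FALSE]^2) - d_ax[inslab]^2
    sel <- which(inslab)[lat2 <= lateral_max_nm^2]
    if (!length(sel)) next
    centro[i, ] <- colMeans(pts[sel, , drop = FALSE])
  }
  centro <- centro[!is.na(centro[, 1]), , drop = FALSE]
  # voxel quantization makes the raw slab centroids wobble a few nm
  # around the true centerline, which inflates the polyline length;
  # a short moving average removes the wobble without flattening
  # curvature at the 20-nm scale
  smooth_polyline <- function(p, w = 5L) {
    if (nrow(p) < w) return(p)
    h <- (w - 1L) %/% 2L
    out <- p
    for (i in seq_len(nrow(p))) {
      r <- min(h, i - 1L, nrow(p) - i)
      out[i, ] <- colMeans(p[(i - r):(i + r), , drop = FALSE])
    }
    out
  }
  centro <- smooth_polyline(centro)
  # walk outward from both ends in fine steps until the orthogonal slab
  # empties, recovering the tube tips dropped with the terminal bins
  extend_end <- function(centro, head_end) {
    for (iter in seq_len(2L * ceiling(coarse_step_nm / fine_step_nm) + 4L)) {
      n <- nrow(centro)
      k <- min(6L, n)
      tg <- if (head_end) centro[1, ] - centro[k, ] else
        centro[n, ] - centro[n - k + 1L, ]
      tg <- tg / sqrt(sum(tg^2))
      p <- (if (head_end) centro[1, ] else centro[n, ]) + fine_step_nm * tg
      rel <- sweep(pts, 2, p)
      d_ax <- rel %*% tg
      inslab <- abs(d_ax) <= fine_step_nm / 2
      if (!any(inslab)) break
      lat2 <- rowSums(rel[inslab, , drop = FALSE]^2) - d_ax[inslab]^2
      sel <- which(inslab)[lat2 <= lateral_max_nm^2]
      if (!length(sel)) break
      q <- colMeans(pts[sel, , drop = FALSE])
      adv <- sum((q - (if (head_end) centro[1, ] else centro[n, ])) * tg)
      if (adv < fine_step_nm / 4) break
      centro <- if (head_end) rbind(q, centro) else rbind(centro, q)
    }
    centro
  }
  if (nrow(centro) >= 2) {
    centro <- extend_end(centro, TRUE)
    centro <- extend_end(centro, FALSE)
  }
  dimnames(centro) <- NULL
  cumf <- unname(polyline_cumlen(centro))
  Lf <- cumf[length(cumf)]
  if (end_trim_nm > 0) {
    keep <- cumf >= end_trim_nm & cumf <= Lf - end_trim_nm
    if (sum(keep) < 2) stop("end trim leaves no axis")
    centro <- centro[keep, , drop = FALSE]
    cumf <- polyline_cumlen(centro)
    Lf <- cumf[length(cumf)]
  }
  tang <- rbind(centro[2, ] - centro[1, ],
                (centro[-(1:2), , drop = FALSE] -
                 centro[seq_len(nrow(centro) - 2), , drop = FALSE]) / 2,
                centro[nrow(centro), ] - centro[nrow(centro) - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(centroids = centro, cum_s_nm = cumf, tangents = tang,
                 length_nm = Lf, spacing_nm = fine_step_nm),
            class = "chromatid_axis")
}

#' @export
print.chromatid_axis <- function(x, ...) {
  cat(sprintf("<chromatid_axis> %d points, length %.0f nm\n",
              nrow(x$centroids), x$length_nm))
  invisible(x)
}

# local orthonormal frame for a tangent: u in-plane lateral, v ~ z
axis_frame <- function(tg) {
  u <- c(-tg[2], tg[1], 0)
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) u <- c(1, 0, 0) else u <- u / nu
  v <- c(tg[2] * u[3] - tg[3] * u[2],
         tg[3] * u[1] - tg[1] * u[3],
         tg[1] * u[2] - tg[2] * u[1])
  list(u = u, v = v / sqrt(sum(v^2)))
}

# accumulate cross sections orthogonal to the axis over a span of axis
# points; returns matrix [u, v] of summed interpolated intensities
accumulate_cross_sections <- function(stack, axis, idx, u_grid, v_grid) {
  acc <- matrix(0, length(u_grid), length(v_grid))
  gv <- as.matrix(expand.grid(u = u_grid, v = v_grid))
  for (i in idx) {
    fr <- axis_frame(axis$tangents[i, ])
    pts <- matrix(axis$centroids[i, ], nrow(gv), 3, byrow = TRUE) +
      gv[, 1] %o% fr$u + gv[, 2] %o% fr$v
    acc <- acc + matrix(sample_trilinear(stack$data, stack$voxel_size_nm, pts),
                        length(u_grid), length(v_grid))
  }
  acc
}

#' Sliding-window FWHM profile of a tube-like signal along its axis
#'
#' Within each sliding window along the axis (default 2 um, shifted by
#' 200 nm), cross sections orthogonal to the local axis are accumulated
#' and sum-projected along the axial z direction onto a 1D lateral
#' profile. After subtracting the profile's tail median (background),
#' the full width at half maximum is measured by linear interpolation of
#' the half-maximum crossings. The mean over windows is the width of the
#' structure.
#'
#' @param stack preprocessed (isotropic) [image_stack()]
#' @param axis a `chromatid_axis`
#' @param window_nm sliding window length (default 2000)
#' @param step_nm window shift (default 200)
#' @param lateral_extent_nm half-extent of the sampled profile (default
#'   1000)
#' @param axial_extent_nm half-extent of the z-projection (default 600)
#' @param sample_nm sampling pitch of the cross-section grid (default 20)
#' @param subtract_background subtract the tail median before the
#'   half-max search (tails = outer 20% of the profile)
#' @return a `width_profile`: `window_centers_nm`, `fwhm_nm` (NA for
#'   windows without a half-max crossing), `mean_fwhm_nm`
#' @export
compute_fwhm_profile <- function(stack, axis, window_nm = 2000,
                                 step_nm = 200, lateral_extent_nm = 1000,
                                 axial_extent_nm = 600, sample_nm = 20,
                                 subtract_background = TRUE) {
  L <- axis$length_nm
  if (L <= window_nm) stop("axis shorter than one window")
  u_grid <- seq(-lateral_extent_nm, lateral_extent_nm, by = sample_nm)
  v_grid <- seq(-axial_extent_nm, axial_extent_nm, by = sample_nm)
  centers <- seq(window_nm / 2, L - window_nm / 2, by = step_nm)
  fwhm <- rep(NA_real_, length(centers))
  for (k in seq_along(centers)) {
    idx <- which(axis$cum_s_nm >= centers[k] - window_nm / 2 &
                 axis$cum_s_nm <= centers[k] + window_nm / 2)
    cs <- accumulate_cross_sections(stack, axis, idx, u_grid, v_grid)
    prof <- rowSums(cs)
    fwhm[k] <- profile_fwhm(u_grid, prof, subtract_background)
  }
  structure(list(window_centers_nm = centers, fwhm_nm = fwhm,
                 mean_fwhm_nm = mean(fwhm, na.rm = TRUE)),
            class = "width_profile")
}

# FWHM of a 1D profile by linear interpolation of half-max crossings;
# NA when the half level is never crossed on either side of the peak
profile_fwhm <- function(x, y, subtract_background = TRUE) {
  if (subtract_background) {
    ntail <- max(1L, floor(0.1 * length(y)))
    bg <- median(c(head(y, ntail), tail(y, ntail)))
    y <- y - bg
  }
  ipk <- which.max(y)
  half <- y[ipk] / 2
  if (y[ipk] <= 0) return(NA_real_)
  left <- NA_real_
  for (i in seq(ipk, 2)) if (y[i - 1] < half && y[i] >= half) {
    left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
    break
  }
  right <- NA_real_
  for (i in seq(ipk, length(y) - 1)) if (y[i] >= half && y[i + 1] < half) {
    right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
    break
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Radial intensity distribution around the chromatid axis
#'
#' All cross sections along the axis are accumulated into one 2D image.
#' A reference point is found where the total intensity inside a window
#' of 0.4x the mean chromatid width (laterally) by 0.6x (axially)
#' reaches its maximum; the 1D lateral profile through that point is
#' symmetrized by averaging its left and right halves, peak-normalized,
#' and truncated at the chromatid radius. Containment radii treat the
#' symmetrized profile as a radially symmetric 2D distribution (mass
#' element `profile(r) * r dr`).
#'
#' @param stack preprocessed (isotropic) [image_stack()]
#' @param axis a `chromatid_axis`
#' @param chromatid_width_nm mean chromatid width (FWHM of the DNA
#'   channel), used for the reference window and the radial cutoff
#' @param sample_nm cross-section sampling pitch
#' @param quantiles containment quantiles to report
#' @return a `radial_profile`: `radius_nm`, `intensity`
#'   (peak-normalized), `containment_radius_nm` (named by quantile)
#' @export
compute_radial_profile <- function(stack, axis, chromatid_width_nm,
                                   sample_nm = 20,
                                   quantiles = c(0.5, 0.9)) {
  ext <- dim(stack$data) * stack$voxel_size_nm
  if (chromatid_width_nm > 2 * max(ext))
    stop("reference window larger than the image extent")
  half_u <- chromatid_width_nm
  half_v <- chromatid_width_nm
  u_grid <- seq(-half_u, half_u, by = sample_nm)
  v_grid <- seq(-half_v, half_v, by = sample_nm)
  cs <- accumulate_cross_sections(stack, axis, seq_len(nrow(axis$centroids)),
                                  u_grid, v_grid)
  wu <- round(0.4 * chromatid_width_nm / sample_nm)
  wv <- round(0.6 * chromatid_width_nm / sample_nm)
  if (wu >= length(u_grid) || wv >= length(v_grid))
    stop("reference window larger than the sampled cross section")
  # total intensity in a (wu x wv) window centered on each pixel
  best <- c(NA, NA); best_val <- -Inf
  hu <- floor(wu / 2); hv <- floor(wv / 2)
  for (i in seq(1 + hu, length(u_grid) - hu))
    for (j in seq(1 + hv, length(v_grid) - hv)) {
      v <- sum(cs[(i - hu):(i + hu), (j - hv):(j + hv)])
      if (v > best_val) { best_val <- v; best <- c(i, j) }
    }
  prof <- cs[, best[2]]
  i0 <- best[1]
  nr <- min(i0 - 1, length(u_grid) - i0)
  r <- (0:nr) * sample_nm
  sym <- vapply(0:nr, function(k)
    mean(c(prof[i0 - k], prof[i0 + k])), numeric(1))
  keep <- r <= chromatid_width_nm / 2
  r <- r[keep]; sym <- sym[keep]
  sym_n <- sym / sym[1]
  mass <- cumsum(sym * pmax(r, sample_nm / 4))
  mass <- mass / mass[length(mass)]
  cont <- vapply(quantiles, function(q) r[which(mass >= q)[1]], numeric(1))
  structure(list(radius_nm = r, intensity = sym_n,
                 containment_radius_nm = setNames(cont, quantiles),
                 reference_uv = c(u_grid[best[1]], v_grid[best[2]])),
            class = "radial_profile")
}
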