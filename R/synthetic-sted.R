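# --- helpers -----------------------------------------------------------

# resolve an axis specification into a dense polyline (nm), ~5-nm steps
resolve_axis_spec <- function(axis_spec) {
  if (is.matrix(axis_spec)) return(axis_spec)
  type <- axis_spec$type %||% "straight"
  step <- axis_spec$step_nm %||% 5
  if (type == "straight") {
    L <- axis_spec$length_nm
    s <- seq(0, L, by = step)
    cbind(x = s, y = rep(0, length(s)), z = rep(0, length(s)))
  } else if (type == "arc") {
    r <- axis_spec$radius_nm
    ang <- axis_spec$angle_rad %||% (pi / 2)
    th <- seq(0, ang, by = step / r)
    cbind(x = r * sin(th), y = r * (1 - cos(th)), z = rep(0, length(th)))
  } else stop("unknown axis_spec type: ", type)
}

polyline_arclength <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# cumulative arc length at each vertex
polyline_cumlen <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

# point on polyline at arc length s (linear interpolation), plus tangent
polyline_point <- function(p, cum, s) {
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(p) - 1L)
  f <- (s - cum[i]) / pmax(cum[i + 1L] - cum[i], 1e-12)
  p[i, , drop = FALSE] * (1 - f) + p[i + 1L, , drop = FALSE] * f
}

# add an anisotropic Gaussian blob at position pos (nm) into array a
add_gaussian_blob <- function(a, voxel_size_nm, pos, amplitude, sigma_nm) {
  d <- dim(a)
  lo <- pmax(1L, floor((pos - 4 * sigma_nm) / voxel_size_nm + 0.5))
  hi <- pmin(d, ceiling((pos + 4 * sigma_nm) / voxel_size_nm + 0.5))
  if (any(lo > hi)) return(a)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- exp(-(((ix - 0.5) * voxel_size_nm[1] - pos[1])^2) / (2 * sigma_nm[1]^2))
  gy <- exp(-(((iy - 0.5) * voxel_size_nm[2] - pos[2])^2) / (2 * sigma_nm[2]^2))
  gz <- exp(-(((iz - 0.5) * voxel_size_nm[3] - pos[3])^2) / (2 * sigma_nm[3]^2))
  blob <- amplitude * outer(outer(gx, gy), gz)
  a[ix, iy, iz] <- a[ix, iy, iz] + blob
  a
}

# --- generators ---------------------------------------------------------

#' Simulate a STED z stack of a Condensin-decorated chromatid
#'
#' Places point emitters at fixed arc-length spacing along a chromatid
#' axis (straight or arc-shaped), each with an integer multiplicity and a
#' small lateral offset drawn within the chromatid tube, and renders two
#' channels on the native STED voxel grid (20 nm in xy, 140 nm in z): a
#' protein channel of anisotropic Gaussian spots (lateral STED
#' resolution, diffraction-limited axially) and a DNA channel rendered as
#' a tube with Gaussian radial profile.
#'
#' @param axis_spec `list(type = "straight", length_nm =)` or
#'   `list(type = "arc", radius_nm =, angle_rad =)` or an explicit
#'   polyline matrix (nm); the generated axis is offset to sit centrally
#'   in the stack
#' @param spot_spacing_nm spacing between consecutive emitters along the
#'   axis (> 0); emitters sit at arc lengths 0, s, 2s, ...
#' @param multiplicity_dist function(n) returning n integer
#'   multiplicities (default: all 1)
#' @param psf list: `sigma_xy_nm` (default 30, STED lateral), `sigma_z_nm`
#'   (default 250, poorer axial resolution); `sigma_z >= sigma_xy` required
#' @param tube_radius_sigma_nm SD of lateral emitter offsets from the
#'   axis (truncated at 3 sigma); 0 places spots exactly on the axis
#' @param dna_sigma_nm radial SD of the DNA tube profile
#' @param amplitude peak intensity of a multiplicity-1 spot
#' @param detection_efficiency probability that an emitter is rendered
#'   (truth keeps all emitters with a `rendered` flag)
#' @param voxel_size_nm voxel size, default `c(20, 20, 140)`
#' @param margin_nm empty margin around the axis bounding box
#' @param seed integer seed
#' @return list with `protein` and `dna` [image_stack()]s and `truth`
#'   (`axis_points`, `spot_positions`, `spot_s_nm` arc-length positions,
#'   `spot_multiplicities`, `rendered`, psf and tube parameters)
#' @export
gen_sted_chromatid <- function(axis_spec, spot_spacing_nm = 56,
                               multiplicity_dist = NULL,
                               psf = list(sigma_xy_nm = 30, sigma_z_nm = 250),
                               tube_radius_sigma_nm = 0,
                               dna_sigma_nm = 200,
                               amplitude = 1000,
                               detection_efficiency = 1,
                               voxel_size_nm = c(20, 20, 140),
                               margin_nm = NULL,
                               seed = 1L) {
  if (spot_spacing_nm <= 0) stop("spot_spacing_nm must be positive")
  if (psf$sigma_z_nm < psf$sigma_xy_nm)
    stop("axial PSF sigma must be >= lateral sigma")
  set.seed(as.integer(seed))

  poly <- resolve_axis_spec(axis_spec)
  margin <- margin_nm %||% max(3 * dna_sigma_nm, 600)
  marg3 <- c(margin, margin, max(margin, 2 * psf$sigma_z_nm))
  offset <- marg3 - apply(poly, 2, min)
  poly <- sweep(poly, 2, offset, `+`)
  ext <- apply(poly, 2, max) + marg3
  dims <- pmax(ceiling(ext / voxel_size_nm), 4L)

  cum <- polyline_cumlen(poly)
  L <- cum[length(cum)]
  if (L <= 0) stop("axis arc length must be positive")
  s_spots <- seq(0, L, by = spot_spacing_nm)
  n <- length(s_spots)
  mult <- if (is.null(multiplicity_dist)) rep(1L, n) else as.integer(multiplicity_dist(n))

  pos <- polyline_point(poly, cum, s_spots)
  if (tube_radius_sigma_nm > 0) {
    # lateral offsets orthogonal to the local tangent, truncated at 3 sigma
    for (i in seq_len(n)) {
      tg <- polyline_point(poly, cum, min(s_spots[i] + 10, L)) -
            polyline_point(poly, cum, max(s_spots[i] - 10, 0))
      tg <- tg / sqrt(sum(tg^2))
      # orthonormal frame
      u <- if (abs(tg[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- u - sum(u * tg) * tg; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(tg[2] * e1[3] - tg[3] * e1[2],
              tg[3] * e1[1] - tg[1] * e1[3],
              tg[1] * e1[2] - tg[2] * e1[1])
      repeat {
        o <- rnorm(2, 0, tube_radius_sigma_nm)
        if (sqrt(sum(o^2)) <= 3 * tube_radius_sigma_nm) break
      }
      pos[i, ] <- pos[i, ] + o[1] * e1 + o[2] * e2
    }
  }
  rendered <- runif(n) <= detection_efficiency

  prot <- array(0, dims)
  sig <- c(psf$sigma_xy_nm, psf$sigma_xy_nm, psf$sigma_z_nm)
  for (i in which(rendered))
    prot <- add_gaussian_blob(prot, voxel_size_nm, pos[i, ],
                              amplitude * mult[i], sig)

  dna <- array(0, dims)
  dsig <- c(dna_sigma_nm, dna_sigma_nm,
            sqrt(dna_sigma_nm^2 + psf$sigma_z_nm^2))
  # line integral of Gaussians along a densely sampled axis
  s_line <- seq(0, L, by = 10)
  pline <- polyline_point(poly, cum, s_line)
  for (i in seq_along(s_line))
    dna <- add_gaussian_blob(dna, voxel_size_nm, pline[i, ], 1, dsig)

  truth <- structure(list(
    axis_points = poly, axis_length_nm = L,
    spot_positions = pos, spot_s_nm = s_spots,
    spot_multiplicities = mult, rendered = rendered,
    tube_radius_sigma_nm = tube_radius_sigma_nm,
    psf_sigma_xy_nm = psf$sigma_xy_nm, psf_sigma_z_nm = psf$sigma_z_nm),
    class = "synthetic_chromatid_truth")
  list(protein = image_stack(prot, voxel_size_nm, "protein"),
       dna = image_stack(dna, voxel_size_nm, "dna"),
       truth = truth)
}

#' Simulate two-channel STED data with a known colocalization fraction
#'
#' Channel A spots are placed uniformly in the volume (with a minimum
#' pairwise separation); a fraction `overlap_fraction` of channel B spots
#' is placed exactly at channel A positions, the remainder at least
#' 3 lateral PSF widths away from every A spot.
#'
#' @param overlap_fraction fraction of B spots coincident with A spots,
#'   in `[0, 1]`
#' @param counts number of spots per channel (>= 1)
#' @param dims stack dimensions in voxels
#' @param voxel_size_nm voxel size (default STED grid)
#' @param psf as in [gen_sted_chromatid()]
#' @param amplitude peak spot intensity
#' @param seed integer seed
#' @return list with `stack_a`, `stack_b` and `truth` (`pos_a`, `pos_b`,
#'   `n_coincident`)
#' @export
gen_two_channel_sted <- function(overlap_fraction, counts,
                                 dims = c(192L, 192L, 9L),
                                 voxel_size_nm = c(20, 20, 140),
                                 psf = list(sigma_xy_nm = 30, sigma_z_nm = 250),
                                 amplitude = 1000,
                                 seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (counts < 1) stop("counts must be >= 1")
  set.seed(as.integer(seed))
  ext <- dims * voxel_size_nm
  marg <- c(4 * psf$sigma_xy_nm, 4 * psf$sigma_xy_nm, psf$sigma_z_nm)
  draw <- function() marg + runif(3) * (ext - 2 * marg)
  sep <- 3 * psf$sigma_xy_nm

  pos_a <- matrix(0, counts, 3)
  k <- 0
  while (k < counts) {
    p <- draw()
    if (k == 0 || min(sqrt(colSums((t(pos_a[seq_len(k), , drop = FALSE]) - p)^2))) > sep) {
      k <- k + 1; pos_a[k, ] <- p
    }
  }
  n_ov <- round(overlap_fraction * counts)
  pos_b <- matrix(0, counts, 3)
  if (n_ov > 0) pos_b[seq_len(n_ov), ] <- pos_a[seq_len(n_ov), , drop = FALSE]
  # non-overlapping B spots must be >= 3 PSF widths from every A spot
  k <- n_ov
  while (k < counts) {
    p <- draw()
    if (min(sqrt(colSums((t(pos_a) - p)^2))) < 3 * 3 * psf$sigma_xy_nm) next
    k <- k + 1; pos_b[k, ] <- p
  }

  sig <- c(psf$sigma_xy_nm, psf$sigma_xy_nm, psf$sigma_z_nm)
  render <- function(pos) {
    a <- array(0, dims)
    for (i in seq_len(nrow(pos)))
      a <- add_gaussian_blob(a, voxel_size_nm, pos[i, ], amplitude, sig)
    a
  }
  list(stack_a = image_stack(render(pos_a), voxel_size_nm, "condensin_I"),
       stack_b = image_stack(render(pos_b), voxel_size_nm, "condensin_II"),
       truth = list(pos_a = pos_a, pos_b = pos_b, n_coincident = n_ov,
                    overlap_fraction = overlap_fraction))
}
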