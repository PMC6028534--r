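#' Align two channels by integer-voxel cross-correlation
#'
#' Searches the offset maximizing the cross-correlation of the two
#' stacks within a physical neighborhood (default 350 nm laterally,
#' 600 nm axially). The returned offset is the shift to apply to the
#' DNA channel to align it onto the reference channel.
#'
#' @param dna_stack,condensin_stack [image_stack()]s on the same grid
#' @param neighborhood_nm half-widths of the search window, length 3
#' @return integer offset vector (voxels) with attribute `"flat"` set
#'   TRUE (and a warning) when either channel is constant
#' @export
align_channels <- function(dna_stack, condensin_stack,
                           neighborhood_nm = c(350, 350, 600)) {
  a <- condensin_stack$data; b <- dna_stack$data
  stopifnot(all(dim(a) == dim(b)))
  if (diff(range(a)) == 0 || diff(range(b)) == 0) {
    warning("flat channel: zero offset assumed")
    off <- c(0L, 0L, 0L); attr(off, "flat") <- TRUE
    return(off)
  }
  vox <- condensin_stack$voxel_size_nm
  mx <- pmax(0L, floor(neighborhood_nm / vox))
  d <- dim(a)
  best <- c(0L, 0L, 0L); best_val <- -Inf
  for (sx in -mx[1]:mx[1]) for (sy in -mx[2]:mx[2]) for (sz in -mx[3]:mx[3]) {
    ax <- max(1, 1 + sx):min(d[1], d[1] + sx)
    ay <- max(1, 1 + sy):min(d[2], d[2] + sy)
    az <- max(1, 1 + sz):min(d[3], d[3] + sz)
    va <- a[ax, ay, az, drop = FALSE]
    vb <- b[ax - sx, ay - sy, az - sz, drop = FALSE]
    v <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2) + 1e-300)
    if (v > best_val) { best_val <- v; best <- c(sx, sy, sz) }
  }
  attr(best, "flat") <- FALSE
  best
}

#' Estimate the local background around a segmented object
#'
#' On the z slice with the most object-positive voxels, the object mask
#' is dilated with a diamond structuring element of radius 9 px and
#' eroded with one of radius 7 px; the difference ring (rim) samples the
#' immediate surroundings. The background is the mean of the rim
#' intensities after discarding the lowest 10% and the highest 50% of
#' the sorted values. If the rim is empty (object touching the image
#' border), the fall-back is the 10th percentile of the whole slice,
#' flagged via attribute `"fallback"`.
#'
#' @param mask logical 3D array (object segmentation)
#' @param intensity 3D array (or [image_stack()]) of the same size
#' @param dilate_r,erode_r diamond radii in pixels
#' @return background level (scalar) with attribute `"fallback"`
#' @export
estimate_background <- function(mask, intensity, dilate_r = 9L, erode_r = 7L) {
  a <- if (inherits(intensity, "image_stack")) intensity$data else intensity
  z <- which.max(apply(mask, 3, sum))
  msl <- mask[, , z]; isl <- a[, , z]
  diamond <- function(r) {
    k <- 2L * r + 1L
    br <- matrix(0L, k, k)
    for (i in seq_len(k)) for (j in seq_len(k))
      if (abs(i - r - 1L) + abs(j - r - 1L) <= r) br[i, j] <- 1L
    br
  }
  dil <- EBImage::dilate(EBImage::Image(msl * 1), diamond(dilate_r)) > 0
  ero <- EBImage::erode(EBImage::Image(msl * 1), diamond(erode_r)) > 0
  rim <- dil & !ero & !msl
  if (!any(rim)) {
    bg <- unname(quantile(isl, 0.1))
    attr(bg, "fallback") <- TRUE
    warning("empty rim (object touches border): global low-percentile fallback")
    return(bg)
  }
  v <- sort(isl[rim])
  n <- length(v)
  lo <- floor(0.1 * n) + 1L
  hi <- floor(0.5 * n)
  band <- if (hi >= lo) v[lo:hi] else v
  bg <- mean(band)
  attr(bg, "fallback") <- FALSE
  bg
}

#' Central-axis length of a segmented region
#'
#' The farthest pair of boundary voxels defines the slicing direction;
#' cross sections orthogonal to it are taken at `step_nm` spacing and
#' their centroids form the central axis, whose polyline length is
#' returned. The region should be on an isotropic grid (interpolate
#' first if not).
#'
#' @param region_mask logical 3D array or [image_stack()] of the region
#' @param voxel_size_nm voxel size (from the stack if given)
#' @param step_nm cross-section spacing (default 50)
#' @return length in nm, with attribute `"degenerate"` TRUE when the
#'   region has no dominant axis (length then approximates the diameter)
#' @export
region_axis_length <- function(region_mask, voxel_size_nm = NULL,
                               step_nm = 50) {
  if (inherits(region_mask, "image_stack")) {
    voxel_size_nm <- region_mask$voxel_size_nm
    region_mask <- region_mask$data > 0
  }
  pts <- voxel_coords_nm(region_mask, voxel_size_nm)
  if (nrow(pts) < 4) stop("region smaller than two cross sections")
  # boundary voxels: any 6-neighbour outside the mask
  idx <- which(region_mask, arr.ind = TRUE)
  d <- dim(region_mask)
  is_boundary <- vapply(seq_len(nrow(idx)), function(i) {
    x <- idx[i, 1]; y <- idx[i, 2]; z <- idx[i, 3]
    x == 1 || y == 1 || z == 1 || x == d[1] || y == d[2] || z == d[3] ||
      !(region_mask[x - 1, y, z] && region_mask[x + 1, y, z] &&
        region_mask[x, y - 1, z] && region_mask[x, y + 1, z] &&
        region_mask[x, y, z - 1] && region_mask[x, y, z + 1])
  }, logical(1))
  bpts <- sweep(idx[is_boundary, , drop = FALSE] - 0.5, 2, voxel_size_nm, `*`)
  if (nrow(bpts) > 400) bpts <- bpts[seq(1, nrow(bpts), length.out = 400), ]
  dm <- as.matrix(dist(bpts))
  far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  v <- bpts[far[2], ] - bpts[far[1], ]
  v <- v / sqrt(sum(v^2))

  ctr <- colMeans(pts)
  eg <- eigen(crossprod(sweep(pts, 2, ctr)) / nrow(pts), symmetric = TRUE)
  degenerate <- sqrt(eg$values[1] / max(eg$values[2], 1e-12)) < 2
  if (degenerate) warning("region has no dominant axis")

  tproj <- sweep(pts, 2, bpts[far[1], ]) %*% v
  br <- seq(min(tproj) - 1e-9, max(tproj) + step_nm, by = step_nm)
  bin <- findInterval(tproj, br)
  centro <- do.call(rbind, lapply(sort(unique(bin)), function(b)
    colMeans(pts[bin == b, , drop = FALSE])))
  if (nrow(centro) < 2) stop("region smaller than two cross sections")
  len <- polyline_arclength(centro)
  attr(len, "degenerate") <- degenerate
  len
}

#' Whole-cell chromatid length by intensity-ratio extrapolation
#'
#' For each manually segmented axis region, the estimator multiplies the
#' region's central-axis length by the ratio of total
#' background-subtracted Condensin intensity inside the DNA volume to
#' the intensity inside the region:
#' `total_length_i = (I_total / I_region_i) * L_region_i`; the
#' per-region estimates are combined by their arithmetic mean. The
#' estimator is exactly unbiased when Condensin intensity per unit axis
#' length is uniform.
#'
#' @param dna_stack,condensin_stack [image_stack()]s (same grid)
#' @param region_masks list of logical arrays (one per segmented region)
#' @param dna_mask optional logical array for the DNA volume; if NULL it
#'   is segmented from the DNA channel with the combined global Otsu and
#'   local mean threshold ([segment_high_density()])
#' @param sigma_dna,sigma_cond in-plane Gaussian prefilter sigmas in
#'   pixels (defaults 2.5 and 2.0)
#' @param background Condensin background level; if NULL it is estimated
#'   from the rim of the DNA mask via [estimate_background()]
#' @return a `length_estimate`: `total_length_um`,
#'   `per_region_estimates_um`, `region_axis_lengths_nm`,
#'   `region_intensity_fractions`, `background`, `n_regions_dropped`
#' @export
total_chromatid_length <- function(dna_stack, condensin_stack, region_masks,
                                   dna_mask = NULL, sigma_dna = 2.5,
                                   sigma_cond = 2.0, background = NULL) {
  stopifnot(length(region_masks) >= 1)
  dna <- gaussian_smooth3(dna_stack$data, c(sigma_dna, sigma_dna, 0))
  cond <- gaussian_smooth3(condensin_stack$data, c(sigma_cond, sigma_cond, 0))
  if (is.null(dna_mask))
    dna_mask <- segment_high_density(image_stack(dna, dna_stack$voxel_size_nm))
  if (is.null(background)) background <- estimate_background(dna_mask, cond)
  cond_bs <- pmax(cond - as.numeric(background), 0)

  total_int <- sum(cond_bs[dna_mask])
  per_region <- numeric(0); lens <- numeric(0); fracs <- numeric(0)
  dropped <- 0L
  for (rm in region_masks) {
    ri <- sum(cond_bs[rm & dna_mask])
    if (ri <= 0) { dropped <- dropped + 1L; next }
    L <- region_axis_length(rm, condensin_stack$voxel_size_nm)
    per_region <- c(per_region, (total_int / ri) * L / 1000)
    lens <- c(lens, as.numeric(L))
    fracs <- c(fracs, ri / total_int)
  }
  if (!length(per_region)) stop("no usable regions after background subtraction")
  structure(list(total_length_um = mean(per_region),
                 per_region_estimates_um = per_region,
                 region_axis_lengths_nm = lens,
                 region_intensity_fractions = fracs,
                 background = as.numeric(background),
                 n_regions_dropped = dropped),
            class = "length_estimate")
}
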