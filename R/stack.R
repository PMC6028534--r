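#' @importFrom stats median sd quantile rnorm rpois runif setNames coef
#'   optim dist pnorm
#' @importFrom utils head tail read.csv write.csv
NULL

# molecules per (nM * um^3): 1e-9 mol/L * 1e-15 L * N_A
AVOGADRO <- 6.02214076e23
NM_UM3_TO_MOLECULES <- 1e-24 * AVOGADRO

#' Convert a concentration and volume into a molecule count
#'
#' Concentrations are in nanomolar and volumes in cubic micrometers
#' throughout the package; the conversion factor is
#' \eqn{10^{-9} \cdot 10^{-15} \cdot N_A \approx 0.6022} molecules per
#' nM um^3.
#'
#' @param conc_nM concentration in nM
#' @param volume_um3 volume in um^3
#' @return number of molecules (not rounded)
#' @export
molecules_from_conc <- function(conc_nM, volume_um3) {
  conc_nM * volume_um3 * NM_UM3_TO_MOLECULES
}

#' Image stack container
#'
#' A minimal voxel-grid container: a 3D numeric array indexed
#' `[x, y, z]` plus the physical voxel size in nanometers. Physical
#' positions are measured at voxel centers, so 1-based index `i` maps to
#' `(i - 0.5) * voxel_size_nm`.
#'
#' @param data 3D numeric array (`[x, y, z]`); 2D matrices are promoted
#'   to a single-slice stack
#' @param voxel_size_nm numeric length-3 vector, nm per voxel along x, y, z
#' @param channel optional channel name
#' @return an `image_stack` object
#' @export
image_stack <- function(data, voxel_size_nm, channel = NULL) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, length(voxel_size_nm) == 3L,
            all(voxel_size_nm > 0))
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
                 channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels @ %g x %g x %g nm%s\n",
              d[1], d[2], d[3], x$voxel_size_nm[1], x$voxel_size_nm[2],
              x$voxel_size_nm[3],
              if (is.null(x$channel)) "" else paste0(" [", x$channel, "]")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Voxel volume of a stack in cubic micrometers
#' @param stack an `image_stack`
#' @return scalar, um^3 per voxel
#' @export
voxel_volume_um3 <- function(stack) {
  prod(stack$voxel_size_nm) * 1e-9   # nm^3 -> um^3
}

# physical center coordinates (nm) of voxels selected by a logical array
voxel_coords_nm <- function(mask, voxel_size_nm) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 0.5, 2, voxel_size_nm, `*`)
}

# separable Gaussian smoothing of a 3D array; sigma in voxels per dim,
# 0 disables a dimension; replicate-padded convolution
gaussian_smooth3 <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3L, length(sigma) == 3L)
  smooth_dim <- function(a, s, along) {
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2)); k <- k / sum(k)
    n <- dim(a)[along]
    idx <- outer(seq_len(n), seq(-r, r), `+`)
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    ap <- aperm(a, c(along, setdiff(1:3, along)))
    d <- dim(ap); m <- matrix(ap, nrow = d[1])
    out <- matrix(0, nrow = d[1], ncol = ncol(m))
    for (j in seq_len(2L * r + 1L)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    dim(out) <- d
    aperm(out, order(c(along, setdiff(1:3, along))))
  }
  a <- smooth_dim(a, sigma[1], 1L)
  a <- smooth_dim(a, sigma[2], 2L)
  smooth_dim(a, sigma[3], 3L)
}

# trilinear interpolation of a 3D array at physical points (nm), matrix n x 3;
# points outside the grid evaluate to `fill`
sample_trilinear <- function(a, voxel_size_nm, pts_nm, fill = 0) {
  d <- dim(a)
  # continuous voxel coordinate: center of voxel i is i - 0.5 (1-based)
  p <- sweep(pts_nm, 2, voxel_size_nm, `/`) + 0.5
  i0 <- floor(p); f <- p - i0
  out <- numeric(nrow(p))
  acc <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    lin <- (pmin(pmax(iz, 1), d[3]) - 1) * d[1] * d[2] +
           (pmin(pmax(iy, 1), d[2]) - 1) * d[1] + pmin(pmax(ix, 1), d[1])
    v <- a[lin]
    acc[ok] <- acc[ok] + w[ok] * v[ok]
    out <- acc
  }
  nin <- rowSums(cbind(p[, 1] < 0.5 | p[, 1] > d[1] + 0.5,
                       p[, 2] < 0.5 | p[, 2] > d[2] + 0.5,
                       p[, 3] < 0.5 | p[, 3] > d[3] + 0.5)) > 0
  out[nin] <- fill
  out
}

#' Global Otsu threshold of a numeric array
#'
#' Thin wrapper around [EBImage::otsu()] on the intensity range of the
#' input, returning the threshold on the original intensity scale.
#'
#' @param a numeric array or `image_stack`
#' @param levels number of histogram levels
#' @return scalar threshold
#' @export
otsu_threshold <- function(a, levels = 256L) {
  if (inherits(a, "image_stack")) a <- a$data
  rng <- range(a)
  if (diff(rng) == 0) return(rng[1])
  x <- (a - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = levels)
  rng[1] + mean(th) * diff(rng)
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' The TIFF holds one z slice per page (32-bit float, intensities scaled
#' to the unit range); voxel size and channel metadata go to
#' `<path>.json`.
#'
#' @param stack an `image_stack`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  a <- stack$data
  mx <- max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(z) t(a[, , z]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(voxel_size_nm = stack$voxel_size_nm, channel = stack$channel,
               intensity_scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#' @param path TIFF path (expects `<path>.json` sidecar)
#' @return an `image_stack`
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) a[, , z] <- t(pages[[z]])
  image_stack(a * meta$intensity_scale, meta$voxel_size_nm, meta$channel)
}
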