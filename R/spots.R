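# --- wavelet background filter -----------------------------------------

# sampled B-spline smoothing kernel of a given order and scale
# (samples of the order-q B-spline at 1/scale spacing, normalized)
bspline_kernel <- function(order = 2L, scale = 4L) {
  half <- (order + 1) / 2
  x <- seq(-half, half, by = 1 / scale)
  bsp <- function(x, q) {
    if (q == 0) return(as.numeric(abs(x) < 0.5 | x == -0.5))
    ((x + (q + 1) / 2) * bsp(x + 0.5, q - 1) +
     ((q + 1) / 2 - x) * bsp(x - 0.5, q - 1)) / q
  }
  k <- bsp(x, order)
  k / sum(k)
}

# separable 2D convolution with replicate padding; `spacing` inserts
# a-trous holes between kernel taps
conv_sep2d <- function(m, k, spacing = 1L) {
  r <- (length(k) - 1L) %/% 2L * spacing
  d <- dim(m)
  offs <- seq(-r, r, by = spacing)
  out <- matrix(0, d[1], d[2])
  for (j in seq_along(offs)) {
    xi <- pmin(pmax(seq_len(d[1]) + offs[j], 1L), d[1])
    out <- out + k[j] * m[xi, , drop = FALSE]
  }
  m2 <- out; out <- matrix(0, d[1], d[2])
  for (j in seq_along(offs)) {
    yi <- pmin(pmax(seq_len(d[2]) + offs[j], 1L), d[2])
    out <- out + k[j] * m2[, yi, drop = FALSE]
  }
  out
}

# a-trous B-spline wavelet decomposition of a 2D slice: V1 = K*V0,
# V2 = K2*V1 (holes of 1). F1 = V0 - V1 carries the pixel noise and
# sets the detection threshold; F2 = V1 - V2 is the band-pass plane in
# which spot-sized structures peak
wavelet_planes <- function(m, order = 2L, scale = 2L) {
  k <- bspline_kernel(order, scale)
  v1 <- conv_sep2d(m, k, 1L)
  v2 <- conv_sep2d(v1, k, 2L)
  list(F1 = m - v1, F2 = v1 - v2)
}

# integrated (pixel-area) Gaussian model on a square window
integrated_gaussian <- function(xc, yc, sigma, N, b, xs, ys) {
  ex <- (pnorm(xs + 0.5, xc, sigma) - pnorm(xs - 0.5, xc, sigma))
  ey <- (pnorm(ys + 0.5, yc, sigma) - pnorm(ys - 0.5, yc, sigma))
  N * outer(ex, ey) + b
}

#' Detect sub-pixel spot localizations in a STED z stack
#'
#' Per-slice detection: the slice is decomposed with a second-order
#' B-spline a-trous wavelet filter; candidate peaks are local maxima of
#' the band-pass wavelet plane (F2, in which spot-sized structures
#' peak) above `threshold_k` times the standard deviation of the first
#' wavelet plane (F1, which carries the pixel noise); each candidate is refined to sub-pixel precision by fitting an
#' integrated-Gaussian PSF model (free position, width, amplitude and
#' offset; sigma initialized at 2.2 px, fit radius 2 px) by least
#' squares on the raw intensities. Detections carry the z position of
#' their slice; grouping across slices is the clustering step's job
#' ([cluster_spots()]).
#'
#' @param stack an [image_stack()] on the native STED grid
#' @param threshold_k peak threshold in SDs of the filtered image
#' @param sigma_px initial PSF sigma in pixels (default 2.2)
#' @param fit_radius_px half-size of the fitting window (default 2)
#' @param wavelet_order B-spline order of the wavelet kernel (default 2)
#' @param wavelet_scale kernel sampling scale; should match the spot
#'   footprint in pixels (default 2, suiting PSF sigmas of 1-2 px;
#'   kernel-sampling conventions for this parameter differ between
#'   localization tools)
#' @return a `spot_table` data frame: `x_nm`, `y_nm`, `z_nm`,
#'   `intensity` (fitted integrated counts), `sigma_nm`, `slice`
#' @export
detect_spots <- function(stack, threshold_k = 3, sigma_px = 2.2,
                         fit_radius_px = 2L, wavelet_order = 2L,
                         wavelet_scale = 2L) {
  a <- stack$data
  vox <- stack$voxel_size_nm
  res <- list()
  for (z in seq_len(dim(a)[3])) {
    sl <- a[, , z]
    wp <- wavelet_planes(sl, wavelet_order, wavelet_scale)
    f2 <- wp$F2
    th <- threshold_k * sd(wp$F1)
    d <- dim(sl)
    cand <- which(f2 > th, arr.ind = TRUE)
    if (!nrow(cand)) next
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      x <- cand[i, 1]; y <- cand[i, 2]
      xr <- max(1, x - 1):min(d[1], x + 1)
      yr <- max(1, y - 1):min(d[2], y + 1)
      keep[i] <- f2[x, y] >= max(f2[xr, yr])
    }
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    for (i in seq_len(nrow(cand))) {
      x <- cand[i, 1]; y <- cand[i, 2]
      if (x <= fit_radius_px || y <= fit_radius_px ||
          x > d[1] - fit_radius_px || y > d[2] - fit_radius_px) next
      xs <- (x - fit_radius_px):(x + fit_radius_px)
      ys <- (y - fit_radius_px):(y + fit_radius_px)
      w <- sl[xs, ys]
      obj <- function(p) {
        mdl <- integrated_gaussian(p[1], p[2], exp(p[3]), exp(p[4]), p[5],
                                   xs, ys)
        sum((mdl - w)^2)
      }
      p0 <- c(x, y, log(sigma_px), log(max(sum(w - min(w)), 1e-6)), min(w))
      op <- tryCatch(
        optim(p0, obj, method = "L-BFGS-B",
              lower = c(x - fit_radius_px, y - fit_radius_px,
                        log(0.5), -Inf, -Inf),
              upper = c(x + fit_radius_px, y + fit_radius_px,
                        log(4 * sigma_px), Inf, Inf)),
        error = function(e) NULL)
      if (is.null(op)) next
      res[[length(res) + 1L]] <- data.frame(
        x_nm = (op$par[1] - 0.5) * vox[1],
        y_nm = (op$par[2] - 0.5) * vox[2],
        z_nm = (z - 0.5) * vox[3],
        intensity = exp(op$par[4]),
        sigma_nm = exp(op$par[3]) * vox[1],
        slice = z)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
               intensity = numeric(), sigma_nm = numeric(),
               slice = integer())
  class(out) <- c("spot_table", class(out))
  out
}

# --- clustering ---------------------------------------------------------

# deterministic DBSCAN on a coordinate matrix; returns integer labels,
# 0 for noise; points visited in lexicographic coordinate order
dbscan_labels <- function(x, eps, min_pts) {
  n <- nrow(x)
  if (n == 0) return(integer(0))
  ord <- do.call(order, as.data.frame(x))
  d <- as.matrix(dist(x))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  labels <- integer(n)          # 0 = unassigned/noise
  visited <- logical(n)
  cl <- 0L
  for (i in ord) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(neigh[[i]]) < min_pts) next   # provisional noise
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neigh[[i]], i)
    queue <- queue[order(match(queue, ord))]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        if (length(neigh[[j]]) >= min_pts) {
          add <- setdiff(neigh[[j]], c(j, queue))
          add <- add[!visited[add] | labels[add] == 0L]
          queue <- c(queue, add[order(match(add, ord))])
        }
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

#' Cluster detections into Condensin localizations
#'
#' Density-based clustering (DBSCAN, `eps = 45`, `minPts = 2`) in an
#' anisotropically scaled coordinate space: coordinates are in nm
#' (divided by `coord_unit_nm`, default 1) and z is additionally
#' multiplied by `z_scale` (default 1/8) to compensate the ~8x poorer
#' axial resolution, so detections of one emitter in adjacent z slices
#' (140 nm apart, 17.5 after scaling) fall within `eps` of each other
#' and merge, while neighbouring complexes ~56 nm apart along the axis
#' stay separate. Points that DBSCAN marks as noise are retained as
#' singleton clusters, since an isolated detection is a valid single
#' complex. Tie-breaking is deterministic (lexicographic visiting
#' order), making the result independent of input row order.
#'
#' @param spots a `spot_table` from [detect_spots()] (or any data frame
#'   with `x_nm`, `y_nm`, `z_nm`, `intensity`)
#' @param eps DBSCAN radius in scaled coordinate units (default 45)
#' @param min_pts DBSCAN minPts (default 2)
#' @param z_scale multiplier on z in the scaled space (default 1/8)
#' @param coord_unit_nm nm per coordinate unit of the scaled space
#'   (default 1: eps is in nm; set 20 to work in detector pixels)
#' @return a `cluster_table` data frame: `cluster_id`, `x_nm`, `y_nm`,
#'   `z_nm` (centroids), `total_intensity`, `member_count`,
#'   `multiplicity` (1 until [correct_multiplicity()])
#' @export
cluster_spots <- function(spots, eps = 45, min_pts = 2L, z_scale = 1 / 8,
                          coord_unit_nm = 1) {
  if (nrow(spots) == 0)
    return(structure(data.frame(cluster_id = integer(), x_nm = numeric(),
                                y_nm = numeric(), z_nm = numeric(),
                                total_intensity = numeric(),
                                member_count = integer(),
                                multiplicity = integer()),
                     class = c("cluster_table", "data.frame")))
  xs <- cbind(spots$x_nm, spots$y_nm, spots$z_nm * z_scale) / coord_unit_nm
  labels <- dbscan_labels(xs, eps, min_pts)
  # noise points become singleton clusters
  nz <- labels == 0L
  if (any(nz)) labels[nz] <- max(labels) + seq_len(sum(nz))
  agg <- lapply(sort(unique(labels)), function(l) {
    m <- labels == l
    data.frame(cluster_id = l,
               x_nm = mean(spots$x_nm[m]), y_nm = mean(spots$y_nm[m]),
               z_nm = mean(spots$z_nm[m]),
               total_intensity = sum(spots$intensity[m]),
               member_count = sum(m), multiplicity = 1L)
  })
  out <- do.call(rbind, agg)
  out$cluster_id <- seq_len(nrow(out))
  class(out) <- c("cluster_table", class(out))
  out
}

#' Correct cluster counts for multiple complexes per cluster
#'
#' A cluster brighter than the single-complex intensity unit is counted
#' as several complexes: `multiplicity = max(1, ceiling(total_intensity
#' / intensity_unit))`, i.e. the unit and its multiples act as
#' thresholds for counting two or more complexes per cluster.
#'
#' @param clusters a `cluster_table`
#' @param intensity_unit intensity of a single complex in detector
#'   arbitrary units (default 3000); must be positive
#' @return the table with updated `multiplicity`
#' @export
correct_multiplicity <- function(clusters, intensity_unit = 3000) {
  if (intensity_unit <= 0) stop("intensity_unit must be positive")
  clusters$multiplicity <- pmax(1L,
    as.integer(ceiling(clusters$total_intensity / intensity_unit)))
  clusters
}

#' Nearest-neighbour, axis-distance and axial-spacing statistics
#'
#' Three coordinate-based readouts for clustered localizations on a
#' chromatid: NN, the per-centroid minimum pairwise distance (computed
#' in the anisotropically scaled clustering space by default, or in raw
#' nm coordinates); CA, the distance of each centroid from the chromatid
#' axis polyline; and AS, the successive differences of the sorted
#' arc-length positions after orthogonal projection of the centroids
#' onto the axis. The localization density uses multiplicity-corrected
#' counts over the axis length.
#'
#' @param clusters a `cluster_table` (>= 2 rows for NN/AS)
#' @param axis a `chromatid_axis` from [trace_axis()]
#' @param scaled_nn compute NN in the z-scaled space (default TRUE)
#' @param z_scale as in [cluster_spots()]
#' @return a `spacing_stats`: vectors `nn_nm`, `ca_nm`, `as_nm` and
#'   their medians, plus `clusters_per_um`
#' @export
spacing_stats <- function(clusters, axis, scaled_nn = TRUE,
                          z_scale = 1 / 8) {
  if (nrow(clusters) < 2) stop("need >= 2 clusters for spacing statistics")
  pts <- as.matrix(clusters[, c("x_nm", "y_nm", "z_nm")])
  np <- if (scaled_nn) cbind(pts[, 1], pts[, 2], pts[, 3] * z_scale) else pts
  dm <- as.matrix(dist(np)); diag(dm) <- Inf
  nn <- apply(dm, 1, min)

  # distance to, and arc-length projection onto, the axis polyline
  cax <- axis$centroids
  cum <- axis$cum_s_nm
  ca <- numeric(nrow(pts)); s_proj <- numeric(nrow(pts))
  nseg <- nrow(cax) - 1L
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    # nearest vertex, then exact projection on its adjacent segments
    d2v <- colSums((t(cax) - p)^2)
    j <- which.min(d2v)
    best_d2 <- d2v[j]; best_s <- cum[j]
    for (k in max(1, j - 1):min(nseg, j)) {
      v <- cax[k + 1, ] - cax[k, ]
      L2 <- sum(v^2)
      tt <- min(max(sum((p - cax[k, ]) * v) / L2, 0), 1)
      proj <- cax[k, ] + tt * v
      d2 <- sum((p - proj)^2)
      if (d2 < best_d2) { best_d2 <- d2; best_s <- cum[k] + tt * sqrt(L2) }
    }
    ca[i] <- sqrt(best_d2); s_proj[i] <- best_s
  }
  as_nm <- diff(sort(s_proj))
  structure(list(nn_nm = nn, ca_nm = ca, as_nm = as_nm,
                 median_nn_nm = median(nn), median_ca_nm = median(ca),
                 median_as_nm = median(as_nm),
                 clusters_per_um = sum(clusters$multiplicity) /
                   (axis$length_nm / 1000)),
            class = "spacing_stats")
}
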