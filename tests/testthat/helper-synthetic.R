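# shared synthetic fixtures, built in code at test time

# straight tube along x with Gaussian radial profile (isotropic voxels)
make_gaussian_tube <- function(sigma_nm = 100, length_nm = 4000,
                               vox_nm = 20, lateral_halfwidth_nm = 800,
                               axial_halfwidth_nm = 400, pad_x_nm = 200,
                               amplitude = 1) {
  nx <- round((length_nm + 2 * pad_x_nm) / vox_nm)
  ny <- 2 * round(lateral_halfwidth_nm / vox_nm) + 1
  nz <- 2 * round(axial_halfwidth_nm / vox_nm) + 1
  ay <- ((seq_len(ny)) - 0.5) * vox_nm - ny * vox_nm / 2
  az <- ((seq_len(nz)) - 0.5) * vox_nm - nz * vox_nm / 2
  sl <- amplitude * exp(-outer(ay^2, az^2, `+`) / (2 * sigma_nm^2))
  a <- array(0, c(nx, ny, nz))
  x0 <- round(pad_x_nm / vox_nm) + 1
  x1 <- x0 + round(length_nm / vox_nm) - 1
  for (x in x0:x1) a[x, , ] <- sl
  list(stack = image_stack(a, rep(vox_nm, 3)),
       mask = a > 0.05 * amplitude,
       truth_length_nm = (x1 - x0) * vox_nm,
       sigma_nm = sigma_nm)
}

# quarter-circle tube of radius r in the xy mid-plane
make_arc_tube_mask <- function(radius_nm = 2000, tube_r_nm = 120,
                               vox_nm = 20, nz = 21) {
  n <- round((radius_nm + 400) / vox_nm)
  cx <- (seq_len(n) - 0.5) * vox_nm
  cz <- (seq_len(nz) - 0.5) * vox_nm - nz * vox_nm / 2
  center <- c(200, radius_nm + 200)
  dxy <- sqrt(outer((cx - center[1])^2, (cx - center[2])^2, `+`))
  phi <- atan2(matrix(cx - center[2], n, n, byrow = TRUE),
               matrix(cx - center[1], n, n))
  quart <- phi >= -pi / 2 & phi <= 0
  m <- array(FALSE, c(n, n, nz))
  for (z in seq_len(nz))
    m[, , z] <- ((dxy - radius_nm)^2 + cz[z]^2 <= tube_r_nm^2) & quart
  list(mask = m, vox_nm = rep(vox_nm, 3),
       truth_length_nm = pi * radius_nm / 2)
}

# render a half-bleach FRAP movie following the exchange model, with an
# optional multiplicative photobleaching decay per frame
make_frap_movie <- function(a_true = 0.15, rate_per_min = 0.5,
                            n_frames = 40, dt_s = 20, bleach_decay = 0,
                            contrast = 0.5, nx = 64, ny = 40) {
  dna <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny))
    if (((i - (nx + 1) / 2) / (0.45 * nx))^2 +
        ((j - (ny + 1) / 2) / (0.35 * ny))^2 <= 1) dna[i, j] <- 1
  ts <- (seq_len(n_frames) - 1) * dt_s
  b <- a_true + (1 - a_true) * exp(-rate_per_min * ts / 60)
  g <- exp(-bleach_decay * (seq_len(n_frames) - 1))
  ps <- vector("list", n_frames); ds <- vector("list", n_frames)
  half <- nx %/% 2
  for (k in seq_len(n_frames)) {
    p <- matrix(0, nx, ny)
    p[seq_len(half), ] <- g[k] * (1 - contrast * b[k]) * 100
    p[(half + 1):nx, ] <- g[k] * (1 + contrast * b[k]) * 100
    ps[[k]] <- image_stack(array(p * dna, c(nx, ny, 1)), c(250, 250, 750))
    ds[[k]] <- image_stack(array(dna * g[k], c(nx, ny, 1)), c(250, 250, 750))
  }
  list(protein = ps, dna = ds, t_s = ts, model = b)
}

# cell of many parallel non-overlapping tubes with uniform intensity per
# voxel; returns stacks, masks, a few region masks and the truth length
make_tube_cell <- function(n_tubes = 128, seed = 77, vox_nm = 50,
                           region_ids = c(5, 40, 77, 110)) {
  set.seed(seed)
  n_cols <- 5L; n_rows <- ceiling(n_tubes / n_cols)
  dims <- c(n_cols * 54L, n_rows * 6L + 4L, 24L)
  cond <- array(0, dims)
  cell_mask <- array(FALSE, dims)
  regions <- list()
  truth_total_nm <- 0
  k <- 0L
  for (row in seq_len(n_rows)) for (col in seq_len(n_cols)) {
    k <- k + 1L
    if (k > n_tubes) break
    x0 <- (col - 1L) * 54L + 3L
    y0 <- (row - 1L) * 6L + 3L
    z0 <- sample(4:20, 1)
    nx <- round(runif(1, 1500, 2500) / vox_nm)
    xs <- x0:(x0 + nx - 1L)
    truth_total_nm <- truth_total_nm + (length(xs) - 1L) * vox_nm
    for (dy in -1:1) for (dz in -1:1) {
      if (abs(dy) + abs(dz) > 1) next
      cond[xs, y0 + dy, z0 + dz] <- 100
    }
    cell_mask[xs, (y0 - 2):(y0 + 2), (z0 - 2):(z0 + 2)] <- TRUE
    if (k %in% region_ids) {
      rm_ <- array(FALSE, dims)
      rm_[xs, (y0 - 2):(y0 + 2), (z0 - 2):(z0 + 2)] <- TRUE
      regions[[length(regions) + 1L]] <- rm_
    }
  }
  list(cond = image_stack(cond, rep(vox_nm, 3), "condensin"),
       dna = image_stack(cond * 0.8, rep(vox_nm, 3), "dna"),
       dna_mask = cell_mask, regions = regions,
       truth_total_um = truth_total_nm / 1000)
}

# trace a chromatid axis from the DNA channel of a gen_sted_chromatid()
# output (stands in for the paper's manual tube segmentation)
axis_from_dna <- function(g, threshold_frac = 0.3) {
  ppd <- preprocess_stack(g$dna, drift_correct = FALSE)
  trace_axis(ppd$data > threshold_frac * max(ppd$data), ppd$voxel_size_nm,
             end_trim_nm = 0)
}
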