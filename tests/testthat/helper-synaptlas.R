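# shared fixtures: small geometries and coarse grids keep the suite fast

std_geometry <- function() make_geometry(20, 20, 20)

coarse_mask <- function(geometry = std_geometry(), voxel = 0.8) {
  make_neuropil_mask(geometry, voxel_size = rep(voxel, 3))
}

# a small single-cluster model for detector fixtures
cluster_only_model <- function(total = 50, ...) {
  genotype_model(
    region_weights = c(i1 = 1, i2 = 0, i3 = 0, late = 0),
    total_count_mean = total, ...
  )
}

# independent brute-force oracle for inclusive thresholding: scan every
# candidate threshold (the spot-voxel density values) and keep the largest
# achieving the inclusion fraction
brute_force_inclusive <- function(density, spots, fraction) {
  idx <- world_to_index(spots[, c("x_um", "y_um", "z_um")], density)
  d <- dim(density$data)
  lin <- idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
  dvals <- density$data[lin]
  need <- ceiling(fraction * nrow(spots))
  cands <- sort(unique(dvals), decreasing = TRUE)
  best <- NULL
  for (t in cands) {
    if (sum(dvals >= t) >= need) {
      best <- t
      break
    }
  }
  list(threshold = best, mask = density$data >= best)
}

# independent oracle for the volume-matched subtraction threshold
brute_force_late <- function(hb, wt, target_volume) {
  D <- wt$data - hb$data
  vox <- prod(wt$voxel_size)
  cands <- sort(unique(D[D > 0]), decreasing = TRUE)
  vols <- vapply(cands, function(t) sum(D >= t) * vox, 0)
  k <- which.min(abs(vols - target_volume))
  list(threshold = cands[k], volume = vols[k])
}

# long-hand Welch computation (kept independent of stats::t.test)
welch_by_hand <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
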