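#' 3D volume container
#'
#' A minimal container for a single-channel 3D image: a numeric (or logical)
#' array plus the physical voxel size and the world coordinate of the
#' volume's lower corner. Voxel `(i, j, k)` (1-based) has its center at
#' `origin + (c(i, j, k) - 0.5) * voxel_size`.
#'
#' @param data 3D array
#' @param voxel_size length-3 positive voxel size (um)
#' @param origin length-3 world coordinate (um) of the lower corner
#' @return an object of class `volume3d`
#' @export
volume3d <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3 || any(dim(data) < 1)) {
    stop("volume data must be a non-empty 3D array", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive numbers", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf(
    "<%s> %s voxels @ %s um, origin (%s)\n",
    class(x)[1], paste(dim(x$data), collapse = " x "),
    paste(signif(x$voxel_size, 3), collapse = " x "),
    paste(signif(x$origin, 3), collapse = ", ")
  ))
  invisible(x)
}

#' Empty volume covering a hemisegment box
#'
#' @param geometry a [make_geometry()] object
#' @param voxel_size length-3 voxel size (um)
#' @param value fill value
#' @return a zero-filled [volume3d()]
#' @export
volume_grid <- function(geometry, voxel_size = c(0.1, 0.1, 0.22), value = 0) {
  ext <- geometry$box["upper", ] - geometry$box["lower", ]
  dims <- pmax(1L, as.integer(ceiling(ext / voxel_size - 1e-9)))
  volume3d(array(value, dims), voxel_size, origin = geometry$box["lower", ])
}

#' World coordinates of every voxel center
#' @param volume a [volume3d()]
#' @return an (n_voxel x 3) matrix in array order
#' @export
voxel_centers <- function(volume) {
  d <- dim(volume$data)
  vs <- volume$voxel_size
  o <- volume$origin
  cbind(
    rep(o[1] + (seq_len(d[1]) - 0.5) * vs[1], times = d[2] * d[3]),
    rep(rep(o[2] + (seq_len(d[2]) - 0.5) * vs[2], each = d[1]), times = d[3]),
    rep(o[3] + (seq_len(d[3]) - 0.5) * vs[3], each = d[1] * d[2])
  )
}

#' Map world coordinates to voxel indices
#'
#' @param points n x 3 matrix of um coordinates
#' @param volume a [volume3d()]
#' @return n x 3 integer matrix of 1-based voxel indices; indices outside the
#'   grid fall outside `1..dim`
#' @export
world_to_index <- function(points, volume) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  idx <- sweep(p, 2, volume$origin, "-")
  idx <- sweep(idx, 2, volume$voxel_size, "/")
  storage.mode(idx) <- "double"
  matrix(as.integer(floor(idx)) + 1L, ncol = 3)
}

#' World coordinate of voxel centers given indices
#' @param idx n x 3 integer matrix
#' @param volume a [volume3d()]
#' @return n x 3 matrix (um)
#' @export
index_to_world <- function(idx, volume) {
  i <- if (is.null(dim(idx))) matrix(idx, ncol = 3) else as.matrix(idx)
  sweep(sweep(i - 0.5, 2, volume$voxel_size, "*"), 2, volume$origin, "+")
}

in_grid <- function(idx, dims) {
  idx[, 1] >= 1L & idx[, 1] <= dims[1] &
    idx[, 2] >= 1L & idx[, 2] <= dims[2] &
    idx[, 3] >= 1L & idx[, 3] <= dims[3]
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  if (sigma <= 1e-8) return(1)
  h <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

# convolve a 3D array along one axis with a centered odd-length kernel,
# zero-padded at the borders; stats::filter runs column-wise in C
convolve_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1) return(a * kernel)
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  h <- (length(kernel) - 1) / 2
  pad <- matrix(0, nrow = h, ncol = ncol(m))
  mp <- rbind(pad, m, pad)
  # stats::filter convolution: out[t] = sum_j f[j] * x[t + h + 1 - j]
  f <- stats::filter(mp, rev(kernel), method = "convolution", sides = 2)
  m2 <- as.matrix(f[(h + 1):(h + dp[1]), , drop = FALSE])
  out <- array(m2, dp)
  aperm(out, order(perm))
}

#' Separable anisotropic Gaussian blur of a 3D volume
#'
#' Kernels are truncated at 4 sigma and normalized to unit sum, so a blur
#' preserves the array total away from borders (borders are zero-padded).
#'
#' @param volume a [volume3d()] (or bare 3D array)
#' @param sigma_um per-axis standard deviation (um); scalars are recycled
#' @return blurred volume of the same class
#' @export
gaussian_blur <- function(volume, sigma_um) {
  a <- if (inherits(volume, "volume3d")) volume$data else volume
  vs <- if (inherits(volume, "volume3d")) volume$voxel_size else c(1, 1, 1)
  sigma_um <- rep_len(sigma_um, 3)
  if (any(sigma_um < 0)) stop("sigma must be non-negative", call. = FALSE)
  storage.mode(a) <- "double"
  for (ax in 1:3) {
    a <- convolve_axis(a, gaussian_kernel_1d(sigma_um[ax] / vs[ax]), ax)
  }
  if (inherits(volume, "volume3d")) {
    out <- volume
    out$data <- a
    out
  } else {
    a
  }
}

# shift a 3D array by integer offsets, padding with `fill`
shift_array <- function(a, off, fill) {
  d <- dim(a)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(array(fill, d))
    if (o >= 0) {
      src[[ax]] <- 1:(d[ax] - o)
      dst[[ax]] <- (1 + o):d[ax]
    } else {
      src[[ax]] <- (1 - o):d[ax]
      dst[[ax]] <- 1:(d[ax] + o)
    }
  }
  out <- array(fill, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# strict-ish 26-neighborhood local maxima: >= all neighbours and > at least
# one; borders never qualify (treated as +Inf), so flat volumes yield none
local_maxima_3d <- function(a) {
  d <- dim(a)
  ge_all <- array(TRUE, d)
  gt_any <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- shift_array(a, c(dx, dy, dz), fill = Inf)
    ge_all <- ge_all & (a >= nb)
    gt_any <- gt_any | (a > nb)
  }
  which(ge_all & gt_any, arr.ind = TRUE)
}

#' Read / write single-channel 3D TIFF volumes
#'
#' Volumes are stored as one 32-bit float slice per anterior-posterior plane
#' (`z`), each slice indexed `[dv, ml]` as is conventional for image rasters.
#' Voxel size and origin travel in a JSON sidecar written next to the TIFF.
#'
#' @param volume a [volume3d()]
#' @param path output `.tif` path
#' @return `path`, invisibly
#' @export
write_volume_tiff <- function(volume, path) {
  a <- volume$data
  storage.mode(a) <- "double"
  mx <- max(a)
  scale <- if (mx > 0) mx else 1
  slices <- lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]) / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  meta <- list(
    voxel_size = volume$voxel_size, origin = volume$origin,
    dim = dim(a), intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param path input `.tif` path (with its `.tif.json` sidecar)
#' @export
read_volume_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  a <- array(0, d)
  for (k in seq_along(slices)) a[, , k] <- t(slices[[k]])
  a <- a * meta$intensity_scale
  volume3d(a, meta$voxel_size, meta$origin)
}
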