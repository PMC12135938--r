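#' Affine transform in 3D
#'
#' Maps subject micrometre coordinates to template micrometre coordinates as
#' `y = A x + t`. The inverse is stored alongside.
#'
#' @param A 3 x 3 linear part, invertible
#' @param t length-3 translation (um)
#' @return an object of class `affine3d`
#' @export
affine3d <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (abs(det(A)) <= 1e-6) {
    stop("affine linear part is (near) singular", call. = FALSE)
  }
  Ainv <- solve(A)
  structure(
    list(A = A, t = as.numeric(t), Ainv = Ainv, tinv = -Ainv %*% as.numeric(t)),
    class = "affine3d"
  )
}

#' @rdname affine3d
#' @param transform an `affine3d`
#' @param points n x 3 matrix of um coordinates
#' @param inverse apply the inverse map instead
#' @return transformed n x 3 matrix
#' @export
apply_affine <- function(transform, points, inverse = FALSE) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  out <- if (inverse) {
    sweep(p %*% t(transform$Ainv), 2, as.numeric(transform$tinv), "+")
  } else {
    sweep(p %*% t(transform$A), 2, transform$t, "+")
  }
  if (is.null(dim(points))) drop(out) else out
}

#' Transform a spot table into template space
#'
#' @param spots a spot table
#' @param transform an [affine3d()]
#' @return the spot table with mapped coordinates
#' @export
transform_spots <- function(spots, transform) {
  if (nrow(spots) == 0) return(spots)
  xyz <- apply_affine(transform, spot_xyz(spots))
  spots$x_um <- xyz[, 1]
  spots$y_um <- xyz[, 2]
  spots$z_um <- xyz[, 3]
  spots
}

rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

params_to_affine <- function(p, centre) {
  R <- rotation_matrix(p[4], p[5], p[6])
  # clamp scales so a wandering optimizer cannot reach a singular map
  S <- diag(exp(pmin(2, pmax(-2, p[7:9]))))
  A <- R %*% S
  # rotate/scale about the moving centroid, then translate
  t <- p[1:3] + centre - A %*% centre
  affine3d(A, t)
}

mask_fg_points <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  index_to_world(idx, mask)
}

# trilinear interpolation of a 3D array at world points (0 outside)
trilinear <- function(volume, points) {
  d <- dim(volume$data)
  g <- sweep(sweep(points, 2, volume$origin, "-"), 2, volume$voxel_size, "/") + 0.5
  i0 <- floor(g)
  f <- g - i0
  val <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0 + matrix(rep(c(dx, dy, dz), each = nrow(points)), ncol = 3)
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
      (if (dy == 1) f[, 2] else 1 - f[, 2]) *
      (if (dz == 1) f[, 3] else 1 - f[, 3])
    ok <- in_grid(ii, d)
    if (any(ok)) {
      lin <- ii[ok, 1] + (ii[ok, 2] - 1L) * d[1] + (ii[ok, 3] - 1L) * d[1] * d[2]
      val[ok] <- val[ok] + w[ok] * volume$data[lin]
    }
  }
  val
}

#' Dice overlap of a transformed mask with a template
#'
#' The moving mask is resampled into the template grid through the
#' transform (nearest neighbour) and compared voxel-wise, so volume changes
#' are penalized correctly.
#'
#' @param mask,template `neuropil_mask` objects (same voxel size)
#' @param transform an [affine3d()] (identity when `NULL`)
#' @return Dice coefficient in `[0, 1]`
#' @export
mask_dice <- function(mask, template, transform = NULL) {
  if (is.null(transform)) transform <- affine3d()
  rs <- resample_mask(mask, transform, template)
  2 * sum(rs & template$data) / (sum(rs) + sum(template$data))
}

#' Register a neuropil mask to a template
#'
#' Nine-parameter registration (translation, rotation, per-axis scale)
#' maximizing mask overlap. Initialization matches foreground centroids and
#' per-axis second moments; refinement runs Nelder-Mead on a smooth
#' soft-overlap objective (the mean, over moving foreground voxels, of a
#' trilinearly interpolated, lightly blurred template membership), and the
#' result is scored with the binary Dice coefficient.
#'
#' @param mask moving `neuropil_mask`
#' @param template fixed `neuropil_mask` (same voxel size)
#' @param min_dice registrations scoring below this final Dice raise an
#'   alignment-failure error (the study discarded images that failed to
#'   align)
#' @param maxit Nelder-Mead iteration budget
#' @return an [affine3d()] with attributes `dice` and `soft_score`
#' @export
register_to_template <- function(mask, template, min_dice = 0.5,
                                 maxit = 300) {
  if (any(abs(mask$voxel_size - template$voxel_size) > 1e-9)) {
    stop("mask and template must share a voxel size", call. = FALSE)
  }
  mv <- mask_fg_points(mask)
  if (nrow(mv) == 0 || sum(template$data) == 0) {
    stop("registration requires non-empty masks", call. = FALSE)
  }
  # subsample foreground for speed; Dice is computed on the full mask
  if (nrow(mv) > 3000) {
    keep <- round(seq(1, nrow(mv), length.out = 3000))
    mvs <- mv[keep, , drop = FALSE]
  } else {
    mvs <- mv
  }
  tp <- mask_fg_points(template)
  c_m <- colMeans(mv)
  c_t <- colMeans(tp)
  sd_m <- apply(mv, 2, stats::sd)
  sd_t <- apply(tp, 2, stats::sd)
  soft <- template
  soft$data <- gaussian_blur(volume3d(template$data * 1, template$voxel_size,
                                      template$origin),
                             1.0 * template$voxel_size)$data
  t_init <- c_t - c_m
  n_t_eff <- sum(template$data) * nrow(mvs) / nrow(mv)
  # soft Dice: each moving voxel carries volume |det A| in template space,
  # so shrinking into the template interior is not a free lunch; the tiny
  # penalty breaks ties along symmetry flats of near-symmetric masks
  objective <- function(p) {
    tr <- params_to_affine(p, c_m)
    detA <- abs(det(tr$A))
    inter <- detA * sum(trilinear(soft, apply_affine(tr, mvs)))
    sdice <- 2 * inter / (detA * nrow(mvs) + n_t_eff)
    pen <- 1e-5 * (sum(p[4:9]^2) + sum((p[1:3] - t_init)^2) / 100)
    -sdice + pen
  }
  init1 <- c(t_init, 0, 0, 0, log(pmax(sd_t / pmax(sd_m, 1e-6), 1e-3)))
  init2 <- c(t_init, 0, 0, 0, 0, 0, 0)
  best <- stats::optim(init1, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-6))
  if (best$value > -0.98) {
    fit <- stats::optim(init2, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-6))
    if (fit$value < best$value) best <- fit
  }
  tr <- params_to_affine(best$par, c_m)
  dice <- mask_dice(mask, template, tr)
  if (dice < min_dice) {
    stop(sprintf("alignment failure: final Dice %.3f < %.2f", dice, min_dice),
         call. = FALSE)
  }
  attr(tr, "dice") <- dice
  attr(tr, "soft_score") <- -best$value
  tr
}

#' Resample a mask into a template grid through a transform
#'
#' Nearest-neighbour pull-back: each template voxel center is mapped through
#' the inverse transform and looked up in the moving mask.
#'
#' @param mask moving `neuropil_mask`
#' @param transform subject-to-template [affine3d()]
#' @param template grid-defining `neuropil_mask`
#' @return logical array on the template grid
#' @export
resample_mask <- function(mask, transform, template) {
  ctr <- voxel_centers(template)
  src <- apply_affine(transform, ctr, inverse = TRUE)
  idx <- world_to_index(src, mask)
  ok <- in_grid(idx, dim(mask$data))
  out <- logical(nrow(ctr))
  if (any(ok)) {
    lin <- idx[ok, 1] + (idx[ok, 2] - 1L) * dim(mask$data)[1] +
      (idx[ok, 3] - 1L) * prod(dim(mask$data)[1:2])
    out[ok] <- mask$data[lin]
  }
  array(out, dim(template$data))
}

#' Build a template neuropil from a set of masks
#'
#' Iterative shape averaging: the template is initialized as the first mask;
#' each round registers every input to the current template, averages the
#' aligned masks and re-binarizes at 0.5. Iteration stops when the mean Dice
#' improves by less than `tol` or after `n_iterations` rounds.
#'
#' @param masks list of `neuropil_mask` objects, same voxel size, all in the
#'   left frame (mirror right-side masks first)
#' @param n_iterations maximum averaging rounds
#' @param tol convergence tolerance on mean Dice improvement
#' @param min_dice per-image alignment-failure threshold
#' @return list with `template` (a `neuropil_mask`), `transforms` (one
#'   [affine3d()] per input) and `mean_dice`
#' @export
build_template <- function(masks, n_iterations = 3, tol = 1e-3,
                           min_dice = 0.5) {
  if (length(masks) < 2) {
    stop("template construction needs at least 2 masks", call. = FALSE)
  }
  template <- masks[[1]]
  prev_dice <- -Inf
  transforms <- NULL
  for (round in seq_len(n_iterations)) {
    transforms <- vector("list", length(masks))
    dices <- numeric(length(masks))
    acc <- array(0, dim(template$data))
    for (i in seq_along(masks)) {
      tr <- tryCatch(
        register_to_template(masks[[i]], template, min_dice = min_dice),
        error = function(e) {
          stop(sprintf("input %d failed to align: %s", i, conditionMessage(e)),
               call. = FALSE)
        }
      )
      transforms[[i]] <- tr
      dices[i] <- attr(tr, "dice")
      acc <- acc + resample_mask(masks[[i]], tr, template)
    }
    template$data <- (acc / length(masks)) >= 0.5
    if (mean(dices) - prev_dice < tol) {
      prev_dice <- mean(dices)
      break
    }
    prev_dice <- mean(dices)
  }
  list(template = template, transforms = transforms, mean_dice = prev_dice)
}

#' Mirror spots or a mask across the hemisegment midline
#'
#' Reflection across the midline plane; an exact involution. For volumes the
#' plane must be axis-aligned (which the hemisegment midline always is).
#'
#' @param x a spot table or a [volume3d()] / `neuropil_mask`
#' @param plane midline plane `list(normal, offset)`
#' @return the mirrored object
#' @export
mirror_hemisegment <- function(x, plane) {
  if (is.data.frame(x)) return(mirror_spots(x, plane))
  stopifnot(inherits(x, "volume3d"))
  ax <- which(abs(plane$normal) > 1e-12)
  if (length(ax) != 1) {
    stop("volume mirroring requires an axis-aligned plane", call. = FALSE)
  }
  d <- dim(x$data)
  out <- x
  perm <- list(d[1]:1, seq_len(d[2]), seq_len(d[3]))
  if (ax == 2) perm <- list(seq_len(d[1]), d[2]:1, seq_len(d[3]))
  if (ax == 3) perm <- list(seq_len(d[1]), seq_len(d[2]), d[3]:1)
  out$data <- x$data[perm[[1]], perm[[2]], perm[[3]], drop = FALSE]
  dpl <- plane$offset / plane$normal[ax]
  out$origin[ax] <- 2 * dpl - (x$origin[ax] + d[ax] * x$voxel_size[ax])
  out
}

#' Gaussian kernel-density map of puncta in template space
#'
#' Each punctum deposits unit mass into its voxel; the count grid is then
#' blurred with an isotropic Gaussian (the study's 1-um filter) and
#' converted to a density (mass per um^3) so that the map integrates to
#' `scale_factor * n_spots`. The Hb-filtered channel uses `scale_factor =
#' 10` to equate its intensity with the 10x-more-numerous wild-type puncta;
#' wild-type maps use 1.
#'
#' @param spots spot table in template coordinates
#' @param template grid-defining `neuropil_mask` (or any [volume3d()])
#' @param sigma_um Gaussian filter SD (um)
#' @param scale_factor per-hemisegment intensity normalization
#' @return a `density_map` ([volume3d()] subclass) with fields `sigma_um`,
#'   `scale_factor`, `n_spots`
#' @export
density_map <- function(spots, template, sigma_um = 1.0, scale_factor = 1) {
  if (sigma_um <= 0) stop("sigma_um must be positive", call. = FALSE)
  d <- dim(template$data)
  counts <- array(0, d)
  n <- nrow(spots)
  if (n > 0) {
    idx <- world_to_index(spot_xyz(spots), template)
    ok <- in_grid(idx, d)
    if (any(ok)) {
      lin <- idx[ok, 1] + (idx[ok, 2] - 1L) * d[1] + (idx[ok, 3] - 1L) * d[1] * d[2]
      tab <- tabulate(lin, nbins = prod(d))
      counts <- array(tab, d)
    }
  }
  v <- volume3d(counts, template$voxel_size, template$origin)
  v <- gaussian_blur(v, rep(sigma_um, 3))
  v$data <- v$data * scale_factor / prod(template$voxel_size)
  v$sigma_um <- sigma_um
  v$scale_factor <- scale_factor
  v$n_spots <- n
  class(v) <- c("density_map", class(v))
  v
}

#' Threshold a density map to include a fraction of the puncta
#'
#' Returns the suprathreshold voxel set for the largest threshold `t` such
#' that at least `fraction` of the puncta fall in voxels with density >= t
#' (the largest-threshold convention minimizes the region volume; the
#' study's regions include 95% of the presynapses). Ties across
#' equal-density voxels are included.
#'
#' @param density a [density_map()]
#' @param spots the puncta the inclusion criterion is evaluated on
#' @param fraction inclusion fraction in `(0, 1]`
#' @return a `region_mask`: [volume3d()] with logical data and fields
#'   `label`, `threshold`, `volume_um3`, `n_inside`
#' @export
threshold_inclusive <- function(density, spots, fraction = 0.95) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(spots)
  if (n == 0) {
    stop("cannot threshold on zero spots", call. = FALSE)
  }
  idx <- world_to_index(spot_xyz(spots), density)
  ok <- in_grid(idx, dim(density$data))
  dvals <- rep(-Inf, n)
  if (any(ok)) {
    lin <- idx[ok, 1] + (idx[ok, 2] - 1L) * dim(density$data)[1] +
      (idx[ok, 3] - 1L) * prod(dim(density$data)[1:2])
    dvals[ok] <- density$data[lin]
  }
  need <- ceiling(fraction * n)
  thr <- sort(dvals, decreasing = TRUE)[need]
  if (!is.finite(thr)) {
    stop("inclusion fraction unreachable: some spots lie outside the grid",
         call. = FALSE)
  }
  region_mask(density$data >= thr, density, label = "hb_all",
              threshold = thr, n_inside = sum(dvals >= thr))
}

region_mask <- function(bin, grid, label, threshold = NA_real_,
                        n_inside = NA_integer_) {
  v <- volume3d(array(as.logical(bin), dim(grid$data)), grid$voxel_size,
                grid$origin)
  v$label <- label
  v$threshold <- threshold
  v$volume_um3 <- sum(bin) * prod(grid$voxel_size)
  v$n_inside <- n_inside
  class(v) <- c("region_mask", class(v))
  v
}

#' Define the late-born region by volume-matched density subtraction
#'
#' Subtracts the (intensity-equalized) Hb-filtered density from the
#' wild-type density and thresholds the difference `D = wt - hb` at the
#' value `t* > 0` whose suprathreshold volume best matches `target_volume`
#' (by exact search over the sorted positive values of `D`). Because
#' `t* > 0`, the late region is disjoint from territory where the
#' Hb-filtered density dominates.
#'
#' @param hb_density,wt_density [density_map()]s on the same grid
#' @param target_volume target region volume (um^3); the study sets it equal
#'   to the Hb+ region volume
#' @return a `region_mask` labelled `"late"` with the achieved volume
#' @export
define_late_region <- function(hb_density, wt_density,
                               target_volume) {
  if (!all(dim(hb_density$data) == dim(wt_density$data))) {
    stop("densities must share a grid", call. = FALSE)
  }
  if (target_volume <= 0) stop("target_volume must be positive", call. = FALSE)
  D <- wt_density$data - hb_density$data
  pos <- D[D > 0]
  vox <- prod(wt_density$voxel_size)
  if (length(pos) * vox < 0.5 * target_volume) {
    stop("volume unreachable: subtracted density has too little positive support (WT and Hb densities too similar)",
         call. = FALSE)
  }
  vals <- sort(pos, decreasing = TRUE)
  target_n <- target_volume / vox
  # volume at threshold vals[k] is >= k (ties); search unique values
  uq <- unique(vals)
  counts <- findInterval(-uq, -vals) # voxels with D >= uq[k], ties included
  k <- which.min(abs(counts - target_n))
  thr <- uq[k]
  region_mask(D >= thr, wt_density, label = "late", threshold = thr)
}

#' Partition the Hb+ region into i1-i3 along the medial-lateral axis
#'
#' @param hb_all `region_mask` of the combined Hb+ territory
#' @param ml_boundaries two strictly increasing medial-lateral positions
#'   (um); slabs `(-Inf, b1)`, `[b1, b2)`, `[b2, Inf)` are labelled by
#'   `labels` in order of increasing lateral position
#' @param labels slab labels from medial to lateral
#' @return named list of three `region_mask`s, pairwise disjoint, whose
#'   union is `hb_all`
#' @export
partition_subregions <- function(hb_all, ml_boundaries,
                                 labels = c("i1", "i2", "i3")) {
  if (length(ml_boundaries) != 2 || diff(ml_boundaries) <= 0) {
    stop("ml_boundaries must be two strictly increasing positions",
         call. = FALSE)
  }
  lo <- hb_all$origin[1]
  hi <- hb_all$origin[1] + dim(hb_all$data)[1] * hb_all$voxel_size[1]
  if (any(ml_boundaries < lo) || any(ml_boundaries > hi)) {
    stop("ml_boundaries fall outside the template extent", call. = FALSE)
  }
  d <- dim(hb_all$data)
  x <- hb_all$origin[1] + (seq_len(d[1]) - 0.5) * hb_all$voxel_size[1]
  slab <- findInterval(x, ml_boundaries) + 1L # 1, 2, 3
  out <- list()
  for (s in 1:3) {
    bin <- hb_all$data
    bin[slab != s, , ] <- FALSE
    out[[labels[s]]] <- region_mask(bin, hb_all, label = labels[s])
  }
  out[c("i1", "i2", "i3")]
}

#' Quantify puncta per template-space region
#'
#' Counts each hemisegment's puncta in the i1-i3 and late-born region masks
#' and normalizes by the hemisegment's total count, matching the
#' centroid-frame normalization contract. Spots must already be transformed
#' to template space and mirrored to the left frame; if more than half of a
#' hemisegment's spots fall outside the template grid the hemisegment is
#' treated as unregistered and an error is raised.
#'
#' @param spots spot table in template space (with `hemisegment_id`)
#' @param regions named list of `region_mask`s (e.g. `i1`, `i2`, `i3`,
#'   `late`); earlier entries take precedence for voxels claimed twice
#' @return a `region_counts` data.frame as in [assign_and_percent()]
#' @export
quantify_template <- function(spots, regions) {
  labels <- names(regions)
  grid <- regions[[1]]
  d <- dim(grid$data)
  hids <- unique(spots$hemisegment_id)
  rows <- lapply(hids, function(hid) {
    sp <- spots[spots$hemisegment_id == hid, , drop = FALSE]
    idx <- world_to_index(spot_xyz(sp), grid)
    ok <- in_grid(idx, d)
    if (nrow(sp) > 0 && mean(ok) < 0.5) {
      stop(sprintf(
        "hemisegment %s: %d%% of spots outside the template grid; spots are likely unregistered",
        hid, round(100 * mean(!ok))
      ), call. = FALSE)
    }
    assigned <- rep(NA_character_, nrow(sp))
    lin <- rep(NA_integer_, nrow(sp))
    lin[ok] <- idx[ok, 1] + (idx[ok, 2] - 1L) * d[1] + (idx[ok, 3] - 1L) * d[1] * d[2]
    for (lab in labels) {
      inside <- !is.na(lin) & regions[[lab]]$data[ifelse(is.na(lin), 1L, lin)]
      assigned[is.na(assigned) & inside] <- lab
    }
    total <- nrow(sp)
    counts <- vapply(labels, function(l) sum(assigned == l, na.rm = TRUE), 0L)
    row <- data.frame(
      hemisegment_id = hid,
      genotype = if ("genotype" %in% names(sp) && total > 0) {
        sp$genotype[1]
      } else {
        NA_character_
      },
      stringsAsFactors = FALSE
    )
    for (l in labels) row[[paste0(l, "_n")]] <- counts[[l]]
    row$outside_n <- total - sum(counts)
    row$total_n <- total
    for (l in labels) {
      row[[paste0(l, "_pct")]] <- if (total > 0) 100 * counts[[l]] / total else NA_real_
    }
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(hemisegment_id = character(0))
  class(out) <- c("region_counts", "data.frame")
  out
}
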