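#' @title Seed substreams
#' @description All randomness in the generator flows from one top-level seed
#'   through named substreams (a stable string hash folded into the seed), so
#'   adding hemisegments or genotypes to a cohort never perturbs earlier
#'   draws.
#' @param seed top-level integer seed
#' @param key character label of the substream
#' @return an integer seed < 2^31
#' @export
substream_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Genotype model for synthetic presynapse cohorts
#'
#' Describes the mixture structure of presynaptic puncta within one
#' hemisegment: three compact clusters (the i1-i3 territories of the
#' early-born Hb+ interneurons) plus a diffuse late-born component, with a
#' genotype encoded purely by the mixture weights and total count. Cluster
#' centers are offsets (um) from the hemisegment centroid; each cluster is an
#' anisotropic Gaussian, elongated along the anterior-posterior axis because
#' presynapses distribute along that axis. Across hemisegments the cluster
#' centers themselves jitter around their population mean
#' (`center_jitter_sd`), which is what gives the reference-derived region
#' boxes (mean offset +/- 2 SD of per-hemisegment centers) a usable width.
#'
#' @param region_weights named proportions over `c(i1, i2, i3, late)`,
#'   summing to 1 (tolerance 1e-9)
#' @param cluster_centers 3 x 3 matrix (rows i1-i3) of um offsets from the
#'   centroid (ml, dv, ap)
#' @param cluster_sd 3 x 3 matrix (rows i1-i3) of per-axis Gaussian SD (um)
#' @param center_jitter_sd SD (um) of the per-hemisegment jitter of cluster
#'   centers in the ml and dv axes
#' @param late_distribution `"gaussian"` (broad anisotropic Gaussian at
#'   `late_center`/`late_sd`, truncated to the neuropil) or `"uniform"`
#'   (uniform inside the neuropil)
#' @param late_center,late_sd center offset and SD (um) of the Gaussian late
#'   component
#' @param total_count_mean expected puncta per hemisegment (> 0)
#' @param intensity_meanlog,intensity_sdlog log-normal puncta intensity
#'   parameters (arbitrary units)
#' @return an object of class `genotype_model`
#' @export
genotype_model <- function(region_weights = c(i1 = 0.0405, i2 = 0.0390,
                                              i3 = 0.0774, late = 0.8431),
                           cluster_centers = default_cluster_centers(),
                           cluster_sd = default_cluster_sd(),
                           center_jitter_sd = 0.6,
                           late_distribution = c("gaussian", "uniform"),
                           late_center = c(0, 0, 0),
                           late_sd = c(5, 5, 6),
                           total_count_mean = 340.2,
                           intensity_meanlog = log(5),
                           intensity_sdlog = 0.3) {
  late_distribution <- match.arg(late_distribution)
  w <- region_weights
  if (is.null(names(w))) names(w) <- c("i1", "i2", "i3", "late")
  w <- w[c("i1", "i2", "i3", "late")]
  if (any(is.na(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("region_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (total_count_mean <= 0) {
    stop("total_count_mean must be positive", call. = FALSE)
  }
  structure(
    list(
      region_weights = w,
      cluster_centers = cluster_centers,
      cluster_sd = cluster_sd,
      center_jitter_sd = center_jitter_sd,
      late_distribution = late_distribution,
      late_center = late_center, late_sd = late_sd,
      total_count_mean = total_count_mean,
      intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog
    ),
    class = "genotype_model"
  )
}

#' @rdname genotype_model
#' @export
default_cluster_centers <- function() {
  # distinct medial-lateral positions (the subregions are separable along
  # ml); i2 lies furthest from the centroid
  m <- rbind(
    i1 = c(-6, -3, 0),
    i2 = c(6, 5, 0),
    i3 = c(0, 4, 0)
  )
  colnames(m) <- c("ml", "dv", "ap")
  m
}

#' @rdname genotype_model
#' @export
default_cluster_sd <- function() {
  m <- rbind(
    i1 = c(0.5, 0.5, 5),
    i2 = c(0.5, 0.5, 5),
    i3 = c(0.5, 0.5, 5)
  )
  colnames(m) <- c("ml", "dv", "ap")
  m
}

#' Study-condition genotype models
#'
#' `wt_model()` carries the wild-type mixture (region weights set to the
#' manual-registration wild-type percentages, ~340 puncta per hemisegment);
#' `hboe_model()` shifts mass into i1/i2 and out of i3/late as seen under
#' prolonged Hunchback expression (~356 puncta); `hb_filtered_model()`
#' emulates the Hb-filtered reference labelling in which only the early-born
#' clusters are marked (about a tenth of the wild-type count, hence the 10x
#' intensity normalization used by the template procedure).
#'
#' @param ... overrides passed to [genotype_model()]
#' @return a `genotype_model`
#' @export
wt_model <- function(...) {
  args <- list(...)
  do.call(genotype_model, args)
}

#' @rdname wt_model
#' @export
hboe_model <- function(...) {
  args <- utils::modifyList(
    list(
      region_weights = c(i1 = 0.0845, i2 = 0.1016, i3 = 0.0513, late = 0.7626),
      total_count_mean = 356
    ),
    list(...)
  )
  do.call(genotype_model, args)
}

#' @rdname wt_model
#' @export
hb_filtered_model <- function(...) {
  w <- c(4.05, 3.90, 7.74)
  w <- w / sum(w)
  args <- utils::modifyList(
    list(
      region_weights = c(i1 = w[1], i2 = w[2], i3 = w[3], late = 0),
      total_count_mean = 34
    ),
    list(...)
  )
  do.call(genotype_model, args)
}

# vectorized rejection sampler: draw n points from `draw(n)` subject to
# `keep(pts)`, with a cap on resampling rounds
rejection_sample <- function(n, draw, keep, what, cap = 1000) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  for (round in seq_len(cap)) {
    pts <- draw(length(need))
    ok <- keep(pts)
    if (any(ok)) {
      out[need[ok], ] <- pts[ok, , drop = FALSE]
      need <- need[!ok]
    }
    if (length(need) == 0) return(out)
  }
  stop(sprintf(
    "rejection sampling for %s exceeded %d rounds; component lies outside the geometry",
    what, cap
  ), call. = FALSE)
}

#' Sample a synthetic presynapse spot table
#'
#' Draws `n_total` puncta from the genotype's mixture: each spot is assigned
#' a ground-truth region from the region weights; cluster spots come from the
#' per-region truncated Gaussian (centered on this hemisegment's jittered
#' cluster center), late spots from the diffuse late component. All spots lie
#' inside the neuropil outline. Reproducible given `seed`.
#'
#' @param model a [genotype_model()]
#' @param geometry a [make_geometry()] object
#' @param n_total number of puncta; if `NULL`, drawn as
#'   `rpois(1, model$total_count_mean)`
#' @param seed integer seed (used via a local RNG scope)
#' @param hemisegment_id,genotype labels copied into the table
#' @return a spot table: `data.frame` with columns `spot_id`, `x_um`, `y_um`,
#'   `z_um`, `intensity`, `hemisegment_id`, `genotype`, `true_region`
#' @export
sample_presynapses <- function(model, geometry, n_total = NULL, seed = NULL,
                               hemisegment_id = "h1", genotype = "WT") {
  stopifnot(inherits(model, "genotype_model"),
            inherits(geometry, "hemisegment_geometry"))
  with_seed(seed, {
    if (is.null(n_total)) n_total <- stats::rpois(1, model$total_count_mean)
    if (n_total < 0) stop("n_total must be >= 0", call. = FALSE)
    centroid <- hemisegment_centroid(geometry)
    labels <- c("i1", "i2", "i3", "late")
    region <- if (n_total > 0) {
      sample(labels, n_total, replace = TRUE, prob = model$region_weights)
    } else {
      character(0)
    }
    # mirror cluster/late offsets for right hemisegments so left and right
    # are anatomical mirror images
    sgn <- if (geometry$side == "left") 1 else -1
    flip <- function(off) {
      off[1] <- sgn * off[1]
      off
    }
    xyz <- matrix(NA_real_, n_total, 3)
    for (lab in c("i1", "i2", "i3")) {
      idx <- which(region == lab)
      if (length(idx) == 0) next
      mu0 <- centroid + flip(model$cluster_centers[lab, ])
      # per-hemisegment biological variation of the cluster center,
      # truncated so the center stays inside the neuropil
      mu <- mu0
      for (try in seq_len(100)) {
        mu <- mu0 + c(stats::rnorm(2, 0, model$center_jitter_sd), 0)
        if (point_in_neuropil(mu, geometry, shrink = 0.95)) break
        if (try == 100) mu <- mu0
      }
      sdv <- model$cluster_sd[lab, ]
      xyz[idx, ] <- rejection_sample(
        length(idx),
        draw = function(m) {
          cbind(
            stats::rnorm(m, mu[1], sdv[1]),
            stats::rnorm(m, mu[2], sdv[2]),
            stats::rnorm(m, mu[3], sdv[3])
          )
        },
        keep = function(p) point_in_neuropil(p, geometry),
        what = paste("cluster", lab)
      )
    }
    idx <- which(region == "late")
    if (length(idx) > 0) {
      if (model$late_distribution == "uniform") {
        lo <- geometry$box["lower", ]
        hi <- geometry$box["upper", ]
        drawfun <- function(m) {
          cbind(
            stats::runif(m, lo[1], hi[1]),
            stats::runif(m, lo[2], hi[2]),
            stats::runif(m, lo[3], hi[3])
          )
        }
      } else {
        mu <- centroid + flip(model$late_center)
        sdv <- model$late_sd
        drawfun <- function(m) {
          cbind(
            stats::rnorm(m, mu[1], sdv[1]),
            stats::rnorm(m, mu[2], sdv[2]),
            stats::rnorm(m, mu[3], sdv[3])
          )
        }
      }
      xyz[idx, ] <- rejection_sample(
        length(idx), drawfun,
        keep = function(p) point_in_neuropil(p, geometry),
        what = "late component"
      )
    }
    intensity <- stats::rlnorm(n_total, model$intensity_meanlog,
                               model$intensity_sdlog)
    data.frame(
      spot_id = if (n_total > 0) {
        sprintf("%s_s%04d", hemisegment_id, seq_len(n_total))
      } else {
        character(0)
      },
      x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
      intensity = intensity,
      hemisegment_id = rep(hemisegment_id, n_total),
      genotype = rep(genotype, n_total),
      true_region = region,
      stringsAsFactors = FALSE
    )
  })
}

#' Render a spot table into a noisy 3D volume
#'
#' Forward model for the spot detector: each punctum contributes an
#' anisotropic Gaussian whose integrated intensity equals the spot's
#' intensity (so the sum of the above-background volume times the voxel
#' volume recovers the total spot intensity), on top of a constant background
#' with additive Gaussian read noise. The peak voxel value of a spot of
#' intensity I is `I / ((2*pi)^1.5 * prod(psf_sigma))`.
#'
#' @param spots a spot table (see [sample_presynapses()])
#' @param geometry a [make_geometry()] object; the grid covers its box
#' @param voxel_size length-3 voxel size (um)
#' @param psf_sigma per-axis PSF standard deviation (um)
#' @param background constant background level (AU)
#' @param noise_sd additive Gaussian noise SD (AU)
#' @param seed integer seed for the noise
#' @return a [volume3d()]
#' @export
render_volume <- function(spots, geometry, voxel_size = c(0.1, 0.1, 0.22),
                          psf_sigma = c(0.12, 0.12, 0.42),
                          background = 0, noise_sd = 0, seed = NULL) {
  if (any(psf_sigma <= 0)) stop("psf_sigma must be positive", call. = FALSE)
  v <- volume_grid(geometry, voxel_size)
  d <- dim(v$data)
  a <- v$data
  n_clip <- 0L
  if (nrow(spots) > 0) {
    for (s in seq_len(nrow(spots))) {
      p <- c(spots$x_um[s], spots$y_um[s], spots$z_um[s])
      ax <- vector("list", 3)
      idxr <- vector("list", 3)
      clipped <- FALSE
      for (k in 1:3) {
        half <- 4 * psf_sigma[k]
        lo <- floor((p[k] - half - v$origin[k]) / voxel_size[k]) + 1
        hi <- ceiling((p[k] + half - v$origin[k]) / voxel_size[k])
        if (lo < 1 || hi > d[k]) clipped <- TRUE
        lo <- max(1, lo)
        hi <- min(d[k], hi)
        if (lo > hi) {
          idxr[[k]] <- integer(0)
          next
        }
        idxr[[k]] <- lo:hi
        ctr <- v$origin[k] + (idxr[[k]] - 0.5) * voxel_size[k]
        ax[[k]] <- stats::dnorm(ctr, p[k], psf_sigma[k])
      }
      if (clipped) n_clip <- n_clip + 1L
      if (any(lengths(idxr) == 0)) next
      blob <- spots$intensity[s] *
        (ax[[1]] %o% ax[[2]] %o% ax[[3]])
      a[idxr[[1]], idxr[[2]], idxr[[3]]] <-
        a[idxr[[1]], idxr[[2]], idxr[[3]]] + blob
    }
  }
  if (n_clip > 0) {
    warning(sprintf("%d spot(s) extended beyond the volume and were clipped",
                    n_clip), call. = FALSE)
  }
  a <- a + background
  if (noise_sd > 0) {
    a <- a + with_seed(seed, array(stats::rnorm(prod(d), 0, noise_sd), d))
  }
  v$data <- a
  v
}

#' Simulate a multi-genotype cohort
#'
#' Generates spot tables (and optionally rendered volumes and neuropil
#' masks) for a set of genotypes, each with a configured number of
#' hemisegments. Hemisegments alternate left/right sides; ground truth
#' (`true_region`) is retained. When `out_dir` is given, writes a
#' self-describing dataset: one CSV of all spots, per-hemisegment TIFF
#' volumes/masks if rendered, and a JSON manifest (geometry, models, seed).
#'
#' @param models named list of [genotype_model()] objects (names are the
#'   genotype labels)
#' @param n_hemisegments hemisegments per genotype (recycled)
#' @param geometry a [make_geometry()] object used for every left
#'   hemisegment (right ones use its mirror)
#' @param seed top-level integer seed; per-hemisegment substreams are derived
#'   from it
#' @param render if `TRUE`, also render each hemisegment volume
#' @param voxel_size,psf_sigma,background,noise_sd rendering parameters
#' @param out_dir optional output directory
#' @return a list with `spots` (combined spot table with a `side` column),
#'   `geometries` (per hemisegment), optionally `volumes` and `masks`, and
#'   `manifest`
#' @export
simulate_cohort <- function(models, n_hemisegments = 22,
                            geometry = make_geometry(20, 20, 20),
                            seed = 1, render = FALSE,
                            voxel_size = c(0.1, 0.1, 0.22),
                            psf_sigma = c(0.12, 0.12, 0.42),
                            background = 0, noise_sd = 0,
                            out_dir = NULL) {
  if (length(models) < 1 || is.null(names(models))) {
    stop("models must be a non-empty named list of genotype models",
         call. = FALSE)
  }
  n_hemisegments <- rep_len(n_hemisegments, length(models))
  spots_all <- list()
  geoms <- list()
  vols <- list()
  masks <- list()
  for (gi in seq_along(models)) {
    gt <- names(models)[gi]
    for (h in seq_len(n_hemisegments[gi])) {
      side <- if (h %% 2 == 1) "left" else "right"
      geo <- if (side == "left") {
        geometry
      } else {
        make_geometry(geometry$length_ml, geometry$height_dv,
                      geometry$depth_ap, side = "right",
                      origin = geometry$origin,
                      neuropil_exponent = geometry$neuropil_exponent)
      }
      hid <- sprintf("%s_h%02d", gt, h)
      sseed <- substream_seed(seed, paste0("hemi/", hid))
      sp <- sample_presynapses(models[[gi]], geo, seed = sseed,
                               hemisegment_id = hid, genotype = gt)
      sp$side <- rep(side, nrow(sp))
      spots_all[[hid]] <- sp
      geoms[[hid]] <- geo
      if (render) {
        vols[[hid]] <- render_volume(
          sp, geo, voxel_size, psf_sigma, background, noise_sd,
          seed = substream_seed(seed, paste0("noise/", hid))
        )
        masks[[hid]] <- make_neuropil_mask(geo, voxel_size)
      }
    }
  }
  spots <- do.call(rbind, c(spots_all, list(make.row.names = FALSE)))
  if (is.null(spots)) {
    spots <- data.frame(
      spot_id = character(0), x_um = numeric(0), y_um = numeric(0),
      z_um = numeric(0), intensity = numeric(0),
      hemisegment_id = character(0), genotype = character(0),
      true_region = character(0), side = character(0)
    )
  }
  manifest <- list(
    seed = seed,
    genotypes = names(models),
    n_hemisegments = as.list(stats::setNames(n_hemisegments, names(models))),
    geometry = list(
      length_ml = geometry$length_ml, height_dv = geometry$height_dv,
      depth_ap = geometry$depth_ap, neuropil_exponent = geometry$neuropil_exponent
    ),
    models = lapply(models, function(m) {
      list(
        region_weights = as.list(m$region_weights),
        total_count_mean = m$total_count_mean,
        late_distribution = m$late_distribution
      )
    }),
    rendered = render,
    package = "synaptlas"
  )
  out <- list(spots = spots, geometries = geoms, manifest = manifest)
  if (render) {
    out$volumes <- vols
    out$masks <- masks
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spot_table(spots, file.path(out_dir, "spots.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (render) {
      for (hid in names(vols)) {
        write_volume_tiff(vols[[hid]], file.path(out_dir, paste0(hid, ".tif")))
        write_volume_tiff(
          volume3d(masks[[hid]]$data * 1, masks[[hid]]$voxel_size,
                   masks[[hid]]$origin),
          file.path(out_dir, paste0(hid, "_mask.tif"))
        )
      }
    }
  }
  out
}
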