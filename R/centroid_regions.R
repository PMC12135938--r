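#' Mirror a spot table into the left-hemisegment frame
#'
#' Right-hemisegment data are treated as independent observations and
#' reflected across the midline so that all hemisegments can be pooled in a
#' single left frame.
#'
#' @param spots a spot table
#' @param plane midline plane (`list(normal, offset)`), e.g.
#'   `geometry$midline`
#' @return the spot table with reflected coordinates
#' @export
mirror_spots <- function(spots, plane) {
  if (nrow(spots) == 0) return(spots)
  xyz <- reflect_points(spot_xyz(spots), plane)
  spots$x_um <- xyz[, 1]
  spots$y_um <- xyz[, 2]
  spots$z_um <- xyz[, 3]
  spots
}

#' Per-hemisegment center of a labelled reference region
#'
#' The mean medial-lateral / dorsal-ventral position of the labelled
#' reference puncta, expressed as an offset from the hemisegment centroid.
#' The anterior-posterior axis is ignored because presynapses distribute
#' along it, spanning the hemisegment depth.
#'
#' @param reference_spots spot table for one hemisegment, carrying
#'   `true_region` labels
#' @param label region label (`"i1"`, `"i2"` or `"i3"`)
#' @param geometry the hemisegment's [make_geometry()] object
#' @return named numeric offset `c(ml, dv)` in um
#' @export
region_center_per_hemisegment <- function(reference_spots, label, geometry) {
  sel <- reference_spots$true_region == label
  if (!any(sel)) {
    hid <- unique(reference_spots$hemisegment_id)
    stop(sprintf(
      "no reference spots labelled '%s' in hemisegment %s", label,
      if (length(hid)) paste(hid, collapse = ",") else "<unknown>"
    ), call. = FALSE)
  }
  ctr <- hemisegment_centroid(geometry)
  c(
    ml = mean(reference_spots$x_um[sel]) - ctr[1],
    dv = mean(reference_spots$y_um[sel]) - ctr[2]
  )
}

#' Build a centroid-frame region definition from reference offsets
#'
#' The region is an axis-aligned box in the centroid frame: centred on the
#' mean of the per-hemisegment center offsets, with half-width two sample
#' standard deviations (n-1 denominator) per axis, spanning the full
#' hemisegment depth in the anterior-posterior axis. When the offsets are
#' degenerate (SD 0) the half-width is clamped to `min_halfwidth` so the
#' region is still usable.
#'
#' @param offsets matrix (or list) of per-hemisegment `(ml, dv)` offsets, one
#'   row per hemisegment; at least 2 rows
#' @param label region label
#' @param geometry a [make_geometry()] object (left frame)
#' @param min_halfwidth floor on the half-widths (um); default one lateral
#'   voxel of the acquisition
#' @return an object of class `region_definition` with the box in world
#'   coordinates
#' @export
build_region_definition <- function(offsets, label, geometry,
                                    min_halfwidth = 0.1) {
  if (is.list(offsets) && !is.data.frame(offsets)) {
    offsets <- do.call(rbind, offsets)
  }
  offsets <- as.matrix(offsets)
  if (nrow(offsets) < 2) {
    stop("at least 2 reference hemisegments are required to define a region",
         call. = FALSE)
  }
  mu <- colMeans(offsets)
  sdv <- apply(offsets, 2, stats::sd)
  hw <- pmax(2 * sdv, min_halfwidth)
  ctr <- hemisegment_centroid(geometry)
  lower <- c(ctr[1] + mu[1] - hw[1], ctr[2] + mu[2] - hw[2],
             geometry$box["lower", 3])
  upper <- c(ctr[1] + mu[1] + hw[1], ctr[2] + mu[2] + hw[2],
             geometry$box["upper", 3])
  box <- rbind(lower = lower, upper = upper)
  colnames(box) <- c("ml", "dv", "ap")
  structure(
    list(
      label = label,
      mean_offset = c(ml = unname(mu[1]), dv = unname(mu[2])),
      sd = c(ml = unname(sdv[1]), dv = unname(sdv[2])),
      halfwidth = c(ml = unname(hw[1]), dv = unname(hw[2])),
      box = box, n_reference = nrow(offsets)
    ),
    class = "region_definition"
  )
}

#' Build all region definitions from a reference cohort
#'
#' Convenience wrapper: mirrors right hemisegments into the left frame,
#' measures each hemisegment's per-region center offset, and builds the
#' mean +/- 2 SD boxes.
#'
#' @param reference list returned by [simulate_cohort()] (or a compatible
#'   list with `spots` and `geometries`), whose spots carry `true_region`
#' @param geometry the left-frame [make_geometry()] object
#' @param labels region labels to build
#' @param min_halfwidth floor on the half-widths (um)
#' @return named list of [build_region_definition()] objects
#' @export
build_regions_from_reference <- function(reference,
                                         geometry,
                                         labels = c("i1", "i2", "i3"),
                                         min_halfwidth = 0.1) {
  spots <- reference$spots
  geoms <- reference$geometries
  out <- list()
  for (lab in labels) {
    offs <- list()
    for (hid in unique(spots$hemisegment_id)) {
      sp <- spots[spots$hemisegment_id == hid, , drop = FALSE]
      geo <- geoms[[hid]]
      if (geo$side == "right") sp <- mirror_spots(sp, geo$midline)
      if (!any(sp$true_region == lab)) next
      offs[[hid]] <- region_center_per_hemisegment(sp, lab, geometry)
    }
    out[[lab]] <- build_region_definition(do.call(rbind, offs), lab,
                                          geometry, min_halfwidth)
  }
  out
}

point_in_box <- function(xyz, box) {
  xyz[, 1] >= box["lower", 1] & xyz[, 1] <= box["upper", 1] &
    xyz[, 2] >= box["lower", 2] & xyz[, 2] <= box["upper", 2] &
    xyz[, 3] >= box["lower", 3] & xyz[, 3] <= box["upper", 3]
}

boxes_overlap <- function(a, b) {
  all(a["lower", ] <= b["upper", ]) && all(b["lower", ] <= a["upper", ])
}

#' Count spots per centroid-frame region and normalize to percentages
#'
#' A spot belongs to a region iff its center lies inside the closed region
#' box; a spot on a shared face of two regions is assigned to the region
#' listed first (regions are expected to be disjoint; overlap triggers a
#' warning). Percentages are normalized by the hemisegment's total spot
#' count. Hemisegments with zero spots get `NA` percentages (flagged, never
#' zero).
#'
#' @param spots spot table (one or more hemisegments, left frame)
#' @param regions named list of [build_region_definition()] objects
#' @param geometry a [make_geometry()] object (unused except for validation)
#' @param hemisegment_ids hemisegments to report; defaults to those present
#'   in `spots`, but passing the full cohort list lets empty hemisegments
#'   surface as `NA` percentages instead of silently disappearing
#' @return a `region_counts` data.frame: one row per hemisegment with
#'   `<label>_n` counts, `outside_n`, `total_n`, and `<label>_pct`
#' @export
assign_and_percent <- function(spots, regions, geometry = NULL,
                               hemisegment_ids = NULL) {
  labels <- names(regions)
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i < j && boxes_overlap(regions[[i]]$box, regions[[j]]$box)) {
        warning(sprintf("region boxes '%s' and '%s' overlap; spots on shared faces go to '%s'",
                        labels[i], labels[j], labels[i]), call. = FALSE)
      }
    }
  }
  hids <- if (is.null(hemisegment_ids)) {
    unique(spots$hemisegment_id)
  } else {
    hemisegment_ids
  }
  rows <- lapply(hids, function(hid) {
    sp <- spots[spots$hemisegment_id == hid, , drop = FALSE]
    xyz <- spot_xyz(sp)
    assigned <- rep(NA_character_, nrow(sp))
    for (lab in labels) {
      inside <- point_in_box(xyz, regions[[lab]]$box)
      assigned[is.na(assigned) & inside] <- lab
    }
    total <- nrow(sp)
    counts <- vapply(labels, function(l) sum(assigned == l, na.rm = TRUE), 0L)
    outside <- total - sum(counts)
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
    row$outside_n <- outside
    row$total_n <- total
    for (l in labels) {
      row[[paste0(l, "_pct")]] <- if (total > 0) 100 * counts[[l]] / total else NA_real_
    }
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(hemisegment_id = character(0))
  }
  class(out) <- c("region_counts", "data.frame")
  out
}

#' Held-out capture rate of a region definition
#'
#' Validation of a region box against held-out labelled hemisegments: a
#' hemisegment is "captured" when a strict majority (> 50%) of its labelled
#' reference spots fall inside the region box.
#'
#' @param region a [build_region_definition()] object
#' @param held_out spot table of one or more held-out hemisegments carrying
#'   `true_region` labels
#' @param label the reference label to validate (defaults to the region's)
#' @return list with `captured`, `n_hemisegments` and `rate`
#' @export
capture_rate <- function(region, held_out, label = region$label) {
  sel <- held_out[held_out$true_region == label, , drop = FALSE]
  hids <- unique(sel$hemisegment_id)
  if (length(hids) == 0) {
    stop("held-out set carries no spots with the requested label",
         call. = FALSE)
  }
  cap <- vapply(hids, function(hid) {
    sp <- sel[sel$hemisegment_id == hid, , drop = FALSE]
    mean(point_in_box(spot_xyz(sp), region$box)) > 0.5
  }, logical(1))
  list(captured = sum(cap), n_hemisegments = length(hids),
       rate = mean(cap))
}

#' Calibrate mixture weights to target measured percentages
#'
#' The centroid-frame boxes capture slightly less than all of a cluster's
#' puncta (a +/- 2 SD box truncates the tails) and pick up a small number of
#' diffuse late-born puncta, so the generating mixture weights and the
#' expected measured percentages differ by a linear map. This routine
#' estimates that capture/contamination matrix by Monte Carlo (simulating a
#' large cohort with known ground truth, building reference regions from an
#' Hb-filtered reference cohort, and cross-tabulating true region against
#' assigned box) and solves for the weights whose expected measured
#' percentages equal `target_pct`.
#'
#' @param target_pct named target percentages for `i1`, `i2`, `i3` (the
#'   measured scale, e.g. the study's wild-type 4.05 / 3.90 / 7.74)
#' @param geometry a [make_geometry()] object
#' @param base_model model supplying cluster geometry and totals
#' @param reference an optional pre-built reference cohort list (as from
#'   [simulate_cohort()] with [hb_filtered_model()]); built internally when
#'   `NULL`
#' @param n_cal hemisegments in the calibration cohort
#' @param seed integer seed
#' @return list with `model` (the calibrated [genotype_model()]), `weights`,
#'   `capture_matrix` and `regions` (the reference-derived boxes)
#' @export
calibrate_region_weights <- function(target_pct = c(i1 = 4.05, i2 = 3.90,
                                                    i3 = 7.74),
                                     geometry = make_geometry(20, 20, 20),
                                     base_model = wt_model(),
                                     reference = NULL,
                                     n_cal = 400, seed = 99) {
  if (is.null(reference)) {
    reference <- simulate_cohort(
      list(HBF = hb_filtered_model()),
      n_hemisegments = 20, geometry = geometry,
      seed = substream_seed(seed, "calibration-reference")
    )
  }
  regions <- build_regions_from_reference(reference, geometry)
  cal <- simulate_cohort(
    list(CAL = base_model), n_hemisegments = n_cal, geometry = geometry,
    seed = substream_seed(seed, "calibration-cohort")
  )
  sp <- pool_left_frame(cal)
  xyz <- spot_xyz(sp)
  labels <- names(regions)
  true_labels <- c("i1", "i2", "i3", "late")
  assigned <- rep(NA_character_, nrow(sp))
  for (lab in labels) {
    inside <- point_in_box(xyz, regions[[lab]]$box)
    assigned[is.na(assigned) & inside] <- lab
  }
  # C[b, r] = P(counted in box b | true region r)
  C <- matrix(0, length(labels), length(true_labels),
              dimnames = list(labels, true_labels))
  for (r in true_labels) {
    sel <- sp$true_region == r
    if (!any(sel)) next
    for (b in labels) {
      C[b, r] <- mean(!is.na(assigned[sel]) & assigned[sel] == b)
    }
  }
  t_frac <- target_pct[labels] / 100
  # measured_b = sum_r C[b,r] w_r with w_late = 1 - sum(w_1..3)
  A <- C[, 1:3] - C[, "late"]
  rhs <- t_frac - C[, "late"]
  w <- solve(A, rhs)
  if (any(w < 0) || sum(w) > 1) {
    stop("calibration produced infeasible weights; targets unreachable under this geometry",
         call. = FALSE)
  }
  weights <- c(w, late = 1 - sum(w))
  names(weights) <- true_labels
  model <- genotype_model(
    region_weights = weights,
    cluster_centers = base_model$cluster_centers,
    cluster_sd = base_model$cluster_sd,
    center_jitter_sd = base_model$center_jitter_sd,
    late_distribution = base_model$late_distribution,
    late_center = base_model$late_center, late_sd = base_model$late_sd,
    total_count_mean = base_model$total_count_mean,
    intensity_meanlog = base_model$intensity_meanlog,
    intensity_sdlog = base_model$intensity_sdlog
  )
  list(model = model, weights = weights, capture_matrix = C,
       regions = regions)
}

#' Pool a cohort's spots into the left frame
#'
#' @param cohort a [simulate_cohort()] result
#' @return single spot table with right hemisegments mirrored across their
#'   midline
#' @export
pool_left_frame <- function(cohort) {
  spots <- cohort$spots
  out <- list()
  for (hid in unique(spots$hemisegment_id)) {
    sp <- spots[spots$hemisegment_id == hid, , drop = FALSE]
    geo <- cohort$geometries[[hid]]
    if (geo$side == "right") sp <- mirror_spots(sp, geo$midline)
    out[[hid]] <- sp
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) spots else res
}
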