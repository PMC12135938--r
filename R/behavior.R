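#' Soma-to-neuropil distance
#'
#' Euclidean distance (um) from a soma center to the nearest neuropil
#' foreground voxel center, used as a proxy for neuronal birth order
#' (early-born somata sit close to the neuropil, late-born ones far).
#' Returns 0 for somata inside the mask.
#'
#' @param soma length-3 um coordinate, or an n x 3 matrix / data.frame with
#'   columns `x_um`, `y_um`, `z_um`
#' @param mask a `neuropil_mask`
#' @return numeric vector of distances (um)
#' @export
soma_neuropil_distance <- function(soma, mask) {
  if (sum(mask$data) == 0) {
    stop("neuropil mask is empty", call. = FALSE)
  }
  p <- if (is.data.frame(soma)) {
    as.matrix(soma[, c("x_um", "y_um", "z_um")])
  } else if (is.null(dim(soma))) {
    matrix(soma, ncol = 3)
  } else {
    as.matrix(soma)
  }
  fg <- mask_fg_points(mask)
  idx <- world_to_index(p, mask)
  d <- dim(mask$data)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    inside <- in_grid(idx[i, , drop = FALSE], d) &&
      mask$data[idx[i, 1], idx[i, 2], idx[i, 3]]
    out[i] <- if (inside) {
      0
    } else {
      sqrt(min(rowSums(sweep(fg, 2, p[i, ], "-")^2)))
    }
  }
  out
}

track_fps <- function(track, fps = NULL) {
  if (!is.null(fps)) return(fps)
  f <- attr(track, "fps")
  if (is.null(f)) stop("track has no fps attribute; pass fps explicitly",
                       call. = FALSE)
  f
}

# fill frame gaps of up to `max_gap` frames by linear interpolation
regularize_track <- function(track, max_gap = 3) {
  fr <- track$frame
  if (any(diff(fr) <= 0)) stop("track frames must be increasing", call. = FALSE)
  gaps <- diff(fr) - 1
  if (all(gaps == 0)) return(track)
  if (any(gaps > max_gap)) {
    stop(sprintf("track has a gap of %d frames (max %d); cannot interpolate",
                 max(gaps), max_gap), call. = FALSE)
  }
  full <- seq(fr[1], fr[length(fr)])
  out <- data.frame(frame = full)
  for (col in setdiff(names(track), "frame")) {
    out[[col]] <- stats::approx(fr, track[[col]], xout = full)$y
  }
  attr(out, "fps") <- attr(track, "fps")
  out
}

#' Per-frame crawling speed of the track midpoint
#'
#' `speed[i] = ||mid[i+1] - mid[i]|| * fps`, in track units per second.
#' Frame gaps of up to 3 frames are linearly interpolated; larger gaps are
#' an error.
#'
#' @param track a larva track data.frame (`frame`, `mid_x`, `mid_y`, ...)
#' @param fps frames per second; defaults to the track's `fps` attribute
#' @return numeric vector of length `n_frames - 1`
#' @export
crawl_speed_series <- function(track, fps = NULL) {
  fps <- track_fps(track, fps)
  track <- regularize_track(track)
  if (nrow(track) < 2) stop("need at least 2 frames", call. = FALSE)
  dx <- diff(track$mid_x)
  dy <- diff(track$mid_y)
  sqrt(dx^2 + dy^2) * fps
}

#' Area under the speed-time curve
#'
#' Riemann sum of the speed samples over the recording: each sample covers
#' one frame interval of `1/fps` seconds, so a constant speed `v` held for
#' `T` seconds (i.e. `fps * T` samples) integrates to exactly `v * T`.
#'
#' @param series per-frame speed samples (units/s)
#' @param fps frames per second
#' @return the AUC (units: speed units x seconds = distance)
#' @export
speed_auc <- function(series, fps) {
  if (length(series) < 2) stop("need at least 2 speed samples", call. = FALSE)
  sum(series) / fps
}

#' Per-frame body-bend angle from 180 degrees
#'
#' For each frame, the interior angle at the midpoint between the
#' head-midpoint and tail-midpoint vectors; the bend metric is its absolute
#' deviation from 180 degrees (0 for a straight larva, 90 for a right-angle
#' posture). Frames with coincident spine points are returned as `NA` and
#' excluded from summaries.
#'
#' @param track a larva track data.frame with head/mid/tail columns
#' @return numeric vector (degrees, in `[0, 180]`, `NA` for invalid frames)
#' @export
bend_angle_series <- function(track) {
  need <- c("head_x", "head_y", "mid_x", "mid_y", "tail_x", "tail_y")
  if (!all(need %in% names(track))) {
    stop("track must contain head/mid/tail coordinates", call. = FALSE)
  }
  hx <- track$head_x - track$mid_x
  hy <- track$head_y - track$mid_y
  tx <- track$tail_x - track$mid_x
  ty <- track$tail_y - track$mid_y
  nh <- sqrt(hx^2 + hy^2)
  nt <- sqrt(tx^2 + ty^2)
  bad <- nh < 1e-12 | nt < 1e-12
  cosang <- (hx * tx + hy * ty) / (nh * nt)
  cosang <- pmin(1, pmax(-1, cosang))
  theta <- acos(cosang) * 180 / pi
  out <- 180 - theta
  out[bad] <- NA_real_
  out
}

#' Per-larva locomotion summary
#'
#' @param track a larva track
#' @param fps frames per second (defaults to the track attribute)
#' @return one-row data.frame with `mean_speed`, `speed_auc`,
#'   `mean_bend_deg` (mean of the per-frame bend metric over valid frames)
#'   and `n_invalid_frames`
#' @export
track_metrics <- function(track, fps = NULL) {
  fps <- track_fps(track, fps)
  sp <- crawl_speed_series(track, fps)
  bend <- bend_angle_series(track)
  data.frame(
    mean_speed = mean(sp),
    speed_auc = speed_auc(sp, fps),
    mean_bend_deg = mean(bend, na.rm = TRUE),
    n_invalid_frames = sum(is.na(bend))
  )
}

#' Infer the number of divisions behind a temporal window's neuron count
#'
#' Each neuroblast division in a temporal-factor window produces one
#' ganglion mother cell, which divides once into two sibling neurons, so a
#' window containing `n` neurons implies `ceiling(n / 2)` divisions (an odd
#' count implies a division with one undetected or missing sibling: 5
#' neurons imply three divisions, 2 neurons one division).
#'
#' @param counts non-negative integer neuron counts (possibly named by
#'   window)
#' @return integer divisions per window
#' @export
infer_division_windows <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  out <- as.integer(ceiling(counts / 2))
  names(out) <- names(counts)
  out
}

#' Read a FIMTrack-style track table
#'
#' @param path CSV with columns `frame`, `head_x`, `head_y`, `mid_x`,
#'   `mid_y`, `tail_x`, `tail_y`
#' @param fps frames per second (stored as an attribute)
#' @return a larva track data.frame
#' @export
read_track <- function(path, fps) {
  df <- utils::read.csv(path)
  need <- c("frame", "head_x", "head_y", "mid_x", "mid_y", "tail_x", "tail_y")
  if (!all(need %in% names(df))) {
    stop("track table missing required columns", call. = FALSE)
  }
  attr(df, "fps") <- fps
  df
}
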