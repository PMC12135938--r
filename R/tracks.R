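#' Simulate a larval crawling track
#'
#' Emulates a FIMTrack-style 3-point spine (head, midpoint, tail) sampled at
#' `fps` for `duration` seconds. The midpoint advances along the current
#' heading with per-frame speed drawn from a (non-negative truncated) normal
#' distribution, so the instantaneous midpoint speed has the configured mean.
#' Bend events arrive with exponential gaps (`1/bend_event_rate` mean) and
#' last `bend_duration` seconds; during an event the head deflects from the
#' body axis by `bend_amplitude_deg` (random side), so the head-mid-tail
#' interior angle departs from 180 degrees by exactly the amplitude, and the
#' larva re-orients by half the deflection when the event ends. With a zero
#' event rate the track is perfectly straight.
#'
#' Default speed and bend parameters are calibrated so the expected per-larva
#' summaries match the wild-type control group of the study (speed AUC about
#' 159 over a 2-minute recording; mean bend-from-180 about 17.5 degrees with
#' a 50% bend duty cycle).
#'
#' @param mean_speed mean midpoint speed (units/s)
#' @param speed_sd per-frame speed SD (units/s)
#' @param bend_event_rate bend events per second (>= 0)
#' @param bend_amplitude_deg head deflection during a bend (degrees)
#' @param bend_duration bend event length (s)
#' @param fps frames per second (> 0); the study's videos are saved at 25
#' @param duration recording length (s); the study records 2 minutes
#' @param body_half_length distance midpoint-to-head and midpoint-to-tail
#' @param seed integer seed
#' @return a `larva_track`: data.frame with columns `frame`, `head_x`,
#'   `head_y`, `mid_x`, `mid_y`, `tail_x`, `tail_y` and attributes `fps`,
#'   `duration`
#' @export
simulate_track <- function(mean_speed = 1.325, speed_sd = 0.3,
                           bend_event_rate = 1, bend_amplitude_deg = 35,
                           bend_duration = 1, fps = 25, duration = 120,
                           body_half_length = 0.75, seed = NULL) {
  if (fps <= 0 || duration <= 0) {
    stop("fps and duration must be positive", call. = FALSE)
  }
  if (bend_event_rate < 0 || bend_amplitude_deg < 0) {
    stop("bend rate and amplitude must be non-negative", call. = FALSE)
  }
  n <- round(fps * duration)
  with_seed(seed, {
    # schedule non-overlapping bend events over [0, duration]
    bend_of_frame <- numeric(n) # signed deflection in degrees per frame
    if (bend_event_rate > 0) {
      t0 <- stats::rexp(1, bend_event_rate)
      while (t0 < duration) {
        side <- sample(c(-1, 1), 1)
        f0 <- floor(t0 * fps) + 1
        f1 <- min(n, f0 + max(1, round(bend_duration * fps)) - 1)
        if (f0 <= n) bend_of_frame[f0:f1] <- side * bend_amplitude_deg
        t0 <- t0 + bend_duration + stats::rexp(1, bend_event_rate)
      }
    }
    speeds <- pmax(0, stats::rnorm(n, mean_speed, speed_sd))
    heading <- numeric(n)
    phi <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(n)) {
      heading[i] <- phi
      # re-orient after a bend ends
      if (i > 1 && bend_of_frame[i - 1] != 0 && bend_of_frame[i] == 0) {
        phi <- phi + bend_of_frame[i - 1] * pi / 180 / 2
      }
    }
    mid <- matrix(0, n, 2)
    for (i in 2:max(2, n)) {
      if (i > n) break
      step <- speeds[i - 1] / fps
      mid[i, ] <- mid[i - 1, ] + step * c(cos(heading[i - 1]), sin(heading[i - 1]))
    }
    u <- cbind(cos(heading), sin(heading))
    head_ang <- heading + bend_of_frame * pi / 180
    uh <- cbind(cos(head_ang), sin(head_ang))
    head <- mid + body_half_length * uh
    tail <- mid - body_half_length * u
    out <- data.frame(
      frame = seq_len(n),
      head_x = head[, 1], head_y = head[, 2],
      mid_x = mid[, 1], mid_y = mid[, 2],
      tail_x = tail[, 1], tail_y = tail[, 2]
    )
    attr(out, "fps") <- fps
    attr(out, "duration") <- duration
    class(out) <- c("larva_track", "data.frame")
    out
  })
}

#' HbOE track parameters
#'
#' Convenience wrapper with defaults calibrated to the Hb-overexpression
#' group of the study (speed AUC about 107 over 2 minutes; mean bend about
#' 28.3 degrees).
#'
#' @param ... overrides passed to [simulate_track()]
#' @return a `larva_track`
#' @export
simulate_track_hboe <- function(...) {
  args <- utils::modifyList(
    list(mean_speed = 0.891, bend_amplitude_deg = 56.62),
    list(...)
  )
  do.call(simulate_track, args)
}
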