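as_eye_trace <- function(trace) {
  if (inherits(trace, "eye_trace")) return(trace)
  stopifnot(is.list(trace), all(c("time_s", "angle_deg",
                                  "drum_velocity_dps") %in% names(trace)))
  trace
}

#' Segment a nystagmus trace into fast and slow phases
#'
#' Frame-to-frame angular velocity is computed by central differences.
#' Samples whose speed exceeds `velocity_factor` times the drum speed and
#' whose direction opposes the slow (tracking) phase are grouped into
#' fast-phase (saccadic reset) events; the remaining runs of at least
#' `min_slow_frames` samples form slow-phase intervals, each assigned a
#' least-squares velocity.
#'
#' @param trace an `eye_trace` (see [generate_okr_trace()]) or a list with
#'   `time_s`, `angle_deg`, `drum_velocity_dps` (signed: positive = nasal
#'   stimulus direction).
#' @param velocity_factor fast-phase speed criterion as a multiple of drum
#'   speed (default 3).
#' @param min_slow_frames minimum number of frames in a slow-phase
#'   interval (default 3).
#' @return A list of class `nystagmus_segmentation`: `events` (data.frame
#'   `time_s`, `direction`), `slow_intervals` (data.frame `start_s`,
#'   `end_s`, `velocity_dps`, `n_frames`), `drum_velocity_dps`,
#'   `duration_s`.
#' @examples
#' tr <- generate_okr_trace(okr_trace_spec(gain = 0.6))
#' detect_fast_phases(tr)$slow_intervals$velocity_dps
#' @export
detect_fast_phases <- function(trace, velocity_factor = 3,
                               min_slow_frames = 3L) {
  trace <- as_eye_trace(trace)
  t <- trace$time_s
  a <- trace$angle_deg
  n <- length(t)
  if (n < 3L) stop_spec("need at least 1 s of data")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop_spec("non-uniform sampling")
  }
  dt <- dt[1L]
  v <- c(NA, (a[3:n] - a[1:(n - 2L)]) / (2 * dt), NA)
  slow_sign <- sign(trace$drum_velocity_dps)
  fast <- !is.na(v) &
    abs(v) > velocity_factor * abs(trace$drum_velocity_dps) &
    sign(v) == -slow_sign
  fast[is.na(fast)] <- FALSE

  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_idx <- which(r$values)
  events <- data.frame(
    time_s = vapply(ev_idx, function(k)
      mean(t[starts[k]:ends[k]]), numeric(1)),
    direction = rep(if (slow_sign > 0) "temporal" else "nasal",
                    length(ev_idx)))

  sl_idx <- which(!r$values & r$lengths >= min_slow_frames)
  slow <- do.call(rbind, lapply(sl_idx, function(k) {
    i <- starts[k]:ends[k]
    fit <- stats::lm.fit(cbind(1, t[i]), a[i])
    data.frame(start_s = t[starts[k]], end_s = t[ends[k]],
               velocity_dps = unname(fit$coefficients[2L]),
               n_frames = length(i))
  }))
  if (is.null(slow)) {
    slow <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       velocity_dps = numeric(0), n_frames = integer(0))
  }
  structure(list(events = events, slow_intervals = slow,
                 drum_velocity_dps = trace$drum_velocity_dps,
                 duration_s = t[n] - t[1L]),
            class = "nystagmus_segmentation")
}

#' Optokinetic gain
#'
#' Ratio between eye velocity and drum velocity; a gain of 1 is perfect
#' tracking of the moving stimulus.  The eye velocity is summarized as the
#' median over slow-phase intervals (robust to residual saccade
#' contamination; the mean is available via `summary_fn`), and the ratio
#' is signed so that tracking the stimulus gives a positive gain.
#'
#' @param seg a `nystagmus_segmentation`.
#' @param drum_velocity_dps signed drum velocity; taken from the
#'   segmentation when omitted.
#' @param summary_fn summary over slow-phase velocities (default
#'   [stats::median()]).
#' @return The optokinetic gain (dimensionless).
#' @examples
#' tr <- generate_okr_trace(okr_trace_spec(gain = 1))
#' optokinetic_gain(detect_fast_phases(tr))  # 1
#' @export
optokinetic_gain <- function(seg, drum_velocity_dps = NULL,
                             summary_fn = stats::median) {
  stopifnot(inherits(seg, "nystagmus_segmentation"))
  if (is.null(drum_velocity_dps)) drum_velocity_dps <- seg$drum_velocity_dps
  if (nrow(seg$slow_intervals) == 0L) stop_spec("no slow-phase intervals")
  summary_fn(seg$slow_intervals$velocity_dps) / drum_velocity_dps
}

#' Eye-tracking movements per time window
#'
#' Counts fast-phase events of the stated direction in consecutive windows
#' (10 s by default) and averages over complete windows.
#'
#' @param seg a `nystagmus_segmentation`.
#' @param direction `"nasal"` or `"temporal"` (direction of the fast
#'   reset).
#' @param window_s window length in seconds.
#' @return Mean event count per window.
#' @export
count_etms <- function(seg, direction = c("nasal", "temporal"),
                       window_s = 10) {
  stopifnot(inherits(seg, "nystagmus_segmentation"))
  direction <- match.arg(direction)
  if (seg$duration_s < window_s) {
    stop_spec("trace shorter than the counting window")
  }
  times <- seg$events$time_s[seg$events$direction == direction]
  n_win <- floor(seg$duration_s / window_s)
  counts <- vapply(seq_len(n_win), function(w)
    sum(times >= (w - 1) * window_s & times < w * window_s), numeric(1))
  mean(counts)
}

#' Positive-response criterion for one spatial frequency
#'
#' A response is positive when at least `min_cycles` consecutive
#' nystagmus cycles (a slow phase terminated by a fast reset) occur
#' without an inter-event gap exceeding `max_gap_s`, in both the
#' temporal-to-nasal and nasal-to-temporal stimulus directions.
#'
#' @param seg_tn,seg_nt segmentations of the recordings under
#'   temporal-to-nasal and nasal-to-temporal stimulation; pass one
#'   segmentation to assess a single direction.
#' @param min_cycles minimum run of consecutive cycles (default 3).
#' @param max_gap_s maximum allowed gap between consecutive fast phases
#'   within a run, in seconds (default 2, accommodating typical reset
#'   rates of 0.5-2 per second).
#' @return Logical: positive response.
#' @export
okr_response_positive <- function(seg_tn, seg_nt = NULL, min_cycles = 3L,
                                  max_gap_s = 2) {
  has_run <- function(seg) {
    times <- sort(seg$events$time_s)
    if (length(times) < min_cycles) return(FALSE)
    gaps <- diff(times)
    run <- 1L
    best <- 1L
    for (g in gaps) {
      run <- if (g <= max_gap_s) run + 1L else 1L
      best <- max(best, run)
    }
    best >= min_cycles
  }
  ok <- has_run(seg_tn)
  if (!is.null(seg_nt)) ok <- ok && has_run(seg_nt)
  ok
}

#' Acuity staircase over ascending spatial frequencies
#'
#' The grating spatial frequency rises in 0.05 cpd steps from 0.15 cpd
#' until the optokinetic response can no longer be elicited, and the
#' highest (first negative) frequency is repeated to verify the loss.  The
#' visual acuity is the highest frequency with a positive response.
#'
#' @param responses data.frame in test order with columns `frequency_cpd`
#'   and `positive` (logical); the terminating frequency appears twice
#'   (test and verification).
#' @param start_cpd,step_cpd staircase grid (defaults 0.15 and 0.05).
#' @param gains optional named numeric vector of per-frequency gains
#'   carried into the result.
#' @param etm_counts optional named numeric vector of per-frequency ETM
#'   counts per 10-s interval.
#' @return A list of class `acuity_result`: `acuity_cpd` (NA with
#'   `below_start = TRUE` if the first frequency is negative), `verified`
#'   (TRUE when the terminating negative was confirmed by its repeat),
#'   `responses`, `gains`, `etm_counts`.
#' @examples
#' r <- data.frame(frequency_cpd = c(0.15, 0.20, 0.25, 0.30, 0.30),
#'                 positive = c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' acuity_staircase(r)$acuity_cpd  # 0.25
#' @export
acuity_staircase <- function(responses, start_cpd = 0.15, step_cpd = 0.05,
                             gains = NULL, etm_counts = NULL) {
  stopifnot(is.data.frame(responses),
            all(c("frequency_cpd", "positive") %in% names(responses)))
  f <- responses$frequency_cpd
  p <- responses$positive
  expected <- start_cpd + step_cpd * (seq_along(unique(f)) - 1L)
  if (any(abs(sort(unique(f)) - expected) > 1e-9)) {
    stop_spec("frequencies must form the ascending staircase grid ",
              sprintf("starting at %.2f cpd in %.2f cpd steps",
                      start_cpd, step_cpd))
  }
  if (any(diff(f) < -1e-9)) stop_spec("frequencies must be tested in ascending order")

  below_start <- !p[1L]
  pos_f <- f[p]
  acuity <- if (length(pos_f)) max(pos_f) else NA_real_
  top <- max(f)
  top_tests <- p[abs(f - top) < 1e-9]
  verified <- length(top_tests) >= 2L && !any(top_tests)
  structure(list(acuity_cpd = acuity, below_start = below_start,
                 verified = verified, responses = responses,
                 gains = gains, etm_counts = etm_counts),
            class = "acuity_result")
}
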