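as_erg <- function(trace) {
  stopifnot(is.list(trace),
            all(c("time_ms", "voltage_uv", "onsets_ms") %in% names(trace)))
  trace
}

#' Baseline-correct an ERG trace
#'
#' Subtracts the mean voltage over the `window_ms` (default 50 ms)
#' immediately preceding the first stimulus onset from the whole trace.
#' Idempotent: correcting a corrected trace changes nothing.
#'
#' @param trace an `erg_trace` (see [generate_erg_trace()]) or a list with
#'   `time_ms`, `voltage_uv`, `onsets_ms`.
#' @param window_ms baseline window length in ms (default 50).
#' @return The trace with corrected `voltage_uv` and a `baseline_uv`
#'   element recording the subtracted value.
#' @export
baseline_correct <- function(trace, window_ms = 50) {
  trace <- as_erg(trace)
  on1 <- trace$onsets_ms[1L]
  sel <- trace$time_ms >= on1 - window_ms & trace$time_ms < on1
  if (!any(sel) || (on1 - min(trace$time_ms)) < window_ms) {
    stop_spec("insufficient pre-stimulus data: need >= ", window_ms,
              " ms before the first onset")
  }
  base <- mean(trace$voltage_uv[sel])
  trace$voltage_uv <- trace$voltage_uv - base
  trace$baseline_uv <- base
  trace
}

#' Average the per-stimulus response epochs
#'
#' Extracts onset-aligned epochs of equal length (the smaller of the
#' inter-stimulus interval and `epoch_ms`) and averages them point-wise.
#'
#' @param trace a (baseline-corrected) ERG trace.
#' @param epoch_ms maximum epoch length in ms (default 1000).
#' @return A list of class `erg_epoch`: `time_ms` (relative to onset),
#'   `voltage_uv` (averaged), `n_stimuli`.
#' @export
average_responses <- function(trace, epoch_ms = 1000) {
  trace <- as_erg(trace)
  onsets <- sort(trace$onsets_ms)
  if (length(onsets) < 1L) stop_spec("no stimulus onsets")
  if (length(onsets) > 1L) {
    # cap the epoch at the inter-stimulus interval so epochs never overlap
    epoch_ms <- min(epoch_ms, min(diff(onsets)))
  }
  dt <- trace$time_ms[2L] - trace$time_ms[1L]
  len <- floor(epoch_ms / dt)
  epochs <- vapply(onsets, function(on) {
    i0 <- which(trace$time_ms >= on - 1e-9)[1L]
    if (is.na(i0) || i0 + len - 1L > length(trace$voltage_uv)) {
      stop_spec("epoch extends past the end of the trace")
    }
    trace$voltage_uv[i0:(i0 + len - 1L)]
  }, numeric(len))
  structure(list(time_ms = (seq_len(len) - 1L) * dt,
                 voltage_uv = rowMeans(epochs),
                 n_stimuli = length(onsets)),
            class = "erg_epoch")
}

#' Maximal B-wave amplitude of an averaged epoch
#'
#' Maximum of the averaged, baseline-corrected response within the
#' post-onset search window.
#'
#' @param epoch an `erg_epoch` (see [average_responses()]).
#' @param search_ms search window after onset in ms (default 500).
#' @return B-wave amplitude in microvolts.
#' @examples
#' tr <- baseline_correct(generate_erg_trace(erg_trace_spec(
#'   b_amplitude_uv = 200, baseline_uv = 50)))
#' b_wave_amplitude(average_responses(tr))  # 200
#' @export
b_wave_amplitude <- function(epoch, search_ms = 500) {
  stopifnot(inherits(epoch, "erg_epoch"))
  sel <- epoch$time_ms >= 0 & epoch$time_ms <= search_ms
  if (!any(sel)) stop_spec("empty search window")
  max(epoch$voltage_uv[sel])
}

#' Normalize a B-wave amplitude by body length
#'
#' @param amplitude_uv B-wave amplitude in microvolts.
#' @param body_length_mm body length in millimetres (> 0).
#' @return Amplitude in microvolts per millimetre.
#' @examples
#' normalize_by_body_length(200, 20)  # 10
#' @export
normalize_by_body_length <- function(amplitude_uv, body_length_mm) {
  if (any(body_length_mm <= 0)) stop_spec("body length must be > 0")
  amplitude_uv / body_length_mm
}
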