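# Hemodynamic response modelling shared by the synthetic generator and the
# first-level GLM.

#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking near 5 s minus an
#' undershoot gamma peaking near 15 s scaled by 1/6, sampled at `dt`-second
#' intervals over `duration` seconds and normalized to peak 1.
#'
#' @param dt Sampling interval in seconds (typically the TR).
#' @param duration Length of the sampled kernel in seconds.
#' @return Numeric vector of kernel weights at times `0, dt, 2 dt, ...`.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  stopifnot(dt > 0, duration > dt)
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Convolve a frame-resolution boxcar with an HRF kernel, truncated to the
# boxcar's length. `hrf = "identity"` returns the boxcar unchanged (degenerate
# model used in tests).
convolve_boxcar <- function(boxcar, tr, hrf = "spm") {
  if (identical(hrf, "identity")) {
    return(boxcar)
  }
  if (identical(hrf, "spm")) {
    kernel <- canonical_hrf(tr)
  } else if (is.numeric(hrf)) {
    kernel <- hrf
  } else {
    abort("`hrf` must be \"spm\", \"identity\", or a numeric kernel.")
  }
  out <- convolve(boxcar, rev(kernel), type = "open")
  out[seq_along(boxcar)]
}

# Frame-resolution boxcar for one event. Frame i covers time
# [(i-1) tr, i tr); a frame is "on" if its onset time falls inside the event.
event_boxcar <- function(onset, duration, n_frames, tr) {
  frame_onsets <- (seq_len(n_frames) - 1) * tr
  as.numeric(frame_onsets >= onset & frame_onsets < onset + duration)
}
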