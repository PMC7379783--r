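#' Detect stance from the vertical ground reaction force
#'
#' Stance runs from heel strike (vGRF rising through the threshold) to toe-off
#' (vGRF falling back through it). Crossing times are located by linear
#' interpolation between samples; ties at the exact threshold resolve toward
#' the earlier sample. Supra-threshold episodes shorter than 50 ms are treated
#' as force-plate spikes and ignored; zero or multiple remaining episodes are
#' an error.
#'
#' @param time Timestamps of the vGRF samples, seconds.
#' @param vgrf Vertical GRF, newtons (low-pass filtered).
#' @param threshold Contact threshold, newtons (default 10).
#' @return List with `heel_strike` and `toe_off`, seconds.
#' @export
detect_stance <- function(time, vgrf, threshold = 10) {
  stopifnot(length(time) == length(vgrf))
  up <- vgrf > threshold
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  epi <- which(r$values)
  if (length(epi)) {
    dur <- time[ends[epi]] - time[starts[epi]]
    epi <- epi[dur >= 0.050]
  }
  if (length(epi) == 0) {
    if (any(up)) stop("spike rejected, no stance")
    stop("ambiguous stance: no supra-threshold episode")
  }
  if (length(epi) > 1) stop("ambiguous stance: multiple supra-threshold episodes")
  i0 <- starts[epi]; i1 <- ends[epi]
  heel_strike <- if (i0 == 1) time[1] else
    .cross_time(time[i0 - 1], time[i0], vgrf[i0 - 1], vgrf[i0], threshold)
  toe_off <- if (i1 == length(vgrf)) time[i1] else
    .cross_time(time[i1], time[i1 + 1], vgrf[i1], vgrf[i1 + 1], threshold)
  list(heel_strike = heel_strike, toe_off = toe_off)
}

.cross_time <- function(t0, t1, v0, v1, level) {
  if (v0 == level) return(t0)            # tie resolves to the earlier sample
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

#' Detect the braking/propulsion transition
#'
#' Within stance the anterior-posterior GRF on the runner is braking-directed
#' (negative in this package's convention, +X forward) early and propulsive
#' (positive) late. The braking phase ends at the last zero crossing after
#' which the AP GRF stays propulsive until toe-off, located by linear
#' interpolation.
#'
#' @param time Timestamps, seconds.
#' @param ap_grf Anterior-posterior GRF, newtons (filtered; negative while
#'   braking).
#' @param stance List with `heel_strike` and `toe_off` (from
#'   [detect_stance()]).
#' @return `brake_end`, seconds.
#' @export
detect_brake_end <- function(time, ap_grf, stance) {
  inside <- time > stance$heel_strike & time < stance$toe_off
  t <- time[inside]; ap <- ap_grf[inside]
  if (length(t) < 3) stop("no braking/propulsion transition: stance too short")
  # polarity check over the first 10% of stance
  early <- t <= stance$heel_strike + 0.1 * (stance$toe_off - stance$heel_strike)
  if (mean(ap[early]) > 0) stop("unexpected AP polarity: propulsive at heel strike")
  # deadband (2% of the AP range) so filter-edge ripple and measurement noise
  # near toe-off do not masquerade as late sign changes
  thr <- 0.02 * max(abs(ap))
  if (!any(ap > thr)) stop("no braking/propulsion transition")
  k <- max(which(ap < -thr))            # last clearly braking sample
  j <- k + which(ap[(k + 1):length(ap)] > 0)[1]
  if (is.na(j)) stop("no braking/propulsion transition")
  brake_end <- .cross_time(t[j - 1], t[j], ap[j - 1], ap[j], 0)
  if (brake_end <= stance$heel_strike || brake_end >= stance$toe_off)
    stop("no braking/propulsion transition")
  brake_end
}

#' Partition a trial into gait phases
#'
#' Detects stance and the braking/propulsion transition from the (filtered)
#' force stream and returns the four phase intervals used throughout the
#' package: preactivation (the 50 ms immediately before heel strike), stance,
#' braking and push-off. Braking and push-off partition stance exactly.
#'
#' @param recording A [trial_recording()] or a data frame with `time`, `Fz`,
#'   `Fx` columns already low-pass filtered.
#' @param threshold vGRF contact threshold, newtons.
#' @param filter If `TRUE` (default) low-pass filter the force stream at 50 Hz
#'   before detection; set `FALSE` if the input is already filtered.
#' @return An object of class `gait_phases` with fields `heel_strike`,
#'   `toe_off`, `brake_end`, `preactivation_start` and a named list
#'   `intervals` of half-open `[start, end)` intervals.
#' @export
segment_phases <- function(recording, threshold = 10, filter = TRUE) {
  if (inherits(recording, "trial_recording")) {
    fo <- recording$forces
    rate <- recording$force_rate
  } else {
    fo <- recording
    rate <- .infer_rate(fo$time, "force")
  }
  fz <- fo$Fz; fx <- fo$Fx
  if (filter) {
    fz <- lowpass(fz, rate, filter_spec(50))
    fx <- lowpass(fx, rate, filter_spec(50))
  }
  stance <- detect_stance(fo$time, fz, threshold)
  brake_end <- detect_brake_end(fo$time, fx, stance)
  pre_start <- stance$heel_strike - 0.050
  if (pre_start < min(fo$time) - 1e-9)
    stop("insufficient pre-contact data")
  structure(
    list(heel_strike = stance$heel_strike, toe_off = stance$toe_off,
         brake_end = brake_end, preactivation_start = pre_start,
         intervals = list(
           preactivation = c(pre_start, stance$heel_strike),
           stance = c(stance$heel_strike, stance$toe_off),
           braking = c(stance$heel_strike, brake_end),
           push_off = c(brake_end, stance$toe_off))),
    class = "gait_phases"
  )
}

#' @export
print.gait_phases <- function(x, ...) {
  cat("<gait_phases>\n")
  for (p in names(x$intervals)) {
    iv <- x$intervals[[p]]
    cat(sprintf("  %-13s [%.4f, %.4f) s  (%.1f ms)\n", p, iv[1], iv[2],
                1000 * diff(iv)))
  }
  invisible(x)
}

#' Write a phase report TSV
#' @param phases A `gait_phases` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_report <- function(phases, path) {
  df <- do.call(rbind, lapply(names(phases$intervals), function(p) {
    iv <- phases$intervals[[p]]
    data.frame(phase = p, start_s = iv[1], end_s = iv[2],
               duration_s = diff(iv))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
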