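#' Chamber area time series from a mask sequence
#'
#' @param masks List of binary masks or a `beat_sequence`.
#' @param fps Frame rate in Hz (taken from the sequence if one is given).
#' @return An object of class `area_trace`: list with `times` (s, uniform
#'   at 1/fps starting at 0), `areas` (px^2), `fps`.
#' @export
area_trace <- function(masks, fps) {
  if (inherits(masks, "beat_sequence")) {
    fps <- masks$config$fps
    masks <- masks$masks
  }
  if (length(masks) == 0) stop("empty mask sequence", call. = FALSE)
  stopifnot(fps > 0)
  areas <- vapply(masks, mask_area, numeric(1))
  new_area_trace((seq_along(areas) - 1) / fps, areas, fps)
}

#' Construct an area trace from raw vectors
#'
#' @param times Seconds, strictly increasing.
#' @param areas Areas (px^2), non-negative, same length as `times`.
#' @param fps Sampling rate in Hz.
#' @return An `area_trace` object.
#' @export
new_area_trace <- function(times, areas, fps) {
  stopifnot(length(times) == length(areas), length(times) >= 2,
            all(diff(times) > 0), all(areas >= 0), fps > 0)
  structure(list(times = as.numeric(times), areas = as.numeric(areas),
                 fps = fps), class = "area_trace")
}

#' @export
print.area_trace <- function(x, ...) {
  cat(sprintf("<area_trace> %d samples at %g fps (%.3f..%.3f s)\n",
              length(x$times), x$fps, x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

# centered moving average with edge replication, window w (odd preferred)
moving_average <- function(v, w) {
  if (w <= 1) return(v)
  half <- floor(w / 2)
  padded <- c(rep(v[1], half), v, rep(v[length(v)], w - half - 1))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[
    (half + 1):(half + length(v))]
}

# topographic prominence of interior local maxima (indices into v): lowest
# valley between the peak and the nearest strictly higher sample each side
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    left <- v[seq_len(p - 1)]
    higher_l <- which(left > v[p])
    lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
    lmin <- min(left[lo:(p - 1)])
    right <- v[(p + 1):length(v)]
    higher_r <- which(right > v[p])
    hi <- if (length(higher_r)) min(higher_r) - 1L else length(right)
    rmin <- min(right[seq_len(hi)])
    v[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect diastole peaks in a chamber area trace
#'
#' Diastole (heart relaxation) corresponds to local maxima of chamber
#' area. The trace is smoothed with a centered moving average, local maxima
#' are located, low-prominence maxima (below
#' `min_prominence_frac * (max - min)` of the smoothed trace) are dropped,
#' and a refractory separation of `min_period_s` is enforced greedily from
#' the highest peak down (a 0.1 s default corresponds to a 600 bpm
#' ceiling, above any water-flea heart rate).
#'
#' @param trace An [area_trace()].
#' @param smooth_window Moving-average window in frames (default 5).
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   smoothed trace's amplitude (default 0.3).
#' @param min_period_s Minimum separation between accepted peaks, seconds
#'   (default 0.1).
#' @return An object of class `beat_series`: list with `peak_times` (s,
#'   strictly increasing), `peak_indices` (1-based frame indices), `ibis`
#'   (inter-beat intervals, s, length `length(peak_times) - 1`).
#' @export
detect_diastole_peaks <- function(trace, smooth_window = 5,
                                  min_prominence_frac = 0.3,
                                  min_period_s = 0.1) {
  stopifnot(inherits(trace, "area_trace"),
            length(trace$areas) > smooth_window)
  v <- moving_average(trace$areas, smooth_window)
  amp <- max(v) - min(v)
  if (amp == 0) stop("insufficient beats: trace is constant", call. = FALSE)

  d <- diff(v)
  # local maxima, with plateaus resolved to their first index
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand)) {
    prom <- peak_prominence(v, cand)
    cand <- cand[prom >= min_prominence_frac * amp]
  }
  # greedy refractory filter: accept by descending smoothed height
  if (length(cand) > 1) {
    ord <- cand[order(v[cand], decreasing = TRUE)]
    accepted <- integer(0)
    for (p in ord) {
      if (!length(accepted) ||
          all(abs(trace$times[accepted] - trace$times[p]) >= min_period_s)) {
        accepted <- c(accepted, p)
      }
    }
    cand <- sort(accepted)
  }
  if (length(cand) < 2) {
    stop("insufficient beats: fewer than 2 diastole peaks detected",
         call. = FALSE)
  }
  peak_times <- trace$times[cand]
  structure(list(peak_times = peak_times, peak_indices = cand,
                 ibis = diff(peak_times)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d diastole peaks, mean IBI %.4f s\n",
              length(x$peak_times), mean(x$ibis)))
  invisible(x)
}

#' Heart rate in beats per minute
#'
#' 60 divided by the mean inter-beat interval.
#'
#' @param beats A `beat_series` from [detect_diastole_peaks()], or a
#'   numeric vector of inter-beat intervals in seconds.
#' @return Heart rate, beats/min.
#' @export
heart_rate <- function(beats) {
  ibis <- if (inherits(beats, "beat_series")) beats$ibis else as.numeric(beats)
  if (length(ibis) < 1) stop("need at least one inter-beat interval",
                             call. = FALSE)
  stopifnot(all(ibis > 0))
  60 / mean(ibis)
}

#' Poincare SD1/SD2 heart-rate variability
#'
#' From the lag-1 scatter of successive inter-beat intervals
#' `(ibi_i, ibi_{i+1})`: SD1 measures short-term variability (dispersion
#' perpendicular to the identity line) and SD2 long-term variability
#' (dispersion along it). Both are computed geometrically as sample
#' standard deviations (n - 1 denominator) of the rotated coordinates
#' `(ibi_{i+1} - ibi_i) / sqrt(2)` and `(ibi_{i+1} + ibi_i) / sqrt(2)`.
#' SD1 is therefore exactly `sqrt(Var(diff(ibis)) / 2)`, and SD2 agrees
#' with the familiar identity `sqrt(2 Var(ibi) - SD1^2)` up to the
#' finite-sample difference between the full series and its lag-1 pair
#' windows.
#'
#' @param ibis Numeric vector of inter-beat intervals (>= 3), or a
#'   `beat_series`.
#' @param unit Unit the intervals are expressed in; recorded in the result
#'   (`"s"` or `"ms"`), no conversion is performed.
#' @return An object of class `hrv_stats`: list with `sd1`, `sd2`, `unit`,
#'   `n_intervals`.
#' @export
poincare <- function(ibis, unit = "s") {
  if (inherits(ibis, "beat_series")) ibis <- ibis$ibis
  ibis <- as.numeric(ibis)
  if (length(ibis) < 3) stop("need at least 3 inter-beat intervals",
                             call. = FALSE)
  a <- ibis[-length(ibis)]
  b <- ibis[-1]
  sd1 <- stats::sd((b - a) / sqrt(2))
  sd2 <- stats::sd((b + a) / sqrt(2))
  structure(list(sd1 = sd1, sd2 = sd2, unit = unit,
                 n_intervals = length(ibis)),
            class = "hrv_stats")
}

#' @export
print.hrv_stats <- function(x, ...) {
  cat(sprintf("<hrv_stats> sd1 %.5f %s, sd2 %.5f %s (n = %d)\n",
              x$sd1, x$unit, x$sd2, x$unit, x$n_intervals))
  invisible(x)
}

#' Cross-sectional area change, percent
#'
#' `(EDV area - ESV area) / EDV area * 100`, where the end-diastolic area
#' is the maximal and the end-systolic the minimal chamber area. The
#' default `global` mode takes the extremes over the whole recorded trace
#' (all cardiac cycles in the video); `per_beat` computes the same ratio
#' within each detected beat (between consecutive diastole peaks) and
#' averages. Global extremes dominate per-beat means on noisy traces,
#' which is why whole-trace automated estimates exceed estimates from a
#' few hand-picked cycles.
#'
#' @param trace An [area_trace()].
#' @param mode `"global"` (default) or `"per_beat"`.
#' @param beats A `beat_series`; required for `per_beat` (computed with
#'   default parameters if omitted).
#' @return Area change in percent.
#' @export
area_change <- function(trace, mode = c("global", "per_beat"), beats = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "area_trace"))
  if (max(trace$areas) == 0) stop("trace has no foreground area", call. = FALSE)
  if (mode == "global") {
    return((max(trace$areas) - min(trace$areas)) / max(trace$areas) * 100)
  }
  if (is.null(beats)) beats <- detect_diastole_peaks(trace)
  idx <- beats$peak_indices
  per <- vapply(seq_len(length(idx) - 1), function(i) {
    seg <- trace$areas[idx[i]:idx[i + 1]]
    (max(seg) - min(seg)) / max(seg) * 100
  }, numeric(1))
  mean(per)
}
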