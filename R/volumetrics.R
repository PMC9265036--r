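#' Prolate-spheroid chamber volume from long and short axes
#'
#' A single 2-D projection gives only two chamber diameters, so the 3-D
#' chamber is modeled as a prolate spheroid: the long axis `L` is the polar
#' diameter and the short axis `S` serves as both equatorial diameters,
#' giving `V = (pi / 6) * L * S^2`.
#'
#' @param L Long (major) full axis, px; `L >= S`.
#' @param S Short (minor) full axis, px; `S > 0`. Vectorized.
#' @return Volume in px^3.
#' @export
ellipsoid_volume <- function(L, S) {
  if (any(S <= 0) || any(L <= 0)) {
    stop("axes must be positive", call. = FALSE)
  }
  if (any(L < S)) stop("long axis smaller than short axis (swapped inputs?)",
                       call. = FALSE)
  pi / 6 * L * S^2
}

#' Per-frame chamber volume trace
#'
#' @param long_axes,short_axes Full axis lengths per frame, px.
#' @param times Frame times, seconds.
#' @return An object of class `volume_trace`: list with `times`, `volumes`
#'   (px^3), `long_axes`, `short_axes`.
#' @export
volume_trace <- function(long_axes, short_axes, times) {
  n <- length(times)
  if (n == 0) stop("empty input", call. = FALSE)
  stopifnot(length(long_axes) == n, length(short_axes) == n)
  structure(list(times = as.numeric(times),
                 volumes = ellipsoid_volume(long_axes, short_axes),
                 long_axes = as.numeric(long_axes),
                 short_axes = as.numeric(short_axes)),
            class = "volume_trace")
}

#' @export
print.volume_trace <- function(x, ...) {
  cat(sprintf("<volume_trace> %d frames, volume %.1f..%.1f px^3\n",
              length(x$times), min(x$volumes), max(x$volumes)))
  invisible(x)
}

#' Volumetric cardiac endpoints from a chamber volume trace
#'
#' End-diastolic volume (EDV) is the maximal and end-systolic volume (ESV)
#' the minimal chamber volume — in the default `global` mode over the whole
#' recording, in `per_beat` mode averaged over individual beats delimited
#' by consecutive diastole peaks. Derived endpoints:
#' stroke volume `SV = EDV - ESV`; ejection fraction
#' `EF = SV / EDV * 100`; fractional shortening
#' `FS = (S_d - S_s) / S_d * 100` on the short axis at the EDV and ESV
#' frames (echocardiographic convention; set `fs_axis = "long"` to use the
#' long axis); cardiac output `CO = SV * hr_bpm` (px^3 per minute).
#' When `body_size` is given, `normalized_stroke_volume` and
#' `normalized_cardiac_output` divide by `body_size ^ norm_exponent`
#' (default 3, making normalized volumes dimensionless).
#'
#' @param vtrace A [volume_trace()].
#' @param hr_bpm Heart rate in beats/min.
#' @param beats Optional `beat_series`, required for `mode = "per_beat"`.
#' @param body_size Body length in px for normalization (optional).
#' @param mode `"global"` (default) or `"per_beat"`.
#' @param norm_exponent Exponent applied to `body_size` (1 or 3;
#'   default 3).
#' @param fs_axis Axis used for fractional shortening, `"short"` (default)
#'   or `"long"`.
#' @return An object of class `cardiac_endpoints`: list with `edv`, `esv`,
#'   `stroke_volume`, `ejection_fraction_pct`, `fractional_shortening_pct`,
#'   `cardiac_output`, `hr_bpm`, `normalized_stroke_volume`,
#'   `normalized_cardiac_output` (NA when no `body_size`), `mode`.
#' @export
endpoints <- function(vtrace, hr_bpm, beats = NULL, body_size = NULL,
                      mode = c("global", "per_beat"), norm_exponent = 3,
                      fs_axis = c("short", "long")) {
  mode <- match.arg(mode)
  fs_axis <- match.arg(fs_axis)
  stopifnot(inherits(vtrace, "volume_trace"), hr_bpm > 0,
            norm_exponent %in% c(1, 3))
  if (!is.null(body_size)) stopifnot(body_size > 0)

  axis_vec <- if (fs_axis == "short") vtrace$short_axes else vtrace$long_axes

  one_window <- function(sel) {
    vol <- vtrace$volumes[sel]
    i_ed <- sel[which.max(vol)]
    i_es <- sel[which.min(vol)]
    c(edv = vtrace$volumes[i_ed], esv = vtrace$volumes[i_es],
      ax_d = axis_vec[i_ed], ax_s = axis_vec[i_es])
  }

  if (mode == "global") {
    w <- one_window(seq_along(vtrace$volumes))
  } else {
    if (is.null(beats)) {
      stop("per_beat mode requires a beat_series", call. = FALSE)
    }
    idx <- beats$peak_indices
    per <- vapply(seq_len(length(idx) - 1), function(i) {
      one_window(idx[i]:idx[i + 1])
    }, numeric(4))
    w <- rowMeans(per)
  }

  edv <- unname(w["edv"]); esv <- unname(w["esv"])
  if (edv == 0) stop("EDV is zero", call. = FALSE)
  sv <- edv - esv
  fs <- (w[["ax_d"]] - w[["ax_s"]]) / w[["ax_d"]] * 100
  norm <- if (is.null(body_size)) NA_real_ else body_size^norm_exponent
  structure(list(
    edv = edv, esv = esv, stroke_volume = sv,
    ejection_fraction_pct = sv / edv * 100,
    fractional_shortening_pct = fs,
    cardiac_output = sv * hr_bpm,
    hr_bpm = hr_bpm,
    normalized_stroke_volume = sv / norm,
    normalized_cardiac_output = sv * hr_bpm / norm,
    body_size = if (is.null(body_size)) NA_real_ else body_size,
    norm_exponent = norm_exponent, fs_axis = fs_axis, mode = mode
  ), class = "cardiac_endpoints")
}

#' @export
print.cardiac_endpoints <- function(x, ...) {
  cat(sprintf("<cardiac_endpoints> (%s mode)\n", x$mode))
  cat(sprintf("  EDV %.1f  ESV %.1f  SV %.1f px^3\n", x$edv, x$esv,
              x$stroke_volume))
  cat(sprintf("  EF %.1f%%  FS %.1f%% (%s axis)  CO %.1f px^3/min at %.1f bpm\n",
              x$ejection_fraction_pct, x$fractional_shortening_pct,
              x$fs_axis, x$cardiac_output, x$hr_bpm))
  if (!is.na(x$normalized_stroke_volume)) {
    cat(sprintf("  normalized SV %.3g, CO %.3g (body size %g, exponent %d)\n",
                x$normalized_stroke_volume, x$normalized_cardiac_output,
                x$body_size, x$norm_exponent))
  }
  invisible(x)
}
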