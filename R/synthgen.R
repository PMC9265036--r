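#' Ground-truth parameters of a synthetic beating heart
#'
#' A `beat_config` fixes every parameter of the synthetic recording: frame
#' geometry, the diastolic ellipse of the heart chamber, the contraction
#' depth, the beat frequency, and the acquisition settings. Defaults emulate
#' the recording conditions the pipeline targets: a single immobilized water
#' flea filmed for 10 s at 200 fps, with the chamber beating in the 3-8 Hz
#' physiological range.
#'
#' Both ellipse axes contract by the same factor, so the true ejection
#' fraction and fractional shortening are available in closed form:
#' `EF = (1 - (1 - c)^3) * 100` and `FS = 100 * c`, where `c` is
#' `contraction_fraction`.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' `x` = column and `y` = row; all modules of the package share this
#' convention.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param center_x,center_y Chamber center, pixels (0-based pixel centers).
#' @param diastolic_major,diastolic_minor Full axis lengths (diameters, px)
#'   at maximal relaxation.
#' @param contraction_fraction Fraction of each axis lost at peak systole,
#'   in (0, 1). Systolic axis = diastolic axis * (1 - contraction_fraction).
#' @param beat_freq Beat frequency in Hz; must satisfy the Nyquist bound
#'   `beat_freq < fps / 2`.
#' @param phase Phase of the axis oscillation in radians. The default
#'   `-pi/2` puts full diastole at t = 0.
#' @param fps Frame rate, frames per second.
#' @param duration_s Recording duration in seconds.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (intensity units on the 0-255 scale); applied to frames only, never to
#'   masks.
#' @param fg_level,bg_level Chamber and background intensity (0-255).
#' @param orientation_deg Major-axis orientation, degrees in [0, 180),
#'   measured from the +x axis toward +y.
#' @param body_length Animal body length in pixels, used only for body-size
#'   normalization of volumetric endpoints.
#' @param seed Integer seed governing the frame noise.
#'
#' @return An object of class `beat_config` (a validated list).
#' @seealso [axes_at()], [generate_sequence()]
#' @export
beat_config <- function(frame_height = 128, frame_width = 128,
                        center_x = 63.5, center_y = 63.5,
                        diastolic_major = 60, diastolic_minor = 36,
                        contraction_fraction = 0.2,
                        beat_freq = 7.5, phase = -pi / 2,
                        fps = 200, duration_s = 10,
                        noise_sd = 10, fg_level = 200, bg_level = 50,
                        orientation_deg = 0, body_length = 120,
                        seed = 1L) {
  cfg <- list(
    frame_height = frame_height, frame_width = frame_width,
    center_x = center_x, center_y = center_y,
    diastolic_major = diastolic_major, diastolic_minor = diastolic_minor,
    contraction_fraction = contraction_fraction,
    beat_freq = beat_freq, phase = phase,
    fps = fps, duration_s = duration_s,
    noise_sd = noise_sd, fg_level = fg_level, bg_level = bg_level,
    orientation_deg = orientation_deg %% 180, body_length = body_length,
    seed = as.integer(seed)
  )
  validate_beat_config(cfg)
  structure(cfg, class = "beat_config")
}

validate_beat_config <- function(cfg) {
  stopifnot(
    cfg$fps > 0, cfg$duration_s > 0,
    cfg$contraction_fraction > 0, cfg$contraction_fraction < 1,
    cfg$diastolic_major >= cfg$diastolic_minor, cfg$diastolic_minor > 0,
    cfg$noise_sd >= 0, cfg$body_length > 0
  )
  if (cfg$beat_freq >= cfg$fps / 2) {
    stop("beat_freq must be below the Nyquist frequency fps/2", call. = FALSE)
  }
  if (cfg$fg_level == cfg$bg_level) {
    stop("fg_level and bg_level must differ", call. = FALSE)
  }
  # the diastolic (largest) ellipse must fit inside the frame at any rotation
  th <- cfg$orientation_deg * pi / 180
  a <- cfg$diastolic_major / 2
  b <- cfg$diastolic_minor / 2
  wx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  wy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  if (cfg$center_x - wx < 0 || cfg$center_x + wx > cfg$frame_width - 1 ||
      cfg$center_y - wy < 0 || cfg$center_y + wy > cfg$frame_height - 1) {
    stop("diastolic ellipse does not fit inside the frame", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.beat_config <- function(x, ...) {
  cat(sprintf(
    "<beat_config> %dx%d px, %g fps x %g s, beat %g Hz, contraction %g\n",
    x$frame_width, x$frame_height, x$fps, x$duration_s,
    x$beat_freq, x$contraction_fraction
  ))
  cat(sprintf(
    "  diastolic axes %g x %g px at (%g, %g), orientation %g deg, seed %d\n",
    x$diastolic_major, x$diastolic_minor, x$center_x, x$center_y,
    x$orientation_deg, x$seed
  ))
  invisible(x)
}

#' True ellipse axes of the synthetic chamber at a time point
#'
#' The axis timecourse is sinusoidal with both axes scaled by the same
#' factor:
#' `axis(t) = diastolic_axis * (1 - c * (1 + sin(2*pi*f*t + phase)) / 2)`
#' so each axis oscillates between its diastolic value (at the sine minima)
#' and `diastolic_axis * (1 - c)` (at the sine maxima, full systole).
#'
#' @param config A [beat_config()].
#' @param t Time(s) in seconds, `t >= 0`; vectorized.
#' @return A list with numeric vectors `major` and `minor` (full axis
#'   lengths, px).
#' @export
axes_at <- function(config, t) {
  stopifnot(inherits(config, "beat_config"), all(t >= 0))
  s <- 1 - config$contraction_fraction *
    (1 + sin(2 * pi * config$beat_freq * t + config$phase)) / 2
  list(major = config$diastolic_major * s,
       minor = config$diastolic_minor * s)
}

# inside-ellipse test on the shared 0-based pixel-center grid; xg/yg are
# matrices of pixel-center coordinates
ellipse_mask <- function(xg, yg, cx, cy, major, minor, theta_rad) {
  dx <- xg - cx
  dy <- yg - cy
  u <- dx * cos(theta_rad) + dy * sin(theta_rad)
  v <- -dx * sin(theta_rad) + dy * cos(theta_rad)
  m <- (u / (major / 2))^2 + (v / (minor / 2))^2 <= 1
  storage.mode(m) <- "integer"
  m
}

#' Generate a synthetic beating-heart recording with ground truth
#'
#' Renders the frame and mask sequences defined by a [beat_config()]: each
#' frame is a `bg_level` background with a `fg_level` ellipse whose axes
#' follow [axes_at()], rotated by `orientation_deg`, plus zero-mean Gaussian
#' noise (`noise_sd`, seeded, clipped to [0, 255]). Each mask is the
#' noise-free rasterized ellipse (a pixel is foreground iff its center
#' satisfies the ellipse inequality). Two runs with the same seed are
#' identical; runs with different seeds differ only in frame noise, never in
#' masks.
#'
#' @param config A [beat_config()].
#' @return A list of class `beat_sequence` with components
#'   \describe{
#'     \item{frames}{list of `frame_height x frame_width` intensity matrices
#'       (0-255).}
#'     \item{masks}{list of binary integer matrices aligned 1:1 with frames.}
#'     \item{timestamps}{seconds, `(0:(n-1)) / fps`.}
#'     \item{truth_axes}{`n x 2` matrix of true (major, minor) full axis
#'       lengths per frame.}
#'     \item{truth_area}{analytic ellipse area `pi * major * minor / 4` per
#'       frame.}
#'     \item{config}{the generating `beat_config`.}
#'   }
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "beat_config"))
  n <- round(config$fps * config$duration_s)
  ts <- (seq_len(n) - 1) / config$fps
  ax <- axes_at(config, ts)
  th <- config$orientation_deg * pi / 180

  xg <- matrix(rep(0:(config$frame_width - 1), each = config$frame_height),
               nrow = config$frame_height)
  yg <- matrix(rep(0:(config$frame_height - 1), config$frame_width),
               nrow = config$frame_height)

  masks <- vector("list", n)
  frames <- vector("list", n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  for (i in seq_len(n)) {
    m <- ellipse_mask(xg, yg, config$center_x, config$center_y,
                      ax$major[i], ax$minor[i], th)
    f <- config$bg_level + (config$fg_level - config$bg_level) * m
    if (config$noise_sd > 0) {
      f <- f + matrix(stats::rnorm(length(m), sd = config$noise_sd),
                      nrow = nrow(m))
    }
    masks[[i]] <- m
    frames[[i]] <- pmin(pmax(f, 0), 255)
  }
  structure(
    list(frames = frames, masks = masks, timestamps = ts,
         truth_axes = cbind(major = ax$major, minor = ax$minor),
         truth_area = pi * ax$major * ax$minor / 4,
         config = config),
    class = "beat_sequence"
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.beat_sequence <- function(x, ...) {
  cat(sprintf("<beat_sequence> %d frames (%dx%d px) at %g fps, %g s\n",
              length(x$frames), x$config$frame_width,
              x$config$frame_height, x$config$fps, x$config$duration_s))
  invisible(x)
}

#' Inject controlled errors into a binary mask
#'
#' Degradation modes for testing segmentation metrics against known error
#' structure: `dilate_px` grows the foreground (adds only false positives
#' with respect to the original), `erode_px` shrinks it (adds only false
#' negatives), and `flip_rate` flips each pixel independently with
#' probability `amount`.
#'
#' @param mask Binary matrix.
#' @param mode One of `"dilate_px"`, `"erode_px"`, `"flip_rate"`.
#' @param amount Non-negative; pixels for the morphological modes (integer),
#'   per-pixel flip probability for `flip_rate`.
#' @param seed Seed for `flip_rate` (ignored by the deterministic modes).
#' @return A binary integer matrix of the same shape.
#' @export
degrade_mask <- function(mask, mode = c("dilate_px", "erode_px", "flip_rate"),
                         amount, seed = 1L) {
  mode <- match.arg(mode)
  mask <- as_binary_mask(mask)
  if (amount < 0) stop("amount must be non-negative", call. = FALSE)
  if (amount == 0) return(mask)
  out <- switch(mode,
    dilate_px = {
      brush <- EBImage::makeBrush(2 * as.integer(amount) + 1, shape = "box")
      em <- EBImage::dilate(mask, brush)
      matrix(as.integer(em > 0), nrow = nrow(mask))
    },
    erode_px = {
      brush <- EBImage::makeBrush(2 * as.integer(amount) + 1, shape = "box")
      em <- EBImage::erode(mask, brush)
      matrix(as.integer(em > 0), nrow = nrow(mask))
    },
    flip_rate = {
      stopifnot(amount <= 1)
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit(restore_seed(old_seed), add = TRUE)
      set.seed(seed)
      flips <- matrix(stats::runif(length(mask)) < amount, nrow = nrow(mask))
      matrix(as.integer(xor(mask > 0, flips)), nrow = nrow(mask))
    }
  )
  out
}

as_binary_mask <- function(mask) {
  if (!all(mask %in% c(0, 1))) {
    stop("mask must be binary {0,1}", call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  mask
}

#' Write a synthetic sequence to disk as numbered PNGs
#'
#' Frames go to `frame_0000.png`, `frame_0001.png`, ... and masks to
#' `mask_0000.png`, ...; the generating parameters and per-frame true axes
#' are written to a `truth.csv` sidecar.
#'
#' @param seq A `beat_sequence` from [generate_sequence()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "beat_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_frames(seq$frames, dir, prefix = "frame")
  save_masks(seq$masks, dir, prefix = "mask")
  truth <- data.frame(
    frame_index = seq_along(seq$frames) - 1L,
    time_s = seq$timestamps,
    true_major_px = seq$truth_axes[, "major"],
    true_minor_px = seq$truth_axes[, "minor"],
    true_area_px2 = seq$truth_area
  )
  cfg_line <- paste0("# config: ", config_fingerprint_string(seq$config))
  path <- file.path(dir, "truth.csv")
  writeLines(cfg_line, path)
  suppressWarnings(utils::write.table(truth, path, sep = ",", row.names = FALSE,
                                      col.names = TRUE, append = TRUE))
  invisible(dir)
}
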