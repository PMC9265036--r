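#' Classical threshold segmentation baseline
#'
#' Segmentation backend that needs no training: forms a binary mask of
#' pixels above an Otsu-derived or fixed intensity threshold, then keeps
#' the largest connected component. On a bright chamber over a darker body
#' this recovers the chamber mask; it stands behind the same mask-sequence
#' interface that externally produced (e.g. network-predicted) masks use.
#'
#' @param frame Grayscale intensity matrix (0-255).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level Threshold for `method = "fixed"` (0-255 scale).
#' @param connectivity Passed to [largest_component()].
#' @return Binary integer matrix.
#' @export
threshold_segment <- function(frame, method = c("otsu", "fixed"),
                              level = NULL, connectivity = 8) {
  method <- match.arg(method)
  if (diff(range(frame)) == 0 && method == "otsu") {
    stop("degenerate threshold: frame is constant", call. = FALSE)
  }
  thr <- switch(method,
    otsu = EBImage::otsu(frame / 255, range = c(0, 1), levels = 256) * 255,
    fixed = {
      if (is.null(level)) stop("fixed method needs a level", call. = FALSE)
      level
    }
  )
  raw <- matrix(as.integer(frame > thr), nrow = nrow(frame))
  if (sum(raw) == 0) stop("threshold produced an empty mask", call. = FALSE)
  largest_component(raw, connectivity)
}

# ---- PNG series I/O --------------------------------------------------------

#' Save frames / masks as zero-padded numbered PNG files
#'
#' Frames are written as 8-bit grayscale (`prefix_0000.png`, ...). Masks
#' are written with foreground = 255.
#'
#' @param frames,masks Lists of matrices (frames 0-255, masks binary).
#' @param dir Target directory, created if needed.
#' @param prefix File name prefix (default `"frame"` / `"mask"`).
#' @return `dir`, invisibly.
#' @export
save_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    png::writePNG(pmin(pmax(frames[[i]] / 255, 0), 1),
                  file.path(dir, sprintf("%s_%04d.png", prefix, i - 1L)))
  }
  invisible(dir)
}

#' @rdname save_frames
#' @export
save_masks <- function(masks, dir, prefix = "mask") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(masks)) {
    png::writePNG(matrix(as.numeric(masks[[i]] > 0), nrow = nrow(masks[[i]])),
                  file.path(dir, sprintf("%s_%04d.png", prefix, i - 1L)))
  }
  invisible(dir)
}

# list numbered PNGs, ordered by their numeric index; fails listing any gaps
indexed_pngs <- function(dir, prefix) {
  files <- list.files(dir, pattern = paste0("^", prefix, "_\\d+\\.png$"))
  if (length(files) == 0) {
    stop(sprintf("no '%s_NNNN.png' files in %s", prefix, dir), call. = FALSE)
  }
  idx <- as.integer(sub(paste0("^", prefix, "_(\\d+)\\.png$"), "\\1", files))
  ord <- order(idx)
  idx <- idx[ord]; files <- files[ord]
  expected <- seq(min(idx), max(idx))
  missing <- setdiff(expected, idx)
  if (length(missing)) {
    stop(sprintf("missing frame indices: %s",
                 paste(utils::head(missing, 20), collapse = ", ")),
         call. = FALSE)
  }
  file.path(dir, files)
}

#' Load a numbered PNG frame series
#'
#' Files named `prefix_NNNN.png` are ordered by numeric index; gaps in the
#' index sequence are an error (the missing indices are listed). Frames
#' are returned as 0-255 intensity matrices; color PNGs are converted to
#' grayscale by channel averaging.
#'
#' @param dir Directory containing the series.
#' @param prefix File name prefix (default `"frame"`).
#' @return List of intensity matrices of one common shape.
#' @export
load_frames <- function(dir, prefix = "frame") {
  paths <- indexed_pngs(dir, prefix)
  frames <- lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    a * 255
  })
  check_common_shape(frames)
  frames
}

#' Load a numbered PNG mask series
#'
#' Same ordering and gap rules as [load_frames()]. Single-channel masks
#' are binarized at 128 (of 255); multi-channel mask files are collapsed
#' by the any-channel-nonzero rule (a pixel is foreground iff any channel
#' is nonzero).
#'
#' @inheritParams load_frames
#' @return List of binary integer matrices.
#' @export
load_masks <- function(dir, prefix = "mask") {
  paths <- indexed_pngs(dir, prefix)
  masks <- lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 3) {
      m <- apply(a, c(1, 2), function(v) any(v > 0))
      matrix(as.integer(m), nrow = dim(a)[1])
    } else {
      matrix(as.integer(a * 255 >= 128), nrow = nrow(a))
    }
  })
  check_common_shape(masks)
  masks
}

check_common_shape <- function(mats) {
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) > 1) {
    stop("inconsistent frame shapes across the series", call. = FALSE)
  }
  invisible(mats)
}

# ---- provenance-stamped CSV ------------------------------------------------

config_fingerprint_string <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Write a data.frame as CSV with provenance header lines
#'
#' Header comment lines (prefixed `#`) carry the run-configuration
#' fingerprint and any free-form metadata, so every output file records
#' the parameters that produced it. Read back with [read_csv_header()].
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param meta Named character/numeric vector written as `# key: value`
#'   lines.
#' @return `path`, invisibly.
#' @export
write_csv_stamped <- function(df, path, meta = c()) {
  lines <- c(sprintf("# %s: %s", names(meta), as.character(meta)))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (length(meta)) writeLines(lines, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_csv_stamped
#' @export
read_csv_header <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
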