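#' Labeled image: grayscale frame plus binary chamber mask
#'
#' @param image Grayscale intensity matrix (0-255).
#' @param mask Binary matrix of the same shape.
#' @param source_id Identifier string carried through splitting and
#'   augmentation.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(image, mask, source_id = "") {
  mask <- as_binary_mask(mask)
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask must share one shape", call. = FALSE)
  }
  structure(list(image = image, mask = mask, source_id = source_id),
            class = "labeled_image")
}

#' Select frames at a fixed interval
#'
#' Picks frames at indices 0, `interval`, `2 * interval`, ... (0-based),
#' the standard way a handful of stills is pulled from a heartbeat video
#' for labeling. A 2000-frame recording sampled every 200 frames yields 10
#' stills.
#'
#' @param frames List of frames (or a `beat_sequence`, whose frames are
#'   used).
#' @param interval Sampling stride in frames, `>= 1`.
#' @param count Maximum number of frames to return; `Inf` takes every
#'   available index. If fewer than `count` are available, all are returned
#'   with a warning.
#' @return A list of frames.
#' @export
extract_frames <- function(frames, interval, count = Inf) {
  if (inherits(frames, "beat_sequence")) frames <- frames$frames
  n <- length(frames)
  if (n == 0) stop("empty sequence", call. = FALSE)
  stopifnot(interval >= 1, count >= 1)
  idx0 <- seq(0L, n - 1L, by = as.integer(interval))
  if (is.finite(count) && length(idx0) > count) {
    idx0 <- idx0[seq_len(count)]
  } else if (is.finite(count) && length(idx0) < count) {
    warning(sprintf("only %d frames available at interval %d (requested %d)",
                    length(idx0), as.integer(interval), as.integer(count)))
  }
  frames[idx0 + 1L]
}

#' Split labeled images into training and validation sets
#'
#' Seeded random partition: `n_val` items go to validation, the rest to
#' training. The union of the two sets is exactly the input and they are
#' disjoint.
#'
#' @param items List of [labeled_image()] objects.
#' @param n_val Number of validation items, `0 < n_val < length(items)`.
#' @param seed Integer seed for the shuffle.
#' @return A list of class `dataset_split` with elements `train` and `val`.
#' @export
split_dataset <- function(items, n_val, seed = 1L) {
  n <- length(items)
  if (n_val <= 0 || n_val >= n) {
    stop("n_val must satisfy 0 < n_val < number of items", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  val_idx <- sample.int(n, n_val)
  structure(list(train = items[-val_idx], val = items[val_idx]),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / val %d\n",
              length(x$train), length(x$val)))
  invisible(x)
}

# ---- geometric resampling --------------------------------------------------
# All geometric transforms share one inverse-map bilinear resampler so an
# image and its mask always receive the same geometry. src_x/src_y give, for
# every output pixel (0-based coordinates), the source location to sample.
resample_bilinear <- function(img, src_x, src_y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(src_x); y0 <- floor(src_y)
  fx <- src_x - x0;   fy <- src_y - y0

  pick <- function(xx, yy) {
    ok <- xx >= 0 & xx <= (w - 1) & yy >= 0 & yy <= (h - 1)
    v <- rep(fill, length(xx))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v00 <- pick(x0, y0);     v10 <- pick(x0 + 1, y0)
  v01 <- pick(x0, y0 + 1); v11 <- pick(x0 + 1, y0 + 1)
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  matrix(out, nrow = h)
}

out_grid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), nrow = h),
       y = matrix(rep(0:(h - 1), w), nrow = h))
}

# smooth displacement field: coarse seeded offsets bilinearly upsampled to
# full resolution; max_disp caps the absolute displacement in pixels
smooth_field <- function(h, w, grid_n, max_disp) {
  coarse <- function() {
    g <- matrix(stats::runif((grid_n + 2)^2, -1, 1), nrow = grid_n + 2)
    # upsample coarse grid to h x w by bilinear interpolation
    gx <- seq(0, grid_n + 1, length.out = w)
    gy <- seq(0, grid_n + 1, length.out = h)
    x0 <- pmin(floor(gx), grid_n); y0 <- pmin(floor(gy), grid_n)
    fx <- gx - x0; fy <- gy - y0
    up <- outer(1 - fy, 1 - fx) * g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))] +
      outer(1 - fy, fx) * g[cbind(rep(y0 + 1, w), rep(x0 + 2, each = h))] +
      outer(fy, 1 - fx) * g[cbind(rep(y0 + 2, w), rep(x0 + 1, each = h))] +
      outer(fy, fx) * g[cbind(rep(y0 + 2, w), rep(x0 + 2, each = h))]
    matrix(up, nrow = h)
  }
  list(dx = coarse() * max_disp, dy = coarse() * max_disp)
}

# apply one named augmentation op; geometric ops warp image and mask through
# the same source coordinates, photometric ops touch the image only
apply_aug_op <- function(item, op, fill) {
  img <- item$image; msk <- item$mask
  h <- nrow(img); w <- ncol(img)
  geom <- function(src_x, src_y) {
    img2 <- resample_bilinear(img, src_x, src_y, fill = fill)
    msk2 <- resample_bilinear(msk, src_x, src_y, fill = 0)
    list(image = img2, mask = matrix(as.integer(msk2 >= 0.5), nrow = h))
  }
  res <- switch(op,
    hflip = list(image = img[, w:1, drop = FALSE],
                 mask = msk[, w:1, drop = FALSE]),
    vflip = list(image = img[h:1, , drop = FALSE],
                 mask = msk[h:1, , drop = FALSE]),
    rotate = {
      ang <- stats::runif(1, -15, 15) * pi / 180
      g <- out_grid(h, w)
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      dx <- g$x - cx; dy <- g$y - cy
      geom(cx + cos(ang) * dx - sin(ang) * dy,
           cy + sin(ang) * dx + cos(ang) * dy)
    },
    crop = {
      frac <- stats::runif(1, 0.8, 0.95)
      ch <- max(2, round(h * frac)); cw <- max(2, round(w * frac))
      oy <- sample.int(h - ch + 1, 1) - 1
      ox <- sample.int(w - cw + 1, 1) - 1
      g <- out_grid(h, w)
      geom(ox + g$x / (w - 1) * (cw - 1),
           oy + g$y / (h - 1) * (ch - 1))
    },
    brightness_contrast = {
      alpha <- stats::runif(1, 0.8, 1.2)
      beta <- stats::runif(1, -20, 20)
      mu <- mean(img)
      list(image = pmin(pmax(alpha * (img - mu) + mu + beta, 0), 255),
           mask = msk)
    },
    elastic = {
      f <- smooth_field(h, w, grid_n = 8, max_disp = 0.05 * min(h, w))
      g <- out_grid(h, w)
      geom(g$x + f$dx, g$y + f$dy)
    },
    grid_distort = {
      f <- smooth_field(h, w, grid_n = 4, max_disp = 0.05 * min(h, w))
      g <- out_grid(h, w)
      geom(g$x + f$dx, g$y + f$dy)
    },
    optical_distort = {
      k <- stats::runif(1, -0.3, 0.3)
      g <- out_grid(h, w)
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      dx <- (g$x - cx) / cx; dy <- (g$y - cy) / cy
      r2 <- dx^2 + dy^2
      geom(cx + dx * (1 + k * r2) * cx, cy + dy * (1 + k * r2) * cy)
    },
    stop(sprintf("unknown augmentation op '%s'", op), call. = FALSE)
  )
  labeled_image(res$image, res$mask, item$source_id)
}

#' Augment a labeled image into n paired variants
#'
#' Each replicate samples one operation from `ops` (with seeded random
#' parameters where the op has any) and applies it: geometric transforms are
#' applied identically to the image and its mask through a shared resampler,
#' photometric transforms to the image only. Masks are re-binarized at 0.5
#' after interpolation, so every output mask is binary and shape is
#' preserved.
#'
#' @param item A [labeled_image()].
#' @param n_aug Number of augmented outputs (default 15).
#' @param ops Character vector drawn from `hflip`, `vflip`, `rotate`,
#'   `crop`, `brightness_contrast`, `elastic`, `grid_distort`,
#'   `optical_distort`.
#' @param seed Integer seed; the same seed reproduces the same outputs.
#' @param fill Image fill value for pixels mapped from outside the frame
#'   (background level); mask fill is always 0.
#' @return A list of `n_aug` [labeled_image()] objects.
#' @export
augment <- function(item, n_aug = 15,
                    ops = c("hflip", "vflip", "rotate", "crop",
                            "brightness_contrast", "elastic",
                            "grid_distort", "optical_distort"),
                    seed = 1L, fill = 0) {
  stopifnot(inherits(item, "labeled_image"), n_aug >= 1, length(ops) >= 1)
  known <- c("hflip", "vflip", "rotate", "crop", "brightness_contrast",
             "elastic", "grid_distort", "optical_distort")
  bad <- setdiff(ops, known)
  if (length(bad)) {
    stop(sprintf("unknown augmentation op '%s'", bad[1]), call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_aug), function(i) {
    op <- ops[[sample.int(length(ops), 1)]]
    apply_aug_op(item, op, fill = fill)
  })
}

#' Augment every item of a dataset, with bookkeeping
#'
#' @param items List of [labeled_image()] objects.
#' @param n_aug Augmentations per item.
#' @param ops,fill Passed to [augment()].
#' @param seed Base seed; item `i` uses `seed + i - 1` so the whole run is
#'   reproducible while items get independent draws.
#' @return A flat list of `length(items) * n_aug` labeled images.
#' @export
augment_dataset <- function(items, n_aug = 15,
                            ops = c("hflip", "vflip", "rotate", "crop",
                                    "brightness_contrast", "elastic",
                                    "grid_distort", "optical_distort"),
                            seed = 1L, fill = 0) {
  out <- lapply(seq_along(items), function(i) {
    augment(items[[i]], n_aug = n_aug, ops = ops, seed = seed + i - 1L,
            fill = fill)
  })
  unlist(out, recursive = FALSE)
}
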