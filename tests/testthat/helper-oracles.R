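# Independent brute-force oracles, kept deliberately naive: plain loops and
# textbook definitions, no shared code with the implementation paths they
# check.

# per-pixel four-way confusion tally
oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] > 0
      t <- truth[i, j] > 0
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# recursive flood fill census of component sizes
oracle_component_sizes <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  sizes <- integer(0)
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (mask[r0, c0] > 0 && !seen[r0, c0]) {
      sz <- 0L
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack)) {
        cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        sz <- sz + 1L
        for (k in seq_along(dr)) {
          r <- cur[1] + dr[k]; c <- cur[2] + dc[k]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              mask[r, c] > 0 && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
      sizes <- c(sizes, sz)
    }
  }
  sizes
}

# boundary pixels: foreground with at least one background 8-neighbor
# (frame border counts as background)
oracle_boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pts <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] > 0) {
      bg <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w || mask[rr, cc] == 0) {
          bg <- TRUE
        }
      }
      if (bg) pts <- rbind(pts, c(x = c - 1L, y = r - 1L))
    }
  }
  pts
}

# rotated-coordinate Poincare definition
oracle_poincare <- function(x) {
  n <- length(x)
  u <- (x[2:n] - x[1:(n - 1)]) / sqrt(2)
  v <- (x[2:n] + x[1:(n - 1)]) / sqrt(2)
  list(sd1 = sd(u), sd2 = sd(v))
}

# exact points on an ellipse (full axes major/minor, angle degrees)
ellipse_points <- function(n, cx, cy, major, minor, angle_deg) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  a <- major / 2; b <- minor / 2; ang <- angle_deg * pi / 180
  cbind(x = cx + a * cos(th) * cos(ang) - b * sin(th) * sin(ang),
        y = cy + a * cos(th) * sin(ang) + b * sin(th) * cos(ang))
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# small fast beat config for tests; beat_freq adapts to low test fps
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(frame_height = 96, frame_width = 96, center_x = 47.5,
                   center_y = 47.5, diastolic_major = 56,
                   diastolic_minor = 34, noise_sd = 0)
  if (!is.null(args$fps) && is.null(args$beat_freq) && args$fps <= 16) {
    defaults$beat_freq <- args$fps / 5
  }
  do.call(beat_config, utils::modifyList(defaults, args))
}
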