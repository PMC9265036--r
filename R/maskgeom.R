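#' Keep only the largest connected component of a binary mask
#'
#' Noise-suppression step before contour tracing: retains the connected
#' foreground component with the most pixels. Ties are broken by the
#' component containing the smallest row-major pixel index (rows scanned
#' top to bottom, columns left to right).
#'
#' @param mask Binary matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return Binary integer matrix with a single component.
#' @export
largest_component <- function(mask, connectivity = 8) {
  mask <- as_binary_mask(mask)
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask > 0)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  k <- length(idx)
  imap <- integer(h * w)
  imap[idx] <- seq_len(k)
  row <- (idx - 1L) %% h + 1L
  col <- (idx - 1L) %/% h + 1L

  # candidate neighbor offsets in column-major linear indexing
  offs <- list(
    list(d = h, ok = col < w),                 # right
    list(d = 1L, ok = row < h)                 # down
  )
  if (connectivity == 8) {
    offs <- c(offs, list(
      list(d = h + 1L, ok = col < w & row < h),   # down-right
      list(d = h - 1L, ok = col < w & row > 1L)   # up-right
    ))
  }
  edges <- lapply(offs, function(o) {
    from <- idx[o$ok]
    to <- from + o$d
    keep <- imap[to] > 0L
    cbind(imap[from[keep]], imap[to[keep]])
  })
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) {
    g <- igraph::add_edges(g, t(el))
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    rowmajor <- (row - 1L) * w + (col - 1L)
    first_px <- vapply(best, function(b) {
      min(rowmajor[comp$membership == b])
    }, numeric(1))
    best <- best[which.min(first_px)]
  }
  out <- matrix(0L, h, w)
  out[idx[comp$membership == best]] <- 1L
  out
}

# clockwise Moore neighborhood offsets (x right, y down): E SE S SW W NW N NE
.moore_dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.moore_dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Trace the closed boundary contour of a single-component mask
#'
#' Moore-neighbor boundary following with 8-connected foreground, starting
#' at the first foreground pixel in row-major order and terminating by
#' Jacob's criterion (re-entering the start pixel from the starting
#' direction). Every contour point is a foreground pixel with at least one
#' background 8-neighbor; the returned polygon is closed implicitly (last
#' point connects back to the first) and has no consecutive duplicates.
#'
#' @param mask Binary matrix with exactly one connected component (apply
#'   [largest_component()] first).
#' @return A matrix of class `contour` with columns `x`, `y` (0-based
#'   pixel coordinates, ordered along the boundary).
#' @export
extract_contour <- function(mask) {
  mask <- as_binary_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (sum(mask) == 0) stop("empty mask", call. = FALSE)
  fg <- function(x, y) {
    x >= 0 && x < w && y >= 0 && y < h && mask[y + 1, x + 1] > 0
  }
  # first foreground pixel in row-major scan
  rowmajor_lin <- which(t(mask) > 0)[1]          # t() gives row-major order
  sy <- (rowmajor_lin - 1L) %/% w
  sx <- (rowmajor_lin - 1L) %% w

  px <- sx; py <- sy
  bx <- sx - 1L; by <- sy                         # backtrack: W neighbor, background
  xs <- integer(0); ys <- integer(0)
  xs[1] <- sx; ys[1] <- sy
  n_pts <- 1L
  first_dir <- NA_integer_
  max_iter <- 4L * sum(mask) + 8L

  for (iter in seq_len(max_iter)) {
    # index of backtrack among the neighbors of p
    kdx <- bx - px; kdy <- by - py
    k <- which(.moore_dx == kdx & .moore_dy == kdy)
    found <- FALSE
    for (j in 1:8) {
      jj <- (k - 1L + j - 1L) %% 8L + 1L
      nx <- px + .moore_dx[jj]; ny <- py + .moore_dy[jj]
      if (fg(nx, ny)) {
        prev <- (jj - 2L) %% 8L + 1L
        bx <- px + .moore_dx[prev]; by <- py + .moore_dy[prev]
        px <- nx; py <- ny
        found <- TRUE
        if (iter == 1L) first_dir <- jj
        break
      }
      bx <- px + .moore_dx[jj]; by <- py + .moore_dy[jj]
    }
    if (!found) break                             # isolated pixel
    # Jacob's stopping criterion: back at start, leaving the same way
    if (px == sx && py == sy) {
      kdx2 <- bx - px; kdy2 <- by - py
      k2 <- which(.moore_dx == kdx2 & .moore_dy == kdy2)
      nj <- 0L
      for (j in 1:8) {
        jj <- (k2 - 1L + j - 1L) %% 8L + 1L
        if (fg(px + .moore_dx[jj], py + .moore_dy[jj])) { nj <- jj; break }
      }
      if (!is.na(first_dir) && nj == first_dir) break
    }
    n_pts <- n_pts + 1L
    xs[n_pts] <- px; ys[n_pts] <- py
  }
  # drop a duplicated closing start point if present
  if (n_pts > 1 && xs[n_pts] == sx && ys[n_pts] == sy) n_pts <- n_pts - 1L
  if (n_pts < 5) {
    stop("contour has fewer than 5 points; component too small for ellipse fitting",
         call. = FALSE)
  }
  structure(cbind(x = xs[seq_len(n_pts)], y = ys[seq_len(n_pts)]),
            class = c("contour", "matrix", "array"))
}

#' Direct least-squares ellipse fit (ellipse-constrained conic)
#'
#' Fits the conic `a x^2 + b xy + c y^2 + d x + e y + f = 0` minimizing
#' algebraic distance subject to the ellipse constraint
#' `4ac - b^2 = 1`, using the numerically stable block decomposition of the
#' direct method. Input points are pre-centered and isotropically scaled
#' before fitting, and the geometric parameters are mapped back, so the fit
#' is invariant to translation and well conditioned for pixel-scale
#' coordinates. The fit is deterministic and needs no initialization.
#'
#' @param contour A `contour` matrix from [extract_contour()], or any
#'   two-column matrix of (x, y) points; at least 5 non-collinear points.
#' @return An object of class `ellipse_fit`: list with `center_x`,
#'   `center_y`, `major_len`, `minor_len` (full axis lengths, px,
#'   `major_len >= minor_len`), `angle_deg` (major-axis direction in
#'   [0, 180), from +x toward +y), and `residual` (mean absolute algebraic
#'   distance of the normalized conic in scaled coordinates).
#' @export
fit_ellipse <- function(contour) {
  pts <- unclass(contour)
  if (!is.matrix(pts) || ncol(pts) < 2 || nrow(pts) < 5) {
    stop("need at least 5 (x, y) points", call. = FALSE)
  }
  x <- as.numeric(pts[, 1]); y <- as.numeric(pts[, 2])
  mx <- mean(x); my <- mean(y)
  s <- sqrt(mean((x - mx)^2 + (y - my)^2) / 2)
  if (s == 0) stop("degenerate point set", call. = FALSE)
  xs <- (x - mx) / s; ys <- (y - my) / s

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("degenerate (collinear) point configuration", call. = FALSE)
  })
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0) {
    stop("no ellipse solution (degenerate conic)", call. = FALSE)
  }
  a1 <- vecs[, ok[1]]
  coef <- c(a1, as.numeric(Tm %*% a1))      # A B C D E F in scaled coords

  geo <- conic_to_ellipse(coef)
  # undo the isotropic scaling and centering
  fit <- structure(list(
    center_x = geo$cx * s + mx,
    center_y = geo$cy * s + my,
    major_len = 2 * geo$a * s,
    minor_len = 2 * geo$b * s,
    angle_deg = geo$angle_deg,
    residual = mean(abs(cbind(D1, D2) %*% (coef / sqrt(sum(coef^2)))))
  ), class = "ellipse_fit")
  fit
}

# conic coefficients (A B C D E F) -> ellipse center, semi-axes a >= b,
# major-axis angle in [0, 180)
conic_to_ellipse <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; Ff <- p[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse", call. = FALSE)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  M0 <- matrix(c(Ff, D / 2, E / 2,
                 D / 2, A, B / 2,
                 E / 2, B / 2, C), 3, 3, byrow = TRUE)
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Mq, symmetric = TRUE)
  lam <- eg$values
  ratio <- -det(M0) / (det(Mq) * lam)
  if (any(ratio <= 0)) stop("conic is not a real ellipse", call. = FALSE)
  semi <- sqrt(ratio)                        # paired with lam
  i_major <- which.max(semi)
  v <- eg$vectors[, i_major]
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  list(cx = cx, cy = cy, a = max(semi), b = min(semi), angle_deg = ang)
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> center (%.2f, %.2f), axes %.2f x %.2f px, angle %.1f deg\n",
    x$center_x, x$center_y, x$major_len, x$minor_len, x$angle_deg))
  invisible(x)
}

#' Long and short chamber axes from a binary mask
#'
#' The composition [largest_component()] -> [extract_contour()] ->
#' [fit_ellipse()]: isolates the chamber, traces its boundary, and fits an
#' ellipse whose full axis lengths are the chamber's long axis `L` and
#' short axis `S`.
#'
#' Contour points are centers of boundary pixels and therefore sit on
#' average half a pixel inside the true region edge, biasing each fitted
#' semi-axis low by about 0.5 px. `edge_correction_px` (default 1, i.e.
#' half a pixel per side) is added to both full axis lengths to compensate;
#' set it to 0 for the raw fit.
#'
#' @param mask Binary matrix, non-empty.
#' @param connectivity Passed to [largest_component()].
#' @param edge_correction_px Full-axis rasterization-bias correction in
#'   pixels (default 1).
#' @return A list with `L`, `S` (px) and the full `fit` ([fit_ellipse()]
#'   object, uncorrected).
#' @export
axes_from_mask <- function(mask, connectivity = 8, edge_correction_px = 1) {
  comp <- largest_component(mask, connectivity)
  fit <- fit_ellipse(extract_contour(comp))
  list(L = fit$major_len + edge_correction_px,
       S = fit$minor_len + edge_correction_px,
       fit = fit)
}

#' Chamber cross-sectional area: foreground pixel count
#'
#' @param mask Binary matrix.
#' @return Number of foreground pixels (px^2).
#' @export
mask_area <- function(mask) {
  sum(as_binary_mask(mask) > 0)
}

#' Per-frame chamber geometry table
#'
#' Runs [axes_from_mask()] and [mask_area()] over a mask sequence,
#' producing the per-frame record that downstream rhythm and volumetric
#' analyses consume. The angle column is the major-axis direction in
#' degrees, [0, 180), measured from +x toward +y.
#'
#' @param masks List of binary matrices (or a `beat_sequence`, whose masks
#'   are used).
#' @param fps Frame rate (Hz) used to compute `time_s = frame_index / fps`.
#' @return data.frame with columns `frame_index`, `time_s`, `area_px2`,
#'   `long_axis_px`, `short_axis_px`, `center_x`, `center_y`, `angle_deg`.
#' @export
geometry_table <- function(masks, fps) {
  if (inherits(masks, "beat_sequence")) {
    fps <- masks$config$fps
    masks <- masks$masks
  }
  stopifnot(length(masks) > 0, fps > 0)
  rows <- lapply(seq_along(masks), function(i) {
    ax <- axes_from_mask(masks[[i]])
    data.frame(
      frame_index = i - 1L,
      time_s = (i - 1) / fps,
      area_px2 = mask_area(masks[[i]]),
      long_axis_px = ax$L,
      short_axis_px = ax$S,
      center_x = ax$fit$center_x,
      center_y = ax$fit$center_y,
      angle_deg = ax$fit$angle_deg
    )
  })
  do.call(rbind, rows)
}
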