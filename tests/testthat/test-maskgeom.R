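test_that("largest_component keeps the biggest blob and matches a flood-fill census", {
  m <- matrix(0L, 12, 12)
  m[2:8, 2:8] <- 1L                       # 49 px
  m[11, 11] <- 1L                         # 1 px speck
  out <- largest_component(m)
  expect_equal(sum(out), 49)
  expect_equal(out[11, 11], 0L)

  single <- matrix(0L, 6, 6); single[2:4, 3:5] <- 1L
  expect_identical(largest_component(single), single)

  set.seed(21)
  for (i in 1:15) {
    for (conn in c(4, 8)) {
      rm_ <- random_mask(15, 15, p = 0.35)
      if (sum(rm_) == 0) next
      out <- largest_component(rm_, connectivity = conn)
      expect_equal(sum(out), max(oracle_component_sizes(rm_, conn)))
      expect_equal(length(oracle_component_sizes(out, conn)), 1)
    }
  }
  expect_error(largest_component(matrix(0L, 4, 4)), "empty")
})

test_that("component ties break on the smallest row-major first pixel", {
  m <- matrix(0L, 8, 8)
  m[6, 2:4] <- 1L                         # 3 px, first pixel row-major idx 41
  m[2, 5:7] <- 1L                         # 3 px, first pixel row-major idx 12
  out <- largest_component(m)
  expect_equal(sum(out), 3)
  expect_equal(out[2, 5], 1L)
  expect_equal(out[6, 2], 0L)
})

test_that("contour of a filled rectangle enumerates exactly its boundary pixels", {
  m <- matrix(0L, 14, 18)
  m[4:9, 5:14] <- 1L                      # 6 rows x 10 cols
  ct <- extract_contour(m)
  ob <- oracle_boundary_pixels(m)
  expect_equal(nrow(ct), nrow(ob))        # 2*6 + 2*10 - 4 = 28
  key <- function(p) sort(paste(p[, 1], p[, 2]))
  expect_identical(key(ct), key(ob))
  # no consecutive duplicates
  expect_true(all(rowSums(abs(diff(unclass(ct)))) > 0))
})

test_that("contour is unchanged by padding the mask border with background", {
  cfg <- quick_config(fps = 10, duration_s = 0.1)
  m <- generate_sequence(cfg)$masks[[1]]
  ct <- extract_contour(m)
  padded <- rbind(cbind(m, matrix(0L, nrow(m), 7)),
                  matrix(0L, 5, ncol(m) + 7))
  expect_identical(unclass(extract_contour(padded)), unclass(ct))
  expect_error(extract_contour({z <- matrix(0L, 5, 5); z[3, 3] <- 1L; z}),
               "fewer than 5")
})

test_that("contour pixel set agrees with EBImage's object contour", {
  skip_if_not_installed("EBImage")
  cfg <- quick_config(fps = 10, duration_s = 0.1, orientation_deg = 25)
  m <- generate_sequence(cfg)$masks[[1]]
  ct <- extract_contour(m)
  oc <- EBImage::ocontour(EBImage::bwlabel(t(m)))[[1]]  # x-major, 0-based
  key <- function(x, y) sort(paste(x, y))
  expect_identical(key(ct[, "x"], ct[, "y"]), key(oc[, 1], oc[, 2]))
})

test_that("exact ellipse point sets are fitted to machine precision", {
  set.seed(22)
  for (i in 1:10) {
    major <- runif(1, 20, 80); minor <- major * runif(1, 0.3, 1)
    ang <- runif(1, 0, 180)
    pts <- ellipse_points(60, runif(1, -50, 50), runif(1, -50, 50),
                          major, minor, ang)
    f <- fit_ellipse(pts)
    expect_lt(f$residual, 1e-8)
    expect_equal(f$major_len, major, tolerance = 1e-6)
    expect_equal(f$minor_len, minor, tolerance = 1e-6)
  }
})

test_that("rotating input points rotates the fitted angle and keeps axes", {
  pts <- ellipse_points(80, 0, 0, 50, 24, 10)
  base <- fit_ellipse(pts)
  for (theta in c(17, 45, 120)) {
    r <- theta * pi / 180
    rot <- cbind(pts[, 1] * cos(r) - pts[, 2] * sin(r),
                 pts[, 1] * sin(r) + pts[, 2] * cos(r))
    f <- fit_ellipse(rot)
    expect_equal(f$major_len, base$major_len, tolerance = 0.5)
    expect_equal(f$minor_len, base$minor_len, tolerance = 0.5)
    expect_equal(f$angle_deg, (base$angle_deg + theta) %% 180,
                 tolerance = 1e-6)
  }
})

test_that("fit is invariant to contour point order and traversal direction", {
  cfg <- quick_config(fps = 10, duration_s = 0.1, orientation_deg = 40)
  ct <- extract_contour(generate_sequence(cfg)$masks[[1]])
  f0 <- fit_ellipse(ct)
  n <- nrow(ct)
  rolled <- ct[c(17:n, 1:16), ]
  reversed <- ct[n:1, ]
  for (v in list(rolled, reversed)) {
    f <- fit_ellipse(v)
    expect_equal(f$major_len, f0$major_len, tolerance = 1e-9)
    expect_equal(f$angle_deg, f0$angle_deg, tolerance = 1e-9)
  }
})

test_that("degenerate inputs are rejected as non-ellipses", {
  expect_error(fit_ellipse(cbind(1:3, 1:3)), "at least 5")
  line_pts <- cbind(seq(0, 10, length.out = 20), seq(0, 5, length.out = 20))
  expect_error(fit_ellipse(line_pts), "degenerate|ellipse")
  thin <- matrix(0L, 10, 10); thin[3, 2:9] <- 1L   # 1-px line mask
  expect_error(axes_from_mask(thin), "ellipse|degenerate|fewer")
})

test_that("axes recovered from synthetic masks match the generator truth", {
  cfg <- beat_config(diastolic_major = 60, diastolic_minor = 30,
                     noise_sd = 0, fps = 10, duration_s = 0.1,
                     beat_freq = 2, orientation_deg = 30)
  sq <- generate_sequence(cfg)
  ax <- axes_from_mask(sq$masks[[1]])
  expect_equal(ax$L, 60, tolerance = 1.5)
  expect_equal(ax$S, 30, tolerance = 1.5)
  # mask pixel count vs fitted ellipse area within 5%
  fit_area <- pi * ax$L * ax$S / 4
  expect_lt(abs(mask_area(sq$masks[[1]]) - fit_area) / fit_area, 0.05)
})

test_that("axis recovery error shrinks as the chamber grows", {
  err_at <- function(minor) {
    cfg <- beat_config(frame_height = 160, frame_width = 160,
                       center_x = 79.5, center_y = 79.5,
                       diastolic_major = minor * 1.8, diastolic_minor = minor,
                       orientation_deg = 25, noise_sd = 0,
                       fps = 10, duration_s = 0.1, beat_freq = 2)
    sq <- generate_sequence(cfg)
    # raw fit: the rasterization error itself must shrink with size
    ax <- axes_from_mask(sq$masks[[1]], edge_correction_px = 0)
    abs(ax$S - minor) / minor + abs(ax$L - minor * 1.8) / (minor * 1.8)
  }
  errs <- vapply(c(10, 20, 40), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("mask_area counts foreground pixels exactly", {
  expect_equal(mask_area(matrix(0L, 8, 8)), 0)
  expect_equal(mask_area(matrix(1L, 8, 8)), 64)
  set.seed(23)
  m <- random_mask(13, 9)
  cnt <- 0L
  for (i in seq_len(13)) for (j in seq_len(9)) if (m[i, j] > 0) cnt <- cnt + 1L
  expect_equal(mask_area(m), cnt)
})

test_that("geometry_table reports the per-frame CSV contract columns", {
  cfg <- quick_config(fps = 50, duration_s = 0.2)
  sq <- generate_sequence(cfg)
  g <- geometry_table(sq)
  expect_equal(nrow(g), 10)
  expect_named(g, c("frame_index", "time_s", "area_px2", "long_axis_px",
                    "short_axis_px", "center_x", "center_y", "angle_deg"))
  expect_equal(g$time_s, (0:9) / 50)
  expect_true(all(g$long_axis_px >= g$short_axis_px))
  expect_true(all(g$angle_deg >= 0 & g$angle_deg < 180))
})
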