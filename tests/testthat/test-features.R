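# Hand-computed arithmetic checks of the feature definitions, plus
# invariance properties on constructed footfall sequences. sequence
# references use the internal frame: heel = heel-region centroid,
# mid = midline midpoint, cen = overall centroid, mdir = unit midline.

make_ref <- function(heel, mid = heel, cen = mid, fc, lc = fc + 0.6,
                     side = rep(c("left", "right"), length.out = nrow(heel)),
                     mdir = matrix(rep(c(0, 1), nrow(heel)), ncol = 2, byrow = TRUE)) {
  data.frame(side = side, first_contact = fc, last_contact = lc,
             heel_x = heel[, 1], heel_y = heel[, 2],
             mid_x = mid[, 1], mid_y = mid[, 2],
             cen_x = cen[, 1], cen_y = cen[, 2],
             mdir_x = mdir[, 1], mdir_y = mdir[, 2])
}

test_that("step, stride and width features follow their definitions", {
  heel <- rbind(c(0, 100), c(10, 160), c(0, 220))
  ref <- make_ref(heel, fc = c(0, 0.55, 1.10))
  f <- gaitmat:::sequence_features(ref)
  expect_equal(f$step_length[2], 60)                      # longitudinal gap
  expect_equal(f$stride_length[3], 120)                   # same-side Euclid
  expect_equal(f$step_time[2], 0.55)
  expect_equal(f$stride_time[3], 1.10)
  expect_equal(f$stride_velocity[3], 120 / 1.10)
  # base width: heel (10,160) against the line through (0,100)-(0,220)
  expect_equal(f$base_width[2], 10)
  expect_equal(f$step_width[2], 10)                       # lateral component
  expect_true(all(is.na(f[1, c("step_length", "step_time", "stride_length")])))
})

test_that("support times follow the contact-time definitions", {
  ref <- make_ref(rbind(c(0, 0), c(5, 60), c(0, 120), c(5, 180)),
                  fc = c(0, 0.55, 1.10, 1.65), lc = c(0.70, 1.25, 1.80, 2.35))
  f <- gaitmat:::sequence_features(ref)
  expect_equal(f$stance_time, rep(0.70, 4))
  expect_equal(f$double_support_time[1], 0.70 - 0.55)     # toe-off minus next heel strike
  expect_equal(f$single_support_time[1], 1.10 - 0.70)     # next same-foot strike minus toe-off
  # flight (negative double support) clips to zero with a warning
  ref2 <- make_ref(rbind(c(0, 0), c(5, 60), c(0, 120)),
                   fc = c(0, 0.55, 1.10), lc = c(0.50, 1.05, 1.60))
  expect_warning(f2 <- gaitmat:::sequence_features(ref2), regexp = "flight")
  expect_equal(f2$double_support_time[1], 0)
})

test_that("toe angle is measured against the line of progression, out positive", {
  # left-foot midline parallel to a vertical LOP: zero toe angle
  heel <- rbind(c(0, 0), c(8, 60), c(0, 120), c(8, 180))
  ref <- make_ref(heel, fc = c(0, 0.5, 1.0, 1.5), side = c("left", "right", "left", "right"))
  f <- gaitmat:::sequence_features(ref)
  expect_equal(f$toe_angle_signed[1], 0)
  # left-foot midline rotated 10 degrees outward (counter-clockwise, away
  # from the body midline on the left side) gives +10
  a <- 10 * pi / 180
  mdir <- matrix(rep(c(0, 1), 4), ncol = 2, byrow = TRUE)
  mdir[1, ] <- c(-sin(a), cos(a))
  mdir[2, ] <- c(sin(a), cos(a))    # right foot outward = clockwise
  f2 <- gaitmat:::sequence_features(make_ref(heel, fc = c(0, 0.5, 1.0, 1.5),
                                             side = c("left", "right", "left", "right"),
                                             mdir = mdir))
  expect_equal(f2$toe_angle_signed[1], 10, tolerance = 1e-9)
  expect_equal(f2$toe_angle_signed[2], 10, tolerance = 1e-9)
})

test_that("toe direction encodes the sign as a binary category", {
  expect_equal(unlist(toe_direction_split(-5)), c(toe_angle_unsigned = 5, toe_direction = 0))
  expect_equal(unlist(toe_direction_split(7)), c(toe_angle_unsigned = 7, toe_direction = 1))
  expect_equal(unlist(toe_direction_split(0)), c(toe_angle_unsigned = 0, toe_direction = 1))
})

test_that("line-of-progression deviation is the unsigned angle to the mat axis", {
  cen <- rbind(c(0, 0), c(5, 60), c(10, 120))
  ref <- make_ref(cen, cen = cen, fc = c(0, 0.5, 1.0))
  f <- gaitmat:::sequence_features(ref)
  expect_equal(f$lop_deviation_angle[1], atan(10 / 120) * 180 / pi, tolerance = 1e-9)
  # purely lateral displacement: 90 degrees
  cen2 <- rbind(c(0, 50), c(5, 50), c(10, 50))
  f2 <- gaitmat:::sequence_features(make_ref(cen2, cen = cen2, fc = c(0, 0.5, 1.0)))
  expect_equal(f2$lop_deviation_angle[1], 90)
  # parallel to the walkway: 0 degrees
  cen3 <- rbind(c(4, 0), c(9, 60), c(4, 120))
  f3 <- gaitmat:::sequence_features(make_ref(cen3, cen = cen3, fc = c(0, 0.5, 1.0)))
  expect_equal(f3$lop_deviation_angle[1], 0)
})

test_that("foot dimensions follow the centroid and cell-count rules", {
  # uniform rectangle footprint: length = 1.5 x centroid gap
  pts <- expand.grid(x_cm = seq(35, 45, by = 0.5), y_cm = seq(100, 124, by = 0.5))
  ff <- list(points = pts,
             geometry = segment_footprint(pts, walk_dir = c(0, 1)))
  class(ff) <- "footfall"
  d <- foot_dimensions(ff)
  expect_equal(unname(d["foot_length"]), 24, tolerance = 0.3)
  expect_equal(unname(d["foot_width"]), 10, tolerance = 1e-6)
  expect_equal(unname(d["foot_area"]), nrow(pts) * 1.27^2)
  # the quoted arithmetic: heel centroid (0,0), fore centroid (0,16) -> 24
  ff$geometry$heel_centroid <- c(0, 0)
  ff$geometry$fore_centroid <- c(0, 16)
  expect_equal(unname(foot_dimensions(ff)["foot_length"]), 24)
})

test_that("BOS area pools two prints and dominates both hulls", {
  sq1 <- expand.grid(x_cm = seq(0, 1, 0.25), y_cm = seq(0, 1, 0.25))
  sq2 <- sq1; sq2$x_cm <- sq2$x_cm + 3
  expect_equal(bos_area(sq1, sq2), 4.0)
  expect_equal(bos_area(sq1, sq1), hull_area(sq1))
  set.seed(3)
  c1 <- data.frame(x_cm = runif(30, 0, 10), y_cm = runif(30, 0, 25))
  c2 <- data.frame(x_cm = runif(30, 8, 20), y_cm = runif(30, 40, 70))
  b <- bos_area(c1, c2)
  expect_gte(b, hull_area(c1) - 1e-12)
  expect_gte(b, hull_area(c2) - 1e-12)
  expect_equal(b, brute_hull_area(rbind(as.matrix(c1), as.matrix(c2))),
               tolerance = 1e-12)
})

test_that("spatial features are translation invariant and angles rotate correctly", {
  coh <- sd0_cohort()
  pk <- reduce_to_peak(coh$events)
  p1 <- split_passes(pk, coh$metadata)[[1]]
  rows0 <- assemble_feature_rows(suppressWarnings(segment_pass(p1)))
  shifted <- p1
  shifted$points$x_cm <- shifted$points$x_cm + 3.1
  shifted$points$y_cm <- shifted$points$y_cm - 7.7
  rows1 <- assemble_feature_rows(suppressWarnings(segment_pass(shifted)))
  spatial <- c("foot_length", "foot_width", "hull_area", "bos_area",
               "step_length", "step_width", "stride_length", "stride_width",
               "base_width", "toe_angle_signed", "lop_deviation_angle")
  for (v in spatial) expect_equal(rows1[[v]], rows0[[v]], tolerance = 1e-9)
  # rotating the pass about the mat normal leaves the toe angle (a relative
  # angle) unchanged but shifts the LOP deviation by the rotation
  ang <- 4 * pi / 180
  rot <- p1
  xy <- gaitmat:::rotate_xy(cbind(p1$points$x_cm - 45, p1$points$y_cm - 200), ang)
  rot$points$x_cm <- xy[, 1] + 45; rot$points$y_cm <- xy[, 2] + 200
  rows2 <- assemble_feature_rows(suppressWarnings(segment_pass(rot)))
  expect_equal(rows2$toe_angle_signed, rows0$toe_angle_signed, tolerance = 0.2)
  expect_equal(rows2$stride_length, rows0$stride_length, tolerance = 1e-6)
  d <- abs(rows2$lop_deviation_angle - rows0$lop_deviation_angle)
  expect_equal(mean(d, na.rm = TRUE), 4, tolerance = 0.3)
})

test_that("assembled rows carry consistent derived columns", {
  feats <- noisy_cohort()$features
  expect_equal(feats$toe_angle_unsigned, abs(feats$toe_angle_signed))
  idx <- !is.na(feats$toe_angle_signed)
  expect_equal(feats$toe_direction[idx], as.integer(feats$toe_angle_signed[idx] >= 0))
  ok <- !is.na(feats$bos_area) & !is.na(feats$hull_area)
  expect_true(all(feats$bos_area[ok] >= feats$hull_area[ok] - 1e-9))
  ok2 <- !is.na(feats$step_velocity)
  expect_equal(feats$step_velocity[ok2],
               (feats$step_length / feats$step_time)[ok2])
  expect_true(all(feats$stance_time >= 0))
})
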