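test_that("planned sequences are deterministic and honour degenerate profiles", {
  prof <- gait_profile("control",
                       step_length = c(60, 0), step_width = c(10, 0),
                       toe_angle = c(7, 0), step_time = c(0.55, 0),
                       stance_time = c(0.62, 0), foot_length = c(25.4, 0),
                       foot_width = c(10.16, 0), lop_drift = c(0, 0),
                       n_steps = c(6, 6))
  s1 <- sample_gait_sequence(prof, seed = 1)
  s2 <- sample_gait_sequence(prof, seed = 1)
  expect_identical(s1, s2)
  # sd = 0: heel gaps all exactly the mean step length, contacts the mean step time
  expect_equal(diff(s1$heel_y), rep(60, nrow(s1) - 1))
  expect_equal(diff(s1$first_contact), rep(0.55, nrow(s1) - 1))
  expect_true(all(s1$side[-1] != s1$side[-nrow(s1)]))  # strict alternation
})

test_that("infeasible profiles are rejected at validation", {
  expect_error(
    gait_profile("control", step_length = c(60, 0), step_width = c(95, 0),
                 toe_angle = c(7, 0), step_time = c(0.55, 0),
                 stance_time = c(0.62, 0), foot_length = c(25.4, 0),
                 foot_width = c(10.16, 0)),
    class = "gaitmat_validation_error")
  expect_error(
    gait_profile("control", step_length = c(60, 0), step_width = c(10, 0),
                 toe_angle = c(7, 0), step_time = c(0.3, 0),
                 stance_time = c(0.7, 0), foot_length = c(25.4, 0),
                 foot_width = c(10.16, 0)),
    class = "gaitmat_validation_error")
  expect_error(foot_template(0, 10), class = "gaitmat_validation_error")
})

test_that("rasterization emits exactly the grid cells inside the outline", {
  # 10.16 x 25.4 cm rectangle placed generically: 8 x 20 = 160 cells
  pose <- data.frame(step_index = 1, side = "left", heel_x = 40.05,
                     heel_y = 100.40, midline_angle = pi / 2,
                     first_contact = 1, last_contact = 1.6,
                     foot_length = 25.4, foot_width = 10.16)
  ras <- rasterize_footprint(pose, foot_template(25.4, 10.16))
  expect_equal(nrow(ras$cells), 160)
  # brute-force point-in-polygon over the full grid agrees
  tmpl <- foot_template(25.4, 10.16)
  outline <- sweep(tmpl$outline, 2, c(pose$heel_x, pose$heel_y), "+")
  grid <- expand.grid(x = 0:70 * 1.27, y = 0:330 * 1.27)
  n_in <- sum(gaitmat:::points_in_convex_polygon(as.matrix(grid), outline))
  expect_equal(nrow(ras$cells), n_in)
})

test_that("rotating a footprint by 90 degrees about a lattice point preserves cells", {
  heel <- c(30 * 1.27, 100 * 1.27)  # lattice point: grid maps to itself
  mk <- function(angle) {
    pose <- data.frame(step_index = 1, side = "left", heel_x = heel[1] + 0.40,
                       heel_y = heel[2] + 0.40, midline_angle = angle,
                       first_contact = 1, last_contact = 1.6,
                       foot_length = 25.4, foot_width = 10.16)
    nrow(rasterize_footprint(pose, foot_template(25.4, 10.16))$cells)
  }
  # the +0.40 cm offset also rotates cleanly only for the 0/90 pair about
  # the lattice; compare counts for axis-aligned and 90-degree rotations
  pose0 <- data.frame(step_index = 1, side = "left", heel_x = heel[1] + 0.4,
                      heel_y = heel[2] + 0.4, midline_angle = pi / 2,
                      first_contact = 1, last_contact = 1.6,
                      foot_length = 25.4, foot_width = 10.16)
  pose90 <- data.frame(step_index = 1, side = "left", heel_x = heel[1] - 0.4,
                       heel_y = heel[2] + 0.4, midline_angle = pi,
                       first_contact = 1, last_contact = 1.6,
                       foot_length = 25.4, foot_width = 10.16)
  n0 <- nrow(rasterize_footprint(pose0, foot_template(25.4, 10.16))$cells)
  n90 <- nrow(rasterize_footprint(pose90, foot_template(25.4, 10.16))$cells)
  expect_equal(n90, n0)
})

test_that("out-of-mat footprints raise a generation error naming the step", {
  pose <- data.frame(step_index = 4, side = "left", heel_x = 2,
                     heel_y = 410, midline_angle = pi / 2,
                     first_contact = 1, last_contact = 1.6,
                     foot_length = 25.4, foot_width = 10.16)
  expect_error(rasterize_footprint(pose, foot_template(25.4, 10.16)),
               regexp = "step 4", class = "gaitmat_generation_error")
})

test_that("cohort generation is deterministic and correctly sized", {
  c1 <- suppressWarnings(
    generate_cohort(n_patients = 2, n_controls = 1, passes_per_subject = 3, seed = 7))
  c2 <- suppressWarnings(
    generate_cohort(n_patients = 2, n_controls = 1, passes_per_subject = 3, seed = 7))
  expect_identical(c1$events, c2$events)
  expect_identical(c1$truth, c2$truth)
  expect_equal(nrow(c1$metadata), 3 * 3)
  pk <- reduce_to_peak(c1$events)
  passes <- split_passes(pk, c1$metadata)
  expect_length(passes, 9)
  expect_equal(sort(unique(c1$metadata$class_label)), c("control", "patient"))
})

test_that("ground-truth cell memberships partition each pass's points", {
  coh <- noisy_cohort()
  pk <- reduce_to_peak(coh$events)
  m <- coh$memberships
  # one reduced point (cell episode) per true membership record, and no
  # cell assigned to two footfalls of the same pass
  expect_equal(nrow(pk), nrow(m))
  expect_equal(anyDuplicated(m[, c("pass_index", "x_cm", "y_cm", "footfall_id")]), 0)
})

test_that("extracted hull area converges to the outline area as pitch shrinks", {
  tmpl <- foot_template(25.4, 10.16)
  rel_err <- vapply(c(1.27, 1.27 / 2, 1.27 / 4), function(pitch) {
    mat <- mat_spec(pitch_cm = pitch)
    pose <- data.frame(step_index = 1, side = "left", heel_x = 40.11,
                       heel_y = 100.23, midline_angle = pi / 2 + 0.12,
                       first_contact = 1, last_contact = 1.6,
                       foot_length = 25.4, foot_width = 10.16)
    ras <- rasterize_footprint(pose, tmpl, mat)
    abs(hull_area(ras$cells) - tmpl$area) / tmpl$area
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
})
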