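# Parametric walkway simulator. Generates raw sensor-grid recordings from a
# planned gait sequence with known per-footfall ground truth, emulating the
# statistical structure the downstream analysis assumes: alternating
# left/right footprints advancing along the mat, class-conditional shifts in
# spatial, temporal and foot-shape parameters, and a heel-to-toe pressure
# rollover so that peak-timestamp reduction is meaningful.
#
# Conventions: mat frame has x lateral (0..90 cm) and y longitudinal
# (0..420 cm); walking progresses towards +y; toe angles are signed with
# toe-out positive.

#' Class-conditional gait profile
#'
#' Parameter distributions (mean, sd) from which a synthetic subject's gait
#' is drawn. Between-subject and within-subject (step-to-step) variation
#' split the stated sd (see [generate_cohort()]).
#'
#' @param class_label `"patient"` or `"control"`.
#' @param step_length,step_width,toe_angle,step_time,stance_time,foot_length,foot_width,lop_drift
#'   numeric `c(mean, sd)`; units cm, degrees, seconds as named.
#'   `lop_drift` is the per-pass deviation (degrees) of the walking path
#'   from the mat's long axis.
#' @param n_steps integer `c(min, max)` footfalls per pass; a pass stops
#'   early if the next footprint would leave the mat.
#' @return object of class `gait_profile`.
#' @export
gait_profile <- function(class_label,
                         step_length, step_width, toe_angle,
                         step_time, stance_time,
                         foot_length, foot_width,
                         lop_drift = c(0, 1),
                         n_steps = c(5, 7)) {
  p <- list(class_label = class_label,
            step_length = step_length, step_width = step_width,
            toe_angle = toe_angle, step_time = step_time,
            stance_time = stance_time, foot_length = foot_length,
            foot_width = foot_width, lop_drift = lop_drift,
            n_steps = as.integer(n_steps))
  validate_gait_profile(p)
  structure(p, class = "gait_profile")
}

validate_gait_profile <- function(p, mat = mat_spec()) {
  two <- c("step_length", "step_width", "toe_angle", "step_time",
           "stance_time", "foot_length", "foot_width", "lop_drift")
  for (nm in two) {
    v <- p[[nm]]
    if (length(v) != 2 || !is.numeric(v)) {
      gm_stop(sprintf("profile field '%s' must be numeric c(mean, sd)", nm),
              "gaitmat_validation_error")
    }
    if (v[2] < 0) gm_stop(sprintf("profile sd for '%s' is negative", nm),
                          "gaitmat_validation_error")
  }
  if (p$step_length[1] <= 0 || p$step_time[1] <= 0 || p$stance_time[1] <= 0 ||
      p$foot_length[1] <= 0 || p$foot_width[1] <= 0) {
    gm_stop("profile means must be positive", "gaitmat_validation_error")
  }
  if (p$stance_time[1] >= 2 * p$step_time[1]) {
    gm_stop("infeasible profile: stance_time must be < 2 x step_time",
            "gaitmat_validation_error")
  }
  if (p$step_width[1] + p$foot_width[1] > mat$width_cm) {
    gm_stop("infeasible profile: mean step width + foot width exceeds mat width",
            "gaitmat_validation_error")
  }
  if (p$n_steps[1] < 1 || p$n_steps[2] < p$n_steps[1]) {
    gm_stop("invalid n_steps range", "gaitmat_validation_error")
  }
  invisible(p)
}

#' Default control-like gait profile
#'
#' Steady gait with narrow base, small toe-out and low variability; values
#' sit in the range reported for healthy adult walking.
#' @export
control_profile <- function() {
  gait_profile("control",
               step_length = c(62, 4), step_width = c(9, 2),
               toe_angle = c(7, 2), step_time = c(0.54, 0.04),
               stance_time = c(0.62, 0.05),
               foot_length = c(25.4, 1.0), foot_width = c(10.2, 0.5),
               lop_drift = c(0, 1), n_steps = c(5, 7))
}

#' Default patient-like gait profile
#'
#' Shorter, more variable steps, wider base, larger toe-angle variance,
#' longer stance (hence longer double support) and more path drift. Used
#' as a test fixture for class separation; not a clinical claim.
#' @export
ms_profile <- function() {
  gait_profile("patient",
               step_length = c(48, 7), step_width = c(13, 3),
               toe_angle = c(9, 4), step_time = c(0.66, 0.07),
               stance_time = c(0.80, 0.07),
               foot_length = c(25.4, 1.0), foot_width = c(10.2, 0.5),
               lop_drift = c(0, 2.5), n_steps = c(5, 7))
}

#' Convex foot outline template
#'
#' Foot-local coordinates: heel-edge midpoint at the origin, long axis +y,
#' laterally centred. The default is a rectangle, for which the
#' heel/fore slice-centroid spacing is exactly 2/3 of the length (the basis
#' of the 1.5 foot-length multiplier); `"hex"` clips the rectangle's four
#' corners for a slightly rounded print.
#'
#' @param length_cm,width_cm outline dimensions.
#' @param shape `"rectangle"` or `"hex"`.
#' @return object of class `foot_template` with `outline` polygon and area.
#' @export
foot_template <- function(length_cm, width_cm, shape = c("rectangle", "hex")) {
  shape <- match.arg(shape)
  if (length_cm <= 0 || width_cm <= 0) {
    gm_stop("degenerate foot template (non-positive dimension)", "gaitmat_validation_error")
  }
  w <- width_cm / 2
  outline <- switch(shape,
    rectangle = rbind(c(-w, 0), c(w, 0), c(w, length_cm), c(-w, length_cm)),
    hex = {
      c1 <- 0.15 * length_cm
      rbind(c(-w, c1), c(0, 0), c(w, c1), c(w, length_cm - c1),
            c(0, length_cm), c(-w, length_cm - c1))
    })
  structure(list(outline = outline, length_cm = length_cm, width_cm = width_cm,
                 area = polygon_area(outline), shape = shape),
            class = "foot_template")
}

#' Plan a pass: sample a sequence of footfall poses
#'
#' Draws alternating left/right footfall poses from a gait profile. Heel
#' positions advance monotonically along the walking (+y) axis; lateral
#' placement straddles a (possibly drifting) central line at half the step
#' width; first contacts advance by the step time, stance gives the last
#' contact. The pass is truncated when the next footprint would leave the
#' mat.
#'
#' @param profile a [gait_profile()].
#' @param seed integer seed; identical seeds give identical sequences.
#' @param mat a [mat_spec()].
#' @param start_margin_cm heel position of the first footfall along y.
#' @param start_side `"left"`, `"right"`, or `"random"`.
#' @return data.frame of planned poses: side, heel_x/heel_y (heel-edge
#'   midpoint, cm), midline angle (radians, global), first/last contact (s)
#'   and the drawn per-step parameters.
#' @export
sample_gait_sequence <- function(profile, seed, mat = mat_spec(),
                                 start_margin_cm = 15,
                                 start_side = "random") {
  validate_gait_profile(profile, mat)
  with_seed(seed, {
    n_range <- profile$n_steps[1]:profile$n_steps[2]
    n_max <- if (length(n_range) == 1) n_range else sample(n_range, 1L)
    draw <- function(par) stats::rnorm(1, profile[[par]][1], profile[[par]][2])
    side0 <- if (identical(start_side, "random")) {
      sample(c("left", "right"), 1L)
    } else start_side
    drift_deg <- draw("lop_drift")
    center_x0 <- mat$width_cm / 2 + stats::rnorm(1, 0, 1)
    L <- max(10, draw("foot_length"))
    W <- max(4, draw("foot_width"))
    poses <- list()
    y <- start_margin_cm + stats::runif(1, 0, 2)
    t_fc <- 0.5
    side <- side0
    for (i in seq_len(n_max)) {
      sl <- if (i == 1) 0 else max(10, draw("step_length"))
      sw <- max(2, draw("step_width"))
      st <- max(0.2, draw("step_time"))
      stc <- max(0.2, draw("stance_time"))
      stc <- min(stc, 1.9 * st)
      psi <- draw("toe_angle")
      y <- y + sl
      if (y + L + 1 > mat$length_cm) break
      cx <- center_x0 + tan(drift_deg * pi / 180) * (y - start_margin_cm)
      s_lat <- if (side == "right") 1 else -1
      heel_x <- cx + s_lat * sw / 2
      s_out <- if (side == "left") 1 else -1
      midline_angle <- pi / 2 + s_out * psi * pi / 180
      # truncate the pass if the planned outline would leave the mat
      mdir <- c(cos(midline_angle), sin(midline_angle))
      ldir <- c(-mdir[2], mdir[1]) * W / 2
      corners <- rbind(c(heel_x, y) + ldir, c(heel_x, y) - ldir,
                       c(heel_x, y) + L * mdir + ldir,
                       c(heel_x, y) + L * mdir - ldir)
      if (any(corners[, 1] < 0.5 | corners[, 1] > mat$width_cm - 0.5 |
              corners[, 2] < 0.5 | corners[, 2] > mat$length_cm - 0.5)) {
        if (i == 1) gm_stop("first footfall does not fit on the mat",
                            "gaitmat_validation_error")
        break
      }
      t_fc <- if (i == 1) t_fc else t_fc + st
      poses[[i]] <- data.frame(
        step_index = i, side = side, heel_x = heel_x, heel_y = y,
        midline_angle = midline_angle, first_contact = t_fc,
        last_contact = t_fc + stc, foot_length = L, foot_width = W,
        toe_angle_true = psi, step_length_drawn = sl, step_width_drawn = sw,
        step_time_drawn = st, stance_time_drawn = stc,
        stringsAsFactors = FALSE
      )
      side <- if (side == "left") "right" else "left"
    }
    if (length(poses) == 0) {
      gm_stop("no footfall fits on the mat with this profile", "gaitmat_validation_error")
    }
    do.call(rbind, poses)
  })
}

#' Rasterize a planned footfall onto the sensor grid
#'
#' Emits raw sensor events for every grid cell whose centre falls inside
#' the rotated and translated foot outline. Each cell emits three time
#' samples (rise, peak, fall) inside the stance window; the per-cell peak
#' time maps the cell's position along the foot axis linearly onto
#' `[first_contact, last_contact]` (normalised across the footprint's
#' cells), so heel cells peak first and the earliest/latest peak
#' timestamps equal the true contact times.
#'
#' @param pose one row of [sample_gait_sequence()] output.
#' @param template a [foot_template()]; defaults to a rectangle with the
#'   pose's drawn foot dimensions.
#' @param mat a [mat_spec()].
#' @param base_pressure peak pressure scale, device units.
#' @return list with `events` (raw sensor event data.frame) and `cells`
#'   (the emitted cell centres, cm).
#' @export
rasterize_footprint <- function(pose, template = NULL, mat = mat_spec(),
                                base_pressure = 60) {
  if (is.null(template)) template <- foot_template(pose$foot_length, pose$foot_width)
  if (template$area <= 0) gm_stop("degenerate zero-area outline", "gaitmat_validation_error")
  alpha <- pose$midline_angle - pi / 2
  outline <- rotate_xy(template$outline, alpha)
  outline <- sweep(outline, 2, c(pose$heel_x, pose$heel_y), "+")
  if (any(outline[, 1] < 0 | outline[, 1] > mat$width_cm |
          outline[, 2] < 0 | outline[, 2] > mat$length_cm)) {
    gm_stop(sprintf("footprint at step %d falls outside the mat", pose$step_index),
            "gaitmat_generation_error")
  }
  pitch <- mat$pitch_cm
  ix <- seq(max(0L, floor(min(outline[, 1]) / pitch)),
            min(mat$max_x_index, ceiling(max(outline[, 1]) / pitch)))
  iy <- seq(max(0L, floor(min(outline[, 2]) / pitch)),
            min(mat$max_y_index, ceiling(max(outline[, 2]) / pitch)))
  grid <- expand.grid(x_index = ix, y_index = iy)
  centres <- cbind(grid$x_index * pitch, grid$y_index * pitch)
  keep <- points_in_convex_polygon(centres, outline)
  grid <- grid[keep, , drop = FALSE]
  centres <- centres[keep, , drop = FALSE]
  if (nrow(grid) == 0) {
    gm_stop(sprintf("footprint at step %d covers no sensor cell", pose$step_index),
            "gaitmat_generation_error")
  }
  mdir <- c(cos(pose$midline_angle), sin(pose$midline_angle))
  proj <- centres %*% mdir
  rng <- range(proj)
  frac <- if (diff(rng) < 1e-12) rep(0.5, nrow(grid)) else (proj - rng[1]) / diff(rng)
  fc <- pose$first_contact; lc <- pose$last_contact
  t_pk <- fc + frac * (lc - fc)
  p_pk <- base_pressure * (1 + 0.25 * cos(pi * frac))  # heel loads harder
  dt <- 0.03
  n <- nrow(grid)
  events <- data.frame(
    time = c(pmax(fc, t_pk - dt), t_pk, pmin(lc, t_pk + dt)),
    x_index = rep(grid$x_index, 3), y_index = rep(grid$y_index, 3),
    pressure = c(0.55 * p_pk, p_pk, 0.6 * p_pk),
    foot_type = pose$side, foot_count = pose$step_index,
    footfall = NA_real_, pass_index = NA_real_
  )
  events <- events[order(events$time, events$x_index, events$y_index), ]
  rownames(events) <- NULL
  list(events = events, cells = data.frame(x_cm = centres[, 1], y_cm = centres[, 2]))
}

subject_profile <- function(profile, seed, between_frac = 0.8, within_frac = 0.6) {
  # Draw subject-level means once; the residual sd feeds step-to-step noise.
  with_seed(seed, {
    p <- unclass(profile)
    for (nm in c("step_length", "step_width", "toe_angle", "step_time",
                 "stance_time", "foot_length", "foot_width", "lop_drift")) {
      m <- p[[nm]][1] + stats::rnorm(1, 0, between_frac * p[[nm]][2])
      p[[nm]] <- c(m, within_frac * p[[nm]][2])
    }
    # keep feasibility under perturbation
    p$step_time[1] <- max(p$step_time[1], 0.25)
    p$stance_time[1] <- min(max(p$stance_time[1], 0.25), 1.85 * p$step_time[1])
    p$step_length[1] <- max(p$step_length[1], 15)
    p$foot_length[1] <- max(p$foot_length[1], 12)
    p$foot_width[1] <- max(p$foot_width[1], 5)
    structure(p, class = "gait_profile")
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject gait parameters from class-conditional profiles
#' (subject-level means once, then step-to-step perturbation), plans and
#' rasterizes every pass, and returns the raw event table, per-pass
#' metadata, and a per-footfall ground-truth table whose feature values
#' are computed from the planned continuous geometry (and the emitted cell
#' sets for the area features) using the same definitions the extractor
#' implements.
#'
#' @param profile_patient,profile_control class profiles ([gait_profile()]).
#' @param n_patients,n_controls subjects per class (the study design has a
#'   roughly 6:1 patient:control ratio).
#' @param passes_per_subject passes recorded per subject visit.
#' @param seed integer master seed; all randomness derives from it.
#' @param mat a [mat_spec()].
#' @param sd_zero if `TRUE`, all profile sds are forced to zero (degenerate
#'   cohort used for exact recovery checks).
#' @param template_shape foot outline shape passed to [foot_template()].
#' @return list with `events`, `metadata` (one row per pass), `truth`
#'   (one row per footfall, aligned with `pass_index` + `order_index`),
#'   and `memberships` (one row per emitted cell episode with its true
#'   footfall id).
#' @export
generate_cohort <- function(profile_patient = ms_profile(),
                            profile_control = control_profile(),
                            n_patients = 6, n_controls = 2,
                            passes_per_subject = 2, seed = 1,
                            mat = mat_spec(), sd_zero = FALSE,
                            template_shape = "rectangle") {
  stopifnot(n_patients >= 1, n_controls >= 1, passes_per_subject >= 1)
  zero_sd <- function(p) {
    for (nm in c("step_length", "step_width", "toe_angle", "step_time",
                 "stance_time", "foot_length", "foot_width", "lop_drift")) {
      p[[nm]][2] <- 0
    }
    p$n_steps <- rep(p$n_steps[1], 2)
    p
  }
  if (sd_zero) {
    profile_patient <- zero_sd(profile_patient)
    profile_control <- zero_sd(profile_control)
  }
  classes <- c(rep("patient", n_patients), rep("control", n_controls))
  subj_ids <- sprintf("S%02d", seq_along(classes))
  heights <- with_seed(seed * 7 + 1, round(stats::rnorm(length(classes), 170, 8), 1))
  if (sd_zero) heights <- rep(170, length(classes))

  events_list <- list(); meta_list <- list(); truth_list <- list(); memb_list <- list()
  pass_counter <- 0L
  footfall_counter <- 0L
  for (si in seq_along(subj_ids)) {
    prof0 <- if (classes[si] == "patient") profile_patient else profile_control
    sseed <- as.integer((as.numeric(seed) * 1009 + si) %% 2100000000)
    sprof <- if (sd_zero) prof0 else subject_profile(prof0, seed = sseed)
    for (pi in seq_len(passes_per_subject)) {
      pass_counter <- pass_counter + 1L
      pseed <- as.integer((as.numeric(seed) * 131071 + si * 100003 + pi * 97) %% 2100000000)
      poses <- sample_gait_sequence(sprof, seed = pseed, mat = mat,
                                    start_side = if (sd_zero) "left" else "random")
      cells_by_ff <- vector("list", nrow(poses))
      ev_pass <- vector("list", nrow(poses))
      for (fi in seq_len(nrow(poses))) {
        footfall_counter <- footfall_counter + 1L
        tmpl <- foot_template(poses$foot_length[fi], poses$foot_width[fi],
                              shape = template_shape)
        ras <- rasterize_footprint(poses[fi, ], tmpl, mat)
        ras$events$footfall <- footfall_counter
        ras$events$pass_index <- pass_counter
        ev_pass[[fi]] <- ras$events
        cells_by_ff[[fi]] <- ras$cells
        memb_list[[length(memb_list) + 1L]] <- data.frame(
          pass_index = pass_counter, footfall_id = footfall_counter,
          order_index = fi, x_cm = ras$cells$x_cm, y_cm = ras$cells$y_cm
        )
      }
      truth <- true_features(poses, cells_by_ff, template_shape = template_shape)
      truth$pass_index <- pass_counter
      truth$subject_id <- subj_ids[si]
      truth$visit_id <- paste0(subj_ids[si], "_v1")
      truth$class_label <- classes[si]
      truth$height_cm <- heights[si]
      truth_list[[pass_counter]] <- truth
      ev <- do.call(rbind, ev_pass)
      ev <- ev[order(ev$time, ev$x_index, ev$y_index), ]
      events_list[[pass_counter]] <- ev
      meta_list[[pass_counter]] <- data.frame(
        pass_index = pass_counter, subject_id = subj_ids[si],
        visit_id = paste0(subj_ids[si], "_v1"), class_label = classes[si],
        height_cm = heights[si], stringsAsFactors = FALSE
      )
    }
  }
  events <- do.call(rbind, events_list); rownames(events) <- NULL
  list(events = events,
       metadata = do.call(rbind, meta_list),
       truth = do.call(rbind, truth_list),
       memberships = do.call(rbind, memb_list))
}

# Ground-truth features from planned continuous geometry. For a uniform
# rectangular footprint the heel/mid/fore slice centroids lie at L/6, L/2
# and 5L/6 along the midline from the heel edge; area features come from
# the emitted cell sets because those features are defined on sensor
# points.
true_features <- function(poses, cells_by_ff, template_shape = "rectangle") {
  n <- nrow(poses)
  mdir <- cbind(cos(poses$midline_angle), sin(poses$midline_angle))
  L <- poses$foot_length
  heel_c <- cbind(poses$heel_x, poses$heel_y) + mdir * (L / 6)
  mid_pt <- cbind(poses$heel_x, poses$heel_y) + mdir * (L / 2)
  ref <- data.frame(
    side = poses$side,
    first_contact = poses$first_contact, last_contact = poses$last_contact,
    heel_x = heel_c[, 1], heel_y = heel_c[, 2],
    mid_x = mid_pt[, 1], mid_y = mid_pt[, 2],
    cen_x = mid_pt[, 1], cen_y = mid_pt[, 2],
    mdir_x = mdir[, 1], mdir_y = mdir[, 2]
  )
  seqf <- sequence_features(ref)
  areas <- vapply(seq_len(n), function(i) {
    cells <- cells_by_ff[[i]]
    ha <- tryCatch(hull_area(cells), gaitmat_degenerate = function(e) NA_real_)
    c(nrow(cells) * WALKWAY_PITCH_CM^2, ha)
  }, numeric(2))
  bos <- vapply(seq_len(n), function(i) {
    if (i == 1) return(NA_real_)
    tryCatch(hull_area(rbind(cells_by_ff[[i]], cells_by_ff[[i - 1]])),
             gaitmat_degenerate = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(
    order_index = poses$step_index, side = poses$side,
    foot_length = poses$foot_length, foot_width = poses$foot_width,
    foot_area = areas[1, ], hull_area = areas[2, ], bos_area = bos,
    first_contact = poses$first_contact, last_contact = poses$last_contact
  )
  cbind(out, seqf)
}
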