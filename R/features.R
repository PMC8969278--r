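# Standard and geometric gait features computed from segmented footfalls.
#
# Conventions (documented package choices where the field leaves room):
# "heel center" = heel-region sub-centroid; "midline midpoint" = midpoint of
# the heel->fore centroid segment; step length is the longitudinal
# (walkway-axis) component while stride length is the Euclidean heel-to-heel
# distance of same-side prints; step width is the lateral component between
# consecutive midline midpoints; toe angle is signed with toe-out positive.
# Step/stride quantities look back to the preceding print(s); toe angle,
# line-of-progression deviation and support times look forward, so boundary
# footfalls carry missing values.

#' Foot dimensions of a segmented footfall
#'
#' Foot length is the heel-to-fore sub-centroid distance multiplied by 1.5
#' (exact for a uniformly activated rectangular print, whose slice
#' centroids sit 2/3 of the length apart); foot width is the width of the
#' enclosing quadrilateral's fore slice measured through its midpoint
#' perpendicular to the long axis (the rectangle's short side); foot area
#' is the count of distinct activated cells times the cell area.
#'
#' @param footfall a `footfall` from [segment_pass()].
#' @param pitch_cm sensor pitch.
#' @return named numeric: `foot_length`, `foot_width`, `foot_area` (cm, cm, cm^2).
#' @export
foot_dimensions <- function(footfall, pitch_cm = WALKWAY_PITCH_CM) {
  g <- footfall$geometry
  len <- 1.5 * sqrt(sum((g$heel_centroid - g$fore_centroid)^2))
  ncells <- nrow(unique(footfall$points[, c("x_cm", "y_cm")]))
  c(foot_length = len, foot_width = g$rect$len_short,
    foot_area = ncells * pitch_cm^2)
}

#' Split a signed toe angle into magnitude and direction
#'
#' Direction is a binary categorical: 0 for a negative toe angle, 1 for a
#' toe angle greater than or equal to zero.
#' @param toe_angle_signed signed degrees.
#' @return data.frame with `toe_angle_unsigned`, `toe_direction`.
#' @export
toe_direction_split <- function(toe_angle_signed) {
  data.frame(toe_angle_unsigned = abs(toe_angle_signed),
             toe_direction = ifelse(is.na(toe_angle_signed), NA_integer_,
                                    as.integer(toe_angle_signed >= 0)))
}

#' Base-of-support area of a footfall and its preceding print
#'
#' Convex-hull area of the pooled sensor points of the two prints.
#' @param points_current,points_previous data.frames with `x_cm`, `y_cm`.
#' @return area cm^2.
#' @export
bos_area <- function(points_current, points_previous) {
  hull_area(rbind(as_xy(points_current), as_xy(points_previous)))
}

# Sequence features from per-footfall reference points. `ref` has one row
# per footfall in contact order with columns: side, first_contact,
# last_contact, heel_x/heel_y (heel center), mid_x/mid_y (midline
# midpoint), cen_x/cen_y (overall centroid), mdir_x/mdir_y (unit midline
# direction). The same engine serves the extractor (points estimated from
# sensors) and the generator's ground truth (planned continuous geometry).
sequence_features <- function(ref) {
  n <- nrow(ref)
  heel <- cbind(ref$heel_x, ref$heel_y)
  mid <- cbind(ref$mid_x, ref$mid_y)
  cen <- cbind(ref$cen_x, ref$cen_y)
  fc <- ref$first_contact; lc <- ref$last_contact
  na <- rep(NA_real_, n)
  out <- data.frame(step_length = na, step_width = na, stride_length = na,
                    stride_width = na, base_width = na, step_time = na,
                    stride_time = na, single_support_time = na,
                    double_support_time = na, stance_time = lc - fc,
                    step_velocity = na, stride_velocity = na,
                    toe_angle_signed = na, lop_deviation_angle = na)
  flight_warned <- FALSE
  for (i in seq_len(n)) {
    if (i >= 2) {
      out$step_length[i] <- abs(heel[i, 2] - heel[i - 1, 2])
      out$step_width[i] <- abs(mid[i, 1] - mid[i - 1, 1])
      out$step_time[i] <- fc[i] - fc[i - 1]
    }
    if (i >= 3) {
      out$stride_length[i] <- sqrt(sum((heel[i, ] - heel[i - 2, ])^2))
      out$stride_time[i] <- fc[i] - fc[i - 2]
    }
    if (i >= 2 && i < n) {
      out$stride_width[i] <- tryCatch(
        point_line_distance(mid[i, ], mid[i - 1, ], mid[i + 1, ]),
        gaitmat_degenerate = function(e) NA_real_)
      out$base_width[i] <- tryCatch(
        point_line_distance(heel[i, ], heel[i - 1, ], heel[i + 1, ]),
        gaitmat_degenerate = function(e) NA_real_)
    }
    if (i + 2 <= n) {
      out$single_support_time[i] <- fc[i + 2] - lc[i]
      lop <- heel[i + 2, ] - heel[i, ]
      if (sqrt(sum(lop^2)) > 1e-9) {
        a <- signed_angle_deg(lop, c(ref$mdir_x[i], ref$mdir_y[i]))
        out$toe_angle_signed[i] <- if (ref$side[i] == "left") a else -a
      }
      seg <- cen[i + 2, ] - cen[i, ]
      nrm <- sqrt(sum(seg^2))
      if (nrm > 1e-9) {
        out$lop_deviation_angle[i] <- acos(min(1, abs(seg[2]) / nrm)) * 180 / pi
      }
    }
    if (i + 1 <= n) {
      ds <- lc[i] - fc[i + 1]
      if (!is.na(ds) && ds < 0) {
        if (!flight_warned) {
          gm_warn("negative double support (flight phase): reported as 0")
          flight_warned <- TRUE
        }
        ds <- 0
      }
      out$double_support_time[i] <- ds
    }
  }
  out$step_velocity <- ifelse(is.na(out$step_time) | out$step_time <= 0,
                              NA_real_, out$step_length / out$step_time)
  out$stride_velocity <- ifelse(is.na(out$stride_time) | out$stride_time <= 0,
                                NA_real_, out$stride_length / out$stride_time)
  out
}

#' Assemble per-footfall feature rows from a segmented pass
#'
#' Computes every spatial, temporal and geometric feature for each
#' retained footfall of a pass and returns one row per footfall with the
#' visit identifier as cross-validation group key. Boundary footfalls
#' carry missing values for features that need a neighbour; degenerate
#' footfalls were already excluded during segmentation.
#'
#' @param seg a `segmented_pass` from [segment_pass()].
#' @return data.frame of feature rows.
#' @export
assemble_feature_rows <- function(seg) {
  ff <- Filter(Negate(is.null), seg$footfalls)
  if (length(ff) == 0) return(NULL)
  ref <- do.call(rbind, lapply(ff, function(f) {
    g <- f$geometry
    mdir <- g$fore_centroid - g$heel_centroid
    mdir <- mdir / sqrt(sum(mdir^2))
    mp <- (g$heel_centroid + g$fore_centroid) / 2
    data.frame(side = f$side, first_contact = f$first_contact,
               last_contact = f$last_contact,
               heel_x = g$heel_centroid[1], heel_y = g$heel_centroid[2],
               mid_x = mp[1], mid_y = mp[2],
               cen_x = g$overall_centroid[1], cen_y = g$overall_centroid[2],
               mdir_x = mdir[1], mdir_y = mdir[2])
  }))
  seqf <- sequence_features(ref)
  dims <- t(vapply(ff, foot_dimensions, numeric(3)))
  hulls <- vapply(ff, function(f) {
    tryCatch(hull_area(f$points), gaitmat_degenerate = function(e) NA_real_)
  }, numeric(1))
  bos <- vapply(seq_along(ff), function(i) {
    if (i == 1) return(NA_real_)
    tryCatch(bos_area(ff[[i]]$points, ff[[i - 1]]$points),
             gaitmat_degenerate = function(e) NA_real_)
  }, numeric(1))
  td <- toe_direction_split(seqf$toe_angle_signed)
  data.frame(
    subject_id = seg$subject_id, visit_id = seg$visit_id,
    class_label = seg$class_label, height_cm = seg$height_cm,
    pass_index = seg$pass_index,
    order_index = vapply(ff, `[[`, numeric(1), "order_index"),
    foot_type = vapply(ff, `[[`, character(1), "side"),
    first_contact = ref$first_contact, last_contact = ref$last_contact,
    foot_length = dims[, "foot_length"], foot_width = dims[, "foot_width"],
    foot_area = dims[, "foot_area"], hull_area = hulls, bos_area = bos,
    toe_angle_signed = seqf$toe_angle_signed,
    toe_angle_unsigned = td$toe_angle_unsigned,
    toe_direction = td$toe_direction,
    lop_deviation_angle = seqf$lop_deviation_angle,
    seqf[, c("step_length", "step_width", "stride_length", "stride_width",
             "base_width", "step_time", "stride_time", "single_support_time",
             "double_support_time", "stance_time", "step_velocity",
             "stride_velocity")],
    row.names = NULL
  )
}

#' Extract the full feature table from raw events and metadata
#'
#' End-to-end extraction: peak-pressure reduction, pass splitting,
#' per-pass segmentation, and feature assembly.
#'
#' @param events raw sensor events ([read_raw_export()] or
#'   [generate_cohort()]`$events`).
#' @param metadata per-pass metadata table.
#' @param mat a [mat_spec()].
#' @return data.frame of per-footfall feature rows (class `gait_features`).
#' @export
extract_features <- function(events, metadata, mat = mat_spec()) {
  pts <- reduce_to_peak(events, mat = mat)
  passes <- split_passes(pts, metadata)
  rows <- lapply(passes, function(p) assemble_feature_rows(segment_pass(p)))
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  class(out) <- c("gait_features", "data.frame")
  out
}
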