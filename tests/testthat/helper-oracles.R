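# Independent oracles and shared fixtures. The oracles deliberately avoid
# the code paths they check: the hull oracle enumerates candidate hull
# edges by brute force instead of calling any hull routine, and the AUROC
# oracle counts concordant score pairs.

# Brute-force convex hull area: (i, j) is a hull edge iff every other
# point lies on one side of the directed line i -> j; hull vertices are
# ordered by angle about their centroid and the shoelace formula applied.
brute_hull_area <- function(xy, tol = 1e-9) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  stopifnot(n >= 3)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || (on_hull[i] && on_hull[j])) next
      d <- xy[j, ] - xy[i, ]
      cr <- d[1] * (xy[, 2] - xy[i, 2]) - d[2] * (xy[, 1] - xy[i, 1])
      if (all(cr >= -tol)) on_hull[i] <- on_hull[j] <- TRUE
    }
  }
  v <- xy[on_hull, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# AUROC as the Mann-Whitney concordance fraction over all
# positive/negative score pairs (ties count one half).
brute_auroc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  cmp <- outer(sp, sn, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sp) * length(sn))
}

# Cached synthetic cohorts so several test files can share one generation.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

sd0_cohort <- function() {
  fixture("sd0", function() {
    coh <- generate_cohort(n_patients = 2, n_controls = 2,
                           passes_per_subject = 2, seed = 401, sd_zero = TRUE)
    coh$features <- suppressWarnings(extract_features(coh$events, coh$metadata))
    coh
  })
}

noisy_cohort <- function() {
  fixture("noisy", function() {
    coh <- suppressWarnings(generate_cohort(n_patients = 8, n_controls = 4,
                                            passes_per_subject = 4, seed = 402))
    coh$features <- suppressWarnings(extract_features(coh$events, coh$metadata))
    coh
  })
}

# Profiles with a wide class gap and small variance, used by the
# end-to-end recovery checks.
separated_profiles <- function() {
  list(
    control = gait_profile("control",
                           step_length = c(60, 2.5), step_width = c(8, 1.2),
                           toe_angle = c(6, 1.5), step_time = c(0.50, 0.03),
                           stance_time = c(0.58, 0.03),
                           foot_length = c(26, 0.8), foot_width = c(10.2, 0.4),
                           lop_drift = c(0, 0.8), n_steps = c(6, 7)),
    patient = gait_profile("patient",
                           step_length = c(44, 4), step_width = c(14, 2),
                           toe_angle = c(11, 3), step_time = c(0.70, 0.05),
                           stance_time = c(0.86, 0.05),
                           foot_length = c(26, 0.8), foot_width = c(10.2, 0.4),
                           lop_drift = c(0, 2), n_steps = c(6, 7))
  )
}

# Classes that differ ONLY in foot geometry (identical spatiotemporal
# parameters): all signal sits in the foot/hull/BOS features.
geometry_only_profiles <- function() {
  base <- list(step_length = c(58, 3), step_width = c(10, 1.5),
               toe_angle = c(7, 2), step_time = c(0.55, 0.035),
               stance_time = c(0.64, 0.035), lop_drift = c(0, 1),
               n_steps = c(6, 7))
  list(
    control = do.call(gait_profile, c(list("control",
                                           foot_length = c(27.5, 0.7),
                                           foot_width = c(11, 0.35)), base)),
    patient = do.call(gait_profile, c(list("patient",
                                           foot_length = c(23.5, 0.7),
                                           foot_width = c(9.4, 0.35)), base))
  )
}
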