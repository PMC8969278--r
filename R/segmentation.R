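# Footfall segmentation: partition a pass's peak-pressure sensor points
# into individual footfalls (k-means with a longitudinal gap-scan seeding),
# label left/right sides from lateral offsets, and build each footprint's
# minimum-area enclosing quadrilateral with heel/mid/fore subregions,
# sub-centroids and midline.

#' Estimate the number of footfalls in a pass
#'
#' Gap scan on the longitudinal (walking-axis) projection: contiguous runs
#' of activated rows separated by gaps wider than `min_gap_cm` form initial
#' segments; fragments shorter than `merge_frac` times the median segment
#' extent are merged into their nearest neighbour. At walking speed
#' footprints are longitudinally well separated, so the run count equals
#' the footfall count.
#'
#' @param points data.frame with `x_cm`, `y_cm` for one pass.
#' @param min_gap_cm minimum longitudinal gap that separates two
#'   footprints; default two grid cells.
#' @param merge_frac fragments below this fraction of the median extent
#'   merge with the closer neighbouring segment.
#' @return list with `k`, `breaks` (y boundaries) and `centers` (k x 2
#'   seed centroids for clustering).
#' @export
estimate_footfall_count <- function(points, min_gap_cm = 2 * WALKWAY_PITCH_CM + 0.1,
                                    merge_frac = 0.3) {
  stopifnot(nrow(points) >= 1)
  y <- sort(unique(points$y_cm))
  gaps <- diff(y)
  cut_after <- which(gaps > min_gap_cm)
  seg_start <- c(1, cut_after + 1)
  seg_end <- c(cut_after, length(y))
  segs <- data.frame(lo = y[seg_start], hi = y[seg_end])
  if (nrow(segs) > 1) {
    repeat {
      ext <- segs$hi - segs$lo
      med <- stats::median(ext)
      small <- which(ext < merge_frac * med)
      if (length(small) == 0 || nrow(segs) == 1) break
      i <- small[1]
      gap_prev <- if (i > 1) segs$lo[i] - segs$hi[i - 1] else Inf
      gap_next <- if (i < nrow(segs)) segs$lo[i + 1] - segs$hi[i] else Inf
      j <- if (gap_prev <= gap_next) i - 1 else i + 1
      lo <- min(segs$lo[c(i, j)]); hi <- max(segs$hi[c(i, j)])
      segs <- segs[-i, , drop = FALSE]
      j2 <- if (j > i) j - 1 else j
      segs$lo[j2] <- lo; segs$hi[j2] <- hi
      rownames(segs) <- NULL
    }
  }
  k <- nrow(segs)
  centers <- t(vapply(seq_len(k), function(i) {
    in_seg <- points$y_cm >= segs$lo[i] - 1e-9 & points$y_cm <= segs$hi[i] + 1e-9
    c(mean(points$x_cm[in_seg]), mean(points$y_cm[in_seg]))
  }, numeric(2)))
  list(k = k, breaks = segs, centers = centers)
}

#' Cluster sensor points into k footfalls
#'
#' K-means on the (x, y) coordinates: each point joins the cluster with
#' the nearest centroid. Seeding with the gap-scan segment centroids makes
#' the assignment deterministic (no random initialisation).
#'
#' @param points data.frame with `x_cm`, `y_cm`.
#' @param k number of footfalls.
#' @param centers optional k x 2 matrix of initial centroids; defaults to
#'   longitudinal quantile seeds.
#' @return integer cluster assignment (1..k), attribute `centers`.
#' @export
cluster_footfalls <- function(points, k, centers = NULL) {
  n <- nrow(points)
  if (k > n) gm_stop("k exceeds the number of points", "gaitmat_parameter_error")
  xy <- cbind(points$x_cm, points$y_cm)
  if (k == 1) {
    return(structure(rep(1L, n), centers = matrix(colMeans(xy), 1)))
  }
  if (is.null(centers)) {
    qs <- stats::quantile(points$y_cm, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    centers <- cbind(rep(mean(points$x_cm), k), qs)
  }
  centers <- unique(centers)
  if (nrow(centers) < k) gm_stop("duplicate seed centres", "gaitmat_parameter_error")
  km <- stats::kmeans(xy, centers = centers, iter.max = 100, algorithm = "Lloyd")
  structure(as.integer(km$cluster), centers = km$centers)
}

#' Assign left/right side labels to footfalls
#'
#' Footfalls are taken in first-contact order. A central line is fitted
#' through the footfall centroids (total-least-squares direction), signed
#' lateral offsets are measured against it, and the alternating
#' left/right labelling that best agrees with the offset signs is chosen
#' (negative offset relative to the walking direction = left). When
#' offsets carry no lateral information the alternation is imposed from
#' contact order with a warning.
#'
#' @param centroids n x 2 matrix of footfall centroids in contact order.
#' @return list with `sides` (character), `confidence` (fraction of
#'   offsets agreeing with the labelling) and `offsets`.
#' @export
assign_sides <- function(centroids) {
  centroids <- as_xy(centroids)
  n <- nrow(centroids)
  if (n == 1) {
    gm_warn("single footfall: side labelled by lateral offset sign alone (low confidence)")
    return(list(sides = "left", confidence = 0, offsets = 0))
  }
  ctr <- colMeans(centroids)
  centred <- sweep(centroids, 2, ctr)
  sv <- svd(centred)
  w <- sv$v[, 1]                               # progression direction
  if (sum((centroids[n, ] - centroids[1, ]) * w) < 0) w <- -w
  lat <- c(-w[2], w[1])                        # left of walking direction
  offsets <- drop(centred %*% lat)
  cand1 <- rep(c("left", "right"), length.out = n)
  cand2 <- rep(c("right", "left"), length.out = n)
  agree <- function(sides) mean((offsets > 0) == (sides == "left"))
  a1 <- agree(cand1); a2 <- agree(cand2)
  if (abs(a1 - a2) < 1e-12) {
    gm_warn("lateral offsets uninformative: alternation imposed from contact order")
  }
  sides <- if (a1 >= a2) cand1 else cand2
  list(sides = sides, confidence = max(a1, a2), offsets = offsets)
}

#' Segment a footprint into quadrilateral, regions and centroids
#'
#' The enclosing quadrilateral is the minimum-area rotated bounding
#' rectangle of the footprint's points. It is cut into three equal-length
#' slices along its long axis (heel, mid, fore, ordered by the walking
#' direction); each sub-centroid is the mean of the sensor points falling
#' in its slice and the midline joins the heel and fore centroids.
#'
#' @param points data.frame with `x_cm`, `y_cm` (one footprint).
#' @param walk_dir length-2 unit vector, the pass's direction of
#'   progression; the fore end of the foot is the end farther along it.
#' @return object of class `footfall_geometry`.
#' @export
segment_footprint <- function(points, walk_dir = c(0, 1)) {
  xy <- as_xy(points)
  if (nrow(unique(xy)) < 3 || points_collinear(unique(xy))) {
    gm_stop("degenerate footprint: fewer than 3 non-collinear points",
            "gaitmat_degenerate")
  }
  rect <- min_area_rect(xy)
  u <- rect$axis_long
  if (sum(u * walk_dir) < 0) u <- -u          # heel->fore along walking direction
  v <- c(-u[2], u[1])
  pu <- drop(xy %*% u)
  u0 <- min(drop(rect$corners %*% u)); u1 <- max(drop(rect$corners %*% u))
  b1 <- u0 + (u1 - u0) / 3; b2 <- u0 + 2 * (u1 - u0) / 3
  slice <- findInterval(pu, c(b1, b2)) + 1L    # 1 heel, 2 mid, 3 fore
  cents <- lapply(1:3, function(s) {
    if (!any(slice == s)) return(NULL)
    colMeans(xy[slice == s, , drop = FALSE])
  })
  if (any(vapply(cents, is.null, logical(1)))) {
    gm_stop("degenerate footprint: empty heel/mid/fore slice", "gaitmat_degenerate")
  }
  v0 <- min(drop(rect$corners %*% v)); v1 <- max(drop(rect$corners %*% v))
  region <- function(a, b) rbind(a * u + v0 * v, b * u + v0 * v,
                                 b * u + v1 * v, a * u + v1 * v)
  heel_c <- cents[[1]]; fore_c <- cents[[3]]
  structure(
    list(
      quad = rect$corners, rect = rect, axis_long = u, axis_short = v,
      regions = list(heel = region(u0, b1), mid = region(b1, b2), fore = region(b2, u1)),
      heel_centroid = heel_c, mid_centroid = cents[[2]], fore_centroid = fore_c,
      overall_centroid = colMeans(xy),
      midline = rbind(heel_c, fore_c),
      slice = slice, n_points = nrow(xy)
    ),
    class = "footfall_geometry"
  )
}

#' Segment a pass into footfalls
#'
#' Full per-pass segmentation: estimate the footfall count, cluster the
#' points, order clusters by first contact, label sides, and build each
#' footprint's geometry. Degenerate footprints are excluded with a logged
#' reason.
#'
#' @param pass a `pass_recording` from [split_passes()].
#' @param k optional override for the footfall count.
#' @return object of class `segmented_pass`: list of footfalls (each with
#'   `points`, `side`, `order_index`, contacts and geometry), plus
#'   `walk_dir`, `k`, and `exclusions`.
#' @export
segment_pass <- function(pass, k = NULL) {
  pts <- pass$points
  est <- estimate_footfall_count(pts)
  if (is.null(k)) k <- est$k
  cl <- cluster_footfalls(pts, k, centers = if (k == est$k) est$centers else NULL)
  first_contact <- vapply(seq_len(k), function(i) min(pts$t_peak[cl == i]), numeric(1))
  ord <- order(first_contact)
  centroids <- t(vapply(ord, function(i) {
    c(mean(pts$x_cm[cl == i]), mean(pts$y_cm[cl == i]))
  }, numeric(2)))
  if (nrow(centroids) >= 2) {
    disp <- centroids[nrow(centroids), ] - centroids[1, ]
    walk_dir <- disp / sqrt(sum(disp^2))
  } else {
    walk_dir <- c(0, 1)
  }
  sides <- if (k >= 2) assign_sides(centroids)$sides else {
    withCallingHandlers(assign_sides(centroids)$sides,
                        warning = function(w) invokeRestart("muffleWarning"))
  }
  footfalls <- vector("list", length(ord)); exclusions <- list()
  for (j in seq_along(ord)) {
    i <- ord[j]
    p_i <- pts[cl == i, , drop = FALSE]
    geom <- tryCatch(segment_footprint(p_i, walk_dir), gaitmat_degenerate = function(e) e)
    if (inherits(geom, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        list(order_index = j, reason = conditionMessage(geom), n_points = nrow(p_i))
      next
    }
    footfalls[[j]] <- structure(
      list(points = p_i, side = sides[j], order_index = j,
           first_contact = min(p_i$t_peak), last_contact = max(p_i$t_peak),
           geometry = geom),
      class = "footfall"
    )
  }
  structure(
    list(footfalls = footfalls, k = k, walk_dir = walk_dir,
         cluster = cl, order = ord, exclusions = exclusions,
         pass_index = pass$pass_index, subject_id = pass$subject_id,
         visit_id = pass$visit_id, class_label = pass$class_label,
         height_cm = pass$height_cm),
    class = "segmented_pass"
  )
}

#' Diagnostic plot of a segmented pass
#'
#' Draws sensor points coloured by footfall, the enclosing quadrilaterals,
#' the heel/mid/fore sub-centroids and the foot midlines.
#' @param x a `segmented_pass`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.segmented_pass <- function(x, ...) {
  pts <- do.call(rbind, lapply(x$footfalls, function(f) if (!is.null(f)) f$points))
  cols <- grDevices::rainbow(length(x$footfalls))
  graphics::plot(pts$x_cm, pts$y_cm, pch = 16, cex = 0.4, col = "grey70",
                 xlab = "x (cm)", ylab = "y (cm)", asp = 1, ...)
  for (j in seq_along(x$footfalls)) {
    f <- x$footfalls[[j]]
    if (is.null(f)) next
    g <- f$geometry
    graphics::polygon(g$quad, border = cols[j])
    graphics::segments(g$midline[1, 1], g$midline[1, 2],
                       g$midline[2, 1], g$midline[2, 2], col = "orange", lwd = 2)
    graphics::points(rbind(g$heel_centroid, g$mid_centroid, g$fore_centroid),
                     col = c("red", "blue", "darkgreen"), pch = 3)
    graphics::text(g$overall_centroid[1], g$overall_centroid[2],
                   labels = paste0(j, substr(f$side, 1, 1)), cex = 0.8)
  }
  invisible(x)
}
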