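# Planar geometry primitives: shoelace areas, convex hulls, minimum-area
# rotated bounding rectangles, and angle conventions used by the footfall
# geometry features. Coordinates are centimetres in mat frame (x lateral,
# y longitudinal) unless stated otherwise.

as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_cm", "y_cm") %in% names(points))) {
      points <- cbind(points$x_cm, points$y_cm)
    } else {
      points <- as.matrix(points[, 1:2])
    }
  }
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 2)
  m
}

#' Signed shoelace area of a polygon
#' @param xy two-column matrix of vertices in order (not closed).
#' @return area in squared input units (absolute value).
#' @keywords internal
polygon_area <- function(xy) {
  xy <- as_xy(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

points_collinear <- function(xy, tol = 1e-9) {
  xy <- as_xy(xy)
  if (nrow(xy) < 3) return(TRUE)
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2, ctr))$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Convex hull vertices of a point set
#'
#' Thin wrapper over [grDevices::chull()] returning the hull vertices in
#' counter-clockwise order.
#' @param points two-column matrix or data frame with `x_cm`/`y_cm`.
#' @return matrix of hull vertices (counter-clockwise, not closed).
#' @export
convex_hull <- function(points) {
  xy <- as_xy(points)
  idx <- grDevices::chull(xy)      # clockwise order
  xy[rev(idx), , drop = FALSE]
}

#' Area of the convex hull of a footprint's sensor points
#'
#' The hull area feature: the enclosed area of the convex polygon bounding
#' the footprint's activated sensor coordinates.
#'
#' @param points two-column matrix or data frame with `x_cm`, `y_cm`.
#' @return area in cm^2.
#' @export
hull_area <- function(points) {
  xy <- unique(as_xy(points))
  if (nrow(xy) < 3 || points_collinear(xy)) {
    gm_stop("hull_area needs >= 3 non-collinear points", "gaitmat_degenerate")
  }
  polygon_area(convex_hull(xy))
}

#' Minimum-area rotated bounding rectangle
#'
#' Rotating-calipers search over convex-hull edges: the minimum-area
#' enclosing rectangle of a convex polygon has a side collinear with one
#' of its edges.
#'
#' @param points two-column matrix or data frame.
#' @return list with `corners` (4 x 2, in order around the rectangle),
#'   `center`, `axis_long` / `axis_short` (unit vectors), `len_long`,
#'   `len_short`, `area`.
#' @export
min_area_rect <- function(points) {
  xy <- unique(as_xy(points))
  if (nrow(xy) < 3 || points_collinear(xy)) {
    gm_stop("min_area_rect needs >= 3 non-collinear points", "gaitmat_degenerate")
  }
  hull <- convex_hull(xy)
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    a <- hull[i, ]
    b <- hull[if (i == n) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area - 1e-12) {
      best <- list(u = u, v = v, u0 = min(pu), u1 = max(pu),
                   v0 = min(pv), v1 = max(pv), area = area)
    }
  }
  with(best, {
    corners <- rbind(
      u0 * u + v0 * v, u1 * u + v0 * v,
      u1 * u + v1 * v, u0 * u + v1 * v
    )
    lu <- u1 - u0; lv <- v1 - v0
    if (lu >= lv) {
      axis_long <- u; axis_short <- v; len_long <- lu; len_short <- lv
    } else {
      axis_long <- v; axis_short <- u; len_long <- lv; len_short <- lu
    }
    list(
      corners = corners,
      center = ((u0 + u1) / 2) * u + ((v0 + v1) / 2) * v,
      axis_long = axis_long, axis_short = axis_short,
      len_long = len_long, len_short = len_short, area = area
    )
  })
}

#' Perpendicular distance from a point to the infinite line through a, b
#' @keywords internal
point_line_distance <- function(p, a, b) {
  p <- as.numeric(p); a <- as.numeric(a); b <- as.numeric(b)
  d <- b - a
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) gm_stop("degenerate line (a == b)", "gaitmat_degenerate")
  abs(d[1] * (a[2] - p[2]) - d[2] * (a[1] - p[1])) / nrm
}

#' Membership of points in a convex polygon
#'
#' @param points n x 2 matrix of query points.
#' @param poly convex polygon vertices in order.
#' @param eps boundary tolerance: points within `eps` of an edge count as
#'   inside when `eps > 0`, strictly inside when `eps < 0`.
#' @return logical vector.
#' @keywords internal
points_in_convex_polygon <- function(points, poly, eps = 1e-9) {
  pts <- as_xy(points)
  poly <- as_xy(poly)
  # ensure counter-clockwise
  x <- poly[, 1]; y <- poly[, 2]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0) {
    poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  }
  inside <- rep(TRUE, nrow(pts))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    edge_len <- sqrt(sum((b - a)^2))
    inside <- inside & (cr >= -eps * max(edge_len, 1))
  }
  inside
}

#' Signed angle from one direction to another, degrees
#'
#' Positive counter-clockwise, in (-180, 180].
#' @keywords internal
signed_angle_deg <- function(from, to) {
  from <- as.numeric(from); to <- as.numeric(to)
  a <- atan2(from[1] * to[2] - from[2] * to[1], sum(from * to)) * 180 / pi
  if (a <= -180) a + 360 else a
}

rotate_xy <- function(xy, theta_rad) {
  xy <- as_xy(xy)
  R <- matrix(c(cos(theta_rad), sin(theta_rad),
                -sin(theta_rad), cos(theta_rad)), 2, 2)
  xy %*% t(R)
}
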