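#' Polygon utilities for base-of-support geometry
#'
#' The base of support (BoS) is represented as a simple polygon in the
#' ground plane, stored as an n x 2 matrix of vertices in metres, ordered
#' counter-clockwise.  All geometric primitives operate in metres
#' internally; distances are reported in centimetres and areas in square
#' centimetres at the user-facing boundary, the units in which gait
#' balance-control measures are conventionally reported.
#'
#' @name polygon-geometry
NULL

## signed shoelace area in m^2 (positive for counter-clockwise order)
signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

## orient a polygon counter-clockwise
orient_ccw <- function(poly) {
  if (signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

## exact test for self-intersection, O(n^2) over edge pairs
edges_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(den) < 1e-15) return(FALSE)          # parallel: adjacency handles touching
  t <- ((q1[1L] - p1[1L]) * d2[2L] - (q1[2L] - p1[2L]) * d2[1L]) / den
  u <- ((q1[1L] - p1[1L]) * d1[2L] - (q1[2L] - p1[2L]) * d1[1L]) / den
  eps <- 1e-12
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

#' Validate a base-of-support polygon
#'
#' Checks that a vertex matrix describes a simple polygon with at least
#' three vertices and strictly positive area, and returns it oriented
#' counter-clockwise.
#'
#' @param poly numeric n x 2 matrix of vertices (metres).
#' @param check_simple logical; test all non-adjacent edge pairs for
#'   crossings (O(n^2), skip for polygons known to be convex).
#' @return the validated polygon, counter-clockwise.
#' @export
as_polygon <- function(poly, check_simple = TRUE) {
  poly <- as.matrix(poly)
  if (!is.numeric(poly) || ncol(poly) != 2L)
    stop("polygon must be a numeric n x 2 matrix")
  if (nrow(poly) < 3L)
    stop("polygon needs at least 3 vertices, got ", nrow(poly))
  if (any(!is.finite(poly)))
    stop("polygon vertices must be finite")
  if (check_simple) {
    n <- nrow(poly)
    for (i in seq_len(n - 2L)) {
      jmax <- if (i == 1L) n - 1L else n
      j <- i + 2L
      while (j <= jmax) {
        if (edges_intersect(poly[i, ], poly[i %% n + 1L, ],
                            poly[j, ], poly[j %% n + 1L, ]))
          stop("polygon is self-intersecting (edges ", i, " and ", j, ")")
        j <- j + 1L
      }
    }
  }
  if (abs(signed_area(poly)) < 1e-14)
    stop("degenerate polygon: area is zero")
  orient_ccw(poly)
}

#' Area of a base-of-support polygon
#'
#' Shoelace area of a simple polygon, reported in cm^2.
#'
#' @inheritParams as_polygon
#' @return area in cm^2.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  abs(signed_area(poly)) * 1e4
}

## minimum distance (m) from point p to the closed polygonal boundary,
## vectorised over edges
dist_to_boundary_m <- function(p, poly) {
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- ex^2 + ey^2
  t <- ((p[1L] - x1) * ex + (p[2L] - y1) * ey) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- x1 + t * ex - p[1L]
  dy <- y1 + t * ey - p[2L]
  sqrt(min(dx^2 + dy^2))
}

## even-odd crossing test; points within `eps` of the boundary count as inside
point_in_polygon <- function(p, poly, eps = 1e-12) {
  if (dist_to_boundary_m(p, poly) <= eps) return(TRUE)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  crosses <- ((y > p[2L]) != (yn > p[2L]))
  if (!any(crosses)) return(FALSE)
  xs <- x[crosses] + (p[2L] - y[crosses]) * (xn[crosses] - x[crosses]) /
    (yn[crosses] - y[crosses])
  sum(xs > p[1L]) %% 2L == 1L
}

#' CoM-to-BoS distance
#'
#' Minimum Euclidean distance from the horizontal projection of the centre
#' of mass to the boundary of the base of support; the static
#' balance-control measure.  The distance is always non-negative; whether
#' the CoM projection lies inside the BoS is reported separately.
#'
#' @param com_xy numeric length-2 vector, CoM ground-plane position (m).
#' @param poly BoS polygon, n x 2 matrix in metres.
#' @return list with `distance` (cm) and `inside` (logical).
#' @export
com_bos_distance <- function(com_xy, poly) {
  poly <- as_polygon(poly)
  com_xy <- as.numeric(com_xy)
  if (length(com_xy) < 2L || any(!is.finite(com_xy[1:2])))
    stop("com_xy must be a finite (x, y) position")
  com_xy <- com_xy[1:2]
  d <- dist_to_boundary_m(com_xy, poly)
  list(distance = d * 100, inside = point_in_polygon(com_xy, poly))
}

## first positive ray/boundary intersection parameter (m), or NA if the ray
## never meets the boundary.  `org` in m, `dir` a unit vector.
ray_boundary_m <- function(org, dir, poly) {
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  ex <- x2 - x1; ey <- y2 - y1
  den <- dir[1L] * ey - dir[2L] * ex
  ok <- abs(den) > 1e-15
  t <- ((x1 - org[1L]) * ey - (y1 - org[2L]) * ex) / den
  u <- ((x1 - org[1L]) * dir[2L] - (y1 - org[2L]) * dir[1L]) / den
  hit <- ok & t >= 0 & u >= -1e-12 & u <= 1 + 1e-12
  if (!any(hit, na.rm = TRUE)) return(NA_real_)
  min(t[which(hit)])
}

#' CoM displacement along the velocity vector to the BoS boundary
#'
#' Length of the ray from the CoM ground-plane projection, along the unit
#' horizontal CoM velocity direction, to its first intersection with the
#' BoS boundary; the dynamic balance-control measure.  Defined for every
#' interior CoM; for a CoM outside the BoS it is defined only when the ray
#' re-enters the polygon.
#'
#' @inheritParams com_bos_distance
#' @param velocity_xy numeric length-2 horizontal CoM velocity (m/s).
#' @param velocity_eps speed below which the direction is considered
#'   undefined (m/s).
#' @return list with `displacement` (cm, `NA` when undefined), `defined`
#'   (logical) and `reason` (`"ok"`, `"zero_velocity"` or `"no_intersection"`).
#' @export
comv_bos_displacement <- function(com_xy, velocity_xy, poly,
                                  velocity_eps = 1e-4) {
  poly <- as_polygon(poly)
  com_xy <- as.numeric(com_xy)[1:2]
  v <- as.numeric(velocity_xy)[1:2]
  speed <- sqrt(sum(v^2))
  if (!is.finite(speed) || speed <= velocity_eps)
    return(list(displacement = NA_real_, defined = FALSE,
                reason = "zero_velocity"))
  t <- ray_boundary_m(com_xy, v / speed, poly)
  if (is.na(t))
    return(list(displacement = NA_real_, defined = FALSE,
                reason = "no_intersection"))
  list(displacement = t * 100, defined = TRUE, reason = "ok")
}

#' Convex hull of a vertex set
#'
#' Counter-clockwise convex hull, used for the double-support base of
#' support.
#'
#' @param pts numeric n x 2 matrix (metres).
#' @return hull polygon, counter-clockwise.
#' @export
convex_hull <- function(pts) {
  pts <- as.matrix(pts)
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  orient_ccw(pts[idx, , drop = FALSE])
}
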