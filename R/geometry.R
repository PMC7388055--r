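# 3D primitives of the virtual workspace. All coordinates are millimetres in
# a right-handed frame: origin at the centre of the sensor pad, +y up,
# +z toward the user. Points are length-3 numeric vectors; point sets are
# n x 3 matrices. All shapes are closed sets: boundary contact counts as
# containment/contact.

#' Construct a 3D point
#'
#' Points are plain length-3 numeric vectors `c(x, y, z)` in millimetres.
#' This helper validates finiteness.
#'
#' @param x,y,z Coordinates in mm.
#' @return A numeric vector of length 3.
#' @export
pt3 <- function(x, y, z) {
  p <- c(as.numeric(x), as.numeric(y), as.numeric(z))
  if (length(p) != 3L || !all(is.finite(p)))
    stop("point coordinates must be three finite numbers", call. = FALSE)
  p
}

as_point_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    storage.mode(q) <- "double"
    q
  } else {
    matrix(pt3(q[1], q[2], q[3]), nrow = 1L)
  }
}

#' Shape constructors
#'
#' Scene shapes used by the six training tasks: spheres (graspable objects
#' and diathermy targets), cylinders (containers and the traversal conduit;
#' `hollow = TRUE` marks open-ended containers), and axis-aligned cuboids
#' (the workspace bounds and the placement cube). All are closed sets.
#'
#' @param center,radius Sphere centre (mm) and radius (mm > 0).
#' @param axis_a,axis_b Cylinder axis endpoints (distinct points, mm).
#' @param hollow Logical; hollow cylinders are containers open at the ends.
#' @param min_corner,max_corner Cuboid corners, `min_corner < max_corner`
#'   componentwise.
#' @return A shape object (list with class `"lapskill_shape"`).
#' @name shapes
NULL

#' @rdname shapes
#' @export
sphere <- function(center, radius) {
  center <- pt3(center[1], center[2], center[3])
  if (!is.finite(radius) || radius <= 0) stop("sphere radius must be > 0", call. = FALSE)
  structure(list(kind = "sphere", center = center, radius = as.numeric(radius)),
            class = "lapskill_shape")
}

#' @rdname shapes
#' @export
cylinder <- function(axis_a, axis_b, radius, hollow = FALSE) {
  axis_a <- pt3(axis_a[1], axis_a[2], axis_a[3])
  axis_b <- pt3(axis_b[1], axis_b[2], axis_b[3])
  if (all(axis_a == axis_b)) stop("cylinder axis endpoints must be distinct", call. = FALSE)
  if (!is.finite(radius) || radius <= 0) stop("cylinder radius must be > 0", call. = FALSE)
  structure(list(kind = "cylinder", axis_a = axis_a, axis_b = axis_b,
                 radius = as.numeric(radius), hollow = isTRUE(hollow)),
            class = "lapskill_shape")
}

#' @rdname shapes
#' @export
cuboid <- function(min_corner, max_corner) {
  min_corner <- pt3(min_corner[1], min_corner[2], min_corner[3])
  max_corner <- pt3(max_corner[1], max_corner[2], max_corner[3])
  if (!all(min_corner < max_corner))
    stop("cuboid requires min_corner < max_corner componentwise", call. = FALSE)
  structure(list(kind = "cuboid", min_corner = min_corner, max_corner = max_corner),
            class = "lapskill_shape")
}

#' Construct a 3D polyline
#'
#' Polylines carry the ideal path of a task: the shortest tip route a
#' flawless execution would follow. Consecutive vertices must be distinct.
#'
#' @param vertices An n x 3 numeric matrix (n >= 2) of vertices in mm, or a
#'   list of length-3 points.
#' @return An n x 3 matrix with class `"lapskill_polyline"`.
#' @export
polyline3 <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  v <- as_point_matrix(vertices)
  if (nrow(v) < 2L) stop("a polyline needs at least 2 vertices", call. = FALSE)
  if (!all(is.finite(v))) stop("polyline vertices must be finite", call. = FALSE)
  seglen <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  if (any(seglen == 0)) stop("consecutive polyline vertices must be distinct", call. = FALSE)
  structure(v, class = c("lapskill_polyline", "matrix", "array"))
}

#' Total arc length of a polyline
#'
#' @param p A polyline (see [polyline3()]) or an n x 3 matrix of vertices.
#' @return Length in mm (non-negative).
#' @export
polyline_length <- function(p) {
  v <- as_point_matrix(unclass(p))
  if (nrow(v) < 2L) stop("a polyline needs at least 2 vertices", call. = FALSE)
  sum(sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}

# Distances from a set of points (n x 3) to one segment a-b. Returns n values.
dist_points_segment <- function(q, a, b) {
  q <- as_point_matrix(q)
  ab <- b - a
  den <- sum(ab * ab)
  if (den == 0) return(sqrt(rowSums(sweep(q, 2L, a)^2)))
  t <- pmin(1, pmax(0, (sweep(q, 2L, a) %*% ab) / den))
  foot <- matrix(a, nrow(q), 3L, byrow = TRUE) + outer(drop(t), ab)
  sqrt(rowSums((q - foot)^2))
}

#' Minimum distance from a point to a polyline
#'
#' Used to decide whether the instrument tip is inside the ideal-path
#' corridor. Zero iff the point lies on the polyline.
#'
#' @param q A point (length-3 vector) or an n x 3 matrix of points.
#' @param p A polyline or vertex matrix.
#' @return Distance(s) in mm, one per row of `q`.
#' @export
dist_point_polyline <- function(q, p) {
  q <- as_point_matrix(q)
  v <- as_point_matrix(unclass(p))
  if (nrow(v) < 2L) stop("a polyline needs at least 2 vertices", call. = FALSE)
  d <- rep(Inf, nrow(q))
  for (i in seq_len(nrow(v) - 1L))
    d <- pmin(d, dist_points_segment(q, v[i, ], v[i + 1L, ]))
  d
}

# Arc length of the nearest point on the polyline for each query point,
# alongside the distance. Used by the traversal-coverage completion test.
polyline_nearest_arclength <- function(q, p) {
  q <- as_point_matrix(q)
  v <- as_point_matrix(unclass(p))
  nseg <- nrow(v) - 1L
  seglen <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seglen))
  best_d <- rep(Inf, nrow(q)); best_s <- rep(0, nrow(q))
  for (i in seq_len(nseg)) {
    a <- v[i, ]; b <- v[i + 1L, ]; ab <- b - a
    den <- sum(ab * ab)
    t <- pmin(1, pmax(0, (sweep(q, 2L, a) %*% ab) / den))
    foot <- matrix(a, nrow(q), 3L, byrow = TRUE) + outer(drop(t), ab)
    d <- sqrt(rowSums((q - foot)^2))
    upd <- d < best_d
    best_s[upd] <- cum0[i] + drop(t)[upd] * seglen[i]
    best_d[upd] <- d[upd]
  }
  list(distance = best_d, arclength = best_s, total = cum0[nseg + 1L])
}

unit_to <- function(from, to) {
  d <- to - from
  d / sqrt(sum(d * d))
}

# touch point on a sphere, penetrating `pen` mm, approached from the pivot side
touch_point <- function(shape, pivot, pen = 3) {
  shape$center + (shape$radius - pen) * unit_to(shape$center, pivot)
}

#' Minimum distance between two segments
#'
#' Supports instrument-clash detection (shaft-to-shaft distance). Symmetric
#' in its arguments; handles degenerate and parallel cases.
#'
#' @param a1,b1 Endpoints of the first segment (mm).
#' @param a2,b2 Endpoints of the second segment (mm).
#' @return Distance in mm.
#' @export
dist_segments <- function(a1, b1, a2, b2) {
  # Ericson, Real-Time Collision Detection, closest-point-of-two-segments.
  d1 <- b1 - a1; d2 <- b2 - a2; r <- a1 - a2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    s <- 0; t <- pmin(1, pmax(0, f / e))
  } else {
    c_ <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- pmin(1, pmax(0, -c_ / a))
    } else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > eps) pmin(1, pmax(0, (b * f - c_ * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- pmin(1, pmax(0, -c_ / a)) }
      else if (t > 1) { t <- 1; s <- pmin(1, pmax(0, (b - c_) / a)) }
    }
  }
  p1 <- a1 + s * d1; p2 <- a2 + t * d2
  sqrt(sum((p1 - p2)^2))
}

#' Point-in-shape test
#'
#' Closed-set containment: boundary points are contained. For cylinders
#' (hollow or solid) containment means within `radius` of the axis and
#' between the planes through the axis endpoints.
#'
#' @param shape A shape from [sphere()], [cylinder()] or [cuboid()].
#' @param q A point or an n x 3 matrix of points.
#' @return Logical vector, one per query point.
#' @export
shape_contains <- function(shape, q) {
  q <- as_point_matrix(q)
  switch(shape$kind,
    sphere = sqrt(rowSums(sweep(q, 2L, shape$center)^2)) <= shape$radius,
    cylinder = {
      ab <- shape$axis_b - shape$axis_a
      L2 <- sum(ab * ab)
      t <- (sweep(q, 2L, shape$axis_a) %*% ab) / L2
      foot <- matrix(shape$axis_a, nrow(q), 3L, byrow = TRUE) + outer(drop(t), ab)
      radial <- sqrt(rowSums((q - foot)^2))
      drop(t) >= 0 & drop(t) <= 1 & radial <= shape$radius
    },
    cuboid = {
      apply(q, 1L, function(p) all(p >= shape$min_corner) && all(p <= shape$max_corner))
    },
    stop("unknown shape kind: ", shape$kind, call. = FALSE))
}

#' Signed/surface distance from points to a shape
#'
#' The contact queries behind event detection. For spheres and cuboids this
#' is the signed distance to the surface (negative inside); for cylinders it
#' is the unsigned distance to the lateral shell (the "margins" of a
#' container), including the rim when the point lies beyond the end planes.
#'
#' @param shape A shape object.
#' @param q A point or n x 3 matrix of points.
#' @return Numeric vector of distances in mm.
#' @export
shape_sdf <- function(shape, q) {
  q <- as_point_matrix(q)
  switch(shape$kind,
    sphere = sqrt(rowSums(sweep(q, 2L, shape$center)^2)) - shape$radius,
    cuboid = {
      # axis-aligned box SDF
      ctr <- (shape$min_corner + shape$max_corner) / 2
      half <- (shape$max_corner - shape$min_corner) / 2
      d <- abs(sweep(q, 2L, ctr)) - matrix(half, nrow(q), 3L, byrow = TRUE)
      outside <- sqrt(rowSums(pmax(d, 0)^2))
      inside <- pmin(apply(d, 1L, max), 0)
      outside + inside
    },
    cylinder = {
      ab <- shape$axis_b - shape$axis_a
      L <- sqrt(sum(ab * ab)); u <- ab / L
      rel <- sweep(q, 2L, shape$axis_a)
      s <- drop(rel %*% u)                       # axial coordinate
      radial <- sqrt(pmax(rowSums(rel^2) - s^2, 0))
      dr <- abs(radial - shape$radius)           # to the shell, radially
      dz <- pmax(pmax(-s, s - L), 0)             # axial overshoot beyond ends
      ifelse(dz > 0, sqrt(dr^2 + dz^2), dr)
    },
    stop("unknown shape kind: ", shape$kind, call. = FALSE))
}
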