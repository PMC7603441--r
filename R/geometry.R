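# 2-D construction geometry: directed lines, circles, intersections,
# least-squares concurrency. All angles in degrees; undirected line
# directions live in [0, 180).

#' Construct a 2-D point
#'
#' Points are plain length-2 numeric vectors `c(x, y)`; this constructor
#' only validates.
#'
#' @param x,y finite coordinates (mm or px, caller's choice but consistent).
#' @return Numeric vector `c(x, y)`.
#' @export
point2d <- function(x, y) {
  p <- c(as.numeric(x), as.numeric(y))
  if (length(p) != 2L || !all(is.finite(p)))
    stop("point coordinates must be two finite numbers")
  unname(p)
}

.as_pt <- function(p) {
  p <- unname(as.numeric(p))
  if (length(p) != 2L || !all(is.finite(p)))
    stop("expected a finite 2-D point")
  p
}

#' Normalize an undirected line direction to [0, 180) degrees
#' @param deg angle in degrees (any real).
#' @return Equivalent direction in `[0, 180)`.
#' @export
norm_dir <- function(deg) {
  d <- deg %% 180
  d[d < 0] <- d[d < 0] + 180
  # guard against 180 - eps rounding back up to exactly 180
  d[d >= 180] <- 0
  d
}

#' Construct a line from an anchor point and a direction
#'
#' Lines are stored as anchor + direction (not slope) so vertical planes
#' are representable.
#'
#' @param anchor point on the line.
#' @param direction_deg direction in degrees; normalized modulo 180.
#' @return Object of class `"line2d"` with fields `anchor`, `direction`.
#' @export
line2d <- function(anchor, direction_deg) {
  a <- .as_pt(anchor)
  if (!is.finite(direction_deg)) stop("line direction must be finite")
  structure(list(anchor = a, direction = norm_dir(direction_deg)),
            class = "line2d")
}

#' Line through two distinct points
#' @param p,q distinct points.
#' @return A [line2d()].
#' @export
line_through <- function(p, q) {
  p <- .as_pt(p); q <- .as_pt(q)
  if (isTRUE(all.equal(p, q, tolerance = 0)) || all(p == q))
    stop("cannot build a line through coincident points")
  line2d(p, atan2(q[2] - p[2], q[1] - p[1]) * 180 / pi)
}

#' Construct a circle
#' @param center center point.
#' @param radius strictly positive radius.
#' @return Object of class `"circle2d"` with fields `center`, `radius`.
#' @export
circle2d <- function(center, radius) {
  if (!is.finite(radius) || radius <= 0)
    stop("circle radius must be a positive finite number")
  structure(list(center = .as_pt(center), radius = as.numeric(radius)),
            class = "circle2d")
}

# unit direction vector of a line
.dir_vec <- function(l) {
  th <- l$direction * pi / 180
  c(cos(th), sin(th))
}

# tolerance below which two directions (mod 180) count as parallel, degrees
PARALLEL_TOL_DEG <- 1e-7

# smallest difference between two undirected directions, in [0, 90]
.dir_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Intersect two lines
#'
#' @param a,b objects of class `line2d`.
#' @return The intersection point, or `NULL` when the directions differ by
#'   less than the parallel tolerance (1e-7 degrees).
#' @export
intersect_lines <- function(a, b) {
  stopifnot(inherits(a, "line2d"), inherits(b, "line2d"))
  if (.dir_diff(a$direction, b$direction) < PARALLEL_TOL_DEG) return(NULL)
  da <- .dir_vec(a); db <- .dir_vec(b)
  # a$anchor + t*da = b$anchor + s*db ; solve for t via 2x2 cross products
  rhs <- b$anchor - a$anchor
  det <- da[1] * (-db[2]) - (-db[1]) * da[2]
  t <- (rhs[1] * (-db[2]) - (-db[1]) * rhs[2]) / det
  unname(a$anchor + t * da)
}

#' Perpendicular distance from a point to an infinite line
#' @param p a point; `l` a `line2d`.
#' @param l line.
#' @return Non-negative distance.
#' @export
perpendicular_distance <- function(p, l) {
  stopifnot(inherits(l, "line2d"))
  p <- .as_pt(p)
  d <- .dir_vec(l)
  v <- p - l$anchor
  abs(d[1] * v[2] - d[2] * v[1])
}

#' Intersect a line with a circle
#'
#' Tangency (distance from center to line within `1e-9 * radius` of the
#' radius) yields exactly one point. Results are ordered by signed position
#' along the line direction.
#'
#' @param l a `line2d`.
#' @param c a `circle2d`.
#' @return A list of 0, 1 or 2 points.
#' @export
intersect_line_circle <- function(l, c) {
  stopifnot(inherits(l, "line2d"), inherits(c, "circle2d"))
  d <- .dir_vec(l)
  v <- c$center - l$anchor
  t0 <- sum(d * v)                 # foot of perpendicular, along-line coord
  h <- abs(d[1] * v[2] - d[2] * v[1])  # center-to-line distance
  r <- c$radius
  if (abs(h - r) <= 1e-9 * r) {
    return(list(unname(l$anchor + t0 * d)))
  }
  if (h > r) return(list())
  half <- sqrt(r * r - h * h)
  list(unname(l$anchor + (t0 - half) * d),
       unname(l$anchor + (t0 + half) * d))
}

#' Least-squares concurrency point of a set of lines
#'
#' Finds the point minimizing the sum of squared perpendicular distances to
#' all lines, by the closed-form normal equations, together with the
#' root-mean-square residual distance. With two non-parallel lines this is
#' their intersection (residual 0); with concurrent lines the common point.
#'
#' @param lines list of `line2d` objects, length >= 2, not all mutually
#'   parallel.
#' @return List with `point` and `residual` (rms of perpendicular
#'   distances, same units as the coordinates).
#' @export
least_squares_point <- function(lines) {
  if (!is.list(lines) || length(lines) < 2L)
    stop("need at least two lines")
  lapply(lines, function(l) stopifnot(inherits(l, "line2d")))
  dirs <- vapply(lines, function(l) l$direction, numeric(1))
  if (all(.dir_diff(dirs, dirs[1]) < PARALLEL_TOL_DEG))
    stop("degenerate configuration: all lines are mutually parallel")
  # minimize sum_i (n_i . (p - a_i))^2 with unit normals n_i
  A <- matrix(0, 2, 2); b <- c(0, 0)
  for (l in lines) {
    d <- .dir_vec(l)
    n <- c(-d[2], d[1])
    A <- A + tcrossprod(n)
    b <- b + n * sum(n * l$anchor)
  }
  p <- solve(A, b)
  res <- vapply(lines, function(l) perpendicular_distance(p, l)^2, numeric(1))
  list(point = unname(p), residual = sqrt(mean(res)))
}

#' Circular mean of undirected line directions
#'
#' Angles are doubled, vector-averaged and halved, which makes the mean
#' well defined modulo 180 degrees (so 179 and 1 average to 0, not 90).
#'
#' @param angles_deg one or more directions in degrees.
#' @return Mean direction in `[0, 180)`.
#' @export
mean_direction <- function(angles_deg) {
  if (length(angles_deg) < 1L || !all(is.finite(angles_deg)))
    stop("need at least one finite angle")
  th <- 2 * angles_deg * pi / 180
  cx <- mean(cos(th)); sy <- mean(sin(th))
  if (sqrt(cx^2 + sy^2) < 1e-12)
    stop("directions are perfectly spread: mean direction undefined")
  norm_dir(atan2(sy, cx) * 90 / pi)
}

#' Rigid rotation of a point about a center
#' @param p point to rotate.
#' @param center rotation center.
#' @param angle_deg signed angle, positive counter-clockwise.
#' @return Rotated point.
#' @export
rotate_point <- function(p, center, angle_deg) {
  p <- .as_pt(p); center <- .as_pt(center)
  th <- angle_deg * pi / 180
  v <- p - center
  unname(center + c(cos(th) * v[1] - sin(th) * v[2],
                    sin(th) * v[1] + cos(th) * v[2]))
}
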