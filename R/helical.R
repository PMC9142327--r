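#' Helical (screw) axis decomposition of a rigid transform
#'
#' By Chasles' theorem every rigid displacement equals a rotation about a
#' unique line — the finite helical axis — plus a translation along it.
#' `helical_axis_from_transform` extracts that line (unit direction `h`,
#' on-axis point `q`), the rotation angle `theta` about it and the signed
#' screw translation `t` along it. The axis point is the locus of minimal
#' displacement: for on-axis points the displacement vector `p` is parallel
#' to the axis and rotation-invariant, `p = A^T p`.
#'
#' Rotations below `degeneracy_threshold` leave the axis position undefined
#' (the normal equations become rank-0); the decomposition then degrades
#' gracefully to a pure-translation description with `degenerate = TRUE`.
#' Rotations above the threshold but below 0.5 degrees keep a defined axis
#' yet its position is highly sensitive to measurement error, so the result
#' is flagged `unreliable` rather than rejected.
#'
#' @param t a [rigid_transform].
#' @param degeneracy_threshold angle in degrees below which the rotation is
#'   treated as degenerate (default 0.1, well below the smallest rotations
#'   of interest at dental scale, ~0.8 deg).
#' @param axis_point_strategy `"minimum_norm"` (default): the on-axis point
#'   closest to the origin, from the pseudoinverse of the rank-2 normal
#'   system; or `"fix_coordinate"`: zero the coordinate with the largest
#'   axis component and solve the remaining 2x2 system. Both lie on the
#'   same line.
#' @return An object of class `helical_axis`: list with `h` (unit
#'   direction), `q` (on-axis point, mm; `NA` when degenerate), `theta`
#'   (degrees, in `[0, 180]`), `t` (signed mm along `h`), `degenerate`,
#'   `unreliable` flags.
#' @examples
#' tr <- screw_transform(c(0, 0, 1), c(5, 0, 0), theta_deg = 2, t_mm = 0.1)
#' helical_axis_from_transform(tr)
#' @export
helical_axis_from_transform <- function(t, degeneracy_threshold = 0.1,
                                        axis_point_strategy = c("minimum_norm",
                                                                "fix_coordinate")) {
  stopifnot(is_rigid_transform(t))
  axis_point_strategy <- match.arg(axis_point_strategy)
  theta <- rotation_angle(t$A)
  o_norm <- sqrt(sum(t$o^2))
  if (theta < degeneracy_threshold) {
    if (o_norm > 0) {
      return(new_helical_axis(h = t$o / o_norm, q = rep(NA_real_, 3L),
                              theta = theta, t = o_norm,
                              degenerate = TRUE, unreliable = TRUE))
    }
    return(new_helical_axis(h = c(0, 0, 1), q = rep(NA_real_, 3L),
                            theta = theta, t = 0,
                            degenerate = TRUE, unreliable = TRUE))
  }
  h <- axis_direction(t$A, degeneracy_threshold = degeneracy_threshold)
  q <- axis_point(t, strategy = axis_point_strategy,
                  degeneracy_threshold = degeneracy_threshold)
  tt <- screw_translation(t, h)
  new_helical_axis(h = h, q = q, theta = theta, t = tt,
                   degenerate = FALSE, unreliable = theta < 0.5)
}

new_helical_axis <- function(h, q, theta, t, degenerate, unreliable) {
  structure(list(h = as.numeric(h), q = as.numeric(q),
                 theta = as.numeric(theta), t = as.numeric(t),
                 degenerate = isTRUE(degenerate),
                 unreliable = isTRUE(unreliable)),
            class = "helical_axis")
}

#' @export
print.helical_axis <- function(x, ...) {
  cat("Finite helical axis\n")
  if (x$degenerate) {
    cat(sprintf("  degenerate (theta = %.4f deg below axis-definition threshold)\n",
                x$theta))
    cat(sprintf("  pure translation: %.4f mm along (%.4f, %.4f, %.4f)\n",
                x$t, x$h[1], x$h[2], x$h[3]))
  } else {
    cat(sprintf("  direction h: (%.4f, %.4f, %.4f)\n", x$h[1], x$h[2], x$h[3]))
    cat(sprintf("  point q:     (%.3f, %.3f, %.3f) mm\n", x$q[1], x$q[2], x$q[3]))
    cat(sprintf("  rotation:    %.2f deg about h (right-hand rule)\n", x$theta))
    cat(sprintf("  translation: %.3f mm along h\n", x$t))
    if (x$unreliable)
      cat("  note: rotation < 0.5 deg; axis position is sensitive to noise\n")
  }
  invisible(x)
}

#' Rotation axis direction of a rotation matrix
#'
#' The unit eigenvector `h` of eigenvalue 1 (`A h = h`), oriented by the
#' right-hand rule via the skew-symmetric part of `A`. Near 180 degrees the
#' skew part vanishes and the axis is taken from the dominant eigenvector
#' of the symmetric part `(A + K)/2`, sign fixed so the first non-zero
#' component is positive.
#'
#' @param A 3x3 proper rotation matrix or [rigid_transform].
#' @param degeneracy_threshold degrees; below it the axis is undefined and
#'   an error is raised (callers should use the pure-translation path).
#' @return Unit length-3 direction vector.
#' @export
axis_direction <- function(A, degeneracy_threshold = 0.1) {
  if (is_rigid_transform(A)) A <- A$A
  theta <- rotation_angle(A)
  if (theta < degeneracy_threshold)
    stop("rotation angle ", format(theta),
         " deg is below the degeneracy threshold; axis direction undefined")
  s <- c(A[3, 2] - A[2, 3], A[1, 3] - A[3, 1], A[2, 1] - A[1, 2])  # 2 sin(theta) h
  ns <- sqrt(sum(s^2))
  if (ns > 1e-6) return(s / ns)
  # theta ~ 180 deg: axis from the symmetric part (A + K)/2, eigenvalue 1
  e <- eigen((A + diag(3)) / 2, symmetric = TRUE)
  h <- e$vectors[, which.max(e$values)]
  nz <- which(abs(h) > 1e-12)[1L]
  if (h[nz] < 0) h <- -h
  h / sqrt(sum(h^2))
}

#' A point on the helical axis of a rigid transform
#'
#' Solves the on-axis condition `(A + A^T - 2K) n + (K - A^T) o = 0`, whose
#' solutions are exactly the minimal-displacement points forming the axis.
#' The system is rank 2 (its null space is the axis direction), so a
#' convention picks one solution: `"minimum_norm"` returns the axis point
#' closest to the origin (pseudoinverse solution); `"fix_coordinate"` zeroes
#' the coordinate with the largest absolute axis component and solves the
#' remaining 2-unknown system — the classical fix-one-coordinate device,
#' generalized so it stays well-posed for any axis orientation.
#'
#' @param t a [rigid_transform] with non-degenerate rotation.
#' @param strategy `"minimum_norm"` or `"fix_coordinate"`.
#' @param degeneracy_threshold degrees; below it an error is raised.
#' @return Length-3 point on the axis (mm).
#' @export
axis_point <- function(t, strategy = c("minimum_norm", "fix_coordinate"),
                       degeneracy_threshold = 0.1) {
  stopifnot(is_rigid_transform(t))
  strategy <- match.arg(strategy)
  theta <- rotation_angle(t$A)
  if (theta < degeneracy_threshold)
    stop("rotation angle ", format(theta),
         " deg is below the degeneracy threshold; axis position undefined")
  M <- t$A + t(t$A) - 2 * diag(3)
  b <- -drop((diag(3) - t(t$A)) %*% t$o)
  if (strategy == "minimum_norm") {
    s <- svd(M)
    pos <- s$d > max(s$d) * 1e-12
    dinv <- ifelse(pos, 1 / s$d, 0)
    return(drop(s$v %*% (dinv * crossprod(s$u, b))))
  }
  h <- axis_direction(t$A, degeneracy_threshold = degeneracy_threshold)
  k <- which.max(abs(h))
  x2 <- qr.solve(M[, -k, drop = FALSE], b)
  n <- numeric(3L)
  n[-k] <- x2
  n
}

#' Signed screw translation along the helical axis
#'
#' The displacement of any on-axis point is parallel to the axis; its
#' component along `h` is the screw translation. Computed as the dot
#' product of the on-axis displacement with `h` (equivalently `o . h`,
#' since the rotational part of the displacement is perpendicular to `h`).
#'
#' @param t a [rigid_transform].
#' @param h unit axis direction of `t`.
#' @return Signed translation in mm along `h`.
#' @export
screw_translation <- function(t, h) {
  stopifnot(is_rigid_transform(t))
  h <- as.numeric(h)
  if (abs(sqrt(sum(h^2)) - 1) > 1e-6) stop("'h' must be a unit vector")
  theta <- rotation_angle(t$A)
  if (theta >= 0.1) {
    q <- axis_point(t)
    p <- drop((t$A - diag(3)) %*% q) + t$o
    # consistency: on-axis displacement must be parallel to h
    perp <- p - sum(p * h) * h
    if (sqrt(sum(perp^2)) > 1e-6 * max(1, sqrt(sum(p^2))))
      stop("'h' is not the helical axis direction of 't' ",
           "(on-axis displacement not parallel to h)")
    return(sum(p * h))
  }
  sum(t$o * h)
}

#' Orthogonal projection of a point onto the helical axis
#'
#' Foot of the perpendicular from `d` to the line through `q` with
#' direction `h`: `q' = q + (((d - q) . h) / (h . h)) h`.
#'
#' @param d point to project (mm).
#' @param q a point on the axis (mm).
#' @param h axis direction (non-zero; need not be unit length).
#' @return The projected point `q'`; `(d - q')` is perpendicular to `h`.
#' @export
project_onto_axis <- function(d, q, h) {
  d <- as.numeric(d); q <- as.numeric(q); h <- as.numeric(h)
  hh <- sum(h^2)
  if (hh == 0) stop("'h' must be non-zero")
  q + (sum((d - q) * h) / hh) * h
}

#' Rotation angle about the helical axis from an off-axis point
#'
#' Geometric construction of the rotation angle: track an arbitrary
#' off-axis point `d0` to its image `d1 = A d0 + o`, remove the screw
#' translation (`d2 = d1 - t h`), project `d0` and `d2` onto the axis at
#' their common foot `q'`, and measure the angle between `(d0 - q')` and
#' `(d2 - q')`. For any valid `d0` this equals the trace-formula angle
#' [rotation_angle()].
#'
#' @param t the [rigid_transform].
#' @param axis the [helical_axis] of `t`.
#' @param d0 a point strictly off the axis (perpendicular distance
#'   > 1e-6 mm).
#' @return Angle in degrees.
#' @export
rotation_angle_about_axis <- function(t, axis, d0) {
  stopifnot(is_rigid_transform(t), inherits(axis, "helical_axis"))
  if (axis$degenerate) stop("axis is degenerate; angle construction undefined")
  d0 <- as.numeric(d0)
  q1 <- project_onto_axis(d0, axis$q, axis$h)
  r0 <- d0 - q1
  if (sqrt(sum(r0^2)) <= 1e-6)
    stop("'d0' lies on or within 1e-6 mm of the axis; ill-conditioned point")
  d1 <- drop(t$A %*% d0) + t$o
  d2 <- d1 - axis$t * axis$h
  r2 <- d2 - q1
  cosang <- sum(r0 * r2) / (sqrt(sum(r0^2)) * sqrt(sum(r2^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Reconstruct the rigid transform of a helical axis
#'
#' Inverse of [helical_axis_from_transform()]: rotate `theta` about the
#' line `(q, h)`, then translate `t` along `h`.
#'
#' @param axis a [helical_axis] (non-degenerate, or a pure translation).
#' @return A [rigid_transform].
#' @export
transform_from_helical_axis <- function(axis) {
  stopifnot(inherits(axis, "helical_axis"))
  if (axis$degenerate)
    return(rigid_transform(diag(3), axis$t * axis$h))
  screw_transform(axis$h, axis$q, axis$theta, axis$t)
}
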