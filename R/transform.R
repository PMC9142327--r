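#' Construct a rigid transform
#'
#' A rigid transform maps a point `n` to `A n + o`, with `A` a proper
#' (det = +1) orthogonal 3x3 rotation matrix and `o` a translation vector
#' in mm. Orthogonality and handedness are checked to 1e-9 on construction;
#' a matrix failing the check is rejected unless `project = TRUE`, in which
#' case it is re-projected onto the nearest rotation by SVD (silent repair
#' hides upstream bugs, so projection is opt-in).
#'
#' @param A 3x3 rotation matrix (dimensionless).
#' @param o length-3 translation vector (mm). Default zero.
#' @param project if `TRUE`, replace `A` by its nearest proper rotation
#'   before validating.
#' @return An object of class `rigid_transform` with elements `A` and `o`.
#' @examples
#' t <- rigid_transform(diag(3), c(1, 2, 3))
#' apply_transform(t, point_cloud(rbind(c(0, 0, 0))))
#' @export
rigid_transform <- function(A, o = c(0, 0, 0), project = FALSE) {
  A <- as.matrix(A)
  o <- as.numeric(o)
  if (!all(dim(A) == c(3L, 3L))) stop("'A' must be a 3x3 matrix")
  if (length(o) != 3L) stop("'o' must be a length-3 vector")
  if (anyNA(A) || anyNA(o)) stop("transform contains non-finite values")
  if (project) A <- nearest_rotation(A)
  tol <- 1e-9
  if (max(abs(crossprod(A) - diag(3))) > tol)
    stop("'A' is not orthogonal within tolerance 1e-9 ",
         "(use project = TRUE to re-project)")
  if (abs(det(A) - 1) > tol)
    stop("'A' must be a proper rotation (det = +1); reflections are invalid")
  dimnames(A) <- NULL
  structure(list(A = A, o = o), class = "rigid_transform")
}

#' Nearest proper rotation to a matrix
#'
#' Orthogonal Procrustes projection: the proper rotation closest to `M` in
#' Frobenius norm, via SVD with a sign flip of the smallest singular
#' direction when needed.
#'
#' @param M 3x3 numeric matrix.
#' @return A 3x3 proper rotation matrix.
#' @export
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("matrix is rank-deficient; nearest rotation undefined")
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (m = A n + o)\n")
  cat("Rotation angle:", format(rotation_angle(x$A), digits = 6), "deg\n")
  cat("A =\n")
  print(round(x$A, 6))
  cat("o = (", paste(format(x$o, digits = 6), collapse = ", "), ") mm\n")
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Apply a rigid transform to a point cloud
#'
#' Each output point is `A n + o`; labels and point order are preserved.
#'
#' @param t a [rigid_transform].
#' @param cloud a [point_cloud], or a numeric n x 3 matrix / length-3 vector
#'   of coordinates (returned in kind).
#' @param frame_id optional new frame tag for the returned cloud; by default
#'   the input tag is suffixed with `"*"` to mark the frame change.
#' @return The transformed cloud (or matrix / vector).
#' @export
apply_transform <- function(t, cloud, frame_id = NULL) {
  stopifnot(is_rigid_transform(t))
  if (is.numeric(cloud)) {
    if (is.matrix(cloud)) return(tcrossprod(cloud, t$A) + rep(t$o, each = nrow(cloud)))
    if (length(cloud) == 3L) return(drop(t$A %*% cloud) + t$o)
    stop("numeric input must be a 3-vector or an n x 3 matrix")
  }
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- tcrossprod(cloud$points, t$A)
  pts <- pts + rep(t$o, each = nrow(pts))
  if (is.null(frame_id))
    frame_id <- if (nzchar(cloud$frame_id)) paste0(cloud$frame_id, "*") else ""
  point_cloud(pts, labels = cloud$labels, frame_id = frame_id)
}

#' Displacement field of a rigid transform over a cloud
#'
#' Returns, index-wise, the displacement vector `p = (A - K) n + o` of each
#' point (`K` the 3x3 unit matrix) — identical to the transformed cloud
#' minus the input cloud.
#'
#' @param t a [rigid_transform].
#' @param cloud a [point_cloud] or n x 3 matrix.
#' @return An n x 3 numeric matrix of displacement vectors (mm).
#' @export
displacement_field <- function(t, cloud) {
  stopifnot(is_rigid_transform(t))
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  tcrossprod(pts, t$A - diag(3)) + rep(t$o, each = nrow(pts))
}

#' Compose two rigid transforms
#'
#' `compose(t2, t1)` applies `t1` first, then `t2`:
#' `A = A2 A1`, `o = A2 o1 + o2`.
#'
#' @param t2,t1 [rigid_transform] objects.
#' @return The composite `rigid_transform`.
#' @export
compose <- function(t2, t1) {
  stopifnot(is_rigid_transform(t2), is_rigid_transform(t1))
  rigid_transform(t2$A %*% t1$A, drop(t2$A %*% t1$o) + t2$o)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform].
#' @return The inverse transform: `A^-1 = A^T`, `o^-1 = -A^T o`.
#' @export
invert <- function(t) {
  stopifnot(is_rigid_transform(t))
  rigid_transform(t(t$A), -drop(crossprod(t$A, t$o)))
}

#' Identity rigid transform
#' @return The identity `rigid_transform`.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Rotation angle of a rotation matrix
#'
#' The unsigned rotation angle in degrees, from the trace identity
#' `theta = acos((tr(A) - 1) / 2)`, with the acos argument clamped to
#' `[-1, 1]` to absorb floating-point drift near 0 and 180 degrees.
#'
#' @param A 3x3 proper rotation matrix, or a [rigid_transform].
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(A) {
  if (is_rigid_transform(A)) A <- A$A
  A <- as.matrix(A)
  tol <- 1e-9
  if (!all(dim(A) == c(3L, 3L)) ||
      max(abs(crossprod(A) - diag(3))) > tol || abs(det(A) - 1) > tol)
    stop("'A' is not a valid proper rotation matrix")
  c_theta <- (sum(diag(A)) - 1) / 2
  acos(min(1, max(-1, c_theta))) * 180 / pi
}

#' Rotation matrix from axis and angle (Rodrigues formula)
#'
#' @param axis length-3 direction vector (normalized internally).
#' @param theta_deg rotation angle in degrees (right-hand rule about `axis`).
#' @return A 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta_deg) {
  h <- as.numeric(axis)
  nh <- sqrt(sum(h^2))
  if (nh == 0) stop("'axis' must be non-zero")
  h <- h / nh
  th <- theta_deg * pi / 180
  K <- matrix(c(0, h[3], -h[2],
                -h[3], 0, h[1],
                h[2], -h[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform of a screw motion
#'
#' Builds the transform that rotates by `theta_deg` about the line through
#' `q` with direction `h` (right-hand rule) and then translates by `t_mm`
#' along `h`: `A = R(h, theta)`, `o = (K - A) q + t h`.
#'
#' @param h axis direction (normalized internally).
#' @param q a point on the axis (mm).
#' @param theta_deg rotation angle, degrees.
#' @param t_mm signed translation along the axis, mm.
#' @return A [rigid_transform].
#' @export
screw_transform <- function(h, q, theta_deg, t_mm) {
  h <- as.numeric(h); h <- h / sqrt(sum(h^2))
  q <- as.numeric(q)
  A <- rotation_about_axis(h, theta_deg)
  o <- q - drop(A %*% q) + t_mm * h
  rigid_transform(A, o)
}
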