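# Independent oracles: quaternion rotation, brute-force rotation-grid
# rigid fit, brute-force plane search. These share no code with the
# package's SVD/eigen-based implementations.

# --- quaternion rotation oracle ---------------------------------------

quat_from_axis_angle <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  c(cos(th / 2), sin(th / 2) * u)
}

quat_mult <- function(p, q) {
  c(p[1] * q[1] - sum(p[-1] * q[-1]),
    p[1] * q[-1] + q[1] * p[-1] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}

quat_rotate <- function(q, v) {
  quat_mult(quat_mult(q, c(0, v)), c(q[1], -q[-1]))[-1]
}

quat_rotation_matrix <- function(axis, theta_deg) {
  q <- quat_from_axis_angle(axis, theta_deg)
  sapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
         function(e) quat_rotate(q, e))
}

# --- random rigid transforms (caller controls the RNG seed) -----------

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

random_rigid <- function(trans_scale = 1) {
  rigid_transform(random_rotation(), rnorm(3, sd = trans_scale))
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# distance of a point to the line through q0 with unit direction h0
point_line_distance <- function(p, q0, h0) {
  d <- p - q0
  d <- d - sum(d * h0) * h0
  sqrt(sum(d^2))
}

# --- brute-force rotation-grid rigid fit ------------------------------

fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# Minimum of sum ||R s + o - t||^2 over a dense axis-angle grid (~2 deg
# spacing) with Nelder-Mead refinement. The objective for a candidate
# rotation uses only the 3x3 cross-covariance: residual =
# Ss + St - 2 tr(R H), with the optimal translation eliminated.
grid_rotation_fit <- function(S, T_, angle_step = 2, n_axes = 10000,
                              refine = TRUE) {
  cs <- colMeans(S); ct <- colMeans(T_)
  Sc <- sweep(S, 2, cs); Tc <- sweep(T_, 2, ct)
  H <- crossprod(Sc, Tc)           # sum over points of s t^T
  Ss <- sum(Sc^2); St <- sum(Tc^2); trH <- sum(diag(H))
  skew <- c(H[2, 3] - H[3, 2], H[3, 1] - H[1, 3], H[1, 2] - H[2, 1])
  U <- fib_sphere(n_axes)
  a <- drop(U %*% skew)            # tr(K H) per axis
  b <- rowSums((U %*% H) * U) - trH  # tr(K^2 H) per axis
  th <- seq(0, 180, by = angle_step) * pi / 180
  gain <- outer(a, sin(th)) + outer(b, 1 - cos(th))
  best <- arrayInd(which.max(gain), dim(gain))
  u0 <- U[best[1], ]; th0 <- th[best[2]]
  neggain <- function(p) {
    u <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    -(sum(u * skew) * sin(p[3]) +
        (drop(u %*% H %*% u) - trH) * (1 - cos(p[3])))
  }
  p <- c(acos(min(1, max(-1, u0[3]))), atan2(u0[2], u0[1]), th0)
  if (refine)
    p <- stats::optim(p, neggain, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))$par
  list(residual = Ss + St - 2 * (trH - neggain(p)),
       grid_residual = Ss + St - 2 * (trH + max(gain)))
}

# --- brute-force plane search -----------------------------------------

# Orthogonal plane fit by dense normal-sphere sampling (offset optimal in
# closed form per normal) plus refinement.
plane_brute_force <- function(P, n_dirs = 20000, refine = TRUE) {
  U <- fib_sphere(n_dirs)
  proj <- P %*% t(U)
  m <- colMeans(proj)
  ss <- colSums(proj^2) - nrow(P) * m^2
  j <- which.min(ss)
  f <- function(p) {
    u <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
    v <- drop(P %*% u)
    sum((v - mean(v))^2)
  }
  p <- c(acos(min(1, max(-1, U[j, 3]))), atan2(U[j, 2], U[j, 1]))
  if (refine)
    p <- stats::optim(p, f, control = list(reltol = 1e-15, maxit = 5000))$par
  u <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
  v <- drop(P %*% u)
  dev <- v - mean(v)
  list(normal = u, max_abs = max(abs(dev)), rms = sqrt(mean(dev^2)))
}

# random screw draw at dental scale; caller controls the seed
random_screw_spec <- function(theta_range = c(0.5, 10), t_range = c(0, 0.5),
                              q_radius = 20) {
  screw_motion_spec(h = random_unit(),
                    q = random_unit() * runif(1, 0, q_radius),
                    theta = runif(1, theta_range[1], theta_range[2]),
                    t = sample(c(-1, 1), 1) * runif(1, t_range[1], t_range[2]))
}
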