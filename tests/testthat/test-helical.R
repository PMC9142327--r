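test_that("axis_direction recovers the generating axis with its sign", {
  expect_equal(axis_direction(rotation_about_axis(c(0, 0, 1), 30)),
               c(0, 0, 1), tolerance = 1e-12)
  expect_equal(axis_direction(rotation_about_axis(c(1, 1, 1), 120)),
               rep(1, 3) / sqrt(3), tolerance = 1e-12)
  set.seed(41)
  worst <- 0
  for (i in 1:500) {
    h <- random_unit()
    A <- quat_rotation_matrix(h, runif(1, 0.5, 179))
    worst <- max(worst, max(abs(axis_direction(A) - h)))
  }
  expect_lt(worst, 1e-8)
  # theta ~ 180: skew part vanishes; symmetric-part fallback, sign fixed
  h180 <- axis_direction(rotation_about_axis(c(0.6, -0.8, 0), 180))
  expect_equal(abs(sum(h180 * c(0.6, -0.8, 0))), 1, tolerance = 1e-7)
  expect_gt(h180[which(abs(h180) > 1e-12)[1]], 0)
  expect_error(axis_direction(diag(3)), "degeneracy threshold")
})

test_that("axis_point lies on the helical axis under both strategies", {
  # 90 deg about the vertical line through (1, 0, 0): minimum-norm point
  tr <- screw_transform(c(0, 0, 1), c(1, 0, 0), 90, 0)
  q <- axis_point(tr)
  expect_equal(q[1:2], c(1, 0), tolerance = 1e-10)
  expect_equal(q[3], 0, tolerance = 1e-10)  # minimum-norm picks z = 0
  p <- drop(displacement_field(tr, matrix(c(1, 0, 5), 1)))
  expect_lt(sqrt(sum((p - sum(p * c(0, 0, 1)) * c(0, 0, 1))^2)), 1e-10)

  # pure rotation about an axis through the origin
  tr0 <- rigid_transform(rotation_about_axis(c(1, 2, -1), 25))
  expect_lt(max(abs(axis_point(tr0))), 1e-10)

  set.seed(51)
  for (i in 1:500) {
    h <- random_unit(); q0 <- rnorm(3, sd = 8)
    tr <- screw_transform(h, q0, runif(1, 1, 90), runif(1, -0.5, 0.5))
    qm <- axis_point(tr, "minimum_norm")
    qf <- axis_point(tr, "fix_coordinate")
    expect_lt(point_line_distance(qm, q0, h), 1e-8)
    expect_lt(point_line_distance(qf, q0, h), 1e-8)
    # the two conventions differ only along the axis
    d <- qf - qm
    if (sqrt(sum(d^2)) > 1e-12) {
      sine <- sqrt(sum((d - sum(d * h) * h)^2)) / sqrt(sum(d^2))
      expect_lt(sine, 1e-8)
    }
  }
  expect_error(axis_point(identity_transform()), "degeneracy threshold")
})

test_that("screw_translation is the axial displacement component", {
  # pure rotation: no axial translation
  tr <- screw_transform(c(0, 1, 0), c(3, 0, 1), 40, 0)
  expect_equal(screw_translation(tr, c(0, 1, 0)), 0, tolerance = 1e-10)
  # 90 deg about z through the origin plus 2 mm axial shift
  tr2 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(0, 0, 2))
  expect_equal(screw_translation(tr2, c(0, 0, 1)), 2, tolerance = 1e-12)
  # wrong axis is rejected as inconsistent
  expect_error(screw_translation(tr2, c(1, 0, 0)), "not the helical axis")
  set.seed(61)
  for (i in 1:200) {
    h <- random_unit()
    tt <- runif(1, -0.5, 0.5)
    tr <- screw_transform(h, rnorm(3, sd = 8), runif(1, 1, 120), tt)
    expect_equal(screw_translation(tr, h), tt, tolerance = 1e-9)
  }
})

test_that("project_onto_axis returns the perpendicular foot", {
  expect_equal(project_onto_axis(c(0, 0, 7), c(0, 0, 0), c(0, 0, 1)),
               c(0, 0, 7))
  expect_equal(project_onto_axis(c(3, 4, 7), c(0, 0, 0), c(0, 0, 1)),
               c(0, 0, 7))
  expect_error(project_onto_axis(c(1, 1, 1), c(0, 0, 0), c(0, 0, 0)),
               "non-zero")
  set.seed(71)
  for (i in 1:50) {
    q <- rnorm(3); h <- random_unit(); d <- rnorm(3, sd = 5)
    qp <- project_onto_axis(d, q, h)
    expect_lt(abs(sum((d - qp) * h)), 1e-12)
    # minimal over a dense sampling of the line
    line <- outer(seq(-20, 20, length.out = 4001), h) +
      rep(q, each = 4001)
    dists <- sqrt(rowSums((line - rep(d, each = 4001))^2))
    expect_lte(sqrt(sum((d - qp)^2)), min(dists) + 1e-9)
  }
})

test_that("projection-construction angle equals the trace angle", {
  # 90 deg about z through the origin with 2 mm axial screw translation
  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(0, 0, 2))
  ax <- helical_axis_from_transform(tr)
  expect_equal(rotation_angle_about_axis(tr, ax, c(1, 0, 0)), 90,
               tolerance = 1e-10)
  expect_error(rotation_angle_about_axis(tr, ax, ax$q + ax$h * 3),
               "ill-conditioned")
  set.seed(81)
  for (i in 1:200) {
    tr <- screw_transform(random_unit(), rnorm(3, sd = 8),
                          runif(1, 0.5, 170), runif(1, -0.5, 0.5))
    ax <- helical_axis_from_transform(tr)
    d0 <- ax$q + random_unit() * runif(1, 0.5, 10)
    if (point_line_distance(d0, ax$q, ax$h) < 1e-3) next
    expect_equal(rotation_angle_about_axis(tr, ax, d0), ax$theta,
                 tolerance = 1e-8)
  }
})

test_that("helical decomposition handles degenerate motions gracefully", {
  ax_id <- helical_axis_from_transform(identity_transform())
  expect_true(ax_id$degenerate)
  expect_equal(ax_id$theta, 0)
  expect_equal(ax_id$t, 0)

  ax_tr <- helical_axis_from_transform(
    rigid_transform(diag(3), c(0.1, 0, 0)))
  expect_true(ax_tr$degenerate)
  expect_equal(ax_tr$h, c(1, 0, 0))
  expect_equal(ax_tr$t, 0.1)

  # just above the threshold: defined but flagged unreliable
  ax_small <- helical_axis_from_transform(
    screw_transform(c(0, 0, 1), c(1, 1, 0), 0.3, 0.05))
  expect_false(ax_small$degenerate)
  expect_true(ax_small$unreliable)
})

test_that("screw round trip recovers axis, angle and translation", {
  set.seed(91)
  for (i in 1:300) {
    sp <- random_screw_spec(theta_range = c(0.5, 10), t_range = c(0, 0.5))
    tr <- screw_transform(sp$h, sp$q, sp$theta, sp$t)
    ax <- helical_axis_from_transform(tr)
    expect_false(ax$degenerate)
    expect_lt(abs(ax$theta - sp$theta), 1e-9)
    expect_lt(abs(sum(ax$h * sp$h) - 1), 1e-9)
    expect_lt(abs(ax$t - sp$t), 1e-9)
    expect_lt(point_line_distance(ax$q, sp$q, sp$h), 1e-7)
    # reconstruction reproduces the transform
    tr2 <- transform_from_helical_axis(ax)
    expect_lt(max(abs(tr2$A - tr$A)), 1e-9)
    expect_lt(max(abs(tr2$o - tr$o)), 1e-9)
  }
})

test_that("on-axis displacement is minimal among off-axis points", {
  set.seed(101)
  for (i in 1:50) {
    sp <- random_screw_spec(theta_range = c(1, 45))
    tr <- screw_transform(sp$h, sp$q, sp$theta, sp$t)
    ax <- helical_axis_from_transform(tr)
    p_axis <- sqrt(sum(displacement_field(tr, matrix(ax$q, 1))^2))
    X <- matrix(rnorm(3000, sd = 10), ncol = 3)
    p_off <- sqrt(rowSums(displacement_field(tr, X)^2))
    expect_true(all(p_axis <= p_off + 1e-12))
  }
})

test_that("axis position is noise-sensitive at small rotations", {
  # qualitative sensitivity ordering: the axis of a 0.2 deg screw scatters
  # more under measurement noise than that of a 5 deg screw
  crown <- generate_crown(c(0, 0, 0), n_points = 200, seed = 5)
  err_for_theta <- function(theta, n_rep = 30) {
    h <- c(0, 0, 1); q0 <- c(2, 1, 0)
    tr <- screw_transform(h, q0, theta, 0.1)
    moved <- apply_transform(tr, crown)
    vapply(seq_len(n_rep), function(r) {
      a <- add_scanner_noise(crown, rep(0.02, 3), seed = 1000 + r)
      b <- add_scanner_noise(moved, rep(0.02, 3), seed = 2000 + r)
      fit <- kabsch_fit(a, b)
      ax <- helical_axis_from_transform(fit)
      point_line_distance(ax$q, q0, h)
    }, numeric(1))
  }
  expect_gt(median(err_for_theta(0.2)), median(err_for_theta(5)))
})
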