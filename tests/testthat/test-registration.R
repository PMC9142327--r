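test_that("kabsch_fit solves the trivial and forced cases", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.2, 1)))
  fit <- kabsch_fit(pc, pc)
  expect_lt(max(abs(fit$A - diag(3))), 1e-12)
  expect_lt(max(abs(fit$o)), 1e-12)

  shifted <- point_cloud(sweep(pc$points, 2, c(1, 2, 3), "+"))
  fit2 <- kabsch_fit(pc, shifted)
  expect_lt(max(abs(fit2$A - diag(3))), 1e-12)
  expect_equal(fit2$o, c(1, 2, 3), tolerance = 1e-12)

  expect_error(kabsch_fit(pc$points[1:2, ], pc$points[1:2, ]),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_fit(line, line), "collinear")
  expect_error(kabsch_fit(pc$points, pc$points[1:3, ]), "equal point counts")
})

test_that("kabsch_fit never produces a reflection", {
  # near-planar clouds with a mirrored target push the naive SVD solution
  # toward det = -1; the sign flip must keep it a proper rotation
  set.seed(111)
  for (i in 1:20) {
    S <- cbind(rnorm(10), rnorm(10), rnorm(10, sd = 1e-4))
    T_ <- S %*% diag(c(1, 1, -1)) + matrix(rnorm(30, sd = 0.01), 10)
    fit <- kabsch_fit(S, T_)
    expect_equal(det(fit$A), 1, tolerance = 1e-9)
  }
})

test_that("kabsch_fit recovers a noisy screw and matches the grid oracle", {
  set.seed(121)
  S <- matrix(rnorm(30, sd = 5), ncol = 3)
  tr <- screw_transform(c(1, -1, 2), c(1, 0, 0), 4, 0.2)
  T_ <- apply_transform(tr, S) + matrix(rnorm(30, sd = 0.01), ncol = 3)
  fit <- kabsch_fit(S, T_)
  rel <- compose(invert(tr), fit)
  expect_lt(rotation_angle(rel$A), 0.5)
  expect_lt(sqrt(sum((fit$o - tr$o)^2)), 0.02 * 5)  # mm at the cloud scale
  res_svd <- sum((apply_transform(fit, S) - T_)^2)
  oracle <- grid_rotation_fit(S, T_)
  expect_lte(res_svd, oracle$residual + 1e-9 * max(1, res_svd))
  expect_lte(res_svd, oracle$grid_residual)
})

test_that("kabsch_fit is equivariant under a common rigid motion", {
  set.seed(131)
  S <- matrix(rnorm(60, sd = 3), ncol = 3)
  T_ <- matrix(rnorm(60, sd = 3), ncol = 3)
  fit <- kabsch_fit(S, T_)
  Q <- random_rigid()
  fitQ <- kabsch_fit(apply_transform(Q, S), apply_transform(Q, T_))
  conj <- compose(Q, compose(fit, invert(Q)))
  expect_lt(max(abs(fitQ$A - conj$A)), 1e-9)
  expect_lt(max(abs(fitQ$o - conj$o)), 1e-9)
})

test_that("mean_fitting_error is the mean nearest-neighbour distance", {
  pc <- point_cloud(matrix(rnorm(60), ncol = 3))
  expect_equal(mean_fitting_error(pc, pc), 0)
  expect_error(mean_fitting_error(pc, point_cloud(matrix(numeric(0), ncol = 3))),
               "empty")

  # dense plane grid shifted perpendicular by 0.05 mm
  g <- as.matrix(expand.grid(x = seq(0, 1, by = 0.01),
                             y = seq(0, 1, by = 0.01)))
  a <- cbind(g, 0)
  b <- cbind(g, 0.05)
  expect_equal(mean_fitting_error(a, b), 0.05, tolerance = 0.02 * 0.05)

  # exhaustive pairwise oracle on small random clouds
  set.seed(141)
  for (i in 1:10) {
    A <- matrix(rnorm(45), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
    expect_equal(mean_fitting_error(A, B),
                 mean(sqrt(pmax(0, apply(d2, 1, min)))), tolerance = 1e-10)
  }
  # asymmetric by definition; symmetric flag averages both directions
  A <- rbind(c(0, 0, 0), c(10, 0, 0))
  B <- rbind(c(0, 0, 1), c(0, 0, 2), c(10, 0, 1), c(20, 0, 0))
  expect_equal(mean_fitting_error(A, B), 1)
  expect_equal(mean_fitting_error(B, A), (1 + 2 + 1 + 10) / 4)
  expect_equal(mean_fitting_error(A, B, symmetric = TRUE), (1 + 3.5) / 2)
})

test_that("nearest-neighbour ties break to the lowest target index", {
  src <- matrix(c(0, 0, 0), 1)
  tgt <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  nn <- helaxis:::nn_exact(src, tgt)
  expect_equal(nn$index, 1L)
})

test_that("icp_register converges on exact and displaced clouds", {
  crown <- generate_crown(c(0, 0, 0), n_points = 400, seed = 7)
  reg0 <- icp_register(crown, crown)
  expect_true(reg0$converged)
  expect_lte(reg0$iterations, 2)
  expect_equal(reg0$mean_fitting_error, 0)
  expect_lt(max(abs(reg0$transform$A - diag(3))), 1e-12)

  tr <- screw_transform(c(0.3, 1, -0.2), c(1, 1, 2), 2, 0.2)
  moved <- apply_transform(tr, crown)
  reg <- icp_register(crown, moved, tol = 1e-9)
  expect_true(reg$converged)
  expect_lt(reg$mean_fitting_error, 1e-6)
  back <- apply_transform(reg$transform, crown)
  expect_lt(mean_fitting_error(back, moved), 1e-6)
  # per-iteration error is non-increasing from the second entry onward
  expect_true(all(diff(reg$per_iteration_error[-1]) <= 1e-12))

  expect_error(icp_register(crown, moved, trim_fraction = 0.6), "0.5")
  expect_error(icp_register(point_cloud(matrix(rnorm(9), 3)), crown),
               "at least 10")
})

test_that("icp fitting error under noise sits at the Monte-Carlo noise floor", {
  crown <- generate_crown(c(0, 0, 0), n_points = 200, seed = 9)
  tr <- screw_transform(c(0, 1, 0), c(1, 0, 0), 2, 0.2)
  moved <- apply_transform(tr, crown)
  sigma <- 0.02
  # oracle: mean NN distance between two sigma-noised copies at truth
  floor_reps <- vapply(1:20, function(r) {
    a <- add_scanner_noise(moved, rep(sigma, 3), seed = 4000 + r)
    b <- add_scanner_noise(moved, rep(sigma, 3), seed = 5000 + r)
    mean_fitting_error(a, b)
  }, numeric(1))
  noisy_target <- add_scanner_noise(moved, rep(sigma, 3), seed = 61)
  noisy_source <- add_scanner_noise(crown, rep(sigma, 3), seed = 62)
  reg <- icp_register(noisy_source, noisy_target, tol = 1e-9)
  expect_gt(reg$mean_fitting_error, 0.8 * median(floor_reps))
  expect_lt(reg$mean_fitting_error, 1.3 * median(floor_reps))
})

test_that("icp reports non-convergence without raising", {
  crown <- generate_crown(c(0, 0, 0), n_points = 200, seed = 13)
  moved <- apply_transform(screw_transform(c(0, 0, 1), c(0, 0, 0), 4, 0.5),
                           crown)
  reg <- icp_register(crown, moved, max_iter = 1, tol = 1e-12)
  expect_false(reg$converged)
  expect_s3_class(reg, "icp_registration")
})

test_that("normalize_series anchors every scan to the reference frame", {
  layout <- arch_layout(n_points_tooth = 250, n_points_reference = 250)
  specs <- list(screw_motion_spec(c(0, 0, 1), c(0, 22, 0), 3, 0.2,
                                  label = "central_incisor"))
  ser <- generate_series(layout, specs, n_timepoints = 2, noise = c(0, 0, 0),
                         seed = 17, global_perturbation = TRUE)
  norm <- normalize_series(ser$scans, "first_molars", tol = 1e-10)
  # reference subsets coincide after normalization
  r0 <- subset_label(norm$scans[[1]], "first_molars")
  r1 <- subset_label(norm$scans[[2]], "first_molars")
  expect_lt(mean_fitting_error(r1, r0), 1e-6)
  # an unmoved tooth coincides too; the moved incisor retains its motion
  c0 <- subset_label(norm$scans[[1]], "canine")
  c1 <- subset_label(norm$scans[[2]], "canine")
  expect_lt(mean_fitting_error(c1, c0), 1e-6)
  i0 <- subset_label(norm$scans[[1]], "central_incisor")
  i1 <- subset_label(norm$scans[[2]], "central_incisor")
  # the common frame is scan 0's scanner pose G0, so the simulated screw
  # acts conjugated: G0 . screw . G0^-1
  G0 <- ser$global_transforms[[1]]
  conj <- compose(G0, compose(screw_transform(specs[[1]]$h, specs[[1]]$q,
                                              specs[[1]]$theta, specs[[1]]$t),
                              invert(G0)))
  truth_moved <- apply_transform(conj, i0)
  expect_lt(max(abs(truth_moved$points - i1$points)), 1e-6)

  # identical scans give identity transforms
  norm2 <- normalize_series(list(ser$scans[[1]], ser$scans[[1]]),
                            "first_molars")
  expect_lt(max(abs(norm2$transforms[[2]]$A - diag(3))), 1e-9)
  expect_lt(max(abs(norm2$transforms[[2]]$o)), 1e-9)

  bad <- point_cloud(matrix(rnorm(60), ncol = 3),
                     labels = rep("x", 20))
  expect_error(normalize_series(list(ser$scans[[1]], bad), "first_molars"),
               "scan 2")
})
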