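# Deterministic synthetic scan-series generator. All randomness is local:
# each operation seeds its own RNG stream (derived from a single global
# seed by stable hashing) and restores the caller's RNG state on exit.

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a global seed and a context key
#'
#' Stable string hash (polynomial over UTF-8 codes, modulo a Mersenne
#' prime) so one global seed fans out deterministically to independent
#' per-operation streams keyed by operation name, structure label and
#' timepoint. Result always fits a 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param ... context parts (operation, label, timepoint, ...), coerced to
#'   character and concatenated.
#' @return A positive integer seed.
#' @export
child_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), as.character(unlist(list(...)))),
               collapse = "\r")
  h <- 0
  p <- 2147483647  # 2^31 - 1
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% p
  as.integer(h %% (p - 1L) + 1L)
}

#' Generate a crown-like synthetic point cloud
#'
#' Quasi-uniform surface sampling of a superellipsoid
#' `|x/a|^(2/e) + |y/b|^(2/e) + |z/c|^(2/e) = 1` with roundness exponent
#' `e = 0.8`, a box-round solid of roughly tooth-crown proportions at the
#' default half-axes 4 x 3 x 5 mm. Random unit directions are scaled onto
#' the implicit surface, so every point satisfies the implicit equation
#' exactly (up to floating point). Deterministic for a given seed.
#'
#' @param center length-3 crown centre, mm.
#' @param size length-3 positive half-axes `(a, b, c)`, mm.
#' @param n_points number of surface points (>= 50).
#' @param seed integer seed.
#' @param roundness superellipsoid roundness exponent `e` (2 = ellipsoid,
#'   smaller = boxier). Default 0.8.
#' @param label optional structure label applied to every point.
#' @return A [point_cloud].
#' @examples
#' crown <- generate_crown(c(0, 0, 0), n_points = 100, seed = 42)
#' @export
generate_crown <- function(center = c(0, 0, 0), size = c(4, 3, 5),
                           n_points = 500, seed = 1, roundness = 0.8,
                           label = NULL) {
  size <- as.numeric(size)
  if (length(size) != 3L || any(size <= 0)) stop("'size' must be 3 positive half-axes")
  if (n_points < 50L) stop("'n_points' must be at least 50")
  p <- 2 / roundness
  pts <- with_local_seed(seed, {
    d <- matrix(stats::rnorm(3L * n_points), ncol = 3L)
    d <- d / sqrt(rowSums(d^2))
    r <- (abs(d[, 1L] / size[1L])^p + abs(d[, 2L] / size[2L])^p +
            abs(d[, 3L] / size[3L])^p)^(-1 / p)
    d * r
  })
  pts <- sweep(pts, 2L, as.numeric(center), "+")
  point_cloud(pts,
              labels = if (is.null(label)) NULL else rep(label, n_points),
              frame_id = "synthetic")
}

#' Implicit superellipsoid surface value
#'
#' `|x/a|^(2/e) + |y/b|^(2/e) + |z/c|^(2/e)` evaluated per point; exactly 1
#' on the surface. Exposed so generated crowns can be checked against the
#' surface they claim to sample.
#'
#' @param points n x 3 matrix or [point_cloud], coordinates relative to the
#'   crown centre.
#' @param size half-axes `(a, b, c)`.
#' @param roundness exponent `e`.
#' @return Numeric vector of implicit values.
#' @export
superellipsoid_implicit <- function(points, size = c(4, 3, 5), roundness = 0.8) {
  P <- if (inherits(points, "point_cloud")) points$points else as.matrix(points)
  p <- 2 / roundness
  abs(P[, 1L] / size[1L])^p + abs(P[, 2L] / size[2L])^p + abs(P[, 3L] / size[3L])^p
}

#' Specify a ground-truth screw motion
#'
#' The simulator's unit of ground truth: a rotation of `theta` degrees
#' about the line through `q` with unit direction `h`, plus a translation
#' of `t` mm along `h`, applied to the structure `label` over the timepoint
#' interval `interval`.
#'
#' @param h axis direction (normalized internally).
#' @param q axis point, mm.
#' @param theta rotation angle, degrees (>= 0).
#' @param t signed screw translation, mm.
#' @param label structure the motion applies to.
#' @param interval length-2 integer `(from, to)` timepoint indices
#'   (1-based; `to = from + 1` for consecutive intervals).
#' @return An object of class `screw_motion_spec`.
#' @export
screw_motion_spec <- function(h, q, theta, t, label = "structure",
                              interval = c(1L, 2L)) {
  h <- as.numeric(h)
  nh <- sqrt(sum(h^2))
  if (nh == 0) stop("'h' must be non-zero")
  if (theta < 0) stop("'theta' must be >= 0 (direction is carried by h)")
  structure(list(h = h / nh, q = as.numeric(q), theta = as.numeric(theta),
                 t = as.numeric(t), label = as.character(label),
                 interval = as.integer(interval)),
            class = "screw_motion_spec")
}

#' @export
print.screw_motion_spec <- function(x, ...) {
  cat(sprintf("Screw motion: '%s' T%d->T%d  theta %.3f deg, t %.3f mm\n",
              x$label, x$interval[1L] - 1L, x$interval[2L] - 1L, x$theta, x$t))
  cat(sprintf("  axis: h (%.4f, %.4f, %.4f) through q (%.2f, %.2f, %.2f) mm\n",
              x$h[1], x$h[2], x$h[3], x$q[1], x$q[2], x$q[3]))
  invisible(x)
}

#' Apply a ground-truth screw motion to a cloud
#'
#' Builds the rigid transform of the spec (Rodrigues rotation about the
#' line plus axial translation) and applies it — the motion the downstream
#' analysis must invert.
#'
#' @param cloud a [point_cloud].
#' @param spec a [screw_motion_spec].
#' @return The displaced cloud.
#' @export
apply_screw <- function(cloud, spec) {
  stopifnot(inherits(spec, "screw_motion_spec"))
  apply_transform(screw_transform(spec$h, spec$q, spec$theta, spec$t), cloud,
                  frame_id = cloud$frame_id)
}

#' Add anisotropic scanner noise to a cloud
#'
#' Independent zero-mean Gaussian perturbation per axis. The default sigma
#' is the quantization-equivalent of scanner resolutions 0.01 mm (x, z)
#' and 0.1 mm (y): a uniform quantizer of step s has noise variance
#' s^2/12, so sigma = step/sqrt(12). A pure quantization mode (`model =
#' "quantize"`, rounding each axis to its step) is available.
#'
#' @param cloud a [point_cloud].
#' @param sigma_xyz length-3 non-negative noise scales per axis, mm. Under
#'   `model = "quantize"` these are the quantization steps.
#' @param seed integer seed.
#' @param model `"gaussian"` (default) or `"quantize"`.
#' @return The perturbed cloud (labels, order, frame preserved).
#' @export
add_scanner_noise <- function(cloud, sigma_xyz = c(0.01, 0.1, 0.01) / sqrt(12),
                              seed = 1, model = c("gaussian", "quantize")) {
  stopifnot(inherits(cloud, "point_cloud"))
  model <- match.arg(model)
  sigma_xyz <- as.numeric(sigma_xyz)
  if (length(sigma_xyz) != 3L || any(sigma_xyz < 0))
    stop("'sigma_xyz' must be 3 non-negative values")
  n <- n_points(cloud)
  if (n == 0L || all(sigma_xyz == 0)) return(cloud)
  pts <- if (model == "gaussian") {
    noise <- with_local_seed(seed, matrix(stats::rnorm(3L * n), ncol = 3L))
    cloud$points + sweep(noise, 2L, sigma_xyz, "*")
  } else {
    q <- cloud$points
    for (j in 1:3) if (sigma_xyz[j] > 0)
      q[, j] <- round(q[, j] / sigma_xyz[j]) * sigma_xyz[j]
    q
  }
  point_cloud(pts, labels = cloud$labels, frame_id = cloud$frame_id)
}

#' Default synthetic dental-arch layout
#'
#' Three movable "teeth" (central incisor, lateral incisor, canine) along an
#' arch plus a bilateral first-molar reference structure (two crowns, one
#' label) standing in for molars joined by a transpalatal bar — the stable
#' superimposition reference. Coordinates in mm; crowns are superellipsoids
#' of roughly natural crown half-axes.
#'
#' @param n_points_tooth surface points per movable crown.
#' @param n_points_reference surface points per reference crown (two
#'   crowns share the reference label).
#' @return A list of structure descriptors (`name`, `center`, `size`,
#'   `n_points`, `reference` flag) with attribute `reference_label`.
#' @export
arch_layout <- function(n_points_tooth = 1000, n_points_reference = 700) {
  structures <- list(
    list(name = "central_incisor", center = c(0, 22, 0), size = c(4, 3, 5),
         n_points = n_points_tooth, reference = FALSE),
    list(name = "lateral_incisor", center = c(7, 20, 0), size = c(3.3, 3, 4.5),
         n_points = n_points_tooth, reference = FALSE),
    list(name = "canine", center = c(13, 16, 0), size = c(3.8, 3.5, 5.5),
         n_points = n_points_tooth, reference = FALSE),
    list(name = "first_molars", center = c(18, 0, 0), size = c(5, 5.5, 4),
         n_points = n_points_reference, reference = TRUE),
    list(name = "first_molars", center = c(-18, 0, 0), size = c(5, 5.5, 4),
         n_points = n_points_reference, reference = TRUE)
  )
  attr(structures, "reference_label") <- "first_molars"
  structures
}

#' Draw random per-tooth screw motions for a series
#'
#' One screw per (tooth, consecutive interval), with rotation angle uniform
#' in `theta_range` degrees and axial translation uniform in `t_range` mm —
#' the magnitudes reported for orthodontic leveling over two-month
#' observation windows. The axis passes near the tooth (within `q_jitter`
#' mm of its centre) in a uniformly random direction.
#'
#' @param layout an [arch_layout()]-style structure list.
#' @param n_timepoints number of timepoints (intervals = n - 1).
#' @param seed integer seed.
#' @param theta_range degrees, default `c(0.5, 5)`.
#' @param t_range mm, default `c(0.05, 0.5)`.
#' @param q_jitter mm, max axis-point offset from the crown centre.
#' @return List of [screw_motion_spec]s, one per movable tooth per interval.
#' @export
random_motion_specs <- function(layout, n_timepoints = 5, seed = 1,
                                theta_range = c(0.5, 5),
                                t_range = c(0.05, 0.5), q_jitter = 3) {
  specs <- list()
  for (st in layout) {
    if (st$reference) next
    for (iv in seq_len(n_timepoints - 1L)) {
      specs[[length(specs) + 1L]] <- with_local_seed(
        child_seed(seed, "motion", st$name, iv), {
          h <- stats::rnorm(3L)
          q <- st$center + stats::runif(3L, -q_jitter, q_jitter)
          th <- stats::runif(1L, theta_range[1L], theta_range[2L])
          tt <- sample(c(-1, 1), 1L) * stats::runif(1L, t_range[1L], t_range[2L])
          screw_motion_spec(h, q, th, tt, label = st$name,
                            interval = c(iv, iv + 1L))
        })
    }
  }
  specs
}

#' Generate a synthetic serial scan series with known ground truth
#'
#' Emulates a five-timepoint dental-cast study: timepoint 1 is the base
#' arch; each later timepoint applies that interval's per-tooth screw
#' motions to the named teeth (cumulatively, tooth position at T(k) is the
#' screwed position at T(k-1)), leaves the reference structure fixed in
#' anatomy, then optionally applies a random whole-scan pose perturbation
#' (the casts are placed arbitrarily in the scanner) and adds scanner
#' noise. Fully deterministic for a given seed.
#'
#' @param layout structure list from [arch_layout()] (or same shape).
#' @param specs list of [screw_motion_spec]s; labels/intervals must exist.
#' @param n_timepoints number of scans (>= 2). Default 5 (T0..T4).
#' @param noise length-3 Gaussian sigma per axis, mm (see
#'   [add_scanner_noise()]); `c(0, 0, 0)` for noise-free.
#' @param seed integer global seed; all child streams derive from it.
#' @param global_perturbation apply a random whole-scan rigid pose offset
#'   per timepoint (rotation uniform in `[0, 5]` degrees about a random
#'   axis through the arch centroid, translation uniform in `[0, 5]` mm in
#'   a random direction). Default `TRUE`.
#' @return An object of class `synthetic_series`: list with `scans`
#'   (labelled [point_cloud]s, one per timepoint, in scanner frames),
#'   `true_scans` (same, without pose perturbation or noise),
#'   `specs`, `global_transforms` (the per-timepoint pose perturbations),
#'   `reference_label`, `noise_sigma`, `seed`.
#' @export
generate_series <- function(layout = arch_layout(), specs = list(),
                            n_timepoints = 5,
                            noise = c(0.01, 0.1, 0.01) / sqrt(12),
                            seed = 1, global_perturbation = TRUE) {
  if (n_timepoints < 2L) stop("'n_timepoints' must be >= 2")
  labels_avail <- unique(vapply(layout, `[[`, "", "name"))
  for (sp in specs) {
    if (!sp$label %in% labels_avail)
      stop("motion spec references unknown structure '", sp$label, "'")
    if (sp$interval[2L] != sp$interval[1L] + 1L ||
        sp$interval[1L] < 1L || sp$interval[2L] > n_timepoints)
      stop("motion spec for '", sp$label, "' has interval outside the series")
    ref_lab <- attr(layout, "reference_label")
    if (!is.null(ref_lab) && sp$label == ref_lab)
      stop("the reference structure '", ref_lab, "' must stay fixed")
  }
  # base arch: per-structure crowns, concatenated with labels
  base_parts <- lapply(seq_along(layout), function(i) {
    st <- layout[[i]]
    generate_crown(st$center, st$size, st$n_points,
                   seed = child_seed(seed, "crown", st$name, i),
                   label = st$name)
  })
  pts <- do.call(rbind, lapply(base_parts, function(p) p$points))
  labs <- unlist(lapply(base_parts, function(p) p$labels))
  base <- point_cloud(pts, labels = labs, frame_id = "T0")
  arch_centroid <- colMeans(base$points)

  true_scans <- vector("list", n_timepoints)
  true_scans[[1L]] <- base
  for (k in 2:n_timepoints) {
    prev <- true_scans[[k - 1L]]
    cur_pts <- prev$points
    for (sp in specs) {
      if (sp$interval[2L] != k) next
      idx <- prev$labels == sp$label
      tr <- screw_transform(sp$h, sp$q, sp$theta, sp$t)
      cur_pts[idx, ] <- apply_transform(tr, cur_pts[idx, , drop = FALSE])
    }
    true_scans[[k]] <- point_cloud(cur_pts, labels = prev$labels,
                                   frame_id = paste0("T", k - 1L))
  }

  scans <- vector("list", n_timepoints)
  g_tr <- vector("list", n_timepoints)
  for (k in seq_len(n_timepoints)) {
    g <- if (global_perturbation) {
      with_local_seed(child_seed(seed, "pose", k), {
        ax <- stats::rnorm(3L); ax <- ax / sqrt(sum(ax^2))
        ang <- stats::runif(1L, 0, 5)
        dirv <- stats::rnorm(3L); dirv <- dirv / sqrt(sum(dirv^2))
        mag <- stats::runif(1L, 0, 5)
        A <- rotation_about_axis(ax, ang)
        # rotate about the arch centroid, then shift
        rigid_transform(A, arch_centroid - drop(A %*% arch_centroid) + mag * dirv)
      })
    } else identity_transform()
    g_tr[[k]] <- g
    sc <- apply_transform(g, true_scans[[k]],
                          frame_id = paste0("T", k - 1L, "_scanner"))
    if (any(noise > 0))
      sc <- add_scanner_noise(sc, noise, seed = child_seed(seed, "noise", k))
    scans[[k]] <- sc
  }
  structure(list(scans = scans, true_scans = true_scans, specs = specs,
                 global_transforms = g_tr,
                 reference_label = attr(layout, "reference_label"),
                 noise_sigma = noise, seed = seed),
            class = "synthetic_series")
}

#' @export
print.synthetic_series <- function(x, ...) {
  cat("Synthetic scan series: ", length(x$scans), " timepoints, ",
      n_points(x$scans[[1L]]), " points per scan (seed ", x$seed, ")\n",
      sep = "")
  cat("Reference structure: ", x$reference_label, "\n", sep = "")
  cat("Scanner noise sigma (mm): ",
      paste(format(x$noise_sigma, digits = 3), collapse = ", "), "\n", sep = "")
  cat("Ground-truth screw motions: ", length(x$specs), "\n", sep = "")
  invisible(x)
}
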