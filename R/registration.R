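#' Least-squares rigid superposition of corresponded point sets (Kabsch)
#'
#' Finds the proper rigid transform minimizing
#' `sum_i || A s_i + o - t_i ||^2` over rotations `A` and translations `o`,
#' for index-wise corresponded clouds: SVD of the centered cross-covariance,
#' with a sign flip of the smallest singular direction so that
#' `det(A) = +1` always (never a reflection).
#'
#' @param source,target [point_cloud]s (or n x 3 matrices) with equal point
#'   counts >= 3 and index-wise correspondence.
#' @return A [rigid_transform] mapping `source` onto `target`.
#' @examples
#' src <- point_cloud(matrix(rnorm(30), ncol = 3))
#' tr <- screw_transform(c(0, 0, 1), c(1, 1, 0), 10, 0.2)
#' kabsch_fit(src, apply_transform(tr, src))
#' @export
kabsch_fit <- function(source, target) {
  S <- if (inherits(source, "point_cloud")) source$points else as.matrix(source)
  T_ <- if (inherits(target, "point_cloud")) target$points else as.matrix(target)
  if (nrow(S) != nrow(T_))
    stop("source and target must have equal point counts (",
         nrow(S), " vs ", nrow(T_), ")")
  if (nrow(S) < 3L)
    stop("degenerate geometry: need at least 3 corresponded points, got ",
         nrow(S))
  cs <- colMeans(S); ct <- colMeans(T_)
  Sc <- sweep(S, 2L, cs); Tc <- sweep(T_, 2L, ct)
  H <- crossprod(Sc, Tc)  # sum s_c t_c^T
  sv <- svd(Sc)
  if (sv$d[2L] < max(sv$d[1L], 1) * 1e-10)
    stop("degenerate geometry: source points are collinear or coincident ",
         "(rank < 2); the rotation is not identifiable")
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  A <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  o <- ct - drop(A %*% cs)
  rigid_transform(A, o)
}

#' Mean fitting error between two registered point sets
#'
#' The registration-quality statistic: the mean, over the points of `a`, of
#' the Euclidean distance from each point to its nearest neighbour in `b`.
#' Asymmetric by definition (direction a -> b); set `symmetric = TRUE` to
#' average both directions.
#'
#' @param a,b non-empty [point_cloud]s (or n x 3 matrices).
#' @param symmetric average the a->b and b->a means (default `FALSE`).
#' @return Mean nearest-neighbour distance in mm (>= 0).
#' @export
mean_fitting_error <- function(a, b, symmetric = FALSE) {
  A <- if (inherits(a, "point_cloud")) a$points else as.matrix(a)
  B <- if (inherits(b, "point_cloud")) b$points else as.matrix(b)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("mean fitting error is undefined for empty clouds")
  e <- mean(nn_exact(A, B)$distance)
  if (symmetric) e <- (e + mean(nn_exact(B, A)$distance)) / 2
  e
}

#' Iterative closest point rigid registration
#'
#' Registers `source` onto `target` without known correspondences by
#' alternating exact nearest-neighbour matching (source -> target, ties to
#' the lowest target index) with a Kabsch least-squares fit on the kept
#' pairs, until the mean fitting error improves by less than `tol` or
#' `max_iter` is reached. Initialization is the identity: serial casts
#' scanned in one apparatus are coarsely pre-aligned, and no global
#' (feature/RANSAC) fallback is attempted.
#'
#' @param source,target [point_cloud]s with >= 10 points each.
#' @param max_iter maximum number of correspondence/fit rounds.
#' @param tol convergence tolerance on the mean fitting error, mm.
#' @param trim_fraction fraction in `[0, 0.5)` of the worst-matched source
#'   points discarded from each fit (robustness to partial overlap); 0
#'   keeps every pair.
#' @return An object of class `icp_registration`: list with `transform`
#'   (cumulative [rigid_transform] source -> target), `mean_fitting_error`
#'   (mm), `iterations`, `converged` flag, `per_iteration_error` (mm; entry
#'   1 is the pre-registration error, entries thereafter follow each
#'   update and are non-increasing), plus the call's source/target sizes.
#'   Non-convergence is reported via `converged = FALSE`, never an error.
#' @examples
#' crown <- generate_crown(c(0, 0, 0), n_points = 200, seed = 1)
#' moved <- apply_transform(screw_transform(c(0, 1, 0), c(0, 0, 0), 2, 0.1), crown)
#' icp_register(crown, moved)
#' @export
icp_register <- function(source, target, max_iter = 100, tol = 1e-6,
                         trim_fraction = 0) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  if (n_points(source) < 10L || n_points(target) < 10L)
    stop("ICP needs at least 10 points in each cloud")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("'trim_fraction' must lie in [0, 0.5)")
  S0 <- source$points
  T_ <- target$points
  n_keep <- max(3L, ceiling((1 - trim_fraction) * nrow(S0)))
  cum <- identity_transform()
  moved <- S0
  errs <- numeric(0)
  converged <- FALSE
  k <- 0L
  repeat {
    k <- k + 1L
    nn <- nn_exact(moved, T_)
    keep <- order(nn$distance, seq_along(nn$distance))[seq_len(n_keep)]
    e <- mean(nn$distance[keep])
    errs <- c(errs, e)
    if (k > 1L && abs(errs[k - 1L] - e) < tol) {
      converged <- TRUE
      break
    }
    if (k > max_iter) break
    fit <- kabsch_fit(moved[keep, , drop = FALSE],
                      T_[nn$index[keep], , drop = FALSE])
    cum <- compose(fit, cum)
    moved <- tcrossprod(S0, cum$A) + rep(cum$o, each = nrow(S0))
  }
  structure(list(transform = cum,
                 mean_fitting_error = errs[length(errs)],
                 iterations = k,
                 converged = converged,
                 per_iteration_error = errs,
                 trim_fraction = trim_fraction,
                 n_source = nrow(S0), n_target = nrow(T_)),
            class = "icp_registration")
}

#' @export
print.icp_registration <- function(x, ...) {
  cat("ICP rigid registration (", x$n_source, " -> ", x$n_target,
      " points)\n", sep = "")
  cat(sprintf("  mean fitting error: %.6g mm\n", x$mean_fitting_error))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "max iterations reached"))
  cat(sprintf("  rotation %.4f deg, translation %.4f mm\n",
              rotation_angle(x$transform$A),
              sqrt(sum(x$transform$o^2))))
  invisible(x)
}

#' @export
summary.icp_registration <- function(object, ...) {
  ax <- helical_axis_from_transform(object$transform)
  out <- list(registration = object, axis = ax)
  class(out) <- "summary.icp_registration"
  out
}

#' @export
print.summary.icp_registration <- function(x, ...) {
  print(x$registration)
  cat("\nHelical decomposition of the recovered transform:\n")
  print(x$axis)
  invisible(x)
}

#' @export
coef.icp_registration <- function(object, ...) {
  c(setNames(as.vector(object$transform$A),
             paste0("A", outer(1:3, 1:3, function(i, j) paste0(i, j)))),
    setNames(object$transform$o, c("o1", "o2", "o3")))
}

#' @export
predict.icp_registration <- function(object, newdata, ...) {
  apply_transform(object$transform, newdata)
}

#' @export
residuals.icp_registration <- function(object, source, target, ...) {
  if (missing(source) || missing(target))
    stop("supply the 'source' and 'target' clouds used in the fit")
  moved <- apply_transform(object$transform, source)
  nn_exact(moved$points, target$points)$distance
}

#' @export
plot.icp_registration <- function(x, ...) {
  graphics::plot(seq_along(x$per_iteration_error) - 1L, x$per_iteration_error,
                 type = "b", xlab = "iteration",
                 ylab = "mean fitting error (mm)",
                 main = "ICP convergence", log = "y", ...)
  invisible(x)
}

#' Normalize a serial scan sequence onto a stable reference structure
#'
#' Brings every scan of a timepoint series into the coordinate frame of the
#' first scan by ICP-registering the reference-labelled subset of each later
#' scan onto the first scan's reference subset, then applying the resulting
#' transform to the whole scan. The reference should be a structure that is
#' anatomically stable across timepoints (e.g. first molars joined by a
#' transpalatal bar); after normalization, per-structure motion between
#' consecutive scans is measured in this common frame.
#'
#' @param scans list of labelled [point_cloud]s, one per timepoint; the
#'   first is the anchor frame.
#' @param reference_label label of the stable reference structure; must be
#'   present in every scan.
#' @param ... ICP settings passed to [icp_register()] (`max_iter`, `tol`,
#'   `trim_fraction`).
#' @return An object of class `normalized_series`: list with `scans` (the
#'   normalized clouds; scan 1 unchanged), `transforms` (the normalizing
#'   [rigid_transform] per scan; identity for scan 1), `registrations`
#'   (the `icp_registration` per scan, `NULL` for scan 1) and
#'   `reference_label`.
#' @export
normalize_series <- function(scans, reference_label, ...) {
  stopifnot(is.list(scans), length(scans) >= 1L)
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    if (!inherits(sc, "point_cloud") || is.null(sc$labels) ||
        !any(sc$labels == reference_label))
      stop("scan ", i, " has no points labelled '", reference_label,
           "'; cannot normalize the series")
  }
  ref0 <- subset_label(scans[[1L]], reference_label)
  out_scans <- vector("list", length(scans))
  out_tr <- vector("list", length(scans))
  out_reg <- vector("list", length(scans))
  out_scans[[1L]] <- scans[[1L]]
  out_tr[[1L]] <- identity_transform()
  for (i in seq_along(scans)[-1L]) {
    refi <- subset_label(scans[[i]], reference_label)
    reg <- icp_register(refi, ref0, ...)
    out_reg[[i]] <- reg
    out_tr[[i]] <- reg$transform
    out_scans[[i]] <- apply_transform(reg$transform, scans[[i]],
                                      frame_id = scans[[1L]]$frame_id)
  }
  structure(list(scans = out_scans, transforms = out_tr,
                 registrations = out_reg,
                 reference_label = reference_label),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat("Normalized scan series: ", length(x$scans), " timepoints, reference '",
      x$reference_label, "'\n", sep = "")
  for (i in seq_along(x$scans)) {
    if (i == 1L) {
      cat("  scan 1: anchor frame (identity)\n")
    } else {
      cat(sprintf("  scan %d: reference fitting error %.6g mm (%d iterations)\n",
                  i, x$registrations[[i]]$mean_fitting_error,
                  x$registrations[[i]]$iterations))
    }
  }
  invisible(x)
}
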