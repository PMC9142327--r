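#' Least-squares plane fit to a calibration plate scan
#'
#' Measurement-accuracy check for a surface scanner: fit a plane to the
#' scanned points of a flat calibration plate and report the deviation
#' statistics. The default fit is orthogonal (total) least squares — the
#' plane through the centroid whose normal is the smallest principal
#' direction — because the accuracy metric is geometric distance to the
#' plane. A coordinate-regression variant (`z` on `x, y`) is exposed for
#' comparison; its deviations are still measured as geometric (orthogonal)
#' distances to the fitted plane, so the orthogonal fit can never have a
#' larger RMS deviation.
#'
#' @param cloud a [point_cloud] (or n x 3 matrix) with >= 3 non-collinear
#'   points.
#' @param method `"orthogonal"` (default) or `"regression"`.
#' @return An object of class `plane_fit`: list with `normal` (unit
#'   3-vector, sign fixed so the z-component — or the first non-zero
#'   component — is positive), `offset` (signed plane-to-origin distance,
#'   mm; the plane is `normal . x = offset`), `max_abs_deviation` and
#'   `rms_deviation` (mm), `deviations` (signed per-point distances) and
#'   `method`.
#' @examples
#' g <- as.matrix(expand.grid(x = 0:10, y = 0:10))
#' fit_plane(point_cloud(cbind(g, z = 0)))
#' @export
fit_plane <- function(cloud, method = c("orthogonal", "regression")) {
  method <- match.arg(method)
  P <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(P) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2L, ctr)
  sv <- svd(Pc, nu = 0)
  if (sv$d[2L] < max(sv$d[1L], 1) * 1e-12)
    stop("degenerate input: points are collinear or coincident; ",
         "the plane is not identifiable")
  if (method == "orthogonal") {
    normal <- sv$v[, 3L]
    # sign convention: positive z-component, else first non-zero positive
    nz <- if (abs(normal[3L]) > 1e-12) 3L else which(abs(normal) > 1e-12)[1L]
    if (normal[nz] < 0) normal <- -normal
    offset <- sum(ctr * normal)
  } else {
    # plane z = c0 + c1 x + c2 y, rewritten as normal . x = offset
    co <- stats::lm.fit(cbind(1, P[, 1:2]), P[, 3L])$coefficients
    raw <- c(-co[2L], -co[3L], 1)
    s <- sqrt(sum(raw^2))
    normal <- raw / s
    offset <- co[1L] / s
  }
  dev <- drop(P %*% normal) - offset
  structure(list(normal = as.numeric(normal), offset = offset,
                 max_abs_deviation = max(abs(dev)),
                 rms_deviation = sqrt(mean(dev^2)),
                 deviations = dev, n = nrow(P), method = method),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat("Calibration plane fit (", x$method, " least squares, ", x$n,
      " points)\n", sep = "")
  cat(sprintf("  normal: (%.6f, %.6f, %.6f), offset %.4f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  cat(sprintf("  max |deviation|: %.5f mm   RMS deviation: %.5f mm\n",
              x$max_abs_deviation, x$rms_deviation))
  invisible(x)
}
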