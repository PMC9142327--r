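#' Construct a point cloud
#'
#' A point cloud is an ordered set of 3D points in millimetres, optionally
#' carrying a per-point structure label (e.g. a tooth name) and a tag naming
#' the coordinate frame the points live in.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), or anything
#'   coercible to one (rows are points).
#' @param labels optional character vector of per-point structure labels,
#'   same length as the number of points.
#' @param frame_id character tag for the coordinate frame (free text).
#' @return An object of class `point_cloud`: a list with elements `points`
#'   (n x 3 numeric matrix), `labels` (character or `NULL`) and `frame_id`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' pc
#' @export
point_cloud <- function(points, labels = NULL, frame_id = "") {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 3L)
  if (ncol(points) != 3L)
    stop("'points' must have exactly 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points)))
    stop("every point must have 3 finite coordinates")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(points))
      stop("'labels' must have one entry per point (",
           length(labels), " labels for ", nrow(points), " points)")
  }
  dimnames(points) <- NULL
  structure(list(points = points, labels = labels,
                 frame_id = as.character(frame_id)[1L]),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("Point cloud: ", nrow(x$points), " points",
      if (nzchar(x$frame_id)) paste0(" [frame: ", x$frame_id, "]"), "\n",
      sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("Labels: ",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$points) > 0L) {
    rng <- apply(x$points, 2L, range)
    cat(sprintf("Extent (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
as.matrix.point_cloud <- function(x, ...) x$points

#' Extract the sub-cloud carrying a given label
#'
#' @param cloud a [point_cloud] with labels.
#' @param label structure label to keep.
#' @return A `point_cloud` of the points whose label equals `label`,
#'   order preserved.
#' @export
subset_label <- function(cloud, label) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$labels))
    stop("cloud has no labels; cannot subset by label")
  keep <- cloud$labels == label
  if (!any(keep))
    stop("no points carry label '", label, "'")
  point_cloud(cloud$points[keep, , drop = FALSE],
              labels = cloud$labels[keep], frame_id = cloud$frame_id)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud].
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)
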