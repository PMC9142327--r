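# Point-cloud file formats: PLY (ascii + binary_little_endian), OBJ
# (vertex records only) and XYZ (whitespace "x y z [label]" lines).
# Coordinates are millimetres throughout.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, ply = "ply", obj = "obj", xyz = , txt = "xyz",
         stop("cannot guess point-cloud format from extension '.", ext,
              "'; pass 'format' explicitly"))
}

#' Read a point cloud from PLY, OBJ or XYZ
#'
#' PLY: ascii or binary_little_endian, element `vertex` with `x`, `y`, `z`
#' properties (`float` or `double`); an optional integer `label` property
#' is mapped to structure labels via `comment label <index> <name>` header
#' lines (or kept as the integer's text). Unsupported properties are
#' skipped with a warning. OBJ: `v` records only; faces and normals are
#' ignored. XYZ: whitespace-separated `x y z [label]` lines; blank lines
#' and `#` comments skipped.
#'
#' @param path file to read.
#' @param format `"ply"`, `"obj"` or `"xyz"`; guessed from the extension
#'   by default.
#' @param frame_id frame tag for the returned cloud (default: file name).
#' @return A [point_cloud].
#' @export
read_point_cloud <- function(path, format = guess_format(path),
                             frame_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("ply", "obj", "xyz"))
  switch(format,
         xyz = read_xyz(path, frame_id),
         obj = read_obj(path, frame_id),
         ply = read_ply(path, frame_id))
}

read_xyz <- function(path, frame_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 3L))
    stop("malformed XYZ record at line ", lineno[which(nt < 3L)[1L]],
         ": fewer than 3 fields")
  xyz <- suppressWarnings(
    t(vapply(toks, function(tk) as.numeric(tk[1:3]), numeric(3L))))
  if (anyNA(xyz))
    stop("malformed XYZ record at line ",
         lineno[which(rowSums(is.na(xyz)) > 0)[1L]], ": non-numeric coordinate")
  labels <- if (any(nt >= 4L))
    vapply(toks, function(tk) if (length(tk) >= 4L) tk[4L] else NA_character_,
           character(1L))
  point_cloud(xyz, labels = labels, frame_id = frame_id)
}

read_obj <- function(path, frame_id) {
  lines <- readLines(path, warn = FALSE)
  vidx <- grep("^v(\\s)", lines)
  if (length(vidx) == 0L) stop("no 'v' vertex records in OBJ file ", path)
  toks <- strsplit(trimws(lines[vidx]), "\\s+")
  bad <- which(lengths(toks) < 4L)
  if (length(bad))
    stop("malformed OBJ vertex at line ", vidx[bad[1L]], ": fewer than 3 coordinates")
  xyz <- suppressWarnings(
    t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3L))))
  if (anyNA(xyz))
    stop("malformed OBJ vertex at line ",
         vidx[which(rowSums(is.na(xyz)) > 0)[1L]], ": non-numeric coordinate")
  point_cloud(xyz, frame_id = frame_id)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

read_ply <- function(path, frame_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; n_vertex <- NA_integer_
  props <- character(0); types <- character(0)
  label_map <- character(0)
  in_vertex <- FALSE; other_elements <- FALSE
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of PLY header in ", path)
    tk <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tk) == 0L) next
    if (tk[1L] == "end_header") break
    if (tk[1L] == "format") {
      fmt <- tk[2L]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format '", fmt, "' in ", path)
    } else if (tk[1L] == "comment") {
      if (length(tk) >= 4L && tk[2L] == "label")
        label_map[tk[3L]] <- paste(tk[-(1:3)], collapse = " ")
    } else if (tk[1L] == "element") {
      if (tk[2L] == "vertex") {
        n_vertex <- as.integer(tk[3L]); in_vertex <- TRUE
      } else {
        in_vertex <- FALSE; other_elements <- TRUE
      }
    } else if (tk[1L] == "property" && in_vertex) {
      if (tk[2L] == "list")
        stop("list properties on the vertex element are not supported (", path, ")")
      props <- c(props, tk[3L]); types <- c(types, tk[2L])
    }
  }
  if (is.na(n_vertex)) stop("PLY header has no vertex element (", path, ")")
  if (!all(c("x", "y", "z") %in% props))
    stop("PLY vertex element lacks x/y/z properties (", path, ")")
  extra <- setdiff(props, c("x", "y", "z", "label"))
  if (length(extra))
    warning("ignoring unsupported PLY vertex properties: ",
            paste(extra, collapse = ", "))
  if (other_elements)
    warning("ignoring non-vertex PLY elements (faces etc.) in ", basename(path))
  unknown <- setdiff(types, names(ply_type_size))
  if (length(unknown))
    stop("unsupported PLY property type(s): ", paste(unknown, collapse = ", "))

  if (fmt == "ascii") {
    vals <- scan(con, what = double(), n = n_vertex * length(props),
                 quiet = TRUE)
    if (length(vals) < n_vertex * length(props))
      stop("PLY data truncated: expected ", n_vertex, " vertices (", path, ")")
    M <- matrix(vals, ncol = length(props), byrow = TRUE)
  } else {
    M <- matrix(NA_real_, nrow = n_vertex, ncol = length(props))
    sizes <- ply_type_size[types]
    is_float <- types %in% c("float", "float32", "double", "float64")
    is_signed <- !types %in% c("uchar", "uint8", "ushort", "uint16",
                               "uint", "uint32")
    rec <- sum(sizes)
    raw_all <- readBin(con, "raw", n = n_vertex * rec)
    if (length(raw_all) < n_vertex * rec)
      stop("PLY binary data truncated (", path, ")")
    offs <- c(0L, cumsum(sizes))
    for (j in seq_along(props)) {
      # gather this property's bytes across all records
      sel <- as.vector(outer(seq_len(sizes[j]) + offs[j],
                             (seq_len(n_vertex) - 1L) * rec, "+"))
      bytes <- raw_all[sel]
      M[, j] <- if (is_float[j])
        readBin(bytes, "double", n = n_vertex, size = sizes[j],
                endian = "little")
      else
        readBin(bytes, "integer", n = n_vertex, size = sizes[j],
                signed = is_signed[j] || sizes[j] == 4L, endian = "little")
    }
  }
  colnames(M) <- props
  labels <- NULL
  if ("label" %in% props) {
    li <- as.character(as.integer(M[, "label"]))
    labels <- ifelse(li %in% names(label_map), label_map[li], li)
  }
  point_cloud(M[, c("x", "y", "z"), drop = FALSE], labels = labels,
              frame_id = frame_id)
}

#' Write a point cloud to PLY, OBJ or XYZ
#'
#' PLY output stores `x`, `y`, `z` as `double` by default (`precision =
#' "float32"` for compact single-precision files); labels become an integer
#' `label` vertex property with `comment label <index> <name>` header
#' lines. OBJ stores `v` records (labels dropped). XYZ appends the label as
#' a fourth column when present.
#'
#' @param cloud a [point_cloud].
#' @param path output file.
#' @param format `"ply"`, `"obj"` or `"xyz"`; guessed from the extension.
#' @param binary for PLY: write `binary_little_endian` (default `TRUE`).
#' @param precision for PLY: `"double"` (default, lossless) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = guess_format(path),
                              binary = TRUE, precision = c("double", "float32")) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format, c("ply", "obj", "xyz"))
  precision <- match.arg(precision)
  P <- cloud$points
  if (format == "xyz") {
    df <- as.data.frame(P)
    if (!is.null(cloud$labels)) df$label <- cloud$labels
    utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  if (format == "obj") {
    writeLines(sprintf("v %.17g %.17g %.17g", P[, 1L], P[, 2L], P[, 3L]), path)
    return(invisible(path))
  }
  # PLY
  has_lab <- !is.null(cloud$labels)
  ftype <- if (precision == "double") "double" else "float"
  header <- c("ply",
              paste("format",
                    if (binary) "binary_little_endian" else "ascii", "1.0"))
  if (has_lab) {
    levs <- unique(cloud$labels)
    lab_idx <- match(cloud$labels, levs) - 1L
    header <- c(header,
                sprintf("comment label %d %s", seq_along(levs) - 1L, levs))
  }
  header <- c(header,
              paste("element vertex", nrow(P)),
              paste("property", ftype, "x"),
              paste("property", ftype, "y"),
              paste("property", ftype, "z"))
  if (has_lab) header <- c(header, "property int label")
  header <- c(header, "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    fsize <- if (precision == "double") 8L else 4L
    if (has_lab) {
      for (i in seq_len(nrow(P))) {
        writeBin(as.numeric(P[i, ]), con, size = fsize, endian = "little")
        writeBin(lab_idx[i], con, size = 4L, endian = "little")
      }
    } else {
      writeBin(as.numeric(t(P)), con, size = fsize, endian = "little")
    }
  } else {
    lines <- if (has_lab)
      sprintf("%.17g %.17g %.17g %d", P[, 1L], P[, 2L], P[, 3L], lab_idx)
    else
      sprintf("%.17g %.17g %.17g", P[, 1L], P[, 2L], P[, 3L])
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write a per-tooth motion report to CSV or JSON
#'
#' Fixed column order: `tooth`, `interval`, `theta_deg`, `t_mm`, `h_x`,
#' `h_y`, `h_z`, `q_x`, `q_y`, `q_z`, `mean_fitting_error_mm`,
#' `degenerate`, `unreliable`. Angles are printed to 2 decimals and
#' lengths to 3 — digits below the scanner resolution are noise.
#'
#' @param rows a `motion_report` data frame from [run_pipeline()] (or a
#'   data frame with the columns above).
#' @param path output file.
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_motion_report <- function(rows, path,
                                format = tolower(tools::file_ext(path))) {
  format <- match.arg(format, c("csv", "json"))
  cols <- c("tooth", "interval", "theta_deg", "t_mm", "h_x", "h_y", "h_z",
            "q_x", "q_y", "q_z", "mean_fitting_error_mm", "degenerate",
            "unreliable")
  rows <- as.data.frame(rows)
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols))
    stop("motion report lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- rows[, cols, drop = FALSE]
  ang <- "theta_deg"
  len <- c("t_mm", "h_x", "h_y", "h_z", "q_x", "q_y", "q_z",
           "mean_fitting_error_mm")
  out[ang] <- lapply(out[ang], round, digits = 2L)
  out[len] <- lapply(out[len], round, digits = 3L)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read an analysis configuration from JSON
#'
#' The configuration mirrors [analysis_config()] field for field; see
#' there for semantics and defaults.
#'
#' @param path JSON file.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, cfg)
}

#' Build an analysis configuration
#'
#' @param timepoint_files named character vector or list of scan paths in
#'   timepoint order (names `T0`, `T1`, ... are used in the report;
#'   unnamed inputs are named automatically).
#' @param reference_label label of the stable reference structure.
#' @param tooth_labels labels of the moving structures to analyze; must not
#'   include `reference_label`.
#' @param icp list of ICP settings: `max_iter`, `tol`, `trim_fraction`
#'   (defaults 100, 1e-6 mm, 0.1 — the trimmed default is robust to
#'   partial crown overlap; tests use 0).
#' @param degeneracy_threshold degrees (see
#'   [helical_axis_from_transform()]).
#' @param axis_point_strategy `"minimum_norm"` or `"fix_coordinate"`.
#' @param intervals `"consecutive"` (T0->T1, T1->T2, ...) or an n x 2
#'   matrix / list of 1-based timepoint index pairs for arbitrary
#'   intervals.
#' @param seed integer seed for any stochastic stage.
#' @param report_path optional path the CLI writes the report to.
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(timepoint_files, reference_label, tooth_labels,
                            icp = list(), degeneracy_threshold = 0.1,
                            axis_point_strategy = "minimum_norm",
                            intervals = "consecutive", seed = 1,
                            report_path = NULL) {
  timepoint_files <- unlist(timepoint_files)
  if (length(timepoint_files) < 2L)
    stop("need at least 2 timepoints")
  if (is.null(names(timepoint_files)) || any(!nzchar(names(timepoint_files))))
    names(timepoint_files) <- paste0("T", seq_along(timepoint_files) - 1L)
  tooth_labels <- as.character(unlist(tooth_labels))
  if (reference_label %in% tooth_labels)
    stop("'reference_label' must not appear in 'tooth_labels'")
  icp_def <- list(max_iter = 100, tol = 1e-6, trim_fraction = 0.1)
  icp_def[names(icp)] <- icp
  axis_point_strategy <- match.arg(axis_point_strategy,
                                   c("minimum_norm", "fix_coordinate"))
  if (!identical(intervals, "consecutive")) {
    intervals <- do.call(rbind, lapply(intervals, as.integer))
    if (ncol(intervals) != 2L) stop("'intervals' pairs must have 2 entries")
  }
  structure(list(timepoint_files = timepoint_files,
                 reference_label = as.character(reference_label),
                 tooth_labels = tooth_labels, icp = icp_def,
                 degeneracy_threshold = degeneracy_threshold,
                 axis_point_strategy = axis_point_strategy,
                 intervals = intervals, seed = as.integer(seed),
                 report_path = report_path),
            class = "analysis_config")
}
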