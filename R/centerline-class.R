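#' Construct a centerline object
#'
#' A centerline is an arclength-parameterized 3-D curve through the lumen of a
#' tubular vessel, carrying the local lumen radius at every station. It is the
#' geometric backbone used for bulge insertion, virtual aneurysm excision and
#' region blanking.
#'
#' @param points Numeric matrix (n x 3) of 3-D coordinates in meters, ordered
#'   from inlet to outlet.
#' @param arclength Numeric vector of cumulative arclength per point (m),
#'   strictly increasing and starting at 0.
#' @param radius Numeric vector of local lumen radius per point (m), all > 0.
#' @param provenance One of `"synthetic"`, `"extracted"`, `"interpolated"`.
#'
#' @return An object of class `vaa_centerline`: a list with elements
#'   `points`, `arclength`, `radius`, `provenance`.
#' @export
centerline <- function(points, arclength, radius,
                       provenance = c("synthetic", "extracted", "interpolated")) {
  provenance <- match.arg(provenance)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3 || nrow(points) < 2) {
    vaa_abort("centerline needs an n x 3 numeric point matrix with n >= 2",
              "vaaflow_invalid_parameter")
  }
  arclength <- as.numeric(arclength)
  radius <- as.numeric(radius)
  if (length(arclength) != nrow(points) || length(radius) != nrow(points)) {
    vaa_abort("arclength and radius must have one value per point",
              "vaaflow_invalid_parameter")
  }
  if (abs(arclength[1]) > 1e-12 || any(diff(arclength) <= 0)) {
    vaa_abort("arclength must start at 0 and be strictly increasing",
              "vaaflow_invalid_parameter")
  }
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    vaa_abort("all radii must be positive and finite", "vaaflow_invalid_parameter")
  }
  structure(list(points = points, arclength = arclength, radius = radius,
                 provenance = provenance),
            class = "vaa_centerline")
}

#' @export
print.vaa_centerline <- function(x, ...) {
  cat(sprintf("<vaa_centerline> %d points, length %.4g mm, radius %.3g-%.3g mm (%s)\n",
              nrow(x$points), 1e3 * x$arclength[length(x$arclength)],
              1e3 * min(x$radius), 1e3 * max(x$radius), x$provenance))
  invisible(x)
}

#' Interpolate centerline radius at arbitrary arclength stations
#'
#' @param line A [centerline()].
#' @param s Arclength values (m); clamped to the line's range.
#' @return Numeric vector of radii (m).
#' @export
centerline_radius_at <- function(line, s) {
  s <- pmin(pmax(s, line$arclength[1]), line$arclength[length(line$arclength)])
  stats::approx(line$arclength, line$radius, xout = s, rule = 2)$y
}

#' Write / read a centerline as CSV
#'
#' Columns: `s_m, x_m, y_m, z_m, radius_m`.
#'
#' @param line A [centerline()].
#' @param path File path.
#' @return `write_centerline_csv` returns `path` invisibly;
#'   `read_centerline_csv` returns a [centerline()].
#' @export
write_centerline_csv <- function(line, path) {
  df <- data.frame(s_m = line$arclength,
                   x_m = line$points[, 1], y_m = line$points[, 2],
                   z_m = line$points[, 3], radius_m = line$radius)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @param provenance Provenance recorded on the read-back line.
#' @export
read_centerline_csv <- function(path, provenance = "synthetic") {
  df <- utils::read.csv(path)
  need <- c("s_m", "x_m", "y_m", "z_m", "radius_m")
  if (!all(need %in% names(df))) {
    vaa_abort(sprintf("centerline CSV must have columns %s", paste(need, collapse = ", ")),
              "vaaflow_format_error")
  }
  centerline(as.matrix(df[, c("x_m", "y_m", "z_m")]), df$s_m, df$radius_m,
             provenance = provenance)
}
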