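#' Synthetic vessel geometry generation
#'
#' These functions build ground-truth-labelled tubular vessel geometries in the
#' visceral-artery size range (lumen radius a few millimeters): a centerline
#' path with a constant healthy radius, optional stenoses and aneurysm bulges,
#' and a swept triangulated tube surface. They stand in for patient-derived
#' CTA segmentations so that every downstream stage (centerline extraction,
#' excision, wall-shear indices, region statistics) can be validated against a
#' known answer.
#'
#' @name vessel-synth
NULL

# Smooth compactly supported cosine-squared bump: 1 at u = 0, 0 for |u| >= 1/2.
cos2_bump <- function(u) ifelse(abs(u) < 0.5, cos(pi * u)^2, 0)

#' Create a centerline path
#'
#' @param kind `"straight"`, `"curved"` (planar circular arc) or `"helical"`.
#' @param length Total arclength of the path (m).
#' @param base_radius Constant healthy lumen radius (m).
#' @param n_points Number of stations along the path (>= 2).
#' @param curvature_radius Radius of the arc for `kind = "curved"` (m).
#' @param helix_radius,helix_pitch Geometry of the helix for `kind = "helical"`.
#' @return A [centerline()] with constant radius and `provenance = "synthetic"`.
#' @export
#' @examples
#' path <- make_centerline_path("straight", length = 0.05, base_radius = 0.002)
make_centerline_path <- function(kind = c("straight", "curved", "helical"),
                                 length, base_radius, n_points = 101,
                                 curvature_radius = 0.02,
                                 helix_radius = 0.01, helix_pitch = 0.004) {
  kind <- match.arg(kind)
  if (!is.numeric(length) || length <= 0 || !is.numeric(base_radius) || base_radius <= 0) {
    vaa_abort("length and base_radius must be positive", "vaaflow_invalid_parameter")
  }
  if (n_points < 2) vaa_abort("n_points must be >= 2", "vaaflow_invalid_parameter")
  s <- seq(0, length, length.out = n_points)
  pts <- switch(kind,
    straight = cbind(s, 0, 0),
    curved = {
      if (curvature_radius <= 0) vaa_abort("curvature_radius must be positive",
                                           "vaaflow_invalid_parameter")
      th <- s / curvature_radius
      cbind(curvature_radius * sin(th), curvature_radius * (1 - cos(th)), 0)
    },
    helical = {
      cfac <- sqrt(helix_radius^2 + helix_pitch^2)
      t <- s / cfac
      cbind(helix_radius * cos(t), helix_radius * sin(t), helix_pitch * t)
    })
  centerline(pts, s, rep(base_radius, n_points), provenance = "synthetic")
}

#' Narrow a path with a smooth stenosis
#'
#' The radius inside the stenosis interval is multiplied by
#' `1 - severity * bump(s)` with a cosine-squared bump, so the minimum radius
#' at the stenosis center is exactly `(1 - severity)` times the healthy radius
#' and the profile is continuous with compact support.
#'
#' @param path A [centerline()].
#' @param center_s Arclength of the stenosis center (m).
#' @param extent Arclength span of the stenosis (m).
#' @param severity Fractional lumen reduction, strictly in (0, 1). A severity
#'   of 1 (occlusion) is rejected: the pulsatile flow surrogate requires a
#'   positive lumen everywhere.
#' @return The narrowed [centerline()]; the stenosis interval is recorded in
#'   `attr(, "stenosis_interval")`.
#' @export
apply_stenosis <- function(path, center_s, extent, severity) {
  stopifnot(inherits(path, "vaa_centerline"))
  if (!is.numeric(severity) || severity <= 0) {
    vaa_abort("severity must be in (0, 1)", "vaaflow_invalid_parameter")
  }
  if (severity >= 1) {
    vaa_abort("severity >= 1 means occlusion, which the flow surrogate cannot carry",
              "vaaflow_unsupported_for_flow")
  }
  if (extent <= 0) vaa_abort("extent must be positive", "vaaflow_invalid_parameter")
  smax <- path$arclength[length(path$arclength)]
  if (center_s - extent / 2 < 0 || center_s + extent / 2 > smax) {
    vaa_abort("stenosis interval must lie inside the path", "vaaflow_invalid_parameter")
  }
  u <- (path$arclength - center_s) / extent
  r <- path$radius * (1 - severity * cos2_bump(u))
  out <- centerline(path$points, path$arclength, r, provenance = path$provenance)
  attr(out, "stenosis_interval") <- c(center_s - extent / 2, center_s + extent / 2)
  attr(out, "saccular_spec") <- attr(path, "saccular_spec")
  out
}

#' Specify an aneurysm bulge
#'
#' @param center_s Arclength of the bulge center (m).
#' @param extent Arclength span of the bulge support (m).
#' @param amplitude Maximal radial excess over the healthy radius (m).
#' @param shape `"fusiform"` (axisymmetric dilation) or `"saccular"`
#'   (one-sided pouch at a given azimuth).
#' @param azimuth Angular position of a saccular bulge in the tube frame (rad,
#'   in `[0, 2*pi)`).
#' @return A list of class `vaa_aneurysm_spec`.
#' @export
aneurysm_spec <- function(center_s, extent, amplitude,
                          shape = c("fusiform", "saccular"), azimuth = 0) {
  shape <- match.arg(shape)
  if (extent <= 0 || amplitude <= 0) {
    vaa_abort("extent and amplitude must be positive", "vaaflow_invalid_parameter")
  }
  if (azimuth < 0 || azimuth >= 2 * pi) {
    vaa_abort("azimuth must be in [0, 2*pi)", "vaaflow_invalid_parameter")
  }
  structure(list(center_s = center_s, extent = extent, amplitude = amplitude,
                 shape = shape, azimuth = azimuth),
            class = "vaa_aneurysm_spec")
}

#' Insert an aneurysm bulge into a path
#'
#' Fusiform bulges increase the radius by `amplitude * bump(s)`; saccular
#' bulges are recorded on the path and realized at the sweep stage as a ring
#' offset toward one azimuth combined with a half-amplitude radius increase,
#' so the near wall bulges by exactly `amplitude` while the far wall stays on
#' the healthy tube.
#'
#' @param path A [centerline()], possibly already stenosed.
#' @param spec An [aneurysm_spec()].
#' @return A list with `path` (the modified [centerline()]) and `truth`, a
#'   partial ground-truth record carrying `healthy_radius` and
#'   `aneurysm_interval`.
#' @export
apply_aneurysm <- function(path, spec) {
  stopifnot(inherits(path, "vaa_centerline"), inherits(spec, "vaa_aneurysm_spec"))
  smax <- path$arclength[length(path$arclength)]
  s1 <- spec$center_s - spec$extent / 2
  s2 <- spec$center_s + spec$extent / 2
  if (s1 < 0 || s2 > smax) {
    vaa_abort("aneurysm interval must lie inside the path", "vaaflow_invalid_parameter")
  }
  sten <- attr(path, "stenosis_interval")
  if (!is.null(sten) && s1 < sten[2] && sten[1] < s2) {
    vaa_abort("aneurysm and stenosis intervals overlap", "vaaflow_invalid_configuration")
  }
  healthy <- path$radius
  u <- (path$arclength - spec$center_s) / spec$extent
  if (spec$shape == "fusiform") {
    r <- path$radius + spec$amplitude * cos2_bump(u)
    out <- centerline(path$points, path$arclength, r, provenance = path$provenance)
  } else {
    out <- centerline(path$points, path$arclength, path$radius,
                      provenance = path$provenance)
    attr(out, "saccular_spec") <- spec
  }
  attr(out, "stenosis_interval") <- sten
  truth <- list(healthy_radius = healthy, aneurysm_interval = c(s1, s2),
                shape = spec$shape)
  list(path = out, truth = truth)
}

#' Sweep a triangulated tube surface along a path
#'
#' Circular cross-sections are swept along the path on rotation-minimizing
#' (parallel-transport) frames and triangulated as an open tube. If the path
#' carries a saccular bulge specification, ring centers are offset toward the
#' bulge azimuth. Faces are labelled from the ground-truth aneurysm interval:
#' centroids projecting into the interval are `aneurysm`, those within one
#' interval length before/after are `upstream`/`downstream`, the rest `other`.
#'
#' @param path A [centerline()], typically from [apply_aneurysm()].
#' @param n_circumferential Number of points per ring (>= 8).
#' @param truth Optional partial ground truth from [apply_aneurysm()].
#' @return A list with `mesh` (a [surface_mesh()]) and `truth` (ground truth
#'   completed with per-face `face_labels`).
#' @export
sweep_tube_mesh <- function(path, n_circumferential = 48, truth = NULL) {
  stopifnot(inherits(path, "vaa_centerline"))
  if (n_circumferential < 8) {
    vaa_abort("n_circumferential must be >= 8", "vaaflow_invalid_parameter")
  }
  pts <- path$points
  n <- nrow(pts)
  kappa <- discrete_curvature(pts, path$arclength)
  if (any(path$radius * kappa >= 1)) {
    vaa_abort("tube radius exceeds local curvature radius: sweep would self-intersect",
              "vaaflow_geometry_error")
  }
  fr <- transport_frames(pts)
  sac <- attr(path, "saccular_spec")
  theta <- 2 * pi * (0:(n_circumferential - 1)) / n_circumferential
  verts <- matrix(0, n * n_circumferential, 3)
  for (i in seq_len(n)) {
    ctr <- pts[i, ]
    r_ring <- rep(path$radius[i], n_circumferential)
    if (!is.null(sac)) {
      b <- cos2_bump((path$arclength[i] - sac$center_s) / sac$extent)
      if (b > 0) {
        udir <- cos(sac$azimuth) * fr$e1[i, ] + sin(sac$azimuth) * fr$e2[i, ]
        ctr <- ctr + (sac$amplitude / 2) * b * udir
        r_ring <- r_ring + (sac$amplitude / 2) * b
      }
    }
    ring <- matrix(ctr, n_circumferential, 3, byrow = TRUE) +
      r_ring * (cos(theta) %o% fr$e1[i, ] + sin(theta) %o% fr$e2[i, ])
    verts[(i - 1) * n_circumferential + seq_len(n_circumferential), ] <- ring
  }
  faces <- matrix(0L, 2 * (n - 1) * n_circumferential, 3)
  k <- 1L
  for (i in seq_len(n - 1)) {
    o1 <- (i - 1L) * n_circumferential
    o2 <- i * n_circumferential
    j2 <- c(seq_len(n_circumferential - 1L) + 1L, 1L)
    for (j in seq_len(n_circumferential)) {
      a <- o1 + j; b <- o1 + j2[j]; cc <- o2 + j; d <- o2 + j2[j]
      faces[k, ] <- c(a, b, d); faces[k + 1L, ] <- c(a, d, cc)
      k <- k + 2L
    }
  }
  mesh <- surface_mesh(verts, faces)
  # enforce outward normals (centroid minus local ring center along normal > 0)
  ring_of_face <- rep(rep(seq_len(n - 1), each = 1), each = 2 * n_circumferential)
  ctr_of_face <- (pts[ring_of_face, , drop = FALSE] + pts[ring_of_face + 1L, , drop = FALSE]) / 2
  outward <- rowSums(mesh$face_normal * (mesh$face_centroid - ctr_of_face))
  if (mean(outward > 0) < 0.5) {
    mesh <- surface_mesh(verts, faces[, c(1, 3, 2)])
  }
  # face labels from the aneurysm interval (centroid arclength projection)
  s_face <- project_onto_polyline(mesh$face_centroid, pts, path$arclength)$s
  labels <- rep("other", nrow(mesh$faces))
  if (!is.null(truth) && !is.null(truth$aneurysm_interval)) {
    iv <- truth$aneurysm_interval
    w <- iv[2] - iv[1]
    labels[s_face >= iv[1] & s_face < iv[2]] <- "aneurysm"
    labels[s_face >= iv[1] - w & s_face < iv[1]] <- "upstream"
    labels[s_face >= iv[2] & s_face < iv[2] + w] <- "downstream"
  }
  truth_out <- truth %||% list(healthy_radius = path$radius, aneurysm_interval = NULL)
  truth_out$face_labels <- labels
  list(mesh = mesh, truth = truth_out)
}

#' Generate a labelled cohort of synthetic aneurysm models
#'
#' Emulates a case series of visceral-artery aneurysm models split into a
#' high-WSS-like and a low-WSS-like flow scenario group (defaults: 11 high,
#' 3 low). Each model is a tubular vessel (radius drawn from
#' `radius_range_m`) carrying one aneurysm bulge; the scenario tag fixes the
#' flow regime used later by the wall-shear surrogate: high-group models get a
#' mean flow targeting a time-averaged wall shear near 1.3 Pa with a local
#' shear elevation at the bulge site, low-group models a flow targeting
#' roughly 0.26 Pa with a local shear deficit and a stronger oscillatory
#' component.
#'
#' @param config List with elements `n_high`, `n_low`, `radius_range_m`,
#'   `length_m`, `n_points`, `n_circumferential`, `amp_ratio_range`,
#'   `extent_ratio_range` (bulge extent as a multiple of the local diameter),
#'   `saccular_fraction`, `stenosis_fraction`, `stenosis_severity_range`.
#'   Missing elements take the defaults of [cohort_spec()].
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return List of models, each a list with `id`, `mesh`, `truth`, `path`,
#'   `scenario` (list with `tag`, `q_mean_m3s`, `aneurysm_scale`,
#'   `reversal_frac`).
#' @export
generate_cohort <- function(config = cohort_spec(), seed = 1L) {
  config <- utils::modifyList(cohort_spec(), config)
  n_total <- config$n_high + config$n_low
  if (n_total < 1) vaa_abort("cohort config lists no models", "vaaflow_invalid_configuration")
  with_seed(seed, {
    tags <- c(rep("high", config$n_high), rep("low", config$n_low))
    lapply(seq_len(n_total), function(i) {
      tag <- tags[i]
      base_r <- stats::runif(1, config$radius_range_m[1], config$radius_range_m[2])
      len <- config$length_m
      kind <- sample(c("straight", "curved"), 1, prob = c(0.5, 0.5))
      path <- make_centerline_path(kind, len, base_r, config$n_points,
                                   curvature_radius = stats::runif(1, 0.04, 0.08))
      extent <- stats::runif(1, config$extent_ratio_range[1], config$extent_ratio_range[2]) *
        2 * base_r
      center_s <- stats::runif(1, 0.44, 0.56) * len
      amp <- stats::runif(1, config$amp_ratio_range[1], config$amp_ratio_range[2]) * base_r
      shape <- if (stats::runif(1) < config$saccular_fraction) "saccular" else "fusiform"
      spec <- aneurysm_spec(center_s, extent, amp, shape,
                            azimuth = stats::runif(1, 0, 2 * pi - 1e-9))
      # optional stenosis, kept clear of the aneurysm and its para windows
      has_sten <- stats::runif(1) < config$stenosis_fraction
      if (has_sten) {
        sev <- stats::runif(1, config$stenosis_severity_range[1],
                            config$stenosis_severity_range[2])
        sten_extent <- 3 * base_r
        sten_center <- center_s - 2.5 * extent - sten_extent
        if (sten_center - sten_extent / 2 > 0.02 * len) {
          path <- apply_stenosis(path, sten_center, sten_extent, sev)
        }
      }
      an <- apply_aneurysm(path, spec)
      swept <- sweep_tube_mesh(an$path, config$n_circumferential, an$truth)
      # flow regime: mean flow chosen so the healthy-segment Poiseuille shear
      # sits at the group's characteristic TAWSS level
      tawss_target <- if (tag == "high") stats::runif(1, 1.1, 1.6) else stats::runif(1, 0.2, 0.33)
      q_mean <- tawss_target * pi * base_r^3 / (4 * 0.0035)
      scenario <- list(
        tag = tag,
        q_mean_m3s = q_mean,
        aneurysm_scale = if (tag == "high") stats::runif(1, 1.45, 1.9) else stats::runif(1, 0.45, 0.7),
        reversal_frac = if (tag == "high") stats::runif(1, 0.01, 0.04) else stats::runif(1, 0.08, 0.18)
      )
      list(id = sprintf("model_%02d", i), mesh = swept$mesh, truth = swept$truth,
           path = an$path, scenario = scenario)
    })
  })
}

#' Default cohort configuration
#'
#' Defaults mirror the study conditions: 14 single-aneurysm models (11
#' high-WSS-like, 3 low-WSS-like), visceral-artery lumen radii of 2-5 mm, one
#' bulge per model with amplitude 50-90% of the healthy radius.
#'
#' @param n_high,n_low Group sizes.
#' @param ... Overrides for the remaining fields documented in
#'   [generate_cohort()].
#' @return A named list.
#' @export
cohort_spec <- function(n_high = 11, n_low = 3, ...) {
  out <- utils::modifyList(list(
    n_high = n_high, n_low = n_low,
    radius_range_m = c(0.002, 0.005),
    length_m = 0.07,
    n_points = 121,
    n_circumferential = 32,
    amp_ratio_range = c(0.5, 0.9),
    extent_ratio_range = c(1.2, 1.8),
    saccular_fraction = 0.3,
    stenosis_fraction = 0.4,
    stenosis_severity_range = c(0.3, 0.6)
  ), list(...))
  out
}
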