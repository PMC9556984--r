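#' Mark the aneurysm-affected centerline segment
#'
#' The healthy baseline radius is taken as the linear trend between the two
#' ends of the line; the aneurysm segment is the maximal contiguous run where
#' the radius exceeds that baseline by more than `rel_threshold`, expanded
#' outward to where the relative excess decays below 2% (the practical edge
#' of a smooth bulge's support). If several disjoint runs exceed the
#' threshold, the largest is returned with a warning (models with multiple
#' aneurysms are processed one aneurysm at a time).
#'
#' @param line A [centerline()].
#' @param rel_threshold Relative radius excess marking aneurysmal dilation
#'   (default 0.2, i.e. 20% over baseline); must be positive.
#' @return Numeric `c(s1, s2)` arclength interval (m), or `NULL` when no
#'   segment exceeds the threshold.
#' @export
mark_aneurysm_segment <- function(line, rel_threshold = 0.2) {
  stopifnot(inherits(line, "vaa_centerline"))
  if (!is.numeric(rel_threshold) || rel_threshold <= 0) {
    vaa_abort("rel_threshold must be positive", "vaaflow_invalid_parameter")
  }
  s <- line$arclength
  n <- length(s)
  # robust end levels (median of the outermost stations) so a single noisy
  # end section cannot tilt the baseline
  k <- max(2L, round(0.05 * n))
  r_in <- stats::median(line$radius[seq_len(k)])
  r_out <- stats::median(line$radius[(n - k + 1L):n])
  base <- r_in + (r_out - r_in) * (s - s[1]) / (s[n] - s[1])
  excess <- line$radius / base - 1
  above <- excess > rel_threshold
  if (!any(above)) return(NULL)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values)
  if (length(hit) > 1L) {
    warning("multiple dilated segments found; returning the largest (run per aneurysm)")
  }
  widths <- s[ends[hit]] - s[starts[hit]]
  k <- hit[which.max(widths)]
  i1 <- starts[k]; i2 <- ends[k]
  # expand to the practical support edge of the bulge; the expansion is capped
  # at three core run widths per side (far beyond any smooth compact bulge's
  # support) purely so profile noise cannot drag the interval down the vessel
  eps <- 0.02
  # cap width: three core run widths, but never less than a few lumen radii
  # (a weak-signal bulge can cross the threshold at a single station)
  runw <- max(3 * (s[i2] - s[i1]), 8 * stats::median(line$radius))
  lo_cap <- s[i1] - runw
  hi_cap <- s[i2] + runw
  while (i1 > 1L && excess[i1 - 1L] > eps && s[i1 - 1L] >= lo_cap) i1 <- i1 - 1L
  while (i2 < n && excess[i2 + 1L] > eps && s[i2 + 1L] <= hi_cap) i2 <- i2 + 1L
  c(s[i1], s[i2])
}

#' Interpolate a centerline across an excised interval
#'
#' Points inside the interval are replaced by a cubic Hermite curve matching
#' position and tangent at the healthy endpoints; the radius across the gap is
#' interpolated linearly between the endpoint radii.
#'
#' @param line A [centerline()].
#' @param interval Numeric `c(s1, s2)` strictly inside the line, with at
#'   least two healthy stations on each side.
#' @return A [centerline()] with `provenance = "interpolated"`.
#' @export
interpolate_centerline <- function(line, interval) {
  stopifnot(inherits(line, "vaa_centerline"))
  s <- line$arclength
  n <- length(s)
  s1 <- interval[1]; s2 <- interval[2]
  if (s1 >= s2) vaa_abort("interval must satisfy s1 < s2", "vaaflow_invalid_parameter")
  inside <- which(s > s1 & s < s2)
  ia <- if (length(inside)) min(inside) - 1L else max(which(s <= s1))
  ib <- if (length(inside)) max(inside) + 1L else min(which(s >= s2))
  if (ia < 2L || ib > n - 1L) {
    vaa_abort("excised interval touches an end of the centerline: cannot interpolate",
              "vaaflow_cannot_interpolate")
  }
  pa <- line$points[ia, ]; pb <- line$points[ib, ]
  gap <- s[ib] - s[ia]
  # endpoint tangents from the healthy sides, scaled to the gap length
  ta <- unitize(line$points[ia, ] - line$points[ia - 1L, ]) * gap
  tb <- unitize(line$points[ib + 1L, ] - line$points[ib, ]) * gap
  u <- (s[inside] - s[ia]) / gap
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  new_pts <- h00 %o% pa + h10 %o% ta + h01 %o% pb + h11 %o% tb
  pts <- line$points
  pts[inside, ] <- new_pts
  rad <- line$radius
  rad[inside] <- line$radius[ia] +
    (line$radius[ib] - line$radius[ia]) * (s[inside] - s[ia]) / gap
  arc <- c(0, cumsum(row_norms(diff(pts))))
  centerline(pts, arc, rad, provenance = "interpolated")
}

#' Reconstruct the parent-artery surface over an excised interval
#'
#' Faces whose centroid projects into the interval are removed; the gap is
#' bridged by a lofted tube of circular cross-sections centered on the
#' interpolated centerline with the interpolated radii (the envelope of the
#' interpolated spheres for a slowly varying radius), stitched to the retained
#' boundary rings. The output approximates the hypothetical vessel before
#' aneurysm formation.
#'
#' @param line A [centerline()] already interpolated across `interval`
#'   (see [interpolate_centerline()]); a raw line is interpolated on the fly.
#' @param mesh The aneurysmal [surface_mesh()].
#' @param interval Numeric `c(s1, s2)` excised arclength interval (m).
#' @param n_circumferential Points per lofted ring (default 48).
#' @return A list of class `vaa_excision` with `interpolated_line`,
#'   `reconstructed_mesh`, `excised_interval`.
#' @export
reconstruct_parent_surface <- function(line, mesh, interval, n_circumferential = 48) {
  stopifnot(inherits(line, "vaa_centerline"), inherits(mesh, "vaa_mesh"))
  s1 <- interval[1]; s2 <- interval[2]
  if (s2 - s1 <= 0) {
    return(structure(list(interpolated_line = line, reconstructed_mesh = mesh,
                          excised_interval = interval), class = "vaa_excision"))
  }
  if (line$provenance != "interpolated") line <- interpolate_centerline(line, interval)
  proj <- project_onto_polyline(mesh$face_centroid, line$points, line$arclength)
  drop <- proj$s >= s1 & proj$s < s2
  if (!any(drop)) {
    return(structure(list(interpolated_line = line, reconstructed_mesh = mesh,
                          excised_interval = interval), class = "vaa_excision"))
  }
  kept_faces <- mesh$faces[!drop, , drop = FALSE]
  kept <- surface_mesh(mesh$vertices, kept_faces, validate = FALSE)
  loops <- boundary_loops(kept)
  if (length(loops) < 2) {
    vaa_abort("face removal did not open two boundary rings (non-tubular topology)",
              "vaaflow_topology_error")
  }
  loop_s <- vapply(loops, function(l) {
    mean(project_onto_polyline(mesh$vertices[l, , drop = FALSE],
                               line$points, line$arclength)$s)
  }, numeric(1))
  up_loop <- loops[[which.min(abs(loop_s - s1))]]
  down_loop <- loops[[which.min(abs(loop_s - s2))]]
  if (identical(up_loop, down_loop)) {
    vaa_abort("could not separate upstream and downstream boundary rings",
              "vaaflow_topology_error")
  }
  # stations across the gap at roughly the mesh's own ring spacing
  spacing <- 2 * sqrt(stats::median(mesh$face_area))
  k <- max(3L, ceiling((s2 - s1) / spacing))
  st <- seq(s1, s2, length.out = k + 1L)
  frame_line <- resample_centerline(line, st)
  fr <- transport_frames(frame_line$points)
  theta <- 2 * pi * (0:(n_circumferential - 1)) / n_circumferential
  rings <- lapply(seq_along(st), function(i) {
    matrix(frame_line$points[i, ], n_circumferential, 3, byrow = TRUE) +
      frame_line$radius[i] * (cos(theta) %o% fr$e1[i, ] + sin(theta) %o% fr$e2[i, ])
  })
  # replace the end rings by the actual boundary loops, resampled at the loft
  # frame angles (phase-aligned with the interior rings, so the bridge has no
  # twist and no chords cutting inside the lumen)
  kk <- length(st)
  rings[[1]] <- loop_ring_at_angles(mesh$vertices[up_loop, , drop = FALSE],
                                    frame_line$points[1, ], fr$e1[1, ], fr$e2[1, ],
                                    theta)
  rings[[kk]] <- loop_ring_at_angles(mesh$vertices[down_loop, , drop = FALSE],
                                     frame_line$points[kk, ], fr$e1[kk, ], fr$e2[kk, ],
                                     theta)
  nv0 <- nrow(mesh$vertices)
  new_verts <- do.call(rbind, rings)
  faces_new <- tube_strip_faces(length(rings), n_circumferential, offset = nv0)
  all_verts <- rbind(mesh$vertices, new_verts)
  all_faces <- rbind(kept_faces, faces_new)
  recon <- surface_mesh(all_verts, all_faces, validate = FALSE)
  structure(list(interpolated_line = line, reconstructed_mesh = recon,
                 excised_interval = c(s1, s2)),
            class = "vaa_excision")
}

#' @export
print.vaa_excision <- function(x, ...) {
  cat(sprintf("<vaa_excision> interval [%.2f, %.2f] mm, reconstructed mesh: %d faces\n",
              1e3 * x$excised_interval[1], 1e3 * x$excised_interval[2],
              nrow(x$reconstructed_mesh$faces)))
  invisible(x)
}

# Resample a centerline at given arclength stations (linear in position and
# radius; adequate at the mesh's own ring spacing).
resample_centerline <- function(line, st) {
  s <- line$arclength
  pts <- cbind(stats::approx(s, line$points[, 1], st, rule = 2)$y,
               stats::approx(s, line$points[, 2], st, rule = 2)$y,
               stats::approx(s, line$points[, 3], st, rule = 2)$y)
  rad <- stats::approx(s, line$radius, st, rule = 2)$y
  list(points = pts, radius = rad)
}

# Resample a boundary loop (as an unordered vertex set on the tube wall) at
# the given frame angles around `center`: for each target angle the bracketing
# loop vertices are interpolated angularly, giving a ring phase-matched to the
# loft frame regardless of the loop's traversal order.
loop_ring_at_angles <- function(loop_pts, center, e1, e2, theta) {
  rel <- loop_pts - matrix(center, nrow(loop_pts), 3, byrow = TRUE)
  ang <- atan2(rel %*% e2, rel %*% e1) %% (2 * pi)
  ord <- order(ang)
  ang <- ang[ord]
  rel <- rel[ord, , drop = FALSE]
  n <- length(ang)
  out <- matrix(0, length(theta), 3)
  for (j in seq_along(theta)) {
    th <- theta[j] %% (2 * pi)
    i2 <- which(ang >= th)[1]
    if (is.na(i2)) { i1 <- n; i2 <- 1L; a1 <- ang[n]; a2 <- ang[1] + 2 * pi }
    else if (i2 == 1L) { i1 <- n; a1 <- ang[n] - 2 * pi; a2 <- ang[1] }
    else { i1 <- i2 - 1L; a1 <- ang[i1]; a2 <- ang[i2] }
    w <- if (a2 > a1) (th - a1) / (a2 - a1) else 0
    out[j, ] <- center + (1 - w) * rel[i1, ] + w * rel[i2, ]
  }
  out
}

# Quad-strip triangulation between consecutive rings of equal size.
tube_strip_faces <- function(n_rings, n_circ, offset = 0L) {
  faces <- matrix(0L, 2L * (n_rings - 1L) * n_circ, 3L)
  k <- 1L
  j2 <- c(seq_len(n_circ - 1L) + 1L, 1L)
  for (i in seq_len(n_rings - 1L)) {
    o1 <- offset + (i - 1L) * n_circ
    o2 <- offset + i * n_circ
    for (j in seq_len(n_circ)) {
      a <- o1 + j; b <- o1 + j2[j]; cc <- o2 + j; d <- o2 + j2[j]
      faces[k, ] <- c(a, b, d); faces[k + 1L, ] <- c(a, d, cc)
      k <- k + 2L
    }
  }
  faces
}

#' Round-trip radius-recovery experiment
#'
#' Validation harness for the excision stage: generates a seeded cohort of
#' synthetic aneurysm models, runs centerline extraction, automatic marking,
#' excision and parent-vessel reconstruction on each, and measures the
#' relative error between the reconstructed inscribed-radius profile and the
#' profile of the ground-truth healthy vessel measured identically (the same
#' inscribed-sphere probe at the same stations, so steep-taper and
#' discretization effects of the probe itself cancel).
#'
#' @param n_models Number of models (default 20).
#' @param seed Integer seed.
#' @param config A [cohort_spec()]; defaults to `n_models` high-scenario
#'   models (the flow scenario is irrelevant here).
#' @return data.frame with one row per model: `id`, `median_err`, `max_err`
#'   (relative radius errors).
#' @export
radius_recovery_experiment <- function(n_models = 20, seed = 1L,
                                       config = cohort_spec(n_high = n_models, n_low = 0)) {
  cohort <- generate_cohort(config, seed = seed)
  rows <- lapply(cohort, function(m) {
    n <- nrow(m$path$points)
    cl <- extract_centerline(m$mesh, m$path$points[1, ], m$path$points[n, ])
    exc <- excise_aneurysm(m$mesh, cl,
                           n_circumferential = config$n_circumferential)
    prof <- inscribed_radius_profile(exc$reconstructed_mesh, exc$interpolated_line)
    healthy_line <- centerline(m$path$points, m$path$arclength,
                               m$truth$healthy_radius, provenance = "synthetic")
    healthy_mesh <- sweep_tube_mesh(healthy_line, config$n_circumferential)$mesh
    healthy <- inscribed_radius_profile(healthy_mesh, exc$interpolated_line)
    err <- abs(prof - healthy) / healthy
    data.frame(id = m$id, median_err = stats::median(err), max_err = max(err))
  })
  do.call(rbind, rows)
}

#' Excise an aneurysm and reconstruct the parent vessel in one call
#'
#' Convenience wrapper: marks the dilated segment (unless an interval is
#' given), interpolates the centerline across it and reconstructs the parent
#' surface.
#'
#' @param mesh Aneurysmal [surface_mesh()].
#' @param line Its [centerline()].
#' @param interval Optional `c(s1, s2)`; when `NULL` the segment is marked
#'   automatically with [mark_aneurysm_segment()].
#' @param rel_threshold Threshold forwarded to [mark_aneurysm_segment()].
#' @param n_circumferential Loft resolution.
#' @param pad Extra margin (m) removed on each side of the marked interval so
#'   that the faint tails of a smooth bulge do not survive the excision;
#'   default one centerline station spacing. The padded interval is clipped
#'   so at least two healthy stations remain on each side.
#' @return A `vaa_excision` (see [reconstruct_parent_surface()]).
#' @export
excise_aneurysm <- function(mesh, line, interval = NULL, rel_threshold = 0.2,
                            n_circumferential = 48, pad = NULL) {
  if (is.null(interval)) {
    interval <- mark_aneurysm_segment(line, rel_threshold)
    if (is.null(interval)) {
      vaa_abort("no aneurysmal dilation found above the threshold", "vaaflow_geometry_error")
    }
    pad <- pad %||% stats::median(diff(line$arclength))
    s <- line$arclength
    lo <- max(interval[1] - pad, s[3])
    hi <- min(interval[2] + pad, s[length(s) - 2])
    interval <- c(lo, hi)
  }
  reconstruct_parent_surface(line, mesh, interval, n_circumferential)
}
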