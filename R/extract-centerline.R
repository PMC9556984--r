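#' Extract a centerline from a tubular surface mesh
#'
#' Marching cross-section algorithm: starting from the inlet, the mesh is cut
#' with a plane normal to the current axis estimate; the (length-weighted)
#' centroid of the cross-section curve becomes the next centerline point, the
#' mean centroid-to-boundary distance the local radius, and the axis estimate
#' is updated from consecutive centroids. The march terminates at the outlet.
#'
#' @param mesh A [surface_mesh()] forming a single tube between the two points.
#' @param inlet_point,outlet_point 3-D coordinates (m) near the tube ends.
#' @param step March step (m); default half the initial cross-section radius.
#' @return A [centerline()] with `provenance = "extracted"`.
#' @export
extract_centerline <- function(mesh, inlet_point, outlet_point, step = NULL) {
  stopifnot(inherits(mesh, "vaa_mesh"))
  inlet_point <- as.numeric(inlet_point)
  outlet_point <- as.numeric(outlet_point)
  if (!is.null(step) && step <= 0) vaa_abort("step must be positive", "vaaflow_invalid_parameter")
  axis <- unitize(outlet_point - inlet_point)
  # nudge the first section plane just inside the tube so it cannot sit
  # exactly on the inlet boundary ring
  eps <- 1e-4 * sqrt(sum((outlet_point - inlet_point)^2))
  sec <- plane_section(mesh, inlet_point + eps * axis, axis,
                       prev_center = inlet_point)
  ctr <- sec$centroid
  rad <- sec$radius
  if (is.null(step)) step <- rad / 2
  centers <- list(ctr)
  radii <- c(rad)
  total_len <- sum(sqrt(sum((outlet_point - inlet_point)^2)))
  max_steps <- ceiling(4 * total_len / step) + 50L
  for (it in seq_len(max_steps)) {
    remaining <- sum((outlet_point - ctr) * axis)
    if (remaining < 1.5 * step) break
    target <- ctr + step * axis
    sec <- plane_section(mesh, target, axis, prev_center = ctr)
    new_ctr <- sec$centroid
    # leap rejection: a section centroid far from the predicted station is an
    # oblique-cut artifact (typical inside large bulges); fall back to the
    # predicted point and let the refinement sweep settle it
    if (sqrt(sum((new_ctr - target)^2)) > 1.5 * step) {
      new_ctr <- target
      sec$radius <- radii[length(radii)]
    }
    new_axis <- new_ctr - ctr
    if (sqrt(sum(new_axis^2)) < 1e-12) break
    prop <- unitize(0.5 * axis + 0.5 * unitize(new_axis))
    # clamp the turn per step: a tube that sweeps without self-intersection
    # cannot bend faster than its own radius allows, so sharper apparent
    # turns are section artifacts (e.g. oblique cuts inside a bulge)
    cosang <- sum(prop * axis)
    max_turn <- 0.5
    if (cosang < cos(max_turn)) {
      ax_rot <- cross3(axis, prop)
      prop <- if (sqrt(sum(ax_rot^2)) < 1e-12) axis else
        as.numeric(rotation_about(ax_rot, max_turn) %*% axis)
    }
    axis <- prop
    ctr <- new_ctr
    centers[[length(centers) + 1L]] <- ctr
    radii <- c(radii, sec$radius)
  }
  # close out at the outlet
  centers[[length(centers) + 1L]] <- outlet_point
  radii <- c(radii, radii[length(radii)])
  pts <- do.call(rbind, centers)
  # refinement sweep: the marching axis lags the true tangent on curved
  # vessels (the first station uses the inlet-outlet chord), which makes
  # sections oblique; recut every section with the tangent of the marched
  # curve, nudging the end planes just inside the tube
  n_st <- nrow(pts)
  if (n_st >= 3) {
    for (pass in 1:5) {
      # despike: a station whose radius estimate towers over both neighbours
      # is a section artifact; replace it by the neighbour midpoint before
      # recutting
      for (i in 2:(n_st - 1)) {
        if (radii[i] > 1.4 * max(radii[i - 1], radii[i + 1])) {
          pts[i, ] <- (pts[i - 1, ] + pts[i + 1, ]) / 2
          radii[i] <- (radii[i - 1] + radii[i + 1]) / 2
        }
      }
      moved <- 0
      for (i in seq_len(n_st)) {
        # the two stations at each end take their tangent from the adjacent
        # interior segment: an end station's own position estimate is the
        # least reliable and must not feed back into its cutting plane
        tg <- if (n_st >= 6 && i <= 2) {
          pts[i + 2, ] - pts[i + 1, ]
        } else if (n_st >= 6 && i >= n_st - 1) {
          pts[i - 1, ] - pts[i - 2, ]
        } else if (i == 1) {
          pts[2, ] - pts[1, ]
        } else if (i == n_st) {
          pts[n_st, ] - pts[n_st - 1, ]
        } else {
          pts[i + 1, ] - pts[i - 1, ]
        }
        tg <- unitize(tg)
        origin <- pts[i, ]
        # end sections sit half a step inside the tube: a plane exactly at a
        # boundary ring is clipped as soon as the tangent estimate tilts
        if (i == 1 && pass == 1) origin <- origin + (step / 2) * tg
        if (i == n_st && pass == 1) origin <- origin - (step / 2) * tg
        sec <- tryCatch(plane_section(mesh, origin, tg, prev_center = origin),
                        error = function(e) NULL)
        # accept a recut only if it stays on the tube: a radius towering over
        # both neighbours or a centroid leaping away marks an oblique cut
        nb_r <- max(radii[max(i - 1, 1)], radii[min(i + 1, n_st)])
        if (!is.null(sec) && sec$radius <= 1.4 * nb_r &&
            sqrt(sum((sec$centroid - pts[i, ])^2)) <= 2 * step) {
          moved <- max(moved, sqrt(sum((sec$centroid - pts[i, ])^2)))
          pts[i, ] <- sec$centroid
          radii[i] <- sec$radius
        }
      }
      if (moved < 1e-3 * step) break
    }
  }
  arc <- c(0, cumsum(row_norms(diff(pts))))
  keep <- c(TRUE, diff(arc) > 1e-9)
  centerline(pts[keep, , drop = FALSE], arc[keep], radii[keep], provenance = "extracted")
}

# Cut the mesh with the plane through `origin` with normal `normal`; return the
# connected cross-section component nearest `prev_center` as a set of segment
# midpoints with lengths, its length-weighted centroid and mean
# centroid-to-boundary distance.
plane_section <- function(mesh, origin, normal, prev_center) {
  v <- mesh$vertices
  d <- as.numeric((v - matrix(origin, nrow(v), 3, byrow = TRUE)) %*% normal)
  f <- mesh$faces
  df <- cbind(d[f[, 1]], d[f[, 2]], d[f[, 3]])
  crossing <- which((rowSums(df > 0) > 0) & (rowSums(df < 0) > 0))
  if (length(crossing) == 0) {
    vaa_abort("plane section is empty: point outside tube or step too large",
              "vaaflow_geometry_error")
  }
  segs <- section_segments(mesh, crossing, d)
  comp <- section_components(mesh, crossing)
  if (length(unique(comp)) > 1L) {
    mids_by_comp <- lapply(split(seq_along(crossing), comp), function(ix) {
      colMeans((segs$p1[ix, , drop = FALSE] + segs$p2[ix, , drop = FALSE]) / 2)
    })
    dists <- vapply(mids_by_comp, function(m) sqrt(sum((m - prev_center)^2)), numeric(1))
    ord <- order(dists)
    # a genuine branch shows two sections of comparable distance near the axis
    if (length(ord) >= 2) {
      r_guess <- stats::median(row_norms(
        (segs$p1 + segs$p2) / 2 - matrix(prev_center, length(crossing), 3, byrow = TRUE)))
      if (dists[ord[2]] < dists[ord[1]] + 4 * r_guess) {
        vaa_abort(paste("plane section has multiple nearby components (branch point?):",
                        "extract each branch separately"),
                  "vaaflow_branch_error")
      }
    }
    sel <- comp == names(mids_by_comp)[ord[1]]
    segs$p1 <- segs$p1[sel, , drop = FALSE]
    segs$p2 <- segs$p2[sel, , drop = FALSE]
  }
  mid <- (segs$p1 + segs$p2) / 2
  len <- row_norms(segs$p2 - segs$p1)
  w <- len / sum(len)
  centroid <- colSums(mid * w)
  radius <- sum(w * row_norms(mid - matrix(centroid, nrow(mid), 3, byrow = TRUE)))
  list(centroid = centroid, radius = radius)
}

# Intersection segment of each crossing face with the plane (signed vertex
# distances d already computed).
section_segments <- function(mesh, crossing, d) {
  f <- mesh$faces[crossing, , drop = FALSE]
  v <- mesh$vertices
  n <- length(crossing)
  p1 <- matrix(0, n, 3)
  p2 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    vid <- f[i, ]
    dv <- d[vid]
    pts <- matrix(0, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      da <- dv[e[1]]; db <- dv[e[2]]
      if ((da > 0 && db < 0) || (da < 0 && db > 0)) {
        t <- da / (da - db)
        pts <- rbind(pts, v[vid[e[1]], ] + t * (v[vid[e[2]], ] - v[vid[e[1]], ]))
      } else if (da == 0) {
        pts <- rbind(pts, v[vid[e[1]], ])
      }
    }
    if (nrow(pts) < 2) pts <- rbind(pts, pts)
    p1[i, ] <- pts[1, ]
    p2[i, ] <- pts[2, ]
  }
  list(p1 = p1, p2 = p2)
}

# Connected components of the crossing faces through shared vertices
# (union-find).
section_components <- function(mesh, crossing) {
  f <- mesh$faces[crossing, , drop = FALSE]
  n <- length(crossing)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  vmap <- list()
  for (i in seq_len(n)) {
    for (vtx in f[i, ]) {
      key <- as.character(vtx)
      j <- vmap[[key]]
      if (is.null(j)) {
        vmap[[key]] <- i
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Inscribed-radius profile of a centerline inside a mesh
#'
#' For every centerline station the inscribed radius is the minimum distance
#' from the station point to the mesh surface (the radius of the largest
#' sphere centered on the line that fits inside the lumen), matching the
#' sphere semantics of the excision stage.
#'
#' @param mesh A [surface_mesh()].
#' @param line A [centerline()] lying inside the mesh.
#' @return Numeric vector of inscribed radii (m), one per station.
#' @export
inscribed_radius_profile <- function(mesh, line) {
  stopifnot(inherits(mesh, "vaa_mesh"), inherits(line, "vaa_centerline"))
  r <- min_distance_to_mesh(mesh, line$points)
  if (any(r <= 0)) vaa_abort("centerline touches or exits the mesh", "vaaflow_geometry_error")
  r
}
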