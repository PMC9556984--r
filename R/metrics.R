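#' Wall-shear-derived hemodynamic indices
#'
#' Per-face maps computed from a pulsatile wall shear vector field over one
#' cycle: TAWSS (time-averaged magnitude), OSI (directional reversal), AFI
#' (alignment with the cycle-mean vector), WSSG (surface gradient of the
#' magnitude) and the peak-systole magnitude. Cycle integrals use the periodic
#' trapezoid rule, which on a uniform grid over one full period is the sample
#' mean (spectrally accurate for smooth periodic fields).
#'
#' @name hemo-metrics
NULL

field_magnitude <- function(field) {
  sqrt(field$tau[, , 1]^2 + field$tau[, , 2]^2 + field$tau[, , 3]^2)
}

check_field <- function(field) {
  stopifnot(inherits(field, "vaa_wall_shear_field"))
  if (any(!is.finite(field$tau))) vaa_abort("wall shear field contains non-finite values",
                                            "vaaflow_data_error")
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) * integral over one cycle of |tau| dt`, per face.
#'
#' @param field A `vaa_wall_shear_field`.
#' @return Numeric vector (Pa), one value per face.
#' @export
tawss <- function(field) {
  check_field(field)
  rowMeans(field_magnitude(field))
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |mean vector| / mean |tau|)`, in `[0, 0.5]`: 0 for
#' strictly unidirectional shear, 0.5 for perfectly balanced reversal. Faces
#' with identically zero shear over the whole cycle are undefined (`NA`), not
#' zero.
#'
#' @param field A `vaa_wall_shear_field`.
#' @return Numeric vector, one value per face (`NA` where undefined).
#' @export
osi <- function(field) {
  check_field(field)
  mean_vec <- sapply(1:3, function(d) rowMeans(field$tau[, , d, drop = FALSE][, , 1]))
  if (is.null(dim(mean_vec))) mean_vec <- matrix(mean_vec, nrow = 1)
  num <- sqrt(rowSums(mean_vec^2))
  den <- rowMeans(field_magnitude(field))
  out <- 0.5 * (1 - num / den)
  out[den <= 0] <- NA_real_
  pmin(pmax(out, 0), 0.5)
}

#' Aneurysm formation index (AFI)
#'
#' Per instant, `AFI(t)` is the cosine of the angle between the instantaneous
#' wall shear vector and its cycle-mean vector; the reported per-face value is
#' the cycle-time average (instants with zero shear are excluded). Steady
#' unidirectional shear gives exactly 1. Faces whose cycle-mean vector
#' vanishes are undefined (`NA`).
#'
#' @param field A `vaa_wall_shear_field`.
#' @param reduce `"mean"` (default) or `"min"` over the cycle.
#' @return Numeric vector in `[-1, 1]`, one value per face (`NA` undefined).
#' @export
afi <- function(field, reduce = c("mean", "min")) {
  check_field(field)
  reduce <- match.arg(reduce)
  mean_vec <- sapply(1:3, function(d) rowMeans(field$tau[, , d, drop = FALSE][, , 1]))
  if (is.null(dim(mean_vec))) mean_vec <- matrix(mean_vec, nrow = 1)
  mv_norm <- sqrt(rowSums(mean_vec^2))
  mag <- field_magnitude(field)
  dotp <- field$tau[, , 1] * mean_vec[, 1] + field$tau[, , 2] * mean_vec[, 2] +
    field$tau[, , 3] * mean_vec[, 3]
  cosang <- dotp / (pmax(mag, 1e-300) * pmax(mv_norm, 1e-300))
  cosang[mag <= 0] <- NA
  out <- if (reduce == "mean") rowMeans(cosang, na.rm = TRUE) else
    apply(cosang, 1, min, na.rm = TRUE)
  # a cycle-mean vector at rounding level is a vanishing mean: undefined
  out[mv_norm <= 1e-12 * rowMeans(mag)] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Wall shear stress gradient (WSSG)
#'
#' Per time sample, the surface gradient of the scalar `|tau|` is estimated on
#' each face by least squares over adjacent face centroids projected into the
#' face plane; WSSG is the cycle-time average of the gradient magnitude
#' (N/m^3). Faces without neighbours are undefined (`NA`).
#'
#' @param field A `vaa_wall_shear_field`.
#' @param mesh The [surface_mesh()] the field lives on (defaults to the one
#'   referenced by the field).
#' @return Numeric vector (N/m^3), one value per face.
#' @export
wssg <- function(field, mesh = NULL) {
  check_field(field)
  mesh <- mesh %||% field$mesh
  m <- nrow(mesh$faces)
  nbr <- face_neighbors(mesh)
  nn <- lengths(nbr)
  # per-face in-plane basis
  nrm <- mesh$face_normal
  u <- t(apply(nrm, 1, pick_orthogonal))
  v <- cross3_rows(nrm, u)
  # pad neighbour lists to fixed width for vectorized gradient evaluation
  width <- max(nn, 1L)
  NBR <- matrix(rep(seq_len(m), width), m, width)
  W <- matrix(0, m, width)
  Du <- matrix(0, m, width)
  Dv <- matrix(0, m, width)
  ctr <- mesh$face_centroid
  for (i in seq_len(m)) {
    if (nn[i] == 0) next
    js <- nbr[[i]]
    NBR[i, seq_along(js)] <- js
    d <- ctr[js, , drop = FALSE] - matrix(ctr[i, ], length(js), 3, byrow = TRUE)
    Du[i, seq_along(js)] <- d %*% u[i, ]
    Dv[i, seq_along(js)] <- d %*% v[i, ]
    W[i, seq_along(js)] <- 1
  }
  # normal-equation terms for the 2x2 LS solve, per face
  A11 <- rowSums(W * Du * Du)
  A12 <- rowSums(W * Du * Dv)
  A22 <- rowSums(W * Dv * Dv)
  det <- A11 * A22 - A12^2
  ok <- nn > 0 & det > 1e-30
  mag <- field_magnitude(field)
  nt <- ncol(mag)
  acc <- numeric(m)
  for (t in seq_len(nt)) {
    vals <- mag[, t]
    diffs <- matrix(vals[NBR], m, width) - vals
    b1 <- rowSums(W * Du * diffs)
    b2 <- rowSums(W * Dv * diffs)
    gu <- (A22 * b1 - A12 * b2) / det
    gv <- (A11 * b2 - A12 * b1) / det
    acc <- acc + sqrt(gu^2 + gv^2)
  }
  out <- acc / nt
  out[!ok] <- NA_real_
  out
}

#' Peak-systole wall shear and field maximum
#'
#' Per-face `|tau|` at the peak-systole instant (the time of maximal inlet
#' flow), and the maximum over faces, optionally restricted to a region.
#'
#' @param field A `vaa_wall_shear_field` with `peak_systole_time` set.
#' @param region Optional logical/integer face subset for the field maximum.
#' @return List with `wss_peak` (per-face, Pa) and `wss_max` (scalar, Pa).
#' @export
wss_peak <- function(field, region = NULL) {
  check_field(field)
  it <- which.min(abs(field$times - field$peak_systole_time))
  per_face <- sqrt(field$tau[, it, 1]^2 + field$tau[, it, 2]^2 + field$tau[, it, 3]^2)
  sel <- if (is.null(region)) seq_along(per_face) else region
  list(wss_peak = per_face, wss_max = max(per_face[sel]))
}

#' Mesh-convergence selection on a peak-WSS series
#'
#' Given peak wall shear maxima from a coarse-to-fine mesh family, returns
#' the first index whose relative change from the previous mesh is within 1%
#' (the mesh-refinement stopping rule).
#'
#' @param wssmax_series Positive numeric vector, coarse to fine.
#' @param tol Relative-change tolerance (default 0.01).
#' @return Integer index of the chosen mesh, or `NA` with a warning when the
#'   series never settles.
#' @export
mesh_convergence_check <- function(wssmax_series, tol = 0.01) {
  if (length(wssmax_series) < 2) {
    vaa_abort("need at least two meshes to assess convergence", "vaaflow_invalid_parameter")
  }
  if (any(!is.finite(wssmax_series)) || any(wssmax_series <= 0)) {
    vaa_abort("WSSmax values must be positive and finite", "vaaflow_data_error")
  }
  rel <- abs(diff(wssmax_series)) / abs(wssmax_series[-length(wssmax_series)])
  hit <- which(rel <= tol)
  if (length(hit) == 0) {
    warning("mesh series did not converge to within the tolerance")
    return(NA_integer_)
  }
  hit[1] + 1L
}

#' Compute all hemodynamic maps for a field
#'
#' @param field A `vaa_wall_shear_field`.
#' @param mesh Optional [surface_mesh()] override for WSSG connectivity.
#' @return A data.frame of class `vaa_maps` with one row per face: `tawss_pa`,
#'   `osi`, `wssg_nm3`, `afi`, `wsspeak_pa`; the cycle period is kept in
#'   `attr(, "period")` and the undefined-face fraction in
#'   `attr(, "undefined_fraction")`.
#' @export
compute_hemodynamic_maps <- function(field, mesh = NULL) {
  mesh <- mesh %||% field$mesh
  pk <- wss_peak(field)
  out <- data.frame(tawss_pa = tawss(field),
                    osi = osi(field),
                    wssg_nm3 = wssg(field, mesh),
                    afi = afi(field),
                    wsspeak_pa = pk$wss_peak)
  attr(out, "period") <- field$period
  attr(out, "undefined_fraction") <- mean(!stats::complete.cases(out))
  class(out) <- c("vaa_maps", class(out))
  out
}
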