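# Shared in-code fixtures: small tubes and analytically constructed wall
# shear fields. All fixtures are generated at test time; nothing on disk.

cyl_mesh <- function(radius = 0.002, length = 0.05, n_points = 51, n_circ = 32) {
  path <- make_centerline_path("straight", length, radius, n_points)
  sweep_tube_mesh(path, n_circ)$mesh
}

# Colinear field along the tube axis (x) on a straight-tube mesh: per-face
# magnitude history mag_t (length nt) times an optional per-face scale.
colinear_field <- function(mesh, mag_t, period = 1, face_scale = 1) {
  nt <- length(mag_t)
  m <- nrow(mesh$faces)
  times <- period * (0:(nt - 1)) / nt
  tau <- array(0, dim = c(m, nt, 3))
  tau[, , 1] <- outer(rep(1, m) * face_scale, mag_t)
  wall_shear_field(mesh, times, tau, period)
}

# An aneurysmal straight-tube model with ground truth, small enough for
# fast per-test use.
bulged_model <- function(amp_ratio = 0.75, radius = 0.002, length = 0.05,
                         n_points = 101, n_circ = 32, shape = "fusiform") {
  path <- make_centerline_path("straight", length, radius, n_points)
  spec <- aneurysm_spec(center_s = length / 2, extent = 4 * radius,
                        amplitude = amp_ratio * radius, shape = shape)
  an <- apply_aneurysm(path, spec)
  sw <- sweep_tube_mesh(an$path, n_circ, an$truth)
  list(mesh = sw$mesh, truth = sw$truth, path = an$path, base = radius)
}

# Absolute-difference comparison for values quoted at fixed decimal
# precision (expect_equal's tolerance is relative).
expect_near <- function(actual, expected, tol = 5e-4) {
  expect_lt(max(abs(actual - expected)), tol)
}

# Least-squares circle fit in the xy-plane; returns the curvature 1/R.
fit_curvature_xy <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  1 / r
}
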