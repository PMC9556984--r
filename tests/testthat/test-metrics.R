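# Index checks against closed forms on analytically constructed fields.

test_that("TAWSS averages the shear magnitude over the cycle", {
  mesh <- cyl_mesh(n_points = 21, n_circ = 16)
  expect_equal(as.numeric(tawss(colinear_field(mesh, rep(1, 16)))),
               rep(1, nrow(mesh$faces)))
  # |sin| has a known cycle mean of 2/pi
  n <- 256
  fld <- colinear_field(mesh, sin(2 * pi * (0:(n - 1)) / n))
  expect_equal(as.numeric(tawss(fld)), rep(2 / pi, nrow(mesh$faces)),
               tolerance = 1e-3)
  # spectral accuracy on a smooth field
  fld2 <- colinear_field(mesh, 2 + sin(2 * pi * (0:63) / 64))
  expect_equal(as.numeric(tawss(fld2)), rep(2, nrow(mesh$faces)),
               tolerance = 1e-12)
})

test_that("OSI is 0 without reversal, 0.5 for zero mean, 0.152 in between", {
  mesh <- cyl_mesh(n_points = 21, n_circ = 16)
  n <- 512
  ph <- 2 * pi * (0:(n - 1)) / n
  expect_equal(as.numeric(osi(colinear_field(mesh, 1 + sin(ph)))),
               rep(0, nrow(mesh$faces)), tolerance = 1e-9)
  expect_equal(as.numeric(osi(colinear_field(mesh, sin(ph)))),
               rep(0.5, nrow(mesh$faces)), tolerance = 1e-9)
  # independent quadrature oracle for the 1 + 2 sin profile
  mean_abs <- stats::integrate(function(u) abs(1 + 2 * sin(u)), 0, 2 * pi,
                               subdivisions = 1000L)$value / (2 * pi)
  osi_expect <- 0.5 * (1 - 1 / mean_abs)
  expect_near(osi_expect, 0.152)
  expect_equal(as.numeric(osi(colinear_field(mesh, 1 + 2 * sin(ph)))),
               rep(osi_expect, nrow(mesh$faces)), tolerance = 1e-4)
})

test_that("AFI is 1 for steady flow, 1/3 for the 1 + 2 sin profile, NA for zero mean", {
  mesh <- cyl_mesh(n_points = 21, n_circ = 16)
  expect_equal(as.numeric(afi(colinear_field(mesh, rep(2, 16)))),
               rep(1, nrow(mesh$faces)))
  n <- 1024
  ph <- 2 * pi * (0:(n - 1)) / n
  # reversal occupies exactly a third of the cycle
  expect_near(as.numeric(afi(colinear_field(mesh, 1 + 2 * sin(ph)))),
              rep(1 / 3, nrow(mesh$faces)), tol = 2e-3)
  expect_true(all(is.na(afi(colinear_field(mesh, sin(ph))))))
})

test_that("index ranges hold on an arbitrary mixed-direction field", {
  path <- make_centerline_path("straight", 0.03, 0.002, 41)
  mesh <- sweep_tube_mesh(path, 24)$mesh
  wf <- default_waveform(1e-6, 1, 64)
  fld <- synthesize_wall_shear_field(mesh, path, wf, n_timesteps = 32,
                                     scenario = list(reversal_frac = 0.4,
                                                     noise_sd = 0.1), seed = 5L)
  maps <- compute_hemodynamic_maps(fld)
  expect_true(all(maps$tawss_pa >= 0))
  expect_true(all(maps$osi >= 0 & maps$osi <= 0.5, na.rm = TRUE))
  expect_true(all(maps$afi >= -1 & maps$afi <= 1, na.rm = TRUE))
  expect_true(all(maps$wssg_nm3 >= 0, na.rm = TRUE))
  expect_true(all(maps$wsspeak_pa >= 0))
  # algebraic identity for colinear fields: TAWSS*(1-2*OSI) = |mean vector|
  cf <- colinear_field(mesh, 1 + 2 * sin(2 * pi * (0:255) / 256))
  lhs <- tawss(cf) * (1 - 2 * osi(cf))
  expect_equal(as.numeric(lhs), rep(1, nrow(mesh$faces)), tolerance = 1e-9)
})

test_that("WSSG vanishes on uniform fields and recovers linear gradients", {
  mesh <- cyl_mesh(radius = 0.002, length = 0.03, n_points = 61, n_circ = 32)
  uni <- colinear_field(mesh, rep(2, 8))
  expect_equal(as.numeric(wssg(uni)), rep(0, nrow(mesh$faces)), tolerance = 1e-9)
  # |tau|(s) = 1 + 10 s along the tube
  s_face <- vaaflow:::project_onto_polyline(
    mesh$face_centroid,
    make_centerline_path("straight", 0.03, 0.002, 61)$points,
    make_centerline_path("straight", 0.03, 0.002, 61)$arclength)$s
  lin <- colinear_field(mesh, rep(1, 8), face_scale = 1 + 10 * s_face)
  g <- wssg(lin)
  inner <- s_face > 0.003 & s_face < 0.027
  expect_equal(as.numeric(g[inner]), rep(10, sum(inner)), tolerance = 0.02)
})

test_that("WSSG matches the analytic taper gradient of a Poiseuille field", {
  # R(s) = 0.002 - 0.1 (s - 0.004): gradient of 4 mu Q / (pi R^3) at R = 0.002
  # is 12 mu Q k / (pi R^4) = 83.6 N/m^3
  n_pts <- 161
  s <- seq(0, 0.008, length.out = n_pts)
  r <- 0.002 - 0.1 * (s - 0.004)
  line <- centerline(cbind(s, 0, 0), s, r)
  mesh <- sweep_tube_mesh(line, 48)$mesh
  s_face <- vaaflow:::project_onto_polyline(mesh$face_centroid, line$points,
                                            line$arclength)$s
  r_face <- 0.002 - 0.1 * (s_face - 0.004)
  mag <- 4 * 0.0035 * 1e-6 / (pi * r_face^3)
  fld <- colinear_field(mesh, rep(1, 8), face_scale = mag)
  g <- wssg(fld)
  at_R <- abs(s_face - 0.004) < 2.5e-4
  expect_equal(mean(g[at_R]), 12 * 0.0035 * 1e-6 * 0.1 / (pi * 0.002^4),
               tolerance = 0.05)
})

test_that("peak-systole shear and field maxima behave as defined", {
  mesh <- cyl_mesh(n_points = 21, n_circ = 16)
  fld <- colinear_field(mesh, rep(5, 8))
  pk <- wss_peak(fld)
  expect_equal(pk$wss_max, 5)
  expect_equal(as.numeric(pk$wss_peak), rep(5, nrow(mesh$faces)))
  # sinusoidal flow peaking at T/4: per-face peak equals the T/4 magnitude
  n <- 32
  fld2 <- colinear_field(mesh, 2 + sin(2 * pi * (0:(n - 1)) / n))
  expect_equal(fld2$peak_systole_time, 0.25)
  expect_equal(as.numeric(wss_peak(fld2)$wss_peak), rep(3, nrow(mesh$faces)))
  # region restriction can only lower the maximum
  region <- seq_len(nrow(mesh$faces) %/% 2)
  expect_lte(wss_peak(fld2, region)$wss_max, wss_peak(fld2)$wss_max)
})

test_that("the mesh-convergence rule picks the first sub-1% change", {
  expect_equal(mesh_convergence_check(c(10, 9, 8.6, 8.55, 8.54)), 4L)
  expect_equal(mesh_convergence_check(c(5, 5)), 2L)
  expect_warning(ix <- mesh_convergence_check(c(10, 8)), "did not converge")
  expect_true(is.na(ix))
  expect_error(mesh_convergence_check(c(10, -1)), class = "vaaflow_data_error")
  expect_error(mesh_convergence_check(5), class = "vaaflow_invalid_parameter")
})

test_that("indices are stable under time refinement of a smooth field", {
  path <- make_centerline_path("straight", 0.03, 0.002, 41)
  mesh <- sweep_tube_mesh(path, 24)$mesh
  wf <- default_waveform(1e-6, 1, 128)
  get_maps <- function(nt) {
    fld <- synthesize_wall_shear_field(mesh, path, wf, n_timesteps = nt)
    cbind(tawss(fld), osi(fld), afi(fld))
  }
  m64 <- get_maps(64)
  m128 <- get_maps(128)
  rel <- abs(m128 - m64) / pmax(abs(m128), 1e-12)
  expect_lt(max(rel, na.rm = TRUE), 0.005)
})
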