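test_that("fourier decomposition is exact for band-limited waveforms", {
  t64 <- (0:63) / 64
  wf_const <- flow_waveform(t64, rep(3e-6, 64), 1)
  cf <- fourier_decompose(wf_const, 8)
  expect_equal(Re(cf[1]), 3e-6)
  expect_lt(max(Mod(cf[-1])), 1e-18)

  wf_sin <- flow_waveform(t64, sin(2 * pi * t64), 1)
  cs <- fourier_decompose(wf_sin, 8)
  expect_equal(Mod(cs[2]), 1, tolerance = 1e-10)
  expect_lt(max(Mod(cs[c(-1, -2)])), 1e-10)
  expect_lt(attr(cs, "rms_error"), 1e-12)
})

test_that("waveform and harmonic-count preconditions are enforced", {
  t64 <- (0:63) / 64
  expect_error(flow_waveform(t64[1:4], rep(1, 4), 1), class = "vaaflow_invalid_parameter")
  wf <- flow_waveform(t64[1:16], rep(1, 16), 1)
  expect_error(fourier_decompose(wf, 9), class = "vaaflow_invalid_parameter")
})

test_that("the Womersley number matches hand evaluation and scales linearly", {
  fl <- fluid_properties(1056, 0.0035)
  expect_equal(womersley_number(0.002, 2 * pi, fl), 2.75, tolerance = 0.01)
  expect_equal(womersley_number(0.004, 2 * pi, fl) /
                 womersley_number(0.002, 2 * pi, fl), 2)
  expect_lt(womersley_number(0.002, 1e-8, fl), 1e-3)
  expect_error(womersley_number(-1, 1, fl), class = "vaaflow_invalid_parameter")
})

test_that("steady flow gives the Poiseuille wall shear 4*mu*Q/(pi*R^3)", {
  fl <- fluid_properties()
  st <- womersley_station(0.002, 1, complex(real = 1e-6), fl)
  expect_equal(womersley_wall_shear(st, fl, 0), 0.557, tolerance = 1e-3)
  st0 <- womersley_station(0.002, 1, complex(real = 0), fl)
  expect_equal(womersley_wall_shear(st0, fl, seq(0, 0.9, by = 0.1)),
               rep(0, 10))
})

test_that("the oscillatory wall shear is quasi-steady at alpha = 0.05", {
  fl <- fluid_properties()
  R <- 0.05 / sqrt(2 * pi / fl$nu)
  wf <- default_waveform(q_mean = 1e-8, period = 1, n = 64)
  cf <- fourier_decompose(wf, 8)
  st <- womersley_station(R, 1, cf, fl)
  tt <- seq(0, 1, length.out = 201)
  tau <- womersley_wall_shear(st, fl, tt)
  qs <- 4 * fl$viscosity * vaaflow:::reconstruct_waveform(cf, tt, 1) / (pi * R^3)
  expect_lt(max(abs(tau - qs) / abs(qs)), 0.01)
  # exact periodicity over one cycle
  expect_equal(tau[1], tau[201], tolerance = 1e-10)
})

test_that("outlet flow split is area-proportional and mass-conserving", {
  t64 <- (0:63) / 64
  wf <- flow_waveform(t64, 1e-5 * (1 + 0.5 * sin(2 * pi * t64)), 1)
  sp <- split_flow_by_outlet_area(wf, c(3e-6, 2e-6))
  expect_equal(sp[[1]]$flow, wf$flow * 0.6)
  expect_equal(sp[[2]]$flow, wf$flow * 0.4)
  expect_equal(sp[[1]]$flow + sp[[2]]$flow, wf$flow)
  one <- split_flow_by_outlet_area(wf, 5e-6)
  expect_equal(one[[1]]$flow, wf$flow)
  expect_error(split_flow_by_outlet_area(wf, numeric(0)),
               class = "vaaflow_invalid_parameter")
})

test_that("a steady field on a uniform tube is the Poiseuille value everywhere", {
  path <- make_centerline_path("straight", 0.03, 0.002, 61)
  mesh <- sweep_tube_mesh(path, 32)$mesh
  t64 <- (0:63) / 64
  wf <- flow_waveform(t64, rep(1e-6, 64), 1)
  fld <- synthesize_wall_shear_field(mesh, path, wf, n_timesteps = 16)
  mag <- sqrt(fld$tau[, , 1]^2 + fld$tau[, , 2]^2 + fld$tau[, , 3]^2)
  expect_equal(as.numeric(mag), rep(0.5570, length(mag)), tolerance = 1e-3)
  # shear is tangent to every face
  dotn <- abs(fld$tau[, 1, 1] * mesh$face_normal[, 1] +
                fld$tau[, 1, 2] * mesh$face_normal[, 2] +
                fld$tau[, 1, 3] * mesh$face_normal[, 3])
  expect_lt(max(dotn / mag[, 1]), 1e-6)
})

test_that("a 50% stenosis raises the local steady shear eightfold", {
  path <- make_centerline_path("straight", 0.04, 0.002, 161)
  st <- apply_stenosis(path, 0.02, 0.012, 0.5)
  mesh <- sweep_tube_mesh(st, 32)$mesh
  t64 <- (0:63) / 64
  wf <- flow_waveform(t64, rep(1e-6, 64), 1)
  fld <- synthesize_wall_shear_field(mesh, st, wf, n_timesteps = 16)
  mag <- sqrt(fld$tau[, 1, 1]^2 + fld$tau[, 1, 2]^2 + fld$tau[, 1, 3]^2)
  s_face <- vaaflow:::project_onto_polyline(mesh$face_centroid, st$points,
                                            st$arclength)$s
  throat <- abs(s_face - 0.02) < 2e-4
  healthy <- s_face < 0.005
  expect_equal(mean(mag[throat]) / mean(mag[healthy]), 8, tolerance = 0.01)
  # monotone in radius: smaller lumen, larger shear
  expect_gt(min(mag[throat]), max(mag[healthy]))
})

test_that("a pure reversal scenario yields a zero-mean oscillating field", {
  path <- make_centerline_path("straight", 0.03, 0.002, 61)
  mesh <- sweep_tube_mesh(path, 24)$mesh
  wf <- default_waveform(1e-6, 1, 64)
  fld <- synthesize_wall_shear_field(mesh, path, wf, n_timesteps = 32,
                                     scenario = list(reversal_frac = 1))
  o <- osi(fld)
  expect_equal(as.numeric(o), rep(0.5, length(o)), tolerance = 1e-9)
})

test_that("field synthesis is deterministic under a fixed seed", {
  path <- make_centerline_path("straight", 0.03, 0.002, 61)
  mesh <- sweep_tube_mesh(path, 24)$mesh
  wf <- default_waveform(1e-6, 1, 64)
  f1 <- synthesize_wall_shear_field(mesh, path, wf, n_timesteps = 16,
                                    scenario = list(noise_sd = 0.05), seed = 9L)
  f2 <- synthesize_wall_shear_field(mesh, path, wf, n_timesteps = 16,
                                    scenario = list(noise_sd = 0.05), seed = 9L)
  expect_identical(f1$tau, f2$tau)
})
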