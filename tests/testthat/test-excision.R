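test_that("the dilated segment is marked to within one station of the truth", {
  m <- bulged_model(amp_ratio = 0.75, n_points = 101)
  iv <- mark_aneurysm_segment(m$path, rel_threshold = 0.2)
  step <- 0.05 / 100
  expect_lt(abs(iv[1] - m$truth$aneurysm_interval[1]), step + 1e-9)
  expect_lt(abs(iv[2] - m$truth$aneurysm_interval[2]), step + 1e-9)
})

test_that("marking returns NULL on a constant tube and rejects bad thresholds", {
  p <- make_centerline_path("straight", 0.05, 0.002, 101)
  expect_null(mark_aneurysm_segment(p))
  expect_error(mark_aneurysm_segment(p, rel_threshold = 0),
               class = "vaaflow_invalid_parameter")
})

test_that("two disjoint bulges trigger the largest-run warning", {
  p <- make_centerline_path("straight", 0.08, 0.002, 161)
  a1 <- apply_aneurysm(p, aneurysm_spec(0.025, 0.012, 0.0015, "fusiform"))
  a2 <- apply_aneurysm(a1$path, aneurysm_spec(0.055, 0.006, 0.0012, "fusiform"))
  expect_warning(iv <- mark_aneurysm_segment(a2$path), "multiple dilated")
  # the larger (first) bulge wins
  expect_lt(abs(iv[1] - 0.019), 0.002)
})

test_that("centerline interpolation bridges straight and curved gaps", {
  p <- make_centerline_path("straight", 0.05, 0.002, 101)
  li <- interpolate_centerline(p, c(0.02, 0.03))
  expect_equal(li$provenance, "interpolated")
  expect_lt(max(abs(li$points[, 2:3])), 1e-6)

  arc <- make_centerline_path("curved", 0.04, 0.002, 201, curvature_radius = 0.02)
  gap <- c(0.015, 0.025)
  ai <- interpolate_centerline(arc, gap)
  inside <- arc$arclength > gap[1] & arc$arclength < gap[2]
  dev <- sqrt(rowSums((ai$points[inside, ] - arc$points[inside, ])^2))
  expect_lt(max(dev), 0.02 * (gap[2] - gap[1]))
})

test_that("gap radii are linearly interpolated between the endpoint radii", {
  p <- make_centerline_path("straight", 0.05, 0.002, 101)
  r <- p$radius
  r[p$arclength >= 0.03] <- 0.0022
  p2 <- centerline(p$points, p$arclength, r)
  li <- interpolate_centerline(p2, c(0.02, 0.03))
  mid <- which.min(abs(li$arclength - 0.025))
  # endpoints roughly 2.0 and 2.2 mm -> 2.1 mm at the midpoint
  expect_equal(li$radius[mid], 0.0021, tolerance = 0.02)
  # no new extremes: bridged radii within the endpoint range
  inside <- li$arclength > 0.02 & li$arclength < 0.03
  expect_true(all(li$radius[inside] >= 0.002 - 1e-12 &
                    li$radius[inside] <= 0.0022 + 1e-12))
})

test_that("intervals touching an end of the line cannot be interpolated", {
  p <- make_centerline_path("straight", 0.05, 0.002, 101)
  expect_error(interpolate_centerline(p, c(0, 0.01)),
               class = "vaaflow_cannot_interpolate")
  expect_error(interpolate_centerline(p, c(0.045, 0.05)),
               class = "vaaflow_cannot_interpolate")
})

test_that("a zero-length excision is the identity", {
  m <- bulged_model()
  res <- reconstruct_parent_surface(m$path, m$mesh, c(0.02, 0.02))
  expect_identical(res$reconstructed_mesh, m$mesh)
})

test_that("reconstruction restores a healthy tube over the excised interval", {
  m <- bulged_model(amp_ratio = 0.75, n_points = 101, n_circ = 32)
  cl <- extract_centerline(m$mesh, c(0, 0, 0), c(0.05, 0, 0))
  exc <- excise_aneurysm(m$mesh, cl, n_circumferential = 32)
  prof <- inscribed_radius_profile(exc$reconstructed_mesh, exc$interpolated_line)
  expect_equal(prof, rep(0.002, length(prof)), tolerance = 0.05)
  # lofted area over the interval close to the cylinder formula
  iv <- exc$excised_interval
  proj <- vaaflow:::project_onto_polyline(exc$reconstructed_mesh$face_centroid,
                                          exc$interpolated_line$points,
                                          exc$interpolated_line$arclength)
  in_iv <- proj$s >= iv[1] & proj$s < iv[2]
  area_iv <- sum(exc$reconstructed_mesh$face_area[in_iv])
  expect_equal(area_iv, 2 * pi * 0.002 * (iv[2] - iv[1]), tolerance = 0.1)
})

test_that("excising an already-reconstructed vessel changes radii by under 1%", {
  m <- bulged_model(amp_ratio = 0.75, n_points = 101, n_circ = 32)
  cl <- extract_centerline(m$mesh, c(0, 0, 0), c(0.05, 0, 0))
  exc1 <- excise_aneurysm(m$mesh, cl, n_circumferential = 32)
  line2 <- extract_centerline(exc1$reconstructed_mesh, c(0, 0, 0), c(0.05, 0, 0))
  exc2 <- reconstruct_parent_surface(line2, exc1$reconstructed_mesh,
                                     exc1$excised_interval, 32)
  p1 <- inscribed_radius_profile(exc1$reconstructed_mesh, exc1$interpolated_line)
  p2 <- inscribed_radius_profile(exc2$reconstructed_mesh, exc1$interpolated_line)
  expect_lt(max(abs(p2 - p1) / p1), 0.01)
})

test_that("round-trip recovery holds across a randomized cohort", {
  rec <- suppressWarnings(radius_recovery_experiment(6, seed = 3L,
    config = cohort_spec(n_high = 6, n_low = 0)))
  expect_equal(nrow(rec), 6)
  expect_lt(max(rec$median_err), 0.03)
  expect_lt(max(rec$max_err), 0.10)
})
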