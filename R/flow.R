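#' Blood fluid properties
#'
#' Defaults are the incompressible Newtonian blood model used throughout:
#' density 1056 kg/m^3 and dynamic viscosity 0.0035 Pa s.
#'
#' @param density Density rho (kg/m^3).
#' @param viscosity Dynamic viscosity mu (Pa s).
#' @return List with `density`, `viscosity` and kinematic viscosity `nu`.
#' @export
fluid_properties <- function(density = 1056, viscosity = 0.0035) {
  if (density <= 0 || viscosity <= 0) {
    vaa_abort("density and viscosity must be positive", "vaaflow_invalid_parameter")
  }
  list(density = density, viscosity = viscosity, nu = viscosity / density)
}

#' Periodic volumetric flow waveform
#'
#' @param times Sample times in `[0, T)` (s), strictly increasing.
#' @param flow Volumetric flow at the samples (m^3/s).
#' @param period Cycle period T (s).
#' @return List of class `vaa_waveform`.
#' @export
flow_waveform <- function(times, flow, period) {
  if (period <= 0) vaa_abort("period must be positive", "vaaflow_invalid_parameter")
  if (length(times) < 8 || length(times) != length(flow)) {
    vaa_abort("waveform needs >= 8 samples with matching flow values",
              "vaaflow_invalid_parameter")
  }
  if (any(diff(times) <= 0) || times[1] < 0 || times[length(times)] >= period) {
    vaa_abort("times must be strictly increasing within [0, period)",
              "vaaflow_invalid_parameter")
  }
  structure(list(times = as.numeric(times), flow = as.numeric(flow),
                 period = period), class = "vaa_waveform")
}

#' Default mesenteric-like pulse waveform
#'
#' A two-harmonic pulse with its systolic peak at 0.2 T, always-positive flow
#' and a peak-to-mean ratio of about 1.85 — a generic visceral-artery shape
#' used when no measured waveform is supplied.
#'
#' @param q_mean Cycle-mean flow (m^3/s).
#' @param period Cycle period (s).
#' @param n Number of uniform samples.
#' @return A [flow_waveform()].
#' @export
default_waveform <- function(q_mean = 5e-6, period = 1, n = 64) {
  t <- period * (0:(n - 1)) / n
  ph <- 2 * pi * (t - 0.2 * period) / period
  q <- q_mean * (1 + 0.6 * cos(ph) + 0.25 * cos(2 * ph))
  flow_waveform(t, q, period)
}

#' Fourier decomposition of a flow waveform
#'
#' Trigonometric least squares (the DFT for uniform samples): returns complex
#' coefficients `c_n` such that `Q(t) = Re(sum_n c_n exp(i n w t))` with
#' `c_0` the real cycle mean.
#'
#' @param waveform A [flow_waveform()].
#' @param n_harmonics Number of harmonics (in addition to the mean); at most
#'   half the sample count.
#' @return Complex vector of length `n_harmonics + 1` (`c_0 ... c_H`), with
#'   the root-mean-square reconstruction error in `attr(, "rms_error")`.
#' @export
fourier_decompose <- function(waveform, n_harmonics = 8) {
  stopifnot(inherits(waveform, "vaa_waveform"))
  N <- length(waveform$times)
  if (2 * n_harmonics > N) {
    vaa_abort("need at least 2 * n_harmonics samples", "vaaflow_invalid_parameter")
  }
  w <- 2 * pi / waveform$period
  t <- waveform$times
  q <- waveform$flow
  uniform <- max(abs(diff(t) - waveform$period / N)) < 1e-9 * waveform$period
  coef <- complex(n_harmonics + 1)
  if (uniform) {
    for (n in 0:n_harmonics) {
      cn <- sum(q * exp(-1i * n * w * t)) / N
      coef[n + 1] <- if (n == 0) Re(cn) + 0i else 2 * cn
    }
  } else {
    # trigonometric least squares on the design [1, cos, sin, ...]
    X <- cbind(rep(1, N))
    for (n in 1:n_harmonics) X <- cbind(X, cos(n * w * t), sin(n * w * t))
    beta <- stats::lsfit(X, q, intercept = FALSE)$coefficients
    coef[1] <- beta[1] + 0i
    for (n in 1:n_harmonics) {
      coef[n + 1] <- complex(real = beta[2 * n], imaginary = -beta[2 * n + 1])
    }
  }
  recon <- reconstruct_waveform(coef, t, waveform$period)
  attr(coef, "rms_error") <- sqrt(mean((recon - q)^2))
  coef
}

reconstruct_waveform <- function(coef, times, period) {
  w <- 2 * pi / period
  out <- rep(Re(coef[1]), length(times))
  for (n in seq_len(length(coef) - 1)) {
    out <- out + Re(coef[n + 1] * exp(1i * n * w * times))
  }
  out
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega / nu)`: the ratio of tube radius to viscous
#' penetration depth; small alpha means quasi-steady (Poiseuille-like)
#' pulsatile flow.
#'
#' @param R Tube radius (m).
#' @param omega Angular frequency (rad/s).
#' @param fluid A [fluid_properties()].
#' @return Dimensionless alpha.
#' @export
womersley_number <- function(R, omega, fluid = fluid_properties()) {
  if (R <= 0 || omega <= 0) vaa_abort("R and omega must be positive", "vaaflow_invalid_parameter")
  R * sqrt(omega / fluid$nu)
}

# Complex-argument Bessel J0/J1 by power series; accurate for |z| <~ 25,
# which covers the alpha range of millimetric vessels at cardiac harmonics.
bessel_j01_complex <- function(z) {
  if (any(Mod(z) > 30)) {
    vaa_abort("Womersley kernel series unstable for alpha > 30", "vaaflow_invalid_parameter")
  }
  q <- -(z * z) / 4
  term0 <- rep(1 + 0i, length(z))
  term1 <- rep(1 + 0i, length(z))
  j0 <- term0
  j1s <- term1
  for (k in 1:80) {
    term0 <- term0 * q / (k * k)
    term1 <- term1 * q / (k * (k + 1))
    j0 <- j0 + term0
    j1s <- j1s + term1
    if (max(Mod(term0)) < 1e-18 && max(Mod(term1)) < 1e-18) break
  }
  list(j0 = j0, j1 = (z / 2) * j1s)
}

# Wall-shear transfer coefficient k_n with tau_w,n(t) = Re(k_n Q_n e^{i n w t}).
# Steady limit (alpha -> 0) is 4 mu / (pi R^3).
womersley_shear_coef <- function(R, omega, fluid) {
  alpha <- womersley_number(R, omega, fluid)
  lam <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^{3/2} alpha
  bj <- bessel_j01_complex(lam)
  mu <- fluid$viscosity
  -mu * lam^2 * bj$j1 / (pi * R^3 * (lam * bj$j0 - 2 * bj$j1))
}

#' Womersley station: radius + flow harmonics
#'
#' Packages everything the analytic wall-shear evaluation needs at one axial
#' station: tube radius, cycle period, and complex flow harmonics.
#'
#' @param R Tube radius (m).
#' @param period Cycle period (s).
#' @param harmonics Complex coefficients from [fourier_decompose()].
#' @param fluid A [fluid_properties()].
#' @return List of class `vaa_womersley_station` including the per-harmonic
#'   Womersley numbers `alpha`.
#' @export
womersley_station <- function(R, period, harmonics, fluid = fluid_properties()) {
  if (R <= 0) vaa_abort("R must be positive", "vaaflow_invalid_parameter")
  w <- 2 * pi / period
  H <- length(harmonics) - 1
  alpha <- if (H >= 1) vapply(1:H, function(n) womersley_number(R, n * w, fluid), numeric(1)) else numeric(0)
  structure(list(R = R, period = period, harmonics = harmonics,
                 alpha = alpha, fluid = fluid),
            class = "vaa_womersley_station")
}

#' Analytic pulsatile wall shear at a station
#'
#' The steady harmonic contributes the Poiseuille value `4 mu Q0 / (pi R^3)`;
#' each oscillatory harmonic is mapped through the Womersley wall-shear
#' transfer function (complex Bessel kernel). The result is the real,
#' T-periodic wall shear magnitude history at the station.
#'
#' @param station A [womersley_station()].
#' @param fluid A [fluid_properties()]; defaults to the station's.
#' @param times Evaluation times (s).
#' @return Numeric vector of wall shear (Pa) at `times`.
#' @export
womersley_wall_shear <- function(station, fluid = NULL, times) {
  stopifnot(inherits(station, "vaa_womersley_station"))
  fluid <- fluid %||% station$fluid
  R <- station$R
  w <- 2 * pi / station$period
  coef <- station$harmonics
  tau <- rep(4 * fluid$viscosity * Re(coef[1]) / (pi * R^3), length(times))
  for (n in seq_len(length(coef) - 1)) {
    k <- womersley_shear_coef(R, n * w, fluid)
    tau <- tau + Re(k * coef[n + 1] * exp(1i * n * w * times))
  }
  tau
}

#' Split a parent flow across outlets by cross-sectional area
#'
#' `Q_i(t) = Q_parent(t) * A_i / sum(A)`; mass is conserved exactly at every
#' sample.
#'
#' @param waveform Parent [flow_waveform()].
#' @param outlet_areas Positive outlet cross-sectional areas (m^2).
#' @return List of [flow_waveform()]s, one per outlet.
#' @export
split_flow_by_outlet_area <- function(waveform, outlet_areas) {
  stopifnot(inherits(waveform, "vaa_waveform"))
  if (length(outlet_areas) == 0) {
    vaa_abort("outlet_areas must be non-empty", "vaaflow_invalid_parameter")
  }
  if (any(outlet_areas <= 0)) {
    vaa_abort("all outlet areas must be positive", "vaaflow_invalid_parameter")
  }
  fr <- outlet_areas / sum(outlet_areas)
  lapply(fr, function(f) flow_waveform(waveform$times, waveform$flow * f, waveform$period))
}

#' Synthesize a pulsatile wall shear vector field on a vessel surface
#'
#' Per face, the wall shear direction is the local axial tangent projected
#' into the face plane, and the magnitude history comes from the analytic
#' Womersley wall shear at the local lumen radius carrying the branch flow.
#' Scenario modulation emulates the local flow disturbances that a tube-law
#' model cannot produce: `aneurysm_scale` multiplies the magnitude on faces
#' labelled `aneurysm`, and `reversal_frac` mixes in a zero-mean reversing
#' component (raising OSI); multiplicative per-face noise adds
#' patient-to-patient texture. With `reversal_frac = 1` the field is a pure
#' zero-mean sinusoid (OSI of exactly 0.5).
#'
#' @param mesh A [surface_mesh()].
#' @param line Its [centerline()] (gives local radius and axial direction).
#' @param waveform Branch [flow_waveform()].
#' @param fluid A [fluid_properties()].
#' @param n_timesteps Samples over one cycle (>= 8).
#' @param scenario List with `aneurysm_scale` (default 1), `reversal_frac`
#'   (default 0), `noise_sd` (lognormal sd of per-face scale, default 0).
#' @param labels Optional per-face labels; needed when `aneurysm_scale != 1`.
#' @param n_harmonics Harmonics kept from the waveform (default 8).
#' @param seed Integer seed controlling the per-face noise.
#' @return A `vaa_wall_shear_field`: list with `mesh`, `times`, `tau`
#'   (faces x times x 3 array, Pa), `peak_systole_time`, `period`.
#' @export
synthesize_wall_shear_field <- function(mesh, line, waveform,
                                        fluid = fluid_properties(),
                                        n_timesteps = 32,
                                        scenario = list(),
                                        labels = NULL,
                                        n_harmonics = 8,
                                        seed = NULL) {
  stopifnot(inherits(mesh, "vaa_mesh"), inherits(line, "vaa_centerline"),
            inherits(waveform, "vaa_waveform"))
  if (n_timesteps < 8) vaa_abort("n_timesteps must be >= 8", "vaaflow_invalid_parameter")
  if (any(line$radius <= 0)) vaa_abort("occluded branch (zero radius) unsupported",
                                       "vaaflow_unsupported_for_flow")
  sc <- utils::modifyList(list(aneurysm_scale = 1, reversal_frac = 0, noise_sd = 0),
                          scenario)
  T <- waveform$period
  times <- T * (0:(n_timesteps - 1)) / n_timesteps
  n_harmonics <- min(n_harmonics, floor(length(waveform$times) / 2))
  coef <- fourier_decompose(waveform, n_harmonics)
  m <- nrow(mesh$faces)
  proj <- project_onto_polyline(mesh$face_centroid, line$points, line$arclength)
  r_face <- centerline_radius_at(line, proj$s)
  # axial direction projected into each face plane
  fr <- transport_frames(line$points)
  idx <- vapply(proj$s, function(s) which.min(abs(line$arclength - s)), integer(1))
  ax <- fr$tangent[idx, , drop = FALSE]
  nrm <- mesh$face_normal
  ax_t <- ax - nrm * rowSums(ax * nrm)
  ax_t <- ax_t / pmax(row_norms(ax_t), 1e-12)
  az <- cross3_rows(nrm, ax_t)
  # Womersley magnitude per unique radius bin (radii vary smoothly; bin to
  # 200 levels for speed, error far below the geometric tolerances)
  rb <- seq(min(r_face), max(r_face), length.out = 200)
  if (max(r_face) - min(r_face) < 1e-12) rb <- c(min(r_face))
  tau_bin <- vapply(rb, function(R) {
    st <- womersley_station(R, T, coef, fluid)
    womersley_wall_shear(st, fluid, times)
  }, numeric(length(times)))  # times x bins
  bin_of <- if (length(rb) == 1) rep(1L, m) else {
    pmin(pmax(round((r_face - rb[1]) / (rb[length(rb)] - rb[1]) * (length(rb) - 1)) + 1, 1),
         length(rb))
  }
  mag <- t(tau_bin)[bin_of, , drop = FALSE]  # faces x times
  scale_face <- rep(1, m)
  if (sc$aneurysm_scale != 1) {
    if (is.null(labels)) {
      vaa_abort("aneurysm_scale modulation needs per-face labels", "vaaflow_invalid_configuration")
    }
    scale_face[labels == "aneurysm"] <- sc$aneurysm_scale
  }
  if (sc$noise_sd > 0) {
    noise <- with_seed(seed, exp(stats::rnorm(m, 0, sc$noise_sd)))
    scale_face <- scale_face * noise
  }
  mag <- mag * scale_face
  rev <- sc$reversal_frac
  amp_face <- rowMeans(abs(mag))
  osc <- sin(2 * pi * times / T)
  m_ax <- (1 - rev) * mag
  m_az <- rev * (amp_face %o% osc)
  tau <- array(0, dim = c(m, n_timesteps, 3))
  for (d in 1:3) {
    tau[, , d] <- m_ax * ax_t[, d] + m_az * az[, d]
  }
  q_rec <- reconstruct_waveform(coef, times, T)
  structure(list(mesh = mesh, times = times, tau = tau,
                 peak_systole_time = times[which.max(q_rec)],
                 period = T),
            class = "vaa_wall_shear_field")
}

#' Construct a wall shear vector field explicitly
#'
#' Low-level constructor for a time-resolved per-face wall shear field, used
#' when the shear history comes from somewhere other than the built-in
#' Womersley surrogate (e.g. analytic test fields or an external solver
#' export).
#'
#' @param mesh A [surface_mesh()].
#' @param times Sample times covering one cycle, within `[0, period)` (s).
#' @param tau Numeric array `faces x times x 3` of wall shear vectors (Pa).
#' @param period Cycle period (s).
#' @param peak_systole_time Peak-systole instant (s); defaults to the time of
#'   maximal face-averaged shear magnitude.
#' @return A `vaa_wall_shear_field`.
#' @export
wall_shear_field <- function(mesh, times, tau, period,
                             peak_systole_time = NULL) {
  stopifnot(inherits(mesh, "vaa_mesh"))
  tau <- unclass(tau)
  if (length(dim(tau)) != 3 || dim(tau)[1] != nrow(mesh$faces) ||
      dim(tau)[2] != length(times) || dim(tau)[3] != 3) {
    vaa_abort("tau must be a faces x times x 3 array", "vaaflow_invalid_parameter")
  }
  if (any(!is.finite(tau))) vaa_abort("tau must be finite", "vaaflow_data_error")
  if (any(times < 0) || any(times >= period) || any(diff(times) <= 0)) {
    vaa_abort("times must be strictly increasing within [0, period)",
              "vaaflow_invalid_parameter")
  }
  if (is.null(peak_systole_time)) {
    mm <- colMeans(sqrt(tau[, , 1]^2 + tau[, , 2]^2 + tau[, , 3]^2))
    peak_systole_time <- times[which.max(mm)]
  }
  structure(list(mesh = mesh, times = times, tau = tau,
                 peak_systole_time = peak_systole_time, period = period),
            class = "vaa_wall_shear_field")
}

#' @export
print.vaa_wall_shear_field <- function(x, ...) {
  cat(sprintf("<vaa_wall_shear_field> %d faces x %d timesteps, period %.3g s, peak systole %.3g s\n",
              dim(x$tau)[1], dim(x$tau)[2], x$period, x$peak_systole_time))
  invisible(x)
}
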