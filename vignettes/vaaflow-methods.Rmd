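---
title: "Wall-shear analysis of aneurysm formation sites: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall-shear analysis of aneurysm formation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vaaflow` studies the hemodynamic environment in which visceral artery
aneurysms form: the vessel is restored to its hypothetical pre-aneurysm
state by virtual excision, a pulsatile wall shear field is imposed on the
reconstructed parent artery, and the aneurysm-forming area is compared
against the vessel segments immediately upstream and downstream. This
vignette documents the models behind each stage, the parameters that matter,
and the choices made where the design was genuinely open.

## The flow model and its assumptions

A full 3-D Navier–Stokes solve on a patient geometry is outside the scope of
a reusable desk-scale pipeline, so the wall shear field comes from the
analytic Womersley solution for fully developed pulsatile flow in a rigid
circular tube. The inlet waveform $Q(t)$ is decomposed into complex
harmonics $Q_n$ (trigonometric least squares; the exact DFT on uniform
samples). At an axial station of lumen radius $R$ each harmonic passes
through the wall-shear transfer function

$$k_n = \frac{-\mu \Lambda^2 J_1(\Lambda)}{\pi R^3\,[\Lambda J_0(\Lambda) - 2 J_1(\Lambda)]},
\qquad \Lambda = i^{3/2}\alpha_n,\quad \alpha_n = R\sqrt{n\omega/\nu},$$

whose $\alpha \to 0$ limit is the Poiseuille coefficient $4\mu/(\pi R^3)$.
The complex-argument Bessel functions are evaluated by power series, which
is accurate and stable for the $\alpha \lesssim 25$ regime of millimetric
vessels at cardiac frequencies; larger arguments are rejected rather than
approximated. Assumptions inherited from the study design: incompressible
Newtonian blood ($\rho = 1056$ kg m⁻³, $\mu = 0.0035$ Pa s), rigid no-slip
walls, and outlet flows split in proportion to outlet cross-sectional area.
The surrogate is exactly time-periodic, so the conventional "run three
cardiac cycles and keep the last" protocol is honoured trivially by
computing one cycle.

What the tube law cannot produce — secondary flows at bends, jet impingement,
local recirculation — is emulated by *scenario modulation*, which is explicit
and documented rather than hidden: a multiplicative shear scale on the faces
of the aneurysm-forming region (above 1 for high-shear scenarios, below 1
for low-shear ones), a zero-mean reversing component mixed in by
`reversal_frac` to create oscillatory shear (at `reversal_frac = 1` the
field is a pure sinusoid and OSI is exactly 0.5), and mild per-face
lognormal noise (sd 0.03 in the pipeline) for patient-to-patient texture.
Consequently the *absolute* shear levels and OSI scales of a cohort are
scenario parameters, not predictions; what the pipeline genuinely computes
is the geometry processing, the index definitions and the statistics on top
of them.

## The indices

All cycle integrals use the periodic trapezoid rule on a uniform grid over
one period (the sample mean), which is spectrally accurate for smooth
periodic integrands. Per face:

* **TAWSS** — mean of $|\tau|$ over the cycle; non-negative.
* **OSI** — $\tfrac12(1 - |\bar\tau|/\overline{|\tau|})$, clamped to
  $[0, 0.5]$. Identically zero shear over the cycle is flagged undefined
  (`NA`), not zero.
* **AFI** — cosine between $\tau(t)$ and the cycle-mean vector $\bar\tau$.
  The reported scalar is the *cycle-time average* (a minimum-over-cycle
  option exists): a single stable number that reduces to 1 for steady
  unidirectional flow. Instants with $|\tau| = 0$ are excluded; faces whose
  mean vector vanishes (to within $10^{-12}$ of the mean magnitude, the
  floating-point zero) are undefined. AFI is treated as dimensionless — it
  is a cosine, whatever units appear next to it in clinical tables.
* **WSSG** — per time sample, the in-plane gradient of the scalar $|\tau|$
  is estimated on each face by least squares over the adjacent face
  centroids projected into the face plane; the reported value is the cycle
  average of the gradient magnitude. This frame-free variant (not split into
  streamwise/transverse components) is a deliberate dialect choice: it is
  well defined on unstructured triangulations and needs no flow-direction
  frame. Faces without neighbours are undefined.
* **WSS$_{max}$** — the per-face magnitude at peak systole (the instant of
  maximal inlet flow), maximized over a region. Peak systole rather than
  all-cycle maximum is used wherever a single "maximum WSS" is reported,
  matching the convention of the mesh-refinement stopping rule
  (`mesh_convergence_check`, first relative change ≤ 1%).

Undefined values propagate as `NA` and are excluded from area-weighted
means, with the undefined fraction recorded on the map object.

## Synthetic vessels and what they do (not) represent

The generator produces tubes in the visceral-artery calibre range — lumen
radius 2–5 mm, 70 mm long, straight or circular-arc (curvature radius
40–80 mm) — with one aneurysm per model: fusiform (axisymmetric
cosine-squared bulge, amplitude 50–90% of the healthy radius, extent
1.2–1.8 lumen diameters) or saccular (30% of models; ring offset of half the
amplitude toward one azimuth plus a half-amplitude radius increase, so the
near wall bulges by exactly the amplitude while the far wall stays on the
healthy tube). 40% of models carry an upstream stenosis (severity 0.3–0.6,
cosine-squared taper), reflecting the common coexistence of feeding-artery
stenosis with these aneurysms; the stenosis is kept clear of the aneurysm
and its para-windows so the regional statistics are not confounded by it.
Sweeping uses rotation-minimizing (parallel-transport) frames, not Frenet
frames, to avoid torsion flips on straight segments. The cohort default is
14 models, 11 in a high-WSS-like flow scenario (mean flow chosen so the
healthy-segment TAWSS sits at 1.1–1.6 Pa, aneurysm-site scale 1.45–1.9) and
3 in a low-WSS-like one (TAWSS 0.2–0.33 Pa, scale 0.45–0.7, stronger
reversal), with a positive two-harmonic pulse (systolic peak at 0.2 T,
period 1 s). Everything is deterministic given the seed.

These models exercise the geometric and statistical machinery, but they are
smooth single-branch tubes: passing tests demonstrates correctness of the
pipeline, not fidelity to CTA-derived anatomies with bifurcation aneurysms,
surface noise or non-circular lumens. Bifurcations are supported only as
separate per-branch analyses (mass-conserving area-proportional flow split),
never as a merged watertight surface.

## Centerline extraction and virtual excision

Extraction is by marching cross-sections: from the inlet, the mesh is cut
with a plane normal to the running axis estimate; the length-weighted
centroid of the nearest connected section component becomes the next
station, the length-weighted mean centroid-to-boundary distance the local
radius (i.e. half the mean section diameter), and the march steps half an
inlet radius at a time. Robustness measures that practical tube geometries
forced: the per-step axis turn is clamped (a tube that swept without
self-intersection cannot bend faster than its radius allows, so sharper
turns are oblique-cut artifacts); section centroids that leap away from the
predicted station are rejected in favour of the prediction; and after the
march a refinement sweep recuts every section with tangents from the marched
curve (end stations take their tangent from the adjacent interior segment
and sit half a step inside the tube, since a plane exactly at a boundary
ring clips as soon as the tangent tilts), iterated to convergence with a
despiking guard that refuses any recut whose radius towers over both
neighbours. Multi-component sections with a second component nearby raise a
branch error instructing per-branch extraction.

The aneurysm segment is marked automatically on the extracted line: the
baseline is the linear trend between robust (median-of-end-stations) end
radii; the marked run is where the radius exceeds baseline by more than 20%,
expanded outward while the excess stays above 2% (the practical support edge
of a smooth bulge — the 20% core of a cosine-squared bulge covers only about
two thirds of its support), with the expansion capped at three core run
widths or a few lumen radii so profile noise cannot drag the interval down a
healthy vessel. The excision then pads the interval by one station spacing
per side so the faint bulge tails do not survive. Excision replaces the
in-interval centerline by a cubic Hermite bridge matching position and
tangent at the healthy endpoints, with linear radius interpolation, and
lofts circular cross-sections of the interpolated radius on
parallel-transport frames — the envelope of the interpolated inscribed
spheres for slowly varying radius — stitched to the retained boundary rings.
Boundary loops are resampled *at the loft frame angles* (rather than by
perimeter arclength), which phase-aligns the stitch by construction, leaves
no twist, and cannot cut chords inside the lumen.

Validation is by parameter recovery (`radius_recovery_experiment`): on
seeded 20-model cohorts, the reconstructed inscribed-radius profile is
compared with the same probe applied to the ground-truth healthy vessel —
like-for-like, so steep-taper and discretization effects of the probe itself
cancel. Across seeds the median per-model error is at the rounding level and
the worst per-station error stays in the few-percent range, dominated by the
stitch neighbourhoods.

## Regions, classification and statistics

Blanking labels each face by projecting its centroid onto the centerline:
the excised interval is the aneurysm-forming area; the windows immediately
before and after it — of length equal to the interval, a symmetric and
scale-free default since no standard defines the para-extent — are upstream
and downstream. Faces straddling a boundary go by centroid projection; no
area splitting. Region values are area-weighted means (undefined faces
excluded); the para value of a metric is the plain average of the upstream
and downstream cells. A model is classified *high-WSS* when the
aneurysm-area TAWSS is at least the para value, with ties classifying high;
TAWSS is the default classification metric (the most stable area statistic),
with the regional WSS$_{max}$ available as an option.

The Wilcoxon signed-rank implementation deliberately reproduces the
conventions of the major commercial statistics packages: zero differences
dropped, mid-ranks for ties, $T$ the smaller rank sum,
$\sigma_T = \sqrt{n(n+1)(2n+1)/24 - \sum(t^3 - t)/48}$, no continuity
correction, and the normal approximation applied at any $n$ — under these
conventions an all-one-sign sample of 11 gives $Z = -2.934$, $p = 0.003$,
and of 3 gives $Z = -1.604$, $p = 0.109$, exactly the cells a consistent
cohort forces. The Fisher exact test uses the two-sided probability-sum rule
(relative tolerance $10^{-7}$ on the comparison); the chi-square is
uncorrected Pearson with a warning recommending Fisher when an expected cell
is below 5. No multiple-testing correction is applied by default, matching
the clinical reporting convention; Holm adjustment can be layered on by the
user via `p.adjust`.

## Numerical choices and problem sizes

Arclength intervals are half-open $[s_1, s_2)$ throughout; meshes use
0-based indices in files and 1-based in memory; SI meters internally with a
unit scale applied at mesh I/O (millimeter STL being the common convention).
Mesh I/O covers ASCII/binary STL reading and ASCII STL/PLY writing — the
formats the pipeline itself consumes and produces. The default test and
pipeline sizes — 32–48 points per ring, 120-station centerlines, 16–32
timesteps per cycle, 14-model cohorts — were chosen as the smallest sizes at
which the discretization-sensitive checks (area convergence, gradient
recovery, time-refinement stability) sit comfortably inside their
tolerances; all scale up linearly if finer maps are wanted.

Known limitations: no secondary-flow physics beyond scenario modulation; no
fluid–structure interaction or non-Newtonian rheology; reconstruction across
bifurcation apices is out of scope (single-branch intervals only); and the
synthetic cohorts cannot validate absolute shear magnitudes against patient
measurements — only the relative regional contrasts the statistics operate
on.
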