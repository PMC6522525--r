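---
title: "Simulated HRTFs and their eigenmode representation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated HRTFs and their eigenmode representation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A head-related transfer function (HRTF) is the direction-dependent
acoustic filter between a farfield source and a point at the entrance of
the ear canal, expressed relative to the free field. HRTFs are unique to
each listener, so spatial-audio systems serving many listeners face a
storage problem; a standard remedy is to represent the per-ear,
direction-dependent part of the spectrum — the directional transfer
function (DTF), i.e. the HRTF minus the ear's mean spectrum over all
directions — as a weighted sum of a small number of *eigenmodes*, the
principal components of a large DTF ensemble.

`hrtfeigen` implements the full computational chain needed to study this
representation without any measured data:

1. a voxel-based FDTD acoustic solver with impedance boundaries and a
   perfectly matched layer (PML), plus Kirchhoff–Helmholtz (KH) farfield
   integration and free-field normalization, producing HRTF spectra from
   a head geometry;
2. a processing pipeline (cubic-spline resampling to a uniform 50 Hz
   grid from 500 Hz to 14 kHz — 271 bins; DTF conversion; assembly of the
   frequency-by-observation matrix);
3. eigenmode (PCA) analysis with k-mode reconstruction, RMS-dB error
   distributions and leave-one-person-out cross-validation;
4. a DCT-smoothing comparison with a correspondence matching between
   coefficient counts and eigenmode counts;
5. eigenmode generality testing against reference profiles with optimal
   log-frequency scaling; and
6. equal-area (Hammer) spatial maps of eigenmode weights.

A synthetic-data module generates parametric voxel head geometries and
HRTF populations with *planted* low-rank structure so that every stage
has an exact, known ground truth.

## The acoustic model

The solver integrates linear acoustics (pressure $p$, particle velocity
$\mathbf v$) in a leap-frog scheme on a staggered cubic grid:

$$\partial_t p = -\rho c^2 \nabla\!\cdot\!\mathbf v + s(t)\,\delta_{\text{src}},
\qquad \rho\,\partial_t \mathbf v = -\nabla p .$$

Updates run only at air cells. Every air–solid face carries a locally
reacting, frequency-independent normal impedance $Z$ (default
$1.48\times10^6$ rayl, the characteristic impedance of water, i.e. an
air–water interface — acoustically near-rigid), discretized
semi-implicitly so the wall is passive at any $Z$. The domain is closed
by a 10-cell split-field PML with cubic conductivity grading; the peak
conductivity is set from a target normal-incidence reflection of
$10^{-6}$, which in practice yields a measured reflection below
$10^{-3}$ (dominated by discretization, as for any graded PML).

Key numerical choices:

* **Time step.** `dt = spacing / (4 c sqrt(3))` by default — a 4×
  margin on the 3-D CFL limit; at 2 mm spacing this is ≈1.2 MHz
  sampling. A tighter step mainly reduces dispersion anisotropy.
* **Source.** An additive ("soft") pressure source with a
  differentiated-Gaussian pulse (default spectral peak 7 kHz): zero DC
  content avoids a non-physical static pressure offset, and the spectrum
  is non-vanishing over the whole 0.35–15 kHz analysis range. The
  equivalent free-space monopole is known in closed form,
  $p(r,t) = h^3\,\dot s(t - r/c)/(4\pi r c^2\,\Delta t)$,
  and the solver reproduces it at a probe to better than 1% L2 on a
  1 mm grid.
* **Free-field reference.** HRTF normalization uses this analytic
  monopole (source at head center) rather than a second empty-domain
  run; the two agree to the monopole-validation tolerance, and the
  analytic route removes one source of numerical noise. An empty-domain
  simulated reference remains available through the same API.
* **Farfield.** Pressure and outward normal velocity are recorded on a
  closed rectangular surface between the head and the PML (velocities
  time-centered by averaging adjacent half-steps, collocated with
  pressures on the surface cells). The KH integral is evaluated per
  frequency bin of the run's native FFT grid (a 5 ms timeline gives
  200 Hz bins) against the free-space Green's function; per-direction
  time series are then reassembled with decimation by spectral
  truncation at the new Nyquist rate (the downsample factor is 10 by
  default). The 50 Hz analysis grid is reached later by natural
  cubic-spline resampling of the magnitude spectra, so the coarse
  native resolution is never interpolated in the complex domain.
* **Dispersion.** The second-order scheme's phase-velocity error grows
  as $(kh)^2$; it bounds the solver's accuracy at high frequencies and
  coarse grids. Validation problems therefore state their grids
  explicitly: the sphere-scattering oracle runs at 4 mm (compared over
  0.5–6 kHz, mean absolute error well under 1.5 dB) with an 8 mm run
  demonstrating convergence, and monopole oracles run at 1 mm.

The solver oracle is the exact partial-wave series for scattering of a
point source by an impedance sphere (`analytic_sphere_hrtf()`), used via
reciprocity: the simulated configuration (source at the ear, farfield
receivers) equals the series configuration (far point source, receiver
at the ear point). The series is validated internally by
self-convergence at doubled truncation order.

## The synthetic population

`generate_synthetic_hrtf_set()` draws, for each person $p$, pinna and
direction $d$,

$$\mathrm{HRTF}(d, f) = m_p(f) + \sum_{k} w_k(d)\, e_k(f / s_p) + \varepsilon,$$

* $e_k$: smooth frequency profiles, orthonormalized (order-preserving
  Gram–Schmidt) on the realized grid. The defaults mimic familiar
  shapes: a head-shadow low-pass contrast, a mid-frequency (≈4–9 kHz)
  emphasis against the highs, and an 8–11 kHz band emphasis against its
  neighbours.
* $w_k$: analytic direction fields — an ipsi/contralateral contrast
  (`side_sign * sin(lateral)`), an elevation contrast (the z component
  of the direction), and a front–back contrast tilted upward by 35°.
  The fields are centered and orthogonalized on the realized observation
  set; together with orthonormal profiles this makes the planted
  variance fractions exact in closed form
  (`planted_variance_fractions()`) and the eigenmodes exactly
  recoverable, which is what the recovery tests assert.
* $s_p$: optional per-person log-uniform frequency-scale jitter
  (`inter_person_scale_sd`, default 0). It is off by default because the
  planted-recovery conditions are stated for a homogeneous population;
  population-level scale shifts (of the several-percent order reported
  across real populations) are planted explicitly in the generality
  experiments instead.
* $m_p$: a smooth random per-person mean spectrum (removed exactly by
  DTF conversion) and $\varepsilon$ iid Gaussian noise in dB
  (default 0.1 dB).

One seeded generator per dataset makes output bit-reproducible; the seed
is stored in the output metadata.

What the generator does *not* emulate: spectral notches that move
systematically with elevation, measurement artifacts, torso/shoulder
reflections, and any anthropometric covariance between persons. Passing
tests on synthetic data therefore demonstrate the correctness of the
machinery (projection, error bookkeeping, cross-validation, scaling
search, mapping) — not that real HRTF ensembles are rank-3.

The parametric voxel head (`make_parametric_head()`) is an ellipsoid
with two thin pinna flanges (a rectangular plate with a hemispherical
concha depression), the flare angle tilting the plate laterally outward
from a parasagittal plane and the rotation angle tilting its major axis
backward from vertical (defaults 23° and 13°, typical adult values).
Ear canals are blocked at their entrance plane — the entrance is part of
the solid surface and the simulation source sits at the first air voxel
directly adjacent to it. This geometry is deliberately schematic; only
the flare/rotation angles are anatomically anchored.

## Analysis conventions

* **Magnitudes** are $20\log_{10}|H|$ throughout; all errors are RMS
  differences in dB over 0.5–14 kHz.
* **Coordinates** are left-handed interaural-polar: lateral angle
  positive toward the left ear, polar angle 0 at the front, 90 up, 180
  behind. The default direction grid is the CIPIC-style sampling of 25
  lateral × 50 polar angles = 1250 directions at 1 m.
* **Centering.** DTF conversion removes the per-pinna mean; `fit_pca()`
  additionally removes the grand mean over observations before the
  eigendecomposition and reconstruction adds both back. Variance
  fractions are reported for the grand-mean-centered ensemble.
* **Eigendecomposition** is a thin SVD of the centered 271 × N matrix
  (numerically stabler than accumulating the covariance; equivalence to
  the dense covariance eigendecomposition is a tested oracle).
  Eigenvector sign is fixed by making each vector's largest-magnitude
  element positive; analyses that compare against planted or reference
  profiles carry the signed correlation alongside.
* **Quantiles** use the linear-interpolation definition (R type 7).
* **DCT smoothing** uses the orthonormal type-II DCT of the dB spectrum
  on a uniform 50 Hz grid over 350 Hz–15 kHz (294 bins), truncated to
  `n_coef` coefficients and inverted; smoothed spectra are
  spline-resampled to the evaluation grid before error computation,
  mirroring the PCA path. The comparison defaults to the same
  per-pinna-mean-removed spectra used for PCA so the two error
  distributions are commensurable.
* **Correspondence matching** extends each DCT error summary to the
  eigenmode count minimizing the equally weighted sum of absolute
  differences of (q1, median, q3); ties break toward the smaller count.
* **Optimal frequency scaling** searches one common multiplicative
  factor $s \in [0.80, 1.25]$ on a 0.1% logarithmic grid (with $s = 1$
  always included, so scaling can never reduce the mean correlation);
  the scaled mode value at frequency $f$ is the fitted profile evaluated
  at $f/s$, i.e. $s > 1$ shifts the fitted modes' features upward —
  the direction expected when the fitted population's heads are
  proportionally larger than the reference population's. Correlations
  are computed on the 3–14 kHz overlap after spline resampling.
* **Spatial maps** average each mode's weights across pinnae per
  direction after right-pinna maps are reflected about the median plane
  (so left/right mean ipsi/contralateral). The map color bound is ±1
  standard deviation of the per-direction means pooled over directions
  (the pooling convention is a package choice and is recorded here).
  The Hammer projection places the front direction at the center with
  longitude = azimuth and latitude = elevation derived through Cartesian
  unit vectors; reference lines (median, frontal, horizontal planes) are
  drawing metadata only.

## Cross-validation

`loocv()` refits the basis with all of one person's observations held
out, projects the held-out DTFs on the reduced basis, and pools held-out
errors over persons per mode count. For a population of identical
persons this reduces exactly to the all-inclusive analysis (a tested
identity), and on homogeneous synthetic populations the pooled median
changes by well under 10% at the planted rank.

## Problem sizes

The package's own test and reporting runs use: a 19-person synthetic
population on the full 1250-direction, 271-bin grid (47,500
observations) for the eigenmode/DCT analyses; a 10-person population on
a reduced mirror-symmetric 13 × 25 grid for cross-validation and
recovery checks; a 6 cm sphere at 4 mm (with an 8 mm refinement
companion) for the scattering oracle; and 1 mm empty-domain grids for
the monopole and KH oracles. These sizes were chosen so each check isolates
one error source at a scale where its expected magnitude is known.

## Known limitations

* The solver is second-order; coarse grids are dispersive at high
  frequencies, which is why solver validation bands stop below the
  frequency where $\lambda/h < {\sim}10$.
* The boundary impedance is frequency-independent by design; skin and
  hair absorption are not modeled.
* No torso or shoulder; no near-field HRTFs (radii other than 1 m are
  supported by the KH integrator but not validated).
* Serialization uses plain-text containers (run-length voxel grids, TSV
  spectra tables) rather than a binary interchange format.
* The parametric head is schematic: it produces HRTF-like spectra with
  controllable symmetry and pinna angles, not any individual's HRTFs.
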