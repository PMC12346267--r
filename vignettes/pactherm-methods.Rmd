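---
title: "Methods: photoacoustic thermometry and photothermal therapy simulation with pactherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photoacoustic thermometry and photothermal therapy simulation with pactherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pactherm is a desk-scale re-implementation of the computational core of an
integrated photoacoustic-computed-tomography (PACT) / photothermal-therapy
(PTT) platform: a full-view ring-array ultrasound detector images a tumor
slice in real time while a continuous-wave laser heats it, and the frame
series is converted into temperature maps and a thermal dose. Every input is
synthetic and generated by the package itself, so the whole pipeline is
testable without instruments or animals. This vignette records the models,
the tunable parameters, and the design decisions taken where the underlying
physics or instrument description left the choice open.

## 1. Synthetic acquisition model

**Geometry.** `ring_geometry()` describes the detector: 512 elements on a
40-mm-radius ring, 5-MHz center frequency, sampled at 40 MS/s. The element
impulse response is a Gaussian-modulated cosine at the center frequency whose
Gaussian power spectrum has full width at half maximum equal to the
fractional bandwidth (default 0.7) times the center frequency; both numbers
are configurable. The speed of sound defaults to 1.50 mm/µs, a standard
value for water-coupled soft-tissue imaging near body temperature, and is
likewise configurable per dataset.

**Forward model.** `forward_project()` treats every nonzero phantom pixel as
an in-plane point source. The initial pressure is proportional to the
specific optical absorption times the Grüneisen parameter, and each element
receives the band-limited pulse delayed by distance over speed of sound and
scaled by 1/r spreading. The model is deliberately 2D: thermometry operates
on a single imaging slice, so elevational focusing, transducer directivity
and full-wave propagation (including skull/bone aberration) are out of
scope. Channel noise is i.i.d. Gaussian with a standard deviation expressed
in units of the peak noise-free amplitude, so "SNR 20" means
`noise_sd = 0.05`; a frame series shares one absolute noise level fixed by
its baseline frame.

**Heating sequences.** `simulate_thermometry_sequence()` generates a full
treatment session (default 1 min baseline, 10 min heating, 1 min cool-down)
at a decimated frame rate (default 10 frames/min; the instrument acquires at
10 frames/s, which adds nothing computationally). While the laser is on, the
source amplitude of heated pixels scales as `1 + dT/(T0 + c/b)` — exactly the
forward counterpart of the thermometry inversion, which is what makes
end-to-end recovery a meaningful consistency check rather than a tautology:
the signal passes through pulse convolution, reconstruction, filtering and
registration before being inverted. The default heating model is the
exponential rise actually fitted to the platform's PA thermometry data
(amplitude 15.865 °C, rate 3.104 min⁻¹). Rigid inter-frame jitter
(per-frame rotation/translation drawn uniformly within stated bounds) is
available but defaults to zero, since the animal is held fixed during 2D
thermometry; registration tests exercise explicit jitter.

What the generator does *not* emulate: acoustic heterogeneity and
reflections (other than synthetic echoes injected for the half-time tests),
elevational point spread, transducer directivity, multiplexed two-pulse
acquisition (a DAQ detail; frames are delivered fully populated), shot-to-shot
laser energy drift, and physiological motion beyond rigid jitter. Passing
tests therefore demonstrate the correctness of the computational chain under
its own forward model, not robustness to every artifact of real data.

## 2. Half-time delay-and-sum reconstruction

`build_projector()` precomputes the delay-and-sum (DAS) operator as a sparse
matrix from the flattened RF record to image pixels: per pixel and element,
the time-of-flight is mapped to a fractional sample index and spread over
the two bracketing samples by linear interpolation (nearest-neighbor is
available for speed). Reconstruction is then a single sparse
matrix-vector product (`das_reconstruct()`), with a deliberately naive
triple-loop implementation (`das_naive()`) kept as an independent oracle;
the two agree to 1e-10 relative tolerance in the tests.

**Half-time rule.** Reflected signals arrive late; the instrument discards
the late half of the record. The exact truncation bound is not specified,
so the package uses: keep the pixel-element contribution only when the
time-of-flight satisfies `t <= ring_radius / c` — i.e. the first half of a
record that covers the full ring transit `2R/c`. Geometrically this
reconstructs each pixel from its *near-side* elements: direct arrivals from
the field of view all reach the near side within the bound, while in-ring
reflections land beyond it. A bound at the *maximum* direct delay
`(R + r_fov)/c` was considered and rejected: every direct contribution
already satisfies it, so it would exclude nothing and the flag would be a
no-op. The bound is configurable (`half_time_bound`), and pixel rows are
normalized by the number of contributing elements so amplitudes remain
comparable between half-time and full reconstructions. No apodization and no
envelope detection are applied; amplitude images are plain absolute values
of the bipolar reconstruction.

## 3. RF conditioning and registration

Thermal tracking rides on low-frequency signal content, so before
reconstruction each channel is (i) Wiener-deconvolved by the electrical
impulse response, `X = Y H* / (|H|² + q·max|H|²)` with relative noise floor
`q = 1e-3` by default, and (ii) low-pass filtered at 0.5 MHz with a
zero-phase 4th-order Butterworth (forward-backward, with odd-reflection
padding so the zero-state edge transients of the IIR filter do not leak
into the record). Zero phase matters: arrival times feed the baseline map,
and a phase-shifting filter would bias the delays. The filter family and
order are not dictated by the instrument description; Butterworth order 4 is
the conventional choice and both are configurable. In simulation the true
impulse response kernel is known (`eir_kernel()`); a measured kernel can be
supplied as an `impulse_response` object.

`select_frame()` implements motion-mitigating frame selection: among
candidate frames it returns the one whose normalized 2D cross-correlation
with the reference peaks highest (after a light Gaussian blur that
suppresses pixel noise), ties breaking to the lowest index.
`register_rigid()` estimates rotation + translation in two stages: a coarse
stage — 1-degree rotation scan with golden-section refinement of the
correlation peak, subpixel translation from the parabola-refined peak, on
blurred copies — brings the estimate into the basin of attraction, and a
joint Nelder–Mead minimization of the sum of squared differences over
(rotation, dx, dy) on the raw images then refines it. The refinement is the
maximum-likelihood estimate under white noise; the correlation-only
estimator was measured several times farther from the Cramér–Rao bound at
the noise levels the pipeline targets (the tests require median errors
below 0.25 px and 0.25°). Registration operates on amplitude images by
default; whether the instrument registered bipolar or amplitude frames is
unstated, and amplitude images are smoother targets for correlation.
Deformable registration and learned denoising are out of scope.

## 4. Grüneisen thermometry and CEM43T50 dose

Over the hyperthermia range the Grüneisen parameter is linear in
temperature, `Γ = bT + c`, so the relative amplitude change between a frame
and the baseline maps to temperature as `dT = a · Δp/p0` with
`a = T0 + c/b`. Two calibrations ship with the package: water-bath phantom
(`T0 = 22` °C, `c/b = 2.75`, giving `a = 24.75` °C) and soft tissue
(`T0 = 37` °C, `c/b = 13.14`, `a = 50.14` °C). Absolute maps add the body
core temperature (37 °C in vivo, the bath temperature for phantoms).

Decisions where the processing description left room:

* **Baseline.** `p0` is the pixelwise mean amplitude over all frames of the
  first baseline minute (the laser-off lead-in), not a single frame.
* **Validity floor.** The inversion divides by `p0`; pixels whose baseline
  amplitude is below 5% of the ROI's median baseline are flagged invalid
  (NA) and excluded from ROI statistics.
* **Interval pooling.** `T_avg` and `T50` for a reporting interval pool all
  ROI pixels of all frames in that interval (mean and median of the pooled
  sample) rather than picking one representative frame; with several frames
  per minute, pooling is the lower-variance reading of "the median of the
  ROI during the 1-min interval".
* **Dose breakpoint.** The CEM43T50 dose is
  `Σ t · R^(43 − T50_i)` with `R = 0.5` at or above 43 °C and `R = 0.25`
  below — the standard CEM43 convention; the reporting interval defaults to
  1 min over the 10 heating intervals.

Absolute (baseline-free) thermometry and perfusion-corrected thermometry are
out of scope.

## 5. Heating kinetics

`fit_exponential_rise()` fits `T(t) = a(1 − e^{−kt}) + b` by
Levenberg–Marquardt least squares with a heuristic start (baseline = first
sample, amplitude = last − first, rate = inverse time to 63% of the
amplitude) and up to 5 jittered restarts on non-convergence. A constant
trace has no identifiable rate and is flagged degenerate rather than fitted.
Cycle stability is summarized by `cycle_change()` as percent changes relative
to the first cycle (positive = decrease). Refitting noiseless curves built
from the published first/fifth-cycle fits reproduces the printed stability
figures: 0.37% amplitude / 2.3% rate for PA thermometry, and for the
thermocouple trace a 20.14% amplitude decrease (printed as 20.2% — the
printed inputs are rounded) with an 11.94% rate increase. Note the symbol
overloading: the kinetics `a`, `b` are unrelated to the Grüneisen constants;
they live in separate types for that reason.

## 6. Monte Carlo photon transport and Pennes bioheat

The PTT simulation reproduces, at reduced fidelity, the two-step scheme used
to explain why submerged treatment spares the skin: photon transport gives
the absorbed power density, which drives a bioheat solve.

**Tissue model.** A 2-cm cube at 0.25-mm voxels (default): 1.1 cm muscle,
0.075 cm skin, an ellipsoidal tumor with semi-axes 3.5 × 4 × 2.5 mm placed
with its top tangent to the skin–muscle interface (its exact depth is not
fully specified; tangent placement keeps a well-defined tumor–skin contact
for the boundary probe, and is configurable in source). The stated radii
give an analytic volume of 146.6 mm³; the voxelization matches this within
5%. All tissue gets µa = 0.1, µs = 100 cm⁻¹; the tumor's absorption is
raised by 1.36 cm⁻¹ for the nanoparticle loading; water absorbs 0.02 cm⁻¹.
Anisotropy is unstated for this model; g = 0.9, the standard soft-tissue
value, is adopted and configurable. Thermal properties and perfusion rates
defer to literature-typical values (shipped as a documented, fully
overridable table; tumor perfusion equals muscle perfusion, as specified for
the original model). Refractive-index mismatch and Fresnel reflection at
boundaries are omitted (matched-index transport) — a documented
simplification that mainly underestimates shallow fluence in the open-air
case.

**Monte Carlo.** Standard voxel random walk: exponential free paths in
µa + µs tracked across voxel boundaries by accumulating optical depth,
absorption-weighted deposition (a fraction µa/µt of the packet weight per
interaction), Henyey–Greenstein scattering. Instead of Russian roulette —
which conserves energy only in expectation — packets below a 1e-4 weight
threshold deposit their residual weight locally, so deposited + escaped
energy equals launched energy *exactly* at every run; the bias is bounded by
the threshold. The beam is a 16-mm Gaussian clipped by a 4.8-mm-radius iris
at 2.5 W/cm², entering the top face. A scattering-free configuration
reproduces Beer–Lambert depth deposition within 2% at 10⁶ photons.

**Bioheat solve.** The Pennes equation
`ρc ∂T/∂t = ∇·(κ∇T) + Q + ωρ_b c_b (T_a − T)` is integrated implicitly with
a locally-one-dimensional (LOD) splitting of backward Euler: three
tridiagonal solves per step along x, y, z with harmonic-mean face
conductivities. The scheme is unconditionally stable, which matters because
the air region's high thermal diffusivity makes explicit stepping
prohibitive; a monolithic sparse backward-Euler solve per step would be
equivalent in stability but far more expensive on a 80³ grid, and the
splitting error at dt = 0.5 s is negligible against minutes-long thermal
time scales. Since the coefficients are time-invariant, each line's LU
factorization is computed once and the time loop performs only O(n)
eliminations. The outermost voxel shell is held at fixed temperatures by
medium — 20 °C where it is air, 35 °C where it is water, 37 °C where tissue
touches the boundary — which are also the initial temperatures.

**Coupling media.** Still air is solved as a stagnant conductor
(κ = 0.026 W/m/K): it insulates the skin, which is exactly why open-air
treatment overheats it. The water bath, by contrast, is actively temperature
controlled in the real platform; stagnant conduction cannot represent a
stirred bath (a first implementation solving water conductively barely
cooled the skin over 10 min, because the cold outer boundary is ~8 mm of
quiescent water away). The bath is therefore treated as isothermal at
35 °C — the limit of vigorous mixing — by pinning all water voxels
(`isothermal_coupling`, overridable). With these defaults the simulation
reproduces the platform's characteristic inversion: in open air the hottest
probe is the tumor–skin boundary closely followed by the skin, while
submerged the maximum moves to the tumor center and the skin becomes the
coolest probe, with the maximum-temperature location correspondingly deeper.

Finite-element parity with a commercial solver, vascular or
temperature-dependent property models, and whole-body fluence simulation are
non-goals.

## 7. Numerical conventions and problem sizes

World coordinates are in mm with the ring center at the origin; image grids
are pixel-center addressed. Acoustic time is in µs, schedules in minutes,
bioheat in SI units. All stochastic components (channel noise, motion
jitter, photon paths, fit restarts) are seeded; identical seeds give
bit-identical RF data and Monte Carlo deposition (the transport code uses
its own xoshiro256++ generator so results do not depend on R's RNG state).

The shipped tests exercise the pipeline at sizes chosen to keep the full
suite comfortably interactive while remaining in the regime where the
physics is nontrivial: 16–64 ring elements, 32×32–128×128 pixel grids for
reconstruction and thermometry, 10-seed noise ensembles for the end-to-end
recovery, and the full 80³-voxel, 10⁶-photon configuration for the PTT
comparison. Degenerate inputs (empty phantoms, flat images, constant heating
traces, all-invalid baselines, zero-energy kernels) error with explicit
messages rather than propagating NaNs.

## 8. Known limitations

* The forward model and reconstruction share the same delay convention, so
  systematic speed-of-sound errors cancel in the round trip; real data would
  show defocusing the synthetic tests cannot reveal.
* Amplitude images rectify noise (|x| of a noisy bipolar image is biased
  upward); the thermometry ratio largely cancels this, but at very low SNR
  the residual bias would matter.
* The LOD splitting is first-order in time; with strongly
  temperature-dependent properties (not modelled) a Crank–Nicolson or ADI
  variant would be preferable.
* The isothermal-bath idealization bounds the real bath's cooling from
  above; the conductive-water alternative bounds it from below. The
  qualitative submerged/open-air inversion holds at the isothermal end, and
  the stagnant end still shows strong skin cooling relative to air.
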