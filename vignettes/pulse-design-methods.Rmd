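---
title: "Spectrally selective universal pTx pulse design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrally selective universal pTx pulse design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxgrape)
```

## The design problem

At ultra-high field (7 T) the transmit RF field $B_1^+$ interferes
destructively across the head: a circularly polarized (CP) drive of an
8-channel array produces a centre-bright, periphery-dark flip-angle
pattern with coefficients of variation well above 15%. Parallel
transmission (pTx) addresses this by driving every channel with its own
RF waveform, and optimal-control ("GRAPE") design additionally frees the
three gradient waveforms, optimizing all controls sample by sample.

For *slice- and slab-selective* excitation a further requirement appears:
under a constant selection gradient, position along the slice axis maps
linearly onto precession frequency,
$f = \bar\gamma\, G_\mathrm{sel}\, x$ with
$\bar\gamma = 42.577$ Hz/(mT/m·mm). A pulse therefore excites a clean,
shiftable slice exactly when *every voxel* shows the same rectangular
*spectral* response. `ptxgrape` designs such pulses by running hard-pulse
Bloch simulations per voxel at randomly drawn frequency offsets inside
the optimization loop, on a database of subjects at once, yielding
*universal* pulses that need no per-subject calibration.

## Cost function

Let $\mathrm{FA}(f)$ and $\varphi(f)$ be the simulated flip angle and
transverse phase of a voxel at injected offset $f$. The target is a box:
$\mathrm{FA}_T(f) = \mathrm{FA}_T$ for $|f| \le BW_T/2$, zero otherwise
(`target_fa()`). The design minimizes

$$
c = \sqrt{\;\overline{\sum_{\mathrm{subj}}\sum_{\mathrm{vox},f}
w(\Delta B_0, f)\,
\Big(\tfrac{\mathrm{FA}(f)-\mathrm{FA}_T(f)}{\mathrm{FA}_T(0)}\Big)^2
\;+\;\lambda_\mathrm{ph}
\sum_{\mathrm{passband}} w_\mathrm{ph}(\mathrm{FA})\, w\,
\Big(\tfrac{\varphi(f)-\varphi(f{+}\Delta f)-\pi\Delta f T}
{\pi\Delta f T}\Big)^2}\;,
$$

where the overbar denotes normalization by the number of
(subject, voxel, $f$) samples, so that $\lambda_\mathrm{ph}$ keeps its
meaning across problem sizes. The first term is a magnitude-least-squares
(MLS) objective on the flip angle. The second enforces *linear spectral
phase*: the phase difference between $f$ and a slightly shifted
$f+\Delta f$ must equal the free-precession phase over half the pulse
duration, $\pi \Delta f T$. A linear-phase passband is what makes the
slice refocusable with an ordinary rephasing gradient; a pure MLS design
would scatter phase across the slice and dephase the signal, while a
complex-least-squares target would over-constrain the spatial phase. The
residual is wrapped to $(-\pi,\pi]$ before squaring.

Three weights shape the cost (`weighting_config()`):

* `weight_profile(f)` — 1 deep in the passband, decaying to exactly 0 at
  the band edges $\pm BW_T/2$ over a raised-cosine transition (default
  total width $0.3\,BW_T$), then rising to a stopband plateau (default
  0.5). The transition region is de-weighted because a physical pulse of
  duration $T$ cannot realize a discontinuous profile; without the
  de-weighting the unavoidable roll-off would dominate the quadratic
  cost. The nonzero stopband plateau keeps side lobes suppressed.
* the off-resonance factor $1 + \lambda_{B_0}\,|\Delta B_0|$ (Hz) —
  voxels near air cavities get extra weight so the design does not
  sacrifice them. The absolute value keeps the weight admissible for
  both off-resonance signs.
* `weight_phase(FA)` — a smooth $\tanh$ gate centred at 20% of
  $\mathrm{FA}_T$ (steepness $10/\mathrm{FA}_T$ per degree, saturating
  within about $\pm 0.2\,\mathrm{FA}_T$ of the centre), switching the
  phase term off where almost nothing is excited: phase is meaningless
  (and numerically wild) at near-zero flip angles.

Frequency offsets are drawn once per design, per voxel and held fixed
(`sample_frequencies()`): every voxel receives its own independent draws
(Gaussian or uniform), which prevents coherent spectral ripples from
forming across the volume, and fixing them keeps the objective
deterministic for the optimizer. Defaults follow the two applications:
slice-selective designs use 5 Gaussian offsets per voxel with
$\sigma = 6.6$ kHz, $\lambda_{B_0} = 0.02$, $\lambda_\mathrm{ph} = 3$;
slab-selective designs use 3 uniform offsets in $[-6.25, 6.25]$ kHz,
$\lambda_{B_0} = 0.01$, $\lambda_\mathrm{ph} = 3$. A wide Gaussian
suppresses side lobes everywhere in the brain (needed for multi-slice
imaging); a bounded uniform draw is enough for a slab, whose aliased
side lobes fall outside the field of view. $\Delta f$ defaults to
100 Hz — "slightly shifted" relative to kHz-scale structure; the model
is first-order in $\Delta f$, so any value well below the transition
width behaves identically.

ROI-specific (per-slice) designs multiply every voxel's contribution by
`roi_weight`, $w_\mathrm{slice} = e^{-d/10\,\mathrm{mm}}$ with $d$ the
distance from the slice centre, and `design_roi()` optimizes only every
second slice, reusing each result for its neighbour — the exponential
decay makes adjacent-slice reuse essentially free.

## Bloch simulation and conventions

`simulate_voxel()` composes exact axis-angle rotations per time sample
(hard-pulse approximation): sample $n$ applies the rotation generated by
the transverse drive $b_1[n] = \sum_c s_c V_c[n]$ (complex, Hz) and the
longitudinal offset
$\omega[n] = \Delta B_0 + f + \bar\gamma\, \mathbf{g}[n]\cdot\mathbf{r}$
(Hz) for $dt$ seconds. Relaxation is neglected during excitation (3 ms
against tissue $T_2$ of tens of ms). Conventions, fixed and relied on
throughout:

* rotation vector $\mathbf{a} = -2\pi\,dt\,(b_{1x}, b_{1y}, \omega)$: a
  positive offset precesses the transverse magnetization clockwise in
  the rotating frame (free-precession phase $-2\pi f\tau$). This sign
  choice is what makes the phase-consistency target $+\pi\Delta f T$.
* flip angle is extracted as $\mathrm{atan2}(|M_{xy}|, M_z)$, which stays
  monotone beyond 90°; phase as $\arg(M_x + iM_y)$, reported as 0 at
  numerically zero $|M_{xy}|$.
* volts map to field through the sensitivities in Hz/V. The reference
  calibration assumes each channel contributes 11.75 Hz/V coherently at
  the head centre, so `make_cp_sinc()` scales its envelope such that the
  CP combination ($N_c \times 11.75$ Hz/V) produces the requested flip
  angle. Under this convention the 20° reference pulse and a feasible
  90° slab design both sit comfortably inside the power limits.

Slice profiles (`slice_profile()`) place 3000 spins along a 6 mm segment
(both configurable), map position to frequency through the selection
gradient, and linearly interpolate $\Delta B_0$ and $B_1^+$ along the
segment; the pulse's own optimized gradients also act on the spin
positions. The phase-sensitive `slice_integral()` — magnitude of the
*complex* spin sum — is the signal proxy: intra-slice phase dispersion
reduces it even when the central flip angle is perfect.

## Symmetry and the phase model

Pulses are optimized as time-symmetric waveforms
(`symmetrize()`): complex RF and gradients mirror about the pulse
centre, halving the parameter count. In the small-tip limit a symmetric
pulse has spectral response
$M_{xy}(f) \propto i\,e^{-i\pi f T} H(f)$ with $H$ the centred envelope
transform, so the phase slope is $-\pi T$ — exactly the free-precession
model of the phase term. One subtlety: mirror symmetry of a *complex*
envelope makes $H(f)$ even but not real, so the envelope can contribute
its own slowly varying spectral phase; with real (or Hermitian)
envelopes the model is exact wherever $H$ does not change sign. The
phase term's $\tanh$ gate masks the sign-flip nulls, and the property
suite asserts the $\pi\Delta f T$ model on random real-envelope
symmetric pulses in the region above 20% of the peak flip angle.

## Constrained optimization

The designer (`design_pulse()`) minimizes $c$ over the symmetric
half-parameters on a coarse 30 µs grid and linearly interpolates the
result to the 10 µs playout grid, following the coarse-to-fine scheme
that keeps per-iteration cost proportional to the sample count.
Gradients of the full Bloch chain are computed by reverse-mode
(adjoint-state) differentiation through the rotation sequence — the
derivative of each axis-angle rotation is evaluated in closed form — and
validated against central finite differences in the test suite;
finite differences alone would cost one simulation per parameter and are
hopeless even at desk scale.

Hardware limits (70 mT/m gradient, 200 T/m/s slew including the ramps
from and to zero at the pulse edges, 190 V peak, 8 W total and 1 W
per-channel pulse-average power at 50 Ω) enter as smooth quartic-hinge
penalties with a 2% interior margin, escalated over four continuation
rounds ($\mu = 10, 3\cdot10^2, 9\cdot10^3, 2.7\cdot10^5$); each round
runs an L-BFGS-B inner solver for up to `max_iter` iterations (default
300 per round). After every round the iterate is projected to *exact*
feasibility — all five limits are positively homogeneous in either the
RF or the gradient waveform, so a scalar rescale suffices — and the best
feasible iterate by true cost is retained; the returned pulse therefore
never violates a limit and never costs more than its initialization.
Edge slew is checked against the *fine* sample duration already during
coarse-grid optimization, because interpolation shortens the edge ramp.
Power is averaged over the pulse duration, not a TR duty cycle; absolute
energy values are reported under this 50 Ω convention.

The quadratic-penalty/continuation scheme with quasi-Newton inner solves
and exact final verification was chosen over an SQP-type solver because
the active constraints here are simple homogeneous bounds: continuation
reaches the same constrained optimum while every intermediate iterate
remains cheap, and determinism (identical results for identical config,
cohort and seed) is easy to guarantee.

## Synthetic field-map cohort

Measured multi-subject map databases are not redistributable, so
`generate_cohort()` builds one: an ellipsoidal head (default semi-axes
55/45/40 mm on a 5 mm grid, ≈3.5k brain voxels) inside a ring of 8
loop-like sources at 135 mm radius. Channel magnitude decays with
distance from each source (exponent 1.5); channel phase advances with
propagation distance at the ≈13 cm in-tissue wavelength of 297 MHz, and
is referenced to the CP mode (the azimuthal drive phase is absorbed, as
after a vendor CP phase calibration — hence `make_cp_sinc()`'s default
zero phase increment). The coherent sum is centre-bright while the
periphery decoheres, reproducing the 7 T pattern; the generator's
defaults give a CP-mode coefficient of variation well above the 15%
floor the test suite asserts, so the design problem is never trivially
easy. $\Delta B_0$ is a smooth low-order polynomial (±150 Hz) plus
Gaussian hotspots (up to ±600 Hz, widths 16 mm) at the
anterior-inferior and lateral-inferior mask boundary, mimicking frontal
sinus and ear-canal susceptibility — plausible 7 T head values, held as
configuration, not as claims. Subjects differ by seeded jitter of head
size (5%), position (4 mm), tilt (0.07 rad), coil loading (10%) and
hotspot strength; the whole cohort is a pure function of its
configuration.

What the generator does *not* emulate: full-wave electrodynamics
(no FDTD), anatomy and tissue heterogeneity, receive fields, and the
true inter-subject variance of a scanner database. Passing tests
therefore demonstrate the *machinery* — constraint handling, spectral
shaping, universality across a cohort of this variability class — not
in-vivo image quality.

## Echo-train simulation

`epg_simulate()` implements the extended phase graph over configuration
orders: excitation populates the transverse states from equilibrium,
and each echo period applies relaxation over the two half-spacings, unit
dephasing shifts and the RF mixing matrix, reading echoes from the
zero-order state. The mixing matrix uses the same rotation handedness as
the Bloch kernel, so phases travel consistently between the two
simulators; the CPMG condition (transverse magnetization along the
refocusing axis) then reads $\varphi_\mathrm{exc} =
\varphi_\mathrm{ref} - \pi/2$. The defining correctness property — EPG
equals a uniformly dephased isochromat ensemble — is asserted against a
512-spin oracle, where it holds to machine precision because the
discrete ensemble is an exact quadrature for integer dephasing orders.

The default train (`default_vfa_train()`) is a stand-in for a
T2-weighted variable-flip-angle TSE: 107 refocusing pulses (one initial
180°, then an exponential ramp 120°→55°), 6.65 ms echo spacing with a
12.5 ms first spacing (a short excitation pulse permits the short first
spacing, which is itself a large signal lever), and default tissue
$T_1/T_2 = 1500/60$ ms — plausible 7 T brain values, configurable, not
claims. Train *design* is out of scope; trains are inputs, readable from
a two-column text file (`read_train()`).

## Problem sizes and numerical choices

The test and acceptance workloads are desk-scale by choice: the
constrained slab design runs on 200 masked voxels subsampled from one
synthetic subject with 3 offsets per voxel (about a minute), and the
universality/improvement checks use a 3-subject cohort on a 12 mm grid
with 150 inner iterations per round. Scaling to a full 20-subject, 5 mm,
whole-brain design changes only wall-clock time, not code paths.
Further numerical choices: frequency samples per voxel are independent
streams of one seeded generator; ties in the FWHM measurement are
resolved by linear interpolation of the half-maximum crossings adjacent
to the peak; degenerate inputs (empty masks, zero sensitivities,
non-positive time steps, mismatched shapes) are rejected with explicit
errors rather than silently repaired; the only silent repair is the
documented feasibility projection of an infeasible initialization, which
warns.

## Known limitations

* The spectral-response formalism treats the selection gradient as a
  frequency axis; oblique or time-varying selection gradients during
  evaluation are supported only through the pulse's own gradient
  waveforms.
* The phase-linearity guarantee of symmetric pulses is exact only up to
  the envelope's own spectral phase (see above); strongly complex
  optimized envelopes rely on the phase term of the cost, not on
  symmetry alone.
* Power accounting uses a fixed 50 Ω convention and pulse-duration
  averaging; SAR beyond the stated power limits (e.g. virtual
  observation points) is out of scope.
* The EPG neglects diffusion and flow, and relaxation during RF pulses.
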