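---
title: "Methods: an eight-channel EIT instrument as a digital twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an eight-channel EIT instrument as a digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eittwin)
```

This vignette explains what the package models, which choices were open
and how they were settled, and what the simulations can and cannot say
about the physical instrument.

## The signal chain

The instrument synthesizes its excitation not with a conventional
voltage-controlled current source but with a discrete amplitude loop: a
direct digital synthesizer produces a cosine voltage of amplitude `a[k]`,
the load current amplitude `IL[k]` is sensed once per period, and the
next period is scaled by

\[ a[k] \;=\; a[k-1]\,\frac{I_d}{I_L[k]},\qquad a[0] = 1\,\mathrm{V}. \]

For a resistive load this law is exact after a single update regardless of
the load value: the first period measures the current the 1 V start
produces, and the rescaled second period delivers the setpoint \(I_d\).
The twin reproduces the residual error sources the analysis ignores —
8-bit DAC register quantization and the 10-bit SAR ADC on the shunt
voltage — so the simulated second-period current is the setpoint *within
one quantization step* (0.9864 mA for a 0.98 mA setpoint on 1 kΩ), not
exactly.

**Cosine synthesis.** Two current DACs in source mode carry the positive
and negative half-waves.  With sample table \(S_i=\cos(2 i \pi / 55)\),
requested amplitude \(V\) and feedback resistance \(R_{fb}\), the register
sequences are

\[ D_i^{\pm} = \left\lfloor \frac{255\,V}{31.875\,\mu\mathrm{A}\cdot
R_{fb}} \max(0, \pm S_i) \right\rfloor , \]

and trans-impedance stages referenced at \(V_r\) convert the two currents
to the bipolar load voltage \(V_L = R_{fb}(I_2 - I_1)\).  Two numerical
choices matter here:

* **Floor, not round.**  The autorange table is only consistent with a
  floor: 1.275 V at 80 kΩ gives a scale factor of exactly 127.5 and the
  tabulated register is 127.  The floor is applied to the full product
  including \(\max(0,\pm S_i)\), so every emitted register is integral,
  and it is guarded by a one-part-per-billion epsilon so that scale
  factors that are exact integers in real arithmetic (e.g. 255·V at an
  interval bound) are not pushed down a step by binary rounding.
* **Autoranging.**  Small amplitudes at fixed \(R_{fb}\) exercise only the
  low DAC bits and distort the cosine — below 0.16 V at 20 kΩ the
  registers stay under 63, using five of eight bits.  \(R_{fb}\) is
  therefore switched over six half-open intervals covering
  [0.15 V, 4.625 V).  The package verifies the intended effect: total
  harmonic distortion of the synthesized period falls monotonically as
  the register ceiling rises from 63 to 255.

**Open behaviors settled by the package.**  The reference design does not
state what happens when the amplitude law requests a voltage outside the
synthesizable span: the twin clamps to the nearest interval boundary and
flags the state, and a run that clips in *every* period raises an
unreachable-setpoint error.  The ADC is modeled as a mid-rise uniform
quantizer over a ±2.048 V differential range (the resolution is fixed by
the hardware, the range is a choice).  \(V_r\) is set per period to
\(R_{fb}\cdot 31.875\,\mu\mathrm{A} + 0.1\) V, which satisfies the
single-supply feasibility inequalities with margin.  Peak current is
sensed at the sample of maximum \(|S_i|\), i.e. the first sample of the
period.

## Acquisition protocol and frames

The adjacent protocol drives each pair of consecutive electrodes in turn
and measures the differential voltage across every consecutive pair not
touching the drive, giving \(n(n-3)\) measurements — an 8 × 5 frame for 8
electrodes.  The protocol is implemented canonically on geometric
electrode indices; a pin permutation in the layout type expresses any
connector wiring without changing the pattern.  Frames are stored one per
text file (`Frame0.txt` = homogeneous reference), written with 17
significant digits so round trips are exact; the reader also accepts a
single-column layout and scientific notation.

The noise model adds white Gaussian noise per measurement slot plus a
random-walk drift across the 40 slots of a frame.  The three named
profiles mirror the effect of multiplexer switching times: `1ms` (white
noise only, 0.1 % of the reference voltage → ≈60 dB channel SNR), `10ms`
(0.25 % + mild drift → ≈50 dB) and `100ms` (25 % + strong drift →
≈10 dB).  The *ordering* of these profiles is the modeled contract — the
absolute magnitudes are calibrated choices, since the underlying transient
physics is not simulated.

## Forward model

The forward problem \( \nabla\cdot(\sigma\nabla u)=0 \) is solved with
linear triangular finite elements on a structured disk mesh built from
concentric rings (ring \(j\) carries \(8j\) nodes, so sector boundaries
and electrode angles coincide exactly with mesh nodes; element count is
\(8\,n_{\mathrm{rings}}^2\)).  Current injection uses point electrodes —
the reference device's contact impedances are unreported, and the point
model keeps the solver minimal and exactly reciprocal; a complete-electrode
extension would attach at the layout type.  The singular Neumann system is
gauged by a zero-mean potential constraint via a Lagrange multiplier.
The DC solution stands in for the 50 kHz envelope: all phantoms are purely
resistive, so complex impedance is out of scope.

Correctness is anchored to a closed form: for a homogeneous disk with
boundary point drive at \(x_+\), \(x_-\),

\[ u(x) = \frac{I}{\pi\sigma}\left(\ln|x-x_-| - \ln|x-x_+|\right), \]

which the FEM matches to better than 2 % relative \(L_2\) on the boundary
at ≈2000 elements (0.5 % on the 40 protocol voltages).  The sensitivity
Jacobian is computed by the adjoint method — one extra field per
measurement pair, reusing the eight consecutive-pair solves — and agrees
with central finite differences to numerical precision; its rows satisfy
the Euler identity \(\sum_e \sigma_e \partial V/\partial\sigma_e = -V\)
for homogeneous \(\sigma\).

Protocol voltages are reported as magnitudes, matching the RMS
demodulator, and the Jacobian rows are signed accordingly so both refer to
the same measurement convention.

## Reconstruction

Difference imaging linearizes around the homogeneous background: the
normalized differences \( \Delta v(k) = (v_{nh}(k)-v_h(k))/v_h(k) \) are
mapped to pixel values by

\[ R \;=\; P\,(J^{\mathsf T}J + \lambda^2 L^{\mathsf T}L)^{-1} J^{\mathsf T}, \]

a 1024 × 40 matrix for the 32 × 32 grid, where \(P\) is an area-sampled
element-to-pixel interpolation (each in-disk pixel averages the elements
under a 3 × 3 stencil of its area; pixels outside the disk are zero).
Conductive inclusions reconstruct positive, insulating ones negative.

Choices made where the design was open:

* **\(\lambda\) = 0.05 of the largest singular value of \(J\).**  The
  reference reconstruction's hyperparameters are unreported; a fixed
  fraction of \(\sigma_{\max}(J)\) makes the default scale-free.  It is
  exposed in the API.
* **Identity prior by default.**  An adjacency-Laplacian smoothness prior
  is available, but measured on the two-rod saline scenario it places
  spurious extrema at the tank rim: the rim elements are small and nearly
  unobservable, and penalizing only *differences* leaves their absolute
  level free.  The identity prior localizes both rods correctly and is
  therefore the default.
* **Dual meshes.**  Scenario voltages are solved on a finer mesh
  (≈8000 elements) than the Jacobian/inverse mesh (≈2000).  Besides
  avoiding an inverse crime, this is necessary for resolution: with the
  centroid inclusion rule, the ≈2000-element ring mesh has 4.4 mm radial
  resolution and cannot distinguish the 2.5 cm from the 2.7 cm cavity.
* **GN–TV.**  The iterative reconstruction minimizes
  \(\|J x - \Delta v\|^2 + \lambda_r^2\|x\|^2 + \lambda_{TV}
  \sum_{ij}\sqrt{(x_i-x_j)^2+\beta^2}\)
  over element edges by lagged diffusivity with backtracking, so the
  objective is non-increasing.  \(\beta\) is \(10^{-4}\) of the initial
  solution's dynamic range (floored at \(10^{-12}\)); the small ridge
  \(\lambda_r\) keeps every iteration well-posed and makes the
  zero-TV-weight, one-iteration case reduce exactly to the one-step
  identity-prior solution.  Lagged diffusivity was preferred over
  primal-dual methods for implementation economy; it is one standard
  reading of total-variation regularization.

## Performance indices

Per channel \(i\) over repeated frames \(j\):
\( \mathrm{SNR}_i = 20\log_{10}(|\overline{m}_i| / s_i) \) and
\( \mathrm{Ac}_i = (1 - |(\overline{m}_i - m_i^T)/m_i^T|)\cdot 100. \)
Two readings were open and are both exposed: the SNR denominator is the
standard deviation by default (the 20·log form pairs amplitude ratios,
and ≈60 dB at sub-millivolt scatter on millivolt signals is only
consistent with sd), with the raw-variance reading selectable; the
accuracy reference \(m^T\) is the noise-free forward-model voltage in
simulation.  Logarithms are base 10 throughout.

The global impedance sums the reconstructed pixels,
\( GI = \sum_f \sum_k I_f(k) \), reported per frame and cumulatively
together with the inverse magnitude \(|GI|^{-1}\).

**Direction of the volume index.**  In this twin the magnitude of the
pixel sum grows monotonically with cavity area (and with cavity
conductivity at fixed area): a larger conductive inclusion perturbs more
channels more strongly, \(\Delta v\) scales roughly with inclusion area,
and the reconstruction is linear in \(\Delta v\).  Consequently
\(|GI|^{-1}\) *decreases* strictly with cavity radius — the index is
strictly monotone in volume, which is what makes it usable for
volume tracking, but its direction here is the opposite of what has been
reported for hardware measurements processed through other reconstruction
stacks.  The package asserts the strict monotonicity it actually
produces; the direction discrepancy is an honest property of the
transparent linear pipeline and is left visible rather than patched.

## The phantom generator

`make_phantom()` reproduces the reference scenarios: a 7 cm tank of
0.278 S/m saline with a 2.1 cm insulating rod (σ = 10⁻⁶ S/m stand-in for
PVC) and/or a 2.15 cm conductive rod (copper's 5.8·10⁷ S/m clipped to
10³ S/m for finite-element conditioning — only the contrast sign matters
in difference imaging); and 0.217 S/m agar with a centered saline cavity
of radius 2.7 / 2.5 / 1.3 cm at 1.227 / 1.890 / 2.07 S/m.  Rod centers
are not reported for the reference experiments; the single rods are
placed at mid-radius (±3 cm) and the joint scenario at ±3.5 cm, symmetric
and non-overlapping.  Element membership is decided by centroid — simple,
deterministic, and convergent under refinement (the assigned area matches
\(\pi r^2\) within 5 % at ≈8000 elements).

## Problem sizes and determinism

The test suite runs forward solves at 200–2048 elements, end-to-end
scenarios with an 8192-element forward mesh and a 2048-element inverse
mesh, and 48–50-frame noisy acquisitions; the full pipeline over all nine
agar scenarios completes in well under a minute.  The 25 511-element scale
of the reference reconstruction is reachable through
`build_disk_mesh(0.07, 25511)` but is not the default desk scale.  All
stochastic stages draw from a seeded `noise_model`, so every simulated
experiment is exactly reproducible.

## What the twin does and does not show

Passing simulations demonstrate the *logic* of the instrument: protocol
arithmetic, quantization behavior, loop convergence, solver correctness,
localization and sign of reconstructed inclusions, and monotonicity of
the volume index.  They do not validate hardware figures: frame rate,
absolute SNR/accuracy of the physical device, oscilloscope
cross-calibration, electrode contact effects, reactive (non-resistive)
tissue behavior, and 3D current spreading in a real 30 cm tank are all
outside the model.  The 2D disk is the electrode plane of a cylindrical
tank; treating it as such is standard for this electrode geometry but is
an approximation.
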