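---
title: "Methods: combined gradient and RF heating of a hip implant"
author: "implantheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined gradient and RF heating of a hip implant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices and the
limitations of the pipeline: pulse-sequence synthesis, gradient-coil (GC)
eddy-current power deposition in a metallic hip implant, radiofrequency
(RF) power maps, the nonlinear bioheat solution, and the safety metrics
derived from it.

## The exposure problem

A patient with a metallic hip prosthesis inside a cylindrical-bore scanner
is exposed simultaneously to two heat sources with very different spatial
signatures. The switched gradient fields (kHz band) induce eddy currents
in the conductive implant itself: their magnitude grows with the distance
of the implant from the isocenter, because the gradient field is linear in
position, so gradient heating is *largest when the implant is outside the
imaging region*. The RF transmit field deposits power in the conductive
tissue around the implant (the metal behaves as a perfect electric
conductor at MHz frequencies and is excluded), so RF heating is largest
when the implant lies *inside the transmit coil*. Because thermoregulation
is nonlinear, the temperature increase under combined exposure is not the
sum of the single-source increases; the package therefore solves the three
exposure cases P1 (GC only), P2 (RF only) and P3 (both) separately.

All temperatures are handled as increases ΔT over the resting state; this
sidesteps the need for the unknown resting temperature field. Thresholds
of 1 K and 3 K on ΔT are used for the safety metrics, corresponding to
local-temperature limits of 39 °C and 41 °C under a conservative 38 °C
resting maximum.

## Synthetic phantom and implant

No licensed anatomical model is bundled. The generator builds a layered
cylindrical soft-tissue phantom — skin (2 mm), subcutaneous adipose tissue
(6 mm), fat (12 mm), muscle, and a 20 mm-radius cortical-bone core — on a
2 mm isotropic grid (default 100 × 100 × 250 voxels, i.e. a
0.2 × 0.2 × 0.5 m body segment), with a simplified unilateral hip implant
embedded on its axis:

* CoCrMo stem (radius 7 mm, length 142 mm) and neck, hemispherical head
  (diameter 30 mm), hemispherical acetabular shell (outer diameter 66 mm,
  thickness 8 mm), fixation screw (length 34 mm), total stem-to-head
  height 230 mm;
* a 10 mm polyethylene liner filling the gap between head and shell.

The pose is a documented canonical one (axis vertical, dome up, screw
axial). Two consequences are deliberate: the liner electrically separates
the femoral component (stem + head) from the acetabular component
(shell + screw), as in a real prosthesis, so the eddy problem has two
conductor components; and the stem-to-head distance requires a connecting
neck cylinder, whose radius (7 mm) is a canonical choice — the printed
geometry does not constrain it. Voxel membership uses the voxel-*center*
rule, which is deterministic and convergent (the 1 mm rasterisation is
closer to the analytic primitive volume than the 2 mm one; both are within
10 %).

CoCrMo and polyethylene carry handbook properties (σ = 1.16 MS/m,
λ = 14 W/mK, c_p = 450 J/kgK, ρ = 8445 kg/m³; σ = 0, ρ = 940 kg/m³). The
soft-tissue entries are literature-typical values of the kind tabulated in
tissue-property databases; they are *configuration* — the table travels
with the model object and can be swapped (e.g. for a Ti-alloy implant).

`placeBody()` moves the phantom along the bore axis so the implant head
sits at one of 12 standard offsets, +288 mm down to −416 mm in 64 mm
steps, spanning thorax-analog to femur/knee-analog imaging positions.

What the phantom does **not** emulate: anatomy (organ geometry,
77-tissue segmentation), bilateral implants, realistic implant pose, or
implant-induced RF field enhancement. Passing tests on this phantom
demonstrate the correctness of the numerics and the direction and rough
magnitude of position effects — not patient-specific dosimetry.

## Pulse-sequence synthesis

Four families are provided with their study parameter sets: TSE
(90°/180°, TR 260 ms, ETL 16, matrix 128², FOV 450 mm, 69 kHz), EPI (90°,
TR 43 ms, 64², 182 mm, 150 kHz), GRE (20°, TR 500 ms, 256², 140 mm,
20.83 kHz, 11 slices/TR) and TrueFISP (45°, TR 6.4 ms, 256²,
120 × 180 mm, 126.3 kHz), plus the two TrueFISP variants (RF pulse 1 →
1.5 ms at fixed time-bandwidth product; readout bandwidth → 200 kHz).

Numerical choices:

* sample interval dt = 4 µs (≥ 250 samples across the shortest 1 ms
  pulse; Nyquist 125 kHz, above the 100 kHz harmonic cap);
* sinc RF pulses with apodization 0.5; amplitude from pulse-area
  proportionality to flip angle for all flips — the pipeline needs
  relative B1² power, not Bloch accuracy;
* trapezoidal lobes ramp at the slew limit with integer-sample ramps and
  exact discrete areas; readout amplitude, phase-encode steps and
  slice-select amplitude follow the standard moment relations; lobe
  timings follow the usual layout of each family qualitatively, with
  balanced-TR lobes run concurrently on their channels for TrueFISP;
* the representative interval Δ is the TR, except for single-shot EPI
  where it is the whole-slice acquisition frame. At the stated bandwidth
  and slew the synthesized EPI frame (~44.6 ms) slightly exceeds the
  nominal TR of 43 ms; the schedule period is max(TR, frame), a
  documented compromise;
* one TSE acquisition is matrix/ETL = 8 repetitions of TR (2.08 s); the
  SAR dead time is inserted after each acquisition. Acquisition counting
  uses round-to-nearest — the only rule consistent with both printed
  schedules (151 acquisitions at 0.3 s dead time, 47 at 5.65 s, in
  360 s). The quoted per-position whole-body SAR values (2.29 and
  7.43 W/kg for TSE) are *inputs*: they cannot be recomputed without
  full-wave RF fields.

## Gradient-coil eddy currents

The coil model is the idealized uniform-gradient one by default: per unit
gradient the z coil produces B = G(−x/2, −y/2, z) and the transverse
coils their curl/divergence-free analogues; the source vector potential is
taken in the symmetric gauge (A_z-coil = G z(−y, x, 0)/2, etc.). Only the
total E = −∂A/∂t − ∇φ is physical; the gauge is fixed and documented. A
filamentary Biot–Savart mode exists for explicit windings (validated
against the on-axis loop field); the printed coil sensitivities
(56.1/56.1/57.8 µT m⁻¹ A⁻¹) convert current to gradient there.

Each channel over Δ is split into subsignals: quiescent runs (≥ 256
samples) split segments, and a change-point refinement detects a dominant
lobe period from the autocorrelation and separates an aperiodic prefix
(e.g. the EPI pre-phasers) from a periodic train. The classification is
configuration (explicit breakpoints override it); it affects only how the
truncation budget is spent. Each subsignal is Fourier-expanded and
coefficient groups are retained by descending energy until 99.9 % of the
mean-square is captured, with a 100 kHz frequency cap; the captured
fraction is reported (Parseval bookkeeping), and reconstruction error is
bounded by √(1−fraction) × RMS.

For each harmonic the electromagnetic problem is solved in the
quasi-static resistive limit: E = −jω(A + ∇ψ) with ψ solving the discrete
conservation problem ∇·(σE) = 0 inside the metal with zero normal current
on its surface (harmonic-mean face conductances; pure-Neumann system
pinned per connected component by a diagonal penalty; sparse Cholesky).
Neglecting the reaction field makes the spatial solution
frequency-independent: every harmonic is the per-axis unit-gradient
pattern W_a = σ(a_a + ∇ψ_a) scaled by −j2πf c. The time-domain current is
therefore J(t) = −Σ_a Ġ_a(t) W_a — axes superpose *vectorially before
squaring* — and P_GC(t) = |J(t)|²/σ. Validity is monitored via the skin
depth δ = √(2/µσω) (≈ 14.8 mm in CoCrMo at 1 kHz): a warning is issued
when δ drops below the smallest implant extent at a retained harmonic.

The factorisation has a practical payoff: the power averaged over a
thermal marching step is a contraction of six per-voxel maps
(W_a·W_b/σ) with the six time-averaged products ⟨Ġ_aĠ_b⟩ over the step,
computed exactly from cumulative integrals at the 4 µs resolution and the
acquisition/dead-time schedule. Energy is conserved between the
instantaneous and the step-averaged representation to well within 0.5 %.

Oracles: a CoCrMo disk (a = 20 mm, t = 4 mm) under a uniform axial field
reproduces the closed-form resistive-limit power σω²B²πta⁴/16 within 5 %
at 1 mm voxels (observed ≈ 1.2 % low, the staircase-boundary bias);
discrete charge conservation holds to solver precision; power scales
quadratically with amplitude; and the two-axis case agrees with fresh
instantaneous solves, confirming vector superposition.

## RF power maps

Imported maps (NIfTI) are remapped conservatively: identical grids pass
through; integer-factor finer grids are block-averaged, preserving local
volume integrals. The synthetic generator is an explicit, documented
stand-in for a full-wave birdcage simulation: inside the 450 mm coil
footprint P ∝ σ·r² (the quasi-static birdcage E ∝ r scaling), with a
raised-cosine roll-off over 0.15 m beyond the coil ends, normalised to a
stated reference ⟨B1²⟩ and scaled to a sequence by ⟨B1²⟩/reference —
dead time thus dilutes the map exactly as it dilutes SAR, and the
dead-time rule closes the loop at 2 W/kg. Static-field strength enters
only as a scale factor on the map (default 3.8 between the 3 T and 1.5 T
configurations, the squared Larmor-frequency ratio); frequency-dependent
field redistribution is out of scope. The map is axially *flat* inside
the footprint: position studies with this stand-in show a plateau across
all positions whose surroundings overlap the coil, falling off only
beyond the coil and its roll-off — the interior peak seen with a real
coil and implant-enhanced fields is not reproducible here, and the tests
assert the plateau form. PEC masking zeroes the metal voxels
(idempotent); whole-body SAR is ΣP·V / Σρ·V with the implant excluded
from the numerator but counted in the mass.

## Bioheat solution

The equation, in temperature-increase form with instantaneous
thermoregulation:

ρc ∂ΔT/∂t = ∇·(λ∇ΔT) − 2^(ΔT/ΔB) h_b0 ΔT + (1.1^ΔT − 1) P_met0 + P_em,

with ΔB = 1.6 K, the perfusion multiplier capped at 15 (32 for skin), and
clamped at 1 for ΔT ≤ 0 (the model is silent about cooling; the clamp is
an explicit assumption). Robin condition λ∂ΔT/∂n = −h_amb ΔT with
h_amb = 7 W/m²K on tissue–air faces, applied through a half-cell series
resistance (1/h + dx/2λ); sweating and temperature-dependent material
properties are neglected.

Douglas–Gunn time splitting advances diffusion implicitly with three
directional tridiagonal solves per step (precomputed Thomas
factorisations, plane-ordered sweeps); the nonlinear perfusion and
metabolic terms are lagged one step (Picard linearisation) — their
relaxation rates (≲ 0.01 s⁻¹) make this benign at the default marching
step of 0.1 s. Air voxels are excluded; grid-boundary faces are insulated
by default because the phantom is a body segment that continues axially
(`robinAtBounds = TRUE` exposes them). Implant voxels conduct with their
handbook λ, ρc and zero perfusion/metabolism; interfaces use
harmonic-mean conductances.

Verification: (i) the uniform-perfusion balance h_b0 = P_em = 2700 SI
reaches the scalar nonlinear root ΔT ≈ 0.729 K within 0.5 %; (ii) on a
20³ grid with a smooth heterogeneous source the solution at 60 s matches
an independent explicit-Euler integration at 100× finer steps within 1 %;
(iii) a 1D slab with Robin ends matches the closed-form parabolic steady
profile within 0.5 %; (iv) Richardson self-convergence shows the expected
second-order step-size behaviour on a smooth linear decay problem; (v) at
steady state, deposited power balances perfusion removal plus boundary
flux within 1 %.

## Safety metrics

Maximum ΔT (whole grid or within a mask); heated tissue mass above a
threshold per tissue (implant excluded), reported inside a region of
influence — a 21.7 × 18.8 × 28.2 cm box centred on the implant bounding
box, taken as a configured constant rather than re-derived, and clipped
to the grid; time-to-threshold from the running spatial maximum with
linear interpolation between marching steps (the step-quantised
alternative differs by at most one step; interpolation is the documented
choice); and per-voxel ΔT versus the exact Euclidean distance to the
implant surface (separable distance transform, verified against
brute-force nearest-neighbour search; center-to-center metric against the
surface voxel set).

## Study sizes and the position sweep

The position studies in the tests and the acceptance script run the EPI
exposure for 60 s at a 0.25 s marching step on the 100 × 100 × 250
phantom, with the thermal solve confined to the implant bounding box
padded by 30 mm. The confinement is physical, not merely economical: the
thermal diffusion length over 60 s is √(4αt) ≈ 6 mm in soft tissue, so
the cut (insulated) faces 30 mm away cannot influence the near-implant
field; gradient power is deposited only in the implant, and the RF
plateau value inside the crop equals the value at its boundary radius.
The 0.25 s step was checked against the 0.1 s default (max ΔT changes by
far less than 0.5 %). Full-bore 360 s / 900 s solves on the whole phantom
use the 0.1 s default.

The sweep reproduces the expected exposure geography: gradient-only
heating is minimal with the implant near the isocenter and maximal at the
extreme axial positions (the ratio is ~30 for EPI at 60 s), identical
between the 1.5 T and 3 T configurations (bit-for-bit — the gradient
pathway has no static-field input); RF-only heating sits on its footprint
plateau when the implant is inside the coil and decays beyond the
roll-off; and the combined-exposure field never exceeds the sum of the
single-source fields once thermoregulation engages (concavity of the
perfusion response).

## Known limitations

* Quasi-static eddy solver: no skin-effect resolution; degrades above a
  few kHz for thick parts (monitored, warned).
* The RF deposition stand-in is non-physical for absolute dosimetry: no
  implant-field interaction, no standing-wave structure, frequency enters
  only as a scale.
* The phantom is geometric, not anatomical; masses above thresholds are
  indicative only.
* Sequence synthesis is moment-accurate, not Bloch-accurate; crushers and
  spoiler subtleties are schematic.
* Schedules are treated as unbounded repetitions of the acquisition
  pattern; exposure duration is the caller's choice (360 s and 900 s are
  the conventional evaluation points).
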