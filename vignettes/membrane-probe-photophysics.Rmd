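---
title: "Snapshot-based photophysics of a membrane probe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot-based photophysics of a membrane probe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probephase)
```

## The problem this package addresses

Diphenylhexatriene (DPH) is a rod-like conjugated fluorophore whose S1
transition dipole moment (tdm) lies along its long axis.  Embedded in a lipid
bilayer, its linear and non-linear optical responses depend on the phase of
the surrounding membrane — liquid-disordered (Ld, e.g. DOPC), solid gel (So,
e.g. DPPC) or liquid-ordered (Lo, e.g. a 2:1 sphingomyelin/cholesterol
mixture) — which makes the probe a reporter of membrane order and fluidity.

Multiscale studies of such probes produce *snapshot ensembles*: a few dozen
frames extracted from a membrane trajectory, each carrying excited-state
properties from an electronic-structure calculation (excitation energies,
transition dipoles, two-photon strengths, hyperpolarizability tensors)
together with geometric descriptors (probe depth, membrane normal, backbone
dihedrals).  This package is the analysis layer for such ensembles: it turns
per-frame records into spectra, cross sections, scattering responses,
lifetimes, anisotropy decays and conformer statistics.  A seeded synthetic
generator emulates the phase-specific statistics of the three membrane
environments so that every stage is testable end to end without a
quantum-chemistry or molecular-dynamics engine.

## Frame records

The unit of data is one `frame_record`: frame id and time, a phase label, a
unit membrane normal (lab +z by convention), the probe depth in nm (distance
of the probe's center of mass from the phosphorus plane), seven backbone
dihedral angles in degrees on (−180, 180], at least one excited state
(energy in eV, tdm in atomic units in the lab frame, two-photon strength
δ in au), and optionally static and dynamic (810 nm) first-hyperpolarizability
tensors (27 molecular-frame components, au).  Frames serialize to JSON Lines
at full double precision; round-trips are lossless to better than 1e-12
relative, and validation is total — every field has rejecting fixtures in the
test suite.  Transition dipoles are stored in the lab frame, which is the
frame the orientation analysis needs; imports from molecular-frame data must
rotate before writing records.

## One-photon absorption and photoselection

Each transition contributes an oscillator strength f = (2/3) ω |μ|² (atomic
units).  Ensemble spectra place a unit-area lineshape in *energy* space at
each state's excitation energy, scale it by f, average over frames, and map
to the wavelength grid with the Jacobian |dE/dλ| = hc/λ².  Consequently the
wavelength integral of the unweighted spectrum equals the ensemble-mean total
oscillator strength — an exact conservation law the tests enforce to 1e-6
with the Gaussian lineshape.  The default lineshape is Lorentzian with a full
width at half maximum Γ = 0.1 eV (the same width convention is used for
two-photon broadening); Γ is configurable.  The conservation check uses the
Gaussian shape deliberately: a Lorentzian's heavy ~Γ/E² tails leave of order
1e-6 of its area outside any physically meaningful grid, so tight quadrature
closure is a property only fast-decaying lineshapes admit — the law itself is
lineshape-independent.

Photoselection for excitation polarized along the membrane normal weights
each contribution by cos²θ, with θ the tdm angle to the normal.  Angles are
reported unfolded on [0, 180°] so that flip-flopped populations (θ and
180° − θ, the same physical orientation of a symmetric rod) remain visible
in orientation–wavelength correlation tables; cos² makes the fold immaterial
for the weights.  S2 and S3 are carried through the machinery even though
they are one-photon dark in the systems of interest.

## Two-photon absorption

The two-photon strength δ (au) converts to a peak cross section in
Göppert-Mayer units (1 GM = 1e-50 cm⁴ s/photon) via

σ(GM) = 8π² α² a0⁴ t0 · (ω/2)² · δ / Γ,

with ω the one-photon excitation energy and ω, δ, Γ in atomic units; a0⁴t0
carries the cm⁴·s dimension.  This is the single-Lorentzian-maximum
convention with Γ in the denominator; the constant assembly is pinned to
1e-6 relative against an independent SI evaluation built from CODATA values
in the acceptance tests.  σ is linear in δ and quadratic in ω.  Spectra are
reported on the two-photon wavelength axis (twice the one-photon wavelength)
with peak-normalized lineshapes, so a single frame's spectral peak reads its
own σ; the per-frame, per-state cross-section table accompanies every
spectrum.

## Hyper-Rayleigh scattering

The HRS response of an isotropically tumbling molecule is β_HRS =
√(⟨β²_ZZZ⟩ + ⟨β²_XZZ⟩), with lab-frame averages over molecular orientation,
and the depolarization ratio ⟨β²_ZZZ⟩/⟨β²_XZZ⟩.  Rather than transcribing
the published component formulas, the averages are evaluated from the exact
isotropic moments of the rotation group, valid for a *general* 27-component
tensor (no Kleinman symmetry assumed):

* ⟨β²_ZZZ⟩ = (1/105) Σ over the 15 pair-contractions of β⊗β (the rank-6
  isotropic moment of a uniform unit vector);
* ⟨β²_XZZ⟩ = (⟨|A|²⟩ − ⟨β²_ZZZ⟩)/2, where A_i(Z) = β_ijk Z_j Z_k and
  ⟨|A|²⟩ = (1/15)(Σ_i(Σ_j β_ijj)² + Σβ²_ijk + Σβ_ijk β_ikj), using the
  rank-4 moment and the uniformity of the lab X axis on the circle normal
  to Z.

These closed forms are exactly rotation invariant and reproduce the known
single-component limits (β_HRS/|β_zzz| = √(6/35), depolarization ratio 5).
An independent Monte-Carlo oracle — uniform random rotations drawn by the
quaternion method, explicit tensor rotation, sample averages with standard
errors — must agree with the analytic path within 3 standard errors on
batches of random tensors; this dual-route check is a mandatory test gate.
Values are reported in au and in 1e-30 esu (1 au of β = e³a0³/E_h² =
8.639e-33 esu).  The dynamic (810 nm) tensor is consumed as given; no
dispersion model is applied.  Frames without a dynamic tensor make the
dynamic report explicitly "not available" instead of failing.

## Radiative lifetime and its medium correction

The vacuum spontaneous-emission rate is Γ0 = (4/3)·|μ|²/(4πε0ħ)·(ω/c)³,
evaluated in SI after unit conversion.  In a medium of refractive index n
the photon-energy renormalization gives Γr = nΓ0, so τ = 1/(nΓ0): lifetimes
shorten by exactly 1/n, a law tested exactly alongside a 1e-9 agreement with
an independently assembled CODATA evaluation.  Default refractive indices
are 1.378 (DOPC), 1.789 (DPPC), 1.555 (SM/Chol 2:1), overridable per phase
through a YAML configuration.  Emission energies default to the stored
(absorption) S1 energies because the frame schema carries no excited-state
relaxation — a documented limitation: absolute lifetimes inherit whatever
Stokes shift the upstream data ignores.  Absorption and emission dipoles are
taken as parallel, appropriate for an effectively cylindrically symmetric
probe.  The ensemble display is the cumulative (running) mean of τ versus
frame index.

## Fluorescence anisotropy

With b the angle between a frame's S1 tdm and a reference dipole (first
frame by default; a fixed lab vector optionally), the emission intensities
are I∥ ∝ ω³μ²(1 + 2cos²b) and I⊥ ∝ ω³μ²(2 − cos²b), restricted to the
S1→S0 channel, and r = (I∥ − I⊥)/(I∥ + 2I⊥).  For a single emitting state
the ω³μ² factors cancel and r = 0.4·P₂(cos b) exactly (checked to 1e-12),
bounded by −0.2 (b = 90°) and 0.4 (b = 0).  Two modes are provided, and
recorded in every output because the decay shape depends on them:
instantaneous r per frame, or cumulative averaging of the intensities before
forming r.  The limiting anisotropy is the mean of r over the final third of
the trace by default (window configurable).

## The synthetic generator: what it emulates and what it does not

`builtin_preset()` encodes one preset per phase, 40 frames each, reflecting
the statistical structure such ensembles show:

* **DPPC (So)** — unimodal tdm orientation 36° ± 5° to the normal; S1 at
  346 ± 2.5 nm; depth uniform on 1.1–1.6 nm; lifetime 0.69 ± 0.02 ns;
  largest δ and β magnitudes.
* **DOPC (Ld)** — bimodal orientation (40°/140°, sd 8°, equal weights) with
  persistent lobe occupancy (Markov switch probability 0.1 per frame,
  emulating sporadic flip-flops); S1 at 336 ± 3 nm; depth 1.3–2.1 nm;
  lifetime 0.87 ± 0.03 ns; S1 nearly two-photon dark but S2 strong.
* **SM/Chol (Lo)** — main orientation 160° ± 6° plus a perpendicular
  subpopulation of exactly 8 of 40 frames (90° ± 1.5°) at consecutive
  indices 5–12; the broadest S1 distribution (337 ± 9 nm; the spread is a
  free emulation parameter, chosen so the Lo spectrum is visibly broader
  than the others); depth narrow at 1.10 ± 0.05 nm; lifetime uniform on
  0.7–1.2 ns; wandering outer dihedrals dh3/dh5/dh7 (sd 25°/70°/90°)
  while the other phases stay all-trans with ~5–6° jitter.

Orientations are realized by drawing the polar angle from the preset model
and an azimuth about the normal; because the frame sequence doubles as a
time series for the anisotropy analysis, azimuths carry per-phase memory —
a random walk with a 4° step in the gel phase (hindered rotation, so the
anisotropy plateaus high), 12° in Ld, and no memory in Lo.  The S1 dipole
magnitude is obtained by *inverting* the emission-rate law at the drawn
energy, lifetime and phase refractive index, so the emission stage recovers
the preset lifetimes by construction (closure within 5% at n = 40 is an
acceptance property).  Two-photon strengths and β scales are set so that the
ensemble means land in the experimentally meaningful decades for this class
of probe (tens of GM; units of 1e-30 esu, with the gel phase strongest and a
10× dynamic enhancement applied componentwise) — these are emulation
targets, not predictions.  The generator does **not** simulate lipid
dynamics, electrostatics, flip-flop kinetics or any real electronic
structure; passing closure tests shows the *analysis* is correct, not that
real membranes behave this way.

The wobbling-in-cone harness (`generate_cone_trajectory()`) provides
dynamics with a known answer: for 0 < S < 1 the dipole sits on the cone of
polar angle θ* with P₂(cos θ*) = S (cos θ* = √((2S+1)/3)) and performs
azimuthal Brownian motion; by the addition theorem the tail-averaged
anisotropy tends to 0.4·S² exactly, with vanishing variance once the azimuth
has wrapped many times.  S = 1 freezes the dipole (r ≡ 0.4); S = 0 switches
to isotropic rotational diffusion (r → 0).  The acceptance check uses
rate 20 rad²/ns, 6000 steps of 0.05 ns — tail fluctuations well under the
0.02 tolerance.

## Conformers and dihedrals

The signed torsion angle uses the standard atan2 formulation; it is
invariant under rigid motions and under reversing the atom order, and flips
sign under mirror reflection (all verified property-based).  Classification
uses a configurable cis/trans tolerance, default 30° — a conventional choice
midway between the basins.  The 2³ cis/trans codes over the three rotatable
designations group under end-for-end molecular symmetry (string reversal)
into 6 classes — palindromes singly degenerate, the rest doubly — with
degeneracies summing to 8; the implementation generalizes to k sites and is
tested against a brute-force orbit oracle.  Boltzmann populations use
k_B = 0.0019872 kcal·mol⁻¹·K⁻¹ with max-shifted exponentials for stability;
class energies are *input data* (torsional barrier profiles are consumed via
`torsion_profile()`, never computed here), so no specific population
percentages are claimed.  Per-dihedral summaries use circular statistics
(resultant-vector mean and spread), which the ±180° wrap of trans angles
makes mandatory.

## Numerical choices and degenerate inputs

* Γ is interpreted as FWHM for both lineshapes; lineshapes are unit-area in
  energy space (Lorentzian (Γ/2π)/((ΔE)² + (Γ/2)²), Gaussian with
  σ = Γ/(2√(2 ln 2))).
* Zero-length transition dipoles are flagged, not fatal, in orientation
  tables and lifetime records (infinite lifetime); they are an error in the
  anisotropy trace, where a direction is indispensable.
* Degenerate torsion geometries (coincident or collinear points) raise
  explicit errors.
* Angles are wrapped to (−180, 180] with 180 kept (trans), not mapped to
  −180.
* Monte-Carlo rotations are uniform over SO(3) via normalized quaternions;
  every stochastic routine takes an explicit integer seed and identical
  seeds give byte-identical outputs.
* Problem sizes in the shipped checks — 40-frame ensembles, 1e6-rotation
  oracle batches, 1e5-sample isotropic averages, 6000-step cone
  trajectories — were chosen as the smallest sizes at which the Monte-Carlo
  error bands above are comfortably resolved.

## Known limitations

* No non-radiative decay channels or quantum yields: "lifetime" always
  means the radiative lifetime.
* No Stokes shift: emission energies are the stored absorption energies.
* No dispersion model for the dynamic hyperpolarizability; the 810 nm
  tensor is used as supplied.
* No parsing of native quantum-chemistry outputs; the JSON-Lines schema is
  the import surface, and an adapter from program logs is a documented
  extension point.
* The mapping of conformer classes to specific energies requires external
  torsional data; the package supplies the combinatorics and the Boltzmann
  machinery only.
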