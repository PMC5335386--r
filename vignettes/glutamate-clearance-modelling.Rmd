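---
title: "Modelling glutamate clearance at hippocampal synapses with GluClear"
author: "GluClear authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glutamate clearance at hippocampal synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GluClear)
```

# The scientific problem

Astrocytic processes wrap excitatory synapses and carry a very high surface
density of glutamate transporters (~10,800 per µm²). How fast a synaptically
released glutamate quantum is cleared from the cleft and the surrounding
neuropil therefore depends on the local 3D arrangement of those processes:
how many there are, how much membrane they present, and how far they sit
from the postsynaptic density (PSD). Astrocytic PAR1 receptor activation
(e.g. with the TFLLR peptide) remodels this arrangement within minutes —
more, smaller processes at a larger PSD distance — and the question the
package addresses is whether such remodelling speeds or slows clearance,
and how that propagates to AMPA (GluA) and NMDA (GluN) receptor signalling.

GluClear provides the four computational instruments needed to study this
question without any wet-lab data:

1. a **geometry builder** producing triangulated synapse/astrocyte scenes
   with stated volumes, areas and PSD–astrocyte distances;
2. a **particle-based Monte Carlo reaction–diffusion engine** propagating
   individual glutamate molecules through those scenes, with stochastic
   transporter kinetics on astrocytic membranes;
3. **recording analyses**: deconvolution of astrocyte synaptic transporter
   currents (fSTCs) into glutamate clearance waveforms, and two-photon
   line-scan diffusion analysis (tortuosity, hydrodynamic diameter);
4. a deterministic **kinetic EPSC simulator** for receptor schemes with
   competitive antagonists.

A seeded synthetic-data module generates every input class these analyses
consume, with ground truth attached, so the whole pipeline is testable at
the desk.

# Simplified synapse scenes

`buildScene()` realises a `SceneSpec` as a set of watertight triangle
meshes inside a 1 µm³ reflective world box, with the synapse axis along +z
and the cleft centred at the origin:

* the presynaptic and postsynaptic terminals are spheres of the stated
  radii truncated at the cleft planes (cleft height 20 nm) and uniformly
  rescaled so their mesh volumes match the stated volumes exactly;
* the PSD is a flat disc with the stated area on the postsynaptic cleft
  face (placed 0.5 nm inside the cleft so it is not coplanar with the
  terminal mesh);
* astrocytic processes are thin (50 nm) curved sheets — cylindrical
  segments wrapped around the cleft axis, arranged symmetrically — each
  dimensioned so its total mesh area equals the stated per-process area,
  with the inner face at the stated nearest distance from the PSD. Sheets
  keep a preferred height (0.5 µm) and widen around the axis as the area
  grows; once neighbouring sheets would touch they grow vertically
  instead, so per-process areas across the observed range remain
  realisable inside the world box.

The source text states the scalar constraints but not the compartment
shapes, so the shapes above are this package's design choice; every stated
scalar (volumes, areas, distances) is reproduced within 1 % (distances
within 2 nm). Two published variants of the control/TFLLR astrocytic areas
exist (narrative: 2 × 0.69 µm² and 4 × 0.54 µm²; tabulated: 2 × 0.89 and
4 × 0.60 µm²). The package's default presets follow the narrative values;
`sceneSpec("control_table2")` and `sceneSpec("tfllr_table2")` provide the
tabulated variants. We do not attempt to reconcile the two.

Surface molecules are placed with a deterministic count,
`round(density × area)`, and area-weighted uniform positions. A Poisson
draw would add placement variance that the analyses never exploit; the
density is the specified quantity, and the deterministic count makes
placement exactly testable.

Meshing uses rings of vertices whose point counts double or halve with the
local circumference (target edge length 20 nm by default). This keeps
triangle sizes nearly uniform — no vertex accumulates a large triangle fan
— which both bounds the area/volume discretisation error (≤ 1 % at the
default resolution) and keeps the engine's spatial grid balanced.

The worked occupancy numbers deserve a note: summing the tabulated
compartment volumes gives an occupied volume fraction of ~0.19–0.21, while
the narrative quotes 18 %; with the package's sheet-shaped astrocytes
(volume fixed by area × 50 nm thickness) the built control scene occupies
~0.15. `occupiedVolumeFraction()` reports whatever the meshes actually
enclose; nothing is adjusted to force a published figure.

# Transporter kinetics

The astrocytic transporter is the three-state cycle: outward-facing free
(T), outward-bound (TG), inward-facing (Tin), with

* binding `T + Glu → TG` at k_on = 6 × 10⁶ M⁻¹ s⁻¹ (consumes a free
  glutamate),
* unbinding `TG → T` at k_off = 601 s⁻¹ (re-releases it),
* translocation `TG → Tin` at k_trans = 2,000 s⁻¹ (sequesters it), and
* reorientation `Tin → T` at k_reorient = 50 s⁻¹.

All rates are Q10-scaled (Q10 = 3) from the 25 °C recording temperature to
35 °C — one full factor of 3 — when `applyQ10 = TRUE`. Whether the
bimolecular binding rate should also be scaled is not settled; the package
scales it by default for consistency, and the scheme builder makes the
choice explicit and editable.

The steady-state affinity of this cycle is

$$K_m = \frac{(k_{off} + k_{trans})\,k_{reorient}}
             {k_{on}\,(k_{reorient} + k_{trans})},$$

which evaluates to 10.6 µM with the rates above — not the 13 µM quoted
alongside them. No standard steady-state expression reconciles the
(13 µM, 601 s⁻¹) pair, so the package keeps both numbers as independent
configuration entries: `apparentKm()` computes the cyclic value, and the
printed k_off wins over a re-derivation. The property linking them is
tested instead: the analytic cycle flux is hyperbolic in glutamate with
half-saturation exactly at `apparentKm()`.

Schemes are stored as plain YAML (`states`, `transitions`, `conducting`)
so receptor models from the literature can be supplied without touching
code. The packaged `ampa_generic_synthetic.yaml` is an order-of-magnitude
AMPA-like template, not a fit of any published model.

# The Monte Carlo engine

Each of the 2,000 released glutamate molecules takes per-axis Gaussian
steps with σ = √(2 D Δt), Δt = 10 µs, over 5,000 iterations (50 ms).
D is region-dependent and chosen by the particle's pre-step position:
3.3 × 10⁻⁶ cm²/s inside the cleft cylinder (radius = PSD radius, between
the terminal faces) and 1.41 × 10⁻⁶ cm²/s outside, the latter being the
published tortuosity-corrected value. The tortuosity budget
(λ = 1.6, λ_g = 1.48, λ_v = 1.38, λ_x = 1.11) is carried as metadata only:
the two printed diffusion coefficients are taken literally, since the
published combination rule is not recoverable and 3.3e-6/1.6² ≠ 1.41e-6.

Numerical choices, each pinned by a test:

* **Release**: on the cleft axis, 1 nm off the presynaptic face
  (`releaseMode = "point"`); a uniform mode exists for calibration runs.
* **Reflection**: all surfaces are reflective; the residual displacement is
  reflected specularly and iterated, with a safety cap of 10 reflections
  per step after which the particle keeps its last valid position and the
  event is counted (`@clamped`). In the 20-nm cleft a few per mille of
  steps hit the cap.
* **Binding**: each surface molecule owns a tile of area (mesh area /
  count). A trajectory segment crossing a triangle lands on a given
  population's tiles with probability (n · tile area / triangle area), and
  a landing on a free molecule binds with
  p = k_on′ √(π Δt / D) / A_tile. The constant follows from the one-sided
  crossing flux of per-step Gaussian rays — n √(D Δt / π) crossings per
  unit area per step from a uniform bulk — so that p realises the
  mass-action rate k_on′ n per molecule. The contract is not the formula
  but the calibration test: in a sealed box with k_trans = 0, the
  stochastic bound count must track the mass-action ODE within 5 %
  (in a regime where binding is slow compared with mixing across the box;
  at high wall densities the stochastic engine is *slower* than
  mass action because a genuine depletion layer forms — the physically
  correct behaviour, not a calibration error).
* **Unimolecular events** fire with per-step probability 1 − exp(−k_tot Δt)
  and branch proportionally to rates; unbound glutamate re-enters 1 nm off
  the surface along the face normal; translocated glutamate leaves the
  diffusing pool permanently.
* **RNG**: one self-contained PCG32 stream per seed, so a run is
  bit-reproducible from (scene, schemes, config, seed) alone, independent
  of R's RNG state.

Mass conservation (free-in-cleft + free-outside + bound + translocated =
2,000) is asserted at every recorded step by the `SimResult` validity
method, and a ray-casting audit checks that no particle ends inside a
solid compartment.

The headline in-silico result reproduces with this engine: the
PAR1-activated geometry (4 × 0.54 µm² sheets at 190 nm) clears both cleft
and neuropil glutamate faster than the control geometry (2 × 0.69 µm² at
116 nm), despite the larger PSD distance, because total uptake capacity is
~40 % higher; halving transporter density to 5,400 µm⁻² slows neuropil
clearance. The tests establish these orderings with one-sided t-tests over
30 seeds per condition at full problem size (2,000 molecules × 5,000
steps); summary statistics use the temporal centroid ⟨t⟩ = Σ t·n(t)/Σ n(t)
of the free-glutamate counts.

# Transporter-current analysis

The facilitated STC is isolated from interleaved single and paired
(100 ms interval) stimuli: the single response is subtracted from the
paired record, the residual second-pulse response is re-referenced to its
own stimulus, and the single-response template is subtracted once more, so
that the result is the facilitated excess (zero without facilitation).

The fSTC is fitted with a rising-phase × biexponential-decay product,

$$I(t) = A\,(1 - e^{-(t-t_0)/\tau_{rise}})\,
  (f\,e^{-(t-t_0)/\tau_{fast}} + (1-f)\,e^{-(t-t_0)/\tau_{slow}}),$$

by multi-start Levenberg–Marquardt with bounds (f ∈ [0,1],
τ_fast ≤ τ_slow by relabelling); the exponent on the rising term is fixed
at 1 but configurable. The exact published fit equation is not printed in
the source; this standard form is the package's choice, and its contracts
are self-consistency (exact recovery of model-generated data) and
Monte-Carlo robustness (median parameter error < 5 % at 1 % noise).

Clearance is recovered by the filter/deconvolution argument: an fSTC
recorded in sub-saturating TBOA (10 µM), where uptake capacity is low,
decays approximately like clearance itself, so modelling that trace as an
instantaneously rising biexponential and deconvolving it from the recorded
trace yields the recording filter; deconvolving the filter from the
control fSTC yields control clearance. Deconvolution is FFT division with
scalar Wiener regularisation, the noise floor estimated from the
pre-stimulus segment; negative excursions are rectified to zero before the
centroid is taken. A fit-based alternative
(`estimateClearanceFit()`) parameterizes clearance as a biexponential and
optimizes it through the convolution, avoiding frequency-domain division;
the two routes are cross-checked against each other on synthetic data. The regularisation contract is the round trip:
convolving the estimate with the filter reproduces the input within 5 %
RMS on synthetic data at SNR ≥ 20, and the clearance centroid is recovered
within 5 % at 1 % noise over 100 seeded repeats.

# Line-scan diffusion analysis

Fluorescence profiles are extracted every 150 ms from 625 Hz line scans,
with the average pre-puff profile subtracted to remove residual
fluorescence. Each profile is fitted with A·exp(−(x−x₀)²/γ²); the γ
convention is forced by the regression used downstream, γ²/4 versus time,
whose slope over a 2 s window is the diffusion coefficient (γ² = 4Dt for a
spreading point source). Because the profiles are baseline-subtracted, the
pipeline fits without a free additive offset — with wide late profiles the
offset and width are otherwise degenerate on a finite scan line — while
`fitGaussianProfile()` retains the free-offset form for raw profiles.
The regression is unweighted, profiles failing the Gaussian fit are
dropped, and at least 3 surviving profiles are required.

Tortuosity is λ = √(D_free/D*). The hydrodynamic diameter is the
Stokes–Einstein value d_H = kT/(3πηD) with T = 295 K and
η = 9.68 × 10⁻⁴ Pa·s; the analysis applies it to whichever coefficient is
passed — including the in-tissue apparent D*, which is unconventional but
matches the reported per-slice estimates (e.g. D* = 0.38 µm²/ms gives
1.17 nm).

# Kinetic EPSCs with competitive antagonists

`simulateEPSC()` integrates receptor-state occupancies with fixed-step RK4
(5 µs) under a glutamate transient with instantaneous rise and
monoexponential decay; the antagonist is a constant bath concentration,
and the initial state is the glutamate-free steady state under that
antagonist (bath pre-equilibration). Probability conservation is better
than 10⁻⁹ per run and halving the step changes peaks by < 0.1 %.

The block ratio (peak with antagonist / peak without) is evaluated over a
grid of transient peaks and decays (`blockContour()`); for a competitive
antagonist it is monotone non-decreasing along both axes, it matches the
Schild-type equilibrium form (1 + L/K_L)/(1 + L/K_L + B/K_B) within 2 %
for slow transients, and an iso-block level set (e.g. the experimentally
observed 0.29) can be extracted with `isoBlockLevel()`. Trains
(default 5 pulses at the 100 ms experimental paired-pulse interval; the
published train timing is not stated) report per-pulse peaks and the
summation index; with a desensitising scheme, smaller transients summate
closer to unity — the mechanism linking reduced glutamate transients to
increased EPSC summation.

# What the synthetic generators do and do not emulate

`synthFSTC()` constructs currents exactly as the analysis assumes them to
arise — clearance ⊗ filter, facilitation on the second pulse, additive
Gaussian noise — so recovery tests probe the analysis, not the biology.
Defaults are calibrated so the *fitted* fSTC decay matches the control
condition (τ_fast ≈ 5.3 ms, τ_slow ≈ 18.3 ms, 20–80 % rise ≈ 2.3 ms) with
a clearance centroid ≈ 16.5 ms; the filter is a gamma kernel (shape 2,
~2 ms time-to-peak), a shape the source does not specify — only round-trip
recoverability matters. `synthKymograph()` uses the analytic Gaussian
solution of an instantaneous point source placed 7 µm off the scan line
with Poisson photon noise; `synthSceneSpecs()` draws geometry fields from
truncated normals with the reconstruction means and SDs.

None of the generators emulate electrode artifacts, series-resistance
errors, drift, photobleaching, or correlated noise, and the engine has no
electrodiffusion, voltage dependence, or K⁺ dynamics (the sustained
K⁺-current window of `measureSustainedCurrent()` is measured, not
modelled). Passing tests therefore demonstrate correctness of the
computational machinery under the stated model assumptions, not robustness
to every artefact of real recordings.

# Problem sizes and runtime choices

The packaged experiment configuration (`fig4_quick.yaml`) and the test
suite run the three headline conditions at the full per-run size
(2,000 molecules × 5,000 steps × 10 µs) with 30 seeds per condition —
enough for the one-sided condition comparisons at α = 0.05, at roughly
3–4 s per seed on one CPU. Three hundred seeds, as used for the published
averages, simply sharpen the same means and can be requested through
`seeds:` in the configuration. Unit tests use reduced scenes (fewer
molecules, coarser meshes) chosen so each file runs in seconds;
calibration checks use the sizes at which their tolerances were derived
(10⁴ particles × 10³ steps for the Einstein-relation check, 100 repeats
for the deconvolution round trip).

# Known limitations

* Simplified compartment shapes are stylised (spheres, discs, sheets);
  reconstructed-mesh simulations are supported through OBJ import
  (`readMeshOBJ()`), but no tomogram processing is included.
* The cleft/neuropil diffusion-coefficient switch is a sharp boundary with
  no interfacial correction.
* The reflection cap (10 per step) clamps a small fraction of cleft steps;
  the count is reported per run and is not hidden.
* Receptor surface populations participate only through their scheme
  files; the packaged AMPA-like scheme is an illustrative template.
* The deconvolution regularisation is a scalar Wiener floor; heavily
  structured noise would call for a frequency-dependent noise model.
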