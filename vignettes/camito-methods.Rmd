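---
title: "Methods: the calcium-mitochondria model and its thermodynamic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the calcium-mitochondria model and its thermodynamic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`camito` implements a deterministic kinetic model of the cross-talk between
cytosolic Ca^2+^ signaling and mitochondrial energy metabolism, together
with a nonequilibrium thermodynamic analysis of the mitochondrial "engine".
Eighteen variables evolve in time: the cytosolic and mitochondrial adenine
nucleotides (ATP~c~/ADP~c~, ATP~m~/ADP~m~), the mitochondrial pyridine pool
(NAD^+^/NADH), the eight TCA-cycle intermediates (CIT, ISOC, αKG, SCoA,
SUC, FUM, MAL, OAA), free Ca^2+^ in the cytosol, mitochondria and ER, and
the inner-membrane potential ΔΨ. Seventeen processes connect them:

* **Ca^2+^ signaling** — ER release through IP~3~ receptors with biphasic
  Ca^2+^ regulation (activation at sub-micromolar, inhibition at higher
  Ca^2+^) plus a passive leak; SERCA uptake consuming one ATP per two
  Ca^2+; mitochondrial uptake by the uniporter (UNI, voltage-gated) and
  efflux by the Na^+^/Ca^2+^ exchanger (NCX, electrogenic, 3 Na^+^ per
  Ca^2+^).
* **TCA cycle** — eight enzymatic steps with literature rate laws;
  isocitrate dehydrogenase and α-ketoglutarate dehydrogenase are activated
  by mitochondrial Ca^2+^, which is the signal-to-metabolism arm of the
  cross-talk.
* **Oxidative phosphorylation** — six-state pump reductions for the
  respiratory chain (Ox, 10 H^+^ pumped per NADH) and the F~1~F~0~-ATPase
  (F1, 3 H^+^ per ATP), both driven by ΔΨ and the fixed pH difference.
* **Exchange** — the adenine nucleotide translocator (ANT), a proton leak,
  and bulk cytosolic ATP hydrolysis standing in for all other cellular
  ATP consumption. The metabolism-to-signal arm of the cross-talk is the
  ATP dependence of SERCA.

Five pools are conserved exactly by construction: the two adenine totals,
the pyridine total, the TCA-intermediate total, and the volume-weighted
cellular Ca^2+^ total. The conservation tests assert that numerical
trajectories keep them to better than 10^-6^ relative over 10^4^ s.

Units: concentrations in mM except the Ca^2+^ pools and IP~3~ (µM, with
the conversion factor γ = 10^3^ µM/mM in the Ca^2+^ balance equations);
ΔΨ in mV with F·ΔΨ in J/mol (F = 96.485 C/mmol); rates in mM/s; RT/F ≈
26.7 mV at T = 310 K. The ER release law multiplies a first-order rate by
a Ca^2+^ difference in µM and is divided by γ so that every flux is
numerically in mM/s; this is the only reading under which the uniform
f~c~γ prefactor of the Ca^2+^ equations is dimensionally consistent and
the ER release balances the mM/s SERCA flux at a physiological steady
state.

## The engine and its thermodynamics

For the thermodynamic analysis the eleven processes that interconvert
matrix metabolites and nucleotides (ANT, F1, Ox and the eight TCA steps)
are the *internal reactions* of an open chemical reaction network; the
remaining six (Ca^2+^ fluxes, proton leak, bulk hydrolysis) are external.
Twelve species are internal (only touched by internal reactions), twelve
are exchanged. On the resulting 24 x 11 stoichiometric matrix, computed in
exact rational arithmetic:

* the left null space has dimension 13 — the conservation laws, three of
  which (matrix adenine, pyridine, TCA carbon) survive in the open system;
* the right null space of the internal-species block has dimension 2 — the
  *emergent cycles*, normalized so the first produces exactly one
  cytosolic ATP and the second translocates exactly one proton. Their
  images on the exchanged species are the *effective reactions*: net ATP~c~
  synthesis from ADP~c~ and phosphate (the output), and fractional
  acetyl-CoA oxidation (the input), with coefficients such as 3/22 O~2~
  and 1/11 AcCoA per ATP.

Each reaction carries a transformed Gibbs energy Δ~r~G′ built from tabled
standard values (compartmental pH, ionic strength 0.12 M, pMg 3.4),
concentration logarithms on the mM scale, and F·ΔΨ terms for the
electrogenic steps; the translocator uses fixed pseudoisomer fractions
([ATP^4-^] = 0.05[ATP], [ADP^3-^] = 0.45[ADP]~c~ or 0.36[ADP]~m~). The
entropy production rate of the engine is Tσ̇ = -Σ J~κ~Δ~r~G′~κ~ over the
eleven internal reactions, reported on the model's volumetric scale
(mM/s × J/mol); the SI-strict value (÷10^3^) is exported alongside.

The nonconservative work rate splits into three parts along the effective
reactions: ẇ~r1out~ (free energy released by cytosolic ATP synthesis),
ẇ~r1in~ and ẇ~r2~ (free energy supplied by substrate oxidation and the
proton force). The driving work over one oscillation period is obtained
as the residual of the second law, ẇ~driv~ = ⟨Tσ̇ - ẇ~nc~⟩, because the
internal Gibbs energy is a state function and its variation integrates to
zero over a period; at a steady state this residual vanishes identically,
which doubles as the module's central cross-validation (two independent
code paths agree to 10^-8^ relative). The thermodynamic efficiency is

η = -ẇ~r1out~ / (ẇ~r1in~ + ẇ~r2~ + ẇ~driv~),

with numerator and denominator averaged separately over an integer number
of periods in oscillatory regimes.

## Design choices where the rate-law sources are ambiguous

Four structural readings of the printed rate laws are genuinely ambiguous
in their sources; each is exposed as a documented switch with the default
chosen by internal-consistency criteria, never by the downstream results
alone:

* `ares_sqrt` (default `TRUE`): the respiratory redox drive uses
  A~res~ = K~res~·sqrt([NADH]/[NAD]), the standard six-state reduction.
* `kgdh_form` (default `"product"`): in the α-ketoglutarate dehydrogenase
  denominator the Ca^2+^/Mg^2+^ activation divides the product of the
  substrate terms. The additive alternative leaves [αKG] comparable to
  [ISOC] at steady state and makes isocitrate dehydrogenase run *against*
  its own force (Δ~r~G′ > 0), violating the second-law consistency that
  the calibrated model must satisfy; the product form keeps every process
  dissipative.
* `ox_half` (default `FALSE`): the six-state respiration reduction is
  sometimes written with a leading 1/2. With the calibrated pump density
  ρ~res~ = 1.0 mM, including the 1/2 caps respiration ~30% below what the
  physiological ATP:ADP window requires at baseline (a flux-balance
  argument independent of any downstream target), so the default absorbs
  the factor into the calibrated density.
* `thermo_constants(r1out_phosphate)` (default `"cytosolic"`): the output
  effective force is the exact reverse of cytosolic hydrolysis,
  Δ~r~G′~r1out~ = +28300 + RT ln([ATP]~c~/([ADP]~c~[Pi]~c~)). The split
  ẇ~r1in~ = ẇ~r1~ - ẇ~r1out~ is exact by construction either way.

## Numerical choices

* Stiff integration (lsoda via a compiled right-hand side; an R reference
  implementation of every rate law is kept and tested against the
  compiled kernel to 10^-12^ relative). Default tolerances rtol 10^-8^,
  atol 10^-10^. States probed marginally below zero by the integrator are
  clamped; saturating denominators evaluate to their analytic limits at
  zero concentrations.
* The uniporter voltage factor x/(1-e^-x^) switches to a series for
  |x| < 10^-4^, making the flux continuous through ΔΨ = ΔΨ*.
* Exponentials of the voltage are clamped at e^700^; for |ΔΨ| ≤ 500 mV
  all expressions are evaluated exactly.
* Steady states: damped Newton on the 13-dimensional reduced system (the
  five conserved pools eliminated), numerical Jacobian, fallback to
  long-time integration; stability from the reduced Jacobian's
  eigenvalues.
* Classification: 5000 s transient discard, then peak detection on
  cytosolic Ca^2+^ with quadratic refinement and a prominence filter.
  Oscillatory means relative amplitude > 5% of the mean *and* inter-peak
  coefficient of variation < 2%; the horizon is extended (up to 4x) until
  at least 8 periods are resolved. Period-doubled cycles (alternating
  inter-spike intervals with nearly constant pair sums, which occur close
  to the oscillation onset) are folded to their true period. Anything
  still ambiguous is flagged `transient`, never silently classified.
* Period averages use trapezoidal integration with the window endpoints
  interpolated exactly onto the first and last refined peak times, so all
  averages run over an integer number of periods; this matters for the
  driving-work residual, which is of order 10^-4^ of the dissipation.
* Scans use continuation (each grid point starts from the previous
  attractor); bifurcation brackets are refined by bisection to 10^-3^ µM
  on request.

## The scenario generator

`baseline_scenario()` encodes the reference condition (acetyl-CoA 10 µM,
basal IP~3~ 0.1 µM). Variants: `inhibited_serca_variant()` (V~max~ 0.096
mM/s), `uncoupled_serca_variant()` (SERCA stripped of its ATP dependence
and of its ATP cost, bulk hydrolysis raised to 0.13 mM/s — deliberately
unphysiological, isolating the role of the coupling), and
`er_leak_variant()` (IP~3~-independent steady Ca^2+^ elevation).
`perturbation_realizations(n, seed)` multiplies each of the 18 leading
constants by an independent uniform draw from [0.9, 1.1]; realization *i*
under seed *s* always uses derived seed *s + i - 1*, so batches are
reproducible and single members re-generable. A published table of ten
such realizations ships as a plain-text fixture
(`sensitivity_realizations_table()`); its original column headers were
garbled, so columns were remapped by matching the reference row to the
reference constants (one entry, 0.1250 against kf~SL~ = 0.127, does not
match exactly and is preserved as printed). The generator emulates
parameter variability only; it does not emulate stochastic channel
gating, spatial Ca^2+^ microdomains, or pH dynamics, so passing tests
support the deterministic, well-mixed, clamped-pH regime and nothing
beyond it.

## What the pipeline reproduces, and known limitations

With the default configuration the package reproduces, from scratch (see
`scripts/acceptance.R` and the test suite): the exact topology (13 laws,
2 cycles, the printed fractional generators and effective reactions); a
basal steady state inside the physiological windows (ΔΨ ≈ 155 mV, total
ATP:ADP ≈ 3.2, basal Ca^2+^ ≈ 0.17 µM, every reaction dissipative); an
oscillatory window in IP~3~ at physiological substrate whose onset shows
a cusp-like rise of the efficiency, a maximum efficiency of ≈40% inside
the window, saturation of efficiency near 0.34 at strong stimulation, and
a period-averaged driving work below ~2×10^-4^ of the dissipation.

Known limitations, documented rather than hidden:

* The saturating total dissipation we compute (~4.0×10^4^ in the
  volumetric convention) exceeds the ~2.7×10^4^ scale reported for this
  system; the gap traces to the strong-stimulation exchange current
  (our plateau keeps a higher cytosolic Ca^2+^ and hence a larger SERCA
  ATP demand). No single reading of the ambiguous rate-law factors
  removes this gap without breaking the calibration windows.
* The substrate-limited oscillation regime (low acetyl-CoA at moderate
  IP~3~) exists in the model — ATP~c~ collapse makes SERCA ATP-limited
  and slow large-amplitude spiking appears — but its boundary sits near
  0.2-0.3 µM acetyl-CoA rather than ~5 µM, for the same respiration-scale
  reason. Consequently the period-ordering contrast between the coupled
  and uncoupled pumps at low stimulation is out of reach of this
  transcription.
* Attractors are not always unique: close to the oscillation onset
  (IP~3~ ≈ 0.30 µM at 10 µM acetyl-CoA) a stable focus coexists with a
  stable limit cycle, so the branch a scan reports there depends on the
  continuation direction. Away from onset the attractor is unique in all
  conditions we probed.
* The period-averaged driving work peaks at ~2.1×10^-4^ of the
  dissipation in the middle of the oscillatory window, slightly above the
  ~1.7×10^-4^ bound reported for this system.

## Problem sizes

The shipped tests integrate single attractors for 10^3^-10^4^ s of model
time (seconds of wall time through the compiled kernel), scan 10-20 grid
points per axis, and evaluate ten perturbation realizations; the
acceptance script uses a 58-point IP~3~ grid (step 0.02 µM) and a
10-point substrate grid. These sizes resolve every quantity the analysis
reports (periods to <1%, efficiencies to <0.1 percentage points, the
driving-work residual to ~10^-5^ of the dissipation).
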