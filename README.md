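# camito

Thermodynamic efficiency of calcium-regulated mitochondrial metabolism.

Cytosolic Ca²⁺ signals and mitochondrial ATP production regulate each
other: Ca²⁺ released from the ER activates two TCA-cycle dehydrogenases
(IDH, KGDH) and thereby boosts NADH supply, respiration and ATP synthesis,
while Ca²⁺ removal by SERCA pumps consumes cytosolic ATP. `camito` is for
researchers in computational cell biology and nonequilibrium biophysics
who want to quantify what this cross-talk does to the *energetics* of the
pathway, not just to its kinetics.

The package couples two things:

1. **A kinetic model** — 18 stiff ODEs for the adenine and pyridine
   nucleotide pools, the eight TCA intermediates, free Ca²⁺ in cytosol /
   mitochondria / ER, and the inner-membrane potential ΔΨ, driven by 17
   literature rate laws (IP₃-receptor release with biphasic Ca²⁺
   regulation, SERCA, mitochondrial uniporter and Na⁺/Ca²⁺ exchanger,
   Magnus–Keizer six-state reductions of respiration and the
   F₁F₀-ATPase, the adenine nucleotide translocator, a proton leak and
   bulk ATP consumption).

2. **A nonequilibrium chemical-reaction-network analysis** of the
   mitochondrial "engine" (the 11 internal reactions). In exact rational
   arithmetic the 24×11 stoichiometric matrix yields 13 conservation laws
   (3 unbroken) and 2 emergent cycles whose effective reactions are net
   cytosolic ATP synthesis (r1out), fractional acetyl-CoA oxidation
   (r1in), and proton translocation (r2). Each reaction carries a
   transformed Gibbs energy ΔᵣG′; the entropy production rate is
   Tσ̇ = −Σ Jκ ΔᵣG′κ, the nonconservative work splits along the effective
   reactions, the driving work over an oscillation period is the
   second-law residual ⟨Tσ̇ − ẇ_nc⟩, and the thermodynamic efficiency is

   η = −ẇ_r1out / (ẇ_r1in + ẇ_r2 + ẇ_driv),

   with numerator and denominator period-averaged separately in
   oscillatory regimes.

The headline behavior the pipeline reproduces: Ca²⁺ *oscillations*, set
off by stimulation (IP₃) or substrate limitation (acetyl-CoA), raise the
thermodynamic efficiency of mitochondrial ATP production — the efficiency
shows a cusp-like rise at the oscillation onset and a maximum of ≈40%
inside the oscillatory window, while a steady Ca²⁺ elevation of the same
magnitude (e.g. by an increased ER leak) does not.

## Worked example

```r
library(camito)

# basal conditions: acetyl-CoA 10 uM, IP3 0.1 uM
ss <- find_steady_state()
round(ss[c("ATPc", "ADPc", "NADH", "Cac", "CaER", "DPsi")], 3)
#>    ATPc    ADPc    NADH     Cac    CaER    DPsi
#>   2.767   0.233   0.078   0.173 138.636 154.972

work_ledger(ss)[, c("I_ATPc", "w_r1out", "w_r1in", "w_r2", "Tsigma", "eta")]
#>    I_ATPc   w_r1out  w_r1in     w_r2   Tsigma    eta
#> 1 -0.5178 -17956.12 44781.4 1394.115 28219.39 0.3889
```

The basal cell sits at ΔΨ ≈ 155 mV with a total ATP:ADP ratio ≈ 3.2 and a
basal cytosolic Ca²⁺ of ≈0.17 µM; the engine exports free energy through
cytosolic ATP synthesis at ẇ_r1out ≈ −1.80×10⁴ (mM/s × J/mol) against an
input of ≈4.6×10⁴, i.e. a steady-state efficiency of 39%, and every one of
the 17 processes dissipates (`thermo_audit(ss)`).

Stimulating the IP₃ receptors puts the cell in the oscillatory regime:

```r
ctrl <- mito_controls(IP3 = 0.35)   # uM
tr0 <- simulate_model(seq(0, 20000, 2000), init = ss, ctrl = ctrl)
s1  <- unlist(tr0[nrow(tr0), state_names()])
tr  <- simulate_model(seq(0, 12000, 0.25), init = s1, ctrl = ctrl)
(cm <- classify_and_measure(tr, transient = 0))
#> <oscillation_summary>
#>  regime: oscillatory
#>  period: 293.53 s (se 0.037, cv 0.0008, 40 periods)

period_work_ledger(tr, cm, ctrl = ctrl)[
  , c("w_r1out", "w_r1in", "w_r2", "w_driv", "Tsigma", "eta")]
#>     w_r1out   w_r1in     w_r2 w_driv  Tsigma    eta
#> 1 -21009.28 50765.28 1552.819 1.6743 31310.5 0.4016
```

Ca²⁺ spikes between 0.16 and 1.2 µM with a 294 s period; the
period-averaged efficiency rises to 0.40, and the driving work — the free
energy injected by the time-dependence itself — is only ~5×10⁻⁵ of the
dissipation. Scans chain into the tidyverse:

```r
sc <- scan_parameter("IP3", seq(0.05, 1.2, by = 0.05))
glance(sc)                       # efficiency maximum and its location
autoplot(sc)                     # eta vs IP3, regimes as point shapes
plot_efficiency_dissipation(sc)  # eta vs total dissipation
```

`scenarios` cover the structural variants (`uncoupled_serca_variant()`,
`inhibited_serca_variant()`, `er_leak_variant()`) and seeded ±10%
perturbations of all 18 leading constants
(`perturbation_realizations(n, seed)`).

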