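# relaxfit

Backbone ¹⁵N relaxation analysis for solution NMR: exponential rate
fitting, heteronuclear NOE, reduced spectral density mapping, rotational
diffusion-tensor estimation, and Lipari–Szabo model-free fitting with
five-model selection — plus chemical-shift-perturbation mapping and the
coordinate utilities (NH vectors, ensemble RMSD, B-factor value maps) that
a backbone-dynamics study needs around them.

It is written for NMR spectroscopists characterizing the ps–ns and µs–ms
dynamics of small proteins — the motivating system is a monomeric
flavodoxin-like protein of ~150–180 residues observed at 800 MHz, whose
cofactor-binding loops trade conformational exchange for rigidity upon
ligand binding.

## The model

Relaxation of a backbone ¹⁵N spin is driven by reorientation of its N–H
bond, summarized by the spectral density

J(ω) = (2/5) Σₖ Aₖ [ S² τₖ / (1 + (ωτₖ)²) + (Sf² − S²) τ′ₖ / (1 + (ωτ′ₖ)²) ],

where the τₖ and amplitudes Aₖ(θ) describe global tumbling (one term for
isotropic diffusion; three, weighted by the N–H/unique-axis angle θ, for an
axially symmetric tensor with anisotropy D∥/D⊥), S² and Sf² are the
generalized and fast-limit order parameters, and 1/τ′ₖ = 1/τₖ + 1/τe with
τe the internal correlation time. The observables at a given field are

- R1 = (d²/4)[J(ωH−ωN) + 3J(ωN) + 6J(ωH+ωN)] + c²J(ωN)
- R2 = (d²/8)[4J(0) + J(ωH−ωN) + 3J(ωN) + 6J(ωH) + 6J(ωH+ωN)] + (c²/6)[4J(0) + 3J(ωN)] + Rex
- NOE = 1 + (d²/4R1)(γH/γN)[6J(ωH+ωN) − J(ωH−ωN)]

with dipolar and CSA constants d², c² built from r_NH = 1.02 Å and
Δσ = −160 ppm (both configurable, both recorded in output headers). The
analysis inverts these relations three ways: model-free fitting over the
standard ladder M1 (S²), M2 (S², τe), M3 (S², Rex), M4 (S², τe, Rex),
M5 (Sf², S², τe); reduced spectral density mapping onto J(0), J(ωN),
J(0.87 ωH); and R2/R1-based diffusion-tensor estimation with
isotropic-vs-axial selection whose F-test null is calibrated by parametric
bootstrap (the axis orientation does not exist under the isotropic null, so
the analytic F reference is anticonservative).

A seeded synthetic-data generator emulates the full study — rigid core
(S² ≈ 0.88), flexible termini, loops, exchange patches with Rex up to
15 s⁻¹, apo/holo peak lists with loop-concentrated missing residues — so
every stage is testable with no downloads.

## Worked example

```r
library(relaxfit)

fs  <- field_spec(800)
cst <- dipolar_csa_constants(fs)            # r_NH = 1.02 A, CSA = -160 ppm

## simulate a 150-residue protein: tau_m = 8 ns, D_par/D_perp = 1.15
scn   <- scenario(n_residues = 150, seed = 20)
tpl   <- make_template(scn)
truth <- assign_dynamics(tpl, scn)
sim   <- simulate_relaxation(truth, tpl, scn)

## diffusion tensor from rigid-residue R2/R1
sub <- select_rigid_subset(sim$records)
axi <- fit_axial_tensor(sub, tpl$nh, cst)
round(c(tau_m = axi$tensor$tau_m, ratio = axi$tensor$ratio), 3)
#> tau_m ratio
#> 7.971 1.153
```

The recovered correlation time (7.971 ns vs the generating 8 ns) and
anisotropy (1.153 vs 1.15) come from 110 rigid residues; the flexible
termini, loops and exchange-broadened sites were removed by the NOE cutoff
and the iterative R2/R1 trim. Fixing this tensor and running

```r
res <- modelfree_table(sim$records, scn$tensor, tpl$nh, cst, n_mc_crit = 100)
print(summarize_models(res)$table, digits = 3)
#>   model   n mean_S2  sd_S2
#> 1    M1 100   0.876 0.0329
#> 2    M2  27   0.733 0.1759
#> 3    M3   6   0.881 0.0424
#> 4    M4   4   0.877 0.0447
#> 5    M5  12   0.593 0.1573
```

One hundred residues sit in the simplest model M1 with mean S² = 0.876 —
the rigid core — while the flexible termini land in the two-timescale
model M5 with mean S² ≈ 0.59 and the exchange patch splits between M3 and
M4 with fitted Rex values.

assigns each residue to the simplest model its data justify and summarizes
per-model counts and mean S², the quantities a backbone-dynamics paper
reports. `run_pipeline()` (or `inst/scripts/relaxfit-pipeline.R` from a
shell) chains simulate → fitrates → jmap → tensor → modelfree → csp →
report into delimited-text artifacts whose headers carry the resolved
configuration and input hashes; identical config and seed give
byte-identical outputs.

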