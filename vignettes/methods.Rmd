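---
title: "Methods: backbone 15N relaxation analysis in relaxfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backbone 15N relaxation analysis in relaxfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`relaxfit` implements the standard single-field backbone dynamics workflow
for ¹⁵N relaxation: peak-intensity decays are fitted to single
exponentials to give R1 and R2, saturated/reference intensity pairs give
the steady-state heteronuclear NOE, and the triple (R1, R2, NOE) per
residue is then inverted three complementary ways — reduced spectral
density mapping, rotational diffusion-tensor estimation, and Lipari–Szabo
model-free fitting.

The physical core is the model-free spectral density. Internal motion is
condensed into an order parameter S² (amplitude of ps–ns motion, 1 =
rigid), an effective internal correlation time τe, and optionally a
fast-limit order parameter Sf² for two-timescale motion; micro- to
millisecond exchange appears only as an additive R2 contribution Rex.
Global tumbling is either isotropic (τm) or axially symmetric
(τm, D∥/D⊥, unique-axis orientation), in which case each residue's
spectral density mixes three Lorentzian lobes with amplitudes set by the
angle between its N–H bond and the unique axis. Assumptions inherited from
this formalism: motions are statistically independent of tumbling, the
molecule is a single rigid rotor (no domain motion), relaxation is purely
dipolar + axially symmetric ¹⁵N CSA, and all data come from one field.

Angular frequencies are carried in rad/s internally; the interface uses ns
for τm and ps for τe, converted once at the boundary. The ¹⁵N
gyromagnetic ratio is carried with its negative sign; it is what makes
NOE < 1 (and strongly negative for very mobile residues) and what places
the weight-6 double-quantum term at |ωH + ωN| ≈ 0.90 ωH.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| r_NH | 1.02 | Å | community-standard amide bond length; recorded in all output headers |
| Δσ (¹⁵N CSA) | −160 | ppm | community standard; c² scales with the square of the field |
| NOE cutoff (rigid subset) | 0.65 | — | removes residues whose R2/R1 is biased by fast internal motion |
| MAD trim multiplier | 3.0 | — | iterative removal of exchange-broadened R2/R1 outliers |
| α (all selection tests) | 0.05 | — | the conventional 95% confidence ladder |
| CSP nitrogen weight | 1/5 | — | dominant literature scaling of ¹⁵N onto the ¹H shift range |
| CSP class edges | 0.1, 0.5 | ppm | strict inequalities; boundary values are `intermediate` |
| Monte-Carlo refits (rates) | 500 | — | uncertainty of exponential fits |
| Monte-Carlo simulations (selection) | 100–300 | — | critical values and parameter errors |

Both physical constants are configurable; results reproduced from deposited
data can shift by a few percent under different r_NH/CSA conventions, which
is why every artifact header records them.

# Rate fitting

`fit_exponential()` fits I(t) = I₀·exp(−R·t) with the amplitude profiled
out in closed form, leaving a 1-D search in R that cannot diverge, followed
by a Levenberg–Marquardt polish for full precision. There is deliberately
no baseline term: a two-parameter single exponential is the model
throughout. Duplicate delays are kept as independent points, and when no
noise estimate is supplied the pooled variance of replicate-delay
intensities provides one. Uncertainties come from seeded Monte-Carlo refits
(default 500) rather than the asymptotic covariance — robust to the short,
duplicated delay grids used in practice. A decay statistically
indistinguishable from constant is returned with a flag, not an error.

# Reduced spectral density mapping

The three observables are mapped onto J(0), J(ωN) and J(0.87 ωH) under the
usual assumption that J(ω) ∝ 1/ω² above ωH − ωN. The combination
coefficients are *computed from the field's exact frequencies* at run time
rather than hard-coded: the familiar rounded constants (the 5 in
(4R1 − 5σ)/(3d² + 4c²), the 2.72 in the J(0) numerator, the 0.870 itself)
emerge to three digits at the ¹⁵N/¹H frequency ratio, and the package's
tests validate the mapping against a numerical-quadrature oracle via
forward-model round trips rather than against any literature constant.
Exchange contaminates only J(0) — which is precisely why the J(0) ladder
and the R2·R1 / R2/R1 indicators are useful exchange detectors. Exchange
flagging uses the trimmed mean (10%) plus 1.5 standard deviations, with
the SD taken over the *untrimmed* sample: trimming protects the centre
estimate from the outliers being sought, while the full-sample SD keeps
the threshold conservative.

# Diffusion tensor

The tensor is estimated from R2/R1 of a rigid subset only (NOE ≥ 0.65,
then iterative 3·MAD trimming of R2/R1; if the MAD degenerates to zero the
sample SD substitutes so isolated outliers are still caught). R2/R1 is
nearly independent of S² for rigid residues, so the fit reports on
tumbling alone. The axial fit is two-phase: a Fibonacci grid of candidate
axes on the upper hemisphere scored at fixed (τm, ratio), then Nelder–Mead
refinement of all four parameters from the best candidates. Axial tensors
are directionless; fitted axes are canonicalized to θ ∈ [0, π/2].

Model selection between isotropic and axial uses
F = [(χ²iso − χ²ax)/3] / [χ²ax/(n−4)]. The axis angles exist only under
the alternative, so under the isotropic null the likelihood-ratio
statistic is a supremum over the axis sphere and is stochastically larger
than χ²₃ — the analytic F(3, n−4) reference rejects the isotropic model
far too often. `tensor_model_selection()` therefore calibrates the null by
parametric bootstrap (default 40 simulations of the ratios from the fitted
isotropic model, both models refitted), the same philosophy as the
Monte-Carlo critical values in model-free selection; the analytic
reference remains available when no calibration data are passed.

# Model-free fitting and selection

Each residue is fitted over the five-model ladder with the tensor fixed
(two-stage protocol; no global re-iteration by default, since a single
tensor is the reported quantity). Numerical choices:

- Rex enters R2 linearly and nothing else, so for M3/M4 it is profiled
  out in closed form (R̂ex = max(0, R2obs − R2calc)), reducing every fit to
  at most three search dimensions and making noiseless M3 recovery exact.
- M5 is parametrized as S² = Sf²·Ss² with both factors in [0, 1], so the
  constraint S² ≤ Sf² is structural rather than penalized.
- Fits are initialized by coarse grid search and refined by bounded
  L-BFGS-B with a Nelder–Mead polish; bounds are 0 ≤ S² ≤ Sf² ≤ 1,
  0 ≤ τe ≤ τm, Rex ≥ 0, and fits pinned at a bound are flagged.

Selection is staged. M1 is accepted if its χ² passes a goodness-of-fit
test whose critical value comes from seeded simulations of Gaussian noise
around the M1 fit — at 0–2 degrees of freedom with bounded parameters,
analytic χ² quantiles are unreliable. Otherwise M2 and M3 are tested by
F-statistic improvement over M1, each against its own simulated null from
the same noise draws. M4 and M5 have zero degrees of freedom at a single
field and are last resorts: accepted only when everything simpler is
rejected, the lower residual norm breaking the tie, and flagged through
`dof = 0`. When even the zero-dof models leave residuals above the
noise-derived critical level the residue is reported `unfit`, mirroring
how experimental studies leave some residues unanalyzed. The simulation
fits run on dense parameter grids evaluated through single vectorized
forward-model calls, which is what keeps per-residue selection at a few
hundred simulations affordable.

# Chemical shift perturbation

Δδcomp = √(ΔδH² + (ΔδN/5)²), the conventional scaling of the nitrogen
range onto the proton range; the weight is configurable and recorded in
outputs. Classification uses strict inequalities (< 0.1 small, > 0.5
large), so exact boundary values fall in `intermediate`. Residues present
in the holo list but absent in apo are a first-class category
(`missing_in_apo`) because in exchange-broadened systems missingness *is*
the signal.

# Structures

PDB I/O goes through bio3d. "Backbone" means N, Cα, C′ (O optional) —
deliberately minimal, since carbonyl inclusion is convention-dependent.
Superposition is Kabsch SVD with the reflection branch rejected;
ensemble-vs-ensemble comparisons default to representative model 1 of
each, with mean-pairwise RMSD available separately, because published
ensemble RMSD protocols frequently leave this unstated. For structures
without amide protons, ideal H placement uses the planar bisector of the
C′(i−1)–N and Cα–N directions at 1.02 Å; affected residues are logged.
Value maps write per-residue quantities into the B column, clamped to the
fixed-width range with a warning, with a sentinel (recorded in a REMARK)
for unmapped residues.

# The synthetic generator: what it does and does not emulate

`scenario()` defaults describe the study conditions: a 150-residue
monomeric protein at 800 MHz, τm = 8 ns, D∥/D⊥ = 1.15, a rigid core with
S² ~ N(0.88, 0.03²), two flexible loops (M2; τe 20–200 ps), flexible
termini (M5; S² 0.3–0.7, τe 0.5–2 ns, Sf² 0.75–0.9 — the fast-limit range
is the package's choice, as two-timescale termini need Sf² below 1 but
well above S²), and a binding-loop exchange patch (M3/M4, Rex 2–15 s⁻¹).
Noise defaults are 2% on rates and 0.02 absolute on NOE, the precision
regime implied by the tight tensor uncertainties such studies report.
Decay series use the duplicated 12-point R1 and R2 delay grids of the
motivating experiments, with intensity noise at 2% of the initial
amplitude. CSP simulation draws class-dependent shift changes and
missingness concentrated at the exchange patch and loops (~30% of the
chain missing overall).

What it does not emulate: peak overlap and integration errors, field
inhomogeneity, anisotropic CSA, rotamer exchange, correlated noise between
R1 and R2, or real residue-specific chemistry. Passing tests therefore
demonstrate that the estimators are correct and calibrated under the
stated noise model — not that real spectra of comparable quality will
yield errors this small.

# Problem sizes

The test suite and `scripts/acceptance.R` use 150–200-residue scenarios,
500 decay series for rate-bias/coverage checks, 50 replicates per tensor
kind for selection accuracy (12 per kind in the faster acceptance script),
100–200 residues per model-free recovery check with 100 selection
simulations per residue, and 200-draw parameter sweeps against the
quadrature oracles. These sizes were chosen so each property is measured
with comfortable statistical margin while the full suite stays fast enough
to run routinely.

# Known limitations

- Single-field data only; Rex is field-attached and not scaled, and M4/M5
  are unverifiable (zero dof) at one field.
- No rhombic (fully anisotropic) diffusion; proteins with three distinct
  principal values will be approximated by the nearest axial tensor.
- The two-stage protocol does not iterate tensor and internal parameters
  to self-consistency; with a rigid, exchange-trimmed subset the effect is
  small, but it is a documented simplification.
- Reported Monte-Carlo uncertainties reflect the stated measurement noise
  only, not model misspecification.
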