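---
title: "Measuring platelet contraction force with a torsion-beam MEMS sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring platelet contraction force with a torsion-beam MEMS sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotforce)
```

## The measurement problem

When a blood clot forms, the platelets inside it contract along fibrin
strands and the clot as a whole pulls on whatever it is attached to. That
contractile force is the mechanical output of the platelet actomyosin motor,
which is gated by phosphorylation of the myosin regulatory light chain (MLC):
a kinase (MLCK) phosphorylates MLC and a phosphatase (MLCP) removes the
phosphate, and a cascade of upstream effectors converges on that pair.

`clotforce` analyses data from a silicon clot contraction sensor (CCS): a
4 mm platform suspended from its frame by sixteen rectangular torsion beams.
A clot formed between two plates pulls the platform down; a camera tracks
the deflection, and force follows from Hooke's law, `F = k x`. The package
covers four layers:

1. **Suspension mechanics** — from beam geometry and material to the chip
   spring constant `k`, plus calibration-linearity scoring.
2. **Trace pipeline** — displacement traces to force traces to per-sample
   contraction summaries.
3. **Phosphorylation assays and statistics** — ELISA pMLC normalisation,
   the study's percent-change convention, group summaries, and the
   force-versus-pMLC regression.
4. **Signalling model** — a signed directed graph of the MLCK/MLCP cascade
   that predicts the direction of pMLC change under each reagent.

A synthetic-data generator stands in for blood samples (none are publicly
deposited), so every stage is exercised end to end by code alone.

## Torsion-beam mechanics

Each beam of length $L$ with rectangular cross-section $a \times b$
($a \ge b$) has torsional constant $J = \beta a b^3$, where the shape factor
is computed from the standard closed-form approximation

$$\beta = \tfrac{1}{3} - 0.21 \tfrac{b}{a}\left(1 - \tfrac{(b/a)^4}{12}\right),$$

validated in the test suite against the classical Saint-Venant series
solution (agreement is better than 0.2% for aspect ratios 1–10, far inside
the 0.5% we require). For the chip's 680 × 50 × 10 µm beams, $\beta = 0.291$.

The angular form of Hooke's law is $\tau = \kappa\,\theta$ with torsion
stiffness $\kappa = G J / L$. (One sometimes sees this relation typeset
upside-down as $L/(GJ)$, which is dimensionally inconsistent with
$\tau = \kappa \theta$; only $GJ/L$ reproduces a ~100 N/m chip from this
geometry, so that is what the package implements.) $G$ is the shear modulus,
configurable with a default of 50.9 GPa for silicon. Silicon is anisotropic
(roughly 50–80 GPa depending on crystal orientation); since the connection-arm
length is solved to meet the target spring constant, the arm absorbs whatever
value is chosen.

A platform displacement $x$ twists every beam by $\theta = x/C$ through the
rigid connection arm of length $C$ (the kinematic relation is
$x = C\sin\theta$; at the chip's working range $x/C \le 0.25$ the small-angle
error in force is below a percent, and below $10^{-4}$ at $x/C = 0.01$, which
the tests verify against the exact kinematics). The stored energy is
$U = \tfrac{n}{2}\kappa (x/C)^2$ for $n$ beams, so the platform spring
constant is

$$k = \frac{n\,\kappa}{C^2}.$$

The composition assumes all beams twist equally and arms/anchors are
perfectly stiff. Its inversion, `solve_arm_length()`, gives the arm length
meeting a target `k`:

```{r design}
ccs_design(680, 50, 10, k_target = 100)
```

The arm length is not itself reported for the physical device, and neither is
the silicon orientation, so "approximately 100 N/m" is under-determined as an
exact reproduction; the design report shows one self-consistent solution
(C ≈ 418 µm) and the round trip through `effective_spring_constant()` is
exact by construction. We take the sixteen-beam layout (four arms of four
beams) as the device description; where a figure caption loosely speaks of
"four beam springs" it is counting arms.

**Calibration linearity.** The instrument is validated by deflecting the
platform 0–100 µm with a nanoindenter. "Linearity" is not given a formula in
assay reports; we define the score as $100 \times R^2$ of the
ordinary-least-squares fit of force on deflection, with a max-residual
alternative (`metric = "max_residual"`) for users who prefer a worst-case
measure. Chips of 5, 100 and 300 N/m are all supported; scores for the
synthetic calibration generator land in the reported 96–99% band.

## From displacement to contraction summaries

`to_force_trace()` applies `F = k x` pointwise (with `k` in N/m and `x` in
µm, `F` is directly in µN). Deflections slightly below zero are tolerated
down to a configurable −1 µm (thermal drift and tracking jitter); anything
lower is treated as corrupt data rather than silently clamped.

`max_contraction_force()` reports the maximum of a moving-average-smoothed
force series. The camera signal's filtering is not documented, so smoothing
is our choice: a centred 30 s window, wide enough to suppress single-sample
noise spikes but narrow against the ~300 s rise time of the contraction
curve; `smooth_window = 0` disables it. Because the maximum of a smoothed
noisy plateau sits slightly above the true plateau (extreme-value bias of
order the smoothed noise SD, ~10–20 µN at default noise), the plateau
estimate (mean of the final 10% of samples) is also available via
`statistic = "plateau"` — whether an instrument's "max force" means the raw
maximum or a plateau estimate is ambiguous, so both are reported.
`contraction_kinetics()` adds a lag time (first crossing of 5% of maximum)
and time to half-maximum (50%); the 5% and 10% fractions are conventions
exposed as arguments, not measured properties.

## Percent changes, group summaries, correlation

Group summaries use the mean ± sample SD (and median/IQR with type-7
quartiles) per condition. Percent change versus control follows a deliberate,
non-standard convention:

- increases are expressed relative to the **treated** mean:
  $+100\,(t - c)/t$;
- decreases relative to the **control** mean: $-100\,(c - t)/c$.

This is the only reading that reproduces both published force changes
(7337 vs 2958 µN printed as "60% higher", and 922 vs 2958 µN printed as
"69% lower"), so the package adopts it throughout for comparability — note
that both directions are therefore bounded by 100%, and the convention is
globally antisymmetric under swapping the two means (the larger mean is
always the denominator). `fit_force_phospho()` regresses per-condition mean
pMLC on per-condition mean force by OLS and reports slope, intercept and
$R^2$.

## ELISA normalisation

The in-cell ELISA reads OD450 for phosphorylated MLC and total MLC wells per
condition. The kit's exact normalisation is not published, so we use the
standard ratio form:

$$\text{pMLC ratio} = \frac{\overline{OD}_{pMLC} - \overline{OD}_{blank}}
                            {\overline{OD}_{totalMLC} - \overline{OD}_{blank}},$$

with well aggregation by mean (plates here have few replicate wells) and a
below-background error when the denominator is not positive. Percent changes
are computed on these ratios rather than raw pMLC ODs — the ratio cancels
seeding density and gain, which is also what makes the measure comparable
across conditions. Blot lanes are quantified as pMLC intensity over the
β-actin loading control by default, with total-MLC normalisation as an
option.

## The signed signalling network

`build_default_network()` encodes the cascade as a directed graph whose
edges carry +1 (activation) or −1 (inhibition): the kinase arm
Ras → RAF-1 → MEK → ERK → MLCK plus calcium–calmodulin → MLCK; the
phosphatase arm MLCP ⊣ pMLC, inhibited by CPI-17 (driven by PKC) and by
ROCK (driven by RhoA, itself activated by RAF-1, calcium and TNFα); PKC
activated by PLC, inhibited by PKG; PKG raised by nitric oxide and lowered
through the prostacyclin arm PGI₂ → cAMP → PKA → PDE5 ⊣ PKG (PDE5 degrades
the cGMP that sustains PKG — where the cascade diagram's prose is ambiguous
about intermediate signs in this sub-chain, we follow the explicit sildenafil
chain PDE5 ⊣ cGMP/PKG ⊣ PKC, and flag the sub-chain as the least certain part
of the encoding). The PKC → ERK feedback is encoded as a forward edge; no
cyclic dynamics are simulated — prediction is static sign propagation on an
acyclic graph. Calcium's dual role (calmodulin arm and RhoA activation) is
retained as two outgoing edges of the calcium–calmodulin node.

A reagent perturbation binds one node with a mode (±1); its predicted effect
on pMLC is the mode sign times the product of edge signs along each simple
path to the sink, and the prediction is *up*/*down* when all paths agree,
*ambiguous* otherwise.

```{r network}
ccs_predict_directions()
```

Seven of the eight reagents are concordant with the measured directions.
Sildenafil is the documented exception: as a PDE5 inhibitor the cascade
predicts lower pMLC, but the measured force and pMLC go up — candidate
explanations (lower fibrinogen, pMLC-force uncoupling, ATP-driven secondary
activation) lie outside a static sign model, and we deliberately keep the
mismatch visible rather than patching the graph.

## What the synthetic generator emulates — and what it does not

The generator is the package's stand-in for blood samples and defines the
conditions everything is tested under:

- **Contraction traces.** A lagged logistic deflection curve re-anchored to
  start at zero,
  $x(t) = \frac{F_\infty}{k}\,
  \frac{\sigma((t-t_{1/2})/\tau) - \sigma(-t_{1/2}/\tau)}
       {1 - \sigma(-t_{1/2}/\tau)}$,
  plus Gaussian deflection noise. The published force curve is shown but not
  parameterised, so the shape is our choice; defaults $t_{1/2} = 900$ s,
  $\tau = 300$ s, noise 0.2 µm, one-hour assay sampled every 5 s (721 points).
  Re-anchoring shifts the half-max crossing slightly past $t_{1/2}$ (~930 s at
  the defaults). A zero plateau gives the flat no-clot (no-calcium) trace.
- **Condition table.** Control 2958 ± 373 µN, U46619 7337 ± 1408 µN, Cpd7a
  922 ± 504 µN as reported; the other six means are back-computed from the
  reported percent changes under the percent-change convention (e.g. ML-7 =
  2958 × (1 − 0.535)), and are *derived, not printed*. Their SDs are likewise
  unpublished and set once to the control group's CV (≈12.6%) times the mean.
  Per-subject plateaus are drawn from a zero-truncated normal; subjects share
  kinetics and differ only in plateau (whether real subjects also differ in
  kinetics is unknowable from the published data).
- **Calibration.** Evenly spaced deflections over the stroke with Gaussian
  force noise, default SD 4% of full scale — chosen so a 50-point series
  scores in the reported 96–99% linearity band, for any chip stiffness.
- **ELISA plates.** Control ratio fixed at 1; each condition's ratio is the
  exact inversion of its configured percent effect, so at zero noise the
  round trip is exact; wells carry mean-one multiplicative log-normal noise
  (default CV 5%).

What it does **not** emulate: fibrin-network viscoelasticity, single-platelet
force scales, inter-subject kinetic variability, plate-edge effects, or any
mechanistic link between the force and pMLC arms (their correlation arises
only from the configured condition effects). Passing round-trip tests
therefore demonstrates that the pipeline is unbiased and internally
consistent under the reported statistical structure — not that the model
captures real clot biophysics.

A pleasant consequence of the defaults: the zero-noise force means and pMLC
ratios of the nine conditions, which come from two independent sets of
published numbers, correlate with $R^2 = 0.902$ — essentially the published
force-phosphorylation $R^2$ of 0.91, which was computed on unpublished
per-volunteer averages and is therefore not desk-reproducible exactly.

## Numerical and design choices

- Units: geometry in µm, moduli in Pa, $J$ in m⁴, $\kappa$ in N·m/rad, `k` in
  N/m, deflections in µm, forces in µN (N/m × µm = µN, so no conversion
  constants appear in the pipeline).
- `beam_geometry()` normalises inputs so the thickness is the long side;
  degenerate (non-positive) dimensions are classed errors, as are negative
  displacements; over-stroke displacements warn rather than error because
  calibration hardware can overshoot.
- Determinism: every generator takes a `seed`; identical seeds give
  bit-identical datasets. Workflow functions write a YAML manifest echoing
  the seed and full configuration, which is sufficient to reproduce
  deterministic outputs bit-for-bit.
- Problem sizes in the test-suite: 200–300 seeds for calibration and ELISA
  batteries, 250 subjects per condition for the full round trip, 1000 for
  the control-recovery check — large enough that the 3-standard-error CLT
  bounds are meaningful, small enough to keep the default run around ten
  seconds.
- One reported condition name ("MLCK18", appearing once alongside ML-7) has
  no defined target anywhere else and is excluded from the default condition
  and reagent lists.

## Known limitations

- The suspension model is small-angle and quasi-static; no finite-element,
  fabrication-tolerance, or resonance effects.
- Sign propagation cannot express dose, saturation, or the dynamic feedbacks
  it linearises away — sildenafil shows exactly where that boundary is.
- The percent-change convention, while faithful to the published numbers, is
  non-standard; anyone comparing against other studies should recompute with
  a single-denominator convention from the per-sample values, which the
  pipeline retains.
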