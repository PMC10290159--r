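---
title: "Modelling circadian irinotecan toxicity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian irinotecan toxicity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotox)
```

## The scientific problem

Irinotecan toxicity in colorectal cancer cells depends on when during the
circadian cycle the drug is delivered: the enzymes that activate the
prodrug (CES2), inactivate its metabolite SN-38 (UGT1A1) and export both
(ABCB/ABCC transporters) are clock-controlled. `chronotox` couples a
transcription-translation model of the core circadian clock to a cellular
pharmacokinetic/pharmacodynamic (PK-PD) model of irinotecan and predicts
the circadian toxicity profile — the area under the dead-cell curve,
normalized to an untreated control, as a function of treatment time. The
same machinery simulates external Zeitgebers (light-like pulses acting on
PER transcription, pharmacological/feeding pulses acting on NR1D),
entrainment to a light-dark cycle, and the resulting shifts of both gene
expression and toxicity timing.

## The clock network

The transcription-translation network carries thirteen mRNAs — the core
regulators ARNTL, CLOCK, PER, CRY, NR1D, ROR, DBP (PAR-family
representative), NFIL3, PPARA and the drug-metabolism genes CES2, ABCB,
ABCC, UGT1A1 — where PER, CRY and NR1D are lumped paralog-family
variables fitted to the summed expression of their members (PER1-3,
CRY1/2, NR1D1/2). The lumping reflects paralog compensation: in PER2 and
NR1D1 knock-outs the remaining paralog is upregulated so the family sum
is roughly preserved, which makes the family sum, not the individual
transcript, the robust dynamical quantity. ARNTL is not lumped because
its paralog is co-reduced, not compensating, in ARNTL knock-outs.

Each core regulator has cytoplasmic and nuclear protein pools; PER and
CRY proteins form a nuclear complex that blocks the DNA-binding activity
of the CLOCK/ARNTL activator complex at E-boxes (blocking, rather than
sequestration, keeps the model at intermediate complexity). Regulation is
Hill-type throughout. The topology implements the refinements of the
extended model this package follows: PPARα inhibits *CES2*; NFIL3
activates *CES2* only indirectly, by inhibiting *NR1D* which in turn
inhibits *CES2*; NFIL3 inhibits *PER*; NFIL3 and the PAR-family
activator compete for the same binding sites on the ABC transporters
(implemented as a competitive D-box denominator); *TOP1* is excluded from
the transcription network entirely and enters the PK layer as a constant
protein. The drug-metabolism mRNAs are translated in the PK-PD layer with
*circadian protein degradation* — a cosine-modulated first-order
degradation rate per protein — replacing chains of post-transcriptional
intermediate steps.

Because the published fitted rate constants are not distributed with
this package, the default parameter vector
(`default_clock_parameters()`) is the package's own calibration: a
numerically located Hopf-unstable operating point, refined by a
stochastic search on the simulated limit cycle, then rescaled in time so
the free-running period is 23.8 h — detuned from 24 h, as is typical of
cancer cell lines, so that entrainment is a real locking phenomenon
rather than a degenerate one. Under the defaults every mRNA oscillates
with relative amplitude above the 5% fitting constraint (minimum ≈ 0.16,
ARNTL ≈ 0.39). All quantities that depend on this calibration
(entrainment threshold, phase-response magnitudes, toxicity peak times)
should be read as properties of this parameterization, not of the
published one.

## Simulation

`simulate_clock()` integrates with `deSolve::lsoda` at relative
tolerance 1e-4 and absolute tolerance 1e-12. Light forcing is a
piecewise-constant multiplier on the maximal transcription rate of the
target gene (`f × Vmax` while light is on, `Vmax` otherwise); the
integration is split at every light on/off and pulse boundary, so the
solver never steps across a discontinuity. A pulse *replaces* the LD
baseline factor for its target during the pulse window rather than
multiplying it — with one guard: a strength-1 pulse is by definition no
pulse and leaves the baseline untouched. Trajectories are clipped at
zero within the solver's absolute tolerance. `limit_cycle()` discards a
10-day transient (relaxation takes a couple of simulated days; ten is
conservative) and estimates the period from successive maxima of a
reference species (ARNTL mRNA by default), with quadratic sub-grid peak
refinement; systems whose post-transient relative amplitude falls below
2% are reported as damped rather than assigned a meaningless period.

## Fitting

The cost is the squared error between data and simulation at the data
sampling times, each gene normalized by its data maximum so all mRNAs
carry equal weight regardless of expression level. Fitted trajectories
must oscillate with relative amplitude `(max − min)/max > 0.05`;
UGT1A1 is exempt for HCT116-like lines, where it is essentially
unexpressed. The constraint is enforced as a large additive penalty
proportional to the shortfall — not by rejecting candidates — so the
optimizer retains a usable search signal near the boundary.

Optimization uses CMA-ES, the evolutionary strategy customary for this
model family; the implementation in `cma_es()` is the standard
(μ/μ_w, λ) algorithm with weighted recombination, cumulative step-size
adaptation and rank-one plus rank-μ covariance updates, run in log-space
over multiplicative bounds (default 0.01×-100× the initial value) with
three seeded restarts. The desk-scale evaluation budget default is 5000;
the package's own tests use 1200-1500 evaluations on 6-9 free
parameters, which suffices because the self-consistency problems start
near the optimum.

Knock-out cell lines are fitted with LASSO regularization: the cost
gains `λ/n_par × Σ|p_i − p_i^WT|/p_i^WT`, the mean absolute relative
divergence from the wild-type fit, so only a few parameters move far
from the wild type. Parameters with `|p^WT| < 1e-9` are excluded from
the penalty and from divergence counts, where the relative deviation is
undefined. A parameter counts as divergent when it deviates more than 5%
from its wild-type value. `penalty_sweep()` re-fits at each penalty with
the same seed so the penalty effect is isolated from sampling noise; the
choice of operating penalty is reported as a diagnostic table (R² and
divergent count per λ), not automated, since the published choice (λ = 5)
balanced divergence reduction against fit quality by inspection. On the
data side, a knock-out removes the knocked-out paralog's contribution
from the lumped family sum; the lumped model variable itself is never
structurally deleted.

Initial conditions default to the first data timepoint for fitted mRNAs
and small positive constants for unobserved protein states; recovery
tests that compare against model-generated data supply the generating
state explicitly through `fit_config(init_state=)`, since otherwise the
protein-pool transient would contaminate a fit whose data contain no
information about it.

## PK-PD layer

CES2, ABCB, ABCC and UGT1A1 proteins follow translation with circadian
degradation `d(t) = d0 (1 + a cos(2π(t − φ)/24))`, are rescaled to
reference maximal concentrations (shape-preserving), and drive the drug
equations: CPT-11 uptake and ABCB efflux, CES2-mediated activation to
SN-38 (a single pool shared between nucleus and cytoplasm), UGT1A1-
mediated inactivation, ABCC efflux, and TOP1-dependent DNA-damage
formation. For HCT116-like lines the UGT protein is scaled by 0.1
(10-fold reduction); from treatment onset UGT is additionally multiplied
by the sigmoid `1 + M_UGT/(1 + exp(k_UGT t + 4))` with free magnitude
and slope, the `+4` offset being fixed. The death rate is a baseline
plus a treatment-independent circadian modulation plus, after treatment,
a transient alpha-function increase `A (s/τ) exp(1 − s/τ)` — the
unit-peak parameterization, chosen so that `A` is directly the peak
height (at `s = τ`) of the transient; the family was specified but not
its normalization, and this form keeps both fitted parameters
interpretable.

Toxicity profiles divide the trapezoidal AUC of the dead-cell variable
`D` (resampled to a uniform 0.1 h grid) by the AUC of an untreated
control started at the same circadian time; the control profile is
therefore exactly 1, the ratio is invariant under joint rescaling of
`D`, and the peak time is refined by quadratic interpolation on the
periodic treatment-time grid (ties to the earliest time). The default
treatment grid is every 3 h over one cycle; the observation horizon is
72 h. `phase_adapt()` shifts all circadian degradation phases and the
death-modulation phase by a given ARNTL phase difference (mod 24),
leaving everything else unchanged — the mechanism used to transfer a
fitted PK-PD layer to a cell line with a different clock phase.

## Zeitgeber analysis

Entrainment is judged on two criteria: the post-transient period equals
24 h within ±0.1 h, and the relative amplitude over a 64 h window is at
least 95% of the free-running amplitude ("at least similarly strong" is
operationalized as a 5% tolerance, both config-exposed). A 480 h
transient precedes the verdict because locking near threshold is slow.
Phase shifts are measured on ARNTL expression as the time difference of
the *second* maximum after the pulse between the unpulsed and pulsed
runs, both started from the same entrained state. The sign convention —
stated in all outputs because the source material reports a range
without defining sign — is: positive shift = phase advance (pulsed peak
earlier than reference). Shifts are reported modulo the cycle in
(−12, 12] h. Pulse-perturbed toxicity delivers treatments in the cycle
following the pulse day, when the perturbation is still relaxing.

Under the package calibration a 12:12 LD cycle entrains from a light
factor of about 1.13 upward; 1 h pulses of strength 1.75 on PER produce
phase shifts of roughly ±0.2 h with the largest responses near ZT 22.5,
and NR1D pulses respond maximally near ZT 7.5 with smaller magnitudes
(NR1D's slow mRNA turnover integrates a 1 h pulse weakly). These
magnitudes are substantially smaller, and the response timings differ,
from those reported for the published fitted parameterization
(entrainment at 1.07; ±2 h shifts; maxima at ZT 12 for PER and ZT 3 for
NR1D): the attractor of our calibrated oscillator is more rigid than the
fitted one. The qualitative structure — null shifts at unit strength,
24 h periodicity, near-linear growth with strength and duration,
relaxation within days, PER relaxing no slower than the clock output
CES2, and pulse-timing-dependent movement of the toxicity peak — is
reproduced and tested; the quantitative Zeitgeber targets tied to the
published parameter values are asserted in the acceptance suite and
documented as not met under this calibration.

## Synthetic data

The generator emulates the statistical structure of the RNA-seq inputs:
cosinor oscillations (`mesor (1 + amp cos(2π(t − φ)/24)) + drift·t`)
with per-gene phases spread over the cycle, linear drifts on the genes
that show pronounced trends in long time courses (ROR, PPARA, CES2),
near-zero UGT1A1 for HCT116-like panels, multiplicative log-normal noise
(CPM-like heteroscedasticity; the noise model is the package's choice,
as none is stated for the source data), and 3 h sampling over 45 h.
Knock-outs set the target gene to a residual 1e-3 of the family mesor
(avoiding degenerate normalizers) and apply the family rule:
`compensate` redistributes the lost expression over the remaining
paralogs so the family sum is preserved per timepoint; `co_reduce`
scales the remaining members down (the ARNTL2 behaviour). What the
generator does *not* emulate: count noise (negative binomial), gene-gene
correlation beyond family structure, and batch effects — so passing
recovery tests demonstrate algorithmic correctness on clean inputs, not
robustness to real RNA-seq artefacts.

Cytotoxicity curves are forward simulations of the PK-PD model per
treatment time plus control, with optional multiplicative noise and the
ground-truth normalized-AUC profile attached for recovery tests.

## Numerical choices and problem sizes

Solver tolerances are 1e-4/1e-12 (relative/absolute) for the clock
network and 1e-6/1e-9 for the cell-population equations, loosened to
1e-4/1e-6 inside PK-PD fitting loops — within the 1e-3 to 1e-7 absolute
range customary for these equations. Peak detection operates on a
0.05 h output grid with quadratic refinement; AUCs use the trapezoidal
rule on a 0.1 h grid. The test and acceptance runs use deliberately
modest problem sizes — 6-9 free parameters, 1200-1500 CMA-ES
evaluations with 2-3 restarts, 16-point phase-response grids, 8-point
treatment grids — chosen so the full suite exercises every pipeline
stage end to end; fitting real multi-cell-line panels would use the
same interfaces with the 5000+ evaluation presets and denser grids.

## Known limitations

- The default parameterization is a calibrated stand-in, not the
  published fitted vector; quantities that are emergent properties of
  the fitted parameters (entrainment threshold, shift magnitudes and
  timings, absolute peak times) differ from the published ones and are
  reported as computed.
- Light acts directly on PER transcription (and NR1D for pharmacological
  pulses) with no SCN-periphery signalling chain, no lux-to-molecular
  transfer function, and no stochastic or spatial effects.
- The PK layer is cellular: no whole-body pharmacokinetics, no repeated
  clinical dosing regimens.
- LASSO divergence reporting is a parameter-selection heuristic, not an
  identifiability analysis.
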