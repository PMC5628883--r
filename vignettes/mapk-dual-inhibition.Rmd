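---
title: "Modeling dual MEK/ERK inhibition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dual MEK/ERK inhibition: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkdual)
```

## The scientific problem

In RAS-mutant tumors the RAS-RAF-MEK-ERK cascade is chronically active,
and single-agent MEK or ERK inhibitors suppress pathway output only
transiently: doubly phosphorylated ERK (ppERK) drives negative feedback
(inhibitory phosphorylation of CRAF and MEK, DUSP phosphatase induction,
SPRY-mediated inhibition of Grb2-SOS signaling to RAS), so inhibiting the
pathway relieves its own brakes and output rebounds within 24-72 h. The
package implements a mass-action kinetics model of this circuit with
reversible inhibitor binding, and the downstream analysis toolkit used in
combination pharmacology: 4PL dose-response fitting with GI50 extraction,
Loewe/Bliss expectation surfaces, isobolograms, excess-based synergy
scores with a sham-combination control, pathway-reactivation metrics, and
xenograft efficacy metrics (%TGI, PFS). Its central computational claim is
qualitative: combined MEK+ERK inhibition is more than additive when RAF
activation is coupled to RAS (the KRAS-mutant setting), because the
combination prevents the feedback reactivation that limits each single
agent; when RAF is decoupled from RAS (a BRAF-mutant mimic) the feedback
loops cannot transmit and the advantage disappears.

## The reaction network

Species are concentrations in nM; time is in hours. The cascade is

* a Ras nucleotide cycle driven by a clamped Grb2-SOS input (`GS`), with
  activation gated by SPRY: the effective input is
  `GS / (1 + SPRY / k_spry)`;
* RAF activation by Ras-GTP (`ras_coupled = TRUE`) or at a constitutive
  first-order rate (`ras_coupled = FALSE`); active RAF can be
  feedback-phosphorylated by free ppERK into an inactive pool (`RAFi`);
* single-step MEK activation by active RAF, with a ppERK-driven feedback
  phosphorylation site (`MEKf`) that blocks activation;
* distributive two-step ERK phosphorylation by free (non-drug-bound)
  pMEK. Dephosphorylation of the four phospho-ERK pools (pERK, ppERK and
  their drug-bound counterparts) is catalyzed by a shared phosphatase
  activity -- basal plus DUSP-proportional -- with competitive
  Michaelis-Menten kinetics: every phospho-ERK form occupies the same
  phosphatase pool (`km_erk` is the shared Michaelis constant). This is
  the standard quasi-steady-state reduction of the underlying mass-action
  enzyme mechanism; the linear regime is recovered for `km_erk` much
  larger than the phospho-ERK load, and the Goldbeter-Koshland
  ultrasensitive regime for `km_erk` small. A test verifies the model's
  ERK stage against the closed-form algebraic fixed point of the reduced
  two-step cycle.
* DUSP and SPRY synthesis driven by free ppERK through a Hill term
  (`vmax`, `k_half`, `hill_fb`) with first-order decay. Their half-lives
  are constrained to at least 1 h: transcriptional feedback must be slower
  than the phosphorylation cycles.

Inhibitors bind every phosphoform of their target with state-independent
affinity (`Kd = koff/kon`); bound forms keep their phosphorylation state
and remain substrates, but are catalytically dead, and inhibitor-bound
ppERK contributes neither to pathway output nor to any feedback drive --
this is precisely how ERK inhibition relieves feedback. Free drug is
clamped (no depletion), consistent with the observation that replacing
drug-containing media does not change reactivation kinetics. The pathway
output (`pathway_output()`) is free, non-drug-bound ppERK, a proxy for
p-p90RSK-level pharmacodynamic readouts; no explicit RSK or viability
species is carried.

Integration uses `deSolve::lsoda` with relative tolerance 1e-8 and
absolute tolerance 1e-10 nM; every trajectory records the relative drift
of each conserved protein total (below 1e-6 in the shipped tests).
Identical inputs give bitwise-identical trajectories.

## Calibrated default parameters

Published rate-constant tables for this exact circuit are not available,
so the shipped defaults (`inst/extdata/params_default.yaml`) are a
reconstruction: orders of magnitude follow classic two-step distributive
MAPK models, and the free constants were then calibrated by the staged
procedure in `scripts/calibrate.R` against a behavioral constraint suite
(vehicle ppERK at least 20% of total ERK; MEK-inhibitor output nadir
within 6 h and rebound of at least half the suppressed amplitude by 72 h,
abolished when DUSP/SPRY feedback is disabled; 6-h active-CRAF induction
ordered combination > MEKi >= ERKi > 1 with the MEKi fold in the 2-4
band; half-dose combination exposure below either full-dose single
agent). Choices a reader should know about:

* **Reference doses are acute output-EC50s.** `output_ec50()` returns the
  dose at which the *pre-adaptation output nadir* is half the vehicle
  output, the analog of an EC50 measured at the early pharmacodynamic
  trough. Defining the reference dose by the fully adapted steady state
  instead would make "rebound of half the suppressed amplitude" logically
  unreachable: at such a dose the 72-h output is half-vehicle by
  construction, so the index `(out72 - nadir)/(out0 - nadir)` is capped
  below 0.5. The steady-state definition remains available.
* **Binding kinetics are slow, and slower for the MEK inhibitor.** Kd
  values are low-nanomolar placeholders (10 and 30 nM); the kon/koff
  pairs give association times of tens of minutes at reference doses,
  in line with the long target residence reported for clinically used
  MEK inhibitors. The kinetic asymmetry matters: the MEK inhibitor's
  suppression develops while transcriptional feedback relief is already
  under way, which shifts its nadir-matched reference dose upward and
  separates the 6-h CRAF fold-changes of the two agents in the observed
  order (MEKi above ERKi, combination above both).
* **The phospho-feedback arms are weak.** Any output rebound contributed
  by the fast CRAF/MEK phosphorylation feedback would survive DUSP/SPRY
  ablation, which the constraint suite forbids; reactivation is therefore
  carried almost entirely by the transcriptional loops, dominated by the
  SPRY -> RAS -> CRAF axis. The reactions are present (and gated by
  `fb_phospho`) but carry small rate constants.
* **Decoupled RAF is not feedback-phosphorylated.** With
  `ras_coupled = FALSE` the constitutively active RAF mimics monomeric
  mutant BRAF, which is insensitive both to RAS input and to
  ERK-dependent CRAF/dimer feedback; only the MEK arm of the
  phospho-feedback remains. The constitutive activation rate is sized by
  root finding so the vehicle steady-state output matches the coupled
  network within 0.1%, isolating topology from baseline.
* **Transcriptional induction is steep** (`hill_fb = 6`,
  `k_half` about 1.35x the vehicle ppERK level). The model's two
  transcriptional species stand in for a multi-gene panel (DUSP4/6,
  SPRY2/4); measured transcript suppression under treatment exceeds 96%,
  consistent with an effectively cooperative shutoff.

## From output to viability

The paper-scale readout of a combination matrix is fractional viability.
The link (`viability_link()`) maps an exposure metric -- by default the
0-72 h time integral of free ppERK relative to vehicle, selectable to the
post-treatment steady state -- through a normalized Hill transform with
maximal kill `emax = 0.95`, half-kill near 25% of vehicle exposure and
slope 2. The normalization anchors vehicle exposure exactly at viability
1 and complete suppression exactly at `1 - emax`; the textbook half-kill
interpretation of `k_rel` is exact in the limit `k_rel << 1`. Effects are
percent (0-100) in fitting and GI50 work, and fractions (0-1) in synergy
surfaces; converters are explicit (`effect_as_fraction()`).

## Synergy analysis

Loewe additivity is the primary null: the expected effect of a dose pair
solves `dA/D_A(E) + dB/D_B(E) = 1`, with `D(E)` the analytic inverse of a
fitted 4PL, by bracketed monotone root finding (tolerance 1e-12; a
brute-force scan over 10,000 effect values is kept as an independent
oracle in the tests). With unequal asymptotes the solvable range is
capped at the smaller top and flagged saturated rather than extrapolated.
Bliss independence (`eA + eB - eA*eB`) is provided for fixed-dose
comparisons. Scores are a weighted sum of the excess over the null,
scaled by 100; the default is the uniform mean (the weighting scheme of
the commercial implementation used in screening pipelines is unpublished,
so scores here are internally comparable only). Isoboles are extracted by
monotone cubic interpolation on the log-dose lattice and reported in
linear dose, where Loewe additivity predicts straight lines; the
straightness statistic is the maximum perpendicular deviation from the
contour chord as a fraction of chord length.

The sham combination -- one drug combined with itself, the cell at
`(dA, dB)` simulated at the single dose `dA + dB` -- is the additivity
control: its only nonzero excess is 4PL lack-of-fit on the model's
margins, and `sham_surface()` turns that into an explicit noise band
(three times the largest absolute sham score) against which real
combination scores are judged.

## Known limitations

* The decoupled (BRAF-mutant-like) network is *less* synergistic than the
  RAS-coupled network at the defaults, and ablating all feedbacks lowers
  the score further, but its Loewe score does not reach the sham noise
  floor. This is structural, not a calibration accident: two inhibitors
  binding independent sites produce a response surface whose isoboles bow
  inward whenever the log-response is concave in dose (any separable
  surface built from hyperbolic binding does this), so a small positive
  score survives in the feedback-free limit. Driving the ERK stage deep
  into the zero-order ultrasensitive regime does flatten that floor, but
  in the same stroke it breaks fractional-dose superiority (near a hard
  switch, one full dose beats two half doses) and makes the steep margins
  poorly representable by 4PLs, inflating the sham noise floor itself.
  The shipped defaults therefore prioritize the single-agent reactivation
  pharmacology, and the coupled-vs-decoupled contrast should be read as
  an ordering, not as additivity in the strict Loewe sense.
* The model ends at ppERK: p-p90RSK, transcription-factor outputs and
  cell-cycle commitment are absorbed into the viability link.
* Per-animal OLS on log2 volumes plus group averaging stands in for the
  linear mixed-effects fit used with in-vivo data; in balanced designs
  the group slopes coincide, and the substitution is recorded in the
  `tgi()` output metadata. PFS interpolates crossing times on the log2
  volume scale (exact for exponential growth, and the reason a noiseless
  doubling-time-5 cohort progresses at exactly day 5); the volume scale
  for the %TGI area is selectable (`linear` default, `log2` optional)
  because the convention is ambiguous in the field.
* The synthetic generators emulate the statistical structure the
  analyses assume -- 4PL curves with additive Gaussian noise clipped to
  the effect scale, combination matrices built under a named null with an
  optional localized synergy bump, exponential xenograft growth with
  animal-level slope jitter and scale-proportional (lognormal) caliper
  noise on a twice-weekly schedule -- and deliberately not plate spatial
  effects, batch drift, pharmacokinetics, or non-exponential growth.
  Passing recovery tests on them demonstrates correctness of the
  estimators under their own assumptions, not robustness to real-data
  pathologies.

## Problem sizes

The shipped tests and the acceptance script use the 9-point half-log dose
ladder (0.1-1000 nM) per axis, 72-h exposures at 0.5-1 h output
resolution, 50-200 replicates for stochastic recovery checks, and
xenograft cohorts of 6-12 animals per group on a twice-weekly schedule --
sizes chosen to mirror the corresponding bench designs while keeping a
full run in minutes on one core.

## A note on dose grids

A "1 to 1000 nM in half-log steps" layout contains seven doses, not
nine; `default_dose_grid()` keeps nine half-log-spaced points by
anchoring the top at 1000 nM and extending to 0.1 nM, and a
zero-anchored alternative (`zero_anchored = TRUE`) carries explicit
single-agent margins in the matrix itself.
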