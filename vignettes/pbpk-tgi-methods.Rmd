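---
title: "Whole-body PBPK and tumor growth inhibition modelling of MBQ-167"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK and tumor growth inhibition modelling of MBQ-167}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpktgi)
```

## The model

`pbpktgi` implements a physiologically based pharmacokinetic (PBPK) model
of the Rac/Cdc42 inhibitor MBQ-167 in mice, coupled to Simeoni tumor
growth inhibition (TGI) dynamics for HER2+ and Triple Negative breast
cancer xenografts.  The package covers the full workflow: system
(physiology) and compound parameterization, mechanistic tissue
partitioning, hepatic-clearance calibration, whole-body simulation under
arbitrary intraperitoneal (IP) dosing regimens, permeability-limited
tumor disposition, TGI simulation, non-compartmental verification
statistics, weighted least-squares estimation, local sensitivity
analysis and synthetic study-data generation.

### Whole-body disposition

The body is a set of anatomical compartments — lung, heart, kidney,
liver, spleen, gut, muscle, adipose, skin, bone, brain and a
rest-of-body remainder — connected by blood flows, with separate
arterial and venous blood pools.  Distribution is perfusion-limited:
each tissue receives arterial blood at its regional flow $Q_t$ and
returns venous blood at concentration $C_t \cdot (B\!/\!P) / K_{p,t}$,
where $K_{p,t}$ is the tissue:plasma partition coefficient and $B/P$
the blood-to-plasma ratio.  The spleen and gut drain into the portal
vein, so the liver receives hepatic-arterial plus portal inflow.  The
state vector carries amounts (ng); the system is linear and is
integrated with `deSolve::lsoda` at rtol 1e-8 / atol 1e-10, with doses
applied as state discontinuities.  Cumulative eliminated amounts are
tracked per route, so mass balance is assertable at every output time
(the suite requires closure to 1e-6 of the administered dose).

IP administration is represented the way the study implemented it: a
first-order depot (ka = 3 1/h) emptying directly into venous blood
after a 0.17 h lag with complete bioavailability, bypassing gut and
liver first-pass.  "Fed state" is metadata only; it has no mechanistic
consequence in this model.

### Partitioning

Tissue:plasma partition coefficients are predicted with the
Rodgers-Rowland mechanistic equations ("method 2"): the neutral species
distributes into tissue water, neutral lipid (scaled by
$P = 10^{\log P}$; a vegetable-oil:water correlation for adipose) and
neutral phospholipid ($0.3P + 0.7$); moderate-to-strong bases
(pKa $\ge$ 7) additionally bind acidic phospholipids with an
association constant back-calculated from $B/P$, while acids, neutrals
and weak bases carry an albumin-binding term back-calculated from
$f_u$ (clamped at zero when plasma lipid partitioning alone accounts
for the measured binding — the case for MBQ-167, whose $f_u = 0.02$ at
logP 4.944).  With pKa 0.27 the molecule is un-ionized at physiological
pH (ionized fraction $\sim 7\times 10^{-8}$).

Five partition coefficients (heart, kidney, liver, lung, spleen) were
optimized against tissue data in the source study and are used
verbatim; all remaining tissues use the mechanistic prediction times
the global scalar 0.29.  We apply the scalar only to predicted tissues:
applying it to the optimized values as well drives the steady-state
volume of distribution far below the reported 20.21 L/kg, so the
overrides-verbatim convention is the one consistent with the study.

The tissue composition table (water, neutral lipid, neutral
phospholipid, acidic phospholipid, albumin ratio) is pinned from the
published rat composition compilation — the standard surrogate when no
mouse table exists — and shipped as a CSV asset.  This is the single
largest source of numerical freedom in the package: with this table and
the 0.29 scalar, Vss evaluates to about 16.6 L/kg against the reported
20.21 L/kg (the original simulator's internal mouse composition is not
published).  We deliberately keep the printed scalar rather than
re-tuning it.

### Elimination

Hepatic clearance is scaled from in vitro hepatocyte intrinsic
clearance (79 uL/min/10^6 cells, read as microlitres since 79 mL would
be physiologically impossible) via hepatocellularity (135e6 cells/g)
and liver weight, divided by the incubation unbound fraction
$f_{u,inc}$, and embedded in the well-stirred liver model
$CL_b = Q f_{u,b} CL_{int,u} / (Q + f_{u,b} CL_{int,u})$.  Because the
printed unit is ambiguous, $f_{u,inc}$ is calibrated (closed-form
inversion of the monotone well-stirred expression) so that hepatic plus
renal plasma clearance reproduces the observed systemic value of
2.15 mL/min; the calibration target and the renal value (0.3 mL/min,
the mouse glomerular filtration rate — the tabulated value, not the
inconsistent 12-18 mL/min text range) fix the clearance budget at
1.85 + 0.30 mL/min, i.e. an 86% hepatic share.  Renal elimination draws
on arterial plasma at the kidney.

### Tumor disposition

The tumor (default 0.5 mL, reflecting the tumor-PK experiment) has a
vascular space fixed at 16% of tumor volume, plus extracellular (EC)
and intracellular (IC) water.  Defaults for what the study does not
print: the non-vascular volume splits 0.40/0.44 into EC/IC (typical
tumor water fractions); tumor perfusion is 0.1 mL/min per mL tumor;
capillary permeability is ten times the EC-IC permeability so the
EC-IC barrier (PS = 1.2 mL/min/mL) is rate-determining.  The efflux
transporter (7 mL/min/mL) moves drug IC to EC, and the tumor intrinsic
clearance (2.2 mL/min/mL) acts on IC — the transporter direction and
clearance site are taken from the model diagram since the text does not
state them.  Tumor water is treated as binding-free (unbound equals
total in EC/IC), and the tumor is not coupled to TGI growth because the
effect model is driven by total plasma concentration.  With these
choices tumor exposure shows the qualitative signature reported for the
study — lower Cmax and later Tmax than plasma — and the tumor
quantities are verified by property, not by number.

### Tumor growth inhibition

Unperturbed growth follows Simeoni dynamics,
$\dot w = G(w)\,x_1$ with
$G(w) = \lambda_0 / [1 + (\lambda_0 w / \lambda_1)^{\Psi}]^{1/\Psi}$:
exponential at small masses, settling to the zero-order rate
$\lambda_1$, with the transition sharpness set by $\Psi$.  Drug effect
is an Emax kill term
$k(C) = K_{max} C^{H} / (IC_{50}^{H} + C^{H})$ applied to the
proliferating compartment, feeding a transit chain of damaged cells
(3 stages for HER2+, 4 for Triple Negative) advancing at $k_1$; only
the last stage leaves the tumor mass, and damaged cells still count in
the mass feedback of $G(w)$ (the original Simeoni convention).  $IC_{50}$
is given in uM and converted to ng/mL with MW 338.414 before comparison
with the plasma input.  The printed net-effect unit (mL/ng/day) is
internally inconsistent with the printed ratios 533 and 19.7, which
equal $K_{max}/IC_{50}$ in 1/(uM day); the package reports the ratio in
1/(uM day).

The TGI system runs in days; the PBPK plasma profile (hours) enters as
an interpolated forcing function held at zero outside its support, and
the integrator's maximum step is capped at 0.02 days so inter-dose
concentration swings are resolved.  The every-other-day, three-times-a-
week schedule is encoded as days 0, 2 and 4 of each 7-day cycle.

The Triple Negative $k_1 = 0.0007$/day implies damaged cells
essentially never clear — treatment arrests rather than removes mass.
That is the reported parameterization and is used as printed.

## Estimation and verification

The estimation layer minimizes the study's objective — residual sums of
squares per dataset weighted by the reciprocal of the squared maximum
observation — with Nelder-Mead (standard coefficients, via
`stats::optim`; Brent in one dimension), log-transforms where declared,
bound violations rejected by penalty, and the relative-improvement
termination threshold exposed as a `fit_spec` field (the study rule is
1%; recovery tests use tighter values so convergence error does not
contaminate the comparison).  Manual optimization steps of the original
workflow are replaced by scripted fits with documented initials.

Verification metrics are linear trapezoidal AUC without extrapolation
(predicted/observed comparisons use matched time windows), first-
attainment Cmax/Tmax, log-linear terminal half-life, predicted/observed
fold error, percent relative error, and t-based 95% confidence
intervals of replicate observations.  Local sensitivity analysis uses
central differences at a default +/-20% perturbation (the study does
not state its scheme) and returns normalized coefficients.

## What the synthetic data emulate — and what they do not

`generate_pk_dataset` mirrors the destructive-sampling tissue PK study:
5 pseudo-animals per time point at 0.5, 1, 3, 6, 9, 12 and 24 h, with
independent records (no within-animal correlation, as in the real
design).  `generate_tgi_dataset` mirrors the xenograft studies: 10
subjects per group, imaging at treatment day 1 and weekly thereafter
for 65 or 108 days, a lognormal per-subject baseline jitter (CV 10%)
on $w_0$, and median-preserving proportional lognormal residuals
(the study reports no residual model; concentrations and volumes are
positive, so a lognormal is the natural choice).  Seeds are explicit
required arguments, and generation is bit-reproducible given the seed.
The generators do not emulate fluorescence-imaging physics, dropout,
or inter-animal physiological variability, so passing recovery tests
demonstrate pipeline correctness, not robustness to every feature of
real data.

A caution the tests make explicit: with 15% observation noise the
growth triple ($\lambda_0$, $\lambda_1$, $\Psi$) is not reliably
recoverable under the max-weighted WLS objective.  The weighting makes
early small-tumor observations contribute thousands of times less than
late ones, leaving a near-flat ridge along which degenerate parameter
sets (large $\lambda_0$, small $\Psi$) fit noisy data slightly better
than the generating values.  This is a known identifiability weakness
of the Simeoni shape factor (historically fixed, e.g. at 20, rather
than estimated).  Zero-noise recovery is exact to better than 1%, and
the absorption parameters (ka, lag) are recoverable within their
stochastic band from the replicate design.

## Numerical choices and problem sizes

* Solver: `lsoda`, rtol 1e-8, atol 1e-10; doses as additive state
  events at `dose_time + lag`.
* Simulation grids: 0.005 h over 24 h for single-dose NCA (so Tmax is
  resolved to the grid); 0.05 h over the 65- and 108-day regimens
  feeding the TGI forcing function; TGI output every 0.25 days.
* The fold-error comparison evaluates the predicted profile at the
  study sampling times (0.5-12 h, with a zero pre-dose anchor) to match
  the observed AUC's support.
* Terminal half-life regresses all dense grid points in the 6-24 h
  window, the study's terminal interval.
* Tiny negative solver excursions in TGI states are clamped to zero
  with a warning above 1e-6 g.

## Known limitations

* Physiology defaults and the tissue composition table are pinned
  rodent reference values; the original simulator's internal mouse
  tables are unpublished, which is the main driver of the Vss and
  terminal-half-life differences discussed above.
* No inter-individual variability, metabolite kinetics, enterohepatic
  recirculation, transporter saturation, or spatially resolved tumor
  model.
* The tumor-driven effect mode (`drug_input = "tumor_total"`) exists as
  a flag but is untested against reported numbers, mirroring the
  original work's plasma-driven choice.
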