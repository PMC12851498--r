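---
title: "A mechano-signaling reaction-diffusion model of post-traumatic collagen loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechano-signaling reaction-diffusion model of post-traumatic collagen loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartdegen)
```

## The model

`cartdegen` simulates how a single injurious compression of a cartilage
explant (3 mm wide, 1 mm thick in cross-section) turns into depth-wise
collagen loss over a 12-day culture period. The causal chain is:

1. **Mechanics.** Injurious compression produces a field of maximum shear
   strain, the largest pairwise difference of the principal
   Green--Lagrange strains,
   $\varepsilon = \max\{|\varepsilon_{p,1}-\varepsilon_{p,2}|,
   |\varepsilon_{p,1}-\varepsilon_{p,3}|,
   |\varepsilon_{p,2}-\varepsilon_{p,3}|\}$.
   The package does not solve the fibril-reinforced poroelastic contact
   problem; it accepts the scalar field from three pluggable sources: a
   homogeneous incompressible-deformation surrogate, a parametric
   depth-decaying generator, or a CSV import of an externally computed
   field. The strain field is a static snapshot at peak compression; no
   strain history is modelled.

2. **Cell damage.** A stepwise nonlinear function maps shear strain to
   the fraction of damaged chondrocytes: zero below
   $\varepsilon_{dmg,init} = 0.4$, one at
   $\varepsilon_{dmg,max} = 1.5$, and a continuous concave branch
   $f = (\varepsilon_{dmg,max}/\varepsilon)\,
   (\varepsilon - \varepsilon_{dmg,init}) /
   (\varepsilon_{dmg,max} - \varepsilon_{dmg,init})$ in between. The
   intermediate branch admits two readings that both satisfy the
   boundary conditions $f(0.4)=0$, $f(1.5)=1$; the concave one is the
   default and a convex alternative sits behind the `branch=` switch of
   `damage_parameters()`. Damaged-cell concentration is
   $C_{cell,dmg} = k_{INJ}\, f(\varepsilon)\, C_{cell,healthy}$ with
   $k_{INJ} = 0.35$ capping damage at 35 % of the healthy population
   ($10^{14}$ cells m$^{-3}$, homogeneous). Damage is computed once and
   held constant: the model contains no cell proliferation, recovery, or
   secondary death.

3. **Delayed protease release.** Two stimulus variables delay MMP and
   aggrecanase activation after injury:
   $\partial S_j/\partial t = \alpha_j (k_j C_{cell,dmg} - S_j)$. With
   constant damage the stimulus relaxes exponentially to
   $k_j C_{cell,dmg}$ with time constant $1/\alpha_j$.

4. **Reaction--diffusion.** Six species evolve by
   $\partial C_i/\partial t = D_i \nabla^2 C_i \pm R_i$: intact and
   degraded collagen, intact and degraded aggrecan, MMP, aggrecanase.
   MMP is produced from its stimulus ($k_{rate,mmp} S_{mmp}$) and
   consumed by binding to degraded collagen
   ($k_{mmp,cold}\, C_{mmp} C_{cold}\, n_{R,cold}$; the binding-site
   count enters as a linear multiplier, not an exponent). Intact
   collagen is cleaved with Michaelis--Menten kinetics modulated by a
   Hill factor of total aggrecan,
   $f_{agg} = 1/(1 + ((C_{agg}+C_{aggd})/k_{act})^{-n})$, and decays
   with a first-order basal rate $k_{basal}$ that represents
   culture-condition loss observed in free-swelling controls. The Hill
   factor as printed **increases** with aggrecan (half-maximal at
   $k_{act}$); this direction is self-consistent with the observed
   sensitivity direction of $k_{act}$ (raising it lowers MMP activity
   and preserves superficial collagen), so it is the default, with the
   reciprocal "protection" variant behind `hill_direction=`. The
   aggrecanase/aggrecan subsystem mirrors the MMP chain by structural
   analogy: stimulus-driven aggrecanase production and Michaelis--Menten
   aggrecan cleavage, with degraded aggrecan gaining exactly what intact
   aggrecan loses.

### Initial and boundary conditions

Initial collagen follows a degree-6 polynomial in normalized depth
(FTIR-like absorption units) scaled by $1/46.2276$ so the depth mean is
0.2 mol m$^{-3}$; initial aggrecan converts the fixed-charge-density
polynomial (mEq ml$^{-1}$) at 0.1005 mol m$^{-3}$ per unit. Everything
else starts at zero. All species have zero flux across the bottom;
aggrecan, degraded aggrecan and MMP exchange with the bath through
Robin conditions on the top and lateral faces (bath concentration 0,
infinite sink — medium renewal is not modelled); degraded collagen and
aggrecanase have Dirichlet zero on those faces. An optional lesion
polygon cut into the top surface is represented as a node mask whose
exposed faces inherit the top condition per species, so the lesion void
communicates with the bath; it exists to visualize peri-lesion loss and
is not part of the mechanics.

## Parameters

Every constant lives in a registry with value, units and a provenance
tag. Three tags matter:

* `paper` — fixed by the reference study design: the damage thresholds
  and cap, and the reference values of the six swept constants
  ($k_{rate,mmp} = 3.6\times10^{-5}$ s$^{-1}$,
  $k_{mmp} = 0.35\times10^{-21}$ mol,
  $k_{mmp,catalytic} = 1.5$ s$^{-1}$, $k_{act} = 3\times10^{-5}$
  mol m$^{-3}$). These are locked: `calibrate()` refuses to move them.
* `default` — literature-lineage choices: protease diffusivities and
  the aggrecanase analogues of the MMP constants, Hill coefficient
  $n = 2$ (typical cooperativity), Robin coefficients of order
  $D/100\,\mu$m, healthy cell density $10^{14}$ cells m$^{-3}$.
* `calibrated` — frozen by the shipped calibration
  (`inst/scripts/calibrate_reference.R`, registry in
  `inst/extdata/params_reference.csv`): $k_{basal} =
  \ln(1/0.81)/1.0368\times10^{6}\,\mathrm{s} = 2.0324\times10^{-7}$
  s$^{-1}$ in closed form from the 19 % free-swelling loss;
  $D_{mmp} = 10^{-14}$ m$^2$ s$^{-1}$ and $h_{mmp} = 10^{-11}$ m
  s$^{-1}$, which confine MMP to the superficial production zone;
  $\alpha_{mmp} = 3\times10^{-6}$ s$^{-1}$ (a ~3.9-day activation
  delay); $K_{m,mmp} = 0.15$ mol m$^{-3}$; and the binding rate
  $k_{mmp,cold} = 2\times10^{-4}$ m$^3$ mol$^{-1}$ s$^{-1}$, the single
  remaining degree of freedom used to hit the 30 % reference bulk loss.

The reference injury strain field is the parametric generator with
surface peak 2.0 (saturating the damage function superficially), deep
plateau 0.44 (just above the damage threshold, giving a small deep
contribution) and decay depth 0.27 in normalized units. It is a
calibrated stand-in for an external finite-element solve and is tagged
as such in the provenance manifest of every run.

A dimensional audit (`audit_units()`) checks symbolically, from the
units recorded in the registry, that every reaction term reduces to
mol m$^{-3}$ s$^{-1}$ and every boundary flux to mol m$^{-2}$ s$^{-1}$.

## Numerics

The domain is a node-centered structured grid, by default 61 x 21
(50 um spacing). Fields are vectors in column-major order with depth
fastest. The diffusion operator is a finite-volume 5-point Laplacian;
Robin faces appear as surface sinks scaled by the half-cell width,
outer Dirichlet faces pin their nodes at zero, and lesion-adjacent
faces use a ghost value at the half-cell face. Quadrature weights are
trapezoidal, zero on masked nodes.

Time integration is Strang-split with a 300 s macro step: an implicit
(backward Euler) diffusion half-step per diffusible species — the
system matrices are LU-factorized once per run, and backward Euler with
an M-matrix preserves non-negativity — then an adaptive explicit
Dormand--Prince 4(5) reaction step over all nodes at once (`deSolve`,
rtol $10^{-6}$, atol $10^{-15}$), then a second diffusion half-step.
Two hardening choices matter for robustness: reaction rates are
evaluated on the projected non-negative state, because trial states of
an adaptive integrator can dip below zero and would otherwise flip the
bilinear MMP-binding sink into a spurious source; and the reaction
substep is capped by a per-step stiffness estimate built from the
fastest bilinear and Michaelis terms. Residual negative values after a
macro step are clipped to zero with the clipped mass logged; a run
aborts if the cumulative clipped mass exceeds $10^{-9}$ of the total
initial inventory (the per-species form of this guard is undefined for
species that start empty, hence the total-inventory scale).

Convergence: the day-12 bulk loss changes by less than 0.1 percentage
points between the 31 x 21 grid at a 600 s step and the 61 x 21 grid at
300 s, so the sensitivity sweeps run on the coarser setting while
headline runs use the full grid; `convergence_study()` automates the
refinement check and flags changes above 0.5 points.

## The synthetic-data generator

`synth_config()` fixes the emulated study conditions: group sizes of
the explant experiment (control day 0 n = 18, day 12 n = 21; injury day
0 n = 18, day 12 n = 6), 5.5 um FTIR-like pixels, and per-group
depth-wise mean loss curves. The day-12 control loses a uniform 20 %;
the day-12 injury group follows
$\mathrm{loss}(d) = 0.26 + 0.27\,e^{-d/0.33}$ — about 34.5 % bulk,
weighted toward the surface, and deliberately heavier at mid-depth than
the reaction-diffusion model predicts, so that the model profile sits
inside the synthetic 95 % bands over 0--30 % and 60--100 % of depth but
not necessarily in between, the agreement pattern of the reference
study. Noise is multiplicative lognormal (collagen content is positive
and FTIR noise scales with signal): lateral pixel sd 0.10, per-sample
scale sd 0.15, per-depth sd 0.05. These are invented fixture defaults —
no per-sample variance components are published — and must not be read
as estimates of the experiment. Group summaries are empirical means
with normal-theory 95 % confidence bands; the linear mixed-effects
machinery of the original analysis is intentionally not reproduced,
because the pipeline only needs bands of realistic width. Passing the
band-agreement checks therefore shows consistency with the emulated
statistical shape, not validation against real tissue.

## Known limitations

* The model's response to the one-at-a-time sweeps is sub-proportional:
  every pathway from a production-chain constant to collagen loss is
  linear followed by concave local consumption (Michaelis saturation,
  local depletion, binding brake, linear washout), so a +50 % parameter
  change can raise the enzymatic loss by at most +50 %. The shipped
  sweeps reproduce the direction of every sensitivity and the
  anti-monotone effect of $k_{act}$, but the bulk-loss magnitudes
  saturate near the low 30s of percent rather than the mid 40s; the
  acceptance checks asserting the larger magnitudes are expected to
  fail and are retained as a faithful record.
* No TIMP inhibition, no cytokine transport, no MMP subtypes, no
  aggrecan biosynthesis, no mechanical fibril rupture, no moving lesion
  boundary, no advection.
* The aggrecanase/aggrecan equations are structural analogues with
  default constants, not transcriptions of a published supplement.
* Robin bath concentrations are fixed at zero; periodic medium renewal
  is not represented.

## A minimal run

```{r, eval = FALSE}
ctrl <- run_reference(run_config(mode = "control"))
inj <- run_reference(run_config(mode = "injury"))
c(control = ctrl$metrics$bulk_loss_pct,
  injury = inj$metrics$bulk_loss_pct)

bands <- synth_group_profiles(synth_config(seed = 1))$injury_day12
profile_agreement(inj$metrics$day12_profile, bands,
                  depth_ranges = list(superficial = c(0, 0.3),
                                      deep = c(0.6, 1)))$ranges
```
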