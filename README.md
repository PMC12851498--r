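# cartdegen

Mechano-signaling simulation of post-traumatic collagen loss in
cartilage explants.

After a joint injury, cartilage can degenerate for years
(post-traumatic osteoarthritis). One candidate mechanism for the
earliest collagen loss is cell-mediated: excessive shear strain during
the injurious compression damages chondrocytes, damaged cells release
matrix metalloproteinases (MMPs) with a delay of days, and the enzymes
cleave the collagen network — most strongly near the articular surface
where strains concentrate. `cartdegen` implements this chain as a
testable pipeline for a 3 mm x 1 mm explant cross-section:

* **Damage function**: maximum shear strain
  `eps = max(|e1-e2|, |e1-e3|, |e2-e3|)` of the principal
  Green–Lagrange strains maps to a damaged-cell fraction — zero below
  `eps = 0.4`, saturating at `eps = 1.5`, capped at 35 % of the healthy
  population (`k_INJ = 0.35`).
* **Delayed release**: stimulus variables
  `dS/dt = alpha (k C_dmg - S)` delay MMP and aggrecanase activation.
* **Reaction–diffusion**: six species (intact/degraded collagen,
  intact/degraded aggrecan, MMP, aggrecanase) evolve by
  `dC/dt = D lap(C) ± R` on a structured grid with zero-flux, Robin and
  Dirichlet boundary conditions; collagen is cleaved by
  Michaelis–Menten MMP kinetics modulated by a Hill function of total
  aggrecan, plus a first-order basal loss calibrated to the 19 %
  12-day loss of free-swelling controls.
* **Metrics and sensitivity**: bulk percent loss, depth-wise profiles
  against banded reference profiles, and one-at-a-time sweeps of the
  six design parameters.
* **Synthetic data**: FTIR-like collagen maps, depth-wise group
  profiles with 95 % confidence bands, strain-field fixtures and lesion
  polygons, all seeded — every stage is testable with no downloads.

The mechanics itself (fibril-reinforced poroelastic finite elements) is
out of scope: the shear-strain field is pluggable (analytic surrogate,
parametric depth-decaying generator, or CSV import).

## Worked example

```r
library(cartdegen)

ctrl <- run_reference(run_config(mode = "control"))
inj  <- run_reference(run_config(mode = "injury"))
round(c(control = ctrl$metrics$bulk_loss_pct,
        injury = inj$metrics$bulk_loss_pct), 2)
#> control  injury
#>   19.00   30.07

head(round(inj$metrics$day12_profile, 2), 4)
#>   depth value
#> 1  0.00 47.68
#> 2  0.05 48.01
#> 3  0.10 51.40
#> 4  0.15 55.60
```

The free-swelling control loses 19.0 % of bulk collagen over 12 days
(pure basal decay, matching the closed-form exponential); the injury
run loses 30.1 %, concentrated superficially: at day 12 the surface
retains ~48 % of its initial collagen while the deep tissue retains
~77 % (mostly basal loss). Comparing against synthetic group profiles:

```r
bands <- synth_group_profiles(synth_config(seed = 1))$injury_day12
ag <- profile_agreement(inj$metrics$day12_profile, bands,
                        depth_ranges = list(superficial = c(0, 0.3),
                                            deep = c(0.6, 1)))
ag$ranges
#> superficial        deep
#>           1           1
```

The simulated day-12 profile lies entirely inside the 95 % bands of the
synthetic injury group over the superficial (0–30 %) and deep
(60–100 %) depth ranges. A sensitivity sweep:

```r
sw <- run_sweep(sweep_spec("k_INJ", c(0.2, 0.35, 0.5)),
                run_config(mode = "injury", nx = 31, nz = 21, dt = 600))
sw$table
#>   parameter value bulk_loss_pct delta_vs_reference
#> 1     k_INJ  0.20      26.78619          -3.316663
#> 2     k_INJ  0.35      30.10285           0.000000
#> 3     k_INJ  0.50      32.74110           2.638245
```

Bulk loss increases monotonically with the damaged-cell cap, with the
extra loss concentrated in the superficial region.

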