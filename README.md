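# toxsel

Spatial dynamic flux balance analysis (dFBA) of selection for microbial
toxin production, plus the companion comparative-genomics statistics.

## The problem

Secreting an antimicrobial toxin is costly, and whether it pays depends on
how localized competition is. In a well-mixed culture a diffusible toxin is
shared with everyone — including resistant cheaters that pay no cost — and
producers lose. On a surface, toxins and nutrients travel a finite distance
per generation, so a producer can suppress its immediate susceptible
neighbours and keep the freed resources. Because faster growth shortens
that interaction length scale, growth rate itself should modulate selection
for toxin production.

`toxsel` is for microbial ecologists and modellers who want to simulate
this mechanism quantitatively. It implements:

* **Strain models** — generic 3–5 reaction stoichiometric models of a toxin
  producer (biomass reaction: $-(1+\alpha)\,\mathrm{carbon} \rightarrow
  \tau(1+\alpha)\,\mathrm{toxin}$ per unit biomass flux, cost $\alpha$,
  toxin coefficient $\tau$ in mmol/gDW), a susceptible competitor and a
  resistant cheater. Per-step growth solves
  $\max v_{\text{biomass}}$ s.t. $Sv = 0$, $0 \le v \le u$, with closed
  form $\mu = \min(u\,Y/(1+\alpha),\, b_{\text{signal}})$.
* **A signalling extension** — the susceptible growth bound falls
  bounded-linearly with the local toxin level:
  $b = \mu_{\max}\max(0,\, 1 - \mathrm{conc}/K)$, zero at and beyond
  $K = 15$.
* **A lattice batch engine** — 50 × 50 boxes (0.01 cm), carbon seeded once,
  explicit reaction–diffusion stepping with no-flux boundaries, automatic
  diffusion sub-stepping, per-colony biomass layers, stationary-phase
  termination; plus a deterministic well-mixed control mode.
* **Metrics** — producer invasion and producer-vs-cheater relative fitness,
  maximum spatial coefficient of variation of toxin, and the
  proximity-effect slope (susceptible biomass vs distance to producers).
* **Experiment drivers** — the growth-rate series (5 rates × 15 layouts +
  liquid controls) and one-axis parameter sweeps (toxin coefficient, toxin
  diffusion, colony density, seeding ratio).
* **Genomics statistics** — logistic regressions of biosynthetic gene
  cluster presence on maximal growth rate ($\mu = \ln 2/d$), Poisson
  regressions for toxin-gene counts, Benjamini–Hochberg correction, and a
  confidence-interval resampling robustness procedure, with a synthetic
  feature-table generator for validation.

See `vignettes/toxin-selection-methods.Rmd` for the model, assumptions and
design decisions.

## Worked example

```r
library(toxsel)

cfg <- simulation_config(growth_rate = 1, spatial_seed = 1)
res <- run_batch(cfg)
res
#> <toxsim_result> 50 colonies, t = 13.7 hr (stationary)
#> final biomass by role (gDW):
#>     producer    resistant  susceptible
#> 9.699622e-05 1.050028e-04 7.970410e-04

fitness_summary(res)
#> # A tibble: 1 x 5
#>   producer_fraction_total producer_fraction_vs_resistant invaded beats_resistant
#>                     <dbl>                          <dbl> <lgl>   <lgl>
#> 1                  0.0971                          0.480 FALSE   FALSE
#> # i 1 more variable: initial_producer_frequency <dbl>

toxin_cv_max(res)
#> [1] 3.470129
proximity_effect(res)
#> [1] 1.329037
```

At the default conditions the producer ends just below its 10% starting
frequency (its 1% growth cost slightly outweighs the toxin benefit), while
the positive proximity slope shows susceptible colonies near producers grew
measurably less — the localization signal. Running the same configuration
at `growth_rate = 0.125` gives a smaller slope (≈0.46): slower growth makes
competition more global. `run_well_mixed(cfg)` gives the liquid control,
`autoplot(res)` / `autoplot(res, "toxin")` plot trajectories and fields,
and

```r
tab <- run_sweep(preset_parameter_sweep("toxin_coefficient"))
plot_sweep_heatmap(tab, "toxin_coefficient")
```

runs and draws a full sweep. The genomics side works on plain data frames:

```r
gt <- synth_genome_table(1000, betas = c(nrps = 2, terpene = 0), seed = 1)
fit_bgc_all(gt)
resample_robustness(gt, scheme = "uniform_ci", n_reps = 1000, seed = 1)
```

A thin command-line wrapper with `simulate`, `sweep` and `stats`
subcommands is installed at `inst/cli/toxsel`.

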