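---
title: "Modelling selection for toxin production in structured microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling selection for toxin production in structured microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxsel)
```

## The question and the model

Many soil and surface-dwelling bacteria secrete costly antimicrobial
compounds. Whether such toxin production is selected for depends on how
localized competitive interactions are: in a well-mixed culture a diffusible
toxin is shared with the whole community (including resistant cheaters that
pay no production cost), while on a surface it can stay concentrated around
the producer and clear out the immediate neighbourhood. Because faster
growth shortens the distance over which nutrients and toxins travel per
generation, growth rate itself should tune the strength of selection for
production.

`toxsel` implements a minimal dynamic flux balance analysis (dFBA) model of
this situation. Three generic strains compete for a single carbon source on
a two-dimensional lattice (or in a well-mixed batch):

* a **producer**, which secretes a toxin in direct proportion to its growth
  and pays a fractional cost;
* a **susceptible** competitor, whose growth bound falls with the local
  toxin level;
* a **resistant** cheater, which neither produces nor responds.

Each strain is a three-to-five reaction stoichiometric model (carbon
exchange, carbon transport, biomass; producers add toxin transport and
exchange; susceptibles add a structural, zero-flux toxin uptake reaction).
The biomass reaction of a strain with fractional cost $c$ and yield $Y$
(gDW biomass per mmol carbon) consumes $(1+c)/Y$ carbon per unit biomass
flux; a producer with toxin coefficient $\tau$ (mmol toxin per gDW) also
emits $\tau(1+c)$ toxin per unit flux. Per box and time step the growth
linear program

$$\max \; v_{\text{biomass}} \quad \text{s.t.} \quad S v = 0,\;
0 \le v \le u$$

has the closed-form optimum
$\mu = \min\!\big(u_{\text{uptake}}\, Y/(1+c),\; b_{\text{signal}}\big)$,
which the engine uses directly; `solve_growth(method = "lp")` solves the
same LP generically (any stoichiometric matrix) through a simplex routine
and is cross-checked against the closed form in the test suite.

All strains share one carbon uptake bound $v_{\max} = \mu_{\text{target}}/Y$,
so the cost is a true growth-rate cost: with a 1% production cost the
producer grows at $\mu_{\text{target}}/1.01$ and reaches 99% of the biomass
of a cost-free strain on the same carbon.

### The toxin signal

The susceptible response is *bounded linear*: the growth bound is
$b(\text{conc}) = \mu_{\max} \max(0, 1 - \text{conc}/K)$ — unmodified at
zero toxin, zero at and beyond `conc_where_effect_ends` ($K$, default 15),
never negative. The signal level is, by default, the local toxin
**concentration**: the per-box amount divided by the box volume
$\mathrm{dx}^3$ (units mmol cm$^{-3}$). This is the convention of
lattice dFBA platforms, where media amounts are tracked per box in mmol and
kinetic/signalling functions act on concentrations;
`signal_on = "amount"` switches to the raw per-box amount instead. The
choice of reference volume matters quantitatively (see *Limitations*), so
it is stated with every result.

Other functional forms can be attached through `signal_response(form =
"custom")`; only the bounded-linear form is built in, since alternative
shapes change quantitative detail rather than the phenomenon the package
studies.

## The lattice engine

`run_batch()` integrates a batch culture by operator splitting with macro
step `dt` (default 0.1 hr):

1. **Growth**: in every box, every colony's growth rate comes from the
   closed-form flux solution under its carbon-limited uptake bound (the
   bound is capped so one Euler step cannot overdraw the box's carbon) and
   its signal bound from the local toxin. If the summed demand in a box
   still exceeds the carbon present, all colonies' uptake there is scaled
   by one common factor — proportional, order-independent allocation.
   Biomass updates are explicit Euler ($\Delta B = (\mu - \delta) B\,dt$),
   keeping the resource coupling exact within a step.
2. **Diffusion**: carbon, toxin and each colony's biomass layer diffuse by
   an explicit 5-point stencil with no-flux boundaries, internally
   sub-stepped so every sub-step satisfies $D\,dt/dx^2 \le 0.25$. The
   update conserves mass to floating point and preserves non-negativity
   for any diffusion constant, so no separate stability configuration is
   needed.

Each founder colony is simulated as its own biomass layer, so
individual-colony trajectories are exact even though genotypes may overlap
in a box. Runs terminate at stationary phase — relative change of total
biomass per macro step below `stationary_tol` (default $10^{-6}$) —
extending past the nominal `max_time` (default 75 hr) when needed; a run
still changing at the hard cap is returned flagged (`converged = FALSE`),
never silently truncated.

`run_well_mixed()` is the liquid control: a single box holding the whole
carbon inventory and all inocula, no diffusion, signal referenced to the
whole-environment volume. It is deterministic (bit-identical across
repeats) because placement randomness is the only stochastic element of the
model.

### Default study conditions

| parameter | default | unit |
|---|---|---|
| lattice | 50 × 50 boxes, dx = 0.01 | cm |
| carbon per box | 4e-7 | mmol |
| founder colonies | 40 susceptible / 5 resistant / 5 producer | — |
| inoculum per colony | 2e-10 | gDW |
| growth rate target | 0.125–1 | hr⁻¹ |
| production cost | 1% | of growth |
| resistance cost | 0 | — |
| toxin coefficient | 15 | mmol/gDW |
| K (effect ends) | 15 | signal units |
| D (resource / toxin / biomass) | 5e-6 / 5e-7 / 5e-9 | cm² s⁻¹ |
| dt (macro) | 0.1 | hr |

The biomass diffusion constant is not part of the published parameter
tables this design mirrors; 5e-9 cm² s⁻¹ keeps colony spreading slow
relative to solutes (a colony blurs over a few boxes during a run). The
macro step defaults to 0.1 hr rather than a coarser cycle because the
operator-split integrator is then convergent: halving `dt` changes final
per-strain totals by well under 1% (tested). Both are configurable, and the
acceptance script prints the values used alongside its results.

## Metrics

* `fitness_summary()`: producer fraction of the final total biomass
  (invasion if strictly above the initial producer frequency) and of the
  producer+resistant pool (strictly above 0.5 beats the cheater, matching
  the 1:1 producer:resistant seeding).
* `toxin_cv_max()`: per recorded step, the coefficient of variation of the
  toxin field over all boxes (population SD, $n$ denominator, divided by
  the mean; zero-mean steps skipped), maximized over the run — peak spatial
  heterogeneity of toxin exposure.
* `proximity_effect()`: OLS slope of each susceptible colony's final
  biomass — scaled by the replicate's maximum susceptible colony biomass —
  against its mean Euclidean distance (cm) to all producer founders.
  Max-scaling makes the slope scale-free; mean-scaling and raw biomass are
  available (`scale =`), since the choice of normalization is a genuine
  free parameter of this statistic.
* `classify_fitness()`: low / intermediate / high against a threshold, with
  exact equality mapped to intermediate (float ratios rarely hit it; the
  classification is meant for tabulated summaries).

## Experiment drivers

`preset_growth_rate_series()` enumerates the reference design: growth rates
{0.125, 0.25, 0.5, 0.75, 1} hr⁻¹ × 15 seeded spatial layouts plus one
liquid run per rate. `preset_parameter_sweep(axis)` crosses one axis —
toxin coefficient {1, 15, 30, 50, 75}, toxin diffusion {5e-8 … 5e-5}
cm² s⁻¹, colony density {10 … 90} at the fixed 80:10:10 ratio, or
producer/resistant seeding fraction {0.02 … 0.4} — with the growth-rate
axis and layout seeds {1, 2, 5}. Fractional colony counts round to the
nearest integer with susceptibles absorbing the remainder
(`colony_counts()`). `run_sweep()` executes the grid deterministically and
returns one tidy row per run with parameters, fitness, toxin CV and
proximity slope.

## Comparative-genomics module

Independent of the simulator, `toxsel` ships the statistical pipeline for
testing whether genomes predicted to grow faster are more likely to carry
biosynthetic gene clusters (BGCs):

* growth rates from doubling times, $\mu = \ln 2 / d$;
* per-class logistic regressions of presence on growth rate
  (`fit_bgc_logistic()`, `fit_bgc_all()`), with profile-likelihood 95% CIs
  (Wald fallback, flagged) and manual Benjamini–Hochberg step-up adjustment
  (`bh_adjust()`, verified against `stats::p.adjust` in the tests);
* Poisson log-link regressions for toxin-gene counts
  (`fit_count_poisson()`);
* `resample_robustness()`: redraw each genome's doubling time from its 95%
  CI — uniform between the bounds, or normal with
  $\mathrm{sd} = \sqrt{n}\,(\text{upper} - \text{lower})/(2 \times 1.96)$ —
  refit everything, re-adjust, and flag classes significant with a
  consistent coefficient sign in ≥95% of replicates.

Two deliberate decisions deserve emphasis. First, the "sample size" term in
the normal-resampling SD formula is implemented exactly as written and
exposed as the `sample_size` argument, because with $n$ = number of genomes
it inflates the SD far beyond the CI width (for ~3000 genomes, ~14× the
interval) — a scientifically surprising but faithful reading; callers can
pass `sample_size = 1` for an SD on the scale of the interval itself.
Second, significance inside replicates uses BH-adjusted p-values (matching
the main analysis); replicate fits use Wald slope tests for speed, while
the reference fit uses the full profile machinery. Normal draws are
truncated below at 0.01 hr so resampled doubling times stay positive.

`synth_genome_table()` generates feature tables with known ground truth —
lognormal doubling times (median 1.5 hr, most mass 0.5–5 hr, a realistic
copiotroph range), logistic presence classes, multiplicative CI bounds and
optional Poisson counts — which is how the regression machinery is
validated (null behaviour, parameter recovery, consistency with an
independent IRLS oracle). The generator emulates the *shape* of real
feature tables, not their confounders: no phylogenetic correlation, no
class co-occurrence, no growth-rate measurement structure beyond the CI
widths. Passing its tests therefore demonstrates correctness of the
estimators, not that real genomic correlations will replicate.

## Numerical and design notes

* Proportional carbon allocation in shared boxes is deterministic and
  order-independent; a joint LP across colonies would differ only when the
  signal bound binds asymmetrically and is out of scope.
* Coordinates are 0-based (row, column); distances are in box units times
  `dx`.
* Colony placement uses a private RNG stream (the caller's `.Random.seed`
  is untouched), uniform without replacement; identical seeds give
  identical layouts.
* Genotype overlap in a box is allowed; each colony's layer keeps its
  identity under diffusion.
* Degenerate inputs: zero-growth worlds converge immediately; zero inocula
  stay zero; all-zero communities raise an error in `fitness_summary()`;
  constant or separated presence columns are flagged degenerate and
  excluded from multiplicity adjustment.

## Limitations

The headline caveat is quantitative. With the default study conditions the
total toxin inventory at stationary is
$\tau(1+\alpha) \times$ (producer biomass) $\approx 1.5\times10^{-3}$ mmol
over a 2.5×10⁻³ cm³ environment — a mean concentration of ~0.6 mmol cm⁻³
against $K = 15$, with simulated per-box peaks of only ~1.6–3.6 near
producers at $\mu = 1$ hr⁻¹. Susceptible growth is therefore reduced by at
most ~10–25%, locally and late in growth. The qualitative localization
trends are robust (toxin heterogeneity and the proximity-effect slope rise
with growth rate; producers always fare better spatially than in liquid),
but at these parameter values the producer's toxin benefit does not exceed
its 1% growth-rate cost by enough to cross the strict invasion thresholds,
and sweep optima over toxin output and density are correspondingly shallow.
Rescaling the signal reference volume to force threshold crossings makes
producers invade in liquid and at low growth rates instead — inverting the
phenomenon — so the package keeps the faithful parameterization and reports
what it produces. Treat absolute fitness fractions as model-relative, and
the localization metrics as the robust outputs.

Other scope limits: two-dimensional lattices only; bacteriostatic toxin
action (a death-rate signal hook exists but no lysis/nutrient recycling);
constitutive production; single batch cycles (no chemostat flow); and the
genomics module accepts pre-computed feature tables only — it does not run
gene-cluster prediction or growth-rate inference tools, and performs no
phylogenetic correction.

## Problem sizes

Unit and property tests run on reduced lattices (10–21 boxes a side, 4–10
colonies) where every identity is checked to tight tolerances; the
acceptance-level checks run the full 50 × 50 design with 3 layout seeds per
condition and growth rates down to 0.125 hr⁻¹, the sizes at which the
package's own headline numbers are computed.
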