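# lacdfe

Distribution of fitness effects (DFE) of regulatory mutations in the
*E. coli* lactose-utilization network, simulated from a mechanistic ODE
model of the *lac* operon.

## Who this is for

Evolutionary systems biologists who want to derive the statistical
properties of a fitness landscape — which fraction of mutations is
beneficial, how effect sizes are distributed, how beneficial mutations
interact — from the mathematical model of a specific, well-characterized
regulatory network rather than from abstract mutational models or
population data.

## The model

Three dynamic species (LacZ, LacY, intracellular lactose) plus a decoupled
repressor pool:

```
d[LacZ]/dt   = Bas1 + K^y/(K^y_m + [lacI]) − kd1 [LacZ]
d[LacY]/dt   = (Bas1 + K^y/(K^y_m + [lacI])) Kt − kd2 [LacY]
[lacI_tot]   = Bas2/kd3              (steady state of a linear equation)
[lacI]       = [lacI_tot] / (1 + [lac_in]/K)
d[lac_in]/dt = k1 [LacY] lac_out/(k2 + lac_out) − k3 [LacZ] [lac_in]/(k4 + [lac_in])
```

Fitness is a steady-state cost–benefit balance,

```
f = Benefit − Cost
  = k3 [LacZ][lac_in]/(k4+[lac_in]) − α (α_z [LacZ] + α_y [LacY] + α_I [lacI_tot]),
```

lactose metabolized per unit time minus the protein-production expenditure
needed to sustain it. Mutations perturb one of five regulatory parameters
(`bas1`, `bas2`, `Ky`, `Kmy`, `Kt`) at a time, redrawn from a normal
distribution centred on the current value; the resulting fitness changes
over ~10,000 mutations form the DFE of a genetic background. The pipeline

1. estimates the maximum attainable fitness `fmax` over the mutable box,
2. samples replicated, distinct parameter sets at 0.001, 0.1 and 0.5 of
   `fmax`,
3. builds and classifies DFEs on each background, fits exponential
   distributions to beneficial and deleterious effect sizes by binned
   least squares, and detects two-peaked deleterious DFEs,
4. quantifies pairwise epistasis between beneficial mutations
   (Δf on the original background vs Δf\* on mutated backgrounds).

The numeric defaults (`inst/extdata/default_config.yaml`) are documented
package choices in consistent arbitrary units — see the methods vignette
(`vignettes/lacdfe-methods.Rmd`) for every parameter, its units, and the
rationale, as well as for the design decisions and known divergences
between the printed model equations and the published narrative.

## Worked example

```r
library(lacdfe)
cfg <- lac_config()

fm <- estimate_fmax(cfg, seed = 1)
fm
#> <lac_fmax> fmax = 23799 (best of 32 starts)
#>   at: bas1=0.5, bas2=0.001, Ky=20, Kmy=0.01, Kt=1

sets <- sample_at_fitness(cfg, fraction = 0.001, count = 3,
                          fmax = fm$fmax, seed = 7)
sets
#>     bas1   bas2      Ky    Kmy     Kt fitness fraction fmax_used
#> 1 0.4945 0.7961  8.5731 3.4967 1.0000  23.799    0.001  23798.97
#> 2 0.4235 0.9967 15.8117 7.1182 1.0000  23.799    0.001  23798.97
#> 3 0.1685 0.0010  5.7403 2.9844 0.8423  23.799    0.001  23798.97

bg  <- unlist(sets[1, mutable_params()])
dfe <- build_dfe(bg, 10000, cfg, seed = 42)
classify_dfe(dfe)
#>       n fraction_beneficial fraction_deleterious fraction_neutral ...
#> 1 10000               0.309                0.691                0

fit_exponential(dfe$delta_fitness[dfe$effect == "beneficial"])
#> <lac_expfit> lambda = 0.717984, R2 = 0.9743 (34 bins, n = 3090)
```

Reading the output: the three sampled backgrounds all sit at fitness
23.8 = 0.001·fmax but at different points of parameter space. On the first
background, 30.9% of 10,000 random regulatory mutations increase fitness,
and the distribution of beneficial effect sizes is well described by an
exponential with rate λ ≈ 0.72 (R² = 0.97 on the binned density) — the
exponential-beneficial-DFE regime, with the beneficial share shrinking on
fitter backgrounds. `dfe_experiment()` repeats this across fitness levels,
`epistasis_scan()` runs the two-background comparison, `autoplot()` methods
draw each result type, and `run_full_study()` writes the full set of TSV
tables plus a reproducibility manifest. A thin command-line wrapper with
the same stages lives in `inst/cli/lacdfe`.

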