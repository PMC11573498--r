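# oystergrowth

Size demography for archaeological oyster assemblages: tools to decide
whether the shells in a midden got smaller because people harvested them
younger, or because the oysters grew more slowly.

A small shell is ambiguous — it may be *young* (harvest pressure) or
*slow-grown* (poor growing conditions). `oystergrowth` separates the two
channels for per-shell records of hinge size (mm, the size proxy that
survives fragmentation) and sclerochronological age (integer years from
annual increment lines):

* **Growth model** — fits the standardized von Bertalanffy growth curve
  `H(A) = H∞(1 − e^(−k(A − t0)))` to all hinge-at-age records by
  nonlinear least squares, and computes each shell's growth residual
  `rᵢ = Hᵢ − H(Aᵢ)` (negative = slower than typical for its age).
* **Size conversion** — estimated total length `= 35.4 · ln(hinge)`
  (both mm), derived on demand.
* **Comparisons** — two-sided Mann–Whitney U tests (exact enumeration
  for small samples, tie-corrected normal approximation otherwise),
  variance-ratio F and Levene tests for spread, Bonferroni correction
  with per-variable site families.
* **Variance partition** — Johnson relative-weights analysis splitting
  each site's hinge-size variance between age and growth rate
  (plus multiple regression with standardized coefficients and VIFs).
* **Stratigraphy** — ordered layer-by-layer summaries, run structure of
  layer-to-layer changes, and age–size concordance.
* **Synthetic assemblages** — a seeded generator with independent
  harvest-pressure and growing-condition knobs per layer, plus named
  scenario presets, so the whole pipeline is testable end to end.

## Worked example

```r
library(oystergrowth)

asm <- simulate_assemblage(scenario_preset("stable", seed = 42))
asm
#> <assemblage> 2030 shells from 20 site(s)
#>   hinge+age: 1335  hinge only: 594  age only: 101
#>   provenance: simulated scenario (seed 42, 20 sites x 8 layers x 13 shells)

summarize_metrics(asm)
#> Summary metrics (present values only):
#>   variable    n  min   q1 median mean   q3   max
#>   hinge_mm 1929  1.5  4.5    7.9  8.9 12.5  28.4
#>  length_mm 1929 14.4 53.2   73.2 70.1 89.4 118.5
#>  age_years 1436  1.0  2.0    3.0  4.4  6.0  25.0

fit <- fit_growth_curve(asm)
fit
#> Standardized von Bertalanffy growth curve
#>   h_inf = 26.1006 mm   k = 0.10945 /y   t0 = -0.0118 y
#>   n = 1335 complete records   SSR = 1495.4597 mm^2   converged: TRUE (4 iterations)

res <- compute_residuals(fit, asm)
part <- partition_by_site(asm, res)
head(as.data.frame(part), 3)
#>   site  n n_levels r_squared weight_age_pct weight_growth_pct reliable
#> 1  S01 68        8 0.9617149       95.76050          4.239504     TRUE
#> 2  S02 63        8 0.9583509       92.21626          7.783739     TRUE
#> 3  S03 61        8 0.8755445       92.16050          7.839501     TRUE

attribution_summary(part)$majority
#> [1] "age"
```

The fitted curve recovers the scenario's generating parameters
(H∞ = 26, k = 0.11, t0 = 0), and — because the `"stable"` scenario varies
age-at-harvest but holds growing conditions fixed — the partition
attributes almost all hinge-size variance to age. Swapping in the
`"environmental_decline"` preset flips the majority to growth rate;
`compare_by_period()` and `layer_sequence()`/`trend_descriptors()` give
the period-level tests and stratigraphic trends for the same objects.

Real data enter through `read_assemblage("shells.csv")` (canonical
columns `shell_id,site,period,layer_label,layer_order,hinge_mm,age_years`;
arbitrary headers via a column-mapping), and `run_pipeline()` executes
every stage in order, writing one config-stamped CSV per stage. A thin
command-line wrapper lives at `inst/scripts/oyster-pipeline.R`.

## The methods vignette

`vignettes/decoupling-harvest-and-environment.Rmd` documents the model
and its assumptions, every numerical choice in the fitter and the tests,
the design of the scenario presets, and what a passing simulation suite
does and does not establish about real middens.
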