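# phantomqa

Virtual phantom simulation and quality assurance for cardiac T1/T2
mapping.

Quantitative cardiovascular magnetic resonance (CMR) T2 mapping can flag
myocardial oedema and inflammation, but measured T2 varies with scanner,
software and sequence, so sites need a reference object — a phantom of
nickel-chloride/agarose gel tubes with known relaxation times — and a
reproducible chain of arithmetic to qualify it. `phantomqa` implements
that chain end to end for a nine-tube phantom covering the myocardial
T2 range (~35–70 ms by spin echo), entirely in software:

- **Recipe design.** Relaxation rates are modeled as linear in the
  ingredient concentrations,
  `R1 = 1000/T1 = r1_0 + r1_Ni·[Ni²⁺] + r1_ag·[agarose]` (1/s; Ni²⁺ in
  mM, agarose in % w/v) and analogously for `R2`. Fitting the planes by
  ordinary least squares to a calibration table and inverting the 2×2
  slope matrix yields the concentrations for any feasible target
  (T1, T2) pair.
- **Virtual phantom.** A 3×3 array of 24 mm tubes in a 100×100 mm body
  is rasterized to per-pixel ground truth; simulators generate the
  acquisitions used in phantom QA — inversion-recovery gradient echo
  and single-echo spin echo (closed-form reference sequences), 5(3)3
  MOLLI and T2-prepared bSSFP (full Bloch-vector event simulations),
  dual-echo B0 mapping and double-angle B1 mapping — with Rician noise,
  B0/B1 field conditions and temperature scaling.
- **Map fitting.** Pixel-wise mono-exponential T2, three-parameter
  inversion recovery with polarity restoration, and Look-Locker
  corrected MOLLI T1 (`T1 = T1*·(B/A − 1)`), all via variable projection
  with deterministic global initialization.
- **QA statistics.** Central-50%-radius tube ROIs, bias tables against
  the spin-echo reference (per-tube differences, all-tube and
  corner-tube means), two-point coefficients of variation,
  baseline-vs-repeat reproducibility, temperature trends and the
  boundary-inclusive CoV ≤ 2.7% qualification verdict.

The packaged fixtures include the published nine-tube calibration table
(bench 1.4 T relaxometry plus 1.5 T/3 T reference measurements) and the
published benchmark tables of bSSFP-vs-spin-echo T2 and 12-month repeat
T2, which the package recomputes cell by cell.

## Worked example

```r
library(phantomqa)

# 1. Fit the relaxivity model and design a recipe for T1 600 ms / T2 45 ms
model <- fit_relaxivity_model(calibration_fixture(), "1.4T")
model
#> Relaxivity model (1.4T, n = 9 rows)
#>   R1 [1/s] = 0.3765 + -0.0003 [Ni mM] + 0.6680 [agarose %]  (sd 0.0025)
#>   R2 [1/s] = -0.2708 + 7.7639 [Ni mM] + 0.7498 [agarose %]  (sd 0.1213)
design_recipe(600, 45, model)
#> $agarose_pct
#> [1] 1.932319
#> $ni_mM
#> [1] 2.710504
```

The fit's dominant coefficients are large and positive (each ingredient
shortens its relaxation time); the tiny negative Ni-on-R1 cross term is
far below the residual SD — see the methods vignette on the collinearity
of this calibration. The designed recipe reproduces the target exactly
under the forward model.

```r
# 2. Simulate a noisy T2-prepared bSSFP acquisition at 1.5 T and map T2
truth <- rasterize_layout(default_phantom_layout(), pixel_size = 1,
                          field = "1.5T")
stack <- simulate_t2prep_bssfp(truth, noise_sd = 0.004, seed = 42)
t2map <- reconstruct_map(stack, truth = truth)
stats <- tube_statistics(t2map, locate_tube_rois(truth))

# 3. Bias of mapped T2 against the spin-echo truth
se_ref <- setNames(vapply(1:9, function(l)
  truth$t2_map[truth$label_map == l][1], numeric(1)), truth$tube_ids)
bias_table(setNames(stats$mean, stats$tube_id), se_ref)$summary
#>     group n mean_abs_diff_ms mean_pct
#> 1     all 9             8.71    17.19
#> 2  corner 4            14.51    33.93
#> 3 central 5             4.08     7.15
```

The simulated bSSFP mapping overestimates T2 everywhere (mean +8.7 ms),
far more for the short-T1 post-contrast corner tube I (+27.7 ms,
truth 41 ms) than for the long-T1 central tubes — the T1-dependent
readout bias that makes corner/central and per-tube bias tables the
core of phantom QA reporting.

```r
# 4. Recompute the published benchmark-table arithmetic
res <- reproduce_tables()
res$all_match
#> [1] TRUE
```

A command-line wrapper (`inst/cli/phantomqa`) exposes the same pipeline
as subcommands `design`, `simulate`, `fit`, `fieldmap`, `qa` and
`reproduce-tables`, e.g.
`phantomqa design --t1 600 --t2 45 --out recipe.csv`.

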