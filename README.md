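# brdusim

Simulation of full label-intensity distributions for proliferating cell
populations in BrdU labeling experiments.

Bromodeoxyuridine (BrdU) is a thymidine analogue incorporated into newly
synthesized DNA at cell division.  While label is administered
("uplabeling"), content accumulates over divisions; once it is withdrawn
("delabeling"), content halves at every division.  Classical analyses
collapse the measured intensities into the fraction of labeled cells or
the mean fluorescence intensity (MFI), discarding the shape of the
distribution — and they assume every division takes up the same fixed
amount of label, which real data contradict.

`brdusim` treats the per-division uptake as a random draw `U` from a
*labeling-efficacy distribution* and simulates the resulting
population-level intensity distribution.  For whom: modelers of
proliferation assays (BrdU, and by extension other dilution labels) who
want distribution-level model output to compare against cytometry
histograms.

## Model

Two components are combined:

1. **Division-structured population model.**  Cell counts `N(i|t)` are
   indexed by the vector `i = (i_1, ..., i_K)` of divisions undergone
   during each labeling phase `(T_{k-1}, T_k]`, and obey the linear ODEs
   (during phase `k`)

   ```
   dN(i|t)/dt = -(alpha_i(t) + beta_i(t)) N(i|t) + 2 alpha_{i-e_k}(t) N(i-e_k|t)
   ```

   with all cells undivided at `t = 0`.  The index set is truncated at
   `S` divisions per phase (default 20); the truncation deficit is
   quantified by `truncation_error()`.

2. **Label-content model.**  A daughter cell keeps half of its mother's
   content and receives half of a fresh uptake draw:
   `X' = U/2 + X/2`.  Iterating from `X = 0` gives the conditional
   density `p(x|i)` — computed in closed form for Dirac/normal/mixture
   efficacies (mixtures of Gaussians and point masses) or by exact
   grid convolution for arbitrary densities.

The measurable output is the overall label distribution

```
m(x|t) = sum_i N(i|t) p(x|i)
```

with summaries `fraction_labeled()` (threshold count), `mean_intensity()`
(MFI), `count_peaks()`, and `sample_intensities()` (simulated listmode
readout).  A transport-equation solver (`pde_reference_solver()`)
integrates the number densities `n(x, i|t)` directly and cross-validates
the decomposed construction.

## Worked example

The built-in noisy-uptake scenario: 1000 cells, division and death rates
`alpha = beta = 0.1/d`, 10 days of uplabeling with efficacy
`N(1, 0.2^2)`, then 10 days of delabeling:

```r
library(brdusim)
res <- run_scenario(scenario_noisy_uptake())
res$summaries
#>    time_d total mean_intensity peaks frac_labeled_0.1
#> 1       2  1000         0.1813     1           0.3297
#> 2       4  1000         0.3297     1           0.5507
#> 3       6  1000         0.4512     2           0.6988
#> 4       8  1000         0.5507     2           0.7981
#> 5      10  1000         0.6321     2           0.8647
#> 6      12  1000         0.5175     3           0.8579
#> 7      14  1000         0.4237     5           0.8308
#> 8      16  1000         0.3469     7           0.7815
#> 9      18  1000         0.2840     8           0.7146
#> 10     20  1000         0.2325     7           0.6368
```

Reading the table: the total stays at 1000 cells because division and
death balance.  The MFI after `t` days of uplabeling equals
`1 - E[2^-D]` with `D ~ Poisson(2 alpha t)`, i.e. `1 - exp(-alpha t)`
(`0.6321` at day 10, as printed).  Although the population contains cells of many
division numbers, uptake noise merges their intensity peaks: one mode at
days 2–4, only two (strongly overlapping) modes at days 6–10 — so
division numbers cannot be read off the histogram.  During delabeling
(days 12–20) separated peaks reappear, but only at very low intensities
(mode locations halve every expected division).

Configurations can also be run from files or the shell:

```sh
Rscript inst/cli/brdusim.R scenario --name noisy_uptake --outdir out/
Rscript inst/cli/brdusim.R simulate --config inst/extdata/spatial_heterogeneity.yaml --outdir out2/
Rscript inst/cli/brdusim.R check
```

Each run writes `population.csv`, `distribution.csv`, `atoms.csv`,
`summaries.json`, and a `manifest.json` with checksums and the seed.

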