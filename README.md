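# tftitrate

Quantitative analysis of titratable transcription-factor (TF) expression
libraries in bacteria. The package implements the analysis machinery
behind single-cell TF titration experiments — strains in which one TF is
expressed from an inducible promoter over a 100–1,000-fold range while a
fluorescent fusion reports its copy number — and ships seeded synthetic
generators for every input table, so the entire pipeline runs and is
tested without microscopy or plate-reader data.

## What it computes

**Fluorescence calibration from division partitioning.** A fluorophore
count *N* gives signal *I = vN*. When *N* molecules partition binomially
between two daughters, Var(*I*₁ − *I*₂ | *N*) = *v*² *N*, so

> E[(*I*₁ − *I*₂)²] = *v* · (*I*₁ + *I*₂),

and the calibration factor *v* (fluorescence units per molecule) is the
origin-constrained slope of the binned mean squared intensity difference
against the mean intensity sum, with a bootstrap CI
(`fit_calibration()`). Copy numbers follow as `total_fluor / v`
(`intensity_to_copies()`).

**Thermodynamic fold-change model.** Expression relative to the
unregulated promoter for a TF at copy number *N*&#x2080; binding one
specific site against *N*ₙₛ nonspecific genomic sites with energy Δε
(in units of *k*\_B*T*, negative = favorable):

> FC = (1 + FC_max · *x*) / (1 + *x*),  *x* = *N*₀ e^(−Δε) / *N*ₙₛ,

where FC_max is the fold change at saturating occupancy (0 = complete
steric blockage, < 1 repression, > 1 activation). `fit_binding_energy()`
infers Δε at steric-hindrance positions (FC_max = 0), `fit_fcmax()`
infers FC_max elsewhere with Δε held fixed, `test_affinity_equality()`
asks whether two conditions share one Δε, and
`classify_regulatory_mode()` places paralogous TF pairs in the
activation/repression quadrants.

**Kinetic model of zinc-responsive regulation.** A MerR-family TF
(ZntR) represses its target (the zinc exporter ZntA) when apo and
activates it when zinc-bound; the exporter in turn clears zinc. The
five-variable ODE model (`derivatives()`, `steady_state()`) yields the
target's fold change versus effective zinc
(`sweep_zinc_response()`), reproducing the repressor-to-activator
switch controlled by the basal-to-activated expression ratio r₀/r and
the TF-number-robust activation at high zinc (`collapse_metric()`).

**Growth phenotypes.** `extract_growth_rate()` recovers the maximal
specific growth rate from OD600 time series via sliding-window
polynomial fits on log OD (noise-weighted, median-filtered trace);
`normalize_to_wildtype()`, `correlate_rate_vs_induction()` and
`cluster_growth_profiles()` build and cluster the strain-by-induction
growth-phenotype matrix.

## Worked example

```r
library(tftitrate)

# 1. Calibrate: 2000 simulated divisions at v_true = 100
pairs <- simulate_partition_pairs(
  partition_sim_config(v_true = 100, copy_mean = 1000,
                       n_pairs = 2000, seed = 1))
fit_calibration(pairs, seed = 1)
#> Calibration factor v = 104.9 (95% CI 97.21-113.1), 2000 pairs, 10 bins

# 2. Infer a binding energy from noisy single-cell fold-change data
cells <- simulate_foldchange_dataset(
  foldchange_sim_config(delta_eps = -13.8, fc_max = 0,
                        n_cells = 2000, noise_cv = 0.1, seed = 42))
fit_binding_energy(bin_foldchange_by_tf(cells, 10))
#> Thermo fit: delta_eps = -13.79 (95% CI -13.8 to -13.78), fc_max fixed at 0, 10 bins

# 3. Zinc response of the kinetic model, weak basal promoter (r0/r = 0.01)
sweep_zinc_response(kinetic_params(), zinc_grid = c(0, 0.1, 10),
                    tf_totals = c(100, 1000), r0_over_r_list = 0.01)
#>   tf_total r0_over_r zinc_out effective_zinc fold_change
#> 1      100      0.01      0                0     0.0450
#> 2     1000      0.01      0                0     0.00465
#> 3      100      0.01      0.1             10    10.9
#> 4     1000      0.01      0.1             10    11.1
#> 5      100      0.01     10             1000    65.0
#> 6     1000      0.01     10             1000    67.1
```

The calibration recovers *v* = 100 within its CI. The steric fit
recovers the seeded binding energy of −13.8 *k*\_B*T* to within
0.01 *k*\_B*T* of the truth under 10% measurement noise. The zinc sweep
shows the signature regulatory logic: without zinc the TF represses, and
more strongly the more TF is present (fold change 0.045 at 100 copies
versus 0.005 at 1,000); at high zinc the promoter is strongly activated
and the response is nearly independent of TF copy number (65 versus 67
over a 10-fold TF range — the curves collapse).

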