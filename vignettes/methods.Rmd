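---
title: "Models and methods behind tftitrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tftitrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tftitrate)
```

This vignette explains the models the package implements, the
assumptions they rest on, the tunable parameters that matter, and the
numerical choices made where the design was genuinely open. It states
no empirical result that the test suite does not itself compute.

## 1. Calibration from partitioning statistics

### Model

Fluorescent signal is proportional to fluorophore count, $I = vN$. At
division, each of the mother's $N$ fluorophores lands in daughter 1
independently with probability $1/2$ (random partitioning; the method
is invalid for TFs that localize or partition with volume). Then
$\mathrm{Var}(I_1 - I_2 \mid N) = v^2 N$, and since
$E[I_1 + I_2 \mid N] = vN$,

$$E[(I_1 - I_2)^2] = v\,(I_1 + I_2).$$

The calibration factor $v$ (fluorescence units per molecule) is the
slope of this relation. `fit_calibration()` bins daughter pairs by
summed intensity (equal-count bins; robust to the right-skewed sum
distributions that copy-number variability produces), regresses the
per-bin mean squared difference on the per-bin mean sum through the
origin weighted by bin counts, and bootstraps pairs (default 1,000
resamples, rebinned per resample) for the 95% CI.

### Choices and caveats

* **Moment regression, not a binomial likelihood.** The slope form is
  the standard published estimator for this partitioning method and is
  what the binned sum/squared-difference presentation depicts. A full
  likelihood would weight pairs differently but estimates the same
  slope; the regression form is transparent and assumption-light.
* **Through the origin.** Zero total fluorescence implies zero
  fluctuation by construction; an intercept would only absorb
  background that the input contract already requires to be
  subtracted.
* **Defaults**: 10 bins, minimum 30 pairs per bin. Undersized bins
  (possible with ties) are merged with a neighbor.
* **Measurement noise inflates the slope.** Multiplicative
  daughter-level noise adds a variance term proportional to the squared
  sum; the estimator does not correct for it (the field's standard
  treatment does not either). Calibrations are therefore best run on
  low-noise imaging data; the simulator's `noise_cv` lets the bias be
  quantified.
* Deviations beyond 2-fold from the pooled mean (`pool_calibrations()`)
  are flagged as fold ratios: a factor of 50 against a mean of 116.7 is
  a 2.33-fold deviation and is flagged. Library-wide conversion uses
  the pooled mean; per-strain factors should be measured where precise
  counts matter.

## 2. Thermodynamic fold-change model

### Model

A TF at copy number $N_0$ partitions between one specific site and
$N_{ns}$ nonspecific genomic sites (default $4.6 \times 10^6$, the
E. coli genome length in bp — the standard convention). With binding
energy $\Delta\varepsilon$ in $k_BT$ (negative favorable; Boltzmann
weight $e^{-\Delta\varepsilon}$), the specific site's relative
statistical weight is $x = N_0 e^{-\Delta\varepsilon}/N_{ns}$ — the
*effective TF concentration* — and

$$\mathrm{FC} = \frac{1 + \mathrm{FC_{max}}\,x}{1 + x},$$

where $\mathrm{FC_{max}}$ is the fold change at saturating occupancy:
0 for complete steric blockage, below 1 repression, above 1
activation. Curves for different TFs and sites collapse when plotted
against $x$ — exactly, in the model; this is tested as an identity.

`two_state_oracle()` re-derives FC by explicit enumeration of the two
promoter states (weights $1$ and $x$, rates $1$ and
$\mathrm{FC_{max}}$) and is kept as an independent cross-check; the
suite requires agreement to $10^{-12}$.

### Two-step fitting

Single-cell records are binned into equal-count TF bins per
(site, position, cofactor) group; fits run on bin means weighted by
$1/\mathrm{SEM}^2$ (matching how such data are presented and averaged),
falling back to equal weights for noiseless curves.

1. `fit_binding_energy()`: at downstream steric-hindrance positions the
   bound TF blocks polymerase regardless of cofactor state, so
   $\mathrm{FC_{max}} = 0$ and $\Delta\varepsilon$ is the sole free
   parameter.
2. `fit_fcmax()`: at other positions $\Delta\varepsilon$ is held at the
   sterically measured value and $\mathrm{FC_{max}}$ is the sole free
   parameter (bounded below at 0).

This mirrors the measurement logic and avoids the joint
non-identifiability of $(\Delta\varepsilon, \mathrm{FC_{max}})$ when
the TF range does not reach saturation. Because each fit is
one-dimensional, minimisation uses an exact bounded 1-D search
(`stats::optimize` on $[-30, 5]\,k_BT$ and $[0, 10^3]$ respectively)
rather than multi-start gradient descent — deterministic and immune to
start-point luck. CIs come from the local curvature of the weighted
SSE (Gauss–Newton approximation with a t quantile). A curve
statistically indistinguishable from 1 triggers a weak-binding boundary
warning instead of a spurious energy.

`test_affinity_equality()` fits two curves separately and pooled and
reports the energy difference with a CI plus an F-style residual
comparison — used to establish that a cofactor shifts the bound TF's
regulatory function rather than its occupancy.
`classify_regulatory_mode()` compares paralogs' $\mathrm{FC_{max}}$
values to 1; a CI spanning 1 yields "indeterminate" rather than a
forced call, and overlapping CIs flag the one-to-one diagonal.

## 3. Kinetic model of zinc-responsive regulation

### Model

The MerR-family regulator switches from repressor to activator with
its cofactor. States: intracellular zinc $Z_{in}$, apo TF, holo TF*
(zinc-bound), promoter fractions $P_{off}$ (free), $P_{on}$
(apo-bound), $P^*_{on}$ (holo-bound), exporter $E$ (also the model's
reporter):

$$
\begin{aligned}
\dot Z_{in} &= \beta_{in} Z_{out} - \beta_{out} Z_{in} E
  - \gamma_1 Z_{in}\,\mathrm{TF} + \gamma_2 \mathrm{TF}^* \\
\dot{\mathrm{TF}}^* &= \gamma_1 Z_{in}\,\mathrm{TF} - \gamma_2 \mathrm{TF}^*
  - k_{on} \mathrm{TF}^* P_{off} + k_{off} P^*_{on} \\
\dot P_{on} &= k_{on} \mathrm{TF}\, P_{off} - k_{off} P_{on} \\
\dot P^*_{on} &= k_{on} \mathrm{TF}^* P_{off} - k_{off} P^*_{on} \\
\dot E &= r P^*_{on} + r_0 P_{off} - \gamma E
\end{aligned}
$$

with conservation $P_{off} + P_{on} + P^*_{on} = 1$,
$\mathrm{TF} + \mathrm{TF}^* + P_{on} + P^*_{on} = \mathrm{TF}_{tot}$,
and, in the closed-system mode,
$\mathrm{TF}^* + P^*_{on} + Z_{in} + Z_{out} = Z_{tot}$. The apo-bound
promoter is fully repressed (rate 0), the free promoter expresses at
basal rate $r_0$, the holo-bound promoter at $r$. Apo and holo TF bind
DNA with the same $k_{on}/k_{off}$ — the experimental observation that
the cofactor does not change occupancy, encoded as
$k_{on}/k_{off} = e^{-\Delta\varepsilon}/N_{ns}$ with
$\Delta\varepsilon = -13.8\,k_BT$. Fold change of the target is
$E_{ss}/(r_0/\gamma)$, plotted against the effective zinc
$Z_{out}\gamma_1\beta_{in}/(\gamma_2\beta_{out})$.

### Parameter defaults

The model is used for qualitative-regime analysis, and its defaults are
package choices at order-of-magnitude plausibility, fully
configurable: $\gamma = \ln 2 / 0.5\,\mathrm{h}^{-1}$ (dilution at a
30-min cell cycle), $k_{off} = 100\,\mathrm{h}^{-1}$ (promoter kinetics
fast against the cell cycle) with $k_{on}$ tied to the measured binding
energy, $\beta_{in} = 1$, $\beta_{out} = 10^{-3}$ per exporter,
$\gamma_1 = 1$, $\gamma_2 = 10$, $r = 1000$, and $r_0$ set through the
swept ratio $r_0/r$. The regimes the tests assert — repression at zero
zinc that deepens with TF number; activation above 1 at saturating zinc
only when $r_0 < r$; high-zinc fold change nearly independent of a
10-fold TF range — are structural properties of the model, not
fine-tuned outcomes.

### Numerics

`steady_state()` integrates the stiff system (deSolve, lsoda, relative
tolerance $10^{-8}$) from the empty state over geometrically growing
horizons until the relative derivative norm falls below $10^{-10}$,
then polishes the root with a damped Newton iteration
(finite-difference Jacobian) so returned states satisfy the algebraic
system and conservation to $10^{-8}$ or better. The reduced state
(five variables; $P_{off}$, free TF and, in closed mode, $Z_{out}$
derived from the conservation laws) makes the constraints exact by
construction rather than approximately maintained. External zinc is a
clamped boundary condition by default (a media reservoir); the closed
mode honors the full zinc budget and is what the conservation tests
exercise.

## 4. Growth-rate extraction and clustering

### Method

OD600 series (30-min sampling up to 20 h in the simulator, matching
plate-reader practice) are blank-subtracted, floored at $10^{-3}$
(points at the floor are excluded), log-transformed, and fit with a
degree-1 polynomial over a sliding 5-point (2.5 h) window; the window
slope traces lag noise, a growth-phase peak, and a stationary plateau,
and the peak is the growth rate. Degree 1 on log OD makes the fitted
coefficient the specific growth rate directly; both degree and window
are configurable.

Two robustness measures temper the raw peak, both aimed at additive
plate-reader noise, which explodes on the log scale when OD approaches
the noise floor: window fits are weighted by $\mathrm{OD}^2$ (the
inverse variance of $\log \mathrm{OD}$ under additive OD noise), and
the slope trace is median-filtered (width 3) before its maximum is
taken, which removes isolated lag-phase spikes. Both measures vanish on
clean data — on a noise-free exponential every window slope equals the
rate and the estimate is exact for any window and degree, a property
the suite asserts together with invariance to multiplicative OD
rescaling. Even so, a single noisy curve whose initial OD is only a
few times the noise SD carries limited information about the maximal
log-slope: replicate scatter of around $\pm$10% remains at the
simulator's default noise, and the tests therefore assert central
(median-across-replicates) recovery at 5%, not per-curve recovery.
Curves whose best slope stays below 0.05/h are flagged `no-growth`.

### Downstream

Rates are normalized to the wild-type reference measured at the same
inducer level, Pearson-correlated against induction, and clustered with
Ward linkage (`ward.D2`) on Euclidean distances — compact, balanced
clusters for profile data; linkage and metric are configurable and both
a fixed-$k$ and a cut-height interface are provided, since a cluster
count is an analysis input, not an estimate. Missing profile entries
are column-mean imputed; all-missing strains are rejected by name.

## 5. Synthetic-data generators

The generators define the study conditions the tests run under:

* **Partitioning** (`simulate_partition_pairs()`): mother copy numbers
  lognormal (positive, right-skewed, the standard shape for protein
  counts; mean 1,000, CV 0.3 by default), strict binomial $p = 1/2$
  splitting, optional multiplicative lognormal daughter noise.
* **Fold change** (`simulate_foldchange_dataset()`): the exact
  thermodynamic model evaluated on a log-spaced TF grid (1–1,000 by
  default, with multiplicative cell-to-cell jitter, CV 0.1) times
  lognormal measurement noise — a ratio of positive intensities, so
  noise is multiplicative and positivity is preserved. With noise off
  it round-trips exactly through `fold_change()`.
* **Titration snapshots** (`simulate_titration_snapshots()`):
  gamma-distributed copy numbers per inducer level scaled by the true
  calibration factor plus Gaussian background.
* **Growth** (`simulate_growth_curves()`): logistic-with-lag
  trajectories, additive Gaussian noise, floored at $10^{-4}$.

Every generator is a pure function of its config including its seed
(bit-identical reruns). What the generators do *not* emulate bounds
what passing tests show about real data: no segmentation errors, no
unequal-volume division, no photobleaching, no plate effects or media
drift, no promoter-architecture effects beyond the single-site model.

## 6. Problem sizes and reproducibility

Test and acceptance runs use 2,000 division pairs per calibration,
2,000 cells per fold-change fit, steady-state sweeps over 2 TF levels
$\times$ 2 promoter ratios $\times$ 9 zinc points, and 48-strain
profile matrices — sizes at which every recovery property is stable
while the whole suite runs in about a minute. The pipeline driver
(`run_pipeline()`) derives per-stage seeds from one global seed and
writes md5 checksums of every output into a manifest; reruns with the
same config are bit-identical, which the suite verifies end to end.

## 7. Known limitations

* The calibration estimator does not de-bias measurement noise (see
  above); its CI is a bootstrap over pairs, not over imaging sessions.
* Thermo fits treat binned means as the data; an unbinned option exists
  at the binning step but residual structure within bins is not
  modelled.
* The kinetic model is deterministic mean-field with continuous
  promoter fractions; no stochastic single-promoter effects, no zinc
  buffering by other metalloproteins, no cofactor cross-talk.
* Multi-site promoters (cooperativity, looping) are out of scope; the
  fold-change model is strictly single-site.
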