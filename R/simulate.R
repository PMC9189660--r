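# Seeded generators for every input table the pipeline consumes.
# Each generator emulates the statistical structure the downstream
# analysis assumes, so the whole pipeline is testable without microscopy
# or plate-reader data.

# Config constructors -----------------------------------------------------

#' Configuration for simulating daughter-pair partitioning data
#'
#' Parameters of the generative model behind the fluorescence calibration
#' experiment: a mother cell carrying `N` fluorophores (drawn from a
#' lognormal with mean `copy_mean` and CV `copy_cv`, rounded to an integer
#' >= 1) divides, each fluorophore lands in daughter 1 with probability
#' 1/2, and each daughter's total fluorescence is `v_true` per fluorophore
#' times an optional multiplicative measurement-noise factor.
#'
#' @param v_true Fluorescence units contributed by one fluorophore (> 0).
#' @param copy_mean Mean mother-cell fluorophore count (> 0).
#' @param copy_cv Coefficient of variation of mother counts (>= 0).
#' @param n_pairs Number of divisions to simulate (>= 1).
#' @param noise_cv Multiplicative measurement-noise CV per daughter (>= 0).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `partition_sim_config` list.
#' @export
partition_sim_config <- function(v_true = 100, copy_mean = 1000,
                                 copy_cv = 0.3, n_pairs = 2000,
                                 noise_cv = 0, seed = 1L) {
  check_scalar(v_true, "v_true", positive = TRUE)
  check_scalar(copy_mean, "copy_mean", positive = TRUE)
  check_scalar(copy_cv, "copy_cv", nonneg = TRUE)
  check_scalar(n_pairs, "n_pairs", integer = TRUE)
  if (n_pairs < 1) config_error("n_pairs", "must be >= 1")
  check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(v_true = v_true, copy_mean = copy_mean, copy_cv = copy_cv,
                 n_pairs = as.integer(n_pairs), noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "partition_sim_config")
}

#' Configuration for simulating inducer-titration snapshots
#'
#' @param atc_levels Inducer (aTC) concentrations, ng/ml.
#' @param mean_tf_per_level Mean TF copies per cell at each level
#'   (same length as `atc_levels`, all >= 0).
#' @param cell_cv Cell-to-cell CV of copy number (>= 0).
#' @param n_cells_per_level Cells simulated per level.
#' @param v_true Fluorescence units per fluorophore.
#' @param background_mean,background_sd Gaussian background fluorescence.
#' @param seed Integer seed.
#' @return A `titration_sim_config` list.
#' @export
titration_sim_config <- function(atc_levels = c(0, 1, 3, 7),
                                 mean_tf_per_level = c(10, 100, 500, 1000),
                                 cell_cv = 0.3, n_cells_per_level = 200,
                                 v_true = 100, background_mean = 0,
                                 background_sd = 0, seed = 1L) {
  if (length(atc_levels) != length(mean_tf_per_level))
    config_error("mean_tf_per_level",
                 "must have the same length as atc_levels")
  if (any(mean_tf_per_level < 0))
    config_error("mean_tf_per_level", "must be >= 0")
  check_scalar(cell_cv, "cell_cv", nonneg = TRUE)
  check_scalar(n_cells_per_level, "n_cells_per_level", integer = TRUE)
  if (n_cells_per_level < 1) config_error("n_cells_per_level", "must be >= 1")
  check_scalar(v_true, "v_true", positive = TRUE)
  check_scalar(background_sd, "background_sd", nonneg = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(atc_levels = atc_levels,
                 mean_tf_per_level = mean_tf_per_level,
                 cell_cv = cell_cv,
                 n_cells_per_level = as.integer(n_cells_per_level),
                 v_true = v_true, background_mean = background_mean,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "titration_sim_config")
}

#' Configuration for simulating single-cell fold-change data
#'
#' Generative twin of the thermodynamic fold-change model: each cell gets
#' a TF copy number from `tf_grid` (with multiplicative cell-to-cell
#' jitter), its fold change is the model evaluated at that copy number,
#' times lognormal measurement noise of CV `noise_cv`.
#'
#' @param delta_eps Binding energy in units of kT (negative = favorable).
#' @param fc_max Maximum fold change at saturating TF occupancy (>= 0).
#' @param n_ns Number of nonspecific genomic binding sites (> 0).
#' @param tf_grid TF copy numbers sampled (recycled over cells).
#' @param n_cells Number of cells.
#' @param noise_cv Multiplicative CV on fold change (>= 0).
#' @param tf_jitter_cv Multiplicative cell-to-cell CV on TF copy number.
#' @param seed Integer seed.
#' @return A `foldchange_sim_config` list.
#' @export
foldchange_sim_config <- function(delta_eps = -13.8, fc_max = 0,
                                  n_ns = 4.6e6,
                                  tf_grid = 10^seq(0, 3, length.out = 10),
                                  n_cells = 2000, noise_cv = 0.1,
                                  tf_jitter_cv = 0.1, seed = 1L) {
  check_scalar(delta_eps, "delta_eps")
  check_scalar(fc_max, "fc_max", nonneg = TRUE)
  check_scalar(n_ns, "n_ns", positive = TRUE)
  if (length(tf_grid) < 1 || any(tf_grid < 0))
    config_error("tf_grid", "must be non-empty and >= 0")
  check_scalar(n_cells, "n_cells", integer = TRUE)
  if (n_cells < 1) config_error("n_cells", "must be >= 1")
  check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  check_scalar(tf_jitter_cv, "tf_jitter_cv", nonneg = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(delta_eps = delta_eps, fc_max = fc_max, n_ns = n_ns,
                 tf_grid = tf_grid, n_cells = as.integer(n_cells),
                 noise_cv = noise_cv, tf_jitter_cv = tf_jitter_cv,
                 seed = as.integer(seed)),
            class = "foldchange_sim_config")
}

#' Configuration for simulating plate-reader growth curves
#'
#' Logistic-with-lag OD600 trajectories sampled on a regular grid
#' (default every 30 min up to 20 h) with additive Gaussian noise,
#' floored at a small positive value so the log transform is defined.
#'
#' @param rate Exponential growth rate, per hour (>= 0).
#' @param lag_h Lag time, hours.
#' @param carrying_capacity Carrying capacity, OD units (> od0).
#' @param od0 Initial OD (> 0).
#' @param sample_interval_h Sampling interval, hours.
#' @param duration_h Total duration, hours.
#' @param noise_sd Additive OD noise SD.
#' @param strain,atc_ng_ml Labels carried into the output table.
#' @param seed Integer seed.
#' @return A `growth_sim_config` list.
#' @export
growth_sim_config <- function(rate = 0.7, lag_h = 2,
                              carrying_capacity = 1.0, od0 = 0.005,
                              sample_interval_h = 0.5, duration_h = 20,
                              noise_sd = 0.002, strain = "strain1",
                              atc_ng_ml = 0, seed = 1L) {
  check_scalar(rate, "rate", nonneg = TRUE)
  check_scalar(lag_h, "lag_h", nonneg = TRUE)
  check_scalar(od0, "od0", positive = TRUE)
  check_scalar(carrying_capacity, "carrying_capacity", positive = TRUE)
  if (carrying_capacity <= od0)
    config_error("carrying_capacity", "must exceed od0")
  check_scalar(sample_interval_h, "sample_interval_h", positive = TRUE)
  check_scalar(duration_h, "duration_h", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(rate = rate, lag_h = lag_h,
                 carrying_capacity = carrying_capacity, od0 = od0,
                 sample_interval_h = sample_interval_h,
                 duration_h = duration_h, noise_sd = noise_sd,
                 strain = strain, atc_ng_ml = atc_ng_ml,
                 seed = as.integer(seed)),
            class = "growth_sim_config")
}

# Generators --------------------------------------------------------------

#' Simulate daughter-pair fluorescence partitioning at division
#'
#' For each division a mother-cell fluorophore count `N` is drawn from a
#' lognormal (mean `copy_mean`, CV `copy_cv`; rounded to an integer >= 1),
#' the count inherited by daughter 1 is binomial(`N`, 1/2), and the two
#' daughter fluorescences are `v_true` times the inherited counts, each
#' multiplied by an independent noise factor of CV `noise_cv`.
#' Because partitioning is binomial, `E[(I1 - I2)^2] = v_true * (I1 + I2)`
#' in the noise-free case — the identity the calibration fit exploits.
#'
#' @param cfg A [partition_sim_config()].
#' @return A tibble with columns `division_id`, `I1`, `I2` and the
#'   hidden truth columns `n_mother`, `n1` (useful for testing).
#' @export
simulate_partition_pairs <- function(cfg) {
  stopifnot(inherits(cfg, "partition_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_pairs
  n_mother <- pmax(1L, as.integer(round(
    rlnorm_meancv(n, cfg$copy_mean, cfg$copy_cv))))
  n1 <- rbinom(n, size = n_mother, prob = 0.5)
  f1 <- lnorm_noise_factor(n, cfg$noise_cv)
  f2 <- lnorm_noise_factor(n, cfg$noise_cv)
  tibble(
    division_id = seq_len(n),
    I1 = cfg$v_true * n1 * f1,
    I2 = cfg$v_true * (n_mother - n1) * f2,
    n_mother = n_mother,
    n1 = n1
  )
}

#' Simulate a single-cell fold-change dataset from the thermodynamic model
#'
#' @param cfg A [foldchange_sim_config()].
#' @param site_id,position,cofactor_uM Labels carried into the table.
#' @return A `fold-change table`: tibble with columns `cell_id`,
#'   `site_id`, `position`, `cofactor_uM`, `tf_copies`, `fold_change`.
#'   All fold changes are strictly positive.
#' @export
simulate_foldchange_dataset <- function(cfg, site_id = "site1",
                                        position = "+16.5",
                                        cofactor_uM = 0) {
  stopifnot(inherits(cfg, "foldchange_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  tf_base <- rep_len(cfg$tf_grid, n)
  tf <- tf_base * lnorm_noise_factor(n, cfg$tf_jitter_cv)
  params <- thermo_params(delta_eps = cfg$delta_eps, fc_max = cfg$fc_max,
                          n_ns = cfg$n_ns)
  fc <- fold_change(tf, params) * lnorm_noise_factor(n, cfg$noise_cv)
  tibble(
    cell_id = seq_len(n),
    site_id = site_id,
    position = position,
    cofactor_uM = cofactor_uM,
    tf_copies = tf,
    fold_change = fc
  )
}

#' Simulate per-cell fluorescence snapshots across an inducer titration
#'
#' Per-cell total fluorescence is `v_true` times a gamma-distributed copy
#' number (mean from `mean_tf_per_level`, CV `cell_cv`) plus Gaussian
#' background, grouped by aTC level.
#'
#' @param cfg A [titration_sim_config()].
#' @param strain,channel Labels carried into the table.
#' @return A cell-intensity tibble with columns `cell_id`, `strain`,
#'   `atc_ng_ml`, `cofactor_uM`, `channel`, `total_fluor`.
#' @export
simulate_titration_snapshots <- function(cfg, strain = "strain1",
                                         channel = "mCherry") {
  stopifnot(inherits(cfg, "titration_sim_config"))
  set.seed(cfg$seed)
  out <- lapply(seq_along(cfg$atc_levels), function(k) {
    m <- cfg$mean_tf_per_level[k]
    n <- cfg$n_cells_per_level
    copies <- if (cfg$cell_cv <= 0 || m == 0) {
      rep(m, n)
    } else {
      shape <- 1 / cfg$cell_cv^2
      rgamma(n, shape = shape, rate = shape / m)
    }
    bg <- if (cfg$background_sd > 0 || cfg$background_mean != 0)
      rnorm(n, cfg$background_mean, cfg$background_sd) else rep(0, n)
    tibble(
      strain = strain,
      atc_ng_ml = cfg$atc_levels[k],
      cofactor_uM = 0,
      channel = channel,
      total_fluor = cfg$v_true * copies + bg
    )
  })
  res <- dplyr::bind_rows(out)
  res$cell_id <- seq_len(nrow(res))
  res[, c("cell_id", "strain", "atc_ng_ml", "cofactor_uM", "channel",
          "total_fluor")]
}

# Logistic-with-lag OD trajectory on a time grid (noise-free).
#' @noRd
logistic_od <- function(t, rate, lag_h, K, od0) {
  te <- pmax(0, t - lag_h)
  od0 * K / (od0 + (K - od0) * exp(-rate * te))
}

#' Simulate plate-reader growth curves
#'
#' Each config yields one logistic-with-lag OD600 trajectory on the grid
#' `seq(0, duration_h, by = sample_interval_h)` with additive Gaussian
#' noise, floored at `1e-4` so downstream log transforms are defined.
#'
#' @param cfgs A single [growth_sim_config()] or a list of them.
#' @return A tibble with columns `strain`, `atc_ng_ml`, `time_h`, `od600`.
#' @export
simulate_growth_curves <- function(cfgs) {
  if (inherits(cfgs, "growth_sim_config")) cfgs <- list(cfgs)
  stopifnot(all(vapply(cfgs, inherits, TRUE, "growth_sim_config")))
  od_floor <- 1e-4
  dplyr::bind_rows(lapply(cfgs, function(cfg) {
    set.seed(cfg$seed)
    t <- seq(0, cfg$duration_h, by = cfg$sample_interval_h)
    od <- logistic_od(t, cfg$rate, cfg$lag_h, cfg$carrying_capacity,
                      cfg$od0)
    if (cfg$noise_sd > 0) od <- od + rnorm(length(t), 0, cfg$noise_sd)
    tibble(strain = cfg$strain, atc_ng_ml = cfg$atc_ng_ml,
           time_h = t, od600 = pmax(od_floor, od))
  }))
}
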