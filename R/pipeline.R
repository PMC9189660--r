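# Top-level pipeline binding the stages into a reproducible run:
# simulate -> calibrate -> to-copies -> fit-thermo, with a manifest of
# checksums so reruns can be verified bit-identical.

#' Pipeline configuration
#'
#' All randomness flows from the single global `seed`: each stage draws
#' a derived seed, so a rerun with the same config is bit-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param stages Character vector of stages to run, in dependency order
#'   from `simulate`, `calibrate`, `to_copies`, `fit_thermo`,
#'   `growth_rates`.
#' @param partition Partition-pair generator config
#'   ([partition_sim_config()]); its `seed` is overridden.
#' @param titration Titration snapshot config ([titration_sim_config()]).
#' @param foldchange Fold-change generator config
#'   ([foldchange_sim_config()]).
#' @param growth List of growth configs ([growth_sim_config()]).
#' @param n_bins Bin count used by calibration and thermo fits.
#' @param n_boot Bootstrap resamples for the calibration CI.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "calibrate",
                                       "to_copies", "fit_thermo",
                                       "growth_rates"),
                            partition = partition_sim_config(),
                            titration = titration_sim_config(),
                            foldchange = foldchange_sim_config(),
                            growth = list(growth_sim_config()),
                            n_bins = 10, n_boot = 200) {
  check_scalar(seed, "seed", integer = TRUE)
  known <- c("simulate", "calibrate", "to_copies", "fit_thermo",
             "growth_rates")
  if (!all(stages %in% known))
    config_error("stages", paste("must be among:",
                                 paste(known, collapse = ", ")))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, partition = partition,
                 titration = titration, foldchange = foldchange,
                 growth = growth, n_bins = n_bins, n_boot = n_boot),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes a run
#' manifest (JSON) with per-output md5 checksums. Stages needing an
#' upstream output that was neither run nor already on disk abort with a
#' dependency error.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  outputs <- character(0)
  need <- function(f, stage) {
    if (!file.exists(path(f)))
      stop(sprintf("stage '%s' needs missing upstream output %s",
                   stage, f), call. = FALSE)
    path(f)
  }
  seed_of <- function(i) derive_seed(config$seed, i)

  if ("simulate" %in% config$stages) {
    cfg <- config$partition; cfg$seed <- seed_of(1L)
    pairs <- simulate_partition_pairs(cfg)
    write_table(pairs[, c("division_id", "I1", "I2")],
                path("partition_pairs.csv"), seed = cfg$seed)
    cfg <- config$titration; cfg$seed <- seed_of(2L)
    cells <- simulate_titration_snapshots(cfg)
    write_table(cells, path("cells.csv"), seed = cfg$seed)
    cfg <- config$foldchange; cfg$seed <- seed_of(3L)
    fcs <- simulate_foldchange_dataset(cfg)
    write_table(fcs, path("foldchange.csv"), seed = cfg$seed)
    growth_cfgs <- lapply(seq_along(config$growth), function(i) {
      g <- config$growth[[i]]; g$seed <- derive_seed(seed_of(4L), i); g
    })
    write_table(simulate_growth_curves(growth_cfgs), path("growth.csv"),
                seed = seed_of(4L))
    outputs <- c(outputs, "partition_pairs.csv", "cells.csv",
                 "foldchange.csv", "growth.csv")
  }
  if ("calibrate" %in% config$stages) {
    pairs <- read_table(need("partition_pairs.csv", "calibrate"),
                        "partition_pairs")
    calib <- fit_calibration(pairs, n_bins = config$n_bins,
                             n_boot = config$n_boot, seed = seed_of(5L))
    jsonlite::write_json(
      list(v = calib$v, ci95_lo = calib$ci95_lo,
           ci95_hi = calib$ci95_hi, n_pairs = calib$n_pairs),
      path("calib.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "calib.json")
  }
  if ("to_copies" %in% config$stages) {
    cells <- read_table(need("cells.csv", "to_copies"), "cells")
    calib <- jsonlite::read_json(need("calib.json", "to_copies"))
    copies <- intensity_to_copies(cells, calib$v)
    write_table(copies, path("copies.csv"), seed = config$seed)
    outputs <- c(outputs, "copies.csv")
  }
  if ("fit_thermo" %in% config$stages) {
    fcs <- read_table(need("foldchange.csv", "fit_thermo"), "foldchange")
    curve <- bin_foldchange_by_tf(fcs, n_bins = config$n_bins)
    fit <- fit_binding_energy(curve, n_ns = config$foldchange$n_ns)
    jsonlite::write_json(
      list(delta_eps = fit$params$delta_eps,
           delta_eps_ci95 = fit$ci95$delta_eps,
           fc_max = fit$params$fc_max, fixed = fit$fixed,
           n_bins_used = fit$n_bins_used),
      path("thermo_fits.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "thermo_fits.json")
  }
  if ("growth_rates" %in% config$stages) {
    growth <- read_table(need("growth.csv", "growth_rates"), "growth")
    rates <- extract_growth_rates(growth)
    write_table(rates, path("rates.csv"), seed = config$seed)
    outputs <- c(outputs, "rates.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tftitrate")),
    seed = config$seed,
    stages = config$stages,
    outputs = as.list(setNames(
      unname(tools::md5sum(vapply(outputs, path, character(1)))),
      outputs)))
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
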