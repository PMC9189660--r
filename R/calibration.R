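# Fluorescence calibration from partitioning statistics.
#
# A fluorophore count N split binomially (p = 1/2) between daughters with
# intensities I = v * n gives Var(I1 - I2 | N) = v^2 * N = v * E[I1 + I2],
# so the slope of the mean squared difference against the mean sum,
# through the origin, estimates the calibration factor v (fluorescence
# units per molecule).

#' Bin daughter-pair data by summed fluorescence
#'
#' Equal-count (quantile) bins over `I1 + I2`; per bin the mean sum, mean
#' squared difference and pair count are returned. Bins that end up below
#' `min_per_bin` (possible with heavily tied sums) are merged with their
#' neighbor.
#'
#' @param pairs Data frame with numeric columns `I1`, `I2`.
#' @param n_bins Number of equal-count bins (default 10).
#' @param min_per_bin Minimum pairs per bin (default 30).
#' @return A tibble with columns `bin`, `mean_sum`, `mean_sqdiff`, `n`.
#' @export
bin_partition_pairs <- function(pairs, n_bins = 10, min_per_bin = 30) {
  stopifnot(is.data.frame(pairs), all(c("I1", "I2") %in% names(pairs)))
  usable <- pairs$I1 + pairs$I2 > 0
  pairs <- pairs[usable, , drop = FALSE]
  needed <- n_bins * min_per_bin
  if (nrow(pairs) < needed)
    stop(sprintf(paste0("insufficient data: %d usable pairs available, ",
                        "%d needed (%d bins x %d per bin)"),
                 nrow(pairs), needed, n_bins, min_per_bin), call. = FALSE)
  s <- pairs$I1 + pairs$I2
  d2 <- (pairs$I1 - pairs$I2)^2
  ord <- order(s)
  s <- s[ord]; d2 <- d2[ord]
  # equal-count assignment; ties in s can collapse bins, handled below
  idx <- ceiling(seq_along(s) / (length(s) / n_bins))
  idx <- pmin(idx, n_bins)
  # merge tied sums into one bin so identical inputs give one bin
  if (length(unique(s)) == 1L) idx <- rep(1L, length(s))
  tab <- tibble(bin = idx, s = s, d2 = d2) %>%
    group_by(.data$bin) %>%
    summarise(mean_sum = mean(.data$s), mean_sqdiff = mean(.data$d2),
              n = dplyr::n(), .groups = "drop")
  # merge undersized bins with their neighbor
  while (nrow(tab) > 1L && any(tab$n < min_per_bin)) {
    i <- which(tab$n < min_per_bin)[1L]
    j <- if (i == nrow(tab)) i - 1L else i + 1L
    ntot <- tab$n[i] + tab$n[j]
    tab$mean_sum[j] <- (tab$mean_sum[i] * tab$n[i] +
                          tab$mean_sum[j] * tab$n[j]) / ntot
    tab$mean_sqdiff[j] <- (tab$mean_sqdiff[i] * tab$n[i] +
                             tab$mean_sqdiff[j] * tab$n[j]) / ntot
    tab$n[j] <- ntot
    tab <- tab[-i, , drop = FALSE]
  }
  tab$bin <- seq_len(nrow(tab))
  tab
}

# Count-weighted origin-constrained slope of mean_sqdiff on mean_sum.
#' @noRd
slope_through_origin <- function(bin_table) {
  w <- bin_table$n
  x <- bin_table$mean_sum
  y <- bin_table$mean_sqdiff
  sum(w * x * y) / sum(w * x^2)
}

#' Fit the calibration factor from daughter-pair partitioning
#'
#' Estimates v as the slope (through the origin, weighted by bin counts)
#' of the per-bin mean squared intensity difference against the mean
#' intensity sum. The 95% CI comes from a nonparametric bootstrap over
#' pairs (rebinned and refit per resample).
#'
#' @param pairs Data frame with columns `I1`, `I2`.
#' @param n_bins,min_per_bin Binning scheme, see [bin_partition_pairs()].
#' @param n_boot Bootstrap resamples for the CI (default 1000; 0 skips
#'   the bootstrap and returns `NA` CIs).
#' @param seed Seed for the bootstrap resampling.
#' @return A `calibration_result` list: `v`, `ci95_lo`, `ci95_hi`,
#'   `n_pairs`, `bin_table`.
#' @export
fit_calibration <- function(pairs, n_bins = 10, min_per_bin = 30,
                            n_boot = 1000, seed = 1L) {
  bin_table <- bin_partition_pairs(pairs, n_bins, min_per_bin)
  if (nrow(bin_table) < 3L)
    stop("calibration fit needs >= 3 bins; got ", nrow(bin_table),
         call. = FALSE)
  v <- slope_through_origin(bin_table)
  if (!is.finite(v) || v <= 0)
    stop(paste("degenerate fit: non-positive slope; partitioning",
               "fluctuations are inconsistent with the binomial model"),
         call. = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    usable <- pairs[pairs$I1 + pairs$I2 > 0, , drop = FALSE]
    n <- nrow(usable)
    boots <- vapply(seq_len(n_boot), function(b) {
      res <- usable[sample.int(n, n, replace = TRUE), , drop = FALSE]
      bt <- tryCatch(bin_partition_pairs(res, n_bins, min_per_bin),
                     error = function(e) NULL)
      if (is.null(bt)) return(NA_real_)
      slope_through_origin(bt)
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(v = v, ci95_lo = ci[1], ci95_hi = ci[2],
                 n_pairs = sum(bin_table$n), bin_table = bin_table),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration factor v = %.4g (95%% CI %.4g-%.4g), %d pairs, %d bins\n",
              x$v, x$ci95_lo, x$ci95_hi, x$n_pairs, nrow(x$bin_table)))
  invisible(x)
}

#' Pool calibration factors across strains
#'
#' The study design measures v for a handful of strains and applies the
#' mean to the whole library, flagging strains whose individual factor
#' deviates more than `fold_threshold`-fold from that mean.
#'
#' @param results List of `calibration_result` objects (or a numeric
#'   vector of v values).
#' @param fold_threshold Flag deviations beyond this fold (default 2).
#' @return List with `v_mean`, and a tibble `per_result` of
#'   (`v`, `fold_deviation`, `flagged`).
#' @export
pool_calibrations <- function(results, fold_threshold = 2) {
  if (length(results) == 0) stop("no calibration results to pool",
                                 call. = FALSE)
  vs <- if (is.numeric(results)) results
        else vapply(results, function(r) r$v, numeric(1))
  v_mean <- mean(vs)
  fold_dev <- ifelse(vs >= v_mean, vs / v_mean, v_mean / vs)
  list(v_mean = v_mean,
       per_result = tibble(v = vs, fold_deviation = fold_dev,
                           flagged = fold_dev > fold_threshold))
}

#' Convert total fluorescence to absolute TF copy number
#'
#' Copies = total fluorescence / v. Negative (background-subtracted)
#' fluorescence values are clipped to zero and counted.
#'
#' @param cells Data frame with a `total_fluor` column (see
#'   [simulate_titration_snapshots()] for the schema), or one with
#'   `mean_pixel_intensity` and `pixel_area` from which `total_fluor` is
#'   derived.
#' @param v Calibration factor (> 0).
#' @return The input with a `tf_copies` column added; attribute
#'   `n_clipped` counts negative inputs clipped to 0.
#' @export
intensity_to_copies <- function(cells, v) {
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
    stop("calibration factor v must be a positive number", call. = FALSE)
  cells <- derive_total_fluor(cells)
  clipped <- cells$total_fluor < 0
  cells$tf_copies <- pmax(0, cells$total_fluor) / v
  attr(cells, "n_clipped") <- sum(clipped)
  cells
}

#' Apply a linear fluorophore-variant correction
#'
#' Maps fluorescence measured with one fluorophore variant onto the scale
#' of another via the linear correlation between the two:
#' `total_fluor <- slope * total_fluor + intercept`.
#'
#' @param cells Data frame with a `total_fluor` column.
#' @param slope Correction slope (> 0).
#' @param intercept Correction intercept.
#' @return Corrected table; the correction is recorded in attribute
#'   `fluorophore_correction`.
#' @export
apply_fluorophore_correction <- function(cells, slope, intercept = 0) {
  if (!is.numeric(slope) || length(slope) != 1 || slope <= 0)
    stop("correction slope must be > 0", call. = FALSE)
  stopifnot("total_fluor" %in% names(cells))
  cells$total_fluor <- slope * cells$total_fluor + intercept
  attr(cells, "fluorophore_correction") <-
    list(slope = slope, intercept = intercept)
  cells
}
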