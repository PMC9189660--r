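# Growth-rate extraction from plate-reader OD600 time series, wild-type
# normalization, rate-vs-induction correlation, and hierarchical
# clustering of titration growth phenotypes.

#' Extract the steady-state growth rate from one OD600 time series
#'
#' Blank-subtracts, floors the OD (default 1e-3, points at the floor are
#' excluded), log-transforms, and fits a polynomial over a sliding window
#' of `window_points` samples. The fitted log-slope at each window center
#' traces out a noisy lag regime, a distinct peak in exponential phase,
#' and a stationary plateau; the peak value is the growth rate.
#'
#' Two robustness measures temper the raw peak of the slope trace, both
#' aimed at additive plate-reader noise that explodes on the log scale
#' at low OD: window fits are weighted by OD squared (the inverse
#' variance of log-OD under additive OD noise), and the slope trace is
#' median-filtered (width 3) before its maximum is taken, which removes
#' isolated noise spikes in the lag phase. Both reduce exactly to the
#' plain peak on clean data.
#'
#' @param curve Data frame with columns `time_h`, `od600` (one well).
#' @param window_points Sliding-window width in samples (default 5,
#'   i.e. 2.5 h at 30-min sampling).
#' @param poly_degree Polynomial degree for the window fit (default 1:
#'   on log-OD the linear coefficient is the growth rate directly).
#' @param blank Blank OD subtracted before the log transform.
#' @param od_floor Floor applied after blank subtraction.
#' @param min_rate Below this max slope the curve is flagged `no-growth`.
#' @return A `growth_rate_result` list: `rate` (per h), `doubling_time`
#'   (min, `60*log(2)/rate`), `window_center` (h), `quality` in
#'   {ok, no-growth, noisy}, and the full `slope_trace`.
#' @export
extract_growth_rate <- function(curve, window_points = 5, poly_degree = 1,
                                blank = 0, od_floor = 1e-3,
                                min_rate = 0.05) {
  stopifnot(all(c("time_h", "od600") %in% names(curve)))
  stopifnot(window_points >= poly_degree + 1)
  ord <- order(curve$time_h)
  t <- curve$time_h[ord]
  od <- pmax(curve$od600[ord] - blank, od_floor)
  keep <- od > od_floor
  if (sum(keep) < window_points)
    stop(sprintf(paste0("insufficient data: %d points above the OD floor, ",
                        "window needs %d"), sum(keep), window_points),
         call. = FALSE)
  t <- t[keep]
  lod <- log(od[keep])
  n <- length(t)
  n_win <- n - window_points + 1L
  centers <- numeric(n_win)
  slopes <- numeric(n_win)
  odk <- od[keep]
  for (i in seq_len(n_win)) {
    idx <- i:(i + window_points - 1L)
    tw <- t[idx]
    tc <- mean(tw)
    # slope of the polynomial at the window center; centering makes the
    # degree-1 coefficient that derivative for any degree
    fit <- lm(lod[idx] ~ poly(I(tw - tc), degree = poly_degree,
                              raw = TRUE), weights = odk[idx]^2)
    centers[i] <- tc
    slopes[i] <- coef(fit)[2]
  }
  trace_f <- if (n_win >= 3) stats::runmed(slopes, 3) else slopes
  imax <- which.max(trace_f)
  rate <- max(0, trace_f[imax])
  quality <- if (rate < min_rate) "no-growth" else "ok"
  # noisy flag: slope trace with no coherent peak (negative slopes
  # dominating around the maximum)
  if (quality == "ok" && mean(slopes < 0) > 0.5) quality <- "noisy"
  structure(list(rate = rate,
                 doubling_time = if (rate > 0) 60 * log(2) / rate
                                 else Inf,
                 window_center = centers[imax],
                 quality = quality,
                 slope_trace = tibble(window_center = centers,
                                      slope = slopes)),
            class = "growth_rate_result")
}

#' Extract growth rates for every (strain, aTC) curve in a table
#'
#' @param growth Long table with columns `strain`, `atc_ng_ml`,
#'   `time_h`, `od600` (see [simulate_growth_curves()]).
#' @param ... Passed to [extract_growth_rate()].
#' @return Tibble with columns `strain`, `atc_ng_ml`, `rate`,
#'   `doubling_time_min`, `quality`.
#' @export
extract_growth_rates <- function(growth, ...) {
  groups <- split(growth,
                  interaction(growth$strain, growth$atc_ng_ml,
                              drop = TRUE))
  dplyr::bind_rows(lapply(groups, function(g) {
    res <- extract_growth_rate(g[, c("time_h", "od600")], ...)
    tibble(strain = g$strain[1], atc_ng_ml = g$atc_ng_ml[1],
           rate = res$rate, doubling_time_min = res$doubling_time,
           quality = res$quality)
  }))
}

#' Normalize strain growth rates to wild type at matched induction
#'
#' @param rates Tibble from [extract_growth_rates()] for library strains.
#' @param wt_rates Same, for the wild-type reference strain.
#' @return A growth-profile matrix (strains x aTC levels) of rates
#'   relative to wild type at the same aTC level.
#' @export
normalize_to_wildtype <- function(rates, wt_rates) {
  levels_used <- sort(unique(rates$atc_ng_ml))
  wt <- setNames(wt_rates$rate, as.character(wt_rates$atc_ng_ml))
  for (lv in levels_used) {
    key <- as.character(lv)
    if (!key %in% names(wt) || is.na(wt[key]))
      stop(sprintf("missing wild-type reference at aTC = %s", key),
           call. = FALSE)
    if (wt[key] <= 0)
      stop(sprintf("wild-type growth rate is zero at aTC = %s", key),
           call. = FALSE)
  }
  strains <- unique(rates$strain)
  m <- matrix(NA_real_, length(strains), length(levels_used),
              dimnames = list(strains, as.character(levels_used)))
  for (i in seq_len(nrow(rates))) {
    key <- as.character(rates$atc_ng_ml[i])
    m[rates$strain[i], key] <- rates$rate[i] / wt[key]
  }
  m
}

#' Correlate growth rate with induction level for one strain
#'
#' Pearson correlation between a strain's (normalized) growth rates and
#' the inducer concentrations (or estimated TF copy numbers when
#' supplied).
#'
#' @param rates Numeric vector of growth rates across levels.
#' @param atc_levels Matching inducer concentrations (>= 3).
#' @return List with `r` (Pearson coefficient, `NA` when undefined) and
#'   `defined` (FALSE when either variable has zero variance).
#' @export
correlate_rate_vs_induction <- function(rates, atc_levels) {
  stopifnot(length(rates) == length(atc_levels))
  keep <- is.finite(rates) & is.finite(atc_levels)
  rates <- rates[keep]; atc_levels <- atc_levels[keep]
  if (length(rates) < 3)
    stop("need >= 3 induction levels", call. = FALSE)
  if (sd(rates) == 0 || sd(atc_levels) == 0)
    return(list(r = NA_real_, defined = FALSE))
  list(r = cor(rates, atc_levels), defined = TRUE)
}

#' Cluster growth-phenotype profiles
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances by default) of wild-type-normalized growth-rate profiles.
#' Deterministic given its inputs; either a cluster count `k` or a
#' dendrogram `cut_height` selects the partition.
#'
#' @param matrix Profile matrix from [normalize_to_wildtype()]; rows are
#'   strains. Missing entries are imputed with the column mean first;
#'   all-missing rows are an error.
#' @param k Number of clusters (used when `cut_height` is NULL).
#' @param cut_height Dendrogram cut height (overrides `k`).
#' @param method,metric Linkage and distance (defaults `ward.D2`,
#'   `euclidean`).
#' @return List with `assignments` (named integer vector), `tree`
#'   (hclust object), `k`.
#' @export
cluster_growth_profiles <- function(matrix, k = 6, cut_height = NULL,
                                    method = "ward.D2",
                                    metric = "euclidean") {
  all_missing <- rowSums(!is.na(matrix)) == 0
  if (any(all_missing))
    stop("strains with all-missing profiles: ",
         paste(rownames(matrix)[all_missing], collapse = ", "),
         call. = FALSE)
  for (j in seq_len(ncol(matrix))) {
    miss <- is.na(matrix[, j])
    if (any(miss)) matrix[miss, j] <- mean(matrix[, j], na.rm = TRUE)
  }
  tree <- hclust(dist(matrix, method = metric), method = method)
  assignments <- if (!is.null(cut_height)) cutree(tree, h = cut_height)
                 else cutree(tree, k = k)
  list(assignments = assignments, tree = tree,
       k = length(unique(assignments)))
}
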