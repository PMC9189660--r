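# Thermodynamic model of simple-regulation fold change.
#
# A TF at copy number N_TF partitions between one specific site and N_ns
# nonspecific genomic sites. With binding energy delta_eps (in kT,
# negative = favorable) the specific site's occupancy weight is
# x = N_TF * exp(-delta_eps) / N_ns, and expression relative to the
# unregulated promoter is
#
#   fold change = (1 + FC_max * x) / (1 + x),
#
# where FC_max is the fold change at saturating occupancy: 0 for complete
# steric blockage, < 1 repression, > 1 activation.

#' Parameters of the thermodynamic fold-change model
#'
#' @param delta_eps Binding energy in kT; negative = stronger binding.
#' @param fc_max Fold change at saturating TF occupancy (>= 0).
#' @param n_ns Number of nonspecific genomic sites (> 0); defaults to the
#'   E. coli genome length in bp.
#' @return A `thermo_params` list.
#' @export
thermo_params <- function(delta_eps, fc_max = 0, n_ns = 4.6e6) {
  check_scalar(delta_eps, "delta_eps")
  check_scalar(fc_max, "fc_max", nonneg = TRUE)
  check_scalar(n_ns, "n_ns", positive = TRUE)
  structure(list(delta_eps = delta_eps, fc_max = fc_max, n_ns = n_ns),
            class = "thermo_params")
}

#' Effective TF concentration
#'
#' TF copy number weighted by site affinity relative to the nonspecific
#' genomic background: `tf_copies * exp(-delta_eps) / n_ns`. Fold-change
#' curves for different (TF, site) combinations collapse when plotted
#' against this quantity.
#'
#' @param tf_copies TF copy number(s), >= 0.
#' @param delta_eps Binding energy in kT.
#' @param n_ns Nonspecific site count.
#' @return Dimensionless effective concentration(s).
#' @export
effective_tf_concentration <- function(tf_copies, delta_eps, n_ns = 4.6e6) {
  if (any(tf_copies < 0)) stop("tf_copies must be >= 0", call. = FALSE)
  tf_copies * exp(-delta_eps) / n_ns
}

#' Thermodynamic fold change
#'
#' @param tf_copies TF copy number(s), >= 0 (vectorised).
#' @param params A [thermo_params()].
#' @return Strictly positive fold change(s); exactly 1 at `tf_copies = 0`
#'   and tending to `fc_max` at saturating TF.
#' @export
fold_change <- function(tf_copies, params) {
  stopifnot(inherits(params, "thermo_params"))
  x <- effective_tf_concentration(tf_copies, params$delta_eps, params$n_ns)
  (1 + params$fc_max * x) / (1 + x)
}

#' Two-state statistical-weight oracle for the fold change
#'
#' Independent evaluation used for testing: enumerates the two promoter
#' states explicitly (unbound: weight 1, rate 1; TF-bound: weight x, rate
#' fc_max) and returns the weight-averaged rate. Must agree with
#' [fold_change()] to machine precision.
#'
#' @inheritParams fold_change
#' @return Fold change(s).
#' @export
two_state_oracle <- function(tf_copies, params) {
  stopifnot(inherits(params, "thermo_params"))
  vapply(tf_copies, function(tf) {
    x <- tf * exp(-params$delta_eps) / params$n_ns
    weights <- c(unbound = 1, bound = x)
    rates <- c(unbound = 1, bound = params$fc_max)
    sum(weights * rates) / sum(weights)
  }, numeric(1))
}

#' Bin single-cell fold-change data by TF copy number
#'
#' Within each (site_id, position, cofactor_uM) group, cells are split
#' into `n_bins` equal-count bins over `tf_copies`; per bin the mean TF
#' copy number, mean fold change, its standard error and the count are
#' returned.
#'
#' @param table Fold-change table (see [simulate_foldchange_dataset()]).
#' @param n_bins Bins per group (default 10).
#' @return A tibble with columns `site_id`, `position`, `cofactor_uM`,
#'   `bin`, `mean_tf`, `mean_fc`, `sem_fc`, `n`.
#' @export
bin_foldchange_by_tf <- function(table, n_bins = 10) {
  stopifnot(all(c("tf_copies", "fold_change") %in% names(table)))
  for (col in c("site_id", "position", "cofactor_uM"))
    if (!col %in% names(table)) table[[col]] <- NA
  groups <- split(table, interaction(table$site_id, table$position,
                                     table$cofactor_uM, drop = TRUE))
  out <- lapply(groups, function(g) {
    if (nrow(g) < n_bins)
      stop(sprintf(paste0("insufficient records for group (site %s, ",
                          "position %s, cofactor %s): %d < %d bins"),
                   g$site_id[1], g$position[1], g$cofactor_uM[1],
                   nrow(g), n_bins), call. = FALSE)
    ord <- order(g$tf_copies)
    g <- g[ord, , drop = FALSE]
    idx <- pmin(ceiling(seq_len(nrow(g)) / (nrow(g) / n_bins)), n_bins)
    g$bin <- idx
    g %>%
      group_by(.data$site_id, .data$position, .data$cofactor_uM,
               .data$bin) %>%
      summarise(mean_tf = mean(.data$tf_copies),
                mean_fc = mean(.data$fold_change),
                sem_fc = stats::sd(.data$fold_change) /
                  sqrt(dplyr::n()),
                n = dplyr::n(), .groups = "drop")
  })
  res <- dplyr::bind_rows(out)
  res$sem_fc[is.na(res$sem_fc)] <- 0
  res
}

# Weighted SSE of the model on a binned curve, as a function of the free
# parameter. Weights 1/SEM^2; zero/degenerate SEMs fall back to equal
# weights so noiseless curves remain fittable.
#' @noRd
curve_weights <- function(curve) {
  if (all(curve$sem_fc > 0)) 1 / curve$sem_fc^2 else rep(1, nrow(curve))
}

#' @noRd
wsse_thermo <- function(curve, w, delta_eps, fc_max, n_ns) {
  p <- thermo_params(delta_eps = delta_eps, fc_max = fc_max, n_ns = n_ns)
  pred <- fold_change(curve$mean_tf, p)
  sum(w * (curve$mean_fc - pred)^2)
}

# 95% CI half-width from the local curvature of the weighted SSE:
# var(theta) ~ s2 * (J' W J)^-1 with J by central differences.
#' @noRd
wnls_ci <- function(curve, w, pred_fun, theta, h) {
  jac <- (pred_fun(theta + h) - pred_fun(theta - h)) / (2 * h)
  jtwj <- sum(w * jac^2)
  resid <- curve$mean_fc - pred_fun(theta)
  dof <- max(1L, nrow(curve) - 1L)
  s2 <- sum(w * resid^2) / dof
  if (jtwj <= 0) return(Inf)
  qt_975 <- stats::qt(0.975, dof)
  qt_975 * sqrt(s2 / jtwj)
}

#' Fit the binding energy under the steric-hindrance model
#'
#' Fits `delta_eps` — the sole free parameter — by weighted nonlinear
#' least squares of the model with `fc_max` fixed at 0 to a binned
#' fold-change curve. Minimisation is an exact 1-D bounded search;
#' weights are 1/SEM^2 (equal weights when SEMs are all zero).
#'
#' @param curve Binned curve from [bin_foldchange_by_tf()] (columns
#'   `mean_tf`, `mean_fc`, `sem_fc`, `n`).
#' @param n_ns Nonspecific site count.
#' @param bounds Search interval for `delta_eps` in kT.
#' @return A `thermo_fit` list: `params` ([thermo_params()]), `ci95`
#'   (named list per fitted parameter), `fixed` (names of fixed
#'   parameters), `n_bins_used`, `residual_wsse`, and `boundary_warning`
#'   when the curve carries no repression signal.
#' @export
fit_binding_energy <- function(curve, n_ns = 4.6e6,
                               bounds = c(-30, 5)) {
  stopifnot(all(c("mean_tf", "mean_fc") %in% names(curve)))
  if (!"sem_fc" %in% names(curve)) curve$sem_fc <- 0
  if (nrow(curve) < 3)
    stop("binding-energy fit needs >= 3 bins", call. = FALSE)
  w <- curve_weights(curve)
  obj <- function(de) wsse_thermo(curve, w, de, fc_max = 0, n_ns = n_ns)
  opt <- optimize(obj, interval = bounds, tol = 1e-10)
  de_hat <- opt$minimum
  boundary <- de_hat > bounds[2] - 0.5
  if (all(curve$mean_fc > 0.99)) boundary <- TRUE
  if (boundary)
    warning(paste("curve is consistent with no repression;",
                  "delta_eps is at or near the weak-binding boundary"),
            call. = FALSE)
  pred_fun <- function(de)
    fold_change(curve$mean_tf, thermo_params(de, 0, n_ns))
  half <- wnls_ci(curve, w, pred_fun, de_hat, h = 1e-4)
  structure(list(
    params = thermo_params(delta_eps = de_hat, fc_max = 0, n_ns = n_ns),
    ci95 = list(delta_eps = c(de_hat - half, de_hat + half)),
    fixed = "fc_max",
    n_bins_used = nrow(curve),
    residual_wsse = opt$objective,
    boundary_warning = boundary
  ), class = "thermo_fit")
}

#' Fit the saturating fold change with the binding energy held fixed
#'
#' Mirrors the two-step inference: `delta_eps` is measured first at a
#' steric-hindrance position, then `fc_max` is the sole fit parameter at
#' other positions. `fc_max >= 0` is enforced by the search bound.
#'
#' @param curve Binned curve (see [fit_binding_energy()]).
#' @param delta_eps_fixed Binding energy, in kT, from the steric fit.
#' @param n_ns Nonspecific site count.
#' @param upper Upper search bound for `fc_max`.
#' @return A `thermo_fit` list with `fc_max` fitted, `delta_eps` fixed.
#' @export
fit_fcmax <- function(curve, delta_eps_fixed, n_ns = 4.6e6, upper = 1e3) {
  stopifnot(all(c("mean_tf", "mean_fc") %in% names(curve)))
  if (!"sem_fc" %in% names(curve)) curve$sem_fc <- 0
  if (nrow(curve) < 2)
    stop("fc_max fit needs >= 2 bins", call. = FALSE)
  w <- curve_weights(curve)
  obj <- function(fm)
    wsse_thermo(curve, w, delta_eps_fixed, fc_max = fm, n_ns = n_ns)
  opt <- optimize(obj, interval = c(0, upper), tol = 1e-12)
  fm_hat <- opt$minimum
  # optimize() cannot land exactly on the bound; snap when the bound is
  # at least as good
  if (obj(0) <= opt$objective + 1e-15) {
    fm_hat <- 0
    opt$objective <- obj(0)
  }
  pred_fun <- function(fm)
    fold_change(curve$mean_tf,
                thermo_params(delta_eps_fixed, max(0, fm), n_ns))
  # one-sided step at the zero bound
  half <- wnls_ci(curve, w, pred_fun, max(fm_hat, 1e-6), h = 1e-6)
  structure(list(
    params = thermo_params(delta_eps = delta_eps_fixed, fc_max = fm_hat,
                           n_ns = n_ns),
    ci95 = list(fc_max = c(max(0, fm_hat - half), fm_hat + half)),
    fixed = "delta_eps",
    n_bins_used = nrow(curve),
    residual_wsse = opt$objective,
    boundary_warning = fm_hat == 0
  ), class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  free <- setdiff(c("delta_eps", "fc_max"), x$fixed)
  ci <- x$ci95[[free]]
  cat(sprintf("Thermo fit: %s = %.4g (95%% CI %.4g to %.4g), %s fixed at %.4g, %d bins\n",
              free, x$params[[free]], ci[1], ci[2],
              x$fixed, x$params[[x$fixed]], x$n_bins_used))
  invisible(x)
}

#' Test whether two conditions share the same binding affinity
#'
#' Fits `delta_eps` separately to two steric-model curves and jointly to
#' their pooled bins, reports the difference with a 95% CI, and an
#' F-style comparison of pooled vs separate weighted residuals. Used to
#' ask, e.g., whether a cofactor changes the TF's affinity for its site.
#'
#' @param curve_a,curve_b Binned curves (see [fit_binding_energy()]).
#' @param n_ns Nonspecific site count.
#' @return List with `fit_a`, `fit_b`, `fit_joint`, `difference`
#'   (delta_eps_a - delta_eps_b), `difference_ci95`, `f_statistic`,
#'   `p_value`, and `equal` (TRUE when the difference CI covers 0).
#' @export
test_affinity_equality <- function(curve_a, curve_b, n_ns = 4.6e6) {
  if (is.null(curve_a) || nrow(curve_a) == 0)
    stop("curve_a is empty", call. = FALSE)
  if (is.null(curve_b) || nrow(curve_b) == 0)
    stop("curve_b is empty", call. = FALSE)
  fit_a <- fit_binding_energy(curve_a, n_ns)
  fit_b <- fit_binding_energy(curve_b, n_ns)
  pooled <- dplyr::bind_rows(
    curve_a[, c("mean_tf", "mean_fc", "sem_fc", "n")],
    curve_b[, c("mean_tf", "mean_fc", "sem_fc", "n")])
  fit_j <- fit_binding_energy(pooled, n_ns)
  diff <- fit_a$params$delta_eps - fit_b$params$delta_eps
  se_a <- diff(range(fit_a$ci95$delta_eps)) / 2
  se_b <- diff(range(fit_b$ci95$delta_eps)) / 2
  half <- sqrt(se_a^2 + se_b^2)
  sse_sep <- fit_a$residual_wsse + fit_b$residual_wsse
  sse_pool <- fit_j$residual_wsse
  df_sep <- nrow(pooled) - 2L
  fstat <- if (sse_sep > 0) ((sse_pool - sse_sep) / 1) / (sse_sep / df_sep)
           else Inf
  pval <- if (is.finite(fstat)) stats::pf(fstat, 1, df_sep,
                                          lower.tail = FALSE) else 0
  equal <- abs(diff) <= half
  if (sse_sep == 0 && sse_pool == 0) { equal <- TRUE; fstat <- 0; pval <- 1 }
  list(fit_a = fit_a, fit_b = fit_b, fit_joint = fit_j,
       difference = diff, difference_ci95 = c(diff - half, diff + half),
       f_statistic = fstat, p_value = pval, equal = equal)
}

#' Classify the joint regulatory mode of two paralogous TFs at one site
#'
#' Compares each TF's fitted `fc_max` to 1 (activation above, repression
#' below). A fit whose 95% CI spans 1 is called indeterminate. When the
#' two CIs overlap each other the site is additionally flagged as lying
#' on the one-to-one diagonal (quantitatively identical regulation).
#'
#' @param fit_a,fit_b `thermo_fit` objects with `fc_max` CIs (TF A and
#'   TF B at the same binding site/position).
#' @param site_id Label carried into the result.
#' @return A `quadrant_call` list: `site_id`, `fc_max_a`, `fc_max_b`,
#'   their CIs, `quadrant` in {both-activate, both-repress,
#'   A-activates/B-represses, A-represses/B-activates, indeterminate},
#'   and `on_diagonal`.
#' @export
classify_regulatory_mode <- function(fit_a, fit_b, site_id = NA) {
  for (f in list(fit_a, fit_b))
    if (is.null(f$ci95$fc_max))
      stop("both fits must carry fc_max confidence intervals",
           call. = FALSE)
  ci_a <- fit_a$ci95$fc_max
  ci_b <- fit_b$ci95$fc_max
  spans1 <- function(ci) ci[1] <= 1 && ci[2] >= 1
  mode_of <- function(fm, ci) {
    if (spans1(ci)) "indeterminate" else if (fm > 1) "activates"
    else "represses"
  }
  m_a <- mode_of(fit_a$params$fc_max, ci_a)
  m_b <- mode_of(fit_b$params$fc_max, ci_b)
  quadrant <- if (m_a == "indeterminate" || m_b == "indeterminate") {
    "indeterminate"
  } else if (m_a == "activates" && m_b == "activates") {
    "both-activate"
  } else if (m_a == "represses" && m_b == "represses") {
    "both-repress"
  } else if (m_a == "activates") {
    "A-activates/B-represses"
  } else {
    "A-represses/B-activates"
  }
  on_diag <- ci_a[1] <= ci_b[2] && ci_b[1] <= ci_a[2]
  structure(list(site_id = site_id,
                 fc_max_a = fit_a$params$fc_max, ci95_a = ci_a,
                 fc_max_b = fit_b$params$fc_max, ci95_b = ci_b,
                 quadrant = quadrant, on_diagonal = on_diag),
            class = "quadrant_call")
}
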