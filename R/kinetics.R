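# Kinetic model of metal-responsive regulation by a MerR-family TF.
#
# External zinc is imported at rate beta_in and exported by the
# transporter E (the TF's own target gene) at rate beta_out per exporter.
# Intracellular zinc binds the TF (gamma1) to form the holo form TF*,
# which unbinds at gamma2. Both apo-TF and TF* bind the single target
# promoter with rate k_on and unbind with k_off (equal affinity: the
# cofactor changes the bound TF's regulatory function, not its
# occupancy). The promoter has three states: free (P_off, basal
# expression rate r0), apo-TF-bound (P_on, fully repressed, rate 0), and
# TF*-bound (P_on*, activated, rate r). The exporter is degraded/diluted
# at rate gamma.
#
#   dZin/dt  = beta_in*Zout - beta_out*Zin*E - gamma1*Zin*TF + gamma2*TF*
#   dTF*/dt  = gamma1*Zin*TF - gamma2*TF* - k_on*TF**P_off + k_off*P_on*
#   dPon/dt  = k_on*TF*P_off - k_off*P_on
#   dPon*/dt = k_on*TF**P_off - k_off*P_on*
#   dE/dt    = r*P_on* + r0*P_off - gamma*E
#
# with conservation: P_off + P_on + P_on* = 1,
# TF + TF* + P_on + P_on* = TF_total, and (closed system)
# TF* + P_on* + Zin + Zout = Zinc_total.

#' Parameters of the TF-zinc-exporter kinetic model
#'
#' Defaults are order-of-magnitude choices for an E. coli cell growing
#' with a 30-min cell cycle: `gamma = log(2)/0.5` per hour, promoter
#' kinetics fast relative to the cell cycle (`k_off = 100`/h), and
#' `k_on/k_off = exp(-delta_eps)/n_ns` tied to the measured binding
#' energy. All rates are per hour; copy numbers are molecules per cell.
#'
#' @param beta_in Zinc import rate constant (per h).
#' @param beta_out Zinc export rate constant per exporter (per h).
#' @param gamma1,gamma2 TF-zinc binding/unbinding rates.
#' @param k_off TF-promoter unbinding rate (> 0).
#' @param k_on TF-promoter binding rate; defaults to
#'   `k_off * exp(-delta_eps)/n_ns`.
#' @param r Expression rate from the TF*-bound promoter.
#' @param r0 Basal expression rate from the free promoter.
#' @param gamma Exporter degradation/dilution rate (> 0).
#' @param tf_total Total TF copies (conserved).
#' @param zinc_out External zinc concentration (clamped mode).
#' @param zinc_total Total zinc (closed mode); `NULL` for clamped mode.
#' @param delta_eps,n_ns Used only for the default `k_on`.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(beta_in = 1, beta_out = 1e-3,
                           gamma1 = 1, gamma2 = 10,
                           k_off = 100,
                           k_on = k_off * exp(-delta_eps) / n_ns,
                           r = 1000, r0 = 10,
                           gamma = log(2) / 0.5,
                           tf_total = 100,
                           zinc_out = 0, zinc_total = NULL,
                           delta_eps = -13.8, n_ns = 4.6e6) {
  for (nm in c("beta_in", "beta_out", "gamma1", "gamma2", "k_on", "r",
               "r0", "tf_total", "zinc_out"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  check_scalar(k_off, "k_off", positive = TRUE)
  check_scalar(gamma, "gamma", positive = TRUE)
  if (!is.null(zinc_total)) check_scalar(zinc_total, "zinc_total",
                                         nonneg = TRUE)
  structure(list(beta_in = beta_in, beta_out = beta_out, gamma1 = gamma1,
                 gamma2 = gamma2, k_on = k_on, k_off = k_off, r = r,
                 r0 = r0, gamma = gamma, tf_total = tf_total,
                 zinc_out = zinc_out, zinc_total = zinc_total),
            class = "kinetic_params")
}

#' A kinetic model state
#'
#' The five dynamic components; the derived quantities `tf_free`,
#' `p_off` and (closed mode) `zinc_out` follow from conservation.
#'
#' @param zinc_in Intracellular zinc.
#' @param tf_star Zinc-bound (holo) TF.
#' @param p_on Apo-TF-bound promoter fraction.
#' @param p_on_star Holo-TF-bound promoter fraction.
#' @param e Exporter concentration.
#' @return A named numeric vector of class `kinetic_state`.
#' @export
kinetic_state <- function(zinc_in = 0, tf_star = 0, p_on = 0,
                          p_on_star = 0, e = 0) {
  structure(c(zinc_in = zinc_in, tf_star = tf_star, p_on = p_on,
              p_on_star = p_on_star, e = e),
            class = "kinetic_state")
}

# Derived components from conservation.
#' @noRd
state_completion <- function(y, params) {
  p_off <- 1 - y[["p_on"]] - y[["p_on_star"]]
  tf_free <- params$tf_total - y[["tf_star"]] - y[["p_on"]] -
    y[["p_on_star"]]
  zinc_out <- if (is.null(params$zinc_total)) params$zinc_out
  else params$zinc_total - y[["zinc_in"]] - y[["tf_star"]] -
    y[["p_on_star"]]
  list(p_off = p_off, tf_free = tf_free, zinc_out = zinc_out)
}

#' Time derivatives of the kinetic model
#'
#' @param state A [kinetic_state()] (or named vector with components
#'   `zinc_in`, `tf_star`, `p_on`, `p_on_star`, `e`).
#' @param params A [kinetic_params()].
#' @return Named vector of the five time-derivatives plus `p_off`
#'   (`d p_off/dt = -(d p_on/dt + d p_on_star/dt)`, so the promoter-state
#'   sum is conserved identically).
#' @export
derivatives <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  y <- unclass(state)
  cmp <- state_completion(y, params)
  p <- params
  zin <- y[["zinc_in"]]; tfs <- y[["tf_star"]]
  pon <- y[["p_on"]]; pons <- y[["p_on_star"]]; e <- y[["e"]]
  poff <- cmp$p_off; tff <- cmp$tf_free; zout <- cmp$zinc_out
  d_zin <- p$beta_in * zout - p$beta_out * zin * e -
    p$gamma1 * zin * tff + p$gamma2 * tfs
  d_tfs <- p$gamma1 * zin * tff - p$gamma2 * tfs -
    p$k_on * tfs * poff + p$k_off * pons
  d_pon <- p$k_on * tff * poff - p$k_off * pon
  d_pons <- p$k_on * tfs * poff - p$k_off * pons
  d_e <- p$r * pons + p$r0 * poff - p$gamma * e
  c(zinc_in = d_zin, tf_star = d_tfs, p_on = d_pon,
    p_on_star = d_pons, e = d_e, p_off = -(d_pon + d_pons))
}

#' @noRd
deriv_vec <- function(y, params) {
  unname(derivatives(y, params)[1:5])
}

# Damped Newton on the 5-dim algebraic steady-state system with a
# finite-difference Jacobian; polishes the integrator's endpoint.
#' @noRd
newton_polish <- function(y, params, tol = 1e-12, max_iter = 50) {
  nm <- c("zinc_in", "tf_star", "p_on", "p_on_star", "e")
  y <- setNames(as.numeric(y[nm]), nm)
  fy <- deriv_vec(y, params)
  for (it in seq_len(max_iter)) {
    if (max(abs(fy)) < tol) break
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      h <- max(1e-8, 1e-8 * abs(y[j]))
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (deriv_vec(yp, params) - fy) / h
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      y_new <- y + lambda * step
      f_new <- deriv_vec(y_new, params)
      if (all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(fy)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    y <- y + lambda * step
    fy <- deriv_vec(y, params)
  }
  y
}

#' Solve the kinetic model to steady state
#'
#' Integrates the ODE system with a stiff solver (lsoda) from a
#' consistent initial state until the maximum relative derivative falls
#' below `tol`, then polishes with a damped Newton iteration on the
#' algebraic system. The returned state satisfies the conservation
#' constraints to 1e-8.
#'
#' @param params A [kinetic_params()].
#' @param tol Relative-derivative convergence tolerance (default 1e-10).
#' @param t_max Maximum integration time (model hours).
#' @return A [kinetic_state()] with attributes `p_off`, `tf_free`,
#'   `zinc_out`, `residual` (max absolute derivative).
#' @export
steady_state <- function(params, tol = 1e-10, t_max = 1e6) {
  stopifnot(inherits(params, "kinetic_params"))
  y0 <- c(zinc_in = 0, tf_star = 0, p_on = 0, p_on_star = 0, e = 0)
  rhs <- function(t, y, p) list(deriv_vec(y, p))
  t_end <- 1000
  y <- y0
  scale_of <- function(y) pmax(abs(y), c(1, 1, 1e-3, 1e-3, 1))
  repeat {
    sol <- suppressWarnings(
      deSolve::ode(y = y, times = c(0, t_end), func = rhs,
                   parms = params, method = "lsoda",
                   rtol = 1e-8, atol = 1e-10, maxsteps = 100000))
    y <- setNames(pmax(0, as.numeric(sol[nrow(sol), -1])), names(y0))
    rel <- max(abs(deriv_vec(y, params)) / scale_of(y))
    if (rel < tol || t_end >= t_max) break
    t_end <- t_end * 100
  }
  y <- newton_polish(y, params)
  resid <- max(abs(deriv_vec(y, params)))
  rel <- max(abs(deriv_vec(y, params)) / scale_of(y))
  if (rel > 1e-6)
    stop(sprintf(paste0("steady state did not converge by t_max = %g ",
                        "(max relative derivative %.3g)"), t_max, rel),
         call. = FALSE)
  der <- state_completion(y, params)
  out <- kinetic_state(zinc_in = y[["zinc_in"]], tf_star = y[["tf_star"]],
                       p_on = y[["p_on"]], p_on_star = y[["p_on_star"]],
                       e = y[["e"]])
  attr(out, "p_off") <- der$p_off
  attr(out, "tf_free") <- der$tf_free
  attr(out, "zinc_out") <- der$zinc_out
  attr(out, "residual") <- resid
  out
}

#' Steady-state fold change of the TF's target gene
#'
#' Exporter level at steady state with the TF present divided by the
#' level with `tf_total = 0` (which is `r0/gamma` exactly); equivalently
#' `(r * p_on_star + r0 * p_off) / r0`.
#'
#' @param params A [kinetic_params()].
#' @param ... Passed to [steady_state()].
#' @return Dimensionless fold change.
#' @export
fold_change_of_target <- function(params, ...) {
  if (params$r0 <= 0)
    stop("fold change undefined for r0 = 0 (no reference expression)",
         call. = FALSE)
  ss <- steady_state(params, ...)
  p0 <- params
  p0$tf_total <- 0
  ss0 <- steady_state(p0, ...)
  ss[["e"]] / ss0[["e"]]
}

#' Effective intracellular zinc concentration
#'
#' The composite axis `zinc_out * gamma1 * beta_in / (gamma2 * beta_out)`
#' combining import/export and TF-zinc binding rates.
#'
#' @param zinc_out External zinc concentration(s).
#' @param params A [kinetic_params()].
#' @return Dimensionless effective zinc.
#' @export
effective_zinc <- function(zinc_out, params) {
  if (params$gamma2 <= 0 || params$beta_out <= 0)
    stop("effective zinc undefined: gamma2 and beta_out must be > 0",
         call. = FALSE)
  zinc_out * params$gamma1 * params$beta_in /
    (params$gamma2 * params$beta_out)
}

#' Sweep the zinc response over TF totals and promoter strengths
#'
#' Computes fold change of the target versus external zinc for every
#' combination of `tf_totals` and `r0_over_r`. `r` is held fixed and the
#' basal rate `r0` scaled, modelling promoter-strength changes as changes
#' in basal expression.
#'
#' @param params Baseline [kinetic_params()].
#' @param zinc_grid External zinc concentrations (non-empty).
#' @param tf_totals TF totals to sweep (non-empty).
#' @param r0_over_r_list Ratios r0/r to sweep (non-empty).
#' @return A tibble with columns `tf_total`, `r0_over_r`, `zinc_out`,
#'   `effective_zinc`, `fold_change`.
#' @export
sweep_zinc_response <- function(params, zinc_grid, tf_totals,
                                r0_over_r_list) {
  if (length(zinc_grid) == 0 || length(tf_totals) == 0 ||
      length(r0_over_r_list) == 0)
    stop("zinc_grid, tf_totals and r0_over_r_list must be non-empty",
         call. = FALSE)
  grid <- expand.grid(tf_total = tf_totals, r0_over_r = r0_over_r_list,
                      zinc_out = zinc_grid)
  fc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$tf_total <- grid$tf_total[i]
    p$r0 <- params$r * grid$r0_over_r[i]
    p$zinc_out <- grid$zinc_out[i]
    fc[i] <- tryCatch(fold_change_of_target(p), error = function(e)
      stop(sprintf("convergence failure at tf_total=%g, r0_over_r=%g, zinc_out=%g: %s",
                   p$tf_total, grid$r0_over_r[i], p$zinc_out,
                   conditionMessage(e)), call. = FALSE))
  }
  tibble(tf_total = grid$tf_total, r0_over_r = grid$r0_over_r,
         zinc_out = grid$zinc_out,
         effective_zinc = effective_zinc(grid$zinc_out, params),
         fold_change = fc)
}

#' Cross-curve spread of the zinc response above a zinc threshold
#'
#' Quantifies the collapse of fold-change curves across TF totals: for
#' every grid point with `effective_zinc > zinc_threshold`, the relative
#' spread `(max - min)/mean` of fold change across curves is computed and
#' the maximum over points returned. Near-zero spread at high zinc is the
#' signature of TF-number-robust activation.
#'
#' @param curves Output of [sweep_zinc_response()] (one `r0_over_r`),
#'   with curves distinguished by `tf_total` on a shared zinc grid.
#' @param zinc_threshold Restrict to `effective_zinc` strictly above
#'   this value (default `-Inf`: all points).
#' @return Maximum relative spread (dimensionless).
#' @export
collapse_metric <- function(curves, zinc_threshold = -Inf) {
  stopifnot(all(c("tf_total", "effective_zinc", "fold_change") %in%
                  names(curves)))
  split_curves <- split(curves, curves$tf_total)
  if (length(split_curves) < 2)
    stop("need >= 2 curves differing in tf_total", call. = FALSE)
  grids <- lapply(split_curves, function(g)
    sort(g$effective_zinc))
  for (g in grids[-1])
    if (length(g) != length(grids[[1]]) ||
        any(abs(g - grids[[1]]) > 1e-9 * pmax(1, abs(grids[[1]]))))
      stop("curves must share the same zinc grid", call. = FALSE)
  sub <- curves[curves$effective_zinc > zinc_threshold, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no grid points above zinc_threshold", call. = FALSE)
  spread <- sub %>%
    group_by(.data$effective_zinc) %>%
    summarise(rel = (max(.data$fold_change) - min(.data$fold_change)) /
                mean(.data$fold_change), .groups = "drop")
  max(spread$rel)
}
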