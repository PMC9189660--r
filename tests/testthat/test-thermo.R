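# Thermodynamic fold-change model: evaluation, fitting, comparison.

test_that("fold change hits its anchor points", {
  p <- thermo_params(delta_eps = -13.8, fc_max = 0, n_ns = 4.6e6)
  expect_identical(fold_change(0, p), 1)
  expect_equal(fold_change(100, p), 0.0446, tolerance = 1e-2)
  # forced arithmetic: x = 1, fc_max = 5 -> (1+5)/2
  p5 <- thermo_params(delta_eps = 0, fc_max = 5, n_ns = 4.6e6)
  expect_equal(fold_change(4.6e6, p5), 3)
  expect_error(fold_change(-1, p), "tf_copies")
})

test_that("effective TF concentration is the affinity-weighted copy number", {
  expect_equal(effective_tf_concentration(4.6e6, 0, 4.6e6), 1)
  expect_identical(effective_tf_concentration(0, -10, 4.6e6), 0)
  expect_equal(effective_tf_concentration(100, -13.8, 4.6e6), 21.40,
               tolerance = 1e-3)
})

test_that("fold change is monotone with the sign set by fc_max", {
  tf <- 10^seq(0, 4, length.out = 50)
  dec <- fold_change(tf, thermo_params(-12, 0.3))
  inc <- fold_change(tf, thermo_params(-12, 3))
  flat <- fold_change(tf, thermo_params(-12, 1))
  expect_true(all(diff(dec) < 0))
  expect_true(all(diff(inc) > 0))
  expect_equal(flat, rep(1, 50))
  # saturation limit equals fc_max
  p <- thermo_params(-13.8, 0.3)
  tf_sat <- 1e8 * 4.6e6 * exp(-13.8)
  expect_equal(fold_change(tf_sat, p), 0.3, tolerance = 1e-6)
})

test_that("curves collapse exactly at equal effective TF concentration", {
  # (tf, delta_eps) pairs engineered to share x
  x_target <- effective_tf_concentration(100, -13.8, 4.6e6)
  tf2 <- 1000
  de2 <- -log(x_target * 4.6e6 / tf2)
  for (fm in c(0, 0.5, 2)) {
    f1 <- fold_change(100, thermo_params(-13.8, fm))
    f2 <- fold_change(tf2, thermo_params(de2, fm))
    expect_equal(f1, f2)
  }
})

test_that("model agrees with the two-state enumeration oracle", {
  set.seed(11)
  for (i in 1:100) {
    tf <- runif(1, 0, 5000)
    de <- runif(1, -18, 0)
    fm <- runif(1, 0, 10)
    p <- thermo_params(de, fm)
    expect_equal(fold_change(tf, p), two_state_oracle(tf, p),
                 tolerance = 1e-12)
  }
  p <- thermo_params(-13.8, 1)
  expect_identical(two_state_oracle(0, p), 1)
  expect_equal(two_state_oracle(123, p), 1)
})

test_that("binning by TF copy number gives equal-count bins and SEMs", {
  cfg <- foldchange_sim_config(n_cells = 300, noise_cv = 0,
                               tf_jitter_cv = 0, fc_max = 1, seed = 2)
  d <- simulate_foldchange_dataset(cfg)
  b <- bin_foldchange_by_tf(d, n_bins = 10)
  expect_equal(nrow(b), 10L)
  expect_equal(b$n, rep(30L, 10))
  expect_equal(b$mean_fc, rep(1, 10))
  expect_equal(b$sem_fc, rep(0, 10))
  expect_error(bin_foldchange_by_tf(d[1:5, ], n_bins = 10),
               "insufficient records")
})

test_that("noiseless binned curves reproduce the model to < 1%", {
  cfg <- foldchange_sim_config(delta_eps = -13, fc_max = 0.2,
                               n_cells = 1000, noise_cv = 0,
                               tf_jitter_cv = 0.05, seed = 3)
  d <- simulate_foldchange_dataset(cfg)
  b <- bin_foldchange_by_tf(d, n_bins = 10)
  pred <- fold_change(b$mean_tf, thermo_params(-13, 0.2))
  expect_lt(max(abs(b$mean_fc - pred) / pred), 0.01)
})

test_that("binding energy is recovered from noiseless curves", {
  curve <- make_model_curve(-13.8)
  fit <- fit_binding_energy(curve)
  expect_equal(fit$params$delta_eps, -13.8, tolerance = 0.05 / 13.8)
  expect_identical(fit$fixed, "fc_max")
  expect_true(fit$ci95$delta_eps[1] <= fit$params$delta_eps &&
                fit$params$delta_eps <= fit$ci95$delta_eps[2])
})

test_that("flat curves trigger the no-repression boundary warning", {
  flat <- tibble::tibble(mean_tf = 10^seq(0, 3, length.out = 6),
                         mean_fc = 1, sem_fc = 0, n = 30L)
  expect_warning(fit <- fit_binding_energy(flat), "no repression")
  expect_true(fit$boundary_warning)
})

test_that("binding energy recovery tolerates 10% measurement noise", {
  ok <- 0L
  for (s in 1:10) {
    d <- simulate_foldchange_dataset(
      foldchange_sim_config(delta_eps = -13.8, fc_max = 0,
                            n_cells = 2000, noise_cv = 0.1, seed = s))
    fit <- fit_binding_energy(bin_foldchange_by_tf(d, 10))
    if (abs(fit$params$delta_eps + 13.8) < 0.2) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("fc_max is recovered with the binding energy held fixed", {
  curve <- make_model_curve(-13.8, fc_max = 5)
  fit <- fit_fcmax(curve, delta_eps_fixed = -13.8)
  expect_equal(fit$params$fc_max, 5, tolerance = 1e-4)
  expect_identical(fit$fixed, "delta_eps")
  # neutral curve: fc_max = 1 within its CI
  flat <- make_model_curve(-13.8, fc_max = 1)
  fit1 <- fit_fcmax(flat, -13.8)
  expect_true(fit1$ci95$fc_max[1] <= 1 + 1e-6 &&
                1 - 1e-6 <= fit1$ci95$fc_max[2])
  # steric curve: recovered at the zero bound
  zero <- make_model_curve(-13.8, fc_max = 0)
  expect_equal(fit_fcmax(zero, -13.8)$params$fc_max, 0)
})

test_that("joint recovery covers the design grid", {
  for (de in c(-16, -10)) for (fm in c(0, 0.3, 3)) {
    curve <- make_model_curve(de, fm,
                              tf = 10^seq(0, 5, length.out = 12))
    fit_de <- fit_binding_energy(make_model_curve(de, 0,
      tf = 10^seq(0, 5, length.out = 12)))
    expect_equal(fit_de$params$delta_eps, de, tolerance = 0.01)
    fit_fm <- fit_fcmax(curve, fit_de$params$delta_eps)
    expect_equal(fit_fm$params$fc_max, fm, tolerance = 0.02 + 0.02 * fm)
  }
})

test_that("affinity equality test separates shared from distinct energies", {
  a <- make_model_curve(-13.8)
  b <- make_model_curve(-13.8)
  same <- test_affinity_equality(a, b)
  expect_true(same$equal)
  expect_equal(same$difference, 0, tolerance = 1e-6)
  # power: -13.8 vs -11.8 with noise, most replicates called different
  diff_calls <- 0L
  for (s in 1:5) {
    da <- simulate_foldchange_dataset(
      foldchange_sim_config(delta_eps = -13.8, n_cells = 2000,
                            noise_cv = 0.1, seed = s))
    db <- simulate_foldchange_dataset(
      foldchange_sim_config(delta_eps = -11.8, n_cells = 2000,
                            noise_cv = 0.1, seed = s + 100))
    res <- test_affinity_equality(bin_foldchange_by_tf(da, 10),
                                  bin_foldchange_by_tf(db, 10))
    if (!res$equal) diff_calls <- diff_calls + 1L
  }
  expect_gte(diff_calls, 4L)
  expect_error(test_affinity_equality(a, a[0, ]), "curve_b is empty")
})

test_that("quadrant classification follows the fc_max CIs", {
  mk <- function(fm, half) {
    structure(list(params = thermo_params(-13, fm),
                   ci95 = list(fc_max = c(fm - half, fm + half)),
                   fixed = "delta_eps"),
              class = "thermo_fit")
  }
  expect_equal(classify_regulatory_mode(mk(3, 0.2), mk(0.2, 0.05))$quadrant,
               "A-activates/B-represses")
  expect_equal(classify_regulatory_mode(mk(0.5, 0.1), mk(0.5, 0.1))$quadrant,
               "both-repress")
  expect_equal(classify_regulatory_mode(mk(1.05, 0.2), mk(3, 0.1))$quadrant,
               "indeterminate")
  expect_equal(classify_regulatory_mode(mk(2, 0.1), mk(3, 0.1))$quadrant,
               "both-activate")
  call <- classify_regulatory_mode(mk(0.5, 0.1), mk(0.55, 0.1))
  expect_true(call$on_diagonal)
  bad <- structure(list(params = thermo_params(-13, 1), ci95 = list()),
                   class = "thermo_fit")
  expect_error(classify_regulatory_mode(bad, mk(2, 0.1)), "fc_max")
})
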