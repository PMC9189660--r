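# TF-zinc-exporter kinetic model: derivatives, steady state, regimes.

test_that("derivatives reduce correctly in degenerate states", {
  p <- kinetic_params(tf_total = 0, zinc_out = 0)
  d <- derivatives(kinetic_state(), p)
  expect_equal(d[["e"]], p$r0)
  expect_equal(unname(d[c("zinc_in", "tf_star", "p_on", "p_on_star")]),
               rep(0, 4))
  # no binder: promoter-binding derivatives vanish for any zinc
  p0 <- kinetic_params(tf_total = 0, zinc_out = 5)
  d0 <- derivatives(kinetic_state(zinc_in = 2, e = 1), p0)
  expect_equal(d0[["p_on"]], 0)
  expect_equal(d0[["p_on_star"]], 0)
})

test_that("promoter-state occupancies sum to a conserved total", {
  p <- kinetic_params(tf_total = 50, zinc_out = 3)
  set.seed(5)
  for (i in 1:20) {
    s <- kinetic_state(zinc_in = runif(1, 0, 5),
                       tf_star = runif(1, 0, 10),
                       p_on = runif(1, 0, 0.4),
                       p_on_star = runif(1, 0, 0.4),
                       e = runif(1, 0, 100))
    d <- derivatives(s, p)
    expect_equal(d[["p_off"]], -(d[["p_on"]] + d[["p_on_star"]]))
  }
})

test_that("steady state matches closed forms without TF or zinc", {
  p <- kinetic_params(tf_total = 0, zinc_out = 2)
  ss <- steady_state(p)
  expect_equal(attr(ss, "p_off"), 1, tolerance = 1e-8)
  expect_equal(ss[["e"]], p$r0 / p$gamma, tolerance = 1e-8)
  # no cofactor: pure repression by the apo TF
  pz <- kinetic_params(tf_total = 100, zinc_out = 0)
  ssz <- steady_state(pz)
  expect_equal(ssz[["tf_star"]], 0, tolerance = 1e-10)
  expect_equal(ssz[["p_on_star"]], 0, tolerance = 1e-10)
  expect_equal(ssz[["e"]], pz$r0 * attr(ssz, "p_off") / pz$gamma,
               tolerance = 1e-8)
  expect_lt(ssz[["e"]], pz$r0 / pz$gamma)
})

test_that("conservation and solver/root-finder agreement hold on random draws", {
  set.seed(17)
  for (i in 1:15) {
    p <- kinetic_params(
      beta_in = runif(1, 0.1, 2), beta_out = 10^runif(1, -4, -2),
      gamma1 = runif(1, 0.5, 2), gamma2 = runif(1, 5, 20),
      r = 10^runif(1, 2, 3), r0 = 10^runif(1, 0, 2),
      tf_total = 10^runif(1, 1, 3),
      zinc_out = 0, zinc_total = runif(1, 10, 100))
    ss <- steady_state(p)
    # algebraic residual at the returned state
    expect_lt(attr(ss, "residual"), 1e-8)
    # closed-mode zinc conservation
    zsum <- ss[["zinc_in"]] + ss[["tf_star"]] + ss[["p_on_star"]] +
      attr(ss, "zinc_out")
    expect_equal(zsum, p$zinc_total, tolerance = 1e-8)
    # promoter and TF conservation
    expect_equal(ss[["p_on"]] + ss[["p_on_star"]] + attr(ss, "p_off"),
                 1, tolerance = 1e-10)
    expect_equal(ss[["tf_star"]] + ss[["p_on"]] + ss[["p_on_star"]] +
                   attr(ss, "tf_free"), p$tf_total, tolerance = 1e-8)
    # Newton restarted from a perturbed point lands on the same root
    y <- unclass(ss)[1:5] * 0.9
    y2 <- tftitrate:::newton_polish(y, p)
    expect_equal(as.numeric(y2), as.numeric(unclass(ss)[1:5]),
                 tolerance = 1e-6)
  }
})

test_that("effective zinc is the stated rate composite", {
  p <- kinetic_params(beta_in = 1, beta_out = 1, gamma1 = 1, gamma2 = 1)
  expect_equal(effective_zinc(0, p), 0)
  expect_equal(effective_zinc(7, p), 7)
  p2 <- kinetic_params(beta_in = 2, beta_out = 1, gamma1 = 1,
                       gamma2 = 1)
  expect_equal(effective_zinc(7, p2), 14)
  p_bad <- kinetic_params()
  p_bad$gamma2 <- 0
  expect_error(effective_zinc(1, p_bad), "gamma2")
})

test_that("target fold change is 1 without TF and repressive without zinc", {
  p <- kinetic_params(tf_total = 0, zinc_out = 1)
  expect_equal(fold_change_of_target(p), 1, tolerance = 1e-8)
  pz <- kinetic_params(tf_total = 100, zinc_out = 0)
  fc <- fold_change_of_target(pz)
  ss <- steady_state(pz)
  expect_equal(fc, attr(ss, "p_off"), tolerance = 1e-6)
  expect_lt(fc, 1)
})

test_that("fold change approaches 1 from below when r equals r0", {
  p <- kinetic_params(r = 100, r0 = 100, tf_total = 100,
                      zinc_out = 1e3)
  fc <- fold_change_of_target(p)
  expect_lt(fc, 1)
  expect_gt(fc, 0.95)
})

test_that("fold change is monotone non-decreasing in zinc", {
  p <- kinetic_params(tf_total = 100)
  sw <- sweep_zinc_response(p, c(0, 0.01, 0.1, 1, 10),
                            tf_totals = 100, r0_over_r_list = 0.01)
  expect_true(all(diff(sw$fold_change) > -1e-8))
})

test_that("zero-zinc repression is consistent with the steric formula", {
  # low TF so nonspecific depletion is mild; 5% agreement expected
  p <- kinetic_params(tf_total = 10, zinc_out = 0)
  fc_kin <- fold_change_of_target(p)
  fc_thermo <- fold_change(10, thermo_params(-13.8, 0, 4.6e6))
  expect_lt(abs(fc_kin - fc_thermo) / fc_thermo, 0.05)
})

test_that("collapse metric measures relative cross-curve spread", {
  grid <- c(0.1, 1, 10)
  c1 <- tibble::tibble(tf_total = 10, effective_zinc = grid,
                       fold_change = c(2, 3, 4))
  c2 <- c1
  c2$tf_total <- 100
  expect_equal(collapse_metric(dplyr::bind_rows(c1, c2)), 0)
  c2$fold_change <- c1$fold_change * 1.1
  expect_equal(collapse_metric(dplyr::bind_rows(c1, c2)), 0.1 / 1.05,
               tolerance = 1e-12)
  c_bad <- c2
  c_bad$effective_zinc <- grid * 2
  expect_error(collapse_metric(dplyr::bind_rows(c1, c_bad)),
               "same zinc grid")
  expect_error(collapse_metric(c1), ">= 2 curves")
})

test_that("sweep propagates flat unity curves for zero TF", {
  p <- kinetic_params()
  sw <- sweep_zinc_response(p, c(0, 1), tf_totals = 0,
                            r0_over_r_list = c(0.1, 2))
  expect_equal(sw$fold_change, rep(1, 4), tolerance = 1e-8)
})
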