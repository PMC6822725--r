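# Constitutive Hill relations and cyclic contraction analytics.

test_that("force and consumption branches join continuously at vr = 0", {
  eps <- 1e-12
  expect_equal(fiber_force_rel(0), 1)
  expect_equal(fiber_force_rel(-eps), 1, tolerance = 1e-9)
  expect_equal(fiber_consumption_rel(0), 0.07)
  expect_equal(fiber_consumption_rel(-eps), 0.07, tolerance = 1e-9)
})

test_that("constitutive relations match hand-computed values", {
  expect_equal(fiber_force_rel(1), 0)
  expect_equal(fiber_force_rel(-1), 1.8)
  expect_equal(fiber_force_rel(0.31), 0.69 / 2.24)
  expect_equal(fiber_consumption_rel(-1), 0.01 + 0.11 + 0.06 * exp(-23))
  expect_equal(fiber_consumption_rel(0.23), 0.23 - 0.16 * exp(-8 * 0.23))
  # force non-increasing on the concentric branch
  v <- seq(0, 1, length.out = 200)
  expect_true(all(diff(fiber_force_rel(v)) <= 0))
  # consumption strictly positive everywhere
  v <- seq(-1, 1, length.out = 400)
  expect_true(all(fiber_consumption_rel(v) > 0))
})

test_that("domain violations raise errors", {
  expect_error(fiber_force_rel(1.01), "outside")
  expect_error(fiber_consumption_rel(-1.5), "outside")
  expect_error(fiber_efficiency(0), "concentric")
  expect_error(fiber_efficiency(-0.2), "concentric")
  expect_error(activation_fraction(0.5, 1.2), "outside")
  expect_error(fiber_params(F0 = -1))
})

test_that("fiber efficiency peaks at 45.1% near vr = 0.23", {
  o <- max_fiber_efficiency()
  expect_equal(o$eta_f, 0.4508763, tolerance = 1e-5)
  expect_equal(round(o$vr, 2), 0.23)
  # limits: vanishes toward both ends of the concentric branch
  expect_lt(fiber_efficiency(1e-6), 1e-4)
  expect_equal(fiber_efficiency(1), 0)
})

test_that("peak constant-rate power matches the closed form for G = 4", {
  o <- peak_power_point()
  expect_equal(o$vr, (sqrt(5) - 1) / 4, tolerance = 1e-6)
  expect_equal(o$p_rel, 0.0954915, tolerance = 1e-6)
  expect_equal(o$p_mass, 71.61863, tolerance = 1e-4)
})

test_that("activation fraction follows force demand over capacity", {
  expect_equal(activation_fraction(0, 0.3), 0)
  expect_equal(activation_fraction(1, 0), 1)
  mu <- activation_fraction(0.5, 0.31)
  expect_equal(mu, 0.5 / (0.69 / 2.24))
  expect_gt(mu, 1)  # infeasible demand is reported, not raised
})

test_that("cycle-average output matches the sinusoid closed form", {
  set.seed(11)
  for (k in 1:100) {
    Fh <- stats::runif(1, 0, 1.2)
    vh <- stats::runif(1, 0, 0.95)
    Phi <- stats::runif(1, 0, 180)
    cm <- cycle_metrics(cyclic_load(Fh, vh, Phi), n_quad = 256L)
    expect_equal(cm$p_bar_rel, 0.5 * Fh * vh * cos(Phi * pi / 180),
                 tolerance = 1e-10)
    expect_true(cm$q_bar_rel >= 0)
    if (Fh > 0) expect_gt(cm$q_bar_rel, 0)
  }
})

test_that("muscle efficiency is invariant to the force amplitude", {
  for (Fh in c(0.1, 0.35, 0.9)) {
    cm <- cycle_metrics(cyclic_load(Fh, 0.2, 60))
    ref <- cycle_metrics(cyclic_load(0.5, 0.2, 60))
    expect_equal(cm$eta_m, ref$eta_m, tolerance = 1e-12)
  }
})

test_that("quadrature of the worked cross-section example reproduces 33.6%", {
  cm <- cycle_metrics(cyclic_load(0.35, 0.20, 60), n_quad = 2048L)
  expect_equal(cm$p_bar_rel, 0.0175, tolerance = 1e-10)
  expect_equal(cm$eta_m, 0.33639, tolerance = 1e-4)
  expect_true(cm$feasible)
  expect_lt(cm$mu_hat, 1)
  expect_gt(cm$braking_fraction, 0)
})

test_that("quarter-phase lag yields zero net work and zero efficiency", {
  cm <- cycle_metrics(cyclic_load(0.5, 0.3, 90))
  expect_equal(cm$p_bar_rel, 0, tolerance = 1e-12)
  expect_equal(cm$eta_m, 0)
  expect_gt(cm$q_bar_rel, 0)
  # net braking beyond 90 degrees
  cm2 <- cycle_metrics(cyclic_load(0.5, 0.3, 135))
  expect_lt(cm2$p_bar_rel, 0)
  expect_equal(cm2$eta_m, 0)
})

test_that("max cyclic output is unimodal, peaks at the constant-rate optimum", {
  o <- max_psi_peak()
  expect_equal(o$vhat_r, (sqrt(5) - 1) / 4, tolerance = 1e-5)
  expect_equal(o$psi, 35.80931, tolerance = 1e-4)
  expect_equal(max_psi(0), 0)
  # exactly half the constant-rate peak
  expect_equal(o$psi / peak_power_point()$p_mass, 0.5, tolerance = 1e-8)
  # unimodal: increasing then decreasing around the peak
  v <- seq(0.01, 0.95, length.out = 100)
  dp <- diff(max_psi(v))
  expect_true(all(dp[v[-1] < o$vhat_r] > 0))
  expect_true(all(dp[v[-length(v)] > o$vhat_r] < 0))
})

test_that("max cyclic consumption has the analytic zero-rate limit and 81.2 peak", {
  cst <- swim_constants()
  expect_equal(max_theta(0), (2 / pi) * 0.07 * cst$F0 * cst$vmax / cst$rho_m,
               tolerance = 1e-4)
  o <- max_theta_peak()
  expect_equal(o$theta, 81.2224, tolerance = 1e-3)
  # argmax near (slightly above) the peak-power rate
  expect_lt(abs(o$vhat_r - 0.36), 0.01)
})

test_that("cyclic muscle efficiency peaks at 44.5% near amplitude 0.27", {
  o <- max_eta_m()
  expect_equal(o$eta_m, 0.4450978, tolerance = 1e-4)
  expect_equal(round(o$vhat_r, 2), 0.27)
  expect_equal(eta_m_phi0(0), 0)
  # marginally below the constant-rate fiber maximum
  expect_lt(o$eta_m, max_fiber_efficiency()$eta_f)
  # global bound over a sweep of loads
  for (Phi in c(0, 30, 60, 85)) for (vh in c(0.1, 0.27, 0.5, 0.9)) {
    cm <- cycle_metrics(cyclic_load(0.4, vh, Phi), n_quad = 512L)
    expect_lte(cm$eta_m, 0.4451)
  }
})

test_that("force loop degenerates to a line at 0/180 degrees and binds at the envelope", {
  for (Phi in c(0, 180)) {
    fl <- force_loop(cyclic_load(0.3, 0.2, Phi))
    # collinearity of (vr, Fm) samples
    expect_equal(abs(cor(fl$loop$vr, fl$loop$Fm_rel)), 1, tolerance = 1e-9)
  }
  # envelope-amplitude loading at Phi = 0 is feasible with mu_hat = 1
  vh <- 0.25
  fl <- force_loop(cyclic_load(fiber_force_rel(vh), vh, 0), n_quad = 4096L)
  expect_true(fl$feasible)
  expect_equal(fl$mu_hat, 1, tolerance = 1e-5)
  # the worked example sits strictly inside the envelope
  fl2 <- force_loop(cyclic_load(0.35, 0.20, 60))
  expect_true(fl2$feasible)
  expect_lt(fl2$mu_hat, 1)
})

test_that("muscle curve tables are consistent with the point functions", {
  mc <- muscle_curves(n = 21L, n_quad = 256L)
  expect_equal(mc$fiber$force_rel, fiber_force_rel(mc$fiber$vr))
  i <- 16L  # a point with vr > 0
  expect_equal(mc$fiber$eta_f[i], fiber_efficiency(mc$fiber$vr[i]))
  expect_equal(mc$cyclic$max_psi, max_psi(mc$cyclic$vhat_r))
})
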