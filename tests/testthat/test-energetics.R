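# Longitudinal profiles, integral report, and whole-body energy bookkeeping.

test_that("reference swimmer report is finite, feasible and self-consistent", {
  rep <- ref_report()
  expect_true(rep$feasible)
  expect_gt(rep$U, 0)
  expect_gt(rep$COT, 0)
  expect_gt(rep$Q, rep$P)          # consumption exceeds net output
  expect_gt(rep$eta_H, 0); expect_lt(rep$eta_H, 1)
  expect_gt(rep$eta_I, 0); expect_lte(rep$eta_I, 1)
  cst <- swim_constants()
  expect_equal(rep$COT, (rep$P_s + rep$Q) / (rep$m * cst$g * rep$U))
  expect_equal(rep$eta_T, rep$eta_H * rep$eta_M * rep$eta_I)
  expect_equal(rep$eta_M_star, rep$eta_M * rep$eta_I)
  expect_equal(rep$Psi, rep$P / rep$m_M)
  expect_equal(rep$P_s, 0.1327 * rep$m^0.80)
})

test_that("net muscle output decomposes into fluid power plus tissue losses", {
  rep <- ref_report()
  expect_equal(rep$P, rep$P_H + rep$P_V, tolerance = 5e-3)
})

test_that("section work sign follows the phase lag", {
  pr <- ref_report()$profiles$profile
  act <- pr$Fhat_m > 1e-6 & pr$vhat_r > 1e-6
  expect_true(all((pr$p_bar[act] > 0) == (pr$Phi_deg[act] < 90)))
  # consumption is positive wherever muscle works
  expect_true(all(pr$q_bar[act] > 0))
  # efficiency profile respects the cyclic-contraction bound
  expect_true(all(pr$eta_m <= 0.4451))
})

test_that("frequency-domain profiles match a direct time-domain simulation", {
  sw <- sample_feasible_swimmers(3, seed = 21)
  for (s in sw) {
    g <- build_geometry(shape_params(DL = s$params[1], BL = s$params[2],
                                     c_d1 = s$params[3], c_d2 = s$params[4],
                                     c_b1 = s$params[5]),
                        s$m, n_grid = 192L)
    mo <- motion_spec(s$params[6], s$params[7:9], g)
    hy <- solve_speed(g, mo)
    st <- bending_moment(g, mo, hy$recoil, hy$U)
    cf <- contraction_field(g, mo)
    prof <- longitudinal_profiles(st, cf, g, n_quad = 512L)
    # time-domain reconstruction on a fine cycle grid
    cst <- g$constants
    fp <- fiber_params(cst$F0, cst$vmax, cst$G, cst$rho_m)
    nt <- 512L
    tt <- seq(0, 2 * pi / mo$omega, length.out = nt + 1L)[-(nt + 1L)]
    P_td <- 0; Q_td <- 0
    Fm_amp <- st$Fm
    V_amp <- cf$V
    for (t in tt) {
      Fm_t <- Re(Fm_amp * exp(-1i * mo$omega * t))
      v_t <- Re(V_amp * exp(-1i * mo$omega * t))
      p_t <- Fm_t * v_t
      va <- sign(Fm_t) * v_t
      va <- pmax(pmin(va / cst$vmax, 1), -1)
      mu <- abs(Fm_t) / (fiber_force_rel(va, fp) * cst$F0 * pmax(g$A_m, 1e-300))
      q_t <- mu * g$A_m * fiber_consumption_rel(va, fp) * cst$F0 * cst$vmax
      P_td <- P_td + sum((p_t[-1] + p_t[-length(p_t)]) / 2) * g$dx / nt
      Q_td <- Q_td + sum((q_t[-1] + q_t[-length(q_t)]) / 2) * g$dx / nt
    }
    expect_equal(prof$P, P_td, tolerance = 5e-3)
    expect_equal(prof$Q, Q_td, tolerance = 5e-3)
  }
})

test_that("consumption rises with tail-beat frequency at fixed shape and envelope", {
  g <- build_geometry(shape_params(), 1)
  Qs <- vapply(c(10, 14, 18), function(om) {
    mo <- motion_spec(om, c(0.121, 0.066, 0.011), g)
    hy <- solve_speed(g, mo)
    st <- bending_moment(g, mo, hy$recoil, hy$U)
    longitudinal_profiles(st, contraction_field(g, mo), g, n_quad = 512L)$Q
  }, numeric(1))
  expect_true(all(diff(Qs) > 0))
})

test_that("cost of transport blows up as the speed vanishes", {
  rep <- ref_report()
  slow <- evaluate_swimmer(c(reference_params(1)[1:6], 0.02, 0.011, 0.002), 1)
  expect_true(slow$feasible)
  expect_lt(slow$U, 0.1 * rep$U)
  expect_gt(slow$COT, 5 * rep$COT)
})

test_that("infeasible configurations degrade gracefully", {
  # zero-amplitude envelope: no thrust, no steady speed
  rep <- evaluate_swimmer(c(0.15, 0.12, 0.06, 1.5, 1, 14, 0, 0, 0), 1)
  expect_false(rep$feasible)
  expect_match(rep$diagnostic, "degenerate|steady")
})
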