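# Slender-body lateral forces, recoil balance, thrust, drag and the
# steady-speed solution.

make_gm <- function(m = 1, omega = 14, e = c(0.121, 0.066, 0.011),
                    n_grid = 256L) {
  g <- build_geometry(shape_params(), m, n_grid = n_grid)
  list(geom = g, motion = motion_spec(omega, e, g))
}

test_that("lateral force reduces to added-mass inertia for rigid heave at rest", {
  gm <- make_gm()
  Y0 <- 0.01 + 0i
  FL <- lateral_force_field(gm$geom, rep(Y0, length(gm$geom$x)), U = 0,
                            omega = gm$motion$omega)
  expect_equal(FL, -gm$motion$omega^2 * gm$geom$m_a * Y0, tolerance = 1e-12)
  # zero motion gives zero force
  FL0 <- lateral_force_field(gm$geom, rep(0 + 0i, length(gm$geom$x)), 1, 14)
  expect_true(all(Mod(FL0) == 0))
})

test_that("the material derivative annihilates a wave traveling at speed U", {
  gm <- make_gm()
  g <- gm$geom
  g$m_a <- rep(1, length(g$x))  # uniform added mass isolates the operator
  k <- 2 * pi / g$L
  omega <- 10
  H <- exp(1i * k * g$x)
  FL <- lateral_force_field(g, H, U = omega / k, omega = omega)
  expect_lt(max(Mod(FL)) / (omega^2 * 1), 1e-4)
})

test_that("recoil balance closes with round-off residuals and converges in grid", {
  gm <- make_gm()
  rec <- solve_recoil(gm$geom, gm$motion, U = 0.5)
  expect_lt(rec$residual_force, 1e-10)
  expect_lt(rec$residual_moment, 1e-10)
  # zero motion: no recoil
  mo0 <- motion_spec(14, c(0, 0, 0), gm$geom)
  rec0 <- solve_recoil(gm$geom, mo0, U = 0.5)
  expect_equal(Mod(rec0$Y0), 0, tolerance = 1e-15)
  expect_equal(Mod(rec0$Phi_r), 0, tolerance = 1e-15)
  # refinement stability of the recoil amplitudes
  gm2 <- make_gm(n_grid = 512L)
  rec2 <- solve_recoil(gm2$geom, gm2$motion, U = 0.5)
  expect_equal(Mod(rec$Y0), Mod(rec2$Y0), tolerance = 1e-3)
  expect_equal(Mod(rec$Phi_r), Mod(rec2$Phi_r), tolerance = 1e-3)
})

test_that("thrust matches the closed form at rest and vanishes at wave speed", {
  gm <- make_gm()
  g <- gm$geom
  n <- length(g$x)
  # heaving at rest: F_T = m_a(L) omega^2 a^2 / 4
  a <- 0.02
  rec <- list(Hhat = rep(a + 0i, n))
  expect_equal(mean_thrust(g, gm$motion, rec, U = 0),
               g$m_a[n] * gm$motion$omega^2 * a^2 / 4, tolerance = 1e-10)
  # uniform envelope, recoil off, U = wave speed: thrust vanishes
  mo <- motion_spec(10, c(0.2, 0, 0), g)   # constant r(x)
  expect_equal(diff(range(mo$r)), 0)
  Uw <- mo$omega * mo$lambda_b / (2 * pi)
  FT <- mean_thrust(g, mo, list(Hhat = mo$H), U = Uw)
  FT0 <- mean_thrust(g, mo, list(Hhat = mo$H), U = 0)
  expect_lt(abs(FT) / FT0, 1e-5)
  # thrust decreases monotonically with U for fixed kinematics
  Us <- seq(0, Uw, length.out = 8)
  FTs <- vapply(Us, function(U) mean_thrust(g, mo, list(Hhat = mo$H), U),
                numeric(1))
  expect_true(all(diff(FTs) < 0))
})

test_that("drag coefficient matches the empirical law and its jump", {
  expect_equal(drag_coefficient(1e4, DL = 0)$C_f, 0.0133)
  expect_equal(drag_coefficient(1e4, DL = 0)$C_D, 0.0133)
  cst <- swim_constants()
  jump <- drag_coefficient(cst$Re_cr, 0.2, branch = "turbulent")$C_f /
          drag_coefficient(cst$Re_cr, 0.2, branch = "laminar")$C_f
  expect_equal(jump, 0.072 * cst$Re_cr^-0.2 / (1.33 * cst$Re_cr^-0.5))
  expect_equal(jump, 2.77, tolerance = 2e-3)
  # shape factor raises drag above friction
  dc <- drag_coefficient(1e5, DL = 0.2)
  expect_gt(dc$C_D, dc$C_f)
})

test_that("steady speed balances thrust and drag on a consistent branch", {
  gm <- make_gm()
  hy <- solve_speed(gm$geom, gm$motion)
  expect_lt(abs(hy$F_T - hy$F_D) / hy$F_D, 1e-6)
  expect_equal(hy$Re, hy$U * gm$geom$L / gm$geom$constants$nu)
  if (hy$branch == "laminar") expect_lte(hy$Re, gm$geom$constants$Re_cr * (1 + 1e-9))
  else expect_gte(hy$Re, gm$geom$constants$Re_cr * (1 - 1e-9))
  # independent coarse bisection on the same balance components
  f <- function(U) {
    rec <- solve_recoil(gm$geom, gm$motion, U)
    FT <- mean_thrust(gm$geom, gm$motion, rec, U)
    Re <- U * gm$geom$L / gm$geom$constants$nu
    CD <- drag_coefficient(Re, gm$geom$d[length(gm$geom$d)] / gm$geom$L,
                           branch = "laminar")$C_D
    FT - 0.5 * gm$geom$constants$rho * U^2 * gm$geom$S * CD
  }
  lo <- 1e-3; hi <- gm$geom$constants$Re_cr * gm$geom$constants$nu / gm$geom$L
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(hy$U, (lo + hi) / 2, tolerance = 1e-8)
  # smaller envelope amplitude gives a slower swimmer
  mo_small <- motion_spec(gm$motion$omega, 0.2 * c(0.121, 0.066, 0.011),
                          gm$geom)
  hy_small <- solve_speed(gm$geom, mo_small)
  expect_lt(hy_small$U, 0.2 * hy$U)
  # degenerate motion errors
  expect_error(solve_speed(gm$geom, motion_spec(14, c(0, 0, 0), gm$geom)),
               "degenerate")
})

test_that("power to the fluid exceeds thrust power by the tail wake flux", {
  gm <- make_gm()
  hy <- solve_speed(gm$geom, gm$motion)
  expect_gt(hy$P_H, 0)
  expect_gt(hy$eta_H, 0)
  expect_lt(hy$eta_H, 1)
  expect_gte(hy$P_H - hy$F_T * hy$U, 0)
  # Lighthill energy identity: the excess is the wake kinetic-energy flux
  n <- length(gm$geom$x)
  w <- -1i * gm$motion$omega * hy$recoil$Hhat +
    hy$U * undulate:::fd_deriv(hy$recoil$Hhat, gm$geom$dx)
  wake <- 0.5 * gm$geom$m_a[n] * hy$U * 0.5 * Mod(w[n])^2
  expect_equal(hy$P_H - hy$F_T * hy$U, wake, tolerance = 2e-3)
})
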