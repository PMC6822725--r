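#' Hill-type muscle fiber parameters
#'
#' Constitutive constants of the force-velocity and energy-consumption
#' relations of red (aerobic) muscle fibers.
#'
#' @param F0 Isometric stress (N/m^2).
#' @param vmax Maximum contraction strain rate (fiber-lengths/s, s^-1).
#' @param G Dimensionless curvature constant of the concentric branch.
#' @param rho_m Muscle density (kg/m^3).
#' @return An object of class `fiber_params`.
#' @export
#' @examples
#' fp <- fiber_params()
#' fiber_force_rel(0.31, fp)
fiber_params <- function(F0 = 150e3, vmax = 5, G = 4, rho_m = 1000) {
  vals <- c(F0 = F0, vmax = vmax, G = G, rho_m = rho_m)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("fiber_params: all parameters must be positive and finite")
  structure(as.list(vals), class = "fiber_params")
}

#' @export
print.fiber_params <- function(x, ...) {
  cat("Hill fiber parameters:\n")
  cat(sprintf("  F0    = %g N/m^2 (isometric stress)\n", x$F0))
  cat(sprintf("  vmax  = %g s^-1 (max strain rate)\n", x$vmax))
  cat(sprintf("  G     = %g (force-velocity curvature)\n", x$G))
  cat(sprintf("  rho_m = %g kg/m^3 (muscle density)\n", x$rho_m))
  invisible(x)
}

check_vr <- function(vr) {
  if (!is.numeric(vr) || any(!is.finite(vr)))
    stop("relative contraction rate must be finite numeric")
  if (any(vr < -1 | vr > 1))
    stop("relative contraction rate outside [-1, 1]: motion infeasible")
  invisible(vr)
}

#' Relative fiber force (Hill force-velocity relation)
#'
#' Force a fully activated fiber can produce while contracting at the
#' relative strain rate `vr = v/vmax`, normalized by the isometric force
#' `F0`. Positive `vr` is shortening (concentric), negative is active
#' lengthening (eccentric), where the force rises above isometric.
#'
#' @param vr Relative strain rate, in `[-1, 1]`; vectorized.
#' @param params A [fiber_params()] object.
#' @return Relative force `F_f / F0` (dimensionless).
#' @export
#' @examples
#' fiber_force_rel(c(-1, 0, 0.31, 1))
fiber_force_rel <- function(vr, params = fiber_params()) {
  check_vr(vr)
  G <- params$G
  ifelse(vr >= 0,
         (1 - vr) / (1 + G * vr),
         1.8 - 0.8 * (1 + vr) / (1 - 7.56 * G * vr))
}

#' Relative fiber energy consumption rate
#'
#' Metabolic power consumed by a fully activated fiber contracting at the
#' relative strain rate `vr`, normalized by `F0 * vmax`. Strictly positive
#' on the whole domain: active muscle always consumes energy, including
#' during eccentric (braking) contraction.
#'
#' @inheritParams fiber_force_rel
#' @return Relative consumption `Q_f / (F0 * vmax)` (dimensionless).
#' @export
fiber_consumption_rel <- function(vr, params = fiber_params()) {
  check_vr(vr)
  ifelse(vr >= 0,
         0.23 - 0.16 * exp(-8 * vr),
         0.01 - 0.11 * vr + 0.06 * exp(23 * vr))
}

#' Fiber efficiency under constant-rate contraction
#'
#' Mechanical power output over metabolic consumption,
#' `eta_f = vr * F_f(vr) / Q_f(vr)`, defined for concentric contraction
#' only (`vr > 0`).
#'
#' @param vr Relative strain rate in `(0, 1]`; vectorized.
#' @inheritParams fiber_force_rel
#' @return Efficiency in `[0, 1)`.
#' @export
fiber_efficiency <- function(vr, params = fiber_params()) {
  check_vr(vr)
  if (any(vr <= 0))
    stop("fiber efficiency is defined only for concentric contraction (vr > 0)")
  vr * fiber_force_rel(vr, params) / fiber_consumption_rel(vr, params)
}

#' Maximum fiber efficiency and its contraction rate
#'
#' Maximizes [fiber_efficiency()] over `vr` in `(0, 1]`.
#'
#' @inheritParams fiber_force_rel
#' @param tol Optimization tolerance on `vr`.
#' @return List with `vr` (argmax) and `eta_f` (maximum efficiency).
#' @export
max_fiber_efficiency <- function(params = fiber_params(), tol = 1e-6) {
  o <- stats::optimize(fiber_efficiency, c(1e-9, 1), params = params,
                       maximum = TRUE, tol = tol)
  list(vr = o$maximum, eta_f = o$objective)
}

#' Peak constant-rate power point
#'
#' Maximizes the constant-rate fiber power `vr * F_f(vr)` on `[0, 1]`.
#' For `G = 4` the argmax has the closed form `(sqrt(5) - 1) / 4`.
#'
#' @inheritParams fiber_force_rel
#' @param tol Optimization tolerance on `vr`.
#' @return List with `vr` (argmax), `p_rel` (peak power in `F0 * vmax`
#'   units) and `p_mass` (peak power per unit muscle mass, W/kg).
#' @export
peak_power_point <- function(params = fiber_params(), tol = 1e-8) {
  o <- stats::optimize(function(v) v * fiber_force_rel(v, params),
                       c(0, 1), maximum = TRUE, tol = tol)
  list(vr = o$maximum, p_rel = o$objective,
       p_mass = o$objective * params$F0 * params$vmax / params$rho_m)
}

#' Muscle activation fraction
#'
#' Fraction of the muscle cross section that must be recruited to produce a
#' required relative force at the contraction rate currently experienced by
#' the fibers on the active side. The active side is the side of the sign of
#' the force; `v_active_rel` is positive when those fibers are shortening.
#' Values above 1 signal an infeasible demand, not an error.
#'
#' @param Fm_rel Signed required force, relative to `F0 * A_m` (vectorized).
#' @param v_active_rel Signed relative strain rate of the active-side fibers,
#'   in `[-1, 1]`.
#' @inheritParams fiber_force_rel
#' @return Activation fraction `mu >= 0`.
#' @export
activation_fraction <- function(Fm_rel, v_active_rel, params = fiber_params()) {
  check_vr(v_active_rel)
  abs(Fm_rel) / fiber_force_rel(v_active_rel, params)
}

#' Cyclic (sinusoidal) muscle load
#'
#' A single-harmonic load on one cross section of muscle: the required force
#' and the contraction rate are pure sinusoids of common frequency, so the
#' load is fully described by two amplitudes and a phase lag.
#'
#' @param Fhat_m Force amplitude relative to the full-activation isometric
#'   capacity `F0 * A_m` (>= 0).
#' @param vhat_r Relative contraction-rate amplitude, in `[0, 1)`.
#' @param Phi Phase lag of the contraction rate behind the force (degrees,
#'   in `[0, 180]`). `Phi < 90` gives net positive work, `Phi > 90` net
#'   braking.
#' @param omega Angular frequency (rad/s); metrics per cycle do not depend
#'   on it, it is kept for dimensional time axes.
#' @return An object of class `cyclic_load`.
#' @export
cyclic_load <- function(Fhat_m, vhat_r, Phi, omega = 2 * pi) {
  stopifnot(is.numeric(Fhat_m), Fhat_m >= 0,
            is.numeric(vhat_r), vhat_r >= 0,
            is.numeric(Phi), Phi >= 0, Phi <= 180,
            is.numeric(omega), omega > 0)
  if (vhat_r >= 1)
    stop("cyclic_load: vhat_r must be < 1 (contraction rate cannot reach vmax)")
  structure(list(Fhat_m = Fhat_m, vhat_r = vhat_r, Phi = Phi, omega = omega),
            class = "cyclic_load")
}

# Vectorized engine for cycle averages over many cross sections at once.
# Fhat, vhat, Phi_deg are parallel vectors (one entry per section); returns
# a list of per-section cycle averages in F0*vmax units.
cycle_metrics_field <- function(Fhat, vhat, Phi_deg, params = fiber_params(),
                                n_quad = 1024L) {
  stopifnot(n_quad >= 64L)
  nx <- length(Fhat)
  th <- seq(0, 2 * pi, length.out = n_quad + 1L)   # omega * t over one period
  s_f <- sin(th)
  # rows: time samples, cols: sections
  Fm <- outer(s_f, Fhat)                           # Fhat * sin(wt)
  vR <- sin(outer(th, rep(1, nx)) -
            matrix(Phi_deg * pi / 180, n_quad + 1L, nx, byrow = TRUE)) *
        matrix(vhat, n_quad + 1L, nx, byrow = TRUE)
  va <- sign(Fm) * vR                              # active-side rate
  p <- Fm * vR
  mu <- abs(Fm) / fiber_force_rel(va, params)
  q <- mu * fiber_consumption_rel(va, params)
  w <- rep(1, n_quad + 1L); w[c(1L, n_quad + 1L)] <- 0.5  # trapezoid, periodic
  wsum <- n_quad
  list(p_bar = colSums(p * w) / wsum,
       q_bar = colSums(q * w) / wsum,
       mu_hat = apply(mu, 2L, max),
       braking_fraction = colSums((p < 0) * w) / wsum)
}

#' Cycle-averaged performance of a sinusoidally loaded muscle section
#'
#' Integrates one period of the force and contraction-rate sinusoids,
#' tracking which side of the body is active (the side of the force sign),
#' the recruited activation fraction, the instantaneous mechanical output
#' `p = F_m * v` and metabolic consumption `q = mu * Q_f(v_active)`.
#'
#' @param load A [cyclic_load()] object.
#' @param params A [fiber_params()] object.
#' @param n_quad Number of uniform quadrature intervals per period (>= 64).
#' @return An object of class `cycle_metrics` with elements
#'   `p_bar_rel`, `q_bar_rel` (cycle averages in `F0 * vmax` units),
#'   `p_bar`, `q_bar` (W per m^3 of muscle), `eta_m` (local muscle
#'   efficiency, 0 when the net output is non-positive), `mu_hat` (peak
#'   activation fraction), `braking_fraction` (fraction of the period with
#'   `p < 0`) and `feasible` (`mu_hat <= 1`).
#' @export
#' @examples
#' cm <- cycle_metrics(cyclic_load(0.35, 0.20, 60))
#' cm$eta_m      # about 0.336
#' cm$p_bar_rel  # exactly 0.5 * 0.35 * 0.20 * cos(60 deg) up to quadrature
cycle_metrics <- function(load, params = fiber_params(), n_quad = 1024L) {
  stopifnot(inherits(load, "cyclic_load"))
  f <- cycle_metrics_field(load$Fhat_m, load$vhat_r, load$Phi, params, n_quad)
  if (f$q_bar == 0 && f$p_bar > 0)
    stop("cycle_metrics: positive output with zero consumption is impossible")
  scale <- params$F0 * params$vmax
  structure(list(
    p_bar_rel = f$p_bar, q_bar_rel = f$q_bar,
    p_bar = f$p_bar * scale, q_bar = f$q_bar * scale,
    eta_m = if (f$p_bar > 0) f$p_bar / f$q_bar else 0,
    mu_hat = f$mu_hat, braking_fraction = f$braking_fraction,
    feasible = f$mu_hat <= 1 && load$vhat_r < 1
  ), class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat("Cyclic muscle contraction metrics:\n")
  cat(sprintf("  p_bar = %.4g F0*vmax (%.4g W/m^3)\n", x$p_bar_rel, x$p_bar))
  cat(sprintf("  q_bar = %.4g F0*vmax (%.4g W/m^3)\n", x$q_bar_rel, x$q_bar))
  cat(sprintf("  eta_m = %.3f, mu_hat = %.3f, braking = %.1f%%, feasible = %s\n",
              x$eta_m, x$mu_hat, 100 * x$braking_fraction, x$feasible))
  invisible(x)
}

#' Maximum cycle-averaged power output per muscle mass
#'
#' For in-phase loading (`Phi = 0`) with the force amplitude on the
#' full-activation envelope (`Fhat_m = F_f(vhat_r)/F0`), the cycle-averaged
#' output has the closed form `0.5 * F_f(vhat_r) * vhat_r` in `F0 * vmax`
#' units; this returns it converted to W per kg of muscle.
#'
#' @param vhat_r Relative contraction-rate amplitude in `[0, 1)`; vectorized.
#' @inheritParams cycle_metrics
#' @return Maximum obtainable cycle-averaged output (W/kg).
#' @export
max_psi <- function(vhat_r, params = fiber_params()) {
  stopifnot(all(vhat_r >= 0), all(vhat_r < 1))
  0.5 * fiber_force_rel(vhat_r, params) * vhat_r *
    params$F0 * params$vmax / params$rho_m
}

#' Peak of the maximum cyclic power output
#'
#' Maximizes [max_psi()] over the contraction-rate amplitude. The peak sits
#' at the same rate as the constant-rate power optimum and equals exactly
#' half of the constant-rate peak (a direct consequence of sinusoidal
#' averaging).
#'
#' @inheritParams cycle_metrics
#' @param tol Optimization tolerance on `vhat_r`.
#' @return List with `vhat_r` (argmax) and `psi` (W/kg).
#' @export
max_psi_peak <- function(params = fiber_params(), tol = 1e-8) {
  o <- stats::optimize(max_psi, c(0, 1 - 1e-9), params = params,
                       maximum = TRUE, tol = tol)
  list(vhat_r = o$maximum, psi = o$objective)
}

#' Maximum cycle-averaged consumption per muscle mass
#'
#' At `Phi = 0` with the force amplitude on the full-activation envelope,
#' the active side is always concentric; the activation fraction over the
#' cycle is `mu(t) = F_f(vhat_r) |sin| / F_f(vhat_r |sin|)` and the
#' consumption `theta(t) = mu(t) * Q_f(vhat_r |sin|)`. Returns the cycle
#' average in W/kg. At `vhat_r = 0` this limits to `(2/pi) * Q_f(0)`.
#'
#' @inheritParams max_psi
#' @param n_quad Quadrature intervals per period.
#' @return Maximum obtainable cycle-averaged consumption (W/kg); vectorized
#'   over `vhat_r`.
#' @export
max_theta <- function(vhat_r, params = fiber_params(), n_quad = 1024L) {
  stopifnot(all(vhat_r >= 0), all(vhat_r < 1))
  vapply(vhat_r, function(vh) {
    f <- cycle_metrics_field(fiber_force_rel(vh, params), vh, 0,
                             params, n_quad)
    f$q_bar * params$F0 * params$vmax / params$rho_m
  }, numeric(1))
}

#' Peak of the maximum cyclic consumption
#'
#' @inheritParams max_theta
#' @param tol Optimization tolerance on `vhat_r`.
#' @return List with `vhat_r` (argmax) and `theta` (W/kg).
#' @export
max_theta_peak <- function(params = fiber_params(), n_quad = 2048L,
                           tol = 1e-6) {
  o <- stats::optimize(function(v) max_theta(v, params, n_quad),
                       c(0, 1 - 1e-9), maximum = TRUE, tol = tol)
  list(vhat_r = o$maximum, theta = o$objective)
}

#' Cyclic muscle efficiency at zero phase lag
#'
#' The local muscle efficiency `eta_m = p_bar / q_bar` of an in-phase
#' sinusoidal load. Both averages scale linearly with the force amplitude,
#' so the ratio depends on the contraction-rate amplitude alone.
#'
#' @inheritParams max_theta
#' @return Efficiency (dimensionless); vectorized over `vhat_r`.
#' @export
eta_m_phi0 <- function(vhat_r, params = fiber_params(), n_quad = 1024L) {
  stopifnot(all(vhat_r >= 0), all(vhat_r < 1))
  vapply(vhat_r, function(vh) {
    if (vh == 0) return(0)
    f <- cycle_metrics_field(1, vh, 0, params, n_quad)
    f$p_bar / f$q_bar
  }, numeric(1))
}

#' Overall maximum cyclic muscle efficiency
#'
#' Maximizes [eta_m_phi0()] over the contraction-rate amplitude. The
#' maximum is marginally below the constant-rate fiber-efficiency maximum.
#'
#' @inheritParams max_theta
#' @param tol Optimization tolerance on `vhat_r`.
#' @return List with `vhat_r` (argmax) and `eta_m` (maximum efficiency).
#' @export
max_eta_m <- function(params = fiber_params(), n_quad = 2048L, tol = 1e-6) {
  o <- stats::optimize(function(v) eta_m_phi0(v, params, n_quad),
                       c(1e-9, 1 - 1e-9), maximum = TRUE, tol = tol)
  list(vhat_r = o$maximum, eta_m = o$objective)
}

#' Force loop (force-velocity ellipse) of a cyclic load
#'
#' Samples the parametric curve of muscle force against contraction rate
#' over one period. For a sinusoidal load it is an ellipse, degenerating to
#' a line for phase lags of 0 or 180 degrees. The motion is feasible when
#' the loop is contained within the full-activation force envelope
#' (activation fraction `mu <= 1` throughout).
#'
#' @inheritParams cycle_metrics
#' @return A list with `loop` (data frame: `t_rel`, `vr`, `Fm_rel`, `mu`),
#'   `envelope` (data frame: `vr`, `upper`, `lower`; the lower branch is the
#'   left-side envelope `-F_f(-vr)/F0`), `mu_hat` and `feasible`.
#' @export
force_loop <- function(load, params = fiber_params(), n_quad = 1024L) {
  stopifnot(inherits(load, "cyclic_load"))
  th <- seq(0, 2 * pi, length.out = n_quad + 1L)
  Fm <- load$Fhat_m * sin(th)
  vR <- load$vhat_r * sin(th - load$Phi * pi / 180)
  va <- sign(Fm) * vR
  mu <- abs(Fm) / fiber_force_rel(va, params)
  vr_env <- seq(-1, 1, length.out = 401L)
  env <- data.frame(vr = vr_env,
                    upper = fiber_force_rel(vr_env, params),
                    lower = -fiber_force_rel(-vr_env, params))
  list(loop = data.frame(t_rel = th / (2 * pi), vr = vR, Fm_rel = Fm, mu = mu),
       envelope = env,
       mu_hat = max(mu),
       feasible = max(mu) <= 1 && load$vhat_r < 1)
}

#' Tabulate the constitutive and cyclic muscle curves
#'
#' Convenience tables of the constant-rate fiber relations (force,
#' consumption, efficiency) and of the maximum cyclic performance curves
#' (max output, max consumption, efficiency at zero phase lag) used for
#' reporting and plotting.
#'
#' @inheritParams cycle_metrics
#' @param n Number of samples per curve.
#' @return List of two data frames, `fiber` and `cyclic`.
#' @export
muscle_curves <- function(params = fiber_params(), n = 201L, n_quad = 1024L) {
  vr <- seq(-1, 1, length.out = n)
  fiber <- data.frame(
    vr = vr,
    force_rel = fiber_force_rel(vr, params),
    consumption_rel = fiber_consumption_rel(vr, params),
    eta_f = ifelse(vr > 0, NA_real_, NA_real_)
  )
  pos <- vr > 0
  fiber$eta_f[pos] <- fiber_efficiency(vr[pos], params)
  vh <- seq(0, 1 - 1e-6, length.out = n)
  cyclic <- data.frame(
    vhat_r = vh,
    max_psi = max_psi(vh, params),
    max_theta = max_theta(vh, params, n_quad),
    eta_m = eta_m_phi0(vh, params, n_quad)
  )
  list(fiber = fiber, cyclic = cyclic)
}
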