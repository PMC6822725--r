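#' Longitudinal profiles of muscle loading and energetics
#'
#' Converts the bending-moment and contraction-rate amplitude fields into
#' per-cross-section cyclic muscle metrics. At each station the relative
#' force amplitude is `|Fm| / (F0 A_m)`, the relative contraction-rate
#' amplitude `|V| / vmax`, and the phase lag the phase of the contraction
#' rate behind the force, folded to `[0, 180]` degrees; the section is then
#' treated as a sinusoidally loaded muscle (see [cycle_metrics()]).
#'
#' @param structural A [bending_moment()] result.
#' @param cfield A [contraction_field()] result.
#' @param geom A [build_geometry()] object.
#' @param params A [fiber_params()] object; defaults to the fiber constants
#'   stored in the geometry's [swim_constants()].
#' @param n_quad Quadrature intervals per contraction cycle.
#' @return An object of class `swim_profiles`: a data frame `profile` with
#'   columns `x`, `x_rel`, `p_bar` and `q_bar` (W/m), `eta_m`, `Phi_deg`,
#'   `mu_hat`, `vhat_r`, `Fhat_m`, `braking_fraction`, plus scalars
#'   `P` (net mechanical output, W), `Q` (metabolic consumption, W) and
#'   `feasible` (`mu_hat <= 1` and `vhat_r < 1` everywhere).
#' @export
longitudinal_profiles <- function(structural, cfield, geom,
                                  params = NULL, n_quad = 1024L) {
  stopifnot(inherits(structural, "structural_result"),
            inherits(geom, "body_geometry"))
  cst <- geom$constants
  if (is.null(params))
    params <- fiber_params(cst$F0, cst$vmax, cst$G, cst$rho_m)
  denom <- cst$F0 * geom$A_m
  Fhat <- numeric(length(denom))
  pos <- denom > 0
  Fhat[pos] <- Mod(structural$Fm[pos]) / denom[pos]
  if (any(!pos)) Fhat[!pos] <- 0
  vhat_r <- cfield$vhat_r
  # phase lag: h = Re[A exp(-i w t)] = |A| cos(wt - arg A), so the rate
  # lags the force by arg(V) - arg(Fm); fold to [0, 180] degrees
  dphi <- Arg(cfield$V) - Arg(structural$Fm)
  dphi <- atan2(sin(dphi), cos(dphi))
  Phi_deg <- abs(dphi) * 180 / pi
  Phi_deg[Fhat == 0 | vhat_r == 0] <- 0
  vq <- pmin(vhat_r, 1 - 1e-12)   # clamp for quadrature; feasibility flags the excess
  f <- cycle_metrics_field(Fhat, vq, Phi_deg, params, n_quad)
  scale <- cst$F0 * geom$A_m * cst$vmax   # F0 A_m vmax: W/m per relative unit
  p_bar <- f$p_bar * scale
  q_bar <- f$q_bar * scale
  eta_m <- ifelse(f$p_bar > 0 & f$q_bar > 0, f$p_bar / f$q_bar, 0)
  profile <- data.frame(
    x = geom$x, x_rel = geom$xi,
    p_bar = p_bar, q_bar = q_bar, eta_m = eta_m,
    Phi_deg = Phi_deg, mu_hat = f$mu_hat,
    vhat_r = vhat_r, Fhat_m = Fhat,
    braking_fraction = f$braking_fraction
  )
  structure(list(
    profile = profile,
    P = trapz_c(geom$x, p_bar),
    Q = trapz_c(geom$x, q_bar),
    feasible = all(f$mu_hat <= 1) && all(vhat_r < 1)
  ), class = "swim_profiles")
}

#' Integral energetic report of a swimmer
#'
#' Assembles the whole-body energetic quantities: net mechanical output
#' `P`, metabolic consumption `Q`, standard metabolic rate `P_s`, cost of
#' transport `COT = (P_s + Q) / (m g U)`, the muscle (`eta_M = P/Q`),
#' internal (`eta_I = 1/(1 + P_V/P_H)`), hydrodynamic (`eta_H`) and total
#' (`eta_T = eta_H eta_M eta_I`) efficiencies, and the specific powers
#' `Psi = P / m_M` and `Theta = Q / m_M` per one-side muscle mass.
#'
#' @param profiles A [longitudinal_profiles()] result.
#' @param hydro A [solve_speed()] result.
#' @param structural A [bending_moment()] result.
#' @param geom A [build_geometry()] object.
#' @return An object of class `swimmer_report`.
#' @export
integral_report <- function(profiles, hydro, structural, geom) {
  stopifnot(inherits(profiles, "swim_profiles"),
            inherits(hydro, "hydro_result"))
  cst <- geom$constants
  P <- profiles$P
  Q <- profiles$Q
  if (Q <= 0) stop("integral_report: non-positive total consumption")
  P_s <- standard_metabolic_rate(geom$m, cst)
  U <- hydro$U
  eta_M <- P / Q
  eta_I <- internal_efficiency(hydro$P_H, structural$P_V)
  eta_H <- hydro$eta_H
  structure(list(
    U = U, Re = hydro$Re, branch = hydro$branch,
    COT = (P_s + Q) / (geom$m * cst$g * U),
    P = P, Q = Q, P_s = P_s,
    P_H = hydro$P_H, P_V = structural$P_V,
    eta_H = eta_H, eta_I = eta_I, eta_M = eta_M,
    eta_M_star = eta_M * eta_I,
    eta_T = eta_H * eta_M * eta_I,
    Psi = P / geom$m_M, Theta = Q / geom$m_M,
    m = geom$m, L = geom$L, m_M = geom$m_M,
    feasible = profiles$feasible,
    profiles = profiles
  ), class = "swimmer_report")
}

#' @export
print.swimmer_report <- function(x, ...) {
  cat(sprintf("Swimmer report (m = %.4g kg, L = %.4g m)\n", x$m, x$L))
  cat(sprintf("  U = %.4g m/s  (Re = %.3g, %s branch)\n", x$U, x$Re, x$branch))
  cat(sprintf("  COT = %.4g   P = %.4g W  Q = %.4g W  P_s = %.4g W\n",
              x$COT, x$P, x$Q, x$P_s))
  cat(sprintf("  P_H = %.4g W  P_V = %.4g W\n", x$P_H, x$P_V))
  cat(sprintf("  eta_H = %.3f  eta_M = %.3f  eta_I = %.3f  eta_T = %.3f\n",
              x$eta_H, x$eta_M, x$eta_I, x$eta_T))
  cat(sprintf("  Psi = %.4g W/kg  Theta = %.4g W/kg  feasible = %s\n",
              x$Psi, x$Theta, x$feasible))
  invisible(x)
}

#' Evaluate a swimmer configuration end to end
#'
#' Runs the full pipeline for one swimmer: geometry scaled to the target
#' mass, undulatory kinematics, steady-speed solution with recoil balance,
#' bending-moment extraction, per-section muscle metrics and the integral
#' report. Feasibility requires a steady speed to exist, the contraction
#' rate to stay below `vmax`, and the activation fraction to stay at or
#' below 1 everywhere.
#'
#' @param params Numeric 9-vector `c(DL, BL, c_d1, c_d2, c_b1, omega,
#'   e0, e1, e2)`: five shape coefficients (see [shape_params()]), the
#'   tail-beat angular frequency (rad/s) and three envelope coefficients
#'   (see [motion_spec()]).
#' @param m Body mass (kg).
#' @param constants A [swim_constants()] object.
#' @param n_grid Grid points along the body.
#' @param n_quad Quadrature intervals per contraction cycle.
#' @return A `swimmer_report` (see [integral_report()]). If the evaluation
#'   fails (invalid shape, no steady speed), a minimal object with
#'   `feasible = FALSE` and a `diagnostic` message is returned instead of
#'   an error.
#' @export
#' @examples
#' rep <- evaluate_swimmer(reference_params(1), m = 1)
#' rep$U; rep$COT
evaluate_swimmer <- function(params, m, constants = swim_constants(),
                             n_grid = 256L, n_quad = 1024L) {
  stopifnot(is.numeric(params), length(params) == 9L)
  out <- tryCatch({
    shape <- shape_params(DL = params[1], BL = params[2], c_d1 = params[3],
                          c_d2 = params[4], c_b1 = params[5])
    geom <- build_geometry(shape, m, constants, n_grid)
    motion <- motion_spec(params[6], params[7:9], geom)
    cfield <- contraction_field(geom, motion)
    hydro <- solve_speed(geom, motion)
    structural <- bending_moment(geom, motion, hydro$recoil, hydro$U)
    profiles <- longitudinal_profiles(structural, cfield, geom,
                                      n_quad = n_quad)
    rep <- integral_report(profiles, hydro, structural, geom)
    rep$params <- params
    rep
  }, error = function(e) {
    structure(list(feasible = FALSE, diagnostic = conditionMessage(e),
                   params = params, m = m,
                   U = NA_real_, COT = NA_real_),
              class = "swimmer_report")
  })
  out
}
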