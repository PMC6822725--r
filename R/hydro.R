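# Slender-body (reactive) hydrodynamics in the frequency domain. All
# lateral fields are complex amplitudes of a single harmonic exp(-i omega t);
# time averages of products of two harmonics are 0.5 * Re(A * Conj(B)).

# Material-derivative operator (d/dt + U d/dx) applied to a complex
# amplitude field: (-i omega) f + U f'.
material_deriv <- function(f, U, omega, dx) {
  -1i * omega * f + U * fd_deriv(f, dx)
}

#' Lateral hydrodynamic force field
#'
#' Reactive lateral force per unit length exerted on the fluid by a slender
#' undulating body, `F_L = (d/dt + U d/dx)[m_a (d/dt + U d/dx) h]`,
#' evaluated on complex amplitudes.
#'
#' @param geom A [build_geometry()] object.
#' @param Hhat Complex amplitude field of the total lateral deflection
#'   (undulation plus rigid-body recoil), on the geometry grid (m).
#' @param U Forward swimming speed (m/s, >= 0).
#' @param omega Angular frequency (rad/s).
#' @return Complex amplitude field of `F_L` (N/m).
#' @export
lateral_force_field <- function(geom, Hhat, U, omega) {
  stopifnot(inherits(geom, "body_geometry"), U >= 0)
  material_deriv(geom$m_a * material_deriv(Hhat, U, omega, geom$dx),
                 U, omega, geom$dx)
}

#' Solve the rigid-body recoil
#'
#' The prescribed undulation does not by itself conserve lateral momentum
#' and angular momentum; a lateral (`y0`) and angular (`phi`) rigid-body
#' recoil is superposed so that the whole-body lateral force and moment
#' balances hold:
#' `int (rho A d2h/dt2 + F_L) dx = 0` and the same weighted by `x`.
#' Both balances are linear in the two complex recoil amplitudes, giving a
#' 2x2 complex system.
#'
#' @inheritParams lateral_force_field
#' @param motion A [motion_spec()] object.
#' @return List with complex recoil amplitudes `Y0` (m) and `Phi_r` (rad),
#'   the total deflection amplitude `Hhat = H + Y0 + x * Phi_r`, and the
#'   relative residuals of the two balances.
#' @export
solve_recoil <- function(geom, motion, U) {
  stopifnot(inherits(motion, "motion_spec"))
  omega <- motion$omega
  x <- geom$x
  rhoA <- geom$constants$rho * geom$A
  load_of <- function(f)
    -omega^2 * rhoA * f + lateral_force_field(geom, f, U, omega)
  # Discrete balance functionals: the force balance is the trapezoidal
  # integral; the moment balance uses the repeated-trapezoid functional
  # (a consistent quadrature of the first-moment balance), which is exactly
  # the functional the bending-moment double integration applies -- so the
  # free-free moment closure at the tail holds to round-off on the grid.
  bal_force <- function(f) trapz_c(x, f)
  bal_moment <- function(f) trapz_c(x, cumtrapz_c(x, f))
  L1 <- load_of(rep(1 + 0i, length(x)))
  Lx <- load_of(x + 0i)
  LH <- load_of(motion$H)
  Amat <- matrix(c(bal_force(L1), bal_force(Lx),
                   bal_moment(L1), bal_moment(Lx)),
                 2L, 2L, byrow = TRUE)
  bvec <- -c(bal_force(LH), bal_moment(LH))
  sol <- tryCatch(solve(Amat, bvec),
                  error = function(e) stop("solve_recoil: singular recoil system (degenerate geometry)"))
  Y0 <- sol[1]; Phi_r <- sol[2]
  Hhat <- motion$H + Y0 + x * Phi_r
  Ltot <- load_of(Hhat)
  scale <- max(abs(trapz_c(x, abs(LH))), .Machine$double.xmin)
  list(Y0 = Y0, Phi_r = Phi_r, Hhat = Hhat,
       residual_force = abs(bal_force(Ltot)) / scale,
       residual_moment = abs(bal_moment(Ltot)) / (scale * geom$L))
}

#' Mean thrust of a slender undulating body
#'
#' Time-averaged thrust from the reactive tail term,
#' `F_T = 0.5 * m_a(L) * [ <(dh/dt)^2> - U^2 <(dh/dx)^2> ]` evaluated at
#' the tail, with `< >` the time average (half the squared amplitude for a
#' single harmonic). Uses the total deflection including recoil.
#'
#' @inheritParams solve_recoil
#' @param recoil A [solve_recoil()] result consistent with `U`.
#' @return Mean thrust (N). Zero with a warning if the tail carries no
#'   added mass.
#' @export
mean_thrust <- function(geom, motion, recoil, U) {
  n <- length(geom$x)
  ma_L <- geom$m_a[n]
  if (ma_L == 0) {
    warning("mean_thrust: zero added mass at the tail; thrust is zero")
    return(0)
  }
  Hx <- fd_deriv(recoil$Hhat, geom$dx)
  0.25 * ma_L * (motion$omega^2 * Mod(recoil$Hhat[n])^2 - U^2 * Mod(Hx[n])^2)
}

#' Friction and total drag coefficients
#'
#' Flat-plate friction coefficient with a discontinuous laminar-turbulent
#' transition at the critical Reynolds number, and the shape-corrected
#' total drag coefficient
#' `C_D = C_f * (1 + 1.5 (D/L)^1.5 + 7 (D/L)^3)`.
#'
#' @param Re Reynolds number `U L / nu` (> 0); vectorized.
#' @param DL Tail-height ratio `D/L`.
#' @param constants A [swim_constants()] object (for `Re_cr`).
#' @param branch `"auto"` selects the branch by comparing `Re` to `Re_cr`;
#'   `"laminar"` or `"turbulent"` force one branch (used while solving for
#'   the steady speed on a fixed branch).
#' @return List with `C_f` and `C_D`.
#' @export
#' @examples
#' drag_coefficient(1e4, DL = 0)$C_f  # 0.0133
drag_coefficient <- function(Re, DL, constants = swim_constants(),
                             branch = c("auto", "laminar", "turbulent")) {
  stopifnot(all(Re > 0))
  branch <- match.arg(branch)
  lam <- 1.33 * Re^-0.5
  turb <- 0.072 * Re^-0.2
  C_f <- switch(branch,
                auto = ifelse(Re <= constants$Re_cr, lam, turb),
                laminar = lam,
                turbulent = turb)
  list(C_f = C_f, C_D = C_f * (1 + 1.5 * DL^1.5 + 7.0 * DL^3))
}

# Thrust-minus-drag residual at speed U on a fixed drag branch; recoil is
# re-solved at each U. Returns the residual and the pieces for reuse.
thrust_drag_balance <- function(geom, motion, U, branch) {
  cst <- geom$constants
  recoil <- solve_recoil(geom, motion, U)
  F_T <- mean_thrust(geom, motion, recoil, U)
  DL <- geom$d[length(geom$d)] / geom$L
  Re <- U * geom$L / cst$nu
  C_D <- drag_coefficient(max(Re, .Machine$double.xmin), DL, cst,
                          branch = branch)$C_D
  F_D <- 0.5 * cst$rho * U^2 * geom$S * C_D
  list(residual = F_T - F_D, F_T = F_T, F_D = F_D, Re = Re, recoil = recoil)
}

#' Solve for the steady swimming speed
#'
#' Finds the speed at which the mean slender-body thrust balances the
#' empirical drag `0.5 rho U^2 S C_D(Re)`. Because the friction drag jumps
#' discontinuously at the critical Reynolds number, the laminar
#' (`Re <= Re_cr`) and turbulent branches are searched separately and a
#' root is accepted only if its Reynolds number is consistent with its
#' branch. When both branches admit a consistent root the faster one is
#' reported as primary.
#'
#' @inheritParams solve_recoil
#' @param U_range Search bracket for the speed (m/s).
#' @param tol Relative root tolerance on `U`.
#' @return An object of class `hydro_result`: `U`, `Re`, `branch`, `F_T`,
#'   `F_D`, `P_H` (mean power to the fluid, W), `eta_H` (Froude
#'   efficiency), the recoil solution at `U`, and `all_roots` (one row per
#'   consistent branch root). Errors if no branch admits a positive root.
#' @export
solve_speed <- function(geom, motion, U_range = c(1e-4, 1e3), tol = 1e-10) {
  stopifnot(inherits(geom, "body_geometry"), inherits(motion, "motion_spec"))
  if (all(motion$r == 0) || motion$omega == 0)
    stop("solve_speed: degenerate motion produces no thrust")
  cst <- geom$constants
  U_cr <- cst$Re_cr * cst$nu / geom$L
  roots <- list()
  for (br in c("laminar", "turbulent")) {
    lo <- U_range[1]
    hi <- U_range[2]
    if (br == "laminar") hi <- min(hi, U_cr) else lo <- max(lo, U_cr)
    if (lo >= hi) next
    fres <- function(U) thrust_drag_balance(geom, motion, U, br)$residual
    # coarse log-spaced scan for a sign change, then bisection refinement
    Us <- exp(seq(log(lo), log(hi), length.out = 25L))
    vals <- vapply(Us, fres, numeric(1))
    idx <- which(vals[-length(vals)] > 0 & vals[-1] <= 0)
    if (!length(idx)) next
    k <- idx[1]
    root <- stats::uniroot(fres, c(Us[k], Us[k + 1]),
                           tol = tol * Us[k + 1])$root
    Re <- root * geom$L / cst$nu
    consistent <- if (br == "laminar") Re <= cst$Re_cr * (1 + 1e-9)
                  else Re >= cst$Re_cr * (1 - 1e-9)
    if (consistent) roots[[br]] <- c(U = root, Re = Re)
  }
  if (!length(roots))
    stop("solve_speed: no steady swimming speed (thrust insufficient on both branches)")
  tab <- do.call(rbind, roots)
  primary <- rownames(tab)[which.max(tab[, "U"])]
  U <- tab[primary, "U"]
  bal <- thrust_drag_balance(geom, motion, U, primary)
  pe <- hydro_power_and_efficiency(geom, motion, bal$recoil, U)
  structure(list(U = U, Re = bal$Re, branch = primary,
                 F_T = bal$F_T, F_D = bal$F_D,
                 P_H = pe$P_H, eta_H = pe$eta_H,
                 recoil = bal$recoil,
                 all_roots = as.data.frame(tab)),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("Steady swimming: U = %.4g m/s (Re = %.3g, %s branch)\n",
              x$U, x$Re, x$branch))
  cat(sprintf("  F_T = %.4g N, P_H = %.4g W, eta_H = %.3f\n",
              x$F_T, x$P_H, x$eta_H))
  invisible(x)
}

#' Mean power to the fluid and Froude efficiency
#'
#' The mean rate of work done on the fluid by the lateral motion,
#' `P_H = int < F_L dh/dt > dx`, and the hydrodynamic (Froude) efficiency
#' `eta_H = F_T U / P_H`.
#'
#' @inheritParams mean_thrust
#' @return List with `P_H` (W) and `eta_H`. At `U = 0`, `eta_H = 0`.
#' @export
hydro_power_and_efficiency <- function(geom, motion, recoil, U) {
  FL <- lateral_force_field(geom, recoil$Hhat, U, motion$omega)
  hdot <- -1i * motion$omega * recoil$Hhat
  P_H <- trapz_c(geom$x, 0.5 * Re(FL * Conj(hdot)))
  if (P_H <= 0)
    stop("hydro_power_and_efficiency: non-positive power to the fluid")
  F_T <- mean_thrust(geom, motion, recoil, U)
  list(P_H = P_H, eta_H = if (U > 0) F_T * U / P_H else 0)
}
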