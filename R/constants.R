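#' Physical and physiological constants of the swimming model
#'
#' Bundles the fluid, tissue and muscle properties shared by all model
#' components. The defaults are characteristic values for aquatic
#' vertebrates powered by red (aerobic) muscle swimming in fresh water.
#'
#' @param F0 Isometric stress of fully activated muscle (N/m^2).
#' @param vmax Maximum fiber contraction strain rate (fiber-lengths/s, s^-1).
#' @param G Dimensionless shape constant of the Hill force-velocity curve.
#' @param rho_m Muscle density (kg/m^3); used to convert volumetric powers
#'   to powers per unit muscle mass.
#' @param E Aggregate Young's modulus of the passive body tissues (N/m^2).
#' @param nu_b Aggregate visco-elastic damping coefficient of the passive
#'   tissues (N s/m^2); enters the beam equation as `nu_b * I(x)` acting on
#'   the curvature rate.
#' @param mu0 Fraction of each cross section occupied by locomotory muscle
#'   (both sides together); the one-side muscle area is `0.5 * mu0 * A(x)`.
#' @param rho Water density (kg/m^3). The body is assumed neutrally buoyant,
#'   so this is also the body density.
#' @param nu Kinematic viscosity of water (m^2/s).
#' @param Re_cr Critical Reynolds number for the laminar-turbulent
#'   transition of the boundary layer.
#' @param Ps_coef,Ps_exp Coefficient and exponent of the allometric standard
#'   metabolic rate `P_s = Ps_coef * m^Ps_exp` (W, with m in kg).
#' @param g Gravitational acceleration (m/s^2), used only to nondimensionalize
#'   the cost of transport.
#'
#' @return An object of class `swim_constants` (a validated named list).
#' @export
#' @examples
#' cst <- swim_constants()
#' cst$F0 * cst$vmax / cst$rho_m  # specific power scale, W/kg
swim_constants <- function(F0 = 150e3, vmax = 5, G = 4, rho_m = 1000,
                           E = 1e5, nu_b = 1e4, mu0 = 0.1,
                           rho = 1000, nu = 1e-6, Re_cr = 5e5,
                           Ps_coef = 0.1327, Ps_exp = 0.80, g = 9.81) {
  cst <- list(F0 = F0, vmax = vmax, G = G, rho_m = rho_m,
              E = E, nu_b = nu_b, mu0 = mu0, rho = rho, nu = nu,
              Re_cr = Re_cr, Ps_coef = Ps_coef, Ps_exp = Ps_exp, g = g)
  bad <- names(cst)[!vapply(cst, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("swim_constants: entries must be positive finite scalars: ",
         paste(bad, collapse = ", "))
  if (cst$mu0 >= 1) stop("swim_constants: mu0 must be < 1")
  class(cst) <- "swim_constants"
  cst
}

#' Standard metabolic rate
#'
#' Speed-independent baseline metabolic power of an organism of mass `m`,
#' from the allometric relation `P_s = Ps_coef * m^Ps_exp`.
#'
#' @param m Body mass (kg).
#' @param constants A [swim_constants()] object.
#' @return Standard metabolic rate (W).
#' @export
standard_metabolic_rate <- function(m, constants = swim_constants()) {
  stopifnot(is.numeric(m), all(m > 0))
  constants$Ps_coef * m^constants$Ps_exp
}
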