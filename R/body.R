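#' Body shape parameters
#'
#' Five-coefficient smooth family describing the height and width profiles
#' of an elongated swimmer with elliptical cross sections. With `xi = x/L`:
#' \deqn{d(xi)/L = DL \, xi + c_{d1} (4 xi (1 - xi))^{c_{d2}}}
#' \deqn{b(xi)/L = BL (4 xi (1 - xi))^{c_{b1}}}
#' The height vanishes at the snout (pointed nose, so the leading edge
#' carries no added mass and the tail-only thrust formula is energetically
#' consistent) and rises to the non-zero tail value `D = DL * L` (so the
#' tail does carry added mass), with a body bump of amplitude `c_d1` and
#' bluntness `c_d2`; the width vanishes at snout and tail with bluntness
#' `c_b1`. The family spans fusiform outlines (moderate `c_d1`, blunt
#' bump) and peduncled ones (large `c_d1` with a fast-decaying bump,
#' leaving a narrow-depth peduncle ahead of the tail).
#'
#' @param DL Tail-height ratio `D/L` (> 0).
#' @param BL Maximum-width ratio `B/L` (> 0).
#' @param c_d1 Height-bump amplitude relative to `L` (>= 0 allowed;
#'   negative values are accepted if the profile stays positive).
#' @param c_d2 Height-bump bluntness exponent (> 0).
#' @param c_b1 Width bluntness exponent, in `(0, 1]`; the upper bound keeps
#'   the muscle force amplitude finite at the tapering ends.
#' @return An object of class `shape_params`.
#' @export
shape_params <- function(DL = 0.15, BL = 0.12, c_d1 = 0.06, c_d2 = 1.5,
                         c_b1 = 1) {
  sp <- list(DL = DL, BL = BL, c_d1 = c_d1, c_d2 = c_d2, c_b1 = c_b1)
  if (!all(vapply(sp, function(v) is.numeric(v) && length(v) == 1L &&
                  is.finite(v), logical(1))))
    stop("shape_params: all coefficients must be finite scalars")
  if (DL <= 0 || BL <= 0 || c_d2 <= 0)
    stop("shape_params: DL, BL and c_d2 must be positive")
  if (c_b1 <= 0 || c_b1 > 1)
    stop("shape_params: c_b1 must be in (0, 1]")
  xi <- seq(0, 1, length.out = 257L)[-c(1L, 257L)]
  if (any(height_profile(xi, sp) <= 0))
    stop("shape_params: height profile must be positive along the body interior")
  class(sp) <- "shape_params"
  sp
}

height_profile <- function(xi, shape) {
  shape$DL * xi + shape$c_d1 * (4 * xi * (1 - xi))^shape$c_d2
}

width_profile <- function(xi, shape) {
  shape$BL * (4 * xi * (1 - xi))^shape$c_b1
}

# Ramanujan's approximation to the perimeter of an ellipse with semi-axes
# a, b; exact enough (relative error < 1e-5 for any aspect ratio) for the
# wetted-surface integral.
ellipse_perimeter <- function(a, b) {
  s <- a + b
  h <- ifelse(s > 0, ((a - b) / ifelse(s > 0, s, 1))^2, 0)
  ifelse(s > 0, pi * s * (1 + 3 * h / (10 + sqrt(4 - 3 * h))), 0)
}

#' Build a discretized body geometry of prescribed mass
#'
#' Scales the normalized shape profiles to the body length that gives the
#' target mass under neutral buoyancy, `m = rho * (pi/4) * L^3 *
#' integral(d~ * b~)`, and tabulates all sectional fields on a uniform grid:
#' section area `A`, one-side muscle area `A_m = 0.5 * mu0 * A`,
#' lateral-bending second moment `I = (pi/64) d b^3`, lateral added mass
#' `m_a = rho * pi * d^2 / 4` (set by the section height, as for an
#' elliptic cylinder moving sideways), and the wetted surface `S`.
#'
#' @param shape A [shape_params()] object.
#' @param m Target body mass (kg).
#' @param constants A [swim_constants()] object.
#' @param n_grid Number of grid points along the body.
#' @return An object of class `body_geometry`.
#' @export
#' @examples
#' geom <- build_geometry(shape_params(), m = 1)
#' geom$L; geom$m_M / geom$m  # one-side muscle mass fraction 0.05
build_geometry <- function(shape, m, constants = swim_constants(),
                           n_grid = 256L) {
  stopifnot(inherits(shape, "shape_params"))
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("build_geometry: mass must be a positive scalar")
  stopifnot(n_grid >= 16L)
  xi <- seq(0, 1, length.out = n_grid)
  dt <- height_profile(xi, shape)
  bt <- width_profile(xi, shape)
  if (any(dt < 0) || any(dt[-1L] <= 0) || any(bt < 0) || all(bt == 0))
    stop("build_geometry: invalid shape profiles")
  # volume integral of the normalized profiles with the same quadrature used
  # for all later integrals, so mass closes exactly on the grid
  vol_xi <- trapz_c(xi, (pi / 4) * dt * bt)
  L <- (m / (constants$rho * vol_xi))^(1 / 3)
  x <- xi * L
  d <- dt * L
  b <- bt * L
  A <- pi * d * b / 4
  geom <- list(
    x = x, dx = x[2] - x[1], xi = xi,
    d = d, b = b, A = A,
    A_m = 0.5 * constants$mu0 * A,
    I = (pi / 64) * d * b^3,
    m_a = constants$rho * pi * d^2 / 4,
    L = L, m = m, m_M = 0.5 * constants$mu0 * m,
    S = trapz_c(x, ellipse_perimeter(d / 2, b / 2)),
    shape = shape, constants = constants
  )
  class(geom) <- "body_geometry"
  geom
}

#' @export
print.body_geometry <- function(x, ...) {
  cat(sprintf("Body geometry: L = %.4g m, m = %.4g kg, S = %.4g m^2\n",
              x$L, x$m, x$S))
  cat(sprintf("  tail height D = %.4g m, max width B = %.4g m, muscle m_M = %.4g kg\n",
              x$d[length(x$d)], max(x$b), x$m_M))
  invisible(x)
}

#' Undulatory motion specification
#'
#' A single-harmonic traveling wave of lateral deflection,
#' `h(x, t) = r(x) cos(2 pi x / lambda_b - omega t)`, with the body
#' wavelength fixed at the body length. The envelope is parameterized as
#' the square of a truncated Chebyshev series,
#' `r(x)/L = (e0 T0 + e1 T1(s) + e2 T2(s))^2` with `s = 2 x/L - 1`,
#' which keeps `r(x)` smooth and non-negative for any coefficients.
#'
#' @param omega Tail-beat angular frequency (rad/s).
#' @param env_coef Numeric vector of 3 Chebyshev coefficients `(e0, e1, e2)`
#'   of the square-root envelope.
#' @param geom A [build_geometry()] result (sets the grid and `lambda_b = L`).
#' @return An object of class `motion_spec` with the envelope `r`, tail
#'   amplitude `h_T = r(L)`, complex deflection amplitude `H(x) = r(x)
#'   exp(i 2 pi x / lambda_b)` (so that `h = Re[H exp(-i omega t)]`), and
#'   period `T`.
#' @export
motion_spec <- function(omega, env_coef, geom) {
  stopifnot(inherits(geom, "body_geometry"),
            is.numeric(omega), length(omega) == 1L, omega >= 0,
            is.numeric(env_coef), length(env_coef) == 3L,
            all(is.finite(env_coef)))
  s <- 2 * geom$xi - 1
  series <- env_coef[1] + env_coef[2] * s + env_coef[3] * (2 * s^2 - 1)
  r <- geom$L * series^2
  lambda_b <- geom$L
  H <- r * exp(1i * 2 * pi * geom$x / lambda_b)
  structure(list(omega = omega, lambda_b = lambda_b, env_coef = env_coef,
                 r = r, h_T = r[length(r)],
                 H = H, T = if (omega > 0) 2 * pi / omega else Inf),
            class = "motion_spec")
}

#' Muscle contraction-rate field of an undulating body
#'
#' The strain rate of the superficial muscle fibers follows from the
#' curvature rate of the body midline: `v(x, t) = +/- (b(x)/2) *
#' d/dt(d^2 h/dx^2)`, the sign selecting the body side. In the frequency
#' domain the right-side complex amplitude is `V(x) = (b/2) (-i omega)
#' H''(x)`.
#'
#' @param geom A [build_geometry()] object.
#' @param motion A [motion_spec()] object on the same grid.
#' @return List with the complex amplitude `V` (s^-1), its envelope `vhat`,
#'   the relative envelope `vhat_r = vhat / vmax`, and `feasible`
#'   (`TRUE` when `vhat_r < 1` everywhere).
#' @export
contraction_field <- function(geom, motion) {
  stopifnot(inherits(geom, "body_geometry"), inherits(motion, "motion_spec"))
  Hxx <- fd_deriv2(motion$H, geom$dx)
  V <- 0.5 * geom$b * (-1i * motion$omega) * Hxx
  vhat <- Mod(V)
  vhat_r <- vhat / geom$constants$vmax
  list(V = V, vhat = vhat, vhat_r = vhat_r,
       feasible = all(vhat_r < 1))
}
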