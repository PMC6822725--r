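# Small numerical kernels shared by the geometry, hydrodynamic and
# structural modules. All of them accept complex vectors, which the
# frequency-domain formulation relies on throughout.

# Trapezoidal integral of y(x) on a (possibly non-uniform) grid.
trapz_c <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Cumulative trapezoidal integral, starting at 0 at x[1].
cumtrapz_c <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# First derivative on a uniform grid, 4th-order central differences with
# 4th-order one-sided closures at the two points nearest each end.
fd_deriv <- function(f, dx) {
  n <- length(f)
  if (n < 6L) stop("fd_deriv: need at least 6 grid points")
  d <- f * 0
  i <- 3:(n - 2)
  d[i] <- (f[i - 2] - 8 * f[i - 1] + 8 * f[i + 1] - f[i + 2]) / (12 * dx)
  d[1] <- (-25 * f[1] + 48 * f[2] - 36 * f[3] + 16 * f[4] - 3 * f[5]) / (12 * dx)
  d[2] <- (-3 * f[1] - 10 * f[2] + 18 * f[3] - 6 * f[4] + f[5]) / (12 * dx)
  d[n - 1] <- (3 * f[n] + 10 * f[n - 1] - 18 * f[n - 2] + 6 * f[n - 3] - f[n - 4]) / (12 * dx)
  d[n] <- (25 * f[n] - 48 * f[n - 1] + 36 * f[n - 2] - 16 * f[n - 3] + 3 * f[n - 4]) / (12 * dx)
  d
}

# Second derivative as two applications of fd_deriv (keeps one consistent
# stencil family for all operators, including products with x-dependent
# coefficients).
fd_deriv2 <- function(f, dx) fd_deriv(fd_deriv(f, dx), dx)
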