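# Plain-text (YAML) run configuration: a constants block, a swimmer block
# (mass + the 9 shape/motion parameters) and a run block (numerical
# resolutions and optimizer budgets).

default_run_block <- function() {
  list(n_grid = 256L, n_quad = 1024L, seed = 1L,
       pop_size = 40L, generations = 60L)
}

param_names <- c("DL", "BL", "c_d1", "c_d2", "c_b1",
                 "omega", "e0", "e1", "e2")

#' Assemble a run configuration
#'
#' @param mass Body mass (kg).
#' @param params Named or positional numeric 9-vector of shape/motion
#'   parameters (see [evaluate_swimmer()]).
#' @param constants A [swim_constants()] object (or a named list of
#'   overrides of its defaults).
#' @param run Named list of run settings overriding the defaults
#'   (`n_grid`, `n_quad`, `seed`, `pop_size`, `generations`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mass = 1, params = reference_params(mass),
                       constants = swim_constants(), run = list()) {
  if (!inherits(constants, "swim_constants"))
    constants <- do.call(swim_constants, as.list(constants))
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0,
            is.numeric(params), length(params) == 9L)
  params <- stats::setNames(as.numeric(params), param_names)
  rb <- default_run_block()
  unknown <- setdiff(names(run), names(rb))
  if (length(unknown))
    stop("run_config: unknown run settings: ", paste(unknown, collapse = ", "))
  rb[names(run)] <- run
  structure(list(mass = mass, params = params, constants = constants,
                 run = rb),
            class = "run_config")
}

#' Write a run configuration to a plain-text file
#'
#' @param config A [run_config()] object.
#' @param path Output path (YAML key-value text).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(mass = config$mass,
              params = as.list(config$params),
              constants = unclass(config$constants),
              run = config$run)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a run configuration from a plain-text file
#'
#' Missing blocks are filled with defaults; unknown keys are rejected.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML key-value file.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  known <- c("mass", "params", "constants", "run")
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("load_config: unknown top-level keys: ",
         paste(unknown, collapse = ", "))
  mass <- if (is.null(obj$mass)) 1 else as.numeric(obj$mass)
  cst <- if (is.null(obj$constants)) swim_constants() else {
    extra <- setdiff(names(obj$constants), names(unclass(swim_constants())))
    if (length(extra))
      stop("load_config: unknown constants: ", paste(extra, collapse = ", "))
    do.call(swim_constants, obj$constants)
  }
  params <- if (is.null(obj$params)) reference_params(mass) else {
    p <- unlist(obj$params)
    if (!is.null(names(p)) && all(names(p) %in% param_names) &&
        length(p) == 9L) p <- p[param_names]
    if (length(p) != 9L || any(!is.finite(p)))
      stop("load_config: params must be 9 finite numbers")
    p
  }
  run_config(mass = mass, params = params, constants = cst,
             run = if (is.null(obj$run)) list() else obj$run)
}

#' Reference swimmer parameters
#'
#' A deterministic, documented swimmer configuration that is feasible at
#' any mass in the supported range: a fusiform outline (tail height 0.15 L,
#' maximum width 0.12 L) with a tail-growing envelope reaching about
#' 0.04 L at the tail. The tail-beat frequency follows `m^(-1/3)` above
#' 1 kg (isometric) and a much flatter `m^(-0.065)` below it, where the
#' visco-elastic bending moment would otherwise exceed the muscle capacity
#' of fast-beating small swimmers. Masses whose base frequency falls into
#' the laminar-turbulent branch gap (no self-consistent steady speed on
#' either drag branch) are nudged to a 30% higher frequency, repeatedly if
#' needed, which carries them onto the turbulent branch; the nudge is
#' deterministic, so fixtures are identical across runs.
#'
#' @param mass Body mass (kg), in `[1e-3, 1e6]`.
#' @param omega_1kg Tail-beat angular frequency of the 1 kg reference
#'   (rad/s).
#' @return Named numeric 9-vector of shape/motion parameters.
#' @export
#' @examples
#' reference_params(1)
reference_params <- function(mass = 1, omega_1kg = 14) {
  stopifnot(is.numeric(mass), length(mass) == 1L,
            mass >= 1e-3, mass <= 1e6)
  omega0 <- if (mass >= 1) omega_1kg * mass^(-1 / 3)
            else omega_1kg * mass^(-0.065)
  base <- c(0.15, 0.12, 0.06, 1.5, 1, omega0, 0.121, 0.066, 0.011)
  for (k in 0:5) {
    p <- base
    p[6] <- omega0 * 1.3^k
    rep <- evaluate_swimmer(p, mass)
    if (isTRUE(rep$feasible))
      return(stats::setNames(p, param_names))
  }
  stop("reference_params: no feasible reference configuration at this mass")
}

#' Generate a reference swimmer fixture
#'
#' Deterministic feasible swimmer configuration at the requested mass,
#' wrapped as a full [run_config()].
#'
#' @inheritParams reference_params
#' @param style Currently only `"fusiform"`.
#' @return A [run_config()] object.
#' @export
generate_fixture <- function(mass, style = "fusiform") {
  style <- match.arg(style)
  run_config(mass = mass, params = reference_params(mass))
}
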