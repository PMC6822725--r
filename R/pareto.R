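# Two-objective optimization of swimmers: maximize the sustained speed U,
# minimize the cost of transport COT, over the 9 shape/motion parameters
# at fixed body mass.

#' Default optimization bounds for the shape/motion parameters
#'
#' Box bounds wide enough that converged optima do not press against them:
#' shape ratios within realistic elongated-body proportions, tail-beat
#' frequency spanning hovering insects-in-water absurdity down to whale
#' beats, and envelope coefficients keeping tail amplitudes below about
#' 0.2 L.
#'
#' @return A 2 x 9 matrix with rows `lower`, `upper`.
#' @export
default_bounds <- function() {
  lower <- c(DL = 0.05, BL = 0.05, c_d1 = 0.00, c_d2 = 0.5, c_b1 = 0.5,
             omega = 0.1, e0 = 0.05, e1 = -0.2, e2 = -0.2)
  upper <- c(DL = 0.30, BL = 0.25, c_d1 = 0.15, c_d2 = 3.0, c_b1 = 1.0,
             omega = 200, e0 = 0.40, e1 = 0.2, e2 = 0.2)
  rbind(lower = lower, upper = upper)
}

#' Non-dominated filter for (maximize U, minimize COT)
#'
#' A candidate is dominated if another has speed at least as high and cost
#' of transport at least as low, with at least one strict. Duplicated
#' objective pairs on the front are all kept.
#'
#' @param U Numeric vector of speeds.
#' @param COT Numeric vector of costs of transport (same length).
#' @return Integer indices of the non-dominated candidates, ordered by
#'   decreasing `U`.
#' @export
#' @examples
#' non_dominated(c(1, 2, 1.5), c(1, 2, 0.5))  # points 2 and 3
non_dominated <- function(U, COT) {
  stopifnot(length(U) == length(COT), length(U) >= 1L,
            all(is.finite(U)), all(is.finite(COT)))
  keep <- logical(length(U))
  best_cot <- Inf   # min COT among candidates strictly faster than this group
  for (u in sort(unique(U), decreasing = TRUE)) {
    grp <- which(U == u)
    gmin <- min(COT[grp])
    # survivors must match the group's best COT and strictly beat every
    # faster candidate's COT (exact duplicates are all kept)
    if (gmin < best_cot) keep[grp[COT[grp] == gmin]] <- TRUE
    best_cot <- min(best_cot, gmin)
  }
  idx <- which(keep)
  idx[order(-U[idx])]
}

#' Assemble a Pareto front from evaluated candidates
#'
#' @param candidates List of `swimmer_report` objects (see
#'   [evaluate_swimmer()]); infeasible ones are excluded before sorting.
#' @param mass Body mass the candidates were evaluated at (kg).
#' @return An object of class `pareto_front`: `members` (the non-dominated
#'   reports, fastest first), `objectives` (data frame of `U`, `COT`),
#'   `U_opt` and `COT_opt` (the two front extremes) and `mass`.
#' @export
pareto_front <- function(candidates, mass) {
  feas <- Filter(function(r) isTRUE(r$feasible), candidates)
  if (!length(feas))
    stop("pareto_front: no feasible candidate")
  U <- vapply(feas, `[[`, numeric(1), "U")
  COT <- vapply(feas, `[[`, numeric(1), "COT")
  idx <- non_dominated(U, COT)
  members <- feas[idx]
  structure(list(
    members = members,
    objectives = data.frame(U = U[idx], COT = COT[idx]),
    U_opt = members[[1L]],
    COT_opt = members[[length(members)]],
    mass = mass
  ), class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front at m = %.4g kg: %d members\n",
              x$mass, length(x$members)))
  cat(sprintf("  U-optimal:   U = %.4g m/s, COT = %.4g\n",
              x$U_opt$U, x$U_opt$COT))
  cat(sprintf("  COT-optimal: U = %.4g m/s, COT = %.4g\n",
              x$COT_opt$U, x$COT_opt$COT))
  invisible(x)
}

# Rank the combined population into non-dominated fronts; within the
# tail front, prefer spread via crowding distance on normalized objectives.
select_survivors <- function(U, COT, n_keep) {
  n <- length(U)
  remaining <- seq_len(n)
  chosen <- integer(0)
  while (length(chosen) < n_keep && length(remaining)) {
    fr <- remaining[non_dominated(U[remaining], COT[remaining])]
    if (length(chosen) + length(fr) <= n_keep) {
      chosen <- c(chosen, fr)
    } else {
      need <- n_keep - length(chosen)
      cd <- crowding_distance(U[fr], COT[fr])
      chosen <- c(chosen, fr[order(-cd)][seq_len(need)])
    }
    remaining <- setdiff(remaining, fr)
  }
  chosen
}

crowding_distance <- function(U, COT) {
  n <- length(U)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (obj in list(U, COT)) {
    rng <- diff(range(obj))
    if (rng == 0) next
    o <- order(obj)
    cd[o[c(1L, n)]] <- Inf
    cd[o[2:(n - 1L)]] <- cd[o[2:(n - 1L)]] +
      (obj[o[3:n]] - obj[o[1:(n - 2L)]]) / rng
  }
  cd
}

#' Two-objective evolutionary optimization of a swimmer at fixed mass
#'
#' Elitist evolution strategy with per-individual step-size adaptation (a
#' scalar-step simplification of multi-objective CMA-ES): each surviving
#' individual produces one offspring by Gaussian mutation scaled to the
#' box-bound widths, offspring and parents compete jointly under
#' non-dominated sorting with crowding-distance tie-breaks, and an
#' individual's step size grows on success (offspring survives) and decays
#' otherwise. Infeasible candidates never enter the surviving population.
#' Fully reproducible for a given seed.
#'
#' @param m Body mass (kg).
#' @param pop_size Population size (>= 4).
#' @param generations Number of generations.
#' @param seed Integer random seed.
#' @param bounds 2 x 9 bounds matrix (see [default_bounds()]).
#' @param constants A [swim_constants()] object.
#' @param n_grid,n_quad Evaluation resolutions (see [evaluate_swimmer()]).
#' @param sigma0 Initial step size relative to the bound widths.
#' @param init_retries Maximum sampling attempts per initial individual.
#' @param verbose Print per-generation progress.
#' @return A [pareto_front()] of the final population, with attribute
#'   `n_evaluations`.
#' @export
pareto_optimize <- function(m, pop_size = 40L, generations = 60L, seed = 1L,
                            bounds = default_bounds(),
                            constants = swim_constants(),
                            n_grid = 192L, n_quad = 512L,
                            sigma0 = 0.15, init_retries = 400L,
                            verbose = FALSE) {
  stopifnot(pop_size >= 4L, generations >= 1L)
  set.seed(seed)
  lower <- bounds["lower", ]; upper <- bounds["upper", ]
  width <- upper - lower
  evals <- 0L
  eval_cand <- function(p) {
    evals <<- evals + 1L
    evaluate_swimmer(p, m, constants, n_grid = n_grid, n_quad = n_quad)
  }
  # initial feasible population by rejection sampling (frequency sampled
  # log-uniformly: feasibility is sharply frequency-dependent)
  pop <- vector("list", pop_size)
  sig <- rep(sigma0, pop_size)
  for (i in seq_len(pop_size)) {
    ok <- FALSE
    for (k in seq_len(init_retries)) {
      p <- lower + stats::runif(9) * width
      p[6] <- exp(stats::runif(1, log(lower[6]), log(upper[6])))
      r <- eval_cand(p)
      if (isTRUE(r$feasible)) { pop[[i]] <- r; ok <- TRUE; break }
    }
    if (!ok)
      stop("pareto_optimize: could not find a feasible initial individual")
  }
  for (g in seq_len(generations)) {
    offspring <- vector("list", pop_size)
    for (i in seq_len(pop_size)) {
      p <- pop[[i]]$params + sig[i] * width * stats::rnorm(9)
      p <- pmin(pmax(p, lower), upper)
      offspring[[i]] <- eval_cand(p)
    }
    all_ind <- c(pop, offspring)
    feas <- vapply(all_ind, function(r) isTRUE(r$feasible), logical(1))
    idx_f <- which(feas)
    U <- vapply(all_ind[idx_f], `[[`, numeric(1), "U")
    COT <- vapply(all_ind[idx_f], `[[`, numeric(1), "COT")
    keep <- idx_f[select_survivors(U, COT, pop_size)]
    # success-based step adaptation before reindexing
    new_sig <- numeric(pop_size)
    new_pop <- vector("list", pop_size)
    for (j in seq_along(keep)) {
      src <- keep[j]
      parent_slot <- if (src > pop_size) src - pop_size else src
      survived_offspring <- src > pop_size
      new_sig[j] <- sig[parent_slot] *
        if (survived_offspring) exp(0.25) else exp(-0.08)
      new_sig[j] <- min(max(new_sig[j], 1e-4), 0.5)
      new_pop[[j]] <- all_ind[[src]]
    }
    pop <- new_pop
    sig <- new_sig
    if (verbose)
      message(sprintf("gen %d: best U = %.4g, best COT = %.4g",
                      g, max(vapply(pop, `[[`, numeric(1), "U")),
                      min(vapply(pop, `[[`, numeric(1), "COT"))))
  }
  front <- pareto_front(pop, m)
  attr(front, "n_evaluations") <- evals
  front
}

#' Scan optimal swimmers across body masses
#'
#' Runs [pareto_optimize()] on a grid of body masses and tabulates the
#' front extremes, flagging masses whose optima sit just below the
#' critical Reynolds number (the laminar-turbulent transition range, where
#' optimal swimmers hold `Re` under `Re_cr` to avoid the drag jump).
#'
#' @param masses Numeric vector of body masses (kg).
#' @param pop_size,generations,seed,constants,... Passed to
#'   [pareto_optimize()]; each mass uses `seed + position - 1`.
#' @param transition_band Relative band below `Re_cr` flagged as
#'   transition-range behavior.
#' @return A list with `table` (one row per mass and objective extreme:
#'   `m`, `which`, `U`, `COT`, `Re`, `branch`, `eta_M`, `eta_H`, `eta_T`,
#'   `Psi`, `Theta`, `transition`), `fronts` (the per-mass
#'   [pareto_front()] objects) and `failed` (masses whose optimization
#'   errored, with messages).
#' @export
mass_scan <- function(masses, pop_size = 40L, generations = 60L, seed = 1L,
                      constants = swim_constants(), transition_band = 0.05,
                      ...) {
  fronts <- list()
  failed <- list()
  rows <- list()
  for (k in seq_along(masses)) {
    m <- masses[k]
    res <- tryCatch(
      pareto_optimize(m, pop_size, generations, seed = seed + k - 1L,
                      constants = constants, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[[as.character(m)]] <- conditionMessage(res)
      next
    }
    fronts[[as.character(m)]] <- res
    for (which in c("U_opt", "COT_opt")) {
      r <- res[[which]]
      rows[[length(rows) + 1L]] <- data.frame(
        m = m, which = sub("_opt", "", which),
        U = r$U, COT = r$COT, Re = r$Re, branch = r$branch,
        eta_M = r$eta_M, eta_H = r$eta_H, eta_T = r$eta_T,
        Psi = r$Psi, Theta = r$Theta,
        transition = r$Re >= (1 - transition_band) * constants$Re_cr &&
          r$Re <= constants$Re_cr)
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else NULL,
       fronts = fronts, failed = failed)
}
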