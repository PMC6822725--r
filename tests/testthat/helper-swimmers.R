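# Shared fixtures built in code. The reference swimmer evaluation is cached
# per session since several test files inspect it.

ref_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- evaluate_swimmer(reference_params(1), 1)
    cache
  }
})

# Deterministic jittered swimmers around the reference configuration;
# returns the first `n` feasible evaluations (mass, params, report).
sample_feasible_swimmers <- function(n, seed = 1, max_tries = 40 * n,
                                     n_grid = 192L, n_quad = 512L) {
  set.seed(seed)
  out <- list()
  for (k in seq_len(max_tries)) {
    m <- 10^stats::runif(1, -2, 2)
    base <- c(0.15, 0.12, 0.06, 1.5, 1,
              if (m >= 1) 14 * m^(-1 / 3) else 14 * m^(-0.065),
              0.121, 0.066, 0.011)
    p <- base * c(stats::runif(5, 0.85, 1.2),
                  stats::runif(1, 0.8, 1.25),
                  stats::runif(3, 0.7, 1.3))
    p[5] <- min(p[5], 1)
    rep <- evaluate_swimmer(p, m, n_grid = n_grid, n_quad = n_quad)
    if (isTRUE(rep$feasible)) {
      out[[length(out) + 1L]] <- list(m = m, params = p, report = rep)
      if (length(out) == n) return(out)
    }
  }
  stop("sample_feasible_swimmers: could not find enough feasible swimmers")
}

# Brute-force O(n^2) dominance oracle for (maximize U, minimize COT).
brute_force_front <- function(U, COT) {
  n <- length(U)
  keep <- vapply(seq_len(n), function(i) {
    !any(U >= U[i] & COT <= COT[i] & (U > U[i] | COT < COT[i]))
  }, logical(1))
  sort(which(keep))
}
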