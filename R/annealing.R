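# Generic simulated annealing: Metropolis acceptance with a geometric
# cooling schedule. Minimization convention throughout; callers that
# maximize pass the negated objective. The same engine drives both the
# feature-weight search (FSSA) and classifier training.

#' Annealing schedule
#'
#' @param T0 Initial temperature (> 0). Default 1.0.
#' @param gamma Geometric cooling rate in `(0, 1]`; the temperature after
#'   `t` steps is `T0 * gamma^t`. Default 0.95.
#' @param max_iter Iteration budget (>= 0). Default 500.
#' @param T_min Early-termination temperature; the chain stops once the
#'   temperature falls below it.
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T0 = 1.0, gamma = 0.95, max_iter = 500L,
                            T_min = 1e-6) {
  if (!is.numeric(T0) || T0 <= 0) stop("`T0` must be positive")
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("`gamma` must lie in (0, 1]")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 0L) stop("`max_iter` must be >= 0")
  if (!is.numeric(T_min) || T_min < 0) stop("`T_min` must be >= 0")
  structure(list(T0 = T0, gamma = gamma, max_iter = max_iter, T_min = T_min),
            class = "anneal_schedule")
}

#' Metropolis acceptance probability
#'
#' Under minimization: an improving or tying proposal (`delta_E <= 0`) is
#' accepted with certainty; a worsening one with probability
#' `exp(-delta_E / T)`.
#'
#' @param delta_E Energy difference, proposed minus current.
#' @param T Temperature (> 0).
#' @return Probability in `(0, 1]`.
#' @export
acceptance_probability <- function(delta_E, T) {
  if (!is.numeric(T) || any(T <= 0)) stop("temperature must be positive")
  ifelse(delta_E <= 0, 1, exp(-delta_E / T))
}

#' Geometric cooling step
#'
#' @param T Current temperature (> 0).
#' @param gamma Cooling rate in `(0, 1]`.
#' @return `T * gamma`.
#' @export
cool <- function(T, gamma) {
  if (!is.numeric(T) || any(T <= 0)) stop("temperature must be positive")
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("`gamma` must lie in (0, 1]")
  T * gamma
}

#' Run simulated annealing
#'
#' Each iteration perturbs the current solution, evaluates its energy,
#' accepts by the Metropolis rule at the current temperature, then cools
#' geometrically. A rejected proposal leaves the chain where it is. The
#' best solution ever visited is tracked and returned; the best-energy
#' sequence in the trace is therefore monotone non-increasing. Fully
#' reproducible for a given `seed`.
#'
#' @param energy_fn Function solution -> finite numeric energy (minimized).
#' @param perturb_fn Function solution -> proposed solution; draws from the
#'   active RNG stream.
#' @param x0 Initial solution.
#' @param schedule An [anneal_schedule()].
#' @param seed Optional integer seed; when given, the run is bit-reproducible.
#' @return List with `best` (lowest-energy solution seen), `best_energy`,
#'   and `trace`, a data.frame with one row per executed iteration:
#'   `iteration`, `temperature`, `energy` (of the proposal), `accepted`,
#'   `best_energy`.
#' @export
anneal <- function(energy_fn, perturb_fn, x0, schedule = anneal_schedule(),
                   seed = NULL) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  current <- x0
  E_cur <- energy_fn(x0)
  if (!is.finite(E_cur)) stop("non-finite energy at the initial solution")
  best <- x0
  E_best <- E_cur
  n <- schedule$max_iter
  temperature <- numeric(n); energy <- numeric(n)
  accepted <- logical(n); best_energy <- numeric(n)
  T <- schedule$T0
  t <- 0L
  while (t < n && T >= schedule$T_min) {
    t <- t + 1L
    proposal <- perturb_fn(current)
    E_prop <- energy_fn(proposal)
    if (!is.finite(E_prop))
      stop("non-finite energy at iteration ", t)
    p <- acceptance_probability(E_prop - E_cur, T)
    acc <- p >= 1 || stats::runif(1) < p
    if (acc) {
      current <- proposal
      E_cur <- E_prop
      if (E_cur < E_best) {
        best <- current
        E_best <- E_cur
      }
    }
    temperature[t] <- T
    energy[t] <- E_prop
    accepted[t] <- acc
    best_energy[t] <- E_best
    T <- cool(T, schedule$gamma)
  }
  trace <- data.frame(iteration = seq_len(t),
                      temperature = temperature[seq_len(t)],
                      energy = energy[seq_len(t)],
                      accepted = accepted[seq_len(t)],
                      best_energy = best_energy[seq_len(t)])
  list(best = best, best_energy = E_best, trace = trace)
}

# Save/restore the global RNG state so seeded runs do not disturb callers.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
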