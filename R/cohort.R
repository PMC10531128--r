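#' Closed-cohort simulation settings
#'
#' Describes the cohort that is pushed through the transition matrix: entry
#' age, the age at which the model stops (the average national life
#' expectancy in the bundled fixture), the Markov cycle length and the
#' starting state. The number of cycles is `ceiling((life_expectancy -
#' start_age) / cycle_length)`, so a fractional final cycle is modelled as a
#' whole cycle.
#'
#' @param start_age entry age in years (fixture default 40).
#' @param life_expectancy age in years at which simulation stops; must exceed
#'   `start_age`.
#' @param cycle_length cycle length in years, in (0, 1] (fixture default 0.5,
#'   i.e. 6 months).
#' @param initial_state id of the state holding the whole cohort at cycle 0.
#' @param cohort_mass size of the closed cohort (dimensionless, default 1).
#' @return A list of class `cohort_spec` with the fields above plus
#'   `horizon_cycles`.
#' @examples
#' cohort_spec(40, 73.6, 0.5, "acetaminophen")
#' @export
cohort_spec <- function(start_age, life_expectancy, cycle_length = 0.5,
                        initial_state, cohort_mass = 1) {
  stopifnot(is.numeric(start_age), is.numeric(life_expectancy),
            is.numeric(cycle_length), is.numeric(cohort_mass))
  if (cycle_length <= 0 || cycle_length > 1)
    stop("`cycle_length` must be in (0, 1] years", call. = FALSE)
  if (life_expectancy <= start_age)
    stop("`life_expectancy` must exceed `start_age`", call. = FALSE)
  if (cohort_mass < 0)
    stop("`cohort_mass` must be non-negative", call. = FALSE)
  horizon <- ceiling((life_expectancy - start_age) / cycle_length)
  if (horizon < 1)
    stop("model horizon is empty (horizon_cycles < 1)", call. = FALSE)
  structure(list(start_age = start_age, life_expectancy = life_expectancy,
                 cycle_length = cycle_length,
                 initial_state = as.character(initial_state),
                 cohort_mass = cohort_mass, horizon_cycles = as.integer(horizon)),
            class = "cohort_spec")
}

#' Run a closed cohort forward through a Markov chain
#'
#' Iterates `row[t + 1] = row[t] %*% probs` from the initial distribution,
#' producing the cycle-by-cycle state-occupancy trace. Also records, for each
#' cycle, the mass newly entering each state (used for costs charged once on
#' state entry, e.g. a surgical procedure).
#'
#' @param tmat a valid [transition_matrix()].
#' @param spec a [cohort_spec()]; `spec$initial_state` must name a state of
#'   `matrix`.
#' @return An object of class `cohort_trace`: list with
#'   \describe{
#'     \item{occupancy}{`(horizon_cycles + 1) x n_states` matrix; row `t + 1`
#'       is the distribution after `t` cycles, row 1 the initial one.}
#'     \item{entrants}{`horizon_cycles x n_states` matrix of mass arriving in
#'       each state from a *different* state at each cycle.}
#'     \item{states, cycle_length, start_age, cohort_mass}{bookkeeping.}
#'   }
#' @examples
#' st <- health_states(c("treat", "death"), c("treatment", "death"))
#' tm <- transition_matrix(st, rbind(c(0.6, 0.4), c(0, 1)))
#' tr <- run_cohort(tm, cohort_spec(40, 45, 0.5, "treat"))
#' head(as.data.frame(tr))
#' @export
run_cohort <- function(tmat, spec) {
  stopifnot(inherits(tmat, "transition_matrix"), inherits(spec, "cohort_spec"))
  viol <- validate_matrix(tmat)
  if (length(viol))
    stop("transition matrix fails validation:\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  ids <- tmat$states$id
  i0 <- match(spec$initial_state, ids)
  if (is.na(i0))
    stop("initial state '", spec$initial_state, "' not among: ",
         paste(ids, collapse = ", "), call. = FALSE)
  n <- length(ids)
  Tn <- spec$horizon_cycles
  occ <- matrix(0, Tn + 1L, n, dimnames = list(0:Tn, ids))
  occ[1L, i0] <- spec$cohort_mass
  ent <- matrix(0, Tn, n, dimnames = list(1:Tn, ids))
  P <- tmat$probs
  Poff <- P; diag(Poff) <- 0
  for (t in seq_len(Tn)) {
    occ[t + 1L, ] <- occ[t, ] %*% P
    ent[t, ] <- occ[t, ] %*% Poff
  }
  structure(list(occupancy = occ, entrants = ent, states = tmat$states,
                 cycle_length = spec$cycle_length, start_age = spec$start_age,
                 cohort_mass = spec$cohort_mass),
            class = "cohort_trace")
}

#' Undiscounted person-time spent in a state
#'
#' Converts occupancy into person-years. Without half-cycle correction,
#' membership is counted at cycle end: the sum of occupancy over cycles
#' `1..T`, times the cycle length. With correction, consecutive rows are
#' averaged (trapezoid rule), approximating mid-cycle transitions.
#'
#' @param trace a [run_cohort()] result.
#' @param state_id one state id present in the trace.
#' @param half_cycle logical; apply the half-cycle (trapezoidal) correction.
#' @return Person-years (scaled by the cohort mass).
#' @export
time_in_state <- function(trace, state_id, half_cycle = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"))
  j <- match(state_id, trace$states$id)
  if (is.na(j))
    stop("unknown state id '", state_id, "'", call. = FALSE)
  occ <- trace$occupancy[, j]
  Tn <- length(occ) - 1L
  w <- if (half_cycle) (occ[1:Tn] + occ[2:(Tn + 1L)]) / 2 else occ[2:(Tn + 1L)]
  sum(w) * trace$cycle_length
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  Tn <- nrow(x$occupancy) - 1L
  data.frame(cycle = 0:Tn,
             age = x$start_age + (0:Tn) * x$cycle_length,
             x$occupancy, check.names = FALSE, row.names = NULL)
}

#' @export
print.cohort_trace <- function(x, ...) {
  Tn <- nrow(x$occupancy) - 1L
  cat("Cohort trace:", Tn, "cycles of", x$cycle_length, "y over",
      nrow(x$states), "states\n")
  cat("Final occupancy:\n")
  print(round(x$occupancy[Tn + 1L, ], 4))
  invisible(x)
}
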