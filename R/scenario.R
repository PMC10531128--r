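#' Configuration for the synthetic scenario generator
#'
#' The generator emulates the statistical structure of the sequential
#' treatment model — an ordered no-backtracking chain of treatment states
#' ending in surgery and absorbing death, utilities in (0, 1], non-negative
#' costs in three classes — so that every stage of the pipeline can be
#' exercised on unlimited reproducible instances. One integer seed drives a
#' private pseudo-random stream; the global RNG state is never touched.
#'
#' @param seed integer seed; fully determines the instance.
#' @param n_treatment_states number of treatment lines before surgery (2-8).
#' @param escalation_prob_range sub-interval of (0, 1) for per-cycle
#'   escalation probabilities (surgery's death transition included).
#' @param utility_range sub-interval of (0, 1] for state utilities.
#' @param cost_scale VND magnitude around which per-cycle costs are drawn
#'   log-uniformly (over one decade either side).
#' @param horizon_cycles model horizon in cycles.
#' @param discount_rate annual discount rate.
#' @param cycle_length cycle length in years.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed, n_treatment_states = 4,
                            escalation_prob_range = c(0.05, 0.9),
                            utility_range = c(0.3, 0.95),
                            cost_scale = 1e6, horizon_cycles = 40,
                            discount_rate = 0.03, cycle_length = 0.5) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (n_treatment_states < 2 || n_treatment_states > 8)
    stop("`n_treatment_states` must be in 2..8", call. = FALSE)
  ok_range <- function(r, lo, hi) length(r) == 2 && r[1] <= r[2] &&
    r[1] >= lo && r[2] <= hi
  if (!ok_range(escalation_prob_range, 0, 1))
    stop("`escalation_prob_range` must be an ordered sub-interval of [0, 1]",
         call. = FALSE)
  if (!ok_range(utility_range, 0, 1))
    stop("`utility_range` must be an ordered sub-interval of [0, 1]",
         call. = FALSE)
  if (cost_scale <= 0 || horizon_cycles < 1 || discount_rate < 0)
    stop("invalid `cost_scale`, `horizon_cycles` or `discount_rate`",
         call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_treatment_states = as.integer(n_treatment_states),
                 escalation_prob_range = escalation_prob_range,
                 utility_range = utility_range, cost_scale = cost_scale,
                 horizon_cycles = as.integer(horizon_cycles),
                 discount_rate = discount_rate, cycle_length = cycle_length),
            class = "scenario_config")
}

#' Draw one synthetic model instance
#'
#' Generates treatment lines with escalation probabilities and utilities
#' uniform within the configured ranges and costs log-uniform at the
#' configured scale (drug cost always positive; companion, non-medical and
#' indirect components each present with probability 1/2), a surgery line
#' whose one-off procedure cost is 10x the cost scale, and a synthetic
#' economy. The surgery row escalates toward death, so every instance has a
#' strictly positive path to absorption. The same seed always yields the
#' identical instance.
#'
#' @param config a [scenario_config()].
#' @return A `cua_inputs` object with a single sequence named `"base"`,
#'   directly consumable by [cua()], [tornado()] and [build_regimen()].
#' @examples
#' m <- random_model(scenario_config(1))
#' fit <- cua("base", m)
#' @export
random_model <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_private_seed(config$seed, {
    n <- config$n_treatment_states
    epr <- config$escalation_prob_range
    utr <- config$utility_range
    log_cost <- function(k) exp(stats::runif(k, log(config$cost_scale / 10),
                                             log(config$cost_scale * 10)))
    treatments <- list()
    for (i in seq_len(n)) {
      nm <- paste0("s", i)
      treatments[[nm]] <- treatment_spec(
        nm,
        escalation_prob = stats::runif(1, epr[1], epr[2]),
        drug_cost = log_cost(1),
        companion_cost = if (stats::runif(1) < 0.5) log_cost(1) else 0,
        nonmedical_cost = if (stats::runif(1) < 0.5) log_cost(1) else 0,
        indirect_cost = if (stats::runif(1) < 0.5) log_cost(1) else 0,
        utility = stats::runif(1, utr[1], utr[2]))
    }
    treatments$surgery <- treatment_spec(
      "surgery", escalation_prob = stats::runif(1, epr[1], epr[2]),
      drug_cost = log_cost(1) * 10,
      nonmedical_cost = log_cost(1), indirect_cost = log_cost(1),
      utility = stats::runif(1, utr[1], utr[2]),
      kind = "surgery", cost_timing = "on_entry")
    structure(list(
      treatments = treatments,
      sequences = list(base = names(treatments)),
      economy = economy_params(
        gdp_per_capita_usd = round(stats::runif(1, 1000, 50000)),
        exchange_rate = round(stats::runif(1, 1, 30000))),
      discount = discount_spec(config$discount_rate),
      cohort = list(start_age = 0,
                    life_expectancy = config$horizon_cycles * config$cycle_length,
                    cycle_length = config$cycle_length, cohort_mass = 1),
      options = list(surgery = "escalate"),
      seed = config$seed), class = "cua_inputs")
  })
}

#' Insert one extra treatment line into a synthetic instance
#'
#' Mirrors the before/after construction of the bundled regimens: the
#' returned instance differs from `model` only by one inserted treatment
#' line, exposed as an additional sequence `"variant"` alongside the
#' untouched `"base"`. No other state's specification is modified, so the
#' pair supports insertion-position comparisons.
#'
#' @param model a `cua_inputs` instance (typically from [random_model()]).
#' @param position 1-based position within the treatment lines at which the
#'   new line is inserted (1 = first; `n + 1` = just before surgery).
#' @param spec a [treatment_spec()] for the inserted line; by default one is
#'   drawn reproducibly from the instance's seed.
#' @param sequence which sequence of `model` to vary (default `"base"`).
#' @return The augmented `cua_inputs` with sequences `"base"` and
#'   `"variant"`.
#' @export
paired_variant <- function(model, position, spec = NULL, sequence = "base") {
  stopifnot(inherits(model, "cua_inputs"))
  seq_ids <- model$sequences[[sequence]]
  if (is.null(seq_ids)) stop("no sequence named '", sequence, "'", call. = FALSE)
  n_treat <- length(seq_ids) - 1L  # last entry is surgery
  if (position < 1 || position > n_treat + 1L)
    stop("`position` must be in 1..", n_treat + 1L, call. = FALSE)
  if (is.null(spec)) {
    seed <- if (is.null(model$seed)) 0L else model$seed
    spec <- with_private_seed(seed + 104729L + position, treatment_spec(
      "inserted", escalation_prob = stats::runif(1, 0.05, 0.9),
      drug_cost = exp(stats::runif(1, log(1e5), log(1e7))),
      utility = stats::runif(1, 0.3, 0.95)))
  }
  if (spec$kind != "treatment")
    stop("only treatment lines can be inserted", call. = FALSE)
  if (spec$name %in% names(model$treatments))
    stop("a treatment named '", spec$name, "' already exists", call. = FALSE)
  model$treatments[[spec$name]] <- spec
  model$sequences$variant <- append(seq_ids, spec$name, after = position - 1L)
  model
}
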