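#' One treatment line of a sequential regimen
#'
#' A treatment line bundles everything the model needs about one rung of the
#' escalation ladder: the per-cycle probability of escalating to the next
#' line (treatment failure / non-response), the per-cycle cost components,
#' and the health-state utility while on it. Surgery lines may carry their
#' procedure and recovery costs once, on entry (`cost_timing = "on_entry"`),
#' since an arthroplasty is performed once rather than repeated every cycle
#' of residence.
#'
#' @param name state id.
#' @param escalation_prob per-cycle probability of moving to the next line,
#'   in [0, 1].
#' @param drug_cost VND: drug or procedure cost.
#' @param companion_cost VND: co-prescribed drug (e.g. the PPI covering an
#'   NSAID).
#' @param nonmedical_cost VND: direct non-medical cost (food, transport).
#' @param indirect_cost VND: productivity loss (absenteeism).
#' @param utility health-state utility in [0, 1].
#' @param kind `"treatment"` or `"surgery"`.
#' @param cost_timing `"per_cycle"` (costs accrue every cycle of residence)
#'   or `"on_entry"` (charged once when the state is entered).
#' @return A list of class `treatment_spec`.
#' @export
treatment_spec <- function(name, escalation_prob, drug_cost,
                           companion_cost = 0, nonmedical_cost = 0,
                           indirect_cost = 0, utility,
                           kind = c("treatment", "surgery"),
                           cost_timing = c("per_cycle", "on_entry")) {
  kind <- match.arg(kind)
  cost_timing <- match.arg(cost_timing)
  if (escalation_prob < 0 || escalation_prob > 1)
    stop("`escalation_prob` must be in [0, 1]", call. = FALSE)
  if (utility < 0 || utility > 1)
    stop("`utility` must be in [0, 1]", call. = FALSE)
  costs <- c(drug_cost, companion_cost, nonmedical_cost, indirect_cost)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  structure(list(name = as.character(name), escalation_prob = escalation_prob,
                 drug_cost = drug_cost, companion_cost = companion_cost,
                 nonmedical_cost = nonmedical_cost,
                 indirect_cost = indirect_cost, utility = utility,
                 kind = kind, cost_timing = cost_timing),
            class = "treatment_spec")
}

#' Published model inputs: six knee-osteoarthritis treatment sequences
#'
#' The full input set of the bundled Vietnamese cost-utility analysis, as
#' published: per-cycle escalation probabilities, drug/procedure costs in
#' VND (with the PPI cost attached to Diclofenac as a companion drug, and the
#' 1-month post-surgery food, transport and absenteeism costs attached to
#' the arthroplasty state), utilities per state, the six regimen sequences,
#' economy parameters (GDP per capita USD 3756 at 23,486 VND/USD), a 3%
#' annual discount rate, 6-month cycles, and a cohort entering at age 40.
#' All values are frozen constants taken from the published input table —
#' never recomputed. Note the published absenteeism cost (7,342,373 VND for
#' the 1-month recovery) is kept as printed even though dividing the
#' published annual GDP by 12 gives 7,351,118; see the methods vignette.
#'
#' Sequences (each ends in total knee arthroplasty, then death):
#' \describe{
#'   \item{PD}{Acetaminophen, Diclofenac+PPI, Triamcinolone, TKA.}
#'   \item{PDE}{PD with Etoricoxib between Diclofenac+PPI and Triamcinolone.}
#'   \item{PGD / PDG}{PD with crystalline glucosamine sulfate inserted
#'     before / after Diclofenac+PPI.}
#'   \item{PGDE / PDEG}{PDE with glucosamine before Diclofenac+PPI / after
#'     Etoricoxib.}
#' }
#'
#' @param life_expectancy stop age in years; defaults to 73.6, the average
#'   Vietnamese life expectancy in 2021 (the publication cites the average
#'   without printing a figure; configurable).
#' @param surgery how the surgery row of the transition matrix is closed:
#'   `"stay"` (absorbing until the horizon — death enters the model only by
#'   truncation, the default) or `"escalate"` (the published TKA probability
#'   0.5122 moves mass on to death each cycle).
#' @return An object of class `cua_inputs`: list with `treatments` (named
#'   `treatment_spec` list), `sequences` (named list of state-id vectors),
#'   `economy`, `discount`, `cohort` (start age, life expectancy, cycle
#'   length) and `options`.
#' @examples
#' inp <- oa_inputs()
#' inp$treatments$tka$utility       # 0.76
#' names(inp$sequences)             # the six regimen codes
#' @export
oa_inputs <- function(life_expectancy = 73.6,
                      surgery = c("stay", "escalate")) {
  surgery <- match.arg(surgery)
  recovery_months <- 1
  treatments <- list(
    acetaminophen = treatment_spec("acetaminophen", 0.3380,
                                   drug_cost = 588600, utility = 0.7010),
    glucosamine = treatment_spec("glucosamine", 0.3857,
                                 drug_cost = 186300, utility = 0.6760),
    diclofenac_ppi = treatment_spec("diclofenac_ppi", 0.8647,
                                    drug_cost = 60210,
                                    companion_cost = 344700, utility = 0.7230),
    etoricoxib = treatment_spec("etoricoxib", 0.5657,
                                drug_cost = 785700, utility = 0.7230),
    triamcinolone = treatment_spec("triamcinolone", 0.0392,
                                   drug_cost = 19400, utility = 0.6400),
    tka = treatment_spec("tka", 0.5122, drug_cost = 88712500,
                         nonmedical_cost = (2700000 + 2953620) * recovery_months,
                         indirect_cost = 7342373 * recovery_months,
                         utility = 0.7600, kind = "surgery",
                         cost_timing = "on_entry"))
  sequences <- list(
    PD   = c("acetaminophen", "diclofenac_ppi", "triamcinolone", "tka"),
    PDE  = c("acetaminophen", "diclofenac_ppi", "etoricoxib", "triamcinolone", "tka"),
    PGD  = c("acetaminophen", "glucosamine", "diclofenac_ppi", "triamcinolone", "tka"),
    PDG  = c("acetaminophen", "diclofenac_ppi", "glucosamine", "triamcinolone", "tka"),
    PGDE = c("acetaminophen", "glucosamine", "diclofenac_ppi", "etoricoxib",
             "triamcinolone", "tka"),
    PDEG = c("acetaminophen", "diclofenac_ppi", "etoricoxib", "glucosamine",
             "triamcinolone", "tka"))
  structure(list(treatments = treatments, sequences = sequences,
                 economy = economy_params(3756, 23486),
                 discount = discount_spec(0.03),
                 cohort = list(start_age = 40,
                               life_expectancy = life_expectancy,
                               cycle_length = 0.5, cohort_mass = 1),
                 options = list(surgery = surgery)),
            class = "cua_inputs")
}

#' Published base-case results table
#'
#' The published total discounted costs (VND) and QALYs of the six
#' strategies, as printed in the source publication's results table. These
#' are *published outputs*, not model inputs: they serve as operands for
#' incremental (ICER) arithmetic and for verifying [compare_strategies()]
#' against the printed ICERs. The publication does not state the cohort
#' aggregation behind these magnitudes, so the package's own cohort traces
#' are not expected to reproduce them (see the methods vignette).
#'
#' @return Data frame with columns `strategy`, `total_cost`, `total_qalys`.
#' @export
table2_base_case <- function() {
  data.frame(
    strategy = c("PD", "PGD", "PDG", "PDE", "PGDE", "PDEG"),
    total_cost = c(314758471, 348133295, 339027398, 367478671, 443969715,
                   425013733),
    total_qalys = c(56.9374, 100.7445, 92.7119, 129.8038, 230.6720, 211.3288),
    stringsAsFactors = FALSE)
}

#' Assemble a regimen from its code
#'
#' Resolves a sequence code (e.g. `"PGD"`) against an input set and returns
#' the ordered treatment lines, the surgery line, and the appended absorbing
#' death state.
#'
#' @param code a sequence code among `names(inputs$sequences)`, or a
#'   character vector of treatment names (a custom sequence ending in the
#'   surgery state).
#' @param inputs a `cua_inputs` object ([oa_inputs()] by default).
#' @return A list of class `regimen`: `code`, `steps` (list of
#'   `treatment_spec`), and `states` (a [health_states()] table including
#'   death).
#' @examples
#' r <- build_regimen("PGDE")
#' r$states$id  # glucosamine at ordinal 1
#' @export
build_regimen <- function(code, inputs = oa_inputs()) {
  if (length(code) == 1L && code %in% names(inputs$sequences)) {
    seq_ids <- inputs$sequences[[code]]
  } else if (all(code %in% names(inputs$treatments))) {
    seq_ids <- code
    code <- paste(seq_ids, collapse = "+")
  } else {
    stop("unknown regimen code or treatment name(s): ",
         paste(setdiff(code, names(inputs$treatments)), collapse = ", "),
         call. = FALSE)
  }
  steps <- inputs$treatments[seq_ids]
  kinds <- vapply(steps, `[[`, "", "kind")
  if (kinds[length(kinds)] != "surgery")
    stop("a regimen must end in the surgery state", call. = FALSE)
  states <- health_states(c(seq_ids, "death"), c(kinds, "death"))
  structure(list(code = code, steps = steps, states = states,
                 options = inputs$options),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("Regimen", x$code, ":", paste(x$states$id, collapse = " -> "), "\n")
  invisible(x)
}

#' Per-cycle transition matrix of a regimen
#'
#' Each treatment row keeps `1 - escalation_prob` on itself and places
#' `escalation_prob` on the next state in the sequence. The surgery row is
#' closed according to `surgery`: `"stay"` makes it absorbing until the
#' horizon (death by truncation only, the default), `"escalate"` sends its
#' escalation probability on to death. Death is always absorbing.
#'
#' @param regimen a [build_regimen()] result.
#' @param surgery `"stay"` or `"escalate"`; defaults to the option carried by
#'   the input set the regimen was built from.
#' @return A [transition_matrix()].
#' @examples
#' to_transition_matrix(build_regimen("PD"))$probs["acetaminophen", ]
#' @export
to_transition_matrix <- function(regimen, surgery = NULL) {
  stopifnot(inherits(regimen, "regimen"))
  if (is.null(surgery)) surgery <- regimen$options$surgery
  surgery <- match.arg(surgery, c("stay", "escalate"))
  ids <- regimen$states$id
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_along(regimen$steps)) {
    s <- regimen$steps[[i]]
    p <- if (s$kind == "surgery" && surgery == "stay") 0 else s$escalation_prob
    P[i, i] <- 1 - p
    P[i, i + 1L] <- p
  }
  P[n, n] <- 1
  transition_matrix(regimen$states, P)
}

#' Convert trial response into a per-cycle transition probability
#'
#' Published efficacy is typically a response proportion over a trial's
#' duration; the model needs a per-cycle probability. Assuming a constant
#' hazard, `rate = -log(1 - p) / trial_duration` and the per-cycle
#' probability is `1 - exp(-rate * cycle_length)`. When the two durations
#' coincide the input is returned unchanged. A response of exactly 1 maps to
#' a per-cycle probability of 1 (with a message), since a finite duration
#' cannot carry an infinite rate.
#'
#' @param response_prob probability of response over the trial, in [0, 1].
#' @param trial_duration trial duration in years (> 0).
#' @param cycle_length model cycle length in years (> 0).
#' @return Per-cycle probability in [0, 1].
#' @examples
#' efficacy_to_transition(0.8647, 1, 0.5)  # 1 - 0.1353^0.5
#' @export
efficacy_to_transition <- function(response_prob, trial_duration, cycle_length) {
  if (any(response_prob < 0 | response_prob > 1))
    stop("`response_prob` must be in [0, 1]", call. = FALSE)
  if (trial_duration <= 0 || cycle_length <= 0)
    stop("durations must be positive", call. = FALSE)
  out <- numeric(length(response_prob))
  one <- response_prob >= 1
  if (any(one)) {
    message("response probability of 1 maps to per-cycle probability 1")
    out[one] <- 1
  }
  p <- response_prob[!one]
  out[!one] <- 1 - exp(log(1 - p) * cycle_length / trial_duration)
  out
}

# per-cycle and on-entry cost tables for a regimen (death = 0 by construction)
regimen_cost_tables <- function(regimen) {
  per_cycle <- list(); on_entry <- list()
  for (s in regimen$steps) {
    cc <- cost_components(direct_medical = s$drug_cost + s$companion_cost,
                          direct_nonmedical = s$nonmedical_cost,
                          indirect = s$indirect_cost)
    if (s$cost_timing == "on_entry") {
      per_cycle[[s$name]] <- cost_components()
      on_entry[[s$name]] <- cc
    } else {
      per_cycle[[s$name]] <- cc
    }
  }
  per_cycle$death <- cost_components()
  list(per_cycle = per_cycle, on_entry = on_entry)
}

regimen_utilities <- function(regimen) {
  u <- vapply(regimen$steps, `[[`, 0, "utility")
  names(u) <- vapply(regimen$steps, `[[`, "", "name")
  c(u, death = 0)
}
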