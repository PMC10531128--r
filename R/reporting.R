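#' Read and validate a run-configuration file
#'
#' Configurations are a single YAML document. Every key is checked against
#' the schema below; unknown keys anywhere are rejected with a message
#' listing the offenders, so typos never silently fall back to defaults.
#'
#' Top-level keys (all optional unless noted):
#' \describe{
#'   \item{strategies}{character vector of sequence codes (required for
#'     `run_base_case`); defaults to all six bundled codes.}
#'   \item{comparisons}{list of 2-element `[strategy, comparator]` pairs,
#'     or `"all_pairs"` / `"vs_first"`.}
#'   \item{half_cycle}{logical, default `false`.}
#'   \item{surgery}{`stay` (default) or `escalate`.}
#'   \item{cohort}{`start_age`, `life_expectancy`, `cycle_length`,
#'     `cohort_mass`.}
#'   \item{economy}{`gdp_per_capita_usd`, `exchange_rate`.}
#'   \item{discount_rate}{annual rate, default 0.03.}
#'   \item{sensitivity}{`fraction`, `comparisons`, `parameters` (dotted
#'     paths).}
#'   \item{output_dir}{directory for report files.}
#'   \item{seed, scenario}{scenario-generator mode: `scenario` holds
#'     [scenario_config()] fields (minus `seed`).}
#' }
#'
#' @param path path to a YAML file, or a list already parsed.
#' @return The validated configuration list, class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("configuration must be a mapping", call. = FALSE)
  schema <- list(
    strategies = NULL, comparisons = NULL, half_cycle = NULL, surgery = NULL,
    cohort = c("start_age", "life_expectancy", "cycle_length", "cohort_mass"),
    economy = c("gdp_per_capita_usd", "exchange_rate"),
    discount_rate = NULL,
    sensitivity = c("fraction", "comparisons", "parameters"),
    output_dir = NULL, seed = NULL,
    scenario = c("n_treatment_states", "escalation_prob_range",
                 "utility_range", "cost_scale", "horizon_cycles",
                 "cycle_length"))
  bad <- setdiff(names(cfg), names(schema))
  for (blk in names(schema)) {
    if (!is.null(schema[[blk]]) && !is.null(cfg[[blk]])) {
      if (!is.list(cfg[[blk]]))
        stop("config block '", blk, "' must be a mapping", call. = FALSE)
      bad <- c(bad, paste(blk, setdiff(names(cfg[[blk]]), schema[[blk]]),
                          sep = "."))
    }
  }
  bad <- bad[!endsWith(bad, ".")]
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$surgery) && !cfg$surgery %in% c("stay", "escalate"))
    stop("config key 'surgery' must be 'stay' or 'escalate'", call. = FALSE)
  structure(cfg, class = "run_config")
}

# materialize a cua_inputs object from a validated configuration
config_to_inputs <- function(cfg) {
  if (!is.null(cfg$scenario) || !is.null(cfg$seed)) {
    sc_args <- c(list(seed = if (is.null(cfg$seed)) 1L else cfg$seed),
                 cfg$scenario)
    if (!is.null(cfg$discount_rate)) sc_args$discount_rate <- cfg$discount_rate
    inputs <- random_model(do.call(scenario_config, sc_args))
  } else {
    inputs <- oa_inputs(surgery = if (is.null(cfg$surgery)) "stay" else cfg$surgery)
  }
  for (f in names(cfg$cohort)) inputs$cohort[[f]] <- cfg$cohort[[f]]
  if (!is.null(cfg$economy))
    inputs$economy <- do.call(economy_params, cfg$economy)
  if (!is.null(cfg$discount_rate))
    inputs$discount <- discount_spec(cfg$discount_rate)
  inputs
}

report_settings <- function(cfg, inputs) {
  message("discounting at ", inputs$discount$annual_rate,
          "/y; half-cycle correction ",
          if (isTRUE(cfg$half_cycle)) "ON" else "OFF",
          "; surgery row '", inputs$options$surgery,
          "'; drug costs per cycle as printed, surgery costs on entry")
}

#' Run the base-case analysis from a configuration
#'
#' Builds the model inputs described by the configuration (the bundled
#' fixture by default, or a synthetic instance when a `seed`/`scenario`
#' block is present), runs every configured strategy and comparison, and
#' returns the fitted [cua()] object. The modelling conventions in force
#' (discount rate, accrual timing, surgery-row closure, cost timing) are
#' logged so every run is auditable.
#'
#' @param config a path to a YAML file, a list, or a `run_config`.
#' @return A [cua()] object.
#' @export
run_base_case <- function(config) {
  cfg <- read_run_config(config)
  inputs <- config_to_inputs(cfg)
  report_settings(cfg, inputs)
  strategies <- if (is.null(cfg$strategies)) names(inputs$sequences)
                else cfg$strategies
  comparisons <- if (is.null(cfg$comparisons)) "all_pairs" else cfg$comparisons
  cua(strategies, inputs, comparisons = comparisons,
      half_cycle = isTRUE(cfg$half_cycle))
}

#' Run the configured tornado analyses
#'
#' One tornado per configured comparison pair. When the regimens come from
#' the bundled fixture and no pairs are configured, the default set is the
#' four published scenarios: PGD/PD, PDG/PD, PGDE/PDE and PDEG/PDE. A pair
#' whose base case resolves to a dominance label is reported and skipped.
#'
#' @param config a path to a YAML file, a list, or a `run_config`.
#' @return Named list of [tornado()] objects (skipped pairs carry the
#'   dominance label as a character scalar instead).
#' @export
run_tornado <- function(config) {
  cfg <- read_run_config(config)
  inputs <- config_to_inputs(cfg)
  report_settings(cfg, inputs)
  sens <- cfg$sensitivity
  pairs <- sens$comparisons
  if (is.null(pairs)) {
    pairs <- if (all(c("PGD", "PDG", "PGDE", "PDEG") %in% names(inputs$sequences)))
      list(c("PGD", "PD"), c("PDG", "PD"), c("PGDE", "PDE"), c("PDEG", "PDE"))
    else list(names(inputs$sequences)[1:2])
  }
  fraction <- if (is.null(sens$fraction)) 0.20 else sens$fraction
  out <- list()
  for (p in pairs) {
    p <- unlist(p)
    nm <- paste(p, collapse = "_vs_")
    params <- if (is.null(sens$parameters)) NULL else
      lapply(sens$parameters, function(pa)
        default_range(pa, get_param(inputs, pa), fraction))
    out[[nm]] <- tryCatch(
      tornado(inputs, p, params = params, fraction = fraction,
              half_cycle = isTRUE(cfg$half_cycle)),
      error = function(e) {
        message("skipping ", nm, ": ", conditionMessage(e))
        conditionMessage(e)
      })
  }
  out
}

#' Write report tables for a fitted analysis
#'
#' Serializes the per-strategy CEA table and the pairwise comparison table
#' as CSV and JSON. Monetary values are rounded only here, at the
#' serialization boundary: VND half-up to whole units, USD to two decimals;
#' in-memory results stay unrounded.
#'
#' @param fit a [cua()] object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "cua"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cea <- fit$cea
  cea$total_cost_vnd <- round_half_up(cea$total_cost_vnd)
  cea$total_cost_usd <- round_half_up(cea$total_cost_usd, 2)
  comp <- fit$comparisons
  comp$delta_cost <- round_half_up(comp$delta_cost)
  comp$icer <- round_half_up(comp$icer)
  paths <- c(file.path(dir, "cea.csv"), file.path(dir, "comparisons.csv"),
             file.path(dir, "results.json"))
  utils::write.csv(cea, paths[1], row.names = FALSE)
  utils::write.csv(comp, paths[2], row.names = FALSE)
  jsonlite::write_json(list(cea = cea, comparisons = comp), paths[3],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write tornado tables
#'
#' One CSV per comparison (columns: parameter, low, high, icer_low,
#' icer_high, spread, rank), rounding VND quantities half-up at the
#' boundary. Reruns with the same configuration produce byte-identical
#' files.
#'
#' @param tornadoes result of [run_tornado()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_tornado_outputs <- function(tornadoes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tornadoes)) {
    tor <- tornadoes[[nm]]
    if (!inherits(tor, "tornado")) next
    df <- as.data.frame(tor)
    for (col in c("icer_low", "icer_high", "spread"))
      df[[col]] <- round_half_up(df[[col]])
    p <- file.path(dir, paste0("tornado_", nm, ".csv"))
    utils::write.csv(df[, c("parameter", "base_value", "low", "high",
                            "icer_low", "icer_high", "label_low",
                            "label_high", "spread", "rank", "note")],
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a cohort trace as a cycle-by-cycle CSV
#'
#' Columns: cycle, age, one occupancy column per state.
#'
#' @param trace a [run_cohort()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
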