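#' Per-cycle cost components of a health state
#'
#' Costs are split into the three classes of a societal-perspective analysis:
#' direct medical (drugs, procedures), direct non-medical (food, transport to
#' care) and indirect (productivity loss from absenteeism). All in VND per
#' cycle (or per state entry, where a one-off cost is attached).
#'
#' @param direct_medical,direct_nonmedical,indirect non-negative VND amounts.
#' @return A list of class `cost_components` with a `total` field.
#' @export
cost_components <- function(direct_medical = 0, direct_nonmedical = 0,
                            indirect = 0) {
  v <- c(direct_medical, direct_nonmedical, indirect)
  if (any(!is.finite(v)) || any(v < 0))
    stop("cost components must be finite and non-negative", call. = FALSE)
  structure(list(direct_medical = direct_medical,
                 direct_nonmedical = direct_nonmedical,
                 indirect = indirect,
                 total = direct_medical + direct_nonmedical + indirect),
            class = "cost_components")
}

#' Annual discount settings applied to costs and outcomes alike
#'
#' @param annual_rate non-negative annual discount rate (fixture default
#'   0.03).
#' @return A list of class `discount_spec`.
#' @export
discount_spec <- function(annual_rate = 0.03) {
  if (!is.numeric(annual_rate) || annual_rate < 0)
    stop("`annual_rate` must be a non-negative number", call. = FALSE)
  structure(list(annual_rate = annual_rate), class = "discount_spec")
}

#' Discount factor at a given cycle
#'
#' `(1 + annual_rate)^(-cycle_index * cycle_length)`: the present-value weight
#' of a quantity accruing at the end of `cycle_index` cycles.
#'
#' @param spec a [discount_spec()] (or a bare rate).
#' @param cycle_index non-negative integer cycle number.
#' @param cycle_length cycle length in years.
#' @return Factor in (0, 1], non-increasing in `cycle_index`.
#' @examples
#' discount_factor(discount_spec(0.03), 2, 0.5)  # 1/1.03
#' @export
discount_factor <- function(spec, cycle_index, cycle_length) {
  rate <- if (inherits(spec, "discount_spec")) spec$annual_rate else spec
  if (any(cycle_index < 0))
    stop("`cycle_index` must be non-negative", call. = FALSE)
  (1 + rate)^(-cycle_index * cycle_length)
}

#' National-economy parameters for WTP thresholds and currency handling
#'
#' The willingness-to-pay classification is anchored on GDP per capita in
#' local currency, obtained from the USD figure and the exchange rate by
#' exact multiplication. The fixture carries Vietnam's 2021 values:
#' USD 3756 at 23,486 VND/USD, i.e. VND 88,213,416.
#'
#' @param gdp_per_capita_usd annual GDP per capita, USD.
#' @param exchange_rate VND per USD.
#' @param cpi_series optional named numeric vector of consumer-price-index
#'   values, names = years, for [cpi_adjust()].
#' @return A list of class `economy_params` with derived
#'   `gdp_per_capita_vnd` and `monthly_gdp_vnd` fields.
#' @export
economy_params <- function(gdp_per_capita_usd = 3756, exchange_rate = 23486,
                           cpi_series = NULL) {
  if (exchange_rate <= 0) stop("`exchange_rate` must be positive", call. = FALSE)
  if (gdp_per_capita_usd < 0) stop("GDP per capita must be non-negative", call. = FALSE)
  gdp_vnd <- gdp_per_capita_usd * exchange_rate
  structure(list(gdp_per_capita_usd = gdp_per_capita_usd,
                 exchange_rate = exchange_rate,
                 gdp_per_capita_vnd = gdp_vnd,
                 monthly_gdp_vnd = gdp_vnd / 12,
                 cpi_series = cpi_series),
            class = "economy_params")
}

#' Currency conversion at a fixed exchange rate
#'
#' Plain product/quotient with no internal rounding; round only when
#' reporting.
#'
#' @param amount amount to convert.
#' @param rate exchange rate in VND per USD (positive).
#' @return Converted amount.
#' @examples
#' usd_to_vnd(3756, 23486)  # 88,213,416
#' @export
usd_to_vnd <- function(amount, rate) {
  if (any(rate <= 0)) stop("exchange rate must be positive", call. = FALSE)
  amount * rate
}

#' @rdname usd_to_vnd
#' @export
vnd_to_usd <- function(amount, rate) {
  if (any(rate <= 0)) stop("exchange rate must be positive", call. = FALSE)
  amount / rate
}

#' Inflate or deflate a past amount with a consumer price index
#'
#' `amount * cpi[to_year] / cpi[from_year]`. Years absent from the series are
#' an error; no extrapolation is attempted.
#'
#' @param amount VND amount stated in `from_year` prices.
#' @param from_year,to_year years present in `names(cpi_series)`.
#' @param cpi_series named numeric vector of index values.
#' @return The amount in `to_year` prices.
#' @export
cpi_adjust <- function(amount, from_year, to_year, cpi_series) {
  ys <- as.character(c(from_year, to_year))
  miss <- setdiff(ys, names(cpi_series))
  if (length(miss))
    stop("year(s) missing from CPI series: ", paste(miss, collapse = ", "),
         call. = FALSE)
  amount * cpi_series[[ys[2]]] / cpi_series[[ys[1]]]
}

#' Indirect (absenteeism) cost from months of work lost
#'
#' Months absent multiplied by monthly GDP per capita — the human-capital
#' valuation used for post-surgery recovery time.
#'
#' @param absent_months non-negative months of absence.
#' @param economy an [economy_params()].
#' @return VND.
#' @export
indirect_cost <- function(absent_months, economy) {
  if (any(absent_months < 0))
    stop("`absent_months` must be non-negative", call. = FALSE)
  absent_months * economy$monthly_gdp_vnd
}

#' Discounted costs and QALYs from a cohort trace
#'
#' Accumulates, cycle by cycle, occupancy-weighted costs and utility-weighted
#' person-time, each discounted to present value:
#' `total_cost = sum_t sum_s occ[t, s] * cost(s) * df(t)` and
#' `total_qalys = sum_t sum_s occ[t, s] * utility(s) * cycle_length * df(t)`.
#' With `half_cycle = TRUE`, occupancy at cycle `t` is replaced by the
#' average of rows `t - 1` and `t` (trapezoid rule). Costs attached once per
#' state entry (`entry_costs`, e.g. a surgical procedure plus its recovery
#' costs) are charged to the entrant mass of the cycle in which entry occurs.
#'
#' @param trace a [run_cohort()] result.
#' @param costs named list, state id -> [cost_components()], covering every
#'   non-death state (per cycle of residence).
#' @param utilities named numeric vector, state id -> utility in [0, 1],
#'   covering every non-death state. Death, if present, must be 0.
#' @param discount a [discount_spec()].
#' @param half_cycle logical; trapezoidal (mid-cycle) accrual.
#' @param entry_costs optional named list, state id -> [cost_components()],
#'   charged once on entry into the state.
#' @param strategy optional strategy label carried into the result.
#' @return An object of class `cea_result`: `total_cost`, `total_qalys`,
#'   `strategy` label, and a per-cycle `breakdown` data frame whose `cost`
#'   and `qaly` columns sum to the totals.
#' @seealso [compare_strategies()]
#' @export
cea_accumulate <- function(trace, costs, utilities, discount = discount_spec(),
                           half_cycle = FALSE, entry_costs = NULL,
                           strategy = NA_character_) {
  stopifnot(inherits(trace, "cohort_trace"))
  st <- trace$states
  live <- st$id[st$kind != "death"]
  dead <- st$id[st$kind == "death"]
  miss <- setdiff(live, names(costs))
  if (length(miss))
    stop("missing cost entry for state(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(live, names(utilities))
  if (length(miss))
    stop("missing utility for state(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  u <- numeric(nrow(st)); names(u) <- st$id
  u[names(utilities)[names(utilities) %in% st$id]] <-
    unlist(utilities[names(utilities) %in% st$id])
  if (any(u < 0 | u > 1))
    stop("utilities must lie in [0, 1]", call. = FALSE)
  if (length(dead) && !is.na(u[dead]) && u[dead] != 0)
    stop("death utility must be 0", call. = FALSE)
  cvec <- numeric(nrow(st)); names(cvec) <- st$id
  for (s in names(costs)) if (s %in% st$id) {
    cc <- costs[[s]]
    cvec[s] <- if (inherits(cc, "cost_components")) cc$total else sum(unlist(cc))
  }
  if (length(dead) && cvec[dead] != 0)
    stop("death state cost must be 0", call. = FALSE)
  evec <- numeric(nrow(st)); names(evec) <- st$id
  for (s in names(entry_costs)) if (s %in% st$id) {
    cc <- entry_costs[[s]]
    evec[s] <- if (inherits(cc, "cost_components")) cc$total else sum(unlist(cc))
  }

  occ <- trace$occupancy
  Tn <- nrow(occ) - 1L
  w <- occ[2:(Tn + 1L), , drop = FALSE]
  if (half_cycle)
    w <- (occ[1:Tn, , drop = FALSE] + w) / 2
  df <- discount_factor(discount, seq_len(Tn), trace$cycle_length)
  cost_cyc <- as.numeric(w %*% cvec) * df +
    as.numeric(trace$entrants %*% evec) * df
  qaly_cyc <- as.numeric(w %*% u) * trace$cycle_length * df
  breakdown <- data.frame(cycle = seq_len(Tn), discount = df,
                          cost = cost_cyc, qaly = qaly_cyc)
  structure(list(strategy = strategy,
                 total_cost = sum(cost_cyc), total_qalys = sum(qaly_cyc),
                 breakdown = breakdown, half_cycle = half_cycle,
                 discount = discount),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("CEA result", if (!is.na(x$strategy)) paste0("[", x$strategy, "]"), "\n")
  cat(sprintf("  discounted cost : %s VND\n  discounted QALYs: %.4f\n",
              format(round_half_up(x$total_cost), big.mark = ","),
              x$total_qalys))
  invisible(x)
}

#' Incremental comparison of two strategies
#'
#' Computes `delta_cost = cost_a - cost_b` and `delta_qaly = qaly_a -
#' qaly_b` and resolves the cost-effectiveness plane quadrant:
#' \describe{
#'   \item{`icer`}{numeric ICER `delta_cost / delta_qaly` when strategy *a*
#'     costs more and yields more QALYs, or when it costs less *and* yields
#'     fewer (the south-west quadrant, reported as savings per QALY forgone
#'     and flagged via `savings_per_qaly_forgone`).}
#'   \item{`dominant`}{*a* is no more expensive and strictly more effective.}
#'   \item{`dominated`}{*a* is no less expensive and strictly less effective.}
#'   \item{`undefined`}{equal QALYs — no meaningful ratio.}
#' }
#' Raw deltas are always reported, so no information is hidden behind the
#' labels; this avoids the classic ambiguity of signed negative ICERs.
#'
#' @param a,b two [cea_accumulate()] results (computed under identical
#'   discounting and horizon settings — caller's responsibility), or bare
#'   lists with `total_cost` and `total_qalys` (so published cost/QALY pairs
#'   can be compared directly).
#' @return An object of class `cea_comparison`: `strategy_a`, `strategy_b`,
#'   `delta_cost`, `delta_qaly`, `icer` (NA when labelled), `label` (one of
#'   `"icer"`, `"dominant"`, `"dominated"`, `"undefined"`) and
#'   `savings_per_qaly_forgone`.
#' @examples
#' a <- list(total_cost = 348133295, total_qalys = 100.7445)
#' b <- list(total_cost = 314758471, total_qalys = 56.9374)
#' compare_strategies(a, b)$icer  # ~761,858 VND/QALY
#' @export
compare_strategies <- function(a, b) {
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qalys - b$total_qalys
  flag <- FALSE
  if (dq == 0) {
    label <- "undefined"; icer <- NA_real_
  } else if (dc <= 0 && dq > 0) {
    label <- "dominant"; icer <- NA_real_
  } else if (dc >= 0 && dq < 0) {
    label <- "dominated"; icer <- NA_real_
  } else if (dc > 0 && dq > 0) {
    label <- "icer"; icer <- dc / dq
  } else { # dc < 0 && dq < 0: savings per QALY forgone
    label <- "icer"; icer <- dc / dq; flag <- TRUE
  }
  structure(list(strategy_a = if (is.null(a$strategy)) NA_character_ else a$strategy,
                 strategy_b = if (is.null(b$strategy)) NA_character_ else b$strategy,
                 delta_cost = dc, delta_qaly = dq, icer = icer,
                 label = label, savings_per_qaly_forgone = flag),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  hdr <- if (!is.na(x$strategy_a)) paste(x$strategy_a, "vs", x$strategy_b) else ""
  cat("Incremental comparison", hdr, "\n")
  cat(sprintf("  dCost : %s VND\n  dQALY : %.4f\n",
              format(round_half_up(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (x$label == "icer")
    cat(sprintf("  ICER  : %s VND/QALY%s\n",
                format(round_half_up(x$icer), big.mark = ","),
                if (x$savings_per_qaly_forgone) " (savings per QALY forgone)" else ""))
  else
    cat("  label :", x$label, "\n")
  invisible(x)
}

#' Willingness-to-pay classification against GDP-per-capita thresholds
#'
#' Applies the GDP-anchored rule: an ICER below 1x GDP per capita is highly
#' cost-effective, between 1x and 3x cost-effective, above 3x not
#' cost-effective. Values exactly at a threshold fall in the middle band by
#' default (`boundary = "middle"`); `boundary = "favourable"` assigns them to
#' the cheaper class instead. A dominant strategy is classified
#' `highly_cost_effective`; a dominated or QALY-neutral one (and the
#' savings-per-QALY-forgone quadrant, where a cost-per-QALY-gained rule does
#' not apply) is `not_applicable`.
#'
#' @param comparison a [compare_strategies()] result.
#' @param economy an [economy_params()].
#' @param boundary how exact multiples of GDP are classified.
#' @return One of `"highly_cost_effective"`, `"cost_effective"`,
#'   `"not_cost_effective"`, `"not_applicable"`.
#' @export
wtp_classify <- function(comparison, economy,
                         boundary = c("middle", "favourable")) {
  boundary <- match.arg(boundary)
  if (comparison$label == "dominant") return("highly_cost_effective")
  if (comparison$label != "icer" || comparison$savings_per_qaly_forgone)
    return("not_applicable")
  g <- economy$gdp_per_capita_vnd
  icer <- comparison$icer
  if (boundary == "middle") {
    if (icer < g) "highly_cost_effective"
    else if (icer <= 3 * g) "cost_effective"
    else "not_cost_effective"
  } else {
    if (icer <= g) "highly_cost_effective"
    else if (icer <= 3 * g) "cost_effective"
    else "not_cost_effective"
  }
}
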