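#' Cost-utility analysis of sequential treatment strategies
#'
#' The package's central driver: builds each requested strategy's transition
#' matrix, runs the closed cohort over the model horizon, accumulates
#' discounted costs and QALYs, and forms every requested pairwise
#' incremental comparison with ICER/dominance resolution and
#' willingness-to-pay classification.
#'
#' @param strategies character vector of sequence codes (resolved against
#'   `inputs$sequences`), or a named list of treatment-name vectors for
#'   custom sequences.
#' @param inputs a `cua_inputs` object ([oa_inputs()] by default, or a
#'   [random_model()] instance).
#' @param comparisons `"all_pairs"` (every later strategy against every
#'   earlier one, the default), `"vs_first"`, or a list of `c(a, b)` pairs.
#' @param half_cycle logical; accrue costs and QALYs with the half-cycle
#'   (trapezoidal) correction. Default `FALSE` (cycle-end accrual).
#' @return An object of class `cua`: list with
#'   \describe{
#'     \item{results}{named list of `cea_result` objects, one per strategy.}
#'     \item{cea}{data frame: strategy, total cost (VND and USD), QALYs.}
#'     \item{comparisons}{data frame of pairwise deltas, ICER/label and WTP
#'       class.}
#'     \item{traces}{named list of `cohort_trace` objects.}
#'     \item{inputs, half_cycle}{the call's settings.}
#'   }
#' @examples
#' fit <- cua(c("PD", "PGD"))
#' summary(fit)
#' @export
cua <- function(strategies, inputs = oa_inputs(), comparisons = "all_pairs",
                half_cycle = FALSE) {
  stopifnot(inherits(inputs, "cua_inputs"))
  if (is.list(strategies)) {
    if (is.null(names(strategies)) || any(names(strategies) == ""))
      stop("custom strategy lists must be named", call. = FALSE)
    regs <- lapply(names(strategies), function(nm) {
      r <- build_regimen(strategies[[nm]], inputs); r$code <- nm; r
    })
    names(regs) <- names(strategies)
  } else {
    regs <- lapply(strategies, build_regimen, inputs = inputs)
    names(regs) <- strategies
  }
  ch <- inputs$cohort
  results <- list(); traces <- list()
  for (nm in names(regs)) {
    reg <- regs[[nm]]
    tm <- to_transition_matrix(reg)
    spec <- cohort_spec(ch$start_age, ch$life_expectancy, ch$cycle_length,
                        initial_state = reg$states$id[1],
                        cohort_mass = if (is.null(ch$cohort_mass)) 1 else ch$cohort_mass)
    tr <- run_cohort(tm, spec)
    cts <- regimen_cost_tables(reg)
    results[[nm]] <- cea_accumulate(tr, cts$per_cycle, regimen_utilities(reg),
                                    discount = inputs$discount,
                                    half_cycle = half_cycle,
                                    entry_costs = cts$on_entry, strategy = nm)
    traces[[nm]] <- tr
  }
  cea <- data.frame(
    strategy = names(results),
    total_cost_vnd = vapply(results, `[[`, 0, "total_cost"),
    total_cost_usd = vapply(results, function(r)
      vnd_to_usd(r$total_cost, inputs$economy$exchange_rate), 0),
    total_qalys = vapply(results, `[[`, 0, "total_qalys"),
    row.names = NULL, stringsAsFactors = FALSE)

  pairs <- resolve_pairs(comparisons, names(results))
  comp <- lapply(pairs, function(p) {
    cmp <- compare_strategies(results[[p[1]]], results[[p[2]]])
    data.frame(strategy = p[1], comparator = p[2],
               delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
               icer = cmp$icer, label = cmp$label,
               savings_per_qaly_forgone = cmp$savings_per_qaly_forgone,
               wtp_class = wtp_classify(cmp, inputs$economy),
               stringsAsFactors = FALSE)
  })
  comp <- if (length(comp)) do.call(rbind, comp) else
    data.frame(strategy = character(0), comparator = character(0),
               delta_cost = numeric(0), delta_qaly = numeric(0),
               icer = numeric(0), label = character(0),
               savings_per_qaly_forgone = logical(0),
               wtp_class = character(0), stringsAsFactors = FALSE)
  structure(list(results = results, cea = cea, comparisons = comp,
                 traces = traces, inputs = inputs, half_cycle = half_cycle),
            class = "cua")
}

resolve_pairs <- function(comparisons, nms) {
  if (identical(comparisons, "all_pairs")) {
    if (length(nms) < 2) return(list())
    idx <- utils::combn(length(nms), 2, simplify = FALSE)
    lapply(idx, function(ij) c(nms[ij[2]], nms[ij[1]]))
  } else if (identical(comparisons, "vs_first")) {
    lapply(nms[-1], function(a) c(a, nms[1]))
  } else if (is.list(comparisons)) {
    comparisons <- lapply(comparisons, function(p) as.character(unlist(p)))
    for (p in comparisons)
      if (length(p) != 2 || !all(p %in% nms))
        stop("comparison pairs must be length-2 subsets of the strategies",
             call. = FALSE)
    comparisons
  } else stop("invalid `comparisons`", call. = FALSE)
}

#' @export
print.cua <- function(x, ...) {
  cat("Cost-utility analysis:", nrow(x$cea), "strategies,",
      nrow(x$comparisons), "comparisons",
      if (x$half_cycle) "(half-cycle corrected)", "\n\n")
  df <- x$cea
  df$total_cost_vnd <- format(round_half_up(df$total_cost_vnd), big.mark = ",")
  df$total_cost_usd <- sprintf("%.2f", round_half_up(df$total_cost_usd, 2))
  df$total_qalys <- sprintf("%.4f", df$total_qalys)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cua <- function(object, ...) {
  structure(list(cea = object$cea, comparisons = object$comparisons,
                 half_cycle = object$half_cycle,
                 economy = object$inputs$economy), class = "summary.cua")
}

#' @export
print.summary.cua <- function(x, ...) {
  cat("Strategies:\n")
  df <- x$cea
  df$total_cost_vnd <- format(round_half_up(df$total_cost_vnd), big.mark = ",")
  df$total_cost_usd <- sprintf("%.2f", round_half_up(df$total_cost_usd, 2))
  df$total_qalys <- sprintf("%.4f", df$total_qalys)
  print(df, row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\nIncremental comparisons (WTP thresholds at 1x and 3x GDP/capita =",
        format(x$economy$gdp_per_capita_vnd, big.mark = ","), "VND):\n")
    cf <- x$comparisons
    cf$delta_cost <- format(round_half_up(cf$delta_cost), big.mark = ",")
    cf$delta_qaly <- sprintf("%.4f", cf$delta_qaly)
    cf$icer <- ifelse(is.na(cf$icer), cf$label,
                      format(round_half_up(cf$icer), big.mark = ","))
    print(cf[, c("strategy", "comparator", "delta_cost", "delta_qaly",
                 "icer", "wtp_class")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.cua <- function(x, which = c("cea", "comparisons"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Cost-effectiveness plane of a fitted analysis
#'
#' Plots each strategy's discounted total cost against its QALYs (base
#' graphics), labelling points by strategy code.
#'
#' @param x a [cua()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cua <- function(x, ...) {
  df <- x$cea
  graphics::plot(df$total_qalys, df$total_cost_vnd / 1e6,
                 xlab = "Discounted QALYs",
                 ylab = "Discounted cost (million VND)",
                 pch = 19, ...)
  graphics::text(df$total_qalys, df$total_cost_vnd / 1e6,
                 labels = df$strategy, pos = 3, cex = 0.8)
  invisible(x)
}
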