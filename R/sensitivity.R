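#' Reference to one scalar model parameter
#'
#' Parameters are addressed by dotted path: `"<treatment>.<field>"` with
#' field one of `drug_cost`, `companion_cost`, `nonmedical_cost`,
#' `indirect_cost`, `utility`, `escalation_prob`, or `"discount.annual_rate"`.
#' Low/high excursions are clamped to the parameter's domain (probabilities
#' and utilities to [0, 1], costs and rates to non-negative values), with a
#' message when clamping bites.
#'
#' @param path dotted parameter address.
#' @param base_value the base-case value.
#' @param low,high the excursion values; must bracket `base_value`.
#' @return A list of class `param_ref`.
#' @export
param_ref <- function(path, base_value, low, high) {
  if (low > base_value || high < base_value)
    stop("`low` <= `base_value` <= `high` is required for ", path,
         call. = FALSE)
  dom <- param_domain(path)
  cl <- clamp_to_domain(c(low, high), dom)
  if (!isTRUE(all.equal(cl, c(low, high))))
    message("range for ", path, " clamped to its domain [",
            dom[1], ", ", dom[2], "]")
  structure(list(path = path, base_value = base_value,
                 low = cl[1], high = cl[2]),
            class = "param_ref")
}

param_domain <- function(path) {
  field <- sub("^.*\\.", "", path)
  if (field %in% c("utility", "escalation_prob")) c(0, 1) else c(0, Inf)
}

clamp_to_domain <- function(x, dom) pmin(pmax(x, dom[1]), dom[2])

#' Symmetric relative perturbation range for one parameter
#'
#' `base * (1 - fraction)` to `base * (1 + fraction)`, clamped to the
#' parameter's domain. The published analysis states no perturbation ranges,
#' so a +/-20% excursion is the package default.
#'
#' @param path dotted parameter address (determines the domain).
#' @param base_value base-case value.
#' @param fraction positive relative half-width (default 0.20).
#' @return A [param_ref()].
#' @examples
#' default_range("tka.utility", 0.9, 0.2)  # high clamped to 1
#' @export
default_range <- function(path, base_value, fraction = 0.20) {
  if (fraction < 0) stop("`fraction` must be non-negative", call. = FALSE)
  param_ref(path, base_value,
            low = min(base_value, base_value * (1 - fraction)),
            high = max(base_value, base_value * (1 + fraction)))
}

# write one scalar into a cua_inputs object, clamping to domain
set_param <- function(inputs, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("parameter path must be '<treatment>.<field>' or 'discount.annual_rate'",
         call. = FALSE)
  dom <- param_domain(path)
  cl <- clamp_to_domain(value, dom)
  if (cl != value)
    message("value for ", path, " clamped to its domain")
  if (parts[1] == "discount") {
    if (parts[2] != "annual_rate") stop("unknown discount field ", parts[2],
                                        call. = FALSE)
    inputs$discount$annual_rate <- cl
    return(inputs)
  }
  if (!parts[1] %in% names(inputs$treatments))
    stop("unknown treatment '", parts[1], "' in parameter path", call. = FALSE)
  if (!parts[2] %in% c("drug_cost", "companion_cost", "nonmedical_cost",
                       "indirect_cost", "utility", "escalation_prob"))
    stop("unknown field '", parts[2], "' in parameter path", call. = FALSE)
  inputs$treatments[[parts[1]]][[parts[2]]] <- cl
  inputs
}

get_param <- function(inputs, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "discount") return(inputs$discount$annual_rate)
  inputs$treatments[[parts[1]]][[parts[2]]]
}

# default tornado parameter set for a pair of strategies: utility and every
# nonzero cost component of each state appearing in either sequence
default_tornado_params <- function(inputs, comparison, fraction) {
  seqs <- lapply(comparison, function(code)
    if (code %in% names(inputs$sequences)) inputs$sequences[[code]] else code)
  states <- unique(unlist(seqs))
  refs <- list()
  for (s in states) {
    ts <- inputs$treatments[[s]]
    for (f in c("drug_cost", "companion_cost", "nonmedical_cost",
                "indirect_cost")) {
      if (ts[[f]] > 0)
        refs[[paste(s, f, sep = ".")]] <-
          default_range(paste(s, f, sep = "."), ts[[f]], fraction)
    }
    refs[[paste(s, "utility", sep = ".")]] <-
      default_range(paste(s, "utility", sep = "."), ts$utility, fraction)
  }
  unname(refs)
}

#' One-way (tornado) deterministic sensitivity analysis
#'
#' For each parameter, reruns the full pipeline — transition matrices, cohort
#' traces, discounted accumulation, incremental comparison — once at the low
#' and once at the high excursion, all other inputs held at base, and
#' records both ICERs. Entries are ranked by the absolute ICER spread
#' (descending; ties broken by parameter path). The base case is rebuilt
#' from the untouched input object for every parameter, so no perturbation
#' leaks into the next.
#'
#' If an excursion lands in a dominance quadrant its label is recorded in
#' place of a numeric ICER and the spread falls back to the distance between
#' the remaining numeric excursion and the base ICER (flagged in the `note`
#' column).
#'
#' @param inputs a `cua_inputs` object.
#' @param comparison length-2 character vector `c(strategy, comparator)`.
#' @param params list of [param_ref()]s; `NULL` (default) uses the utility
#'   and every nonzero cost component of each state in either sequence, at
#'   +/-`fraction`.
#' @param fraction default relative half-width when `params` is `NULL`.
#' @param half_cycle passed to [cua()].
#' @return An object of class `tornado`: a data frame with columns
#'   `parameter`, `base_value`, `low`, `high`, `icer_low`, `icer_high`,
#'   `label_low`, `label_high`, `spread`, `rank`, `note`, plus attributes
#'   `base_icer` and `comparison`.
#' @examples
#' \donttest{
#' tor <- tornado(oa_inputs(), c("PGD", "PD"))
#' head(tor, 3)
#' }
#' @export
tornado <- function(inputs, comparison, params = NULL, fraction = 0.20,
                    half_cycle = FALSE) {
  stopifnot(inherits(inputs, "cua_inputs"), length(comparison) == 2)
  base_fit <- cua(comparison, inputs, comparisons = list(comparison),
                  half_cycle = half_cycle)
  base_cmp <- base_fit$comparisons
  if (base_cmp$label != "icer")
    stop("base-case comparison is '", base_cmp$label,
         "', not a numeric ICER; tornado analysis requires one", call. = FALSE)
  base_icer <- base_cmp$icer
  if (is.null(params))
    params <- default_tornado_params(inputs, comparison, fraction)

  one_side <- function(path, value) {
    fit <- cua(comparison, set_param(inputs, path, value),
               comparisons = list(comparison), half_cycle = half_cycle)
    cmp <- fit$comparisons
    list(icer = cmp$icer, label = cmp$label)
  }
  rows <- lapply(params, function(p) {
    lo <- one_side(p$path, p$low)
    hi <- one_side(p$path, p$high)
    if (!is.na(lo$icer) && !is.na(hi$icer)) {
      spread <- abs(hi$icer - lo$icer); note <- ""
    } else if (!is.na(lo$icer)) {
      spread <- abs(lo$icer - base_icer); note <- "high excursion non-numeric"
    } else if (!is.na(hi$icer)) {
      spread <- abs(hi$icer - base_icer); note <- "low excursion non-numeric"
    } else {
      spread <- 0; note <- "both excursions non-numeric"
    }
    data.frame(parameter = p$path, base_value = p$base_value,
               low = p$low, high = p$high,
               icer_low = lo$icer, icer_high = hi$icer,
               label_low = lo$label, label_high = hi$label,
               spread = spread, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, base_icer = base_icer, comparison = comparison,
            class = c("tornado", "data.frame"))
}

#' @export
print.tornado <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat("One-way sensitivity:", cmp[1], "vs", cmp[2],
      sprintf("(base ICER %s VND/QALY)\n",
              format(round_half_up(attr(x, "base_icer")), big.mark = ",")))
  df <- as.data.frame(x)
  df$spread <- format(round_half_up(df$spread), big.mark = ",")
  print(df[, c("rank", "parameter", "low", "high", "spread", "note")],
        row.names = FALSE)
  invisible(x)
}

#' Horizontal-bar tornado plot
#'
#' @param x a [tornado()] result.
#' @param n_top number of top-ranked parameters to draw.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.tornado <- function(x, n_top = 10, ...) {
  df <- utils::head(as.data.frame(x), n_top)
  df <- df[rev(seq_len(nrow(df))), ]
  base <- attr(x, "base_icer")
  lo <- ifelse(is.na(df$icer_low), base, df$icer_low)
  hi <- ifelse(is.na(df$icer_high), base, df$icer_high)
  left <- pmin(lo, hi); right <- pmax(lo, hi)
  old <- graphics::par(mar = c(5, 12, 2, 2)); on.exit(graphics::par(old))
  yy <- seq_len(nrow(df))
  graphics::plot(NULL, xlim = range(c(left, right, base)),
                 ylim = c(0.5, nrow(df) + 0.5), yaxt = "n",
                 xlab = "ICER (VND/QALY)", ylab = "", ...)
  graphics::rect(left, yy - 0.35, right, yy + 0.35, col = "grey70")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = yy, labels = df$parameter, las = 1, cex.axis = 0.7)
  invisible(x)
}
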