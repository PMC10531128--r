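#' Health-state table for an ordered treatment sequence
#'
#' Builds the state table used throughout the package: an ordered set of
#' mutually exclusive health states, each of kind `"treatment"`, `"surgery"`
#' or `"death"`. The sequence is strictly ordered (patients never move to a
#' lower ordinal) and must end with exactly one absorbing death state.
#'
#' @param id character vector of unique state labels.
#' @param kind character vector, same length, each one of
#'   `"treatment"`, `"surgery"`, `"death"`.
#' @return A data frame with columns `id`, `kind` and `ordinal` (0-based
#'   position in the sequence), of class `health_states`.
#' @examples
#' health_states(c("acetaminophen", "tka", "death"),
#'               c("treatment", "surgery", "death"))
#' @export
health_states <- function(id, kind) {
  id <- as.character(id)
  kind <- match.arg(as.character(kind), c("treatment", "surgery", "death"),
                    several.ok = TRUE)
  if (length(id) != length(kind))
    stop("`id` and `kind` must have the same length", call. = FALSE)
  if (anyDuplicated(id))
    stop("state ids must be unique: ", paste(id[duplicated(id)], collapse = ", "),
         call. = FALSE)
  n_death <- sum(kind == "death")
  if (n_death != 1L)
    stop("exactly one death state is required (got ", n_death, ")", call. = FALSE)
  if (kind[length(kind)] != "death")
    stop("the death state must be last in the sequence", call. = FALSE)
  out <- data.frame(id = id, kind = kind, ordinal = seq_along(id) - 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("health_states", "data.frame")
  out
}

#' Per-cycle transition matrix over an ordered state sequence
#'
#' Couples a square matrix of per-cycle transition probabilities to its state
#' table. Rows index the source state. The chain is a no-backtracking
#' progression: probability mass may stay or move to a higher ordinal, never
#' back, and the death state is absorbing.
#'
#' Rows whose sum deviates from 1 by no more than `renorm_tol` are
#' renormalized (with a message); larger deviations are an error.
#'
#' @param states a `health_states` table.
#' @param probs numeric square matrix, `nrow(states)` on a side, rows summing
#'   to 1.
#' @param renorm_tol tolerance within which near-stochastic rows are silently
#'   repaired by renormalization (default `1e-8`).
#' @return An object of class `transition_matrix`: a list with elements
#'   `states` and `probs` (dimnames set to the state ids).
#' @seealso [validate_matrix()], [run_cohort()]
#' @export
transition_matrix <- function(states, probs, renorm_tol = 1e-8) {
  if (!inherits(states, "health_states"))
    states <- health_states(states$id, states$kind)
  probs <- as.matrix(probs)
  n <- nrow(states)
  if (!is.numeric(probs) || nrow(probs) != n || ncol(probs) != n)
    stop("`probs` must be a ", n, "x", n,
         " numeric matrix matching the state table", call. = FALSE)
  rs <- rowSums(probs)
  off <- abs(rs - 1)
  if (any(off > renorm_tol & off > 1e-12))
    stop("row(s) ", paste(which(off > renorm_tol), collapse = ", "),
         " are not stochastic (|sum - 1| > ", format(renorm_tol), ")",
         call. = FALSE)
  fix <- off > 1e-12
  if (any(fix)) {
    message("renormalizing ", sum(fix), " row(s) within ", format(renorm_tol),
            " of stochasticity")
    probs[fix, ] <- probs[fix, , drop = FALSE] / rs[fix]
  }
  dimnames(probs) <- list(states$id, states$id)
  out <- list(states = states, probs = probs)
  class(out) <- "transition_matrix"
  viol <- validate_matrix(out)
  if (length(viol))
    stop("invalid transition matrix:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  out
}

#' Check the structural invariants of a transition matrix
#'
#' Validates row-stochasticity, probability bounds, the no-backtracking
#' (upper-triangular-plus-diagonal) structure, and absorption of the death
#' state. A dimension mismatch between the state table and the probability
#' array is a structural error (stop), not a reported violation.
#'
#' @param matrix a `transition_matrix` (or a bare list with `states` and
#'   `probs` elements, which allows validating hand-built candidates).
#' @param tol tolerance on row sums (default `1e-12`).
#' @return Character vector of human-readable violation descriptions; empty
#'   when all invariants hold.
#' @examples
#' st <- health_states(c("a", "death"), c("treatment", "death"))
#' validate_matrix(list(states = st, probs = diag(2)))  # character(0)
#' @export
validate_matrix <- function(matrix, tol = 1e-12) {
  states <- matrix$states
  probs <- matrix$probs
  n <- nrow(states)
  if (!is.matrix(probs) || !is.numeric(probs) || nrow(probs) != n ||
      ncol(probs) != n)
    stop("dimension mismatch: `probs` must be a numeric ", n, "x", n,
         " matrix for ", n, " states", call. = FALSE)
  viol <- character(0)
  rs <- rowSums(probs)
  for (i in which(abs(rs - 1) > tol))
    viol <- c(viol, sprintf("row %d (%s) sums to %.15g, not 1", i,
                            states$id[i], rs[i]))
  bad <- which(probs < 0 | probs > 1, arr.ind = TRUE)
  for (k in seq_len(nrow(bad)))
    viol <- c(viol, sprintf("entry [%d,%d] = %g outside [0, 1]",
                            bad[k, 1], bad[k, 2], probs[bad[k, 1], bad[k, 2]]))
  # no-backtracking: target ordinal below source ordinal must be exactly 0
  back <- which(lower.tri(probs) & probs != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(back)))
    viol <- c(viol, sprintf(
      "backward transition: probs[%d,%d] = %g but %s precedes %s",
      back[k, 1], back[k, 2], probs[back[k, 1], back[k, 2]],
      states$id[back[k, 2]], states$id[back[k, 1]]))
  d <- which(states$kind == "death")
  if (length(d) == 1L) {
    unit <- replace(numeric(n), d, 1)
    if (!isTRUE(all.equal(probs[d, ], unit, tolerance = tol,
                          check.attributes = FALSE)))
      viol <- c(viol, sprintf("death row (%d) is not absorbing", d))
  } else {
    viol <- c(viol, sprintf("model has %d death states, expected 1", length(d)))
  }
  viol
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Per-cycle transition matrix over", nrow(x$states), "states\n")
  print(round(x$probs, digits))
  invisible(x)
}
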