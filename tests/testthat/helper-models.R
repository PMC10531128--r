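# small builders shared across test files

two_state <- function(p = 0.4) {
  st <- health_states(c("treat", "death"), c("treatment", "death"))
  transition_matrix(st, rbind(c(1 - p, p), c(0, 1)))
}

# random valid no-backtracking matrix over n states (last = death),
# drawn with an isolated seed
random_chain <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- c(paste0("s", seq_len(n - 1)), "death")
    kinds <- c(rep("treatment", n - 2), "surgery", "death")
    st <- health_states(ids, kinds)
    P <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      w <- c(rep(0, i - 1), runif(n - i + 1))
      P[i, ] <- w / sum(w)
    }
    P[n, n] <- 1
    transition_matrix(st, P)
  })
}

# cycle-by-cycle double-loop oracle for discounted cost/QALY accumulation,
# written independently of cea_accumulate's vectorized path
accumulate_oracle <- function(trace, cost_totals, utilities, rate,
                              half_cycle = FALSE, entry_totals = NULL) {
  occ <- trace$occupancy
  ids <- trace$states$id
  Tn <- nrow(occ) - 1L
  cost <- 0; qaly <- 0
  for (t in seq_len(Tn)) {
    df <- (1 + rate)^(-t * trace$cycle_length)
    for (s in ids) {
      w <- if (half_cycle) (occ[t, s] + occ[t + 1, s]) / 2 else occ[t + 1, s]
      cost <- cost + w * cost_totals[[s]] * df
      qaly <- qaly + w * utilities[[s]] * trace$cycle_length * df
      if (!is.null(entry_totals) && !is.null(entry_totals[[s]]))
        cost <- cost + trace$entrants[t, s] * entry_totals[[s]] * df
    }
  }
  list(cost = cost, qaly = qaly)
}

# published base-case operands keyed by strategy, for ICER arithmetic tests
published <- function(code) {
  t2 <- table2_base_case()
  r <- t2[t2$strategy == code, ]
  list(strategy = code, total_cost = r$total_cost, total_qalys = r$total_qalys)
}
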