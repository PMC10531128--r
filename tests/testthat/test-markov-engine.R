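test_that("validate_matrix accepts stochastic chains and names each violation", {
  st <- health_states(c("treat", "death"), c("treatment", "death"))
  # identity rows are stochastic: never leaving treatment is not a violation
  expect_identical(validate_matrix(list(states = st, probs = diag(2))),
                   character(0))

  bad_sum <- list(states = st, probs = rbind(c(0.5, 0.4), c(0, 1)))
  v <- validate_matrix(bad_sum)
  expect_length(v, 1)
  expect_match(v, "row 1")

  st3 <- health_states(c("a", "b", "death"),
                       c("treatment", "treatment", "death"))
  back <- rbind(c(0.5, 0.5, 0), c(0, 1, 0), c(0.2, 0, 0.8))
  v <- validate_matrix(list(states = st3, probs = back))
  expect_true(any(grepl("backward", v)))
  expect_true(any(grepl("absorbing", v)))

  # dimension mismatch is structural, not a reported violation
  expect_error(validate_matrix(list(states = st3, probs = diag(2))),
               "dimension mismatch")
})

test_that("transition_matrix renormalizes near-stochastic rows and rejects worse", {
  st <- health_states(c("treat", "death"), c("treatment", "death"))
  expect_message(
    tm <- transition_matrix(st, rbind(c(0.6, 0.4 + 3e-9), c(0, 1))),
    "renormalizing")
  expect_equal(rowSums(tm$probs), c(treat = 1, death = 1))
  expect_error(transition_matrix(st, rbind(c(0.6, 0.5), c(0, 1))),
               "not stochastic")
})

test_that("run_cohort iterates the chain with the expected degenerate behaviour", {
  st <- health_states(c("treat", "death"), c("treatment", "death"))
  spec <- cohort_spec(40, 45, 0.5, "treat")

  tr <- run_cohort(transition_matrix(st, diag(2)), spec)
  for (t in seq_len(spec$horizon_cycles))
    expect_equal(tr$occupancy[t + 1, ], tr$occupancy[1, ])

  tr <- run_cohort(two_state(1), spec)
  expect_equal(unname(tr$occupancy[2, ]), c(0, 1))
  expect_equal(unname(tr$occupancy[spec$horizon_cycles + 1, ]), c(0, 1))

  expect_error(run_cohort(two_state(0.5),
                          cohort_spec(40, 45, 0.5, "nope")), "initial state")
  expect_error(cohort_spec(40, 40, 0.5, "treat"), "must exceed")
})

test_that("simulation matches the matrix-power oracle elementwise", {
  tm <- random_chain(5, seed = 42)
  spec <- cohort_spec(0, 6, 0.5, tm$states$id[1])  # 12 cycles
  tr <- run_cohort(tm, spec)
  # independent oracle: repeated multiplication to the 12th matrix power
  Pk <- diag(nrow(tm$probs))
  for (k in 1:12) Pk <- Pk %*% tm$probs
  v0 <- replace(numeric(5), 1, 1)
  expect_lt(max(abs(tr$occupancy[13, ] - as.numeric(v0 %*% Pk))), 1e-10)
})

test_that("cohort traces conserve mass and absorb monotonically", {
  for (seed in 1:25) {
    n <- 3 + (seed %% 6)
    tm <- random_chain(n, seed)
    spec <- cohort_spec(0, 50, 0.5, tm$states$id[1], cohort_mass = 2)
    tr <- run_cohort(tm, spec)
    expect_lt(max(abs(rowSums(tr$occupancy) - 2)), 1e-9)
    expect_true(all(tr$occupancy >= 0))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
  }
  # with a strictly positive path to death the cohort is fully absorbed
  tm <- two_state(0.3)
  tr <- run_cohort(tm, cohort_spec(0, 200, 1, "treat"))
  expect_equal(unname(tr$occupancy[201, "death"]), 1, tolerance = 1e-12)
})

test_that("time_in_state follows both accrual conventions", {
  st <- health_states(c("treat", "death"), c("treatment", "death"))
  tr <- run_cohort(transition_matrix(st, diag(2)), cohort_spec(0, 5, 0.5, "treat"))
  expect_equal(time_in_state(tr, "treat"), 5)
  expect_equal(time_in_state(tr, "treat", half_cycle = TRUE), 5)

  tr <- run_cohort(two_state(1), cohort_spec(0, 5, 0.5, "treat"))
  expect_equal(time_in_state(tr, "treat"), 0)
  expect_equal(time_in_state(tr, "treat", half_cycle = TRUE), 0.25)

  expect_error(time_in_state(tr, "nope"), "unknown state")

  # against an independent per-cycle summation, and the person-time identity
  tm <- random_chain(6, seed = 7)
  spec <- cohort_spec(0, 10, 0.5, tm$states$id[1])
  tr <- run_cohort(tm, spec)
  total <- 0
  for (s in tm$states$id) {
    direct <- sum(vapply(1:20, function(t) tr$occupancy[t + 1, s], 0)) * 0.5
    expect_equal(time_in_state(tr, s), direct, tolerance = 1e-12)
    total <- total + time_in_state(tr, s)
  }
  expect_equal(total, spec$horizon_cycles * 0.5, tolerance = 1e-12)
})
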