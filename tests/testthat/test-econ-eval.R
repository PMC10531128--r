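test_that("discount_factor has the closed form and its limits", {
  expect_equal(discount_factor(discount_spec(0.03), 0, 0.5), 1)
  expect_equal(discount_factor(discount_spec(0), 17, 0.5), 1)
  expect_equal(discount_factor(discount_spec(0.03), 2, 0.5), 1 / 1.03)
  f <- discount_factor(discount_spec(0.03), 0:40, 0.5)
  expect_true(all(diff(f) < 0) && all(f > 0) && all(f <= 1))
  expect_error(discount_factor(discount_spec(0.03), -1, 0.5), "non-negative")
})

test_that("cea_accumulate reduces to person-time identities in the flat case", {
  st <- health_states(c("treat", "death"), c("treatment", "death"))
  tr <- run_cohort(transition_matrix(st, diag(2)), cohort_spec(0, 10, 0.5, "treat"))
  res <- cea_accumulate(tr, list(treat = cost_components(), death = cost_components()),
                        c(treat = 1, death = 0), discount_spec(0))
  expect_equal(res$total_qalys, 10)
  expect_equal(res$total_cost, 0)
  res <- cea_accumulate(tr, list(treat = cost_components(), death = cost_components()),
                        c(treat = 0.5, death = 0), discount_spec(0))
  expect_equal(res$total_qalys, 5)
  expect_error(cea_accumulate(tr, list(death = cost_components()),
                              c(treat = 1, death = 0), discount_spec(0)),
               "missing cost")
  expect_error(cea_accumulate(tr, list(treat = cost_components(), death = cost_components()),
                              c(treat = 1.2, death = 0), discount_spec(0)),
               "utilities")
})

test_that("cea_accumulate matches the double-loop oracle, with and without corrections", {
  tm <- random_chain(4, seed = 11)
  ids <- tm$states$id
  tr <- run_cohort(tm, cohort_spec(0, 8, 0.5, ids[1]))
  costs <- list()
  ct <- c(123456, 98765, 55555, 0); names(ct) <- ids
  ut <- c(0.8, 0.6, 0.7, 0); names(ut) <- ids
  for (s in ids[1:3]) costs[[s]] <- cost_components(direct_medical = ct[[s]])
  costs[[ids[4]]] <- cost_components()
  entry <- list(); entry[[ids[3]]] <- cost_components(direct_medical = 7e6)
  et <- c(0, 0, 7e6, 0); names(et) <- ids
  for (hc in c(FALSE, TRUE)) {
    res <- cea_accumulate(tr, costs, ut, discount_spec(0.03), half_cycle = hc,
                          entry_costs = entry)
    orc <- accumulate_oracle(tr, as.list(ct), as.list(ut), 0.03,
                             half_cycle = hc, entry_totals = as.list(et))
    expect_equal(res$total_cost, orc$cost, tolerance = 1e-9)
    expect_equal(res$total_qalys, orc$qaly, tolerance = 1e-9)
    # the per-cycle breakdown reconstitutes the totals
    expect_equal(sum(res$breakdown$cost), res$total_cost, tolerance = 1e-6)
    expect_equal(sum(res$breakdown$qaly), res$total_qalys, tolerance = 1e-6)
  }
})

test_that("accumulation is linear in utilities and costs, and discounting shrinks totals", {
  tm <- random_chain(4, seed = 3)
  ids <- tm$states$id
  tr <- run_cohort(tm, cohort_spec(0, 8, 0.5, ids[1]))
  costs <- list()
  for (s in ids[1:3]) costs[[s]] <- cost_components(direct_medical = 1e6, indirect = 2e5)
  costs[[ids[4]]] <- cost_components()
  ut <- c(0.9, 0.5, 0.4, 0); names(ut) <- ids
  base <- cea_accumulate(tr, costs, ut, discount_spec(0.03))
  halfu <- cea_accumulate(tr, costs, ut / 2, discount_spec(0.03))
  expect_equal(halfu$total_qalys, base$total_qalys / 2, tolerance = 1e-12)
  costs2 <- lapply(costs, function(cc)
    cost_components(cc$direct_medical * 3, cc$direct_nonmedical * 3, cc$indirect * 3))
  triple <- cea_accumulate(tr, costs2, ut, discount_spec(0.03))
  expect_equal(triple$total_cost, base$total_cost * 3, tolerance = 1e-12)
  undisc <- cea_accumulate(tr, costs, ut, discount_spec(0))
  expect_gt(undisc$total_cost, base$total_cost)
  expect_gt(undisc$total_qalys, base$total_qalys)
})

test_that("compare_strategies reproduces published incremental ratios", {
  cmp <- compare_strategies(published("PGD"), published("PD"))
  expect_equal(cmp$delta_cost, 33374824)
  expect_equal(cmp$delta_qaly, 43.8071, tolerance = 1e-10)
  expect_equal(cmp$icer, 761858, tolerance = 1e-5)
  expect_identical(cmp$label, "icer")
  expect_false(cmp$savings_per_qaly_forgone)

  cmp <- compare_strategies(published("PDEG"), published("PDE"))
  expect_equal(cmp$icer, 705735, tolerance = 1e-5)
})

test_that("compare_strategies resolves every quadrant and is antisymmetric", {
  mk <- function(c, q) list(total_cost = c, total_qalys = q)
  expect_identical(compare_strategies(mk(90, 11), mk(100, 10))$label, "dominant")
  expect_true(is.na(compare_strategies(mk(90, 11), mk(100, 10))$icer))
  expect_identical(compare_strategies(mk(110, 9), mk(100, 10))$label, "dominated")
  expect_identical(compare_strategies(mk(110, 10), mk(100, 10))$label, "undefined")
  sw <- compare_strategies(mk(90, 9), mk(100, 10))
  expect_identical(sw$label, "icer")
  expect_true(sw$savings_per_qaly_forgone)
  expect_equal(sw$icer, 10)

  ab <- compare_strategies(mk(130, 12), mk(100, 10))
  ba <- compare_strategies(mk(100, 10), mk(130, 12))
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_qaly, -ba$delta_qaly)
  expect_equal(ab$icer, ba$icer)  # identical under swap when both deltas flip
})

test_that("WTP classification follows the GDP bands and is monotone", {
  eco <- economy_params(3756, 23486)
  g <- eco$gdp_per_capita_vnd
  mk <- function(icer) structure(list(icer = icer, label = "icer",
                                      savings_per_qaly_forgone = FALSE),
                                 class = "cea_comparison")
  expect_identical(wtp_classify(mk(761858), eco), "highly_cost_effective")
  expect_identical(wtp_classify(mk(2 * g), eco), "cost_effective")
  expect_identical(wtp_classify(mk(4 * g), eco), "not_cost_effective")
  # boundaries fall in the middle band by default, favourable moves them down
  expect_identical(wtp_classify(mk(g), eco), "cost_effective")
  expect_identical(wtp_classify(mk(3 * g), eco), "cost_effective")
  expect_identical(wtp_classify(mk(g), eco, boundary = "favourable"),
                   "highly_cost_effective")
  # dominance handling
  dom <- structure(list(icer = NA_real_, label = "dominant",
                        savings_per_qaly_forgone = FALSE), class = "cea_comparison")
  expect_identical(wtp_classify(dom, eco), "highly_cost_effective")
  dom$label <- "dominated"
  expect_identical(wtp_classify(dom, eco), "not_applicable")
  # monotone: raising the ICER never improves the class
  lvl <- c(highly_cost_effective = 1, cost_effective = 2, not_cost_effective = 3)
  cls <- lvl[vapply(seq(0.1, 5, by = 0.1) * g,
                    function(x) wtp_classify(mk(x), eco), "")]
  expect_true(all(diff(cls) >= 0))
})

test_that("currency, CPI and absenteeism arithmetic are exact where printed", {
  expect_identical(usd_to_vnd(3756, 23486), 88213416)
  expect_identical(usd_to_vnd(0, 23486), 0)
  expect_equal(vnd_to_usd(186300, 23486), 7.93, tolerance = 1e-3)
  expect_error(usd_to_vnd(1, 0), "positive")

  cpi <- c("2019" = 100, "2021" = 107)
  expect_equal(cpi_adjust(5e5, 2021, 2021, cpi), 5e5)
  expect_equal(cpi_adjust(1e6, 2019, 2021, cpi), 1070000)
  expect_equal(cpi_adjust(1e6, 2019, 2021, c("2019" = 50, "2021" = 100)), 2e6)
  expect_error(cpi_adjust(1e6, 2018, 2021, cpi), "missing")

  eco <- economy_params(3756, 23486)
  expect_equal(eco$monthly_gdp_vnd, 88213416 / 12)
  expect_equal(indirect_cost(0, eco), 0)
  expect_equal(indirect_cost(1, eco), 7351118)
  expect_equal(indirect_cost(2, eco), 2 * indirect_cost(1, eco))
  expect_error(indirect_cost(-1, eco), "non-negative")
})
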