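test_that("discounting matches the closed form and its identities", {
  expect_equal(discount(100, 1, 0.05), 100 / 1.05)
  expect_equal(discount(100, 1, 0.05), 95.2381, tolerance = 1e-6)
  expect_equal(discount(1, 50, 0.05), 1.05^-50)
  expect_equal(discount(1, 50, 0.05), 0.087204, tolerance = 1e-5)
  expect_equal(discount(123.45, 30, 0), 123.45)
  expect_equal(discount(7, 0, 0.2), 7)
  expect_error(discount(1, -1, 0.05), "non-negative")
  expect_error(discount(1, 1, 1), "rate")
})

test_that("annual utility follows health state, age band and survivorship", {
  p <- default_parameters()
  coh <- flat_cohort(6, age = 60)
  coh$age <- c(60L, 82L, 75L, 60L, 60L, 60L)
  coh$health_state <- factor(
    c("free_of_disease", "free_of_disease", "low_risk_adenoma",
      "CRC_D", "CRC_A", "CRC_B"),
    levels = levels(coh$health_state))
  coh$diagnosed <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  coh$dx_stage <- factor(c(NA, "A", NA, "D", NA, "B"),
                         levels = c("A", "B", "C", "D"))
  coh$years_since_diagnosis <- c(NA, 7L, NA, 1L, NA, 6L)
  u <- annual_utility(coh, p)
  expect_equal(u, c(
    0.80, # free of disease, 50-69 norm
    0.70, # survivor (>5 years post diagnosis), 80+ norm
    0.76, # adenoma carries the norm, 70-79 band
    0.68, # stage D
    0.74, # undiagnosed stage A still carries the stage utility
    0.80  # survivor at 60
  ))
  dead <- coh
  dead$health_state <- factor("dead", levels = levels(coh$health_state))
  expect_equal(annual_utility(dead, p), rep(0, 6))
})

test_that("event-log accumulation reprices the published unit costs", {
  p <- default_parameters()
  # one returned negative kit, undiscounted: 8.00 + 2.40 + 17.85
  ev <- tibble::tibble(
    id = 1L, year = 0L,
    kind = c("kit_sent", "kit_returned_negative"),
    stage = NA_character_, value = NA_real_
  )
  res <- accumulate(ev, p, rate = 0, n = 1)
  expect_equal(res$cost_pp, 8.00 + 2.40 + 17.85)
  expect_equal(res$cost_pp, 28.25)
  expect_equal(res$qaly_pp, 0)

  # a stage-B diagnosis at year 0 adds the stage-B treatment cost
  ev_b <- tibble::tibble(id = 1L, year = 0L, kind = "symptomatic_diagnosis",
                         stage = "B", value = NA_real_)
  expect_equal(accumulate(ev_b, p, rate = 0, n = 1)$cost_pp, 52594)

  # alive one cycle at 55 with no events: 0.80 QALYs, zero cost
  ev_u <- tibble::tibble(id = 1L, year = 0L, kind = "utility",
                         stage = NA_character_, value = 0.80)
  res_u <- accumulate(ev_u, p, rate = 0, n = 1)
  expect_equal(res_u$qaly_pp, 0.80)
  expect_equal(res_u$cost_pp, 0)

  expect_error(
    accumulate(tibble::tibble(id = 1L, year = 0L, kind = "teleport",
                              stage = NA_character_, value = NA_real_), p),
    "no cost mapping")
})

test_that("engine accrual agrees with independent event-log accumulation", {
  p <- default_parameters("arabic")
  scen <- scenario("audit", "arabic", p, uplift_pp = 0,
                   intervention_cost_total = 0)
  cen <- gen_census_tables("arabic")
  coh <- sample_cohort(interpolate_population(cen, 2019), 400, seed = 8)
  arm <- run_arm(p, scen, horizon = 50, seed = 12, cohort = coh,
                 log_events = TRUE)
  acc <- accumulate(arm$events, p, rate = p$utilities$discount_rate, n = 400)
  expect_equal(acc$cost_pp, arm$cost_pp, tolerance = 1e-10)
  expect_equal(acc$qaly_pp, arm$qaly_pp, tolerance = 1e-10)
  expect_equal(acc$cost_pp_undisc, arm$cost_pp_undisc, tolerance = 1e-10)
  expect_equal(acc$qaly_pp_undisc, arm$qaly_pp_undisc, tolerance = 1e-10)
  expect_equal(acc$detected, arm$detected)
  expect_equal(acc$crc_cases, arm$crc_cases)
  expect_equal(acc$crc_deaths, arm$crc_deaths)
})

test_that("per-person intervention cost division matches the published figures", {
  expect_equal(intervention_cost_per_person(120863, 17522), 6.90)
  expect_equal(intervention_cost_per_person(120337, 38660), 3.11)
  expect_equal(intervention_cost_per_person(0, 1000), 0)
  expect_error(intervention_cost_per_person(1, 0), "positive")
})

test_that("ICER arithmetic, dominance and threshold logic", {
  arm <- function(c, q) structure(list(cost_pp = c, qaly_pp = q, detected = 0L),
                                  class = "arm_result")
  r <- compute_icer(arm(100, 10), arm(110, 10.01))
  expect_equal(r$icer, 1000)
  expect_equal(r$dominance, "tradeoff")
  expect_true(r$below_wtp)

  # published Mandarin incrementals: 9.94 / 0.010
  r2 <- compute_icer(arm(0, 0), arm(9.94, 0.010))
  expect_equal(r2$icer, 994)

  r3 <- compute_icer(arm(100, 10), arm(90, 10.5))
  expect_equal(r3$dominance, "dominant")
  expect_true(r3$below_wtp)

  r4 <- compute_icer(arm(100, 10), arm(100, 10))
  expect_true(is.na(r4$icer))
  expect_equal(r4$dominance, "undefined")

  # brute-force four-quadrant classification on random pairs
  set.seed(13)
  for (i in 1:200) {
    dc <- stats::runif(1, -10, 10)
    dq <- stats::runif(1, -0.01, 0.01)
    got <- compute_icer(arm(0, 0), arm(dc, dq))$dominance
    want <- if (dq == 0) "undefined"
      else if (dc <= 0 && dq > 0) "dominant"
      else if (dc >= 0 && dq < 0) "dominated"
      else "tradeoff"
    expect_equal(got, want)
  }
})
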