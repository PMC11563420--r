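test_that("dead individuals are absorbing and never transition", {
  p <- default_parameters()
  coh <- flat_cohort(10, age = 70)
  coh$health_state <- factor("dead", levels = levels(coh$health_state))
  coh$alive <- FALSE
  out <- step_natural_history(coh, p)
  expect_true(all(out$cohort$health_state == "dead"))
  expect_false(any(out$cohort$alive))
  expect_equal(nrow(out$events), 0)
  # age does not advance for the dead
  expect_equal(out$cohort$age, coh$age)
})

test_that("single transitions follow supplied uniform draws", {
  p <- load_parameters("arabic", life_table = zero_mortality_life_table())
  coh <- with_state(flat_cohort(1, age = 60), "high_risk_adenoma")
  u <- list(mortality = 1, crc_mortality = 1, diagnosis = 1, dx_stage = 1,
            progression = 0.049) # below the 0.05 high-risk -> CRC probability
  out <- step_natural_history(coh, p, u = u)
  expect_equal(as.character(out$cohort$health_state), "CRC_A")

  u$progression <- 0.051
  out2 <- step_natural_history(coh, p, u = u)
  expect_equal(as.character(out2$cohort$health_state), "high_risk_adenoma")
})

test_that("annual progression probabilities match the transition table", {
  p <- load_parameters("arabic", life_table = zero_mortality_life_table())
  n <- 100000
  coh <- with_state(flat_cohort(n, age = 60), "CRC_B")
  set.seed(21)
  out <- step_natural_history(coh, p)
  frac_c <- mean(out$cohort$health_state == "CRC_C")
  # CRC_B either stays, is diagnosed (stage drawn), or progresses; progression
  # only happens for the undiagnosed: P = (1 - 0.35) * 0.28
  expect_lt(abs(frac_c - (1 - 0.35) * 0.28 -
                  0.35 * p$stage_dist$not_screened[3]),
            binom_3se(0.28, n))
  # undiagnosed-only progression check, isolating the progression kernel
  p_nodx <- p
  p_nodx$sympt_dx$prob <- rep(0, 4)
  p_nodx$sympt_dx$low <- rep(0, 4)
  set.seed(22)
  out2 <- step_natural_history(coh, p_nodx)
  expect_lt(abs(mean(out2$cohort$health_state == "CRC_C") - 0.28),
            binom_3se(0.28, n))
})

test_that("symptomatic diagnosis probabilities match the published schedule", {
  p <- default_parameters()
  n <- 100000
  set.seed(31)
  for (i in seq_len(4)) {
    stg <- c("A", "B", "C", "D")[i]
    prob <- c(0.22, 0.35, 0.59, 1.00)[i]
    hits <- mean(symptomatic_diagnosis(rep(stg, n), p))
    expect_lt(abs(hits - prob), binom_3se(prob, n) + 1e-12)
  }
  # stage D is always diagnosed
  expect_true(all(symptomatic_diagnosis(rep("D", 1000), p)))
  # overriding the probability to zero suppresses diagnosis
  p0 <- p
  p0$sympt_dx$prob <- rep(0, 4)
  p0$sympt_dx$low <- rep(0, 4)
  expect_false(any(symptomatic_diagnosis(rep("A", 1000), p0)))
  expect_error(symptomatic_diagnosis("E", p), "stage")
})

test_that("post-diagnosis survival reproduces cumulative 5-year targets", {
  targets <- c(A = 0.95, B = 0.85, C = 0.65, D = 0.15)
  p <- load_parameters("arabic",
                       life_table = zero_mortality_life_table(),
                       survival = gen_survival_table(targets))
  n <- 100000
  coh <- with_state(flat_cohort(n, age = 60), "CRC_D", diagnosed = TRUE,
                    ysd = 0L)
  set.seed(41)
  # the diagnosis year itself carries no CRC hazard; years 1-5 since
  # diagnosis do, so six cycles span the full 5-year window
  for (i in 1:6) coh <- survival_step(coh, p)
  expect_lt(abs(mean(coh$alive) - 0.15), binom_3se(0.15, n))

  # CRC hazard is zero beyond five years since diagnosis
  coh6 <- with_state(flat_cohort(1000, age = 60), "CRC_D", diagnosed = TRUE,
                     ysd = 6L)
  out <- survival_step(coh6, p)
  expect_true(all(out$alive))

  # survival fixture of 1 in year 1 produces no CRC deaths that year
  p1 <- load_parameters("arabic", life_table = zero_mortality_life_table(),
                        survival = gen_survival_table(c(A = 1, B = 1, C = 1, D = 1)))
  cohy1 <- with_state(flat_cohort(1000, age = 60), "CRC_D", diagnosed = TRUE,
                      ysd = 1L)
  expect_true(all(survival_step(cohy1, p1)$alive))
})

test_that("with zero incidence and mortality everyone stays disease-free", {
  p <- load_parameters("arabic",
                       adenoma_incidence = zero_incidence_schedule(),
                       progressive_fraction = 0.24,
                       life_table = zero_mortality_life_table())
  coh <- flat_cohort(2000, age = 50)
  set.seed(51)
  scen <- scenario("none", "arabic", p, participation_rate = 0,
                   intervention_cost_total = 0)
  arm <- run_arm(p, scen, horizon = 49, seed = 3, cohort = coh)
  occ <- arm$occupancy
  expect_equal(occ[nrow(occ), "free_of_disease"], 2000, ignore_attr = TRUE)
  expect_equal(arm$crc_cases, 0L)
  expect_equal(arm$crc_deaths, 0L)
})

test_that("stage never regresses before diagnosis and nobody resurrects", {
  p <- default_parameters("mandarin")
  n <- 2000
  coh <- flat_cohort(n, age = 55, seed = 2)
  stage_rank <- c(free_of_disease = 0, low_risk_adenoma = 1,
                  high_risk_adenoma = 1, CRC_A = 2, CRC_B = 3, CRC_C = 4,
                  CRC_D = 5, dead = 99)
  set.seed(61)
  prev <- coh
  for (cycle in 1:25) {
    out <- step_natural_history(prev, p)
    cur <- out$cohort
    undiag <- !prev$diagnosed & !cur$diagnosed & cur$alive
    expect_true(all(stage_rank[as.character(cur$health_state[undiag])] >=
                      stage_rank[as.character(prev$health_state[undiag])]))
    expect_false(any(!prev$alive & cur$alive))
    prev <- cur
  }
})
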