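test_that("runs are reproducible and paired arms share random numbers", {
  p <- default_parameters("arabic")
  scen <- scenario("a", "arabic", p, uplift_pp = 0, intervention_cost_total = 0)
  cen <- gen_census_tables("arabic")
  coh <- sample_cohort(interpolate_population(cen, 2019), 1000, seed = 3)

  a1 <- run_arm(p, scen, horizon = 30, seed = 7, cohort = coh)
  a2 <- run_arm(p, scen, horizon = 30, seed = 7, cohort = coh)
  expect_identical(tidy(a1), tidy(a2))
  expect_identical(a1$occupancy, a2$occupancy)

  # identical scenarios under common random numbers give identical arms,
  # so the comparison is exactly null
  cua <- run_cua(p, uplift_pp = 0, n = 1000, horizon = 30, seed = 7,
                 followup_uplift = FALSE, intervention_cost_total = 0)
  expect_equal(cua$delta_qaly, 0)
  expect_equal(cua$delta_cost, 0)
  expect_equal(cua$delta_detected, 0L)
  expect_equal(cua$dominance, "undefined")
})

test_that("microsimulation occupancy matches the matrix-product oracle", {
  q <- 0.01
  p <- make_toy_params(q = q)
  scen <- scenario("toy", "mandarin", p, participation_rate = 0,
                   intervention_cost_total = 0)
  n <- 20000
  horizon <- 20
  coh <- flat_cohort(n, age = 55, seed = 4)
  arm <- run_arm(p, scen, horizon = horizon, seed = 9, cohort = coh)

  P <- toy_oracle_matrix(p, q)
  expect_equal(rowSums(P), rep(1, 9), tolerance = 1e-12)
  expect_occupancy_matches(arm, P, n, horizon)
})

test_that("zero incidence yields no cancer and annuity-exact QALYs", {
  p <- load_parameters("arabic",
                       adenoma_incidence = zero_incidence_schedule(),
                       progressive_fraction = 0.24,
                       life_table = zero_mortality_life_table())
  p$utilities$norm$utility <- c(1, 1, 1) # unit utility isolates discounting
  scen <- scenario("none", "arabic", p, participation_rate = 0,
                   intervention_cost_total = 0)
  coh <- flat_cohort(50, age = 55)
  horizon <- 30
  arm <- run_arm(p, scen, horizon = horizon, seed = 10, cohort = coh)
  expect_equal(arm$crc_cases, 0L)
  expect_equal(arm$detected, 0L)
  # discounted QALYs equal the closed-form annuity; undiscounted equal years
  expect_equal(arm$qaly_pp, sum(1 / 1.05^(0:(horizon - 1))), tolerance = 1e-12)
  expect_equal(arm$qaly_pp_undisc, horizon, tolerance = 1e-12)

  # 0% discounting reproduces undiscounted sums exactly
  arm0 <- run_arm(p, scen, horizon = horizon, seed = 10, cohort = coh,
                  discount_rate = 0)
  expect_equal(arm0$qaly_pp, arm0$qaly_pp_undisc)
  expect_equal(arm0$cost_pp, arm0$cost_pp_undisc)
})

test_that("QALY totals strictly decrease as the discount rate rises", {
  p <- default_parameters("arabic")
  sa <- run_discount_sa(p, uplift_pp = 0.2, rates = c(0, 0.035, 0.05),
                        n = 2000, horizon = 40, seed = 5)
  expect_equal(nrow(sa), 3)
  expect_true(all(diff(sa$base_qaly_pp) < 0))
  expect_true(all(diff(sa$int_qaly_pp) < 0))
  expect_true(all(is.finite(sa$delta_cost)))
})

test_that("PSA collapses to the base case under degenerate ranges", {
  p <- default_parameters("mandarin")
  spec0 <- psa_spec(n_trials = 4, n_patients = 500,
                    sample_transitions = FALSE, sample_sympt_dx = FALSE,
                    sample_treatment_costs = FALSE)
  psa <- run_psa(p, uplift_pp = 1.1, spec = spec0, horizon = 20, seed = 6)
  expect_equal(nrow(psa$trials), 4)
  # all parameters fixed: trial variation comes only from cohorts/seeds;
  # drawing with a fixed seed must be reproducible
  psa2 <- run_psa(p, uplift_pp = 1.1, spec = spec0, horizon = 20, seed = 6)
  expect_identical(psa$trials, psa2$trials)
})

test_that("validation report scales counts to population rates", {
  arm <- structure(list(crc_cases = 600L, crc_deaths = 100L, n = 10000L,
                        horizon = 50L), class = "arm_result")
  v <- validate_model(arm, population = 38660)
  expect_equal(v$simulated[v$metric == "crc_cases_per_year"],
               600 / 10000 * 38660 / 50)
  expect_true(all(c("ratio", "pass") %in% names(v)))
  # zero cases fails the benchmark and is reported, not an error
  arm0 <- structure(list(crc_cases = 0L, crc_deaths = 0L, n = 1000L,
                         horizon = 50L), class = "arm_result")
  v0 <- validate_model(arm0, population = 38660)
  expect_false(any(v0$pass))
})

test_that("tidiers and plots return well-formed objects", {
  p <- default_parameters("mandarin")
  cua <- run_cua(p, uplift_pp = 1.1, n = 500, horizon = 20, seed = 2)
  expect_s3_class(tidy(cua), "tbl_df")
  expect_equal(nrow(tidy(cua)), 2)
  g <- glance(cua)
  expect_equal(nrow(g), 1)
  expect_true(all(c("icer", "dominance", "delta_detected") %in% names(g)))

  spec <- psa_spec(n_trials = 3, n_patients = 300)
  psa <- run_psa(p, uplift_pp = 1.1, spec = spec, horizon = 15, seed = 3)
  expect_s3_class(autoplot(psa), "ggplot")
  arm <- run_cua(p, uplift_pp = 0, n = 300, horizon = 10, seed = 4)$base
  expect_s3_class(autoplot(arm), "ggplot")
  st <- summary_table(list(`+1.1 pp` = cua))
  expect_equal(ncol(st), 3)
  expect_equal(nrow(st), 6)
})
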