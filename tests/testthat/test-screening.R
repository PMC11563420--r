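test_that("invitations go out at even ages 50-74 only", {
  expect_true(invitation_due(62))
  expect_true(all(invitation_due(seq(50, 74, 2))))
  expect_false(invitation_due(75))
  expect_false(invitation_due(51))
  expect_false(invitation_due(49))
  expect_equal(invitation_due(c(50, 51, 74, 75)), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("zero participation yields kits sent but nothing downstream", {
  p <- default_parameters()
  scen <- scenario("none", "arabic", p, participation_rate = 0,
                   intervention_cost_total = 0)
  coh <- flat_cohort(5000, age = 60)
  set.seed(1)
  out <- step_screening(coh, scen, p)
  expect_equal(sort(unique(out$events$kind)), "kit_sent")
  expect_equal(sum(out$events$kind == "kit_sent"), 5000)
})

test_that("positivity and follow-up rates match the published rates", {
  p <- default_parameters()
  n <- 100000
  coh <- flat_cohort(n, age = 60)
  scen <- scenario("full", "arabic", p, participation_rate = 1,
                   intervention_cost_total = 0)
  set.seed(2)
  out <- step_screening(coh, scen, p)
  pos <- sum(out$events$kind == "kit_returned_positive")
  expect_lt(abs(pos / n - 0.064), binom_3se(0.064, n))

  colo <- sum(out$events$kind == "colonoscopy")
  declined <- sum(out$events$kind == "declined_colonoscopy")
  expect_equal(colo + declined, pos)
  expect_lt(abs(colo / pos - 0.543), binom_3se(0.543, pos))

  # decliners leave the screening track permanently
  dec_ids <- out$events$id[out$events$kind == "declined_colonoscopy"]
  expect_true(all(out$cohort$screening_track[dec_ids] == "natural_history"))

  # English-speaking rates via scenario overrides
  scen_en <- scenario("en", "arabic", p, participation_rate = 1,
                      followup_rate = 0.631, positivity_rate = 0.069,
                      intervention_cost_total = 0)
  set.seed(3)
  out_en <- step_screening(coh, scen_en, p)
  pos_en <- sum(out_en$events$kind == "kit_returned_positive")
  colo_en <- sum(out_en$events$kind == "colonoscopy")
  expect_lt(abs(pos_en / n - 0.069), binom_3se(0.069, n))
  expect_lt(abs(colo_en / pos_en - 0.631), binom_3se(0.631, pos_en))
})

test_that("colonoscopy outcomes follow the renormalised prevalence", {
  p <- default_parameters()
  n <- 100000
  set.seed(4)
  oc <- colonoscopy_outcome(n, p)
  prev <- c(0.8740, 0.0609, 0.0565, 0.0313) / 1.0227
  emp <- as.numeric(table(oc$outcome) / n)
  for (i in 1:4) expect_lt(abs(emp[i] - prev[i]), binom_3se(prev[i], n))

  # stage of screen-detected cancer: 49/19/24/8
  crc <- oc$stage[oc$outcome == "crc"]
  emp_stage <- as.numeric(table(crc) / length(crc))
  for (i in 1:4) {
    expect_lt(abs(emp_stage[i] - p$stage_dist$screened[i]),
              binom_3se(p$stage_dist$screened[i], length(crc)))
  }

  # forced 100% free of disease: no findings, no polypectomies
  p_free <- p
  p_free$colonoscopy_prevalence$prob <- c(1, 0, 0, 0)
  oc_free <- colonoscopy_outcome(1000, p_free)
  expect_true(all(oc_free$outcome == "free_of_disease"))
})

test_that("with all rates at 1 every invitee is assessed that round", {
  p <- default_parameters()
  scen <- scenario("all", "arabic", p, participation_rate = 1,
                   followup_rate = 1, positivity_rate = 1,
                   intervention_cost_total = 0)
  coh <- flat_cohort(2000, age = 60)
  set.seed(5)
  out <- step_screening(coh, scen, p)
  expect_equal(sum(out$events$kind == "colonoscopy"), 2000)
})

test_that("screen detection overwrites the latent state as specified", {
  p <- default_parameters()
  scen <- scenario("all", "arabic", p, participation_rate = 1,
                   followup_rate = 1, positivity_rate = 1,
                   intervention_cost_total = 0)
  # cohort with latent high-risk adenomas: detected adenoma -> removed ->
  # surveillance; detected cancer -> diagnosed at screened stage distribution
  coh <- with_state(flat_cohort(20000, age = 60), "high_risk_adenoma")
  set.seed(6)
  out <- step_screening(coh, scen, p)
  ad_ids <- out$events$id[out$events$kind == "adenoma_detected"]
  expect_true(all(out$cohort$health_state[ad_ids] == "free_of_disease"))
  expect_true(all(out$cohort$screening_track[ad_ids] == "surveillance"))
  free_ids <- out$events$id[out$events$kind == "no_disease"]
  expect_true(all(out$cohort$health_state[free_ids] == "free_of_disease"))
  crc_ids <- out$events$id[out$events$kind == "cancer_detected"]
  expect_true(all(out$cohort$diagnosed[crc_ids]))
})

test_that("surveillance runs five-yearly, removes adenomas, stops at 75", {
  p <- default_parameters()
  mk <- function(age, yss, state = "free_of_disease") {
    coh <- with_state(flat_cohort(100, age = age), state)
    coh$screening_track <- factor("surveillance",
                                  levels = levels(coh$screening_track))
    coh$years_since_last_surveillance <- as.integer(yss)
    coh
  }
  # due this year (5th year since last)
  out <- step_surveillance(mk(70, 4, "low_risk_adenoma"), p)
  expect_equal(sum(out$events$kind == "surveillance_colonoscopy"), 100)
  expect_true(all(out$cohort$health_state == "free_of_disease"))
  expect_equal(unique(out$cohort$years_since_last_surveillance), 0L)

  # not yet due
  out2 <- step_surveillance(mk(70, 2), p)
  expect_equal(nrow(out2$events), 0)
  expect_equal(unique(out2$cohort$years_since_last_surveillance), 3L)

  # age 76: no colonoscopy, exits to natural history
  out3 <- step_surveillance(mk(76, 4), p)
  expect_equal(nrow(out3$events), 0)
  expect_true(all(out3$cohort$screening_track == "natural_history"))
})

test_that("screen-detected cancers increase with the participation rate", {
  p <- default_parameters("mandarin")
  lo <- scenario("lo", "mandarin", p, participation_rate = 0.2,
                 intervention_cost_total = 0)
  hi <- scenario("hi", "mandarin", p, participation_rate = 0.8,
                 intervention_cost_total = 0)
  cen <- gen_census_tables("mandarin")
  coh <- sample_cohort(interpolate_population(cen, 2019), 20000, seed = 7)
  a_lo <- run_arm(p, lo, horizon = 30, seed = 11, cohort = coh)
  a_hi <- run_arm(p, hi, horizon = 30, seed = 11, cohort = coh)
  expect_gt(a_hi$detected, a_lo$detected)
})
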