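# Shared fixtures: deterministic parameter variants and an independent
# cohort-model (matrix-product) oracle for occupancy checks.

# Zero background mortality except the forced ceiling at age 100.
zero_mortality_life_table <- function() {
  lt <- gen_life_table()
  lt$qx <- ifelse(lt$age >= 100, 1, 0)
  lt
}

# No adenoma incidence at any age: nobody ever leaves free_of_disease.
zero_incidence_schedule <- function() {
  tibble::tibble(age_lo = 50, age_hi = 150, progressive = 0, all = 0,
                 low_risk = 0)
}

# Flat single-band toy parameters for oracle comparisons: constant background
# mortality, constant adenoma incidence, survival = 1 (diagnosis is
# absorbing up to background death), no screening.
make_toy_params <- function(q = 0.01, prog = 0.004, low = 0.012) {
  lt <- gen_life_table()
  lt$qx <- ifelse(lt$age >= 100, 1, q)
  load_parameters(
    "mandarin",
    adenoma_incidence = tibble::tibble(
      age_lo = 50, age_hi = 150,
      progressive = prog, all = (prog + low), low_risk = low
    ),
    progressive_fraction = prog / (prog + low),
    life_table = lt,
    survival = gen_survival_table(c(A = 1, B = 1, C = 1, D = 1))
  )
}

# Independent 9-category transition matrix reproducing the engine's
# documented cycle order (mortality -> diagnosis -> progression) for a
# no-screening configuration with survival = 1. Categories: free, low, high,
# A..D undiagnosed, diagnosed (any stage), dead.
toy_oracle_matrix <- function(params, q) {
  tr <- stats::setNames(params$transitions$prob, params$transitions$from)
  dx <- stats::setNames(params$sympt_dx$prob, params$sympt_dx$stage)
  pi <- params$adenoma_incidence$progressive[1]
  li <- params$adenoma_incidence$low_risk[1]
  s <- 1 - q
  P <- matrix(0, 9, 9)
  P[1, ] <- c(s * (1 - pi - li), s * li, s * pi, 0, 0, 0, 0, 0, q)
  P[2, ] <- c(0, s * (1 - tr[["low_risk_adenoma"]]), s * tr[["low_risk_adenoma"]],
              0, 0, 0, 0, 0, q)
  P[3, ] <- c(0, 0, s * (1 - tr[["high_risk_adenoma"]]),
              s * tr[["high_risk_adenoma"]], 0, 0, 0, 0, q)
  stay_dx <- function(d, p_next) {
    c(stay = s * (1 - d) * (1 - p_next), move = s * (1 - d) * p_next,
      diag = s * d)
  }
  a <- stay_dx(dx[["A"]], tr[["CRC_A"]])
  P[4, ] <- c(0, 0, 0, a[["stay"]], a[["move"]], 0, 0, a[["diag"]], q)
  b <- stay_dx(dx[["B"]], tr[["CRC_B"]])
  P[5, ] <- c(0, 0, 0, 0, b[["stay"]], b[["move"]], 0, b[["diag"]], q)
  cc <- stay_dx(dx[["C"]], tr[["CRC_C"]])
  P[6, ] <- c(0, 0, 0, 0, 0, cc[["stay"]], cc[["move"]], cc[["diag"]], q)
  P[7, ] <- c(0, 0, 0, 0, 0, 0, s * (1 - dx[["D"]]), s * dx[["D"]], q)
  P[8, ] <- c(0, 0, 0, 0, 0, 0, 0, s, q)
  P[9, 9] <- 1
  P
}

# Uniform-age cohort helper for direct kernel tests.
flat_cohort <- function(n, age = 60, seed = 1) {
  sample_cohort(tibble::tibble(age = age, count = 1), n, seed = seed)
}

# Put a cohort into a given CRC state, optionally diagnosed.
with_state <- function(cohort, state, diagnosed = FALSE, ysd = 0L) {
  cohort$health_state <- factor(state, levels = levels(cohort$health_state))
  if (diagnosed) {
    cohort$diagnosed <- TRUE
    cohort$dx_stage <- factor(sub("CRC_", "", state), levels = c("A", "B", "C", "D"))
    cohort$years_since_diagnosis <- as.integer(ysd)
  }
  cohort
}

binom_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)

# Compare simulated occupancy with the matrix-product expectation, cycle by
# cycle, at the overall confidence of a 3-standard-error criterion. The sweep
# tests horizon x 9 cells, so the per-cell level is Bonferroni-corrected to
# keep the whole comparison at the two-sided 99.73% level (without the
# correction a correct engine fails the sweep roughly one run in five).
# Cells with large expected counts use the normal band; cells with tiny
# expectations, where the normal approximation is invalid, use the exact
# Poisson band at the same per-cell level.
expect_occupancy_matches <- function(arm, P, n, horizon) {
  expected <- c(n, rep(0, 8))
  alpha_cell <- 2 * stats::pnorm(-3) / (horizon * 9)
  zcrit <- stats::qnorm(1 - alpha_cell / 2)
  for (t in seq_len(horizon)) {
    expected <- expected %*% P
    exp_t <- as.numeric(expected)
    obs <- arm$occupancy[t + 1, ]
    pexp <- pmin(pmax(exp_t / n, 0), 1)
    se <- sqrt(n * pexp * (1 - pexp))
    big <- exp_t >= 10
    ok_big <- abs(obs - exp_t) <= zcrit * se + 1e-9
    lo <- stats::qpois(alpha_cell / 2, exp_t)
    hi <- stats::qpois(1 - alpha_cell / 2, exp_t)
    ok_small <- obs >= lo & obs <= hi
    testthat::expect_true(all(ifelse(big, ok_big, ok_small)),
                          label = sprintf("cycle %d occupancy within band", t))
  }
}
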