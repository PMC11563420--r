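# Engine: full microsimulation runs, paired-arm cost-utility comparisons with
# common random numbers, probabilistic sensitivity analysis, discount-rate
# sensitivity analysis, and validation against registry-style benchmarks.

#' Simulate one arm
#'
#' Runs every individual through the interleaved screening, surveillance and
#' natural-history tracks in annual cycles until death, age 100 or the
#' horizon. Within each cycle the order is: background then CRC mortality;
#' screening round (at invitation ages); surveillance; symptomatic diagnosis;
#' progression; utility accrual; then age and post-diagnosis clocks advance.
#' Costs accrue at the start of the cycle of the event; utilities accrue for
#' the cycle lived (the dead contribute zero in their death cycle); both are
#' discounted by `(1 + rate)^-t` with `t = 0` the reference year.
#'
#' Every cycle consumes a fixed number of uniform draws per individual
#' regardless of the scenario, so two arms run with the same `seed` and
#' cohort see identical random streams (common random numbers): paired
#' differences isolate the scenario effect.
#'
#' @param params `crc_parameters`.
#' @param scen a [scenario()].
#' @param n cohort size (used when `cohort` is `NULL`).
#' @param horizon number of annual cycles (default 50).
#' @param seed integer seed driving all simulation randomness.
#' @param cohort optional cohort tibble; defaults to a fresh sample from the
#'   group's census interpolation at 2019.
#' @param discount_rate annual rate for costs and QALYs.
#' @param intervention_cost_pp per-person program cost charged in year 0
#'   (defaults to the scenario's total spread over the eligible population).
#' @param log_events keep a per-individual event log (slow; for audit and
#'   small cohorts).
#' @return an `arm_result`: per-person discounted and undiscounted costs and
#'   QALYs, screen-detected adenoma+cancer count, CRC case and death counts,
#'   an occupancy matrix (cycles x 9 state categories), and the event log if
#'   requested.
#' @export
run_arm <- function(params, scen, n = 10000, horizon = 50, seed = 1,
                    cohort = NULL,
                    discount_rate = params$utilities$discount_rate,
                    intervention_cost_pp =
                      scen$intervention_cost_total / params$eligible_population,
                    log_events = FALSE) {
  if (horizon < 1 || n < 1) stop("horizon and n must be >= 1", call. = FALSE)
  if (is.null(cohort)) {
    census <- gen_census_tables(scen$group)
    pop <- interpolate_population(census, 2019)
    cohort <- sample_cohort(pop, n, seed = seed)
  }
  st <- cohort_to_state(cohort)
  n <- length(st$age)
  lk <- build_lookups(params)
  costs <- params$costs

  cost_d <- cost_u <- qaly_d <- qaly_u <- 0
  detected <- crc_cases <- crc_deaths <- 0L
  occupancy <- matrix(0L, horizon + 1L, 9L,
                      dimnames = list(NULL, c(STATE_LEVELS[1:7],
                                              "diagnosed_crc", "dead")))
  occ_row <- function(st) {
    cat9 <- st$state
    cat9[st$diagnosed & st$state != ST_DEAD] <- 8L
    cat9[st$state == ST_DEAD] <- 9L
    tabulate(cat9, 9L)
  }
  occupancy[1L, ] <- occ_row(st)
  logs <- if (log_events) vector("list", horizon) else NULL

  set.seed(seed)
  for (t in seq_len(horizon) - 1L) {
    u_bg <- stats::runif(n); u_crc <- stats::runif(n)
    u_part <- stats::runif(n); u_pos <- stats::runif(n)
    u_fup <- stats::runif(n); u_colo <- stats::runif(n)
    u_stage <- stats::runif(n); u_sympt <- stats::runif(n)
    u_dxstage <- stats::runif(n); u_prog <- stats::runif(n)
    disc <- 1 / (1 + discount_rate)^t
    age_at <- st$age

    mort <- k_mortality(st, lk, u_bg, u_crc)
    st <- mort$st
    crc_deaths <- crc_deaths + sum(mort$died_crc)

    scr <- k_screening(st, lk, scenario_rates(scen, t), scen$positivity_rate,
                       costs, params$screening_ages,
                       u_part, u_pos, u_fup, u_colo, u_stage)
    st <- scr$st

    srv <- k_surveillance(st, lk, costs, params$surveillance_interval,
                          params$surveillance_max_age)
    st <- srv$st

    ddx <- k_sympt_dx(st, lk, u_sympt, u_dxstage)
    st <- ddx$st
    sympt_cost <- numeric(n)
    sympt_cost[ddx$diagnosed_now] <-
      unname(costs$treatment_by_stage[st$dx_stage[ddx$diagnosed_now]])

    st <- k_progression(st, lk, u_prog)

    util <- k_utility(st, lk)
    cycle_cost <- scr$cost + srv$cost + sympt_cost

    cost_d <- cost_d + sum(cycle_cost) * disc
    cost_u <- cost_u + sum(cycle_cost)
    qaly_d <- qaly_d + sum(util) * disc
    qaly_u <- qaly_u + sum(util)

    detected <- detected + sum(scr$adenoma | scr$crc_detected) +
      sum(srv$adenoma | srv$crc_detected)
    crc_cases <- crc_cases + sum(scr$crc_detected) + sum(srv$crc_detected) +
      sum(ddx$diagnosed_now)

    if (log_events) {
      death_ev <- function(mask, kind) {
        if (!any(mask)) return(NULL)
        tibble::tibble(id = st$id[mask], kind = kind, age = age_at[mask],
                       stage = NA_character_)
      }
      sympt_ev <- if (any(ddx$diagnosed_now)) {
        tibble::tibble(id = st$id[ddx$diagnosed_now],
                       kind = "symptomatic_diagnosis",
                       age = age_at[ddx$diagnosed_now],
                       stage = STAGE_LEVELS[st$dx_stage[ddx$diagnosed_now]])
      }
      srv_ev <- local({
        evl <- function(mask, kind, stg = NULL) {
          if (!any(mask)) return(NULL)
          tibble::tibble(id = st$id[mask], kind = kind, age = age_at[mask],
                         stage = if (is.null(stg)) NA_character_
                                 else STAGE_LEVELS[stg[mask]])
        }
        dplyr::bind_rows(
          evl(srv$due, "gp_visit"), evl(srv$due, "surveillance_colonoscopy"),
          evl(srv$adenoma, "adenoma_detected"),
          evl(srv$crc_detected, "cancer_detected", srv$stage)
        )
      })
      alive_now <- st$state != ST_DEAD
      util_ev <- tibble::tibble(id = st$id[alive_now], kind = "utility",
                                age = age_at[alive_now], stage = NA_character_,
                                value = util[alive_now])
      logs[[t + 1L]] <- dplyr::bind_rows(
        dplyr::mutate(dplyr::bind_rows(
          screening_events(scr, age_at), srv_ev, sympt_ev,
          death_ev(mort$died_background, "background_death"),
          death_ev(mort$died_crc, "crc_death")
        ), value = NA_real_),
        util_ev
      ) |> dplyr::mutate(year = t)
    }

    alive <- st$state != ST_DEAD
    st$age[alive] <- st$age[alive] + 1L
    inc <- alive & st$diagnosed & !is.na(st$ysd)
    st$ysd[inc] <- st$ysd[inc] + 1L
    occupancy[t + 2L, ] <- occ_row(st)
  }

  new_arm_result(
    cost_pp = cost_d / n + intervention_cost_pp,
    qaly_pp = qaly_d / n,
    cost_pp_undisc = cost_u / n + intervention_cost_pp,
    qaly_pp_undisc = qaly_u / n,
    detected = as.integer(detected),
    crc_cases = as.integer(crc_cases),
    crc_deaths = as.integer(crc_deaths),
    n = n, horizon = horizon, discount_rate = discount_rate,
    scenario_name = scen$name, seed = seed,
    occupancy = occupancy,
    events = if (log_events) dplyr::bind_rows(logs) else NULL
  )
}

#' Paired-arm cost-utility comparison
#'
#' Simulates usual practice and the recruitment-intervention scenario on the
#' same cohort with common random numbers (identical seeds and draw order),
#' then compares them with [compute_icer()]. The intervention raises
#' screening participation by `uplift_pp` percentage points and colonoscopy
#' follow-up to the English-speaking rate for `uplift_duration` years (1 by
#' default), and charges the program cost per eligible person in year 0.
#'
#' @param params `crc_parameters` for the group.
#' @param uplift_pp participation uplift in percentage points.
#' @param n,horizon,seed,discount_rate simulation controls (see [run_arm()]).
#' @param intervention_cost_total total program cost; defaults to the
#'   packaged group total.
#' @param followup_uplift raise colonoscopy follow-up to the English rate in
#'   the uplift year(s)?
#' @param uplift_duration years the uplift lasts.
#' @param independent_arms simulate the arms on independent random streams
#'   instead of common random numbers (for fidelity checks; much noisier).
#' @return a `cua_result` with both `arm_result`s attached.
#' @export
run_cua <- function(params, uplift_pp, n = 10000, horizon = 50, seed = 1,
                    discount_rate = params$utilities$discount_rate,
                    intervention_cost_total = params$intervention_total_cost,
                    followup_uplift = TRUE, uplift_duration = 1L,
                    independent_arms = FALSE) {
  group <- params$group
  base_scen <- scenario("usual practice", group, params,
                        uplift_pp = 0, followup_uplift = FALSE,
                        intervention_cost_total = 0)
  int_scen <- scenario(
    sprintf("+%.1f pp participation, 1 y", uplift_pp), group, params,
    uplift_pp = uplift_pp, followup_uplift = followup_uplift,
    uplift_duration = uplift_duration,
    intervention_cost_total = intervention_cost_total
  )
  census <- gen_census_tables(group)
  pop <- interpolate_population(census, 2019)
  cohort <- sample_cohort(pop, n, seed = seed)
  sim_seed <- c(base = seed + 1L,
                int = if (independent_arms) seed + 2L else seed + 1L)
  base_arm <- run_arm(params, base_scen, horizon = horizon,
                      seed = sim_seed[["base"]], cohort = cohort,
                      discount_rate = discount_rate)
  int_arm <- run_arm(params, int_scen, horizon = horizon,
                     seed = sim_seed[["int"]], cohort = cohort,
                     discount_rate = discount_rate)
  compute_icer(base_arm, int_arm, wtp = params$utilities$wtp_threshold)
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the paired-arm comparison across Monte Carlo trials, each with a
#' fresh draw of every ranged parameter (uniform over its printed range, see
#' [draw_psa_parameters()]) and a fresh cohort, and summarises the ICER
#' distribution: mean, 2.5th/97.5th percentile uncertainty interval, and the
#' fraction of trials cost-effective at the willingness-to-pay threshold
#' (dominant trials count as cost-effective). Trials with a zero QALY
#' difference are excluded from the ICER summary and counted.
#'
#' @param params base-case `crc_parameters`.
#' @param uplift_pp participation uplift in percentage points.
#' @param spec a [psa_spec()] (trials and patients per trial).
#' @param horizon,seed,discount_rate,intervention_cost_total,followup_uplift
#'   passed to [run_cua()].
#' @return a `psa_result`: `trials` tibble (one row per trial), `summary`
#'   list (`mean_icer`, `icer_lo`, `icer_hi`, `frac_below_wtp`,
#'   `n_undefined`), and the spec.
#' @export
run_psa <- function(params, uplift_pp, spec = psa_spec(n_trials = 200),
                    horizon = 50, seed = 1,
                    discount_rate = params$utilities$discount_rate,
                    intervention_cost_total = params$intervention_total_cost,
                    followup_uplift = TRUE) {
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_trials)
  rows <- vector("list", spec$n_trials)
  for (k in seq_len(spec$n_trials)) {
    pars_k <- draw_psa_parameters(params, spec, seed = trial_seeds[k])
    cua <- run_cua(pars_k, uplift_pp, n = spec$n_patients, horizon = horizon,
                   seed = trial_seeds[k], discount_rate = discount_rate,
                   intervention_cost_total = intervention_cost_total,
                   followup_uplift = followup_uplift)
    rows[[k]] <- tibble::tibble(
      trial = k, delta_cost = cua$delta_cost, delta_qaly = cua$delta_qaly,
      icer = cua$icer, dominance = cua$dominance,
      below_wtp = cua$below_wtp
    )
  }
  trials <- dplyr::bind_rows(rows)
  defined <- dplyr::filter(trials, !is.na(icer) | dominance == "dominant")
  icers <- defined$icer[!is.na(defined$icer)]
  summary <- list(
    mean_icer = mean(icers),
    icer_lo = unname(stats::quantile(icers, 0.025)),
    icer_hi = unname(stats::quantile(icers, 0.975)),
    frac_below_wtp = mean(defined$below_wtp, na.rm = TRUE),
    n_undefined = sum(trials$dominance == "undefined")
  )
  structure(list(trials = trials, summary = summary, spec = spec,
                 uplift_pp = uplift_pp, wtp = params$utilities$wtp_threshold,
                 seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat("<psa_result> ", nrow(x$trials), " trials x ", x$spec$n_patients,
      " patients, uplift +", x$uplift_pp, " pp\n", sep = "")
  cat(sprintf("  mean ICER $%.0f/QALY (95%% UI $%.0f to $%.0f)\n",
              s$mean_icer, s$icer_lo, s$icer_hi))
  cat(sprintf("  %.1f%% of trials cost-effective at $%s/QALY (%d undefined)\n",
              100 * s$frac_below_wtp, format(x$wtp, big.mark = ","),
              s$n_undefined))
  invisible(x)
}

#' Discount-rate sensitivity analysis
#'
#' Re-runs the identical paired comparison (same seed, same cohort) at each
#' discount rate; only the rate changes.
#'
#' @inheritParams run_cua
#' @param rates discount rates to evaluate.
#' @return tibble with one row per rate: `rate`, `delta_cost`, `delta_qaly`,
#'   `icer`, `base_qaly_pp`, `int_qaly_pp`.
#' @export
run_discount_sa <- function(params, uplift_pp, rates = c(0, 0.035, 0.05),
                            n = 10000, horizon = 50, seed = 1, ...) {
  purrr::map_dfr(rates, function(r) {
    cua <- run_cua(params, uplift_pp, n = n, horizon = horizon, seed = seed,
                   discount_rate = r, ...)
    tibble::tibble(rate = r, delta_cost = cua$delta_cost,
                   delta_qaly = cua$delta_qaly, icer = cua$icer,
                   base_qaly_pp = cua$base$qaly_pp,
                   int_qaly_pp = cua$intervention$qaly_pp)
  })
}

#' Validate simulated outcomes against registry-style benchmarks
#'
#' Scales per-person simulated CRC case and death counts to the eligible
#' population and compares annual rates with supplied benchmarks (for
#' example, registry cases per year attributable to the group).
#'
#' @param arm an `arm_result` from [run_arm()].
#' @param population eligible population the cohort represents.
#' @param benchmarks tibble with columns `metric`
#'   (`"crc_cases_per_year"` / `"crc_deaths_per_year"`) and `value`.
#' @param tolerance relative tolerance for the pass flag (default 0.25).
#' @return tibble: `metric`, `simulated`, `benchmark`, `ratio`, `pass`.
#' @export
validate_model <- function(arm, population,
                           benchmarks = tibble::tibble(
                             metric = c("crc_cases_per_year",
                                        "crc_deaths_per_year"),
                             value = c(46.5, 8)
                           ),
                           tolerance = 0.25) {
  sim <- c(
    crc_cases_per_year = arm$crc_cases / arm$n * population / arm$horizon,
    crc_deaths_per_year = arm$crc_deaths / arm$n * population / arm$horizon
  )
  simulated <- unname(sim[benchmarks$metric])
  ratio <- simulated / benchmarks$value
  tibble::tibble(
    metric = benchmarks$metric,
    simulated = simulated,
    benchmark = benchmarks$value,
    ratio = ratio,
    pass = abs(ratio - 1) <= tolerance
  )
}
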