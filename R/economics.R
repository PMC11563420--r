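# Economics: discounting, utility weights, cost/QALY accumulation from event
# logs, per-person intervention cost, and incremental cost-effectiveness.

#' Present value of a future amount
#'
#' Standard annual discounting: `amount / (1 + rate)^years`.
#'
#' @param amount dollar amount (or any quantity; QALYs discount identically).
#' @param years years from the reference year (>= 0).
#' @param rate annual discount rate in \[0, 1); the base case uses 0.05.
#' @return discounted value.
#' @examples
#' discount(100, 1, 0.05) # 95.2381
#' discount(1, 50, 0.05)  # 0.0872037
#' @export
discount <- function(amount, years, rate = 0.05) {
  if (any(years < 0)) stop("years must be non-negative", call. = FALSE)
  if (any(rate < 0 | rate >= 1)) stop("rate must be in [0, 1)", call. = FALSE)
  amount / (1 + rate)^years
}

#' Utility weight for one annual cycle
#'
#' A CRC health state carries the stage utility (0.74 for stages A-C, 0.68
#' for stage D) whether or not the cancer has been diagnosed; cancer
#' survivors (more than five years after diagnosis) and everyone free of CRC
#' carry the age-band population norm (0.80 for 50-69, 0.76 for 70-79, 0.70
#' for 80+); the dead contribute zero.
#'
#' @param cohort cohort tibble (columns `age`, `health_state`, `diagnosed`,
#'   `years_since_diagnosis`, and `dx_stage` if any are diagnosed).
#' @param params `crc_parameters`.
#' @return numeric vector of utility weights, one per row.
#' @export
annual_utility <- function(cohort, params = default_parameters()) {
  st <- cohort_to_state(cohort)
  lk <- build_lookups(params)
  k_utility(st, lk)
}

#' Accumulate an event log into an arm result
#'
#' Independently re-prices and aggregates a per-individual event log produced
#' by a logged simulation run (see [run_arm()] with `log_events = TRUE`):
#' each event kind is mapped to its resource cost, costs are discounted to
#' the reference year by event year, utility records are discounted the same
#' way, and screen-detection and diagnosis counters are tallied.
#'
#' Cost mapping: `kit_sent` = kit + packaging/postage; a returned kit
#' (negative or positive) adds the laboratory analysis; `gp_visit` the GP
#' consultation; `colonoscopy` and `surveillance_colonoscopy` the
#' no-polypectomy procedure cost, upgraded by the polypectomy differential
#' when the same colonoscopy detected an adenoma; `cancer_detected` and
#' `symptomatic_diagnosis` the stage-specific treatment cost.
#'
#' @param events tibble with columns `id`, `year` (0-based), `kind`, `stage`;
#'   utility records use `kind = "utility"` with the weight in `value`.
#' @param params `crc_parameters` (cost and utility schedules).
#' @param rate discount rate.
#' @param n number of simulated individuals (for per-person averages).
#' @param intervention_cost_per_person added, undiscounted, in year 0.
#' @return an `arm_result` (see [run_arm()]).
#' @export
accumulate <- function(events, params, rate = params$utilities$discount_rate,
                       n = length(unique(events$id)),
                       intervention_cost_per_person = 0) {
  costs <- params$costs
  unit_cost <- c(
    kit_sent = costs$fobt_kit + costs$packaging_postage,
    kit_returned_negative = costs$lab_analysis,
    kit_returned_positive = costs$lab_analysis,
    gp_visit = costs$gp_consult,
    colonoscopy = costs$colonoscopy_no_polypectomy,
    surveillance_colonoscopy = costs$colonoscopy_no_polypectomy,
    adenoma_detected = costs$colonoscopy_polypectomy - costs$colonoscopy_no_polypectomy,
    declined_colonoscopy = 0, no_disease = 0,
    cancer_detected = 0, symptomatic_diagnosis = 0, utility = 0,
    background_death = 0, crc_death = 0
  )
  unknown <- setdiff(unique(events$kind), names(unit_cost))
  if (length(unknown)) {
    stop("no cost mapping for event kind(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ev <- dplyr::mutate(
    events,
    cost = unname(unit_cost[kind]) +
      dplyr::if_else(kind %in% c("cancer_detected", "symptomatic_diagnosis"),
                     unname(costs$treatment_by_stage[stage]), 0),
    disc = 1 / (1 + rate)^year
  )
  util <- dplyr::filter(ev, kind == "utility")
  costev <- dplyr::filter(ev, kind != "utility")

  detected <- sum(costev$kind %in% c("adenoma_detected", "cancer_detected"))
  crc_cases <- sum(costev$kind %in% c("cancer_detected", "symptomatic_diagnosis"))
  crc_deaths <- sum(costev$kind == "crc_death")

  new_arm_result(
    cost_pp = sum(costev$cost * costev$disc) / n + intervention_cost_per_person,
    qaly_pp = sum(util$value * util$disc) / n,
    cost_pp_undisc = sum(costev$cost) / n + intervention_cost_per_person,
    qaly_pp_undisc = sum(util$value) / n,
    detected = detected, crc_cases = crc_cases, crc_deaths = crc_deaths,
    n = n, horizon = if (nrow(ev)) max(ev$year) + 1 else 0,
    discount_rate = rate, scenario_name = "accumulated", seed = NA_integer_
  )
}

new_arm_result <- function(cost_pp, qaly_pp, cost_pp_undisc, qaly_pp_undisc,
                           detected, crc_cases, crc_deaths, n, horizon,
                           discount_rate, scenario_name, seed,
                           occupancy = NULL, events = NULL) {
  structure(list(
    cost_pp = cost_pp, qaly_pp = qaly_pp,
    cost_pp_undisc = cost_pp_undisc, qaly_pp_undisc = qaly_pp_undisc,
    detected = detected, crc_cases = crc_cases, crc_deaths = crc_deaths,
    n = n, horizon = horizon, discount_rate = discount_rate,
    scenario_name = scenario_name, seed = seed,
    occupancy = occupancy, events = events
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result> ", x$scenario_name, "  (n = ", x$n, ", ", x$horizon,
      " cycles, r = ", x$discount_rate, ")\n", sep = "")
  cat(sprintf("  cost/person  $%.2f (undisc. $%.2f)\n", x$cost_pp, x$cost_pp_undisc))
  cat(sprintf("  QALYs/person %.4f (undisc. %.4f)\n", x$qaly_pp, x$qaly_pp_undisc))
  cat(sprintf("  screen-detected adenoma+cancer: %d | CRC cases: %d | CRC deaths: %d\n",
              x$detected, x$crc_cases, x$crc_deaths))
  invisible(x)
}

#' Per-person cost of a recruitment program
#'
#' Spreads the total program delivery cost over the eligible population;
#' reported to the cent.
#'
#' @param total_cost program cost in dollars.
#' @param eligible_population persons aged 50-74 in the target group.
#' @return dollars per person, rounded to cents.
#' @examples
#' intervention_cost_per_person(120863, 17522) # 6.90
#' intervention_cost_per_person(120337, 38660) # 3.11
#' @export
intervention_cost_per_person <- function(total_cost, eligible_population) {
  if (any(eligible_population <= 0)) {
    stop("eligible_population must be positive", call. = FALSE)
  }
  round(total_cost / eligible_population, 2)
}

#' Incremental cost-effectiveness of an intervention arm versus base
#'
#' Computes the incremental cost and QALYs per person, the ICER (incremental
#' cost divided by incremental QALYs), a dominance classification on the
#' cost-effectiveness plane, and whether the point falls below the
#' willingness-to-pay threshold. A zero QALY difference leaves the ICER
#' undefined (`NA`) and flagged rather than infinite.
#'
#' @param base,intervention `arm_result`s simulated on matched cohorts.
#' @param wtp willingness-to-pay threshold, $/QALY.
#' @return a `cua_result` list: `delta_cost`, `delta_qaly`, `icer`,
#'   `dominance` (`"dominant"`, `"dominated"`, `"tradeoff"`, `"undefined"`),
#'   `below_wtp`, `delta_detected`, and both arms.
#' @examples
#' a <- structure(list(cost_pp = 100, qaly_pp = 10, detected = 0), class = "arm_result")
#' b <- structure(list(cost_pp = 110, qaly_pp = 10.01, detected = 2), class = "arm_result")
#' compute_icer(a, b)$icer # 1000
#' @export
compute_icer <- function(base, intervention, wtp = 50000) {
  dc <- intervention$cost_pp - base$cost_pp
  dq <- intervention$qaly_pp - base$qaly_pp
  dominance <-
    if (dq == 0) "undefined"
    else if (dc <= 0 && dq > 0) "dominant"
    else if (dc >= 0 && dq < 0) "dominated"
    else "tradeoff"
  icer <- if (dq == 0) NA_real_ else dc / dq
  below <- switch(dominance,
    dominant = TRUE,
    dominated = FALSE,
    undefined = NA,
    tradeoff = if (dq > 0) icer <= wtp else icer > wtp # cheaper & worse: wtp test reversed
  )
  dd <- tryCatch(intervention$detected - base$detected, error = function(e) NA)
  structure(list(
    delta_cost = dc, delta_qaly = dq, icer = icer,
    dominance = dominance, below_wtp = below, wtp = wtp,
    delta_detected = dd,
    base = base, intervention = intervention
  ), class = "cua_result")
}

#' @export
print.cua_result <- function(x, ...) {
  cat("<cua_result>\n")
  cat(sprintf("  incremental cost/person:  $%.2f\n", x$delta_cost))
  cat(sprintf("  incremental QALYs/person: %.6f\n", x$delta_qaly))
  if (is.na(x$icer)) {
    cat("  ICER: undefined (zero QALY difference)\n")
  } else {
    cat(sprintf("  ICER: $%.0f per QALY (%s, %sbelow $%s/QALY)\n",
                x$icer, x$dominance, if (isTRUE(x$below_wtp)) "" else "not ",
                format(x$wtp, big.mark = ",")))
  }
  if (!is.na(x$delta_detected)) {
    cat(sprintf("  additional adenoma+cancer detected: %s\n",
                format(x$delta_detected)))
  }
  invisible(x)
}
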