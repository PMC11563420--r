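# The organised screening pathway: biennial FOBT invitations at even ages
# 50-74, participation, test positivity, GP follow-up, diagnostic colonoscopy
# with outcomes sampled from observed disease prevalence, stage at screen
# detection, and 5-yearly colonoscopy surveillance after adenoma removal.

#' Scenario definition
#'
#' A named arm of the comparison: the screening participation rate per
#' invitation round, the colonoscopy follow-up (assessment) rate after a
#' positive test, how long an intervention-driven uplift lasts, and the total
#' program cost spread over the eligible population.
#'
#' During the first `uplift_duration` years of the simulation the scenario's
#' `participation_rate` and `colonoscopy_followup_rate` apply; afterwards
#' rates revert to the group baselines (`participation_baseline` and the
#' language-other-than-English follow-up rate).
#'
#' @param name scenario label.
#' @param group `"arabic"` or `"mandarin"`.
#' @param params `crc_parameters` supplying the baselines.
#' @param uplift_pp participation uplift in percentage points added to the
#'   baseline during `uplift_duration`.
#' @param followup_uplift if `TRUE` (the intervention assumption) the
#'   colonoscopy follow-up rate rises to the English-speaking rate during
#'   `uplift_duration`.
#' @param uplift_duration years the uplift lasts (default 1).
#' @param intervention_cost_total total program cost in dollars; spread per
#'   person over the eligible population and charged in year 0.
#' @param participation_rate,followup_rate,positivity_rate explicit rate
#'   overrides (otherwise derived from the baselines and `uplift_pp` /
#'   `followup_uplift`); the overridden rate applies in every year.
#' @return a `crc_scenario` list.
#' @export
scenario <- function(name, group = c("arabic", "mandarin"),
                     params = default_parameters(group),
                     uplift_pp = 0,
                     followup_uplift = uplift_pp > 0,
                     uplift_duration = 1L,
                     intervention_cost_total = 0,
                     participation_rate = NULL,
                     followup_rate = NULL,
                     positivity_rate = NULL) {
  group <- match.arg(group)
  base_part <- params$rates$participation_baseline[[group]]
  part <- base_part + uplift_pp / 100
  fup <- params$rates$colonoscopy_followup
  fup_rate <- if (followup_uplift) fup[["english"]] else fup[["lote"]]
  if (!is.null(participation_rate)) part <- base_part <- participation_rate
  if (!is.null(followup_rate)) fup_rate <- followup_rate
  fup_base <- if (is.null(followup_rate)) fup[["lote"]] else followup_rate
  pos <- if (is.null(positivity_rate)) params$rates$positivity[["lote"]] else positivity_rate
  for (r in c(part, base_part, fup_rate, fup_base, pos)) {
    if (r < 0 || r > 1) stop("scenario rate out of [0, 1]", call. = FALSE)
  }
  structure(list(
    name = name,
    group = group,
    participation_rate = part,
    participation_baseline = base_part,
    colonoscopy_followup_rate = fup_rate,
    colonoscopy_followup_baseline = fup_base,
    positivity_rate = pos,
    uplift_duration = as.integer(uplift_duration),
    intervention_cost_total = intervention_cost_total
  ), class = "crc_scenario")
}

#' @export
print.crc_scenario <- function(x, ...) {
  cat("<crc_scenario> ", x$name, " (", x$group, ")\n", sep = "")
  cat(sprintf("  participation %.3f (baseline %.3f), follow-up %.3f (baseline %.3f)\n",
              x$participation_rate, x$participation_baseline,
              x$colonoscopy_followup_rate, x$colonoscopy_followup_baseline))
  cat(sprintf("  uplift %d y, program cost $%s\n",
              x$uplift_duration, format(x$intervention_cost_total, big.mark = ",")))
  invisible(x)
}

#' Is a screening invitation due at this age?
#'
#' Kits are mailed at even ages 50 through 74.
#'
#' @param age integer vector of ages.
#' @param screening_ages the invitation ages (default even 50-74).
#' @return logical vector.
#' @examples
#' invitation_due(c(50, 51, 62, 74, 75)) # TRUE FALSE TRUE TRUE FALSE
#' @export
invitation_due <- function(age, screening_ages = seq(50L, 74L, 2L)) {
  as.integer(age) %in% screening_ages
}

# Scenario rates in force at a given simulation year (0-based).
scenario_rates <- function(scen, year_index) {
  if (year_index < scen$uplift_duration) {
    c(participation = scen$participation_rate,
      followup = scen$colonoscopy_followup_rate)
  } else {
    c(participation = scen$participation_baseline,
      followup = scen$colonoscopy_followup_baseline)
  }
}

# Vectorized screening kernel. Applies one invitation round to the compact
# state; returns updated state, per-person cycle costs, and the masks needed
# for event logs and counters. Detected disease is imposed: the sampled
# colonoscopy outcome overwrites the latent natural-history state (the model
# works from observed prevalence rather than test sensitivity/specificity).
k_screening <- function(st, lk, rates, positivity, costs, screening_ages,
                        u_part, u_pos, u_fup, u_colo, u_stage) {
  n <- length(st$age)
  alive <- st$state != ST_DEAD
  invited <- alive & st$track == TR_SCREEN & invitation_due(st$age, screening_ages)

  cost <- numeric(n)
  cost[invited] <- costs$fobt_kit + costs$packaging_postage

  participated <- invited & u_part < rates[["participation"]]
  cost[participated] <- cost[participated] + costs$lab_analysis

  positive <- participated & u_pos < positivity
  cost[positive] <- cost[positive] + costs$gp_consult

  colo <- positive & u_fup < rates[["followup"]]
  declined <- positive & !colo
  st$track[declined] <- TR_NATURAL

  outcome <- integer(n) # 1 free, 2 low-risk adenoma, 3 high-risk adenoma, 4 CRC
  outcome[colo] <- findInterval(u_colo[colo], lk$cum_prev) + 1L

  latent <- st$state # retained for diagnostics/logging before overwrite
  no_disease <- colo & outcome == 1L
  adenoma <- colo & (outcome == 2L | outcome == 3L)
  crc_det <- colo & outcome == 4L

  cost[no_disease | crc_det] <- cost[no_disease | crc_det] +
    costs$colonoscopy_no_polypectomy
  cost[adenoma] <- cost[adenoma] + costs$colonoscopy_polypectomy

  st$state[no_disease] <- ST_FREE
  st$state[adenoma] <- ST_FREE # adenoma removed at polypectomy
  st$track[adenoma] <- TR_SURV
  st$yss[adenoma] <- 0L

  stage <- integer(n)
  stage[crc_det] <- findInterval(u_stage[crc_det], lk$cum_stage_screened) + 1L
  st$state[crc_det] <- ST_A - 1L + stage[crc_det]
  st$diagnosed[crc_det] <- TRUE
  st$dx_stage[crc_det] <- stage[crc_det]
  st$ysd[crc_det] <- 0L
  st$track[crc_det] <- TR_NATURAL
  cost[crc_det] <- cost[crc_det] +
    unname(costs$treatment_by_stage[stage[crc_det]])

  list(st = st, cost = cost, invited = invited, participated = participated,
       positive = positive, colonoscopy = colo, declined = declined,
       no_disease = no_disease, adenoma = adenoma, crc_detected = crc_det,
       stage = stage, latent = latent)
}

# Vectorized surveillance kernel: individuals with a removed adenoma get a GP
# referral plus colonoscopy every 5th year; adenomas found are removed
# (polypectomy cost); a latent cancer found is diagnosed at its latent stage;
# at age >= 75 surveillance stops and the individual follows natural history.
k_surveillance <- function(st, lk, costs, interval, max_age) {
  n <- length(st$age)
  alive <- st$state != ST_DEAD
  sv <- alive & st$track == TR_SURV

  exit <- sv & st$age >= max_age
  st$track[exit] <- TR_NATURAL
  sv <- sv & !exit

  st$yss[sv] <- st$yss[sv] + 1L
  due <- sv & st$yss >= interval

  cost <- numeric(n)
  cost[due] <- costs$gp_consult

  aden <- due & (st$state == ST_LOW | st$state == ST_HIGH)
  crc <- due & st$state >= ST_A & st$state <= ST_D & !st$diagnosed
  clear <- due & !aden & !crc

  cost[aden] <- cost[aden] + costs$colonoscopy_polypectomy
  st$state[aden] <- ST_FREE

  cost[clear] <- cost[clear] + costs$colonoscopy_no_polypectomy

  stage <- integer(n)
  stage[crc] <- st$state[crc] - 3L
  cost[crc] <- cost[crc] + costs$colonoscopy_no_polypectomy +
    unname(costs$treatment_by_stage[stage[crc]])
  st$diagnosed[crc] <- TRUE
  st$dx_stage[crc] <- stage[crc]
  st$ysd[crc] <- 0L
  st$track[crc] <- TR_NATURAL

  st$yss[due & !crc] <- 0L

  list(st = st, cost = cost, due = due, adenoma = aden, crc_detected = crc,
       exited = exit, stage = stage)
}

#' One screening round for a cohort
#'
#' Runs one invitation cycle: kit mailed at invitation ages, participation at
#' the scenario rate in force (uplifted while `year_index <
#' uplift_duration`), positivity at the group rate, GP follow-up, colonoscopy
#' at the assessment rate, and colonoscopy outcome sampled from the
#' renormalised observed prevalence. Decliners of colonoscopy move to the
#' natural-history track; negatives re-enter screening; detected adenomas are
#' removed and the individual enters surveillance; detected cancer is
#' diagnosed at a stage drawn from the screen-detected stage distribution.
#'
#' @param cohort cohort tibble.
#' @param scen a [scenario()].
#' @param params `crc_parameters`.
#' @param year_index 0-based simulation year (0 = the intervention year).
#' @param u optional list of uniforms (`participation`, `positivity`,
#'   `followup`, `outcome`, `stage`), each of length `nrow(cohort)`.
#' @return list with `cohort` (updated) and `events` (tibble: `id`, `kind`,
#'   `age`, `stage`).
#' @export
step_screening <- function(cohort, scen, params, year_index = 0L, u = NULL) {
  st <- cohort_to_state(cohort)
  lk <- build_lookups(params)
  n <- length(st$age)
  if (is.null(u)) {
    u <- list(participation = stats::runif(n), positivity = stats::runif(n),
              followup = stats::runif(n), outcome = stats::runif(n),
              stage = stats::runif(n))
  }
  res <- k_screening(
    st, lk, scenario_rates(scen, year_index), scen$positivity_rate,
    params$costs, params$screening_ages,
    u$participation, u$positivity, u$followup, u$outcome, u$stage
  )
  events <- screening_events(res, st$age)
  list(cohort = state_to_cohort(res$st), events = events)
}

screening_events <- function(res, age) {
  ev <- function(mask, kind, stage = NULL) {
    if (!any(mask)) return(NULL)
    tibble::tibble(
      id = res$st$id[mask], kind = kind, age = age[mask],
      stage = if (is.null(stage)) NA_character_ else STAGE_LEVELS[stage[mask]]
    )
  }
  negative <- res$participated & !res$positive
  dplyr::bind_rows(
    ev(res$invited, "kit_sent"),
    ev(negative, "kit_returned_negative"),
    ev(res$positive, "kit_returned_positive"),
    ev(res$positive, "gp_visit"),
    ev(res$colonoscopy, "colonoscopy"),
    ev(res$declined, "declined_colonoscopy"),
    ev(res$no_disease, "no_disease"),
    ev(res$adenoma, "adenoma_detected"),
    ev(res$crc_detected, "cancer_detected", res$stage)
  )
}

#' Diagnostic colonoscopy outcome
#'
#' Samples the finding of a diagnostic colonoscopy from the renormalised
#' observed prevalence (free of disease / low-risk adenoma / high-risk
#' adenoma / CRC), and, for cancers, the stage from the screen-detected stage
#' distribution.
#'
#' @param n number of colonoscopies.
#' @param params `crc_parameters`.
#' @param u,u_stage optional uniforms of length `n`.
#' @return tibble with columns `outcome` (factor) and `stage` (factor,
#'   `NA` unless `outcome == "crc"`).
#' @export
colonoscopy_outcome <- function(n, params = default_parameters(),
                                u = NULL, u_stage = NULL) {
  lk <- build_lookups(params)
  if (is.null(u)) u <- stats::runif(n)
  if (is.null(u_stage)) u_stage <- stats::runif(n)
  oc <- findInterval(u, lk$cum_prev) + 1L
  stage <- ifelse(oc == 4L, findInterval(u_stage, lk$cum_stage_screened) + 1L,
                  NA_integer_)
  tibble::tibble(
    outcome = factor(params$colonoscopy_prevalence$outcome[oc],
                     levels = params$colonoscopy_prevalence$outcome),
    stage = factor(STAGE_LEVELS[stage], levels = STAGE_LEVELS)
  )
}

#' One surveillance cycle for a cohort
#'
#' Individuals in the surveillance track receive a GP referral and a
#' colonoscopy every fifth year since the last one; adenomas present are
#' removed (state reset to free of disease); a latent cancer is diagnosed at
#' its latent stage. From age 75 surveillance ceases and the individual moves
#' to the natural-history track.
#'
#' @param cohort cohort tibble.
#' @param params `crc_parameters`.
#' @return list with `cohort` and `events` (tibble: `id`, `kind`, `age`,
#'   `stage`).
#' @export
step_surveillance <- function(cohort, params) {
  st <- cohort_to_state(cohort)
  lk <- build_lookups(params)
  res <- k_surveillance(st, lk, params$costs, params$surveillance_interval,
                        params$surveillance_max_age)
  ev <- function(mask, kind, stage = NULL) {
    if (!any(mask)) return(NULL)
    tibble::tibble(
      id = res$st$id[mask], kind = kind, age = st$age[mask],
      stage = if (is.null(stage)) NA_character_ else STAGE_LEVELS[stage[mask]]
    )
  }
  events <- dplyr::bind_rows(
    ev(res$due, "gp_visit"),
    ev(res$due, "surveillance_colonoscopy"),
    ev(res$adenoma, "adenoma_detected"),
    ev(res$crc_detected, "cancer_detected", res$stage)
  )
  list(cohort = state_to_cohort(res$st), events = events)
}
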