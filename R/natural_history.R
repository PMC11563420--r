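# Natural history of colorectal cancer: annual-cycle disease progression
# along the adenoma-carcinoma pathway, symptomatic diagnosis, stage-specific
# post-diagnosis survival, and background mortality.
#
# The exported functions operate on cohort tibbles (see sample_cohort());
# internally everything runs on a compact vector representation shared with
# the simulation engine, so single-step calls and full runs follow the same
# code path. Within a cycle the order of operations is fixed and documented:
# mortality (background, then CRC) -> screening/surveillance -> symptomatic
# diagnosis -> progression (at most one state transition per cycle).

# ---- compact state representation ------------------------------------------

cohort_to_state <- function(cohort) {
  st_code <- match(as.character(cohort$health_state), STATE_LEVELS)
  tr_code <- match(as.character(cohort$screening_track), TRACK_LEVELS)
  dxs <- rep(NA_integer_, nrow(cohort))
  if ("dx_stage" %in% names(cohort)) {
    dxs <- match(as.character(cohort$dx_stage), STAGE_LEVELS)
  } else {
    # diagnosed individuals carry their stage in health_state
    dxs[cohort$diagnosed] <- st_code[cohort$diagnosed] - 3L
  }
  list(
    id = cohort$id,
    age = as.integer(cohort$age),
    state = st_code,
    diagnosed = cohort$diagnosed,
    dx_stage = dxs,
    ysd = as.integer(cohort$years_since_diagnosis),
    track = tr_code,
    yss = as.integer(cohort$years_since_last_surveillance)
  )
}

state_to_cohort <- function(st) {
  tibble::tibble(
    id = st$id,
    age = st$age,
    health_state = factor(STATE_LEVELS[st$state], levels = STATE_LEVELS),
    diagnosed = st$diagnosed,
    dx_stage = factor(STAGE_LEVELS[st$dx_stage], levels = STAGE_LEVELS),
    years_since_diagnosis = st$ysd,
    screening_track = factor(TRACK_LEVELS[st$track], levels = TRACK_LEVELS),
    years_since_last_surveillance = st$yss,
    alive = st$state != ST_DEAD
  )
}

# Precompute age-indexed lookup vectors and cumulative distributions so the
# cycle kernels are pure vector arithmetic. Index convention: age a reads
# element a + 1 of a length-151 vector (ages 0..150).
build_lookups <- function(params) {
  max_ix <- 150L
  by_age <- function(tbl, col) {
    v <- numeric(max_ix + 1L)
    for (i in seq_len(nrow(tbl))) {
      lo <- tbl$age_lo[i]; hi <- min(tbl$age_hi[i], max_ix)
      v[(lo:hi) + 1L] <- tbl[[col]][i]
    }
    v
  }
  qx <- numeric(max_ix + 1L)
  qx[params$life_table$age + 1L] <- params$life_table$qx
  qx[(params$max_age:max_ix) + 1L] <- 1  # ceiling age: death is certain

  surv <- matrix(NA_real_, 4, 5)
  sv <- params$survival
  surv[cbind(match(sv$stage, STAGE_LEVELS), sv$year)] <- sv$survival
  if (anyNA(surv)) stop("survival table is incomplete", call. = FALSE)

  tp <- stats::setNames(params$transitions$prob, params$transitions$from)
  list(
    prog_inc = by_age(params$adenoma_incidence, "progressive"),
    low_inc = by_age(params$adenoma_incidence, "low_risk"),
    qx = qx,
    norm_u = by_age(params$utilities$norm, "utility"),
    surv = surv,
    trans = c(
      low2high = unname(tp[["low_risk_adenoma"]]),
      high2crc = unname(tp[["high_risk_adenoma"]]),
      a2b = unname(tp[["CRC_A"]]),
      b2c = unname(tp[["CRC_B"]]),
      c2d = unname(tp[["CRC_C"]])
    ),
    sympt = params$sympt_dx$prob,
    cum_prev = cumsum(params$colonoscopy_prevalence$prob)[1:3],
    cum_stage_screened = cumsum(params$stage_dist$screened)[1:3],
    cum_stage_not_screened = cumsum(params$stage_dist$not_screened)[1:3],
    stage_u = unname(params$utilities$stage),
    max_age = params$max_age
  )
}

age_ix <- function(age) pmin(pmax(age, 0L), 150L) + 1L

# ---- cycle kernels ----------------------------------------------------------

# Background mortality first, then CRC mortality for those diagnosed within
# the last five years (years 1-5 since diagnosis use the stage-specific
# conditional survival; beyond five years the individual is a survivor with
# background mortality only).
k_mortality <- function(st, lk, u_bg, u_crc) {
  alive <- st$state != ST_DEAD
  die_bg <- alive & u_bg < lk$qx[age_ix(st$age)]
  haz <- numeric(length(st$age))
  in_window <- alive & !die_bg & st$diagnosed &
    !is.na(st$ysd) & st$ysd >= 1L & st$ysd <= 5L
  if (any(in_window)) {
    haz[in_window] <- 1 - lk$surv[cbind(st$dx_stage[in_window], st$ysd[in_window])]
  }
  die_crc <- in_window & u_crc < haz
  st$state[die_bg | die_crc] <- ST_DEAD
  list(st = st, died_background = die_bg, died_crc = die_crc)
}

# Symptomatic diagnosis of undiagnosed, alive CRC. Whether a cancer presents
# this cycle depends on its latent stage (per-stage annual probability; stage
# D always presents); the stage recorded at diagnosis — which drives survival,
# treatment cost and utility — is drawn from the not-screened stage-at-
# diagnosis distribution, the model's representation of how symptomatically
# detected cancer presents. Diagnosis starts the survival clock and leaves
# the screening pathway.
k_sympt_dx <- function(st, lk, u, u_stage) {
  eligible <- st$state >= ST_A & st$state <= ST_D & !st$diagnosed
  p <- numeric(length(st$age))
  p[eligible] <- lk$sympt[st$state[eligible] - 3L]
  dx <- eligible & u < p
  stage <- integer(length(st$age))
  stage[dx] <- findInterval(u_stage[dx], lk$cum_stage_not_screened) + 1L
  st$state[dx] <- ST_A - 1L + stage[dx]
  st$diagnosed[dx] <- TRUE
  st$dx_stage[dx] <- stage[dx]
  st$ysd[dx] <- 0L
  st$track[dx] <- TR_NATURAL
  list(st = st, diagnosed_now = dx, stage = stage)
}

# Disease progression / adenoma incidence: at most one transition per cycle,
# evaluated on the state at the start of this step. Diagnosed cancers do not
# progress (their outcomes flow through the survival table).
k_progression <- function(st, lk, u) {
  alive <- st$state != ST_DEAD
  s0 <- st$state
  open <- alive & !st$diagnosed

  pi <- lk$prog_inc[age_ix(st$age)]
  li <- lk$low_inc[age_ix(st$age)]
  free <- open & s0 == ST_FREE
  to_high <- free & u < pi
  to_low <- free & !to_high & u < pi + li
  st$state[to_high] <- ST_HIGH
  st$state[to_low] <- ST_LOW

  up <- function(from, to, p) {
    m <- open & s0 == from & u < p
    st$state[m] <<- to
    m
  }
  up(ST_LOW, ST_HIGH, lk$trans[["low2high"]])
  up(ST_HIGH, ST_A, lk$trans[["high2crc"]])
  up(ST_A, ST_B, lk$trans[["a2b"]])
  up(ST_B, ST_C, lk$trans[["b2c"]])
  up(ST_C, ST_D, lk$trans[["c2d"]])
  st
}

# Quality-of-life weight for the cycle: anyone in a CRC health state carries
# the stage utility (whether or not the cancer has been diagnosed yet);
# cancer survivors (more than five years after diagnosis) and everyone free
# of CRC carry the age-band population norm; the dead contribute zero.
k_utility <- function(st, lk) {
  alive <- st$state != ST_DEAD
  u <- numeric(length(st$age))
  u[alive] <- lk$norm_u[age_ix(st$age[alive])]
  survivor <- st$diagnosed & !is.na(st$ysd) & st$ysd > 5L
  ill <- alive & st$state >= ST_A & st$state <= ST_D & !survivor
  u[ill] <- lk$stage_u[st$state[ill] - 3L]
  u
}

# ---- exported operations ----------------------------------------------------

#' One annual cycle of natural history
#'
#' Applies, in order: background and CRC mortality, symptomatic diagnosis,
#' and disease progression (adenoma incidence or one stage transition), then
#' increments age and the post-diagnosis clock. Screening and surveillance
#' are handled separately by [step_screening()] and [step_surveillance()];
#' the full engine interleaves all three in [run_arm()].
#'
#' @param cohort cohort tibble (see [sample_cohort()]); dead rows pass through
#'   unchanged.
#' @param params `crc_parameters`.
#' @param u optional list of uniform draws (`mortality`, `crc_mortality`,
#'   `diagnosis`, `dx_stage`, `progression`), each of length `nrow(cohort)`;
#'   drawn from
#'   the session RNG when omitted. Supplying them makes single transitions
#'   deterministic, e.g. a progression draw below 0.05 moves a high-risk
#'   adenoma to stage A cancer.
#' @return list with `cohort` (updated tibble) and `events` (tibble of
#'   transition events: `id`, `from_state`, `to_state`, `cause`).
#' @export
step_natural_history <- function(cohort, params, u = NULL) {
  st <- cohort_to_state(cohort)
  lk <- build_lookups(params)
  n <- length(st$age)
  if (is.null(u)) {
    u <- list(mortality = stats::runif(n), crc_mortality = stats::runif(n),
              diagnosis = stats::runif(n), dx_stage = stats::runif(n),
              progression = stats::runif(n))
  }
  before <- st$state
  mort <- k_mortality(st, lk, u$mortality, u$crc_mortality)
  st <- mort$st
  dx <- k_sympt_dx(st, lk, u$diagnosis, u$dx_stage)
  st <- dx$st
  st <- k_progression(st, lk, u$progression)

  alive <- st$state != ST_DEAD
  st$age[alive] <- st$age[alive] + 1L
  inc <- alive & st$diagnosed & !is.na(st$ysd)
  st$ysd[inc] <- st$ysd[inc] + 1L

  changed <- st$state != before | dx$diagnosed_now
  cause <- dplyr::case_when(
    mort$died_background ~ "background_death",
    mort$died_crc ~ "crc_death",
    dx$diagnosed_now ~ "symptomatic_diagnosis",
    before == ST_FREE & st$state %in% c(ST_LOW, ST_HIGH) ~ "adenoma_incidence",
    TRUE ~ "progression"
  )
  events <- tibble::tibble(
    id = st$id[changed],
    from_state = STATE_LEVELS[before[changed]],
    to_state = STATE_LEVELS[st$state[changed]],
    cause = cause[changed]
  )
  list(cohort = state_to_cohort(st), events = events)
}

#' Symptomatic diagnosis draw
#'
#' Annual probability that an undiagnosed cancer presents symptomatically,
#' by stage: A 0.22, B 0.35, C 0.59, D 1.00 (by default).
#'
#' @param stage character vector of stages `"A"`-`"D"`.
#' @param params `crc_parameters`.
#' @param u uniform draws (default: fresh draws), same length as `stage`.
#' @return logical vector: diagnosed this cycle.
#' @export
symptomatic_diagnosis <- function(stage, params = default_parameters(), u = NULL) {
  ix <- match(stage, STAGE_LEVELS)
  if (anyNA(ix)) stop("stage must be one of A, B, C, D", call. = FALSE)
  if (is.null(u)) u <- stats::runif(length(ix))
  u < params$sympt_dx$prob[ix]
}

#' One year of post-diagnosis survival
#'
#' Applies the stage- and year-specific CRC mortality (years 1-5 since
#' diagnosis) on top of background mortality for diagnosed individuals, and
#' advances the post-diagnosis clock. Beyond five years the CRC hazard is
#' zero (the individual is a cancer survivor subject to background mortality
#' only).
#'
#' @inheritParams step_natural_history
#' @return updated cohort tibble.
#' @export
survival_step <- function(cohort, params, u = NULL) {
  if (!all(cohort$diagnosed | !cohort$alive)) {
    stop("survival_step expects diagnosed (or dead) individuals", call. = FALSE)
  }
  st <- cohort_to_state(cohort)
  lk <- build_lookups(params)
  n <- length(st$age)
  if (is.null(u)) {
    u <- list(mortality = stats::runif(n), crc_mortality = stats::runif(n))
  }
  st <- k_mortality(st, lk, u$mortality, u$crc_mortality)$st
  alive <- st$state != ST_DEAD
  st$age[alive] <- st$age[alive] + 1L
  inc <- alive & st$diagnosed & !is.na(st$ysd)
  st$ysd[inc] <- st$ysd[inc] + 1L
  state_to_cohort(st)
}
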