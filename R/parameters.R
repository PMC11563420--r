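# Model parameters: calibrated natural-history, screening, cost and utility
# inputs for the bowel-cancer screening microsimulation, plus validation,
# derivation rules and probabilistic-sensitivity-analysis sampling.

# Internal state codes used throughout the engine.
ST_FREE <- 1L
ST_LOW <- 2L
ST_HIGH <- 3L
ST_A <- 4L
ST_B <- 5L
ST_C <- 6L
ST_D <- 7L
ST_DEAD <- 8L

TR_SCREEN <- 1L
TR_NATURAL <- 2L
TR_SURV <- 3L

STATE_LEVELS <- c(
  "free_of_disease", "low_risk_adenoma", "high_risk_adenoma",
  "CRC_A", "CRC_B", "CRC_C", "CRC_D", "dead"
)
TRACK_LEVELS <- c("screening", "natural_history", "surveillance")
STAGE_LEVELS <- c("A", "B", "C", "D")

# Eligible population totals (Victoria, 2019) used to spread program costs
# and to scale per-person outputs to population scale.
ELIGIBLE_POPULATION <- c(arabic = 17522, mandarin = 38660)

# Total one-year program delivery costs (2019 A$).
INTERVENTION_TOTAL_COST <- c(arabic = 120863, mandarin = 120337)

#' Default model parameters
#'
#' Builds the complete calibrated parameter set used by the microsimulation:
#' adenoma and colorectal cancer (CRC) incidence schedules, annual transition
#' probabilities along the adenoma-carcinoma pathway, screening positivity and
#' colonoscopy assessment rates by language group, stage distributions at
#' diagnosis by screening status, symptomatic diagnosis probabilities, a
#' stage- and year-specific post-diagnosis survival table, a background
#' mortality life table, a cost schedule (2019 Australian dollars) and a
#' utility schedule with the base-case 5% annual discount rate.
#'
#' Survival-by-stage and background mortality are not published as tables in
#' the evidence base this model transcribes; the packaged defaults are
#' synthetic stand-ins built by [gen_survival_table()] and [gen_life_table()]
#' with stage-graded five-year survival (A > B > C > D) and a Gompertz-shaped
#' life table. Replace them via the `survival` / `life_table` arguments of
#' [load_parameters()] when better data are available.
#'
#' @param group `"arabic"` or `"mandarin"`; sets the baseline screening
#'   participation rate (0.307 and 0.40 respectively). Positivity (6.4%) and
#'   colonoscopy assessment (54.3%) use the language-other-than-English rates
#'   for either group.
#' @return An object of class `crc_parameters`: a named list of tibbles and
#'   scalars. Key components: `adenoma_incidence`, `crc_incidence`,
#'   `transitions`, `sympt_dx`, `stage_dist`, `colonoscopy_prevalence`,
#'   `rates`, `survival`, `life_table`, `costs`, `utilities`, and structural
#'   constants (`max_age`, `surveillance_interval`, `surveillance_max_age`,
#'   `screening_ages`, `progressive_fraction`).
#' @examples
#' p <- default_parameters()
#' p$transitions
#' @export
default_parameters <- function(group = c("arabic", "mandarin")) {
  group <- match.arg(group)

  crc_incidence <- tibble::tibble(
    age_lo = c(50, 55, 60, 65, 70, 75, 80, 85),
    age_hi = c(54, 59, 64, 69, 74, 79, 84, 150),
    rate   = c(0.0007, 0.0008, 0.0012, 0.0016, 0.0019, 0.0026, 0.0031, 0.0037)
  )

  progressive_fraction <- 0.24
  progressive <- c(0.0038, 0.0041, 0.0062, 0.0068)
  all_adenoma <- progressive / progressive_fraction
  adenoma_incidence <- tibble::tibble(
    age_lo = c(50, 55, 60, 65),
    age_hi = c(54, 59, 64, 150),
    progressive = progressive,
    all = all_adenoma,
    low_risk = all_adenoma - progressive
  )

  # Printed table rows retained verbatim for audit; the derivation rule
  # (all = progressive / 0.24, low = all - progressive) supplies the
  # schedules actually simulated.
  adenoma_incidence_printed <- tibble::tibble(
    age_lo = c(50, 55, 60, 65),
    age_hi = c(54, 59, 64, 150),
    all = c(0.0012, 0.0015, 0.0019, 0.0025),
    low_risk = c(0.0160, 0.0173, 0.0257, 0.0282)
  )

  transitions <- tibble::tibble(
    from = c("low_risk_adenoma", "high_risk_adenoma", "CRC_A", "CRC_B", "CRC_C"),
    to   = c("high_risk_adenoma", "CRC_A", "CRC_B", "CRC_C", "CRC_D"),
    prob = c(0.02, 0.05, 0.05, 0.28, 0.28),
    low  = c(0.01, 0.02, 0.02, 0.10, 0.10),
    high = c(0.04, 0.10, 0.10, 0.50, 0.50)
  )

  sympt_dx <- tibble::tibble(
    stage = STAGE_LEVELS,
    prob = c(0.22, 0.35, 0.59, 1.00),
    low  = c(0.20, 0.25, 0.49, 0.90),
    high = c(0.24, 0.45, 0.69, 1.00)
  )

  stage_dist <- tibble::tibble(
    stage = STAGE_LEVELS,
    screened     = c(0.49, 0.19, 0.24, 0.08),
    not_screened = c(0.22, 0.32, 0.27, 0.19)
  )

  prev_raw <- c(free_of_disease = 0.8740, low_risk_adenoma = 0.0609,
                high_risk_adenoma = 0.0565, crc = 0.0313)
  colonoscopy_prevalence <- tibble::tibble(
    outcome = names(prev_raw),
    printed = unname(prev_raw),
    prob = unname(prev_raw / sum(prev_raw))
  )

  rates <- list(
    positivity = c(lote = 0.064, english = 0.069),
    colonoscopy_followup = c(lote = 0.543, english = 0.631),
    participation_baseline = c(arabic = 0.307, mandarin = 0.40)
  )

  costs <- list(
    fobt_kit = 8.00,
    packaging_postage = 2.40,
    lab_analysis = 17.85,
    gp_consult = 37.60,
    colonoscopy_no_polypectomy = 2258,
    colonoscopy_polypectomy = 4203,
    treatment_by_stage = c(A = 40999, B = 52594, C = 95754, D = 90272),
    treatment_range = tibble::tibble(
      stage = STAGE_LEVELS,
      low  = c(37657, 48307, 87948, 82913),
      high = c(46025, 59041, 107492, 101338)
    ),
    reference_year = 2019
  )

  utilities <- list(
    stage = c(A = 0.74, B = 0.74, C = 0.74, D = 0.68),
    norm = tibble::tibble(
      age_lo = c(50, 70, 80),
      age_hi = c(69, 79, 150),
      utility = c(0.80, 0.76, 0.70)
    ),
    discount_rate = 0.05,
    wtp_threshold = 50000
  )

  params <- structure(list(
    group = group,
    crc_incidence = crc_incidence,
    adenoma_incidence = adenoma_incidence,
    adenoma_incidence_printed = adenoma_incidence_printed,
    progressive_fraction = progressive_fraction,
    transitions = transitions,
    sympt_dx = sympt_dx,
    stage_dist = stage_dist,
    colonoscopy_prevalence = colonoscopy_prevalence,
    rates = rates,
    survival = gen_survival_table(),
    life_table = gen_life_table(),
    costs = costs,
    utilities = utilities,
    max_age = 100L,
    surveillance_interval = 5L,
    surveillance_max_age = 75L,
    screening_ages = seq(50L, 74L, by = 2L),
    eligible_population = ELIGIBLE_POPULATION[[group]],
    intervention_total_cost = INTERVENTION_TOTAL_COST[[group]]
  ), class = "crc_parameters")

  validate_parameters(params)
}

#' Load and validate model parameters
#'
#' Starts from the packaged defaults and applies user overrides, then runs the
#' full validation suite. Overrides may replace whole components (for example
#' a user-supplied `survival` table read from CSV) or scalar rates.
#'
#' @param group language group for the defaults.
#' @param ... named components of the `crc_parameters` object to replace,
#'   e.g. `survival = my_survival_tbl`, `utilities = modified_utilities`.
#' @return A validated `crc_parameters` object.
#' @seealso [default_parameters()], [write_parameters()], [read_parameters()]
#' @export
load_parameters <- function(group = c("arabic", "mandarin"), ...) {
  params <- default_parameters(group)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad)) {
      stop("unknown parameter component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  }
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every probability lies in \[0, 1\], that the stage distributions and
#' colonoscopy prevalence are normalised (sum to 1 within 1e-9), that the
#' adenoma-incidence derivation identities hold (`all = progressive /
#' progressive_fraction`, `low_risk = all - progressive`), that uncertainty
#' ranges bracket their point values, that age bands partition \[50, max_age\],
#' and that costs are non-negative. Errors name the offending field.
#'
#' @param params a `crc_parameters` object.
#' @return `params`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "crc_parameters"))
  check_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("probability out of [0, 1] in field: ", field, call. = FALSE)
    }
  }
  check_prob(params$crc_incidence$rate, "crc_incidence$rate")
  check_prob(params$adenoma_incidence$progressive, "adenoma_incidence$progressive")
  check_prob(params$adenoma_incidence$all, "adenoma_incidence$all")
  check_prob(params$adenoma_incidence$low_risk, "adenoma_incidence$low_risk")
  check_prob(params$transitions$prob, "transitions$prob")
  check_prob(params$sympt_dx$prob, "sympt_dx$prob")
  check_prob(params$stage_dist$screened, "stage_dist$screened")
  check_prob(params$stage_dist$not_screened, "stage_dist$not_screened")
  check_prob(params$colonoscopy_prevalence$prob, "colonoscopy_prevalence$prob")
  check_prob(params$rates$positivity, "rates$positivity")
  check_prob(params$rates$colonoscopy_followup, "rates$colonoscopy_followup")
  check_prob(params$rates$participation_baseline, "rates$participation_baseline")
  check_prob(params$survival$survival, "survival$survival")
  check_prob(params$life_table$qx, "life_table$qx")
  check_prob(params$utilities$stage, "utilities$stage")
  check_prob(params$utilities$norm$utility, "utilities$norm$utility")

  if (abs(sum(params$stage_dist$screened) - 1) > 1e-9) {
    stop("stage_dist$screened does not sum to 1", call. = FALSE)
  }
  if (abs(sum(params$stage_dist$not_screened) - 1) > 1e-9) {
    stop("stage_dist$not_screened does not sum to 1", call. = FALSE)
  }
  if (abs(sum(params$colonoscopy_prevalence$prob) - 1) > 1e-9) {
    stop("colonoscopy_prevalence$prob does not sum to 1", call. = FALSE)
  }

  ai <- params$adenoma_incidence
  if (max(abs(ai$all - ai$progressive / params$progressive_fraction)) > 1e-12 ||
      max(abs(ai$low_risk - (ai$all - ai$progressive))) > 1e-12) {
    stop("adenoma_incidence violates the derivation identities", call. = FALSE)
  }

  band_check <- function(tbl, field) {
    if (tbl$age_lo[1] != 50) stop(field, " bands must start at age 50", call. = FALSE)
    if (nrow(tbl) > 1 && any(tbl$age_lo[-1] != tbl$age_hi[-nrow(tbl)] + 1)) {
      stop(field, " bands do not partition the age range", call. = FALSE)
    }
    if (tbl$age_hi[nrow(tbl)] < params$max_age) {
      stop(field, " bands do not reach max_age", call. = FALSE)
    }
  }
  band_check(params$crc_incidence, "crc_incidence")
  band_check(params$adenoma_incidence, "adenoma_incidence")

  dr <- params$utilities$discount_rate
  if (!is.finite(dr) || dr < 0 || dr >= 1) {
    stop("utilities$discount_rate out of [0, 1)", call. = FALSE)
  }

  cost_scalars <- unlist(params$costs[c(
    "fobt_kit", "packaging_postage", "lab_analysis", "gp_consult",
    "colonoscopy_no_polypectomy", "colonoscopy_polypectomy", "treatment_by_stage"
  )])
  if (any(cost_scalars < 0)) stop("negative cost in costs schedule", call. = FALSE)
  tr <- params$costs$treatment_range
  tv <- unname(params$costs$treatment_by_stage)
  if (any(tr$low > tv) || any(tr$high < tv)) {
    stop("treatment cost ranges do not bracket point values", call. = FALSE)
  }

  with_range <- list(
    c("transitions", "prob"), c("sympt_dx", "prob")
  )
  for (w in with_range) {
    tbl <- params[[w[1]]]
    if (any(tbl$low > tbl[[w[2]]]) || any(tbl$high < tbl[[w[2]]])) {
      stop(w[1], " ranges do not bracket point values", call. = FALSE)
    }
  }

  sv <- params$survival
  if (!all(c("stage", "year", "survival") %in% names(sv))) {
    stop("survival table must have columns stage, year, survival", call. = FALSE)
  }
  missing_sv <- setdiff(
    paste(rep(STAGE_LEVELS, each = 5), rep(1:5, 4)),
    paste(sv$stage, sv$year)
  )
  if (length(missing_sv)) {
    stop("survival table missing entries: ", paste(missing_sv, collapse = ", "),
         call. = FALSE)
  }

  lt <- params$life_table
  if (min(lt$age) > 50 || max(lt$age) < params$max_age) {
    stop("life_table must cover ages 50 to max_age", call. = FALSE)
  }

  invisible(params)
}

#' @export
print.crc_parameters <- function(x, ...) {
  cat("<crc_parameters>  group:", x$group, "\n")
  cat("  eligible population:", x$eligible_population,
      " | program cost: $", format(x$intervention_total_cost, big.mark = ","), "\n", sep = "")
  cat("  discount rate:", x$utilities$discount_rate,
      "| WTP threshold: $", x$utilities$wtp_threshold, "/QALY\n")
  cat("  screening ages:", paste(range(x$screening_ages), collapse = "-"),
      "(biennial) | surveillance every", x$surveillance_interval,
      "y to age", x$surveillance_max_age, "\n")
  invisible(x)
}

#' Derive adenoma incidence schedules from CRC incidence
#'
#' The progressive-adenoma incidence at an age band is defined as the CRC
#' incidence 20 years later (a band at ages 50-54 takes the cancer incidence
#' of ages 70-74), reflecting the mean adenoma-carcinoma dwell time. The
#' all-adenoma schedule divides by the proportion of adenomas that are
#' progressive, and the low-risk schedule is the remainder.
#'
#' @param crc_incidence tibble with columns `age_lo`, `age_hi`, `rate` in
#'   5-year bands from age 50.
#' @param progressive_fraction proportion of all adenomas that become
#'   progressive (default 0.24).
#' @param shift_years dwell-time shift (default 20, i.e. four 5-year bands).
#' @return tibble with columns `age_lo`, `age_hi`, `progressive`, `all`,
#'   `low_risk`, one row per band whose 20-year shift stays inside the
#'   schedule. The identities `all == progressive / progressive_fraction` and
#'   `low_risk == all - progressive` hold exactly.
#' @examples
#' derive_adenoma_incidence(default_parameters()$crc_incidence)
#' @export
derive_adenoma_incidence <- function(crc_incidence,
                                     progressive_fraction = 0.24,
                                     shift_years = 20) {
  if (!(progressive_fraction > 0 && progressive_fraction <= 1)) {
    stop("progressive_fraction must be in (0, 1]", call. = FALSE)
  }
  band_width <- 5
  shift_bands <- shift_years / band_width
  if (shift_bands != round(shift_bands)) {
    stop("shift_years must be a multiple of the 5-year band width", call. = FALSE)
  }
  n <- nrow(crc_incidence)
  if (n <= shift_bands) {
    stop("the ", shift_years, "-year shift falls outside the schedule for band ",
         crc_incidence$age_lo[1], "-", crc_incidence$age_hi[1],
         " (schedule too short)", call. = FALSE)
  }
  keep <- seq_len(n - shift_bands)
  progressive <- crc_incidence$rate[keep + shift_bands]
  tibble::tibble(
    age_lo = crc_incidence$age_lo[keep],
    age_hi = crc_incidence$age_hi[keep],
    progressive = progressive,
    all = progressive / progressive_fraction,
    low_risk = progressive / progressive_fraction - progressive
  )
}

# ---- serialization ---------------------------------------------------------

#' Write / read a parameter set as plain-text CSV tables
#'
#' `write_parameters()` serialises a `crc_parameters` object to a directory of
#' CSV files (one per component: incidence schedules, transitions, costs,
#' utilities, survival, life table, scalars), with full double precision so a
#' round trip is bit-identical. `read_parameters()` reads the directory back.
#'
#' @param params a `crc_parameters` object.
#' @param dir directory to write to / read from.
#' @return `write_parameters()` returns `dir` invisibly; `read_parameters()`
#'   returns a validated `crc_parameters` object.
#' @export
write_parameters <- function(params, dir) {
  stopifnot(inherits(params, "crc_parameters"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(
      as.data.frame(lapply(df, function(col) {
        if (is.double(col)) sprintf("%.17g", col) else col
      })),
      file.path(dir, paste0(name, ".csv")), row.names = FALSE
    )
  }
  wr(params$crc_incidence, "crc_incidence")
  wr(params$adenoma_incidence, "adenoma_incidence")
  wr(params$adenoma_incidence_printed, "adenoma_incidence_printed")
  wr(params$transitions, "transitions")
  wr(params$sympt_dx, "sympt_dx")
  wr(params$stage_dist, "stage_dist")
  wr(params$colonoscopy_prevalence, "colonoscopy_prevalence")
  wr(params$survival, "survival")
  wr(params$life_table, "life_table")
  wr(params$costs$treatment_range, "treatment_range")
  wr(params$utilities$norm, "utility_norm")
  scalars <- tibble::tibble(
    name = c(
      "group", "progressive_fraction",
      paste0("positivity_", names(params$rates$positivity)),
      paste0("followup_", names(params$rates$colonoscopy_followup)),
      paste0("participation_", names(params$rates$participation_baseline)),
      "fobt_kit", "packaging_postage", "lab_analysis", "gp_consult",
      "colonoscopy_no_polypectomy", "colonoscopy_polypectomy",
      paste0("treatment_", STAGE_LEVELS),
      "reference_year",
      paste0("utility_stage_", STAGE_LEVELS),
      "discount_rate", "wtp_threshold",
      "max_age", "surveillance_interval", "surveillance_max_age",
      "eligible_population", "intervention_total_cost"
    ),
    value = c(
      params$group, sprintf("%.17g", params$progressive_fraction),
      sprintf("%.17g", params$rates$positivity),
      sprintf("%.17g", params$rates$colonoscopy_followup),
      sprintf("%.17g", params$rates$participation_baseline),
      sprintf("%.17g", c(
        params$costs$fobt_kit, params$costs$packaging_postage,
        params$costs$lab_analysis, params$costs$gp_consult,
        params$costs$colonoscopy_no_polypectomy,
        params$costs$colonoscopy_polypectomy,
        params$costs$treatment_by_stage
      )),
      as.character(params$costs$reference_year),
      sprintf("%.17g", params$utilities$stage),
      sprintf("%.17g", c(params$utilities$discount_rate,
                         params$utilities$wtp_threshold)),
      as.character(c(params$max_age, params$surveillance_interval,
                     params$surveillance_max_age)),
      sprintf("%.17g", c(params$eligible_population,
                         params$intervention_total_cost))
    )
  )
  utils::write.csv(scalars, file.path(dir, "scalars.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(dir) {
  rd <- function(name, num_cols) {
    df <- utils::read.csv(file.path(dir, paste0(name, ".csv")),
                          stringsAsFactors = FALSE)
    for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
    tibble::as_tibble(df)
  }
  sc <- utils::read.csv(file.path(dir, "scalars.csv"), stringsAsFactors = FALSE)
  sval <- function(nm) sc$value[match(nm, sc$name)]
  nval <- function(nm) as.numeric(sval(nm))

  params <- default_parameters(sval("group"))
  params$crc_incidence <- rd("crc_incidence", c("age_lo", "age_hi", "rate"))
  params$adenoma_incidence <- rd(
    "adenoma_incidence", c("age_lo", "age_hi", "progressive", "all", "low_risk"))
  params$adenoma_incidence_printed <- rd(
    "adenoma_incidence_printed", c("age_lo", "age_hi", "all", "low_risk"))
  params$transitions <- rd("transitions", c("prob", "low", "high"))
  params$sympt_dx <- rd("sympt_dx", c("prob", "low", "high"))
  params$stage_dist <- rd("stage_dist", c("screened", "not_screened"))
  params$colonoscopy_prevalence <- rd("colonoscopy_prevalence", c("printed", "prob"))
  params$survival <- rd("survival", "survival")       # year stays integer
  params$life_table <- rd("life_table", "qx")         # age stays integer
  params$progressive_fraction <- nval("progressive_fraction")
  params$rates <- list(
    positivity = c(lote = nval("positivity_lote"),
                   english = nval("positivity_english")),
    colonoscopy_followup = c(lote = nval("followup_lote"),
                             english = nval("followup_english")),
    participation_baseline = c(arabic = nval("participation_arabic"),
                               mandarin = nval("participation_mandarin"))
  )
  params$costs$fobt_kit <- nval("fobt_kit")
  params$costs$packaging_postage <- nval("packaging_postage")
  params$costs$lab_analysis <- nval("lab_analysis")
  params$costs$gp_consult <- nval("gp_consult")
  params$costs$colonoscopy_no_polypectomy <- nval("colonoscopy_no_polypectomy")
  params$costs$colonoscopy_polypectomy <- nval("colonoscopy_polypectomy")
  params$costs$treatment_by_stage <- stats::setNames(
    nval(paste0("treatment_", STAGE_LEVELS)), STAGE_LEVELS)
  params$costs$treatment_range <- rd("treatment_range", c("low", "high"))
  params$costs$reference_year <- nval("reference_year")
  params$utilities$stage <- stats::setNames(
    nval(paste0("utility_stage_", STAGE_LEVELS)), STAGE_LEVELS)
  params$utilities$norm <- rd("utility_norm", c("age_lo", "age_hi", "utility"))
  params$utilities$discount_rate <- nval("discount_rate")
  params$utilities$wtp_threshold <- nval("wtp_threshold")
  params$max_age <- as.integer(nval("max_age"))
  params$surveillance_interval <- as.integer(nval("surveillance_interval"))
  params$surveillance_max_age <- as.integer(nval("surveillance_max_age"))
  params$eligible_population <- nval("eligible_population")
  params$intervention_total_cost <- nval("intervention_total_cost")
  validate_parameters(params)
}

# ---- probabilistic sensitivity analysis ------------------------------------

#' PSA sampling specification
#'
#' Describes the probabilistic sensitivity analysis: number of Monte Carlo
#' trials, patients per trial, and which parameters are resampled. Every
#' parameter with a printed uncertainty range (stage transition probabilities,
#' symptomatic diagnosis probabilities, stage-specific treatment costs) is
#' drawn uniformly over its (min, max) range; parameters without a printed
#' range stay fixed at the base case.
#'
#' @param n_trials Monte Carlo trials (the reference analysis uses 2000;
#'   smaller counts are appropriate for desk runs).
#' @param n_patients patients simulated per trial (default 10000).
#' @param sample_transitions,sample_sympt_dx,sample_treatment_costs logical;
#'   switch off a block to collapse its ranges to the point value.
#' @return a `psa_spec` list.
#' @export
psa_spec <- function(n_trials = 2000, n_patients = 10000,
                     sample_transitions = TRUE,
                     sample_sympt_dx = TRUE,
                     sample_treatment_costs = TRUE) {
  structure(list(
    n_trials = as.integer(n_trials),
    n_patients = as.integer(n_patients),
    sample_transitions = isTRUE(sample_transitions),
    sample_sympt_dx = isTRUE(sample_sympt_dx),
    sample_treatment_costs = isTRUE(sample_treatment_costs)
  ), class = "psa_spec")
}

#' Draw one complete parameter set for a PSA trial
#'
#' Resamples every ranged parameter uniformly over its printed (min, max)
#' range and returns a full, validated `crc_parameters` object; unranged
#' parameters are carried over unchanged. Reproducible given the RNG state
#' (call `set.seed()` before a stream of draws, or pass `seed`).
#'
#' @param params base-case parameters.
#' @param spec a [psa_spec()].
#' @param seed optional integer; if supplied the draw is independently
#'   reproducible.
#' @return a validated `crc_parameters` object.
#' @export
draw_psa_parameters <- function(params, spec = psa_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- params
  if (spec$sample_transitions) {
    out$transitions$prob <- stats::runif(
      nrow(out$transitions), out$transitions$low, out$transitions$high)
  }
  if (spec$sample_sympt_dx) {
    out$sympt_dx$prob <- stats::runif(
      nrow(out$sympt_dx), out$sympt_dx$low, out$sympt_dx$high)
  }
  if (spec$sample_treatment_costs) {
    rng <- out$costs$treatment_range
    out$costs$treatment_by_stage <- stats::setNames(
      stats::runif(nrow(rng), rng$low, rng$high), rng$stage)
    # keep the bracket invariant intact for the drawn values
    out$costs$treatment_range <- rng
  }
  validate_parameters(out)
}
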