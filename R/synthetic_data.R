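# Synthetic stand-ins for inputs the analysis needs but that are not
# published as reusable tables: census single-year-of-age populations,
# stage-specific post-diagnosis survival, background-mortality life tables,
# and screening-register style monthly kit-return series with known truth.

#' Generate census-style population tables for two census years
#'
#' Produces smooth single-year-of-age counts for ages 50-74 at the 2016 and
#' 2021 census endpoints such that linear interpolation to the target year
#' (2019 by default) reproduces the requested eligible-population total
#' exactly. The age profile declines geometrically with age, which mimics the
#' shape of migrant-community age pyramids in this age range; the 2021/2016
#' growth ratio defaults to 1.25 (steadily growing communities).
#'
#' The defaults solve to the two eligible-population totals used throughout
#' the analysis: 17,522 (Arabic) and 38,660 (Mandarin) at 2019.
#'
#' @param group `"arabic"` or `"mandarin"`, or use `target_total` directly.
#' @param target_total eligible persons aged 50-74 at `target_year`.
#' @param target_year year the interpolated total must hit (between the
#'   census years).
#' @param growth ratio of 2021 total to 2016 total.
#' @param decay per-year-of-age geometric decline of counts (0.96 means each
#'   age holds 4% fewer people than the age below).
#' @return tibble with columns `age`, `count_2016`, `count_2021` (integers)
#'   whose interpolated total at `target_year` equals `target_total` exactly.
#' @examples
#' cen <- gen_census_tables("arabic")
#' pop <- interpolate_population(cen, target_year = 2019)
#' sum(pop$count) # 17522
#' @export
gen_census_tables <- function(group = c("arabic", "mandarin"),
                              target_total = NULL,
                              target_year = 2019,
                              growth = 1.25,
                              decay = 0.96) {
  if (is.null(target_total)) {
    group <- match.arg(group)
    target_total <- ELIGIBLE_POPULATION[[group]]
  }
  if (target_total <= 0) stop("target_total must be positive", call. = FALSE)
  if (growth <= 0) stop("growth ratio must be positive", call. = FALSE)
  y0 <- 2016; y1 <- 2021
  if (target_year < y0 || target_year > y1) {
    stop("target_year must lie between the census years", call. = FALSE)
  }
  # interpolation weights: total = w0 * T0 + w1 * T1 must equal target exactly
  w1 <- (target_year - y0) / (y1 - y0)
  w0 <- 1 - w1
  # choose integer endpoint totals T0, T1 with T1 ~ growth * T0 solving the
  # weighted sum exactly; weights are multiples of 1/5 so integer solutions
  # exist whenever target_total is an integer
  denom_frac <- (y1 - y0)                       # weights are k/denom_frac
  k1 <- round(w1 * denom_frac)                  # e.g. 3 for 2019
  k0 <- denom_frac - k1                         # e.g. 2
  scaled_target <- target_total * denom_frac    # k0*T0 + k1*T1 = this
  t0 <- round(scaled_target / (k0 + k1 * growth))
  # adjust t0 so the remainder is divisible by k1
  while ((scaled_target - k0 * t0) %% k1 != 0) t0 <- t0 + 1
  t1 <- (scaled_target - k0 * t0) / k1
  if (t1 <= 0) stop("infeasible totals: growth/target combination", call. = FALSE)

  ages <- 50:74
  shape <- decay^(ages - 50)
  alloc <- function(total) {
    # largest-remainder apportionment so integer counts hit the total exactly
    raw <- shape / sum(shape) * total
    base <- floor(raw)
    rem <- total - sum(base)
    if (rem > 0) {
      top <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[top] <- base[top] + 1
    }
    as.integer(base)
  }
  tibble::tibble(age = ages, count_2016 = alloc(t0), count_2021 = alloc(t1))
}

#' Generate a stage- and year-specific post-diagnosis survival table
#'
#' Builds conditional annual survival probabilities for years 1-5 after a CRC
#' diagnosis, per stage, whose cumulative products hit the requested 5-year
#' survival targets exactly. The annual hazard declines geometrically with
#' time since diagnosis (`shape` < 1 puts the heaviest mortality in year 1,
#' the usual pattern for cancer survival curves).
#'
#' These defaults are a documented synthetic approximation with the standard
#' stage gradient (A best, D worst); they are not registry values.
#'
#' @param five_year 5-year cumulative survival targets, named A-D, ordered
#'   A >= B >= C >= D.
#' @param shape geometric decay of the annual log-hazard (1 = constant).
#' @return tibble with columns `stage`, `year` (1-5), `survival` (conditional
#'   probability of surviving year `year` given alive at its start).
#' @examples
#' sv <- gen_survival_table()
#' # cumulative 5-year survival recovers the targets
#' tapply(sv$survival, sv$stage, prod)
#' @export
gen_survival_table <- function(five_year = c(A = 0.95, B = 0.85, C = 0.65, D = 0.15),
                               shape = 0.7) {
  if (is.unsorted(rev(five_year))) {
    stop("five_year survival targets must be ordered A >= B >= C >= D",
         call. = FALSE)
  }
  if (any(five_year <= 0 | five_year > 1)) {
    stop("five_year targets must be in (0, 1]", call. = FALSE)
  }
  w <- shape^(0:4)
  w <- w / sum(w)
  tibble::tibble(
    stage = rep(names(five_year), each = 5),
    year = rep(1:5, length(five_year)),
    survival = as.numeric(vapply(
      five_year, function(s5) exp(log(s5) * w), numeric(5)
    ))
  )
}

#' Generate a background-mortality life table
#'
#' Gompertz-shaped annual probabilities of death from ages 50 to `max_age`,
#' with death forced at `max_age` (the model's ceiling). Defaults approximate
#' the level and slope of an Australian period life table in this age range:
#' about 0.2% at 50, doubling roughly every 6.6 years. A documented synthetic
#' approximation, not official life-table values.
#'
#' @param q50 annual probability of death at age 50.
#' @param slope Gompertz log-slope per year of age.
#' @param max_age ceiling age at which death is certain.
#' @return tibble with columns `age`, `qx`, monotone non-decreasing in age.
#' @export
gen_life_table <- function(q50 = 0.002, slope = 0.105, max_age = 100L) {
  ages <- 50:max_age
  qx <- pmin(q50 * exp(slope * (ages - 50)), 1)
  qx[ages >= max_age] <- 1
  tibble::tibble(age = as.integer(ages), qx = qx)
}

#' Generate monthly kit-return series with known ground truth
#'
#' Emulates screening-register extracts for an interrupted-time-series
#' effectiveness analysis: monthly counts of FOBT kits returned with the
#' number of kits sent as an offset, for a control period (2018) and an
#' intervention period (2019), March through November. Returns are negative
#' binomial around `rate * kits_sent`, with the intervention period's rate
#' multiplied by a known true incidence rate ratio so estimators can be
#' checked against the generating truth.
#'
#' @param base_rate monthly kit-return rate in the control period.
#' @param true_irr multiplicative effect on the return rate in the
#'   intervention period (the recoverable truth).
#' @param kits_sent_per_month offset: kits mailed each month (recycled over
#'   the 9 months).
#' @param dispersion negative-binomial size parameter; larger is closer to
#'   Poisson.
#' @param area label attached to both periods.
#' @param seed optional integer seed.
#' @return tibble with columns `area`, `period` (`"control"`/`"intervention"`),
#'   `month` (3-11), `kits_sent`, `kits_returned`, and attribute `true_irr`.
#' @export
gen_monthly_kit_series <- function(base_rate = 0.40,
                                   true_irr = 1.18,
                                   kits_sent_per_month = 3000,
                                   dispersion = 50,
                                   area = "synthetic",
                                   seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (base_rate <= 0 || base_rate * true_irr > 1) {
    stop("rates must stay within (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  months <- 3:11
  sent <- as.integer(rep_len(kits_sent_per_month, length(months)))
  draw <- function(rate) {
    mu <- rate * sent
    pmin(stats::rnbinom(length(sent), mu = mu, size = dispersion), sent)
  }
  out <- tibble::tibble(
    area = area,
    period = rep(c("control", "intervention"), each = length(months)),
    month = rep(months, 2),
    kits_sent = rep(sent, 2),
    kits_returned = c(draw(base_rate), draw(base_rate * true_irr))
  )
  attr(out, "true_irr") <- true_irr
  out
}
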