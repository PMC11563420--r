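# Cohort construction: interpolate census counts to the analysis year and
# sample simulated individuals by age.

#' Interpolate census populations to a target year
#'
#' Linear interpolation between two census years, per single year of age.
#'
#' @param census tibble with columns `age`, `count_2016`, `count_2021`
#'   covering ages 50-74 (as from [gen_census_tables()]).
#' @param target_year year between the censuses (inclusive).
#' @return tibble with columns `age`, `count` (possibly fractional persons)
#'   and attribute `total`.
#' @examples
#' cen <- tibble::tibble(age = 50, count_2016 = 100, count_2021 = 150)
#' interpolate_population(cen, 2019)$count # 130
#' @export
interpolate_population <- function(census, target_year = 2019) {
  req <- c("age", "count_2016", "count_2021")
  if (!all(req %in% names(census))) {
    stop("census table must have columns age, count_2016, count_2021",
         call. = FALSE)
  }
  if (anyNA(census[req])) stop("census table contains missing values", call. = FALSE)
  if (target_year < 2016 || target_year > 2021) {
    stop("target_year must lie in [2016, 2021]", call. = FALSE)
  }
  w <- (target_year - 2016) / 5
  out <- tibble::tibble(
    age = as.integer(census$age),
    count = (1 - w) * census$count_2016 + w * census$count_2021
  )
  attr(out, "total") <- sum(out$count)
  out
}

#' Sample a simulation cohort from a population table
#'
#' Draws `n` individuals with ages proportional to the population counts.
#' Everyone enters free of disease, undiagnosed, alive, and in the screening
#' track (the screening pathway itself decides, via the participation draw at
#' each invitation, who effectively follows natural history only).
#'
#' @param pop_table tibble with columns `age`, `count`.
#' @param n cohort size (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return tibble of individuals: `id`, `age`, `health_state`, `diagnosed`,
#'   `years_since_diagnosis`, `screening_track`, `years_since_last_surveillance`,
#'   `alive`.
#' @export
sample_cohort <- function(pop_table, n, seed = NULL) {
  if (!all(c("age", "count") %in% names(pop_table)) || nrow(pop_table) == 0) {
    stop("pop_table must be a nonempty table with columns age, count",
         call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (all(pop_table$count <= 0)) stop("all population counts are zero", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- sample.int(nrow(pop_table), size = n, replace = TRUE,
                     prob = pop_table$count / sum(pop_table$count))
  ages <- pop_table$age[rows]
  tibble::tibble(
    id = seq_len(n),
    age = as.integer(ages),
    health_state = factor("free_of_disease", levels = STATE_LEVELS),
    diagnosed = FALSE,
    years_since_diagnosis = NA_integer_,
    screening_track = factor("screening", levels = TRACK_LEVELS),
    years_since_last_surveillance = NA_integer_,
    alive = TRUE
  )
}
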