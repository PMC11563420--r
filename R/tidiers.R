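# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an arm result
#'
#' @param x an `arm_result`.
#' @param ... unused.
#' @return one-row tibble of per-person outcomes and counts.
#' @export
tidy.arm_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario_name,
    cost_pp = x$cost_pp,
    qaly_pp = x$qaly_pp,
    cost_pp_undisc = x$cost_pp_undisc,
    qaly_pp_undisc = x$qaly_pp_undisc,
    detected = x$detected,
    crc_cases = x$crc_cases,
    crc_deaths = x$crc_deaths,
    n = x$n,
    horizon = x$horizon,
    discount_rate = x$discount_rate
  )
}

#' Tidy a cost-utility comparison
#'
#' @param x a `cua_result`.
#' @param ... unused.
#' @return tibble with one row per arm (costs, QALYs, detections).
#' @export
tidy.cua_result <- function(x, ...) {
  dplyr::bind_rows(tidy(x$base), tidy(x$intervention))
}

#' One-row summary of a cost-utility comparison
#'
#' @param x a `cua_result`.
#' @param ... unused.
#' @return one-row tibble: incremental cost, incremental QALYs, ICER,
#'   dominance, threshold flag, additional detections.
#' @export
glance.cua_result <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost,
    delta_qaly = x$delta_qaly,
    icer = x$icer,
    dominance = x$dominance,
    below_wtp = x$below_wtp,
    delta_detected = x$delta_detected
  )
}

#' Tidy PSA trials
#'
#' @param x a `psa_result`.
#' @param ... unused.
#' @return the per-trial tibble.
#' @export
tidy.psa_result <- function(x, ...) x$trials

#' One-row PSA summary
#'
#' @param x a `psa_result`.
#' @param ... unused.
#' @return one-row tibble: mean ICER, 95% uncertainty interval, fraction of
#'   trials cost-effective, undefined-trial count.
#' @export
glance.psa_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_trials = nrow(x$trials),
    n_patients = x$spec$n_patients,
    mean_icer = s$mean_icer,
    icer_lo = s$icer_lo,
    icer_hi = s$icer_hi,
    frac_below_wtp = s$frac_below_wtp,
    n_undefined = s$n_undefined
  )
}

#' Cost-effectiveness plane for a PSA
#'
#' Scatter of per-trial incremental QALYs against incremental costs with the
#' willingness-to-pay threshold line.
#'
#' @param object a `psa_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.psa_result <- function(object, ...) {
  tr <- object$trials
  ggplot2::ggplot(tr, ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(
      x = "Incremental QALYs per person",
      y = "Incremental cost per person (A$)",
      title = sprintf("Cost-effectiveness plane (+%.1f pp participation)",
                      object$uplift_pp),
      subtitle = sprintf("dashed line: $%s per QALY",
                         format(object$wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' State occupancy over time for a simulated arm
#'
#' Stacked view of the cohort's distribution over natural-history categories
#' (free of disease, adenomas, undiagnosed stages, diagnosed cancer, dead) at
#' the end of each cycle.
#'
#' @param object an `arm_result` (occupancy is always recorded).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.arm_result <- function(object, ...) {
  occ <- tibble::as_tibble(object$occupancy)
  occ$cycle <- seq_len(nrow(occ)) - 1L
  long <- tidyr::pivot_longer(occ, -cycle, names_to = "category",
                              values_to = "count")
  long$category <- factor(long$category, levels = colnames(object$occupancy))
  ggplot2::ggplot(long, ggplot2::aes(cycle, count / object$n, fill = category)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (years from 2019)", y = "Proportion of cohort",
                  fill = NULL, title = object$scenario_name) +
    ggplot2::theme_minimal()
}

#' Summary table in the layout of the published results
#'
#' Renders a base-case arm and one or more intervention comparisons as a
#' single tibble: mean QALYs and healthcare costs per person, incremental
#' cost, incremental QALYs, ICER and detected cases per arm.
#'
#' @param cuas named list of `cua_result`s sharing the same base arm.
#' @return tibble with one column per arm.
#' @export
summary_table <- function(cuas) {
  stopifnot(length(cuas) >= 1)
  base <- cuas[[1]]$base
  cols <- c(
    list(`Base case` = c(
      incremental_cost = NA, incremental_qalys = NA, icer = NA,
      mean_qalys_pp = base$qaly_pp, mean_cost_pp = base$cost_pp,
      cases_detected = base$detected
    )),
    purrr::imap(cuas, function(x, nm) c(
      incremental_cost = x$delta_cost, incremental_qalys = x$delta_qaly,
      icer = x$icer, mean_qalys_pp = x$intervention$qaly_pp,
      mean_cost_pp = x$intervention$cost_pp,
      cases_detected = x$intervention$detected
    ))
  )
  out <- tibble::as_tibble(cols)
  out <- dplyr::mutate(out, measure = c(
    "Incremental cost ($/person)", "Incremental QALYs",
    "ICER ($/QALY)", "Mean QALYs per person",
    "Mean healthcare cost per person ($)", "Adenoma+cancer cases detected"
  ), .before = 1)
  out
}
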