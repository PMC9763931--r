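#' Extract index components from raw measurement tables
#'
#' Runs the measurement-level models over every animal of a cohort:
#' logistic concentration-response fits for acetylcholine and nitroprusside
#' (component = fitted upper bound), pass-through of the single hypoxic
#' dilation, the exponential stress-strain fit over each passive
#' pressure-diameter series (component = stiffness coefficient beta, withheld
#' when the fit's log-scale r^2 fails the acceptance rule), and microvessel
#' density. Unconverged or rejected fits drop the affected component with a
#' diagnostic row rather than failing the run.
#'
#' @param cohort A `vhi_cohort` from [read_cohort()] or [simulate_cohort()].
#' @param r2_threshold Stress-strain acceptance threshold (default 0.85).
#' @return List with `components` (tidy tibble: `animal_id`, `bed`,
#'   `component`, `value`), `reactivity_fits` (per-series logistic
#'   diagnostics), and `mechanics_fits` (per-vessel stress-strain
#'   diagnostics).
#' @export
compute_components <- function(cohort, r2_threshold = 0.85) {
  stopifnot(inherits(cohort, "vhi_cohort"))
  comps <- list(); react <- list(); mech <- list()
  agonist_component <- c(acetylcholine = "ach_dilation",
                         nitroprusside = "snp_dilation")

  if (nrow(cohort$dose_response) > 0) {
    series_list <- split(
      cohort$dose_response,
      list(cohort$dose_response$animal_id, cohort$dose_response$bed,
           cohort$dose_response$agonist),
      drop = TRUE
    )
    for (s in series_list) {
      fit <- tryCatch(fit_logistic(s$log_conc, s$response_um),
                      error = function(e) e)
      failed <- inherits(fit, "error") || !isTRUE(fit$converged)
      react[[length(react) + 1]] <- tibble::tibble(
        animal_id = s$animal_id[1], bed = s$bed[1], agonist = s$agonist[1],
        min = if (failed) NA_real_ else fit$min,
        max = if (failed) NA_real_ else fit$max,
        log_ec50 = if (failed) NA_real_ else fit$log_ec50,
        sse = if (failed) NA_real_ else fit$sse,
        converged = !failed
      )
      if (failed) {
        warn(sprintf("Logistic fit failed for %s (%s, %s); component withheld.",
                     s$animal_id[1], s$bed[1], s$agonist[1]))
        next
      }
      comps[[length(comps) + 1]] <- tibble::tibble(
        animal_id = s$animal_id[1], bed = s$bed[1],
        component = agonist_component[[s$agonist[1]]],
        value = dilation_upper_bound(fit)
      )
    }
  }

  if (nrow(cohort$hypoxia) > 0) {
    for (i in seq_len(nrow(cohort$hypoxia))) {
      row <- cohort$hypoxia[i, ]
      comps[[length(comps) + 1]] <- tibble::tibble(
        animal_id = row$animal_id, bed = row$bed,
        component = "hypoxic_dilation",
        value = hypoxic_component(row$dilation_um)
      )
    }
  }

  if (nrow(cohort$pressure_diameter) > 0) {
    series_list <- split(
      cohort$pressure_diameter,
      list(cohort$pressure_diameter$animal_id, cohort$pressure_diameter$bed),
      drop = TRUE
    )
    for (s in series_list) {
      res <- tryCatch(
        suppressWarnings(
          stiffness_component(s$pressure_mmHg, s$inner_um, s$outer_um,
                              r2_threshold = r2_threshold)),
        error = function(e) e
      )
      failed <- inherits(res, "error")
      mech[[length(mech) + 1]] <- tibble::tibble(
        animal_id = s$animal_id[1], bed = s$bed[1],
        sigma5 = if (failed) NA_real_ else res$fit$sigma5,
        beta = if (failed) NA_real_ else res$fit$beta,
        r2 = if (failed) NA_real_ else res$fit$r_squared,
        n_points = if (failed) nrow(s) else res$fit$n,
        accepted = if (failed) FALSE else res$fit$accepted
      )
      if (failed) {
        warn(sprintf("Stress-strain fit failed for %s (%s): %s",
                     s$animal_id[1], s$bed[1], conditionMessage(res)))
        next
      }
      if (is.finite(res$value)) {
        comps[[length(comps) + 1]] <- tibble::tibble(
          animal_id = s$animal_id[1], bed = s$bed[1],
          component = "stiffness_beta", value = res$value
        )
      }
    }
  }

  if (nrow(cohort$mvd) > 0) {
    comps[[length(comps) + 1]] <- tibble::tibble(
      animal_id = cohort$mvd$animal_id, bed = cohort$mvd$bed,
      component = "mvd", value = cohort$mvd$mvd_per_mm2
    )
  }

  list(
    components = dplyr::bind_rows(comps),
    reactivity_fits = dplyr::bind_rows(react),
    mechanics_fits = dplyr::bind_rows(mech)
  )
}

#' End-to-end index pipeline
#'
#' Convenience wrapper: [compute_components()] then [score_cohort()],
#' [group_summary()], and [aggregate_vhi()].
#'
#' @inheritParams compute_components
#' @inheritParams score_cohort
#' @return List with `scores` (per-animal), `summary` (per group x age),
#'   `aggregate` (per group, ages pooled), `components`, and the fit
#'   diagnostic tables.
#' @export
vhi_pipeline <- function(cohort,
                         variants = c("three_component", "five_component"),
                         mode = c("by_study", "pooled"),
                         r2_threshold = 0.85) {
  mode <- match.arg(mode)
  extracted <- compute_components(cohort, r2_threshold = r2_threshold)
  scores <- score_cohort(extracted$components, cohort$animals,
                         variants = variants, mode = mode)
  list(
    scores = scores,
    summary = group_summary(scores),
    aggregate = aggregate_vhi(scores),
    components = extracted$components,
    reactivity_fits = extracted$reactivity_fits,
    mechanics_fits = extracted$mechanics_fits
  )
}
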