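#' Standards of health from lean control animals
#'
#' The denominator of every component score is the mean component value of
#' the matched healthy controls: male, untreated lean (LZR) animals from the
#' same study, vascular bed, and age. This computes those standards from a
#' tidy component table joined with animal metadata.
#'
#' @param components Tibble with columns `animal_id`, `bed`, `component`,
#'   `value` (one row per animal x bed x component).
#' @param animals Tibble with columns `animal_id`, `group`, `age_weeks`,
#'   `study_id`.
#' @param mode `"by_study"` (the default, matching controls within
#'   `study_id`) or `"pooled"` (controls pooled across studies, used when
#'   study identifiers are absent).
#' @return Tibble with columns `study_id` (absent in pooled mode), `bed`,
#'   `age_weeks`, `component`, `standard_value`, `n_controls`.
#' @export
standard_of_health <- function(components, animals,
                               mode = c("by_study", "pooled")) {
  mode <- match.arg(mode)
  ctrl <- dplyr::inner_join(
    components,
    dplyr::filter(animals, .data$group == "LZR"),
    by = "animal_id"
  )
  if (nrow(ctrl) == 0) {
    vhi_abort("No LZR control animals available to define standards of health.",
              class = "vhi_error_missing_standard")
  }
  keys <- if (mode == "by_study") {
    c("study_id", "bed", "age_weeks", "component")
  } else {
    c("bed", "age_weeks", "component")
  }
  ctrl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      standard_value = mean(.data$value),
      n_controls = dplyr::n(),
      .groups = "drop"
    )
}

#' Percent-of-ideal component score
#'
#' Components that decrease with disease score as
#' `(measurement / standard) * 100`; the stiffness coefficient, which
#' increases with disease, has its relative excess above the standard counted
#' as an equal deficit: `100 + (100 - (measurement / standard) * 100)`,
#' i.e. `200 - (measurement / standard) * 100`. Scores are not clamped:
#' values above 100 (better than the control standard) and below 0 (stiffness
#' more than double the standard) are legal and are averaged in unchanged.
#'
#' @param measurement Measured component value(s).
#' @param standard Matched standard-of-health value(s), strictly positive.
#' @param direction `"decreases_with_disease"` or `"increases_with_disease"`.
#' @return Component score(s) in percent. Vectorised over measurements.
#' @examples
#' component_score(122.6, 136.5, "decreases_with_disease")  # 89.82
#' component_score(6.2, 3.1, "increases_with_disease")      # 0
#' @export
component_score <- function(measurement, standard,
                            direction = c("decreases_with_disease",
                                          "increases_with_disease")) {
  direction <- match.arg(direction)
  if (any(!is.finite(standard)) || any(standard <= 0)) {
    vhi_abort("Standards of health must be strictly positive.",
              class = "vhi_error_domain")
  }
  ratio <- measurement / standard * 100
  if (direction == "decreases_with_disease") ratio else 200 - ratio
}

#' Compose component scores into a Vascular Health Index
#'
#' The VHI is the unweighted arithmetic mean of the percent-of-ideal scores
#' of the variant's components (all components weighted equally; the index is
#' descriptive, not predictive, so no regression-derived weights are used).
#'
#' @param scores Named numeric vector or list mapping component name to its
#'   percent score; must contain every component of the variant.
#' @param variant `"three_component"` or `"five_component"`.
#' @return An object of class `vhi_result`: list with `variant`,
#'   `score_pct`, and `component_scores` (named numeric).
#' @examples
#' compute_vhi(c(ach_dilation = 100, mvd = 100, stiffness_beta = 100), "3")
#' @export
compute_vhi <- function(scores, variant) {
  variant <- normalize_variant(variant)
  scores <- unlist(scores)
  need <- VHI_VARIANTS[[variant]]
  missing <- setdiff(need, names(scores))
  if (length(missing) > 0) {
    vhi_abort(
      sprintf("Incomplete component set for %s: missing %s.",
              variant, paste(missing, collapse = ", ")),
      class = "vhi_error_incomplete_components"
    )
  }
  used <- scores[need]
  structure(
    list(variant = variant, score_pct = mean(used),
         component_scores = used),
    class = "vhi_result"
  )
}

#' @export
print.vhi_result <- function(x, ...) {
  cat(sprintf("VHI (%s): %.1f%% of the healthy standard\n",
              gsub("_", "-", x$variant), x$score_pct))
  for (nm in names(x$component_scores)) {
    cat(sprintf("  %-17s %7.1f%%\n", nm, x$component_scores[[nm]]))
  }
  invisible(x)
}

#' Score a cohort of animals against lean-control standards
#'
#' Per-animal scoring: each animal's component values are divided by the
#' standard of health of its matched controls (same study, bed, and age),
#' converted to percent-of-ideal scores, and averaged into the requested
#' index variant(s). Animals missing any required component for a variant are
#' excluded from that variant (and kept for the other if complete there),
#' with a message.
#'
#' @inheritParams standard_of_health
#' @param variants Character vector of variants to compute (default both).
#' @param standards Optional pre-computed standards (from
#'   [standard_of_health()]); computed from `animals`/`components` when
#'   `NULL`.
#' @param mode Standard-matching mode, see [standard_of_health()].
#' @return Tibble with one row per (animal, bed, variant): `animal_id`,
#'   `group`, `age_weeks`, `study_id`, `bed`, `variant`, one column per
#'   component score, and `vhi_pct`.
#' @export
score_cohort <- function(components, animals,
                         variants = c("three_component", "five_component"),
                         standards = NULL, mode = c("by_study", "pooled")) {
  mode <- match.arg(mode)
  variants <- vapply(variants, normalize_variant, character(1))
  if (is.null(standards)) {
    standards <- standard_of_health(components, animals, mode)
  }
  keys <- intersect(c("study_id", "bed", "age_weeks", "component"),
                    names(standards))

  scored <- components |>
    dplyr::inner_join(
      dplyr::select(animals, "animal_id", "group", "age_weeks",
                    dplyr::any_of("study_id")),
      by = "animal_id"
    ) |>
    dplyr::inner_join(standards, by = keys) |>
    dplyr::left_join(component_directions(), by = "component") |>
    dplyr::mutate(
      score = ifelse(
        .data$direction == "decreases_with_disease",
        .data$value / .data$standard_value * 100,
        200 - .data$value / .data$standard_value * 100
      )
    )

  wide <- scored |>
    dplyr::select("animal_id", "group", "age_weeks",
                  dplyr::any_of("study_id"), "bed", "component", "score") |>
    tidyr::pivot_wider(names_from = "component", values_from = "score")

  out <- purrr::map_dfr(unname(variants), function(v) {
    need <- VHI_VARIANTS[[v]]
    have <- intersect(need, names(wide))
    rows <- wide
    if (length(have) < length(need)) {
      rows <- rows[0, , drop = FALSE]
    } else {
      complete <- stats::complete.cases(rows[need])
      if (any(!complete)) {
        inform(sprintf(
          "%d animal/bed row(s) missing components for the %s index; excluded.",
          sum(!complete), v))
      }
      rows <- rows[complete, , drop = FALSE]
    }
    if (nrow(rows) == 0) return(rows)
    rows$variant <- v
    rows$vhi_pct <- rowMeans(rows[need])
    dplyr::select(rows, "animal_id", "group", "age_weeks",
                  dplyr::any_of("study_id"), "bed", "variant",
                  dplyr::all_of(VHI_COMPONENTS[VHI_COMPONENTS %in% names(rows)]),
                  "vhi_pct")
  })
  out
}

#' Score group means directly (group-mean mode)
#'
#' Published summaries report only group means per component; this mode
#' scores a disease or treatment group's mean component values against the
#' matched control group's means and averages the resulting scores. It
#' approximates per-animal scoring (a mean of ratios) by a ratio of means,
#' which agrees to about a percentage point for the dispersions typical of
#' these data.
#'
#' @param means Tibble with columns `group`, `age_weeks`, `bed`,
#'   `component`, `mean` (group mean component value), e.g. from
#'   [zucker_reference()].
#' @param variant `"three_component"` or `"five_component"`.
#' @param control_group Group defining the standard of health
#'   (default `"LZR"`).
#' @return Tibble with one row per (group, age_weeks, bed): component score
#'   columns and `vhi_pct`. The control group scores 100 by construction.
#' @examples
#' ref <- zucker_reference()
#' score_group_means(ref, variant = "5")
#' @export
score_group_means <- function(means, variant, control_group = "LZR") {
  variant <- normalize_variant(variant)
  need <- VHI_VARIANTS[[variant]]
  std <- means |>
    dplyr::filter(.data$group == control_group) |>
    dplyr::select("age_weeks", "bed", "component", standard_value = "mean")
  if (nrow(std) == 0) {
    vhi_abort(sprintf("No '%s' rows to define standards of health.", control_group),
              class = "vhi_error_missing_standard")
  }
  scored <- means |>
    dplyr::filter(.data$component %in% need) |>
    dplyr::inner_join(std, by = c("age_weeks", "bed", "component")) |>
    dplyr::left_join(component_directions(), by = "component") |>
    dplyr::mutate(
      score = ifelse(
        .data$direction == "decreases_with_disease",
        .data$mean / .data$standard_value * 100,
        200 - .data$mean / .data$standard_value * 100
      )
    ) |>
    dplyr::select("group", "age_weeks", "bed", "component", "score") |>
    tidyr::pivot_wider(names_from = "component", values_from = "score")

  complete <- stats::complete.cases(scored[need])
  scored <- scored[complete, , drop = FALSE]
  scored$variant <- variant
  scored$vhi_pct <- rowMeans(scored[need])
  dplyr::arrange(scored, .data$group, .data$bed, .data$age_weeks)
}

#' Aggregate VHI across ages
#'
#' Pools per-animal VHI results across all ages into one value per
#' (group, bed, variant) — the "all ages compiled into one data point"
#' presentation. Pooling is n-weighted over animals; it equals the simple
#' mean of per-age means only when every age contributes equally.
#'
#' @param scores Per-animal results from [score_cohort()].
#' @return Tibble with `group`, `bed`, `variant`, `vhi_pct` (pooled mean),
#'   `se`, `n`.
#' @export
aggregate_vhi <- function(scores) {
  if (nrow(scores) == 0) {
    vhi_abort("No scores to aggregate.", class = "vhi_error_validation")
  }
  scores |>
    dplyr::group_by(.data$group, .data$bed, .data$variant) |>
    dplyr::summarise(
      se = sd(.data$vhi_pct) / sqrt(dplyr::n()),
      n = dplyr::n(),
      vhi_pct = mean(.data$vhi_pct),
      .groups = "drop"
    ) |>
    dplyr::select("group", "bed", "variant", "vhi_pct", "se", "n")
}

#' Group summary of per-animal VHI scores
#'
#' @param scores Per-animal results from [score_cohort()].
#' @return Tibble with `group`, `age_weeks`, `bed`, `variant`, `mean_vhi`,
#'   `se` (`NA` when n = 1), `n`.
#' @export
group_summary <- function(scores) {
  scores |>
    dplyr::group_by(.data$group, .data$age_weeks, .data$bed, .data$variant) |>
    dplyr::summarise(
      mean_vhi = mean(.data$vhi_pct),
      se = if (dplyr::n() > 1) sd(.data$vhi_pct) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
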