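#' Pearson correlation with a two-sided t-based p-value
#'
#' `r = cov(x, y) / (sd(x) sd(y))`, with the two-sided p-value from the
#' t transform on `n - 2` degrees of freedom (as in [stats::cor.test()],
#' which performs the computation).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p_value`, `n`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)$r  # 1
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    vhi_abort("Correlation needs >= 3 complete pairs.",
              class = "vhi_error_insufficient_data")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    vhi_abort("Correlation is undefined when either variable is constant.",
              class = "vhi_error_degenerate_data")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Criterion validity: biomarker-VHI correlation by group
#'
#' In a diseased population the index should track established plasma
#' markers of metabolic disease severity: higher insulin or TNF-alpha should
#' accompany a lower VHI (negative Pearson correlation), while in healthy
#' controls the correlation should be minimal. Animals are pooled across
#' ages within each group, matching how the criterion analysis spans the
#' whole 7-20-week window.
#'
#' @param scores Per-animal results from [score_cohort()] (one bed/variant,
#'   or pass `bed`/`variant` to filter).
#' @param animals Animal metadata including the biomarker column.
#' @param biomarker `"insulin"` or `"tnfa"` (columns `insulin_ng_ml`,
#'   `tnfa_pg_ml`).
#' @param bed,variant Optional filters applied to `scores`.
#' @param min_n Minimum complete pairs per group (default 3); smaller groups
#'   are skipped with a warning.
#' @return Tibble with `group`, `bed`, `variant`, `biomarker`, `pearson_r`,
#'   `p_value`, `n`.
#' @export
criterion_validity <- function(scores, animals,
                               biomarker = c("insulin", "tnfa"),
                               bed = NULL, variant = NULL, min_n = 3) {
  biomarker <- match.arg(biomarker)
  column <- c(insulin = "insulin_ng_ml", tnfa = "tnfa_pg_ml")[[biomarker]]
  if (!column %in% names(animals)) {
    vhi_abort(sprintf("Column '%s' not found in `animals`.", column),
              class = "vhi_error_config")
  }
  if (!is.null(bed)) scores <- dplyr::filter(scores, .data$bed == !!bed)
  if (!is.null(variant)) {
    v <- normalize_variant(variant)
    scores <- dplyr::filter(scores, .data$variant == v)
  }
  joined <- dplyr::inner_join(
    scores,
    dplyr::select(animals, "animal_id", biomarker_value = dplyr::all_of(column)),
    by = "animal_id"
  )
  purrr::map_dfr(
    split(joined, list(joined$group, joined$bed, joined$variant), drop = TRUE),
    function(d) {
      ok <- is.finite(d$biomarker_value) & is.finite(d$vhi_pct)
      if (sum(ok) < min_n) {
        warn(sprintf("Group %s (%s, %s): only %d complete pairs; skipped.",
                     d$group[1], d$bed[1], d$variant[1], sum(ok)))
        return(NULL)
      }
      res <- pearson_r(d$biomarker_value[ok], d$vhi_pct[ok])
      tibble::tibble(
        group = d$group[1], bed = d$bed[1], variant = d$variant[1],
        biomarker = biomarker, pearson_r = res$r, p_value = res$p_value,
        n = res$n
      )
    }
  )
}

# Welch two-sample test that degrades gracefully on zero-variance cells:
# identical constant groups are maximally indistinguishable (p = 1); constant
# groups with different means are perfectly separated (p = 0).
welch_p <- function(a, b) {
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(t.test(a, b, alternative = "two.sided", var.equal = FALSE)$p.value,
           error = function(e) NA_real_)
}

#' Discriminant validity: group separation on VHI alone
#'
#' Tests whether the index alone distinguishes the study populations: at
#' each (age, bed, variant), every non-control group is compared against the
#' lean controls (`vs_LZR`), and every treated group against the untreated
#' diseased group (`vs_OZR`), with a two-sided Welch t-test (robust to the
#' unequal variances and group sizes of these designs). No multiple-testing
#' correction is applied by default, matching the conventional per-age
#' presentation; `adjust = "holm"` applies a Holm correction across the
#' comparisons in the returned table.
#'
#' @param scores Per-animal results from [score_cohort()].
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param min_n Minimum animals per cell (default 2); smaller cells are
#'   skipped with a warning.
#' @return Tibble with `bed`, `variant`, `age_weeks`, `group`, `comparison`
#'   (`"vs_LZR"` or `"vs_OZR"`), `p_value`, `significant`.
#' @export
discriminant_validity <- function(scores, alpha = 0.05, adjust = "none",
                                  min_n = 2) {
  if (!(alpha > 0 && alpha < 1)) {
    vhi_abort("`alpha` must be in (0, 1).", class = "vhi_error_config")
  }
  cells <- split(scores,
                 list(scores$bed, scores$variant, scores$age_weeks),
                 drop = TRUE)
  out <- purrr::map_dfr(cells, function(d) {
    by_group <- split(d$vhi_pct, d$group)
    sizes <- vapply(by_group, length, integer(1))
    usable <- names(sizes)[sizes >= min_n]
    skipped <- setdiff(names(sizes), usable)
    if (length(skipped) > 0) {
      warn(sprintf("Skipping group(s) %s at %s/%s/%s weeks (n < %d).",
                   paste(skipped, collapse = ", "),
                   d$bed[1], d$variant[1], d$age_weeks[1], min_n))
    }
    rows <- list()
    if ("LZR" %in% usable) {
      for (g in setdiff(usable, "LZR")) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          bed = d$bed[1], variant = d$variant[1], age_weeks = d$age_weeks[1],
          group = g, comparison = "vs_LZR",
          p_value = welch_p(by_group[[g]], by_group[["LZR"]])
        )
      }
    }
    if ("OZR" %in% usable) {
      for (g in intersect(usable, c("OZR_EXERCISE", "OZR_CAPTOPRIL"))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          bed = d$bed[1], variant = d$variant[1], age_weeks = d$age_weeks[1],
          group = g, comparison = "vs_OZR",
          p_value = welch_p(by_group[[g]], by_group[["OZR"]])
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(out) == 0) return(out)
  if (adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  }
  out$significant <- out$p_value < alpha
  out
}
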