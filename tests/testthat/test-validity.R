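test_that("pearson_r matches the brute-force covariance formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, brute, tolerance = 1e-12)
  # p from the t transform with n - 2 df
  tstat <- brute * sqrt((4 - 2) / (1 - brute^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 2), tolerance = 1e-12)

  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(1:5, rep(3, 5)), class = "vhi_error_degenerate_data")
  expect_error(pearson_r(1:2, 2:3), class = "vhi_error_insufficient_data")
})

test_that("pearson_r is affine-invariant and flips sign under negation", {
  withr::local_seed(9)
  x <- rnorm(20); y <- rnorm(20) + 0.5 * x
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("criterion validity detects severity coupling and spares the null", {
  spec <- cohort_spec(bed = "cerebral", groups = c("LZR", "OZR"), seed = 301)
  drawn <- draw_component_values(spec)
  scores <- score_cohort(drawn$components, drawn$animals,
                         variants = "five_component")
  res <- criterion_validity(scores, drawn$animals, biomarker = "insulin")
  ozr <- dplyr::filter(res, group == "OZR")
  expect_lt(ozr$pearson_r, 0)
  expect_lt(ozr$p_value, 0.05)
  expect_equal(ozr$n, 40L)  # pooled across the five ages

  # constant biomarker -> undefined correlation
  flat <- dplyr::mutate(drawn$animals, insulin_ng_ml = 5)
  expect_error(criterion_validity(scores, flat, biomarker = "insulin"),
               class = "vhi_error_degenerate_data")

  # too-small groups are skipped with a warning
  few <- dplyr::filter(scores, animal_id %in% scores$animal_id[1:2])
  expect_warning(
    out <- criterion_validity(few, drawn$animals, biomarker = "tnfa"),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("discriminant validity compares each group to its reference", {
  withr::local_seed(31)
  mk <- function(group, age, vhi) {
    tibble::tibble(
      animal_id = sprintf("%s-%d-%d", group, age, seq_along(vhi)),
      group = group, age_weeks = age, study_id = "s1", bed = "peripheral",
      variant = "five_component", vhi_pct = vhi
    )
  }
  scores <- dplyr::bind_rows(
    mk("LZR", 17L, rnorm(10, 100, 3)),
    mk("OZR", 17L, rnorm(10, 70, 3)),
    mk("OZR_EXERCISE", 17L, rnorm(8, 95, 3)),
    mk("OZR_CAPTOPRIL", 17L, rnorm(1, 85, 3))  # below min_n, skipped
  )
  expect_warning(res <- discriminant_validity(scores), "Skipping")
  expect_setequal(
    paste(res$group, res$comparison),
    c("OZR vs_LZR", "OZR_EXERCISE vs_LZR", "OZR_EXERCISE vs_OZR")
  )
  expect_true(all(res$significant))
  expect_true(all(res$p_value < 0.05))
})

test_that("degenerate zero-variance groups yield p = 1 when identical", {
  scores <- tibble::tibble(
    animal_id = sprintf("a%d", 1:8),
    group = rep(c("LZR", "OZR"), each = 4),
    age_weeks = 10L, study_id = "s1", bed = "cerebral",
    variant = "three_component", vhi_pct = 100
  )
  res <- discriminant_validity(scores)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("Holm adjustment only increases p-values", {
  withr::local_seed(17)
  scores <- dplyr::bind_rows(lapply(c(7L, 13L), function(age) {
    tibble::tibble(
      animal_id = sprintf("x-%d-%d", age, 1:12),
      group = rep(c("LZR", "OZR"), each = 6),
      age_weeks = age, study_id = "s1", bed = "cerebral",
      variant = "five_component",
      vhi_pct = c(rnorm(6, 100, 4), rnorm(6, 90, 4))
    )
  }))
  raw <- discriminant_validity(scores, adjust = "none")
  holm <- discriminant_validity(scores, adjust = "holm")
  expect_true(all(holm$p_value >= raw$p_value - 1e-15))
  expect_error(discriminant_validity(scores, alpha = 1.2),
               class = "vhi_error_config")
})
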