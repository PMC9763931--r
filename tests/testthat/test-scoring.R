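test_that("component_score applies the direction-specific formulas", {
  # measurement equal to the standard scores 100 either way
  expect_equal(component_score(3.1, 3.1, "increases_with_disease"), 100)
  expect_equal(component_score(130, 130, "decreases_with_disease"), 100)
  # published 17-week values: stiffness exactly double the standard -> 0
  expect_equal(component_score(6.2, 3.1, "increases_with_disease"), 0)
  # 20-week cerebral stiffness: 245% of standard -> negative, unclamped
  expect_equal(component_score(5.4, 2.2, "increases_with_disease"),
               200 - 5.4 / 2.2 * 100, tolerance = 1e-12)
  expect_lt(component_score(5.4, 2.2, "increases_with_disease"), -45)
  # dilation ratio below 1 -> below 100
  expect_equal(component_score(122.6, 136.5, "decreases_with_disease"),
               89.8168, tolerance = 1e-4)
  expect_error(component_score(1, 0, "decreases_with_disease"),
               class = "vhi_error_domain")
})

test_that("compute_vhi averages the variant's components unweighted", {
  expect_equal(
    compute_vhi(c(ach_dilation = 100, mvd = 100, stiffness_beta = 100),
                "3")$score_pct, 100)
  # the five 17-week peripheral component scores from the reference means
  five <- c(ach_dilation = 89.8168, snp_dilation = 99.6436, mvd = 76.0399,
            hypoxic_dilation = 89.8744, stiffness_beta = 0)
  expect_equal(compute_vhi(five, "5")$score_pct, 71.0749, tolerance = 1e-3)
  # 7-week cerebral 3-component from reference means
  three <- c(ach_dilation = 90.5325, mvd = 94.4828, stiffness_beta = 87.5)
  expect_equal(compute_vhi(three, "3")$score_pct, 90.8384, tolerance = 1e-3)
  expect_error(compute_vhi(five[-1], "5"),
               class = "vhi_error_incomplete_components")
})

test_that("standard_of_health averages matched lean controls only", {
  animals <- tibble::tibble(
    animal_id = c("a", "b", "c", "d"),
    group = c("LZR", "LZR", "LZR", "OZR"),
    age_weeks = 13L, study_id = "s1"
  )
  comps <- components_from_matrix(
    animals$animal_id, "cerebral",
    list(ach_dilation = c(100, 110, 120, 999))
  )
  std <- standard_of_health(comps, animals)
  expect_equal(std$standard_value, 110)  # OZR value excluded
  expect_equal(std$n_controls, 3L)

  one <- standard_of_health(
    components_from_matrix("a", "cerebral", list(ach_dilation = 135.2)),
    animals[1, ])
  expect_equal(one$standard_value, 135.2)

  expect_error(
    standard_of_health(comps, dplyr::mutate(animals, group = "OZR")),
    class = "vhi_error_missing_standard"
  )
})

test_that("a control cohort scored against itself averages exactly 100", {
  withr::local_seed(5)
  n <- 12
  animals <- tibble::tibble(
    animal_id = sprintf("lzr-%02d", 1:n), group = "LZR",
    age_weeks = rep(c(7L, 13L), each = n / 2), study_id = "s1"
  )
  comps <- dplyr::bind_rows(lapply(c("peripheral", "cerebral"), function(bed) {
    components_from_matrix(
      animals$animal_id, bed,
      list(ach_dilation = rnorm(n, 130, 5), snp_dilation = rnorm(n, 140, 5),
           hypoxic_dilation = rnorm(n, 128, 5), mvd = rnorm(n, 800, 40),
           stiffness_beta = rnorm(n, 2.6, 0.3))
    )
  }))
  scores <- score_cohort(comps, animals)
  means <- scores |>
    dplyr::group_by(.data$bed, .data$variant, .data$age_weeks) |>
    dplyr::summarise(m = mean(.data$vhi_pct), .groups = "drop")
  expect_equal(nrow(means), 8)  # 2 beds x 2 variants x 2 ages
  expect_true(all(abs(means$m - 100) < 1e-9))
})

test_that("the index strictly falls when any component deteriorates", {
  base <- c(ach_dilation = 95, snp_dilation = 98, hypoxic_dilation = 96,
            mvd = 90, stiffness_beta = 80)
  v0 <- compute_vhi(base, "5")$score_pct
  for (comp in names(base)) {
    worse <- base
    worse[comp] <- worse[comp] - 5  # a lower score, whatever the direction
    expect_lt(compute_vhi(worse, "5")$score_pct, v0)
  }
  # a higher stiffness measurement lowers its score, hence the index
  s_hi <- component_score(4.0, 2.0, "increases_with_disease")
  s_lo <- component_score(3.0, 2.0, "increases_with_disease")
  expect_lt(s_hi, s_lo)
})

test_that("3- and 5-component variants agree when the added scores equal the base mean", {
  three <- c(ach_dilation = 90, mvd = 80, stiffness_beta = 70)
  m <- mean(three)
  five <- c(three, snp_dilation = m, hypoxic_dilation = m)
  expect_equal(compute_vhi(five, "5")$score_pct,
               compute_vhi(three, "3")$score_pct, tolerance = 1e-12)
})

test_that("group-mean scoring reproduces the published index within tolerance", {
  ref <- zucker_reference()
  v5 <- score_group_means(ref, "5")
  cer <- dplyr::filter(v5, group == "OZR", bed == "cerebral") |>
    dplyr::arrange(age_weeks)
  published <- c(91.3, 87.8, 76.6, 64.7, 52.0)
  expect_equal(cer$age_weeks, c(7L, 10L, 13L, 17L, 20L))
  expect_true(all(abs(cer$vhi_pct - published) <= 1.5))
  # the control group scores 100 by construction at every age
  lzr <- dplyr::filter(v5, group == "LZR")
  expect_true(all(abs(lzr$vhi_pct - 100) < 1e-12))
})

test_that("aggregate pooling is n-weighted and equals age means at equal n", {
  scores <- tibble::tibble(
    animal_id = sprintf("a%d", 1:10), group = "OZR",
    age_weeks = rep(c(7L, 17L), each = 5), study_id = "s1",
    bed = "cerebral", variant = "five_component",
    vhi_pct = c(rep(90, 5), rep(60, 5))
  )
  agg <- aggregate_vhi(scores)
  expect_equal(agg$vhi_pct, 75)  # equal n: mean of age means
  expect_equal(agg$n, 10L)
  # unequal n: pooled mean is weighted toward the larger age cell
  agg2 <- aggregate_vhi(scores[-1, ])
  expect_equal(agg2$vhi_pct, (4 * 90 + 5 * 60) / 9)
  expect_error(aggregate_vhi(scores[0, ]), class = "vhi_error_validation")
})
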