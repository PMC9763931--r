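test_that("reference tables are complete and internally consistent", {
  ref <- zucker_reference()
  # untreated groups have all five components at all five ages in both beds
  full <- ref |>
    dplyr::filter(group %in% c("LZR", "OZR")) |>
    dplyr::count(bed, group)
  expect_true(all(full$n == 25))
  expect_true(all(ref$se >= 0))
  cts <- zucker_counts()
  expect_true(all(cts$n >= 0))
  bio <- zucker_biomarkers()
  expect_setequal(unique(bio$variable),
                  c("mass_g", "insulin_ng_ml", "glucose_mg_dl",
                    "ntyr_ng_dl", "tnfa_pg_ml"))
})

test_that("cohort_spec validates its inputs", {
  spec <- cohort_spec(bed = "cerebral", groups = c("LZR", "OZR"))
  expect_s3_class(spec, "vhi_cohort_spec")
  expect_true(all(spec$cells$n >= 1))
  expect_error(cohort_spec(bed = "hepatic"), class = "vhi_error_config")
  expect_error(cohort_spec(coupling = c(LZR = 0, OZR = 1.2,
                                        OZR_EXERCISE = 0, OZR_CAPTOPRIL = 0)),
               class = "vhi_error_spec")
})

test_that("component draws hit the cell mean and respect se = 0", {
  # degenerate: se = 0 collapses every draw onto the mean
  comp0 <- zucker_reference() |>
    dplyr::mutate(se = 0)
  spec0 <- cohort_spec(bed = "peripheral", groups = c("LZR", "OZR"),
                       ages = 17, components = comp0, seed = 2)
  drawn0 <- draw_component_values(spec0)
  beta0 <- drawn0$components |>
    dplyr::filter(component == "stiffness_beta")
  expect_true(all(beta0$value %in% c(3.1, 6.2)))

  # sampling distribution: OZR 17-week peripheral beta, mean 6.2, se 0.4,
  # n = 28 -> cell mean within 2 SE of the target in most replicates
  spec <- cohort_spec(bed = "peripheral", groups = "OZR", ages = 17)
  hits <- vapply(1:200, function(i) {
    d <- draw_component_values(spec, seed = 1000 + i)
    m <- mean(d$components$value[d$components$component == "stiffness_beta"])
    abs(m - 6.2) <= 2 * 0.4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cell draws follow the generating normal distribution", {
  spec <- cohort_spec(bed = "cerebral", groups = "LZR", ages = 13,
                      n_per_cell = 500, seed = 77)
  d <- draw_component_values(spec)
  ach <- d$components$value[d$components$component == "ach_dilation"]
  # LZR 13-week cerebral: mean 151.8, se 0.8 at published n 10 -> per-animal
  # SD reconstructed with the published n, not the simulated cell size
  n_pub <- 10
  ks <- stats::ks.test(ach, "pnorm", mean = 151.8, sd = 0.8 * sqrt(n_pub))
  expect_gt(ks$p.value, 0.01)
})

test_that("generated series embed their target parameters (round trip)", {
  # dose-response: noiseless series refits to the target upper bound
  dr <- make_dose_response(136.5, min_um = 8, log_ec50 = -7.5, noise_um = 0)
  fit <- fit_logistic(dr$log_conc, dr$response_um)
  expect_equal(fit$max, 136.5, tolerance = 1e-3)
  expect_error(make_dose_response(0), class = "vhi_error_spec")

  # noisy replicates: refitted upper bounds are unbiased around the target
  withr::local_seed(12)
  err <- replicate(200, {
    s <- make_dose_response(120, noise_um = 2)
    f <- fit_logistic(s$log_conc, s$response_um)
    if (f$converged) f$max - 120 else NA_real_
  })
  err <- err[is.finite(err)]
  st <- stats::binom.test(sum(err > 0), length(err))
  expect_gt(st$p.value, 0.05)  # sign test: no systematic bias

  # pressure series: anchor identities and beta recovery
  s <- make_pressure_series(5.4, sigma5 = 2e3, id5_um = 100)
  expect_equal(s$inner_um[1], 100)
  pts <- stress_strain_points(s$pressure_mmHg, s$inner_um, s$outer_um)
  expect_equal(pts$strain[1], 0)
  expect_equal(pts$stress_N_m2[1], 2e3, tolerance = 1e-9)
  fit2 <- fit_stress_strain(pts$strain, pts$stress_N_m2)
  expect_equal(fit2$beta, 5.4, tolerance = 1e-6)
  # conserved wall area links OD to ID at every pressure
  expect_equal(s$outer_um^2 - s$inner_um^2,
               rep(s$outer_um[1]^2 - s$inner_um[1]^2, nrow(s)),
               tolerance = 1e-9)
})

test_that("simulation is deterministic given spec and seed", {
  spec <- cohort_spec(bed = "cerebral", groups = c("LZR", "OZR"),
                      ages = c(7, 17), seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  c2 <- simulate_cohort(spec, seed = 100)
  expect_false(identical(a$animals$insulin_ng_ml, c2$animals$insulin_ng_ml))
})

test_that("the pipeline recovers simulated cell means end to end", {
  spec <- cohort_spec(bed = "cerebral", groups = c("LZR", "OZR"),
                      ages = c(10, 17), seed = 123)
  coh <- simulate_cohort(spec)
  res <- vhi_pipeline(coh, variants = "five_component", mode = "pooled")

  # fitted component cell means close to the generating means: per-cell
  # z-scores (SE of the cell mean = published SE at matched n) should look
  # standard normal, allowing a little extra spread from the fitting noise
  got <- res$components |>
    dplyr::inner_join(dplyr::select(coh$animals, animal_id, group, age_weeks),
                      by = "animal_id") |>
    dplyr::group_by(group, age_weeks, component) |>
    dplyr::summarise(m = mean(value), n_cell = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(spec$components,
                      by = c("group", "age_weeks", "component"))
  z <- abs(got$m - got$mean) / (got$sd / sqrt(got$n_cell))
  expect_gte(mean(z <= 2), 0.85)
  expect_lt(max(z), 5)

  # group-mean VHI consistent with the value implied by the cell means
  implied <- score_group_means(spec$components, "5") |>
    dplyr::filter(group == "OZR")
  sim <- dplyr::filter(res$summary, group == "OZR") |>
    dplyr::inner_join(dplyr::select(implied, age_weeks, implied = vhi_pct),
                      by = "age_weeks")
  expect_true(all(abs(sim$mean_vhi - sim$implied) <= 3 * sim$se + 0.5))
})
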