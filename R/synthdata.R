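#' Published Zucker-rat reference summaries
#'
#' Accessors for the reference summary tables shipped with the package:
#' group mean +/- SE of each index component by group, age, and vascular bed
#' (`zucker_reference()`); the group sizes behind each index variant
#' (`zucker_counts()`); and plasma biomarker summaries (mass, insulin,
#' glucose, nitrotyrosine, TNF-alpha) by group and age
#' (`zucker_biomarkers()`). These summaries parameterise the default
#' synthetic cohort and drive the group-mean worked examples.
#'
#' @return A tibble.
#' @examples
#' head(zucker_reference())
#' @export
zucker_reference <- function() {
  read_extdata("zucker_components.csv",
               cols = readr::cols(
                 bed = readr::col_character(),
                 component = readr::col_character(),
                 group = readr::col_character(),
                 age_weeks = readr::col_integer(),
                 mean = readr::col_double(),
                 se = readr::col_double()
               ))
}

#' @rdname zucker_reference
#' @export
zucker_counts <- function() {
  read_extdata("zucker_counts.csv",
               cols = readr::cols(
                 group = readr::col_character(),
                 age_weeks = readr::col_integer(),
                 bed = readr::col_character(),
                 variant = readr::col_character(),
                 n = readr::col_integer()
               ))
}

#' @rdname zucker_reference
#' @export
zucker_biomarkers <- function() {
  read_extdata("zucker_biomarkers.csv",
               cols = readr::cols(
                 variable = readr::col_character(),
                 group = readr::col_character(),
                 age_weeks = readr::col_integer(),
                 mean = readr::col_double(),
                 se = readr::col_double()
               ))
}

read_extdata <- function(name, cols) {
  path <- system.file("extdata", name, package = "vhindex", mustWork = TRUE)
  readr::read_csv(path, col_types = cols)
}

#' Specify a synthetic cohort
#'
#' Defines the group x age x component distributions of a simulated cohort.
#' Defaults come from the shipped reference summaries: per-cell means and
#' SEs for every component and biomarker, and the published per-cell group
#' sizes for the chosen index variant. The per-animal SD in each cell is
#' reconstructed from the printed standard error as `se * sqrt(n_printed)`.
#'
#' Within each animal a standard-normal latent severity couples the
#' components to the plasma biomarkers: a sicker animal (higher severity)
#' has lower dilator responses and microvessel density, a higher stiffness
#' coefficient, and higher insulin/TNF-alpha, with correlation `coupling`
#' between severity and each measurement (marginal cell means and SDs are
#' preserved). Healthy controls default to zero coupling, giving a null
#' cohort for criterion-validity testing.
#'
#' @param bed Vascular bed to simulate (`"peripheral"` or `"cerebral"`).
#' @param groups Groups to include (default: all groups with data for `bed`).
#' @param ages Ages (weeks) to include.
#' @param variant Variant whose published per-cell n to use
#'   (default `"five_component"`).
#' @param components Per-cell component summaries; defaults to
#'   [zucker_reference()] filtered to `bed`.
#' @param biomarkers Per-cell biomarker summaries; defaults to
#'   [zucker_biomarkers()].
#' @param counts Per-cell group sizes; defaults to [zucker_counts()].
#' @param n_per_cell Optional single n overriding the published cell sizes.
#' @param coupling Named vector of severity-measurement correlations per
#'   group, each in `[0, 1)`.
#' @param dose_response List of generation settings for concentration-response
#'   series: `log_conc` grid, `min_mean`/`min_sd` and
#'   `log_ec50_mean`/`log_ec50_sd` priors, `noise_um` additive Gaussian noise.
#' @param pressure Settings for passive pressure-diameter series:
#'   `pressures_mmHg` grid, `id5_mean`/`id5_sd` and `sigma5_mean`/`sigma5_sd`
#'   priors, `id_noise_um` measurement noise on the inner diameter.
#' @param study_id Study identifier stamped on every animal.
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return An object of class `vhi_cohort_spec`.
#' @export
cohort_spec <- function(bed = "cerebral", groups = NULL, ages = NULL,
                        variant = "five_component",
                        components = NULL, biomarkers = NULL, counts = NULL,
                        n_per_cell = NULL,
                        coupling = c(LZR = 0, OZR = 0.6,
                                     OZR_EXERCISE = 0.4, OZR_CAPTOPRIL = 0.5),
                        dose_response = list(), pressure = list(),
                        study_id = "synthetic-study", seed = 1L) {
  check_bed(bed)
  variant <- normalize_variant(variant)
  if (is.null(components)) components <- zucker_reference()
  if (is.null(biomarkers)) biomarkers <- zucker_biomarkers()
  if (is.null(counts)) counts <- zucker_counts()
  components <- dplyr::filter(components, .data$bed == !!bed)
  counts <- dplyr::filter(counts, .data$bed == !!bed,
                          .data$variant == !!variant, .data$n >= 1)
  if (is.null(groups)) groups <- intersect(VHI_GROUPS, unique(counts$group))
  if (is.null(ages)) ages <- sort(unique(counts$age_weeks))
  cells <- dplyr::filter(counts, .data$group %in% groups,
                         .data$age_weeks %in% ages)
  if (!is.null(n_per_cell)) {
    stopifnot(n_per_cell >= 1)
    cells$n <- as.integer(n_per_cell)
  }
  if (nrow(cells) == 0) {
    vhi_abort("Cohort spec has no cells with n >= 1.", class = "vhi_error_spec")
  }
  if (any(components$se < 0) || any(biomarkers$se < 0)) {
    vhi_abort("Standard errors must be non-negative.", class = "vhi_error_spec")
  }

  # Per-animal SD reconstructed from the published SE and the published group
  # size (se * sqrt(n)); the simulated cell size may differ, so the SD is
  # fixed here rather than at draw time. Cells with no published n fall back
  # to their own simulated size.
  pub_n <- counts |>
    dplyr::filter(.data$group %in% groups, .data$age_weeks %in% ages) |>
    dplyr::select("group", "age_weeks", n_pub = "n")
  add_sd <- function(tab) {
    tab <- dplyr::left_join(tab, pub_n, by = c("group", "age_weeks"))
    tab$sd <- tab$se * sqrt(tab$n_pub)
    dplyr::select(tab, -"n_pub")
  }
  components <- add_sd(components)
  biomarkers <- add_sd(biomarkers)
  if (any(coupling < 0 | coupling >= 1)) {
    vhi_abort("Coupling coefficients must lie in [0, 1).",
              class = "vhi_error_spec")
  }

  dr <- utils::modifyList(list(
    log_conc = c(-9, -8.5, -8, -7.5, -7, -6.5, -6),
    min_mean = 8, min_sd = 2,
    log_ec50_mean = -7.5, log_ec50_sd = 0.2,
    noise_um = 1
  ), dose_response)
  pd <- utils::modifyList(list(
    pressures_mmHg = c(5, seq(20, 160, by = 20)),
    id5_mean = 100, id5_sd = 5,
    sigma5_mean = 2e3, sigma5_sd = 100,
    id_noise_um = 0
  ), pressure)

  structure(
    list(bed = bed, groups = groups, ages = ages, variant = variant,
         components = components, biomarkers = biomarkers, cells = cells,
         coupling = coupling, dose_response = dr, pressure = pd,
         study_id = study_id, seed = as.integer(seed)),
    class = "vhi_cohort_spec"
  )
}

#' @export
print.vhi_cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %s bed, %d cells, %d animals\n",
              x$bed, nrow(x$cells), sum(x$cells$n)))
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  ages (weeks): %s\n", paste(x$ages, collapse = ", ")))
  cat(sprintf("  severity coupling: %s\n",
              paste(sprintf("%s=%.2g", names(x$coupling), x$coupling),
                    collapse = ", ")))
  invisible(x)
}

# Draw one cell's values for a single quantity: marginal N(mean, sd) with
# correlation `coupling` to the latent severity, truncated at zero for
# positive-only quantities. `sign` is +1 for quantities that rise with
# severity and -1 for those that fall.
draw_coupled <- function(n, mean, sd, severity, coupling, sign,
                         positive = TRUE) {
  stopifnot(length(severity) == n)
  draw <- function() {
    mean + sign * coupling * sd * severity +
      sqrt(1 - coupling^2) * sd * rnorm(n)
  }
  x <- draw()
  if (positive) {
    for (i in seq_len(100)) {
      bad <- x <= 0
      if (!any(bad)) break
      x[bad] <- (mean + sign * coupling * sd * severity +
                   sqrt(1 - coupling^2) * sd * rnorm(n))[bad]
    }
    if (any(x <= 0)) {
      vhi_abort("Could not draw positive values; cell mean/SD imply mass at <= 0.",
                class = "vhi_error_spec")
    }
  }
  x
}

#' Draw per-animal component values for a cohort spec
#'
#' Samples the latent severity and all component values (no raw measurement
#' series) for every animal of the spec. This is the distributional core of
#' the generator; [simulate_cohort()] adds the raw series.
#'
#' @param spec A `vhi_cohort_spec`.
#' @param seed RNG seed; defaults to the spec's.
#' @return List with tibbles `animals` (metadata, biomarkers, severity) and
#'   `components` (`animal_id`, `bed`, `component`, `value`).
#' @export
draw_component_values <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "vhi_cohort_spec"))
  local_seed(seed)

  dirs <- setNames(component_directions()$direction,
                   component_directions()$component)
  animals <- list()
  comps <- list()
  for (i in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[i, ]
    n <- cell$n
    ids <- sprintf("%s-%s-%02dwk-%03d", spec$study_id, cell$group,
                   cell$age_weeks, seq_len(n))
    severity <- rnorm(n)
    coup <- spec$coupling[[cell$group]]
    if (is.null(coup) || is.na(coup)) coup <- 0

    bio <- dplyr::filter(spec$biomarkers, .data$group == cell$group,
                         .data$age_weeks == cell$age_weeks)
    bio_draw <- lapply(setNames(bio$variable, bio$variable), function(v) {
      row <- bio[bio$variable == v, ]
      s <- if ("sd" %in% names(row) && is.finite(row$sd)) row$sd
           else row$se * sqrt(n)
      draw_coupled(n, row$mean, s, severity, coup, sign = +1)
    })
    getbio <- function(v) if (v %in% names(bio_draw)) bio_draw[[v]] else NA_real_
    animals[[length(animals) + 1]] <- tibble::tibble(
      animal_id = ids, group = cell$group, age_weeks = cell$age_weeks,
      study_id = spec$study_id,
      mass_g = getbio("mass_g"),
      insulin_ng_ml = getbio("insulin_ng_ml"),
      glucose_mg_dl = getbio("glucose_mg_dl"),
      ntyr_ng_dl = getbio("ntyr_ng_dl"),
      tnfa_pg_ml = getbio("tnfa_pg_ml"),
      severity = severity
    )

    cellcomp <- dplyr::filter(spec$components, .data$group == cell$group,
                              .data$age_weeks == cell$age_weeks)
    for (j in seq_len(nrow(cellcomp))) {
      cc <- cellcomp[j, ]
      sgn <- if (dirs[[cc$component]] == "increases_with_disease") +1 else -1
      s <- if ("sd" %in% names(cc) && is.finite(cc$sd)) cc$sd
           else cc$se * sqrt(n)
      comps[[length(comps) + 1]] <- tibble::tibble(
        animal_id = ids, bed = spec$bed, component = cc$component,
        value = draw_coupled(n, cc$mean, s, severity, coup, sgn)
      )
    }
  }
  list(animals = dplyr::bind_rows(animals),
       components = dplyr::bind_rows(comps))
}

#' Generate one synthetic concentration-response series
#'
#' Builds a 7-point agonist series on the standard log10 concentration grid
#' (-9 to -6) from the logistic model with upper bound `target_upper_um`,
#' lower bound and logEC50 drawn from the spec priors, plus additive
#' Gaussian noise. With `noise_um = 0`, [fit_logistic()] on the result
#' recovers `target_upper_um` to well under 0.1 percent.
#'
#' @param target_upper_um Target fitted upper bound (um), positive.
#' @param min_um,log_ec50 Lower bound (um) and log EC50 of the generating
#'   curve.
#' @param log_conc log10 concentration grid.
#' @param noise_um SD of additive Gaussian measurement noise (um).
#' @return Tibble with `log_conc` and `response_um`.
#' @export
make_dose_response <- function(target_upper_um, min_um = 8, log_ec50 = -7.5,
                               log_conc = c(-9, -8.5, -8, -7.5, -7, -6.5, -6),
                               noise_um = 0) {
  if (!is.finite(target_upper_um) || target_upper_um <= 0) {
    vhi_abort("`target_upper_um` must be a positive number.",
              class = "vhi_error_spec")
  }
  y <- logistic_response(log_conc, min_um, target_upper_um, log_ec50)
  if (noise_um > 0) y <- y + rnorm(length(y), 0, noise_um)
  tibble::tibble(log_conc = log_conc, response_um = y)
}

#' Generate one synthetic passive pressure-diameter series
#'
#' Constructs inner/outer diameters over the passive pressure protocol
#' (5 mmHg anchor, then 20-160 mmHg in 20 mmHg steps) exactly consistent
#' with the exponential wall model `sigma = sigma5 * exp(beta * strain)`.
#' The anchor wall thickness follows from `sigma5` and `id5_um` via the
#' stress formula; away from the anchor the wall cross-sectional area is
#' conserved (incompressible wall: `OD^2 - ID^2` constant), and for each
#' pressure the inner diameter solves
#' `stress(P, ID, WT(ID)) = sigma5 * exp(beta * strain(ID))`.
#' On the noiseless output the mechanics pipeline recovers `target_beta` to
#' better than 1e-4 relative.
#'
#' @param target_beta Stiffness coefficient to embed, positive.
#' @param sigma5 Anchor circumferential stress (N/m^2), positive.
#' @param id5_um Anchor inner diameter (um), positive.
#' @param pressures_mmHg Pressure grid; must start at the 5 mmHg anchor.
#' @param id_noise_um SD of Gaussian measurement noise added to the inner
#'   diameter at the non-anchor pressures (outer diameter recomputed from
#'   the conserved wall area).
#' @return Tibble with `pressure_mmHg`, `inner_um`, `outer_um`.
#' @export
make_pressure_series <- function(target_beta, sigma5 = 2e3, id5_um = 100,
                                 pressures_mmHg = c(5, seq(20, 160, by = 20)),
                                 id_noise_um = 0) {
  if (!is.finite(target_beta) || target_beta <= 0) {
    vhi_abort("`target_beta` must be a positive number.",
              class = "vhi_error_spec")
  }
  stopifnot(sigma5 > 0, id5_um > 0, pressures_mmHg[1] == 5)
  wt5 <- 5 * MMHG_TO_N_M2 * id5_um / (2 * sigma5)
  od5 <- id5_um + 2 * wt5
  wall_area <- od5^2 - id5_um^2   # conserved: OD^2 - ID^2

  od_of <- function(id) sqrt(id^2 + wall_area)
  imbalance <- function(id, p) {
    wt <- (od_of(id) - id) / 2
    p * MMHG_TO_N_M2 * id / (2 * wt) -
      sigma5 * exp(target_beta * (id - id5_um) / id5_um)
  }

  inner <- vapply(pressures_mmHg, function(p) {
    if (p == 5) return(id5_um)
    hi <- id5_um
    repeat {
      hi <- hi * 1.5
      if (imbalance(hi, p) < 0) break
      if (hi > 50 * id5_um) {
        vhi_abort(sprintf(
          "No physical diameter solves the wall model at %g mmHg (beta = %g).",
          p, target_beta), class = "vhi_error_generation")
      }
    }
    uniroot(imbalance, lower = id5_um, upper = hi, p = p,
            tol = 1e-10 * id5_um)$root
  }, numeric(1))

  if (id_noise_um > 0) {
    noisy <- inner + c(0, rnorm(length(inner) - 1, 0, id_noise_um))
    inner <- pmax(noisy, 0.1 * id5_um)
  }
  tibble::tibble(pressure_mmHg = pressures_mmHg, inner_um = inner,
                 outer_um = od_of(inner))
}

#' Simulate a full synthetic cohort
#'
#' Draws per-animal component values with [draw_component_values()] and,
#' when `raw_series = TRUE`, expands each into the raw measurement tables
#' the analysis pipeline reads: acetylcholine and nitroprusside
#' concentration-response series embedding the drawn dilation upper bounds,
#' a single hypoxic dilation, a passive pressure-diameter series embedding
#' the drawn stiffness coefficient, and the microvessel density. Identical
#' spec and seed give identical output.
#'
#' @param spec A `vhi_cohort_spec`.
#' @param seed RNG seed; defaults to the spec's.
#' @param raw_series Generate raw measurement series (slower) or only
#'   component-level values.
#' @return An object of class `vhi_cohort`: list of tibbles `animals`,
#'   `dose_response`, `hypoxia`, `pressure_diameter`, `mvd`, and `truth`
#'   (the drawn component values and latent severity).
#' @export
simulate_cohort <- function(spec, seed = spec$seed, raw_series = TRUE) {
  stopifnot(inherits(spec, "vhi_cohort_spec"))
  local_seed(seed)
  drawn <- draw_component_values(spec, seed = NULL)
  animals <- drawn$animals
  comps <- drawn$components

  value_of <- function(id, comp) {
    v <- comps$value[comps$animal_id == id & comps$component == comp]
    if (length(v) == 1) v else NA_real_
  }

  dr_tab <- list(); hy_tab <- list(); pd_tab <- list(); mvd_tab <- list()
  if (raw_series) {
    dr <- spec$dose_response
    pd <- spec$pressure
    for (id in animals$animal_id) {
      for (agonist in c(acetylcholine = "ach_dilation",
                        nitroprusside = "snp_dilation")) {
        target <- value_of(id, agonist)
        if (!is.finite(target)) next
        series <- make_dose_response(
          target,
          min_um = rnorm(1, dr$min_mean, dr$min_sd),
          log_ec50 = rnorm(1, dr$log_ec50_mean, dr$log_ec50_sd),
          log_conc = dr$log_conc, noise_um = dr$noise_um
        )
        dr_tab[[length(dr_tab) + 1]] <- tibble::tibble(
          animal_id = id, bed = spec$bed,
          agonist = names(which(c(acetylcholine = "ach_dilation",
                                  nitroprusside = "snp_dilation") == agonist)),
          log_conc = series$log_conc, response_um = series$response_um
        )
      }
      hyp <- value_of(id, "hypoxic_dilation")
      if (is.finite(hyp)) {
        hy_tab[[length(hy_tab) + 1]] <- tibble::tibble(
          animal_id = id, bed = spec$bed, dilation_um = hyp)
      }
      beta <- value_of(id, "stiffness_beta")
      if (is.finite(beta)) {
        series <- make_pressure_series(
          beta,
          sigma5 = max(rnorm(1, pd$sigma5_mean, pd$sigma5_sd),
                       0.25 * pd$sigma5_mean),
          id5_um = max(rnorm(1, pd$id5_mean, pd$id5_sd), 0.25 * pd$id5_mean),
          pressures_mmHg = pd$pressures_mmHg,
          id_noise_um = pd$id_noise_um
        )
        pd_tab[[length(pd_tab) + 1]] <- tibble::tibble(
          animal_id = id, bed = spec$bed,
          pressure_mmHg = series$pressure_mmHg,
          inner_um = series$inner_um, outer_um = series$outer_um)
      }
      dens <- value_of(id, "mvd")
      if (is.finite(dens)) {
        mvd_tab[[length(mvd_tab) + 1]] <- tibble::tibble(
          animal_id = id, bed = spec$bed, mvd_per_mm2 = dens)
      }
    }
  }

  structure(
    list(
      animals = dplyr::select(animals, -"severity"),
      dose_response = dplyr::bind_rows(dr_tab),
      hypoxia = dplyr::bind_rows(hy_tab),
      pressure_diameter = dplyr::bind_rows(pd_tab),
      mvd = dplyr::bind_rows(mvd_tab),
      truth = list(components = comps,
                   severity = dplyr::select(animals, "animal_id", "severity"))
    ),
    class = "vhi_cohort"
  )
}

#' @export
print.vhi_cohort <- function(x, ...) {
  cat(sprintf("Synthetic/loaded cohort: %d animals\n", nrow(x$animals)))
  cat(sprintf("  dose-response rows: %d; hypoxia: %d; pressure-diameter: %d; MVD: %d\n",
              nrow(x$dose_response), nrow(x$hypoxia),
              nrow(x$pressure_diameter), nrow(x$mvd)))
  invisible(x)
}

# Seed the RNG for the calling function, restoring the caller's RNG state on
# exit. `seed = NULL` leaves the stream untouched (used for nested calls).
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  withr::local_preserve_seed(.local_envir = env)
  set.seed(seed)
  invisible()
}
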