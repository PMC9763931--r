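# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal three-animal cohort (one LZR control, two OZR) with exact,
# hand-chosen component values embedded in the raw series.
tiny_cohort <- function() {
  animals <- tibble::tibble(
    animal_id = c("ctl-1", "ozr-1", "ozr-2"),
    group = c("LZR", "OZR", "OZR"),
    age_weeks = 17L,
    study_id = "study-A",
    mass_g = c(357.5, 682.3, 680.0),
    insulin_ng_ml = c(1.1, 7.8, 8.0),
    glucose_mg_dl = c(100.2, 179.1, 180.0),
    ntyr_ng_dl = c(16.5, 51.7, 50.0),
    tnfa_pg_ml = c(2.2, 8.1, 8.2)
  )
  x <- c(-9, -8.5, -8, -7.5, -7, -6.5, -6)
  dr <- dplyr::bind_rows(lapply(seq_len(3), function(i) {
    id <- animals$animal_id[i]
    upper_ach <- c(136.5, 122.6, 118.0)[i]
    upper_snp <- c(140.3, 139.8, 135.0)[i]
    dplyr::bind_rows(
      tibble::tibble(animal_id = id, bed = "peripheral",
                     agonist = "acetylcholine", log_conc = x,
                     response_um = logistic_response(x, 8, upper_ach, -7.5)),
      tibble::tibble(animal_id = id, bed = "peripheral",
                     agonist = "nitroprusside", log_conc = x,
                     response_um = logistic_response(x, 8, upper_snp, -7.4))
    )
  }))
  hypoxia <- tibble::tibble(
    animal_id = animals$animal_id, bed = "peripheral",
    dilation_um = c(135.3, 121.6, 120.0)
  )
  pd <- dplyr::bind_rows(lapply(seq_len(3), function(i) {
    beta <- c(3.1, 6.2, 6.0)[i]
    s <- make_pressure_series(beta, sigma5 = 2e3, id5_um = 100)
    tibble::tibble(animal_id = animals$animal_id[i], bed = "peripheral",
                   pressure_mmHg = s$pressure_mmHg,
                   inner_um = s$inner_um, outer_um = s$outer_um)
  }))
  mvd <- tibble::tibble(
    animal_id = animals$animal_id, bed = "peripheral",
    mvd_per_mm2 = c(863.1, 656.3, 650.0)
  )
  structure(
    list(animals = animals, dose_response = dr, hypoxia = hypoxia,
         pressure_diameter = pd, mvd = mvd, truth = NULL),
    class = "vhi_cohort"
  )
}

# Component-level tibbles (no raw series) for scoring tests: one value per
# animal x component, exact control of the numbers.
components_from_matrix <- function(animal_ids, bed, values) {
  # values: named list component -> numeric vector over animals
  dplyr::bind_rows(lapply(names(values), function(comp) {
    tibble::tibble(animal_id = animal_ids, bed = bed, component = comp,
                   value = values[[comp]])
  }))
}
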