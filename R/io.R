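#' Analysis configuration
#'
#' Holds the knobs shared across pipeline stages: index variant, vascular
#' bed, significance level, RNG seed, a bypass switch for pre-computed
#' dilation upper bounds, and a column-name mapping so input CSVs with
#' different headers can be read without rewriting them. The mapping is a
#' named character vector `canonical = "actual"` applied to every table.
#'
#' @param variant Index variant (`"three_component"`/`"3"` or
#'   `"five_component"`/`"5"`).
#' @param bed Vascular bed (`"peripheral"` or `"cerebral"`).
#' @param alpha Significance level in (0, 1).
#' @param rng_seed Integer seed for simulation stages.
#' @param column_map Named character vector renaming file columns to the
#'   canonical names (e.g. `c(response_um = "diameter_change")`).
#' @return An object of class `vhi_config`.
#' @export
vhi_config <- function(variant = "five_component", bed = "peripheral",
                       alpha = 0.05, rng_seed = 1L, column_map = character()) {
  if (!(alpha > 0 && alpha < 1)) {
    vhi_abort("`alpha` must be in (0, 1).", class = "vhi_error_config")
  }
  structure(
    list(variant = normalize_variant(variant), bed = check_bed(bed),
         alpha = alpha, rng_seed = as.integer(rng_seed),
         column_map = column_map),
    class = "vhi_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Path to a YAML (.yml/.yaml) or JSON configuration file whose
#'   top-level keys match the arguments of [vhi_config()].
#' @return A `vhi_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    vhi_abort(sprintf("Configuration file '%s' does not exist.", path),
              class = "vhi_error_config")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      vhi_abort("Package 'yaml' is required to read YAML configurations.",
                class = "vhi_error_config")
    }
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      vhi_abort("Package 'jsonlite' is required to read JSON configurations.",
                class = "vhi_error_config")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw$column_map <- unlist(raw$column_map)
  do.call(vhi_config, raw[names(raw) %in% names(formals(vhi_config))])
}

# Canonical schema of each measurement table.
COHORT_SCHEMA <- list(
  animals = c("animal_id", "group", "age_weeks", "study_id", "mass_g",
              "insulin_ng_ml", "glucose_mg_dl", "ntyr_ng_dl", "tnfa_pg_ml"),
  dose_response = c("animal_id", "bed", "agonist", "log_conc", "response_um"),
  hypoxia = c("animal_id", "bed", "dilation_um"),
  pressure_diameter = c("animal_id", "bed", "pressure_mmHg", "inner_um",
                        "outer_um"),
  mvd = c("animal_id", "bed", "mvd_per_mm2")
)

# Required (the rest, e.g. biomarkers, may be absent or NA).
COHORT_REQUIRED <- list(
  animals = c("animal_id", "group", "age_weeks"),
  dose_response = COHORT_SCHEMA$dose_response,
  hypoxia = COHORT_SCHEMA$hypoxia,
  pressure_diameter = COHORT_SCHEMA$pressure_diameter,
  mvd = COHORT_SCHEMA$mvd
)

read_table <- function(path, table, column_map) {
  tab <- readr::read_csv(path, col_types = readr::cols(),
                         show_col_types = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    vhi_abort(
      sprintf("Unparseable rows in '%s' (lines %s).", path,
              paste(unique(probs$row), collapse = ", ")),
      class = "vhi_error_validation"
    )
  }
  # apply the configured renaming: canonical <- actual
  for (canonical in names(column_map)) {
    actual <- column_map[[canonical]]
    if (actual %in% names(tab)) {
      names(tab)[names(tab) == actual] <- canonical
    }
  }
  required <- COHORT_REQUIRED[[table]]
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    vhi_abort(
      sprintf("'%s' is missing required column(s): %s.", path,
              paste(missing, collapse = ", ")),
      class = "vhi_error_config"
    )
  }
  tab
}

check_numeric_rows <- function(tab, cols, path) {
  for (col in intersect(cols, names(tab))) {
    vals <- tab[[col]]
    if (is.character(vals)) {
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & is.na(parsed))
      if (length(bad) > 0) {
        vhi_abort(
          sprintf("Non-numeric '%s' in '%s' for animal(s) %s (data row %s).",
                  col, path,
                  paste(unique(tab$animal_id[bad]), collapse = ", "),
                  paste(bad, collapse = ", ")),
          class = "vhi_error_validation"
        )
      }
      tab[[col]] <- parsed
    }
  }
  tab
}

#' Read a cohort from tidy CSV measurement tables
#'
#' Loads the per-animal metadata table and whichever measurement tables are
#' present in `dir` (or given explicitly via `paths`), applies the
#' configuration's column mapping, and validates: known groups, positive
#' integer ages, strictly positive biomarkers, outer > inner diameter on
#' every pressure-diameter row (offending rows named), and no orphan
#' measurements (every measured `animal_id` must appear in the metadata).
#'
#' @param dir Directory containing `animals.csv`, `dose_response.csv`,
#'   `hypoxia.csv`, `pressure_diameter.csv`, `mvd.csv` (measurement tables
#'   are optional; the metadata table is not).
#' @param paths Optional named list/vector overriding individual file paths
#'   (names from `animals`, `dose_response`, `hypoxia`, `pressure_diameter`,
#'   `mvd`).
#' @param config A [vhi_config()].
#' @return A `vhi_cohort` (see [simulate_cohort()] for the shape; `truth` is
#'   `NULL` for loaded data).
#' @export
read_cohort <- function(dir = NULL, paths = NULL, config = vhi_config()) {
  files <- lapply(setNames(nm = names(COHORT_SCHEMA)), function(tab) {
    if (!is.null(paths) && tab %in% names(paths)) return(paths[[tab]])
    if (!is.null(dir)) return(file.path(dir, paste0(tab, ".csv")))
    NULL
  })
  if (is.null(files$animals) || !file.exists(files$animals)) {
    vhi_abort("The animal metadata table (animals.csv) is required.",
              class = "vhi_error_config")
  }

  animals <- read_table(files$animals, "animals", config$column_map)
  animals <- check_numeric_rows(
    animals, c("age_weeks", "mass_g", "insulin_ng_ml", "glucose_mg_dl",
               "ntyr_ng_dl", "tnfa_pg_ml"), files$animals)
  bad_group <- !animals$group %in% VHI_GROUPS
  if (any(bad_group)) {
    vhi_abort(
      sprintf("Unknown group(s) %s in '%s'.",
              paste(unique(animals$group[bad_group]), collapse = ", "),
              files$animals),
      class = "vhi_error_validation"
    )
  }
  if (any(animals$age_weeks <= 0 | animals$age_weeks %% 1 != 0)) {
    vhi_abort("`age_weeks` must be positive integers.",
              class = "vhi_error_validation")
  }
  if (anyDuplicated(animals$animal_id)) {
    vhi_abort("Duplicate `animal_id` in the metadata table.",
              class = "vhi_error_validation")
  }
  for (col in c("mass_g", "insulin_ng_ml", "glucose_mg_dl", "ntyr_ng_dl",
                "tnfa_pg_ml")) {
    if (col %in% names(animals) &&
        any(is.finite(animals[[col]]) & animals[[col]] <= 0)) {
      vhi_abort(sprintf("Biomarker '%s' must be strictly positive when present.",
                        col), class = "vhi_error_validation")
    }
  }
  if (!"study_id" %in% names(animals)) animals$study_id <- "unspecified"

  load_measurement <- function(tab, numeric_cols) {
    path <- files[[tab]]
    if (is.null(path) || !file.exists(path)) {
      return(tibble::tibble())
    }
    out <- read_table(path, tab, config$column_map)
    out <- check_numeric_rows(out, numeric_cols, path)
    orphans <- setdiff(unique(out$animal_id), animals$animal_id)
    if (length(orphans) > 0) {
      vhi_abort(
        sprintf("%d orphan measurement animal id(s) in '%s' with no metadata: %s.",
                length(orphans), path,
                paste(head(orphans, 5), collapse = ", ")),
        class = "vhi_error_validation"
      )
    }
    out
  }

  pd <- load_measurement("pressure_diameter",
                         c("pressure_mmHg", "inner_um", "outer_um"))
  if (nrow(pd) > 0) {
    bad <- which(!(pd$outer_um > pd$inner_um) | pd$inner_um <= 0)
    if (length(bad) > 0) {
      vhi_abort(
        sprintf("Outer diameter must exceed inner diameter: violated for animal(s) %s (data row %s).",
                paste(unique(pd$animal_id[bad]), collapse = ", "),
                paste(bad, collapse = ", ")),
        class = "vhi_error_validation"
      )
    }
  }

  structure(
    list(
      animals = animals,
      dose_response = load_measurement("dose_response",
                                       c("log_conc", "response_um")),
      hypoxia = load_measurement("hypoxia", "dilation_um"),
      pressure_diameter = pd,
      mvd = load_measurement("mvd", "mvd_per_mm2"),
      truth = NULL
    ),
    class = "vhi_cohort"
  )
}

#' Write a cohort to tidy CSV measurement tables
#'
#' Inverse of [read_cohort()]: writes `animals.csv` and the non-empty
#' measurement tables into `dir`, which is created if needed.
#'
#' @param cohort A `vhi_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vhi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in names(COHORT_SCHEMA)) {
    data <- cohort[[tab]]
    if (!is.null(data) && nrow(data) > 0) {
      readr::write_csv(data, file.path(dir, paste0(tab, ".csv")))
    }
  }
  invisible(dir)
}

#' Write per-animal VHI scores to CSV
#'
#' One row per (animal, bed, variant), with the component scores and the
#' composite index. Re-reading with [read_scores()] reproduces the values.
#'
#' @param scores Tibble from [score_cohort()], non-empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (is.null(scores) || nrow(scores) == 0) {
    vhi_abort("Refusing to write an empty score table.",
              class = "vhi_error_empty_output")
  }
  readr::write_csv(scores, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
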