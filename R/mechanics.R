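#' Vessel wall thickness
#'
#' `WT = (OD - ID) / 2`, in micrometres.
#'
#' @param od_um Outer diameter (um), must exceed `id_um`.
#' @param id_um Inner diameter (um), positive.
#' @return Wall thickness (um), strictly positive. Vectorised.
#' @examples
#' wall_thickness(150, 100)  # 25
#' @export
wall_thickness <- function(od_um, id_um) {
  if (any(!is.finite(od_um)) || any(!is.finite(id_um)) ||
      any(id_um <= 0) || any(od_um <= id_um)) {
    vhi_abort("Wall thickness requires OD > ID > 0 at every point.",
              class = "vhi_error_geometry")
  }
  (od_um - id_um) / 2
}

#' Circumferential wall stress
#'
#' `sigma = P * ID / (2 * WT)` with intralumenal pressure converted from mmHg
#' at 1 mmHg = 1.334e2 N/m^2. ID and WT must share a length unit so their
#' ratio is dimensionless; the result is in N/m^2.
#'
#' @param pressure_mmHg Intralumenal pressure (mmHg), non-negative.
#' @param id_um Inner diameter (um).
#' @param wt_um Wall thickness (um), strictly positive.
#' @return Circumferential stress (N/m^2). Vectorised.
#' @examples
#' circumferential_stress(100, 100, 25)  # 2.668e4
#' @export
circumferential_stress <- function(pressure_mmHg, id_um, wt_um) {
  if (any(!is.finite(wt_um)) || any(wt_um <= 0)) {
    vhi_abort("Wall thickness must be strictly positive.",
              class = "vhi_error_geometry")
  }
  if (any(pressure_mmHg < 0)) {
    vhi_abort("Intralumenal pressure must be non-negative.",
              class = "vhi_error_validation")
  }
  (pressure_mmHg * MMHG_TO_N_M2) * id_um / (2 * wt_um)
}

#' Circumferential wall strain
#'
#' `epsilon = (ID - ID5) / ID5`, relative to the inner diameter at the lowest
#' intralumenal pressure of the passive protocol (the 5 mmHg anchor, used as
#' the "0 mmHg" point so the vessel never sees negative pressure). Strain is
#' exactly 0 at the anchor and may be negative.
#'
#' @param id_um Inner diameter (um) at the evaluated pressure.
#' @param id5_um Inner diameter (um) at the 5 mmHg anchor, positive.
#' @return Dimensionless strain. Vectorised.
#' @export
circumferential_strain <- function(id_um, id5_um) {
  if (!is.finite(id5_um) || id5_um <= 0) {
    vhi_abort("The anchor diameter ID5 must be a positive number.",
              class = "vhi_error_anchor")
  }
  (id_um - id5_um) / id5_um
}

#' Stress-strain points from a passive pressure-diameter series
#'
#' Converts one vessel's Ca2+-free pressure-diameter series into
#' (strain, stress) pairs: wall thickness is recomputed at each pressure step
#' from that step's OD and ID, stress from that step's pressure, ID and WT,
#' and strain relative to the inner diameter at the 5 mmHg anchor.
#'
#' @param pressure_mmHg Strictly increasing pressures (mmHg); must include
#'   the 5 mmHg anchor.
#' @param inner_um,outer_um Inner and outer diameters (um), `outer > inner`.
#' @param anchor_mmHg Anchor pressure (default 5 mmHg).
#' @return Tibble with columns `pressure_mmHg`, `strain`, `stress_N_m2`.
#' @export
stress_strain_points <- function(pressure_mmHg, inner_um, outer_um,
                                 anchor_mmHg = 5) {
  n <- length(pressure_mmHg)
  if (length(inner_um) != n || length(outer_um) != n) {
    vhi_abort("Pressure and diameter vectors must have equal length.",
              class = "vhi_error_validation")
  }
  if (is.unsorted(pressure_mmHg, strictly = TRUE)) {
    vhi_abort("Pressures must be strictly increasing.",
              class = "vhi_error_validation")
  }
  anchor <- which(pressure_mmHg == anchor_mmHg)
  if (length(anchor) != 1) {
    vhi_abort(
      sprintf("Series is missing the %g mmHg anchor pressure point.", anchor_mmHg),
      class = "vhi_error_anchor"
    )
  }
  wt <- wall_thickness(outer_um, inner_um)
  tibble::tibble(
    pressure_mmHg = pressure_mmHg,
    strain = circumferential_strain(inner_um, inner_um[anchor]),
    stress_N_m2 = circumferential_stress(pressure_mmHg, inner_um, wt)
  )
}

#' Fit the exponential stress-strain stiffness model
#'
#' Ordinary least squares fit of the log-linearised exponential wall model
#' \deqn{\sigma = \sigma_5 e^{\beta \epsilon}
#'   \quad\Leftrightarrow\quad \ln\sigma = \ln\sigma_5 + \beta\epsilon,}
#' where `beta` is the slope coefficient describing arterial stiffness
#' (higher beta = stiffer wall) and `sigma5` the stress at the anchor
#' diameter. The coefficient of determination is computed on the log scale,
#' and fits with `r^2 <= 0.85` are flagged `accepted = FALSE` (the component
#' is withheld for such vessels).
#'
#' @param strain Dimensionless strains, not all equal.
#' @param stress_N_m2 Strictly positive stresses (N/m^2).
#' @param r2_threshold Acceptance threshold on the log-scale r^2
#'   (strict inequality; default 0.85).
#' @return An object of class `vhi_wall_fit`: list with `sigma5`, `beta`,
#'   `r_squared`, `n`, `accepted`, and the `points` used.
#' @examples
#' eps <- seq(0, 1.6, by = 0.2)
#' fit <- fit_stress_strain(eps, 2e3 * exp(3.1 * eps))
#' fit$beta
#' @export
fit_stress_strain <- function(strain, stress_N_m2, r2_threshold = 0.85) {
  keep <- is.finite(strain) & is.finite(stress_N_m2)
  strain <- strain[keep]
  stress <- stress_N_m2[keep]
  if (length(strain) < 3) {
    vhi_abort("A stress-strain fit needs at least 3 points.",
              class = "vhi_error_insufficient_data")
  }
  if (any(stress <= 0)) {
    vhi_abort("Stresses must be strictly positive (log-linear model).",
              class = "vhi_error_domain")
  }
  if (sd(strain) == 0) {
    vhi_abort("Strains are all equal; the slope is unidentifiable.",
              class = "vhi_error_degenerate_data")
  }
  ols <- lm(log(stress) ~ strain)
  ly <- log(stress)
  r2 <- 1 - sum(stats::residuals(ols)^2) / sum((ly - mean(ly))^2)
  structure(
    list(
      sigma5 = exp(coef(ols)[[1]]),
      beta = coef(ols)[[2]],
      r_squared = r2,
      n = length(strain),
      accepted = r2 > r2_threshold,
      points = tibble::tibble(strain = strain, stress_N_m2 = stress)
    ),
    class = "vhi_wall_fit"
  )
}

#' @export
print.vhi_wall_fit <- function(x, ...) {
  cat("Exponential stress-strain fit (ln sigma ~ strain)\n")
  cat(sprintf("  sigma5 = %.4g N/m^2, beta = %.3f, r^2 = %.3f (n = %d)\n",
              x$sigma5, x$beta, x$r_squared, x$n))
  cat(sprintf("  %s\n", if (x$accepted) "accepted (r^2 > threshold)"
              else "rejected (r^2 <= threshold)"))
  invisible(x)
}

#' Wall stiffness component from a pressure-diameter series
#'
#' Composes [stress_strain_points()] and [fit_stress_strain()] over a passive
#' pressure-diameter series and returns the stiffness coefficient beta as the
#' `stiffness_beta` component. Vessels whose fit fails the r^2 acceptance
#' rule yield `NA` with a warning.
#'
#' @inheritParams stress_strain_points
#' @inheritParams fit_stress_strain
#' @return List with `value` (beta, or `NA` if the fit is rejected) and
#'   `fit` (the `vhi_wall_fit`).
#' @export
stiffness_component <- function(pressure_mmHg, inner_um, outer_um,
                                anchor_mmHg = 5, r2_threshold = 0.85) {
  pts <- stress_strain_points(pressure_mmHg, inner_um, outer_um, anchor_mmHg)
  fit <- fit_stress_strain(pts$strain, pts$stress_N_m2, r2_threshold)
  if (!fit$accepted) {
    warn(sprintf(
      "Stress-strain fit rejected (r^2 = %.3f <= %.2f); stiffness component withheld.",
      fit$r_squared, r2_threshold))
    return(list(value = NA_real_, fit = fit))
  }
  list(value = fit$beta, fit = fit)
}
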