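#' Logistic concentration-response model
#'
#' Evaluates the four-parameter-style logistic used for agonist
#' concentration-response curves in pressurised vessel preparations,
#' \deqn{y = min + \frac{max - min}{1 + 10^{(logEC50 - x)}}}
#' where `x` is the log10 molar agonist concentration and `y` the change in
#' vessel diameter (micrometres). At `x = log_ec50` the response is exactly
#' halfway between the bounds; the function is monotone non-decreasing in `x`
#' whenever `max >= min`.
#'
#' @param x Numeric vector of log10 molar concentrations.
#' @param min,max Lower and upper bounds of the diameter change (um).
#' @param log_ec50 log10 concentration of half-maximal response.
#' @return Numeric vector of responses (um).
#' @examples
#' logistic_response(-7.5, min = 0, max = 100, log_ec50 = -7.5)  # 50
#' @export
logistic_response <- function(x, min, max, log_ec50) {
  stopifnot(is.finite(min), is.finite(max), is.finite(log_ec50))
  min + (max - min) / (1 + 10^(log_ec50 - x))
}

#' Fit the logistic concentration-response model
#'
#' Nonlinear least squares fit of [logistic_response()] to one vessel's
#' concentration-response series. Starting values are taken from the data
#' (`min` from the smallest response, `max` from the largest, `log_ec50` from
#' the concentration whose response is nearest the half-range crossing), with
#' up to `restarts` jittered restarts if the optimizer fails to converge.
#' `log_ec50` is constrained to the observed concentration range plus/minus
#' 2 log units so near-flat series cannot drive it to infinity.
#'
#' @param log_conc Numeric vector of log10 molar concentrations, strictly
#'   increasing, at least 4 distinct values.
#' @param response_um Numeric vector of diameter changes (um), same length.
#' @param restarts Maximum number of jittered restarts after a failed fit.
#' @return An object of class `vhi_logistic_fit`: a list with elements
#'   `min`, `max`, `log_ec50`, `sse`, `converged`, `n`, `fitted`.
#' @examples
#' x <- c(-9, -8, -7.5, -7, -6)
#' fit <- fit_logistic(x, logistic_response(x, 10, 120, -7.5))
#' fit$max
#' @export
fit_logistic <- function(log_conc, response_um, restarts = 5) {
  if (length(log_conc) != length(response_um)) {
    vhi_abort("`log_conc` and `response_um` must have equal length.",
              class = "vhi_error_validation")
  }
  keep <- is.finite(log_conc) & is.finite(response_um)
  x <- log_conc[keep]
  y <- response_um[keep]
  if (length(unique(x)) < 4) {
    vhi_abort("A concentration-response fit needs >= 4 distinct concentrations.",
              class = "vhi_error_insufficient_data")
  }
  if (is.unsorted(x, strictly = FALSE)) {
    ord <- order(x)
    x <- x[ord]; y <- y[ord]
  }
  if (sd(y) == 0) {
    vhi_abort("All responses are identical; the logistic model is unidentifiable.",
              class = "vhi_error_degenerate_data")
  }

  lo_ec <- min(x) - 2
  hi_ec <- max(x) + 2
  half <- (min(y) + max(y)) / 2
  start0 <- c(min = min(y), max = max(y),
              log_ec50 = x[which.min(abs(y - half))])

  try_fit <- function(start) {
    start["log_ec50"] <- pmin(pmax(start["log_ec50"], lo_ec), hi_ec)
    tryCatch(
      minpack.lm::nlsLM(
        y ~ logistic_response(x, min, max, log_ec50),
        start = as.list(start),
        lower = c(-Inf, -Inf, lo_ec),
        upper = c(Inf, Inf, hi_ec),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  fit <- try_fit(start0)
  attempt <- 0
  while (is.null(fit) && attempt < restarts) {
    attempt <- attempt + 1
    jitter <- c(min = rnorm(1, 0, 0.05 * diff(range(y)) + 1e-6),
                max = rnorm(1, 0, 0.05 * diff(range(y)) + 1e-6),
                log_ec50 = rnorm(1, 0, 0.5))
    fit <- try_fit(start0 + jitter)
  }

  if (is.null(fit)) {
    out <- list(min = NA_real_, max = NA_real_, log_ec50 = NA_real_,
                sse = NA_real_, converged = FALSE, n = length(x),
                fitted = rep(NA_real_, length(x)))
    return(structure(out, class = "vhi_logistic_fit"))
  }

  est <- coef(fit)
  res <- y - logistic_response(x, est[["min"]], est[["max"]], est[["log_ec50"]])
  structure(
    list(min = est[["min"]], max = est[["max"]], log_ec50 = est[["log_ec50"]],
         sse = sum(res^2), converged = TRUE, n = length(x),
         fitted = logistic_response(x, est[["min"]], est[["max"]], est[["log_ec50"]])),
    class = "vhi_logistic_fit"
  )
}

#' @export
print.vhi_logistic_fit <- function(x, ...) {
  cat("Logistic concentration-response fit\n")
  if (x$converged) {
    cat(sprintf("  min = %.2f um, max = %.2f um, logEC50 = %.3f\n",
                x$min, x$max, x$log_ec50))
    cat(sprintf("  SSE = %.4g over %d points\n", x$sse, x$n))
  } else {
    cat("  did not converge\n")
  }
  invisible(x)
}

#' Upper-bound dilation from a logistic fit
#'
#' The reactivity components of the index (acetylcholine- and
#' nitroprusside-induced dilation) are the fitted upper bound (`max`) of the
#' logistic concentration-response model, in micrometres.
#'
#' @param fit A `vhi_logistic_fit` from [fit_logistic()].
#' @return The fitted upper bound (um). Errors if the fit did not converge.
#' @export
dilation_upper_bound <- function(fit) {
  stopifnot(inherits(fit, "vhi_logistic_fit"))
  if (!isTRUE(fit$converged)) {
    vhi_abort("Cannot extract an upper bound from an unconverged fit.",
              class = "vhi_error_unconverged_fit")
  }
  fit$max
}

#' Hypoxic dilation component
#'
#' The hypoxic challenge is a single PO2 step (roughly 135 to 45 mmHg), not a
#' concentration series, so the measured dilation passes through unchanged as
#' the `hypoxic_dilation` component. A negative dilation (constriction under
#' hypoxia) is passed through with a warning.
#'
#' @param dilation_um Measured dilation (um).
#' @return The dilation (um).
#' @export
hypoxic_component <- function(dilation_um) {
  if (!is.finite(dilation_um)) {
    vhi_abort("Hypoxic dilation must be a finite number.",
              class = "vhi_error_validation")
  }
  if (dilation_um < 0) {
    warn("Negative hypoxic dilation passed through as measured.")
  }
  dilation_um
}
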