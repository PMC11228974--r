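#' TWIMS CCS calibration
#'
#' Traveling-wave ion mobility (TWIMS) drift times have no closed-form
#' relation to collision cross section, so CCS measurement relies on an
#' empirical power-law calibration against ions of known (helium-referenced)
#' literature CCS. The protocol implemented here is the standard corrected
#' power-law procedure: measured arrival times are corrected for the
#' m/z-dependent post-mobility flight time (EDC correction), literature CCS
#' values are corrected for charge and reduced mass, and a straight line is
#' fitted in log-log space, yielding `ln(CCS') = ln(A) + X * ln(td')`.
#' The exponent `X` is the empirically derived calibration constant.
#'
#' @name calibration
NULL

#' EDC-corrected drift time
#'
#' Subtracts the mass-dependent post-mobility flight time from a measured
#' arrival time: `td' = td - edc_coefficient * sqrt(mz) / 1000`.
#'
#' @param td Measured arrival (drift) time in ms. Vectorised.
#' @param mz Ion m/z in Th.
#' @param edc_coefficient Instrument EDC delay coefficient
#'   (ms per sqrt(Th), scaled by 1000). Typical Synapt value ~1.57.
#' @return Corrected drift time in ms.
#' @export
#' @examples
#' corrected_drift_time(10, 4900, 1.57)  # 9.8901
corrected_drift_time <- function(td, mz, edc_coefficient) {
  if (any(!is.finite(td)) || any(td <= 0)) {
    stop_ciufold("drift times must be positive and finite")
  }
  tdp <- td - edc_coefficient * sqrt(mz) / 1000
  if (any(tdp <= 0)) {
    stop_ciufold(
      "EDC correction exceeds measured drift time (td' <= 0); check mz/edc_coefficient"
    )
  }
  tdp
}

#' Charge- and reduced-mass-corrected literature CCS
#'
#' `CCS' = CCS_lit * sqrt(mu) / z` with reduced mass
#' `mu = m * M / (m + M)` of the ion (mass `m`, Da) and the drift gas
#' (mass `M`, Da).
#'
#' @param ccs_lit Literature CCS (any consistent area unit). Vectorised.
#' @param charge Ion charge in elementary charges.
#' @param mass Ion mass in Da.
#' @param drift_gas_mass Drift gas mass in Da (N2 = 28.0134, He = 4.0026).
#' @return Corrected CCS, same units as `ccs_lit`.
#' @export
corrected_literature_ccs <- function(ccs_lit, charge, mass, drift_gas_mass) {
  if (any(c(ccs_lit, charge, mass, drift_gas_mass) <= 0)) {
    stop_ciufold("ccs_lit, charge, mass and drift_gas_mass must all be > 0")
  }
  mu <- mass * drift_gas_mass / (mass + drift_gas_mass)
  ccs_lit * sqrt(mu) / charge
}

#' Fit the power-law TWIMS calibration
#'
#' Ordinary least squares on `(ln td', ln CCS')`: the slope is the
#' empirical exponent `X`, the intercept `ln A`. Calibrant tables typically
#' combine denatured and native protein charge states spanning the analyte
#' mobility range.
#'
#' @param points Data frame with columns `name`, `mass`, `charge`, `mz`,
#'   `ccs_lit`, `td` (see [read_calibrant_table()]).
#' @param edc_coefficient EDC delay coefficient; see [corrected_drift_time()].
#' @param drift_gas_mass Drift gas mass in Da.
#' @return A `ciu_calibration` object: list with `A`, `X`,
#'   `edc_coefficient`, `drift_gas_mass`, `fit_r2`, `residuals`
#'   (per-point relative CCS error), and the input `points`.
#' @export
fit_calibration <- function(points, edc_coefficient = 1.57,
                            drift_gas_mass = 28.0134) {
  required <- c("mass", "charge", "mz", "ccs_lit", "td")
  if (!is.data.frame(points) || !all(required %in% names(points))) {
    stop_ciufold("`points` must be a data frame with columns %s",
                 paste(required, collapse = ", "))
  }
  if (nrow(points) < 3L) {
    stop_ciufold("calibration requires >= 3 calibrant points (got %d)",
                 nrow(points))
  }
  tdp <- corrected_drift_time(points$td, points$mz, edc_coefficient)
  if (stats::sd(log(tdp)) < 1e-12) {
    stop_ciufold("degenerate calibrant set: corrected drift times do not vary")
  }
  omega_p <- corrected_literature_ccs(points$ccs_lit, points$charge,
                                      points$mass, drift_gas_mass)
  fit <- stats::lm(log(omega_p) ~ log(tdp))
  A <- exp(unname(stats::coef(fit)[1L]))
  X <- unname(stats::coef(fit)[2L])
  pred <- exp(stats::fitted(fit))
  model <- structure(
    list(
      A = A, X = X,
      edc_coefficient = edc_coefficient,
      drift_gas_mass = drift_gas_mass,
      fit_r2 = suppressWarnings(summary(fit)$r.squared),
      residuals = unname(pred / omega_p - 1),
      points = points
    ),
    class = "ciu_calibration"
  )
  if (model$A <= 0 || model$X <= 0) {
    stop_ciufold("calibration fit produced non-physical parameters (A=%g, X=%g)",
                 model$A, model$X)
  }
  model
}

#' Construct a calibration model from known parameters
#'
#' Used by the synthetic-data generator (where A and X are ground truth)
#' and when loading a previously fitted model from disk.
#'
#' @param A Power-law prefactor (> 0).
#' @param X Power-law exponent (> 0, dimensionless).
#' @inheritParams fit_calibration
#' @return A `ciu_calibration` object.
#' @export
calibration_model <- function(A, X, edc_coefficient = 1.57,
                              drift_gas_mass = 28.0134) {
  check_scalar_num(A, "A", positive = TRUE)
  check_scalar_num(X, "X", positive = TRUE)
  structure(
    list(A = A, X = X, edc_coefficient = edc_coefficient,
         drift_gas_mass = drift_gas_mass, fit_r2 = NA_real_,
         residuals = numeric(0), points = NULL),
    class = "ciu_calibration"
  )
}

#' @export
print.ciu_calibration <- function(x, ...) {
  cat(sprintf("TWIMS power-law calibration: A = %.6g, X = %.6g\n", x$A, x$X))
  cat(sprintf("  EDC coefficient %.4g, drift gas mass %.4f Da\n",
              x$edc_coefficient, x$drift_gas_mass))
  if (is.finite(x$fit_r2)) {
    cat(sprintf("  fitted on %d calibrants, R^2 = %.6f\n",
                nrow(x$points), x$fit_r2))
  }
  invisible(x)
}

#' Apply a calibration to analyte drift times
#'
#' `CCS = A * td'^X * z / sqrt(mu)`, the inverse of the corrections applied
#' during fitting, giving a calibrated CCS (nm^2 when the calibrant table is
#' in nm^2).
#'
#' @param model A `ciu_calibration` object.
#' @param td Measured arrival time(s) in ms.
#' @param mz Analyte m/z in Th.
#' @param charge Analyte charge.
#' @param mass Analyte mass in Da.
#' @return Calibrated CCS, same units as the calibrant CCS values.
#' @export
calibrated_ccs <- function(model, td, mz, charge, mass) {
  stopifnot(inherits(model, "ciu_calibration"))
  tdp <- corrected_drift_time(td, mz, model$edc_coefficient)
  mu <- mass * model$drift_gas_mass / (mass + model$drift_gas_mass)
  model$A * tdp^model$X * charge / sqrt(mu)
}

#' Invert a calibration: drift time expected for a given CCS
#'
#' Exact inverse of [calibrated_ccs()]; used by the synthetic-data generator
#' to place arrival-time peaks at prescribed CCS values.
#'
#' @inheritParams calibrated_ccs
#' @param ccs Target CCS (> 0), same units as the calibration.
#' @return Arrival time in ms (EDC flight time added back).
#' @export
invert_calibration <- function(model, ccs, mz, charge, mass) {
  stopifnot(inherits(model, "ciu_calibration"))
  if (any(ccs <= 0)) stop_ciufold("ccs must be > 0")
  mu <- mass * model$drift_gas_mass / (mass + model$drift_gas_mass)
  tdp <- (ccs * sqrt(mu) / (model$A * charge))^(1 / model$X)
  tdp + model$edc_coefficient * sqrt(mz) / 1000
}
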