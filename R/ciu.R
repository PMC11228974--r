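#' CIU fingerprints, unfolding curves and CIU_chi statistics
#'
#' Collision-induced unfolding is quantified by converting per-voltage
#' arrival-time distributions to calibrated CCS distributions, reducing each
#' to a centroid CCS, and fitting the centroid-vs-voltage curve with a
#' four-parameter logistic (4PL). The midpoint of the fit is CIU50; the
#' voltage inducing an arbitrary percentage chi of the maximal unfolding is
#' CIU_chi, obtained by inverting the fitted logistic. When ligand ejection
#' occurs at voltages similar to unfolding, CIU50 can mask ligand
#' stabilisation, while low-chi statistics retain discrimination.
#'
#' @name ciu_analysis
NULL

#' Convert an ATD to a calibrated CCS distribution
#'
#' Applies a calibration model bin-wise: each arrival-time bin centre maps
#' to a CCS value, intensities are carried over. Bins whose EDC-corrected
#' drift time would be non-positive are dropped.
#'
#' @param atd An `atd` object (or data frame with `time`, `intensity`) with
#'   attribute `voltage`.
#' @param model A `ciu_calibration`.
#' @param mz,charge,mass Analyte ion properties.
#' @return A `ccs_dist`: data frame with columns `ccs` (nm^2, strictly
#'   increasing) and `intensity`, voltage kept as attribute.
#' @export
atd_to_ccs <- function(atd, model, mz, charge, mass) {
  flight <- model$edc_coefficient * sqrt(mz) / 1000
  keep <- atd$time > flight
  if (!any(keep)) stop_ciufold("no arrival-time bins survive the EDC correction")
  ccs <- calibrated_ccs(model, atd$time[keep], mz, charge, mass)
  structure(data.frame(ccs = ccs, intensity = atd$intensity[keep]),
            voltage = attr(atd, "voltage"), class = c("ccs_dist", "data.frame"))
}

#' Intensity-weighted centroid CCS
#'
#' @param dist A `ccs_dist` (columns `ccs`, `intensity`).
#' @return Centroid CCS (nm^2).
#' @export
centroid_ccs <- function(dist) {
  w <- dist$intensity
  if (all(w <= 0)) stop_ciufold("all-zero intensity distribution has no centroid")
  sum(dist$ccs * w) / sum(w)
}

#' Build a CIU fingerprint matrix
#'
#' Interpolates each per-voltage CCS distribution onto a common CCS bin axis
#' and max-normalises each voltage column to 1 (CIUSuite-style convention),
#' ordering columns by voltage.
#'
#' @param dists List of `ccs_dist` objects, one per voltage.
#' @param ccs_bins Common CCS axis (nm^2); default 25-45 nm^2 at 0.1 nm^2.
#' @return A `ciu_fingerprint`: bins x voltages matrix of normalised
#'   intensity in \[0, 1\], with attributes `ccs_bins` and `voltages`.
#' @export
build_fingerprint <- function(dists, ccs_bins = seq(25, 45, by = 0.1)) {
  volts <- vapply(dists, function(d) attr(d, "voltage"), numeric(1))
  if (anyDuplicated(volts)) {
    stop_ciufold("duplicate voltages in fingerprint input: %s",
                 paste(unique(volts[duplicated(volts)]), collapse = ", "))
  }
  ord <- order(volts)
  cols <- lapply(dists[ord], function(d) {
    y <- stats::approx(d$ccs, d$intensity, xout = ccs_bins, yleft = 0,
                       yright = 0)$y
    m <- max(y)
    if (m > 0) y / m else y
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- format(volts[ord], trim = TRUE)
  structure(mat, ccs_bins = ccs_bins, voltages = volts[ord],
            class = c("ciu_fingerprint", class(mat)))
}

#' Plot a CIU fingerprint
#'
#' @param x A `ciu_fingerprint`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ciu_fingerprint <- function(x, ...) {
  graphics::image(attr(x, "voltages"), attr(x, "ccs_bins"), t(unclass(x)),
                  xlab = "collision voltage (V)", ylab = "CCS (nm^2)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Unfolding curve: centroid CCS vs collision voltage
#'
#' Reduces one replicate's ATD matrix to a centroid-CCS trace.
#'
#' @param atd_matrix An `atd_matrix` (bins x voltages, attributes `time`,
#'   `voltages`).
#' @param model A `ciu_calibration`.
#' @param mz,charge,mass Analyte ion properties.
#' @param reference_voltage Voltage of the most compact (unactivated) state,
#'   used as the zero of [delta_ccs()]. Defaults to the lowest voltage.
#' @param species,replicate Optional labels carried through.
#' @return An `unfolding_curve`: data frame `voltage`, `ccs` with attributes
#'   `reference_voltage`, `species`, `replicate`.
#' @export
unfolding_curve <- function(atd_matrix, model, mz, charge, mass,
                            reference_voltage = NULL, species = NA_character_,
                            replicate = NA_integer_) {
  volts <- attr(atd_matrix, "voltages")
  time <- attr(atd_matrix, "time")
  ccs_vals <- vapply(seq_along(volts), function(k) {
    a <- structure(data.frame(time = time, intensity = atd_matrix[, k]),
                   voltage = volts[k])
    centroid_ccs(atd_to_ccs(a, model, mz, charge, mass))
  }, numeric(1))
  if (is.null(reference_voltage)) reference_voltage <- min(volts)
  if (!any(abs(volts - reference_voltage) < 1e-9)) {
    stop_ciufold("reference_voltage %g not in the voltage grid", reference_voltage)
  }
  structure(data.frame(voltage = volts, ccs = ccs_vals),
            reference_voltage = reference_voltage, species = species,
            replicate = replicate,
            class = c("unfolding_curve", "data.frame"))
}

#' Delta-CCS transform of an unfolding curve
#'
#' Subtracts the CCS at the reference voltage (the most compact,
#' unactivated structure), so curves of species with different absolute
#' sizes can be compared on a common unfolding scale.
#'
#' @param curve An `unfolding_curve`.
#' @return An `unfolding_curve` of delta-CCS values; zero at the reference.
#' @export
delta_ccs <- function(curve) {
  ref <- attr(curve, "reference_voltage")
  idx <- which(abs(curve$voltage - ref) < 1e-9)
  if (length(idx) != 1L) {
    stop_ciufold("reference voltage %g missing from curve", ref)
  }
  out <- curve
  out$ccs <- curve$ccs - curve$ccs[idx]
  out
}

# 4PL model value.
four_pl <- function(v, L, U, v50, h) L + (U - L) / (1 + exp(-h * (v - v50)))

#' Fit a four-parameter logistic to an unfolding curve
#'
#' Least-squares fit of `CCS(V) = L + (U - L) / (1 + exp(-h (V - v50)))`.
#' Initialisation: `L = min`, `U = max`, `v50` at the interpolated
#' half-range crossing, `h = 4 / (20-80% span)`. Optimisation is
#' Nelder-Mead followed by BFGS polish on (L, U, v50, log h), which keeps
#' `h > 0`. A transition amplitude below `min_amplitude` is flagged
#' degenerate rather than fitted. Non-convergence never throws: the result
#' carries `converged = FALSE` and diagnostics.
#'
#' @param curve An `unfolding_curve`, or anything with `voltage` and `ccs`
#'   columns (delta-CCS curves fit identically: the 4PL is translation
#'   invariant in y).
#' @param min_amplitude Minimum y-range treated as a real transition.
#' @return A `four_pl_fit`: list with `L`, `U`, `v50`, `hill`, `rss`,
#'   `converged`, `degenerate`, `message` and the fitted data.
#' @export
fit_4pl <- function(curve, min_amplitude = 1e-8) {
  v <- curve$voltage
  y <- curve$ccs
  if (length(v) < 6L) stop_ciufold("4PL fit requires >= 6 points (got %d)", length(v))
  rng <- range(y)
  out <- list(L = rng[1], U = rng[2], v50 = NA_real_, hill = NA_real_,
              rss = NA_real_, converged = FALSE, degenerate = FALSE,
              message = "", data = data.frame(voltage = v, ccs = y),
              species = attr(curve, "species"),
              replicate = attr(curve, "replicate"))
  class(out) <- "four_pl_fit"
  if (diff(rng) < min_amplitude) {
    out$degenerate <- TRUE
    out$message <- "no transition: y-range below min_amplitude"
    return(out)
  }
  mid <- mean(rng)
  cross <- function(level) {
    i <- which(y >= level)[1L]
    if (is.na(i) || i == 1L) return(v[1L])
    v[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (v[i] - v[i - 1L])
  }
  v20 <- cross(rng[1] + 0.2 * diff(rng))
  v80 <- cross(rng[1] + 0.8 * diff(rng))
  h0 <- if (v80 > v20) 4 / (v80 - v20) else 1
  par0 <- c(rng[1], rng[2], cross(mid), log(h0))
  obj <- function(p) {
    r <- y - four_pl(v, p[1], p[2], p[3], exp(p[4]))
    sum(r * r)
  }
  nm <- stats::optim(par0, obj, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  bf <- tryCatch(
    stats::optim(nm$par, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) nm
  )
  best <- if (bf$value <= nm$value) bf else nm
  p <- best$par
  out$L <- p[1]; out$U <- p[2]; out$v50 <- p[3]; out$hill <- exp(p[4])
  out$rss <- best$value
  out$converged <- is.finite(best$value) && out$U > out$L && out$hill > 0
  if (!out$converged) out$message <- "optimiser failed to find U > L with h > 0"
  out
}

#' @export
print.four_pl_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("4PL fit: degenerate (", x$message, ")\n", sep = "")
  } else {
    cat(sprintf("4PL fit: L = %.4g, U = %.4g, CIU50 = %.4g V, h = %.4g 1/V (rss %.3g, %s)\n",
                x$L, x$U, x$v50, x$hill, x$rss,
                if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' CIU_chi: voltage inducing chi percent of maximal unfolding
#'
#' Exact inverse of the fitted logistic:
#' `V_chi = v50 - ln(100/chi - 1) / h`; `ciu_chi(fit, 50)` equals the
#' fitted CIU50.
#'
#' @param fit A converged `four_pl_fit`.
#' @param chi Percentage(s) in (0, 100). Vectorised.
#' @return Voltage(s) in V.
#' @export
ciu_chi <- function(fit, chi) {
  stopifnot(inherits(fit, "four_pl_fit"))
  if (!isTRUE(fit$converged)) stop_ciufold("ciu_chi requires a converged fit")
  if (any(chi <= 0 | chi >= 100)) stop_ciufold("chi must lie strictly in (0, 100)")
  fit$v50 - log(100 / chi - 1) / fit$hill
}

#' Replicate-aggregated CIU_chi profile
#'
#' Per-chi mean and sd of [ciu_chi()] across replicate fits, mirroring the
#' standard mean +/- sd presentation over independent repeats.
#' Non-converged or degenerate replicates are excluded with a warning.
#'
#' @param fits List of `four_pl_fit` objects (one per replicate).
#' @param chi_grid Percentages; default 10-90 step 10.
#' @return A `chi_profile`: data frame `chi`, `mean_v`, `sd_v`, `n`, plus a
#'   `values` attribute holding the per-replicate matrix.
#' @export
chi_profile <- function(fits, chi_grid = seq(10, 90, by = 10)) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !isTRUE(f$degenerate),
               logical(1))
  if (any(!ok)) {
    warning(sprintf("excluding %d non-converged replicate fit(s)", sum(!ok)),
            call. = FALSE)
  }
  fits <- fits[ok]
  if (length(fits) == 0L) stop_ciufold("no converged replicate fits")
  vals <- vapply(fits, function(f) ciu_chi(f, chi_grid),
                 numeric(length(chi_grid)))
  vals <- matrix(vals, nrow = length(chi_grid))
  out <- data.frame(
    chi = chi_grid,
    mean_v = rowMeans(vals),
    sd_v = apply(vals, 1, stats::sd),
    n = length(fits)
  )
  structure(out, values = vals, class = c("chi_profile", "data.frame"))
}

#' One-way ANOVA comparison of CIU_chi across species
#'
#' Fixed-effects one-way F test of replicate CIU_chi (or CIU50) values
#' between species groups. The fully degenerate case (zero variance
#' everywhere, equal means) returns `p = 1` with a flag instead of failing.
#'
#' @param groups Named list: species -> numeric vector of replicate voltages.
#' @param chi Optional chi label carried through.
#' @return A `species_comparison`: list with `chi`, `group_means`, `f_stat`,
#'   `p_value`, `df`, `degenerate`.
#' @export
anova_compare <- function(groups, chi = NA_real_) {
  if (length(groups) < 2L) stop_ciufold("ANOVA needs >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop_ciufold("every group needs >= 2 replicate values")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  k <- nlevels(g)
  n <- length(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- k - 1L
  df2 <- n - k
  degenerate <- FALSE
  if (ssw <= .Machine$double.eps * sum(y^2)) {
    if (ssb <= .Machine$double.eps * max(1, sum(y^2))) {
      f <- 0; p <- 1; degenerate <- TRUE
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(chi = chi, group_means = gm, f_stat = f, p_value = p,
         df = c(df1, df2), degenerate = degenerate),
    class = "species_comparison"
  )
}

#' @export
print.species_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA%s: F(%d, %d) = %.4g, p = %.4g\n",
              if (is.finite(x$chi)) sprintf(" at chi = %g%%", x$chi) else "",
              x$df[1], x$df[2], x$f_stat, x$p_value))
  invisible(x)
}

#' Ligand ejection fraction
#'
#' `ejected / (bound + ejected)` from the intensities of the ligand-bound
#' and ligand-lost signals at one collision voltage.
#'
#' @param bound,ejected Non-negative intensities. Vectorised.
#' @return Fraction(s) in \[0, 1\].
#' @export
ejection_fraction <- function(bound, ejected) {
  if (any(bound < 0 | ejected < 0)) stop_ciufold("intensities must be >= 0")
  tot <- bound + ejected
  if (any(tot == 0)) stop_ciufold("bound + ejected must be > 0")
  ejected / tot
}

#' Fit a logistic ejection curve
#'
#' Two-parameter logistic fit (asymptotes fixed at 0 and 1) of ejected
#' fraction vs collision voltage, yielding the 50%-ejection voltage and
#' slope.
#'
#' @param voltage Collision voltages (V), >= 5 points.
#' @param fraction Ejected fractions in \[0, 1\].
#' @return An `ejection_fit`: list with `v50_eject`, `slope_eject`, `rss`,
#'   `converged`, `degenerate`, and the data.
#' @export
fit_ejection <- function(voltage, fraction) {
  if (length(voltage) < 5L) stop_ciufold("ejection fit requires >= 5 points")
  if (any(fraction < 0 | fraction > 1)) stop_ciufold("fractions must lie in [0, 1]")
  out <- list(v50_eject = NA_real_, slope_eject = NA_real_, rss = NA_real_,
              converged = FALSE, degenerate = FALSE,
              data = data.frame(voltage = voltage, fraction = fraction))
  class(out) <- "ejection_fit"
  if (diff(range(fraction)) < 1e-8) {
    out$degenerate <- TRUE
    return(out)
  }
  i <- which(fraction >= 0.5)[1L]
  v0 <- if (is.na(i)) stats::median(voltage) else voltage[i]
  obj <- function(p) {
    r <- fraction - stats::plogis(exp(p[2]) * (voltage - p[1]))
    sum(r * r)
  }
  nm <- stats::optim(c(v0, 0), obj, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-14))
  out$v50_eject <- nm$par[1]
  out$slope_eject <- exp(nm$par[2])
  out$rss <- nm$value
  out$converged <- nm$convergence == 0 && is.finite(nm$value)
  out
}

#' Laboratory-frame collision energy
#'
#' `Elab = z * V` in eV: kinetic energy gained by a z-charged ion
#' accelerated through V volts.
#'
#' @param voltage Acceleration (collision) voltage in V. Vectorised.
#' @param charge Charge in elementary charges, >= 1.
#' @return Energy in eV.
#' @export
#' @examples
#' elab(30, 12)  # 360 eV
elab <- function(voltage, charge) {
  if (any(charge < 1)) stop_ciufold("charge must be >= 1")
  charge * voltage
}

#' Per-replicate 4PL fits for one species of a synthetic dataset
#'
#' Convenience wrapper: calibrates every replicate ATD matrix of `species`
#' in a [simulate_dataset()] result with the dataset's own ground-truth
#' calibration, reduces to unfolding curves and fits the 4PL.
#'
#' @param dataset A `ciu_dataset`.
#' @param species Species name present in the dataset.
#' @return List of `four_pl_fit`, one per replicate.
#' @export
fit_dataset_species <- function(dataset, species) {
  stopifnot(inherits(dataset, "ciu_dataset"))
  sp <- NULL
  for (s in dataset$truth$species) if (s$name == species) sp <- s
  if (is.null(sp)) stop_ciufold("species '%s' not in dataset", species)
  model <- instrument_calibration(dataset$inst)
  lapply(seq_along(dataset$atds[[species]]), function(j) {
    cv <- unfolding_curve(dataset$atds[[species]][[j]], model, sp$mz,
                          sp$charge, sp$mass, species = species, replicate = j)
    fit_4pl(cv)
  })
}
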