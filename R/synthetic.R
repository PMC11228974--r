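#' Synthetic CIU data generation
#'
#' Emulates the raw output of a quadrupole-selected CIU experiment on a
#' traveling-wave instrument: per-voltage arrival-time distributions (ATDs)
#' for several co-isolated protein species, each undergoing a single
#' two-state unfolding transition, optionally coupled to a voltage-dependent
#' ligand-ejection channel. Ground-truth generative parameters are retained
#' so every downstream stage (calibration, centroiding, logistic fitting,
#' replicate statistics) can be validated against known values.
#'
#' @name synthetic_data
NULL

#' Collision-voltage ramp with a refined sub-range
#'
#' Union of a coarse voltage grid and a finer grid over a sub-interval
#' (e.g. 20-60 V in 1 V steps with 42-44 V refined in 0.5 V steps, the
#' classic ramp around an unfolding midpoint), sorted, duplicates removed.
#'
#' @param start,stop,step Coarse grid (V).
#' @param refine_start,refine_stop,refine_step Refined sub-grid (V); must
#'   lie inside `[start, stop]`.
#' @return Strictly increasing numeric vector of collision voltages.
#' @export
#' @examples
#' length(make_voltage_grid())  # 43
make_voltage_grid <- function(start = 20, stop = 60, step = 1,
                              refine_start = 42, refine_stop = 44,
                              refine_step = 0.5) {
  if (start >= stop) stop_ciufold("start must be < stop")
  if (step <= 0 || refine_step <= 0) stop_ciufold("steps must be > 0")
  if (refine_start < start || refine_stop > stop || refine_start > refine_stop) {
    stop_ciufold("refinement interval [%g, %g] must lie within [%g, %g]",
                 refine_start, refine_stop, start, stop)
  }
  v <- c(seq(start, stop, by = step), seq(refine_start, refine_stop, by = refine_step))
  sort(unique(round(v, 9)))
}

#' Logistic unfolded fraction
#'
#' Two-state unfolding model: fraction of the population in the extended
#' conformer at collision voltage `v`,
#' `f = 1 / (1 + exp(-slope * (v - v50)))`.
#'
#' @param v Collision voltage (V). Vectorised.
#' @param v50 Transition midpoint (V).
#' @param slope Logistic steepness (1/V), > 0.
#' @return Fraction in \[0, 1\].
#' @export
unfolded_fraction <- function(v, v50, slope) {
  if (slope <= 0) stop_ciufold("slope must be > 0")
  stats::plogis(slope * (v - v50))
}

#' Ligand survival fraction
#'
#' Fraction of ions retaining the ligand at voltage `v`:
#' `S = 1 - logistic(v; v50_eject, slope_eject)`, decreasing in `v`, with
#' `S(v50_eject) = 0.5`.
#'
#' @param v Collision voltage (V). Vectorised.
#' @param v50_eject Ejection midpoint (V).
#' @param slope_eject Logistic steepness (1/V), > 0.
#' @return Fraction in \[0, 1\].
#' @export
survival_fraction <- function(v, v50_eject, slope_eject) {
  if (slope_eject <= 0) stop_ciufold("slope_eject must be > 0")
  1 - stats::plogis(slope_eject * (v - v50_eject))
}

#' Generative parameters for one protein species
#'
#' @param name Species label.
#' @param ccs_compact,ccs_extended CCS of the compact and extended conformer
#'   (nm^2); `ccs_extended > ccs_compact > 0`.
#' @param v50_unfold Unfolding midpoint (V) of the ligand-free / ligand-lost
#'   baseline.
#' @param slope_unfold Logistic steepness (1/V), > 0.
#' @param mass Species mass (Da); used to invert the calibration.
#' @param charge Selected charge state (elementary charges).
#' @param atd_width Gaussian sigma of each conformer's arrival-time peak (ms).
#' @param v50_rep_sd Replicate-to-replicate sd of the unfolding midpoint (V);
#'   models run-to-run drift, the dominant replicate variability in fitted
#'   CIU50 values.
#' @param ejection Optional list `(v50_eject, slope_eject, coupling)`
#'   describing a voltage-dependent ligand-ejection channel. While the ligand
#'   survives, it stabilises the compact fold: the effective unfolding
#'   midpoint is `v50_unfold + coupling * S(v)` with `S` the survival
#'   fraction; the stabilisation fades as the ligand is lost.
#' @return A `species_params` object.
#' @export
species_params <- function(name, ccs_compact, ccs_extended, v50_unfold,
                           slope_unfold, mass, charge = 12,
                           atd_width = 0.15, v50_rep_sd = 0,
                           ejection = NULL) {
  check_scalar_num(ccs_compact, "ccs_compact", positive = TRUE)
  check_scalar_num(ccs_extended, "ccs_extended", positive = TRUE)
  if (ccs_extended <= ccs_compact) {
    stop_ciufold("ccs_extended must exceed ccs_compact")
  }
  check_scalar_num(slope_unfold, "slope_unfold", positive = TRUE)
  check_scalar_num(atd_width, "atd_width", positive = TRUE)
  if (!is.null(ejection)) {
    stopifnot(all(c("v50_eject", "slope_eject", "coupling") %in% names(ejection)))
    check_scalar_num(ejection$slope_eject, "slope_eject", positive = TRUE)
  }
  structure(
    list(name = name, ccs_compact = ccs_compact, ccs_extended = ccs_extended,
         v50_unfold = v50_unfold, slope_unfold = slope_unfold,
         mass = mass, charge = charge, mz = mass / charge + 1.007276,
         atd_width = atd_width, v50_rep_sd = v50_rep_sd, ejection = ejection),
    class = "species_params"
  )
}

#' Default three-species elongation-factor system
#'
#' Apo protein, binary nucleotide complex and ternary antibiotic complex of
#' a ~43 kDa three-domain G-protein at charge state 12+, with compact CCS,
#' unfolding midpoints and replicate sds at the scale reported for EF-Tu
#' CIU experiments (33.8/34.7/35.6 nm^2; 40.3/43.2/43.8 V; sd 0.5-1.0 V),
#' a 42 V ligand-ejection midpoint for the ternary species, and a single
#' unfolding event of ~3.5 nm^2 amplitude between 40 and 50 V.
#'
#' The ternary species shares the binary baseline midpoint (43.2 V); its
#' extra antibiotic stabilisation enters through the ejection coupling
#' (+2.0 V while the ligand survives), so the apparent midpoint sits near
#' 43.8 V and the stabilisation is largest at low unfolded fractions.
#'
#' @return List of three `species_params` objects (apo, binary, ternary).
#' @export
eftu_species_defaults <- function() {
  list(
    species_params("apo", ccs_compact = 33.8, ccs_extended = 37.3,
                   v50_unfold = 40.3, slope_unfold = 0.8,
                   mass = 43313, charge = 12, v50_rep_sd = 0.8),
    species_params("binary", ccs_compact = 34.7, ccs_extended = 38.2,
                   v50_unfold = 43.2, slope_unfold = 0.8,
                   mass = 43859, charge = 12, v50_rep_sd = 0.5),
    species_params("ternary", ccs_compact = 35.6, ccs_extended = 39.1,
                   v50_unfold = 43.2, slope_unfold = 0.8,
                   mass = 44521, charge = 12, v50_rep_sd = 1.0,
                   ejection = list(v50_eject = 42, slope_eject = 0.5,
                                   coupling = 2.0))
  )
}

#' Instrument / acquisition parameters for the generator
#'
#' @param voltage_grid Strictly increasing collision-voltage ramp (V).
#' @param cal_A,cal_X Ground-truth calibration power law.
#' @param edc_coefficient EDC delay coefficient (see [corrected_drift_time()]).
#' @param drift_gas_mass Mobility gas mass (Da), N2 by default.
#' @param bin_width Arrival-time bin width (ms).
#' @param atd_max Upper end of the arrival-time window (ms); the pusher
#'   window of a Synapt-class instrument (0-14 ms by default).
#' @param noise_sd Relative (multiplicative) intensity noise per bin.
#' @param n_replicates Number of independent repeats (quintuplicate by
#'   default).
#' @return An `instrument_params` object.
#' @export
instrument_params <- function(voltage_grid = make_voltage_grid(),
                              cal_A = 0.8, cal_X = 1.41,
                              edc_coefficient = 1.57,
                              drift_gas_mass = 28.0134,
                              bin_width = 0.1, atd_max = 14,
                              noise_sd = 0.03, n_replicates = 5) {
  if (is.unsorted(voltage_grid, strictly = TRUE)) {
    stop_ciufold("voltage_grid must be strictly increasing")
  }
  check_scalar_num(bin_width, "bin_width", positive = TRUE)
  if (n_replicates < 1) stop_ciufold("n_replicates must be >= 1")
  structure(
    list(voltage_grid = voltage_grid, cal_A = cal_A, cal_X = cal_X,
         edc_coefficient = edc_coefficient, drift_gas_mass = drift_gas_mass,
         bin_width = bin_width, atd_max = atd_max, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates)),
    class = "instrument_params"
  )
}

# True calibration model implied by the instrument parameters.
instrument_calibration <- function(inst) {
  calibration_model(inst$cal_A, inst$cal_X, inst$edc_coefficient,
                    inst$drift_gas_mass)
}

# Effective unfolding midpoint at voltage v, including ejection coupling.
effective_v50 <- function(species, v) {
  v50 <- species$v50_unfold
  ej <- species$ejection
  if (!is.null(ej)) {
    v50 <- v50 + ej$coupling * survival_fraction(v, ej$v50_eject, ej$slope_eject)
  }
  v50
}

#' Simulate one arrival-time distribution
#'
#' Two Gaussian conformer peaks centred at the drift times obtained by
#' inverting the instrument calibration at the species' compact and extended
#' CCS, weighted `(1 - f)` and `f` where `f` is the unfolded fraction at the
#' effective midpoint (shifted by the ejection coupling while the ligand
#' survives). Multiplicative Gaussian bin noise, truncated at zero.
#'
#' @param species A `species_params` object.
#' @param inst An `instrument_params` object.
#' @param v Collision voltage (V).
#' @param seed Integer seed; same seed gives a bit-identical ATD.
#' @return An `atd` object: data frame with columns `time` (ms, bin centres)
#'   and `intensity`, with the voltage stored as attribute `voltage`.
#' @export
simulate_atd <- function(species, inst, v, seed = 1) {
  stopifnot(inherits(species, "species_params"),
            inherits(inst, "instrument_params"))
  model <- instrument_calibration(inst)
  td_c <- invert_calibration(model, species$ccs_compact, species$mz,
                             species$charge, species$mass)
  td_e <- invert_calibration(model, species$ccs_extended, species$mz,
                             species$charge, species$mass)
  if (!is.finite(td_c) || !is.finite(td_e) || td_c <= 0 || td_e <= 0) {
    stop_ciufold("calibration is not invertible over positive drift times")
  }
  f <- unfolded_fraction(v, effective_v50(species, v), species$slope_unfold)
  time <- seq(inst$bin_width / 2, inst$atd_max - inst$bin_width / 2,
              by = inst$bin_width)
  base <- (1 - f) * stats::dnorm(time, td_c, species$atd_width) +
    f * stats::dnorm(time, td_e, species$atd_width)
  intensity <- if (inst$noise_sd > 0) {
    with_seed(seed, pmax(0, base * (1 + stats::rnorm(length(base), 0, inst$noise_sd))))
  } else {
    base
  }
  structure(data.frame(time = time, intensity = intensity),
            voltage = v, class = c("atd", "data.frame"))
}

#' Simulate a full CIU dataset
#'
#' Full factorial over species x replicates x voltages. Each replicate
#' draws one unfolding-midpoint offset (sd `v50_rep_sd`), modelling
#' run-to-run drift; each (species, replicate, voltage) ATD uses a
#' deterministic sub-seed derived from `seed`, so regeneration is
#' bit-identical and noise streams are independent.
#'
#' @param species_list List of `species_params` objects.
#' @param inst An `instrument_params` object.
#' @param seed Integer master seed.
#' @return A `ciu_dataset`: list with `atds[[species]][[replicate]]` (each an
#'   `atd_matrix`: bins x voltages matrix with attributes `time` and
#'   `voltages`), `truth` (the generative parameters, including the realised
#'   per-replicate midpoints), `inst`, and `seed`.
#' @export
simulate_dataset <- function(species_list, inst = instrument_params(), seed = 1) {
  if (length(species_list) == 0) stop_ciufold("species_list must be non-empty")
  volts <- inst$voltage_grid
  atds <- list()
  rep_v50 <- list()
  for (i in seq_along(species_list)) {
    sp <- species_list[[i]]
    per_rep <- vector("list", inst$n_replicates)
    offsets <- numeric(inst$n_replicates)
    for (j in seq_len(inst$n_replicates)) {
      offsets[j] <- if (sp$v50_rep_sd > 0) {
        with_seed(sub_seed(seed, i, j), stats::rnorm(1, 0, sp$v50_rep_sd))
      } else 0
      sp_j <- sp
      sp_j$v50_unfold <- sp$v50_unfold + offsets[j]
      cols <- lapply(seq_along(volts), function(k) {
        simulate_atd(sp_j, inst, volts[k], seed = sub_seed(seed, i, j, k))$intensity
      })
      mat <- do.call(cbind, cols)
      colnames(mat) <- format(volts, trim = TRUE)
      time <- seq(inst$bin_width / 2, inst$atd_max - inst$bin_width / 2,
                  by = inst$bin_width)
      per_rep[[j]] <- structure(mat, time = time, voltages = volts,
                                class = c("atd_matrix", class(mat)))
    }
    atds[[sp$name]] <- per_rep
    rep_v50[[sp$name]] <- sp$v50_unfold + offsets
  }
  structure(
    list(atds = atds,
         truth = list(species = species_list, replicate_v50 = rep_v50),
         inst = inst, seed = seed),
    class = "ciu_dataset"
  )
}

#' Simulate a calibrant table
#'
#' Generates measured drift times by inverting a ground-truth power law at
#' each calibrant's corrected literature CCS, then applies multiplicative
#' noise. Round-tripping through [fit_calibration()] recovers
#' `(true_A, true_X)` exactly in the noise-free limit.
#'
#' @param true_A,true_X Ground-truth calibration power law.
#' @param calibrant_specs Data frame with columns `name`, `mass`, `charge`,
#'   `ccs_lit` (nm^2). Defaults to the shipped synthetic calibrant set
#'   (denatured myoglobin, native cytochrome c and ubiquitin charge states).
#' @param noise_sd Relative sd of the drift-time noise.
#' @param seed Integer seed.
#' @param edc_coefficient,drift_gas_mass Passed to the calibration model.
#' @return Data frame of calibrant points (`name`, `mass`, `charge`, `mz`,
#'   `ccs_lit`, `td`) suitable for [fit_calibration()].
#' @export
simulate_calibrants <- function(true_A, true_X,
                                calibrant_specs = read_calibrant_table(),
                                noise_sd = 0, seed = 1,
                                edc_coefficient = 1.57,
                                drift_gas_mass = 28.0134) {
  check_scalar_num(true_A, "true_A", positive = TRUE)
  model <- calibration_model(true_A, true_X, edc_coefficient, drift_gas_mass)
  specs <- calibrant_specs
  mz <- specs$mass / specs$charge + 1.007276
  td <- vapply(seq_len(nrow(specs)), function(i) {
    invert_calibration(model, specs$ccs_lit[i], mz[i], specs$charge[i],
                       specs$mass[i])
  }, numeric(1))
  if (noise_sd > 0) {
    td <- with_seed(seed, td * (1 + stats::rnorm(length(td), 0, noise_sd)))
  }
  out <- data.frame(name = specs$name, mass = specs$mass,
                    charge = specs$charge, mz = mz,
                    ccs_lit = specs$ccs_lit, td = td)
  if (nrow(out) < 3L) {
    attr(out, "insufficient_for_fit") <- TRUE
  }
  out
}

#' Wide-span native calibrant ladder
#'
#' Synthetic nine-point calibrant specification spanning the full TWIMS
#' drift window: native-like proteins and complexes from ~6 kDa to ~800 kDa
#' with CCS scaling as mass^(2/3). Protein calibrant tables bracketing a
#' single analyte cover only a narrow corrected-CCS (CCS/charge) range,
#' which limits how precisely the calibration exponent can be recovered
#' under drift-time noise; this ladder provides the leverage needed to
#' characterise the estimator itself (see the methods vignette).
#'
#' @return Data frame with columns `name`, `mass`, `charge`, `ccs_lit`
#'   suitable for [simulate_calibrants()].
#' @export
native_calibrant_ladder <- function() {
  mass <- c(6e3, 12e3, 25e3, 5e4, 1e5, 2e5, 4e5, 6e5, 8e5)
  data.frame(
    name = sprintf("native_%dkDa", round(mass / 1e3)),
    mass = mass,
    charge = c(4, 6, 8, 11, 15, 20, 26, 30, 34),
    ccs_lit = round(7.0 * (mass / 6e3)^(2 / 3), 1)
  )
}

#' Self-avoiding random-walk toy structure
#'
#' Generates an `n_atoms`-atom pseudo-molecule as a self-avoiding random
#' walk with fixed step length: a geometric stand-in for a polymer used as
#' a fixture for charge placement and projection-approximation CCS.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param bond_length Step length in Angstrom.
#' @param seed Integer seed.
#' @param clash_distance Minimum allowed non-bonded distance (Angstrom).
#' @param max_retries Retries per step before giving up.
#' @return A `structure_model` (see [structure_model()]) of carbon atoms.
#' @export
simulate_structure <- function(n_atoms, bond_length = 1.5, seed = 1,
                               clash_distance = 1.0, max_retries = 200) {
  if (n_atoms < 1) stop_ciufold("n_atoms must be >= 1")
  coords <- matrix(0, nrow = n_atoms, ncol = 3)
  if (n_atoms > 1) {
    with_seed(seed, {
      for (i in 2:n_atoms) {
        placed <- FALSE
        for (r in seq_len(max_retries)) {
          u <- stats::rnorm(3)
          step <- bond_length * u / sqrt(sum(u^2))
          cand <- coords[i - 1, ] + step
          d2 <- rowSums((coords[seq_len(i - 1), , drop = FALSE] -
                           matrix(cand, i - 1, 3, byrow = TRUE))^2)
          # the bonded neighbour sits at exactly bond_length; others must clear
          # the clash distance
          ok <- all(d2[-(i - 1)] > clash_distance^2) || i == 2
          if (ok) {
            coords[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop_ciufold("self-avoiding walk failed after %d retries at atom %d",
                       max_retries, i)
        }
      }
    })
  }
  structure_model(element = rep("C", n_atoms), x = coords[, 1],
                  y = coords[, 2], z = coords[, 3])
}
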