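#' File I/O: ATD matrices, calibrant tables, PDB structures, run configs
#'
#' The on-disk dialect for raw CIU data is the plain CSV matrix used by
#' common CIU processing tools: first column arrival time in ms, one
#' further column per collision voltage, header row carrying the voltages;
#' one file per species per replicate.
#'
#' @name io_formats
NULL

#' Write an ATD matrix as raw CIU CSV
#'
#' @param atd_matrix An `atd_matrix` (bins x voltages with attributes `time`
#'   and `voltages`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_atd_matrix <- function(atd_matrix, path) {
  df <- data.frame(attr(atd_matrix, "time"), unclass(atd_matrix),
                   check.names = FALSE)
  names(df) <- c("time_ms", format(attr(atd_matrix, "voltages"), trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw CIU CSV ATD matrix
#'
#' Validates shape (no ragged rows, numeric cells, no duplicate voltages);
#' unsorted voltage columns are sorted on read with a warning.
#'
#' @param path CSV path; first column arrival time (ms), header row of
#'   collision voltages.
#' @return An `atd_matrix`.
#' @export
read_atd_matrix <- function(path) {
  if (!file.exists(path)) stop_ciufold("file not found: %s", path)
  nf <- utils::count.fields(path, sep = ",")
  if (length(nf) < 2L) stop_ciufold("%s: empty or header-only file", path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop_ciufold("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1L])
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop_ciufold("%s: no voltage columns", path)
  volts <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (any(is.na(volts))) {
    stop_ciufold("%s: non-numeric voltage header(s): %s", path,
                 paste(names(df)[-1L][is.na(volts)], collapse = ", "))
  }
  if (anyDuplicated(volts)) stop_ciufold("%s: duplicate voltage columns", path)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
      stop_ciufold("%s: non-numeric cell in column %d near line %d",
                   path, j, bad + 1L)
    }
  }
  time <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (is.unsorted(volts)) {
    warning(sprintf("%s: voltage columns unsorted; sorting on read", path),
            call. = FALSE)
    ord <- order(volts)
    volts <- volts[ord]
    mat <- mat[, ord, drop = FALSE]
  }
  colnames(mat) <- format(volts, trim = TRUE)
  structure(mat, time = time, voltages = volts,
            class = c("atd_matrix", class(mat)))
}

#' Read a calibrant table
#'
#' CSV with columns `name`, `mass_da`, `charge`, `mz`, `ccs_lit_nm2` and
#' optionally `td_ms`. Without a path, the shipped synthetic calibrant set
#' is loaded (literature-scale CCS values for denatured myoglobin, native
#' cytochrome c and native ubiquitin charge states; stand-ins, not measured
#' values).
#'
#' @param path CSV path, or `NULL` for the shipped fixture.
#' @return Data frame with columns `name`, `mass`, `charge`, `mz`,
#'   `ccs_lit` and, when present in the file, `td`.
#' @export
read_calibrant_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calibrants_synthetic.csv",
                        package = "ciufold", mustWork = TRUE)
  }
  if (!file.exists(path)) stop_ciufold("file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("name", "mass_da", "charge", "ccs_lit_nm2")
  if (!all(need %in% names(df))) {
    stop_ciufold("calibrant table must contain columns %s",
                 paste(need, collapse = ", "))
  }
  out <- data.frame(name = df$name, mass = df$mass_da, charge = df$charge,
                    mz = if ("mz" %in% names(df)) df$mz else
                      df$mass_da / df$charge + 1.007276,
                    ccs_lit = df$ccs_lit_nm2)
  if ("td_ms" %in% names(df)) out$td <- df$td_ms
  out
}

#' Read a PDB file
#'
#' Minimal fixed-column parser for standard ATOM/HETATM records with
#' multi-model support. Alternate locations other than ' ' or 'A' are
#' dropped; the element is taken from columns 77-78 with fallback to the
#' first alphabetic character of the atom name.
#'
#' @param path PDB file path.
#' @param model Which model to return, or `"all"` for every model.
#' @return A `structure_model`, or a list of them when `model = "all"` and
#'   several MODEL records are present.
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop_ciufold("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  frames <- list()
  cur <- character(0)
  in_model <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      in_model <- TRUE
      cur <- character(0)
    } else if (startsWith(r, "ENDMDL")) {
      frames[[length(frames) + 1L]] <- cur
      cur <- character(0)
      in_model <- FALSE
    } else if (r == "ATOM  " || r == "HETATM") {
      cur <- c(cur, lines[i])
    }
  }
  if (length(cur)) frames[[length(frames) + 1L]] <- cur
  frames <- Filter(length, frames)
  if (length(frames) == 0L) stop_ciufold("%s: no ATOM/HETATM records", path)

  parse_frame <- function(atoms) {
    altloc <- substr(atoms, 17, 17)
    atoms <- atoms[altloc %in% c(" ", "A", "")]
    atom_name <- trimws(substr(atoms, 13, 16))
    resn <- trimws(substr(atoms, 18, 20))
    chain <- substr(atoms, 22, 22)
    resseq <- as.integer(substr(atoms, 23, 26))
    x <- as.numeric(substr(atoms, 31, 38))
    y <- as.numeric(substr(atoms, 39, 46))
    z <- as.numeric(substr(atoms, 47, 54))
    el <- trimws(substr(atoms, 77, 78))
    fallback <- toupper(substr(gsub("[^A-Za-z]", "", atom_name), 1, 1))
    el <- ifelse(el == "" | is.na(el), fallback, toupper(el))
    het <- startsWith(atoms, "HETATM")
    structure_model(element = el, x = x, y = y, z = z,
                    residue_name = resn, residue_seq = resseq, chain = chain,
                    atom_name = atom_name,
                    label = ifelse(het, "ligand", "protein"))
  }
  models <- lapply(frames, parse_frame)
  if (identical(model, "all")) models else models[[model]]
}

#' Write a flat key-value config file
#'
#' YAML-like `key: value` lines; vectors are comma-separated; `#` starts a
#' comment. Paired with [read_run_config()], the round trip is lossless for
#' numeric, logical and string scalars/vectors.
#'
#' @param config Named list of scalars/vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt <- function(v) {
    if (is.numeric(v)) paste(format(v, digits = 15, trim = TRUE), collapse = ", ")
    else paste(as.character(v), collapse = ", ")
  }
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' Read a flat key-value config file
#'
#' @param path Config path written by [write_run_config()] (or by hand).
#' @return Named list; values are auto-typed (numeric, logical, character),
#'   comma-separated values become vectors.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_ciufold("config not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop_ciufold("malformed config line: %s", ln)
    key <- trimws(m[2L])
    parts <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (length(parts) && !any(is.na(num))) {
      num
    } else if (all(parts %in% c("TRUE", "FALSE"))) {
      as.logical(parts)
    } else {
      parts
    }
    out[[key]] <- val
  }
  out
}

#' Serialize a calibration model to a config file
#'
#' @param model A `ciu_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  write_run_config(list(A = model$A, X = model$X,
                        edc_coefficient = model$edc_coefficient,
                        drift_gas_mass = model$drift_gas_mass,
                        fit_r2 = model$fit_r2), path)
}

#' Load a calibration model from a config file
#'
#' @param path Config path written by [write_calibration()].
#' @return A `ciu_calibration`.
#' @export
read_calibration <- function(path) {
  cfg <- read_run_config(path)
  m <- calibration_model(cfg$A, cfg$X, cfg$edc_coefficient, cfg$drift_gas_mass)
  if (!is.null(cfg$fit_r2)) m$fit_r2 <- cfg$fit_r2
  m
}
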