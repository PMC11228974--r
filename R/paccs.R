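#' Projection-approximation CCS and trajectory metrics
#'
#' The projection approximation (PA) estimates a molecule's collision cross
#' section as the orientationally averaged area of its shadow: each atom is
#' a hard sphere inflated by the collision-gas probe radius (1.4 A by
#' default), the structure is projected along uniformly random orientations,
#' and the projected union-of-disks area is estimated by Monte Carlo
#' sampling. PA systematically underestimates CCS for proteins, so the
#' result is scaled by an empirical factor of 1.14 to give a corrected
#' value comparable with experimental TWIMS CCS. Companion metrics for
#' multi-frame (trajectory) structures are the Kabsch least-squares RMSD
#' and mass-weighted center-of-mass distances between selections.
#'
#' @name ccs_calc
NULL

# Bondi-style van der Waals radii (A) and standard atomic masses (Da).
VDW_RADII <- stats::setNames(
  c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98, 1.73,
    1.39, 1.40, 2.27, 2.75, 2.31),
  c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "MG",
    "ZN", "FE", "NA", "K", "CA"))
ATOMIC_MASSES <- stats::setNames(
  c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45, 79.904,
    126.904, 24.305, 65.38, 55.845, 22.990, 39.098, 40.078),
  c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "MG",
    "ZN", "FE", "NA", "K", "CA"))
DEFAULT_RADIUS <- 1.70
DEFAULT_MASS <- 12.011

#' Construct a structure model
#'
#' Flat atom table used by the PA-CCS, charge-placement and trajectory
#' code. Radii and masses default to a van der Waals / standard-atomic-mass
#' lookup by element symbol.
#'
#' @param element Element symbols.
#' @param x,y,z Coordinates in Angstrom.
#' @param radius,mass Optional per-atom overrides (A, Da).
#' @param residue_name,residue_seq,chain,atom_name,label Optional
#'   annotations (needed by [find_sites()] and selections).
#' @return A `structure_model` data frame.
#' @export
structure_model <- function(element, x, y, z, radius = NULL, mass = NULL,
                            residue_name = NULL, residue_seq = NULL,
                            chain = NULL, atom_name = NULL, label = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, length(element) == n)
  if (!all(is.finite(c(x, y, z)))) stop_ciufold("coordinates must be finite")
  el <- toupper(element)
  if (is.null(radius)) {
    radius <- unname(ifelse(el %in% names(VDW_RADII), VDW_RADII[el], DEFAULT_RADIUS))
  }
  if (is.null(mass)) {
    mass <- unname(ifelse(el %in% names(ATOMIC_MASSES), ATOMIC_MASSES[el], DEFAULT_MASS))
  }
  if (any(radius <= 0)) stop_ciufold("atomic radii must be > 0")
  df <- data.frame(element = element, radius = radius, mass = mass,
                   x = x, y = y, z = z)
  for (col in c("residue_name", "residue_seq", "chain", "atom_name", "label")) {
    v <- get(col)
    if (!is.null(v)) df[[col]] <- v
  }
  structure(df, class = c("structure_model", "data.frame"))
}

# Uniform random rotation matrix (quaternion method, Shoemake).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_mat(q)
}

quat_to_mat <- function(q) {
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Monte Carlo area of the union of disks (centres n x 2, radii n) within
# the disks' bounding box.
mc_union_area <- function(centres, radii, n_points) {
  xr <- range(centres[, 1] - radii, centres[, 1] + radii)
  yr <- range(centres[, 2] - radii, centres[, 2] + radii)
  px <- stats::runif(n_points, xr[1], xr[2])
  py <- stats::runif(n_points, yr[1], yr[2])
  inside <- rep(FALSE, n_points)
  # chunk over atoms to bound the n_points x n_atoms working set
  chunk <- max(1L, floor(5e6 / n_points))
  for (start in seq(1L, nrow(centres), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(centres))
    d2 <- outer(px, centres[idx, 1], "-")^2 + outer(py, centres[idx, 2], "-")^2
    inside <- inside | rowSums(d2 <= matrix(radii[idx]^2, n_points,
                                            length(idx), byrow = TRUE)) > 0
    if (all(inside)) break
  }
  mean(inside) * diff(xr) * diff(yr)
}

#' Projection-approximation CCS
#'
#' Mean projected union-of-disks area over uniformly random orientations,
#' with per-orientation Monte Carlo area estimation. Atom radii are
#' inflated by `probe_radius`. Internal computation is in A^2; results are
#' reported in nm^2 (1 nm^2 = 100 A^2). Deterministic given `seed`.
#'
#' @param structure A `structure_model` (or data frame with `x`, `y`, `z`,
#'   `radius`).
#' @param probe_radius Collision-gas probe radius in Angstrom (default 1.4).
#' @param n_orientations Number of random orientations averaged.
#' @param n_mc_points Monte Carlo points per orientation.
#' @param seed Integer seed.
#' @return A `pa_ccs_result`: list with `ccs_pa` (nm^2), `ccs_calc`
#'   (= 1.14 x ccs_pa), `stderr` (nm^2, over orientations),
#'   `n_orientations`, `n_mc_points`, `probe_radius`.
#' @export
pa_ccs <- function(structure, probe_radius = 1.4, n_orientations = 100,
                   n_mc_points = 2000, seed = 1) {
  df <- as.data.frame(structure)
  if (nrow(df) < 1L) stop_ciufold("structure must contain at least one atom")
  if (n_orientations < 1L) stop_ciufold("n_orientations must be >= 1")
  if (probe_radius < 0) stop_ciufold("probe_radius must be >= 0")
  xyz <- as.matrix(df[, c("x", "y", "z")])
  radii <- df$radius + probe_radius
  areas <- with_seed(seed, {
    vapply(seq_len(n_orientations), function(o) {
      rot <- random_rotation()
      proj <- xyz %*% t(rot)
      mc_union_area(proj[, 1:2, drop = FALSE], radii, n_mc_points)
    }, numeric(1))
  })
  ccs_pa <- mean(areas) / 100
  se <- if (n_orientations > 1) stats::sd(areas) / sqrt(n_orientations) / 100 else 0
  structure(
    list(ccs_pa = ccs_pa, ccs_calc = corrected_ccs_calc(ccs_pa),
         stderr = se, n_orientations = n_orientations,
         n_mc_points = n_mc_points, probe_radius = probe_radius),
    class = "pa_ccs_result"
  )
}

#' @export
print.pa_ccs_result <- function(x, ...) {
  cat(sprintf("PA CCS: %.4g nm^2 (corrected CCS_CALC %.4g nm^2, se %.2g; %d orientations x %d MC points, probe %.2g A)\n",
              x$ccs_pa, x$ccs_calc, x$stderr, x$n_orientations, x$n_mc_points,
              x$probe_radius))
  invisible(x)
}

#' Empirical PA-to-experiment correction
#'
#' Scales a projection-approximation CCS by the empirical factor 1.14 to
#' give a value comparable with experimental TWIMS CCS.
#'
#' @param ccs_pa PA CCS (> 0), any area unit. Vectorised.
#' @return `1.14 * ccs_pa`.
#' @export
corrected_ccs_calc <- function(ccs_pa) {
  if (any(ccs_pa <= 0)) stop_ciufold("ccs_pa must be > 0")
  1.14 * ccs_pa
}

# Resolve a selection (NULL, logical, integer, label string, or function)
# to row indices of the structure.
resolve_selection <- function(structure, selection) {
  df <- as.data.frame(structure)
  if (is.null(selection)) return(seq_len(nrow(df)))
  if (is.function(selection)) return(which(selection(df)))
  if (is.logical(selection)) return(which(selection))
  if (is.character(selection)) {
    if (!"label" %in% names(df)) stop_ciufold("structure has no `label` column")
    return(which(df$label %in% selection))
  }
  as.integer(selection)
}

#' Kabsch least-squares RMSD
#'
#' Optimal rigid-body superposition (rotation + translation, SVD-based
#' Kabsch algorithm) of `frame` onto `reference`, then root-mean-square
#' deviation over the selected atoms. Rigid motions therefore give RMSD 0.
#'
#' @param frame,reference `structure_model`s with identical atom ordering
#'   over the selection.
#' @param selection Atom selection (indices, logical mask, `label` value or
#'   predicate function); default all atoms.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(frame, reference, selection = NULL) {
  ia <- resolve_selection(frame, selection)
  ib <- resolve_selection(reference, selection)
  if (length(ia) != length(ib)) {
    stop_ciufold("selection sizes differ (%d vs %d)", length(ia), length(ib))
  }
  P <- as.matrix(as.data.frame(frame)[ia, c("x", "y", "z")])
  Q <- as.matrix(as.data.frame(reference)[ib, c("x", "y", "z")])
  if (nrow(P) < 3L) stop_ciufold("need >= 3 atoms for superposition")
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  sv_p <- svd(P)$d
  if (sv_p[2] < 1e-9 * max(sv_p[1], 1)) {
    stop_ciufold("selection is collinear; superposition is ill-defined")
  }
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- P %*% t(R) - Q
  sqrt(sum(diffs^2) / nrow(P))
}

#' Mass-weighted center-of-mass distance
#'
#' Euclidean distance between the mass-weighted centroids of two atom
#' selections (e.g. ligand vs protein).
#'
#' @param structure A `structure_model` with a `mass` column.
#' @param selection_a,selection_b Selections; see [kabsch_rmsd()].
#' @return Distance in Angstrom.
#' @export
com_distance <- function(structure, selection_a, selection_b) {
  df <- as.data.frame(structure)
  com <- function(sel) {
    idx <- resolve_selection(structure, sel)
    if (length(idx) == 0L) stop_ciufold("empty selection")
    m <- df$mass[idx]
    colSums(as.matrix(df[idx, c("x", "y", "z")]) * m) / sum(m)
  }
  sqrt(sum((com(selection_a) - com(selection_b))^2))
}

#' Per-frame trajectory metrics
#'
#' For each frame of a multi-model trajectory: Kabsch RMSD to the
#' reference, ligand-protein center-of-mass distance, and corrected PA CCS
#' (CCS_CALC). Optional stride subsampling (e.g. `stride = 2` keeps every
#' other frame, mirroring trajectory thinning for CCS processing).
#'
#' @param frames List of `structure_model`s with consistent atom ordering.
#' @param reference Reference `structure_model` for RMSD.
#' @param rmsd_selection Selection used for superposition (default all).
#' @param ligand_selection,protein_selection Selections for the COM
#'   distance; when either is `NULL` the distance column is `NA`.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @param probe_radius,n_orientations,n_mc_points,seed Passed to [pa_ccs()].
#' @return Data frame `frame`, `rmsd`, `com_dist`, `ccs_calc`.
#' @export
trajectory_profile <- function(frames, reference, rmsd_selection = NULL,
                               ligand_selection = NULL,
                               protein_selection = NULL, stride = 1,
                               probe_radius = 1.4, n_orientations = 32,
                               n_mc_points = 1000, seed = 1) {
  if (stride < 1) stop_ciufold("stride must be >= 1")
  n_ref <- nrow(as.data.frame(reference))
  counts <- vapply(frames, function(f) nrow(as.data.frame(f)), integer(1))
  if (any(counts != n_ref)) {
    stop_ciufold("frame atom counts differ from reference (%s vs %d)",
                 paste(unique(counts), collapse = ","), n_ref)
  }
  keep <- seq(1L, length(frames), by = stride)
  rows <- lapply(seq_along(keep), function(ii) {
    i <- keep[ii]
    f <- frames[[i]]
    cd <- if (!is.null(ligand_selection) && !is.null(protein_selection)) {
      com_distance(f, ligand_selection, protein_selection)
    } else NA_real_
    data.frame(
      frame = i,
      rmsd = kabsch_rmsd(f, reference, rmsd_selection),
      com_dist = cd,
      ccs_calc = pa_ccs(f, probe_radius, n_orientations, n_mc_points,
                        seed = sub_seed(seed, i))$ccs_calc
    )
  })
  do.call(rbind, rows)
}
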