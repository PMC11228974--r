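# Independent oracles and small fixture builders used across the suite.

# Horn's closed-form quaternion superposition RMSD: an algorithm independent
# of the SVD-based Kabsch implementation it checks.
horn_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  sqrt(max(msd, 0))
}

# Orientation-averaged area of the union of two equal disks of radius R whose
# sphere centres are D apart, by direct numeric integration over the uniform
# orientation measure (cos(theta) uniform on [0, 1]).
two_sphere_union_area <- function(R, D, n = 20000) {
  ct <- (seq_len(n) - 0.5) / n
  d <- D * sqrt(1 - ct^2)            # projected centre separation
  lens <- ifelse(d < 2 * R,
                 2 * R^2 * acos(pmin(d / (2 * R), 1)) -
                   (d / 2) * sqrt(pmax(4 * R^2 - d^2, 0)),
                 0)
  mean(2 * pi * R^2 - lens)
}

random_rigid_transform <- function(xyz) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  a <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  sweep(xyz %*% t(R), 2, stats::rnorm(3, 0, 10), "+")
}

# Annotated toy peptide: one representative atom set per residue, enough for
# find_sites() (N, CA, C backbone plus the charged-group atom where needed).
toy_peptide <- function(residues, chain = "A") {
  atoms <- list()
  for (i in seq_along(residues)) {
    rn <- residues[i]
    base <- c(3 * i, 0, 0)
    add <- function(name, off) {
      atoms[[length(atoms) + 1]] <<- data.frame(
        element = substr(name, 1, 1), atom_name = name,
        residue_name = rn, residue_seq = i, chain = chain,
        x = base[1] + off[1], y = base[2] + off[2], z = base[3] + off[3])
    }
    add("N", c(0, 0, 0)); add("CA", c(1, 0, 0)); add("C", c(2, 0, 0))
    side <- switch(rn, ASP = "CG", GLU = "CD", LYS = "NZ", ARG = "CZ",
                   HIS = "NE2", NULL)
    if (!is.null(side)) add(side, c(1, 1.5, 0))
  }
  df <- do.call(rbind, atoms)
  structure_model(element = df$element, x = df$x, y = df$y, z = df$z,
                  residue_name = df$residue_name, residue_seq = df$residue_seq,
                  chain = df$chain, atom_name = df$atom_name)
}

# Random charge-site geometry with a feasible target, for oracle comparisons.
random_charge_instance <- function(n_sites, box = 15) {
  cls <- sample(c("acidic", "basic"), n_sites, replace = TRUE)
  if (!any(cls == "basic")) cls[1] <- "basic"
  sites <- charge_sites(cls, matrix(stats::runif(3 * n_sites, 0, box), n_sites))
  nb <- sum(cls == "basic"); na_ <- sum(cls == "acidic")
  target <- sample(seq(-na_, nb), 1)
  list(sites = sites, target = target)
}

# Minimal PDB writer for parser round-trips.
write_toy_pdb <- function(path, frames) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (m in seq_along(frames)) {
    df <- as.data.frame(frames[[m]])
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(df))) {
      rec <- if (!is.null(df$label) && identical(df$label[i], "ligand")) {
        "HETATM"
      } else "ATOM  "
      writeLines(sprintf(
        "%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, i, substr(df$atom_name[i], 1, 4), " ", df$residue_name[i],
        df$chain[i], df$residue_seq[i], df$x[i], df$y[i], df$z[i], 1, 0,
        df$element[i]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
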