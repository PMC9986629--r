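# Solvent-accessible surface area, Calpha distance statistics and
# least-squares rigid-body superposition.

# van der Waals radii (A); determinism over coverage, unknown -> carbon
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# per-residue maximum accessible surface area (A^2), theoretical
# Gly-X-Gly reference values (Tien et al. style table)
MAX_ACC <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# deterministic golden-section spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radii <- function(structure) {
  r <- unname(VDW_RADII[structure$element])
  if (anyNA(r)) {
    unk <- unique(structure$element[is.na(r)])
    warn(paste0("Unknown element(s) ", paste(unk, collapse = ", "),
                "; using carbon vdW radius 1.70 A"))
    r[is.na(r)] <- VDW_RADII[["C"]]
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe over each atom by counting golden-spiral sphere points not
#' occluded by neighbouring atoms, sums atom areas per residue, and converts
#' to relative SASA against a fixed per-residue-type maximum-exposure table.
#' A residue is flagged as surface when its relative SASA reaches
#' `surface_threshold` (the conventional 25% cut separating surface from
#' buried residues).
#'
#' @param structure a `pdb_structure`.
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_sphere_points points per atom sphere; more points reduce the
#'   discretization error (~2% at 960).
#' @param surface_threshold relative-SASA cut for the surface flag.
#' @return a tibble with one row per residue: `chain`, `res_seq`, `i_code`,
#'   `res_name`, `key`, `sasa` (A^2), `rel_sasa`, `surface`. Per-atom areas
#'   are attached as attribute `"atom_sasa"`.
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_sphere_points = 960,
                               surface_threshold = 0.25) {
  if (nrow(structure) == 0) abort("Structure has no atoms.")
  xyz <- coord_matrix(structure)
  rad <- atom_radii(structure) + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  atom_area <- numeric(n)
  # pairwise neighbour lists; occlusion possible iff d < r_i + r_j
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj > rad[j]^2
    }
    atom_area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_sphere_points
  }
  res <- structure |>
    mutate(.area = atom_area,
           key = residue_key(.data$chain, .data$res_seq, .data$i_code)) |>
    group_by(.data$chain, .data$res_seq, .data$i_code, .data$res_name,
             .data$key) |>
    summarise(sasa = sum(.data$.area), .groups = "drop") |>
    arrange(.data$chain, .data$res_seq, .data$i_code) |>
    mutate(rel_sasa = .data$sasa / unname(MAX_ACC[.data$res_name]),
           surface = .data$rel_sasa >= surface_threshold)
  attr(res, "atom_sasa") <- atom_area
  res
}

ca_coords <- function(structure, keys) {
  ca <- structure |>
    mutate(key = residue_key(.data$chain, .data$res_seq, .data$i_code)) |>
    filter(.data$name == "CA", .data$key %in% keys)
  miss <- setdiff(keys, ca$key)
  if (length(miss) > 0) {
    abort(paste0("Missing CA atom for residue(s): ",
                 paste(miss, collapse = ", ")))
  }
  m <- coord_matrix(ca)
  rownames(m) <- ca$key
  m[keys, , drop = FALSE]
}

#' Calpha distance statistics between two residue sets
#'
#' Mean and minimum pairwise Calpha-Calpha distance over the query x
#' reference pairs; used e.g. to measure how far a beta-turn sits from the
#' catalytic residues.
#'
#' @param structure a `pdb_structure`.
#' @param query,reference character vectors of residue keys (`"A:15"`).
#' @return a one-row tibble: `mean_dist`, `min_dist`, `n_pairs` (A).
#' @export
ca_distance_stats <- function(structure, query, reference) {
  resolve_keys(structure, unique(c(query, reference)))
  qm <- ca_coords(structure, unique(query))
  rm_ <- ca_coords(structure, unique(reference))
  d <- sqrt(outer(rowSums(qm^2), rowSums(rm_^2), `+`) -
              2 * qm %*% t(rm_))
  d[d < 0 | is.na(d)] <- 0
  tibble(mean_dist = mean(d), min_dist = min(d), n_pairs = length(d))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between two congruent point sets; reflections are
#' corrected by the determinant sign.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @param weights optional non-negative per-point weights.
#' @return an object of class `superposition`: `list(rotation, translation,
#'   rmsd)` with `transformed = mobile %*% t(rotation) + translation`
#'   applied row-wise.
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3)
    abort("mobile and target must be congruent n x 3 matrices.")
  n <- nrow(mobile)
  if (n < 3) abort("Superposition needs at least 3 points.")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) == 0)
    abort("weights must be n non-negative values with positive sum.")
  w <- w / sum(w)
  cm <- colSums(mobile * w); ct <- colSums(target * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (sum(sv$d > 1e-10) < 2) abort("Degenerate (rank-deficient) point sets; cannot superpose.")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cm),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param fit a `superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

# independent latitude-longitude quadrature SASA (test oracle; exported so
# acceptance checks can call it against shrake_rupley_sasa)
#' Grid-quadrature SASA oracle
#'
#' Independent per-atom SASA by area-weighted latitude-longitude quadrature
#' over each expanded sphere. Slower and numerically unrelated to the
#' golden-spiral point count; intended for validation.
#'
#' @inheritParams shrake_rupley_sasa
#' @param n_lat number of latitude bands (longitudes scale with latitude).
#' @return per-atom accessible areas (A^2).
#' @export
sasa_grid_oracle <- function(structure, probe_radius = 1.4, n_lat = 40) {
  xyz <- coord_matrix(structure)
  rad <- atom_radii(structure) + probe_radius
  n <- nrow(xyz)
  th <- (seq_len(n_lat) - 0.5) * pi / n_lat
  out <- numeric(n)
  for (i in seq_len(n)) {
    area <- 0
    tot <- 0
    for (t in th) {
      n_lon <- max(6L, ceiling(2 * n_lat * sin(t)))
      ph <- (seq_len(n_lon) - 0.5) * 2 * pi / n_lon
      wq <- sin(t)                     # band weight per point ~ sin(theta)
      p <- cbind(sin(t) * cos(ph), sin(t) * sin(ph),
                 rep(cos(t), n_lon)) * rad[i]
      p <- sweep(p, 2, xyz[i, ], `+`)
      free <- rep(TRUE, n_lon)
      for (j in seq_len(n)) {
        if (j == i) next
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & dj > rad[j]^2
      }
      area <- area + sum(free) * wq / n_lon
      tot <- tot + wq
    }
    out[i] <- 4 * pi * rad[i]^2 * area / tot
  }
  out
}
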