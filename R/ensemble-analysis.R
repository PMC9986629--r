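# Trajectory-style analytics on coordinate ensembles: superposition-based
# RMSD/RMSF, dynamic cross-correlation, geometric hydrogen-bond and
# salt-bridge detection with frame occupancies, and the constraint-network
# transition-temperature relation.

# resolve an atom selection to row indices of the topology
atom_selection <- function(topology, atoms = "CA", residues = NULL) {
  idx <- if (identical(atoms, "all")) seq_len(nrow(topology)) else
    which(topology$name %in% atoms)
  if (!is.null(residues)) {
    keys <- residue_key(topology$chain, topology$res_seq, topology$i_code)
    idx <- idx[keys[idx] %in% residues]
  }
  if (length(idx) == 0) abort("Selection resolves to no atoms.")
  idx
}

# iteratively superpose all frames onto their converging mean structure
superpose_frames <- function(coords, tol = 1e-6, max_iter = 20) {
  nf <- dim(coords)[1]
  ref <- coords[1, , , drop = TRUE]
  out <- coords
  for (it in seq_len(max_iter)) {
    for (f in seq_len(nf)) {
      fit <- kabsch_superpose(coords[f, , , drop = TRUE], ref)
      out[f, , ] <- apply_superposition(fit, coords[f, , , drop = TRUE])
    }
    new_ref <- apply(out, c(2, 3), mean)
    shift <- sqrt(max(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) break
  }
  list(coords = out, mean = ref)
}

#' Per-frame RMSD against a reference
#'
#' Each frame's selected atoms are rigid-body superposed onto the reference
#' (first frame, or the converged mean structure) before the RMSD is taken,
#' so rigid global motion contributes nothing.
#'
#' @param ensemble a `pdb_ensemble`.
#' @param reference `"first"` or `"mean"`.
#' @param atoms atom-name selection (default Calpha).
#' @param residues optional residue-key subset.
#' @return a tibble (`frame`, `rmsd`) in Angstrom.
#' @export
rmsd_series <- function(ensemble, reference = c("first", "mean"),
                        atoms = "CA", residues = NULL) {
  reference <- match.arg(reference)
  idx <- atom_selection(ensemble$topology, atoms, residues)
  if (length(idx) < 3) abort("Selection resolves to fewer than 3 atoms.")
  sel <- ensemble$coords[, idx, , drop = FALSE]
  ref <- if (reference == "first") sel[1, , , drop = TRUE] else
    superpose_frames(sel)$mean
  rmsd <- vapply(seq_len(n_frames(ensemble)), function(f) {
    kabsch_superpose(sel[f, , , drop = TRUE], ref)$rmsd
  }, numeric(1))
  tibble(frame = seq_len(n_frames(ensemble)), rmsd = rmsd)
}

#' Per-residue RMSF profile
#'
#' Frames are superposed onto the converged mean structure (mean and
#' superposition iterated to < 1e-6 A shift, at most 20 rounds); the RMSF of
#' each selected atom is the root-mean-square deviation from its mean
#' position.
#'
#' @inheritParams rmsd_series
#' @return a tibble (`chain`, `res_seq`, `i_code`, `res_name`, `key`,
#'   `rmsf`) of class `rmsf_profile`.
#' @export
rmsf_profile <- function(ensemble, atoms = "CA", residues = NULL) {
  if (n_frames(ensemble) < 2) abort("RMSF is undefined for a single frame.")
  idx <- atom_selection(ensemble$topology, atoms, residues)
  sp <- superpose_frames(ensemble$coords[, idx, , drop = FALSE])
  dev <- sweep(sp$coords, c(2, 3), sp$mean)
  rmsf <- sqrt(apply(dev^2, 2, function(m) mean(rowSums(m))))
  topo <- ensemble$topology[idx, ]
  out <- tibble(chain = topo$chain, res_seq = topo$res_seq,
                i_code = topo$i_code, res_name = topo$res_name,
                key = residue_key(topo$chain, topo$res_seq, topo$i_code),
                rmsf = rmsf)
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of the selected atoms' displacement vectors about
#' the superposed-ensemble mean: `C_ij = <dr_i . dr_j> /
#' sqrt(<|dr_i|^2><|dr_j|^2>)`, +1 for in-phase and -1 for anti-phase
#' motion. Zero-variance atoms get `NA` rows/columns.
#'
#' @inheritParams rmsd_series
#' @return an n x n matrix of class `dccm_matrix` with residue keys as
#'   dimnames.
#' @export
dccm <- function(ensemble, atoms = "CA", residues = NULL) {
  if (n_frames(ensemble) < 2) abort("DCCM needs at least 2 frames.")
  idx <- atom_selection(ensemble$topology, atoms, residues)
  sp <- superpose_frames(ensemble$coords[, idx, , drop = FALSE])
  dev <- sweep(sp$coords, c(2, 3), sp$mean)     # frames x atoms x 3
  n <- length(idx)
  cov_ij <- matrix(0, n, n)
  for (k in 1:3) cov_ij <- cov_ij + crossprod(dev[, , k]) / dim(dev)[1]
  v <- diag(cov_ij)
  zero <- v < 1e-20
  denom <- sqrt(outer(v, v))
  cm <- cov_ij / denom
  cm[zero, ] <- NA_real_
  cm[, zero] <- NA_real_
  diag(cm)[!zero] <- 1
  keys <- residue_key(ensemble$topology$chain[idx],
                      ensemble$topology$res_seq[idx],
                      ensemble$topology$i_code[idx])
  dimnames(cm) <- list(keys, keys)
  class(cm) <- c("dccm_matrix", class(cm))
  cm
}

# reconstruct the backbone amide hydrogen from N, CA and the previous C:
# H sits 1.01 A from N along the external bisector of C(prev)-N-CA
amide_h_position <- function(N, CA, Cprev) {
  d <- unit_vec(unit_vec(N - Cprev) + unit_vec(N - CA))
  if (anyNA(d)) return(NULL)
  N + 1.01 * d
}

backbone_names <- c("N", "CA", "C", "O")

# donor table for one structure: N/O atoms with explicit or reconstructable H
hbond_donors <- function(structure) {
  keys <- residue_key(structure$chain, structure$res_seq, structure$i_code)
  xyz <- coord_matrix(structure)
  res <- chain_adjacency(structure)
  donors <- list()
  for (i in which(structure$element %in% c("N", "O"))) {
    same_res <- which(keys == keys[i] & substr(structure$name, 1, 1) == "H")
    hs <- list()
    if (length(same_res) > 0) {
      d <- sqrt(rowSums((xyz[same_res, , drop = FALSE] -
                           matrix(xyz[i, ], length(same_res), 3,
                                  byrow = TRUE))^2))
      for (j in same_res[d < 1.25]) hs[[length(hs) + 1]] <- xyz[j, ]
    }
    if (length(hs) == 0 && structure$name[i] == "N") {
      ri <- match(keys[i], res$key)
      if (!is.na(ri) && res$bonded_prev[ri]) {
        prev_key <- res$key[ri - 1]
        ca <- which(keys == keys[i] & structure$name == "CA")
        cp <- which(keys == prev_key & structure$name == "C")
        if (length(ca) == 1 && length(cp) == 1) {
          h <- amide_h_position(xyz[i, ], xyz[ca, ], xyz[cp, ])
          if (!is.null(h)) hs[[1]] <- h
        }
      }
    }
    # O atoms donate only through an explicit hydrogen (carbonyl/carboxyl
    # oxygens are acceptors only); N atoms without a usable H fall back to
    # the distance-only criterion, flagged downstream
    if (structure$element[i] == "O" && length(hs) == 0) next
    donors[[length(donors) + 1]] <- list(
      idx = i, key = keys[i], name = structure$name[i],
      backbone = structure$name[i] %in% backbone_names, h = hs)
  }
  donors
}

#' Geometric hydrogen-bond detection on one structure/frame
#'
#' A donor-acceptor pair is a hydrogen bond when the donor-acceptor distance
#' is at most `d_max_da` and, where a hydrogen is present or reconstructable
#' (backbone amide H from N, CA and the preceding C), the D-H...A angle is at
#' least `angle_min` degrees. Donors without any usable hydrogen fall back to
#' the distance criterion alone, flagged `angle_checked = FALSE`. Pairs
#' within one residue, and backbone-backbone pairs fewer than two residues
#' apart, are excluded.
#'
#' @param structure a `pdb_structure` (one frame).
#' @param d_max_da donor-acceptor distance cutoff (A).
#' @param angle_min D-H...A angle cutoff (degrees).
#' @return a tibble of bonds: donor/acceptor residue keys and atom names,
#'   `distance`, `angle` (NA when not checkable), `angle_checked`.
#' @export
detect_hydrogen_bonds <- function(structure, d_max_da = 3.5,
                                  angle_min = 120) {
  keys <- residue_key(structure$chain, structure$res_seq, structure$i_code)
  xyz <- coord_matrix(structure)
  donors <- hbond_donors(structure)
  acc_idx <- which(structure$element %in% c("N", "O") &
                     substr(structure$name, 1, 1) != "H")
  out <- list()
  for (d in donors) {
    for (a in acc_idx) {
      if (a == d$idx || keys[a] == d$key) next
      if (d$backbone && structure$name[a] %in% backbone_names &&
          structure$chain[a] == structure$chain[d$idx] &&
          abs(structure$res_seq[a] - structure$res_seq[d$idx]) < 2) next
      dist <- vnorm(xyz[a, ] - xyz[d$idx, ])
      if (dist > d_max_da) next
      if (length(d$h) > 0) {
        angs <- vapply(d$h, function(h) {
          v1 <- xyz[d$idx, ] - h; v2 <- xyz[a, ] - h
          acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) *
            180 / pi
        }, numeric(1))
        ang <- max(angs)
        if (ang < angle_min) next
        checked <- TRUE
      } else {
        ang <- NA_real_
        checked <- FALSE
      }
      out[[length(out) + 1]] <- tibble(
        donor_key = d$key, donor_atom = d$name,
        acceptor_key = keys[a], acceptor_atom = structure$name[a],
        distance = dist, angle = ang, angle_checked = checked)
    }
  }
  if (length(out) == 0) {
    return(tibble(donor_key = character(), donor_atom = character(),
                  acceptor_key = character(), acceptor_atom = character(),
                  distance = numeric(), angle = numeric(),
                  angle_checked = logical()))
  }
  list_rbind(out)
}

frame_structure <- function(ensemble, f) {
  s <- ensemble$topology
  xyz <- ensemble$coords[f, , , drop = TRUE]
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

#' Per-frame hydrogen-bond counts
#'
#' @param ensemble a `pdb_ensemble`.
#' @inheritParams detect_hydrogen_bonds
#' @return a tibble (`frame`, `n_hbonds`).
#' @export
hbond_count_series <- function(ensemble, d_max_da = 3.5, angle_min = 120) {
  n <- vapply(seq_len(n_frames(ensemble)), function(f) {
    nrow(detect_hydrogen_bonds(frame_structure(ensemble, f),
                               d_max_da = d_max_da, angle_min = angle_min))
  }, numeric(1))
  tibble(frame = seq_len(n_frames(ensemble)), n_hbonds = as.integer(n))
}

acidic_o_names <- c("OD1", "OD2", "OE1", "OE2")
basic_n_names <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")

#' Salt-bridge occupancy over an ensemble
#'
#' A frame forms the salt bridge when the minimum side-chain
#' oxygen-to-nitrogen distance between the acidic (Asp/Glu) and basic
#' (Arg/Lys/His) residue is at most `d_cut`. Occupancy is the number of
#' bridge-forming frames divided by the total number of frames. The
#' per-frame minimum-distance series is returned alongside.
#'
#' @param ensemble a `pdb_ensemble`.
#' @param acidic,basic residue keys of the partners.
#' @param d_cut distance cutoff (A).
#' @return an object of class `bond_occupancy`: `list(kind, acidic, basic,
#'   d_cut, frames = tibble(frame, min_dist, present), occupancy)`.
#' @export
salt_bridge_occupancy <- function(ensemble, acidic, basic, d_cut = 4.0) {
  topo <- ensemble$topology
  keys <- residue_key(topo$chain, topo$res_seq, topo$i_code)
  resolve_keys(topo, c(acidic, basic))
  a_res <- unique(topo$res_name[keys == acidic])
  b_res <- unique(topo$res_name[keys == basic])
  if (!a_res %in% c("ASP", "GLU")) {
    abort(paste0("Acidic partner must be Asp/Glu, got ", a_res))
  }
  if (!b_res %in% c("ARG", "LYS", "HIS")) {
    abort(paste0("Basic partner must be Arg/Lys/His, got ", b_res))
  }
  ai <- which(keys == acidic & topo$name %in% acidic_o_names)
  bi <- which(keys == basic & topo$name %in% basic_n_names)
  if (length(ai) == 0) abort(paste0("No side-chain O atoms on ", acidic))
  if (length(bi) == 0) abort(paste0("No side-chain N atoms on ", basic))
  nf <- n_frames(ensemble)
  min_d <- vapply(seq_len(nf), function(f) {
    xa <- matrix(ensemble$coords[f, ai, ], ncol = 3)
    xb <- matrix(ensemble$coords[f, bi, ], ncol = 3)
    dd <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
    sqrt(max(0, min(dd)))
  }, numeric(1))
  frames <- tibble(frame = seq_len(nf), min_dist = min_d,
                   present = min_d <= d_cut)
  structure(list(kind = "salt_bridge", acidic = acidic, basic = basic,
                 d_cut = d_cut, frames = frames,
                 occupancy = sum(frames$present) / nf),
            class = "bond_occupancy")
}

#' @export
print.bond_occupancy <- function(x, ...) {
  cat(sprintf("<bond_occupancy> %s %s-%s: %.1f%% of %d frames (cutoff %.1f A)\n",
              x$kind, x$acidic, x$basic, 100 * x$occupancy,
              nrow(x$frames), x$d_cut))
  invisible(x)
}

#' @export
tidy.bond_occupancy <- function(x, ...) x$frames

#' @export
glance.bond_occupancy <- function(x, ...) {
  tibble(kind = x$kind, acidic = x$acidic, basic = x$basic,
         d_cut = x$d_cut, n_frames = nrow(x$frames),
         occupancy = x$occupancy,
         mean_min_dist = mean(x$frames$min_dist))
}

#' Constraint-network transition temperature
#'
#' Maps a hydrogen-bond energy cutoff from constraint-network thermal
#' dilution to a simulated temperature through the affine relation
#' `T = -20 K/(kcal/mol) * E_cut + 300 K`.
#'
#' @param e_cut hydrogen-bond energy cutoff(s), kcal/mol (<= 0 in practice).
#' @return temperature(s) in Kelvin.
#' @examples
#' cna_temperature(-1.84)  # 336.8 K
#' @export
cna_temperature <- function(e_cut) {
  -20 * e_cut + 300
}

#' Read a rigidity order-parameter series
#'
#' Two-column delimited text: `e_cut` (kcal/mol) and `p_inf` (rigidity order
#' parameter in \[0, 1\]); rows are ordered by decreasing `e_cut`.
#'
#' @param path file path.
#' @return a tibble (`e_cut`, `p_inf`).
#' @export
read_cna_series <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE,
                          col_names = c("e_cut", "p_inf"), comment = "#",
                          trim_ws = TRUE)
  if (is.character(df$e_cut)) {      # header row present
    df <- df[-1, ]
    df$e_cut <- as.numeric(df$e_cut); df$p_inf <- as.numeric(df$p_inf)
  }
  arrange(df, dplyr::desc(.data$e_cut))
}

#' Locate the rigid-to-flexible transition in a P-infinity series
#'
#' The transition is the point where the rigidity order parameter suffers its
#' largest single-step drop (the first point of the flexible phase); ties go
#' to the drop at the larger (less negative) energy cutoff. The corresponding
#' temperature comes from [cna_temperature()].
#'
#' @param series a tibble/data frame with columns `e_cut` (strictly
#'   decreasing, kcal/mol) and `p_inf`.
#' @return a one-row tibble (`e_cut`, `p_inf_drop`, `temperature`); all `NA`
#'   with a message when the series never drops.
#' @export
find_transition <- function(series) {
  series <- as_tibble(series)
  if (nrow(series) < 3) abort("Transition detection needs at least 3 points.")
  if (any(diff(series$e_cut) >= 0)) {
    abort("e_cut must be strictly decreasing.")
  }
  drops <- -diff(series$p_inf)
  if (max(drops) <= 0) {
    inform("No transition: p_inf never decreases.")
    return(tibble(e_cut = NA_real_, p_inf_drop = NA_real_,
                  temperature = NA_real_))
  }
  k <- which.max(drops)             # ties: which.max takes the first
  tibble(e_cut = series$e_cut[k + 1], p_inf_drop = drops[k],
         temperature = cna_temperature(series$e_cut[k + 1]))
}
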