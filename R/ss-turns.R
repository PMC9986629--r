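# Backbone dihedrals, torsion-window secondary structure, beta-turn
# detection and typing, and positional amino-acid turn preferences.

torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) return(NA_real_)
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

backbone_atom_coords <- function(structure, atom) {
  s <- structure |> filter(.data$name == atom)
  if (nrow(s) == 0) {
    return(matrix(numeric(0), 0, 3, dimnames = list(character(0), NULL)))
  }
  m <- coord_matrix(s)
  rownames(m) <- residue_key(s$chain, s$res_seq, s$i_code)
  m
}

# residues in chain order with flags for peptide-bond continuity to the
# previous/next residue (C-N distance < 2.5 A)
chain_adjacency <- function(structure) {
  res <- residue_table(structure)
  Nc <- backbone_atom_coords(structure, "N")
  Cc <- backbone_atom_coords(structure, "C")
  n <- nrow(res)
  bonded_prev <- rep(FALSE, n)
  for (i in seq_len(n)[-1]) {
    if (res$chain[i] != res$chain[i - 1]) next
    kp <- res$key[i - 1]; k <- res$key[i]
    if (kp %in% rownames(Cc) && k %in% rownames(Nc)) {
      bonded_prev[i] <- vnorm(Cc[kp, ] - Nc[k, ]) < 2.5
    }
  }
  res$bonded_prev <- bonded_prev
  res$bonded_next <- c(bonded_prev[-1], FALSE)
  res
}

#' Backbone phi/psi dihedral angles
#'
#' Standard torsions from the four backbone atoms; undefined at chain
#' termini, across chain breaks, or where backbone atoms are missing
#' (reported as `NA`, not an error).
#'
#' @param structure a `pdb_structure`.
#' @return a tibble with one row per residue: `chain`, `res_seq`, `i_code`,
#'   `res_name`, `key`, `phi`, `psi` (degrees in (-180, 180]).
#' @export
backbone_dihedrals <- function(structure) {
  res <- chain_adjacency(structure)
  Nc <- backbone_atom_coords(structure, "N")
  CAc <- backbone_atom_coords(structure, "CA")
  Cc <- backbone_atom_coords(structure, "C")
  get <- function(m, k) if (k %in% rownames(m)) m[k, ] else NULL
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- res$key[i]
    Ni <- get(Nc, k); CAi <- get(CAc, k); Ci <- get(Cc, k)
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (res$bonded_prev[i]) {
      Cp <- get(Cc, res$key[i - 1])
      if (!is.null(Cp)) phi[i] <- torsion_angle(Cp, Ni, CAi, Ci)
    }
    if (res$bonded_next[i]) {
      Nn <- get(Nc, res$key[i + 1])
      if (!is.null(Nn)) psi[i] <- torsion_angle(Ni, CAi, Ci, Nn)
    }
  }
  und <- (res$bonded_prev & is.na(phi) &
            res$key %in% rownames(Nc) & res$key %in% rownames(CAc) &
            res$key %in% rownames(Cc))
  if (any(und)) warn("Degenerate (collinear) backbone geometry; some dihedrals undefined.")
  res |>
    select("chain", "res_seq", "i_code", "res_name", "key") |>
    mutate(phi = phi, psi = psi)
}

in_range <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

run_filter <- function(flag, min_len) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}

#' Torsion-window secondary-structure assignment
#'
#' Three-class (helix / sheet / loop) assignment from phi/psi windows: a
#' helix is a run of >= 4 consecutive residues with phi in \[-90, -30\] and
#' psi in \[-77, -17\]; a sheet is a run of >= 3 with phi in \[-170, -70\]
#' and psi in \[80, 180) or (-180, -170\]; everything else (including
#' residues with missing dihedrals) is loop.
#'
#' @param structure a `pdb_structure`.
#' @param dihedrals optional precomputed [backbone_dihedrals()] result.
#' @return the dihedral tibble with an added `ss` column
#'   (`"helix"`/`"sheet"`/`"loop"`).
#' @export
assign_secondary_structure <- function(structure, dihedrals = NULL) {
  dh <- dihedrals %||% backbone_dihedrals(structure)
  helix_like <- in_range(dh$phi, -90, -30) & in_range(dh$psi, -77, -17)
  sheet_like <- in_range(dh$phi, -170, -70) &
    ((!is.na(dh$psi) & dh$psi >= 80 & dh$psi < 180) |
       (!is.na(dh$psi) & dh$psi > -180 & dh$psi <= -170))
  # runs must not span chain breaks: split on chain
  ss <- rep("loop", nrow(dh))
  for (ch in unique(dh$chain)) {
    idx <- which(dh$chain == ch)
    h <- run_filter(helix_like[idx], 4)
    s <- run_filter(sheet_like[idx] & !h, 3)
    ss[idx][h] <- "helix"
    ss[idx][s] <- "sheet"
  }
  dh |> mutate(ss = ss)
}

# canonical (phi,psi) of residues i+1 and i+2 for each named turn type
TURN_CANONICAL <- list(
  I    = c(-60, -30, -90, 0),
  II   = c(-60, 120,  80, 0),
  `I'` = c(60, 30, 90, 0),
  `II'` = c(60, -120, -80, 0),
  VIII = c(-60, -30, -120, 120)
)

classify_turn <- function(phi1, psi1, phi2, psi2) {
  obs <- c(phi1, psi1, phi2, psi2)
  if (anyNA(obs)) return("IV")
  for (ty in names(TURN_CANONICAL)) {
    d <- angle_diff(obs, TURN_CANONICAL[[ty]])
    if (all(d <= 30) || (sum(d > 30) == 1 && all(d <= 45))) return(ty)
  }
  "IV"
}

#' Detect and type beta-turns
#'
#' A four-residue window i..i+3 is a beta-turn when the Calpha(i)-Calpha(i+3)
#' distance is at most `distance_cutoff` and neither central residue is
#' helical. Types I, II, I', II' and VIII are assigned by comparing the
#' central residues' (phi, psi) to canonical values within +-30 degrees
#' (one angle may deviate up to +-45 degrees), in that order of precedence;
#' unmatched turns are type IV. Overlapping windows are all reported, and
#' turns are numbered 1..n from the N terminus.
#'
#' @param structure a `pdb_structure`.
#' @param ss optional [assign_secondary_structure()] result.
#' @param distance_cutoff Calpha(i)-Calpha(i+3) cutoff in Angstrom.
#' @return a tibble of turns: `turn` (ordinal), `chain`, `key_i`..`key_i3`,
#'   `res_seq_i`, `turn_type`, `ca_i_to_i3`, and the four (phi, psi) pairs.
#' @export
detect_beta_turns <- function(structure, ss = NULL, distance_cutoff = 7.0) {
  ss <- ss %||% assign_secondary_structure(structure)
  res <- chain_adjacency(structure)
  CAc <- backbone_atom_coords(structure, "CA")
  out <- list()
  n <- nrow(res)
  for (i in seq_len(max(0, n - 3))) {
    idx <- i:(i + 3)
    if (!all(res$bonded_prev[idx[-1]])) next   # consecutive, same chain
    keys <- res$key[idx]
    if (!all(keys %in% rownames(CAc))) next
    d <- vnorm(CAc[keys[1], ] - CAc[keys[4], ])
    if (d > distance_cutoff) next
    if (any(ss$ss[idx[2:3]] == "helix")) next
    ty <- classify_turn(ss$phi[idx[2]], ss$psi[idx[2]],
                        ss$phi[idx[3]], ss$psi[idx[3]])
    out[[length(out) + 1]] <- tibble(
      chain = res$chain[i],
      key_i = keys[1], key_i1 = keys[2], key_i2 = keys[3], key_i3 = keys[4],
      res_seq_i = res$res_seq[i],
      turn_type = ty, ca_i_to_i3 = d,
      phi_i = ss$phi[idx[1]], psi_i = ss$psi[idx[1]],
      phi_i1 = ss$phi[idx[2]], psi_i1 = ss$psi[idx[2]],
      phi_i2 = ss$phi[idx[3]], psi_i2 = ss$psi[idx[3]],
      phi_i3 = ss$phi[idx[4]], psi_i3 = ss$psi[idx[4]]
    )
  }
  turns <- if (length(out)) list_rbind(out) else tibble(
    chain = character(), key_i = character(), key_i1 = character(),
    key_i2 = character(), key_i3 = character(), res_seq_i = integer(),
    turn_type = character(), ca_i_to_i3 = numeric(),
    phi_i = numeric(), psi_i = numeric(), phi_i1 = numeric(),
    psi_i1 = numeric(), phi_i2 = numeric(), psi_i2 = numeric(),
    phi_i3 = numeric(), psi_i3 = numeric()
  )
  turns |> mutate(turn = dplyr::row_number(), .before = 1)
}

# Positional beta-turn propensities (dimensionless normalized frequencies,
# conventional positional-preference scale). Pro at i+1 is the table
# maximum; Gly dominates i+3, Asn/Asp favour i.
TURN_PREFERENCE_DEFAULT <- local({
  tab <- rbind(
    #        i     i+1   i+2   i+3
    A = c(0.060, 0.076, 0.035, 0.058),
    R = c(0.070, 0.106, 0.099, 0.085),
    N = c(0.161, 0.083, 0.191, 0.091),
    D = c(0.147, 0.110, 0.179, 0.081),
    C = c(0.149, 0.053, 0.117, 0.128),
    Q = c(0.074, 0.098, 0.037, 0.098),
    E = c(0.056, 0.060, 0.077, 0.064),
    G = c(0.102, 0.085, 0.190, 0.152),
    H = c(0.140, 0.047, 0.093, 0.054),
    I = c(0.043, 0.034, 0.013, 0.056),
    L = c(0.061, 0.025, 0.036, 0.070),
    K = c(0.055, 0.115, 0.072, 0.095),
    M = c(0.068, 0.082, 0.014, 0.055),
    F = c(0.059, 0.041, 0.065, 0.065),
    P = c(0.102, 0.301, 0.034, 0.068),
    S = c(0.120, 0.139, 0.125, 0.106),
    T = c(0.086, 0.108, 0.065, 0.079),
    W = c(0.077, 0.013, 0.064, 0.167),
    Y = c(0.082, 0.065, 0.114, 0.125),
    V = c(0.062, 0.048, 0.028, 0.053)
  )
  colnames(tab) <- c("i", "i+1", "i+2", "i+3")
  tab
})

#' Default positional beta-turn preference table
#' @return a 20 x 4 numeric matrix (rows = one-letter amino acids, columns =
#'   turn positions `i`, `i+1`, `i+2`, `i+3`).
#' @export
turn_preference_table <- function() TURN_PREFERENCE_DEFAULT

#' Load a turn preference table from delimited text
#'
#' Expects a header row naming the four turn positions (`i`, `i+1`, `i+2`,
#' `i+3`) and a first column of one-letter amino-acid codes; all 20 amino
#' acids must be present.
#'
#' @param path file path (tab- or comma-delimited).
#' @return a 20 x 4 matrix in the same layout as [turn_preference_table()].
#' @export
load_preference_table <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, name_repair = "minimal")
  aa <- toupper(df[[1]])
  if (!setequal(aa, AA1)) abort("Preference table must list all 20 one-letter amino-acid codes.")
  tab <- as.matrix(df[, -1])
  if (ncol(tab) != 4) abort("Preference table must have four position columns (i, i+1, i+2, i+3).")
  rownames(tab) <- aa
  colnames(tab) <- c("i", "i+1", "i+2", "i+3")
  storage.mode(tab) <- "double"
  if (any(!is.finite(tab)) || any(tab < 0)) abort("Preference scores must be finite and non-negative.")
  tab[AA1, , drop = FALSE]
}

#' Positional preference score for a substitution in a beta-turn
#'
#' @param substitution one-letter amino-acid code of the substituting residue.
#' @param turn_position one of `"i"`, `"i+1"`, `"i+2"`, `"i+3"`.
#' @param table preference table; defaults to the built-in one.
#' @return numeric propensity score.
#' @export
preference_score <- function(substitution, turn_position,
                             table = turn_preference_table()) {
  substitution <- toupper(substitution)
  if (!all(substitution %in% rownames(table))) {
    abort(paste0("Unknown amino-acid code(s): ",
                 paste(setdiff(substitution, rownames(table)), collapse = ", ")))
  }
  if (!all(turn_position %in% colnames(table))) {
    abort("turn_position must be one of 'i', 'i+1', 'i+2', 'i+3'.")
  }
  table[cbind(substitution, turn_position)]
}
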