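# Seeded synthetic-data generators. Every generator emits its planted
# ground truth alongside the data (attribute "truth") so analyses can be
# validated plant-and-recover; identical (spec, seed) gives identical output.

# ideal backbone internal coordinates (A, degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

# place atom D from A-B-C with bond |C-D|, angle B-C-D, torsion A-B-C-D
place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180; ch <- -torsion * pi / 180
  b2 <- unit_vec(C - B)
  n <- unit_vec(vcross(B - A, b2))
  m <- vcross(n, b2)
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  C + d2[1] * b2 + d2[2] * m + d2[3] * n
}

#' Segment constructors for [build_peptide()]
#'
#' `seg_helix()` and `seg_strand()` use ideal alpha (-57, -47) and extended
#' beta (-120, 130) dihedrals; `seg_loop()` uses a window that classifies as
#' neither; `seg_turn()` emits a four-residue window whose central residues
#' carry the canonical dihedrals of the requested beta-turn type, flanked by
#' extended residues.
#'
#' @param n segment length in residues.
#' @param phi,psi backbone dihedrals (degrees).
#' @param type beta-turn type: `"I"`, `"II"`, `"I'"`, `"II'"` or `"VIII"`.
#' @return a segment spec list consumed by [build_peptide()].
#' @export
seg_helix <- function(n) list(kind = "helix", phi = rep(-57, n), psi = rep(-47, n))

#' @rdname seg_helix
#' @export
seg_strand <- function(n) list(kind = "strand", phi = rep(-120, n), psi = rep(130, n))

#' @rdname seg_helix
#' @export
seg_loop <- function(n, phi = -100, psi = 20) {
  list(kind = "loop", phi = rep(phi, n), psi = rep(psi, n))
}

#' @rdname seg_helix
#' @export
seg_turn <- function(type = "I") {
  if (!type %in% names(TURN_CANONICAL)) {
    abort(paste0("Unknown turn type '", type, "'"))
  }
  ct <- TURN_CANONICAL[[type]]
  # flank dihedrals chosen (extended, sheet-window) so that windows
  # overlapping the turn stay above the 7 A detection cutoff
  list(kind = "turn", turn_type = type,
       phi = c(-160, ct[1], ct[3], -80),
       psi = c(170, ct[2], ct[4], 100))
}

#' Build an ideal-geometry peptide with planted annotations
#'
#' Constructs backbone atoms (N, CA, C, O, plus CB and minimal charged side
#' chains where the sequence requires them) by sequential internal-coordinate
#' placement with ideal bond lengths/angles and trans peptide bonds, using
#' each segment's (phi, psi). B-factors are assigned from `b_factors`.
#' The planted secondary-structure intent and turn windows are recorded in
#' attribute `"truth"`.
#'
#' @param segments list of segment specs from [seg_helix()] and friends.
#' @param sequence optional one-letter sequence (defaults to poly-Gly).
#' @param b_factors per-residue B-factors (recycled; default 20).
#' @param chain chain identifier.
#' @param start_res_seq author number of the first residue.
#' @param id structure id.
#' @return a `pdb_structure` with attribute `"truth"`:
#'   `list(ss, turns)` where `turns` is a tibble of planted windows
#'   (`res_seq_i`, `turn_type`).
#' @export
build_peptide <- function(segments, sequence = NULL, b_factors = 20,
                          chain = "A", start_res_seq = 1L, id = "synthetic") {
  phi <- unlist(map(segments, "phi"))
  psi <- unlist(map(segments, "psi"))
  n <- length(phi)
  if (n < 4) abort("Peptide must have at least 4 residues.")
  kinds <- unlist(map(segments, function(s) rep(s$kind, length(s$phi))))
  seq1 <- if (is.null(sequence)) strrep("G", n) else toupper(sequence)
  if (nchar(seq1) != n) abort("sequence length must match total segment length.")
  aa1 <- strsplit(seq1, "")[[1]]
  res_names <- aa_one_to_three(aa1)
  if (anyNA(res_names)) abort("Unknown one-letter code in sequence.")
  b <- rep_len(b_factors, n)

  # backbone chain build
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANG_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANG_C_N_CA, 180)      # omega = 180
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANG_N_CA_C, phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANG_CA_C_O, psi[i] + 180)
  }

  a_res <- integer(0); a_name <- character(0); a_el <- character(0)
  a_xyz <- list()
  add <- function(i, name, xyz, element) {
    a_res[length(a_res) + 1] <<- i
    a_name[length(a_name) + 1] <<- name
    a_el[length(a_el) + 1] <<- element
    a_xyz[[length(a_xyz) + 1]] <<- xyz
  }
  for (i in seq_len(n)) {
    add(i, "N", N[i, ], "N")
    add(i, "CA", CA[i, ], "C")
    add(i, "C", C[i, ], "C")
    add(i, "O", O[i, ], "O")
    if (aa1[i] != "G") {
      n1 <- unit_vec(N[i, ] - CA[i, ]); n2 <- unit_vec(C[i, ] - CA[i, ])
      dir <- unit_vec(-(n1 + n2) + vcross(n2, n1))
      CB <- CA[i, ] + 1.53 * dir
      add(i, "CB", CB, "C")
      u <- unit_vec(CB - CA[i, ])
      p <- unit_vec(vcross(u, n1))
      ext <- function(base, k) base + 1.5 * k * u
      if (aa1[i] == "D") {
        CG <- ext(CB, 1); add(i, "CG", CG, "C")
        add(i, "OD1", CG + 1.25 * unit_vec(u + 0.9 * p), "O")
        add(i, "OD2", CG + 1.25 * unit_vec(u - 0.9 * p), "O")
      } else if (aa1[i] == "E") {
        CG <- ext(CB, 1); CD <- ext(CB, 2)
        add(i, "CG", CG, "C"); add(i, "CD", CD, "C")
        add(i, "OE1", CD + 1.25 * unit_vec(u + 0.9 * p), "O")
        add(i, "OE2", CD + 1.25 * unit_vec(u - 0.9 * p), "O")
      } else if (aa1[i] == "K") {
        add(i, "CG", ext(CB, 1), "C"); add(i, "CD", ext(CB, 2), "C")
        add(i, "CE", ext(CB, 3), "C"); add(i, "NZ", ext(CB, 4), "N")
      } else if (aa1[i] == "R") {
        CG <- ext(CB, 1); CD <- ext(CB, 2); NE <- ext(CB, 3); CZ <- ext(CB, 4)
        add(i, "CG", CG, "C"); add(i, "CD", CD, "C")
        add(i, "NE", NE, "N"); add(i, "CZ", CZ, "C")
        add(i, "NH1", CZ + 1.33 * unit_vec(u + 0.9 * p), "N")
        add(i, "NH2", CZ + 1.33 * unit_vec(u - 0.9 * p), "N")
      } else if (aa1[i] == "H") {
        CG <- ext(CB, 1)
        add(i, "CG", CG, "C")
        add(i, "ND1", CG + 1.38 * unit_vec(u + 0.9 * p), "N")
        add(i, "NE2", CG + 1.38 * unit_vec(u - 0.9 * p), "N")
      }
    }
  }
  xyz <- do.call(rbind, a_xyz)
  atoms <- tibble(
    serial = seq_along(a_res), name = a_name, alt_loc = "",
    res_name = res_names[a_res], chain = chain,
    res_seq = start_res_seq + a_res - 1L, i_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = b[a_res], element = a_el)
  s <- new_pdb_structure(atoms, id = id, source = "build_peptide")

  seg_start <- cumsum(c(1, head(lengths(map(segments, "phi")), -1)))
  turns <- list_rbind(map(seq_along(segments), function(k) {
    if (segments[[k]]$kind != "turn") return(NULL)
    tibble(res_seq_i = as.integer(start_res_seq + seg_start[k] - 1),
           turn_type = segments[[k]]$turn_type)
  }))
  if (is.null(turns)) turns <- tibble(res_seq_i = integer(), turn_type = character())
  attr(s, "truth") <- list(
    ss = tibble(res_seq = start_res_seq + seq_len(n) - 1L, kind = kinds),
    turns = turns, phi = phi, psi = psi)
  s
}

residue_index_of <- function(structure, keys) {
  res <- residue_table(structure)
  match(keys, res$key)
}

#' Build a coordinate ensemble with planted mobility, correlated blocks and
#' bond occupancies
#'
#' Each frame displaces every residue rigidly by an isotropic Gaussian vector
#' whose scale is chosen so the expected RMSF of residue r equals
#' `mobility[r]`. Residues in a correlated block share one latent
#' displacement per frame (sign +1 in-phase, -1 anti-phase), giving DCCM
#' entries near +-1. Bond plants are enforced geometrically after sampling:
#' the named atom pair is placed at `d_in` in exactly the listed frames and
#' `d_out` elsewhere, so planted occupancies are exact.
#'
#' @param structure topology `pdb_structure`.
#' @param n_frames number of frames (>= 2).
#' @param mobility per-residue target RMSF (A): named by residue key, or
#'   unnamed in residue order; default 0 (static).
#' @param blocks list of `list(residues = keys, sigma = A, phase = +-1
#'   per residue)` correlated-motion blocks.
#' @param bond_plants list of `list(key_a, atom_a, key_b, atom_b,
#'   frames_present, d_in = 3.0, d_out = 6.5)`.
#' @param seed integer RNG seed.
#' @return a `pdb_ensemble` with attribute `"truth"` recording the planted
#'   mobility profile, blocks and per-plant occupancy.
#' @export
build_ensemble <- function(structure, n_frames, mobility = NULL,
                           blocks = NULL, bond_plants = NULL, seed = 1L) {
  if (n_frames < 2) abort("An ensemble needs at least 2 frames.")
  res <- residue_table(structure)
  n_res <- nrow(res)
  mob <- rep(0, n_res)
  if (!is.null(mobility)) {
    if (!is.null(names(mobility))) {
      idx <- residue_index_of(structure, names(mobility))
      if (anyNA(idx)) abort("mobility names include unknown residue keys.")
      mob[idx] <- unname(mobility)
    } else {
      mob <- rep_len(mobility, n_res)
    }
  }
  res_of_atom <- match(residue_key(structure$chain, structure$res_seq,
                                   structure$i_code), res$key)
  base <- coord_matrix(structure)
  coords <- array(NA_real_, dim = c(n_frames, nrow(base), 3))

  block_idx <- map(blocks, function(b) {
    idx <- residue_index_of(structure, b$residues)
    if (anyNA(idx)) abort("Correlated block references unknown residue keys.")
    list(idx = idx, sigma = b$sigma,
         phase = rep_len(b$phase %||% 1, length(idx)))
  })
  in_block <- rep(FALSE, n_res)
  for (b in block_idx) in_block[b$idx] <- TRUE

  set.seed(seed)
  for (f in seq_len(n_frames)) {
    disp <- matrix(rnorm(n_res * 3), n_res, 3) * (mob / sqrt(3))
    disp[in_block, ] <- 0
    for (b in block_idx) {
      u <- rnorm(3) * b$sigma / sqrt(3)
      disp[b$idx, ] <- outer(b$phase, u)
    }
    coords[f, , ] <- base + disp[res_of_atom, ]
  }

  truth_plants <- list()
  if (!is.null(bond_plants)) {
    atom_row <- function(key, atom) {
      k <- parse_residue_key(key)
      i <- which(structure$chain == k$chain & structure$res_seq == k$res_seq &
                   structure$i_code == k$i_code & structure$name == atom)
      if (length(i) != 1) abort(paste0("Cannot resolve atom ", key, "/", atom))
      i
    }
    for (p in bond_plants) {
      ia <- atom_row(p$key_a, p$atom_a)
      ib <- atom_row(p$key_b, p$atom_b)
      dir <- unit_vec(base[ib, ] - base[ia, ])
      if (anyNA(dir)) dir <- c(1, 0, 0)
      d_in <- p$d_in %||% 3.0
      d_out <- p$d_out %||% 6.5
      present <- sort(unique(p$frames_present))
      for (f in seq_len(n_frames)) {
        d <- if (f %in% present) d_in else d_out
        coords[f, ib, ] <- coords[f, ia, ] + dir * d
      }
      truth_plants[[length(truth_plants) + 1]] <- list(
        key_a = p$key_a, atom_a = p$atom_a, key_b = p$key_b,
        atom_b = p$atom_b, frames_present = present,
        occupancy = length(present) / n_frames)
    }
  }

  ens <- new_pdb_ensemble(structure, coords)
  attr(ens, "truth") <- list(
    mobility = tibble(key = res$key, rmsf = mob),
    blocks = blocks, bond_plants = truth_plants)
  ens
}

#' Build a synthetic multiple sequence alignment with planted conservation
#'
#' Homologs match the query residue in exactly `match_counts[j]` sequences at
#' column j and carry random non-matching residues elsewhere; no gaps unless
#' `query_gap_columns` asks for columns where the query is gapped.
#'
#' @param query one-letter query sequence.
#' @param n_homologs number of homolog sequences (conservation denominators).
#' @param match_counts per-column number of homologs matching the query
#'   (defaults to a seeded random draw in 0..n_homologs).
#' @param query_gap_columns alignment columns (inserted before the query
#'   positions) where the query carries a gap and homologs a random residue.
#' @param seed integer RNG seed.
#' @param query_id identifier used for the query sequence.
#' @return a list: `fasta` (aligned-FASTA text), `query_id`, and `truth`
#'   (tibble of `query_pos`, `column`, `match_count`, `conservation`).
#' @export
build_msa <- function(query, n_homologs = 13, match_counts = NULL,
                      query_gap_columns = integer(), seed = 1L,
                      query_id = "query") {
  set.seed(seed)
  q <- strsplit(toupper(query), "")[[1]]
  L <- length(q)
  if (is.null(match_counts)) {
    match_counts <- sample(0:n_homologs, L, replace = TRUE)
  }
  if (length(match_counts) != L || any(match_counts > n_homologs)) {
    abort("match_counts must have one entry per query position, each <= n_homologs.")
  }
  n_col <- L + length(query_gap_columns)
  gap_cols <- sort(unique(query_gap_columns))
  qrow <- character(n_col)
  qrow[gap_cols] <- "-"
  qrow[setdiff(seq_len(n_col), gap_cols)] <- q
  hom <- matrix("", n_homologs, n_col)
  qpos <- 0L
  truth <- list()
  for (j in seq_len(n_col)) {
    if (qrow[j] == "-") {
      hom[, j] <- sample(AA1, n_homologs, replace = TRUE)
      next
    }
    qpos <- qpos + 1L
    k <- match_counts[qpos]
    who <- sample(n_homologs, k)
    hom[who, j] <- qrow[j]
    others <- setdiff(seq_len(n_homologs), who)
    hom[others, j] <- sample(setdiff(AA1, qrow[j]), length(others),
                             replace = TRUE)
    truth[[qpos]] <- tibble(query_pos = qpos, column = j,
                            match_count = k,
                            conservation = k / n_homologs)
  }
  ids <- c(query_id, sprintf("homolog_%02d", seq_len(n_homologs)))
  seqs <- c(paste(qrow, collapse = ""),
            apply(hom, 1, paste, collapse = ""))
  fasta <- paste0(">", ids, "\n", seqs, collapse = "\n")
  list(fasta = paste0(fasta, "\n"), query_id = query_id,
       truth = list_rbind(truth))
}

#' Build a saturation-mutagenesis ddG table with a planted stable set
#'
#' Emits all 19 substitutions per position. Substitutions in the planted
#' stable set draw ddG uniformly in \[-5, -0.6\] kJ/mol (predicted
#' stabilizing under the -0.5 kJ/mol threshold); all others draw from
#' \[-0.4, 3\] kJ/mol.
#'
#' @param positions tibble with columns `position` (residue number) and
#'   `wild` (one-letter code), or an integer vector (wild defaults to Gly).
#' @param stable optional tibble (`position`, `mut`) of planted-stable
#'   substitutions; alternatively `n_stable` random ones are chosen.
#' @param n_stable number of random planted-stable substitutions.
#' @param seed integer RNG seed.
#' @param chain chain id recorded in the table.
#' @return a tibble (`chain`, `position`, `wild`, `mut`, `ddg`) with
#'   attribute `"truth"` = the planted stable tibble.
#' @export
build_ddg_table <- function(positions, stable = NULL, n_stable = NULL,
                            seed = 1L, chain = "A") {
  set.seed(seed)
  if (!is.data.frame(positions)) {
    positions <- tibble(position = as.integer(positions), wild = "G")
  }
  tab <- positions |>
    rowwise() |>
    reframe(chain = chain, position = .data$position, wild = .data$wild,
            mut = setdiff(AA1, .data$wild))
  if (is.null(stable)) {
    n_stable <- n_stable %||% 0L
    pick <- sample(nrow(tab), n_stable)
    stable <- tab[pick, c("position", "mut")]
  }
  is_stable <- paste(tab$position, tab$mut) %in%
    paste(stable$position, stable$mut)
  tab$ddg <- ifelse(is_stable,
                    runif(nrow(tab), -5, -0.6),
                    runif(nrow(tab), -0.4, 3))
  tab <- as_tibble(tab)
  attr(tab, "truth") <- as_tibble(stable)
  tab
}

#' Generate noisy enzyme-assay datasets with known parameters
#'
#' `kind = "mm"` draws initial velocities from the Michaelis-Menten model on
#' a 1..10 mg/mL substrate series; `kind = "decay"` draws residual activities
#' from first-order exponential inactivation over a 0..90 min incubation.
#' Gaussian noise of absolute standard deviation `noise_sd` is added.
#'
#' @param kind `"mm"` or `"decay"`.
#' @param params for `"mm"`: `list(vmax, km)`; for `"decay"`:
#'   `list(a0, k)` (k in 1/min).
#' @param noise_sd Gaussian noise standard deviation: absolute response
#'   units, or the coefficient of variation when `proportional = TRUE`.
#' @param n number of observations.
#' @param seed integer RNG seed.
#' @param proportional draw heteroscedastic noise with per-observation
#'   standard deviation `noise_sd * signal` (the constant-CV error model
#'   typical of enzyme assays) instead of a constant absolute deviation.
#' @return a tibble (`substrate`, `velocity`) or (`time`, `activity`) with
#'   attribute `"truth"` = `params`.
#' @export
build_assay_data <- function(kind = c("mm", "decay"), params, noise_sd = 0,
                             n = 10, seed = 1L, proportional = FALSE) {
  kind <- match.arg(kind)
  set.seed(seed)
  noise <- function(mu) {
    if (proportional) rnorm(n, 0, noise_sd * abs(mu)) else
      rnorm(n, 0, noise_sd)
  }
  if (kind == "mm") {
    s <- seq(1, 10, length.out = n)
    mu <- params$vmax * s / (params$km + s)
    out <- tibble(substrate = s, velocity = mu + noise(mu))
  } else {
    t <- seq(0, 90, length.out = n)
    mu <- params$a0 * exp(-params$k * t)
    out <- tibble(time = t, activity = mu + noise(mu))
  }
  attr(out, "truth") <- params
  out
}

#' Build a complete screening fixture with a planted pass set
#'
#' Constructs a surface peptide whose chain runs an N-terminal strand
#' (hosting two catalytic residues) followed by alternating beta-turns and
#' strand spacers; assembles a saturation ddG table over all turn residues
#' and a 13-homolog MSA, planting which substitutions survive the full
#' filter chain. Pass-set membership is decided by the generator's own
#' arithmetic (direct coordinate distances and planted ddG/conservation
#' values), independent of the screening code under test.
#'
#' @param seed integer RNG seed.
#' @param n_turns number of planted beta-turns.
#' @param spacer_len strand residues between consecutive turns.
#' @param min_catalytic_distance the distance cut the fixture plants around
#'   (default 13 A, the screen default).
#' @param conservation_veto the conservation cut planted around.
#' @return a list: `structure`, `ddg` (tibble), `msa` (build_msa output),
#'   `catalytic` (keys), and `truth` (tibble of substitutions expected to
#'   pass: `position`, `wild`, `mut`).
#' @export
build_screen_fixture <- function(seed = 1L, n_turns = 4, spacer_len = 5,
                                 min_catalytic_distance = 13,
                                 conservation_veto = 0.8) {
  set.seed(seed)
  types <- sample(c("I", "II", "I'", "II'"), n_turns, replace = TRUE)
  segs <- list(seg_strand(8))
  for (ty in types) segs <- c(segs, list(seg_turn(ty), seg_strand(spacer_len)))
  n_res <- sum(lengths(map(segs, "phi")))
  b <- runif(n_res, 15, 30)
  s <- build_peptide(segs, b_factors = b)
  catalytic <- c("A:6", "A:8")

  # direct-arithmetic turn distances (generator-side truth)
  ca <- s[s$name == "CA", ]
  ca_xyz <- as.matrix(ca[, c("x", "y", "z")])
  turn_starts <- attr(s, "truth")$turns$res_seq_i
  cat_idx <- match(c(6L, 8L), ca$res_seq)
  far <- vapply(turn_starts, function(st) {
    idx <- match(st:(st + 3L), ca$res_seq)
    d <- outer(idx, cat_idx, function(i, j) {
      sqrt(rowSums((ca_xyz[i, , drop = FALSE] - ca_xyz[j, , drop = FALSE])^2))
    })
    mean(d) >= min_catalytic_distance
  }, logical(1))

  # ddG table over every turn residue; only central (i+1, i+2) residues of
  # far turns can host planted passes (flank residues sit in sheet runs)
  positions <- sort(unlist(map(turn_starts, function(st) st:(st + 3L))))
  pos_tbl <- tibble(position = positions, wild = "G")
  central_far <- unlist(map(which(far), function(k) {
    turn_starts[k] + c(1L, 2L)
  }))
  central_near <- unlist(map(which(!far), function(k) {
    turn_starts[k] + c(1L, 2L)
  }))

  all_subs <- tidyr::crossing(position = positions,
                              mut = setdiff(AA1, "G"))
  # plant: per far-turn-central position, 1-3 stable substitutions; a
  # vetoed position (high conservation) keeps stable ddG but must fail
  vetoed_pos <- if (length(central_far) > 1) central_far[1] else integer()
  stable <- all_subs |>
    filter(.data$position %in% c(central_far, central_near)) |>
    group_by(.data$position) |>
    slice_sample(n = 3) |>
    ungroup()
  ddg <- build_ddg_table(pos_tbl, stable = stable[, c("position", "mut")],
                         seed = seed + 1)

  # conservation plant: vetoed positions >= veto threshold, others low
  qseq <- strrep("G", n_res)
  match_counts <- sample(3:8, n_res, replace = TRUE)      # <= 8/13 = 0.615
  match_counts[vetoed_pos] <- 13L
  msa <- build_msa(qseq, n_homologs = 13, match_counts = match_counts,
                   seed = seed + 2)

  truth <- stable |>
    filter(.data$position %in% setdiff(central_far, vetoed_pos)) |>
    mutate(wild = "G") |>
    select("position", "wild", "mut") |>
    arrange(.data$position, .data$mut)

  list(structure = s, ddg = ddg, msa = msa, catalytic = catalytic,
       truth = truth,
       planted = list(types = types, far = far, turn_starts = turn_starts,
                      vetoed = vetoed_pos))
}
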