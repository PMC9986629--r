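# PDB structure and ensemble input/output.
#
# A structure is a tibble of atoms (one row per atom) with class
# "pdb_structure"; an ensemble is a list(topology, coords) with class
# "pdb_ensemble", where coords is an [n_frames x n_atoms x 3] array congruent
# with the topology's atom order.

new_pdb_structure <- function(atoms, id = "", source = "") {
  structure(
    as_tibble(atoms),
    class = c("pdb_structure", class(as_tibble(atoms))),
    id = id, source = source
  )
}

new_pdb_ensemble <- function(topology, coords) {
  structure(list(topology = topology, coords = coords),
            class = "pdb_ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble a `pdb_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @export
print.pdb_ensemble <- function(x, ...) {
  cat(sprintf("<pdb_ensemble> %d frames x %d atoms (%d residues)\n",
              n_frames(x), nrow(x$topology), nrow(residue_table(x$topology))))
  invisible(x)
}

water_names <- c("HOH", "WAT", "DOD", "H2O")

parse_atom_lines <- function(lines, line_nos, include_hetatm = FALSE,
                             include_waters = FALSE) {
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  line_nos <- line_nos[keep]
  if (length(lines) == 0) abort("No ATOM/HETATM records found (empty structure).")

  fw <- function(from, to) trimws(substr(lines, from, to))
  num <- function(from, to, what) {
    s <- substr(lines, from, to)
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & trimws(s) != ""
    if (any(bad)) {
      abort(sprintf("Malformed %s field at line %d: '%s'",
                    what, line_nos[which(bad)[1]], s[which(bad)[1]]))
    }
    v
  }

  atoms <- tibble(
    record = trimws(rec[keep]),
    serial = as.integer(num(7, 11, "serial")),
    name = fw(13, 16),
    alt_loc = trimws(substr(lines, 17, 17)),
    res_name = fw(18, 20),
    chain = substr(lines, 22, 22),
    res_seq = as.integer(num(23, 26, "resSeq")),
    i_code = trimws(substr(lines, 27, 27)),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = num(55, 60, "occupancy"),
    b_factor = num(61, 66, "B-factor"),
    element = fw(77, 78),
    line = line_nos
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    bad <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))[1]
    abort(sprintf("Missing coordinate at line %d", atoms$line[bad]))
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$b_factor[is.na(atoms$b_factor)] <- 0
  atoms$element <- ifelse(atoms$element == "",
                          gsub("[^A-Za-z].*$", "",
                               sub("^[0-9]*", "", atoms$name)) |>
                            substr(1, 1) |> toupper(),
                          atoms$element)

  if (!include_hetatm) {
    atoms <- atoms[atoms$record == "ATOM" |
                     (include_waters & atoms$res_name %in% water_names), ]
  }
  if (!include_waters) atoms <- atoms[!(atoms$res_name %in% water_names), ]
  if (nrow(atoms) == 0) abort("No atoms left after HETATM/water filtering (empty structure).")

  # highest-occupancy alternate location per (residue, atom name)
  atoms <- atoms |>
    group_by(.data$chain, .data$res_seq, .data$i_code, .data$name) |>
    arrange(dplyr::desc(.data$occupancy), .data$alt_loc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$line)

  if (any(atoms$b_factor < 0)) {
    warn(sprintf("%d atom(s) with negative B-factor clamped to 0",
                 sum(atoms$b_factor < 0)))
    atoms$b_factor[atoms$b_factor < 0] <- 0
  }

  atoms |>
    select(-"record", -"line") |>
    arrange(.data$chain, .data$res_seq, .data$i_code)
}

#' Parse a PDB-format string into an atom tibble
#'
#' Fixed-column parsing of ATOM/HETATM records. Waters and HETATM records are
#' skipped by default; when several alternate locations are present for an
#' atom, the highest-occupancy one is kept. Negative B-factors are clamped to
#' zero with a warning.
#'
#' @param text a single string (or character vector of lines) in PDB format.
#' @param id identifier stored on the result.
#' @param include_hetatm keep non-water HETATM records.
#' @param include_waters keep water residues.
#' @return a `pdb_structure` tibble with one row per atom and columns
#'   `serial`, `name`, `alt_loc`, `res_name`, `chain`, `res_seq`, `i_code`,
#'   `x`, `y`, `z`, `occupancy`, `b_factor`, `element`.
#' @examples
#' pdb <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 20.50           C"
#' parse_pdb(pdb)
#' @export
parse_pdb <- function(text, id = "", include_hetatm = FALSE,
                      include_waters = FALSE) {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  atoms <- parse_atom_lines(lines, seq_along(lines),
                            include_hetatm = include_hetatm,
                            include_waters = include_waters)
  new_pdb_structure(atoms, id = id, source = "parse_pdb")
}

#' Read a PDB file (optionally gzipped)
#' @param path file path; gzip-compressed files are handled transparently.
#' @inheritParams parse_pdb
#' @return a `pdb_structure`.
#' @export
read_pdb <- function(path, include_hetatm = FALSE, include_waters = FALSE) {
  parse_pdb(readLines(path), id = basename(path),
            include_hetatm = include_hetatm, include_waters = include_waters)
}

#' Parse a multi-model PDB string into a coordinate ensemble
#'
#' MODEL/ENDMDL blocks become frames; a file without MODEL records yields a
#' one-frame ensemble. The topology is taken from the first model; all models
#' must agree in atom count and atom identity order.
#'
#' @inheritParams parse_pdb
#' @return a `pdb_ensemble`: `list(topology = pdb_structure,
#'   coords = [frames x atoms x 3] array)`.
#' @export
parse_multimodel_pdb <- function(text, id = "") {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    s <- parse_pdb(lines, id = id)
    coords <- array(coord_matrix(s), dim = c(1, nrow(s), 3))
    return(new_pdb_ensemble(s, coords))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  frames <- map(seq_along(starts), function(k) {
    blk <- lines[(starts[k] + 1):(ends[k] - 1)]
    parse_atom_lines(blk, seq_along(blk) + starts[k])
  })
  topo <- new_pdb_structure(frames[[1]], id = id, source = "parse_multimodel_pdb")
  ident <- function(a) paste(a$chain, a$res_seq, a$i_code, a$name)
  ref_id <- ident(frames[[1]])
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]) != nrow(topo) ||
        !identical(ident(frames[[k]]), ref_id)) {
      abort(sprintf("Model %d is not congruent with model 1 (atom count or order differs)", k))
    }
  }
  coords <- array(NA_real_, dim = c(length(frames), nrow(topo), 3))
  for (k in seq_along(frames)) coords[k, , ] <- coord_matrix(frames[[k]])
  new_pdb_ensemble(topo, coords)
}

#' @rdname parse_multimodel_pdb
#' @param path file path.
#' @export
read_multimodel_pdb <- function(path) {
  parse_multimodel_pdb(readLines(path), id = basename(path))
}

format_atom_line <- function(a, x, y, z, b) {
  name <- if (nchar(a$name) <= 3) sprintf(" %-3s", a$name) else a$name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial, name,
          ifelse(a$alt_loc == "", " ", a$alt_loc),
          a$res_name, a$chain, a$res_seq,
          ifelse(a$i_code == "", " ", a$i_code),
          x, y, z, a$occupancy, b, a$element)
}

#' Write a structure or ensemble as PDB-format text
#'
#' The B-factor column can be overwritten from any per-residue scalar (e.g.
#' to export a flexibility score for visualization).
#'
#' @param structure a `pdb_structure`.
#' @param ensemble optional `pdb_ensemble`; when supplied, one MODEL block is
#'   written per frame using the ensemble's topology.
#' @param b_factor optional per-residue values: either a vector named by
#'   residue key or a tibble with columns `key` (or chain/res_seq/i_code) and
#'   `value`. Every atom of a residue receives its residue's value.
#' @param path optional file path; when given, text is also written there.
#' @return the PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(structure, ensemble = NULL, b_factor = NULL,
                      path = NULL) {
  if (!is.null(ensemble)) structure <- ensemble$topology
  b <- structure$b_factor
  if (!is.null(b_factor)) {
    keys <- residue_key(structure$chain, structure$res_seq, structure$i_code)
    if (is.data.frame(b_factor)) {
      if (!"key" %in% names(b_factor)) {
        b_factor$key <- residue_key(b_factor$chain, b_factor$res_seq,
                                    b_factor$i_code %||% "")
      }
      vals <- setNames(b_factor$value, b_factor$key)
    } else {
      vals <- b_factor
    }
    miss <- setdiff(unique(keys), names(vals))
    if (length(miss) > 0) {
      abort(paste0("No B-factor value for residue(s): ",
                   paste(miss, collapse = ", ")))
    }
    b <- unname(vals[keys])
  }
  frame_lines <- function(xyz, bvec) {
    if (any(abs(xyz) >= 10000)) {
      abort("Coordinates out of PDB fixed-column range (|coord| >= 10000 A)")
    }
    vapply(seq_len(nrow(structure)), function(i) {
      format_atom_line(structure[i, ], xyz[i, 1], xyz[i, 2], xyz[i, 3],
                       bvec[i])
    }, character(1))
  }
  if (is.null(ensemble)) {
    out <- c(frame_lines(coord_matrix(structure), b), "TER", "END")
  } else {
    out <- unlist(map(seq_len(n_frames(ensemble)), function(k) {
      c(sprintf("MODEL     %4d", k),
        frame_lines(ensemble$coords[k, , , drop = TRUE], b),
        "ENDMDL")
    }))
    out <- c(out, "END")
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' Assemble an ensemble from a topology and explicit frame coordinates
#'
#' @param structure a `pdb_structure` providing the topology.
#' @param frames a list of n_atoms-by-3 coordinate matrices.
#' @return a `pdb_ensemble`.
#' @export
ensemble_from_frames <- function(structure, frames) {
  n <- nrow(structure)
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == c(n, 3)),
               logical(1))
  if (!all(ok)) abort("Every frame must be an n_atoms x 3 matrix congruent with the topology.")
  coords <- array(NA_real_, dim = c(length(frames), n, 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  new_pdb_ensemble(structure, coords)
}
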