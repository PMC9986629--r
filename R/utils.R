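# Shared helpers: residue keys, amino-acid code tables, small vector geometry.

# three-letter -> one-letter amino-acid codes
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return character vector of the converted codes; unknown codes become `NA`.
#' @examples
#' aa_three_to_one("PRO")
#' aa_one_to_three("P")
#' @export
aa_three_to_one <- function(x) {
  unname(setNames(AA1, AA3)[toupper(x)])
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  unname(setNames(AA3, AA1)[toupper(x)])
}

#' Build residue keys from chain, sequence number and insertion code
#'
#' Residues are addressed everywhere in the package by author numbering as
#' `"<chain>:<res_seq>"` (with any insertion code appended, e.g. `"A:100A"`),
#' never by list position, so that sites keep the names crystallographers use.
#'
#' @param chain chain identifiers.
#' @param res_seq author residue numbers.
#' @param i_code insertion codes (`""` when absent).
#' @return character vector of keys.
#' @export
residue_key <- function(chain, res_seq, i_code = "") {
  ic <- ifelse(is.na(i_code) | i_code == " ", "", i_code)
  paste0(chain, ":", res_seq, ic)
}

# parse "A:15" / "A:100A" keys into a tibble(chain, res_seq, i_code)
parse_residue_key <- function(keys) {
  m <- stringr::str_match(keys, "^(.+?):(-?[0-9]+)([A-Za-z]?)$")
  if (anyNA(m[, 1])) {
    abort(paste0("Malformed residue key(s): ",
                 paste(keys[is.na(m[, 1])], collapse = ", ")))
  }
  tibble(chain = m[, 2], res_seq = as.integer(m[, 3]), i_code = m[, 4])
}

# per-residue summary of an atom tibble, in structure order
residue_table <- function(structure) {
  structure |>
    mutate(key = residue_key(.data$chain, .data$res_seq, .data$i_code)) |>
    group_by(.data$chain, .data$res_seq, .data$i_code, .data$res_name,
             .data$key) |>
    summarise(n_atoms = dplyr::n(), .groups = "drop") |>
    arrange(.data$chain, .data$res_seq, .data$i_code)
}

# resolve a character vector of keys against a structure; error on misses
resolve_keys <- function(structure, keys, what = "residue") {
  have <- unique(residue_key(structure$chain, structure$res_seq,
                             structure$i_code))
  miss <- setdiff(keys, have)
  if (length(miss) > 0) {
    abort(paste0("Unresolvable ", what, " key(s): ",
                 paste(miss, collapse = ", ")))
  }
  keys
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unit_vec <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) return(rep(NA_real_, 3))
  a / n
}

# smallest absolute angular difference in degrees, wrap-aware
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

coord_matrix <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}
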