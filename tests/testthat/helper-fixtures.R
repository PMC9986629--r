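# Shared fixture builders; everything is generated in code at test time.

# a correctly fixed-column ATOM line
pdb_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                     occ = 1, b = 20, element = substr(name, 1, 1),
                     alt_loc = " ", record = "ATOM  ") {
  nm <- if (nchar(name) <= 3) sprintf(" %-3s", name) else name
  sprintf("%s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt_loc, res_name, chain, res_seq,
          x, y, z, occ, b, element)
}

# three-residue synthetic peptide as raw PDB text
three_res_pdb <- function() {
  paste(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, b = 10),
    pdb_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0, b = 10),
    pdb_line(3, "C", "ALA", "A", 1, 2.0, 1.4, 0, b = 10),
    pdb_line(4, "N", "GLY", "A", 2, 3.3, 1.5, 0, b = 20),
    pdb_line(5, "CA", "GLY", "A", 2, 4.1, 2.7, 0, b = 20),
    pdb_line(6, "C", "GLY", "A", 2, 5.6, 2.5, 0, b = 20),
    pdb_line(7, "N", "SER", "A", 3, 6.3, 3.6, 0, b = 30),
    pdb_line(8, "CA", "SER", "A", 3, 7.8, 3.6, 0, b = 30),
    pdb_line(9, "C", "SER", "A", 3, 8.4, 5.0, 0, b = 30),
    sep = "\n")
}

# minimal donor/H/acceptor geometry: explicit H on the donor N, acceptor O
# at donor-acceptor distance `da` with D-H...A angle `angle` (degrees)
hbond_pair_structure <- function(angle, da = 2.9) {
  phi <- pi - angle * pi / 180
  f <- function(r) sqrt((1.01 + r * cos(phi))^2 + (r * sin(phi))^2) - da
  r <- stats::uniroot(f, c(0.05, 10))$root
  A <- c(1.01 + r * cos(phi), r * sin(phi), 0)
  tibble::tibble(
    serial = 1:3, name = c("N", "H", "OX"), alt_loc = "",
    res_name = "GLY", chain = "A", res_seq = c(1L, 1L, 5L), i_code = "",
    x = c(0, 1.01, A[1]), y = c(0, 0, A[2]), z = 0,
    occupancy = 1, b_factor = 10, element = c("N", "H", "O"))
}

# random turn-bearing peptide with its planted truth, for plant-and-recover
random_turn_peptide <- function(seed) {
  set.seed(seed)
  types <- sample(c("I", "II", "I'", "II'"), sample(2:5, 1), replace = TRUE)
  segs <- list(seg_strand(5))
  for (ty in types) {
    segs <- c(segs, list(seg_turn(ty), seg_strand(sample(4:6, 1))))
  }
  build_peptide(segs)
}

expect_same_pass_set <- function(candidates, truth) {
  expect_setequal(paste(candidates$position, candidates$mut),
                  paste(truth$position, truth$mut))
}
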