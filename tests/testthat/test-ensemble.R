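static_ensemble <- function(n_res = 10, n_frames = 4) {
  s <- build_peptide(list(seg_strand(n_res)))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  ensemble_from_frames(s, replicate(n_frames, xyz, simplify = FALSE))
}

test_that("static and rigidly-moved ensembles have zero RMSD and RMSF", {
  ens <- static_ensemble()
  expect_equal(rmsd_series(ens)$rmsd, rep(0, 4))
  expect_equal(rmsf_profile(ens)$rmsf, rep(0, 10))
  s <- build_peptide(list(seg_strand(10)))
  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  frames <- lapply(1:4, function(k) {
    x <- as.matrix(s[, c("x", "y", "z")])
    for (j in seq_len(k - 1)) x <- x %*% t(R)
    sweep(x, 2, c(k, -2 * k, k), `+`)
  })
  ensr <- ensemble_from_frames(s, frames)
  expect_lt(max(rmsd_series(ensr)$rmsd), 1e-8)
  expect_lt(max(rmsf_profile(ensr)$rmsf), 1e-8)
})

test_that("a superposition-neutral planted displacement gives the closed-form RMSD", {
  # opposite displacements along the pair separation leave the optimal
  # rigid fit at identity: rmsd = a * sqrt(2 / n)
  s <- build_peptide(list(seg_strand(12)))
  ca <- which(s$name == "CA")
  i <- ca[3]; j <- ca[9]
  u <- unlist(s[j, c("x", "y", "z")]) - unlist(s[i, c("x", "y", "z")])
  u <- u / sqrt(sum(u^2))
  a <- 0.9
  xyz <- as.matrix(s[, c("x", "y", "z")])
  moved <- xyz
  moved[i, ] <- moved[i, ] + a * u
  moved[j, ] <- moved[j, ] - a * u
  ens <- ensemble_from_frames(s, list(xyz, moved))
  r <- rmsd_series(ens, reference = "first")
  expect_equal(r$rmsd[2], a * sqrt(2 / length(ca)), tolerance = 1e-6)
})

test_that("an oscillating residue pair recovers RMSF equal to the amplitude", {
  s <- build_peptide(list(seg_strand(12)))
  ca <- which(s$name == "CA")
  i <- ca[3]; j <- ca[9]
  u <- unlist(s[j, c("x", "y", "z")]) - unlist(s[i, c("x", "y", "z")])
  u <- u / sqrt(sum(u^2))
  a <- 0.7
  xyz <- as.matrix(s[, c("x", "y", "z")])
  frames <- lapply(1:10, function(k) {
    sgn <- if (k %% 2 == 0) 1 else -1
    m <- xyz
    m[i, ] <- m[i, ] + sgn * a * u
    m[j, ] <- m[j, ] - sgn * a * u
    m
  })
  ens <- ensemble_from_frames(s, frames)
  prof <- rmsf_profile(ens)
  expect_equal(prof$rmsf[3], a, tolerance = 1e-6)
  expect_equal(prof$rmsf[9], a, tolerance = 1e-6)
  expect_lt(max(prof$rmsf[-c(3, 9)]), 1e-6)
})

test_that("planted per-residue mobility is recovered from a long ensemble", {
  s <- build_peptide(list(seg_strand(40)))
  keys <- paste0("A:", 1:40)
  mob <- setNames(rep(0, 40), keys)
  mob[c("A:10", "A:25")] <- c(0.8, 1.5)
  ens <- build_ensemble(s, n_frames = 500, mobility = mob, seed = 7)
  prof <- rmsf_profile(ens)
  expect_equal(prof$rmsf[prof$key == "A:10"], 0.8, tolerance = 0.1)
  expect_equal(prof$rmsf[prof$key == "A:25"], 1.5, tolerance = 0.1)
})

test_that("RMSF needs at least two frames", {
  s <- build_peptide(list(seg_strand(6)))
  ens <- ensemble_from_frames(s, list(as.matrix(s[, c("x", "y", "z")])))
  expect_error(rmsf_profile(ens), "single frame")
})

test_that("DCCM is symmetric with unit diagonal and recovers planted phases", {
  s <- build_peptide(list(seg_strand(16)))
  blocks <- list(list(residues = c("A:4", "A:5"), sigma = 1, phase = c(1, 1)),
                 list(residues = c("A:11", "A:12"), sigma = 1,
                      phase = c(1, -1)))
  ens <- build_ensemble(s, n_frames = 500, mobility = rep(0.2, 16),
                        blocks = blocks, seed = 8)
  cc <- dccm(ens)
  expect_equal(unclass(cc), t(unclass(cc)), ignore_attr = TRUE)
  expect_equal(unname(diag(cc)), rep(1, 16))
  expect_true(all(abs(cc) <= 1 + 1e-12, na.rm = TRUE))
  expect_gt(cc["A:4", "A:5"], 0.9)
  expect_lt(cc["A:11", "A:12"], -0.9)
})

test_that("zero-variance residues get missing DCCM rows but others keep unit diagonal", {
  # superposition-neutral fixture: an antisymmetric pair oscillates along
  # its separation axis, so static residues keep exactly zero variance
  s <- build_peptide(list(seg_strand(12)))
  ca <- which(s$name == "CA")
  i <- ca[3]; j <- ca[9]
  u <- unlist(s[j, c("x", "y", "z")]) - unlist(s[i, c("x", "y", "z")])
  u <- u / sqrt(sum(u^2))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  frames <- lapply(1:8, function(k) {
    sgn <- if (k %% 2 == 0) 1 else -1
    m <- xyz
    m[i, ] <- m[i, ] + sgn * 0.5 * u
    m[j, ] <- m[j, ] - sgn * 0.5 * u
    m
  })
  cc <- dccm(ensemble_from_frames(s, frames))
  expect_true(all(is.na(cc[1, ])))
  expect_true(all(is.na(cc[, 12])))
  expect_equal(unname(diag(cc)[c(3, 9)]), c(1, 1))
  expect_equal(cc["A:3", "A:9"], -1, tolerance = 1e-9)
})

test_that("DCCM agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  s <- build_peptide(list(seg_strand(10)))
  mob <- seq(0.2, 1.1, length.out = 10)
  ens <- build_ensemble(s, n_frames = 300, mobility = mob, seed = 12)
  cc <- dccm(ens)
  ca <- which(ens$topology$name == "CA")
  xyz <- t(apply(ens$coords[, ca, , drop = FALSE], 1, function(m) as.vector(t(m))))
  fitted <- bio3d::fit.xyz(xyz[1, ], xyz,
                           fixed.inds = 1:ncol(xyz), mobile.inds = 1:ncol(xyz))
  theirs <- bio3d::dccm.xyz(fitted)
  expect_lt(max(abs(unclass(cc) - unclass(theirs))), 0.06)
  expect_equal(unname(diag(theirs)), unname(diag(cc)))
})

test_that("hydrogen-bond geometry criteria follow distance and angle cuts", {
  expect_equal(nrow(detect_hydrogen_bonds(hbond_pair_structure(180, 2.9))), 1)
  expect_equal(nrow(detect_hydrogen_bonds(hbond_pair_structure(100, 2.9))), 0)
  expect_equal(nrow(detect_hydrogen_bonds(hbond_pair_structure(180, 3.6))), 0)
  hb <- detect_hydrogen_bonds(hbond_pair_structure(150, 3.2))
  expect_equal(hb$donor_key, "A:1")
  expect_equal(hb$acceptor_key, "A:5")
  expect_true(hb$angle_checked)
  expect_equal(hb$angle, 150, tolerance = 1e-6)
  expect_equal(hb$distance, 3.2, tolerance = 1e-6)
})

test_that("backbone amide hydrogens are reconstructed for donor geometry", {
  # ideal helix: i -> i-4 backbone hydrogen bonds appear without explicit H
  s <- build_peptide(list(seg_helix(10)))
  hb <- detect_hydrogen_bonds(s)
  expect_gt(nrow(hb), 0)
  expect_true(all(hb$angle_checked[hb$donor_atom == "N"]))
})

test_that("hbond count series toggles with a planted on/off bond", {
  base <- hbond_pair_structure(180, 2.9)
  off <- hbond_pair_structure(180, 5.0)
  ens <- ensemble_from_frames(base, list(
    as.matrix(base[, c("x", "y", "z")]),
    as.matrix(off[, c("x", "y", "z")]),
    as.matrix(base[, c("x", "y", "z")]),
    as.matrix(off[, c("x", "y", "z")])))
  expect_equal(hbond_count_series(ens)$n_hbonds, c(1L, 0L, 1L, 0L))
  static <- static_ensemble()
  expect_equal(length(unique(hbond_count_series(static)$n_hbonds)), 1)
})

test_that("salt-bridge occupancy equals the planted frame count exactly", {
  seqv <- strrep("G", 16)
  substr(seqv, 3, 3) <- "D"
  substr(seqv, 12, 12) <- "R"
  s <- build_peptide(list(seg_strand(6), seg_turn("I"), seg_strand(6)),
                     sequence = seqv)
  set.seed(99)
  present <- sample(900, 461)
  ens <- build_ensemble(s, n_frames = 900, bond_plants = list(
    list(key_a = "A:3", atom_a = "OD2", key_b = "A:12", atom_b = "NH2",
         frames_present = present)), seed = 9)
  sb <- salt_bridge_occupancy(ens, "A:3", "A:12")
  expect_equal(sb$occupancy, 461 / 900)
  expect_equal(round(100 * sb$occupancy, 1), 51.2)
  expect_equal(which(sb$frames$present), sort(present))
  # cutoff below every distance: occupancy 0; generous cutoff: 1
  expect_equal(salt_bridge_occupancy(ens, "A:3", "A:12", d_cut = 1)$occupancy, 0)
  expect_equal(salt_bridge_occupancy(ens, "A:3", "A:12", d_cut = 10)$occupancy, 1)
  expect_error(salt_bridge_occupancy(ens, "A:1", "A:12"), "Asp/Glu")
})

test_that("the transition-temperature relation is affine with the printed anchors", {
  expect_equal(cna_temperature(-1.84), 336.8)
  expect_equal(cna_temperature(-2.76), 355.2)
  expect_equal(cna_temperature(0), 300)
  a <- runif(5, -3, 0); b <- runif(5, -3, 0)
  expect_equal(cna_temperature(a) - cna_temperature(b), -20 * (a - b))
})

test_that("the transition sits at the largest rigidity drop", {
  series <- tibble::tibble(e_cut = c(-1.0, -1.5, -1.84, -2.2),
                           p_inf = c(0.95, 0.93, 0.30, 0.10))
  tr <- find_transition(series)
  expect_equal(tr$e_cut, -1.84)
  expect_equal(tr$temperature, 336.8)
  flat <- tibble::tibble(e_cut = c(-1, -2, -3), p_inf = c(0.5, 0.5, 0.5))
  expect_message(tr2 <- find_transition(flat), "No transition")
  expect_true(is.na(tr2$e_cut))
  ties <- tibble::tibble(e_cut = c(-1, -1.5, -2, -2.5),
                         p_inf = c(0.9, 0.5, 0.5, 0.1))
  expect_equal(find_transition(ties)$e_cut, -1.5)
  expect_error(find_transition(series[1:2, ]), "at least 3")
  expect_error(find_transition(series[c(2, 1, 3), ]), "decreasing")
})

test_that("a P-infinity series file round-trips through the reader", {
  tf <- withr::local_tempfile(lines = c("e_cut\tp_inf", "-1.0\t0.95",
                                        "-1.5\t0.93", "-1.84\t0.30",
                                        "-2.2\t0.10"))
  series <- read_cna_series(tf)
  expect_equal(series$e_cut, c(-1.0, -1.5, -1.84, -2.2))
  expect_equal(find_transition(series)$temperature, 336.8)
})
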