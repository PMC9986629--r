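test_that("isolated atom SASA matches the closed form", {
  s <- parse_pdb(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"))
  got <- shrake_rupley_sasa(s)$sasa
  expect_equal(got, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.02)
})

test_that("well-separated atoms do not occlude each other", {
  txt <- paste(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
               pdb_line(2, "CA", "ALA", "A", 2, 10, 0, 0, element = "C"),
               sep = "\n")
  s <- parse_pdb(txt)
  iso <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(attr(shrake_rupley_sasa(s), "atom_sasa"),
               c(iso, iso), tolerance = 0.02)
})

test_that("an atom caged by neighbours has zero SASA, confirmed by a 3-D grid", {
  # central C atom surrounded by an octahedral cage at 3 A
  offs <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                c(0, 0, 3), c(0, 0, -3),
                c(2, 2, 0), c(-2, 2, 0), c(2, -2, 0), c(-2, -2, 0),
                c(2, 0, 2), c(-2, 0, 2), c(2, 0, -2), c(-2, 0, -2),
                c(0, 2, 2), c(0, -2, 2), c(0, 2, -2), c(0, -2, -2))
  lines <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, element = "C"),
             vapply(seq_len(nrow(offs)), function(i) {
               pdb_line(i + 1, "CA", "ALA", "A", i + 1,
                        offs[i, 1], offs[i, 2], offs[i, 3], element = "C")
             }, character(1)))
  s <- parse_pdb(paste(lines, collapse = "\n"))
  centre <- attr(shrake_rupley_sasa(s), "atom_sasa")[1]
  expect_equal(centre, 0)
  # independent cartesian-grid occupancy oracle: no accessible point on the
  # centre atom's expanded sphere survives at 0.2 A spacing
  r <- 1.70 + 1.4
  g <- seq(-r, r, by = 0.2)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  shell <- abs(sqrt(rowSums(pts^2)) - r) < 0.15
  pts <- pts[shell, ]
  occluded <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(offs))) {
    d2 <- rowSums(sweep(pts, 2, offs[i, ])^2)
    occluded <- occluded | d2 < r^2
  }
  expect_true(all(occluded))
})

test_that("adding a neighbour never increases an atom's SASA", {
  p <- build_peptide(list(seg_strand(5)))
  base <- attr(shrake_rupley_sasa(p), "atom_sasa")
  extra <- dplyr::mutate(p[3, ], serial = 99L, res_seq = 50L, x = x + 2.5)
  more <- attr(shrake_rupley_sasa(dplyr::bind_rows(p, extra)), "atom_sasa")
  expect_true(all(more[seq_along(base)] <= base + 1e-9))
})

test_that("Calpha distances follow hand-computed pair enumeration", {
  s <- parse_pdb(three_res_pdb())
  same <- ca_distance_stats(s, "A:1", "A:1")
  expect_equal(same$mean_dist, 0)
  expect_equal(same$min_dist, 0)
  txt <- paste(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
               pdb_line(2, "CA", "GLY", "A", 2, 3, 4, 0), sep = "\n")
  expect_equal(ca_distance_stats(parse_pdb(txt), "A:1", "A:2")$mean_dist, 5)
  # 4-residue turn vs 2 catalytic residues: brute-force 8-pair average
  p <- build_peptide(list(seg_strand(3), seg_turn("I"), seg_strand(3)))
  q <- paste0("A:", 4:7); r <- paste0("A:", 1:2)
  got <- ca_distance_stats(p, q, r)
  ca <- p[p$name == "CA", ]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- c()
  for (i in 4:7) for (j in 1:2) {
    d <- c(d, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  expect_equal(got$mean_dist, mean(d))
  expect_equal(got$min_dist, min(d))
  expect_equal(got$n_pairs, 8)
})

test_that("missing Calpha atoms are reported by residue", {
  s <- parse_pdb(paste(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                       pdb_line(2, "N", "GLY", "A", 2, 3, 0, 0), sep = "\n"))
  expect_error(ca_distance_stats(s, "A:1", "A:2"), "A:2")
})

test_that("superposition recovers identity and rigid transforms exactly", {
  set.seed(11)
  target <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(target, target)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mobile <- target %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(mobile, target)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(fit, mobile), target, tolerance = 1e-8)
})

test_that("superposition rmsd matches the isotropic-noise expectation", {
  # E[rmsd^2] ~ 3 sigma^2 (1 - 7/(3n)) after removing 6 rigid DOF over
  # 3n coordinates plus correction; Monte-Carlo check against simulation
  set.seed(42)
  n <- 50; sigma <- 0.3
  target <- matrix(rnorm(3 * n), n, 3) * 5
  rmsds <- vapply(1:100, function(k) {
    kabsch_superpose(target + matrix(rnorm(3 * n, 0, sigma), n, 3),
                     target)$rmsd
  }, numeric(1))
  expect_equal(mean(rmsds^2), 3 * sigma^2 * (1 - 2 / n),
               tolerance = 0.05)
})

test_that("superposition is symmetric and idempotent in rmsd", {
  set.seed(3)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, 0, 0.5), 8, 3)
  f1 <- kabsch_superpose(a, b)
  f2 <- kabsch_superpose(b, a)
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)
  moved <- apply_superposition(f1, a)
  f3 <- kabsch_superpose(moved, b)
  expect_equal(f3$rmsd, f1$rmsd, tolerance = 1e-9)
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "egenerate")
})

test_that("superposition agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  a <- matrix(rnorm(36), 12, 3)
  b <- a + matrix(rnorm(36, 0, 0.4), 12, 3)
  ours <- kabsch_superpose(a, b)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})
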