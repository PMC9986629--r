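make_screen_inputs <- function(seed = 1) {
  fx <- build_screen_fixture(seed = seed)
  ss <- assign_secondary_structure(fx$structure)
  list(fx = fx, ss = ss,
       turns = detect_beta_turns(fx$structure, ss),
       sasa = shrake_rupley_sasa(fx$structure),
       ddg = load_ddg_table(fx$ddg),
       prof = conservation_profile(
         parse_alignment(fx$msa$fasta, fx$msa$query_id)))
}

test_that("group means are plain arithmetic means of member residues", {
  s <- parse_pdb(three_res_pdb())
  ss <- assign_secondary_structure(s)   # all loop (short chain)
  sasa <- shrake_rupley_sasa(s)
  st <- flexibility_stats(s, ss, sasa, catalytic = "A:1")
  loop_mean <- st$groups$mean_b[st$groups$level == "loop"]
  expect_equal(loop_mean, mean(c(10, 20, 30)))
  # surface set {30, 40} vs buried {10}: force the partition by hand
  sasa2 <- sasa
  sasa2$surface <- c(FALSE, TRUE, TRUE)
  s2 <- dplyr::mutate(s, b_factor = dplyr::case_when(
    res_seq == 1 ~ 10, res_seq == 2 ~ 30, TRUE ~ 40))
  st2 <- flexibility_stats(s2, ss, sasa2, catalytic = "A:1")
  expect_equal(st2$groups$mean_b[st2$groups$level == "surface"], 35)
  expect_equal(st2$groups$mean_b[st2$groups$level == "buried"], 10)
})

test_that("group means equal an independent per-residue recount", {
  fx <- build_screen_fixture(seed = 4)
  s <- fx$structure
  ss <- assign_secondary_structure(s)
  sasa <- shrake_rupley_sasa(s)
  st <- flexibility_stats(s, ss, sasa, catalytic = fx$catalytic)
  pr <- st$per_residue
  for (lvl in c("helix", "sheet", "loop")) {
    members <- pr$b_factor[pr$ss == lvl]
    want <- if (length(members) == 0) NA_real_ else mean(members)
    expect_equal(st$groups$mean_b[st$groups$level == lvl], want, info = lvl)
  }
  expect_equal(st$groups$mean_b[st$groups$level == "shell"],
               mean(pr$b_factor[pr$in_shell]))
})

test_that("empty groups report missing means, not zero", {
  s <- parse_pdb(three_res_pdb())   # no helix possible
  st <- flexibility_stats(s, assign_secondary_structure(s),
                          shrake_rupley_sasa(s), catalytic = "A:1")
  expect_true(is.na(st$groups$mean_b[st$groups$level == "helix"]))
})

test_that("a saturation table over 20 positions has 380 validated records", {
  tab <- build_ddg_table(1:20, n_stable = 65, seed = 2)
  expect_equal(nrow(tab), 380)
  loaded <- load_ddg_table(tab)
  expect_equal(nrow(loaded), 380)
  expect_equal(length(unique(loaded$position)), 20)
  expect_true(all(table(loaded$position) == 19))
})

test_that("kcal tables are converted to kJ/mol", {
  txt <- "position\twild\tmut\tddg\n1\tA\tP\t1.0\n"
  tab <- load_ddg_table(txt, units = "kcal/mol")
  expect_equal(tab$ddg, 4.184)
})

test_that("wild-type mismatches and duplicates are rejected", {
  s <- parse_pdb(three_res_pdb())   # residue 1 is ALA
  expect_error(load_ddg_table("position\twild\tmut\tddg\n1\tG\tP\t-1\n",
                              structure = s), "mismatch")
  expect_silent(load_ddg_table("position\twild\tmut\tddg\n1\tA\tP\t-1\n",
                               structure = s))
  dup <- "position\twild\tmut\tddg\n1\tA\tP\t-1\n1\tA\tP\t-2\n"
  expect_error(load_ddg_table(dup), "Duplicate")
})

test_that("the ddG threshold partitions 65 stable from 315 excluded", {
  tab <- tibble::tibble(chain = "A", position = rep(1:20, each = 19),
                        wild = "G",
                        mut = rep(setdiff(c("A", "R", "N", "D", "C", "Q",
                                            "E", "G", "H", "I", "L", "K",
                                            "M", "F", "P", "S", "T", "W",
                                            "Y", "V"), "G"), 20),
                        ddg = rep(c(-1, 1), c(65, 315)))
  out <- ddg_filter(tab, threshold = -0.5)
  expect_equal(unname(attr(out, "counts")), c(65, 315))
  # boundary is inclusive on the stable side
  expect_true(ddg_filter(tibble::tibble(ddg = -0.5))$stable)
  expect_false(ddg_filter(tibble::tibble(ddg = -0.499))$stable)
  all_neg <- ddg_filter(tibble::tibble(ddg = c(-1, -2)), threshold = 0)
  expect_true(all(all_neg$stable))
})

test_that("per-residue ddG aggregation exposes min and mean policies", {
  tab <- tibble::tibble(chain = "A", position = c(1, 1, 2, 2),
                        wild = "G", mut = c("A", "P", "A", "P"),
                        ddg = c(-2, 1, 0.5, 1.5))
  expect_equal(ddg_by_residue(tab)$ddg_agg, c(-2, 0.5))
  expect_equal(ddg_by_residue(tab, "mean")$ddg_agg, c(-0.5, 1))
})

test_that("candidate selection returns exactly the planted pass set", {
  inp <- make_screen_inputs(seed = 8)
  cand <- select_candidates(inp$fx$structure, inp$ss, inp$turns, inp$sasa,
                            inp$ddg, inp$fx$catalytic,
                            conservation = inp$prof)
  expect_same_pass_set(cand, inp$fx$truth)
  expect_true(all(cand$pass))
  flags <- cand[, grep("^pass_", names(cand))]
  expect_true(all(as.matrix(flags)))
})

test_that("sites too close to the catalytic residues fail the distance filter", {
  inp <- make_screen_inputs(seed = 8)
  all_cand <- attr(
    select_candidates(inp$fx$structure, inp$ss, inp$turns, inp$sasa,
                      inp$ddg, inp$fx$catalytic, conservation = inp$prof),
    "all_candidates")
  near <- all_cand[!is.na(all_cand$mean_cat_dist) &
                     all_cand$mean_cat_dist < 13, ]
  expect_gt(nrow(near), 0)
  expect_false(any(near$pass_cat_distance))
  expect_false(any(near$pass))
})

test_that("disabling all filters returns every record, ranked", {
  inp <- make_screen_inputs(seed = 8)
  cfg <- screen_config(filters = character(0))
  cand <- select_candidates(inp$fx$structure, inp$ss, inp$turns, inp$sasa,
                            inp$ddg, inp$fx$catalytic,
                            conservation = inp$prof, config = cfg)
  expect_equal(nrow(cand), nrow(inp$ddg))
  expect_true(all(diff(cand$rank_score) <= 1e-12))
})

test_that("the filter chain is order-independent", {
  inp <- make_screen_inputs(seed = 12)
  perms <- list(
    c("loop", "surface", "turn", "cat_distance", "ddg", "conservation",
      "preference"),
    c("ddg", "conservation", "preference", "cat_distance", "turn",
      "surface", "loop"),
    c("turn", "ddg", "loop", "preference", "surface", "conservation",
      "cat_distance"))
  sets <- lapply(perms, function(p) {
    cand <- select_candidates(inp$fx$structure, inp$ss, inp$turns, inp$sasa,
                              inp$ddg, inp$fx$catalytic,
                              conservation = inp$prof,
                              config = screen_config(filters = p))
    sort(paste(cand$position, cand$mut))
  })
  expect_equal(sets[[2]], sets[[1]])
  expect_equal(sets[[3]], sets[[1]])
})

test_that("making one substitution more destabilizing lowers its rank score", {
  inp <- make_screen_inputs(seed = 8)
  base <- attr(select_candidates(inp$fx$structure, inp$ss, inp$turns,
                                 inp$sasa, inp$ddg, inp$fx$catalytic),
               "all_candidates")
  pick <- paste(base$position, base$mut)[1]
  ddg2 <- inp$ddg
  i <- which(paste(ddg2$position, ddg2$mut) == pick)
  ddg2$ddg[i] <- ddg2$ddg[i] + 1.5
  mod <- attr(select_candidates(inp$fx$structure, inp$ss, inp$turns,
                                inp$sasa, ddg2, inp$fx$catalytic),
              "all_candidates")
  expect_lt(mod$rank_score[paste(mod$position, mod$mut) == pick],
            base$rank_score[paste(base$position, base$mut) == pick])
})

test_that("an empty catalytic set with the distance filter enabled is a config error", {
  inp <- make_screen_inputs(seed = 8)
  expect_error(
    select_candidates(inp$fx$structure, inp$ss, inp$turns, inp$sasa,
                      inp$ddg, catalytic = character(0)),
    "mpty")
})

test_that("reports round-trip through tsv and json", {
  inp <- make_screen_inputs(seed = 8)
  cand <- select_candidates(inp$fx$structure, inp$ss, inp$turns, inp$sasa,
                            inp$ddg, inp$fx$catalytic,
                            conservation = inp$prof)
  tsv <- screen_report(cand, "tsv")
  back <- readr::read_tsv(I(tsv), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(cand))
  expect_equal(back$position, cand$position)
  expect_equal(back$rank_score, cand$rank_score)
  js <- screen_report(cand, "json")
  back2 <- jsonlite::fromJSON(js)
  expect_equal(back2$mutation, cand$mutation)
  # empty candidate lists give a header-only report
  empty <- cand[0, ]
  lines <- strsplit(screen_report(empty, "tsv"), "\n")[[1]]
  expect_equal(length(lines), 1)
})

test_that("unknown config keys and bad values are rejected", {
  expect_error(screen_config(filters = "bogus"), "Unknown filter")
  tf <- withr::local_tempfile(lines = c("ddg_threshold = -1.0",
                                        "min_catalytic_distance 10"))
  cfg <- read_screen_config(tf)
  expect_equal(cfg$ddg_threshold, -1)
  expect_equal(cfg$min_catalytic_distance, 10)
  tf2 <- withr::local_tempfile(lines = "nonsense_key = 5")
  expect_error(read_screen_config(tf2), "Unknown config key")
})
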