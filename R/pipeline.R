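# High-level workflow wrappers tying the modules together: the full site
# screen, ensemble analytics, and fixture-bundle simulation. These are the
# package's command surface; each writes deterministic report files.

#' Run the full flexible-site screen on input files
#'
#' Reads a structure, a ddG table and (optionally) an alignment, runs the
#' flexibility statistics, beta-turn detection and candidate selection, and
#' writes `flexibility_stats.tsv`, `turns.tsv` and `candidates.tsv` into
#' `out_dir`.
#'
#' @param pdb path to the structure (PDB).
#' @param ddg path to the ddG table (delimited text).
#' @param catalytic catalytic residues, either a character vector of keys or
#'   a single comma-separated string (`"A:168,A:276"`).
#' @param msa optional aligned-FASTA path for the conservation veto.
#' @param query_id query sequence id in the alignment.
#' @param config a [screen_config()] or path to a key-value config file.
#' @param ddg_units units of the ddG table.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `stats`, `turns`, `candidates` and the
#'   written `files`.
#' @export
run_screen <- function(pdb, ddg, catalytic, msa = NULL, query_id = "query",
                       config = screen_config(), ddg_units = "kJ/mol",
                       out_dir = ".") {
  if (is.character(config)) config <- read_screen_config(config)
  if (length(catalytic) == 1 && grepl(",", catalytic)) {
    catalytic <- trimws(strsplit(catalytic, ",")[[1]])
  }
  s <- read_pdb(pdb)
  resolve_keys(s, catalytic, what = "catalytic residue")
  ss <- assign_secondary_structure(s)
  sasa <- shrake_rupley_sasa(s, surface_threshold = config$surface_threshold)
  turns <- detect_beta_turns(s, ss)
  stats <- flexibility_stats(s, ss, sasa, catalytic,
                             shell_radius = config$shell_radius,
                             policy = config$b_factor_policy)
  tab <- load_ddg_table(ddg, structure = s, units = ddg_units)
  prof <- if (!is.null(msa)) {
    conservation_profile(parse_alignment(msa, query_id))
  } else NULL
  cands <- select_candidates(s, ss, turns, sasa, tab, catalytic,
                             conservation = prof, config = config)
  if (nrow(cands) == 0) warn("No candidate passed the filter chain.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, c("flexibility_stats.tsv", "turns.tsv",
                                "candidates.tsv"))
  readr::write_tsv(stats$groups, files[1])
  readr::write_tsv(turns, files[2])
  writeLines(screen_report(cands, "tsv"), files[3], sep = "")
  invisible(list(stats = stats, turns = turns, candidates = cands,
                 files = files))
}

#' Run ensemble analytics on a multi-model PDB
#'
#' Computes per-frame RMSD, the per-residue RMSF profile, the DCCM and the
#' hydrogen-bond count series, plus optional salt-bridge occupancies and a
#' CNA transition, writing one delimited file per series into `out_dir`.
#'
#' @param pdb path to a multi-model PDB trajectory.
#' @param out_dir output directory.
#' @param salt_bridges optional list of `c(acidic, basic)` key pairs.
#' @param cna_series optional path to a two-column (e_cut, p_inf) file.
#' @param reference RMSD reference (`"first"` or `"mean"`).
#' @return invisibly, a list of the computed tables and written `files`.
#' @export
run_ensemble <- function(pdb, out_dir = ".", salt_bridges = NULL,
                         cna_series = NULL, reference = "first") {
  ens <- read_multimodel_pdb(pdb)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rmsd <- rmsd_series(ens, reference = reference)
  rmsf <- rmsf_profile(ens)
  cc <- dccm(ens)
  hb <- hbond_count_series(ens)
  files <- file.path(out_dir, c("rmsd.tsv", "rmsf.tsv", "dccm.tsv",
                                "hbonds.tsv"))
  readr::write_tsv(rmsd, files[1])
  readr::write_tsv(as_tibble(rmsf), files[2])
  cc_df <- as_tibble(as.data.frame(unclass(cc)), rownames = "key")
  readr::write_tsv(cc_df, files[3])
  readr::write_tsv(hb, files[4])
  out <- list(rmsd = rmsd, rmsf = rmsf, dccm = cc, hbonds = hb)
  if (!is.null(salt_bridges)) {
    sb <- list_rbind(map(salt_bridges, function(p) {
      glance(salt_bridge_occupancy(ens, p[1], p[2]))
    }))
    f <- file.path(out_dir, "salt_bridges.tsv")
    readr::write_tsv(sb, f)
    files <- c(files, f)
    out$salt_bridges <- sb
  }
  if (!is.null(cna_series)) {
    tr <- find_transition(read_cna_series(cna_series))
    f <- file.path(out_dir, "cna_transition.tsv")
    readr::write_tsv(tr, f)
    files <- c(files, f)
    out$cna <- tr
  }
  out$files <- files
  invisible(out)
}

#' Simulate a complete screening fixture bundle on disk
#'
#' Writes the synthetic structure (PDB), ddG table (TSV), alignment (FASTA)
#' and the planted ground truth (JSON sidecar) for a seeded
#' [build_screen_fixture()].
#'
#' @param out_dir output directory.
#' @param seed integer RNG seed.
#' @param n_turns number of planted turns.
#' @return invisibly, the fixture list with `files` added.
#' @export
simulate_fixture_bundle <- function(out_dir, seed = 1L, n_turns = 4) {
  fx <- build_screen_fixture(seed = seed, n_turns = n_turns)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, c("structure.pdb", "ddg.tsv", "msa.fasta",
                                "truth.json"))
  write_pdb(fx$structure, path = files[1])
  readr::write_tsv(fx$ddg, files[2])
  writeLines(sub("\n$", "", fx$msa$fasta), files[3])
  jsonlite::write_json(
    list(seed = seed, catalytic = fx$catalytic,
         query_id = fx$msa$query_id, pass_set = fx$truth),
    files[4], auto_unbox = TRUE, digits = NA)
  fx$files <- files
  invisible(fx)
}
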