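# The RFS candidate-selection pipeline: B-factor flexibility statistics,
# ddG-table triage, the toggleable filter chain, ranking and reporting.

#' Screening configuration
#'
#' Central place for every threshold, weight and filter toggle of the
#' candidate screen; unknown keys are rejected.
#'
#' @param ddg_threshold ddG pass cutoff, kJ/mol (inclusive: ddg <= threshold
#'   passes). Default -0.5, the magnitude of the typical ddG calculation
#'   error, so only predictions clear of the noise band count as stabilizing.
#' @param min_catalytic_distance minimum mean Calpha distance from a turn to
#'   the catalytic residues, A. Default 13: rejected control sites sat at
#'   10.5-11.9 A while accepted sites lay farther out.
#' @param conservation_veto veto positions whose wild-type residue is
#'   conserved in at least this fraction of homologs. Default 0.80, between
#'   the <50% conservation of accepted sites and the >=92.3% of rejected
#'   ones.
#' @param shell_radius catalytic-shell radius, A (any-atom distance).
#' @param surface_threshold relative-SASA surface cut.
#' @param preference_floor minimum positional turn-preference score of the
#'   substitution (default 0 = no floor; Pro substitutions are flagged
#'   preferred regardless).
#' @param b_factor_policy per-residue B-factor reduction: `"mean"` over all
#'   atoms or `"ca"` (Calpha only).
#' @param ddg_aggregate per-residue ddG aggregation used in reporting:
#'   `"min"` over substitutions (default) or `"mean"`.
#' @param weights rank-score weights for the z-scored components
#'   (`b_factor`, `neg_ddg`, `cat_distance`, `preference`).
#' @param filters character vector of enabled filters, any of `"loop"`,
#'   `"surface"`, `"turn"`, `"cat_distance"`, `"ddg"`, `"conservation"`,
#'   `"preference"`.
#' @return a named list of class `screen_config`.
#' @export
screen_config <- function(ddg_threshold = -0.5,
                          min_catalytic_distance = 13,
                          conservation_veto = 0.80,
                          shell_radius = 5,
                          surface_threshold = 0.25,
                          preference_floor = 0,
                          b_factor_policy = c("mean", "ca"),
                          ddg_aggregate = c("min", "mean"),
                          weights = c(b_factor = 1, neg_ddg = 1,
                                      cat_distance = 1, preference = 1),
                          filters = c("loop", "surface", "turn",
                                      "cat_distance", "ddg", "conservation",
                                      "preference")) {
  b_factor_policy <- match.arg(b_factor_policy)
  ddg_aggregate <- match.arg(ddg_aggregate)
  known <- c("loop", "surface", "turn", "cat_distance", "ddg",
             "conservation", "preference")
  if (!all(filters %in% known)) {
    abort(paste0("Unknown filter(s): ",
                 paste(setdiff(filters, known), collapse = ", ")))
  }
  stopifnot(is.numeric(ddg_threshold), is.numeric(min_catalytic_distance),
            min_catalytic_distance >= 0,
            conservation_veto >= 0, conservation_veto <= 1,
            surface_threshold >= 0, shell_radius > 0)
  if (!setequal(names(weights),
                c("b_factor", "neg_ddg", "cat_distance", "preference"))) {
    abort("weights must name b_factor, neg_ddg, cat_distance, preference.")
  }
  structure(list(ddg_threshold = ddg_threshold,
                 min_catalytic_distance = min_catalytic_distance,
                 conservation_veto = conservation_veto,
                 shell_radius = shell_radius,
                 surface_threshold = surface_threshold,
                 preference_floor = preference_floor,
                 b_factor_policy = b_factor_policy,
                 ddg_aggregate = ddg_aggregate,
                 weights = weights, filters = filters),
            class = "screen_config")
}

#' Read a flat key-value screening configuration file
#'
#' Lines of the form `key value` or `key = value`; `filters` and `weights`
#' take comma-separated values. Unknown keys are rejected.
#'
#' @param path file path.
#' @return a `screen_config`.
#' @export
read_screen_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  kv <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*=?\\s*(.+)$")
  if (anyNA(kv[, 1])) abort("Malformed config line(s).")
  args <- setNames(as.list(kv[, 3]), kv[, 2])
  known <- names(formals(screen_config))
  if (!all(names(args) %in% known)) {
    abort(paste0("Unknown config key(s): ",
                 paste(setdiff(names(args), known), collapse = ", ")))
  }
  args <- imap(args, function(v, k) {
    if (k == "filters") return(trimws(strsplit(v, ",")[[1]]))
    if (k == "weights") {
      w <- as.numeric(trimws(strsplit(v, ",")[[1]]))
      return(setNames(w, c("b_factor", "neg_ddg", "cat_distance",
                           "preference")))
    }
    if (k %in% c("b_factor_policy", "ddg_aggregate")) return(v)
    as.numeric(v)
  })
  do.call(screen_config, args)
}

per_residue_bfactor <- function(structure, policy = "mean") {
  s <- if (policy == "ca") filter(structure, .data$name == "CA") else structure
  s |>
    mutate(key = residue_key(.data$chain, .data$res_seq, .data$i_code)) |>
    group_by(.data$chain, .data$res_seq, .data$i_code, .data$res_name,
             .data$key) |>
    summarise(b_factor = mean(.data$b_factor), .groups = "drop") |>
    arrange(.data$chain, .data$res_seq, .data$i_code)
}

# residues with any atom within shell_radius of any catalytic-residue atom
catalytic_shell <- function(structure, catalytic, shell_radius = 5) {
  resolve_keys(structure, catalytic)
  keys <- residue_key(structure$chain, structure$res_seq, structure$i_code)
  cat_xyz <- coord_matrix(structure[keys %in% catalytic, ])
  xyz <- coord_matrix(structure)
  d2 <- outer(rowSums(xyz^2), rowSums(cat_xyz^2), `+`) -
    2 * xyz %*% t(cat_xyz)
  near <- apply(d2 <= shell_radius^2, 1, any)
  sort(unique(keys[near]))
}

#' B-factor flexibility statistics by structural group
#'
#' Mean per-residue B-factor by secondary-structure class, by surface/buried
#' partition, and within the catalytic shell (residues with any atom within
#' `shell_radius` of any catalytic-residue atom). The per-residue B-factor is
#' the mean over that residue's atoms (or the Calpha value, per `policy`).
#' Empty groups report `NA`, never 0.
#'
#' @param structure a `pdb_structure`.
#' @param ss an [assign_secondary_structure()] result.
#' @param sasa a [shrake_rupley_sasa()] result.
#' @param catalytic character vector of catalytic residue keys.
#' @param shell_radius shell radius in Angstrom.
#' @param policy `"mean"` (all-atom) or `"ca"`.
#' @return an object of class `flexibility_stats`: `list(groups = tibble(
#'   group, level, n, mean_b), per_residue = tibble)`.
#' @export
flexibility_stats <- function(structure, ss, sasa, catalytic,
                              shell_radius = 5, policy = c("mean", "ca")) {
  policy <- match.arg(policy)
  pb <- per_residue_bfactor(structure, policy)
  pr <- pb |>
    left_join(ss |> select("key", "ss"), by = "key") |>
    left_join(sasa |> select("key", "rel_sasa", "surface"), by = "key")
  shell <- catalytic_shell(structure, catalytic, shell_radius)
  pr$in_shell <- pr$key %in% shell
  grp_mean <- function(flag) {
    if (!any(flag, na.rm = TRUE)) NA_real_ else
      mean(pr$b_factor[which(flag)])
  }
  groups <- bind_rows(
    tibble(group = "ss", level = c("helix", "sheet", "loop"),
           n = unname(vapply(c("helix", "sheet", "loop"),
                             function(k) sum(pr$ss == k, na.rm = TRUE),
                             numeric(1))),
           mean_b = unname(vapply(c("helix", "sheet", "loop"),
                                  function(k) grp_mean(pr$ss == k),
                                  numeric(1)))),
    tibble(group = "exposure", level = c("surface", "buried"),
           n = c(sum(pr$surface, na.rm = TRUE),
                 sum(!pr$surface, na.rm = TRUE)),
           mean_b = c(grp_mean(pr$surface), grp_mean(!pr$surface))),
    tibble(group = "catalytic_shell", level = "shell",
           n = sum(pr$in_shell), mean_b = grp_mean(pr$in_shell))
  )
  structure(list(groups = groups, per_residue = pr,
                 catalytic = catalytic, shell_radius = shell_radius),
            class = "flexibility_stats")
}

#' @export
print.flexibility_stats <- function(x, ...) {
  cat("<flexibility_stats>\n")
  print(x$groups)
  invisible(x)
}

#' @export
tidy.flexibility_stats <- function(x, ...) x$groups

#' Load a per-mutation ddG table from delimited text
#'
#' Expects columns `position`, `wild`, `mut`, `ddg` (an optional `chain`
#' column defaults to the structure's first chain). Values are converted to
#' kJ/mol (negative = predicted stabilizing); when a structure is supplied,
#' each row's wild-type residue is validated against it.
#'
#' @param x file path, delimited text, or a data frame.
#' @param structure optional `pdb_structure` for wild-type validation.
#' @param units `"kJ/mol"` (default) or `"kcal/mol"` (converted, 1 kcal =
#'   4.184 kJ).
#' @return a `ddg_table` tibble: `chain`, `position`, `wild`, `mut`, `ddg`
#'   (kJ/mol).
#' @export
load_ddg_table <- function(x, structure = NULL,
                           units = c("kJ/mol", "kcal/mol")) {
  units <- match.arg(units)
  df <- if (is.data.frame(x)) {
    as_tibble(x)
  } else if (length(x) == 1 && !grepl("[\n\t,]", x) && file.exists(x)) {
    readr::read_delim(x, show_col_types = FALSE)
  } else {
    readr::read_delim(I(x), show_col_types = FALSE)
  }
  need <- c("position", "wild", "mut", "ddg")
  if (!all(need %in% names(df))) {
    abort(paste0("ddG table must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (!"chain" %in% names(df)) {
    df$chain <- if (!is.null(structure)) structure$chain[1] else "A"
  }
  df <- df |>
    mutate(position = as.integer(.data$position),
           wild = toupper(.data$wild), mut = toupper(.data$mut),
           ddg = as.numeric(.data$ddg)) |>
    select("chain", "position", "wild", "mut", "ddg")
  if (units == "kcal/mol") df$ddg <- df$ddg * 4.184
  if (any(!is.finite(df$ddg))) abort("Non-finite ddG value(s).")
  if (any(df$wild == df$mut)) abort("wild and mut must differ.")
  dup <- df |> count(.data$chain, .data$position, .data$mut) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate (position, mut) row(s): ",
                 paste(paste0(dup$position, dup$mut), collapse = ", ")))
  }
  if (!is.null(structure)) {
    res <- residue_table(structure) |>
      mutate(wild_1 = aa_three_to_one(.data$res_name))
    chk <- df |>
      left_join(res |> select("chain", "res_seq", "wild_1"),
                by = c(chain = "chain", position = "res_seq"))
    bad <- which(is.na(chk$wild_1) | chk$wild_1 != chk$wild)
    if (length(bad) > 0) {
      abort(paste0("Wild-type mismatch vs structure at row(s): ",
                   paste(head(bad, 10), collapse = ", ")))
    }
  }
  class(df) <- c("ddg_table", class(df))
  df
}

#' Partition a ddG table at a stability threshold
#'
#' Predicted-stable substitutions have `ddg <= threshold` (boundary
#' inclusive; the rejected side is the strict `ddg > threshold`).
#'
#' @param table a `ddg_table` (or compatible data frame).
#' @param threshold kJ/mol.
#' @return the table with a logical `stable` column; counts attached as
#'   attribute `"counts"` (`n_stable`, `n_excluded`).
#' @export
ddg_filter <- function(table, threshold = -0.5) {
  out <- as_tibble(table) |> mutate(stable = .data$ddg <= threshold)
  attr(out, "counts") <- c(n_stable = sum(out$stable),
                           n_excluded = sum(!out$stable))
  out
}

#' Per-residue ddG aggregation
#'
#' Collapses a saturation table to one value per position (`min` over
#' substitutions by default, or `mean`), used to flag residues whose entire
#' substitution spectrum is destabilizing.
#'
#' @inheritParams ddg_filter
#' @param aggregate `"min"` or `"mean"`.
#' @return a tibble (`chain`, `position`, `wild`, `ddg_agg`).
#' @export
ddg_by_residue <- function(table, aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  fn <- if (aggregate == "min") min else mean
  as_tibble(table) |>
    group_by(.data$chain, .data$position, .data$wild) |>
    summarise(ddg_agg = fn(.data$ddg), .groups = "drop")
}

#' Select and rank candidate stabilizing mutations
#'
#' Annotates every substitution in the ddG table with its site's B-factor,
#' surface class, secondary structure, beta-turn membership and role, mean
#' Calpha distance to the catalytic residues, conservation and positional
#' turn preference, then applies the enabled filters:
#' \enumerate{
#'   \item residue lies in a loop;
#'   \item residue is on the surface;
#'   \item residue belongs to a beta-turn;
#'   \item the turn's mean Calpha distance to the catalytic residues is at
#'     least `min_catalytic_distance`;
#'   \item `ddg <= ddg_threshold`;
#'   \item conservation below `conservation_veto` (only when a profile is
#'     supplied);
#'   \item positional preference score at least `preference_floor`.
#' }
#' Candidates passing all enabled filters are ranked by a weighted sum of
#' z-scored (B-factor, -ddg, catalytic distance, preference), ties broken by
#' lower ddg, then higher B-factor, then N-to-C position.
#'
#' @param structure a `pdb_structure`.
#' @param ss an [assign_secondary_structure()] result.
#' @param turns a [detect_beta_turns()] result.
#' @param sasa a [shrake_rupley_sasa()] result.
#' @param ddg_table a [load_ddg_table()] result.
#' @param catalytic character vector of catalytic residue keys.
#' @param conservation optional [conservation_profile()]; query position n is
#'   matched to the structure's n-th residue.
#' @param config a [screen_config()].
#' @param preference_table positional preference table.
#' @return a `mutation_screen` tibble of passing candidates (rank order),
#'   with every annotation, per-filter pass flags and `rank_score`; the full
#'   annotated table (passing or not) is attached as attribute
#'   `"all_candidates"`.
#' @export
select_candidates <- function(structure, ss, turns, sasa, ddg_table,
                              catalytic, conservation = NULL,
                              config = screen_config(),
                              preference_table = turn_preference_table()) {
  if ("cat_distance" %in% config$filters && length(catalytic) == 0) {
    abort("Catalytic residue set is empty but the distance filter is enabled.")
  }
  if (length(catalytic) > 0) resolve_keys(structure, catalytic)
  res <- residue_table(structure) |>
    mutate(seq_index = dplyr::row_number())
  pb <- per_residue_bfactor(structure, config$b_factor_policy)

  cand <- as_tibble(ddg_table) |>
    mutate(key = residue_key(.data$chain, .data$position)) |>
    left_join(res |> select("key", "res_name", "seq_index"), by = "key") |>
    left_join(pb |> select("key", "b_factor"), by = "key") |>
    left_join(ss |> select("key", "ss"), by = "key") |>
    left_join(sasa |> select("key", "rel_sasa", "surface"), by = "key")
  if (anyNA(cand$seq_index)) {
    abort(paste0("ddG positions missing from structure: ",
                 paste(unique(cand$key[is.na(cand$seq_index)]),
                       collapse = ", ")))
  }

  # turn membership: first (N-to-C) turn containing the residue, preferring
  # a central (i+1/i+2) role over a flank role
  roles <- c("i", "i+1", "i+2", "i+3")
  membership <- turns |>
    tidyr::pivot_longer(cols = c("key_i", "key_i1", "key_i2", "key_i3"),
                        names_to = "slot", values_to = "key") |>
    mutate(turn_position = roles[match(.data$slot,
                                       c("key_i", "key_i1", "key_i2",
                                         "key_i3"))],
           central = .data$turn_position %in% c("i+1", "i+2")) |>
    arrange(dplyr::desc(.data$central), .data$turn) |>
    distinct(.data$key, .keep_all = TRUE) |>
    select("key", turn_index = "turn", "turn_position")
  cand <- cand |> left_join(membership, by = "key")

  # per-turn mean Calpha distance to the catalytic residues
  if (length(catalytic) > 0 && nrow(turns) > 0) {
    turn_dist <- turns |>
      rowwise() |>
      mutate(mean_cat_dist = ca_distance_stats(
        structure, c(.data$key_i, .data$key_i1, .data$key_i2, .data$key_i3),
        catalytic)$mean_dist) |>
      ungroup() |>
      select(turn_index = "turn", "mean_cat_dist")
    cand <- cand |> left_join(turn_dist, by = "turn_index")
  } else {
    cand$mean_cat_dist <- NA_real_
  }
  # residues outside any turn: their own Calpha distance
  if (length(catalytic) > 0 && any(is.na(cand$turn_index))) {
    solo <- unique(cand$key[is.na(cand$turn_index)])
    solo_d <- vapply(solo, function(k) {
      ca_distance_stats(structure, k, catalytic)$mean_dist
    }, numeric(1))
    miss <- is.na(cand$turn_index)
    cand$mean_cat_dist[miss] <- solo_d[cand$key[miss]]
  }

  cand$conservation <- if (!is.null(conservation)) {
    conservation_at(conservation, cand$seq_index)
  } else NA_real_
  cand$preference <- ifelse(
    is.na(cand$turn_position), NA_real_,
    preference_score(cand$mut,
                     ifelse(is.na(cand$turn_position), "i",
                            cand$turn_position),
                     preference_table))
  cand$pro_preferred <- cand$mut == "P"

  on_ <- function(f) f %in% config$filters
  pass_or_skip <- function(enabled, flag) if (enabled) flag else TRUE
  cand <- cand |>
    mutate(
      pass_loop = pass_or_skip(on_("loop"), .data$ss == "loop"),
      pass_surface = pass_or_skip(on_("surface"), !is.na(.data$surface) &
                                    .data$surface),
      pass_turn = pass_or_skip(on_("turn"), !is.na(.data$turn_index)),
      pass_cat_distance = pass_or_skip(
        on_("cat_distance"),
        !is.na(.data$mean_cat_dist) &
          .data$mean_cat_dist >= config$min_catalytic_distance),
      pass_ddg = pass_or_skip(on_("ddg"),
                              .data$ddg <= config$ddg_threshold),
      pass_conservation = pass_or_skip(
        on_("conservation") && !is.null(conservation),
        is.na(.data$conservation) |
          .data$conservation < config$conservation_veto),
      pass_preference = pass_or_skip(
        on_("preference"),
        is.na(.data$preference) |
          .data$preference >= config$preference_floor),
      pass = .data$pass_loop & .data$pass_surface & .data$pass_turn &
        .data$pass_cat_distance & .data$pass_ddg &
        .data$pass_conservation & .data$pass_preference
    )

  zs <- function(x) {
    x <- ifelse(is.na(x), 0, x)
    if (sd(x) < 1e-12) rep(0, length(x)) else (x - mean(x)) / sd(x)
  }
  w <- config$weights
  cand$rank_score <- w[["b_factor"]] * zs(cand$b_factor) +
    w[["neg_ddg"]] * zs(-cand$ddg) +
    w[["cat_distance"]] * zs(cand$mean_cat_dist) +
    w[["preference"]] * zs(cand$preference)

  cand <- cand |>
    arrange(dplyr::desc(.data$rank_score), .data$ddg,
            dplyr::desc(.data$b_factor), .data$seq_index, .data$mut) |>
    mutate(mutation = paste0(.data$wild, .data$position, .data$mut))
  out <- cand |> filter(.data$pass)
  attr(out, "all_candidates") <- cand
  class(out) <- c("mutation_screen", class(out))
  out
}

#' Serialize a candidate list as TSV or JSON
#'
#' One row per candidate with every annotation and flag, deterministic
#' column order, rank-sorted; round-trips through [readr::read_tsv()] /
#' [jsonlite::fromJSON()].
#'
#' @param candidates a [select_candidates()] result.
#' @param format `"tsv"` or `"json"`.
#' @return report text (single string).
#' @export
screen_report <- function(candidates, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as_tibble(candidates)
  if (format == "tsv") {
    readr::format_tsv(df)
  } else {
    jsonlite::toJSON(df, dataframe = "rows", na = "null", digits = NA,
                     pretty = TRUE) |> as.character()
  }
}
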