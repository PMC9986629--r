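# Multiple-sequence-alignment ingestion and per-column conservation
# relative to the query (structure) sequence.

new_alignment <- function(ids, seqs, query_id) {
  structure(list(ids = ids, seqs = seqs, query_id = query_id),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns (query: %s)\n",
              length(x$ids), nchar(x$seqs[1]), x$query_id))
  invisible(x)
}

#' Parse an aligned FASTA multiple sequence alignment
#'
#' Reads aligned FASTA (all sequences one length), normalizes case and
#' treats `.` as the gap character `-`.
#'
#' @param text FASTA text, a character vector of lines, or a file path.
#' @param query_id identifier of the structure's own sequence in the
#'   alignment.
#' @return an `msa_alignment` object.
#' @export
parse_alignment <- function(text, query_id) {
  path <- if (length(text) == 1 && !grepl("[>\n]", text) && file.exists(text)) {
    text
  } else {
    tf <- tempfile(fileext = ".fasta")
    writeLines(if (length(text) == 1) strsplit(text, "\n")[[1]] else text, tf)
    tf
  }
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort(paste0("Ragged alignment; offending id(s): ",
                 paste(ids[lens != median(lens)], collapse = ", ")))
  }
  if (!query_id %in% ids) abort(paste0("Query id '", query_id, "' not found in alignment."))
  if (length(ids) < 2) abort("Alignment needs the query plus at least one homolog.")
  new_alignment(ids, unname(seqs), query_id)
}

#' Per-column conservation of the query residue
#'
#' Conservation at a column is the fraction of homologs (all sequences except
#' the query) whose residue matches the query's, among homologs that are not
#' gapped at that column. Columns where the query is gapped have no query
#' position; columns where all homologs are gapped get `NA`.
#'
#' @param alignment an `msa_alignment`.
#' @return an object of class `conservation_profile`: a tibble with one row
#'   per alignment column (`column`, `query_res`, `consensus`, `n_homologs`,
#'   `conservation`) carrying the query position -> column map as attribute
#'   `"query_map"` (named integer vector).
#' @export
conservation_profile <- function(alignment) {
  qi <- which(alignment$ids == alignment$query_id)[1]
  mat <- do.call(rbind, strsplit(alignment$seqs, ""))
  q <- mat[qi, ]
  hom <- mat[-qi, , drop = FALSE]
  n_col <- ncol(mat)
  non_gap <- hom != "-"
  n_h <- colSums(non_gap)
  match_q <- colSums(non_gap & sweep(hom, 2, q, `==`))
  cons <- ifelse(n_h > 0, match_q / n_h, NA_real_)
  consensus <- vapply(seq_len(n_col), function(j) {
    v <- hom[non_gap[, j], j]
    if (length(v) == 0) NA_character_ else names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))
  prof <- tibble(column = seq_len(n_col), query_res = q,
                 consensus = consensus, n_homologs = as.integer(n_h),
                 conservation = cons)
  qpos <- which(q != "-")
  qmap <- setNames(qpos, seq_along(qpos))  # query position -> column
  structure(prof, query_map = qmap,
            class = c("conservation_profile", class(prof)))
}

#' Conservation at a 1-based query position
#'
#' @param profile a [conservation_profile()] result.
#' @param query_position 1-based position(s) in the ungapped query sequence.
#' @return conservation fraction(s); `NA` where all homologs are gapped.
#' @export
conservation_at <- function(profile, query_position) {
  qmap <- attr(profile, "query_map")
  if (any(query_position < 1 | query_position > length(qmap))) {
    abort(sprintf("Query position out of range 1..%d", length(qmap)))
  }
  profile$conservation[qmap[as.character(query_position)]]
}

#' Write a conservation profile as delimited text
#' @param profile a `conservation_profile`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_conservation_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
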