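#' Match discovered motifs to a known-motif library
#'
#' Aligns every (discovered, known) PSSM pair with [pssm_identity()] and
#' reports all pairs at or above the identity threshold, sorted by
#' identity descending - one discovered motif may therefore match several
#' transcription factors.
#'
#' @param motifs A `ucr_motif_set` (or list of [pssm()]s).
#' @param library A `motif_library` from [read_transfac()] (or built in
#'   code).
#' @param identity_threshold Minimum percent identity (default 70).
#' @param min_overlap_fraction Passed to [pssm_identity()].
#' @return Tibble with `motif`, `known_id`, `tf`, `identity`, `offset`,
#'   `orientation`.
#' @export
match_to_known <- function(motifs, library, identity_threshold = 70,
                           min_overlap_fraction = 0.75) {
  if (!nrow(library)) abort("Known-motif library is empty.")
  rows <- list()
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    pm <- if (inherits(m, "ucr_motif")) m$pssm else m
    nm <- if (inherits(m, "ucr_motif")) m$name else pm$name
    for (j in seq_len(nrow(library))) {
      al <- tryCatch(
        pssm_identity(pm, library$pssm[[j]], min_overlap_fraction),
        error = function(e) NULL
      )
      if (is.null(al) || al$identity < identity_threshold) next
      rows <- c(rows, list(tibble(
        motif = nm, known_id = library$id[[j]], tf = library$tf[[j]],
        identity = al$identity, offset = al$offset,
        orientation = al$orientation
      )))
    }
  }
  if (!length(rows)) {
    return(tibble(motif = character(), known_id = character(),
                  tf = character(), identity = numeric(), offset = integer(),
                  orientation = character()))
  }
  arrange(bind_rows(rows), desc(.data$identity))
}

#' Consensus binding-site analysis (FTZ-F1 style)
#'
#' Builds a PSSM from an IUPAC consensus (default the FTZ-F1 element
#' `YCAAGGTCR`), scans the group UCRs for sites at least
#' `threshold` percent similar to the consensus, and evaluates the
#' consensus motif's group specificity with the same three statistics used
#' for discovered motifs (Church, ROC-AUC, binomial enrichment) against
#' the universe.
#'
#' @param ucrs Universe sequence set.
#' @param group_ids Group sequence ids (subset of the universe).
#' @param threshold Percent site similarity (default 70).
#' @param consensus IUPAC consensus string (default `"YCAAGGTCR"`).
#' @param name Motif name for the report.
#' @return List with `hits` (site table over the group sequences) and
#'   `report` (one-row score tibble as in [score_motifs()]).
#' @export
ftzf1_site_analysis <- function(ucrs, group_ids, threshold = 70,
                                consensus = "YCAAGGTCR", name = consensus) {
  seqs <- as_seqset(ucrs)
  if (!all(group_ids %in% names(seqs))) {
    abort("`group_ids` must be a subset of the universe sequence ids.")
  }
  pm <- pssm_from_iupac(consensus, name = name)
  hits <- scan_pssm(pm, seqs[group_ids], threshold = threshold)
  report <- score_motifs(list(pm), group_ids, seqs,
                         scan_threshold = threshold)
  list(hits = hits, report = report)
}

#' Write site hits as BED
#'
#' Half-open, 0-based intervals; the similarity is written in the score
#' column.
#'
#' @param hits Site table from [scan_pssm()].
#' @param path Output path.
#' @param name Feature name prefix.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, name = "site") {
  width <- nchar(hits$word)
  lines <- sprintf("%s\t%d\t%d\t%s\t%.1f\t%s",
                   hits$seq_id, hits$offset, hits$offset + width,
                   paste0(name, "_", seq_len(nrow(hits))),
                   hits$similarity, hits$strand)
  writeLines(lines, path)
  invisible(path)
}
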