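#' Position-specific scoring matrices
#'
#' A `pssm` stores per-column base frequencies for a DNA motif: a 4 x width
#' matrix with rows A, C, G, T in which every column sums to 1. It is the
#' common currency of the package: motifs are discovered as PSSMs, scanned
#' against sequences as PSSMs, and compared to known transcription-factor
#' binding-site matrices as PSSMs.
#'
#' @param frequencies 4 x width numeric matrix (rows A,C,G,T), columns
#'   summing to 1.
#' @param name Motif name.
#' @param counts Optional 4 x width nonnegative count matrix the frequencies
#'   were derived from.
#' @param pseudocount Per-base pseudocount used in the derivation, if any.
#' @return An object of class `pssm`.
#' @export
pssm <- function(frequencies, name = "motif", counts = NULL, pseudocount = NA_real_) {
  frequencies <- as.matrix(frequencies)
  if (nrow(frequencies) != 4L) abort("A PSSM needs 4 rows (A, C, G, T).")
  if (ncol(frequencies) < 1L) abort("A PSSM needs at least one column.")
  if (any(frequencies < 0)) abort("PSSM frequencies must be nonnegative.")
  csums <- colSums(frequencies)
  if (any(abs(csums - 1) > 1e-9)) {
    abort("Every PSSM column must sum to 1 (tolerance 1e-9).")
  }
  rownames(frequencies) <- DNA_BASES
  colnames(frequencies) <- NULL
  structure(
    list(name = as.character(name), frequencies = frequencies,
         counts = counts, pseudocount = pseudocount),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s  (width %d, %.2f bits/column)\n",
              x$name, pssm_width(x), information_content(x)$total / pssm_width(x)))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' Width (number of columns) of a PSSM
#' @param x A `pssm`.
#' @return Integer number of columns.
#' @export
pssm_width <- function(x) ncol(x$frequencies)

#' Build a PSSM from aligned-site base counts
#'
#' Frequencies are `(count + pseudocount) / (column total + 4 * pseudocount)`.
#'
#' @param counts 4 x width (rows A,C,G,T) or width x 4 nonnegative matrix.
#' @param pseudocount Per-base additive smoothing (default 0.25).
#' @param name Motif name.
#' @return A `pssm`.
#' @export
pssm_from_counts <- function(counts, pseudocount = 0.25, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L && ncol(counts) == 4L) counts <- t(counts)
  if (nrow(counts) != 4L) abort("Counts must have 4 rows or 4 columns (A,C,G,T).")
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("Counts must be finite and nonnegative.")
  }
  tot <- colSums(counts) + 4 * pseudocount
  if (any(tot == 0)) {
    abort("All-zero count column with pseudocount 0: frequencies undefined.")
  }
  freq <- sweep(counts + pseudocount, 2, tot, "/")
  rownames(counts) <- DNA_BASES
  pssm(freq, name = name, counts = counts, pseudocount = pseudocount)
}

#' Build a PSSM from an IUPAC consensus string
#'
#' Each column is uniform over the bases the IUPAC code allows and zero
#' elsewhere, so e.g. the FTZ-F1 consensus `"YCAAGGTCR"` yields a width-9
#' matrix whose first column splits 0.5/0.5 between C and T.
#'
#' @param consensus IUPAC nucleotide string.
#' @param name Motif name (defaults to the consensus).
#' @return A `pssm`.
#' @export
pssm_from_iupac <- function(consensus, name = consensus) {
  codes <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (length(codes) == 0L) abort("Empty consensus string.")
  bad <- setdiff(codes, names(IUPAC_CODES))
  if (length(bad)) {
    abort(sprintf("Non-IUPAC character(s) in consensus: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  freq <- vapply(codes, function(cc) {
    allowed <- IUPAC_CODES[[cc]]
    v <- numeric(4)
    v[match(allowed, DNA_BASES)] <- 1 / length(allowed)
    v
  }, numeric(4))
  pssm(freq, name = name)
}

#' Build a sharply conserved PSSM around a base consensus
#'
#' Each column puts `conservation` on the consensus base and splits the
#' remainder evenly over the other three; used as the default planted motif
#' in the simulator.
#'
#' @param consensus String over A/C/G/T.
#' @param conservation Probability mass on the consensus base per column.
#' @param name Motif name.
#' @return A `pssm`.
#' @export
consensus_pssm <- function(consensus, conservation = 0.985, name = consensus) {
  bases <- encode_seq(consensus)
  if (anyNA(bases)) abort("`consensus` must be a plain A/C/G/T string.")
  if (conservation <= 0 || conservation > 1) abort("`conservation` must be in (0, 1].")
  freq <- matrix((1 - conservation) / 3, nrow = 4, ncol = length(bases))
  freq[cbind(bases, seq_along(bases))] <- conservation
  pssm(freq, name = name)
}

#' Reverse complement of a PSSM
#' @param x A `pssm`.
#' @return A `pssm` for the opposite strand.
#' @export
pssm_revcomp <- function(x) {
  f <- x$frequencies[4:1, rev(seq_len(pssm_width(x))), drop = FALSE]
  cnt <- if (!is.null(x$counts)) {
    x$counts[4:1, rev(seq_len(ncol(x$counts))), drop = FALSE]
  }
  if (!is.null(cnt)) rownames(cnt) <- DNA_BASES
  pssm(f, name = x$name, counts = cnt, pseudocount = x$pseudocount)
}

#' Majority-base consensus string of a PSSM
#' @param x A `pssm`.
#' @return Character string of per-column modal bases.
#' @export
pssm_consensus <- function(x) {
  paste0(DNA_BASES[apply(x$frequencies, 2, which.max)], collapse = "")
}

#' Information content of a PSSM
#'
#' Per column `2 + sum_b f log2 f` (with `0 log 0 = 0`), in bits.
#'
#' @param x A `pssm`.
#' @return List with `per_column` (numeric vector) and `total`.
#' @export
information_content <- function(x) {
  f <- x$frequencies
  term <- ifelse(f > 0, f * log2(f), 0)
  per_col <- 2 + colSums(term)
  list(per_column = unname(per_col), total = sum(per_col))
}

# per-column ratio matrix f / column-max, used by similarity scoring
ratio_matrix <- function(x) {
  sweep(x$frequencies, 2, apply(x$frequencies, 2, max), "/")
}

#' Percent similarity of words to a PSSM
#'
#' The similarity of a word to a PSSM is the mean, over columns, of the
#' column frequency of the observed base divided by the column maximum,
#' times 100. On a consensus-built PSSM this reads as the percentage of
#' positions whose base the consensus allows; an `N` contributes 0 at its
#' column.
#'
#' @param x A `pssm`.
#' @param word Character vector of words, each of the PSSM's width.
#' @return Numeric vector of percent similarities in `[0, 100]`.
#' @export
site_similarity <- function(x, word) {
  w <- pssm_width(x)
  if (any(nchar(word) != w)) {
    abort(sprintf("Words must match the PSSM width (%d).", w))
  }
  rat <- ratio_matrix(x)
  vapply(word, function(s) {
    b <- encode_seq(s)
    r <- rat[cbind(b, seq_len(w))]
    r[is.na(b)] <- 0
    100 * mean(r)
  }, numeric(1), USE.NAMES = FALSE)
}

# similarity of every window of an encoded sequence against `rat` (4 x w),
# N (NA) contributing 0; returns numeric vector of length L - w + 1
window_similarities <- function(enc, rat) {
  w <- ncol(rat)
  L <- length(enc)
  nwin <- L - w + 1L
  if (nwin < 1L) return(numeric(0))
  acc <- numeric(nwin)
  for (j in seq_len(w)) {
    b <- enc[j:(j + nwin - 1L)]
    r <- rat[cbind(b, rep.int(j, nwin))]
    r[is.na(b)] <- 0
    acc <- acc + r
  }
  100 * acc / w
}

#' Scan sequences for PSSM sites above a similarity threshold
#'
#' Slides the PSSM over every window of every sequence (and, by default, its
#' reverse complement) and reports windows whose [site_similarity()] meets
#' the threshold. Reverse-strand hits are reported at the forward coordinate
#' of the window start, with the matched word given in motif orientation.
#'
#' @param x A `pssm`.
#' @param sequences Named character vector of sequences, or a UCR table with
#'   `gene_id`/`sequence` columns.
#' @param threshold Minimum percent similarity in `[0, 100]` (default 70).
#' @param both_strands Scan the reverse strand too? (default `TRUE`)
#' @return Tibble with columns `seq_id`, `offset` (0-based window start),
#'   `strand`, `similarity`, `word`, sorted by sequence then offset.
#' @export
scan_pssm <- function(x, sequences, threshold = 70, both_strands = TRUE) {
  if (threshold < 0 || threshold > 100) abort("`threshold` must be in [0, 100].")
  seqs <- as_seqset(sequences)
  w <- pssm_width(x)
  rat_f <- ratio_matrix(x)
  rat_r <- ratio_matrix(pssm_revcomp(x))
  res <- imap(seqs, function(s, id) {
    enc <- encode_seq(s)
    sim_f <- window_similarities(enc, rat_f)
    if (!length(sim_f)) return(NULL)
    hit_rows <- function(keep, sim, strand) {
      if (!length(keep)) return(NULL)
      word <- substring(s, keep, keep + w - 1L)
      if (strand == "-") word <- revcomp(word)
      tibble(seq_id = id, offset = keep - 1L, strand = strand,
             similarity = sim[keep], word = word)
    }
    out <- list(hit_rows(which(sim_f >= threshold), sim_f, "+"))
    if (both_strands) {
      sim_r <- window_similarities(enc, rat_r)
      out <- c(out, list(hit_rows(which(sim_r >= threshold), sim_r, "-")))
    }
    bind_rows(out)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(seq_id = character(), offset = integer(),
                  strand = character(), similarity = numeric(),
                  word = character()))
  }
  arrange(out, match(.data$seq_id, names(seqs)), .data$offset, .data$strand)
}

#' Best scan similarity per sequence
#'
#' The per-sequence score used for ROC-AUC discrimination: the maximum
#' window similarity over both strands (0 for sequences shorter than the
#' motif).
#'
#' @inheritParams scan_pssm
#' @return Named numeric vector, one value per sequence.
#' @export
best_similarity <- function(x, sequences, both_strands = TRUE) {
  seqs <- as_seqset(sequences)
  rat_f <- ratio_matrix(x)
  rat_r <- ratio_matrix(pssm_revcomp(x))
  vapply(seqs, function(s) {
    enc <- encode_seq(s)
    sim <- window_similarities(enc, rat_f)
    if (both_strands) sim <- c(sim, window_similarities(enc, rat_r))
    if (!length(sim)) 0 else max(sim)
  }, numeric(1))
}

#' Percent identity between two PSSMs
#'
#' Per overlapping column the identity is the allele-sharing coefficient
#' `1 - 0.5 * sum_b |fa - fb|` (in `[0, 1]`); the reported identity is 100
#' times its mean over the overlap, maximised over all ungapped offsets with
#' overlap at least `max(4, ceiling(min_overlap_fraction * min(widths)))`
#' and over the reverse complement of `b`. Ties resolve to the smallest
#' offset, forward orientation first.
#'
#' @param a,b `pssm` objects.
#' @param min_overlap_fraction Minimum overlap as a fraction of the shorter
#'   motif (default 0.75).
#' @param min_overlap Absolute overlap floor in columns (default 4),
#'   guarding against spurious single-column alignments.
#' @return List with `identity` (percent), `offset` (columns of `b`'s start
#'   relative to `a`'s start) and `orientation` (`"+"` or `"-"`).
#' @export
pssm_identity <- function(a, b, min_overlap_fraction = 0.75, min_overlap = 4L) {
  wa <- pssm_width(a); wb <- pssm_width(b)
  minov <- max(min_overlap, ceiling(min_overlap_fraction * min(wa, wb)))
  offsets <- seq.int(-(wb - minov), wa - minov)
  if (min(wa, wb) < minov || length(offsets) == 0L) {
    abort("No admissible overlap between the two PSSMs.")
  }
  fa <- a$frequencies
  best <- list(identity = -Inf, offset = NA_integer_, orientation = NA_character_)
  for (ori in c("+", "-")) {
    fb <- if (ori == "+") b$frequencies else pssm_revcomp(b)$frequencies
    for (d in offsets) {
      a_cols <- seq.int(max(1L, d + 1L), min(wa, d + wb))
      if (length(a_cols) < minov) next
      b_cols <- a_cols - d
      ci <- 1 - 0.5 * colSums(abs(fa[, a_cols, drop = FALSE] -
                                    fb[, b_cols, drop = FALSE]))
      idv <- 100 * mean(ci)
      if (idv > best$identity + 1e-12) {
        best <- list(identity = idv, offset = as.integer(d), orientation = ori)
      }
    }
  }
  if (!is.finite(best$identity)) abort("No admissible overlap between the two PSSMs.")
  best
}
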