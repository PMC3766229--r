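#' Read gene models from GFF3 or BED
#'
#' Imports an annotation file and returns a gene-model table in the
#' package-wide coordinate convention: 0-based, half-open intervals with
#' strand in `{+, -}`. GFF3 input keeps `gene`-type features only (all
#' features if none are typed `gene`); BED input uses the name column as
#' the gene id. Models are sorted per contig by start.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param contig_lengths Optional named vector of contig lengths for
#'   coordinate validation.
#' @return Tibble with `gene_id`, `contig`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed"),
                            contig_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(as.character(gr$type) == "gene")) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids) || anyNA(ids)) abort("GFF3 gene features need ID attributes.")
  } else {
    ids <- gr$name
    if (is.null(ids) || anyNA(ids)) abort("BED records need a name column.")
  }
  out <- tibble(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  validate_annotation(out, contig_lengths)
}

validate_annotation <- function(annotation, contig_lengths = NULL) {
  needed <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(needed %in% names(annotation))) {
    abort(sprintf("Annotation needs columns: %s.", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(annotation$gene_id)) {
    dup <- unique(annotation$gene_id[duplicated(annotation$gene_id)])
    abort(sprintf("Duplicate gene id(s): %s.", paste(dup, collapse = ", ")))
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    abort("Gene strand must be '+' or '-'.")
  }
  if (any(annotation$start < 0 | annotation$start >= annotation$end)) {
    bad <- annotation$gene_id[annotation$start < 0 | annotation$start >= annotation$end]
    abort(sprintf("Invalid coordinates for gene(s): %s.", paste(bad, collapse = ", ")))
  }
  if (!is.null(contig_lengths)) {
    cl <- contig_lengths[annotation$contig]
    bad <- is.na(cl) | annotation$end > cl
    if (any(bad)) {
      abort(sprintf("Gene(s) outside their contig: %s.",
                    paste(annotation$gene_id[bad], collapse = ", ")))
    }
  }
  arrange(as_tibble(annotation), .data$contig, .data$start)
}

#' Extract upstream control regions (UCRs)
#'
#' For every gene, takes up to `requested_length` bases of sequence
#' immediately upstream of the gene start (5' side on the gene's strand),
#' trimmed wherever another annotated gene body - on either strand - bounds
#' the region, mirroring the rule of building 3 kb upstream databases
#' trimmed at flanking ORFs. The returned sequence reads 5' to 3' toward
#' the gene (reverse-complemented for minus-strand genes). Regions shorter
#' than `min_length` are excluded with a recorded reason.
#'
#' @param annotation Gene-model table (see [read_annotation()]).
#' @param sequences Named character vector of contig sequences (or
#'   `DNAStringSet`).
#' @param requested_length Maximum UCR length in bases (default 3000).
#' @param min_length Minimum acceptable UCR length (default 30).
#' @return Tibble with one row per gene: `gene_id`, `sequence` (`NA` when
#'   excluded), `requested_length`, `actual_length`, `trimmed_by` (the
#'   bounding neighbour's id, `NA` when the cap or the contig edge bounds
#'   the region), `contig`, `ucr_start`, `ucr_end` (0-based half-open
#'   genomic interval), `strand`, `excluded`, `reason`.
#' @export
extract_ucrs <- function(annotation, sequences, requested_length = 3000,
                         min_length = 30) {
  annotation <- validate_annotation(annotation)
  seqs <- toupper(if (inherits(sequences, "DNAStringSet")) {
    setNames(as.character(sequences), names(sequences))
  } else sequences)
  missing_contig <- setdiff(unique(annotation$contig), names(seqs))
  if (length(missing_contig)) {
    abort(sprintf("Contig(s) absent from sequences: %s.",
                  paste(missing_contig, collapse = ", ")))
  }
  rows <- map(seq_len(nrow(annotation)), function(k) {
    g <- annotation[k, ]
    contig_len <- nchar(seqs[[g$contig]])
    if (g$end > contig_len) {
      abort(sprintf("Gene %s extends past the end of contig %s.",
                    g$gene_id, g$contig))
    }
    others <- annotation[annotation$contig == g$contig &
                           annotation$gene_id != g$gene_id, ]
    if (g$strand == "+") {
      cap <- max(0L, g$start - requested_length)
      nb <- others[others$start < g$start, ]
      nb_bound <- if (nrow(nb)) max(pmin(nb$end, g$start)) else -Inf
      lo <- max(cap, nb_bound)
      hi <- g$start
      trimmed_by <- NA_character_
      if (is.finite(nb_bound) && nb_bound > cap && nb_bound > 0) {
        cand <- nb[pmin(nb$end, g$start) == nb_bound, ]
        trimmed_by <- cand$gene_id[[1]]
      }
      iv <- c(lo, hi)
    } else {
      cap <- min(contig_len, g$end + requested_length)
      nb <- others[others$end > g$end, ]
      nb_bound <- if (nrow(nb)) min(pmax(nb$start, g$end)) else Inf
      hi <- min(cap, nb_bound)
      lo <- g$end
      trimmed_by <- NA_character_
      if (is.finite(nb_bound) && nb_bound < cap && nb_bound < contig_len) {
        cand <- nb[pmax(nb$start, g$end) == nb_bound, ]
        trimmed_by <- cand$gene_id[[1]]
      }
      iv <- c(lo, hi)
    }
    len <- max(0L, iv[2] - iv[1])
    if (len < min_length) {
      return(tibble(gene_id = g$gene_id, sequence = NA_character_,
                    requested_length = requested_length, actual_length = len,
                    trimmed_by = trimmed_by, contig = g$contig,
                    ucr_start = iv[1], ucr_end = iv[2], strand = g$strand,
                    excluded = TRUE, reason = "too short"))
    }
    s <- substring(seqs[[g$contig]], iv[1] + 1L, iv[2])
    if (g$strand == "-") s <- revcomp(s)
    tibble(gene_id = g$gene_id, sequence = s,
           requested_length = requested_length, actual_length = len,
           trimmed_by = trimmed_by, contig = g$contig,
           ucr_start = iv[1], ucr_end = iv[2], strand = g$strand,
           excluded = FALSE, reason = NA_character_)
  })
  out <- bind_rows(rows)
  n_exc <- sum(out$excluded)
  if (n_exc > 0) {
    rlang::inform(sprintf("%d gene(s) excluded from the UCR database (too short).",
                          n_exc))
  }
  out
}

#' Extract the UCR of a single gene
#'
#' Convenience wrapper around [extract_ucrs()] for one gene id.
#'
#' @inheritParams extract_ucrs
#' @param gene_id Gene identifier present in `annotation`.
#' @return One-row tibble as in [extract_ucrs()].
#' @export
extract_ucr <- function(gene_id, annotation, sequences,
                        requested_length = 3000, min_length = 30) {
  if (!gene_id %in% annotation$gene_id) {
    abort(sprintf("Unknown gene id: %s.", gene_id))
  }
  all <- suppressMessages(
    extract_ucrs(annotation, sequences, requested_length, min_length)
  )
  all[all$gene_id == gene_id, ]
}

#' Write a UCR database to FASTA plus a TSV provenance sidecar
#'
#' @param ucrs UCR table from [extract_ucrs()].
#' @param fasta_path Output FASTA path (ids are gene ids; excluded genes are
#'   omitted).
#' @param tsv_path Output TSV path for the provenance columns (all genes,
#'   including exclusions).
#' @return `fasta_path`, invisibly.
#' @export
write_ucr_db <- function(ucrs, fasta_path, tsv_path = NULL) {
  keep <- ucrs[!ucrs$excluded, ]
  write_fasta(setNames(keep$sequence, keep$gene_id), fasta_path)
  if (!is.null(tsv_path)) {
    utils::write.table(
      ucrs[, setdiff(names(ucrs), "sequence")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(fasta_path)
}
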