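#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter group_by left_join mutate n
#'   rename select summarise ungroup desc distinct pull
#' @importFrom purrr map map_chr map_dbl map_int map_lgl map2 pmap imap
#' @importFrom stats rbinom runif setNames phyper pbinom
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> allowed bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Run an expression with a private, seeded RNG stream
#'
#' Saves and restores the global `.Random.seed`, so package operations never
#' leak random state into the caller's session. Every randomised operation in
#' the package takes an explicit `seed` and routes through this helper.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed so nested seeded operations stay independent.
# Double arithmetic: exact below 2^53, and the result stays below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483587)
}

# encode "ACGT..." -> integer vector in 1:4, N/other -> NA
encode_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  out <- match(v, DNA_BASES)
  out
}

decode_seq <- function(ints) {
  v <- DNA_BASES[ints]
  v[is.na(ints)] <- "N"
  paste0(v, collapse = "")
}

revcomp <- function(x) {
  stringr::str_to_upper(x) |>
    chartr(old = "ACGTN", new = "TGCAN") |>
    vapply(function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", toupper(x))
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}.", what))
  }
  invisible(x)
}

# Coerce a UCR table / named character vector / DNAStringSet to a named
# character vector of sequences.
as_seqset <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.data.frame(x)) {
    if (!all(c("gene_id", "sequence") %in% names(x))) {
      abort("A sequence table needs `gene_id` and `sequence` columns.")
    }
    keep <- !is.na(x$sequence)
    out <- setNames(x$sequence[keep], x$gene_id[keep])
  } else if (is.character(x)) {
    if (is.null(names(x))) abort("Character sequence sets must be named.")
    out <- x
  } else {
    abort("Cannot interpret this object as a set of sequences.")
  }
  if (anyDuplicated(names(out))) abort("Duplicate sequence ids.")
  toupper(out)
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences, or a tibble with `gene_id`
#'   and `sequence` columns (e.g. a UCR table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- as_seqset(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
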