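# shared fixtures, all built in code under fixed seeds

# n random sequences of length len at uniform composition
rand_seqs <- function(n, len, seed = 1, prefix = "s") {
  withr::with_seed(seed, {
    setNames(
      vapply(seq_len(n), function(i) {
        paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      }, character(1)),
      paste0(prefix, seq_len(n))
    )
  })
}

# small deterministic genome used by several UCR tests
toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    contig = "chr1",
    start = c(1000L, 4000L, 6000L, 9500L),
    end = c(2800L, 4500L, 7000L, 9900L),
    strand = c("+", "+", "-", "-")
  )
}

toy_contig <- function(len = 12000, seed = 99) {
  rand_seqs(1, len, seed = seed, prefix = "chr")["chr1"] |>
    setNames("chr1")
}

# independent interval oracle for UCR extraction (plain loops, no package
# internals)
ucr_interval_oracle <- function(gene, annotation, contig_len, requested = 3000) {
  others <- annotation[annotation$gene_id != gene$gene_id &
                         annotation$contig == gene$contig, ]
  if (gene$strand == "+") {
    lo <- max(0, gene$start - requested)
    for (j in seq_len(nrow(others))) {
      o <- others[j, ]
      if (o$start < gene$start) lo <- max(lo, min(o$end, gene$start))
    }
    c(lo, gene$start)
  } else {
    hi <- min(contig_len, gene$end + requested)
    for (j in seq_len(nrow(others))) {
      o <- others[j, ]
      if (o$end > gene$end) hi <- min(hi, max(o$start, gene$end))
    }
    c(gene$end, hi)
  }
}

# brute-force percent-similarity scan oracle
scan_oracle <- function(pssm_obj, seq, threshold) {
  w <- ucrmotifs::pssm_width(pssm_obj)
  L <- nchar(seq)
  hits <- list()
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  if (L >= w) {
    for (i in seq_len(L - w + 1)) {
      word <- substr(seq, i, i + w - 1)
      for (strand in c("+", "-")) {
        word2 <- if (strand == "+") word else rc(word)
        sim <- ucrmotifs::site_similarity(pssm_obj, word2)
        if (sim >= threshold) {
          hits <- c(hits, list(data.frame(offset = i - 1L, strand = strand,
                                          similarity = sim)))
        }
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(), strand = character(), similarity = numeric())
}

# exhaustive hypergeometric upper-tail oracle
church_oracle <- function(x, s, X, N) {
  ks <- x:min(X, s)
  sum(choose(X, ks) * choose(N - X, s - ks)) / choose(N, s)
}

# direct binomial upper-tail oracle
enrichment_oracle <- function(x, s, X, N) {
  p <- X / N
  ks <- x:s
  sum(choose(s, ks) * p^ks * (1 - p)^(s - ks))
}

# O(n1*n2) pairwise AUC oracle
auc_oracle <- function(g, b) {
  wins <- 0
  for (gi in g) for (bi in b) {
    wins <- wins + if (gi > bi) 1 else if (gi == bi) 0.5 else 0
  }
  wins / (length(g) * length(b))
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  v <- strsplit(s, "")[[1]]
  table(paste0(v[-length(v)], v[-1]))
}
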