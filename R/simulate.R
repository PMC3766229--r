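#' Simulation configuration
#'
#' Collects every parameter of the synthetic-genome generator. Defaults are
#' the package's benchmark study conditions: a 200-gene contig whose
#' intergenic spacing yields ~400 bp upstream control regions, an order-1
#' Markov background at uniform composition, a sharply conserved 8-column
#' planted motif (1.86 bits/column), a 10% "upregulated" foreground at 0.9
#' per-sequence occupancy, and 5 decoy library motifs.
#'
#' @param seed Integer seed; fully determines all simulator output.
#' @param n_genes Number of genes.
#' @param contig_length Contig length in bases.
#' @param gene_length_range Length-2 integer vector, uniform gene-length
#'   bounds.
#' @param intergenic Named list describing the intergenic-spacing
#'   distribution: `list(dist = "fixed", length =)`,
#'   `list(dist = "uniform", min =, max =)` or
#'   `list(dist = "gamma", shape =, rate =)` (values rounded to bases).
#' @param background_order Markov order of the background: 0, 1 or 2.
#' @param base_composition Length-4 probability vector over A,C,G,T.
#' @param planted_motif A [pssm()] to plant in foreground UCRs.
#' @param foreground_fraction Fraction of genes in the upregulated group.
#' @param occupancy Probability a foreground UCR carries a planted
#'   instance.
#' @param decoy_motif_count Number of decoy motifs for the synthetic
#'   library.
#' @param ucr_length Upstream window (bases) used when planting and, by
#'   convention, when extracting the benchmark UCR database.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 200,
                              contig_length = 300000,
                              gene_length_range = c(300, 600),
                              intergenic = list(dist = "uniform", min = 420, max = 520),
                              background_order = 1,
                              base_composition = rep(0.25, 4),
                              planted_motif = consensus_pssm("TTGACCGA",
                                                             conservation = 0.985,
                                                             name = "planted"),
                              foreground_fraction = 0.1,
                              occupancy = 0.9,
                              decoy_motif_count = 5,
                              ucr_length = 400) {
  if (abs(sum(base_composition) - 1) > 1e-9 || any(base_composition < 0)) {
    abort("`base_composition` must be a nonnegative 4-vector summing to 1.")
  }
  if (occupancy < 0 || occupancy > 1) abort("`occupancy` must be in [0, 1].")
  if (foreground_fraction < 0 || foreground_fraction > 1) {
    abort("`foreground_fraction` must be in [0, 1].")
  }
  if (!background_order %in% 0:2) abort("`background_order` must be 0, 1 or 2.")
  if (n_genes < 0) abort("`n_genes` must be nonnegative.")
  if (!is.null(planted_motif)) stopifnot(inherits(planted_motif, "pssm"))
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         contig_length = as.integer(contig_length),
         gene_length_range = as.integer(gene_length_range),
         intergenic = intergenic, background_order = background_order,
         base_composition = base_composition, planted_motif = planted_motif,
         foreground_fraction = foreground_fraction, occupancy = occupancy,
         decoy_motif_count = as.integer(decoy_motif_count),
         ucr_length = as.integer(ucr_length)),
    class = "simulation_config"
  )
}

# draw n intergenic spacings (in bases)
draw_spacings <- function(n, spec) {
  if (n == 0L) return(integer(0))
  out <- switch(
    spec$dist,
    fixed = rep(spec$length, n),
    uniform = round(runif(n, spec$min, spec$max)),
    gamma = round(stats::rgamma(n, shape = spec$shape, rate = spec$rate)),
    abort(sprintf("Unknown intergenic distribution `%s`.", spec$dist))
  )
  as.integer(pmax(out, 0))
}

# Markov background sequence with exact stationary composition `p`.
# Order 1/2 mix an identity ("copy previous base") component with iid draws
# from p, which keeps the stationary distribution equal to p while adding
# short-range autocorrelation.
markov_seq <- function(n, order, p, copy1 = 0.2, copy2 = 0.05) {
  if (n == 0L) return("")
  iid <- sample.int(4L, n, replace = TRUE, prob = p)
  if (order == 0) return(decode_seq(iid))
  if (order == 1) {
    u <- runif(n)
    keep <- u >= copy1
    keep[1] <- TRUE
    src <- cummax(seq_len(n) * keep)
    return(decode_seq(iid[src]))
  }
  # order 2: copy previous base w.p. copy1, base before that w.p. copy2
  out <- integer(n)
  u <- runif(n)
  out[1] <- iid[1]
  if (n >= 2) out[2] <- if (u[2] < copy1) out[1] else iid[2]
  for (t in 3:n) {
    out[t] <- if (u[t] < copy1) out[t - 1L]
    else if (u[t] < copy1 + copy2) out[t - 2L]
    else iid[t]
  }
  decode_seq(out)
}

#' Simulate a genome with gene models, categories and ground truth
#'
#' Lays out non-overlapping genes (random strands) separated by spacings
#' drawn from the configured distribution, on a background sequence from
#' the configured Markov model. A `foreground_fraction` of the genes is
#' marked as the upregulated group and split between the `CP` and `muscle`
#' categories (the rest are `other`). Planting motif instances is a
#' separate, composable step: see [plant_motifs()].
#'
#' @param config A [simulation_config()].
#' @return List with `sequences` (named character, one contig),
#'   `annotation` (gene-model tibble) and `truth` (list with
#'   `foreground_genes`, `category_map` tibble, and an empty `planted`
#'   table).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_rng(config$seed, {
    n <- config$n_genes
    glen <- if (n) round(runif(n, config$gene_length_range[1],
                               config$gene_length_range[2])) else integer(0)
    gaps <- draw_spacings(n, config$intergenic)
    need <- sum(glen) + sum(gaps)
    if (need > config$contig_length) {
      abort(sprintf(
        "Infeasible packing: genes + intergenic need %d bases but the contig has %d (short by %d).",
        need, config$contig_length, need - config$contig_length))
    }
    starts <- integer(n); ends <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + glen[i]
      ends[i] <- pos
    }
    strand <- if (n) sample(c("+", "-"), n, replace = TRUE) else character(0)
    if (n >= 2L && length(unique(strand)) == 1L) {
      strand[2] <- setdiff(c("+", "-"), strand[1])  # keep both strands present
    }
    annotation <- tibble(
      gene_id = if (n) sprintf("g%03d", seq_len(n)) else character(0),
      contig = rep("contig_1", n),
      start = starts, end = ends, strand = strand
    )
    contig <- markov_seq(config$contig_length, config$background_order,
                         config$base_composition)
    n_fg <- round(n * config$foreground_fraction)
    fg <- if (n_fg) sort(sample(annotation$gene_id, n_fg)) else character(0)
    category <- rep("other", n)
    if (n_fg) {
      half <- ceiling(n_fg / 2)
      category[match(fg[seq_len(half)], annotation$gene_id)] <- "CP"
      if (n_fg > half) {
        category[match(fg[(half + 1):n_fg], annotation$gene_id)] <- "muscle"
      }
    }
    truth <- list(
      foreground_genes = fg,
      category_map = tibble(gene_id = annotation$gene_id, category = category),
      planted = tibble(gene_id = character(), ucr_offset = integer(),
                       strand = character(), word = character())
    )
    list(sequences = c(contig_1 = contig), annotation = annotation,
         truth = truth)
  })
}

#' Plant motif instances in foreground upstream regions
#'
#' Each foreground gene's upstream window (the UCR it will yield under
#' [extract_ucrs()] at `ucr_length`) receives, with probability
#' `occupancy`, one instance sampled from the motif PSSM at a uniform
#' offset and uniform strand. Instances are written into the genome
#' sequence and recorded in the ground truth in UCR coordinates, so
#' mapping them through UCR extraction recovers the planted word exactly.
#' Foreground genes whose upstream window is shorter than the motif are
#' skipped with a warning.
#'
#' @param sequences Named character vector of contigs.
#' @param annotation Gene-model tibble.
#' @param truth Ground-truth list from [simulate_genome()].
#' @param motif A [pssm()] to plant.
#' @param occupancy Per-gene planting probability.
#' @param seed Integer seed.
#' @param ucr_length Upstream window length used for planting.
#' @param genes Genes to plant into (default: the foreground set).
#' @return List with updated `sequences` and `truth`.
#' @export
plant_motifs <- function(sequences, annotation, truth, motif, occupancy,
                         seed, ucr_length = 400, genes = NULL) {
  stopifnot(inherits(motif, "pssm"))
  if (occupancy < 0 || occupancy > 1) abort("`occupancy` must be in [0, 1].")
  w <- pssm_width(motif)
  genes <- genes %||% truth$foreground_genes
  ivs <- suppressMessages(
    extract_ucrs(annotation, sequences, requested_length = ucr_length,
                 min_length = 1)
  )
  ivs <- ivs[match(genes, ivs$gene_id), ]
  planted <- list()
  with_rng(seed, {
    for (k in seq_along(genes)) {
      if (runif(1) > occupancy) next
      iv <- ivs[k, ]
      len <- iv$actual_length
      if (is.na(len) || len < w) {
        warn(sprintf("No valid offset for motif in UCR of gene %s; skipped.",
                     iv$gene_id))
        next
      }
      off <- sample.int(len - w + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      word <- sample_pssm_word(motif)
      ucr_sub <- if (strand == "+") word else revcomp(word)
      ctg <- iv$contig
      s <- sequences[[ctg]]
      if (iv$strand == "+") {
        gpos <- iv$ucr_start + off           # 0-based genomic start
        gseg <- ucr_sub
      } else {
        gpos <- iv$ucr_end - off - w
        gseg <- revcomp(ucr_sub)
      }
      substr(s, gpos + 1L, gpos + w) <- gseg
      sequences[[ctg]] <- s
      planted <- c(planted, list(tibble(
        gene_id = iv$gene_id, ucr_offset = as.integer(off), strand = strand,
        word = word
      )))
    }
  })
  truth$planted <- bind_rows(truth$planted, bind_rows(planted))
  list(sequences = sequences, truth = truth)
}

# one word sampled column-wise from a PSSM
sample_pssm_word <- function(motif) {
  f <- motif$frequencies
  b <- vapply(seq_len(ncol(f)), function(j) {
    sample.int(4L, 1L, prob = f[, j])
  }, integer(1))
  decode_seq(b)
}

#' Random decoy PSSM
#'
#' A sharply conserved motif around a random consensus, with per-column
#' conservation drawn uniformly in `[0.9, 0.99]` (1.4-1.9 bits/column) -
#' the decoy class used for the synthetic known-motif library.
#'
#' @param width Motif width.
#' @param seed Integer seed.
#' @param name Motif name.
#' @return A [pssm()].
#' @export
random_decoy_pssm <- function(width, seed, name = "decoy") {
  with_rng(seed, {
    cons <- decode_seq(sample.int(4L, width, replace = TRUE))
    consensus_pssm(cons, conservation = runif(1, 0.9, 0.99), name = name)
  })
}

#' Simulate a complete benchmark study
#'
#' Composes [simulate_genome()], [plant_motifs()] and [extract_ucrs()] into
#' the package's benchmark: a genome with a planted motif in its foreground
#' UCRs, the extracted UCR database, the upregulated group ids, and a
#' synthetic known-motif library holding the planted motif plus decoys.
#'
#' @param config A [simulation_config()].
#' @return List with `ucrs` (UCR tibble, excluded genes dropped),
#'   `group_ids`, `category_map`, `truth`, `library` (a `motif_library`
#'   tibble), `annotation` and `sequences`.
#' @export
simulate_motif_study <- function(config = simulation_config()) {
  g <- simulate_genome(config)
  if (!is.null(config$planted_motif) && config$occupancy > 0 &&
      length(g$truth$foreground_genes)) {
    pl <- plant_motifs(g$sequences, g$annotation, g$truth,
                       motif = config$planted_motif,
                       occupancy = config$occupancy,
                       seed = child_seed(config$seed, 101L),
                       ucr_length = config$ucr_length)
    g$sequences <- pl$sequences
    g$truth <- pl$truth
  }
  ucrs <- suppressMessages(
    extract_ucrs(g$annotation, g$sequences,
                 requested_length = config$ucr_length)
  )
  ucrs <- ucrs[!ucrs$excluded, ]
  decoys <- map(seq_len(config$decoy_motif_count), function(k) {
    random_decoy_pssm(8, seed = child_seed(config$seed, 200L + k),
                      name = sprintf("decoy_%d", k))
  })
  lib_motifs <- c(list(config$planted_motif), decoys)
  lib <- tibble(
    accession = sprintf("M%04d", seq_along(lib_motifs)),
    id = vapply(lib_motifs, function(m) m$name, character(1)),
    tf = c("PlantedTF", sprintf("DecoyTF_%d", seq_len(config$decoy_motif_count))),
    pssm = lib_motifs
  )
  class(lib) <- c("motif_library", class(lib))
  list(ucrs = ucrs, group_ids = g$truth$foreground_genes,
       category_map = g$truth$category_map, truth = g$truth,
       library = lib, annotation = g$annotation, sequences = g$sequences)
}

#' Write simulator output to standard formats
#'
#' FASTA for the contigs, GFF3 for the gene models and TSV tables for the
#' ground truth and category map.
#'
#' @param genome List from [simulate_genome()] (or [simulate_motif_study()],
#'   which carries the same components).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome$sequences, file.path(dir, "genome.fasta"))
  ann <- genome$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand, ID = ann$gene_id, type = "gene", source = "ucrmotifs"
  )
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "GFF3")
  utils::write.table(genome$truth$category_map, file.path(dir, "categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genome$truth$planted, file.path(dir, "planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
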