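#' Build a bipartite motif-gene regulatory network
#'
#' One edge per (motif, gene) pair with at least one site hit in the
#' gene's UCR, annotated with the occurrence count and best similarity;
#' motif nodes carry their matched transcription factors, gene nodes their
#' category (`CP`, `muscle`, `other`). Genes without any hit are not part
#' of the graph.
#'
#' @param hits Site table: scan results for the retained motifs, with a
#'   `motif` column added (see [scan_retained()]).
#' @param category_map Tibble with `gene_id`, `category`.
#' @param matches Optional TF match table from [match_to_known()].
#' @return A `regulatory_network`: list of tibbles `motifs`, `genes`,
#'   `edges`.
#' @export
build_network <- function(hits, category_map, matches = NULL) {
  if (!all(c("motif", "seq_id", "similarity") %in% names(hits))) {
    abort("`hits` needs columns motif, seq_id, similarity.")
  }
  unknown <- setdiff(unique(hits$seq_id), category_map$gene_id)
  if (length(unknown)) {
    abort(sprintf("Hit(s) reference unknown gene(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  edges <- if (nrow(hits)) {
    hits |>
      group_by(motif = .data$motif, gene_id = .data$seq_id) |>
      summarise(n_occurrences = dplyr::n(),
                best_similarity = max(.data$similarity), .groups = "drop") |>
      arrange(.data$motif, .data$gene_id)
  } else {
    tibble(motif = character(), gene_id = character(),
           n_occurrences = integer(), best_similarity = numeric())
  }
  motif_nodes <- tibble(motif = sort(unique(edges$motif)))
  if (!is.null(matches) && nrow(matches)) {
    tfs <- matches |>
      group_by(motif = .data$motif) |>
      summarise(tfs = paste(unique(.data$tf), collapse = ","), .groups = "drop")
    motif_nodes <- left_join(motif_nodes, tfs, by = "motif")
  } else {
    motif_nodes$tfs <- NA_character_
  }
  gene_nodes <- tibble(gene_id = sort(unique(edges$gene_id))) |>
    left_join(category_map, by = "gene_id")
  structure(list(motifs = motif_nodes, genes = gene_nodes, edges = edges),
            class = "regulatory_network")
}

#' Scan a UCR set with a set of retained motifs
#'
#' Convenience step between [filter_cascade()] and [build_network()]:
#' scans every retained motif over the given UCRs and stacks the hits with
#' a `motif` column.
#'
#' @param motifs A `ucr_motif_set`.
#' @param ucrs Sequence set to scan (typically the group UCRs).
#' @param threshold Percent similarity for a hit (same default as scoring
#'   presence, 88).
#' @return Site-hit tibble with a leading `motif` column.
#' @export
scan_retained <- function(motifs, ucrs, threshold = 88) {
  rows <- map(seq_along(motifs), function(k) {
    m <- motifs[[k]]
    pm <- if (inherits(m, "ucr_motif")) m$pssm else m
    nm <- if (inherits(m, "ucr_motif")) m$name else pm$name
    h <- scan_pssm(pm, ucrs, threshold = threshold)
    if (nrow(h)) mutate(h, motif = nm, .before = 1) else NULL
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(motif = character(), seq_id = character(),
                  offset = integer(), strand = character(),
                  similarity = numeric(), word = character())
  }
  out
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d motif(s), %d gene(s), %d edge(s)\n",
              nrow(x$motifs), nrow(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Motifs shared between two gene categories
#'
#' Motifs adjacent to at least one gene of each category - the predicate
#' behind a co-regulation network restricted to motifs found in both the
#' cuticular-protein and muscle gene sets - sorted by total degree
#' descending.
#'
#' @param network A `regulatory_network`.
#' @param category_a,category_b Category labels (defaults `"CP"`,
#'   `"muscle"`).
#' @return Character vector of motif names.
#' @export
shared_motifs <- function(network, category_a = "CP", category_b = "muscle") {
  cats <- unique(network$genes$category)
  missing <- setdiff(c(category_a, category_b), unique(c(cats, "CP", "muscle", "other")))
  if (length(missing)) {
    abort(sprintf("Unknown category label(s): %s.", paste(missing, collapse = ", ")))
  }
  e <- left_join(network$edges, network$genes, by = "gene_id")
  deg <- e |> group_by(.data$motif) |>
    summarise(degree = dplyr::n(),
              in_a = any(.data$category == category_a),
              in_b = any(.data$category == category_b), .groups = "drop")
  deg |>
    filter(.data$in_a & .data$in_b) |>
    arrange(desc(.data$degree), .data$motif) |>
    pull("motif")
}

#' Convert a regulatory network to an igraph graph
#'
#' @param network A `regulatory_network`.
#' @return A bipartite `igraph` graph with node attributes `kind`,
#'   `category`, `tfs` and edge attributes `n_occurrences`,
#'   `best_similarity`.
#' @export
as_igraph <- function(network) {
  nodes <- bind_rows(
    tibble(name = network$motifs$motif, kind = "motif",
           category = NA_character_,
           tfs = network$motifs$tfs %||% NA_character_),
    tibble(name = network$genes$gene_id, kind = "gene",
           category = network$genes$category, tfs = NA_character_)
  )
  nodes$tfs[is.na(nodes$tfs)] <- ""
  nodes$category[is.na(nodes$category)] <- ""
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$motif, to = network$edges$gene_id,
                   n_occurrences = network$edges$n_occurrences,
                   best_similarity = network$edges$best_similarity),
    directed = TRUE, vertices = as.data.frame(nodes)
  )
  igraph::V(g)$type <- igraph::V(g)$kind == "gene"
  g
}

#' Export a regulatory network
#'
#' GraphML (typed node/edge attributes, via igraph) or a TSV edge list
#' with the same columns. A GraphML export re-imports to an isomorphic
#' graph with equal attributes.
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort("Unknown export format."))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    edges <- network$edges |>
      left_join(network$genes, by = "gene_id") |>
      left_join(network$motifs, by = "motif")
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
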