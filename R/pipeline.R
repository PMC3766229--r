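#' Run the full motif pipeline on a grouped UCR database
#'
#' Composes the package end to end: de novo discovery on the group UCRs
#' ([gibbs_discover()]), Monte-Carlo significance
#' ([empirical_significance()]), specificity scoring of the group against
#' the universe ([score_motifs()]), the two-stage [filter_cascade()], TF
#' matching of the retained motifs ([match_to_known()]), and the bipartite
#' co-regulation network over gene categories ([build_network()]).
#'
#' @param ucrs Universe UCR set (tibble from [extract_ucrs()] or named
#'   character vector).
#' @param group_ids Ids of the upregulated group (subset of `ucrs`).
#' @param category_map Tibble `gene_id`, `category`.
#' @param library Optional `motif_library` for TF matching.
#' @param width Motif width (default 8).
#' @param seed Integer seed.
#' @param n_restarts,iterations Sampler effort for discovery.
#' @param n_shuffles Null sets for the significance proxy (default 19).
#' @param null_restarts,null_iterations Sampler effort per null set.
#' @param scan_threshold Presence threshold for scoring and network edges.
#' @param identity_threshold TF-match identity threshold (default 70).
#' @param config A [filter_config()].
#' @return List with `motifs`, `reports`, `retained` (`ucr_motif_set`),
#'   `matches`, `network`, `shared`.
#' @export
run_motif_pipeline <- function(ucrs, group_ids, category_map, library = NULL,
                               width = 8, seed = 1, n_restarts = 6,
                               iterations = 400, n_shuffles = 19,
                               null_restarts = 2, null_iterations = 150,
                               scan_threshold = 88, identity_threshold = 70,
                               config = filter_config()) {
  seqs <- as_seqset(ucrs)
  group <- seqs[group_ids]
  motifs <- gibbs_discover(group, width = width, n_restarts = n_restarts,
                           iterations = iterations, seed = seed)
  null_map <- if (length(motifs)) {
    null_map_distribution(group, width, n_shuffles = n_shuffles,
                          seed = child_seed(seed, 500L),
                          n_restarts = null_restarts,
                          iterations = null_iterations)
  }
  motifs <- motif_set(map(seq_along(motifs), function(k) {
    m <- motifs[[k]]
    sig <- empirical_significance(m, group, null_map = null_map)
    m$evalue_proxy <- sig$proxy
    m$proxy_floor <- sig$floor
    m
  }))
  reports <- if (length(motifs)) {
    filter_cascade(score_motifs(motifs, group_ids, seqs,
                                scan_threshold = scan_threshold), config)
  } else {
    tibble()
  }
  retained <- if (length(motifs)) motifs[reports$retained] else motif_set()
  matches <- if (!is.null(library) && length(retained)) {
    match_to_known(retained, library, identity_threshold = identity_threshold)
  } else {
    NULL
  }
  hits <- scan_retained(retained, group, threshold = scan_threshold)
  network <- build_network(hits, category_map, matches)
  shared <- shared_motifs(network)
  list(motifs = motifs, reports = reports, retained = retained,
       matches = matches, network = network, shared = shared)
}
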