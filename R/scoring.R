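#' Motif presence counts in a group and its universe
#'
#' Presence means at least one [scan_pssm()] hit at `scan_threshold` in a
#' sequence; counts are per sequence, never per occurrence. `x` of the `s`
#' group sequences and `X` of the `N` universe sequences carry the motif.
#'
#' @param motif A [pssm()] or `ucr_motif`.
#' @param group_ids Ids of the group sequences (must be a subset of the
#'   universe).
#' @param ucrs Universe sequence set.
#' @param scan_threshold Percent similarity for a hit (default 88; see the
#'   methods vignette for why presence calls are stricter than the 70%
#'   consensus-site threshold).
#' @return List with `x`, `s`, `X`, `N`.
#' @export
presence_counts <- function(motif, group_ids, ucrs, scan_threshold = 88) {
  if (inherits(motif, "ucr_motif")) motif <- motif$pssm
  seqs <- as_seqset(ucrs)
  if (!all(group_ids %in% names(seqs))) {
    abort("`group_ids` must be a subset of the universe sequence ids.")
  }
  best <- best_similarity(motif, seqs)
  present <- best >= scan_threshold
  list(x = sum(present[group_ids]), s = length(group_ids),
       X = sum(present), N = length(seqs))
}

check_counts <- function(x, s, X, N) {
  if (any(c(x, s, X, N) < 0) || s > N || X > N || x > min(X, s)) {
    abort("Invalid presence counts: need 0 <= x <= min(X, s) and s, X <= N.")
  }
}

#' Church group-specificity score
#'
#' The hypergeometric upper tail `P(K >= x)` for
#' `K ~ Hypergeom(N, X, s)`: the probability that a motif present in `X`
#' of `N` universe sequences shows up in at least `x` of an `s`-sequence
#' group by chance.
#'
#' @param x Group sequences with the motif.
#' @param s Group size.
#' @param X Universe sequences with the motif.
#' @param N Universe size.
#' @return Probability in `[0, 1]`.
#' @export
church_score <- function(x, s, X, N) {
  check_counts(x, s, X, N)
  if (x == 0) return(1)
  stats::phyper(x - 1, X, N - X, s, lower.tail = FALSE)
}

#' Binomial enrichment score
#'
#' The binomial upper tail `P(B >= x)` for `B ~ Binomial(s, X / N)`: how
#' surprising the group presence count is under the universe presence
#' rate.
#'
#' @inheritParams church_score
#' @return Probability in `[0, 1]`.
#' @export
enrichment_score <- function(x, s, X, N) {
  check_counts(x, s, X, N)
  if (x == 0) return(1)
  if (X == 0) abort("Enrichment undefined: x > 0 with X = 0.")
  stats::pbinom(x - 1, s, X / N, lower.tail = FALSE)
}

#' ROC-AUC motif discrimination
#'
#' The area under the ROC curve for separating group from background
#' sequences by their per-sequence motif score (best scan similarity):
#' the normalised Mann-Whitney statistic `U / (n1 * n2)`, with ties
#' credited 0.5.
#'
#' @param group_scores,background_scores Nonempty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(group_scores, background_scores) {
  n1 <- length(group_scores); n2 <- length(background_scores)
  if (n1 == 0 || n2 == 0) abort("Both score vectors must be nonempty.")
  r <- rank(c(group_scores, background_scores))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Filter thresholds for the two-stage motif cascade
#'
#' Stage 1 keeps motifs with `MAP > map_min` and, for imported motifs
#' carrying a genuine E-value, `E <= evalue_max`; internally discovered
#' motifs are instead required to sit at (or below) their Monte-Carlo
#' proxy floor unless `proxy_max` overrides it. Stage 2 keeps motifs with
#' `Church <= church_max`, `ROC-AUC >= roc_auc_min` and binomial
#' enrichment `<= enrichment_p_max`.
#'
#' @param map_min MAP threshold (default 5, exclusive).
#' @param evalue_max E-value ceiling for imported motifs (default 1e-05).
#' @param church_max Church score ceiling (default 1e-04).
#' @param roc_auc_min AUC floor (default 0.7).
#' @param enrichment_p_max Enrichment ceiling (default 0.01).
#' @param proxy_max Ceiling for the Monte-Carlo proxy of internal motifs;
#'   `NULL` (default) means "at the proxy floor".
#' @return A `filter_config` list.
#' @export
filter_config <- function(map_min = 5, evalue_max = 1e-05, church_max = 1e-04,
                          roc_auc_min = 0.7, enrichment_p_max = 0.01,
                          proxy_max = NULL) {
  stopifnot(evalue_max > 0, church_max >= 0, church_max <= 1,
            roc_auc_min >= 0, roc_auc_min <= 1,
            enrichment_p_max >= 0, enrichment_p_max <= 1)
  structure(list(map_min = map_min, evalue_max = evalue_max,
                 church_max = church_max, roc_auc_min = roc_auc_min,
                 enrichment_p_max = enrichment_p_max, proxy_max = proxy_max),
            class = "filter_config")
}

#' Score motifs against a grouped UCR universe
#'
#' Computes, for every motif, the presence counts and the three
#' specificity statistics (Church, ROC-AUC, binomial enrichment) of the
#' group against the universe.
#'
#' @param motifs A `ucr_motif_set` (or list of `pssm`s).
#' @param group_ids Group sequence ids.
#' @param ucrs Universe sequence set (group included).
#' @param scan_threshold Percent similarity defining presence (default 88).
#' @return Tibble with one row per motif: `motif`, `map_score`, `evalue`,
#'   `evalue_proxy`, `proxy_floor`, `x`, `s`, `X`, `N`, `church_p`,
#'   `roc_auc`, `enrichment_p`.
#' @export
score_motifs <- function(motifs, group_ids, ucrs, scan_threshold = 88) {
  seqs <- as_seqset(ucrs)
  if (!all(group_ids %in% names(seqs))) {
    abort("`group_ids` must be a subset of the universe sequence ids.")
  }
  bg_ids <- setdiff(names(seqs), group_ids)
  rows <- map(seq_along(motifs), function(k) {
    m <- motifs[[k]]
    if (inherits(m, "pssm")) m <- ucr_motif(m)
    pc <- presence_counts(m$pssm, group_ids, seqs, scan_threshold)
    best <- best_similarity(m$pssm, seqs)
    auc <- roc_auc(best[group_ids], best[bg_ids])
    enr <- if (pc$x == 0) 1 else enrichment_score(pc$x, pc$s, pc$X, pc$N)
    tibble(
      motif = m$name, map_score = m$map_score, evalue = m$evalue,
      evalue_proxy = m$evalue_proxy, proxy_floor = m$proxy_floor,
      x = pc$x, s = pc$s, X = pc$X, N = pc$N,
      church_p = church_score(pc$x, pc$s, pc$X, pc$N),
      roc_auc = auc, enrichment_p = enr
    )
  })
  bind_rows(rows)
}

#' Two-stage motif filter cascade
#'
#' Applies the printed two-stage rule: stage 1 on discovery strength
#' (`MAP > 5`, and `E-value <= 1e-05` where a genuine E-value exists, or
#' the Monte-Carlo proxy at its floor for internal motifs), stage 2 on
#' group specificity (`Church <= 1e-04`, `ROC-AUC >= 0.7`, enrichment
#' `<= 0.01`). A motif is retained when it passes both.
#'
#' @param reports Score table from [score_motifs()] (every motif must have
#'   a row with `map_score` present).
#' @param config A [filter_config()].
#' @return `reports` with added logical columns `filter1_pass`,
#'   `filter2_pass`, `retained`.
#' @export
filter_cascade <- function(reports, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  needed <- c("motif", "map_score", "church_p", "roc_auc", "enrichment_p")
  if (!all(needed %in% names(reports))) {
    abort(sprintf("Score report lacks column(s): %s.",
                  paste(setdiff(needed, names(reports)), collapse = ", ")))
  }
  if (any(is.na(reports$map_score))) {
    abort(sprintf("Motif(s) without a MAP score: %s.",
                  paste(reports$motif[is.na(reports$map_score)], collapse = ", ")))
  }
  ev <- reports$evalue %||% rep(NA_real_, nrow(reports))
  px <- reports$evalue_proxy %||% rep(NA_real_, nrow(reports))
  pf <- reports$proxy_floor %||% rep(NA_real_, nrow(reports))
  sig1 <- dplyr::case_when(
    !is.na(ev) ~ ev <= config$evalue_max,
    !is.na(px) & !is.null(config$proxy_max) ~ px <= (config$proxy_max %||% 1),
    !is.na(px) ~ px <= pf + 1e-12,
    TRUE ~ TRUE  # no significance value available: MAP alone decides
  )
  f1 <- reports$map_score > config$map_min & sig1
  f2 <- reports$church_p <= config$church_max &
    reports$roc_auc >= config$roc_auc_min &
    reports$enrichment_p <= config$enrichment_p_max
  mutate(reports, filter1_pass = f1, filter2_pass = f2,
         retained = f1 & f2)
}
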