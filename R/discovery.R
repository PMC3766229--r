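#' Discovered motifs
#'
#' A `ucr_motif` bundles a [pssm()] with the aligned sites that produced it,
#' its MAP score and (when available) a significance value: a genuine
#' E-value for imported motifs, or the Monte-Carlo proxy of
#' [empirical_significance()] for internally discovered ones. A
#' `ucr_motif_set` is an ordered list of them.
#'
#' @param pssm A [pssm()].
#' @param sites Tibble with `seq_id`, `offset` (0-based), `strand`, `word`.
#' @param map_score MAP score of the alignment.
#' @param evalue E-value (imported motifs only).
#' @param evalue_proxy Monte-Carlo significance proxy.
#' @param proxy_floor Smallest attainable proxy, `1 / (n_shuffles + 1)`.
#' @param finder `"internal"` or `"imported"`.
#' @param seed,restarts,iterations Run metadata.
#' @return A `ucr_motif`.
#' @export
ucr_motif <- function(pssm, sites = empty_sites(), map_score = NA_real_,
                      evalue = NA_real_, evalue_proxy = NA_real_,
                      proxy_floor = NA_real_, finder = "internal",
                      seed = NA_integer_, restarts = NA_integer_,
                      iterations = NA_integer_) {
  stopifnot(inherits(pssm, "pssm"))
  structure(
    list(name = pssm$name, pssm = pssm, sites = sites, map_score = map_score,
         evalue = evalue, evalue_proxy = evalue_proxy,
         proxy_floor = proxy_floor, finder = finder,
         width = pssm_width(pssm), seed = seed, restarts = restarts,
         iterations = iterations),
    class = "ucr_motif"
  )
}

empty_sites <- function() {
  tibble(seq_id = character(), offset = integer(), strand = character(),
         word = character())
}

#' @export
print.ucr_motif <- function(x, ...) {
  cat(sprintf("<ucr_motif> %s  width %d, %d sites, MAP %.2f (%s)\n",
              x$name, x$width, nrow(x$sites), x$map_score, x$finder))
  invisible(x)
}

#' @rdname ucr_motif
#' @param x List of `ucr_motif` objects.
#' @export
motif_set <- function(x = list()) {
  stopifnot(all(vapply(x, inherits, logical(1), "ucr_motif")))
  names(x) <- vapply(x, function(m) m$name, character(1))
  structure(x, class = "ucr_motif_set")
}

#' @export
`[.ucr_motif_set` <- function(x, i) motif_set(unclass(x)[i])

#' @export
print.ucr_motif_set <- function(x, ...) {
  cat(sprintf("<ucr_motif_set> %d motif(s)\n", length(x)))
  for (m in x) {
    cat(sprintf("  %-12s width %2d  sites %3d  MAP %8.2f  %s\n",
                m$name, m$width, nrow(m$sites), m$map_score,
                pssm_consensus(m$pssm)))
  }
  invisible(x)
}

# ---- background models ------------------------------------------------------

#' Fit a background base-composition model on a sequence set
#'
#' @param sequences Sequence set (see [scan_pssm()] for accepted forms).
#' @param order Markov order, 0 or 1.
#' @return A `ucr_background` with base probabilities (and, for order 1,
#'   a transition matrix) estimated from the pooled sequences.
#' @export
fit_background <- function(sequences, order = 0) {
  seqs <- as_seqset(sequences)
  enc <- lapply(seqs, encode_seq)
  all <- unlist(enc, use.names = FALSE)
  all <- all[!is.na(all)]
  p <- (tabulate(all, 4) + 1) / (length(all) + 4)  # add-one smoothing
  trans <- NULL
  if (order == 1) {
    trans <- matrix(1, 4, 4)  # add-one smoothing
    for (e in enc) {
      ok <- which(!is.na(e[-length(e)]) & !is.na(e[-1]))
      tt <- table(factor(e[ok], levels = 1:4), factor(e[ok + 1L], levels = 1:4))
      trans <- trans + as.matrix(tt)
    }
    trans <- sweep(trans, 1, rowSums(trans), "/")
  } else if (order != 0) {
    abort("Background order must be 0 or 1.")
  }
  structure(list(order = order, p = p, trans = trans,
                 logp = log(p),
                 logtrans = if (!is.null(trans)) log(trans)),
            class = "ucr_background")
}

# log probability of encoded words under a background model; words with N
# get -Inf
word_logbg <- function(word_enc, bg) {
  if (anyNA(word_enc)) return(-Inf)
  if (bg$order == 0) {
    sum(bg$logp[word_enc])
  } else {
    n <- length(word_enc)
    bg$logp[word_enc[1]] +
      sum(bg$logtrans[cbind(word_enc[-n], word_enc[-1])])
  }
}

# per-window background log-probabilities for the forward reading and the
# reverse-complement reading of each window, under an order-0 or order-1
# background model; windows containing N are handled upstream (their motif
# log-likelihood is -Inf), so N is treated as an arbitrary base here
window_logbg_vec <- function(enc, w, bg) {
  enc0 <- enc
  enc0[is.na(enc0)] <- 1L
  L <- length(enc0)
  nwin <- L - w + 1L
  if (nwin < 1L) return(list(f = numeric(0), r = numeric(0)))
  if (bg$order == 0) {
    lp_f <- bg$logp[enc0]
    lp_r <- bg$logp[5L - enc0]
    cs_f <- c(0, cumsum(lp_f))
    cs_r <- c(0, cumsum(lp_r))
    idx <- seq_len(nwin)
    return(list(f = cs_f[idx + w] - cs_f[idx],
                r = cs_r[idx + w] - cs_r[idx]))
  }
  # order 1
  lt <- bg$logtrans
  ltc <- matrix(NA_real_, 4, 4)  # complement-strand transition terms
  for (a in 1:4) for (b in 1:4) ltc[a, b] <- lt[5L - b, 5L - a]
  tf <- lt[cbind(enc0[-L], enc0[-1])]
  tr <- ltc[cbind(enc0[-L], enc0[-1])]
  cs_f <- c(0, cumsum(tf))
  cs_r <- c(0, cumsum(tr))
  idx <- seq_len(nwin)
  list(
    f = bg$logp[enc0[idx]] + cs_f[idx + w - 1L] - cs_f[idx],
    r = bg$logp[5L - enc0[idx + w - 1L]] + cs_r[idx + w - 1L] - cs_r[idx]
  )
}

# window sums of a positional 4 x w log-score matrix over an encoded
# sequence; windows containing N score -Inf
window_logscores <- function(enc, logmat) {
  w <- ncol(logmat)
  nwin <- length(enc) - w + 1L
  if (nwin < 1L) return(numeric(0))
  acc <- numeric(nwin)
  for (j in seq_len(w)) {
    b <- enc[j:(j + nwin - 1L)]
    v <- logmat[cbind(b, rep.int(j, nwin))]
    v[is.na(b)] <- -Inf
    acc <- acc + v
  }
  acc
}

# ---- MAP score --------------------------------------------------------------

#' MAP score of a motif alignment
#'
#' `MAP = sum_sites log2 [P(site | PSSM) / P(site | background)]
#'       - n_sites * log2(T)`, where `T` is the total number of admissible
#' window positions `sum_i (L_i - w + 1)` over the sequence set. The penalty
#' term charges each site for the positional uncertainty of where it could
#' have been. An empty alignment scores 0.
#'
#' @param motif A `ucr_motif` (its sites and PSSM are used), or a [pssm()]
#'   together with `sites`.
#' @param ucrs The sequence set the sites live in.
#' @param background_order Markov order (0 or 1) of the background fitted on
#'   `ucrs`.
#' @param sites Optional sites tibble overriding `motif$sites`.
#' @return A single finite number.
#' @export
map_score <- function(motif, ucrs, background_order = 0, sites = NULL) {
  if (inherits(motif, "ucr_motif")) {
    pm <- motif$pssm
    if (is.null(sites)) sites <- motif$sites
  } else {
    pm <- motif
    if (is.null(sites)) abort("`sites` must be supplied for a bare PSSM.")
  }
  if (nrow(sites) == 0L) return(0)
  seqs <- as_seqset(ucrs)
  w <- pssm_width(pm)
  if (!all(sites$seq_id %in% names(seqs))) {
    abort("Motif sites reference sequences absent from `ucrs`.")
  }
  if (any(sites$offset < 0 | sites$offset + w > nchar(seqs[sites$seq_id]))) {
    abort("Motif sites fall outside their sequences.")
  }
  bg <- fit_background(seqs, order = background_order)
  total_pos <- sum(pmax(nchar(seqs) - w + 1L, 0L))
  logf <- log(pm$frequencies)
  llr <- vapply(seq_len(nrow(sites)), function(k) {
    enc <- encode_seq(sites$word[[k]])
    lf <- sum(logf[cbind(enc, seq_len(w))])
    lb <- word_logbg(enc, bg)
    (lf - lb) / log(2)
  }, numeric(1))
  sum(llr) - nrow(sites) * log2(total_pos)
}

# ---- dinucleotide shuffling -------------------------------------------------

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffling: each sequence is rewritten as a random
#' Eulerian walk over its dinucleotide multigraph, so mono- and
#' dinucleotide counts are preserved exactly. Used to build the null sets
#' for [empirical_significance()].
#'
#' @param sequences Sequence set.
#' @param seed Integer seed.
#' @return Named character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequences, seed) {
  seqs <- as_seqset(sequences)
  with_rng(seed, {
    out <- vapply(seqs, shuffle_one, character(1))
  })
  out
}

shuffle_one <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(v)
  if (L <= 2L) return(s)
  letters_used <- unique(v)
  code <- match(v, letters_used)
  K <- length(letters_used)
  final <- code[L]
  # out-edge target lists
  adj <- split(code[-1], factor(code[-L], levels = seq_len(K)))
  # choose last edges forming a tree into `final`
  repeat {
    last <- integer(K)
    for (vx in seq_len(K)) {
      if (vx == final || length(adj[[vx]]) == 0L) { last[vx] <- NA_integer_; next }
      last[vx] <- sample(length(adj[[vx]]), 1L)
    }
    ok <- TRUE
    for (vx in seq_len(K)) {
      if (vx == final || is.na(last[vx])) next
      cur <- vx; steps <- 0L
      while (cur != final) {
        if (is.na(last[cur]) || steps > K) { ok <- FALSE; break }
        cur <- adj[[cur]][last[cur]]
        steps <- steps + 1L
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute non-last edges, append last edge
  order_adj <- lapply(seq_len(K), function(vx) {
    e <- adj[[vx]]
    if (!length(e)) return(integer(0))
    if (vx == final || is.na(last[vx])) return(e[sample.int(length(e))])
    rest <- setdiff(seq_along(e), last[vx])
    c(e[rest[sample.int(length(rest))]], e[last[vx]])
  })
  # walk
  ptr <- integer(K)
  res <- integer(L)
  res[1] <- code[1]
  cur <- code[1]
  for (t in 2:L) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- order_adj[[cur]][ptr[cur]]
    res[t] <- nxt
    cur <- nxt
  }
  paste0(letters_used[res], collapse = "")
}

# ---- Gibbs sampler ----------------------------------------------------------

#' De novo motif discovery by ZOOPS Gibbs sampling
#'
#' Seeded zero-or-one-occurrence-per-sequence Gibbs sampler. Each restart
#' initialises one random site per sequence, then repeatedly rebuilds the
#' PSSM with one sequence left out and resamples that sequence's site
#' (either strand, or no site) with probability proportional to the
#' likelihood ratio against a background model fitted on the input
#' (order 1 by default, which discounts the short-range autocorrelation -
#' homopolymer runs in particular - that an order-0 model would mistake
#' for motifs); the
#' highest-MAP alignment seen is kept. Restart winners are deduplicated at
#' `dedup_identity` percent [pssm_identity()] (best MAP kept) and returned
#' sorted by MAP.
#'
#' @param ucrs Sequence set (at least 2 sequences, each at least `width`).
#' @param width Motif width in columns.
#' @param n_restarts Number of independent restarts (default 10).
#' @param iterations Maximum Gibbs sweeps per restart (default 500); a
#'   restart stops early when its best MAP has not improved for
#'   `patience` sweeps.
#' @param seed Integer seed; fully determines the result.
#' @param pseudocount Per-base smoothing for the sampled PSSMs.
#' @param zoops_prior Prior probability that a sequence carries a site.
#' @param background_order Markov order (0 or 1) of the background model
#'   fitted on the input (default 1).
#' @param patience Sweeps without improvement before early stop.
#' @param dedup_identity Percent identity above which two restart winners
#'   are considered the same motif.
#' @return A `ucr_motif_set`, sorted by decreasing MAP.
#' @export
gibbs_discover <- function(ucrs, width, n_restarts = 10, iterations = 500,
                           seed = 1, pseudocount = 0.25, zoops_prior = 0.5,
                           background_order = 1, patience = 30,
                           dedup_identity = 95) {
  seqs <- as_seqset(ucrs)
  n <- length(seqs)
  if (n < 2L) abort("Motif discovery needs at least 2 sequences.")
  if (width > min(nchar(seqs))) {
    abort(sprintf("Motif width %d exceeds the shortest sequence (%d bp).",
                  width, min(nchar(seqs))))
  }
  enc <- lapply(seqs, encode_seq)
  nwin <- vapply(enc, length, integer(1)) - width + 1L
  bg <- fit_background(seqs, order = background_order)
  total_pos <- sum(nwin)
  lbg <- lapply(enc, window_logbg_vec, w = width, bg = bg)
  lbg_f <- lapply(lbg, `[[`, "f")
  lbg_r <- lapply(lbg, `[[`, "r")
  log_q <- log(zoops_prior)
  log_1q <- log(1 - zoops_prior)

  winners <- list()
  for (r in seq_len(n_restarts)) {
    res <- with_rng(child_seed(seed, r), {
      run_gibbs_restart(enc, seqs, nwin, width, lbg_f, lbg_r, total_pos,
                        pseudocount, log_q, log_1q, iterations, patience)
    })
    winners[[r]] <- res
  }
  # build motifs from restart winners
  motifs <- list()
  for (r in seq_along(winners)) {
    st <- winners[[r]]$sites
    if (is.null(st) || nrow(st) == 0L) next
    counts <- site_counts(st$word, width)
    pm <- pssm_from_counts(counts, pseudocount = pseudocount,
                           name = sprintf("motif_%d", r))
    m <- ucr_motif(pm, sites = st, map_score = winners[[r]]$map,
                   finder = "internal", seed = as.integer(seed),
                   restarts = as.integer(n_restarts),
                   iterations = as.integer(iterations))
    motifs <- c(motifs, list(m))
  }
  if (!length(motifs)) return(motif_set())
  motifs <- motifs[order(-vapply(motifs, function(m) m$map_score, numeric(1)))]
  # deduplicate, keeping the higher-MAP representative
  kept <- list()
  for (m in motifs) {
    dup <- any(vapply(kept, function(k) {
      pssm_identity(k$pssm, m$pssm)$identity >= dedup_identity
    }, logical(1)))
    if (!dup) kept <- c(kept, list(m))
  }
  for (k in seq_along(kept)) {
    kept[[k]]$name <- sprintf("motif_%d", k)
    kept[[k]]$pssm$name <- kept[[k]]$name
  }
  motif_set(kept)
}

site_counts <- function(words, width) {
  counts <- matrix(0, 4, width)
  for (s in words) {
    e <- encode_seq(s)
    ok <- !is.na(e)
    counts[cbind(e[ok], seq_len(width)[ok])] <-
      counts[cbind(e[ok], seq_len(width)[ok])] + 1
  }
  rownames(counts) <- DNA_BASES
  counts
}

run_gibbs_restart <- function(enc, seqs, nwin, width, lbg_f, lbg_r, total_pos,
                              pseudocount, log_q, log_1q, iterations, patience) {
  n <- length(enc)
  ids <- names(enc)
  # state: position (NA = no site) and strand per sequence
  pos <- vapply(nwin, function(m) sample.int(m, 1L), integer(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  site_word <- function(i) {
    e <- enc[[i]][pos[i]:(pos[i] + width - 1L)]
    if (strand[i] == "-") e <- 5L - rev(e)
    e
  }
  counts <- matrix(0, 4, width)
  for (i in seq_len(n)) {
    e <- site_word(i)
    counts[cbind(e, seq_len(width))] <- counts[cbind(e, seq_len(width))] + 1
  }
  n_sites <- n
  best <- list(map = -Inf, pos = pos, strand = strand)
  stale <- 0L
  for (it in seq_len(iterations)) {
    for (i in seq_len(n)) {
      if (!is.na(pos[i])) {
        e <- site_word(i)
        counts[cbind(e, seq_len(width))] <- counts[cbind(e, seq_len(width))] - 1
        n_sites <- n_sites - 1L
      }
      f <- (counts + pseudocount) / (n_sites + 4 * pseudocount)
      logf <- log(f)
      logf_rc <- logf[4:1, width:1, drop = FALSE]
      llr_f <- window_logscores(enc[[i]], logf) - lbg_f[[i]]
      llr_r <- window_logscores(enc[[i]], logf_rc) - lbg_r[[i]]
      logw <- c(llr_f, llr_r) + log_q - log(nwin[i])
      mx <- max(logw, log_1q)
      wts <- exp(c(logw, log_1q) - mx)
      pick <- sample.int(length(wts), 1L, prob = wts)
      if (pick == length(wts)) {
        pos[i] <- NA_integer_
      } else if (pick <= nwin[i]) {
        pos[i] <- pick; strand[i] <- "+"
      } else {
        pos[i] <- pick - nwin[i]; strand[i] <- "-"
      }
      if (!is.na(pos[i])) {
        e <- site_word(i)
        counts[cbind(e, seq_len(width))] <- counts[cbind(e, seq_len(width))] + 1
        n_sites <- n_sites + 1L
      }
    }
    cur_map <- alignment_map(enc, pos, strand, width, counts, n_sites,
                             pseudocount, lbg_f, lbg_r, total_pos)
    if (cur_map > best$map + 1e-9) {
      best <- list(map = cur_map, pos = pos, strand = strand)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  # materialise best alignment
  keep <- which(!is.na(best$pos))
  if (!length(keep)) return(list(sites = NULL, map = best$map))
  words <- vapply(keep, function(i) {
    e <- enc[[i]][best$pos[i]:(best$pos[i] + width - 1L)]
    if (best$strand[i] == "-") e <- 5L - rev(e)
    decode_seq(e)
  }, character(1))
  sites <- tibble(seq_id = ids[keep], offset = best$pos[keep] - 1L,
                  strand = best$strand[keep], word = words)
  list(sites = sites, map = best$map)
}

# MAP of the current alignment, computed from counts already in hand
alignment_map <- function(enc, pos, strand, width, counts, n_sites,
                          pseudocount, lbg_f, lbg_r, total_pos) {
  if (n_sites == 0L) return(0)
  f <- (counts + pseudocount) / (n_sites + 4 * pseudocount)
  logf <- log(f)
  llr <- 0
  for (i in which(!is.na(pos))) {
    e <- enc[[i]][pos[i]:(pos[i] + width - 1L)]
    if (strand[i] == "-") {
      e2 <- 5L - rev(e)
      lf <- sum(logf[cbind(e2, seq_len(width))])
      lb <- lbg_r[[i]][pos[i]]
    } else {
      lf <- sum(logf[cbind(e, seq_len(width))])
      lb <- lbg_f[[i]][pos[i]]
    }
    llr <- llr + (lf - lb) / log(2)
  }
  llr - n_sites * log2(total_pos)
}

# ---- Monte-Carlo significance ----------------------------------------------

#' Monte-Carlo significance proxy for a discovered motif
#'
#' Re-runs [gibbs_discover()] at the same width on `n_shuffles`
#' dinucleotide-shuffled copies of the sequence set and compares the best
#' shuffled MAP scores with the observed one:
#' `proxy = (1 + #\{shuffled best MAP >= observed MAP\}) / (n_shuffles + 1)`.
#' The smallest attainable value (the floor) is `1 / (n_shuffles + 1)`; a
#' motif at the floor beat every shuffled set.
#'
#' @param motif A `ucr_motif` with a MAP score.
#' @param ucrs The sequence set it was discovered on.
#' @param n_shuffles Number of shuffled null sets (default 19).
#' @param seed Integer seed.
#' @param n_restarts,iterations Sampler effort per null set.
#' @param null_map Optional precomputed null distribution from
#'   [null_map_distribution()]; the null depends only on the sequence set
#'   and width, so it can be shared across motifs of one discovery run.
#' @return List with `proxy`, `floor` and the vector of `null_map` scores.
#' @export
empirical_significance <- function(motif, ucrs, n_shuffles = 19, seed = 1,
                                   n_restarts = 3, iterations = 200,
                                   null_map = NULL) {
  observed <- motif$map_score
  if (!is.finite(observed)) abort("Motif has no finite MAP score.")
  if (is.null(null_map)) {
    null_map <- null_map_distribution(ucrs, motif$width,
                                      n_shuffles = n_shuffles, seed = seed,
                                      n_restarts = n_restarts,
                                      iterations = iterations)
  }
  n <- length(null_map)
  proxy <- (1 + sum(null_map >= observed)) / (n + 1)
  list(proxy = proxy, floor = 1 / (n + 1), null_map = null_map)
}

#' Null distribution of best MAP scores on shuffled sequence sets
#'
#' Runs [gibbs_discover()] on `n_shuffles` dinucleotide-shuffled copies of
#' the sequence set and returns the best MAP score found on each - the
#' reference distribution for [empirical_significance()].
#'
#' @inheritParams empirical_significance
#' @param width Motif width.
#' @return Numeric vector of length `n_shuffles`.
#' @export
null_map_distribution <- function(ucrs, width, n_shuffles = 19, seed = 1,
                                  n_restarts = 3, iterations = 200) {
  if (n_shuffles < 1) abort("`n_shuffles` must be at least 1.")
  vapply(seq_len(n_shuffles), function(k) {
    shuf <- dinucleotide_shuffle(ucrs, seed = child_seed(seed, 2L * k))
    ms <- gibbs_discover(shuf, width = width, n_restarts = n_restarts,
                         iterations = iterations,
                         seed = child_seed(seed, 2L * k + 1L))
    if (!length(ms)) return(-Inf)
    max(vapply(ms, function(m) m$map_score, numeric(1)))
  }, numeric(1))
}
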