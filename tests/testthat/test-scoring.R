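test_that("Church score matches hand-derived hypergeometric tails", {
  expect_equal(church_score(0, 5, 4, 10), 1)
  expect_equal(church_score(4, 5, 4, 10), 6 / 252, tolerance = 1e-12)
  # all of X inside the group with X = s: tail is 1 / C(N, s)
  expect_equal(church_score(4, 4, 4, 8), 1 / choose(8, 4), tolerance = 1e-12)
  expect_error(church_score(5, 4, 6, 10), "Invalid")
})

test_that("Church and enrichment scores equal exhaustive enumeration, N <= 12", {
  for (N in c(3, 6, 9, 12)) {
    for (s in seq_len(N)) {
      for (X in 0:N) {
        for (x in 0:min(X, s)) {
          expect_equal(church_score(x, s, X, N), church_oracle(x, s, X, N),
                       tolerance = 1e-10)
          if (x == 0) {
            expect_equal(enrichment_score(x, s, X, N), 1)
          } else if (X > 0) {
            expect_equal(enrichment_score(x, s, X, N),
                         enrichment_oracle(x, s, X, N), tolerance = 1e-10)
          }
        }
      }
    }
  }
})

test_that("enrichment score reproduces its closed-form examples", {
  expect_equal(enrichment_score(4, 5, 4, 10),
               5 * 0.4^4 * 0.6 + 0.4^5, tolerance = 1e-12)
  expect_equal(enrichment_score(5, 5, 10, 10), 1)  # certain event
  expect_error(enrichment_score(1, 5, 0, 10), "Invalid|undefined")
})

test_that("ROC-AUC equals the pairwise Mann-Whitney oracle", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(2, 3), c(1, 2)), 0.875)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
  for (i in 1:200) {
    withr::with_seed(i, {
      g <- sample(0:5, sample(2:8, 1), replace = TRUE)
      b <- sample(0:5, sample(2:8, 1), replace = TRUE)
    })
    expect_equal(roc_auc(g, b), auc_oracle(g, b), tolerance = 1e-12)
  }
})

test_that("presence counts respect ground truth and threshold monotonicity", {
  study <- simulate_motif_study(simulation_config(
    seed = 19, n_genes = 60, contig_length = 90000,
    foreground_fraction = 1 / 3, occupancy = 1
  ))
  pm <- study$library$pssm[[1]]
  seqs <- setNames(study$ucrs$sequence, study$ucrs$gene_id)
  pc <- presence_counts(pm, study$group_ids, seqs, scan_threshold = 85)
  expect_equal(pc$s, length(study$group_ids))
  expect_equal(pc$N, nrow(study$ucrs))
  expect_gte(pc$x, round(0.9 * pc$s))  # occupancy 1; sampled sites score high
  prev_x <- Inf; prev_X <- Inf
  for (thr in c(70, 85, 95, 100)) {
    pc <- presence_counts(pm, study$group_ids, seqs, scan_threshold = thr)
    expect_lte(pc$x, prev_x); expect_lte(pc$X, prev_X)
    prev_x <- pc$x; prev_X <- pc$X
  }
  # absent motif
  none <- presence_counts(pssm_from_iupac("ACGTACGTACGTACGT"),
                          study$group_ids, seqs, scan_threshold = 100)
  expect_equal(none$x, 0)
  expect_error(presence_counts(pm, "not_a_gene", seqs), "subset")
})

test_that("the filter cascade applies both stages as printed", {
  rep1 <- tibble::tibble(
    motif = c("good", "weak_auc", "weak_map", "bad_church"),
    map_score = c(6, 6, 4, 6),
    evalue = c(1e-6, 1e-6, 1e-6, 1e-6),
    evalue_proxy = NA_real_, proxy_floor = NA_real_,
    x = 10, s = 12, X = 15, N = 100,
    church_p = c(1e-5, 1e-5, 1e-5, 2e-4),
    roc_auc = c(0.8, 0.69, 0.8, 0.8),
    enrichment_p = c(0.005, 0.005, 0.005, 0.005)
  )
  out <- filter_cascade(rep1)
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$filter1_pass, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$filter2_pass, c(TRUE, FALSE, TRUE, FALSE))
  # empty input stays empty
  expect_equal(nrow(filter_cascade(rep1[0, ])), 0)
  # missing MAP is an error naming the motif
  bad <- rep1; bad$map_score[2] <- NA
  expect_error(filter_cascade(bad), "weak_auc")
})

test_that("internal motifs are gated on the Monte-Carlo proxy floor", {
  rep1 <- tibble::tibble(
    motif = c("at_floor", "above_floor"),
    map_score = 10, evalue = NA_real_,
    evalue_proxy = c(0.05, 0.10), proxy_floor = 0.05,
    x = 10, s = 12, X = 15, N = 100,
    church_p = 1e-5, roc_auc = 0.9, enrichment_p = 0.001
  )
  out <- filter_cascade(rep1)
  expect_equal(out$retained, c(TRUE, FALSE))
  # an explicit ceiling overrides the floor rule
  out2 <- filter_cascade(rep1, filter_config(proxy_max = 0.2))
  expect_equal(out2$retained, c(TRUE, TRUE))
})

test_that("tightening any threshold never grows the retained set", {
  withr::with_seed(42, {
    rep1 <- tibble::tibble(
      motif = paste0("m", 1:40),
      map_score = runif(40, 0, 12),
      evalue = 10^runif(40, -8, -3),
      evalue_proxy = NA_real_, proxy_floor = NA_real_,
      x = 5, s = 10, X = 20, N = 100,
      church_p = 10^runif(40, -6, 0),
      roc_auc = runif(40, 0.4, 1),
      enrichment_p = 10^runif(40, -4, 0)
    )
  })
  base <- filter_cascade(rep1)$retained
  tighter <- list(
    filter_config(map_min = 7), filter_config(evalue_max = 1e-6),
    filter_config(church_max = 1e-5), filter_config(roc_auc_min = 0.8),
    filter_config(enrichment_p_max = 0.001)
  )
  for (cfg in tighter) {
    expect_true(all(filter_cascade(rep1, cfg)$retained <= base))
  }
})

test_that("score_motifs assembles a coherent report for the planted motif", {
  study <- simulate_motif_study(simulation_config(
    seed = 23, n_genes = 60, contig_length = 90000, foreground_fraction = 1 / 3
  ))
  seqs <- setNames(study$ucrs$sequence, study$ucrs$gene_id)
  rep1 <- score_motifs(list(study$library$pssm[[1]]), study$group_ids, seqs)
  expect_equal(nrow(rep1), 1)
  expect_lte(rep1$church_p, 1e-4)
  expect_gte(rep1$roc_auc, 0.7)
  expect_lte(rep1$enrichment_p, 0.01)
  expect_true(rep1$x <= min(rep1$X, rep1$s))
})
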