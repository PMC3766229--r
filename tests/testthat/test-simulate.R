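small_cfg <- function(seed = 5, ...) {
  simulation_config(seed = seed, n_genes = 10, contig_length = 15000,
                    intergenic = list(dist = "fixed", length = 500),
                    background_order = 0, ...)
}

test_that("simulation is a pure function of its config", {
  g1 <- simulate_genome(small_cfg())
  g2 <- simulate_genome(small_cfg())
  expect_identical(g1, g2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(g1, d1); write_simulation(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  g3 <- simulate_genome(small_cfg(seed = 6))
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("zero genes yields an empty annotation over pure background", {
  g <- simulate_genome(simulation_config(seed = 1, n_genes = 0,
                                         contig_length = 5000,
                                         foreground_fraction = 0))
  expect_equal(nrow(g$annotation), 0)
  expect_equal(nchar(g$sequences[["contig_1"]]), 5000)
  expect_equal(nrow(g$truth$planted), 0)
})

test_that("infeasible packing fails with the shortfall named", {
  cfg <- simulation_config(seed = 1, n_genes = 50, contig_length = 1000,
                           intergenic = list(dist = "fixed", length = 500))
  expect_error(simulate_genome(cfg), "short by")
})

test_that("genes never overlap and both strands appear", {
  g <- simulate_genome(small_cfg())
  a <- dplyr::arrange(g$annotation, start)
  expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  expect_setequal(unique(a$strand), c("+", "-"))
})

test_that("fixed 500 bp spacing bounds every extracted UCR at 500", {
  # contig sized to the exact packing so no gene borders open sequence
  cfg <- simulation_config(seed = 5, n_genes = 10, contig_length = 9000,
                           gene_length_range = c(400, 400),
                           intergenic = list(dist = "fixed", length = 500),
                           background_order = 0)
  g <- simulate_genome(cfg)
  u <- suppressMessages(extract_ucrs(g$annotation, g$sequences,
                                     requested_length = 3000))
  expect_equal(nrow(u), 10)
  expect_true(all(u$actual_length <= 500))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(base_composition = c(0.5, 0.5, 0.1, 0)),
               "summing to 1")
  expect_error(simulation_config(occupancy = 1.5), "occupancy")
  expect_error(simulation_config(background_order = 3), "order")
})

test_that("background composition matches the configuration at 100 kb", {
  comp <- c(0.4, 0.1, 0.2, 0.3)
  g <- simulate_genome(simulation_config(
    seed = 21, n_genes = 0, contig_length = 100000,
    background_order = 0, base_composition = comp, foreground_fraction = 0
  ))
  obs <- table(factor(strsplit(g$sequences[[1]], "")[[1]],
                      levels = c("A", "C", "G", "T"))) / 100000
  se <- sqrt(comp * (1 - comp) / 100000)
  expect_true(all(abs(as.numeric(obs) - comp) <= 3 * se))
})

test_that("order-1 background preserves composition and is reproducible", {
  comp <- c(0.3, 0.2, 0.2, 0.3)
  cfg <- simulation_config(seed = 8, n_genes = 0, contig_length = 100000,
                           background_order = 1, base_composition = comp,
                           foreground_fraction = 0)
  g <- simulate_genome(cfg)
  obs <- table(factor(strsplit(g$sequences[[1]], "")[[1]],
                      levels = c("A", "C", "G", "T"))) / 100000
  # autocorrelation inflates the sampling error; allow a generous band
  expect_true(all(abs(as.numeric(obs) - comp) < 0.02))
  expect_identical(g, simulate_genome(cfg))
})

test_that("occupancy 0 and 1 hit their planting boundaries", {
  g <- simulate_genome(small_cfg(seed = 9))
  pm <- consensus_pssm("TTGACCGA")
  p0 <- plant_motifs(g$sequences, g$annotation, g$truth, pm, occupancy = 0,
                     seed = 2, genes = g$annotation$gene_id)
  expect_identical(p0$sequences, g$sequences)
  expect_equal(nrow(p0$truth$planted), 0)
  p1 <- plant_motifs(g$sequences, g$annotation, g$truth, pm, occupancy = 1,
                     seed = 2, genes = g$annotation$gene_id)
  expect_equal(nrow(p1$truth$planted), nrow(g$annotation))
})

test_that("planting frequency sits inside exact binomial bounds", {
  cfg <- simulation_config(seed = 31, n_genes = 1000, contig_length = 1200000,
                           intergenic = list(dist = "fixed", length = 600),
                           gene_length_range = c(300, 500),
                           background_order = 0, foreground_fraction = 1)
  g <- simulate_genome(cfg)
  pm <- consensus_pssm("TTGACCGA")
  pl <- plant_motifs(g$sequences, g$annotation, g$truth, pm, occupancy = 0.5,
                     seed = 13)
  n <- nrow(pl$truth$planted)
  expect_gte(n, qbinom(0.005, 1000, 0.5))
  expect_lte(n, qbinom(0.995, 1000, 0.5))
})

test_that("planted coordinates map through UCR extraction to the exact word", {
  g <- simulate_genome(small_cfg(seed = 17))
  pm <- consensus_pssm("TTGACCGA")
  pl <- plant_motifs(g$sequences, g$annotation, g$truth, pm, occupancy = 1,
                     seed = 4, ucr_length = 400, genes = g$annotation$gene_id)
  u <- suppressMessages(extract_ucrs(g$annotation, pl$sequences,
                                     requested_length = 400))
  tr <- pl$truth$planted
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    r <- u[u$gene_id == tr$gene_id[i], ]
    got <- substring(r$sequence, tr$ucr_offset[i] + 1, tr$ucr_offset[i] + 8)
    expected <- if (tr$strand[i] == "+") tr$word[i] else {
      chartr("ACGT", "TGCA", paste(rev(strsplit(tr$word[i], "")[[1]]), collapse = ""))
    }
    expect_identical(got, expected)
  }
})

test_that("the benchmark study carries a library with the planted motif", {
  study <- simulate_motif_study(simulation_config(
    seed = 3, n_genes = 40, contig_length = 60000, foreground_fraction = 0.25,
    decoy_motif_count = 3
  ))
  expect_equal(nrow(study$library), 4)
  expect_equal(study$library$id[1], "planted")
  expect_setequal(
    study$category_map$category[study$category_map$gene_id %in% study$group_ids],
    c("CP", "muscle")
  )
  expect_true(all(study$truth$planted$gene_id %in% study$group_ids))
})
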