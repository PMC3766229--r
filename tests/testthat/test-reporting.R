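# spot table emulating one comparison's printed counts: n_sig significant
# spots of which n_gene map to annotated genes
make_spots <- function(comparison, n_sig, n_gene, array_size = 14400,
                       direction = "up") {
  tibble::tibble(
    spot_id = paste0(comparison, "_spot", seq_len(n_sig)),
    gene_id = c(paste0(comparison, "_gene", seq_len(n_gene)),
                rep(NA_character_, n_sig - n_gene)),
    comparison = comparison,
    direction = direction,
    significant = TRUE
  )
}

test_that("DEG summaries reproduce the printed array percentages", {
  spots <- dplyr::bind_rows(
    make_spots("pw_vs_pbl", 995, 862),
    make_spots("pp_vs_pbl", 1497, 1304)
  )
  out <- deg_summary(spots, array_size = 14400)
  per <- out$per_comparison[match(c("pw_vs_pbl", "pp_vs_pbl"),
                                  out$per_comparison$comparison), ]
  expect_equal(per$pct_of_array, c(6.9, 10.4))
  expect_equal(per$pct_gene_set, c(86.63, 87.11))
  expect_equal(per$n_spots, c(995, 1497))
})

test_that("unique-gene unions follow set arithmetic on shared genes", {
  # 761 and 1173 unique genes with 681 in common -> union 1253
  g1 <- paste0("g", seq_len(761))
  g2 <- paste0("g", c(seq_len(681), 762:1253))
  spots <- dplyr::bind_rows(
    tibble::tibble(spot_id = paste0("a", seq_along(g1)), gene_id = g1,
                   comparison = "c1", direction = "up", significant = TRUE),
    tibble::tibble(spot_id = paste0("b", seq_along(g2)), gene_id = g2,
                   comparison = "c2", direction = "up", significant = TRUE)
  )
  out <- deg_summary(spots, array_size = 14400)
  expect_equal(out$per_comparison$unique_genes, c(761, 1173))
  expect_equal(out$overall$union_genes, 1253)
})

test_that("degenerate DEG tables are handled explicitly", {
  one <- make_spots("c1", 10, 10, array_size = 10)
  expect_equal(deg_summary(one, 10)$per_comparison$pct_of_array, 100)
  expect_error(deg_summary(one[0, ], 10), "Empty")
  dup <- dplyr::bind_rows(one, one[1, ])
  expect_error(deg_summary(dup, 20), "unique")
})

test_that("concordance truncates to one decimal as printed", {
  tab <- tibble::tibble(
    gene_id = paste0("g", 1:72), comparison = "c",
    direction_platform1 = "up",
    direction_platform2 = c(rep("up", 58), rep("down", 14))
  )
  out <- concordance(tab)
  expect_equal(out$percent_agreement, 80.5)  # 58/72 = 80.555..., floored
  expect_equal(sum(out$verdicts$agree), 58)
  all_agree <- dplyr::mutate(tab, direction_platform2 = "up")
  expect_equal(concordance(all_agree)$percent_agreement, 100)
  none <- dplyr::mutate(tab, direction_platform2 = "down")
  expect_equal(concordance(none)$percent_agreement, 0)
  expect_error(concordance(dplyr::mutate(tab, direction_platform2 = "sideways")),
               "up")
})

test_that("concordance is invariant to row order", {
  tab <- tibble::tibble(
    gene_id = paste0("g", 1:20), comparison = "c",
    direction_platform1 = rep(c("up", "down"), 10),
    direction_platform2 = rep(c("up", "up"), 10)
  )
  expect_equal(concordance(tab)$percent_agreement,
               concordance(tab[sample(20), ])$percent_agreement)
})

test_that("PCR efficiency follows the standard-curve equation", {
  expect_equal(pcr_efficiency(-1 / log10(2)), 2, tolerance = 1e-12)
  expect_equal(pcr_efficiency(-3.5), 10^(1 / 3.5), tolerance = 1e-12)
  expect_equal(pcr_efficiency(-1e9), 1, tolerance = 1e-6)
  expect_error(pcr_efficiency(3.3), "negative")
})

test_that("protein features count composition, motifs and mass", {
  f <- protein_features("GGYGG")
  expect_equal(f$glycine_pct, 80)
  expect_equal(f$ggygg_offsets, 0)
  expect_equal(f$ggy_offsets, 0)

  g <- protein_features("G")
  expect_equal(round(g$mass_da, 2), 75.07)

  h <- protein_features("GGYGGAGGY")
  expect_equal(h$ggy_offsets, c(0, 6))
  expect_equal(h$ggygg_offsets, 0)

  expect_error(protein_features("GGX1"), "Non-amino-acid")
  expect_error(protein_features(""), "Empty")
})

test_that("peptide mass is additive over concatenation", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      aa <- names(ucrmotifs:::RESIDUE_MASS_AVG)
      s1 <- paste0(sample(aa, 12, replace = TRUE), collapse = "")
      s2 <- paste0(sample(aa, 20, replace = TRUE), collapse = "")
    })
    water <- 18.01524
    m12 <- protein_features(paste0(s1, s2))$mass_da
    expect_equal(m12, protein_features(s1)$mass_da +
                   protein_features(s2)$mass_da - water,
                 tolerance = 1e-9)
  }
})

test_that("signal-peptide spans switch features to the mature form", {
  f <- protein_features("MKKLLLAGGYGGSS", signal_peptide = 6)
  expect_true(f$has_signal_peptide)
  expect_equal(f$mature$id, "protein_mature")
  expect_equal(f$mature$length, 8)
  expect_equal(f$mature$ggygg_offsets, 1)  # AGGYGGSS
  expect_gt(f$mature$glycine_pct, f$glycine_pct)
  # below-30-kDa flag on a small protein
  expect_true(f$below_30kda)
  expect_error(protein_features("GG", signal_peptide = 5), "shorter")
})

test_that("monoisotopic masses are selectable and smaller than average", {
  avg <- protein_features("ACDEFGHIKLMNPQRSTVWY")$mass_da
  mono <- protein_features("ACDEFGHIKLMNPQRSTVWY", monoisotopic = TRUE)$mass_da
  expect_lt(mono, avg)
})
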