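test_that("pssm construction from counts applies pseudocount smoothing", {
  p <- pssm_from_counts(matrix(c(4, 0, 0, 0), 4), pseudocount = 0)
  expect_equal(p$frequencies[, 1], c(A = 1, C = 0, G = 0, T = 0))

  p <- pssm_from_counts(matrix(c(1, 1, 1, 1), 4), pseudocount = 0.7)
  expect_equal(unname(p$frequencies[, 1]), rep(0.25, 4))

  p <- pssm_from_counts(matrix(c(3, 1, 0, 0), 4), pseudocount = 0.25)
  expect_equal(unname(p$frequencies[, 1]), c(0.65, 0.25, 0.05, 0.05))

  expect_error(pssm_from_counts(matrix(0, 4, 2), pseudocount = 0), "All-zero")
  expect_error(pssm_from_counts(matrix(-1, 4, 1)), "nonnegative")
  # width x 4 orientation is accepted too
  p2 <- pssm_from_counts(matrix(c(3, 1, 0, 0, 0, 0, 2, 2), 2, 4, byrow = TRUE),
                         pseudocount = 0)
  expect_equal(pssm_width(p2), 2)
  expect_equal(unname(p2$frequencies[, 1]), c(0.75, 0.25, 0, 0))
})

test_that("IUPAC consensus conversion spreads mass over allowed bases", {
  p <- pssm_from_iupac("YCAAGGTCR")
  expect_equal(pssm_width(p), 9)
  expect_equal(unname(p$frequencies[, 1]), c(0, 0.5, 0, 0.5))  # Y = C/T
  expect_equal(unname(p$frequencies[, 9]), c(0.5, 0, 0.5, 0))  # R = A/G
  expect_equal(unname(p$frequencies[, 2]), c(0, 1, 0, 0))

  expect_equal(unname(pssm_from_iupac("N")$frequencies[, 1]), rep(0.25, 4))
  p4 <- pssm_from_iupac("ACGT")
  expect_equal(unname(diag(p4$frequencies)), rep(1, 4))
  expect_error(pssm_from_iupac("ACGQ"), "Non-IUPAC")
})

test_that("site similarity counts allowed positions on consensus PSSMs", {
  p <- pssm_from_iupac("YCAAGGTCR")
  expect_equal(site_similarity(p, "CCAAGGTCA"), 100)
  expect_equal(site_similarity(p, "ACAAGGTCA"), 100 * 8 / 9, tolerance = 1e-10)
  expect_equal(site_similarity(p, "AAAAGGAAA"), 100 * 5 / 9, tolerance = 1e-10)
  # N contributes zero at its column
  expect_equal(site_similarity(p, "NCAAGGTCA"), 100 * 8 / 9, tolerance = 1e-10)
  expect_error(site_similarity(p, "ACGT"), "width")
})

test_that("greedy column-maximum word always scores 100", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      f <- matrix(rexp(4 * 6), 4, 6)
      f <- sweep(f, 2, colSums(f), "/")
    })
    p <- pssm(f)
    expect_equal(site_similarity(p, pssm_consensus(p)), 100)
  }
})

test_that("scanning agrees with the brute-force window oracle", {
  p <- pssm_from_counts(matrix(c(5, 1, 0, 0, 0, 6, 0, 0, 1, 0, 5, 0, 0, 0, 0, 6),
                               4), pseudocount = 0.25)
  for (seed in 1:4) {
    s <- rand_seqs(1, 120, seed = seed)
    hits <- scan_pssm(p, s, threshold = 60)
    oracle <- scan_oracle(p, s[[1]], 60)
    expect_equal(nrow(hits), nrow(oracle))
    o <- order(oracle$offset, oracle$strand)
    expect_equal(hits$offset, oracle$offset[o])
    expect_equal(hits$similarity, oracle$similarity[o], tolerance = 1e-9)
  }
})

test_that("hit sets are monotone in the scan threshold", {
  p <- pssm_from_iupac("YCAAGGTCR")
  s <- rand_seqs(2, 300, seed = 7)
  prev <- NULL
  for (thr in c(90, 70, 50, 0)) {
    h <- scan_pssm(p, s, threshold = thr)
    if (!is.null(prev)) {
      key <- function(d) paste(d$seq_id, d$offset, d$strand)
      expect_true(all(key(prev) %in% key(h)))
    }
    prev <- h
  }
  # threshold 0 yields every window on both strands of an N-free sequence
  h0 <- scan_pssm(p, s["s1"], threshold = 0)
  expect_equal(nrow(h0), (300 - 9 + 1) * 2)
  # sequences shorter than the motif give an empty result, not an error
  expect_equal(nrow(scan_pssm(p, c(tiny = "ACGT"))), 0)
})

test_that("a planted consensus instance is found at its offset", {
  p <- pssm_from_iupac("YCAAGGTCR")
  bg <- rand_seqs(1, 400, seed = 42)[[1]]
  planted <- paste0(substr(bg, 1, 200), "TCAAGGTCG", substr(bg, 210, 400))
  hits <- scan_pssm(p, c(u = planted), threshold = 100)
  expect_equal(hits$offset, 200)
  expect_equal(hits$similarity, 100)
})

test_that("PSSM identity behaves on the documented examples", {
  p <- pssm_from_iupac("YCAAGGTCR")
  self <- pssm_identity(p, p)
  expect_equal(self$identity, 100)
  expect_equal(self$offset, 0L)
  expect_equal(self$orientation, "+")

  a <- pssm(matrix(c(1, 0, 0, 0), 4))
  c1 <- pssm(matrix(c(0, 1, 0, 0), 4))
  expect_equal(pssm_identity(a, c1, min_overlap = 1)$identity, 0)

  u <- pssm(matrix(0.25, 4, 1))
  expect_equal(pssm_identity(u, a, min_overlap = 1)$identity, 25)

  expect_error(pssm_identity(a, c1), "overlap")  # default floor is 4 columns
})

test_that("PSSM identity is symmetric with mirrored offsets", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      fa <- matrix(rexp(4 * 8), 4, 8); fa <- sweep(fa, 2, colSums(fa), "/")
      fb <- matrix(rexp(4 * 6), 4, 6); fb <- sweep(fb, 2, colSums(fb), "/")
    })
    ab <- pssm_identity(pssm(fa), pssm(fb))
    ba <- pssm_identity(pssm(fb), pssm(fa))
    expect_equal(ab$identity, ba$identity, tolerance = 1e-9)
  }
})

test_that("information content matches closed forms", {
  expect_equal(information_content(pssm(matrix(c(1, 0, 0, 0), 4)))$total, 2)
  expect_equal(information_content(pssm(matrix(0.25, 4, 1)))$total, 0)
  expect_equal(information_content(pssm(matrix(c(0.5, 0.5, 0, 0), 4)))$total, 1)
  p <- pssm_from_iupac("YCAAGGTCR")
  expect_equal(information_content(p)$per_column[1], 1)
  expect_equal(information_content(p)$total, 7 * 2 + 2 * 1)
})

test_that("reverse complement round-trips and mirrors scanning", {
  p <- pssm_from_counts(matrix(c(5, 1, 0, 0, 0, 6, 0, 0, 1, 0, 5, 0), 4),
                        pseudocount = 0.25)
  expect_equal(pssm_revcomp(pssm_revcomp(p))$frequencies, p$frequencies)
  s <- rand_seqs(1, 200, seed = 3)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s[[1]], "")[[1]]), collapse = ""))
  h_fwd <- scan_pssm(p, s, threshold = 75)
  h_rc <- scan_pssm(p, setNames(rc, names(s)), threshold = 75)
  expect_equal(nrow(h_fwd), nrow(h_rc))
  expect_equal(sort(h_fwd$similarity), sort(h_rc$similarity), tolerance = 1e-9)
})
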