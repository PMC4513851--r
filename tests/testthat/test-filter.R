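test_that("q-values match the enumeration oracle on the worked example", {
  psms <- makePsms(5,
    score = c(10, 9, 8, 7, 8.5),
    protein_ids = c("P1", "P1", "P1", "P1", "DECOY_P1"),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    peptide_seq = sprintf("AAAAAA%s", LETTERS[1:5]))
  q <- computeQvalues(psms)$q_value
  expect_equal(q[1:4], oracleQvalues(psms$score, psms$is_decoy)[1:4])
  # frozen oracle values: the two top targets are clean, below the decoy
  # the best achievable estimate is 1 decoy over 4 targets
  expect_equal(q[1:4], c(0, 0, 0.25, 0.25))
})

test_that("q-values are zero without decoys and monotone in score", {
  psms <- makePsms(4, score = c(3, 1, 2, 5))
  expect_equal(computeQvalues(psms)$q_value, rep(0, 4))
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    p <- makePsms(n, score = round(rnorm(n, 6, 2), 1),
                  is_decoy = runif(n) < 0.3)
    p$protein_ids <- ifelse(p$is_decoy, "DECOY_P1", "P1")
    q <- computeQvalues(p)$q_value
    ord <- order(p$score, decreasing = TRUE)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("q-value computation equals the O(n^2) enumeration oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    scores <- round(rnorm(n, 5, 2), sample(0:2, 1))  # ties likely
    dec <- runif(n) < 0.35
    if (all(dec)) dec[1] <- FALSE
    p <- makePsms(n, score = scores, is_decoy = dec,
                  protein_ids = ifelse(dec, "DECOY_P1", "P1"),
                  spectrum_id = sprintf("s%03d", 1:n))
    expect_equal(computeQvalues(p)$q_value, oracleQvalues(scores, dec),
                 tolerance = 1e-12)
  }
})

test_that("PSM filter applies rank, mass, FDR and decoy rules in order", {
  ## q-values here (enumeration by hand): s001-s003 score 10 -> q = 0;
  ## decoy s004 (score 9) -> q = 1/3; s005 and decoy s006 (bottom scores)
  ## -> q = 0.5.  At fdr 0.4 the attribution is then one per criterion.
  psms <- makePsms(6,
    rank = c(2L, 1L, 1L, 1L, 1L, 1L),
    mass_error_ppm = c(0, 15, 2, 0, 0, 0),
    score = c(10, 10, 10, 9, 1, 2),
    is_decoy = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    protein_ids = c("P1", "P1", "P1", "DECOY_P1", "P1", "DECOY_P1"),
    peptide_seq = sprintf("AAAAAA%s", LETTERS[1:6]))
  psms <- computeQvalues(psms)
  expect_equal(psms$q_value, c(0, 0, 0, 1 / 3, 0.5, 0.5))
  out <- filterPsms(psms, fdrThreshold = 0.4, ppmTolerance = 10)
  expect_equal(out$psms$spectrum_id, "s003")
  k <- filterCounts(out$report)
  expect_equal(unname(k[c("removed_rank", "removed_mass", "removed_fdr",
                          "removed_decoy", "retained")]),
               c(1, 1, 2, 1, 1))
  expect_equal(unname(k[["input"]]), 6)

  ## at 1% FDR the same input keeps only the clean top-score target PSMs
  strict <- filterPsms(psms, fdrThreshold = 0.01, ppmTolerance = 10)
  expect_equal(strict$psms$spectrum_id, "s003")
  expect_equal(unname(filterCounts(strict$report)[["removed_fdr"]]), 3)
})

test_that("filter report counts are conserved on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    dec <- runif(n) < 0.25
    p <- makePsms(n,
      rank = sample(1:2, n, replace = TRUE, prob = c(0.9, 0.1)),
      mass_error_ppm = rnorm(n, 0, 8),
      score = rnorm(n, ifelse(dec, 4, 9), 2),
      is_decoy = dec,
      protein_ids = ifelse(dec, "DECOY_P1", "P1"),
      spectrum_id = sprintf("s%04d", 1:n))
    out <- filterPsms(computeQvalues(p))
    k <- filterCounts(out$report)
    expect_equal(k[["input"]],
                 k[["retained"]] + k[["removed_rank"]] + k[["removed_mass"]] +
                   k[["removed_fdr"]] + k[["removed_decoy"]])
    expect_equal(k[["retained"]], nrow(out$psms))
  }
})

test_that("tightening thresholds never grows the retained set", {
  set.seed(9)
  n <- 200
  dec <- runif(n) < 0.3
  p <- makePsms(n,
    mass_error_ppm = rnorm(n, 0, 8),
    score = rnorm(n, ifelse(dec, 4, 9), 2),
    is_decoy = dec,
    protein_ids = ifelse(dec, "DECOY_P1", "P1"),
    spectrum_id = sprintf("s%04d", 1:n))
  p <- computeQvalues(p)
  loose <- filterPsms(p, fdrThreshold = 0.05, ppmTolerance = 15)$psms
  tightFdr <- filterPsms(p, fdrThreshold = 0.01, ppmTolerance = 15)$psms
  tightPpm <- filterPsms(p, fdrThreshold = 0.05, ppmTolerance = 5)$psms
  expect_true(all(tightFdr$spectrum_id %in% loose$spectrum_id))
  expect_true(all(tightPpm$spectrum_id %in% loose$spectrum_id))
})

test_that("minimum-peptide rule counts distinct peptides across fractions", {
  # 5 PSMs, single peptide -> fails min_peptides = 2
  p1 <- makePsms(5, peptide_seq = "AAAAAAK",
                 spectrum_id = sprintf("s%d", 1:5))
  expect_equal(filterProteins(p1, 2L), character())
  # 2 distinct peptides, one PSM each, in different gel fractions -> passes
  p2 <- makePsms(2, peptide_seq = c("AAAAAAK", "CCCCCCK"),
                 fraction_id = c("F1", "F2"))
  expect_equal(filterProteins(p2, 2L), "P1")
  expect_equal(filterProteins(p2[0, ], 2L), character())
  # shared peptides support every mapped protein
  p3 <- makePsms(2, peptide_seq = c("AAAAAAK", "CCCCCCK"),
                 protein_ids = "P1;P2")
  expect_setequal(filterProteins(p3, 2L), c("P1", "P2"))
})
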