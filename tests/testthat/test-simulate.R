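test_that("proteome generation is deterministic with matched decoys", {
  p1 <- generateProteome(12, 20, c(150, 800), seed = 7)
  p2 <- generateProteome(12, 20, c(150, 800), seed = 7)
  expect_identical(p1$proteome, p2$proteome)
  expect_equal(nrow(p1$proteome), 64L)  # 32 targets + 32 decoys
  expect_equal(sum(p1$proteome$is_decoy), 32L)

  tg <- p1$proteome[!p1$proteome$is_decoy, ]
  dc <- p1$proteome[p1$proteome$is_decoy, ]
  expect_equal(dc$protein_id, paste0("DECOY_", tg$protein_id))
  expect_equal(dc$sequence[1],
               paste(rev(strsplit(tg$sequence[1], "")[[1]]), collapse = ""))

  p3 <- generateProteome(12, 20, c(150, 800), seed = 8)
  expect_false(identical(p1$proteome$sequence, p3$proteome$sequence))
})

test_that("every generated protein has enough detectable tryptic peptides", {
  p <- generateProteome(5, 10, c(60, 300), seed = 3)
  tg <- p$proteome[!p$proteome$is_decoy, ]
  for (s in tg$sequence) {
    peps <- unique(trypticDigest(s, 0, c(7, 30)))
    expect_gte(length(peps), 4L)
  }
})

test_that("protein masses track the published scenario masses", {
  gt <- eif3GroundTruth(seed = 2, nContaminants = 0)
  cx <- leishEIF3Complex()
  pr <- proteome(gt)
  m <- match(cx$protein_id, pr$protein_id)
  expect_true(all(abs(pr$mw_da[m] / 1000 - cx$mw_kda) < 1.5))
})

test_that("simulated runs are deterministic under the same seed", {
  gt <- eif3GroundTruth(seed = 5, nContaminants = 3)
  r1 <- simulateRun(gt, "bait", "B1", seed = 42)
  r2 <- simulateRun(gt, "bait", "B1", seed = 42)
  expect_identical(r1$psms, r2$psms)
  r3 <- simulateRun(gt, "bait", "B1", seed = 43)
  expect_false(identical(r1$psms, r3$psms))
})

test_that("control runs carry no complex-member signal", {
  gt <- eif3GroundTruth(seed = 6)
  ctl <- simulateRun(gt, "control", "C1", seed = 11)
  members <- names(stoichiometry(gt))
  mapped <- unlist(strsplit(ctl$psms$protein_ids, ";", fixed = TRUE))
  expect_length(intersect(mapped, members), 0L)
  # contaminants are present
  expect_gt(length(intersect(mapped, names(contaminants(gt)))), 0L)
})

test_that("saturating depth detects every member with ample peptides", {
  gt <- eif3GroundTruth(seed = 9, nContaminants = 0, depth = 50,
                        noiseCv = 0)
  run <- simulateRun(gt, "bait", "B1", seed = 1)
  long <- run$psms[!run$psms$is_decoy & run$psms$rank == 1L, ]
  u <- tapply(long$peptide_seq, long$protein_ids,
              function(x) length(unique(x)))
  expect_true(all(names(stoichiometry(gt)) %in% names(u)))
  expect_true(all(u[names(stoichiometry(gt))] >= 2L))
})

test_that("decoy PSM fraction matches the injection rate within binomial error", {
  gt <- eif3GroundTruth(seed = 4)
  fr <- vapply(1:6, function(i) {
    r <- simulateRun(gt, "bait", paste0("B", i), seed = 100 + i)
    mean(r$psms$is_decoy)
  }, numeric(1))
  ## noise PSMs arrive at rate 0.3 per true PSM and land on targets and
  ## decoys evenly (equal-size databases): expected decoy share
  ## ~ 0.5 * 0.3 / 1.3, rank-2 siblings shifting it only slightly
  expected <- 0.5 * 0.3 / 1.3
  expect_equal(mean(fr), expected, tolerance = 0.25)
})

test_that("experiment sets round-trip through the on-disk formats", {
  gt <- eif3GroundTruth(seed = 12, nContaminants = 4, nBaitRuns = 2L)
  d <- tempfile()
  out <- simulateExperimentSet(gt, d)
  expect_equal(out$manifest$runs$role, c("bait", "bait", "control"))
  expect_true(all(file.exists(out$manifest$runs$psm_table)))

  m <- readRunManifest(out$manifest_path)
  expect_equal(m$bait_protein_id, "IF3E")
  for (i in seq_len(nrow(m$runs))) {
    back <- readPsmTable(m$runs$psm_table[i])
    expect_equal(nrow(back), nrow(out$runs[[i]]$psms))
  }
  pr <- readFasta(out$proteome_path)
  expect_equal(pr$protein_id, proteome(gt)$protein_id)
  expect_equal(pr$sequence, proteome(gt)$sequence)

  ## same master seed -> byte-identical files
  d2 <- tempfile()
  out2 <- simulateExperimentSet(gt, d2)
  expect_identical(readLines(out$manifest$runs$psm_table[1]),
                   readLines(out2$manifest$runs$psm_table[1]))
  unlink(c(d, d2), recursive = TRUE)
})

test_that("ground-truth validity rejects inconsistent scenarios", {
  gt <- eif3GroundTruth(seed = 1, nContaminants = 2)
  bad <- stoichiometry(gt)
  bad["IF3E"] <- 2
  expect_error(
    groundTruth(proteome(gt), "IF3E", bad, contaminants(gt)),
    "exactly 1")
  expect_error(
    groundTruth(proteome(gt), "IF3E", stoichiometry(gt),
                c(GHOST = 0.5)),
    "missing from proteome")
})
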