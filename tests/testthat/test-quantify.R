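test_that("PAF formula is linear in the count and scales by mass", {
  expect_equal(pafScore(20, 1e5), 2)
  expect_equal(pafScore(0, 5e4), 0)
  expect_equal(pafScore(10, 4e4), 2 * pafScore(5, 4e4))
  expect_error(pafScore(3, 0), "mwDa")
  expect_error(pafScore(-1, 100), "count")
})

test_that("top-3 area averages the three most intense peptides", {
  expect_equal(top3Area(c(9, 7, 5, 1)), 7)
  expect_equal(top3Area(c(8, 2)), 5)
  expect_equal(top3Area(numeric()), 0)
  expect_equal(top3Area(c(4, 1, 2, 3), n = 2L), 3.5)
})

test_that("per-run quantification counts peptides, spectra and areas", {
  # 3 unique peptides with PSM multiplicities 2/1/1, protein of 40 kDa
  psms <- makePsms(4,
    peptide_seq = c("AAAAAAK", "AAAAAAK", "CCCCCCK", "DDDDDDK"),
    intensity = c(5e6, 8e6, 3e6, 1e6),
    spectrum_id = sprintf("s%d", 1:4))
  prot <- makeProteome(c(P1 = "AAAAAAKCCCCCCKDDDDDDK"))
  prot$mw_da <- 40000
  rq <- quantifyRun(psms, prot, "P1")
  q <- quantTable(rq)
  expect_equal(q$U, 3L)
  expect_equal(q$S, 4L)
  expect_equal(q$paf, 3 / 40000 * 1e4)
  # per-peptide intensity is the max PSM intensity: (8e6 + 3e6 + 1e6) / 3
  expect_equal(q$top3_area, 4e6)
})

test_that("shared peptides count toward every mapped protein", {
  psms <- makePsms(2, peptide_seq = c("AAAAAAK", "CCCCCCK"),
                   protein_ids = "P1;P2")
  prot <- makeProteome(c(P1 = "AAAAAAKCCCCCCK", P2 = "AAAAAAKCCCCCCK"))
  rq <- quantifyRun(psms, prot, c("P1", "P2"))
  expect_equal(quantTable(rq)$U, c(2L, 2L))
})

test_that("a quantified protein missing from the proteome is an error", {
  psms <- makePsms(2, peptide_seq = c("AAAAAAK", "CCCCCCK"))
  prot <- makeProteome(c(P9 = "AAAAAAK"))
  expect_error(quantifyRun(psms, prot, "P1"), "absent from proteome")
})

test_that("quantification equals a brute-force recount on simulated runs", {
  cfg <- pullQuantConfig()
  for (s in 1:5) {
    gt <- eif3GroundTruth(seed = 100 + s, nContaminants = 2)
    run <- simulateRun(gt, "bait", "B1", seed = s)
    psms <- computeQvalues(run$psms)
    keep <- filterPsms(psms)$psms
    keep <- keep[seq_len(min(100, nrow(keep))), , drop = FALSE]
    passing <- filterProteins(keep, cfg$min_peptides)
    rq <- quantifyRun(keep, proteome(gt), passing, cfg)
    got <- quantTable(rq)[, c("protein_id", "U", "S", "top3_area", "paf")]
    got <- got[order(got$protein_id), ]
    rownames(got) <- NULL
    want <- oracleQuant(keep, proteome(gt), passing, cfg)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("spectral-count basis switches the PAF numerator", {
  psms <- makePsms(3, peptide_seq = c("AAAAAAK", "AAAAAAK", "CCCCCCK"),
                   spectrum_id = sprintf("s%d", 1:3))
  prot <- makeProteome(c(P1 = "AAAAAAKCCCCCCK"))
  prot$mw_da <- 2e4
  uq <- quantTable(quantifyRun(psms, prot, "P1",
                               pullQuantConfig(paf_basis = "unique")))
  sc <- quantTable(quantifyRun(psms, prot, "P1",
                               pullQuantConfig(paf_basis = "spectral")))
  expect_equal(uq$paf, 2 / 2e4 * 1e4)
  expect_equal(sc$paf, 3 / 2e4 * 1e4)
})

makeRq <- function(runId, ids, U, mw = 4e4, area = 1e6, role = "bait") {
  U <- as.integer(U)
  new("RunQuant", runId = runId, role = role,
      quant = data.frame(protein_id = ids, mw_da = mw, U = U, S = U,
                         top3_area = area, paf = U / mw * 1e4,
                         stringsAsFactors = FALSE),
      basis = "unique", pafScale = 1e4)
}

test_that("control subtraction clamps at zero and removes cancelled rows", {
  bait <- list(makeRq("B1", c("BAIT", "PREY", "CONT"), c(8, 8, 4)))
  ctl <- list(makeRq("C1", "CONT", 10, role = "control"))
  adj <- subtractControl(bait, ctl)
  tab <- quantTable(adj[[1]])
  # control mean PAF of CONT is 10/4e4*1e4 = 2.5 > its bait-run PAF 1.0
  expect_false("CONT" %in% tab$protein_id)
  expect_equal(tab$paf_adj, tab$paf)  # untouched proteins keep their PAF

  # partial subtraction: 2.0 - 0.5 = 1.5
  bait2 <- list(makeRq("B1", "P1", 8))          # paf 2.0
  ctl2 <- list(makeRq("C1", "P1", 2, role = "control"))  # paf 0.5
  adj2 <- subtractControl(bait2, ctl2)
  expect_equal(quantTable(adj2[[1]])$paf_adj, 1.5)

  # no control runs: identity
  adj3 <- subtractControl(bait)
  expect_equal(quantTable(adj3[[1]])$paf_adj,
               quantTable(bait[[1]])$paf)
})

test_that("control mean is taken over all control runs, absences as zero", {
  bait <- list(makeRq("B1", "P1", 8))                     # paf 2.0
  ctl <- list(makeRq("C1", "P1", 8, role = "control"),    # paf 2.0
              makeRq("C2", "OTHER", 8, role = "control")) # P1 absent -> 0
  adj <- subtractControl(bait, ctl)
  expect_equal(quantTable(adj[[1]])$paf_adj, 2.0 - 1.0)
})

test_that("bait normalization yields exact 1 for the bait and errors without it", {
  rq <- makeRq("B1", c("BAIT", "PREY"), c(8, 8), mw = c(4e4, 6.15e4))
  rel <- relativeToBait(rq, "BAIT")
  expect_equal(rel$rel_paf[rel$protein_id == "BAIT"], 1)
  expect_equal(rel$rel_paf[rel$protein_id == "PREY"],
               (8 / 6.15e4) / (8 / 4e4))
  expect_error(relativeToBait(makeRq("B2", "PREY", 4), "BAIT"),
               "absent or zero in bait run 'B2'")
})

test_that("relative PAF is invariant to a global rescaling of counts", {
  rq1 <- makeRq("B1", c("BAIT", "PREY"), c(5, 3))
  rq2 <- makeRq("B1", c("BAIT", "PREY"), c(15, 9))
  expect_equal(relativeToBait(rq1, "BAIT")$rel_paf,
               relativeToBait(rq2, "BAIT")$rel_paf)
})

test_that("replicate aggregation computes mean and sample SD with zeros", {
  prot <- makeProteome(c(BAIT = "AAAAAAK", P2 = "CCCCCCK"))
  mkRel <- function(run, ids, rel) data.frame(
    run_id = run, protein_id = ids, rel_paf = rel, top3_area = 1e6,
    stringsAsFactors = FALSE)
  rels <- list(
    mkRel("B1", c("BAIT", "P2"), c(1, 0.2)),
    mkRel("B2", "BAIT", 1),                    # P2 undetected -> 0
    mkRel("B3", c("BAIT", "P2"), c(1, 0.2)),
    mkRel("B4", c("BAIT", "P2"), c(1, 0.1)))
  ab <- aggregateReplicates(rels, prot, "BAIT")
  tab <- abundance(ab)
  b <- tab[tab$protein_id == "BAIT", ]
  expect_identical(c(b$mean_rel_paf, b$sd_rel_paf), c(1, 0))
  p <- tab[tab$protein_id == "P2", ]
  expect_equal(p$mean_rel_paf, mean(c(0.2, 0, 0.2, 0.1)))
  expect_equal(p$sd_rel_paf, sd(c(0.2, 0, 0.2, 0.1)))
  expect_equal(p$sd_rel_paf, 0.0957, tolerance = 1e-3)
  expect_equal(p$n_runs_detected, 3L)

  # detected-runs-only alternative
  ab2 <- aggregateReplicates(rels, prot, "BAIT",
                             config = pullQuantConfig(missing_as_zero = FALSE))
  p2 <- abundance(ab2)[abundance(ab2)$protein_id == "P2", ]
  expect_equal(p2$mean_rel_paf, mean(c(0.2, 0.2, 0.1)))

  # single run: SD 0 by convention
  ab3 <- aggregateReplicates(rels[1], prot, "BAIT")
  expect_true(all(abundance(ab3)$sd_rel_paf == 0))
})
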