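makeAreaRq <- function(runId, ids, areas) {
  U <- rep(2L, length(ids))
  new("RunQuant", runId = runId, role = "bait",
      quant = data.frame(protein_id = ids, mw_da = 4e4, U = U, S = U,
                         top3_area = areas, paf = U / 4e4 * 1e4,
                         stringsAsFactors = FALSE),
      basis = "unique", pafScale = 1e4)
}

test_that("category percentages are area shares per run", {
  rq <- makeAreaRq("B1", c("P1", "P2"), c(46, 54))
  cs <- compositionPercentages(list(rq), c(P1 = "A", P2 = "B"))
  expect_equal(unname(meanPercent(cs)[c("A", "B")]), c(46, 54))

  one <- compositionPercentages(list(rq), c(P1 = "A", P2 = "A"))
  expect_equal(unname(meanPercent(one)[["A"]]), 100)
})

test_that("mean composition averages per-run percentages, not areas", {
  r1 <- makeAreaRq("B1", c("P1", "P2"), c(50, 50))
  r2 <- makeAreaRq("B2", "P1", 100)
  cs <- compositionPercentages(list(r1, r2), c(P1 = "A", P2 = "B"))
  expect_equal(unname(meanPercent(cs)[c("A", "B")]), c(75, 25))
  expect_equal(cs@nRuns, 2L)
})

test_that("unmapped proteins fall into 'other' and runs sum to 100", {
  rq <- makeAreaRq("B1", c("P1", "P2", "P3"), c(20, 30, 50))
  cs <- compositionPercentages(list(rq), c(P1 = "A"))
  expect_true("other" %in% names(meanPercent(cs)))
  expect_equal(unname(meanPercent(cs)[["other"]]), 80)
  expect_equal(sum(perRunPercent(cs)[1, ]), 100)
})

test_that("composition is invariant to protein order and area rescaling", {
  ids <- c("P1", "P2", "P3", "P4")
  areas <- c(10, 25, 40, 25)
  map <- c(P1 = "A", P2 = "B", P3 = "A", P4 = "C")
  base <- compositionPercentages(list(makeAreaRq("B1", ids, areas)), map)
  perm <- sample(4)
  shuf <- compositionPercentages(
    list(makeAreaRq("B1", ids[perm], areas[perm])), map)
  expect_equal(meanPercent(base), meanPercent(shuf))
  scaled <- compositionPercentages(
    list(makeAreaRq("B1", ids, areas * 17)), map)
  expect_equal(meanPercent(base), meanPercent(scaled))
})

test_that("zero-area runs are excluded with a warning", {
  good <- makeAreaRq("B1", c("P1", "P2"), c(60, 40))
  empty <- makeAreaRq("B2", c("P1", "P2"), c(0, 0))
  expect_warning(cs <- compositionPercentages(list(good, empty),
                                              c(P1 = "A", P2 = "B")),
                 "zero total peak area")
  expect_equal(cs@nRuns, 1L)
  expect_equal(unname(meanPercent(cs)[["A"]]), 60)
})
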