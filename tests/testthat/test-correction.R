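test_that("bestResolution targets a third of the error length", {
  expect_equal(bestResolution(300000, c(1000, 5000, 10000, 1e5, 2.5e5)),
               1e5)
  expect_equal(bestResolution(3 * 5000, c(1000, 5000, 10000)), 5000)
  # equidistant target breaks ties toward the smaller resolution
  expect_equal(bestResolution(3 * 1500, c(1000, 2000)), 1000)
  expect_error(bestResolution(1000, numeric()), "non-empty")
  expect_error(bestResolution(0, 1000), "positive")
})

# hand-built contact fixture: 40 bins at 1 kb; the error occupies
# [10000, 13000); rows 30 (strong, all columns) and 20 (weak, one
# column) carry insertion-site peaks
twoPeakStore <- function() {
  m <- matrix(1, 40, 40)
  for (cc in 11:13) {
    m[31, cc] <- 50; m[cc, 31] <- 50    # peak at 0-based bin 30
    m[32, cc] <- 40; m[cc, 32] <- 40    # shoulder, pruned by distance
  }
  m[21, 11] <- 30; m[11, 21] <- 30      # single-column peak at bin 20
  storeFromMatrix(m, 1000)
}

test_that("findInsertionSite votes across error columns", {
  st <- twoPeakStore()
  site <- findInsertionSite(st, c(10000, 13000))
  expect_equal(as.numeric(site), 30000)   # majority site wins
  expect_equal(attr(site, "bin"), 30)
  # a featureless matrix has no peaks anywhere
  flat <- storeFromMatrix(matrix(5, 40, 40), 1000)
  expect_error(findInsertionSite(flat, c(10000, 13000)),
               class = "noInsertionSite")
})

test_that("insertion sites never fall inside the error interval", {
  for (seed in c(3, 8, 21, 34, 55)) {
    case <- singleTranslocationCase(seed)
    st <- simulateContactStore(case$doc, c(2500, 5000, 10000),
                               contactModel(),
                               truthContigLengths(case$truth))
    site <- tryCatch(findInsertionSite(st, case$error),
                     noInsertionSite = function(cnd) NULL)
    if (is.null(site)) next
    expect_false(site >= case$error[1] && site < case$error[2])
  }
})

test_that("findInsertionSite recovers a planted translocation origin", {
  case <- singleTranslocationCase(12)
  st <- simulateContactStore(case$doc, c(2500, 5000, 10000),
                             contactModel(),
                             truthContigLengths(case$truth))
  site <- findInsertionSite(st, case$error, refine = FALSE)
  expect_lte(abs(as.numeric(site) - case$trueIns),
             2 * attr(site, "resolution"))
  # the refinement stage is at least as close, on the finer grid
  fine <- findInsertionSite(st, case$error, refine = TRUE)
  expect_lte(abs(as.numeric(fine) - case$trueIns),
             2 * attr(site, "resolution"))
})

mkCall <- function(category, s, e, res = 1000) {
  data.frame(iteration = 1L, category = category, x_start = s, x_end = e,
             y_start = s, y_end = e, resolution = res, score = 1,
             tile_id = "t", status = "pending", stringsAsFactors = FALSE)
}

test_that("applyCorrection flips an inversion call's fragment", {
  doc <- toyDoc(c(100, 200, 300))
  st <- storeFromMatrix(matrix(1, 10, 10), 60)
  out <- applyCorrection(doc, mkCall("inversion", 100, 300, res = 10), st)
  expect_equal(out$call$status, "corrected")
  expect_equal(layoutSignature(out$doc)[2], "-ctgA:100-300")
  expect_equal(assemblyLength(out$doc), 600)
})

test_that("debris calls are skipped by default and applied on request", {
  doc <- toyDoc(c(100, 200, 300))
  st <- storeFromMatrix(matrix(1, 10, 10), 60)
  call <- mkCall("debris", 100, 300, res = 10)
  out <- applyCorrection(doc, call, st)
  expect_equal(out$call$status, "skipped")
  expect_equal(out$doc, doc)
  out2 <- applyCorrection(doc, call, st,
                          curationConfig(debris_mode = "adjust"))
  expect_equal(out2$call$status, "corrected")
  expect_equal(length(scaffoldLayout(out2$doc)), 2L)
})

test_that("a translocation whose site is its current position is a no-op", {
  local_mocked_bindings(
    findInsertionSite = function(store, error, refine = TRUE)
      structure(error[1], resolution = 1000, bin = error[1] / 1000),
    .package = "hicCurator")
  doc <- toyDoc(c(1000, 2000, 3000))
  st <- storeFromMatrix(matrix(1, 10, 10), 600)
  out <- applyCorrection(doc, mkCall("translocation", 1000, 3000), st)
  expect_equal(out$call$status, "corrected")
  expect_equal(layoutSignature(out$doc), layoutSignature(doc))
})

test_that("translocations without a findable site are skipped, not fatal", {
  doc <- toyDoc(c(10000, 20000, 10000))
  flat <- storeFromMatrix(matrix(2, 40, 40), 1000)
  out <- applyCorrection(doc, mkCall("translocation", 10000, 30000), flat)
  expect_equal(out$call$status, "skipped")
  expect_match(out$edit$reason, "no insertion site")
  expect_equal(out$doc, doc)
})

test_that("runIterations is a fixed point on an error-free genome", {
  case <- simCase(101, nEvents = 0)
  out <- runIterations(case$doc, case$detector, case$mapProvider,
                       curationConfig(error_min_len = 5000))
  expect_true(out$converged)
  expect_equal(nrow(out$logs), 1L)
  expect_equal(out$logs$edits, 0L)
  expect_equal(layoutSignature(out$doc), layoutSignature(case$doc))
})

test_that("runIterations corrects a planted inversion exactly", {
  case <- NULL
  for (seed in 200:230) {
    cand <- simCase(seed, nEvents = 1)
    if (truthEvents(cand$truth)$category[1] == "inversion") {
      case <- cand; break
    }
  }
  out <- runIterations(case$doc, case$detector, case$mapProvider,
                       curationConfig(error_min_len = 5000))
  expect_true(out$converged)
  expect_equal(sum(out$calls$status == "corrected"), 1L)
  expect_equal(layoutSignature(out$doc),
               layoutSignature(cleanDocument(case$truth)))
})

test_that("max_iterations = 0 returns the input untouched", {
  case <- simCase(300, nEvents = 2)
  out <- runIterations(case$doc, case$detector, case$mapProvider,
                       curationConfig(max_iterations = 0))
  expect_equal(out$doc, case$doc)
  expect_equal(nrow(out$logs), 0L)
  expect_false(out$converged)
})

test_that("a stalling detector aborts with a diagnostic", {
  case <- simCase(301, nEvents = 0)
  # detector that always reports the same phantom error
  phantom <- function(tile, doc) {
    b <- hicCurator:::genomeToBox(c(20000, 60000), c(20000, 60000), tile)
    if (is.null(b)) return(data.frame(category = character(),
                                      x1 = numeric(), y1 = numeric(),
                                      x2 = numeric(), y2 = numeric(),
                                      score = numeric()))
    data.frame(category = "inversion", x1 = b["x1"], y1 = b["y1"],
               x2 = b["x2"], y2 = b["y2"], score = 1,
               stringsAsFactors = FALSE)
  }
  expect_warning(
    out <- runIterations(case$doc, phantom, case$mapProvider,
                         curationConfig(error_min_len = 5000)),
    "did not decrease")
  expect_true(out$stalled)
})
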