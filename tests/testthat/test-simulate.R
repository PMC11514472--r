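test_that("makeGenome is seeded and respects its ranges", {
  g1 <- makeGenome(nContigs = 3, lengthRange = c(100000, 200000),
                   seed = 1)
  g2 <- makeGenome(nContigs = 3, lengthRange = c(100000, 200000),
                   seed = 1)
  expect_identical(as.character(g1$contigs), as.character(g2$contigs))
  expect_true(all(g1$contigLengths >= 1e5 & g1$contigLengths <= 2e5))
  expect_equal(assemblyLength(g1$doc), sum(g1$contigLengths))
  g3 <- makeGenome(nContigs = 3, lengthRange = c(100000, 200000),
                   seed = 2)
  expect_false(identical(as.character(g1$contigs),
                         as.character(g3$contigs)))
})

test_that("makeGenome hits the requested GC content", {
  g <- makeGenome(nContigs = 6, lengthRange = c(160000, 180000),
                  gc = 0.5, seed = 5)
  expect_lt(abs(gcContent(g$contigs) - 0.5), 0.02)
  g2 <- makeGenome(nContigs = 6, lengthRange = c(160000, 180000),
                   gc = 0.35, seed = 5)
  expect_lt(abs(gcContent(g2$contigs) - 0.35), 0.02)
})

test_that("fragmentAndShuffle cuts within range and shuffles the
           requested fraction", {
  g <- makeGenome(nContigs = 1, lengthRange = c(1e6, 1e6), seed = 3,
                  sequences = FALSE)
  fs <- fragmentAndShuffle(g$doc, seed = 3)
  clean <- cleanDocument(fs$truth)
  np <- nFragments(clean)
  expect_gte(np, 20)                       # 1 Mb / 50 kb
  expect_lte(np, 100)                      # 1 Mb / 10 kb
  lens <- fragmentTable(clean)$length
  expect_true(all(lens >= 10000))
  expect_true(all(lens < 60000))           # remainder folded into tail
  expect_equal(nrow(truthEvents(fs$truth)), round(0.6 * np))
  expect_equal(assemblyLength(fs$doc), 1e6)
  # identity when nothing is shuffled
  fs0 <- fragmentAndShuffle(g$doc, shuffleFrac = 0, seed = 3)
  expect_equal(nrow(truthEvents(fs0$truth)), 0L)
  expect_equal(layoutSignature(fs0$doc),
               layoutSignature(cleanDocument(fs0$truth)))
  expect_error(fragmentAndShuffle(g$doc, shuffleFrac = 2), "\\[0, 1\\]")
})

test_that("contact decay is monotone within a chromosome on clean input", {
  g <- makeGenome(nContigs = 2, lengthRange = c(100000, 120000),
                  seed = 4, sequences = FALSE)
  st <- simulateContactStore(g$doc, 5000, contactModel(),
                             g$contigLengths)
  m <- contactMatrix(st, 5000)
  n1 <- floor(g$contigLengths[1] / 5000)    # bins fully inside contig 1
  expect_true(all(diff(m[1, 1:n1]) < 0))
  # symmetric and capped at s0 on the diagonal
  expect_equal(m, t(m))
  expect_equal(max(m), 100)
  # cross-chromosome attenuation
  expect_lt(m[1, n1 + 2], m[1, n1] )
})

test_that("a planted inversion produces the butterfly corner signature", {
  doc <- toyDoc(c(50000, 30000, 50000), contig = "ctgA")
  doc@layout[[1]] <- c(1, -2, 3)           # middle block inverted
  st <- simulateContactStore(doc, 5000, contactModel(),
                             c(ctgA = 130000))
  m <- contactMatrix(st, 5000)
  # apparent far corner of the inverted block touches sequence that is
  # truly adjacent: its contact must exceed the clean-decay expectation
  # for its apparent distance
  aBin <- 9                                 # last bin before the block
  bBin <- 15                                # far edge of inverted block
  apparent <- abs(aBin - bBin)
  expect_gt(m[aBin + 1, bBin + 1], 100 * (1 + apparent)^-1)
})

test_that("contact simulation is deterministic given the seed", {
  case <- simCase(77, nEvents = 3)
  s1 <- simulateContactStore(case$doc, c(5000, 10000),
                             contactModel(noise = "poisson", seed = 9),
                             truthContigLengths(case$truth))
  s2 <- simulateContactStore(case$doc, c(5000, 10000),
                             contactModel(noise = "poisson", seed = 9),
                             truthContigLengths(case$truth))
  expect_identical(contactMatrix(s1, 5000), contactMatrix(s2, 5000))
  expect_identical(contactMatrix(s1, 10000), contactMatrix(s2, 10000))
})

test_that("debris pieces zero out their contact rows and columns", {
  g <- makeGenome(nContigs = 1, lengthRange = c(400000, 400000),
                  seed = 6, sequences = FALSE)
  fs <- fragmentAndShuffle(g$doc, shuffleFrac = 0, seed = 6,
                           debrisFrac = 0.1)
  ev <- truthEvents(fs$truth)
  expect_true(all(ev$category == "debris"))
  expect_gt(nrow(ev), 0)
  st <- simulateContactStore(fs$doc, 5000, contactModel(),
                             truthContigLengths(fs$truth),
                             debrisPieces = ev$piece)
  m <- contactMatrix(st, 5000)
  fl <- hicCurator:::flattenLayout(fs$doc)
  i <- match(ev$piece[1], fl$name)
  bins <- which(seq(2500, by = 5000, length.out = nrow(m)) >=
                  fl$start[i] &
                seq(2500, by = 5000, length.out = nrow(m)) < fl$end[i])
  expect_true(all(m[bins, ] == 0))
  expect_true(all(m[, bins] == 0))
})

test_that("bin permutations are bijective and undo the shuffle", {
  case <- simCase(88, nEvents = 4)
  for (r in c(5000, 10000)) {
    p <- binPermutation(case$doc, r, truthContigLengths(case$truth))
    expect_setequal(p, seq_along(p))       # a true permutation
    inv <- order(p)
    expect_equal(p[inv], seq_along(p))     # applied then inverted
  }
  # the clean document induces the identity permutation
  pClean <- binPermutation(cleanDocument(case$truth), 5000,
                           truthContigLengths(case$truth))
  expect_equal(pClean, seq_along(pClean))
})

test_that("the oracle detector emits exact, clipped event boxes", {
  case <- simCase(99, nEvents = 2)
  st <- case$mapProvider(case$doc)
  Lg <- genomeLength(st)
  region <- fetchRegion(st, 5000, c(0, Lg), c(0, Lg))
  tile <- renderTile(region, quantileThreshold(region@values), id = "g")
  boxes <- case$detector(tile, case$doc)
  errBoxes <- boxes[boxes$category != "chromosome", , drop = FALSE]
  expect_equal(nrow(errBoxes), 2L)
  calls <- boxToGenome(errBoxes, tile)
  fl <- hicCurator:::flattenLayout(case$doc)
  ev <- truthEvents(case$truth)
  for (i in seq_len(nrow(calls))) {
    slot <- match(ev$piece[i], fl$name)
    expect_lte(abs(calls$x_start[i] - fl$start[slot]), 5000)
    expect_lte(abs(calls$x_end[i] - fl$end[slot]), 5000)
  }
  # an error-free document yields no error boxes
  cleanBoxes <- case$detector(tile, cleanDocument(case$truth))
  expect_equal(sum(cleanBoxes$category != "chromosome"), 0L)
  # a tile away from the events holds clipped or no boxes
  sub <- fetchRegion(st, 5000, c(0, 40000), c(0, 40000))
  subTile <- renderTile(sub, quantileThreshold(sub@values), id = "s")
  subBoxes <- case$detector(subTile, case$doc)
  if (nrow(subBoxes)) {
    expect_true(all(subBoxes$x1 >= 0 & subBoxes$x2 <= ncol(subTile@pixels)))
    expect_true(all(subBoxes$y1 >= 0 & subBoxes$y2 <= nrow(subTile@pixels)))
  }
})
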