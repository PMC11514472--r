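canonicalText <- c(">ctgA:0-100 1 100",
                   ">ctgA:100-300 2 200",
                   ">ctgB:0-300 3 300",
                   "1 -2 3")

test_that("readAssembly parses fragments, orientations and layout", {
  doc <- readAssembly(canonicalText)
  expect_equal(nFragments(doc), 3L)
  expect_equal(fragmentTable(doc)$length, c(100, 200, 300))
  expect_equal(scaffoldLayout(doc)[[1]], c(1, -2, 3))
  expect_equal(assemblyLength(doc), 600)
})

test_that("assembly text round trips bit-exactly", {
  expect_identical(writeAssembly(readAssembly(canonicalText)),
                   canonicalText)
  doc <- readAssembly(canonicalText)
  expect_equal(readAssembly(writeAssembly(doc)), doc)
})

test_that("malformed assembly text raises named format errors", {
  expect_error(readAssembly(c(">a:0-1 1 1", ">b:0-1 1 1", "1")),
               "duplicate")
  expect_error(readAssembly(c(">a:0-9 1 9", "1 4")), "unknown")
  expect_error(readAssembly(c(">a:0-9 1 9", ">b:0-9 2 9", "1")),
               "missing from the layout")
  expect_error(readAssembly(c(">a:0-9 1 9", "1 1")), "more than once")
})

test_that("locateAssembly maps positions through the layout", {
  doc <- toyDoc(c(100, 200, 300))
  loc <- locateAssembly(doc, 150)
  expect_equal(loc$fragmentId, 2L)
  expect_equal(loc$offset, 50)
  expect_equal(locateAssembly(doc, 0)$fragmentId, 1L)
  expect_equal(locateAssembly(doc, 0)$offset, 0)
  loc2 <- locateAssembly(doc, 599)
  expect_equal(loc2$fragmentId, 3L)
  expect_equal(loc2$offset, 299)
  expect_error(locateAssembly(doc, 600), "out of range")
})

test_that("splitFragmentAt cuts on the assembly axis", {
  doc <- toyDoc(c(100, 200, 300))
  cut <- splitFragmentAt(doc, 150)     # inside fragment 2 at offset 50
  expect_equal(nFragments(cut), 4L)
  expect_equal(fragmentTable(cut)$length, c(100, 50, 150, 300))
  expect_equal(assemblyLength(cut), 600)
  expect_equal(fragmentTable(cut)$name[2:3],
               c("ctgA:100-150", "ctgA:150-300"))
  # boundary cut is a no-op
  expect_equal(splitFragmentAt(doc, 100), doc)
  expect_equal(splitFragmentAt(doc, 0), doc)
})

test_that("splitFragmentAt reflects the cut point for reverse fragments", {
  doc <- toyDoc(c(100, 200, 300))
  doc@layout[[1]] <- c(1, -2, 3)
  cut <- splitFragmentAt(doc, 150)     # assembly offset 50 into -frag 2
  # native pieces are 150 and 50; assembly-left piece is the native-right
  expect_equal(fragmentTable(cut)$length, c(100, 50, 150, 300))
  expect_equal(fragmentTable(cut)$name[2:3],
               c("ctgA:250-300", "ctgA:100-250"))
  fl <- hicCurator:::flattenLayout(cut)
  expect_true(all(fl$signedId[2:3] < 0))
})

test_that("moveBlock repositions fragment runs", {
  doc <- toyDoc(c(100, 200, 300))
  moved <- moveBlock(doc, 300, 600, 0)        # fragment 3 to the front
  expect_equal(layoutSignature(moved),
               c("+ctgA:300-600", "+ctgA:0-100", "+ctgA:100-300"))
  expect_equal(assemblyLength(moved), 600)
  # identity move
  expect_equal(moveBlock(doc, 300, 600, 600), doc)
  # move there and back restores the layout
  back <- moveBlock(moved, 0, 300, 600)
  expect_equal(layoutSignature(back), layoutSignature(doc))
  expect_error(moveBlock(doc, 100, 300, 200), "inside the block")
})

test_that("invertBlock reverses and negates; an involution", {
  doc <- toyDoc(c(100, 200, 300))
  inv <- invertBlock(doc, 100, 600)           # block `2 3` -> `-3 -2`
  expect_equal(layoutSignature(inv),
               c("+ctgA:0-100", "-ctgA:300-600", "-ctgA:100-300"))
  expect_equal(layoutSignature(invertBlock(inv, 100, 600)),
               layoutSignature(doc))
  one <- invertBlock(doc, 100, 300)           # single fragment flips
  expect_equal(layoutSignature(one)[2], "-ctgA:100-300")
  expect_equal(assemblyLength(inv), 600)
})

test_that("relegateDebris appends blocks to one leftover scaffold", {
  doc <- toyDoc(c(100, 200, 300))
  out <- relegateDebris(doc, 100, 300)        # fragment 2 to the tail
  expect_equal(length(scaffoldLayout(out)), 2L)
  expect_equal(layoutSignature(out),
               c("+ctgA:0-100", "+ctgA:300-600", "+ctgA:100-300"))
  expect_equal(assemblyLength(out), 600)
  # successive relegations accumulate in the same scaffold
  out2 <- relegateDebris(out, 0, 100)
  expect_equal(length(scaffoldLayout(out2)), 2L)
  expect_equal(layoutSignature(out2),
               c("+ctgA:300-600", "+ctgA:100-300", "+ctgA:0-100"))
})

test_that("buildScaffoldFasta assembles slices, strands and gaps", {
  contig <- Biostrings::DNAStringSet(c(ctgA = "ACGTACGTACGTACGTACGT"))
  doc <- toyDoc(c(8, 12), contig = "ctgA")
  fa <- buildScaffoldFasta(doc, contig, gapLen = 0)
  expect_equal(as.character(fa[[1]]), "ACGTACGTACGTACGTACGT")
  # reverse orientation: independent complement-and-reverse oracle
  doc@layout[[1]] <- c(1, -2)
  fa2 <- buildScaffoldFasta(doc, contig, gapLen = 0)
  slice <- substr("ACGTACGTACGTACGTACGT", 9, 20)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", slice), "")[[1]]),
              collapse = "")
  expect_equal(as.character(fa2[[1]]),
               paste0(substr("ACGTACGTACGTACGTACGT", 1, 8), rc))
  # gaps of exactly gapLen Ns between fragments
  fa3 <- buildScaffoldFasta(toyDoc(c(8, 12)), contig, gapLen = 500)
  expect_equal(Biostrings::width(fa3)[1], 20 + 500)
  expect_equal(as.character(Biostrings::subseq(fa3[[1]], 9, 508)),
               strrep("N", 500))
  expect_error(buildScaffoldFasta(toyDoc(10, contig = "nope"), contig),
               "unknown contig")
})

test_that("random edit chains conserve length and base content", {
  contig <- Biostrings::DNAStringSet(c(
    ctgA = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                 collapse = "")))
  # inversion emits the reverse complement, so literal base counts are
  # only conserved up to strand symmetry (A+T and C+G totals)
  baseCount <- function(fa) {
    f <- Biostrings::alphabetFrequency(fa, collapse = TRUE)
    c(AT = unname(f["A"] + f["T"]), CG = unname(f["C"] + f["G"]))
  }
  ref <- baseCount(contig)
  set.seed(33)
  for (rep_ in 1:10) {
    doc <- toyDoc(c(1000, 800, 1200))
    for (step in 1:8) {
      op <- sample(c("split", "move", "invert", "relegate"), 1)
      fl <- hicCurator:::flattenLayout(doc)
      bounds <- unique(c(0, fl$end))
      if (op == "split") {
        doc <- splitFragmentAt(doc, sample(0:3000, 1))
      } else {
        i <- sample(nrow(fl), 1)
        s <- fl$start[i]; e <- fl$end[i]
        if (op == "move") {
          ins <- setdiff(bounds, c(s, e))
          doc <- moveBlock(doc, s, e, ins[sample.int(length(ins), 1)])
        } else if (op == "invert") {
          doc <- invertBlock(doc, s, e)
        } else {
          doc <- relegateDebris(doc, s, e)
        }
      }
      expect_equal(assemblyLength(doc), 3000)
    }
    fa <- buildScaffoldFasta(doc, contig, gapLen = 0)
    expect_equal(baseCount(fa), ref)
    # provenance intervals still partition the contig exactly
    pv <- hicCurator:::parseProvenance(fragmentTable(doc)$name)
    pv <- pv[order(pv$start), ]
    expect_equal(pv$start, c(0, pv$end[-nrow(pv)]))
    expect_equal(max(pv$end), 3000)
  }
})

test_that("mergeAdjacentFragments undoes cuts without changing sequence", {
  doc <- toyDoc(c(100, 200, 300))
  cut <- splitFragmentAt(splitFragmentAt(doc, 150), 400)
  expect_equal(layoutSignature(mergeAdjacentFragments(cut)),
               c("+ctgA:0-600"))   # forward contiguity fuses everything
  # reverse-oriented contiguous pair fuses too
  inv <- invertBlock(cut, 100, 300)
  merged <- mergeAdjacentFragments(inv)
  expect_equal(layoutSignature(merged),
               c("+ctgA:0-100", "-ctgA:100-300", "+ctgA:300-600"))
  # a true rearrangement is not merged away
  moved <- moveBlock(doc, 300, 600, 0)
  expect_equal(layoutSignature(mergeAdjacentFragments(moved)),
               c("+ctgA:300-600", "+ctgA:0-300"))
})

test_that("generated documents round trip through the text format", {
  set.seed(44)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    lens <- sample(50:5000, n, replace = TRUE)
    perm <- sample(n)
    signs <- sample(c(-1, 1), n, replace = TRUE)
    nScaf <- sample(1:min(3, n), 1)
    cuts <- sort(sample(seq_len(n), nScaf - 1))
    grp <- findInterval(seq_len(n), c(0, cuts) + 1)
    doc <- toyDoc(lens, layout = split(perm * signs, grp))
    txt <- writeAssembly(doc)
    expect_identical(writeAssembly(readAssembly(txt)), txt)
  }
})
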