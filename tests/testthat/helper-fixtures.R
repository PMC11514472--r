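# fixture builders shared across test files; everything is generated in
# code so the suite ships no binary data

# an AssemblyDoc from fragment lengths; provenance names place the
# fragments back to back on one synthetic contig per scaffold
toyDoc <- function(lengths, layout = list(seq_along(lengths)),
                   contig = "ctgA") {
  starts <- cumsum(c(0, lengths))[seq_along(lengths)]
  fr <- data.frame(
    name = sprintf("%s:%d-%d", contig, starts, starts + lengths),
    id = seq_along(lengths), length = as.numeric(lengths),
    stringsAsFactors = FALSE)
  new("AssemblyDoc", fragments = fr,
      layout = lapply(layout, as.numeric))
}

# signed layout signature of a document: fragment names with
# orientation, in flattened order (scaffold structure ignored)
layoutSignature <- function(doc) {
  fl <- hicCurator:::flattenLayout(doc)
  paste0(ifelse(fl$signedId < 0, "-", "+"), fl$name)
}

# sequence-level signature on the flattened assembly axis: cuts at
# identical coordinates are invisible in the emitted genome, and
# pre-assignment scaffold grouping is bookkeeping (chromosome
# assignment re-derives it), so collapse scaffolds before merging
canonicalSignature <- function(doc) {
  doc@layout <- list(unlist(doc@layout))
  layoutSignature(mergeAdjacentFragments(doc))
}

# a small deterministic ContactStore built from an explicit matrix
storeFromMatrix <- function(m, resolution, Lg = nrow(m) * resolution) {
  ContactStore(list(m), genomeLength = Lg, resolutions = resolution)
}

# one simulated misassembly scenario: nEvents disturbed pieces over
# nContigs contigs, with the matched oracle detector and map provider
simCase <- function(seed, nEvents, nContigs = 3,
                    lengthRange = c(250000, 400000),
                    resolutions = c(2500, 5000, 10000),
                    noise = "none") {
  g <- makeGenome(nContigs = nContigs, lengthRange = lengthRange,
                  seed = seed, sequences = FALSE)
  probe <- fragmentAndShuffle(g$doc, shuffleFrac = 0, seed = 1)
  np <- nFragments(cleanDocument(probe$truth))
  fs <- fragmentAndShuffle(g$doc, shuffleFrac = nEvents / np, seed = seed)
  tr <- fs$truth
  model <- contactModel(noise = noise, seed = seed)
  list(
    doc = fs$doc, truth = tr, resolutions = resolutions,
    detector = makeOracleDetector(tr),
    mapProvider = function(doc)
      simulateContactStore(doc, resolutions, model,
                           truthContigLengths(tr)))
}

# draw scenarios until the single event is a translocation; returns the
# scenario plus the true insertion junction in current coordinates
singleTranslocationCase <- function(seed, ...) {
  g <- makeGenome(nContigs = 3, lengthRange = c(300000, 380000),
                  seed = seed, sequences = FALSE)
  probe <- fragmentAndShuffle(g$doc, shuffleFrac = 0, seed = 1)
  np <- nFragments(cleanDocument(probe$truth))
  for (try in 0:100) {
    fs <- fragmentAndShuffle(g$doc, shuffleFrac = 1 / np,
                             seed = seed * 53 + try)
    ev <- truthEvents(fs$truth)
    if (nrow(ev) == 1 && ev$category == "translocation") {
      fl <- hicCurator:::flattenLayout(fs$doc)
      pv <- hicCurator:::parseProvenance(fl$name)
      nb <- which(pv$contig == ev$contig & pv$end == ev$trueStart)
      trueIns <- if (length(nb)) fl$end[nb[1]] else {
        nb2 <- which(pv$contig == ev$contig & pv$start == ev$trueEnd)
        fl$start[nb2[1]]
      }
      i <- match(ev$piece, fl$name)
      return(list(doc = fs$doc, truth = fs$truth,
                  error = c(fl$start[i], fl$end[i]), trueIns = trueIns))
    }
  }
  stop("no single-translocation draw found")
}
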