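#' Generate a toy genome with one scaffold per contig
#'
#' Contig lengths are uniform in `lengthRange`; bases are drawn i.i.d.
#' with the requested GC content. Fragment names carry
#' `contig:start-end` provenance so every later edit can be traced back
#' to native coordinates. Deterministic for a fixed seed.
#'
#' @param nContigs number of contigs (simulated chromosomes).
#' @param lengthRange length-2 bp interval for contig lengths.
#' @param gc target GC fraction.
#' @param seed RNG seed.
#' @param sequences generate bases? With `FALSE` only the document and
#'   lengths are returned (much faster for contact-map-only studies).
#' @return list with `contigs` (a [Biostrings::DNAStringSet] or `NULL`),
#'   `doc` (an [AssemblyDoc-class]) and `contigLengths` (named vector).
#' @export
makeGenome <- function(nContigs = 3, lengthRange = c(100000, 200000),
                       gc = 0.5, seed = 1, sequences = TRUE) {
  stopifnot(nContigs >= 1, lengthRange[1] > 0,
            lengthRange[2] >= lengthRange[1], gc >= 0, gc <= 1)
  set.seed(seed)
  rng <- seq(lengthRange[1], lengthRange[2])
  lens <- rng[sample.int(length(rng), nContigs, replace = TRUE)]
  names(lens) <- sprintf("ctg%d", seq_len(nContigs))
  fr <- data.frame(
    name = sprintf("%s:0-%d", names(lens), lens),
    id = seq_len(nContigs), length = as.numeric(lens),
    stringsAsFactors = FALSE)
  doc <- new("AssemblyDoc", fragments = fr,
             layout = as.list(as.numeric(seq_len(nContigs))))
  contigs <- NULL
  if (sequences) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    contigs <- Biostrings::DNAStringSet(vapply(lens, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      ""))
    names(contigs) <- names(lens)
  }
  list(contigs = contigs, doc = doc, contigLengths = as.numeric(lens) |>
         stats::setNames(names(lens)))
}

## cut one fragment length into piece lengths uniform in pieceRange.
## A trailing remainder shorter than the minimum is folded into the
## final piece so pieces stay within the stated range (a sub-minimum
## sliver would be unresolvable at any usable contact resolution).
cutLengths <- function(L, pieceRange) {
  out <- numeric()
  left <- L
  rng <- seq(pieceRange[1], pieceRange[2])
  while (left > 0) {
    len <- min(left, rng[sample.int(length(rng), 1L)])
    if (left - len > 0 && left - len < pieceRange[1]) len <- left
    out <- c(out, len)
    left <- left - len
  }
  out
}

#' Cut contigs into pieces and shuffle a fraction of them
#'
#' Emulates misassembly generation: every contig is cut into pieces
#' with lengths uniform in `pieceRange` (10-50 kb by default; the last
#' piece of a contig may be shorter), then `round(shuffleFrac * n)`
#' pieces are selected without replacement and each is independently
#' either moved to a uniformly chosen foreign fragment boundary
#' (a translocation) or sign-flipped in place (an inversion), with
#' equal probability. An optional further fraction is marked as debris
#' (contact-signal dropout; the layout is untouched). Every event is
#' recorded in the returned [GroundTruth-class].
#'
#' @param doc a clean [AssemblyDoc-class] (e.g. from [makeGenome()]).
#' @param pieceRange length-2 bp interval for piece lengths.
#' @param shuffleFrac fraction of pieces to disturb (default 0.6).
#' @param seed RNG seed.
#' @param moveProb probability that a disturbed piece is moved rather
#'   than flipped.
#' @param debrisFrac fraction of (undisturbed) pieces to mark as debris.
#' @return list with `doc` (the misassembled document) and `truth`
#'   (a [GroundTruth-class]).
#' @export
fragmentAndShuffle <- function(doc, pieceRange = c(10000, 50000),
                               shuffleFrac = 0.6, seed = 1,
                               moveProb = 0.5, debrisFrac = 0) {
  if (shuffleFrac < 0 || shuffleFrac > 1)
    stop("shuffleFrac must be in [0, 1]")
  stopifnot(pieceRange[1] > 0, pieceRange[2] >= pieceRange[1])
  set.seed(seed)
  fl <- flattenLayout(doc)
  pv <- parseProvenance(fl$name)
  ## cut every fragment into pieces, preserving scaffold structure
  rows <- list()
  for (i in seq_len(nrow(fl))) {
    lens <- cutLengths(fl$length[i], pieceRange)
    ends <- pv$start[i] + cumsum(lens)
    starts <- ends - lens
    rows[[i]] <- data.frame(
      scaffold = fl$scaffold[i],
      name = sprintf("%s:%s-%s", pv$contig[i],
                     format(starts, scientific = FALSE, trim = TRUE),
                     format(ends, scientific = FALSE, trim = TRUE)),
      length = lens, sign = sign(fl$signedId[i]),
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  rows$signedId <- seq_len(nrow(rows)) * rows$sign
  rows$id <- seq_len(nrow(rows))
  rows$end <- cumsum(rows$length); rows$start <- rows$end - rows$length
  clean <- docFromFlat(rows)
  ## choose pieces to disturb
  n <- nrow(rows)
  nEvents <- round(shuffleFrac * n)
  chosen <- if (nEvents > 0) sample(n, nEvents) else integer()
  isMove <- stats::runif(length(chosen)) < moveProb
  cur <- clean
  events <- list()
  for (k in seq_along(chosen)) {
    nm <- rows$name[chosen[k]]
    pvk <- parseProvenance(nm)
    flc <- flattenLayout(cur)
    slot <- match(nm, flc$name)
    s <- flc$start[slot]; e <- flc$end[slot]
    if (isMove[k]) {
      bounds <- setdiff(unique(c(0, flc$end)), c(s, e))
      ins <- bounds[sample.int(length(bounds), 1L)]
      cur <- moveBlock(cur, s, e, ins)
      cat_ <- "translocation"
    } else {
      cur <- invertBlock(cur, s, e)
      cat_ <- "inversion"
    }
    events[[length(events) + 1L]] <- data.frame(
      category = cat_, piece = nm, contig = pvk$contig,
      trueStart = pvk$start, trueEnd = pvk$end, stringsAsFactors = FALSE)
  }
  if (debrisFrac > 0) {
    pool <- setdiff(seq_len(n), chosen)
    nDebris <- min(length(pool), round(debrisFrac * n))
    for (i in if (nDebris > 0) sample(pool, nDebris) else integer()) {
      pvk <- parseProvenance(rows$name[i])
      events[[length(events) + 1L]] <- data.frame(
        category = "debris", piece = rows$name[i], contig = pvk$contig,
        trueStart = pvk$start, trueEnd = pvk$end, stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(category = character(), piece = character(),
               contig = character(), trueStart = numeric(),
               trueEnd = numeric(), stringsAsFactors = FALSE)
  contigLengths <- vapply(split(pv$end, pv$contig), max, 1)
  ## preserve the contig order of the input document
  contigLengths <- contigLengths[unique(pv$contig)]
  truth <- new("GroundTruth", events = events, cleanDoc = clean,
               contigLengths = contigLengths)
  list(doc = cur, truth = truth)
}

#' Distance-decay contact model parameters
#'
#' @param alpha power-law decay exponent (expected contact between bins
#'   at true genomic distance `d` bins is `s0 * (1 + d)^-alpha`).
#' @param s0 base intensity at distance zero, in contacts.
#' @param noise `"none"` (expectations) or `"poisson"` (sampled counts).
#' @param crossScale attenuation factor for bin pairs on different
#'   chromosomes (default 0.1).
#' @param seed RNG seed for the Poisson draw.
#' @return a named list.
#' @export
contactModel <- function(alpha = 1, s0 = 100,
                         noise = c("none", "poisson"),
                         crossScale = 0.1, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(alpha > 0, s0 > 0, crossScale >= 0)
  list(alpha = alpha, s0 = s0, noise = noise, crossScale = crossScale,
       seed = seed)
}

## per-bin true genomic midpoints and chromosome, from provenance.
## Returns data.frame(mid, truePos, chrom) with one row per bin.
binTruePositions <- function(doc, resolution, contigLengths) {
  fl <- flattenLayout(doc)
  pv <- parseProvenance(fl$name)
  offsets <- cumsum(c(0, contigLengths))[seq_along(contigLengths)]
  names(offsets) <- names(contigLengths)
  Lg <- assemblyLength(doc)
  nb <- ceiling(Lg / resolution)
  mid <- (seq_len(nb) - 1) * resolution +
    pmin(resolution, Lg - (seq_len(nb) - 1) * resolution) / 2
  k <- findInterval(mid, fl$start)
  off <- mid - fl$start[k]
  native <- ifelse(sign(fl$signedId[k]) > 0,
                   pv$start[k] + off,
                   pv$end[k] - off)
  data.frame(mid = mid, truePos = offsets[pv$contig[k]] + native,
             chrom = pv$contig[k], stringsAsFactors = FALSE)
}

#' Bin permutation induced by an assembly arrangement
#'
#' Ranks the bins of the document's assembly axis by the true genomic
#' position of their midpoints; the result is a bijective permutation
#' (ties broken by assembly order) whose inverse sorts the map back to
#' the clean diagonal.
#'
#' @param doc an [AssemblyDoc-class] with provenance fragment names.
#' @param resolution bin size in bp.
#' @param contigLengths named vector of original contig lengths, in
#'   original genome order.
#' @return integer vector `p` with `p[i]` = true-order rank of assembly
#'   bin `i`.
#' @export
binPermutation <- function(doc, resolution, contigLengths) {
  tp <- binTruePositions(doc, resolution, contigLengths)
  rank(tp$truePos, ties.method = "first")
}

#' Synthesize a multi-resolution contact store for an assembly
#'
#' Expected contact between assembly bins p and q is
#' `s0 * (1 + d(p,q))^-alpha`, where `d` is the distance in bins
#' between the bins' *true* genomic midpoints (via fragment
#' provenance), attenuated by `crossScale` when the bins' true
#' positions lie on different chromosomes. Planted inversions therefore
#' produce anti-diagonal "butterfly" blocks and translocations
#' off-diagonal bands, by construction. With `noise = "poisson"` the
#' upper triangle is sampled and mirrored, keeping the matrix symmetric.
#'
#' @param doc an [AssemblyDoc-class] with provenance fragment names.
#' @param resolutions ascending bin sizes in bp.
#' @param model a [contactModel()] list.
#' @param contigLengths named vector of original contig lengths in
#'   original order.
#' @param debrisPieces fragment names whose bins get zeroed rows and
#'   columns (signal dropout).
#' @return a [ContactStore-class].
#' @export
simulateContactStore <- function(doc, resolutions,
                                 model = contactModel(),
                                 contigLengths, debrisPieces = character()) {
  Lg <- assemblyLength(doc)
  stopifnot(ceiling(Lg / max(resolutions)) >= 10)
  if (!is.null(model$seed)) set.seed(model$seed)
  fl <- flattenLayout(doc)
  mats <- lapply(resolutions, function(r) {
    tp <- binTruePositions(doc, r, contigLengths)
    d <- abs(outer(tp$truePos, tp$truePos, "-")) / r
    m <- model$s0 * (1 + d)^(-model$alpha)
    if (model$crossScale != 1) {
      cross <- outer(tp$chrom, tp$chrom, "!=")
      m[cross] <- m[cross] * model$crossScale
    }
    if (length(debrisPieces)) {
      sl <- match(debrisPieces, fl$name)
      sl <- sl[!is.na(sl)]
      for (i in sl) {
        bins <- which(tp$mid >= fl$start[i] & tp$mid < fl$end[i])
        m[bins, ] <- 0
        m[, bins] <- 0
      }
    }
    if (model$noise == "poisson") {
      up <- upper.tri(m, diag = TRUE)
      m[up] <- stats::rpois(sum(up), m[up])
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    m
  })
  ContactStore(mats, Lg, resolutions)
}

## is a tracked piece at its correct position and orientation? An
## interior piece must abut its native neighbours; a contig-boundary
## piece must additionally sit at a contig seam (its outer neighbour,
## if any, is a boundary piece of a *different* contig), otherwise a
## whole contig head/tail parked elsewhere would look anchored
pieceInPlace <- function(fl, pv, contigLengths, slot) {
  if (sign(fl$signedId[slot]) < 0) return(FALSE)
  s <- pv$start[slot]; e <- pv$end[slot]; ctg <- pv$contig[slot]
  leftOK <- if (s == 0) {
    slot == 1L ||
      (pv$contig[slot - 1L] != ctg &&
         pv$end[slot - 1L] == contigLengths[[pv$contig[slot - 1L]]] &&
         sign(fl$signedId[slot - 1L]) > 0)
  } else {
    slot > 1L && pv$contig[slot - 1L] == ctg &&
      pv$end[slot - 1L] == s && sign(fl$signedId[slot - 1L]) > 0
  }
  rightOK <- if (e == contigLengths[[ctg]]) {
    slot == nrow(fl) ||
      (pv$contig[slot + 1L] != ctg && pv$start[slot + 1L] == 0 &&
         sign(fl$signedId[slot + 1L]) > 0)
  } else {
    slot < nrow(fl) && pv$contig[slot + 1L] == ctg &&
      pv$start[slot + 1L] == e && sign(fl$signedId[slot + 1L]) > 0
  }
  leftOK && rightOK
}

#' Ground-truth oracle detector
#'
#' Builds a detector (the `function(tile, doc)` contract used by
#' [detectErrors()] and [detectChromosomes()]) that emits one box per
#' simulated event still present in the current document: a flipped
#' piece yields an inversion box while its sign is negative, a moved
#' piece a translocation box while it is not flanked by its native
#' neighbours, a debris piece a debris box, and each chromosome whose
#' pieces are currently contiguous a chromosome box. Box corners are
#' the exact (continuous-pixel) inverse of [boxToGenome()], clipped to
#' the tile; scores are 1.
#'
#' @param truth a [GroundTruth-class].
#' @return a detector function.
#' @export
makeOracleDetector <- function(truth) {
  events <- truth@events
  contigLengths <- truth@contigLengths
  function(tile, doc) {
    fl <- flattenLayout(doc)
    pv <- parseProvenance(fl$name)
    boxes <- list()
    addBox <- function(category, interval) {
      b <- genomeToBox(interval, interval, tile)
      if (!is.null(b))
        boxes[[length(boxes) + 1L]] <<- data.frame(
          category = category, x1 = b["x1"], y1 = b["y1"],
          x2 = b["x2"], y2 = b["y2"], score = 1,
          stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(events))) {
      slot <- match(events$piece[i], fl$name)
      if (is.na(slot)) next   # piece was re-cut; oracle tracks whole pieces
      cat_ <- events$category[i]
      emit <- switch(cat_,
        inversion = sign(fl$signedId[slot]) < 0,
        translocation = !pieceInPlace(fl, pv, contigLengths, slot),
        debris = TRUE,
        FALSE)
      if (emit) addBox(cat_, c(fl$start[slot], fl$end[slot]))
    }
    ## chromosome territories: contiguous runs of one contig's pieces
    for (ctg in names(contigLengths)) {
      slots <- which(pv$contig == ctg)
      if (length(slots) == 0L) next
      if (all(diff(slots) == 1L))
        addBox("chromosome", c(min(fl$start[slots]), max(fl$end[slots])))
    }
    if (length(boxes) == 0L)
      return(data.frame(category = character(), x1 = numeric(),
                        y1 = numeric(), x2 = numeric(), y2 = numeric(),
                        score = numeric(), stringsAsFactors = FALSE))
    out <- do.call(rbind, boxes)
    rownames(out) <- NULL
    out
  }
}

#' Ground-truth accessors
#'
#' @param truth a [GroundTruth-class].
#' @return `truthEvents`: the event table. `cleanDocument`: the
#'   pre-shuffle document. `contigLengths`: named lengths of the
#'   original contigs.
#' @export
truthEvents <- function(truth) truth@events

#' @rdname truthEvents
#' @export
cleanDocument <- function(truth) truth@cleanDoc

#' @rdname truthEvents
#' @export
truthContigLengths <- function(truth) truth@contigLengths
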