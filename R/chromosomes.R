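#' Detect chromosome territories on the global contact map
#'
#' Renders the whole-genome heatmap at the resolution chosen by
#' [selectGlobalResolution()] with a Q95 color ceiling, runs the
#' detector, and maps the chromosome-category boxes to genomic
#' intervals using their diagonal (x-axis) span. Overlapping intervals
#' are reconciled at the midpoint of the overlap; uncovered stretches
#' go to the leftover list.
#'
#' @param store a [ContactStore-class].
#' @param detector a `function(tile, doc)` box detector.
#' @param doc the current [AssemblyDoc-class].
#' @param sortByLength name chromosomes `chr_1..chr_N` by descending
#'   length instead of genomic order.
#' @param expectN optional expected chromosome count; a mismatch raises
#'   a warning.
#' @return list with `chromosomes` (data.frame `name, start, end,
#'   length`, genomic order), `leftover` (data.frame of uncovered
#'   intervals) and `resolution` (the global resolution used).
#' @export
detectChromosomes <- function(store, detector, doc,
                              sortByLength = FALSE, expectN = NULL) {
  Lg <- genomeLength(store)
  gres <- selectGlobalResolution(Lg, resolutions(store))
  region <- fetchRegion(store, gres, c(0, Lg), c(0, Lg))
  q95 <- quantileThreshold(region@values, 0.95)
  if (q95 <= 0) q95 <- max(region@values, 1e-9)
  tile <- renderTile(region, q95, id = "global")
  boxes <- detector(tile, doc)
  boxes <- boxes[boxes$category == "chromosome", , drop = FALSE]
  if (nrow(boxes) == 0L)
    stop("chromosome assignment error: the detector returned no ",
         "chromosome boxes on the global map")
  calls <- boxToGenome(boxes, tile)
  calls <- calls[order(calls$x_start, calls$x_end), , drop = FALSE]
  start <- pmax(0, calls$x_start)
  end <- pmin(Lg, calls$x_end)
  ## midpoint reconciliation of overlaps between consecutive intervals
  if (length(start) > 1L) {
    for (i in seq_len(length(start) - 1L)) {
      if (end[i] > start[i + 1L]) {
        mid <- round((start[i + 1L] + end[i]) / 2)
        end[i] <- mid
        start[i + 1L] <- mid
      }
    }
  }
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  if (!is.null(expectN) && length(start) != expectN)
    warning(sprintf("detected %d chromosomes, expected %d",
                    length(start), expectN))
  chrom <- data.frame(name = sprintf("chr_%d", seq_along(start)),
                      start = start, end = end, length = end - start,
                      stringsAsFactors = FALSE)
  if (sortByLength)
    chrom$name <- sprintf("chr_%d", rank(-chrom$length,
                                         ties.method = "first"))
  ## gaps -> leftover
  gapStart <- c(0, end)
  gapEnd <- c(start, Lg)
  nz <- gapEnd > gapStart
  leftover <- data.frame(start = gapStart[nz], end = gapEnd[nz],
                         length = gapEnd[nz] - gapStart[nz])
  list(chromosomes = chrom, leftover = leftover, resolution = gres)
}

#' Partition an assembly into chromosome scaffolds
#'
#' Cuts the document at every chromosome boundary, joins the fragments
#' inside each chromosome interval into one scaffold (assembly order
#' preserved), and appends everything unassigned to a single trailing
#' leftover scaffold. Total length is conserved; the scaffold count is
#' the chromosome count plus one when leftover sequence exists.
#'
#' @param doc an [AssemblyDoc-class].
#' @param chromosomes result of [detectChromosomes()], or a data.frame
#'   with `start`/`end` columns.
#' @return a new [AssemblyDoc-class]; attribute `leftoverScaffold`
#'   gives the index of the leftover scaffold when present.
#' @export
partitionAssembly <- function(doc, chromosomes) {
  if (is.list(chromosomes) && !is.data.frame(chromosomes) &&
      !is.null(chromosomes$chromosomes))
    chromosomes <- chromosomes$chromosomes
  L <- assemblyLength(doc)
  if (any(chromosomes$start < 0) || any(chromosomes$end > L))
    stop("chromosome boundary outside the assembly [0, ", L, "]")
  bounds <- sort(unique(c(chromosomes$start, chromosomes$end)))
  for (b in bounds) doc <- splitFragmentAt(doc, b)
  fl <- flattenLayout(doc)
  mid <- (fl$start + fl$end) / 2
  chromIdx <- rep(NA_integer_, nrow(fl))
  for (i in seq_len(nrow(chromosomes))) {
    inside <- mid >= chromosomes$start[i] & mid < chromosomes$end[i]
    chromIdx[inside] <- i
  }
  nChrom <- nrow(chromosomes)
  chromIdx[is.na(chromIdx)] <- nChrom + 1L       # leftover
  hasLeftover <- any(chromIdx == nChrom + 1L)
  ord <- order(chromIdx, fl$slot)
  fl <- fl[ord, , drop = FALSE]
  fl$scaffold <- chromIdx[ord]
  out <- docFromFlat(fl)
  if (hasLeftover) {
    attr(out, "hasLeftover") <- TRUE
    attr(out, "leftoverScaffold") <- length(out@layout)
  }
  out
}
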