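## Detector contract: a function(tile, doc) returning a data.frame of
## boxes with columns category, x1, y1, x2, y2, score. Pixel coordinates
## are continuous, top-left origin: x grows with genomic x, y (row)
## grows with genomic y. Corners: (x1, y1) upper-left, (x2, y2)
## lower-right, 0 <= x1 < x2 <= Iw, 0 <= y1 < y2 <= Ih.

errorCategories <- c("translocation", "inversion", "debris", "chromosome")

#' An empty error-call table
#'
#' Calls are plain data.frames with one row per detection, in the column
#' order used by the TSV interchange format.
#'
#' @return zero-row data.frame with the call columns.
#' @export
emptyCalls <- function() {
  data.frame(iteration = integer(), category = character(),
             x_start = numeric(), x_end = numeric(),
             y_start = numeric(), y_end = numeric(),
             resolution = numeric(), score = numeric(),
             tile_id = character(), status = character(),
             stringsAsFactors = FALSE)
}

#' Map detector boxes from pixel space to genomic intervals
#'
#' Applies the linear ratio map between tile pixels and the tile's
#' genomic windows: `E(s,x) = x1 * (L(e,x) - L(s,x)) / Iw + L(s,x)` and
#' analogously for `x2` (with the lower-right corner in the width slot)
#' and for the y axis with `Ih`. Results are rounded to the nearest bp;
#' call status starts as `"pending"`.
#'
#' @param boxes data.frame with columns `category, x1, y1, x2, y2,
#'   score` (continuous pixel coordinates within the tile).
#' @param tile the [Tile-class] the boxes were detected on.
#' @return an error-call data.frame (see [emptyCalls()]).
#' @examples
#' ## a tile spanning 0-700 kb at 700 px maps pixel 70 to 70 kb
#' @export
boxToGenome <- function(boxes, tile) {
  stopifnot(is(tile, "Tile"))
  if (nrow(boxes) == 0L) return(emptyCalls())
  Iw <- ncol(tile@pixels)
  Ih <- nrow(tile@pixels)
  if (any(boxes$x1 >= boxes$x2 | boxes$y1 >= boxes$y2))
    stop("zero-area box")
  if (any(boxes$x1 < 0 | boxes$y1 < 0 | boxes$x2 > Iw | boxes$y2 > Ih))
    stop("box outside tile pixel bounds")
  sx <- (tile@xEnd - tile@xStart) / Iw
  sy <- (tile@yEnd - tile@yStart) / Ih
  data.frame(
    iteration = 0L,
    category = boxes$category,
    x_start = round(boxes$x1 * sx + tile@xStart),
    x_end   = round(boxes$x2 * sx + tile@xStart),
    y_start = round(boxes$y1 * sy + tile@yStart),
    y_end   = round(boxes$y2 * sy + tile@yStart),
    resolution = tile@resolution,
    score = boxes$score,
    tile_id = tile@id,
    status = "pending",
    stringsAsFactors = FALSE
  )
}

## inverse of boxToGenome: genomic rectangle -> continuous pixel corners,
## clipped to the tile. Returns NULL when there is no overlap.
genomeToBox <- function(xInterval, yInterval, tile) {
  Iw <- ncol(tile@pixels)
  Ih <- nrow(tile@pixels)
  sx <- Iw / (tile@xEnd - tile@xStart)
  sy <- Ih / (tile@yEnd - tile@yStart)
  x1 <- (xInterval[1] - tile@xStart) * sx
  x2 <- (xInterval[2] - tile@xStart) * sx
  y1 <- (yInterval[1] - tile@yStart) * sy
  y2 <- (yInterval[2] - tile@yStart) * sy
  x1 <- max(x1, 0); y1 <- max(y1, 0)
  x2 <- min(x2, Iw); y2 <- min(y2, Ih)
  if (x1 >= x2 || y1 >= y2) return(NULL)
  c(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Filter calls by genomic length
#'
#' Keeps calls whose x-interval length lies in `[minLen, maxLen]`.
#' Chromosome-category boxes are exempt (they are territories, not
#' errors). Order is preserved; the input is not mutated.
#'
#' @param calls error-call data.frame.
#' @param minLen,maxLen length bounds in bp.
#' @return the filtered data.frame.
#' @export
filterCalls <- function(calls, minLen = 50000, maxLen = Inf) {
  if (minLen < 0 || maxLen < 0) stop("length bounds must be non-negative")
  if (minLen > maxLen) stop("minLen must not exceed maxLen")
  if (nrow(calls) == 0L) return(calls)
  len <- calls$x_end - calls$x_start
  keep <- (len >= minLen & len <= maxLen) | calls$category == "chromosome"
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## rectangle IOU on genomic intervals of two call rows
callIoU <- function(a, b) {
  ix <- max(0, min(a$x_end, b$x_end) - max(a$x_start, b$x_start))
  iy <- max(0, min(a$y_end, b$y_end) - max(a$y_start, b$y_start))
  inter <- ix * iy
  areaA <- (a$x_end - a$x_start) * (a$y_end - a$y_start)
  areaB <- (b$x_end - b$x_start) * (b$y_end - b$y_start)
  u <- areaA + areaB - inter
  if (u <= 0) 0 else inter / u
}

#' Merge duplicate calls across windows and resolutions
#'
#' Overlapping sliding windows and multiple resolutions re-detect the
#' same error. Calls of the same category whose genomic rectangles have
#' IOU at least `iouMin` are clustered (transitively) and each cluster
#' is represented by its best call: highest score, ties broken by larger
#' area, then smaller `x_start`. Deterministic and idempotent.
#'
#' @param calls error-call data.frame.
#' @param iouMin IOU threshold in `[0, 1]`.
#' @return the deduplicated data.frame.
#' @export
mergeCalls <- function(calls, iouMin = 0.5) {
  if (iouMin < 0 || iouMin > 1) stop("iouMin must be in [0, 1]")
  n <- nrow(calls)
  if (n <= 1L) return(calls)
  # union-find over same-category overlapping pairs
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (calls$category[i] != calls$category[j]) next
    if (callIoU(calls[i, ], calls[j, ]) >= iouMin) {
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), findRoot, 1L)
  area <- (calls$x_end - calls$x_start) * (calls$y_end - calls$y_start)
  pick <- vapply(split(seq_len(n), roots), function(idx) {
    o <- order(-calls$score[idx], -area[idx], calls$x_start[idx])
    idx[o[1]]
  }, 1L)
  out <- calls[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick the candidate assembly with the fewest structural errors
#'
#' Given per-candidate call lists (e.g. several scaffolder outputs),
#' returns the index of the candidate minimizing the number of
#' translocation plus inversion calls; debris and chromosome calls do
#' not count. Ties go to the smaller index.
#'
#' @param candidates list of error-call data.frames.
#' @return integer index into `candidates`.
#' @export
selectBestCandidate <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidates given")
  counts <- vapply(candidates, function(calls) {
    sum(calls$category %in% c("translocation", "inversion"))
  }, 1L)
  which.min(counts)   # which.min takes the first minimum
}

#' Count calls by category
#'
#' @param calls error-call data.frame.
#' @return named integer vector over all categories; sums to
#'   `nrow(calls)`.
#' @export
countByType <- function(calls) {
  out <- stats::setNames(integer(length(errorCategories)), errorCategories)
  if (nrow(calls) > 0L) {
    tab <- table(factor(calls$category, levels = errorCategories))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Run a detector over a contact store and collect genomic calls
#'
#' For each resolution in the store, plans diagonal sliding windows
#' ([planWindows()]), fetches and renders each window with a per-tile
#' Q95 color ceiling, runs the detector, maps boxes to genomic
#' intervals, then length-filters and IOU-merges the pooled calls.
#'
#' @param store a [ContactStore-class].
#' @param detector a `function(tile, doc)` returning a box data.frame
#'   (see [makeOracleDetector()] for the contract).
#' @param doc the current [AssemblyDoc-class] (passed to the detector).
#' @param config a [curationConfig()] list.
#' @return an error-call data.frame.
#' @export
detectErrors <- function(store, detector, doc, config = curationConfig()) {
  Lg <- genomeLength(store)
  calls <- list(emptyCalls())
  for (r in resolutions(store)) {
    wins <- planWindows(Lg, r)
    for (i in seq_len(nrow(wins))) {
      w <- c(wins$start[i], wins$end[i])
      region <- fetchRegion(store, r, w, w)
      ceiling_ <- quantileThreshold(region@values, 0.95)
      if (ceiling_ <= 0) next   # blank window
      tile <- renderTile(region, ceiling_,
                         id = sprintf("res%d_win%d", as.integer(r), i))
      boxes <- detector(tile, doc)
      if (NROW(boxes) > 0L)
        calls[[length(calls) + 1L]] <- boxToGenome(boxes, tile)
    }
  }
  calls <- do.call(rbind, calls)
  calls <- filterCalls(calls, config$error_min_len, config$error_max_len)
  mergeCalls(calls, config$merge_iou)
}
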