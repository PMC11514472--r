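#' @import methods
NULL

#' Multi-resolution Hi-C contact store
#'
#' In-memory store of symmetric, unnormalized ("observed NONE") contact
#' matrices at one or more resolutions, together with the genome length
#' they cover. Bin \eqn{b} at resolution \eqn{r} covers the zero-based,
#' half-open interval \eqn{[b r, (b+1) r)}; each matrix is square with
#' side \eqn{\lceil L_g / r \rceil}.
#'
#' @slot genomeLength total genome length in bp.
#' @slot resolutions strictly ascending bin sizes in bp.
#' @slot matrices list of dense matrices, named by resolution.
#'
#' @seealso [ContactStore()], [openStore()], [fetchRegion()]
#' @export
setClass("ContactStore",
  representation(
    genomeLength = "numeric",
    resolutions  = "numeric",
    matrices     = "list"
  )
)

setValidity("ContactStore", function(object) {
  msg <- character()
  Lg <- object@genomeLength
  res <- object@resolutions
  if (length(Lg) != 1L || !is.finite(Lg) || Lg <= 0)
    msg <- c(msg, "genomeLength must be a single positive number")
  if (length(res) == 0L)
    msg <- c(msg, "at least one resolution is required")
  if (any(res <= 0) || is.unsorted(res, strictly = TRUE))
    msg <- c(msg, "resolutions must be strictly ascending and positive")
  if (length(object@matrices) != length(res))
    msg <- c(msg, "one matrix per resolution is required")
  if (!identical(names(object@matrices), as.character(res)))
    msg <- c(msg, "matrices must be named by resolution")
  if (length(msg) == 0L) {
    for (i in seq_along(res)) {
      m <- object@matrices[[i]]
      side <- ceiling(Lg / res[i])
      if (!is.matrix(m) || nrow(m) != side || ncol(m) != side) {
        msg <- c(msg, sprintf(
          "matrix at resolution %g must be %d x %d (is %d x %d)",
          res[i], side, side, NROW(m), NCOL(m)))
        next
      }
      if (any(m < 0))
        msg <- c(msg, sprintf("negative contact values at resolution %g", res[i]))
      tol <- 1e-9 * max(1, max(abs(m)))
      if (max(abs(m - t(m))) > tol)
        msg <- c(msg, sprintf("matrix at resolution %g is not symmetric", res[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Rectangular sub-matrix of a contact map
#'
#' A region fetched from a [ContactStore]: rows cover the x genomic
#' interval, columns the y interval, both snapped outward to bin
#' boundaries at the region's resolution.
#'
#' @slot resolution bin size in bp.
#' @slot xStart,xEnd,yStart,yEnd bin-aligned genomic bounds (bp,
#'   zero-based half-open).
#' @slot values contact count matrix (rows = x bins, cols = y bins).
#' @export
setClass("RegionMatrix",
  representation(
    resolution = "numeric",
    xStart = "numeric", xEnd = "numeric",
    yStart = "numeric", yEnd = "numeric",
    values = "matrix"
  )
)

setValidity("RegionMatrix", function(object) {
  msg <- character()
  r <- object@resolution
  if (object@xStart >= object@xEnd || object@yStart >= object@yEnd)
    msg <- c(msg, "intervals must be non-empty")
  nx <- ceiling((object@xEnd - object@xStart) / r)
  ny <- ceiling((object@yEnd - object@yStart) / r)
  if (nrow(object@values) != nx || ncol(object@values) != ny)
    msg <- c(msg, sprintf("values must be %d x %d bins", nx, ny))
  if (length(msg)) msg else TRUE
})

#' Rendered contact heatmap tile
#'
#' A heatmap window rendered from a [RegionMatrix] on a linear
#' white-to-red ramp clipped at a color ceiling. Pixels follow image
#' convention: rows are the y axis (top row = smallest genomic y),
#' columns the x axis; one pixel per bin. The stored value is the ramp
#' position \eqn{t = \min(v, c)/c \in [0,1]} (0 = white, 1 = saturated
#' red).
#'
#' @slot pixels numeric matrix of ramp positions in \[0,1\]
#'   (`Ih` rows x `Iw` cols).
#' @slot resolution bin size in bp.
#' @slot xStart,xEnd,yStart,yEnd the genomic windows depicted (bp).
#' @slot ceiling color ceiling in contact units.
#' @slot id tile identifier used in call tables.
#' @export
setClass("Tile",
  representation(
    pixels = "matrix",
    resolution = "numeric",
    xStart = "numeric", xEnd = "numeric",
    yStart = "numeric", yEnd = "numeric",
    ceiling = "numeric",
    id = "character"
  )
)

setValidity("Tile", function(object) {
  msg <- character()
  if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
    msg <- c(msg, "tile must have positive pixel dimensions")
  if (object@ceiling <= 0)
    msg <- c(msg, "color ceiling must be positive")
  if (object@xStart >= object@xEnd || object@yStart >= object@yEnd)
    msg <- c(msg, "genomic windows must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Assembly document (3D-DNA dialect)
#'
#' Parsed form of a `.assembly` file: an ordered fragment table plus a
#' scaffold layout of signed fragment ids (sign encodes orientation,
#' `+` forward, `-` reverse). Assembly coordinates used throughout the
#' package are the gapless concatenation of fragments in layout order,
#' scaffold after scaffold.
#'
#' @slot fragments data.frame with columns `name`, `id`, `length`;
#'   ids are `1..F` in table order.
#' @slot layout list of numeric vectors of signed fragment ids, one per
#'   scaffold.
#' @seealso [readAssembly()], [writeAssembly()], [splitFragmentAt()]
#' @export
setClass("AssemblyDoc",
  representation(fragments = "data.frame", layout = "list")
)

setValidity("AssemblyDoc", function(object) {
  fr <- object@fragments
  msg <- character()
  if (!all(c("name", "id", "length") %in% names(fr)))
    return("fragments must have columns name, id, length")
  if (nrow(fr) == 0L) return("at least one fragment is required")
  if (!identical(as.integer(fr$id), seq_len(nrow(fr))))
    msg <- c(msg, "fragment ids must be 1..F in table order")
  if (any(fr$length <= 0))
    msg <- c(msg, "fragment lengths must be positive")
  if (anyDuplicated(fr$name))
    msg <- c(msg, "fragment names must be unique")
  ids <- abs(unlist(object@layout))
  if (length(ids) != nrow(fr) || !setequal(ids, fr$id) || anyDuplicated(ids))
    msg <- c(msg, "layout must reference every fragment id exactly once")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated misassembly
#'
#' Record of the events introduced by [fragmentAndShuffle()]: which
#' pieces were moved (translocation), flipped (inversion) or marked as
#' debris, together with the clean pre-shuffle document and the original
#' contig (chromosome) lengths. Powers the oracle detector and all
#' recovery tests.
#'
#' @slot events data.frame with columns `category`, `piece` (fragment
#'   name), `contig`, `trueStart`, `trueEnd` (native contig coords, bp).
#' @slot cleanDoc the pre-shuffle [AssemblyDoc].
#' @slot contigLengths named numeric vector of original contig lengths.
#' @export
setClass("GroundTruth",
  representation(
    events = "data.frame",
    cleanDoc = "AssemblyDoc",
    contigLengths = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  need <- c("category", "piece", "contig", "trueStart", "trueEnd")
  if (!all(need %in% names(object@events)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (is.null(names(object@contigLengths)))
    return("contigLengths must be named")
  TRUE
})

#' @describeIn ContactStore-class compact display.
#' @param object a `ContactStore`.
#' @export
setMethod("show", "ContactStore", function(object) {
  cat(sprintf("ContactStore: %s bp genome, %d resolution(s): %s\n",
              format(object@genomeLength, big.mark = ",", scientific = FALSE),
              length(object@resolutions),
              paste(object@resolutions, collapse = ", ")))
})

#' @describeIn AssemblyDoc-class compact display.
#' @param object an `AssemblyDoc`.
#' @export
setMethod("show", "AssemblyDoc", function(object) {
  cat(sprintf("AssemblyDoc: %d fragment(s) in %d scaffold(s), %s bp total\n",
              nrow(object@fragments), length(object@layout),
              format(sum(object@fragments$length), big.mark = ",",
                     scientific = FALSE)))
})

#' @describeIn Tile-class compact display.
#' @param object a `Tile`.
#' @export
setMethod("show", "Tile", function(object) {
  cat(sprintf(
    "Tile %s: %d x %d px, res %g bp, x [%g, %g), y [%g, %g), ceiling %.4g\n",
    object@id, nrow(object@pixels), ncol(object@pixels), object@resolution,
    object@xStart, object@xEnd, object@yStart, object@yEnd, object@ceiling))
})

#' @describeIn GroundTruth-class compact display.
#' @param object a `GroundTruth`.
#' @export
setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@events$category)
  cat(sprintf("GroundTruth: %d event(s) [%s] over %d contig(s)\n",
              nrow(object@events),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(object@contigLengths)))
})
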