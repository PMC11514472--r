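#' Construct a ContactStore from dense matrices
#'
#' @param matrices list of square symmetric matrices, one per
#'   resolution, in the same order as `resolutions`.
#' @param genomeLength genome length in bp.
#' @param resolutions ascending bin sizes in bp.
#' @return a [ContactStore-class] object.
#' @examples
#' m <- diag(10)
#' cs <- ContactStore(list(m), genomeLength = 10000, resolutions = 1000)
#' @export
ContactStore <- function(matrices, genomeLength, resolutions) {
  if (length(matrices) != length(resolutions))
    stop("need one matrix per resolution")
  ord <- order(resolutions)
  matrices <- lapply(matrices[ord], function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  names(matrices) <- as.character(resolutions[ord])
  new("ContactStore", genomeLength = as.numeric(genomeLength),
      resolutions = as.numeric(resolutions[ord]), matrices = matrices)
}

#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname accessors
#' @export
setGeneric("resolutions", function(x) standardGeneric("resolutions"))

#' Accessors for ContactStore
#'
#' @param x a [ContactStore-class].
#' @param resolution one of `resolutions(x)`.
#' @return `genomeLength`: genome length in bp. `resolutions`: ascending
#'   bin sizes. `contactMatrix`: the dense matrix at one resolution.
#' @name accessors
#' @export
setMethod("genomeLength", "ContactStore", function(x) x@genomeLength)

#' @rdname accessors
#' @export
setMethod("resolutions", "ContactStore", function(x) x@resolutions)

#' @rdname accessors
#' @export
contactMatrix <- function(x, resolution) {
  key <- as.character(resolution)
  if (!key %in% names(x@matrices))
    stop(sprintf("resolution %g not in store (have: %s)", resolution,
                 paste(x@resolutions, collapse = ", ")))
  x@matrices[[key]]
}

## ---- archive format -------------------------------------------------------
## A directory with manifest.json {genome_length, resolutions, dtype,
## layout} plus one res_<N>.mat per resolution: little-endian float32,
## row-major dense.

#' Save / open a contact archive
#'
#' The archive is a directory holding `manifest.json` (genome length,
#' resolutions, dtype, layout) and one `res_<N>.mat` file per resolution
#' containing the dense matrix as row-major little-endian 32-bit floats.
#' Values exactly representable in float32 (e.g. integer counts) round
#' trip bit-identically.
#'
#' @param store a [ContactStore-class].
#' @param path archive directory.
#' @return `saveStore`: `path`, invisibly. `openStore`: a
#'   [ContactStore-class].
#' @examples
#' cs <- ContactStore(list(diag(10)), 10000, 1000)
#' d <- tempfile(); saveStore(cs, d)
#' cs2 <- openStore(d)
#' @export
saveStore <- function(store, path) {
  stopifnot(is(store, "ContactStore"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "hicCurator-contact-archive",
    version = 1L,
    genome_length = store@genomeLength,
    resolutions = store@resolutions,
    dtype = "float32",
    layout = "row-major"
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (r in store@resolutions) {
    m <- contactMatrix(store, r)
    con <- file(file.path(path, sprintf("res_%d.mat", as.integer(r))), "wb")
    # row-major: write the transpose column-by-column
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' @rdname saveStore
#' @export
openStore <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("not a contact archive: missing manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  Lg <- manifest$genome_length
  res <- as.numeric(manifest$resolutions)
  if (is.null(Lg) || length(res) == 0L)
    stop("malformed manifest: genome_length and resolutions are required")
  mats <- lapply(res, function(r) {
    f <- file.path(path, sprintf("res_%d.mat", as.integer(r)))
    if (!file.exists(f)) stop("archive integrity error: missing ", basename(f))
    side <- ceiling(Lg / r)
    n <- file.size(f) / 4
    if (n != side * side)
      stop(sprintf(
        "archive integrity error: %s holds %g values, expected %d x %d",
        basename(f), n, side, side))
    con <- file(f, "rb")
    v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
    close(con)
    t(matrix(v, nrow = side, ncol = side, byrow = FALSE))
  })
  ContactStore(mats, Lg, res)
}

## ---- region access --------------------------------------------------------

#' Fetch a rectangular region of the contact matrix
#'
#' Returns the stored (unnormalized) contact counts for the bins
#' overlapping the requested x and y intervals. Intervals are zero-based
#' half-open bp and are snapped outward to bin boundaries.
#'
#' @param store a [ContactStore-class].
#' @param resolution one of `resolutions(store)`.
#' @param x,y length-2 numeric intervals `c(start, end)` in bp.
#' @return a [RegionMatrix-class] (rows = x bins, cols = y bins).
#' @export
fetchRegion <- function(store, resolution, x, y = x) {
  stopifnot(is(store, "ContactStore"), length(x) == 2L, length(y) == 2L)
  Lg <- store@genomeLength
  if (x[1] < 0 || y[1] < 0 || x[2] > Lg || y[2] > Lg)
    stop("requested interval lies outside the genome [0, Lg)")
  if (x[1] >= x[2] || y[1] >= y[2]) stop("intervals must be non-empty")
  m <- contactMatrix(store, resolution)   # errors on unknown resolution
  r <- resolution
  xb <- (floor(x[1] / r) + 1L):min(ceiling(x[2] / r), nrow(m))
  yb <- (floor(y[1] / r) + 1L):min(ceiling(y[2] / r), ncol(m))
  new("RegionMatrix", resolution = r,
      xStart = (xb[1] - 1) * r, xEnd = min(xb[length(xb)] * r, ceiling(Lg / r) * r),
      yStart = (yb[1] - 1) * r, yEnd = min(yb[length(yb)] * r, ceiling(Lg / r) * r),
      values = m[xb, yb, drop = FALSE])
}

## ---- quantile threshold ---------------------------------------------------

#' Quantile color threshold with 1-based-rank interpolation
#'
#' Computes the order statistic at rank \eqn{k = q n} on the
#' ascending-sorted values (1-based). When \eqn{k} is integral the value
#' at that rank is returned; otherwise the result is the linear
#' interpolation \eqn{X_{\lfloor k \rfloor} + (k - \lfloor k \rfloor)
#' (X_{\lceil k \rceil} - X_{\lfloor k \rfloor})}. Ranks below 1 return
#' the minimum. This is the Q95 rule used for heatmap color ceilings and
#' for the peak-height threshold; it differs slightly from
#' `stats::quantile` type 7.
#'
#' @param values numeric vector (or matrix) of contact values.
#' @param q quantile fraction, default 0.95.
#' @return a single contact value.
#' @examples
#' quantileThreshold(c(0, 10, 20), 0.95)  # k = 2.85 -> 18.5
#' @export
quantileThreshold <- function(values, q = 0.95) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("at least one value is required")
  if (anyNA(values)) stop("values must not contain NA")
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  x <- sort(values)
  n <- length(x)
  k <- q * n
  if (k < 1) return(x[1])
  kf <- floor(k)
  if (k == kf) return(x[kf])
  x[kf] + (k - kf) * (x[min(kf + 1, n)] - x[kf])
}

## ---- sliding windows ------------------------------------------------------

#' Plan diagonal sliding windows over a contact map
#'
#' Windows of length `700 * resolution` advance along the diagonal in
#' steps of `400 * resolution` (consecutive windows overlap by
#' `300 * resolution`). Windows are generated while their start is
#' inside the genome; the last window is clipped at `Lg`, so the union
#' of windows always covers `[0, Lg)`.
#'
#' @param Lg genome length in bp.
#' @param resolution bin size in bp.
#' @return data.frame with columns `index`, `start`, `end`,
#'   `resolution` (bp, zero-based half-open).
#' @examples
#' planWindows(1e6, 1000)
#' @export
planWindows <- function(Lg, resolution) {
  stopifnot(Lg > 0, resolution > 0)
  starts <- seq(0, Lg - 1, by = 400 * resolution)
  # seq() stops at the last start < Lg because step > 0
  starts <- starts[starts < Lg]
  ends <- pmin(starts + 700 * resolution, Lg)
  # drop trailing windows fully contained in their predecessor
  keep <- c(TRUE, ends[-1] > ends[-length(ends)])
  if (length(starts) > 1L) {
    starts <- starts[keep]; ends <- ends[keep]
  }
  data.frame(index = seq_along(starts), start = starts, end = ends,
             resolution = resolution)
}

#' Pick the resolution for the global (whole-genome) contact image
#'
#' Returns the smallest resolution `r` with `r * 1440 >= Lg`, so the
#' global map fits within a 1440-bin image. If even the largest
#' resolution is too fine, that largest resolution is returned with a
#' warning.
#'
#' @param Lg genome length in bp.
#' @param resolutions ascending bin sizes in bp.
#' @return a single resolution (bp).
#' @examples
#' selectGlobalResolution(6e6, c(1000, 5000, 10000))  # 5000
#' @export
selectGlobalResolution <- function(Lg, resolutions) {
  if (length(resolutions) == 0L) stop("resolutions must be non-empty")
  resolutions <- sort(as.numeric(resolutions))
  ok <- resolutions * 1440 >= Lg
  if (!any(ok)) {
    warning(sprintf(
      "no resolution satisfies r * 1440 >= Lg = %g; using the largest (%g)",
      Lg, max(resolutions)))
    return(max(resolutions))
  }
  resolutions[which(ok)[1]]
}

## ---- rendering ------------------------------------------------------------

#' Render a contact region as a heatmap tile
#'
#' Maps each contact value onto a linear white-to-red ramp:
#' \eqn{t = \min(v, c) / c} where `c` is the color ceiling (values above
#' the ceiling saturate). The tile stores `t` per pixel, one pixel per
#' bin, in image convention (rows = y, top row = smallest y). Rendering
#' is deterministic.
#'
#' @param region a [RegionMatrix-class].
#' @param ceiling positive color ceiling in contact units (typically the
#'   Q95 of the region, see [quantileThreshold()]).
#' @param id tile identifier.
#' @return a [Tile-class].
#' @export
renderTile <- function(region, ceiling, id = "tile") {
  stopifnot(is(region, "RegionMatrix"))
  if (!is.finite(ceiling) || ceiling <= 0)
    stop("color ceiling must be a positive number")
  t_ <- pmin(region@values, ceiling) / ceiling
  new("Tile", pixels = t(t_), resolution = region@resolution,
      xStart = region@xStart, xEnd = region@xEnd,
      yStart = region@yStart, yEnd = region@yEnd,
      ceiling = ceiling, id = id)
}

#' @rdname renderTile
#' @param tile a [Tile-class].
#' @return `tilePixels`: the `Ih x Iw` matrix of ramp positions.
#' @export
tilePixels <- function(tile) tile@pixels

#' Write a tile as PNG plus JSON metadata sidecar
#'
#' The PNG encodes the white-to-red ramp (`rgb = (1, 1-t, 1-t)`); the
#' sidecar records resolution, genomic windows and the color ceiling.
#'
#' @param tile a [Tile-class].
#' @param prefix output path prefix; writes `<prefix>.png` and
#'   `<prefix>.json`.
#' @return named character vector of the two paths, invisibly.
#' @export
writeTile <- function(tile, prefix) {
  t_ <- tile@pixels
  img <- array(1, dim = c(nrow(t_), ncol(t_), 3))
  img[, , 2] <- 1 - t_
  img[, , 3] <- 1 - t_
  pngPath <- paste0(prefix, ".png")
  jsonPath <- paste0(prefix, ".json")
  png::writePNG(img, pngPath)
  jsonlite::write_json(
    list(id = tile@id, resolution = tile@resolution,
         x_start = tile@xStart, x_end = tile@xEnd,
         y_start = tile@yStart, y_end = tile@yEnd,
         ceiling = tile@ceiling),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(png = pngPath, json = jsonPath))
}
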