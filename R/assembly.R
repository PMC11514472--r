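## .assembly dialect: header lines ">name id length", then one line per
## scaffold of space-separated signed fragment ids. Assembly coordinates
## are the gapless concatenation of fragments in layout order.

#' Read / write an assembly document
#'
#' `readAssembly` parses 3D-DNA dialect `.assembly` text (a file path or
#' a character vector of lines); `writeAssembly` serializes a document
#' back to text. The two are exact inverses: `writeAssembly(readAssembly(x))`
#' reproduces canonical input bit-for-bit.
#'
#' @param x a file path or character vector of `.assembly` lines.
#' @return `readAssembly`: an [AssemblyDoc-class].
#' @examples
#' txt <- c(">ctgA:0-100 1 100", ">ctgA:100-300 2 200", "1 -2")
#' doc <- readAssembly(txt)
#' writeAssembly(doc)
#' @export
readAssembly <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  isHeader <- startsWith(lines, ">")
  if (any(isHeader & cumsum(!isHeader) > 0))
    stop("format error: header line after layout lines (line ",
         which(isHeader & cumsum(!isHeader) > 0)[1], ")")
  heads <- lines[isHeader]
  body <- lines[!isHeader]
  if (length(heads) == 0L) stop("format error: no fragment header lines")
  if (length(body) == 0L) stop("format error: no layout lines")
  parts <- strsplit(sub("^>", "", heads), "[[:space:]]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("format error: malformed header at line ", which(isHeader)[bad[1]])
  fr <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    id = as.integer(vapply(parts, `[`, "", 2L)),
    length = as.numeric(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(fr$id) || anyNA(fr$length))
    stop("format error: non-numeric id or length in a header line")
  if (anyDuplicated(fr$id))
    stop("format error: duplicate fragment id ",
         fr$id[anyDuplicated(fr$id)], " (line ",
         which(isHeader)[anyDuplicated(fr$id)], ")")
  ord <- order(fr$id)
  fr <- fr[ord, , drop = FALSE]
  rownames(fr) <- NULL
  if (!identical(fr$id, seq_len(nrow(fr))))
    stop("format error: fragment ids must be 1..F with no gaps")
  layout <- lapply(body, function(l) as.numeric(strsplit(trimws(l),
                                                         "[[:space:]]+")[[1]]))
  ids <- abs(unlist(layout))
  if (anyNA(ids)) stop("format error: non-numeric id in a layout line")
  unknown <- setdiff(ids, fr$id)
  if (length(unknown)) {
    ln <- which(!isHeader)[which(vapply(layout, function(v)
      any(abs(v) %in% unknown), TRUE))[1]]
    stop("format error: layout references unknown fragment id ",
         unknown[1], " (line ", ln, ")")
  }
  if (anyDuplicated(ids))
    stop("format error: fragment id ", ids[anyDuplicated(ids)],
         " appears more than once in the layout")
  missing <- setdiff(fr$id, ids)
  if (length(missing))
    stop("format error: fragment id ", missing[1], " missing from the layout")
  new("AssemblyDoc", fragments = fr, layout = layout)
}

#' @rdname readAssembly
#' @param doc an [AssemblyDoc-class].
#' @param path optional file to write; when `NULL` the text lines are
#'   returned.
#' @return `writeAssembly`: the text lines (invisibly when `path` is
#'   given).
#' @export
writeAssembly <- function(doc, path = NULL) {
  stopifnot(is(doc, "AssemblyDoc"))
  fr <- doc@fragments
  heads <- sprintf(">%s %d %s", fr$name, fr$id,
                   format(fr$length, scientific = FALSE, trim = TRUE))
  body <- vapply(doc@layout, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = " "), "")
  out <- c(heads, body)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' @rdname assemblyLength
#' @export
nFragments <- function(doc) nrow(doc@fragments)

#' Assembly size and layout accessors
#'
#' @param doc an [AssemblyDoc-class].
#' @return `assemblyLength`: total length in bp (gapless; Ns added only
#'   on FASTA export are not counted). `nFragments`: fragment count.
#'   `fragmentTable`: the fragment data.frame. `scaffoldLayout`: list of
#'   signed id vectors.
#' @export
assemblyLength <- function(doc) sum(doc@fragments$length)

#' @rdname assemblyLength
#' @export
fragmentTable <- function(doc) doc@fragments

#' @rdname assemblyLength
#' @export
scaffoldLayout <- function(doc) doc@layout

## Flattened per-fragment table: one row per layout slot, with assembly
## start/end, scaffold index and position, signed id, name, length.
flattenLayout <- function(doc) {
  fr <- doc@fragments
  ids <- unlist(doc@layout)
  scaf <- rep(seq_along(doc@layout), lengths(doc@layout))
  pos <- unlist(lapply(lengths(doc@layout), seq_len))
  len <- fr$length[abs(ids)]
  end <- cumsum(len)
  data.frame(
    slot = seq_along(ids), scaffold = scaf, position = pos,
    signedId = ids, id = abs(ids), name = fr$name[abs(ids)],
    length = len, start = end - len, end = end,
    stringsAsFactors = FALSE
  )
}

#' Locate an assembly coordinate
#'
#' Maps a position on the gapless assembly axis to the scaffold,
#' layout slot and fragment that cover it. The offset is measured along
#' the assembly axis from the fragment's assembly start (for a reverse-
#' oriented fragment this is *not* the native-axis offset; the native
#' cut point is `length - offset`).
#'
#' @param doc an [AssemblyDoc-class].
#' @param g assembly coordinate in `[0, assemblyLength(doc))`.
#' @return list with `scaffold`, `position` (within-scaffold slot),
#'   `fragmentId`, `offset` (bp from the fragment's assembly start) and
#'   `orientation` (`+1`/`-1`).
#' @examples
#' doc <- readAssembly(c(">a:0-100 1 100", ">b:0-200 2 200", "1 2"))
#' locateAssembly(doc, 150)  # fragment 2, offset 50
#' @export
locateAssembly <- function(doc, g) {
  L <- assemblyLength(doc)
  if (g < 0 || g >= L) stop("position out of range [0, ", L, ")")
  fl <- flattenLayout(doc)
  i <- findInterval(g, fl$start)   # starts are sorted; g < end[i]
  list(scaffold = fl$scaffold[i], position = fl$position[i],
       fragmentId = fl$id[i], offset = g - fl$start[i],
       orientation = sign(fl$signedId[i]))
}

## ---- provenance -----------------------------------------------------------
## Fragment names carry "contig:start-end" provenance (0-based half-open,
## native contig coordinates), which stays valid across splits and lets
## build_fasta slice the input contigs.

parseProvenance <- function(names) {
  m <- regmatches(names, regexec("^(.*):([0-9]+)-([0-9]+)$", names))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop("fragment name without contig:start-end provenance: ",
         names[bad[1]])
  data.frame(
    contig = vapply(m, `[`, "", 2L),
    start = as.numeric(vapply(m, `[`, "", 3L)),
    end = as.numeric(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

## rebuild a doc from an edited flattened table (preserves scaffold
## grouping); renumbers ids sequentially in layout order.
docFromFlat <- function(fl) {
  fl$newId <- seq_len(nrow(fl))
  fr <- data.frame(name = fl$name, id = fl$newId, length = fl$length,
                   stringsAsFactors = FALSE)
  layout <- split(fl$newId * sign(fl$signedId),
                  factor(fl$scaffold, levels = unique(fl$scaffold)))
  names(layout) <- NULL
  layout <- lapply(layout, as.numeric)
  layout <- layout[lengths(layout) > 0L]
  new("AssemblyDoc", fragments = fr, layout = layout)
}

#' Cut a fragment at an assembly coordinate
#'
#' Splits the fragment covering `g` into two pieces whose lengths sum to
#' the original. `g` on an existing fragment boundary is a documented
#' no-op. Fragment ids are renumbered sequentially; provenance names are
#' updated so each piece still names its native contig slice. For a
#' reverse-oriented fragment the native cut point is `length - offset`.
#' Edits never mutate: a new document is returned.
#'
#' @param doc an [AssemblyDoc-class].
#' @param g assembly coordinate in bp.
#' @return a new [AssemblyDoc-class].
#' @export
splitFragmentAt <- function(doc, g) {
  L <- assemblyLength(doc)
  if (g < 0 || g > L) stop("position out of range [0, ", L, "]")
  fl <- flattenLayout(doc)
  if (g %in% c(0, L, fl$start, fl$end)) return(doc)  # boundary: no-op
  i <- findInterval(g, fl$start)
  off <- g - fl$start[i]                 # assembly-axis offset, 0 < off < len
  len <- fl$length[i]
  orient <- sign(fl$signedId[i])
  nativeCut <- if (orient > 0) off else len - off
  pv <- parseProvenance(fl$name[i])
  nm1 <- sprintf("%s:%s-%s", pv$contig,
                 format(pv$start, scientific = FALSE, trim = TRUE),
                 format(pv$start + nativeCut, scientific = FALSE, trim = TRUE))
  nm2 <- sprintf("%s:%s-%s", pv$contig,
                 format(pv$start + nativeCut, scientific = FALSE, trim = TRUE),
                 format(pv$end, scientific = FALSE, trim = TRUE))
  # assembly-left piece first; for reverse orientation that is the
  # native-right slice
  if (orient > 0) {
    pieces <- data.frame(name = c(nm1, nm2), length = c(off, len - off))
  } else {
    pieces <- data.frame(name = c(nm2, nm1), length = c(off, len - off))
  }
  top <- fl[seq_len(i - 1L), , drop = FALSE]
  bot <- fl[-seq_len(i), , drop = FALSE]
  mid <- fl[c(i, i), , drop = FALSE]
  mid$name <- pieces$name
  mid$length <- pieces$length
  out <- rbind(top, mid, bot)
  docFromFlat(out)
}

## locate the run of layout slots exactly covering [from, to); boundaries
## must be fragment boundaries.
blockSlots <- function(fl, from, to) {
  if (from >= to) stop("empty block")
  i1 <- match(from, fl$start)
  i2 <- match(to, fl$end)
  if (is.na(i1) || is.na(i2) || i2 < i1)
    stop("block boundaries must coincide with fragment boundaries ",
         "(call splitFragmentAt first)")
  i1:i2
}

#' Move a block of fragments to a new position
#'
#' The block `[blockStart, blockEnd)` (fragment-boundary aligned) is
#' removed and reinserted so that it starts at assembly coordinate
#' `insertion` (measured on the axis *after* removal is accounted for:
#' `insertion` refers to a fragment boundary of the original document
#' outside the block). Orientations and relative order are preserved;
#' total length is conserved.
#'
#' @param doc an [AssemblyDoc-class].
#' @param blockStart,blockEnd assembly coordinates of the block (bp,
#'   fragment-boundary aligned).
#' @param insertion assembly coordinate of the destination boundary,
#'   outside the block.
#' @return a new [AssemblyDoc-class].
#' @export
moveBlock <- function(doc, blockStart, blockEnd, insertion) {
  fl <- flattenLayout(doc)
  sl <- blockSlots(fl, blockStart, blockEnd)
  if (insertion > blockStart && insertion < blockEnd)
    stop("insertion point lies inside the block")
  if (insertion == blockStart || insertion == blockEnd) return(doc)
  L <- assemblyLength(doc)
  if (insertion < 0 || insertion > L)
    stop("insertion out of range [0, ", L, "]")
  if (!insertion %in% c(0, L, fl$start, fl$end))
    stop("insertion must coincide with a fragment boundary")
  block <- fl[sl, , drop = FALSE]
  rest <- fl[-sl, , drop = FALSE]
  # destination slot within `rest`: first slot starting at/after insertion
  at <- which(rest$start >= insertion)
  destScaffold <- if (length(at)) rest$scaffold[at[1]] else
    rest$scaffold[nrow(rest)]
  block$scaffold <- destScaffold
  k <- if (length(at)) at[1] - 1L else nrow(rest)
  out <- rbind(utils::head(rest, k), block, utils::tail(rest, nrow(rest) - k))
  docFromFlat(out)
}

#' Invert a block of fragments
#'
#' Reverses fragment order within the block and flips every sign — an
#' involution. Block boundaries must be fragment boundaries.
#'
#' @inheritParams moveBlock
#' @return a new [AssemblyDoc-class].
#' @export
invertBlock <- function(doc, blockStart, blockEnd) {
  if (blockStart == blockEnd) return(doc)  # empty block: no-op
  fl <- flattenLayout(doc)
  sl <- blockSlots(fl, blockStart, blockEnd)
  fl$signedId[sl] <- -rev(fl$signedId[sl])
  fl$name[sl] <- rev(fl$name[sl])
  fl$length[sl] <- rev(fl$length[sl])
  fl$id[sl] <- rev(fl$id[sl])
  docFromFlat(fl)
}

#' Relegate a block to the trailing leftover scaffold
#'
#' Appends the block's fragments (orientation preserved) to a trailing
#' leftover scaffold, creating it when absent. Used for debris and for
#' sequence not assigned to any chromosome.
#'
#' @inheritParams moveBlock
#' @param leftoverScaffold index of an existing leftover scaffold, or
#'   `NA` to use/create the final scaffold tagged as leftover.
#' @return a new [AssemblyDoc-class] with attribute `leftoverScaffold`
#'   giving the index of the leftover scaffold.
#' @export
relegateDebris <- function(doc, blockStart, blockEnd,
                           leftoverScaffold = NA) {
  fl <- flattenLayout(doc)
  sl <- blockSlots(fl, blockStart, blockEnd)
  hasLeftover <- isTRUE(attr(doc, "hasLeftover")) ||
    (!is.na(leftoverScaffold) && leftoverScaffold <= length(doc@layout))
  nScaf <- length(doc@layout)
  target <- if (hasLeftover) nScaf else nScaf + 1L
  block <- fl[sl, , drop = FALSE]
  rest <- fl[-sl, , drop = FALSE]
  block$scaffold <- target
  out <- rbind(rest, block)
  newDoc <- docFromFlat(out)
  attr(newDoc, "hasLeftover") <- TRUE
  attr(newDoc, "leftoverScaffold") <- length(newDoc@layout)
  newDoc
}

#' Merge provenance-contiguous neighbouring fragments
#'
#' Adjacent fragments of the same scaffold that carry contiguous native
#' coordinates in matching orientation (forward: previous end equals
#' next start; reverse: previous start equals next end) are fused into
#' one fragment. The emitted genome sequence is unchanged; this
#' canonicalizes documents that differ only by cuts at identical
#' coordinates (e.g. left over from correction).
#'
#' @param doc an [AssemblyDoc-class] with provenance fragment names.
#' @return a new [AssemblyDoc-class].
#' @export
mergeAdjacentFragments <- function(doc) {
  fl <- flattenLayout(doc)
  pv <- parseProvenance(fl$name)
  keepRows <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) keepRows[[length(keepRows) + 1L]] <<- cur
  }
  for (i in seq_len(nrow(fl))) {
    sgn <- sign(fl$signedId[i])
    row <- list(scaffold = fl$scaffold[i], contig = pv$contig[i],
                s = pv$start[i], e = pv$end[i], sgn = sgn)
    if (!is.null(cur) && cur$scaffold == row$scaffold &&
        cur$contig == row$contig && cur$sgn == sgn &&
        ((sgn > 0 && cur$e == row$s) || (sgn < 0 && cur$s == row$e))) {
      cur$s <- min(cur$s, row$s)
      cur$e <- max(cur$e, row$e)
    } else {
      flush()
      cur <- row
    }
  }
  flush()
  out <- do.call(rbind, lapply(keepRows, as.data.frame))
  out$name <- sprintf("%s:%s-%s", out$contig,
                      format(out$s, scientific = FALSE, trim = TRUE),
                      format(out$e, scientific = FALSE, trim = TRUE))
  out$length <- out$e - out$s
  out$signedId <- seq_len(nrow(out)) * out$sgn
  docFromFlat(out)
}

#' Build scaffold FASTA from an assembly document
#'
#' Each scaffold is the concatenation of its fragments' native contig
#' slices (reverse-complemented for `-` orientation) joined by
#' `gapLen` Ns. Fragment provenance names (`contig:start-end`) identify
#' the slices.
#'
#' @param doc an [AssemblyDoc-class].
#' @param contigs a [Biostrings::DNAStringSet] of the input contigs.
#' @param gapLen gap size in Ns between fragments (3D-DNA convention,
#'   default 500).
#' @param scaffoldNames optional character vector of scaffold names.
#' @return a [Biostrings::DNAStringSet], one entry per scaffold.
#' @export
buildScaffoldFasta <- function(doc, contigs, gapLen = 500,
                               scaffoldNames = NULL) {
  stopifnot(is(doc, "AssemblyDoc"))
  fl <- flattenLayout(doc)
  pv <- parseProvenance(fl$name)
  missing <- setdiff(unique(pv$contig), names(contigs))
  if (length(missing))
    stop("fragment references unknown contig: ", missing[1])
  cl <- Biostrings::width(contigs)[match(pv$contig, names(contigs))]
  if (any(pv$end > cl))
    stop("fragment slice extends past its contig: ",
         fl$name[which(pv$end > cl)[1]])
  gap <- strrep("N", gapLen)
  seqs <- vapply(seq_len(nrow(fl)), function(i) {
    s <- Biostrings::subseq(contigs[[pv$contig[i]]],
                            start = pv$start[i] + 1L, end = pv$end[i])
    if (fl$signedId[i] < 0) s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, "")
  out <- vapply(split(seqs, fl$scaffold), paste, "", collapse = gap)
  res <- Biostrings::DNAStringSet(out)
  names(res) <- if (is.null(scaffoldNames))
    sprintf("scaffold_%d", seq_along(res)) else scaffoldNames
  res
}
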