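#' Curation pipeline configuration
#'
#' Bundles the tunable knobs of the detect-correct loop.
#'
#' @param max_iterations maximum detect-correct rounds (default 5; the
#'   loop also stops as soon as no translocation or inversion remains).
#' @param stall_patience abort after this many consecutive iterations
#'   without a decrease in the translocation+inversion count.
#' @param debris_mode `"skip"` (default: debris calls are logged but not
#'   acted on) or `"adjust"` (relegate debris to the leftover scaffold).
#' @param error_min_len,error_max_len length filter for error calls, bp.
#' @param merge_iou IOU threshold for deduplicating calls across
#'   windows/resolutions.
#' @param boundary_snap_bins cut and insertion positions within this
#'   many bins (at the call's / peak's resolution) of an existing
#'   fragment junction are snapped to it; misjoins live at junctions and
#'   detector/peak positions are bin-quantized.
#' @param gap_len Ns between fragments on FASTA export.
#' @param seed optional RNG seed recorded in logs.
#' @return a named list.
#' @export
curationConfig <- function(max_iterations = 5, stall_patience = 2,
                           debris_mode = c("skip", "adjust"),
                           error_min_len = 50000, error_max_len = Inf,
                           merge_iou = 0.5, boundary_snap_bins = 2,
                           gap_len = 500, seed = NULL) {
  debris_mode <- match.arg(debris_mode)
  stopifnot(max_iterations >= 0, stall_patience >= 1,
            error_min_len >= 0, error_max_len >= error_min_len)
  list(max_iterations = max_iterations, stall_patience = stall_patience,
       debris_mode = debris_mode, error_min_len = error_min_len,
       error_max_len = error_max_len, merge_iou = merge_iou,
       boundary_snap_bins = boundary_snap_bins, gap_len = gap_len,
       seed = seed)
}

#' Best resolution for a given error length
#'
#' Returns the resolution minimizing `|errorLen / 3 - R|`, so the error
#' spans roughly three bins in the strip used by the peak algorithm.
#' Ties go to the smaller resolution.
#'
#' @param errorLen error length in bp (positive).
#' @param resolutions available bin sizes in bp.
#' @return a single resolution.
#' @examples
#' bestResolution(300000, c(1000, 5000, 10000, 100000, 250000))  # 1e5
#' @export
bestResolution <- function(errorLen, resolutions) {
  if (length(resolutions) == 0L) stop("resolutions must be non-empty")
  if (errorLen <= 0) stop("error length must be positive")
  resolutions <- as.numeric(resolutions)
  d <- abs(errorLen / 3 - resolutions)
  resolutions[order(d, resolutions)[1]]
}

## scipy.signal.find_peaks semantics: local maxima, value >= height,
## then greedy removal (by descending height) of peaks closer than
## `distance` samples to an already-kept higher peak. Returns 1-based
## indices. pracma::findpeaks supplies the local-maxima primitive.
scipyFindPeaks <- function(x, height = -Inf, distance = 1) {
  pk <- pracma::findpeaks(as.numeric(x))
  if (is.null(pk)) return(integer())
  val <- pk[, 1]; idx <- pk[, 2]
  keepH <- val >= height
  val <- val[keepH]; idx <- idx[keepH]
  if (length(idx) <= 1L || distance <= 1) return(sort(idx))
  o <- order(-val, idx)
  kept <- integer()
  for (i in o) {
    if (!any(abs(kept - idx[i]) < distance)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' Find the insertion site of a translocation by contact-peak voting
#'
#' Implements the peak algorithm: (1) choose the resolution closest to
#' a third of the error length ([bestResolution()]); (2) extract the
#' genome-by-error strip of the contact matrix (all rows, the error's
#' columns); (3) for each error column, find the local maxima of the
#' genome-axis profile with height at least `Peak95` (the strip's 95th
#' percentile, [quantileThreshold()]) and minimum peak separation equal
#' to the error's width in bins; (4) discard peaks inside the excluded
#' band `[floor(Es/r) - 2, floor(Ee/r) + 2]` around the error itself;
#' (5) the most frequent surviving bin index wins (ties: larger summed
#' contact over the strip, then smaller index); (6) the insertion
#' position is `index * resolution`.
#'
#' After the coarse vote, a refinement stage repeats the per-column
#' vote at the finest stored resolution with rows restricted to two
#' coarse bins around the coarse site, pinning the insertion to a fine
#' bin (set `refine = FALSE` for the single-stage behaviour).
#'
#' @param store a [ContactStore-class].
#' @param error length-2 numeric `c(start, end)` in bp.
#' @param refine run the fine-resolution localization stage.
#' @param exclude optional list of bp intervals whose bins (padded by
#'   two) are removed from the vote, in addition to the error band;
#'   the iterative pipeline uses it to mask mutually attracted calls.
#' @return insertion position in bp (zero-based), with attribute
#'   `resolution` (the resolution used) and `bin` (the winning
#'   zero-based bin index).
#' @section Errors: throws a condition of class `noInsertionSite` when
#'   no peak survives the exclusion (e.g. a featureless matrix); the
#'   iterative pipeline catches this, skips the call and logs it.
#' @export
findInsertionSite <- function(store, error, refine = TRUE,
                              exclude = NULL) {
  stopifnot(length(error) == 2L, error[1] < error[2])
  Lg <- genomeLength(store)
  if (error[1] < 0 || error[2] > Lg) stop("error interval outside [0, Lg]")
  best <- bestResolution(error[2] - error[1], resolutions(store))
  ## when no vote survives the exclusion band at the best resolution
  ## (the target junction can sit inside the band), retry at finer
  ## resolutions: the band spans error +/- 2 bins, so finer bins
  ## shrink the blind zone in bp
  tryRes <- c(best, sort(resolutions(store)[resolutions(store) < best],
                         decreasing = TRUE))
  out <- NULL
  for (res in tryRes) {
    out <- voteInsertionSite(store, error, res, exclude = exclude)
    if (!is.null(out)) break
  }
  if (is.null(out))
    stop(structure(class = c("noInsertionSite", "error", "condition"),
                   list(message = "no insertion-site peak outside the error band",
                        call = sys.call())))
  if (refine) out <- refineInsertionSite(store, error, out,
                                         exclude = exclude)
  out
}

## drop 0-based bin indices falling in any excluded bp interval
dropExcluded <- function(idx, res, exclude) {
  if (is.null(exclude) || length(idx) == 0L) return(idx)
  for (iv in exclude) {
    lo <- floor(iv[1] / res) - 2
    hi <- floor(iv[2] / res) + 2
    idx <- idx[idx < lo | idx > hi]
  }
  idx
}

## one round of per-column peak voting at a fixed resolution; NULL when
## no vote survives the exclusion band
voteInsertionSite <- function(store, error, res, exclude = NULL) {
  m <- contactMatrix(store, res)
  nb <- nrow(m)
  cols <- (floor(error[1] / res) + 1L):min(ceiling(error[2] / res), nb)
  strip <- m[, cols, drop = FALSE]
  peak95 <- quantileThreshold(strip, 0.95)
  dt <- floor(error[2] / res) - floor(error[1] / res)
  band <- c(floor(error[1] / res) - 2, floor(error[2] / res) + 2)  # 0-based
  votes <- integer()
  for (j in seq_len(ncol(strip))) {
    prof <- strip[, j]
    idx <- scipyFindPeaks(prof, height = peak95, distance = max(1, dt))
    ## profile endpoints qualify when strictly above their single
    ## neighbour (interior-only maxima would make insertion sites at
    ## the genome ends undetectable)
    n <- length(prof)
    if (n >= 2L && prof[1] > prof[2] && prof[1] >= peak95)
      idx <- c(1L, idx)
    if (n >= 2L && prof[n] > prof[n - 1L] && prof[n] >= peak95)
      idx <- c(idx, n)
    idx <- unique(idx) - 1L                 # 0-based bins
    idx <- idx[idx < band[1] | idx > band[2]]
    idx <- dropExcluded(idx, res, exclude)
    votes <- c(votes, idx)
  }
  if (length(votes) == 0L) return(NULL)
  tab <- table(votes)
  topBins <- as.integer(names(tab)[tab == max(tab)])
  if (length(topBins) > 1L) {
    mass <- rowSums(strip)[topBins + 1L]
    topBins <- topBins[order(-mass, topBins)]
  }
  i <- topBins[1]
  structure(i * res, resolution = res, bin = i)
}

## second-stage localization: repeat the per-column argmax vote at the
## finest resolution, with rows restricted to +/- 2 coarse bins around
## the coarse site. The coarse stage (resolution ~ errorLen / 3) is
## only junction-accurate to about one bin; the fine stage pins the
## insertion down to the finest bin so snapping picks the right
## fragment junction.
refineInsertionSite <- function(store, error, coarse, exclude = NULL) {
  resC <- attr(coarse, "resolution")
  resF <- min(resolutions(store))
  if (resF >= resC) return(coarse)
  m <- contactMatrix(store, resF)
  nb <- nrow(m)
  cols <- (floor(error[1] / resF) + 1L):min(ceiling(error[2] / resF), nb)
  lo <- max(0, as.numeric(coarse) - 2 * resC)
  hi <- min(nb * resF, as.numeric(coarse) + 3 * resC)
  rows <- (floor(lo / resF) + 1L):min(ceiling(hi / resF), nb)
  bandF <- c(floor(error[1] / resF) - 2, floor(error[2] / resF) + 2)
  rows <- rows[(rows - 1L) < bandF[1] | (rows - 1L) > bandF[2]]
  rows <- dropExcluded(rows - 1L, resF, exclude) + 1L
  if (length(rows) == 0L) return(coarse)
  sub <- m[rows, cols, drop = FALSE]
  votes <- rows[apply(sub, 2, which.max)] - 1L   # 0-based fine bins
  tab <- table(votes)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1L) {
    mass <- rowSums(m[top + 1L, cols, drop = FALSE])
    top <- top[order(-mass, top)]
  }
  structure(top[1] * resF, resolution = resF, bin = top[1])
}

## nearest fragment junction (incl. 0 and total length) within tol bp;
## returns g unchanged if none is close enough.
snapToJunction <- function(doc, g, tol) {
  fl <- flattenLayout(doc)
  bounds <- unique(c(0, fl$end))
  d <- abs(bounds - g)
  k <- which.min(d)
  if (d[k] <= tol) bounds[k] else g
}

## per-call correction against the current doc + store. Returns
## list(doc, record). Coordinates in `call` must be valid for `doc`.
correctOne <- function(doc, call, store, config) {
  record <- data.frame(iteration = call$iteration, category = call$category,
                       x_start = call$x_start, x_end = call$x_end,
                       insertion = NA_real_, action = "skipped",
                       reason = "", stringsAsFactors = FALSE)
  if (call$category == "debris" && config$debris_mode == "skip") {
    record$reason <- "debris_mode=skip"
    return(list(doc = doc, record = record))
  }
  if (call$category == "chromosome") {
    record$reason <- "chromosome boxes are not errors"
    return(list(doc = doc, record = record))
  }
  tol <- config$boundary_snap_bins * call$resolution
  s <- snapToJunction(doc, call$x_start, tol)
  e <- snapToJunction(doc, call$x_end, tol)
  if (s >= e) {
    record$reason <- "degenerate interval after snapping"
    return(list(doc = doc, record = record))
  }
  if (call$category == "translocation") {
    ins <- tryCatch(findInsertionSite(store, c(call$x_start, call$x_end)),
                    noInsertionSite = function(cnd) NULL)
    if (is.null(ins)) {
      record$reason <- "no insertion site"
      return(list(doc = doc, record = record))
    }
    insRes <- attr(ins, "resolution")
    doc <- splitFragmentAt(splitFragmentAt(doc, s), e)
    ins <- snapToJunction(doc, as.numeric(ins),
                          config$boundary_snap_bins * insRes)
    record$insertion <- ins
    if (ins >= s && ins <= e) {             # already in place
      record$action <- "identity"
      return(list(doc = doc, record = record))
    }
    doc <- splitFragmentAt(doc, ins)
    doc <- moveBlock(doc, s, e, ins)
    record$action <- "move"
  } else if (call$category == "inversion") {
    doc <- splitFragmentAt(splitFragmentAt(doc, s), e)
    doc <- invertBlock(doc, s, e)
    record$action <- "invert"
  } else if (call$category == "debris") {
    doc <- splitFragmentAt(splitFragmentAt(doc, s), e)
    doc <- relegateDebris(doc, s, e)
    record$action <- "relegate"
  }
  list(doc = doc, record = record)
}

#' Apply one error call to an assembly document
#'
#' Translocations are cut at both call boundaries and at the peak-
#' derived insertion site, then moved there; inversions are cut and
#' flipped; debris is relegated to the leftover scaffold only when
#' `debris_mode = "adjust"` (the default is to leave debris untouched).
#' Cut and insertion positions are snapped to nearby fragment junctions
#' (see [curationConfig()]). A failed insertion-site search skips the
#' call rather than aborting.
#'
#' @param doc an [AssemblyDoc-class].
#' @param call a single-row error-call data.frame with coordinates valid
#'   for `doc`.
#' @param store the [ContactStore-class] the call was detected on.
#' @param config a [curationConfig()] list.
#' @return list with the new `doc`, the updated `call` (status
#'   `"corrected"` or `"skipped"`) and an `edit` record row.
#' @export
applyCorrection <- function(doc, call, store,
                            config = curationConfig()) {
  stopifnot(nrow(call) == 1L, call$status == "pending")
  out <- correctOne(doc, call, store, config)
  call$status <- if (out$record$action %in% c("move", "invert", "relegate",
                                              "identity"))
    "corrected" else "skipped"
  list(doc = out$doc, call = call, edit = out$record)
}

## name-level plan of a correction, taken against the iteration-start
## document (after all splits have been executed, so every needed
## junction exists). Executing by fragment name makes plans robust to
## coordinate shifts caused by earlier moves in the same batch.
planByNames <- function(doc, s, e, ins = NA) {
  fl <- flattenLayout(doc)
  sl <- blockSlots(fl, s, e)
  leftName <- if (!is.na(ins) && ins > 0) {
    k <- match(ins, fl$end)
    if (is.na(k)) NA_character_ else fl$name[k]
  } else NA_character_
  list(block = fl$name[sl], leftName = leftName,
       insertAtOrigin = !is.na(ins) && ins == 0)
}

## does a refreshed detection still flag this plan's block? Used to
## drop calls that an earlier edit in the same batch already resolved.
staleCallStillPresent <- function(doc, plan, callsFresh) {
  fl <- flattenLayout(doc)
  sl <- match(plan$block, fl$name)
  sl <- sl[!is.na(sl)]
  if (length(sl) == 0L) return(FALSE)
  s <- min(fl$start[sl]); e <- max(fl$end[sl])
  sub <- callsFresh[callsFresh$category == plan$call$category, ,
                    drop = FALSE]
  any(sub$x_start < e & sub$x_end > s)
}

## execute one translocation: re-locate the block by name in the
## current document, search the (current) store for the insertion
## site, snap, cut and move. Returns the outcome and the new document.
## current assembly span of a fragment-name block; NULL when the block
## was re-cut or scattered by an earlier edit
blockSpan <- function(fl, block) {
  sl <- match(block, fl$name)
  if (anyNA(sl) || (length(sl) > 1L && any(diff(sort(sl)) != 1L)))
    return(NULL)
  sl <- sort(sl)
  c(fl$start[sl[1]], fl$end[sl[length(sl)]])
}

executeMove <- function(doc, plan, store, config,
                        pendingBlocks = list(), deferredBlocks = list()) {
  fl <- flattenLayout(doc)
  span <- blockSpan(fl, plan$block)
  if (is.null(span))
    return(list(edited = FALSE, doc = doc, ins = NA_real_,
                deferred = FALSE,
                reason = "deferred: fragments edited earlier this iteration"))
  s <- span[1]; e <- span[2]
  found <- tryCatch(findInsertionSite(store, c(s, e)),
                    noInsertionSite = function(cnd) NULL)
  if (is.null(found))
    return(list(edited = FALSE, doc = doc, ins = NA_real_,
                deferred = FALSE, reason = "no insertion site"))
  ins <- snapToJunction(doc, as.numeric(found),
                        config$boundary_snap_bins * attr(found, "resolution"))
  if (ins >= s && ins <= e)
    return(list(edited = TRUE, doc = doc, ins = ins, deferred = FALSE,
                reason = "already in place"))
  ## ambiguous pair: the proposed site abuts another flagged block --
  ## the two pieces attract each other, and joining the partner can
  ## cement both in the wrong place. If the partner is still pending,
  ## defer and let its own search act first. If the partner already
  ## deferred towards us, its span is uninformative: redo the search
  ## with it excluded, so the remaining evidence (the true home) wins;
  ## only when nothing else speaks do we join the partner.
  whichAbuts <- function(blocks) {
    hit <- vapply(blocks, function(b) {
      sp <- blockSpan(fl, b)
      !is.null(sp) && (ins == sp[1] || ins == sp[2])
    }, TRUE)
    blocks[hit]
  }
  if (length(whichAbuts(pendingBlocks)) &&
      length(whichAbuts(deferredBlocks)) == 0L)
    return(list(edited = FALSE, doc = doc, ins = ins, deferred = TRUE,
                reason = "deferred: site abuts another pending call"))
  partners <- whichAbuts(deferredBlocks)
  if (length(partners)) {
    spans <- Filter(Negate(is.null), lapply(partners, blockSpan, fl = fl))
    alt <- tryCatch(findInsertionSite(store, c(s, e), exclude = spans),
                    noInsertionSite = function(cnd) NULL)
    if (is.null(alt))
      ## mutual attraction was the only evidence: stay put and let the
      ## deferred partner come to us in its pass
      return(list(edited = FALSE, doc = doc, ins = NA_real_,
                  deferred = FALSE,
                  reason = "skipped: no evidence beyond a mutually attracted call"))
    ins2 <- snapToJunction(doc, as.numeric(alt),
                           config$boundary_snap_bins *
                             attr(alt, "resolution"))
    if (ins2 >= s && ins2 <= e)
      return(list(edited = TRUE, doc = doc, ins = ins2,
                  deferred = FALSE, reason = "already in place"))
    ins <- ins2
  }
  doc <- splitFragmentAt(doc, ins)
  doc <- moveBlock(doc, s, e, ins)
  list(edited = TRUE, doc = doc, ins = ins, deferred = FALSE,
       reason = "")
}

executeNamePlan <- function(doc, plan, action) {
  fl <- flattenLayout(doc)
  sl <- match(plan$block, fl$name)
  if (anyNA(sl) || (length(sl) > 1L && any(diff(sort(sl)) != 1L)))
    return(NULL)                           # consumed by an earlier edit: defer
  sl <- sort(sl)
  s <- fl$start[sl[1]]; e <- fl$end[sl[length(sl)]]
  if (action == "invert") return(invertBlock(doc, s, e))
  if (action == "relegate") return(relegateDebris(doc, s, e))
  # move
  ins <- if (plan$insertAtOrigin) 0 else {
    k <- match(plan$leftName, fl$name)
    if (is.na(k)) return(NULL)
    fl$end[k]
  }
  if (ins >= s && ins <= e) return(doc)    # identity move
  moveBlock(doc, s, e, ins)
}

#' Iterative detect-and-correct loop
#'
#' Repeats: regenerate the contact store from the current document
#' (`mapProvider`), detect errors ([detectErrors()]), and correct every
#' pending call, until no translocation or inversion remains or
#' `max_iterations` is reached. Within an iteration all cuts are
#' executed first (cuts do not shift assembly coordinates), then the
#' moves/flips are executed as fragment-name plans, so edits earlier in
#' the batch cannot invalidate later ones; a call whose fragments were
#' consumed by an earlier edit is deferred to the next iteration. A
#' translocation+inversion count that fails to decrease for
#' `stall_patience` consecutive iterations aborts the loop with a
#' warning.
#'
#' @param doc starting [AssemblyDoc-class].
#' @param detector a `function(tile, doc)` box detector.
#' @param mapProvider a `function(doc)` returning a
#'   [ContactStore-class] for the document (simulator-backed at desk
#'   scale).
#' @param config a [curationConfig()] list.
#' @return list with `doc` (final document), `logs` (one row per
#'   iteration: category counts, edits applied, calls skipped),
#'   `edits` (audit table), `calls` (all calls with final status),
#'   `history` (the document at the start of each iteration, ending
#'   with the final document), `converged`, `stalled`.
#' @export
runIterations <- function(doc, detector, mapProvider,
                          config = curationConfig()) {
  logs <- data.frame(iteration = integer(), translocation = integer(),
                     inversion = integer(), debris = integer(),
                     chromosome = integer(), edits = integer(),
                     skipped = integer())
  edits <- list()
  allCalls <- list(emptyCalls())
  history <- list(doc)   # document at the start of each iteration
  converged <- FALSE; stalled <- FALSE
  prevCount <- Inf; stallRun <- 0L
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    store <- mapProvider(doc)
    calls <- detectErrors(store, detector, doc, config)
    calls <- calls[calls$category != "chromosome", , drop = FALSE]
    if (nrow(calls)) calls$iteration <- iter
    counts <- countByType(calls)
    nErr <- counts[["translocation"]] + counts[["inversion"]]
    if (nErr == 0L) {
      logs[nrow(logs) + 1L, ] <- c(iter, as.list(counts), 0L, 0L)
      allCalls[[length(allCalls) + 1L]] <- calls
      converged <- TRUE
      break
    }
    if (nErr >= prevCount) {
      stallRun <- stallRun + 1L
      if (stallRun >= config$stall_patience) {
        warning(sprintf(
          "aborting: error count did not decrease for %d iteration(s)",
          stallRun))
        stalled <- TRUE
        logs[nrow(logs) + 1L, ] <- c(iter, as.list(counts), 0L, 0L)
        allCalls[[length(allCalls) + 1L]] <- calls
        break
      }
    } else stallRun <- 0L
    prevCount <- nErr
    ## order calls by genomic position for deterministic batching;
    ## inversions are executed first (they shift no coordinates),
    ## translocations one at a time against a refreshed map, debris
    ## relegations (which compact the layout) last
    calls <- calls[order(match(calls$category,
                               c("inversion", "translocation", "debris")),
                         calls$x_start, calls$x_end), , drop = FALSE]
    ## phase A (iteration-start coordinates are valid: cuts do not
    ## shift the assembly axis): snap boundaries, cut, record
    ## fragment-name plans
    plans <- vector("list", nrow(calls))
    for (i in seq_len(nrow(calls))) {
      cl <- calls[i, ]
      if (cl$category == "debris" && config$debris_mode == "skip") {
        plans[[i]] <- list(action = "skipped", reason = "debris_mode=skip",
                           call = cl)
        next
      }
      tol <- config$boundary_snap_bins * cl$resolution
      s <- snapToJunction(doc, cl$x_start, tol)
      e <- snapToJunction(doc, cl$x_end, tol)
      if (s >= e) {
        plans[[i]] <- list(action = "skipped",
                           reason = "degenerate interval", call = cl)
        next
      }
      doc <- splitFragmentAt(splitFragmentAt(doc, s), e)
      action <- switch(cl$category, translocation = "move",
                       inversion = "invert", debris = "relegate")
      plans[[i]] <- c(list(action = action, reason = "", call = cl,
                           ins = NA_real_),
                      planByNames(doc, s, e))
    }
    ## phase B: execute by fragment name. A translocation whose
    ## proposed site abuts another pending translocation is deferred to
    ## a second pass: the partner acts first (with the deferred span
    ## excluded from its search, so mutual attraction cannot override
    ## independent evidence) and the deferred call then follows with
    ## the pair's geometry settled.
    nEdits <- 0L; nSkipped <- 0L
    storeFresh <- NULL            # refreshed before each insertion search
    callsFresh <- NULL
    deferredBlocks <- list()
    record <- function(p, cl) {
      edits[[length(edits) + 1L]] <<- data.frame(
        iteration = iter, category = cl$category, x_start = cl$x_start,
        x_end = cl$x_end,
        insertion = if (is.null(p$ins) || is.na(p$ins)) NA_real_ else p$ins,
        action = p$action, reason = p$reason, stringsAsFactors = FALSE)
      allCalls[[length(allCalls) + 1L]] <<- cl
    }
    execMove <- function(p, cl, pendingBlocks, allowDefer) {
      if (is.null(storeFresh)) {
        if (nEdits == 0L) {
          storeFresh <<- store
          callsFresh <<- NULL      # iteration-start calls still valid
        } else {
          storeFresh <<- mapProvider(doc)
          callsFresh <<- detectErrors(storeFresh, detector, doc, config)
        }
      }
      ## a call can be resolved by an earlier edit in this batch (e.g.
      ## its native neighbour was moved next to it); re-check against
      ## the refreshed detection before cutting
      if (!is.null(callsFresh) &&
          !staleCallStillPresent(doc, p, callsFresh)) {
        nSkipped <<- nSkipped + 1L
        cl$status <- "skipped"
        p$reason <- "resolved by an earlier edit this iteration"
        p$action <- "skipped"
        record(p, cl)
        return(FALSE)
      }
      res <- executeMove(doc, p, storeFresh, config,
                         pendingBlocks = if (allowDefer) pendingBlocks
                                         else list(),
                         deferredBlocks = deferredBlocks)
      p$reason <- res$reason
      p$ins <- res$ins
      if (isTRUE(res$deferred)) {
        deferredBlocks[[length(deferredBlocks) + 1L]] <<- p$block
        return(TRUE)               # handled in the second pass
      }
      if (res$edited) {
        doc <<- res$doc
        nEdits <<- nEdits + 1L
        cl$status <- "corrected"
        storeFresh <<- NULL        # doc changed; next search refreshes
      } else {
        nSkipped <<- nSkipped + 1L
        cl$status <- "skipped"
      }
      record(p, cl)
      FALSE
    }
    passTwo <- integer()
    for (i in seq_along(plans)) {
      p <- plans[[i]]
      cl <- p$call
      if (p$action == "skipped") {
        nSkipped <- nSkipped + 1L
        cl$status <- "skipped"
        record(p, cl)
      } else if (p$action == "move") {
        laterMoves <- plans[seq_along(plans) > i]
        pendingBlocks <- lapply(
          Filter(function(q) identical(q$action, "move"), laterMoves),
          `[[`, "block")
        if (execMove(p, cl, pendingBlocks, allowDefer = TRUE))
          passTwo <- c(passTwo, i)
      } else {
        newDoc <- executeNamePlan(doc, p, p$action)
        if (is.null(newDoc)) {
          nSkipped <- nSkipped + 1L
          cl$status <- "skipped"
          p$reason <- "deferred: fragments edited earlier this iteration"
        } else {
          doc <- newDoc
          nEdits <- nEdits + 1L
          cl$status <- "corrected"
        }
        record(p, cl)
      }
    }
    for (i in passTwo) {
      p <- plans[[i]]
      p$reason <- ""
      execMove(p, p$call, list(), allowDefer = FALSE)
    }
    logs[nrow(logs) + 1L, ] <- c(iter, as.list(counts), nEdits, nSkipped)
    history[[length(history) + 1L]] <- doc
  }
  list(doc = doc, logs = logs,
       edits = if (length(edits)) do.call(rbind, edits) else NULL,
       calls = do.call(rbind, allCalls),
       history = history,
       converged = converged, stalled = stalled)
}
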