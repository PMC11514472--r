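#' Intersection over union of two boxes
#'
#' General clamped form: the intersection is
#' `max(0, min(x2,x2') - max(x1,x1')) * max(0, min(y2,y2') - max(y1,y1'))`
#' and the union is the sum of the two areas minus the intersection.
#' Symmetric, translation invariant, in `[0, 1]`.
#'
#' @param a,b numeric vectors `c(x1, y1, x2, y2)` or single-row
#'   data.frames with those columns.
#' @return IOU fraction.
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
boxIoU <- function(a, b) {
  corners <- function(v) {
    if (is.numeric(v) && is.null(names(v))) return(unname(v[1:4]))
    unname(unlist(v[c("x1", "y1", "x2", "y2")]))
  }
  a <- corners(a)
  b <- corners(b)
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("boxes must have positive area")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union_ <- (a[3] - a[1]) * (a[4] - a[2]) +
    (b[3] - b[1]) * (b[4] - b[2]) - inter
  unname(inter / union_)
}

## greedy one-to-one matching by descending prediction score; a match
## requires IOU >= iouMin against a still-unmatched truth (category is
## NOT required to agree -- category confusion is what the matrix
## shows). Returns integer vector: for each prediction, the matched
## truth row or NA.
matchBoxes <- function(pred, truth, iouMin) {
  matchOf <- rep(NA_integer_, nrow(pred))
  used <- rep(FALSE, nrow(truth))
  for (i in order(-pred$score)) {
    if (nrow(truth) == 0L) break
    ious <- vapply(seq_len(nrow(truth)), function(j) {
      if (used[j]) return(-1)
      boxIoU(pred[i, ], truth[j, ])
    }, 1)
    j <- which.max(ious)
    if (length(j) && ious[j] >= iouMin) {
      matchOf[i] <- j
      used[j] <- TRUE
    }
  }
  matchOf
}

#' Detection confusion matrix
#'
#' Predictions are matched one-to-one to ground-truth boxes greedily by
#' descending score (a match needs IOU at least `iouMin`). Matched
#' pairs increment cell (truth category, predicted category); unmatched
#' truths count against the `background` column (misses) and unmatched
#' predictions against the `background` row (false alarms). The total
#' count equals `n_truths + n_false_alarms`.
#'
#' @param pred data.frame with `category, x1, y1, x2, y2, score`.
#' @param truth data.frame with `category, x1, y1, x2, y2`.
#' @param iouMin IOU threshold in `(0, 1]`.
#' @param categories category universe (rows/cols order).
#' @return integer matrix, rows = truth, cols = predicted, both with a
#'   trailing `background` level.
#' @export
detectionConfusion <- function(pred, truth, iouMin = 0.5,
                               categories = c("translocation",
                                              "inversion", "debris",
                                              "chromosome")) {
  if (iouMin <= 0 || iouMin > 1) stop("iouMin must be in (0, 1]")
  lev <- c(categories, "background")
  m <- matrix(0L, length(lev), length(lev), dimnames = list(
    truth = lev, predicted = lev))
  matchOf <- if (nrow(pred)) matchBoxes(pred, truth, iouMin) else integer()
  for (i in seq_len(nrow(pred))) {
    j <- matchOf[i]
    if (is.na(j)) m["background", pred$category[i]] <-
        m["background", pred$category[i]] + 1L
    else m[truth$category[j], pred$category[i]] <-
        m[truth$category[j], pred$category[i]] + 1L
  }
  missed <- setdiff(seq_len(nrow(truth)), matchOf[!is.na(matchOf)])
  for (j in missed) m[truth$category[j], "background"] <-
      m[truth$category[j], "background"] + 1L
  m
}

#' Precision-recall curve for a box detector
#'
#' Sweeps the score threshold over every distinct prediction score
#' (descending). At each threshold, predictions at or above it are
#' matched greedily to the truths ([detectionConfusion()] matching
#' rule, with the category required to agree for a true positive);
#' precision is TP over retained predictions, recall TP over truths.
#'
#' @param pred,truth box data.frames as in [detectionConfusion()].
#' @param iouMin IOU threshold.
#' @param category restrict to one category (`NULL` = all pooled).
#' @return data.frame with columns `threshold, recall, precision`,
#'   recall non-decreasing.
#' @export
prCurve <- function(pred, truth, iouMin = 0.5, category = NULL) {
  if (!is.null(category)) {
    pred <- pred[pred$category == category, , drop = FALSE]
    truth <- truth[truth$category == category, , drop = FALSE]
  }
  if (nrow(truth) == 0L) stop("no ground-truth boxes to score against")
  thresholds <- sort(unique(pred$score), decreasing = TRUE)
  if (length(thresholds) == 0L) thresholds <- 1
  rows <- lapply(thresholds, function(th) {
    keep <- pred[pred$score >= th, , drop = FALSE]
    matchOf <- if (nrow(keep)) matchBoxes(keep, truth, iouMin) else integer()
    tp <- sum(!is.na(matchOf) &
                keep$category == truth$category[matchOf])
    data.frame(threshold = th,
               recall = tp / nrow(truth),
               precision = if (nrow(keep)) tp / nrow(keep) else 1)
  })
  out <- do.call(rbind, rows)
  out[order(out$recall, -out$precision), , drop = FALSE]
}

#' Area under a precision-recall curve (trapezoid rule)
#'
#' Adjacent (recall, precision) pairs form trapezoids:
#' `sum (p_j + p_{j+1}) / 2 * (r_{j+1} - r_j)`.
#'
#' @param curve data.frame with `recall` and `precision` columns,
#'   recall non-decreasing, at least two points.
#' @return area in `[0, 1]`.
#' @examples
#' auprc(data.frame(recall = c(0, 1), precision = c(1, 1)))  # 1
#' @export
auprc <- function(curve) {
  r <- curve$recall; p <- curve$precision
  if (length(r) < 2L) stop("at least two PR points are required")
  if (is.unsorted(r)) stop("recall must be non-decreasing")
  sum((p[-length(p)] + p[-1]) / 2 * diff(r))
}
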