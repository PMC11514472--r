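box <- function(x1, y1, x2, y2, category = "translocation", score = 1)
  data.frame(category = category, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             score = score, stringsAsFactors = FALSE)

test_that("boxIoU matches hand-computed overlaps", {
  expect_equal(boxIoU(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(boxIoU(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  # symmetric and translation invariant
  expect_equal(boxIoU(c(1, 1, 3, 3), c(0, 0, 2, 2)), 1 / 7)
  expect_equal(boxIoU(c(10, 10, 12, 12), c(11, 11, 13, 13)), 1 / 7)
  expect_error(boxIoU(c(0, 0, 0, 2), c(0, 0, 1, 1)), "positive area")
})

test_that("boxIoU agrees with a unit-grid counting oracle", {
  gridIoU <- function(a, b) {
    # count unit cells inside each box over a shared lattice
    xr <- min(a[1], b[1]):(max(a[3], b[3]) - 1)
    yr <- min(a[2], b[2]):(max(a[4], b[4]) - 1)
    cells <- expand.grid(x = xr, y = yr)
    inA <- cells$x >= a[1] & cells$x < a[3] & cells$y >= a[2] &
      cells$y < a[4]
    inB <- cells$x >= b[1] & cells$x < b[3] & cells$y >= b[2] &
      cells$y < b[4]
    sum(inA & inB) / sum(inA | inB)
  }
  set.seed(60)
  for (i in 1:100) {
    a <- c(sample(0:10, 2), 0, 0); a[3:4] <- a[1:2] + sample(1:8, 2)
    b <- c(sample(0:10, 2), 0, 0); b[3:4] <- b[1:2] + sample(1:8, 2)
    expect_equal(boxIoU(a, b), gridIoU(a, b), tolerance = 1e-12)
  }
})

test_that("detectionConfusion counts matches, misses and false alarms", {
  truth <- rbind(box(0, 0, 10, 10, "translocation"),
                 box(20, 20, 30, 30, "inversion"))
  # perfect predictions give a diagonal matrix
  m <- detectionConfusion(truth, truth, 0.5)
  expect_equal(m["translocation", "translocation"], 1L)
  expect_equal(m["inversion", "inversion"], 1L)
  expect_equal(sum(m), 2L)
  # no predictions: everything is missed
  m0 <- detectionConfusion(truth[0, ], truth, 0.5)
  expect_equal(unname(m0[, "background"]), c(1L, 1L, 0L, 0L, 0L))
  # one truth, two overlapping predictions: one match + one false alarm
  pred <- rbind(box(0, 0, 10, 10, score = 0.9),
                box(1, 1, 11, 11, score = 0.8))
  m1 <- detectionConfusion(pred, truth[1, ], 0.5)
  expect_equal(m1["translocation", "translocation"], 1L)
  expect_equal(m1["background", "translocation"], 1L)
  expect_equal(sum(m1), 2L)          # n_truths + n_false_alarms
  # cross-category matches land off the diagonal
  mx <- detectionConfusion(box(0, 0, 10, 10, "inversion"), truth[1, ],
                           0.5)
  expect_equal(mx["translocation", "inversion"], 1L)
})

test_that("confusion total equals truths plus false alarms", {
  set.seed(61)
  for (i in 1:20) {
    nT <- sample(1:6, 1); nP <- sample(0:6, 1)
    truth <- do.call(rbind, lapply(seq_len(nT), function(j) {
      p <- sample(0:40, 2)
      box(p[1], p[2], p[1] + sample(3:10, 1), p[2] + sample(3:10, 1),
          sample(c("translocation", "inversion", "debris"), 1))
    }))
    pred <- if (nP == 0) truth[0, ] else
      do.call(rbind, lapply(seq_len(nP), function(j) {
        p <- sample(0:40, 2)
        box(p[1], p[2], p[1] + sample(3:10, 1), p[2] + sample(3:10, 1),
            sample(c("translocation", "inversion", "debris"), 1),
            score = stats::runif(1))
      }))
    m <- detectionConfusion(pred, truth, 0.5)
    falseAlarms <- sum(m["background", ])
    expect_equal(sum(m), nT + falseAlarms)
  }
})

test_that("auprc implements the trapezoid sum", {
  expect_equal(auprc(data.frame(recall = c(0, 1), precision = c(1, 1))),
               1)
  crv <- data.frame(recall = c(0, 0.5, 1), precision = c(1, 1, 0.5))
  expect_equal(auprc(crv), 0.875)   # 0.5*0.5*(1+1) + 0.5*0.5*(1+0.5)
  # constant precision c integrates to c
  expect_equal(auprc(data.frame(recall = c(0, 1),
                                precision = c(0.3, 0.3))), 0.3)
  expect_error(auprc(data.frame(recall = 0, precision = 1)),
               "at least two")
  expect_error(auprc(data.frame(recall = c(1, 0),
                                precision = c(1, 1))), "non-decreasing")
})

test_that("auprc agrees with pracma::trapz on random monotone curves", {
  set.seed(62)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    r <- sort(stats::runif(n))
    p <- stats::runif(n)
    expect_equal(auprc(data.frame(recall = r, precision = p)),
                 pracma::trapz(r, p), tolerance = 1e-12)
  }
})

test_that("prCurve sweeps scores with non-decreasing recall", {
  truth <- rbind(box(0, 0, 10, 10, "translocation"),
                 box(20, 20, 30, 30, "translocation"),
                 box(40, 40, 50, 50, "inversion"))
  pred <- rbind(box(0, 0, 10, 10, "translocation", 0.9),
                box(20, 20, 30, 30, "translocation", 0.6),
                box(70, 70, 80, 80, "translocation", 0.4))
  crv <- prCurve(pred, truth, 0.5, category = "translocation")
  expect_false(is.unsorted(crv$recall))
  expect_true(all(crv$precision >= 0 & crv$precision <= 1))
  # at the loosest threshold: 2 TP of 3 predictions, 2 of 2 truths
  last <- crv[nrow(crv), ]
  expect_equal(last$recall, 1)
  expect_equal(last$precision, 2 / 3)
  # a perfect detector traces precision 1 up to recall 1
  perfect <- prCurve(truth, truth, 0.5)
  expect_equal(auprc(rbind(data.frame(threshold = NA, recall = 0,
                                      precision = 1), perfect)), 1)
})
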