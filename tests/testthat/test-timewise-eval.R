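test_that("xi-merging combines close annotations transitively", {
  cfg <- timewiseEvalConfig(epsilon = 1)  # xi = 0.5
  gt <- data.frame(start = c(0, 1.2), end = c(1, 2), label = "t")
  m <- mergeGroundTruth(gt, cfg)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 2))
  far <- data.frame(start = c(0, 2), end = c(1, 3), label = "t")
  expect_equal(nrow(mergeGroundTruth(far, cfg)), 2L)
  chain <- data.frame(start = c(0, 1.3, 2.2), end = c(1, 2, 3),
                      label = "t")
  mc <- mergeGroundTruth(chain, cfg)
  expect_equal(nrow(mc), 1L)
  expect_equal(c(mc$start, mc$end), c(0, 3))
})

test_that("xi-merging is idempotent and order-independent", {
  set.seed(17)
  cfg <- timewiseEvalConfig(mergeXi = 0.3, extendLambda = 0)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    s <- sort(runif(n, 0, 20))
    gt <- data.frame(start = s, end = s + runif(n, 0.1, 1), label = "t")
    m1 <- mergeGroundTruth(gt, cfg)
    expect_equal(mergeGroundTruth(m1, cfg), m1)
    shuffled <- gt[sample(n), , drop = FALSE]
    expect_equal(mergeGroundTruth(shuffled, cfg), m1)
    if (nrow(m1) > 1) expect_true(all(diff(m1$start) > cfg@mergeXi))
  }
})

test_that("time-wise precision/recall reproduces worked intervals", {
  cfg <- timewiseEvalConfig(mergeXi = 0.25, extendLambda = 0.25)
  pred <- data.frame(start = 0.8, end = 1.9)
  gt <- data.frame(start = 1.0, end = 2.0, label = "t")
  pr <- timewisePrecisionRecall(pred, gt, cfg)
  expect_equal(pr$PREC, 1.0)  # pred fully inside [0.75, 2.25]
  expect_equal(pr$TPR, 0.9)   # overlap [1, 1.9] of the 1 s ground truth
  # identity and disjoint cases
  same <- timewisePrecisionRecall(gt, gt, cfg)
  expect_equal(c(same$PREC, same$TPR), c(1, 1))
  off <- timewisePrecisionRecall(data.frame(start = 5, end = 6), gt, cfg)
  expect_equal(off$PREC, 0)
  # empty edge cases
  e1 <- timewisePrecisionRecall(pred[0, ], gt, cfg)
  expect_true(is.na(e1$PREC)); expect_equal(e1$TPR, 0)
  e2 <- timewisePrecisionRecall(pred, gt[0, ], cfg)
  expect_true(is.na(e2$TPR)); expect_equal(e2$PREC, 0)
})

test_that("precision/recall match a grid-sampling oracle", {
  set.seed(23)
  for (i in 1:60) {
    cfg <- timewiseEvalConfig(mergeXi = runif(1, 0, 0.5),
                              extendLambda = runif(1, 0, 0.5))
    np <- sample(0:6, 1); ng <- sample(1:6, 1)
    ps <- sort(runif(np, 0, 18))
    pred <- data.frame(start = ps, end = ps + runif(np, 0.2, 2))
    gs <- sort(runif(ng, 0, 18))
    gt <- data.frame(start = gs, end = gs + runif(ng, 0.2, 2),
                     label = "t")
    pr <- timewisePrecisionRecall(pred, gt, cfg, recordingDuration = 25)
    # dense-grid duration oracle
    grid <- seq(0, 25, by = 1e-3) + 5e-4
    inAny <- function(x, iv) {
      if (nrow(iv) == 0L) return(rep(FALSE, length(x)))
      Reduce(`|`, lapply(seq_len(nrow(iv)), function(k)
        x > iv$start[k] & x < iv$end[k]))
    }
    gtM <- spotcall:::.mergeIntervals(gt$start, gt$end, cfg@mergeXi)
    ext <- data.frame(start = pmax(0, gtM$start - cfg@extendLambda),
                      end = pmin(25, gtM$end + cfg@extendLambda))
    inP <- inAny(grid, pred); inE <- inAny(grid, ext)
    inG <- inAny(grid, gtM)
    if (np > 0) {
      expect_equal(pr$PREC, sum(inP & inE) / sum(inP), tolerance = 2e-2)
      expect_equal(pr$TPR, sum(inG & inP) / sum(inG), tolerance = 2e-2)
      # invariance to splitting a prediction into abutting pieces
      k <- sample(np, 1)
      mid <- (pred$start[k] + pred$end[k]) / 2
      split <- rbind(pred[-k, ],
                     data.frame(start = c(pred$start[k], mid),
                                end = c(mid, pred$end[k])))
      pr2 <- timewisePrecisionRecall(split, gt, cfg,
                                     recordingDuration = 25)
      expect_equal(pr2$PREC, pr$PREC)
      expect_equal(pr2$TPR, pr$TPR)
    }
  }
})

test_that("frame AUC equals rank statistic and handles edge cases", {
  eps <- 1
  mkFrames <- function(p, starts = seq(0, by = 1, length.out = length(p)))
    data.frame(start = starts, end = starts + eps, prob.target = p,
               predicted_label = "x")
  gt <- data.frame(start = 0, end = 2, label = "t")
  # frames 1-2 positive (full overlap), 3-4 negative
  r <- frameRocAuc(mkFrames(c(0.9, 0.8, 0.7, 0.1)), gt, "target")
  expect_equal(r$auc, 1)
  r2 <- frameRocAuc(mkFrames(rep(0.5, 4)), gt, "target")
  expect_equal(r2$auc, 0.5)
  allPos <- frameRocAuc(mkFrames(c(0.9, 0.8)), gt, "target")
  expect_true(is.na(allPos$auc))
  # randomized oracle: trapezoid AUC == Mann-Whitney with midranks
  set.seed(29)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    p <- round(runif(n), 2)  # heavy ties
    truth <- runif(n) < 0.5
    if (all(truth) || !any(truth)) next
    starts <- seq(0, by = 1, length.out = n)
    f <- mkFrames(p, starts)
    gtIv <- data.frame(start = starts[truth], end = starts[truth] + eps)
    res <- frameRocAuc(f, gtIv, "target",
                       timewiseEvalConfig(mergeXi = 0, extendLambda = 0))
    expect_equal(res$auc, spotcall:::.rankAuc(p, truth), tolerance = 1e-9)
  }
})

test_that("frame ground-truth labels need majority overlap", {
  gt <- data.frame(start = 1, end = 10, label = "t")
  f <- data.frame(start = c(0, 0.4, 0.6, 9.6), end = c(1, 1.4, 1.6, 10.6),
                  prob.target = 0.5, predicted_label = "x")
  truth <- spotcall:::.frameTruth(f, gt)
  expect_equal(truth, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("UAR is the unweighted mean of per-class recalls", {
  cu <- confusionAndUar(rep(c("a", "b"), c(10, 10)),
                        c(rep("a", 8), rep("b", 2), rep("a", 5),
                          rep("b", 5)))
  expect_equal(cu$UAR, 0.65)
  expect_equal(unname(cu$confusion["a", "b"]), 2L)
  # perfect diagonal
  expect_equal(confusionAndUar(c("a", "b", "c"), c("a", "b", "c"))$UAR, 1)
  # a supported class with zero recall stays in the mean
  cu4 <- confusionAndUar(c("a", "a", "b", "b", "c", "d"),
                         c("a", "a", "b", "b", "d", "d"),
                         classes = c("a", "b", "c", "d"))
  expect_equal(cu4$UAR, mean(c(1, 1, 0, 1)))
  # zero-support classes are excluded with a warning
  expect_warning(
    cuz <- confusionAndUar(c("a", "b"), c("a", "b"),
                           classes = c("a", "b", "ghost")),
    "ghost")
  expect_equal(cuz$UAR, 1)
  expect_error(confusionAndUar(character(), character()), "empty")
})

test_that("UAR is invariant to class-size rescaling", {
  set.seed(31)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.3,
                 sample(c("a", "b", "c"), 60, replace = TRUE), truth)
  u1 <- confusionAndUar(truth, pred)$UAR
  dup <- truth == "a"
  u2 <- confusionAndUar(c(truth, truth[dup]), c(pred, pred[dup]))$UAR
  expect_equal(u1, u2)
})
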