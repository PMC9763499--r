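test_that("plateau scheduler halves the rate after 4 stale epochs", {
  st <- spotcall:::.schedulerInit(1e-5)
  for (e in 1:5)
    st <- spotcall:::.schedulerStep(st, 0.9, e, 0.5, 4L, 100L)
  # epoch 1 improves (0.9 > -Inf); epochs 2-5 are stale -> decay fires
  expect_equal(st$lr, 0.5e-5)
  st <- spotcall:::.schedulerStep(st, 0.9, 6L, 0.5, 4L, 100L)
  expect_equal(st$lr, 0.5e-5)  # counter was reset by the decay
  for (e in 7:9) st <- spotcall:::.schedulerStep(st, 0.9, e, 0.5, 4L, 100L)
  expect_equal(st$lr, 0.25e-5)  # second decay after 4 more stale epochs
  # ties are stale, improvement resets both counters
  st <- spotcall:::.schedulerStep(st, 0.95, 10L, 0.5, 4L, 100L)
  expect_true(st$improved)
  expect_equal(st$staleLr, 0L)
  expect_equal(st$staleStop, 0L)
})

test_that("early stopping fires after the configured stale epochs", {
  st <- spotcall:::.schedulerInit(1e-3)
  st <- spotcall:::.schedulerStep(st, 0.8, 1L, 0.5, 4L, 1L)
  expect_false(st$stop)
  st <- spotcall:::.schedulerStep(st, 0.7, 2L, 0.5, 4L, 1L)
  expect_true(st$stop)          # stops after 2 epochs
  expect_equal(st$bestEpoch, 1L)  # epoch-1 weights are the best
})

test_that("learning-rate sequence is initial x decay^k", {
  st <- spotcall:::.schedulerInit(2e-4)
  accs <- c(0.5, rep(0.5, 11))
  lrs <- numeric(0)
  for (e in seq_along(accs)) {
    lrs <- c(lrs, st$lr)
    st <- spotcall:::.schedulerStep(st, accs[e], e, 0.5, 4L, 100L)
  }
  ks <- log2(2e-4 / lrs)
  expect_true(all(abs(ks - round(ks)) < 1e-12))
  expect_true(all(diff(lrs) <= 0))
})

test_that("training overfits a tiny separable batch and returns history", {
  recs <- makeTinyCorpus(nClips = 4L, nRec = 4L, seed = 3L)
  sp <- splitByRecording(recs, seed = 1)
  set.seed(11)
  net <- buildNetwork(tinyNetSpec())
  tcfg <- trainingConfig(learningRate = 1e-3, maxEpochs = 5L,
                         earlyStopPatience = 10L, seed = 11L)
  fit <- trainNetwork(net, sp, tinyPcfg(), tcfg)
  h <- fit$history
  expect_named(h, c("epoch", "train_loss", "train_acc", "val_acc", "lr"))
  expect_equal(nrow(h), 5L)
  expect_lt(h$train_loss[5], h$train_loss[1])  # loss decreases
  expect_true(all(diff(h$lr) <= 0))
  expect_error(trainNetwork(net, new("DatasetSplit",
    train = recs[0, ], validation = recs[0, ], test = recs[0, ],
    fractions = c(.7, .15, .15)), tinyPcfg(), tcfg), "non-empty")
})

test_that("seeded training runs are bit-identical", {
  recs <- makeTinyCorpus(nClips = 4L, nRec = 4L, seed = 4L)
  sp <- splitByRecording(recs, seed = 1)
  tcfg <- trainingConfig(learningRate = 1e-3, maxEpochs = 2L, seed = 99L)
  run <- function() {
    set.seed(42)
    net <- buildNetwork(tinyNetSpec())
    trainNetwork(net, sp, tinyPcfg(augment = TRUE), tcfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network@params, f2$network@params)
})

test_that("split evaluation metrics follow the count-based definitions", {
  # 4 TP, 1 FP, 1 FN, 4 TN worked example via a stubbed network is
  # exercised directly on the metric arithmetic
  truth <- c(rep("target", 5), rep("noise", 5))
  pred <- c(rep("target", 4), "noise", "target", rep("noise", 4))
  tp <- sum(truth == "target" & pred == "target")
  fp <- sum(truth == "noise" & pred == "target")
  fn <- sum(truth == "target" & pred == "noise")
  expect_equal(c(tp, fp, fn), c(4, 1, 1))
  # the same counts through evaluateSplit on a trained-enough network are
  # covered by the acceptance suite; here assert the AUC rank statistic
  scores <- c(0.9, 0.8, 0.7, 0.1)
  positive <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(spotcall:::.rankAuc(scores, positive), 1)
  expect_equal(spotcall:::.rankAuc(rep(0.5, 4), positive), 0.5)
  expect_true(is.na(spotcall:::.rankAuc(scores, rep(TRUE, 4))))
})

test_that("evaluateSplit returns the binary metric set on real clips", {
  recs <- makeTinyCorpus(nClips = 5L, nRec = 5L, seed = 6L)
  sp <- splitByRecording(recs, seed = 2)
  set.seed(1)
  net <- buildNetwork(tinyNetSpec())
  m <- evaluateSplit(net, testSet(sp), tinyPcfg())
  expect_named(m, c("ACC", "TPR", "FPR", "PREC", "F1", "AUC"))
  expect_true(m$ACC >= 0 && m$ACC <= 1)
})
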