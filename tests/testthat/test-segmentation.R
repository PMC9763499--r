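test_that("window layout follows the epsilon/kappa arithmetic", {
  sw <- slidingWindowConfig(1, 0.5)
  w <- makeWindows(10, sw)
  expect_equal(nrow(w), 19L)  # floor((10-1)/0.5)+1
  expect_equal(w$start, seq(0, 9, by = 0.5))
  expect_equal(makeWindows(1, sw),
               data.frame(start = 0, end = 1))
  # short recording: one zero-padded window covering the whole file
  expect_equal(makeWindows(0.4, sw), data.frame(start = 0, end = 0.4))
  # residual audio gets a final shorter window ending at the duration
  w2 <- makeWindows(10.2, sw)
  expect_equal(nrow(w2), 20L)
  expect_equal(w2$end[20], 10.2)
  expect_equal(w2$start[20], 9.5)
})

test_that("neighbor smoothing flips only fully-target-surrounded noise", {
  # kappa = epsilon/2: each interior frame overlaps both neighbors
  f <- frameTable(seq(0, 1, by = 0.5), eps = 1,
                  probTarget = c(0.9, 0.4, 0.9))
  expect_equal(f$predicted_label, c("target", "noise", "target"))
  sm <- smoothFrames(f)
  expect_equal(sm$predicted_label, rep("target", 3))
  expect_equal(sm$prob.target, f$prob.target)  # probabilities untouched
  # [N, N, T] unchanged: a noise neighbor blocks the flip
  f2 <- frameTable(seq(0, 1, by = 0.5), 1, c(0.1, 0.2, 0.9))
  expect_equal(smoothFrames(f2)$predicted_label,
               c("noise", "noise", "target"))
  # kappa = epsilon: no overlap, no flips ever
  f3 <- frameTable(seq(0, 4, by = 1), 1, c(0.9, 0.1, 0.9, 0.1, 0.9))
  expect_equal(smoothFrames(f3)$predicted_label, f3$predicted_label)
})

test_that("smoothing is one-directional and order-independent", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(3:15, 1)
    p <- runif(n)
    f <- frameTable(seq(0, by = 0.5, length.out = n), 1, p)
    sm <- smoothFrames(f)
    # never target -> noise
    expect_true(all(sm$predicted_label[f$predicted_label == "target"] ==
                      "target"))
    # brute-force oracle on the original labels
    lab <- f$predicted_label
    oracle <- lab
    for (j in seq_len(n)) {
      if (lab[j] == "noise") {
        nb <- setdiff(which(f$start < f$end[j] - 1e-9 &
                              f$end > f$start[j] + 1e-9), j)
        if (length(nb) && all(lab[nb] == "target")) oracle[j] <- "target"
      }
    }
    expect_equal(sm$predicted_label, oracle)
  }
})

test_that("annotation extraction merges runs above the threshold", {
  sw <- slidingWindowConfig(1, 0.5, threshold = 0.5)
  f <- frameTable(seq(0, 1.5, by = 0.5), 1, c(0.2, 0.95, 0.97, 0.3))
  ann <- extractAnnotations(f, sw, "target")
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$start, 0.5)
  expect_equal(ann$end, 2.0)
  expect_equal(ann$confidence, 0.97)
  # all below threshold -> empty; all above -> one full-span annotation
  expect_equal(nrow(extractAnnotations(
    frameTable(seq(0, 1.5, 0.5), 1, rep(0.4, 4)), sw, "target")), 0L)
  all1 <- extractAnnotations(
    frameTable(seq(0, 1.5, 0.5), 1, rep(0.9, 4)), sw, "target")
  expect_equal(nrow(all1), 1L)
  expect_equal(c(all1$start, all1$end), c(0, 2.5))
  # threshold 1 never extracts
  sw1 <- slidingWindowConfig(1, 0.5, threshold = 1)
  expect_equal(nrow(extractAnnotations(
    frameTable(seq(0, 1.5, 0.5), 1, rep(1, 4)), sw1, "target")), 0L)
})

test_that("run-merging matches a brute-force scan on random labels", {
  set.seed(12)
  sw <- slidingWindowConfig(1, 0.5, threshold = 0.5)
  for (i in 1:200) {
    n <- sample(1:25, 1)
    p <- round(runif(n), 3)
    f <- frameTable(seq(0, by = 0.5, length.out = n), 1, p)
    ann <- extractAnnotations(f, sw, "target")
    pos <- p > 0.5
    # oracle: walk the sequence collecting maximal positive runs
    runs <- list()
    j <- 1
    while (j <= n) {
      if (pos[j]) {
        k <- j
        while (k < n && pos[k + 1]) k <- k + 1
        runs[[length(runs) + 1]] <- c(f$start[j], f$end[k],
                                      max(p[j:k]))
        j <- k + 1
      } else j <- j + 1
    }
    expect_equal(nrow(ann), length(runs))
    for (r in seq_along(runs)) {
      expect_equal(unlist(ann[r, c("start", "end", "confidence")],
                          use.names = FALSE), runs[[r]])
    }
  }
})

test_that("annotations are disjoint, ordered and threshold-monotone", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    p <- runif(n)
    f <- frameTable(seq(0, by = 0.25, length.out = n), 0.5, p)
    durs <- vapply(c(0.3, 0.5, 0.7, 0.9), function(d) {
      ann <- extractAnnotations(
        f, slidingWindowConfig(0.5, 0.25, threshold = d), "target")
      if (nrow(ann) > 1) {
        expect_true(all(diff(ann$start) > 0))
        expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)] - 1e-9))
      }
      sum(ann$end - ann$start)
    }, 1)
    expect_true(all(diff(durs) <= 1e-9))  # raising delta never adds time
  }
})

test_that("selection tables round-trip in both dialects", {
  ann <- data.frame(start = c(0.5, 2.25), end = c(1.5, 3),
                    label = "target", confidence = c(0.9, 0.7))
  f1 <- tempfile(fileext = ".txt")
  writeSelectionTable(ann, f1, "simple")
  back <- readSelectionTable(f1)
  expect_equal(back$start, ann$start)
  expect_equal(back$confidence, ann$confidence)
  f2 <- tempfile(fileext = ".txt")
  writeSelectionTable(ann, f2, "raven")
  raven <- readSelectionTable(f2)
  expect_equal(raven$end, ann$end)
  expect_equal(raven$label, ann$label)
  writeLines("foo\tbar", f1)
  expect_error(readSelectionTable(f1), "unrecognized")
})
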