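# Cross-entropy training with Adam, accuracy-driven plateau learning-rate
# decay and early stopping. Training clips are re-augmented and randomly
# placed every epoch; validation clips are preprocessed once, centered and
# unaugmented, so the validation criterion is stable.

# plateau scheduler: "improvement" is a strict increase of validation
# accuracy over the best seen; ties are stale. The decay counter resets on
# improvement and after a decay fires; the early-stop counter resets on
# improvement only.
.schedulerInit <- function(lr) {
  list(best = -Inf, bestEpoch = 0L, staleLr = 0L, staleStop = 0L, lr = lr)
}

.schedulerStep <- function(st, valAcc, epoch, decayFactor, lrPatience,
                           stopPatience) {
  improved <- valAcc > st$best
  if (improved) {
    st$best <- valAcc
    st$bestEpoch <- epoch
    st$staleLr <- 0L
    st$staleStop <- 0L
  } else {
    st$staleLr <- st$staleLr + 1L
    st$staleStop <- st$staleStop + 1L
    if (st$staleLr >= lrPatience) {
      st$lr <- st$lr * decayFactor
      st$staleLr <- 0L
    }
  }
  st$stop <- st$staleStop >= stopPatience
  st$improved <- improved
  st
}

.loadWaves <- function(records) {
  lapply(records$path, readWav)
}

.labelIndex <- function(labels, classNames) {
  idx <- match(labels, classNames)
  if (anyNA(idx))
    stop("labels not covered by the network's classes: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

#' Train the residual classifier on a recording-exclusive split
#'
#' Runs mini-batch cross-entropy training with the Adam optimizer. Training
#' clips are augmented (when `pcfg@augment` is TRUE) and randomly placed in
#' the sequence window every epoch; validation clips are centered and never
#' augmented. The learning rate is multiplied by `tcfg@lrDecayFactor` after
#' `tcfg@lrPatience` epochs without a strict validation-accuracy
#' improvement, and training stops after `tcfg@earlyStopPatience` stale
#' epochs or `tcfg@maxEpochs`, returning the weights of the best validation
#' epoch.
#'
#' @param net an [AnimalNet-class] whose class names cover the labels (when
#'   the spec carries no class names they are taken from the training data,
#'   sorted).
#' @param split a [DatasetSplit-class] with non-empty train and validation
#'   partitions.
#' @param pcfg a [PreprocessingConfig-class].
#' @param tcfg a [TrainingConfig-class].
#' @param noisePool optional noise templates for augmentation; by default
#'   built from training clips of the class named "noise" when augmenting.
#' @param verbose print one line per epoch.
#' @return list with elements `network` (best-epoch [AnimalNet-class]) and
#'   `history` (data.frame: epoch, train_loss, train_acc, val_acc, lr).
#' @export
trainNetwork <- function(net, split, pcfg, tcfg, noisePool = NULL,
                         verbose = FALSE) {
  trainRecs <- split@train
  valRecs <- split@validation
  if (nrow(trainRecs) == 0L || nrow(valRecs) == 0L)
    stop("train and validation partitions must be non-empty")
  set.seed(tcfg@seed)
  spec <- net@spec
  if (!length(spec@classNames)) {
    spec@classNames <- sort(unique(trainRecs$label))
    if (length(spec@classNames) != spec@nClasses)
      stop("number of training classes does not match the network head")
    net@spec <- spec
  }
  yTrain <- .labelIndex(trainRecs$label, spec@classNames)
  yVal <- .labelIndex(valRecs$label, spec@classNames)

  trainWaves <- .loadWaves(trainRecs)
  valWaves <- .loadWaves(valRecs)
  if (is.null(noisePool) && pcfg@augment) {
    noiseIdx <- which(trainRecs$label == "noise")
    if (length(noiseIdx))
      noisePool <- makeNoisePool(trainWaves[utils::head(noiseIdx, 20L)],
                                 pcfg)
  }
  evalCfg <- pcfg
  evalCfg@augment <- FALSE
  valClips <- lapply(valWaves, preprocessClip, cfg = evalCfg,
                     mode = "center")

  arch <- .archFromSpec(spec)
  params <- net@params
  state <- net@state
  opt <- .adamInit(params)
  sched <- .schedulerInit(tcfg@learningRate)
  best <- list(params = params, state = state)
  history <- NULL

  for (epoch in seq_len(tcfg@maxEpochs)) {
    ord <- sample(nrow(trainRecs))
    losses <- c(); nCorrect <- 0L
    for (bi in split(ord, ceiling(seq_along(ord) / tcfg@batchSize))) {
      clips <- lapply(trainWaves[bi], preprocessClip, cfg = pcfg,
                      noisePool = noisePool,
                      mode = if (pcfg@augment) "random" else "center")
      batch <- .stackClips(clips)
      fw <- .netForward(arch, params, state, batch$x, batch$dims,
                        train = TRUE)
      state <- fw$state
      sx <- .softmaxXent(fw$logits, yTrain[bi])
      losses <- c(losses, sx$loss)
      nCorrect <- nCorrect +
        sum(apply(sx$probs, 2, which.max) == yTrain[bi])
      grads <- .netBackward(arch, params, fw$caches, sx$dlogits)
      upd <- .adamStep(params, grads, opt, sched$lr, tcfg@beta1, tcfg@beta2)
      params <- upd$params
      opt <- upd$opt
    }
    evalNet <- new("AnimalNet", spec = spec, params = params,
                   state = state, preprocessing = evalCfg)
    valProbs <- predictProba(evalNet, valClips)
    valAcc <- mean(apply(valProbs, 1, which.max) == yVal)
    lrUsed <- sched$lr
    sched <- .schedulerStep(sched, valAcc, epoch, tcfg@lrDecayFactor,
                            tcfg@lrPatience, tcfg@earlyStopPatience)
    if (sched$improved) best <- list(params = params, state = state)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses),
      train_acc = nCorrect / nrow(trainRecs), val_acc = valAcc,
      lr = lrUsed))
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  train acc %.3f  val acc %.3f  lr %.2g",
        epoch, mean(losses), nCorrect / nrow(trainRecs), valAcc, lrUsed))
    if (sched$stop) break
  }
  trained <- new("AnimalNet", spec = spec, params = best$params,
                 state = best$state, preprocessing = evalCfg)
  attr(history, "best_epoch") <- sched$bestEpoch
  list(network = trained, history = history)
}

# rank-statistic AUC with midrank tie handling; NA when one class is absent
.rankAuc <- function(scores, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Evaluate a trained network on a labeled clip set
#'
#' Preprocesses the clips (centered, unaugmented), predicts, and reports
#' accuracy plus — for binary tasks — true-positive rate, false-positive
#' rate, precision, F1 and the rank-statistic AUC of the positive-class
#' probability. Multi-class tasks report accuracy, the confusion matrix and
#' the unweighted average recall instead.
#'
#' @param net a trained [AnimalNet-class].
#' @param records data.frame of labeled clip records (path, label).
#' @param pcfg a [PreprocessingConfig-class] (augmentation is forced off).
#' @param positiveClass positive class for the binary metrics; defaults to
#'   the first class not named "noise".
#' @return named list of metrics; binary: ACC, TPR, FPR, PREC, F1, AUC
#'   (AUC is NA when the ground truth is single-class); multi-class: ACC,
#'   confusion, UAR.
#' @export
evaluateSplit <- function(net, records, pcfg, positiveClass = NULL) {
  if (nrow(records) == 0L) stop("empty clip set")
  cls <- net@spec@classNames
  evalCfg <- pcfg
  evalCfg@augment <- FALSE
  clips <- lapply(.loadWaves(records), preprocessClip, cfg = evalCfg,
                  mode = "center")
  probs <- predictProba(net, clips)
  predLab <- cls[apply(probs, 1, which.max)]
  truth <- records$label
  acc <- mean(predLab == truth)
  if (length(cls) > 2L) {
    cu <- confusionAndUar(truth, predLab, classes = cls)
    return(list(ACC = acc, confusion = cu$confusion, UAR = cu$UAR))
  }
  if (is.null(positiveClass)) {
    positiveClass <- setdiff(cls, "noise")[1]
    if (is.na(positiveClass)) positiveClass <- cls[2]
  }
  posTruth <- truth == positiveClass
  posPred <- predLab == positiveClass
  tp <- sum(posTruth & posPred); fp <- sum(!posTruth & posPred)
  fn <- sum(posTruth & !posPred); tn <- sum(!posTruth & !posPred)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(tpr) && prec + tpr > 0)
    2 * prec * tpr / (prec + tpr) else NA_real_
  list(ACC = acc, TPR = tpr, FPR = fpr, PREC = prec, F1 = f1,
       AUC = .rankAuc(probs[, positiveClass], posTruth))
}
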