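# Exported model surface: build the modified residual classifier, run
# batched probability prediction, and round-trip self-describing checkpoints.

#' Build the modified 18-layer residual classifier
#'
#' Constructs the network used throughout the package: a 7x7 stride-2
#' convolutional stem with batch normalization and ReLU but \emph{without}
#' the usual max-pooling stage (removed to preserve spectro-temporal
#' resolution early on), four stages of two basic residual blocks with
#' channel widths 64/128/256/512 (stages 2-4 opening with stride 2, 1x1
#' projection shortcuts on shape change), adaptive global average pooling of
#' the final 512-channel feature maps to a 512-vector, and a linear n-class
#' head. Total downsampling is 16x in both frequency and time. Weights are
#' Kaiming-initialized from R's RNG, so builds are reproducible under
#' [set.seed()].
#'
#' @param spec a [NetworkSpec-class].
#' @return an untrained [AnimalNet-class].
#' @examples
#' set.seed(1)
#' net <- buildNetwork(networkSpec(2, inputShape = c(64L, 32L),
#'                                 classNames = c("noise", "target")))
#' net
#' @export
buildNetwork <- function(spec) {
  validObject(spec)
  arch <- .archFromSpec(spec)
  params <- .initParams(arch)
  new("AnimalNet", spec = spec, params = params,
      state = .initState(params), preprocessing = NULL)
}

#' Number of learnable parameters
#' @param net an [AnimalNet-class].
#' @return integer parameter count.
#' @export
nParameters <- function(net) sum(vapply(net@params, length, 1L))

#' Spatial size of the final feature maps
#'
#' Applies the network's downsampling arithmetic to an input shape; with the
#' stride-2 stem and three stride-2 stages the reduction is 16x per axis.
#'
#' @param net an [AnimalNet-class].
#' @param inputShape c(frequency bins, time frames); defaults to the spec's.
#' @return c(F', T') of the last residual stage's feature maps.
#' @export
featureMapShape <- function(net, inputShape = net@spec@inputShape) {
  h <- inputShape[1]; w <- inputShape[2]
  h <- .convOutDim(h, 7L, 2L, 3L); w <- .convOutDim(w, 7L, 2L, 3L)
  for (bl in .archFromSpec(net@spec)$blocks) {
    h <- .convOutDim(h, 3L, bl$stride, 1L)
    w <- .convOutDim(w, 3L, bl$stride, 1L)
  }
  c(h, w)
}

#' Pooled feature vectors for a batch of clips
#'
#' Runs the feature extractor in evaluation mode and returns the globally
#' average-pooled representation (one 512-vector per clip for the default
#' architecture).
#'
#' @param net an [AnimalNet-class].
#' @param clips list of [NormalizedClip-class] (or matrices).
#' @return features-by-clips matrix.
#' @export
pooledFeatures <- function(net, clips) {
  batch <- .stackClips(clips)
  arch <- .archFromSpec(net@spec)
  fw <- .netForward(arch, net@params, net@state, batch$x, batch$dims,
                    train = FALSE)
  fw$feat
}

#' Per-class probabilities for a batch of clips
#'
#' Evaluation-mode forward pass followed by a softmax. Large batches are
#' processed in chunks to bound memory.
#'
#' @param net an [AnimalNet-class].
#' @param clips list of [NormalizedClip-class] objects or plain matrices
#'   matching the network input shape.
#' @param chunkSize clips per forward pass.
#' @return clips-by-classes matrix of probabilities (rows sum to 1), with
#'   class names as column names when available.
#' @export
predictProba <- function(net, clips, chunkSize = 16L) {
  if (!length(clips)) stop("empty clip list")
  arch <- .archFromSpec(net@spec)
  out <- matrix(NA_real_, length(clips), net@spec@nClasses)
  idx <- split(seq_along(clips),
               ceiling(seq_along(clips) / chunkSize))
  for (ii in idx) {
    batch <- .stackClips(clips[ii])
    if (batch$dims$h != net@spec@inputShape[1] ||
        batch$dims$w != net@spec@inputShape[2])
      stop(sprintf("clip shape %d x %d does not match network input %d x %d",
                   batch$dims$h, batch$dims$w, net@spec@inputShape[1],
                   net@spec@inputShape[2]))
    fw <- .netForward(arch, net@params, net@state, batch$x, batch$dims,
                      train = FALSE)
    logits <- fw$logits
    m <- apply(logits, 2, max)
    e <- exp(sweep(logits, 2, m))
    out[ii, ] <- t(sweep(e, 2, colSums(e), "/"))
  }
  if (length(net@spec@classNames)) colnames(out) <- net@spec@classNames
  out
}

#' Save / load a self-describing checkpoint
#'
#' A checkpoint bundles the weights, batch-norm statistics, architecture
#' specification, preprocessing configuration and class-name ordering, so a
#' loaded network can preprocess and score raw audio without further
#' context.
#'
#' @param net an [AnimalNet-class].
#' @param path checkpoint file path.
#' @return `path` invisibly (save); an [AnimalNet-class] (load).
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(list(format = "spotcall-checkpoint-1", spec = net@spec,
               params = net@params, state = net@state,
               preprocessing = net@preprocessing), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "spotcall-checkpoint-1"))
    stop("not a spotcall checkpoint: ", path)
  new("AnimalNet", spec = ck$spec, params = ck$params, state = ck$state,
      preprocessing = ck$preprocessing)
}
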