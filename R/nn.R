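# Internal neural-network engine. Activations are C x (H*W*N) matrices
# (channel = row; column index = h + H*(w-1) + H*W*(n-1)), convolutions are
# im2col + BLAS gemm, and parameters live in a flat named list so the Adam
# update is a simple loop. Only what the modified 18-layer residual
# classifier needs is implemented: conv / batch norm / ReLU / global average
# pooling / linear head, each with a hand-derived backward pass.

.convOutDim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# architecture descriptor derived from a NetworkSpec; params are referenced
# by name prefix so the same walker drives init, forward and backward
.archFromSpec <- function(spec) {
  ch <- spec@channels
  blocks <- list()
  cin <- ch[1]
  for (s in seq_along(ch)) {
    for (b in seq_len(spec@blocksPerStage[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      blocks[[length(blocks) + 1L]] <- list(
        prefix = sprintf("s%d.b%d", s, b), cin = cin, cout = ch[s],
        stride = stride, proj = (stride != 1L || cin != ch[s]))
      cin <- ch[s]
    }
  }
  list(stemOut = ch[1], blocks = blocks, nFeat = ch[length(ch)],
       nClasses = spec@nClasses)
}

.initConv <- function(cin, cout, k) {
  fanIn <- cin * k * k
  matrix(rnorm(cout * fanIn, sd = sqrt(2 / fanIn)), nrow = cout)
}

.initParams <- function(arch) {
  p <- list()
  p[["stem.conv"]] <- .initConv(1L, arch$stemOut, 7L)
  p[["stem.bn.gamma"]] <- rep(1, arch$stemOut)
  p[["stem.bn.beta"]] <- rep(0, arch$stemOut)
  for (bl in arch$blocks) {
    pre <- bl$prefix
    p[[paste0(pre, ".conv1")]] <- .initConv(bl$cin, bl$cout, 3L)
    p[[paste0(pre, ".bn1.gamma")]] <- rep(1, bl$cout)
    p[[paste0(pre, ".bn1.beta")]] <- rep(0, bl$cout)
    p[[paste0(pre, ".conv2")]] <- .initConv(bl$cout, bl$cout, 3L)
    p[[paste0(pre, ".bn2.gamma")]] <- rep(1, bl$cout)
    p[[paste0(pre, ".bn2.beta")]] <- rep(0, bl$cout)
    if (bl$proj) {
      p[[paste0(pre, ".proj.conv")]] <- .initConv(bl$cin, bl$cout, 1L)
      p[[paste0(pre, ".proj.bn.gamma")]] <- rep(1, bl$cout)
      p[[paste0(pre, ".proj.bn.beta")]] <- rep(0, bl$cout)
    }
  }
  p[["head.W"]] <- matrix(rnorm(arch$nClasses * arch$nFeat,
                                sd = 1 / sqrt(arch$nFeat)),
                          nrow = arch$nClasses)
  p[["head.b"]] <- rep(0, arch$nClasses)
  p
}

.initState <- function(params) {
  st <- list()
  for (nm in grep("\\.gamma$", names(params), value = TRUE)) {
    base <- sub("\\.gamma$", "", nm)
    n <- length(params[[nm]])
    st[[paste0(base, ".mean")]] <- rep(0, n)
    st[[paste0(base, ".var")]] <- rep(1, n)
  }
  st
}

.convFwd <- function(x, dims, w, k, stride, pad) {
  cols <- .im2col(x, dims$h, dims$w, dims$n, k, k, stride, stride, pad, pad)
  list(y = w %*% cols,
       dims = list(h = .convOutDim(dims$h, k, stride, pad),
                   w = .convOutDim(dims$w, k, stride, pad), n = dims$n),
       cache = list(cols = cols, dims = dims, k = k, stride = stride,
                    pad = pad))
}

.convBwd <- function(dy, w, cache) {
  dW <- tcrossprod(dy, cache$cols)
  dcols <- crossprod(w, dy)
  d <- cache$dims
  cin <- nrow(dcols) %/% (cache$k * cache$k)
  dx <- .col2im(dcols, cin, d$h, d$w, d$n, cache$k, cache$k, cache$stride,
                cache$stride, cache$pad, cache$pad)
  list(dW = dW, dx = dx)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

.bnFwd <- function(x, gamma, beta, mean, var, train) {
  if (train) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * istd
    list(y = gamma * xhat + beta,
         cache = list(xhat = xhat, istd = istd, gamma = gamma),
         mean = (1 - BN_MOMENTUM) * mean + BN_MOMENTUM * mu,
         var = (1 - BN_MOMENTUM) * var + BN_MOMENTUM * v)
  } else {
    istd <- 1 / sqrt(var + BN_EPS)
    list(y = gamma * istd * (x - mean) + beta, cache = NULL,
         mean = mean, var = var)
  }
}

.bnBwd <- function(dy, cache) {
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  dx <- cache$istd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# forward pass; train = TRUE records caches for backprop and updates BN
# running statistics
.netForward <- function(arch, params, state, x, dims, train) {
  caches <- list()
  st <- state
  bn <- function(name, x) {
    r <- .bnFwd(x, params[[paste0(name, ".gamma")]],
                params[[paste0(name, ".beta")]],
                st[[paste0(name, ".mean")]], st[[paste0(name, ".var")]],
                train)
    st[[paste0(name, ".mean")]] <<- r$mean
    st[[paste0(name, ".var")]] <<- r$var
    caches[[name]] <<- r$cache
    r$y
  }
  cv <- .convFwd(x, dims, params[["stem.conv"]], 7L, 2L, 3L)
  caches[["stem.conv"]] <- if (train) cv$cache else NULL
  a <- pmax(bn("stem.bn", cv$y), 0)
  caches[["stem.relu"]] <- if (train) a else NULL
  dims <- cv$dims
  for (bl in arch$blocks) {
    pre <- bl$prefix
    inX <- a
    inDims <- dims
    c1 <- .convFwd(a, dims, params[[paste0(pre, ".conv1")]], 3L,
                   bl$stride, 1L)
    caches[[paste0(pre, ".conv1")]] <- if (train) c1$cache else NULL
    a1 <- pmax(bn(paste0(pre, ".bn1"), c1$y), 0)
    caches[[paste0(pre, ".relu1")]] <- if (train) a1 else NULL
    c2 <- .convFwd(a1, c1$dims, params[[paste0(pre, ".conv2")]], 3L, 1L, 1L)
    caches[[paste0(pre, ".conv2")]] <- if (train) c2$cache else NULL
    main <- bn(paste0(pre, ".bn2"), c2$y)
    if (bl$proj) {
      cp <- .convFwd(inX, inDims, params[[paste0(pre, ".proj.conv")]], 1L,
                     bl$stride, 0L)
      caches[[paste0(pre, ".proj.conv")]] <- if (train) cp$cache else NULL
      sc <- bn(paste0(pre, ".proj.bn"), cp$y)
    } else sc <- inX
    a <- pmax(main + sc, 0)
    caches[[paste0(pre, ".out")]] <- if (train) a else NULL
    dims <- c2$dims
  }
  hw <- dims$h * dims$w
  feat <- t(rowsum(t(a), group = rep(seq_len(dims$n), each = hw))) / hw
  logits <- params[["head.W"]] %*% feat + params[["head.b"]]
  caches[["feat"]] <- if (train) feat else NULL
  caches[["featDims"]] <- dims
  list(logits = logits, caches = caches, state = st, dims = dims,
       feat = feat)
}

.netBackward <- function(arch, params, caches, dlogits) {
  grads <- list()
  feat <- caches[["feat"]]
  grads[["head.W"]] <- tcrossprod(dlogits, feat)
  grads[["head.b"]] <- rowSums(dlogits)
  dfeat <- crossprod(params[["head.W"]], dlogits)
  d <- caches[["featDims"]]
  hw <- d$h * d$w
  da <- dfeat[, rep(seq_len(d$n), each = hw), drop = FALSE] / hw
  bnB <- function(name, dy) {
    r <- .bnBwd(dy, caches[[name]])
    grads[[paste0(name, ".gamma")]] <<- r$dgamma
    grads[[paste0(name, ".beta")]] <<- r$dbeta
    r$dx
  }
  for (bl in rev(arch$blocks)) {
    pre <- bl$prefix
    dz <- da * (caches[[paste0(pre, ".out")]] > 0)
    # main branch
    dmain <- bnB(paste0(pre, ".bn2"), dz)
    cb2 <- .convBwd(dmain, params[[paste0(pre, ".conv2")]],
                    caches[[paste0(pre, ".conv2")]])
    grads[[paste0(pre, ".conv2")]] <- cb2$dW
    da1 <- cb2$dx * (caches[[paste0(pre, ".relu1")]] > 0)
    dc1 <- bnB(paste0(pre, ".bn1"), da1)
    cb1 <- .convBwd(dc1, params[[paste0(pre, ".conv1")]],
                    caches[[paste0(pre, ".conv1")]])
    grads[[paste0(pre, ".conv1")]] <- cb1$dW
    dx <- cb1$dx
    # shortcut branch
    if (bl$proj) {
      dsc <- bnB(paste0(pre, ".proj.bn"), dz)
      cbp <- .convBwd(dsc, params[[paste0(pre, ".proj.conv")]],
                      caches[[paste0(pre, ".proj.conv")]])
      grads[[paste0(pre, ".proj.conv")]] <- cbp$dW
      dx <- dx + cbp$dx
    } else {
      dx <- dx + dz
    }
    da <- dx
  }
  da <- da * (caches[["stem.relu"]] > 0)
  dstem <- bnB("stem.bn", da)
  cbs <- .convBwd(dstem, params[["stem.conv"]], caches[["stem.conv"]])
  grads[["stem.conv"]] <- cbs$dW
  grads
}

# softmax cross entropy; y = integer class index per column (1-based)
.softmaxXent <- function(logits, y) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  n <- ncol(logits)
  picked <- probs[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- probs
  dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / n)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, opt, lr, beta1, beta2, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# stack NormalizedClip values (or plain matrices) into the 1 x (H*W*N)
# single-channel batch layout
.stackClips <- function(clips) {
  mats <- lapply(clips, function(cl)
    if (is(cl, "NormalizedClip")) cl@values else cl)
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  for (m in mats)
    if (nrow(m) != h || ncol(m) != w)
      stop("all clips in a batch must share the network input shape")
  list(x = matrix(unlist(mats), nrow = 1L),
       dims = list(h = h, w = w, n = length(mats)))
}
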