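# Internal neural-network engine: forward/backward passes, batch
# normalization without learned affine parameters, Adam, softmax
# cross-entropy, and the plateau learning-rate scheduler. The
# convolution and pooling inner loops live in src/conv1d.cpp.

BN_EPS <- 1e-5

# Convert a WindowSet (or n x C x T array) into the slice layout used by
# the C++ kernels: a (1 x T*B) matrix with B = n*C sequences, channel
# fastest within window, plus geometry.
windowsToSlices <- function(windows) {
  if (is(windows, "WindowSet")) windows <- windows@windows
  d <- dim(windows)
  n <- d[1]; C <- d[2]; T <- d[3]
  X <- matrix(as.numeric(aperm(windows, c(3, 2, 1))), nrow = 1)
  list(X = X, n = n, C = C, T = T)
}

# Column indices occupied by the given window indices (slices are
# contiguous per window).
windowColumns <- function(widx, C, T) {
  span <- C * T
  as.integer(unlist(lapply(widx, function(w)
    ((w - 1L) * span + 1L):(w * span))))
}

newBnState <- function(nMaps) list(mean = rep(0, nMaps), var = rep(1, nMaps))

# Batch normalization on a (maps x columns) matrix for one group.
# Train mode normalizes with batch statistics and blends the running
# statistics as running <- (1 - m) * running + m * batch: the momentum
# is the weight of the NEW batch, so one adaptation sweep moves the
# running statistics almost entirely to the new subject's.
bnGroupForward <- function(x, state, mode, momentum, update = TRUE) {
  if (!ncol(x)) stop("zero-size batch in batch normalization")
  if (mode == "train") {
    st <- row_stats(x)
    mu <- as.numeric(st$mean)
    v <- as.numeric(st$var)
    if (update) {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * v
    }
  } else {
    mu <- state$mean
    v <- state$var
  }
  sd <- sqrt(v + BN_EPS)
  list(y = bn_norm(x, mu, sd), state = state, mu = mu, sd = sd)
}

# Gradient of BN (no affine): given upstream dy and cached xhat, sd.
bnGroupBackward <- function(dy, xhat, sd) {
  bn_bwd(dy, xhat, sd)
}

# Forward pass through the convolutional trunk and both heads.
#
# bnKeys: one BN-registry key per window (routing each sample through
# its own subject's statistics) or a single key for all windows.
# Returns updated BN registry (value semantics).
netForward <- function(model, slices, mode = c("eval", "train"),
                       bnKeys = "shared", dropout = (mode == "train"),
                       updateBn = (mode == "train"), keepCache = FALSE) {
  mode <- match.arg(mode)
  cfg <- model$net
  X <- slices$X; n <- slices$n; C <- slices$C; T <- slices$T
  if (length(bnKeys) == 1L) bnKeys <- rep(bnKeys, n)
  stopifnot(length(bnKeys) == n)
  groups <- split(seq_len(n), factor(bnKeys, levels = unique(bnKeys)))
  groupCols <- lapply(groups, windowColumns, C = C, T = T)
  bn <- model$bn
  caches <- if (keepCache) vector("list", cfg$nBlocks) else NULL
  oneGroup <- length(groups) == 1L
  A <- X
  for (i in seq_len(cfg$nBlocks)) {
    Z <- conv1d_fwd(A, model$blocks[[i]]$W, T, cfg$kernelLength)
    sds <- vector("list", length(groups))
    if (oneGroup) {
      key <- names(groups)[1]
      if (is.null(bn[[key]]))
        stop("no batch-normalization state for subject '", key, "'")
      res <- bnGroupForward(Z, bn[[key]][[i]], mode, cfg$bnMomentum,
                            update = updateBn)
      xhat <- res$y
      bn[[key]][[i]] <- res$state
      sds[[1]] <- res$sd
    } else {
      xhat <- Z
      for (g in seq_along(groups)) {
        key <- names(groups)[g]
        if (is.null(bn[[key]]))
          stop("no batch-normalization state for subject '", key, "'")
        res <- bnGroupForward(Z[, groupCols[[g]], drop = FALSE],
                              bn[[key]][[i]], mode, cfg$bnMomentum,
                              update = updateBn)
        xhat[, groupCols[[g]]] <- res$y
        bn[[key]][[i]] <- res$state
        sds[[g]] <- res$sd
      }
    }
    if (dropout && cfg$dropoutP > 0) {
      ad <- act_dropout_fwd(xhat, cfg$leakySlope, cfg$dropoutP)
      H <- ad$H
      mask <- ad$mask
    } else {
      H <- leaky_fwd(xhat, cfg$leakySlope)
      mask <- NULL
    }
    if (keepCache)
      caches[[i]] <- list(Ain = A, xhat = xhat, mask = mask, sds = sds)
    A <- H
  }
  gapOut <- gap_fwd(A, T)                       # maps x (C*n)
  feat <- matrix(gapOut, cfg$kernels * C, n)    # per-window features
  gScores <- model$linW %*% feat + model$linb
  dScores <- model$domW %*% feat + model$domb
  list(gScores = gScores, dScores = dScores, feat = feat, bn = bn,
       caches = caches, groups = groups, groupCols = groupCols,
       n = n, C = C, T = T)
}

# Backward pass. dGesture / dDomain are gradients w.r.t. the two heads'
# scores; the domain-head gradient reaches the convolutional trunk
# multiplied by -adversarialLambda (gradient reversal), while the
# domain head's own weights receive the unreversed gradient.
netBackward <- function(model, fwd, dGesture, dDomain = NULL,
                        adversarialLambda = 0) {
  cfg <- model$net
  C <- fwd$C; T <- fwd$T
  grads <- list()
  grads$linW <- dGesture %*% t(fwd$feat)
  grads$linb <- rowSums(dGesture)
  dFeat <- t(model$linW) %*% dGesture
  if (!is.null(dDomain)) {
    grads$domW <- dDomain %*% t(fwd$feat)
    grads$domb <- rowSums(dDomain)
    dFeat <- dFeat - adversarialLambda * (t(model$domW) %*% dDomain)
  } else {
    grads$domW <- matrix(0, nrow(model$domW), ncol(model$domW))
    grads$domb <- rep(0, length(model$domb))
  }
  dA <- gap_bwd(matrix(dFeat, cfg$kernels, C * fwd$n), T)
  grads$blocks <- vector("list", cfg$nBlocks)
  oneGroup <- length(fwd$groups) == 1L
  for (i in rev(seq_len(cfg$nBlocks))) {
    cache <- fwd$caches[[i]]
    dXhat <- if (!is.null(cache$mask)) {
      act_dropout_bwd(dA, cache$xhat, cache$mask, cfg$leakySlope,
                      cfg$dropoutP)
    } else {
      leaky_bwd(dA, cache$xhat, cfg$leakySlope)
    }
    if (oneGroup) {
      dZ <- bnGroupBackward(dXhat, cache$xhat, cache$sds[[1]])
    } else {
      dZ <- dXhat
      for (g in seq_along(fwd$groups)) {
        cols <- fwd$groupCols[[g]]
        dZ[, cols] <- bnGroupBackward(dXhat[, cols, drop = FALSE],
                                      cache$xhat[, cols, drop = FALSE],
                                      cache$sds[[g]])
      }
    }
    res <- conv1d_bwd(cache$Ain, model$blocks[[i]]$W, dZ, T,
                      cfg$kernelLength, needInputGrad = i > 1L)
    grads$blocks[[i]] <- res$dW
    dA <- res$dX
  }
  grads
}

softmaxColumns <- function(scores) {
  z <- sweep(scores, 2, apply(scores, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Mean cross-entropy over columns; labels are zero-based.
# Returns the loss and the gradient w.r.t. the scores.
softmaxCrossEntropy <- function(scores, labels) {
  n <- ncol(scores)
  p <- softmaxColumns(scores)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dScores <- p
  dScores[idx] <- dScores[idx] - 1
  list(loss = loss, dScores = dScores / n)
}

# Adam optimizer over a named flat list of parameter arrays.
adamInit <- function(params)
  list(t = 0, m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

flattenParams <- function(model) {
  out <- list(linW = model$linW, linb = model$linb, domW = model$domW,
              domb = model$domb)
  for (i in seq_along(model$blocks))
    out[[paste0("conv", i)]] <- model$blocks[[i]]$W
  out
}

flattenGrads <- function(grads, nBlocks) {
  out <- list(linW = grads$linW, linb = grads$linb, domW = grads$domW,
              domb = grads$domb)
  for (i in seq_len(nBlocks)) out[[paste0("conv", i)]] <- grads$blocks[[i]]
  out
}

unflattenParams <- function(model, params) {
  model$linW <- params$linW; model$linb <- params$linb
  model$domW <- params$domW; model$domb <- params$domb
  for (i in seq_along(model$blocks))
    model$blocks[[i]]$W <- params[[paste0("conv", i)]]
  model
}

#' Plateau learning-rate scheduler
#'
#' Implements the training heuristic: if the monitored loss does not
#' achieve a new minimum within \code{patience} epochs, the learning
#' rate is divided by \code{factor}; training is complete when the
#' learning rate drops below \code{floor}. Returns a stateful closure:
#' \code{s$observe(loss)} after each epoch returns the (possibly
#' decremented) learning rate, and \code{s$finished()} reports whether
#' the floor has been crossed.
#'
#' @param initialLr initial learning rate (default 0.04047).
#' @param patience epochs without a new minimum before decrementing
#'   (default 15).
#' @param factor decrement factor (default 5).
#' @param floor stopping threshold (default 1e-8).
#' @return A list of closures \code{observe}, \code{lr},
#'   \code{finished}.
#' @export
plateauScheduler <- function(initialLr = 0.04047, patience = 15,
                             factor = 5, floor = 1e-8) {
  stopifnot(floor < initialLr, factor > 1)
  env <- new.env()
  env$lr <- initialLr
  env$best <- Inf
  env$since <- 0L
  list(
    observe = function(loss) {
      if (loss < env$best) {
        env$best <- loss
        env$since <- 0L
      } else {
        env$since <- env$since + 1L
        if (env$since >= patience) {
          env$lr <- env$lr / factor
          env$since <- 0L
        }
      }
      env$lr
    },
    lr = function() env$lr,
    finished = function() env$lr < floor
  )
}
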