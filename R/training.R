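#' Training configuration
#'
#' Defaults follow the full-scale training protocol: SGD with learning rate
#' 0.01, weight decay 1e-4 and momentum 0.9; step decay multiplying the
#' learning rate by 0.1 every 80 epochs; smooth-L1 loss (transition beta =
#' 1 pK) averaged per batch of 25; 250 epochs; and per-presentation rigid
#' augmentation of at most 2 Angstrom translation plus a uniform random
#' rotation. Epoch count, step budget and grid settings scale down for desk
#' work.
#'
#' @param epochs training epochs (default 250).
#' @param batchSize examples per batch (default 25).
#' @param learningRate initial SGD learning rate (default 0.01).
#' @param weightDecay L2 weight decay coefficient (default 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param lrStep epochs between learning-rate decays (default 80).
#' @param lrGamma decay factor (default 0.1).
#' @param beta smooth-L1 transition point in pK units (default 1).
#' @param maxShift augmentation translation bound, Angstrom (default 2).
#' @param augment apply rigid augmentation per presentation (default TRUE);
#'   with augmentation off, epochs are bitwise repeatable.
#' @param grid grid settings from \code{\link{gridConfig}}.
#' @param maxSteps optional cap on total optimizer steps.
#' @param seed RNG seed governing shuffling and augmentation.
#' @return config list.
#' @export
trainingConfig <- function(epochs = 250L, batchSize = 25L,
                           learningRate = 0.01, weightDecay = 1e-4,
                           momentum = 0.9, lrStep = 80L, lrGamma = 0.1,
                           beta = 1, maxShift = 2, augment = TRUE,
                           grid = gridConfig(dim = 16L, resolution = 1),
                           maxSteps = NULL, seed = 1L) {
  stopifnot(epochs > 0, batchSize > 0, learningRate > 0, weightDecay >= 0,
            momentum >= 0, lrStep > 0, lrGamma > 0, beta > 0, maxShift >= 0)
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, weightDecay = weightDecay,
       momentum = momentum, lrStep = as.integer(lrStep), lrGamma = lrGamma,
       beta = beta, maxShift = maxShift, augment = augment, grid = grid,
       maxSteps = maxSteps, seed = as.integer(seed))
}

#' Smooth-L1 (Huber-style) loss
#'
#' Per residual r = predicted - observed: 0.5 r^2 / beta when |r| < beta,
#' |r| - 0.5 beta otherwise; averaged over the batch. Continuous at the
#' transition, quadratic near zero, linear in the tails.
#'
#' @param predicted,observed numeric vectors in pK units.
#' @param beta transition point (> 0).
#' @return mean loss value.
#' @examples
#' smoothL1(3, 0, beta = 1)  # 2.5
#' @export
smoothL1 <- function(predicted, observed, beta = 1) {
  stopifnot(beta > 0)
  r <- predicted - observed
  mean(ifelse(abs(r) < beta, 0.5 * r^2 / beta, abs(r) - 0.5 * beta))
}

#' Step-decay learning-rate schedule
#'
#' @param epoch 0-based epoch index.
#' @param learningRate initial rate.
#' @param lrStep epochs between decays.
#' @param lrGamma multiplicative decay.
#' @return the learning rate in force at that epoch.
#' @examples
#' stepDecayLR(0)    # 0.01
#' stepDecayLR(80)   # 0.001
#' stepDecayLR(160)  # 1e-04
#' @export
stepDecayLR <- function(epoch, learningRate = 0.01, lrStep = 80L,
                        lrGamma = 0.1) {
  learningRate * lrGamma^(epoch %/% lrStep)
}

#' Pearson correlation with contract checks
#'
#' Standard product-moment correlation; errors on fewer than two points or
#' a zero-variance margin rather than returning NA.
#'
#' @param predictions,observations numeric vectors of equal length.
#' @return correlation coefficient in [-1, 1].
#' @export
pearsonCor <- function(predictions, observations) {
  stopifnot(length(predictions) == length(observations))
  if (length(predictions) < 2L)
    stop("pearson correlation needs at least two points")
  if (stats::sd(predictions) == 0 || stats::sd(observations) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(predictions, observations)
}

.sgdInitState <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    rapply(p, function(x) x * 0, how = "replace")
  })
}

.sgdStep <- function(params, grads, state, lr, momentum, wd) {
  for (li in seq_along(params)) {
    if (is.null(params[[li]]) || is.null(grads[[li]])) next
    p <- params[[li]]; g <- grads[[li]]; v <- state[[li]]
    if (is.list(p$W)) {
      for (h in seq_along(p$W)) {
        v$W[[h]] <- momentum * v$W[[h]] + g$W[[h]] + wd * p$W[[h]]
        v$b[[h]] <- momentum * v$b[[h]] + g$b[[h]]
        p$W[[h]] <- p$W[[h]] - lr * v$W[[h]]
        p$b[[h]] <- p$b[[h]] - lr * v$b[[h]]
      }
    } else {
      v$W <- momentum * v$W + g$W + wd * p$W
      v$b <- momentum * v$b + g$b
      p$W <- p$W - lr * v$W
      p$b <- p$b - lr * v$b
    }
    params[[li]] <- p; state[[li]] <- v
  }
  list(params = params, state = state)
}

#' Train a CEN on (complex, scaled terms, affinity) triples
#'
#' Stochastic gradient descent on the smooth-L1 loss between observed pK
#' and the predicted dot product of backbone weights with the fixed scaled
#' term vector of each example (gradients flow only through the weight
#' head; the terms are precalculated inputs). Each presentation of an
#' example voxelizes it afresh under a newly sampled rigid transform when
#' augmentation is on; with augmentation off, base grids are voxelized once
#' and runs are bitwise repeatable. Example order is reshuffled per epoch
#' from the run seed.
#'
#' @param model a \linkS4class{CENModel}.
#' @param complexes list of \linkS4class{ComplexStructure}.
#' @param scaledTerms scaled term matrix (rows align to \code{complexes},
#'   columns to the model registry; \code{attr(, "scaled")} must be TRUE).
#' @param labels observed affinities in pK units.
#' @param config from \code{\link{trainingConfig}}.
#' @return list with the trained \code{model} and a \code{history}
#'   data.frame (epoch, lr, loss, steps).
#' @export
trainCEN <- function(model, complexes, scaledTerms, labels,
                     config = trainingConfig()) {
  n <- length(complexes)
  if (n == 0L) stop("input error: empty training set")
  stopifnot(nrow(scaledTerms) == n, length(labels) == n)
  if (!isTRUE(attr(scaledTerms, "scaled")))
    stop("contract violation: term matrix is not scaled")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config$seed)

  baseGrids <- NULL
  if (!config$augment)
    baseGrids <- lapply(complexes, voxelize, config = config$grid)

  # fix any feature-normalization layers from (unaugmented) training grids
  if (any(vapply(model@config$layers, function(l) l$type == "norm",
                 TRUE))) {
    calIdx <- seq_len(min(n, 100L))
    calGrids <- if (!config$augment) baseGrids[calIdx]
                else lapply(complexes[calIdx], voxelize,
                            config = config$grid)
    model <- calibrateModel(model, calGrids)
  }

  params <- model@params
  state <- .sgdInitState(params)
  history <- list()
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- stepDecayLR(epoch, config$learningRate, config$lrStep,
                      config$lrGamma)
    ord <- sample.int(n)
    lossSum <- 0; lossN <- 0L
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      grids <- if (config$augment) {
        lapply(idx, function(i) voxelize(
          complexes[[i]], config$grid,
          transform = sampleAugmentation(config$maxShift)))
      } else baseGrids[idx]
      x <- .stackGrids(grids)
      modelNow <- model; modelNow@params <- params
      fw <- .forwardModel(modelNow, x, keepCache = TRUE)
      tmat <- scaledTerms[idx, , drop = FALSE]
      pred <- rowSums(fw$out * tmat)
      r <- pred - labels[idx]
      loss <- smoothL1(pred, labels[idx], config$beta)
      if (!is.finite(loss))
        stop("NaN/Inf loss at epoch ", epoch, ", step ", step,
             " (lr = ", lr, "); aborting")
      dpred <- pmin(pmax(r / config$beta, -1), 1) / length(idx)
      gout <- tmat * dpred
      grads <- .backwardModel(modelNow, fw$caches, gout)
      upd <- .sgdStep(params, grads, state, lr, config$momentum,
                      config$weightDecay)
      params <- upd$params; state <- upd$state
      lossSum <- lossSum + loss * length(idx)
      lossN <- lossN + length(idx)
      step <- step + 1L
      if (!is.null(config$maxSteps) && step >= config$maxSteps) {
        done <- TRUE; break
      }
    }
    history[[length(history) + 1L]] <-
      data.frame(epoch = epoch, lr = lr, loss = lossSum / lossN,
                 steps = step)
    if (done) break
  }
  model@params <- params
  list(model = model, history = do.call(rbind, history))
}

#' Predict affinities for a set of complexes
#'
#' Voxelizes each complex without augmentation, predicts its weight vector
#' and combines it with its scaled terms.
#'
#' @param model a \linkS4class{CENModel}.
#' @param complexes list of complexes.
#' @param scaledTerms scaled term matrix aligned to \code{complexes}.
#' @param grid grid settings (must match the model input shape).
#' @param chunk complexes per forward batch.
#' @return numeric vector of predicted pK values, named by entry id.
#' @export
predictDataset <- function(model, complexes, scaledTerms,
                           grid = gridConfig(dim = 16L, resolution = 1),
                           chunk = 32L) {
  if (!isTRUE(attr(scaledTerms, "scaled")))
    stop("contract violation: term matrix is not scaled")
  n <- length(complexes)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    grids <- lapply(complexes[idx], voxelize, config = grid)
    w <- predictWeights(model, grids)
    out[idx] <- rowSums(w * scaledTerms[idx, , drop = FALSE])
  }
  names(out) <- vapply(complexes, entryId, "")
  out
}
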