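#' Model configuration
#'
#' Describes the CEN backbone as configuration data: a list of layer
#' specifications (convolution, average pooling, global pooling, flatten,
#' affine) applied to a \code{channels} x \code{gridDim}^3 input, ending in
#' \code{outTerms} outputs, one weight per registry term. Tiny desk-scale
#' backbones and the production backbone share this one representation and
#' one forward/backward code path.
#'
#' @param channels input channels (default 28).
#' @param gridDim voxels per edge (default 48).
#' @param outTerms number of output term weights.
#' @param layers list of layer specs, e.g.
#'   \code{list(list(type = "avgpool", k = 2),
#'   list(type = "conv", filters = 32, kernel = 3, pad = 1,
#'   activation = "relu"), list(type = "flatten"),
#'   list(type = "dense", units = 144, heads = 2))}.
#' @return validated config list.
#' @export
cenModelConfig <- function(channels, gridDim, outTerms, layers) {
  config <- list(channels = as.integer(channels),
                 gridDim = as.integer(gridDim),
                 outTerms = as.integer(outTerms), layers = layers)
  info <- .layerShapes(config)
  if (info$spatialOut)
    stop("config error: backbone must end in a non-spatial stage")
  if (info$outFeatures != config$outTerms)
    stop("config error: final layer produces ", info$outFeatures,
         " features but outTerms is ", config$outTerms)
  config
}

#' Production backbone configuration
#'
#' The full-scale architecture: three average-pool/convolution stages
#' (32, 64 and 128 filters of size 3 with unit padding, each followed by a
#' 1x1x1 mixing convolution at the two lower stages, all ReLU) over a
#' 28-channel 48^3 grid, flattened into two parallel 144-output affine
#' heads whose sum is the weight vector. This configuration has exactly
#' 8,269,024 trainable parameters.
#'
#' @param outTerms number of term weights (default 144).
#' @return config list for \code{\link{buildCENModel}}.
#' @export
cenProductionConfig <- function(outTerms = 144L) {
  cenModelConfig(
    channels = 28L, gridDim = 48L, outTerms = outTerms,
    layers = list(
      list(type = "avgpool", k = 2L),
      list(type = "conv", filters = 32L, kernel = 3L, pad = 1L,
           activation = "relu"),
      list(type = "conv", filters = 32L, kernel = 1L, pad = 0L,
           activation = "relu"),
      list(type = "avgpool", k = 2L),
      list(type = "conv", filters = 64L, kernel = 3L, pad = 1L,
           activation = "relu"),
      list(type = "conv", filters = 64L, kernel = 1L, pad = 0L,
           activation = "relu"),
      list(type = "avgpool", k = 2L),
      list(type = "conv", filters = 128L, kernel = 3L, pad = 1L,
           activation = "relu"),
      list(type = "flatten"),
      list(type = "dense", units = outTerms, heads = 2L,
           activation = "linear")))
}

#' Tiny desk-scale backbone configuration
#'
#' A small CEN for synthetic experiments: per-channel global average
#' pooling followed by one hidden ReLU layer and a linear head. Pooled
#' channel densities expose grid-visible context (e.g. the composition of
#' the pocket lining) while keeping training on a CPU a matter of seconds.
#'
#' @param outTerms number of term weights.
#' @param channels input channels (default 28).
#' @param gridDim voxels per edge (default 16).
#' @param hidden hidden units (default 16).
#' @return config list for \code{\link{buildCENModel}}.
#' @export
cenTinyConfig <- function(outTerms, channels = 28L, gridDim = 16L,
                          hidden = 16L) {
  cenModelConfig(
    channels = channels, gridDim = gridDim, outTerms = outTerms,
    layers = list(
      # gain rescales mean channel densities to order-one features
      list(type = "globalpool", gain = gridDim^3 / 64),
      # per-feature standardization calibrated on the training grids
      list(type = "norm"),
      list(type = "dense", units = as.integer(hidden),
           activation = "relu"),
      list(type = "dense", units = as.integer(outTerms),
           activation = "linear")))
}

#' Build a CEN model with deterministic initialization
#'
#' Allocates and initializes all layer parameters (He-scaled normal
#' weights, zero biases) from the given seed, so the same seed always
#' yields bitwise-identical initial parameters.
#'
#' @param config from \code{\link{cenModelConfig}} and relatives.
#' @param seed integer RNG seed.
#' @param registry term registry the output weights align to (its length
#'   must equal \code{config$outTerms}).
#' @param scaling optional \linkS4class{ScalingFactors} bundled for
#'   self-describing checkpoints.
#' @return a \linkS4class{CENModel}.
#' @export
buildCENModel <- function(config, seed = 1L,
                          registry = NULL, scaling = NULL) {
  if (!is.null(registry)) {
    .checkRegistry(registry)
    if (nrow(registry) != config$outTerms)
      stop("config error: registry has ", nrow(registry),
           " terms but outTerms is ", config$outTerms)
  } else registry <- data.frame()
  info <- .layerShapes(config)
  params <- vector("list", length(config$layers))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  for (li in seq_along(config$layers)) {
    sh <- info$shapes[[li]]; spec <- sh$spec
    if (spec$type == "conv") {
      fanIn <- spec$kernel^3 * sh$cin
      params[[li]] <- list(
        W = matrix(stats::rnorm(fanIn * spec$filters, 0, sqrt(2 / fanIn)),
                   fanIn, spec$filters),
        b = numeric(spec$filters))
    } else if (spec$type == "dense") {
      heads <- if (is.null(spec$heads)) 1L else spec$heads
      fanIn <- sh$cin
      sd0 <- if (identical(spec$init, "zero")) 0 else sqrt(2 / fanIn)
      params[[li]] <- list(
        W = lapply(seq_len(heads), function(h)
          matrix(stats::rnorm(fanIn * spec$units, 0, sd0),
                 fanIn, spec$units)),
        b = lapply(seq_len(heads), function(h) numeric(spec$units)))
    }
  }
  new("CENModel", config = config, params = params,
      registry = registry, scaling = scaling, seed = as.integer(seed))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Calibrate feature-normalization layers from data
#'
#' Runs the backbone forward on a calibration batch and fixes the mean and
#' standard deviation parameters of every uncalibrated \code{norm} layer
#' from the activations reaching it. The parameters are frozen (never
#' updated by training) and stored with the model, so inference reproduces
#' the same standardization. Calibrating an already-calibrated model is a
#' no-op.
#'
#' @param model a \linkS4class{CENModel} whose config contains
#'   \code{norm} layers.
#' @param grids list of \linkS4class{VoxelGrid} (a representative sample
#'   of the training inputs).
#' @return the calibrated model.
#' @export
calibrateModel <- function(model, grids) {
  x <- .stackGrids(grids)
  for (li in seq_along(model@config$layers)) {
    spec <- model@config$layers[[li]]
    if (spec$type == "norm" &&
        (is.null(model@params[[li]]) ||
         is.null(model@params[[li]]$mean))) {
      m <- colMeans(x)
      s <- apply(x, 2, stats::sd)
      s[!is.finite(s) | s < 1e-8] <- 1
      model@params[[li]] <- list(mean = m, sd = s)
    }
    r <- switch(spec$type,
      conv = .forwardConv(spec, model@params[[li]], x),
      avgpool = .forwardAvgpool(spec, x),
      globalpool = .forwardGlobalpool(spec, x),
      norm = .forwardNorm(model@params[[li]], x),
      flatten = .forwardFlatten(x),
      dense = .forwardDense(spec, model@params[[li]], x))
    x <- r$out
  }
  model
}

# full forward pass; x is [n,n,n,C,B]; returns final matrix [B, outTerms]
# plus per-layer caches when keepCache (training) is requested
.forwardModel <- function(model, x, keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(model@config$layers))
  for (li in seq_along(model@config$layers)) {
    spec <- model@config$layers[[li]]
    r <- switch(spec$type,
      conv = .forwardConv(spec, model@params[[li]], x),
      avgpool = .forwardAvgpool(spec, x),
      globalpool = .forwardGlobalpool(spec, x),
      norm = .forwardNorm(model@params[[li]], x),
      flatten = .forwardFlatten(x),
      dense = .forwardDense(spec, model@params[[li]], x))
    x <- r$out
    if (keepCache) caches[[li]] <- r$cache
  }
  list(out = x, caches = caches)
}

# backward pass from output gradient [B, outTerms]; returns per-layer grads
.backwardModel <- function(model, caches, gout) {
  grads <- vector("list", length(model@config$layers))
  for (li in rev(seq_along(model@config$layers))) {
    spec <- model@config$layers[[li]]
    r <- switch(spec$type,
      conv = .backwardConv(spec, model@params[[li]], caches[[li]], gout),
      avgpool = .backwardAvgpool(caches[[li]], gout),
      globalpool = .backwardGlobalpool(caches[[li]], gout),
      norm = .backwardNorm(caches[[li]], gout),
      flatten = .backwardFlatten(caches[[li]], gout),
      dense = .backwardDense(spec, model@params[[li]], caches[[li]], gout))
    gout <- r$gin
    grads[li] <- list(r$grads)  # keep NULLs for parameter-free layers
  }
  grads
}

.stackGrids <- function(grids) {
  if (is(grids, "VoxelGrid")) grids <- list(grids)
  d <- dim(grids[[1]]@densities)
  x <- array(0, c(d[1], d[2], d[3], d[4], length(grids)))
  for (b in seq_along(grids)) x[, , , , b] <- grids[[b]]@densities
  x
}

#' Predict per-complex term weights from a voxel grid
#'
#' Runs the backbone in evaluation mode (deterministic: no augmentation,
#' no stochastic layers) on one grid or a list of grids.
#'
#' @param model a \linkS4class{CENModel}.
#' @param grids a \linkS4class{VoxelGrid} or list thereof.
#' @return named weight vector (single grid) or matrix with one row per
#'   grid, columns named by registry term.
#' @export
predictWeights <- function(model, grids) {
  single <- is(grids, "VoxelGrid")
  x <- .stackGrids(grids)
  d <- dim(x)
  if (d[1] != model@config$gridDim || d[4] != model@config$channels)
    stop("shape error: grid is ", d[4], "x", d[1], "^3 but model expects ",
         model@config$channels, "x", model@config$gridDim, "^3")
  out <- .forwardModel(model, x)$out
  if (!all(is.finite(out))) stop("non-finite weights predicted")
  if (nrow(model@registry))
    colnames(out) <- model@registry$name
  if (single) out[1, ] else out
}

#' Combine weights and scaled terms into a decomposed prediction
#'
#' The predicted affinity is the plain dot product of the weight vector
#' with the scaled term vector -- no intercept -- and the per-term
#' contributions (weight x scaled term) sum to it exactly, by the same
#' arithmetic.
#'
#' @param weights named weight vector (one per term).
#' @param scaledTerms scaled term vector carrying
#'   \code{attr(, "scaled") = TRUE} (a contract violation otherwise).
#' @param entryId identifier for the scored complex.
#' @return a \linkS4class{CENPrediction}.
#' @examples
#' t <- c(a = 0.5, b = -0.25); attr(t, "scaled") <- TRUE
#' predictAffinity(c(a = 1, b = 2), t)
#' @export
predictAffinity <- function(weights, scaledTerms, entryId = "complex") {
  if (!isTRUE(attr(scaledTerms, "scaled")))
    stop("contract violation: term vector is not scaled ",
         "(apply applyScaling() first)")
  if (length(weights) != length(scaledTerms))
    stop("shape error: ", length(weights), " weights vs ",
         length(scaledTerms), " terms")
  contrib <- as.numeric(weights) * as.numeric(scaledTerms)
  names(contrib) <- if (!is.null(names(scaledTerms))) names(scaledTerms)
                    else names(weights)
  w <- as.numeric(weights); names(w) <- names(contrib)
  s <- as.numeric(scaledTerms); names(s) <- names(contrib)
  new("CENPrediction", entryId = as.character(entryId),
      affinity = sum(contrib), contributions = contrib,
      weights = w, scaledTerms = s)
}

#' Save / load a self-describing model checkpoint
#'
#' The checkpoint bundles parameters, configuration, the term registry and
#' the scaling factors, so inference needs nothing but the checkpoint.
#' @param model a \linkS4class{CENModel}.
#' @param path checkpoint path (.rds).
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               registry = model@registry,
               scaling = if (is(model@scaling, "ScalingFactors"))
                 list(factors = model@scaling@factors,
                      nExamples = model@scaling@nExamples) else NULL,
               seed = model@seed), path)
  invisible(model)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  scaling <- if (!is.null(obj$scaling))
    new("ScalingFactors", factors = obj$scaling$factors,
        nExamples = obj$scaling$nExamples) else NULL
  new("CENModel", config = obj$config, params = obj$params,
      registry = obj$registry, scaling = scaling, seed = obj$seed)
}
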