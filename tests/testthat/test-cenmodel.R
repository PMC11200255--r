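test_that("parameter counting is exact for hand-countable configs", {
  # a single affine map from a flattened 2-channel 2^3 grid to 3 outputs:
  # (2*8)*3 + 3 = 51
  cfg <- cenModelConfig(channels = 2, gridDim = 2, outTerms = 3,
                        layers = list(list(type = "flatten"),
                                      list(type = "dense", units = 3,
                                           activation = "linear")))
  expect_equal(countParameters(cfg), 51L)
  # conv layer: k^3 * cin * f + f
  cfg2 <- cenModelConfig(channels = 2, gridDim = 4, outTerms = 5,
    layers = list(list(type = "conv", filters = 3, kernel = 3, pad = 1,
                       activation = "relu"),
                  list(type = "globalpool"),
                  list(type = "dense", units = 5,
                       activation = "linear")))
  expect_equal(countParameters(cfg2), 27 * 2 * 3 + 3 + 3 * 5 + 5)
  # two parallel affine heads double the head parameters
  cfg3 <- cenModelConfig(channels = 2, gridDim = 2, outTerms = 3,
                         layers = list(list(type = "flatten"),
                                       list(type = "dense", units = 3,
                                            heads = 2,
                                            activation = "linear")))
  expect_equal(countParameters(cfg3), 102L)
})

test_that("the production configuration has 8,269,024 parameters", {
  expect_equal(countParameters(cenProductionConfig()), 8269024L)
})

test_that("initialization is deterministic under the seed", {
  cfg <- cenTinyConfig(outTerms = 7, channels = 4, gridDim = 8)
  m1 <- buildCENModel(cfg, seed = 42)
  m2 <- buildCENModel(cfg, seed = 42)
  expect_identical(m1@params, m2@params)
  m3 <- buildCENModel(cfg, seed = 43)
  expect_false(identical(m1@params, m3@params))
})

test_that("weight prediction is finite, deterministic and shape-checked", {
  cfg <- cenTinyConfig(outTerms = 6, channels = 28, gridDim = 8)
  model <- buildCENModel(cfg, seed = 3)
  zero <- new("VoxelGrid",
              densities = array(0, c(8, 8, 8, 28)), resolution = 1,
              center = c(0, 0, 0), channelMap = voxelChannelMap(),
              coverage = 1)
  w <- predictWeights(model, zero)
  expect_length(w, 6)
  expect_true(all(is.finite(w)))
  cx <- toyComplex()
  g <- voxelize(cx, gridConfig(8, 1))
  expect_identical(predictWeights(model, g), predictWeights(model, g))
  bad <- voxelize(cx, gridConfig(16, 1))
  expect_error(predictWeights(model, bad), "shape error")
})

test_that("convolution forward matches a direct triple-loop oracle", {
  cfg <- cenModelConfig(channels = 2, gridDim = 4, outTerms = 3,
    layers = list(list(type = "conv", filters = 3, kernel = 3, pad = 1,
                       activation = "linear"),
                  list(type = "globalpool"),
                  list(type = "dense", units = 3,
                       activation = "linear")))
  model <- buildCENModel(cfg, seed = 5)
  set.seed(8)
  x <- array(rnorm(4^3 * 2), c(4, 4, 4, 2, 1))
  convOut <- censcore:::.forwardConv(cfg$layers[[1]],
                                     model@params[[1]], x)$out
  W <- model@params[[1]]$W  # (k3*cin) x filters, offsets fastest
  ref <- array(0, c(4, 4, 4, 3))
  for (f in 1:3) for (ox in 1:4) for (oy in 1:4) for (oz in 1:4) {
    acc <- model@params[[1]]$b[f]
    row <- 0L
    for (cc in 1:2) for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
      row <- row + 1L
      ix <- ox + dx - 1L; iy <- oy + dy - 1L; iz <- oz + dz - 1L
      v <- if (ix >= 1 && ix <= 4 && iy >= 1 && iy <= 4 &&
               iz >= 1 && iz <= 4) x[ix, iy, iz, cc, 1] else 0
      acc <- acc + v * W[row, f]
    }
    ref[ox, oy, oz, f] <- acc
  }
  expect_equal(convOut[, , , , 1], ref, tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients on a small net", {
  cfg <- cenModelConfig(channels = 2, gridDim = 4, outTerms = 2,
    layers = list(list(type = "avgpool", k = 2),
                  list(type = "conv", filters = 2, kernel = 2, pad = 0,
                       activation = "relu"),
                  list(type = "flatten"),
                  list(type = "dense", units = 2, heads = 2,
                       activation = "linear")))
  model <- buildCENModel(cfg, seed = 21)
  set.seed(33)
  x <- array(rnorm(4^3 * 2 * 2), c(4, 4, 4, 2, 2))
  target <- matrix(rnorm(4), 2, 2)
  lossOf <- function(params) {
    m <- model; m@params <- params
    out <- censcore:::.forwardModel(m, x)$out
    sum((out - target)^2) / 2
  }
  fw <- censcore:::.forwardModel(model, x, keepCache = TRUE)
  gout <- fw$out - target
  grads <- censcore:::.backwardModel(model, fw$caches, gout)
  eps <- 1e-6
  checkOne <- function(getter, setter, gval, li) {
    p <- model@params
    for (probe in seq_len(min(5, length(getter(p[[li]]))))) {
      pPlus <- p; pMinus <- p
      vP <- getter(pPlus[[li]]); vP[probe] <- vP[probe] + eps
      pPlus[[li]] <- setter(pPlus[[li]], vP)
      vM <- getter(pMinus[[li]]); vM[probe] <- vM[probe] - eps
      pMinus[[li]] <- setter(pMinus[[li]], vM)
      num <- (lossOf(pPlus) - lossOf(pMinus)) / (2 * eps)
      expect_equal(gval[probe], num, tolerance = 1e-4)
    }
  }
  # conv weights and bias
  checkOne(function(p) p$W, function(p, v) { p$W[] <- v; p },
           as.numeric(grads[[2]]$W), 2)
  checkOne(function(p) p$b, function(p, v) { p$b <- v; p },
           grads[[2]]$b, 2)
  # second head of the final dense layer
  checkOne(function(p) p$W[[2]], function(p, v) { p$W[[2]][] <- v; p },
           as.numeric(grads[[4]]$W[[2]]), 4)
})

test_that("affinity is the exact dot product with per-term conservation", {
  t <- c(a = 0.5, b = -0.25); attr(t, "scaled") <- TRUE
  p <- predictAffinity(c(a = 1, b = 2), t)
  expect_equal(affinity(p), 0)
  expect_equal(unname(contributions(p)), c(0.5, -0.5))
  # all-zero terms -> zero affinity
  z <- c(a = 0, b = 0); attr(z, "scaled") <- TRUE
  expect_equal(affinity(predictAffinity(c(a = 3, b = -9), z)), 0)
  # conservation against an independent accumulation, length 144
  set.seed(4)
  w <- rnorm(144); tt <- runif(144, -1, 1)
  names(w) <- names(tt) <- paste0("t", 1:144)
  attr(tt, "scaled") <- TRUE
  pred <- predictAffinity(w, tt)
  acc <- 0
  for (j in 1:144) acc <- acc + w[[j]] * tt[[j]]
  expect_equal(affinity(pred), acc, tolerance = 1e-12)
  expect_identical(affinity(pred), sum(contributions(pred)))
  # unscaled vector is a contract violation
  raw <- c(a = 1, b = 2)
  expect_error(predictAffinity(c(a = 1, b = 1), raw), "not scaled")
})

test_that("checkpoints are self-describing round trips", {
  reg <- defaultTermRegistry()
  s <- fitScaling(matrix(runif(3 * nrow(reg)), 3,
                         dimnames = list(NULL, reg$name)))
  model <- buildCENModel(cenTinyConfig(outTerms = nrow(reg)), seed = 2,
                         registry = reg, scaling = s)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(model, f)
  m2 <- loadCheckpoint(f)
  expect_identical(m2@params, model@params)
  expect_equal(m2@registry, model@registry)
  expect_equal(m2@scaling@factors, s@factors)
  cx <- toyComplex()
  g <- voxelize(cx, gridConfig(16, 1))
  expect_identical(predictWeights(m2, g), predictWeights(model, g))
})
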