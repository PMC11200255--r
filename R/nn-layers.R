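# Minimal 3D convolutional network engine. Spatial activations are 5D
# arrays [x, y, z, channel, batch]; vector activations are matrices
# [batch, feature]. Each layer exposes a forward pass returning the output
# plus a cache, and a backward pass returning input and parameter
# gradients. Convolution is evaluated as a matrix product over unrolled
# voxel patches (vol2col), so BLAS does the heavy lifting.

.layerTypes <- c("avgpool", "conv", "globalpool", "flatten", "dense")

# linear indices of the k^3 patch members for every output voxel of a
# single padded channel volume
.vol2colIdx <- function(n, k, pad) {
  pn <- n + 2L * pad
  o <- n - k + 1L + 2L * pad
  if (o < 1L) stop("config error: kernel larger than padded input")
  base <- as.vector(outer(outer(seq_len(o), (seq_len(o) - 1L) * pn, "+"),
                          (seq_len(o) - 1L) * pn * pn, "+"))
  off <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * pn, "+"),
                         (0:(k - 1L)) * pn * pn, "+"))
  list(idx = outer(base, off, "+"), outDim = o, padDim = pn)
}

.padVolume <- function(x, pad) {
  # x: [n, n, n, C]; zero-pad the three spatial dims
  if (pad == 0L) return(x)
  d <- dim(x)
  pn <- d[1] + 2L * pad
  out <- array(0, c(pn, pn, pn, d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

.forwardConv <- function(spec, par, x) {
  d <- dim(x)  # n n n Cin B
  n <- d[1]; cin <- d[4]; B <- d[5]
  k <- spec$kernel; pad <- spec$pad
  v <- .vol2colIdx(n, k, pad)
  o <- v$outDim
  k3 <- k^3
  out <- array(0, c(o, o, o, spec$filters, B))
  cols <- vector("list", B)
  for (b in seq_len(B)) {
    P <- .padVolume(array(x[, , , , b], d[1:4]), pad)
    col <- matrix(0, o^3, k3 * cin)
    for (cc in seq_len(cin)) {
      pc <- P[, , , cc]
      col[, (cc - 1L) * k3 + seq_len(k3)] <- pc[v$idx]
    }
    z <- col %*% par$W + matrix(par$b, o^3, spec$filters, byrow = TRUE)
    cols[[b]] <- col
    out[, , , , b] <- z
  }
  act <- identical(spec$activation, "relu")
  if (act) { pre <- out; out <- pmax(out, 0) } else pre <- NULL
  list(out = out, cache = list(cols = cols, pre = pre, inDim = d, v = v))
}

.backwardConv <- function(spec, par, cache, gout) {
  d <- cache$inDim
  n <- d[1]; cin <- d[4]; B <- d[5]
  k <- spec$kernel; pad <- spec$pad
  v <- cache$v; o <- v$outDim; k3 <- k^3
  if (!is.null(cache$pre)) gout <- gout * (cache$pre > 0)
  dW <- matrix(0, k3 * cin, spec$filters)
  db <- numeric(spec$filters)
  gin <- array(0, d)
  pn <- v$padDim
  interior <- pad + seq_len(n)
  for (b in seq_len(B)) {
    g <- matrix(gout[, , , , b], o^3, spec$filters)
    col <- cache$cols[[b]]
    dW <- dW + crossprod(col, g)
    db <- db + colSums(g)
    dcol <- tcrossprod(g, par$W)        # o^3 x (k3*cin)
    dP <- array(0, c(pn, pn, pn, cin))
    for (cc in seq_len(cin)) {
      dpc <- numeric(pn^3)
      blk <- (cc - 1L) * k3
      for (j in seq_len(k3)) {
        ii <- v$idx[, j]
        dpc[ii] <- dpc[ii] + dcol[, blk + j]
      }
      dP[, , , cc] <- array(dpc, c(pn, pn, pn))
    }
    gin[, , , , b] <- dP[interior, interior, interior, , drop = FALSE]
  }
  list(gin = gin, grads = list(W = dW, b = db))
}

.forwardAvgpool <- function(spec, x) {
  d <- dim(x); k <- spec$k
  if (d[1] %% k != 0L)
    stop("config error: pooling kernel ", k, " does not divide grid dim ",
         d[1])
  m <- d[1] %/% k
  a <- array(x, c(k, m, k, m, k, m, d[4], d[5]))
  ap <- aperm(a, c(1, 3, 5, 2, 4, 6, 7, 8))
  out <- array(colMeans(matrix(ap, nrow = k^3)), c(m, m, m, d[4], d[5]))
  list(out = out, cache = list(inDim = d, k = k, m = m))
}

.backwardAvgpool <- function(cache, gout) {
  d <- cache$inDim; k <- cache$k; m <- cache$m
  g <- gout / k^3
  rep3 <- array(rep(as.vector(g), each = k^3),
                c(k, k, k, m, m, m, d[4], d[5]))
  a <- aperm(rep3, c(1, 4, 2, 5, 3, 6, 7, 8))
  list(gin = array(a, d), grads = NULL)
}

.forwardGlobalpool <- function(spec, x) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  gain <- if (is.null(spec$gain)) 1 else spec$gain
  m <- matrix(x, nrow = nvox)               # nvox x (C*B)
  out <- t(matrix(colMeans(m), d[4], d[5])) * gain  # B x C
  list(out = out, cache = list(inDim = d, gain = gain))
}

.backwardGlobalpool <- function(cache, gout) {
  d <- cache$inDim
  nvox <- prod(d[1:3])
  g <- t(gout) * cache$gain / nvox          # C x B
  gin <- array(rep(as.vector(g), each = nvox), d)
  list(gin = gin, grads = NULL)
}

# fixed (non-trainable) per-feature standardization; parameters are
# calibrated once from training data and travel with the checkpoint
.forwardNorm <- function(par, x) {
  if (is.null(par) || is.null(par$mean)) return(list(out = x, cache = NULL))
  out <- sweep(sweep(x, 2, par$mean), 2, par$sd, "/")
  list(out = out, cache = list(sd = par$sd))
}

.backwardNorm <- function(cache, gout) {
  gin <- if (is.null(cache)) gout else sweep(gout, 2, cache$sd, "/")
  list(gin = gin, grads = NULL)
}

.forwardFlatten <- function(x) {
  d <- dim(x)
  list(out = t(matrix(x, nrow = prod(d[1:4]), ncol = d[5])),
       cache = list(inDim = d))
}

.backwardFlatten <- function(cache, gout) {
  list(gin = array(t(gout), cache$inDim), grads = NULL)
}

.forwardDense <- function(spec, par, x) {
  heads <- length(par$W)
  z <- matrix(0, nrow(x), spec$units)
  for (h in seq_len(heads))
    z <- z + x %*% par$W[[h]] + matrix(par$b[[h]], nrow(x), spec$units,
                                       byrow = TRUE)
  act <- identical(spec$activation, "relu")
  out <- if (act) pmax(z, 0) else z
  list(out = out, cache = list(x = x, pre = if (act) z else NULL))
}

.backwardDense <- function(spec, par, cache, gout) {
  if (!is.null(cache$pre)) gout <- gout * (cache$pre > 0)
  heads <- length(par$W)
  dW <- vector("list", heads); db <- vector("list", heads)
  gin <- matrix(0, nrow(cache$x), ncol(cache$x))
  for (h in seq_len(heads)) {
    dW[[h]] <- crossprod(cache$x, gout)
    db[[h]] <- colSums(gout)
    gin <- gin + tcrossprod(gout, par$W[[h]])
  }
  list(gin = gin, grads = list(W = dW, b = db))
}

# walk the layer list computing activation shapes; returns per-layer
# input shape info needed for parameter allocation and counting
.layerShapes <- function(config) {
  n <- config$gridDim; c <- config$channels
  spatial <- TRUE
  shapes <- vector("list", length(config$layers))
  for (li in seq_along(config$layers)) {
    spec <- config$layers[[li]]
    shapes[[li]] <- list(spec = spec, n = n, cin = c, spatial = spatial)
    if (spec$type == "avgpool") {
      if (!spatial) stop("config error: avgpool after flattening")
      if (n %% spec$k != 0L)
        stop("config error: pool kernel does not divide dim ", n)
      n <- n %/% spec$k
    } else if (spec$type == "conv") {
      if (!spatial) stop("config error: conv after flattening")
      n <- n - spec$kernel + 1L + 2L * spec$pad
      if (n < 1L) stop("config error: conv output dimension < 1")
      c <- spec$filters
    } else if (spec$type == "globalpool") {
      if (!spatial) stop("config error: globalpool after flattening")
      spatial <- FALSE
    } else if (spec$type == "flatten") {
      if (!spatial) stop("config error: flatten applied twice")
      c <- n^3 * c
      spatial <- FALSE
    } else if (spec$type == "norm") {
      if (spatial) stop("config error: norm applies to feature vectors")
    } else if (spec$type == "dense") {
      if (spatial) stop("config error: dense needs flatten/globalpool first")
      c <- spec$units
    } else stop("config error: unknown layer type '", spec$type, "'")
  }
  list(shapes = shapes, outFeatures = c, spatialOut = spatial)
}

#' Count trainable parameters of a model configuration
#'
#' The parameter count is a pure function of the layer configuration:
#' convolution layers contribute kernel^3 x inChannels x filters weights
#' plus filters biases, affine layers inFeatures x units + units per head;
#' pooling layers contribute nothing.
#'
#' @param config a model config (see \code{\link{cenModelConfig}}).
#' @return integer parameter count.
#' @examples
#' countParameters(cenProductionConfig())
#' @export
countParameters <- function(config) {
  info <- .layerShapes(config)
  total <- 0
  for (sh in info$shapes) {
    spec <- sh$spec
    if (spec$type == "conv")
      total <- total + spec$kernel^3 * sh$cin * spec$filters + spec$filters
    if (spec$type == "dense") {
      heads <- if (is.null(spec$heads)) 1L else spec$heads
      total <- total + heads * (sh$cin * spec$units + spec$units)
    }
  }
  as.integer(total)
}
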