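#' Per-atom attribution of typed steric Gaussian contributions
#'
#' For every \code{atom_type_gaussian} descriptor in the registry, each
#' receptor/ligand pair within the cutoff contributes
#' v = g / scalingFactor x weight -- the pair's Gaussian value scaled by
#' the same factor applied to the precalculated term and multiplied by the
#' predicted weight for that term. Half of v is assigned to the receptor
#' atom and half to the ligand atom; atoms participating in several pairs
#' (or several terms) accumulate the sum. The atom totals therefore
#' conserve the summed weighted scaled typed-Gaussian contribution of the
#' prediction exactly.
#'
#' @param complex a \linkS4class{ComplexStructure}.
#' @param weights named weight vector aligned to the registry.
#' @param scaling \linkS4class{ScalingFactors} covering the registry terms.
#' @param registry registry data.frame including typed Gaussian rows.
#' @return an \linkS4class{AttributionMap}.
#' @export
attributeAtoms <- function(complex, weights, scaling, registry) {
  .checkRegistry(registry)
  if (!is(scaling, "ScalingFactors"))
    stop("contract error: scaling factors are required for attribution")
  atg <- registry[registry$family == "atom_type_gaussian", , drop = FALSE]
  if (!nrow(atg))
    stop("registry contains no atom_type_gaussian descriptors")
  if (is.null(names(weights))) names(weights) <- registry$name
  missing <- setdiff(atg$name, names(scaling@factors))
  if (length(missing))
    stop("contract error: no scaling factor for term ", missing[1])
  perAtom <- numeric(0)
  perTerm <- stats::setNames(numeric(nrow(atg)), atg$name)
  cutoffs <- unique(atg$c)
  cache <- lapply(cutoffs, function(cc) enumeratePairs(complex, cc))
  names(cache) <- as.character(cutoffs)
  acc <- new.env()
  add <- function(index, v) {
    key <- as.character(index)
    for (i in seq_along(key)) {
      cur <- acc[[key[i]]]
      acc[[key[i]]] <- if (is.null(cur)) v[i] else cur + v[i]
    }
  }
  for (j in seq_len(nrow(atg))) {
    desc <- atg[j, , drop = FALSE]
    pairs <- cache[[as.character(desc$c)]]
    if (!nrow(pairs)) next
    match <- (pairs$recType == desc$type1 & pairs$ligType == desc$type2) |
             (pairs$recType == desc$type2 & pairs$ligType == desc$type1)
    if (!any(match)) next
    p <- pairs[match, , drop = FALSE]
    ds <- p$d - p$d0
    g <- exp(-((ds - desc$o) / desc$w)^2)
    v <- g / scaling@factors[[desc$name]] * weights[[desc$name]]
    perTerm[desc$name] <- sum(v)
    add(p$recIndex, v / 2)
    add(p$ligIndex, v / 2)
  }
  keys <- ls(acc)
  perAtom <- stats::setNames(
    vapply(keys, function(k) acc[[k]], 0),
    keys)[order(as.integer(keys))]
  names(perAtom) <- sort(as.integer(keys))
  new("AttributionMap", perAtom = perAtom, perTermTotals = perTerm,
      entryId = complex@entryId)
}

#' Weight z-scores of a target set against a reference corpus
#'
#' Per term: the mean predicted weight over the target set (e.g. all
#' docked poses of one screen), the mean and population standard deviation
#' over the reference corpus, and the absolute z-score
#' |targetMean - refMean| / refSd. Terms with zero reference spread are
#' flagged and carry no z-score.
#'
#' @param targetWeights matrix of weight vectors (rows = examples) or a
#'   single named vector treated as the target mean.
#' @param referenceWeights matrix of reference weight vectors (>= 2 rows).
#' @return data.frame (term, target_mean, ref_mean, ref_sd, abs_z,
#'   flagged), sorted by decreasing abs_z; a \code{header} attribute
#'   records that the reference spread is the population standard
#'   deviation.
#' @examples
#' # a printed worked example: target -7.52 vs reference -5.15 +/- 1.72
#' r <- weightZScores(c(electro = -7.52),
#'                    matrix(c(-5.15 - 1.72, -5.15 + 1.72), 2, 1,
#'                           dimnames = list(NULL, "electro")))
#' round(r$abs_z, 2)  # 1.38
#' @export
weightZScores <- function(targetWeights, referenceWeights) {
  if (is.null(dim(referenceWeights)) || nrow(referenceWeights) < 2L)
    stop("input error: need at least two reference weight vectors")
  tmean <- if (is.null(dim(targetWeights))) targetWeights
           else colMeans(targetWeights)
  if (!identical(names(tmean), colnames(referenceWeights)))
    stop("shape error: target and reference registries do not align")
  rmean <- colMeans(referenceWeights)
  rsd <- sqrt(colMeans(sweep(referenceWeights, 2, rmean)^2))  # population
  flagged <- rsd == 0
  absz <- ifelse(flagged, NA_real_, abs(tmean - rmean) / rsd)
  out <- data.frame(term = names(tmean), target_mean = unname(tmean),
                    ref_mean = unname(rmean), ref_sd = unname(rsd),
                    abs_z = unname(absz), flagged = unname(flagged),
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$abs_z), -Inf, out$abs_z)), ]
  rownames(out) <- NULL
  attr(out, "header") <- "reference spread: population standard deviation"
  out
}

#' Write a z-score report as TSV
#' @param report data.frame from \code{\link{weightZScores}}.
#' @param path TSV path.
#' @export
writeZScoreReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(report, "header")), con)
  utils::write.table(report, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(report)
}

# ---- exact t-SNE -----------------------------------------------------------

# per-point conditional Gaussian kernel calibrated to a target perplexity
.tsnePij <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed weight vectors into two dimensions
#'
#' Exact t-distributed stochastic neighbor embedding of the per-complex
#' weight vectors, deterministic under the seed, accompanied by a k-means
#' cluster-consistency score: k-means labels computed in the original
#' weight space are compared with k-means labels on the embedded points
#' (best label matching), quantifying whether similar weight vectors map
#' to adjacent regions.
#'
#' @param weightSet matrix of weight vectors, one row per complex (>= 5).
#' @param seed RNG seed for the initial layout and k-means restarts.
#' @param perplexity t-SNE perplexity (default min(30, (n-1)/3)).
#' @param k clusters for the consistency check (default 2).
#' @param iterations gradient-descent iterations (default 1000).
#' @return data.frame (id, x, y, cluster) with attributes
#'   \code{consistency} (fraction of points whose original-space and
#'   embedded-space k-means labels agree under the best matching) and
#'   \code{silhouette2d}.
#' @export
embedWeights <- function(weightSet, seed = 1L, perplexity = NULL, k = 2L,
                         iterations = 1000L) {
  if (is.null(dim(weightSet)) || nrow(weightSet) < 5L)
    stop("input error: need at least five weight vectors to embed")
  n <- nrow(weightSet)
  if (is.null(perplexity)) perplexity <- max(2, min(30, (n - 1) / 3))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  P <- .tsnePij(weightSet, perplexity)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  vel <- Y * 0
  exaggeration <- 12; stopEx <- 100L; eta <- 100; alpha <- 0.5
  for (it in seq_len(iterations)) {
    Pit <- if (it <= stopEx) P * exaggeration else P
    D2 <- as.matrix(stats::dist(Y))^2
    Qnum <- 1 / (1 + D2); diag(Qnum) <- 0
    Q <- pmax(Qnum / sum(Qnum), 1e-12)
    M <- (Pit - Q) * Qnum
    grad <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
    alpha <- if (it > 250) 0.8 else 0.5
    vel <- alpha * vel - eta * grad
    Y <- Y + vel
    Y <- sweep(Y, 2, colMeans(Y))
  }
  kmO <- stats::kmeans(weightSet, centers = k, nstart = 10)
  kmE <- stats::kmeans(Y, centers = k, nstart = 10)
  consistency <- .bestLabelAgreement(kmO$cluster, kmE$cluster, k)
  out <- data.frame(id = if (!is.null(rownames(weightSet)))
                           rownames(weightSet) else as.character(seq_len(n)),
                    x = Y[, 1], y = Y[, 2], cluster = kmO$cluster,
                    stringsAsFactors = FALSE)
  attr(out, "consistency") <- consistency
  attr(out, "silhouette2d") <- .meanSilhouette(Y, kmO$cluster)
  out
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

.bestLabelAgreement <- function(a, b, k) {
  best <- 0
  for (perm in .permutations(seq_len(k)))
    best <- max(best, mean(perm[b] == a))
  best
}

.meanSilhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(l) mean(D[i, labels == l]), 0)
    b <- min(bs)
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Virtual-screen ranking metrics
#'
#' AUROC via the rank statistic (ties get averaged ranks), equal to the
#' probability a random active outranks a random inactive, and enrichment
#' factors at the requested top fractions: the concentration of actives in
#' the top-scored fraction relative to their overall concentration.
#'
#' @param scores numeric scores, higher = predicted more active.
#' @param labels logical (or 0/1) activity labels.
#' @param topFractions fractions for enrichment factors
#'   (default 0.01, 0.05, 0.1).
#' @return list with \code{auroc}, \code{ef} (named by fraction),
#'   \code{nActives}, \code{nInactives}.
#' @export
screenMetrics <- function(scores, labels, topFractions = c(0.01, 0.05, 0.1)) {
  labels <- as.logical(labels)
  nA <- sum(labels); nI <- sum(!labels)
  if (nA == 0L || nI == 0L)
    stop("metric error: both actives and inactives are required")
  r <- rank(scores)                     # ties averaged
  auroc <- (sum(r[labels]) - nA * (nA + 1) / 2) / (nA * nI)
  n <- length(scores)
  ef <- vapply(topFractions, function(f) {
    ntop <- max(1L, round(f * n))
    top <- order(scores, decreasing = TRUE)[seq_len(ntop)]
    (sum(labels[top]) / ntop) / (nA / n)
  }, 0)
  names(ef) <- paste0("EF", topFractions * 100)
  list(auroc = auroc, ef = ef, nActives = nA, nInactives = nI)
}
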