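#' Drop typed steric terms that are almost always zero
#'
#' Over a raw term matrix computed on a corpus, removes every
#' \code{atom_type_gaussian} descriptor whose fraction of nonzero examples
#' falls below the threshold; all non-steric descriptors are retained
#' unconditionally. The corpus should span all examples the model will be
#' fitted and evaluated on, so train and test are counted jointly.
#'
#' @param termMatrix raw term matrix (rows = examples, columns aligned to
#'   the registry).
#' @param registry registry data.frame the columns align to.
#' @param threshold minimum nonzero fraction, in (0, 1); default 0.01.
#' @return the reduced registry data.frame.
#' @export
filterSparseTerms <- function(termMatrix, registry, threshold = 0.01) {
  .checkRegistry(registry)
  if (is.null(dim(termMatrix)) || nrow(termMatrix) == 0L)
    stop("input error: empty term matrix")
  stopifnot(threshold > 0, threshold < 1,
            ncol(termMatrix) == nrow(registry))
  frac <- colMeans(termMatrix != 0)
  keep <- registry$family != "atom_type_gaussian" | frac >= threshold
  registry[keep, , drop = FALSE]
}

#' Fit dataset-wide term scaling factors
#'
#' For each term the factor is the maximum absolute raw value over all
#' examples of the corpus (train and test jointly); all-zero columns get
#' factor 1. Dividing by these factors is the unique simple rule that maps
#' every term into [-1, 1] while never changing a term's sign.
#'
#' @param termMatrix raw term matrix (rows = examples).
#' @return a \linkS4class{ScalingFactors} object.
#' @export
fitScaling <- function(termMatrix) {
  if (is.null(dim(termMatrix)) || nrow(termMatrix) == 0L)
    stop("input error: empty term matrix")
  f <- apply(abs(termMatrix), 2, max)
  f[f == 0] <- 1
  new("ScalingFactors", factors = f, nExamples = nrow(termMatrix))
}

#' Scale a term vector or matrix
#'
#' Divides each term by its stored factor, marking the result with
#' \code{attr(, "scaled") = TRUE}. Already-scaled input is returned
#' unchanged, so re-application with the same factors is idempotent.
#'
#' @param x named raw term vector, or matrix with term columns.
#' @param scaling a \linkS4class{ScalingFactors}.
#' @return x scaled into [-1, 1] per term, signs preserved.
#' @export
applyScaling <- function(x, scaling) {
  stopifnot(is(scaling, "ScalingFactors"))
  if (isTRUE(attr(x, "scaled"))) return(x)
  f <- scaling@factors
  if (is.matrix(x)) {
    if (ncol(x) != length(f))
      stop("shape error: ", ncol(x), " columns vs ", length(f), " factors")
    if (!is.null(colnames(x)) && !identical(colnames(x), names(f)))
      stop("shape error: term columns do not match scaling factor names")
    out <- sweep(x, 2, f, "/")
  } else {
    if (length(x) != length(f))
      stop("shape error: ", length(x), " terms vs ", length(f), " factors")
    if (!is.null(names(x)) && !identical(names(x), names(f)))
      stop("shape error: term names do not match scaling factor names")
    out <- x / f
  }
  attr(out, "scaled") <- TRUE
  out
}

#' Persist / load scaling factors as JSON
#' @param scaling a \linkS4class{ScalingFactors}.
#' @param path JSON path.
#' @export
writeScalingFactors <- function(scaling, path) {
  jsonlite::write_json(list(factors = as.list(scaling@factors),
                            nExamples = scaling@nExamples),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(scaling)
}

#' @rdname writeScalingFactors
#' @export
readScalingFactors <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ScalingFactors", factors = unlist(obj$factors),
      nExamples = as.integer(obj$nExamples))
}

#' Read / write a term matrix as CSV
#'
#' The CSV has an \code{entry_id} column followed by one column per
#' canonical term name.
#' @param m term matrix with entry-id rownames.
#' @param path CSV path.
#' @export
writeTermMatrix <- function(m, path) {
  df <- data.frame(entry_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(m)
}

#' @rdname writeTermMatrix
#' @export
readTermMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$entry_id
  attr(m, "scaled") <- FALSE
  m
}
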