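#' @import methods
NULL

# Column layout shared by receptor and ligand atom tables. Indices are global
# across the complex (receptor first, then ligand) so the two index spaces
# are disjoint.
ATOM_COLUMNS <- c("index", "element", "x", "y", "z", "charge", "xsType",
                  "isHydrogen", "vdwRadius")

.validAtomTable <- function(df, what) {
  if (!is.data.frame(df)) return(sprintf("%s must be a data.frame", what))
  miss <- setdiff(ATOM_COLUMNS, names(df))
  if (length(miss))
    return(sprintf("%s lacks columns: %s", what, paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
      return(sprintf("%s has non-finite coordinates", what))
    heavy <- !df$isHydrogen
    if (any(df$vdwRadius[heavy] <= 0))
      return(sprintf("%s has heavy atoms with non-positive vdW radius", what))
    if (!all(df$xsType %in% xsTypeTable()$xsType))
      return(sprintf("%s has xs types outside the shipped enumeration", what))
  }
  TRUE
}

#' Protein-ligand complex container
#'
#' Holds the typed, charged 3D atoms of one receptor/ligand pair, the
#' substrate of all pairwise term calculations. Atom tables carry element,
#' coordinates (Angstrom), partial charge (elementary charge units), the XS
#' interaction type and the XS van der Waals radius. Atom indices are global:
#' receptor atoms come first, ligand atoms continue the numbering, so the two
#' index spaces never overlap.
#'
#' @slot entryId single identifier string.
#' @slot receptorAtoms,ligandAtoms data.frames with columns
#'   \code{index, element, x, y, z, charge, xsType, isHydrogen, vdwRadius}.
#' @slot receptorBonds,ligandBonds two-column integer matrices of bonded atom
#'   pairs (rows of the respective atom table), used for XS typing.
#' @slot ligandRotatableBonds non-negative rotatable-bond count.
#' @slot metadata free-form list (charge provenance, source paths, ...).
#' @export
setClass("ComplexStructure",
  representation(entryId = "character",
                 receptorAtoms = "data.frame",
                 ligandAtoms = "data.frame",
                 receptorBonds = "matrix",
                 ligandBonds = "matrix",
                 ligandRotatableBonds = "integer",
                 metadata = "list"),
  prototype(entryId = NA_character_,
            receptorBonds = matrix(integer(), ncol = 2),
            ligandBonds = matrix(integer(), ncol = 2),
            ligandRotatableBonds = 0L,
            metadata = list()))

setValidity("ComplexStructure", function(object) {
  msg <- .validAtomTable(object@receptorAtoms, "receptorAtoms")
  if (!isTRUE(msg)) return(msg)
  msg <- .validAtomTable(object@ligandAtoms, "ligandAtoms")
  if (!isTRUE(msg)) return(msg)
  if (object@ligandRotatableBonds < 0L)
    return("ligandRotatableBonds must be >= 0")
  idx <- c(object@receptorAtoms$index, object@ligandAtoms$index)
  if (anyDuplicated(idx))
    return("receptor and ligand atom index spaces must be disjoint")
  TRUE
})

#' Dataset-wide term scaling factors
#'
#' Per-term positive divisors: the maximum absolute raw term value observed
#' over all T examples of the corpus the factors were fitted on (factor 1 for
#' all-zero columns). Dividing raw terms by these factors maps every term
#' into [-1, 1] without changing its sign, and the stored factors make the
#' transformation reusable at inference time.
#'
#' @slot factors named positive numeric vector, one entry per registry term.
#' @slot nExamples number of examples the factors were fitted over.
#' @export
setClass("ScalingFactors",
  representation(factors = "numeric", nExamples = "integer"))

setValidity("ScalingFactors", function(object) {
  if (is.null(names(object@factors)) || anyDuplicated(names(object@factors)))
    return("factors must be uniquely named by term")
  if (any(!is.finite(object@factors)) || any(object@factors <= 0))
    return("all scaling factors must be finite and > 0")
  TRUE
})

#' Multi-channel voxel density grid
#'
#' Cubic grid of non-negative atom densities, one channel per
#' receptor- or ligand-side XS type group, produced by \code{\link{voxelize}}
#' and consumed by the CEN backbone.
#'
#' @slot densities 4D array \code{[x, y, z, channel]}, non-negative.
#' @slot resolution voxel edge length in Angstrom.
#' @slot center grid center (x, y, z) in Angstrom.
#' @slot channelMap data.frame mapping (side, typeGroup) to channel index.
#' @slot coverage fraction of heavy atoms whose center fell inside the grid.
#' @export
setClass("VoxelGrid",
  representation(densities = "array", resolution = "numeric",
                 center = "numeric", channelMap = "data.frame",
                 coverage = "numeric"))

setValidity("VoxelGrid", function(object) {
  d <- object@densities
  if (length(dim(d)) != 4L) return("densities must be a 4D array")
  if (any(!is.finite(d)) || any(d < 0))
    return("densities must be finite and non-negative")
  if (length(object@center) != 3L) return("center must be a 3-vector")
  if (object@resolution <= 0) return("resolution must be > 0")
  TRUE
})

#' Context explanation network model
#'
#' A configurable stack of 3D convolution, average-pooling, global-pooling
#' and affine layers mapping a \linkS4class{VoxelGrid} to a per-complex
#' weight vector, one weight per registry term. The checkpoint is
#' self-describing: it bundles the layer parameters with the term registry
#' and the scaling factors used at featurization time.
#'
#' @slot config list with \code{channels}, \code{gridDim}, \code{layers}
#'   (layer specification list) and \code{outTerms}.
#' @slot params named list of parameter arrays per parameterized layer.
#' @slot registry term registry data.frame the output weights align to.
#' @slot scaling \linkS4class{ScalingFactors} or NULL-like empty list slot.
#' @slot seed integer seed used for parameter initialization.
#' @export
setClass("CENModel",
  representation(config = "list", params = "list", registry = "data.frame",
                 scaling = "ANY", seed = "integer"))

#' Decomposed affinity prediction
#'
#' The linear combination of a predicted weight vector with the scaled term
#' vector of one complex. The affinity is exactly the sum of the per-term
#' contributions (weight times scaled term); there is no intercept.
#'
#' @slot entryId identifier of the scored complex.
#' @slot affinity predicted affinity in pK units.
#' @slot contributions named per-term contributions (weight x scaled term).
#' @slot weights named predicted weight vector.
#' @slot scaledTerms named scaled term vector.
#' @export
setClass("CENPrediction",
  representation(entryId = "character", affinity = "numeric",
                 contributions = "numeric", weights = "numeric",
                 scaledTerms = "numeric"))

setValidity("CENPrediction", function(object) {
  if (object@affinity != sum(object@contributions))
    return("affinity must equal the sum of per-term contributions")
  TRUE
})

#' Per-atom attribution of typed Gaussian contributions
#'
#' For every typed steric Gaussian term, each receptor/ligand atom pair's
#' Gaussian value is divided by the term's scaling factor, multiplied by the
#' term's predicted weight, and split half/half between the two atoms; atoms
#' participating in several pairs accumulate the sum. Totals over atoms equal
#' the summed weighted scaled typed-Gaussian contributions of the prediction.
#'
#' @slot perAtom numeric named by global atom index.
#' @slot perTermTotals numeric named by term.
#' @slot entryId scored complex identifier.
#' @export
setClass("AttributionMap",
  representation(perAtom = "numeric", perTermTotals = "numeric",
                 entryId = "character"))

#' Cluster-aware k-fold split plan
#'
#' Assignment of retained entries to folds such that no sequence cluster
#' straddles two folds, plus the list of removed entries with reasons.
#'
#' @slot foldOfEntry integer fold index (0-based) named by entry id.
#' @slot clusterOfEntry cluster id named by entry id.
#' @slot removedEntries data.frame with columns \code{entry_id, reason}.
#' @slot k number of folds.
#' @export
setClass("SplitPlan",
  representation(foldOfEntry = "integer", clusterOfEntry = "character",
                 removedEntries = "data.frame", k = "integer"))

setValidity("SplitPlan", function(object) {
  f <- object@foldOfEntry
  if (is.null(names(f))) return("foldOfEntry must be named by entry id")
  if (length(f) && (min(f) < 0L || max(f) >= object@k))
    return("fold indices must lie in 0..k-1")
  cl <- object@clusterOfEntry[names(f)]
  if (length(f)) {
    spread <- tapply(f, cl, function(v) length(unique(v)))
    if (any(spread > 1L)) return("a cluster appears in more than one fold")
  }
  TRUE
})
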