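#' @rdname ComplexStructure-class
#' @param object,x a \linkS4class{ComplexStructure}.
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))

#' @rdname ComplexStructure-class
#' @export
setGeneric("receptorAtoms", function(x) standardGeneric("receptorAtoms"))

#' @rdname ComplexStructure-class
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))

#' @rdname ComplexStructure-class
#' @export
setGeneric("ligandRotatableBonds",
           function(x) standardGeneric("ligandRotatableBonds"))

#' @rdname CENPrediction-class
#' @export
setGeneric("affinity", function(x) standardGeneric("affinity"))

#' @rdname CENPrediction-class
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname CENPrediction-class
#' @export
setGeneric("predictedWeights", function(x) standardGeneric("predictedWeights"))

setMethod("entryId", "ComplexStructure", function(x) x@entryId)
setMethod("receptorAtoms", "ComplexStructure", function(x) x@receptorAtoms)
setMethod("ligandAtoms", "ComplexStructure", function(x) x@ligandAtoms)
setMethod("ligandRotatableBonds", "ComplexStructure",
          function(x) x@ligandRotatableBonds)
setMethod("entryId", "CENPrediction", function(x) x@entryId)
setMethod("affinity", "CENPrediction", function(x) x@affinity)
setMethod("contributions", "CENPrediction", function(x) x@contributions)
setMethod("predictedWeights", "CENPrediction", function(x) x@weights)

setMethod("show", "ComplexStructure", function(object) {
  cat(sprintf("ComplexStructure '%s'\n", object@entryId))
  cat(sprintf("  receptor atoms: %d (%d heavy)\n",
              nrow(object@receptorAtoms),
              sum(!object@receptorAtoms$isHydrogen)))
  cat(sprintf("  ligand atoms:   %d (%d heavy), %d rotatable bonds\n",
              nrow(object@ligandAtoms),
              sum(!object@ligandAtoms$isHydrogen),
              object@ligandRotatableBonds))
})

setMethod("show", "ScalingFactors", function(object) {
  cat(sprintf("ScalingFactors over %d terms (fitted on %d examples)\n",
              length(object@factors), object@nExamples))
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@densities)
  cat(sprintf(
    "VoxelGrid %dx%dx%d, %d channels, %.2f A/voxel, coverage %.2f\n",
    d[1], d[2], d[3], d[4], object@resolution, object@coverage))
})

setMethod("show", "CENModel", function(object) {
  cat(sprintf("CENModel: %d-channel %d^3 input -> %d term weights\n",
              object@config$channels, object@config$gridDim,
              object@config$outTerms))
  cat(sprintf("  layers: %s\n",
              paste(vapply(object@config$layers, `[[`, "", "type"),
                    collapse = " -> ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(countParameters(object@config), big.mark = ",")))
})

setMethod("show", "CENPrediction", function(object) {
  cat(sprintf("CENPrediction '%s': affinity %.3f pK over %d terms\n",
              object@entryId, object@affinity, length(object@contributions)))
  top <- head(sort(abs(object@contributions), decreasing = TRUE), 3)
  for (nm in names(top))
    cat(sprintf("  %-50s %+0.3f\n", nm, object@contributions[[nm]]))
})

setMethod("show", "AttributionMap", function(object) {
  cat(sprintf("AttributionMap '%s': %d atoms, %d typed Gaussian terms\n",
              object@entryId, length(object@perAtom),
              length(object@perTermTotals)))
  cat(sprintf("  total attributed contribution: %+0.4f\n",
              sum(object@perAtom)))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d entries in %d folds (%s), %d removed\n",
              length(object@foldOfEntry), object@k,
              paste(tabulate(object@foldOfEntry + 1L, object@k),
                    collapse = "/"),
              nrow(object@removedEntries)))
})
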