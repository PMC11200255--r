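#' Write per-atom attributions into a PDB B-factor column
#'
#' Writes the complex as a single PDB with each atom's attribution value in
#' the temperature-factor column, the conventional channel for coloring
#' structures by a scalar. Values are clamped to the display color range
#' [-0.15, +0.15]; with the display filter enabled, atoms contributing
#' within (-0.025, +0.025) are written as 0 so only salient contacts light
#' up. Atoms absent from the attribution map get 0.
#'
#' @param complex a \linkS4class{ComplexStructure}.
#' @param attribution an \linkS4class{AttributionMap} (or a numeric vector
#'   named by global atom index).
#' @param path output PDB path.
#' @param displayFilter zero out |value| <= displayThreshold (default TRUE).
#' @param displayThreshold salience threshold, default 0.025.
#' @param clampRange color clamp, default c(-0.15, 0.15).
#' @return invisibly, the vector of B-factors written.
#' @export
writeAttributionPDB <- function(complex, attribution, path,
                                displayFilter = TRUE,
                                displayThreshold = 0.025,
                                clampRange = c(-0.15, 0.15)) {
  stopifnot(is(complex, "ComplexStructure"))
  vals <- if (is(attribution, "AttributionMap")) attribution@perAtom
          else attribution
  rec <- complex@receptorAtoms
  lig <- complex@ligandAtoms
  all <- rbind(rec, lig)
  b <- rep(0, nrow(all))
  hit <- match(as.character(all$index), names(vals))
  b[!is.na(hit)] <- vals[hit[!is.na(hit)]]
  if (displayFilter) b[abs(b) <= displayThreshold] <- 0
  b <- pmin(pmax(b, clampRange[1]), clampRange[2])
  recType <- c(rep("ATOM", nrow(rec)), rep("HETATM", nrow(lig)))
  resid <- c(rep("REC", nrow(rec)), rep("LIG", nrow(lig)))
  chain <- c(rep("A", nrow(rec)), rep("B", nrow(lig)))
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    recType, all$index,
    substr(paste0(toupper(all$element), all$index), 1, 4),
    resid, chain, c(rep(1L, nrow(rec)), rep(1L, nrow(lig))),
    all$x, all$y, all$z, 1.00, b, toupper(all$element))
  ok <- tryCatch({
    writeLines(c(lines, "END"), path)
    TRUE
  }, error = function(e) stop("I/O error writing '", path, "': ",
                              conditionMessage(e)))
  invisible(b)
}
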