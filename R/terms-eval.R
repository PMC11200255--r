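#' Enumerate receptor-ligand atom pairs within a cutoff
#'
#' All heavy-atom receptor/ligand pairs whose interatomic distance d does
#' not exceed the cutoff, with the "optimal distance" d0 (the summed XS van
#' der Waals radii of the two atoms). Pure geometry; the result is defined
#' to equal a brute-force double loop over all pairs.
#'
#' @param complex a \linkS4class{ComplexStructure}.
#' @param cutoff pair cutoff in Angstrom (> 0).
#' @return data.frame with columns \code{recRow, ligRow} (rows of the atom
#'   tables), \code{recIndex, ligIndex} (global atom indices), \code{d},
#'   \code{d0} and the atom XS types.
#' @export
enumeratePairs <- function(complex, cutoff = 8) {
  stopifnot(is(complex, "ComplexStructure"), cutoff > 0)
  rec <- complex@receptorAtoms
  lig <- complex@ligandAtoms
  rHeavy <- which(!rec$isHydrogen)
  lHeavy <- which(!lig$isHydrogen)
  empty <- data.frame(recRow = integer(), ligRow = integer(),
                      recIndex = integer(), ligIndex = integer(),
                      d = numeric(), d0 = numeric(),
                      recType = character(), ligType = character(),
                      stringsAsFactors = FALSE)
  if (!length(rHeavy) || !length(lHeavy)) return(empty)
  R <- as.matrix(rec[rHeavy, c("x", "y", "z")])
  L <- as.matrix(lig[lHeavy, c("x", "y", "z")])
  d2 <- outer(rowSums(R^2), rowSums(L^2), "+") - 2 * (R %*% t(L))
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  ri <- rHeavy[hit[, 1]]
  li <- lHeavy[hit[, 2]]
  data.frame(recRow = ri, ligRow = li,
             recIndex = rec$index[ri], ligIndex = lig$index[li],
             d = sqrt(d2[hit]),
             d0 = rec$vdwRadius[ri] + lig$vdwRadius[li],
             recType = rec$xsType[ri], ligType = lig$xsType[li],
             stringsAsFactors = FALSE)
}

.ramp <- function(ds, g, b) {
  v <- (b - ds) / (b - g)
  pmin(pmax(v, 0), 1)
}

# per-pair values for one descriptor over an enumerated pair table
.pairValues <- function(desc, pairs, complex) {
  ds <- pairs$d - pairs$d0
  fam <- desc$family
  if (fam == "gauss") {
    exp(-((ds - desc$o) / desc$w)^2)
  } else if (fam == "repulsion") {
    ifelse(ds < desc$o, (ds - desc$o)^2, 0)
  } else if (fam == "hydrophobic") {
    tab <- xsTypeTable()
    both <- tab[pairs$recType, "hydrophobic"] & tab[pairs$ligType, "hydrophobic"]
    ifelse(both, .ramp(ds, desc$g, desc$b), 0)
  } else if (fam == "non_dir_h_bond") {
    tab <- xsTypeTable()
    comp <- (tab[pairs$recType, "donor"] & tab[pairs$ligType, "acceptor"]) |
            (tab[pairs$recType, "acceptor"] & tab[pairs$ligType, "donor"])
    ifelse(comp, .ramp(ds, desc$g, desc$b), 0)
  } else if (fam == "electrostatic") {
    q1 <- complex@receptorAtoms$charge[pairs$recRow]
    q2 <- complex@ligandAtoms$charge[pairs$ligRow]
    d <- pmax(pairs$d, 1e-6)
    v <- q1 * q2 / d^desc$i
    sign(v) * pmin(abs(v), desc$cap)
  } else if (fam == "atom_type_gaussian") {
    match <- (pairs$recType == desc$type1 & pairs$ligType == desc$type2) |
             (pairs$recType == desc$type2 & pairs$ligType == desc$type1)
    ifelse(match, exp(-((ds - desc$o) / desc$w)^2), 0)
  } else {
    stop("config error: unknown term family '", fam, "'")
  }
}

.countValue <- function(name, complex) {
  lig <- complex@ligandAtoms
  heavy <- lig[!lig$isHydrogen, , drop = FALSE]
  tab <- xsTypeTable()
  switch(name,
    num_hydrophobic_atoms = sum(tab[heavy$xsType, "hydrophobic"]),
    num_heavy_atoms = nrow(heavy),
    ligand_length = if (nrow(heavy) < 2L) 0 else
      max(stats::dist(as.matrix(heavy[, c("x", "y", "z")]))),
    num_tors_div = complex@ligandRotatableBonds / 5,
    stop("config error: unknown count term '", name, "'"))
}

#' Evaluate one physicochemical term on a complex
#'
#' Sums the descriptor's per-pair value over all receptor-ligand heavy-atom
#' pairs within the descriptor's cutoff (count-family descriptors are
#' whole-ligand counts instead). Surface distance ds = d - d0 drives every
#' distance-dependent family. Rigid motions of the whole complex leave every
#' term unchanged.
#'
#' @param desc one-row registry data.frame (see \code{\link{termDescriptor}}).
#' @param complex a \linkS4class{ComplexStructure}.
#' @param pairs optional pre-enumerated pair table at the descriptor cutoff.
#' @return a single numeric term value.
#' @examples
#' cx <- makeComplex("ex",
#'   receptor = data.frame(element = "C", x = 0, y = 0, z = 0),
#'   ligand = data.frame(element = "C", x = 3.8, y = 0, z = 0))
#' evalTerm(termDescriptor("gauss", o = 0, w = 0.5, c = 8), cx)
#' @export
evalTerm <- function(desc, complex, pairs = NULL) {
  stopifnot(is.data.frame(desc), nrow(desc) == 1L)
  if (desc$family == "count") return(.countValue(desc$name, complex))
  if (is.null(pairs)) pairs <- enumeratePairs(complex, desc$c)
  if (!nrow(pairs)) return(0)
  sum(.pairValues(desc, pairs, complex))
}

#' Compute the raw term vector of a complex
#'
#' One value per registry descriptor, in registry order; deterministic, and
#' equivariant under registry reordering. The result carries
#' \code{attr(, "scaled") = FALSE}; see \code{\link{applyScaling}}.
#'
#' @param complex a \linkS4class{ComplexStructure}.
#' @param registry registry data.frame.
#' @return named numeric vector of raw term values.
#' @export
featurize <- function(complex, registry = defaultTermRegistry()) {
  .checkRegistry(registry)
  cutoffs <- unique(registry$c[registry$family != "count"])
  pairCache <- lapply(cutoffs, function(cc) enumeratePairs(complex, cc))
  names(pairCache) <- as.character(cutoffs)
  vals <- numeric(nrow(registry))
  for (j in seq_len(nrow(registry))) {
    desc <- registry[j, , drop = FALSE]
    vals[j] <- tryCatch({
      if (desc$family == "count") .countValue(desc$name, complex)
      else evalTerm(desc, complex, pairCache[[as.character(desc$c)]])
    }, error = function(e)
      stop("term '", desc$name, "': ", conditionMessage(e)))
  }
  names(vals) <- registry$name
  attr(vals, "scaled") <- FALSE
  vals
}

#' Featurize a list of complexes into a term matrix
#'
#' @param complexes list of \linkS4class{ComplexStructure}.
#' @param registry registry data.frame.
#' @return numeric matrix, one row per complex (rownames = entry ids),
#'   one column per term, with \code{attr(, "scaled") = FALSE}.
#' @export
featurizeDataset <- function(complexes, registry = defaultTermRegistry()) {
  stopifnot(length(complexes) > 0)
  m <- t(vapply(complexes, function(cx) as.numeric(featurize(cx, registry)),
                numeric(nrow(registry))))
  dimnames(m) <- list(vapply(complexes, entryId, ""), registry$name)
  attr(m, "scaled") <- FALSE
  m
}
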