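# XS atom typing in the AutoDock Vina extended scheme: carbon splits into
# hydrophobic vs non-hydrophobic (bonded to a heteroatom) and aliphatic vs
# aromatic; nitrogen and oxygen split by donor/acceptor capability; halogens
# count as hydrophobic; metals act as hydrogen-bond donors.

.XS_TABLE <- local({
  df <- rbind(
    data.frame(xsType = "Hydrogen",                        radius = 0.0, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = FALSE),
    data.frame(xsType = "PolarHydrogen",                   radius = 0.0, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = FALSE),
    data.frame(xsType = "AliphaticCarbonXSHydrophobe",     radius = 1.9, hydrophobic = TRUE,  donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "AliphaticCarbonXSNonHydrophobe",  radius = 1.9, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "AromaticCarbonXSHydrophobe",      radius = 1.9, hydrophobic = TRUE,  donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "AromaticCarbonXSNonHydrophobe",   radius = 1.9, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Nitrogen",                        radius = 1.8, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "NitrogenXSDonor",                 radius = 1.8, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "NitrogenXSAcceptor",              radius = 1.8, hydrophobic = FALSE, donor = FALSE, acceptor = TRUE,  heavy = TRUE),
    data.frame(xsType = "NitrogenXSDonorAcceptor",         radius = 1.8, hydrophobic = FALSE, donor = TRUE,  acceptor = TRUE,  heavy = TRUE),
    data.frame(xsType = "Oxygen",                          radius = 1.7, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "OxygenXSDonor",                   radius = 1.7, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "OxygenXSAcceptor",                radius = 1.7, hydrophobic = FALSE, donor = FALSE, acceptor = TRUE,  heavy = TRUE),
    data.frame(xsType = "OxygenXSDonorAcceptor",           radius = 1.7, hydrophobic = FALSE, donor = TRUE,  acceptor = TRUE,  heavy = TRUE),
    data.frame(xsType = "Sulfur",                          radius = 2.0, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "SulfurAcceptor",                  radius = 2.0, hydrophobic = FALSE, donor = FALSE, acceptor = TRUE,  heavy = TRUE),
    data.frame(xsType = "Phosphorus",                      radius = 2.1, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Fluorine",                        radius = 1.5, hydrophobic = TRUE,  donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Chlorine",                        radius = 1.8, hydrophobic = TRUE,  donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Bromine",                         radius = 2.0, hydrophobic = TRUE,  donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Iodine",                          radius = 2.2, hydrophobic = TRUE,  donor = FALSE, acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Magnesium",                       radius = 1.2, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Manganese",                       radius = 1.2, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Zinc",                            radius = 1.2, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Calcium",                         radius = 1.2, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "Iron",                            radius = 1.2, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "GenericMetal",                    radius = 1.2, hydrophobic = FALSE, donor = TRUE,  acceptor = FALSE, heavy = TRUE),
    data.frame(xsType = "GenericOther",                    radius = 1.5, hydrophobic = FALSE, donor = FALSE, acceptor = FALSE, heavy = TRUE)
  )
  rownames(df) <- df$xsType
  df
})

# element -> base XS info, before the bonding-context refinements
.ELEMENT_BASE <- c(
  H = "Hydrogen", C = "AliphaticCarbonXSHydrophobe", N = "Nitrogen",
  O = "Oxygen", S = "Sulfur", P = "Phosphorus", F = "Fluorine",
  CL = "Chlorine", BR = "Bromine", I = "Iodine", MG = "Magnesium",
  MN = "Manganese", ZN = "Zinc", CA = "Calcium", FE = "Iron",
  NA. = "GenericMetal", K = "GenericMetal", CU = "GenericMetal",
  NI = "GenericMetal", CO = "GenericMetal", CD = "GenericMetal",
  HG = "GenericMetal", B = "GenericOther", SI = "GenericOther",
  SE = "GenericOther")

# single-bond covalent radii (Angstrom) for distance-based bond inference
.COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                     MG = 1.41, MN = 1.39, ZN = 1.22, CA = 1.76, FE = 1.32,
                     B = 0.84, SI = 1.11, SE = 1.20)

#' XS atom-type enumeration
#'
#' The closed enumeration of extended (XS) interaction atom types the term
#' registry is parameterized over, with their van der Waals radii and
#' hydrophobic / hydrogen-bond-donor / acceptor flags. Shipped as data so the
#' typing rules are auditable.
#'
#' @return data.frame with columns \code{xsType}, \code{radius} (Angstrom),
#'   \code{hydrophobic}, \code{donor}, \code{acceptor}, \code{heavy}.
#' @examples
#' head(xsTypeTable())
#' @export
xsTypeTable <- function() .XS_TABLE

#' XS types entering pairwise steric terms
#'
#' The 25 heavy-atom XS types over which typed steric Gaussian descriptors
#' are enumerated (all unordered pairs of these give the 325 candidate
#' steric terms).
#' @return character vector of 25 type names.
#' @export
stericXSTypes <- function() {
  setdiff(.XS_TABLE$xsType[.XS_TABLE$heavy], "GenericOther")
}

.normElement <- function(el) {
  el <- toupper(trimws(el))
  el[el == "NA"] <- "NA."
  el
}

.baseType <- function(el) {
  out <- unname(.ELEMENT_BASE[.normElement(el)])
  out[is.na(out)] <- "GenericOther"
  out
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are considered bonded when their distance is below the sum of
#' their single-bond covalent radii plus a tolerance. Used for receptor
#' structures, where connectivity records are typically absent.
#'
#' @param atoms atom data.frame (element, x, y, z columns).
#' @param tolerance slack added to the covalent-radius sum, Angstrom.
#' @return two-column integer matrix of bonded row pairs.
#' @export
inferBonds <- function(atoms, tolerance = 0.45) {
  n <- nrow(atoms)
  if (n < 2L) return(matrix(integer(), ncol = 2))
  r <- .COVALENT_RADII[.normElement(atoms$element)]
  r[is.na(r)] <- 1.5
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  thr <- outer(r, r, "+") + tolerance
  hit <- which(d2 < thr^2 & upper.tri(d2) & d2 > 0.16, arr.ind = TRUE)
  matrix(as.integer(hit), ncol = 2, dimnames = NULL)
}

#' Assign XS interaction types to every atom of a complex
#'
#' Applies the Vina-style typing rules from element and bonding context:
#' carbons bonded only to carbon or hydrogen are hydrophobic, carbons bonded
#' to a heteroatom are not; aromatic carbons (flagged in the ligand bond
#' block) keep their aromatic subtype; nitrogen and oxygen with a bonded
#' hydrogen are donor-capable, and their lone pairs make oxygen (always) and
#' trivalent-or-less nitrogen acceptor-capable. Hydrogens bonded to N/O/S
#' become polar hydrogens. Idempotent and deterministic.
#'
#' @param complex a \linkS4class{ComplexStructure}.
#' @return the complex with \code{xsType} and \code{vdwRadius} filled in.
#' @export
assignXSTypes <- function(complex) {
  stopifnot(is(complex, "ComplexStructure"))
  complex@receptorAtoms <- .typeAtoms(complex@receptorAtoms,
                                      complex@receptorBonds)
  complex@ligandAtoms <- .typeAtoms(complex@ligandAtoms,
                                    complex@ligandBonds,
                                    aromatic = complex@metadata$ligandAromatic)
  validObject(complex)
  complex
}

.typeAtoms <- function(atoms, bonds, aromatic = NULL) {
  n <- nrow(atoms)
  if (n == 0L) return(atoms)
  el <- .normElement(atoms$element)
  type <- .baseType(atoms$element)
  # adjacency as list of neighbor elements
  nb <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  hasH <- vapply(nb, function(v) any(el[v] == "H"), logical(1))
  hetero <- !(el %in% c("C", "H"))
  bondedHetero <- vapply(nb, function(v) any(hetero[v]), logical(1))
  nHeavyNb <- vapply(nb, function(v) sum(el[v] != "H"), integer(1))

  isC <- el == "C"
  arom <- if (is.null(aromatic)) rep(FALSE, n) else as.logical(aromatic)
  type[isC & !bondedHetero & !arom] <- "AliphaticCarbonXSHydrophobe"
  type[isC & bondedHetero & !arom] <- "AliphaticCarbonXSNonHydrophobe"
  type[isC & !bondedHetero & arom] <- "AromaticCarbonXSHydrophobe"
  type[isC & bondedHetero & arom] <- "AromaticCarbonXSNonHydrophobe"

  isN <- el == "N"
  # nitrogen: acceptor when a lone pair remains accessible (<= 2 neighbors,
  # i.e. sp2 ring / nitrile style); donor when carrying a hydrogen. If the
  # structure carries no hydrogens at all (unprotonated input), fall back to
  # donor-capable nitrogen, the common amine/amide case.
  anyH <- any(el == "H")
  nNb <- lengths(nb)
  nAcc <- isN & nNb <= 2L
  nDon <- isN & (hasH | !anyH)
  type[isN & nDon & nAcc] <- "NitrogenXSDonorAcceptor"
  type[isN & nDon & !nAcc] <- "NitrogenXSDonor"
  type[isN & !nDon & nAcc] <- "NitrogenXSAcceptor"
  type[isN & !nDon & !nAcc] <- "Nitrogen"

  # oxygen: always acceptor-capable; donor too when a hydrogen is attached
  # (hydroxyl). Without explicit hydrogens the donor state of an oxygen is
  # not decidable, so it types as acceptor only.
  isO <- el == "O"
  oDon <- isO & hasH
  type[isO & oDon] <- "OxygenXSDonorAcceptor"
  type[isO & !oDon] <- "OxygenXSAcceptor"

  isS <- el == "S"
  type[isS] <- "Sulfur"

  isH <- el == "H"
  if (any(isH)) {
    polar <- vapply(nb, function(v) any(el[v] %in% c("N", "O", "S")),
                    logical(1))
    type[isH & polar] <- "PolarHydrogen"
    type[isH & !polar] <- "Hydrogen"
  }

  atoms$xsType <- type
  atoms$isHydrogen <- isH
  atoms$vdwRadius <- .XS_TABLE[type, "radius"]
  atoms
}
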