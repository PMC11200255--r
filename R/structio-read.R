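.emptyAtoms <- function() {
  data.frame(index = integer(), element = character(), x = numeric(),
             y = numeric(), z = numeric(), charge = numeric(),
             xsType = character(), isHydrogen = logical(),
             vdwRadius = numeric(), stringsAsFactors = FALSE)
}

.atomTable <- function(element, xyz, charge = NULL) {
  n <- length(element)
  if (n == 0L) return(.emptyAtoms())
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (is.null(charge)) charge <- rep(0, n)
  base <- .baseType(element)
  data.frame(index = seq_len(n), element = as.character(element),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge = as.numeric(charge), xsType = base,
             isHydrogen = .normElement(element) == "H",
             vdwRadius = .XS_TABLE[base, "radius"],
             stringsAsFactors = FALSE)
}

#' Build a complex from atom tables
#'
#' Low-level constructor used by the file readers and the synthetic
#' generator. Assigns disjoint global atom indices (receptor first), infers
#' receptor bonds from distances when none are given, and runs XS typing.
#'
#' @param entryId identifier string.
#' @param receptor,ligand data.frames with at least \code{element, x, y, z}
#'   (optional \code{charge}).
#' @param receptorBonds,ligandBonds optional two-column bond matrices
#'   (row indices into the respective table); receptor bonds are inferred
#'   from distances when omitted.
#' @param ligandRotatableBonds rotatable-bond count (default: counted from
#'   the ligand bond list).
#' @param ligandAromatic optional logical flag per ligand atom.
#' @param metadata free-form list.
#' @return a typed \linkS4class{ComplexStructure}.
#' @export
makeComplex <- function(entryId, receptor, ligand,
                        receptorBonds = NULL, ligandBonds = NULL,
                        ligandRotatableBonds = NULL,
                        ligandAromatic = NULL, metadata = list()) {
  rec <- .atomTable(receptor$element, cbind(receptor$x, receptor$y, receptor$z),
                    receptor$charge)
  lig <- .atomTable(ligand$element, cbind(ligand$x, ligand$y, ligand$z),
                    ligand$charge)
  lig$index <- lig$index + nrow(rec)
  if (is.null(receptorBonds)) receptorBonds <- inferBonds(rec)
  if (is.null(ligandBonds)) ligandBonds <- inferBonds(lig)
  if (is.null(ligandRotatableBonds))
    ligandRotatableBonds <- .countRotatable(lig, ligandBonds)
  metadata$ligandAromatic <- ligandAromatic
  cx <- new("ComplexStructure", entryId = as.character(entryId),
            receptorAtoms = rec, ligandAtoms = lig,
            receptorBonds = .asBondMatrix(receptorBonds),
            ligandBonds = .asBondMatrix(ligandBonds),
            ligandRotatableBonds = as.integer(ligandRotatableBonds),
            metadata = metadata)
  assignXSTypes(cx)
}

.asBondMatrix <- function(b) {
  if (is.null(b) || !length(b)) return(matrix(integer(), ncol = 2))
  matrix(as.integer(as.matrix(b)[, 1:2, drop = FALSE]), ncol = 2,
         dimnames = NULL)
}

# heuristic rotatable-bond count: acyclic single bonds between two heavy
# atoms that each carry at least one further heavy neighbor
.countRotatable <- function(atoms, bonds, bondType = NULL) {
  if (!nrow(bonds)) return(0L)
  el <- .normElement(atoms$element)
  heavy <- el != "H"
  deg <- integer(nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (heavy[i] && heavy[j]) { deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L }
  }
  single <- if (is.null(bondType)) rep(TRUE, nrow(bonds)) else bondType == "1"
  n <- 0L
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (single[k] && heavy[i] && heavy[j] && deg[i] >= 2L && deg[j] >= 2L)
      n <- n + 1L
  }
  n
}

#' Read a receptor/ligand pair into a complex
#'
#' Reads the receptor from PDB (or the PDBQT charge-bearing dialect, which
#' supplies partial charges) and the ligand from SDF or MOL2, strips water
#' molecules, assigns XS interaction types and returns a
#' \linkS4class{ComplexStructure}. MOL2 partial charges are taken from the
#' atom block; SDF partial charges from a \code{PARTIAL_CHARGES} data field
#' (one value per atom). When no charge source is present, charges are
#' zero-filled and \code{metadata$chargesSource} records the fact, so that
#' charge-dependent terms evaluate to zero rather than failing.
#'
#' @param receptorPath path to a PDB/PDBQT file.
#' @param ligandPath path to an SDF or MOL2 file (by extension).
#' @param entryId identifier; defaults to the ligand file stem.
#' @return a typed \linkS4class{ComplexStructure} without waters.
#' @examples
#' rec <- system.file("extdata", "toy_receptor.pdb", package = "censcore")
#' lig <- system.file("extdata", "toy_ligand.sdf", package = "censcore")
#' readComplex(rec, lig)
#' @export
readComplex <- function(receptorPath, ligandPath, entryId = NULL) {
  if (!file.exists(receptorPath))
    stop("receptor file not found: ", receptorPath)
  if (!file.exists(ligandPath))
    stop("ligand file not found: ", ligandPath)
  if (is.null(entryId))
    entryId <- sub("\\.[^.]+$", "", basename(ligandPath))
  rec <- .readReceptor(receptorPath)
  lig <- .readLigand(ligandPath)
  if (nrow(lig$atoms) == 0L)
    stop("input error: ligand '", ligandPath, "' contains no atoms")
  makeComplex(entryId, rec$atoms, lig$atoms,
              ligandBonds = lig$bonds,
              ligandRotatableBonds = lig$rotatable,
              ligandAromatic = lig$aromatic,
              metadata = list(receptorPath = receptorPath,
                              ligandPath = ligandPath,
                              chargesSource = c(receptor = rec$chargesSource,
                                                ligand = lig$chargesSource)))
}

.WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "SOL")

.readReceptor <- function(path) {
  isPdbqt <- grepl("\\.pdbqt$", path, ignore.case = TRUE)
  if (isPdbqt) return(.readPdbqt(path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("format error reading PDB '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  at <- at[!(at$resid %in% .WATER_RESIDUES), , drop = FALSE]
  el <- trimws(at$elesy)
  noEl <- is.na(el) | el == ""
  # fall back on the first letter of the atom name when the element column
  # is blank (common in minimal hand-written files)
  el[noEl] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[noEl])), 1, 1)
  list(atoms = data.frame(element = el, x = at$x, y = at$y, z = at$z,
                          charge = 0, stringsAsFactors = FALSE),
       chargesSource = "none")
}

# PDBQT dialect: fixed PDB columns plus partial charge in columns 67-76
.readPdbqt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[rec]
  if (!length(lines)) stop("format error: no ATOM/HETATM records in ", path)
  resid <- toupper(trimws(substr(lines, 18, 20)))
  keep <- !(resid %in% .WATER_RESIDUES)
  lines <- lines[keep]
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(lines, a, b))))
    if (any(is.na(v)))
      stop("format error in ", path, " line ",
           which(is.na(v))[1], ": unparseable numeric field")
    v
  }
  el <- trimws(substr(lines, 78, 79))
  blank <- el == "" | is.na(el)
  el[blank] <- substr(gsub("[0-9]", "", trimws(substr(lines, 13, 16))[blank]),
                      1, 1)
  # AD types like OA/NA/HD -> element is the first letter
  el <- ifelse(nchar(el) == 2 & !(toupper(el) %in% names(.ELEMENT_BASE)),
               substr(el, 1, 1), el)
  list(atoms = data.frame(element = el, x = num(31, 38), y = num(39, 46),
                          z = num(47, 54),
                          charge = suppressWarnings(
                            as.numeric(trimws(substr(lines, 67, 76)))),
                          stringsAsFactors = FALSE),
       chargesSource = "pdbqt")
}

.readLigand <- function(path) {
  if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE)) .readSdf(path)
  else if (grepl("\\.mol2$", path, ignore.case = TRUE)) .readMol2(path)
  else stop("format error: unsupported ligand format for '", path,
            "' (use .sdf or .mol2)")
}

.readSdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    return(.readSdfV2000(path))
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e)
                    stop("format error reading SDF '", path, "': ",
                         conditionMessage(e)))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  # ChemmineR rejects degenerate molecules (e.g. a single atom with no
  # bonds); fall back to a direct V2000 parse for those
  if (is.null(ab) || is.null(dim(ab)) || nrow(ab) == 0L || ncol(ab) < 3L)
    return(.readSdfV2000(path))
  el <- sub("_.*$", "", rownames(ab))
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  hasBonds <- !is.null(bb) && length(dim(bb)) == 2L && nrow(bb) >= 1L &&
    ncol(bb) >= 3L
  bonds <- if (hasBonds) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
           else matrix(integer(), ncol = 2)
  btype <- if (hasBonds) as.character(bb[, 3]) else character()
  charges <- NULL
  dblock <- tryCatch(ChemmineR::datablock(mol), error = function(e) NULL)
  if (!is.null(dblock) && "PARTIAL_CHARGES" %in% names(dblock)) {
    charges <- as.numeric(strsplit(dblock[["PARTIAL_CHARGES"]],
                                   " __ ", fixed = TRUE)[[1]])
    if (length(charges) != nrow(ab))
      stop("format error in ", path,
           ": PARTIAL_CHARGES length does not match atom count")
  }
  atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      charge = if (is.null(charges)) 0 else charges,
                      stringsAsFactors = FALSE)
  arom <- rep(FALSE, nrow(atoms))
  if (length(btype)) {
    aromB <- btype == "4"
    arom[unique(as.vector(bonds[aromB, , drop = FALSE]))] <- TRUE
  }
  list(atoms = atoms, bonds = bonds, aromatic = arom,
       rotatable = .countRotatable(atoms, bonds, btype),
       chargesSource = if (is.null(charges)) "none" else "sdf-data-field")
}

# direct fixed-format V2000 parse, used when ChemmineR is unavailable or
# declares a degenerate (but well-formed) molecule invalid
.readSdfV2000 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("format error: truncated SDF ", path)
  counts <- lines[4]
  nAtoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nBonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nAtoms) || nAtoms < 1L)
    stop("input error: empty ligand in ", path)
  at <- lines[4L + seq_len(nAtoms)]
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(at, a, b)))
    if (any(is.na(v)))
      stop("format error in ", path, " atom block line ",
           which(is.na(v))[1])
    v
  }
  atoms <- data.frame(element = trimws(substr(at, 32, 34)),
                      x = num(1, 10), y = num(11, 20), z = num(21, 30),
                      charge = 0, stringsAsFactors = FALSE)
  bonds <- matrix(integer(), ncol = 2)
  btype <- character()
  if (!is.na(nBonds) && nBonds > 0L) {
    bl <- lines[4L + nAtoms + seq_len(nBonds)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)))
    btype <- trimws(substr(bl, 7, 9))
  }
  chg <- .sdfChargeField(lines, nrow(atoms), path)
  if (!is.null(chg)) atoms$charge <- chg
  arom <- rep(FALSE, nrow(atoms))
  if (length(btype)) {
    aromB <- btype == "4"
    arom[unique(as.vector(bonds[aromB, , drop = FALSE]))] <- TRUE
  }
  list(atoms = atoms, bonds = bonds, aromatic = arom,
       rotatable = .countRotatable(atoms, bonds, btype),
       chargesSource = if (is.null(chg)) "none" else "sdf-data-field")
}

.sdfChargeField <- function(lines, nAtoms, path) {
  hit <- grep("^>.*<PARTIAL_CHARGES>", lines)
  if (!length(hit)) return(NULL)
  vals <- character()
  i <- hit[1] + 1L
  while (i <= length(lines) && nzchar(trimws(lines[i])) &&
         !startsWith(lines[i], "$$$$")) {
    vals <- c(vals, trimws(lines[i]))
    i <- i + 1L
  }
  chg <- suppressWarnings(as.numeric(vals))
  if (length(chg) != nAtoms || any(is.na(chg)))
    stop("format error in ", path,
         ": PARTIAL_CHARGES length does not match atom count")
  chg
}

.readMol2 <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e)
                  stop("format error reading MOL2 '", path, "': ",
                       conditionMessage(e)))
  at <- m$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("input error: empty ligand in ", path)
  el <- sub("\\..*$", "", at$elety)
  bonds <- if (!is.null(m$bond) && nrow(m$bond))
    cbind(as.integer(m$bond$origin), as.integer(m$bond$target))
  else matrix(integer(), ncol = 2)
  btype <- if (!is.null(m$bond)) as.character(m$bond$type) else character()
  atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                      charge = ifelse(is.na(at$charge), 0, at$charge),
                      stringsAsFactors = FALSE)
  arom <- rep(FALSE, nrow(atoms))
  if (length(btype)) {
    aromB <- btype %in% c("ar", "4")
    arom[unique(as.vector(bonds[aromB, , drop = FALSE]))] <- TRUE
  }
  list(atoms = atoms, bonds = bonds, aromatic = arom,
       rotatable = .countRotatable(atoms, bonds, btype),
       chargesSource = if (all(is.na(at$charge))) "none" else "mol2")
}
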