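# The term registry is a plain data.frame, one row per descriptor, with the
# canonical smina-style name and the family parameters (NA where a family
# does not use a parameter). Keeping it tabular makes the registry editable
# as CSV and auditable at a glance.

REGISTRY_COLUMNS <- c("name", "family", "o", "w", "c", "g", "b", "i", "cap",
                      "type1", "type2")

.fmtNum <- function(x) {
  sub("^-0$", "0", format(x, trim = TRUE, scientific = FALSE))
}

#' Construct a single term descriptor
#'
#' Builds one registry row with the canonical name for the given family and
#' parameters. Families: \code{gauss} (Gaussian of surface distance, offset
#' \code{o}, width \code{w}), \code{repulsion} (squared sub-offset surface
#' distance), \code{hydrophobic} and \code{non_dir_h_bond} (linear ramps
#' between good threshold \code{g} and bad threshold \code{b}, gated on
#' hydrophobic resp. donor/acceptor-complementary pairs),
#' \code{electrostatic} (charge product over distance to the power \code{i},
#' per-pair magnitude capped at \code{cap}), \code{atom_type_gaussian}
#' (Gaussian restricted to one unordered XS type pair) and \code{count}
#' (whole-ligand counts named by \code{countName}).
#'
#' @param family one of the family names above.
#' @param o,w,c,g,b,i,cap numeric parameters (Angstrom except \code{i},
#'   \code{cap}); \code{c} is the pair cutoff.
#' @param type1,type2 XS types for \code{atom_type_gaussian}.
#' @param countName for \code{count}: one of \code{num_tors_div},
#'   \code{num_hydrophobic_atoms}, \code{num_heavy_atoms},
#'   \code{ligand_length}.
#' @return one-row registry data.frame.
#' @examples
#' termDescriptor("gauss", o = 0, w = 0.5, c = 8)
#' termDescriptor("atom_type_gaussian", type1 = "NitrogenXSDonor",
#'                type2 = "OxygenXSAcceptor")
#' @export
termDescriptor <- function(family, o = NA, w = NA, c = 8, g = NA, b = NA,
                           i = NA, cap = NA, type1 = NA, type2 = NA,
                           countName = NA) {
  if (family == "atom_type_gaussian") {
    if (is.na(o)) o <- 0
    if (is.na(w)) w <- 1
  }
  name <- switch(family,
    gauss = sprintf("gauss(o=%s,_w=%s,_c=%s)", .fmtNum(o), .fmtNum(w),
                    .fmtNum(c)),
    repulsion = sprintf("repulsion(o=%s,_c=%s)", .fmtNum(o), .fmtNum(c)),
    hydrophobic = sprintf("hydrophobic(g=%s,_b=%s,_c=%s)", .fmtNum(g),
                          .fmtNum(b), .fmtNum(c)),
    non_dir_h_bond = sprintf("non_dir_h_bond(g=%s,_b=%s,_c=%s)", .fmtNum(g),
                             .fmtNum(b), .fmtNum(c)),
    electrostatic = sprintf("electrostatic(i=%s,_cap=%s,_c=%s)", .fmtNum(i),
                            .fmtNum(cap), .fmtNum(c)),
    atom_type_gaussian = sprintf(
      "atom_type_gaussian(t1=%s,t2=%s,o=%s,_w=%s,_c=%s)",
      type1, type2, .fmtNum(o), .fmtNum(w), .fmtNum(c)),
    count = as.character(countName),
    stop("config error: unknown term family '", family, "'"))
  if (family %in% c("hydrophobic", "non_dir_h_bond") && !(g < b))
    stop("config error: ramp families need g < b (", name, ")")
  if (family != "count" && !(c > 0))
    stop("config error: cutoff c must be > 0 (", name, ")")
  if (family == "electrostatic" && !(cap > 0))
    stop("config error: electrostatic cap must be > 0")
  data.frame(name = name, family = family, o = o, w = w, c = c, g = g,
             b = b, i = i, cap = cap, type1 = type1, type2 = type2,
             stringsAsFactors = FALSE)
}

.countTerm <- function(countName) termDescriptor("count", countName = countName)

#' Typed steric Gaussian descriptors over a type set
#'
#' All unordered pairs (including self-pairs) of the given XS types, each an
#' \code{atom_type_gaussian} descriptor with offset \code{o}, width \code{w}
#' and cutoff \code{c}. Over the full 25-type steric set this yields the 325
#' candidate steric terms.
#'
#' @param types character vector of XS types (default
#'   \code{\link{stericXSTypes}}).
#' @param o,w,c Gaussian offset, width and cutoff (Angstrom).
#' @return registry data.frame with one row per unordered type pair.
#' @export
stericGaussianRegistry <- function(types = stericXSTypes(), o = 0, w = 1,
                                   c = 8) {
  rows <- list()
  for (a in seq_along(types)) for (b in a:length(types)) {
    rows[[length(rows) + 1L]] <- termDescriptor(
      "atom_type_gaussian", type1 = types[a], type2 = types[b],
      o = o, w = w, c = c)
  }
  do.call(rbind, rows)
}

.NON_STERIC_23 <- function() {
  rbind(
    termDescriptor("gauss", o = 0, w = 0.5, c = 8),
    termDescriptor("gauss", o = 3, w = 2, c = 8),
    termDescriptor("gauss", o = 0, w = 0.3, c = 8),
    termDescriptor("gauss", o = 0.5, w = 0.3, c = 8),
    termDescriptor("gauss", o = 1, w = 0.3, c = 8),
    termDescriptor("gauss", o = 1.5, w = 0.3, c = 8),
    termDescriptor("gauss", o = 2, w = 0.3, c = 8),
    termDescriptor("repulsion", o = 0, c = 8),
    termDescriptor("repulsion", o = 0.5, c = 8),
    termDescriptor("repulsion", o = 1, c = 8),
    termDescriptor("hydrophobic", g = 0.5, b = 1.5, c = 8),
    termDescriptor("hydrophobic", g = 0.5, b = 1, c = 8),
    termDescriptor("hydrophobic", g = 0.5, b = 2, c = 8),
    termDescriptor("non_dir_h_bond", g = -0.7, b = 0, c = 8),
    termDescriptor("non_dir_h_bond", g = -0.7, b = 0.2, c = 8),
    termDescriptor("non_dir_h_bond", g = -0.7, b = 0.5, c = 8),
    termDescriptor("non_dir_h_bond", g = -1, b = 0, c = 8),
    termDescriptor("electrostatic", i = 1, cap = 100, c = 8),
    termDescriptor("electrostatic", i = 2, cap = 100, c = 8),
    .countTerm("num_tors_div"),
    .countTerm("num_hydrophobic_atoms"),
    .countTerm("num_heavy_atoms"),
    .countTerm("ligand_length"))
}

#' Default term registries
#'
#' \code{candidateTermRegistry()} builds the 348-descriptor candidate set:
#' 23 non-steric descriptors (Gaussian, repulsion, hydrophobic and
#' hydrogen-bond ramps at several parameterizations, the two capped
#' electrostatic terms, and four whole-ligand counts) plus the 325 typed
#' steric Gaussians over all unordered pairs of the 25 steric XS types.
#' Sparse steric descriptors are meant to be pruned on a corpus with
#' \code{\link{filterSparseTerms}}.
#'
#' \code{defaultTermRegistry()} is the desk-scale default: one descriptor
#' per distinct term family (the five shared scoring terms at their
#' canonical parameters, the two capped electrostatics and the four
#' whole-ligand counts) plus typed Gaussians over a compact type set (the
#' types toy and synthetic complexes exercise). Near-duplicate
#' parameterizations of one family are deliberately excluded here: they
#' make the term matrix ill-conditioned, which degrades any weight
#' estimate without probing anything new.
#'
#' @param stericTypes XS types to enumerate typed Gaussians over.
#' @param stericWidth,stericOffset width/offset of the typed Gaussians
#'   (Angstrom); defaults 1 and 0.
#' @return registry data.frame.
#' @export
defaultTermRegistry <- function(stericTypes = c(
                                  "AliphaticCarbonXSHydrophobe",
                                  "AliphaticCarbonXSNonHydrophobe",
                                  "NitrogenXSDonor",
                                  "NitrogenXSDonorAcceptor",
                                  "OxygenXSAcceptor",
                                  "OxygenXSDonorAcceptor"),
                                stericWidth = 1, stericOffset = 0) {
  base <- rbind(
    termDescriptor("gauss", o = 0, w = 0.5, c = 8),
    termDescriptor("gauss", o = 3, w = 2, c = 8),
    termDescriptor("repulsion", o = 0, c = 8),
    termDescriptor("hydrophobic", g = 0.5, b = 1.5, c = 8),
    termDescriptor("non_dir_h_bond", g = -0.7, b = 0, c = 8),
    termDescriptor("electrostatic", i = 1, cap = 100, c = 8),
    termDescriptor("electrostatic", i = 2, cap = 100, c = 8),
    .countTerm("num_tors_div"),
    .countTerm("num_hydrophobic_atoms"),
    .countTerm("num_heavy_atoms"),
    .countTerm("ligand_length"))
  rbind(base,
        stericGaussianRegistry(stericTypes, o = stericOffset,
                               w = stericWidth))
}

#' @rdname defaultTermRegistry
#' @export
candidateTermRegistry <- function(stericWidth = 1, stericOffset = 0) {
  rbind(.NON_STERIC_23(),
        stericGaussianRegistry(stericXSTypes(), o = stericOffset,
                               w = stericWidth))
}

.checkRegistry <- function(registry) {
  if (!is.data.frame(registry) || !nrow(registry))
    stop("registry must be a nonempty data.frame")
  miss <- setdiff(REGISTRY_COLUMNS, names(registry))
  if (length(miss))
    stop("registry lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(registry$name))
    stop("registry has duplicated term names")
  invisible(registry)
}

#' Read / write a term registry as CSV
#' @param registry registry data.frame.
#' @param path CSV path.
#' @return the registry (invisibly for the writer).
#' @export
writeTermRegistry <- function(registry, path) {
  .checkRegistry(registry)
  utils::write.csv(registry, path, row.names = FALSE)
  invisible(registry)
}

#' @rdname writeTermRegistry
#' @export
readTermRegistry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkRegistry(reg)
  reg
}
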