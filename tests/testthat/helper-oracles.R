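# Shared fixtures and independent oracles. The oracles deliberately avoid
# enumeratePairs()/evalTerm(): they loop over all receptor x ligand heavy
# atoms directly from the atom tables, so they provide a second arithmetic
# path for the term calculators.

# a small complex with known geometry; elements/charges chosen so every
# term family has work to do
toyComplex <- function(entryId = "toy") {
  makeComplex(
    entryId,
    receptor = data.frame(
      element = c("C", "O", "N", "C"),
      x = c(0, 3.0, -3.4, 1.0),
      y = c(4.2, 0.5, 0.2, -4.4),
      z = c(0, 0.2, 0.1, 0.3),
      charge = c(0.02, -0.4, 0.35, -0.01)),
    ligand = data.frame(
      element = c("C", "N", "O"),
      x = c(0, -0.9, 0.9),
      y = c(0.4, -0.7, -0.8),
      z = c(0, 0.2, -0.2),
      charge = c(0.05, 0.3, -0.45)),
    receptorBonds = matrix(integer(), ncol = 2))
}

# random complex with unbonded atoms (pure geometry, base element typing)
randomComplex <- function(nRec = 50, nLig = 20, box = 9, seed = NULL,
                          entryId = "rand") {
  if (!is.null(seed)) set.seed(seed)
  makeComplex(
    entryId,
    receptor = data.frame(
      element = sample(c("C", "N", "O", "S", "F"), nRec, replace = TRUE),
      x = runif(nRec, -box, box), y = runif(nRec, -box, box),
      z = runif(nRec, -box, box),
      charge = runif(nRec, -0.5, 0.5)),
    ligand = data.frame(
      element = sample(c("C", "N", "O"), nLig, replace = TRUE),
      x = runif(nLig, -3, 3), y = runif(nLig, -3, 3),
      z = runif(nLig, -3, 3),
      charge = runif(nLig, -0.5, 0.5)),
    receptorBonds = matrix(integer(), ncol = 2),
    ligandBonds = matrix(integer(), ncol = 2))
}

# brute-force double loop over every receptor x ligand heavy-atom pair
bruteForceTerm <- function(desc, cx) {
  rec <- receptorAtoms(cx); lig <- ligandAtoms(cx)
  rec <- rec[!rec$isHydrogen, , drop = FALSE]
  lig <- lig[!lig$isHydrogen, , drop = FALSE]
  tab <- xsTypeTable()
  if (desc$family == "count") {
    heavy <- lig
    return(switch(desc$name,
      num_hydrophobic_atoms = sum(tab[heavy$xsType, "hydrophobic"]),
      num_heavy_atoms = nrow(heavy),
      ligand_length = if (nrow(heavy) < 2) 0 else
        max(dist(as.matrix(heavy[, c("x", "y", "z")]))),
      num_tors_div = ligandRotatableBonds(cx) / 5))
  }
  total <- 0
  for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(lig))) {
    d <- sqrt(sum((c(rec$x[i], rec$y[i], rec$z[i]) -
                   c(lig$x[j], lig$y[j], lig$z[j]))^2))
    if (d > desc$c) next
    ds <- d - (rec$vdwRadius[i] + lig$vdwRadius[j])
    ti <- rec$xsType[i]; tj <- lig$xsType[j]
    v <- switch(desc$family,
      gauss = exp(-((ds - desc$o) / desc$w)^2),
      repulsion = if (ds < desc$o) (ds - desc$o)^2 else 0,
      hydrophobic = if (tab[ti, "hydrophobic"] && tab[tj, "hydrophobic"]) {
        if (ds <= desc$g) 1 else if (ds >= desc$b) 0
        else (desc$b - ds) / (desc$b - desc$g)
      } else 0,
      non_dir_h_bond = if ((tab[ti, "donor"] && tab[tj, "acceptor"]) ||
                           (tab[ti, "acceptor"] && tab[tj, "donor"])) {
        if (ds <= desc$g) 1 else if (ds >= desc$b) 0
        else (desc$b - ds) / (desc$b - desc$g)
      } else 0,
      electrostatic = {
        raw <- rec$charge[i] * lig$charge[j] / max(d, 1e-6)^desc$i
        sign(raw) * min(abs(raw), desc$cap)
      },
      atom_type_gaussian = if ((ti == desc$type1 && tj == desc$type2) ||
                               (ti == desc$type2 && tj == desc$type1))
        exp(-((ds - desc$o) / desc$w)^2) else 0)
    total <- total + v
  }
  total
}

# rigidly transform every atom of a complex
transformComplex <- function(cx, rotation, translation) {
  mv <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation)
    at$x <- xyz[, 1] + translation[1]
    at$y <- xyz[, 2] + translation[2]
    at$z <- xyz[, 3] + translation[3]
    at
  }
  cx@receptorAtoms <- mv(cx@receptorAtoms)
  cx@ligandAtoms <- mv(cx@ligandAtoms)
  cx
}

extdata <- function(f) system.file("extdata", f, package = "censcore")
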