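#' Synthetic study specification
#'
#' Describes a desk-scale corpus of toy pocket/ligand complexes with
#' context-dependent ground-truth affinities. Each complex belongs to one
#' of K contexts encoded in the composition of the pocket lining (the
#' fraction of hydrophobic carbons among the outer-shell atoms), a property
#' visible both in the voxel channels and to a human auditor. The true
#' affinity is w*_k . t_e + noise, where t_e are the complex's scaled terms
#' and w*_k the true weight vector of its context; by default the contexts
#' share all weights except an opposing-sign weight on the first
#' electrostatic term, so no single global weight vector can explain both
#' contexts.
#'
#' The charged atoms of the pocket (an inner ring of balanced
#' positive/negative partial charges, a few of them placed at
#' hydrogen-bond distance from polar ligand atoms) are drawn identically
#' in every context, so the electrostatic term distribution itself carries
#' no context signal -- only the grid does.
#'
#' @param nComplexes corpus size (default 600).
#' @param nContexts number of contexts K (default 2).
#' @param receptorShellAtoms range of outer-shell atom counts (default
#'   30--44).
#' @param receptorChargedAtoms inner charged-ring atom count (default 12).
#' @param ligandAtomRange ligand heavy-atom count range (default 8--14).
#' @param hydrophobicBands list of K intervals for the shell hydrophobic
#'   fraction (defaults 0.15--0.25 and 0.75--0.85).
#' @param shellRadius,shellSd outer shell placement, Angstrom
#'   (default 6.5 +/- 0.8, floor 5.0).
#' @param chargedRadius,chargedSd charged ring placement (5.0 +/- 0.5,
#'   floor 4.3).
#' @param ligandRadius ligand placement ball radius (default 2.2).
#' @param hbondContacts range of deliberate hydrogen-bond contacts
#'   (default 1--3).
#' @param noiseSd label noise in pK units (default 0.3).
#' @param weightCommon named numeric: shared true weights (terms absent
#'   default to 0).
#' @param weightFlipTerm term whose weight flips sign across contexts.
#' @param weightFlipValue magnitude of the flipped weight (default 6).
#' @param qualifierProbs probabilities of the =, ~, >, < qualifiers.
#' @param ambiguousFraction fraction of entries given a second chain in a
#'   different cluster (exercises ambiguity removal; default 0.02).
#' @param registry term registry (default \code{defaultTermRegistry()}).
#' @param seed base RNG seed.
#' @return spec list.
#' @export
syntheticSpec <- function(nComplexes = 600L, nContexts = 2L,
                          receptorShellAtoms = c(30L, 44L),
                          receptorChargedAtoms = 12L,
                          ligandAtomRange = c(8L, 14L),
                          hydrophobicBands = list(c(0.15, 0.25),
                                                  c(0.75, 0.85)),
                          shellRadius = 6.5, shellSd = 0.8,
                          chargedRadius = 5.0, chargedSd = 0.5,
                          ligandRadius = 2.2, hbondContacts = c(1L, 3L),
                          noiseSd = 0.3,
                          weightCommon = c(
                            "gauss(o=0,_w=0.5,_c=8)" = 0.8,
                            "gauss(o=3,_w=2,_c=8)" = 0.3,
                            "repulsion(o=0,_c=8)" = -0.6,
                            "hydrophobic(g=0.5,_b=1.5,_c=8)" = 0.8,
                            "non_dir_h_bond(g=-0.7,_b=0,_c=8)" = 1.0,
                            "num_tors_div" = -0.5,
                            "num_heavy_atoms" = 6,
                            "ligand_length" = 0.5),
                          weightFlipTerm = "electrostatic(i=1,_cap=100,_c=8)",
                          weightFlipValue = 6,
                          qualifierProbs = c("=" = 0.85, "~" = 0.07,
                                             ">" = 0.04, "<" = 0.04),
                          ambiguousFraction = 0.02,
                          registry = defaultTermRegistry(),
                          seed = 1L) {
  stopifnot(nContexts >= 1L, noiseSd >= 0,
            length(hydrophobicBands) == nContexts,
            all(ligandAtomRange >= 1L))
  if (ligandAtomRange[1] < 1L) stop("spec error: ligand must be nonempty")
  .checkRegistry(registry)
  spec <- list(nComplexes = as.integer(nComplexes),
               nContexts = as.integer(nContexts),
               receptorShellAtoms = receptorShellAtoms,
               receptorChargedAtoms = as.integer(receptorChargedAtoms),
               ligandAtomRange = ligandAtomRange,
               hydrophobicBands = hydrophobicBands,
               shellRadius = shellRadius, shellSd = shellSd,
               chargedRadius = chargedRadius, chargedSd = chargedSd,
               ligandRadius = ligandRadius, hbondContacts = hbondContacts,
               noiseSd = noiseSd, weightCommon = weightCommon,
               weightFlipTerm = weightFlipTerm,
               weightFlipValue = weightFlipValue,
               qualifierProbs = qualifierProbs,
               ambiguousFraction = ambiguousFraction,
               registry = registry, seed = as.integer(seed))
  spec
}

#' True context weight vectors of a synthetic spec
#' @param spec from \code{\link{syntheticSpec}}.
#' @return matrix (nContexts x registry terms) of true weights.
#' @export
trueWeightMatrix <- function(spec) {
  W <- matrix(0, spec$nContexts, nrow(spec$registry),
              dimnames = list(NULL, spec$registry$name))
  for (nm in names(spec$weightCommon))
    if (nm %in% colnames(W)) W[, nm] <- spec$weightCommon[[nm]]
  if (spec$nContexts >= 2L) {
    signs <- rep(c(1, -1), length.out = spec$nContexts)
    W[, spec$weightFlipTerm] <- signs * spec$weightFlipValue
  } else {
    W[, spec$weightFlipTerm] <- spec$weightFlipValue
  }
  W
}

# rescale the positive charges so each molecule is net-neutral: the
# electrostatic term then varies with interaction geometry rather than
# with net-charge fluctuations, keeping its corpus distribution light-
# tailed (heavy tails would let single outliers dominate max-abs scaling)
.balanceCharges <- function(q) {
  sPos <- sum(q[q > 0]); sNeg <- -sum(q[q < 0])
  if (sPos > 1e-9 && sNeg > 1e-9) q[q > 0] <- q[q > 0] * (sNeg / sPos)
  q
}

.randUnit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# rejection-sample n points in a ball with minimum pairwise separation
.packBall <- function(n, radius, minSep = 1.3) {
  pts <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(pts) < n && tries < 8000L) {
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) <= radius^2 &&
        (nrow(pts) == 0L || min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= minSep))
      pts <- rbind(pts, p)
    tries <- tries + 1L
  }
  if (nrow(pts) < n)
    stop("spec error: cannot pack ", n, " ligand atoms into radius ",
         radius)
  pts
}

#' Generate one synthetic complex
#'
#' Ligand heavy atoms (carbon / oxygen / nitrogen mix with signed partial
#' charges on the heteroatoms) are packed into a small ball; the receptor
#' pocket is a charged inner ring (balanced +/- charges, some atoms placed
#' at hydrogen-bond distance from polar ligand atoms, which also yields
#' sub-contact pairs for the repulsion term) surrounded by an outer shell
#' whose hydrophobic-carbon fraction encodes the context. All five
#' distance-dependent term families and the electrostatics are exercised.
#'
#' @param spec from \code{\link{syntheticSpec}}.
#' @param context context index in 1..K.
#' @param entryId identifier.
#' @param seed per-complex RNG seed.
#' @return a \linkS4class{ComplexStructure}; \code{metadata$context}
#'   records the generating context.
#' @export
generateComplex <- function(spec, context = 1L, entryId = "synth",
                            seed = spec$seed) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  nLig <- sample(spec$ligandAtomRange[1]:spec$ligandAtomRange[2], 1)
  ligXYZ <- .packBall(nLig, spec$ligandRadius)
  ligEl <- sample(c("C", "O", "N"), nLig, replace = TRUE,
                  prob = c(0.5, 0.25, 0.25))
  ligQ <- ifelse(ligEl == "O", -stats::runif(nLig, 0.2, 0.5),
          ifelse(ligEl == "N", stats::runif(nLig, 0.2, 0.5),
                 stats::runif(nLig, -0.05, 0.05)))
  ligQ <- .balanceCharges(ligQ)
  # a detached surface carbon (no covalent neighbor, so it types
  # hydrophobic) guarantees the ligand presents a hydrophobic patch
  for (try in 1:200) {
    dirP <- .randUnit(1)
    probe <- dirP * (spec$ligandRadius + 1.0)
    if (min(sqrt(rowSums(sweep(ligXYZ, 2, probe)^2))) >= 2.1) break
  }
  ligXYZ <- rbind(ligXYZ, probe)
  ligEl <- c(ligEl, "C")
  ligQ <- c(ligQ, stats::runif(1, -0.02, 0.02))
  nLig <- nLig + 1L

  # charged inner ring: identical construction in every context
  nq <- spec$receptorChargedAtoms
  qEl <- rep(c("O", "N"), length.out = nq)
  qDir <- .randUnit(nq)
  qR <- pmax(stats::rnorm(nq, spec$chargedRadius, spec$chargedSd), 4.3)
  qXYZ <- qDir * qR
  qQ <- .balanceCharges(ifelse(qEl == "O", -stats::runif(nq, 0.25, 0.5),
                               stats::runif(nq, 0.25, 0.5)))
  # deliberate hydrogen-bond contacts: move a few charged atoms to
  # complementary positions 2.7-3.0 A from polar ligand atoms
  # contacts target polar atoms on the outer half of the ligand so the
  # partner can approach to hydrogen-bond distance without clashing into
  # a different ligand atom; residual near-clashes are relaxed outward
  polar <- which(ligEl != "C")
  if (length(polar) > 2L) {
    rad <- sqrt(rowSums(ligXYZ[polar, , drop = FALSE]^2))
    polar <- polar[rad >= stats::median(rad)]
  }
  nHB <- sample(spec$hbondContacts[1]:spec$hbondContacts[2], 1)
  nHB <- min(nHB, length(polar), nq)
  if (nHB > 0L) {
    tgt <- sample(polar, nHB)
    for (i in seq_len(nHB)) {
      la <- ligXYZ[tgt[i], ]
      outward <- if (sum(la^2) > 1e-8) la / sqrt(sum(la^2)) else c(1, 0, 0)
      p <- la + outward * stats::runif(1, 2.7, 3.0)
      others <- ligXYZ[-tgt[i], , drop = FALSE]
      for (try in 1:6) {
        if (!nrow(others) ||
            min(sqrt(rowSums(sweep(others, 2, p)^2))) >= 2.6 ||
            sqrt(sum((p - la)^2)) >= 3.3) break
        p <- p + outward * 0.15
      }
      qXYZ[i, ] <- p
      # complementary partner: donor for an acceptor and vice versa
      qEl[i] <- if (ligEl[tgt[i]] == "O") "N" else "O"
      qQ[i] <- if (qEl[i] == "O") -stats::runif(1, 0.25, 0.5)
               else stats::runif(1, 0.25, 0.5)
    }
    qQ <- .balanceCharges(qQ)   # restore ring neutrality
  }

  # guaranteed hydrophobic contacts (context-independent, like the ring):
  # one or two near-contact carbons against a carbon of the ligand
  nHC <- sample(1:2, 1)
  hcXYZ <- matrix(0, 0, 3)
  for (i in seq_len(nHC)) {
    la <- ligXYZ[nLig, ]  # the detached hydrophobic surface carbon
    outward <- if (sum(la^2) > 1e-8) la / sqrt(sum(la^2)) else c(0, 0, 1)
    hcXYZ <- rbind(hcXYZ, la + outward * stats::runif(1, 4.1, 4.8) +
                     stats::rnorm(3, 0, 0.3))
  }

  # context-bearing outer shell: hydrophobic carbons vs uncharged polar
  ns <- sample(spec$receptorShellAtoms[1]:spec$receptorShellAtoms[2], 1)
  band <- spec$hydrophobicBands[[context]]
  h <- stats::runif(1, band[1], band[2])
  nH <- round(h * ns)
  sEl <- c(rep("C", nH), sample(c("O", "N"), ns - nH, replace = TRUE))
  sDir <- .randUnit(ns)
  sR <- pmax(stats::rnorm(ns, spec$shellRadius, spec$shellSd), 5.0)
  sXYZ <- sDir * sR
  sQ <- rep(0, ns)

  # physical-plausibility floor: no receptor atom may sit closer than
  # 2.6 A to any ligand atom (apart from its own placement geometry);
  # sub-van-der-Waals clashes would otherwise produce extreme
  # electrostatic/repulsion outliers that compress the dataset-wide
  # max-abs term scales
  minLig <- function(p) min(sqrt(rowSums(sweep(ligXYZ, 2, p)^2)))
  pushOut <- function(xyz, keepRows = integer()) {
    for (i in setdiff(seq_len(nrow(xyz)), keepRows)) {
      for (try in 1:50) {
        if (minLig(xyz[i, ]) >= 2.6) break
        dir <- xyz[i, ] / max(sqrt(sum(xyz[i, ]^2)), 1e-8)
        xyz[i, ] <- xyz[i, ] + dir * 0.4
      }
    }
    xyz
  }
  qXYZ <- pushOut(qXYZ, keepRows = seq_len(nHB))
  sXYZ <- pushOut(sXYZ)

  # keep receptor atoms mutually separated so no spurious bonds are
  # inferred (isolated atoms keep their base hydrophobic/polar typing)
  recXYZ <- rbind(qXYZ, hcXYZ, sXYZ)
  recEl <- c(qEl, rep("C", nrow(hcXYZ)), sEl)
  recQ <- c(qQ, stats::runif(nrow(hcXYZ), -0.02, 0.02), sQ)
  ok <- rep(TRUE, nrow(recXYZ))
  for (i in seq_len(nrow(recXYZ))[-1]) {
    prev <- which(ok[seq_len(i - 1L)])
    if (length(prev) &&
        min(sqrt(rowSums(sweep(recXYZ[prev, , drop = FALSE], 2,
                               recXYZ[i, ])^2))) < 2.2)
      ok[i] <- FALSE
  }
  # contact atoms are load-bearing; never drop them
  ok[seq_len(nHB)] <- TRUE
  ok[nq + seq_len(nrow(hcXYZ))] <- TRUE

  makeComplex(entryId,
              receptor = data.frame(element = recEl[ok],
                                    x = recXYZ[ok, 1], y = recXYZ[ok, 2],
                                    z = recXYZ[ok, 3], charge = recQ[ok]),
              ligand = data.frame(element = ligEl, x = ligXYZ[, 1],
                                  y = ligXYZ[, 2], z = ligXYZ[, 3],
                                  charge = ligQ),
              receptorBonds = matrix(integer(), ncol = 2),
              ligandRotatableBonds = sample(0:8, 1),
              metadata = list(context = context,
                              shellHydrophobicFraction = h))
}

#' Generate a full synthetic corpus
#'
#' Generates complexes across contexts, featurizes and scales them with
#' the spec registry, draws labels pk = w*_k . t_e + Normal(0, noiseSd)
#' clipped to [0, 14], samples affinity qualifiers (so the qualifier
#' filters have work to do), and builds a chain-level cluster table whose
#' cluster ids derive from context plus jitter (with a small fraction of
#' deliberately ambiguous two-cluster entries).
#'
#' @param spec from \code{\link{syntheticSpec}}.
#' @return list with \code{complexes}, \code{records} (affinity table),
#'   \code{clusterTable}, \code{context} (true context per entry),
#'   \code{termMatrix} (raw), \code{scaling}, \code{scaledTerms},
#'   \code{labels} (noisy pK used for the records), \code{trueWeights},
#'   \code{registry}.
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(spec$seed)
  n <- spec$nComplexes
  ctx <- rep_len(seq_len(spec$nContexts), n)
  seeds <- sample.int(2^30, n)
  ids <- sprintf("synth%04d", seq_len(n))
  complexes <- lapply(seq_len(n), function(i)
    generateComplex(spec, context = ctx[i], entryId = ids[i],
                    seed = seeds[i]))
  tm <- featurizeDataset(complexes, spec$registry)
  scaling <- fitScaling(tm)
  st <- applyScaling(tm, scaling)
  W <- trueWeightMatrix(spec)
  clean <- rowSums(st * W[ctx, , drop = FALSE])
  labels <- pmin(pmax(clean + stats::rnorm(n, 0, spec$noiseSd), 0), 14)

  qual <- sample(names(spec$qualifierProbs), n, replace = TRUE,
                 prob = spec$qualifierProbs)
  molar <- 10^(-labels)
  # express values in a natural unit per entry
  unit <- ifelse(molar >= 1e-3, "mM",
          ifelse(molar >= 1e-6, "uM", ifelse(molar >= 1e-9, "nM", "pM")))
  value <- molar / .UNIT_TO_MOLAR[unit]
  records <- affinityRecords(ids, sample(c("Kd", "Ki", "IC50"), n, TRUE),
                             qual, value, unit)

  # 20 jittered clusters per context: enough granularity that greedy
  # size balancing also keeps the fold composition roughly balanced
  cluster <- sprintf("ctx%d_c%02d", ctx, sample.int(20, n, replace = TRUE))
  clusterTable <- data.frame(entry_id = ids, chain = "A",
                             cluster = cluster, stringsAsFactors = FALSE)
  nAmb <- round(spec$ambiguousFraction * n)
  if (nAmb > 0L) {
    amb <- sample.int(n, nAmb)
    clusterTable <- rbind(clusterTable,
                          data.frame(entry_id = ids[amb], chain = "B",
                                     cluster = sprintf("ctx%d_c%02d",
                                                       ctx[amb],
                                                       20L + seq_len(nAmb)),
                                     stringsAsFactors = FALSE))
  }
  list(complexes = complexes, records = records,
       clusterTable = clusterTable, context = ctx, termMatrix = tm,
       scaling = scaling, scaledTerms = st, labels = labels,
       trueWeights = W, registry = spec$registry)
}

#' Write a synthetic corpus to disk in pipeline formats
#'
#' Emits one PDB receptor and one MOL2 ligand (with partial charges) per
#' complex, the affinity table and the cluster table as TSV, so synthetic
#' data flows through the same file-based entry points as real data.
#'
#' @param dataset from \code{\link{generateDataset}}.
#' @param dir output directory (created).
#' @return data.frame manifest (entry_id, receptor, ligand, pk).
#' @export
writeSyntheticCorpus <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(entry_id = character(), receptor = character(),
                    ligand = character(), pk = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(dataset$complexes)) {
    cx <- dataset$complexes[[i]]
    id <- entryId(cx)
    rp <- file.path(dir, paste0(id, "_receptor.pdb"))
    lp <- file.path(dir, paste0(id, "_ligand.mol2"))
    .writePlainPDB(cx@receptorAtoms, rp)
    .writeMol2(cx@ligandAtoms, cx@ligandBonds, cx@ligandRotatableBonds,
               id, lp)
    man <- rbind(man, data.frame(entry_id = id, receptor = rp, ligand = lp,
                                 pk = dataset$records$pk[i]))
  }
  utils::write.table(dataset$records[, c("entry_id", "measure", "qualifier",
                                         "value", "unit")],
                     file.path(dir, "affinities.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$clusterTable, file.path(dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}

.writePlainPDB <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    substr(paste0(toupper(atoms$element), seq_len(nrow(atoms))), 1, 4),
    "POC", "A", 1L, atoms$x, atoms$y, atoms$z, 1.00, 0.00,
    toupper(atoms$element))
  writeLines(c(lines, "END"), path)
}

.writeMol2 <- function(atoms, bonds, ntors, name, path) {
  n <- nrow(atoms)
  nb <- nrow(bonds)
  hdr <- c("@<TRIPOS>MOLECULE", name,
           sprintf(" %d %d 0 0 0", n, nb), "SMALL", "USER_CHARGES",
           "@<TRIPOS>ATOM")
  at <- sprintf("%7d %-8s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
                seq_len(n), paste0(atoms$element, seq_len(n)),
                atoms$x, atoms$y, atoms$z, atoms$element, 1L, "LIG1",
                atoms$charge)
  bd <- if (nb) c("@<TRIPOS>BOND",
                  sprintf("%6d %5d %5d %s", seq_len(nb), bonds[, 1],
                          bonds[, 2], "1")) else "@<TRIPOS>BOND"
  writeLines(c(hdr, at, bd), path)
}
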