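test_that("pair enumeration is exact geometry within the cutoff", {
  cx <- makeComplex("p",
    receptor = data.frame(element = "C", x = 0, y = 0, z = 0),
    ligand = data.frame(element = "C", x = 0, y = 0, z = 5))
  p8 <- enumeratePairs(cx, 8)
  expect_equal(nrow(p8), 1)
  expect_equal(p8$d, 5)
  expect_equal(p8$d0, 3.8)        # two XS carbons
  expect_equal(nrow(enumeratePairs(cx, 4)), 0)
})

test_that("pair enumeration equals the all-pairs oracle", {
  for (seed in 1:3) {
    cx <- randomComplex(50, 20, seed = seed)
    p <- enumeratePairs(cx, 8)
    rec <- receptorAtoms(cx); lig <- ligandAtoms(cx)
    # brute-force double loop
    hits <- 0L
    for (i in seq_len(nrow(rec))) for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                (rec$z[i] - lig$z[j])^2)
      if (d <= 8) {
        hits <- hits + 1L
        k <- which(p$recRow == i & p$ligRow == j)
        expect_length(k, 1)
        expect_equal(p$d[k], d, tolerance = 1e-12)
      }
    }
    expect_equal(nrow(p), hits)
  }
})

test_that("term calculators reproduce hand-computed values", {
  # one C-C pair at d = 3.8 = d0, one polar pair for electrostatics
  cc <- makeComplex("cc",
    receptor = data.frame(element = "C", x = 0, y = 0, z = 0,
                          charge = 0.5),
    ligand = data.frame(element = "C", x = 3.8, y = 0, z = 0,
                        charge = -0.5))
  # atom_type_gaussian at optimal distance contributes exp(0) = 1
  atg <- termDescriptor("atom_type_gaussian",
                        type1 = "AliphaticCarbonXSHydrophobe",
                        type2 = "AliphaticCarbonXSHydrophobe")
  expect_equal(evalTerm(atg, cc), 1.0)
  # gauss(o=0, w=0.5) at ds = 0 is also 1
  expect_equal(evalTerm(termDescriptor("gauss", o = 0, w = 0.5, c = 8), cc),
               1.0)

  # electrostatic i=1: q1 q2 / d = 0.5 * -0.5 / 2 = -0.125
  el <- makeComplex("el",
    receptor = data.frame(element = "N", x = 0, y = 0, z = 0,
                          charge = 0.5),
    ligand = data.frame(element = "O", x = 2, y = 0, z = 0,
                        charge = -0.5))
  expect_equal(evalTerm(termDescriptor("electrostatic", i = 1, cap = 100,
                                       c = 8), el), -0.125)

  # i=2 with q1 q2 / d^2 = 400 is capped at 100
  elcap <- makeComplex("elcap",
    receptor = data.frame(element = "N", x = 0, y = 0, z = 0, charge = 2),
    ligand = data.frame(element = "N", x = 0.1, y = 0, z = 0, charge = 2))
  expect_equal(evalTerm(termDescriptor("electrostatic", i = 2, cap = 100,
                                       c = 8), elcap), 100)

  # hydrophobic ramp midpoint: ds = 1.0 between g=0.5 and b=1.5 -> 0.5
  hp <- makeComplex("hp",
    receptor = data.frame(element = "C", x = 0, y = 0, z = 0),
    ligand = data.frame(element = "C", x = 4.8, y = 0, z = 0))
  expect_equal(evalTerm(termDescriptor("hydrophobic", g = 0.5, b = 1.5,
                                       c = 8), hp), 0.5)

  # a 7-carbon isolated-atom ligand counts 7 hydrophobic atoms
  sevenC <- makeComplex("c7",
    receptor = data.frame(element = "C", x = 0, y = 0, z = 0),
    ligand = data.frame(element = rep("C", 7),
                        x = seq(0, 18, by = 3), y = 5, z = 0),
    ligandBonds = matrix(integer(), ncol = 2))
  expect_equal(evalTerm(termDescriptor("count",
                                       countName = "num_hydrophobic_atoms"),
                        sevenC), 7)
  expect_error(evalTerm(data.frame(name = "x", family = "bogus", o = NA,
                                   w = NA, c = 8, g = NA, b = NA, i = NA,
                                   cap = NA, type1 = NA, type2 = NA),
                        sevenC), "unknown term family")
})

test_that("every term family matches the brute-force oracle", {
  descs <- rbind(
    termDescriptor("gauss", o = 0, w = 0.5, c = 8),
    termDescriptor("gauss", o = 3, w = 2, c = 8),
    termDescriptor("repulsion", o = 0, c = 8),
    termDescriptor("repulsion", o = 0.5, c = 8),
    termDescriptor("hydrophobic", g = 0.5, b = 1.5, c = 8),
    termDescriptor("non_dir_h_bond", g = -0.7, b = 0, c = 8),
    termDescriptor("electrostatic", i = 1, cap = 100, c = 8),
    termDescriptor("electrostatic", i = 2, cap = 100, c = 8),
    termDescriptor("atom_type_gaussian",
                   type1 = "AliphaticCarbonXSHydrophobe",
                   type2 = "OxygenXSAcceptor"),
    termDescriptor("atom_type_gaussian",
                   type1 = "NitrogenXSDonorAcceptor",
                   type2 = "NitrogenXSDonorAcceptor"))
  for (seed in 1:10) {
    cx <- randomComplex(30, 12, seed = 100 + seed)
    for (j in seq_len(nrow(descs))) {
      d <- descs[j, , drop = FALSE]
      expect_equal(evalTerm(d, cx), bruteForceTerm(d, cx),
                   tolerance = 1e-9, info = d$name)
    }
  }
})

test_that("per-pair bounds hold: gauss in (0,1], ramps in [0,1]", {
  for (seed in 1:5) {
    cx <- randomComplex(20, 8, seed = seed)
    p <- enumeratePairs(cx, 8)
    if (!nrow(p)) next
    ds <- p$d - p$d0
    g <- exp(-(ds / 0.5)^2)
    expect_true(all(g > 0 & g <= 1))
    nPairs <- nrow(p)
    hp <- evalTerm(termDescriptor("hydrophobic", g = 0.5, b = 1.5, c = 8),
                   cx)
    expect_true(hp >= 0 && hp <= nPairs)
    el <- evalTerm(termDescriptor("electrostatic", i = 2, cap = 100, c = 8),
                   cx)
    expect_true(abs(el) <= 100 * nPairs)
  }
})

test_that("terms are invariant under rigid motion", {
  reg <- defaultTermRegistry()
  cx <- randomComplex(25, 10, seed = 9)
  v1 <- featurize(cx, reg)
  set.seed(11)
  tr <- sampleAugmentation(maxShift = 5)
  cx2 <- transformComplex(cx, tr$rotation, tr$translation)
  v2 <- featurize(cx2, reg)
  expect_equal(as.numeric(v2), as.numeric(v1), tolerance = 1e-9)
})

test_that("featurize is order-stable and permutation-equivariant", {
  reg <- defaultTermRegistry()
  cx <- toyComplex()
  v <- featurize(cx, reg)
  expect_length(v, nrow(reg))
  expect_identical(names(v), reg$name)
  expect_false(isTRUE(attr(v, "scaled")))
  perm <- sample(nrow(reg))
  vp <- featurize(cx, reg[perm, ])
  expect_equal(as.numeric(vp), as.numeric(v)[perm])
  # distant ligand: interaction terms zero, counts still reflect ligand
  far <- makeComplex("far",
    receptor = data.frame(element = "C", x = 0, y = 0, z = 0),
    ligand = data.frame(element = c("C", "O"), x = c(50, 52), y = 0, z = 0),
    ligandBonds = matrix(integer(), ncol = 2))
  vf <- featurize(far, reg)
  inter <- reg$family %in% c("gauss", "repulsion", "hydrophobic",
                             "non_dir_h_bond", "electrostatic",
                             "atom_type_gaussian")
  expect_true(all(vf[inter] == 0))
  expect_equal(unname(vf["num_heavy_atoms"]), 2)
})

test_that("the candidate registry has the full 348-descriptor layout", {
  reg <- candidateTermRegistry()
  expect_equal(nrow(reg), 348)
  expect_equal(sum(reg$family == "atom_type_gaussian"), 325)
  cx <- toyComplex()
  expect_length(featurize(cx, reg), 348)
})

test_that("sparse steric terms are filtered at the nonzero threshold", {
  reg <- rbind(termDescriptor("gauss", o = 0, w = 0.5, c = 8),
               termDescriptor("atom_type_gaussian",
                              type1 = "Sulfur", type2 = "Sulfur"),
               termDescriptor("atom_type_gaussian",
                              type1 = "Fluorine", type2 = "Fluorine"))
  m <- matrix(0, 200, 3, dimnames = list(NULL, reg$name))
  m[, 1] <- 0            # non-steric stays regardless
  m[1, 2] <- 0.4         # 0.5% nonzero -> dropped
  m[1:3, 3] <- 0.2       # 1.5% nonzero -> kept
  kept <- filterSparseTerms(m, reg, threshold = 0.01)
  expect_identical(kept$name, reg$name[c(1, 3)])
  expect_error(filterSparseTerms(m[0, , drop = FALSE], reg), "empty")
})

test_that("max-abs scaling maps to [-1,1], preserves sign, idempotent", {
  m <- cbind(a = c(2, -4, 1), b = c(0, 0, 0), c = c(0.5, 0.25, -0.1))
  s <- fitScaling(m)
  expect_equal(unname(s@factors), c(4, 1, 0.5))
  sm <- applyScaling(m, s)
  expect_equal(unname(sm[, "a"]), c(0.5, -1, 0.25))
  expect_equal(unname(sm[, "b"]), c(0, 0, 0))
  expect_true(all(sm >= -1 & sm <= 1))
  expect_equal(sign(sm), sign(m), ignore_attr = TRUE)
  # nonzero columns reach |1|
  expect_equal(max(abs(sm[, "a"])), 1)
  # marked scaled; re-application is a no-op
  expect_true(attr(sm, "scaled"))
  expect_identical(applyScaling(sm, s), sm)
  # shape errors
  expect_error(applyScaling(m[, 1:2], s), "shape error")
})

test_that("scaling factors persist through JSON", {
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  s <- fitScaling(m)
  f <- tempfile(fileext = ".json")
  writeScalingFactors(s, f)
  s2 <- readScalingFactors(f)
  expect_equal(s2@factors, s@factors)
  expect_equal(s2@nExamples, s@nExamples)
})

test_that("term matrices round-trip through CSV", {
  cxs <- list(toyComplex("a"), toyComplex("b"))
  m <- featurizeDataset(cxs, defaultTermRegistry())
  f <- tempfile(fileext = ".csv")
  writeTermMatrix(m, f)
  m2 <- readTermMatrix(f)
  expect_equal(m2, m, ignore_attr = TRUE)
  expect_identical(colnames(m2), colnames(m))
})
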