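# a two-pair complex with exact geometry for attribution arithmetic:
# receptor C at origin; ligand C at d = d0 (g = 1) and a second ligand C
# at a chosen surface distance
.attribComplex <- function(d2 = 4.3) {
  makeComplex("attr",
    receptor = data.frame(element = "C", x = 0, y = 0, z = 0),
    ligand = data.frame(element = c("C", "C"),
                        x = c(3.8, -d2), y = 0, z = 0),
    ligandBonds = matrix(integer(), ncol = 2))
}

.ccRegistry <- function() {
  rbind(termDescriptor("atom_type_gaussian",
                       type1 = "AliphaticCarbonXSHydrophobe",
                       type2 = "AliphaticCarbonXSHydrophobe"),
        termDescriptor("gauss", o = 0, w = 0.5, c = 8))
}

test_that("attribution splits each pair value half/half and accumulates", {
  reg <- .ccRegistry()
  s <- new("ScalingFactors",
           factors = stats::setNames(c(2, 1), reg$name), nExamples = 10L)
  w <- stats::setNames(c(0.8, 0), reg$name)
  cx <- .attribComplex()
  am <- attributeAtoms(cx, w, s, reg)
  # pair 1: g = 1, v = 1/2 * 0.8 = 0.4; pair 2: g = exp(-0.5^2) (ds = 0.5)
  g2 <- exp(-((4.3 - 3.8) / 1)^2)
  v1 <- 1 / 2 * 0.8; v2 <- g2 / 2 * 0.8
  # receptor atom participates in both pairs: sums the halves
  expect_equal(unname(am@perAtom["1"]), (v1 + v2) / 2, tolerance = 1e-12)
  expect_equal(unname(am@perAtom["2"]), v1 / 2, tolerance = 1e-12)
  expect_equal(unname(am@perAtom["3"]), v2 / 2, tolerance = 1e-12)
  expect_equal(sum(am@perAtom), sum(am@perTermTotals), tolerance = 1e-12)
})

test_that("attribution conserves the weighted scaled steric contribution", {
  reg <- defaultTermRegistry()
  for (seed in c(3, 7, 21)) {
    cx <- randomComplex(30, 10, seed = seed)
    m <- featurizeDataset(list(cx, randomComplex(25, 8, seed = seed + 50)),
                          reg)
    s <- fitScaling(m)
    st <- applyScaling(m, s)
    set.seed(seed)
    w <- stats::setNames(rnorm(nrow(reg)), reg$name)
    st1 <- st[1, ]; attr(st1, "scaled") <- TRUE
    pred <- predictAffinity(w, st1)
    am <- attributeAtoms(cx, w, s, reg)
    atg <- reg$name[reg$family == "atom_type_gaussian"]
    expect_equal(sum(am@perAtom), sum(contributions(pred)[atg]),
                 tolerance = 1e-9)
    expect_equal(sum(am@perTermTotals), sum(contributions(pred)[atg]),
                 tolerance = 1e-9)
  }
})

test_that("attribution demands scaling factors", {
  reg <- .ccRegistry()
  w <- stats::setNames(c(1, 0), reg$name)
  expect_error(attributeAtoms(.attribComplex(), w, NULL, reg),
               "contract error")
})

test_that("z-scores reproduce the printed electrostatic worked example", {
  # target mean -7.52 against reference -5.15 +/- 1.72 gives |z| = 1.38
  ref <- matrix(c(-5.15 - 1.72, -5.15 + 1.72), 2, 1,
                dimnames = list(NULL, "electrostatic(i=1,_cap=100,_c=8)"))
  r <- weightZScores(
    c("electrostatic(i=1,_cap=100,_c=8)" = -7.52), ref)
  expect_equal(round(r$abs_z, 2), 1.38)
  expect_equal(r$ref_sd, 1.72)
})

test_that("z-score edge cases: equal means and zero spread", {
  ref <- matrix(c(1, 3, 2, 2), 2, 2,
                dimnames = list(NULL, c("a", "b")))
  r <- weightZScores(c(a = 2, b = 5), ref)
  expect_equal(r$abs_z[r$term == "a"], 0)
  expect_true(r$flagged[r$term == "b"])
  expect_true(is.na(r$abs_z[r$term == "b"]))
  expect_error(weightZScores(c(a = 1), ref[1, , drop = FALSE]),
               "at least two")
})

test_that("z-scores are invariant to common affine rescaling", {
  set.seed(6)
  ref <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("t", 1:4)))
  tgt <- stats::setNames(rnorm(4), paste0("t", 1:4))
  z1 <- weightZScores(tgt, ref)
  aff <- function(x) 3.2 * x - 7
  z2 <- weightZScores(aff(tgt), aff(ref))
  expect_equal(z2$abs_z[order(z2$term)], z1$abs_z[order(z1$term)],
               tolerance = 1e-9)
})

test_that("embedding separates distinct weight clusters deterministically", {
  set.seed(10)
  W <- rbind(matrix(rnorm(15 * 6, mean = 0, sd = 0.3), 15, 6),
             matrix(rnorm(15 * 6, mean = 4, sd = 0.3), 15, 6))
  rownames(W) <- sprintf("w%02d", 1:30)
  e1 <- embedWeights(W, seed = 3, k = 2)
  e2 <- embedWeights(W, seed = 3, k = 2)
  expect_identical(e1$x, e2$x)
  expect_gt(attr(e1, "silhouette2d"), 0)
  expect_gt(attr(e1, "consistency"), 0.9)
  # duplicated vectors land together
  W2 <- W; W2[2, ] <- W2[1, ]
  e3 <- embedWeights(W2, seed = 3, k = 2)
  d12 <- sqrt((e3$x[1] - e3$x[2])^2 + (e3$y[1] - e3$y[2])^2)
  spread <- max(dist(cbind(e3$x, e3$y)))
  expect_lt(d12, 0.05 * spread)
  expect_error(embedWeights(W[1:4, ]), "at least five")
})

test_that("AUROC equals the pair-counting oracle and handles ties", {
  # perfect separation
  m <- screenMetrics(c(9, 8, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$auroc, 1)
  # all-tied scores are uninformative
  expect_equal(screenMetrics(rep(1, 10), rep(c(1, 0), 5))$auroc, 0.5)
  # 4 actives / 6 inactives against exhaustive pair counting
  set.seed(17)
  for (rep in 1:20) {
    scores <- sample(1:8, 10, replace = TRUE)  # with ties
    labels <- c(rep(TRUE, 4), rep(FALSE, 6))
    m <- screenMetrics(scores, labels)
    pairs <- 0
    for (i in which(labels)) for (j in which(!labels))
      pairs <- pairs + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    expect_equal(m$auroc, pairs / (4 * 6))
  }
  expect_error(screenMetrics(1:3, c(1, 1, 1)), "metric error")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  ours <- screenMetrics(scores, labels)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("enrichment factors match their definition", {
  scores <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  labels <- c(1, 1, 0, 0, 0, 0, 0, 0, 1, 1)
  m <- screenMetrics(scores, labels, topFractions = c(0.2, 0.5))
  # top 2 are both active: (2/2) / (4/10) = 2.5
  expect_equal(unname(m$ef["EF20"]), 2.5)
  # top 5 holds 2 of 4 actives: (2/5) / (4/10) = 1
  expect_equal(unname(m$ef["EF50"]), 1)
})
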