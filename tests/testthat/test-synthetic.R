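test_that("infeasible specs are rejected", {
  expect_error(syntheticSpec(ligandAtomRange = c(0L, 0L)))
  expect_error(syntheticSpec(nContexts = 3L))  # needs 3 bands
})

test_that("generation is reproducible under a seed", {
  spec <- syntheticSpec(nComplexes = 4, seed = 3)
  a <- generateComplex(spec, context = 1, seed = 77)
  b <- generateComplex(spec, context = 1, seed = 77)
  expect_identical(receptorAtoms(a), receptorAtoms(b))
  expect_identical(ligandAtoms(a), ligandAtoms(b))
  d1 <- generateDataset(spec)
  d2 <- generateDataset(spec)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$termMatrix, d2$termMatrix)
})

test_that("every term family is exercised in most generated complexes", {
  spec <- syntheticSpec(nComplexes = 100, seed = 19)
  ds <- generateDataset(spec)
  fam <- spec$registry$family
  ok <- rep(TRUE, 100)
  for (f in c("gauss", "repulsion", "hydrophobic", "non_dir_h_bond",
              "electrostatic")) {
    nz <- rowSums(ds$termMatrix[, fam == f, drop = FALSE] != 0) > 0
    ok <- ok & nz
  }
  expect_gte(mean(ok), 0.8)
})

test_that("context is written into structure and decodable from the grid", {
  spec <- syntheticSpec(nComplexes = 60, seed = 23)
  ds <- generateDataset(spec)
  frac <- vapply(ds$complexes, function(cx) {
    rec <- receptorAtoms(cx)
    tab <- xsTypeTable()
    mean(tab[rec$xsType, "hydrophobic"])
  }, 0)
  # hydrophobic fraction separates the two contexts cleanly
  expect_gt(min(frac[ds$context == 2]), max(frac[ds$context == 1]))
  # trivial classifier on the pooled hydrophobic-carbon channel
  cmap <- voxelChannelMap()
  chan <- cmap$channel[cmap$side == "receptor" &
                       cmap$group == "CarbonHydrophobe"]
  feat <- vapply(ds$complexes, function(cx)
    sum(voxelize(cx, gridConfig(16, 1))@densities[, , , chan]), 0)
  trainIx <- seq_len(30)
  thr <- mean(tapply(feat[trainIx], ds$context[trainIx], mean))
  predCtx <- 1L + (feat[-trainIx] > thr)
  expect_gt(mean(predCtx == ds$context[-trainIx]), 0.9)
})

test_that("with zero noise and one context a global linear model is exact", {
  spec <- syntheticSpec(nComplexes = 40, nContexts = 1L,
                        hydrophobicBands = list(c(0.3, 0.7)),
                        noiseSd = 0, seed = 31)
  ds <- generateDataset(spec)
  inRange <- ds$labels > 0 & ds$labels < 14   # away from the pK clip
  # predicting with the true weights reproduces the labels exactly
  predTrue <- rowSums(ds$scaledTerms * ds$trueWeights[rep(1, 40), ])
  expect_equal(predTrue[inRange], ds$labels[inRange], tolerance = 1e-12)
  fit <- suppressWarnings(stats::lsfit(ds$scaledTerms[inRange, ],
                                       ds$labels[inRange],
                                       intercept = FALSE))
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("opposing contexts defeat any single global weight vector", {
  spec <- syntheticSpec(nComplexes = 120, noiseSd = 0, seed = 37)
  ds <- generateDataset(spec)
  oracle <- rowSums(ds$scaledTerms * ds$trueWeights[ds$context, ])
  rOracle <- pearsonCor(oracle, ds$labels)
  fit <- suppressWarnings(stats::lsfit(ds$scaledTerms, ds$labels,
                                       intercept = FALSE))
  co <- fit$coefficients; co[is.na(co)] <- 0
  rGlobal <- pearsonCor(as.numeric(ds$scaledTerms %*% co), ds$labels)
  expect_lt(rGlobal, rOracle)
  expect_lt(rGlobal, 0.9)
  expect_gt(rOracle, 0.99)
})

test_that("generated qualifiers exercise the affinity filter as built", {
  spec <- syntheticSpec(nComplexes = 200, seed = 41)
  ds <- generateDataset(spec)
  kept <- filterAffinities(ds$records)
  expect_false(any(kept$qualifier == ">"))
  expect_true(all(ds$records$entry_id[ds$records$qualifier %in%
                                        c("=", "~")] %in% kept$entry_id))
  expect_true(all(kept$molar[kept$qualifier == "<"] <= 1e-6))
})

test_that("a written corpus reads back through the file pipeline", {
  spec <- syntheticSpec(nComplexes = 3, seed = 43)
  ds <- generateDataset(spec)
  dir <- tempfile("corpus")
  man <- writeSyntheticCorpus(ds, dir)
  expect_equal(nrow(man), 3)
  cx <- readComplex(man$receptor[1], man$ligand[1], man$entry_id[1])
  orig <- ds$complexes[[1]]
  expect_equal(nrow(receptorAtoms(cx)), nrow(receptorAtoms(orig)))
  expect_equal(nrow(ligandAtoms(cx)), nrow(ligandAtoms(orig)))
  expect_lt(max(abs(ligandAtoms(cx)$charge - ligandAtoms(orig)$charge)),
            1e-3)
  expect_equal(receptorAtoms(cx)$x, receptorAtoms(orig)$x,
               tolerance = 1e-3)
  rec <- readAffinityTable(file.path(dir, "affinities.tsv"))
  expect_equal(rec$pk, ds$records$pk, tolerance = 1e-4)
  ct <- readClusterTable(file.path(dir, "clusters.tsv"))
  expect_true(all(ds$clusterTable$cluster %in% ct$cluster))
})
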