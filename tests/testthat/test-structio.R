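test_that("readComplex parses PDB + SDF, strips waters, keeps charges", {
  cx <- readComplex(extdata("toy_receptor.pdb"), extdata("toy_ligand.sdf"))
  rec <- receptorAtoms(cx)
  lig <- ligandAtoms(cx)
  # the PDB holds 8 non-water atoms (2 of them hydrogens) and 2 waters
  expect_equal(nrow(rec), 8)
  expect_equal(sum(rec$isHydrogen), 2)
  expect_false(any(rec$element %in% "O" & rec$x == 8))  # waters gone
  expect_equal(nrow(lig), 5)
  # SDF data-field charges round-trip
  expect_equal(lig$charge, c(0.12, -0.42, -0.33, 0.02, -0.01))
  expect_identical(cx@metadata$chargesSource[["ligand"]], "sdf-data-field")
  # disjoint global index spaces
  expect_equal(intersect(rec$index, lig$index), integer(0))
})

test_that("MOL2 ligands carry atom-block charges", {
  cx <- readComplex(extdata("toy_receptor.pdb"), extdata("toy_ligand.mol2"))
  expect_equal(ligandAtoms(cx)$charge, c(0.12, -0.42, -0.33, 0.02, -0.01))
  expect_identical(cx@metadata$chargesSource[["ligand"]], "mol2")
})

test_that("a minimal receptor/ligand pair reads with the right counts", {
  rec <- tempfile(fileext = ".pdb"); lig <- tempfile(fileext = ".sdf")
  writeLines(c(
    "ATOM      1  C1  POC A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  O1  POC A   1       3.000   0.000   0.000  1.00  0.00           O",
    "ATOM      3  N1  POC A   1       0.000   3.000   0.000  1.00  0.00           N",
    "HETATM    4  O   HOH A   9       9.000   9.000   9.000  1.00  0.00           O",
    "END"), rec)
  writeLines(c("m", "", "", "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    1.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END", "$$$$"), lig)
  cx <- readComplex(rec, lig)
  expect_equal(nrow(receptorAtoms(cx)), 3)   # water excluded
  expect_equal(nrow(ligandAtoms(cx)), 1)
})

test_that("empty or unreadable ligands raise input errors", {
  lig <- tempfile(fileext = ".xyz")
  writeLines("not a ligand", lig)
  expect_error(readComplex(extdata("toy_receptor.pdb"), lig),
               "unsupported ligand format")
  expect_error(readComplex(tempfile(), extdata("toy_ligand.sdf")),
               "not found")
})

test_that("XS typing follows the carbon/donor/acceptor rules", {
  # methane-like carbon (no heteroatom neighbor) is hydrophobic; a carbon
  # bonded to oxygen is not; hydroxyl oxygen is donor+acceptor; amide-like
  # N-H is a donor
  # amide-like N: two heavy neighbors plus H -> donor only; an amine-like
  # N with a lone pair left (fewer connections) is donor + acceptor
  cx <- makeComplex("t",
    receptor = data.frame(
      element = c("C", "C", "O", "H", "N", "H", "C", "C"),
      x = c(0, 10, 11.2, 11.5, 20, 20.4, 21.4, 18.9),
      y = c(0, 0, 0.6, 1.5, 0, 0.9, -0.6, -0.9),
      z = 0),
    ligand = data.frame(element = "C", x = 0, y = 0, z = 30))
  t <- receptorAtoms(cx)$xsType
  expect_identical(t[1], "AliphaticCarbonXSHydrophobe")
  expect_identical(t[2], "AliphaticCarbonXSNonHydrophobe")
  expect_identical(t[3], "OxygenXSDonorAcceptor")
  expect_identical(t[4], "PolarHydrogen")
  expect_identical(t[5], "NitrogenXSDonor")
  expect_identical(t[7], "AliphaticCarbonXSNonHydrophobe")
})

test_that("assignXSTypes is idempotent and radii are positive", {
  cx <- readComplex(extdata("toy_receptor.pdb"), extdata("toy_ligand.sdf"))
  cx2 <- assignXSTypes(cx)
  expect_identical(receptorAtoms(cx), receptorAtoms(cx2))
  expect_identical(ligandAtoms(cx), ligandAtoms(cx2))
  heavy <- !receptorAtoms(cx)$isHydrogen
  expect_true(all(receptorAtoms(cx)$vdwRadius[heavy] > 0))
})

test_that("attribution PDB clamps, filters and round-trips coordinates", {
  cx <- readComplex(extdata("toy_receptor.pdb"), extdata("toy_ligand.sdf"))
  rec <- receptorAtoms(cx)
  vals <- c(0.30, 0.010, -0.10)
  names(vals) <- rec$index[!rec$isHydrogen][1:3]
  out <- tempfile(fileext = ".pdb")
  b <- writeAttributionPDB(cx, vals, out)
  expect_equal(unname(b[match(as.integer(names(vals)),
                              c(rec$index, ligandAtoms(cx)$index))]),
               c(0.15, 0.00, -0.10))
  # display filter off keeps small values
  b2 <- writeAttributionPDB(cx, vals, out, displayFilter = FALSE)
  expect_equal(unname(b2[match(as.integer(names(vals))[2],
                               c(rec$index, ligandAtoms(cx)$index))]), 0.01)
  back <- bio3d::read.pdb(out)
  expect_equal(nrow(back$atom), nrow(rec) + nrow(ligandAtoms(cx)))
  orig <- rbind(rec[, c("x", "y", "z")],
                ligandAtoms(cx)[, c("x", "y", "z")])
  expect_equal(back$atom$x, orig$x, tolerance = 1e-3)
  expect_equal(sort(back$atom$b)[1], -0.10, tolerance = 1e-9)
})

test_that("bond inference matches covalent geometry", {
  at <- data.frame(element = c("C", "O", "C"),
                   x = c(0, 1.43, 8), y = 0, z = 0)
  b <- inferBonds(at)
  expect_equal(nrow(b), 1)
  expect_equal(sort(b[1, ]), c(1, 2))
})
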