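test_that("a minimal one-line PDB parses into a single non-hetero atom", {
  p <- writePdbText(pdbLine(1, "CA", "ALA", "A", 1, 1, 2, 3))
  x <- readStructure(p)
  a <- atoms(x)
  expect_equal(nrow(a), 1)
  expect_equal(a$name, "CA")
  expect_equal(a$resName, "ALA")
  expect_false(a$isHetero)
  expect_equal(c(a$x, a$y, a$z), c(1, 2, 3))
})

test_that("alt-loc groups keep the highest-occupancy conformer, ties alphabetical", {
  p <- writePdbText(c(
    pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "B"),
    pdbLine(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, alt = "A")
  ))
  a <- atoms(readStructure(p))
  expect_equal(nrow(a), 1)
  expect_equal(a$altLoc, "A")
  expect_equal(a$occupancy, 0.6)
  # tie -> alphabetically first altLoc
  p2 <- writePdbText(c(
    pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, alt = "B"),
    pdbLine(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.5, alt = "A")
  ))
  expect_equal(atoms(readStructure(p2))$altLoc, "A")
})

test_that("waters are flagged and forced hetero; hydrogens are dropped", {
  p <- writePdbText(c(
    pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbLine(2, "HA", "ALA", "A", 1, 0.5, 0, 0, el = "H"),
    pdbLine(3, "O", "HOH", "W", 2, 5, 5, 5, el = "O", record = "HETATM"),
    pdbLine(4, "O", "WAT", "W", 3, 8, 5, 5, el = "O")  # water via ATOM record
  ))
  a <- atoms(readStructure(p))
  expect_equal(nrow(a), 3)  # hydrogen removed
  expect_false(any(a$element == "H"))
  expect_equal(sum(a$isWater), 2)
  expect_true(all(a$isHetero[a$isWater]))
})

test_that("multi-model files keep the first model with a warning; garbage errors", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
               "ENDMDL", "MODEL     2",
               pdbLine(1, "CA", "ALA", "A", 1, 9, 9, 9), "ENDMDL", "END"), p)
  expect_warning(x <- readStructure(p), "first")
  expect_equal(nAtoms(x), 1)
  expect_equal(atoms(x)$x, 0)
  expect_error(readStructure(tempfile()), "cannot read")
})

test_that("writing and re-reading preserves counts, coordinates and residue ids", {
  fixtures <- list(
    makeFixture("single_atom"),
    makeFixture("dimer", separation = 3.4),
    makeFixture("cluster", nAtoms = 20, seed = 5),
    makeFixture("hollow_shell", shellRadius = 6, center = "water"),
    makeFixture("toy_chain", nRes = 8, seed = 2)
  )
  for (x in fixtures) {
    p <- tempfile(fileext = ".pdb")
    writeStructure(x, p)
    y <- readStructure(p)
    a <- atoms(x); b <- atoms(y)
    expect_equal(nrow(b), nrow(a))
    expect_equal(round(b$x, 3), round(a$x, 3))
    expect_equal(round(b$y, 3), round(a$y, 3))
    expect_equal(round(b$z, 3), round(a$z, 3))
    expect_equal(voropack:::.residueKey(b), voropack:::.residueKey(a))
    expect_equal(b$isWater, a$isWater)
  }
})

test_that("radius assignment follows the bundled table with element and generic fallbacks", {
  tabFile <- system.file("extdata", "united_atom_radii.tsv", package = "voropack")
  ref <- read.delim(tabFile, comment.char = "#")
  alaCA <- ref$radius[ref$res_name == "ALA" & ref$atom_name == "CA"]
  elC <- ref$radius[ref$res_name == ".ELEMENT" & ref$atom_name == "C"]
  default <- ref$radius[ref$res_name == ".DEFAULT"]

  p <- writePdbText(c(
    pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbLine(2, "C9", "LIG", "A", 2, 5, 0, 0, record = "HETATM", el = "C"),
    pdbLine(3, "QQ", "LIG", "A", 2, 8, 0, 0, record = "HETATM", el = "ZQ"),
    pdbLine(4, "O", "HOH", "W", 3, 12, 0, 0, record = "HETATM", el = "O")
  ))
  x <- readStructure(p)
  expect_warning(x <- assignRadii(x), "generic default")
  r <- atomRadii(x)
  expect_equal(r[1], alaCA)
  expect_equal(r[2], elC)        # element fallback
  expect_equal(r[3], default)    # generic default
  expect_equal(r[4], ref$radius[ref$res_name == "HOH" & ref$atom_name == "O"])
  expect_equal(x@nFallbackRadii, 2L)
  expect_true(all(r > 0))
})

test_that("hydrophobicity classification uses < 0 and the closed interval [0, 1.45]", {
  cls <- classifyHydrophobicity(c(-0.6, 0.0, 0.7, 1.45, 2.0))
  expect_equal(as.character(cls),
               c("hydrophobic", "medium_polar", "medium_polar",
                 "medium_polar", "polar"))
  expect_equal(as.character(classifyHydrophobicity(c("ILE", "SER", "ASP"))),
               c("hydrophobic", "medium_polar", "polar"))
  expect_message(u <- classifyHydrophobicity("XYZ"), "medium polar")
  expect_equal(as.character(u), "medium_polar")
  # the classification partitions the real line: exactly one class always
  set.seed(1)
  v <- c(runif(200, -5, 5), 0, 1.45, -1e-12, 1.45 + 1e-12)
  expect_false(anyNA(classifyHydrophobicity(v)))
})

test_that("water policies: keep_all is identity, remove_all drops, internal_only needs flags", {
  sw <- makeFixture("hollow_shell", shellRadius = 7, center = "water")
  expect_identical(atoms(applyWaterPolicy(sw, "keep_all")), atoms(sw))
  expect_equal(sum(atoms(applyWaterPolicy(sw, "remove_all"))$isWater), 0)
  expect_error(applyWaterPolicy(sw, "internal_only"), "burial flags")
})

test_that("internal_only keeps a water sealed in a void and drops surface waters", {
  sw <- makeFixture("hollow_shell", shellRadius = 7, center = "water")
  wb <- classifyWaterBurial(sw, gridSpec(0.4))
  kept <- applyWaterPolicy(sw, "internal_only", waterBuried = wb)
  expect_equal(sum(atoms(kept)$isWater), 1)
  # independent check: the probe cannot reach the water position from outside
  dry <- sw
  dry@atoms <- atoms(sw)[!atoms(sw)$isWater, ]
  expect_false(oracleProbeReaches(dry, c(0, 0, 0), h = 0.25))

  # the same water placed on the outside surface is exposed and dropped
  out <- sw
  wi <- which(out@atoms$isWater)
  out@atoms$x[wi] <- 7 + 3  # outside the shell
  wb2 <- classifyWaterBurial(out, gridSpec(0.4))
  expect_equal(sum(atoms(applyWaterPolicy(out, "internal_only",
                                          waterBuried = wb2))$isWater), 0)
})
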