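seGrid <- function(x, h = 0.4, ...) {
  detectVoids(computeSolventExcluded(buildGrid(x, gridSpec(h, ...)), x))
}

test_that("solid clusters have no voids; a sealed shell has exactly one", {
  cl <- makeFixture("cluster", nAtoms = 27, seed = 1, jitter = 0.05)
  expect_equal(unname(labelCounts(seGrid(cl))["void"]), 0L)

  sh <- makeFixture("hollow_shell", shellRadius = 6)
  cavs <- clusterCavities(seGrid(sh))
  expect_equal(nrow(cavs), 1)
  # volume is exactly the voxel count times the voxel volume
  expect_identical(cavs$volume, cavs$nVox * 0.4^3)
  # the chamber radius is the shell radius minus the atom radius
  expect_lt(abs(cavs$eqRadius - (6 - 1.8)) / (6 - 1.8), 0.1)
  # centroid at the shell centre
  expect_lt(sqrt(cavs$cx^2 + cavs$cy^2 + cavs$cz^2), 0.4)
})

test_that("opening a probe-sized mouth dissolves the cavity", {
  op <- makeFixture("hollow_shell", shellRadius = 6, mouth = TRUE)
  expect_equal(nrow(clusterCavities(seGrid(op))), 0)
  # independent flood-fill oracle agrees: the probe reaches the centre
  expect_true(oracleProbeReaches(op, c(0, 0, 0), h = 0.25))
  sealed <- makeFixture("hollow_shell", shellRadius = 6)
  expect_false(oracleProbeReaches(sealed, c(0, 0, 0), h = 0.25))
})

test_that("two disjoint chambers give two cavities ordered by volume", {
  big <- makeFixture("hollow_shell", shellRadius = 6)
  small <- translateStructure(makeFixture("hollow_shell", shellRadius = 5),
                              c(30, 0, 0))
  both <- combineStructures(big, small)
  cavs <- clusterCavities(seGrid(both))
  expect_equal(nrow(cavs), 2)
  expect_equal(cavs$id, 1:2)
  expect_true(cavs$volume[1] > cavs$volume[2])
  expect_lt(abs(cavs$cx[2] - 30), 0.5)
  # every void voxel belongs to exactly one cavity
  g <- seGrid(both)
  expect_identical(sum(cavs$nVox), unname(labelCounts(g)["void"]))
  expect_false(anyDuplicated(unlist(cavs$voxels)) > 0)
})

test_that("lining covers all shell residues; distant heteroatoms are not neighbors", {
  sh <- makeFixture("hollow_shell", shellRadius = 6)
  far <- atoms(sh)[1, ]
  far$serial <- nAtoms(sh) + 1L
  far$resSeq <- nAtoms(sh) + 1L
  far$x <- 6 + 10; far$y <- 0; far$z <- 0   # 10 A beyond the shell surface
  far$isHetero <- TRUE; far$resName <- "LIG"
  withHet <- sh
  withHet@atoms <- rbind(atoms(sh), far)
  g <- seGrid(withHet)
  cavs <- liningResidues(clusterCavities(g), g, withHet)
  expect_equal(length(cavs$lining[[1]]), nAtoms(sh))  # one residue per shell atom
  expect_equal(length(cavs$neighborHet[[1]]), 0)
  expect_equal(length(cavs$containedHet[[1]]), 0)
})

test_that("cavity hydrophobicity averages lining residues once each", {
  sh <- makeFixture("hollow_shell", shellRadius = 6)   # all-ALA lining
  g <- seGrid(sh)
  cavs <- characterizeCavities(liningResidues(clusterCavities(g), g, sh))
  sc <- loadHydrophobicityScale()
  expect_equal(cavs$meanHydrophobicity, unname(sc$values["ALA"]))
  expect_equal(as.character(cavs$polarityClass), "medium_polar")
  # boundary: values -1 and +1 average to 0 -> medium polar
  fake <- cavs
  fake$lining[[1]] <- c("A|1||ILE", "A|2||ASP")  # -0.60 and 3.49
  fake$meanHydrophobicity <- NULL
  fake <- characterizeCavities(fake)
  expect_equal(fake$meanHydrophobicity, (sc$values[["ILE"]] + sc$values[["ASP"]]) / 2)
  fake$lining[[1]] <- c("A|1||XAA", "A|2||XAB")  # unknown residues
  expect_equal(as.character(characterizeCavities(fake)$polarityClass), "medium_polar")
})

test_that("cavity types: empty, het-neighbor, revealed-by-removal, het-containing", {
  # type 1: empty chamber, no heteroatoms anywhere
  r1 <- runSingle(makeFixture("hollow_shell", shellRadius = 6))
  expect_equal(r1@cavityTable$type, 1L)

  # type 4: water sealed inside the chamber (waters kept)
  r4 <- runSingle(makeFixture("hollow_shell", shellRadius = 7, center = "water"),
                  water = "all")
  expect_equal(r4@cavityTable$type, 4L)
  expect_true(length(r4@cavityTable$containedHet[[1]]) == 1)

  # type 2: a heteroatom embedded in the wall is a direct neighbor
  sh <- makeFixture("hollow_shell", shellRadius = 6)
  a <- atoms(sh)
  a$isHetero[1] <- TRUE
  a$resName[1] <- "LIG"
  wall <- sh
  wall@atoms <- a
  r2 <- runSingle(wall)
  expect_equal(r2@cavityTable$type, 2L)
  expect_equal(r2@cavityTable$neighborHet[[1]], a$serial[1])

  # type 3: a ligand-filled chamber only shows up in the het-free rerun
  r3 <- runSingle(makeFixture("hollow_shell", shellRadius = 6, center = "ligand"))
  expect_equal(r3@cavityTable$type, 3L)

  # the het-free rerun is mandatory once heteroatoms are present
  g <- seGrid(wall)
  cavs <- liningResidues(clusterCavities(g), g, wall)
  expect_error(classifyCavityTypes(cavs, wall, g, hetFree = NULL), "het-free")
})

test_that("every type-4 cavity overlaps a cavity of the het-free rerun", {
  sw <- makeFixture("hollow_shell", shellRadius = 7, center = "water")
  r <- runSingle(sw, water = "all")
  t4 <- r@cavityTable[r@cavityTable$type == 4L, ]
  expect_gt(nrow(t4), 0)
  dry <- sw
  dry@atoms <- atoms(sw)[!atoms(sw)$isHetero, ]
  gHF <- seGrid(dry)
  hfCavs <- clusterCavities(gHF)
  hfKeys <- unlist(lapply(hfCavs$voxels,
                          function(v) voropack:::.globalVoxelKeys(gHF, v)))
  gStd <- seGrid(sw)
  for (ci in seq_len(nrow(t4)))
    expect_true(any(voropack:::.globalVoxelKeys(gStd, t4$voxels[[ci]]) %in% hfKeys))
})

test_that("cavity volumes are invariant under atom reordering", {
  sh <- makeFixture("hollow_shell", shellRadius = 6)
  set.seed(99)
  perm <- sample(nAtoms(sh))
  sh2 <- sh
  sh2@atoms <- atoms(sh)[perm, ]
  sh2@atoms$serial <- seq_len(nrow(sh2@atoms))
  rownames(sh2@atoms) <- NULL
  c1 <- clusterCavities(seGrid(sh))
  c2 <- clusterCavities(seGrid(sh2))
  expect_identical(c1$nVox, c2$nVox)
})

test_that("a sealed chamber's void volume does not grow as the probe shrinks", {
  # in the continuum the probe-swept chamber is probe-independent here
  # (the probe, wherever it fits, sweeps out to the chamber wall), so at a
  # fixed grid the counts may differ only by boundary-layer quantization
  sh <- makeFixture("hollow_shell", shellRadius = 6)
  nv <- vapply(c(1.4, 1.0, 0.7), function(p) {
    g <- seGrid(sh, probeRadius = p)
    as.numeric(labelCounts(g)["void"])
  }, numeric(1))
  expect_true(all(diff(nv) <= 0.03 * nv[1]))
  expect_true(all(abs(nv - nv[1]) <= 0.03 * nv[1]))
})
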