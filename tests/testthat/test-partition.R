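test_that("equal spheres split at the midplane; weighted distance decides otherwise", {
  # equal radii: a voxel just on atom 1's side of the midplane belongs to 1
  d <- makeFixture("dimer", radii = c(1.8, 1.8), separation = 3.4)
  g <- buildGrid(d, gridSpec(0.2))
  g <- detectVoids(computeSolventExcluded(g, d))
  g <- assignVoxels(g, d)
  vi <- voropack:::.pointVoxel(g, rbind(c(-0.1, 0, 0)))
  expect_equal(voxelOwners(g)[vi], 1L)
  vi2 <- voropack:::.pointVoxel(g, rbind(c(0.1, 0, 0)))
  expect_equal(voxelOwners(g)[vi2], 2L)

  # r1 = 2.0 at x = 0, r2 = 1.5 at x = 6; at x = 3.3 the weighted distances
  # are 1.3 vs 1.2, so the smaller, farther-in-Euclidean-terms atom wins.
  # A 2.2 A probe keeps that point solvent-excluded (ownership itself does
  # not depend on the probe).
  d2 <- translateStructure(makeFixture("dimer", radii = c(2.0, 1.5),
                                       separation = 6), c(3, 0, 0))
  g2 <- buildGrid(d2, gridSpec(0.2, probeRadius = 2.2, padding = 7, snap = FALSE))
  g2 <- detectVoids(computeSolventExcluded(g2, d2))
  g2 <- assignVoxels(g2, d2)
  vi3 <- voropack:::.pointVoxel(g2, rbind(c(3.3, 0, 0)))
  expect_equal(voropack:::.voxelCenters(g2, vi3)[1], 3.3, tolerance = 1e-9)
  expect_true(voxelLabels(g2)[vi3] %in% 1:2)
  expect_equal(voxelOwners(g2)[vi3], 2L)
})

test_that("a single atom owns every solvent-excluded voxel", {
  x <- makeFixture("single_atom")
  g <- assignVoxels(detectVoids(computeSolventExcluded(
    buildGrid(x, gridSpec(0.4)), x)), x)
  own <- voxelOwners(g)
  lab <- voxelLabels(g)
  expect_true(all(own[lab %in% 1:2] == 1L))
  expect_true(all(own[!(lab %in% 1:2)] == 0L))
})

test_that("spatial-index ownership equals the exhaustive argmin on small fixtures", {
  fixtures <- list(
    makeFixture("dimer", radii = c(1.8, 1.8), separation = 3.4),
    makeFixture("cluster", nAtoms = 20, seed = 3),
    makeFixture("cluster", nAtoms = 50, seed = 9),
    makeFixture("toy_chain", nRes = 10, seed = 6)
  )
  for (x in fixtures) {
    g <- assignVoxels(detectVoids(computeSolventExcluded(
      buildGrid(x, gridSpec(0.4)), x)), x)
    idx <- which(voxelLabels(g) %in% 1:2)
    expect_identical(voxelOwners(g)[idx], oracleOwners(g, x, idx))
    gb <- assignVoxels(g, x, bruteForce = TRUE)
    expect_identical(voxelOwners(g), voxelOwners(gb))
  }
})

test_that("packing densities follow PD = vVdw / (vVdw + vSe) and stay in [0, 1]", {
  x <- makeFixture("single_atom", radius = 1.88)
  g <- assignVoxels(detectVoids(computeSolventExcluded(
    buildGrid(x, gridSpec(0.2)), x)), x)
  v <- accumulateVolumes(g, x)
  expect_equal(v$packingDensity, v$vVdw / (v$vVdw + v$vSe))
  expect_gt(v$packingDensity, 0.97)  # isolated sphere: SE region ~ vdW sphere

  cl <- makeFixture("cluster", nAtoms = 30, seed = 2)
  gc_ <- assignVoxels(detectVoids(computeSolventExcluded(
    buildGrid(cl, gridSpec(0.4)), cl)), cl)
  vc <- accumulateVolumes(gc_, cl)
  pd <- vc$packingDensity[!vc$noVolume]
  expect_true(all(pd >= 0 & pd <= 1))
})

test_that("residue packing is the pooled volume-weighted density", {
  # two atoms, PD 1.0 (10 + 0) and 0.5 (10 + 10) -> pooled 20/30
  vols <- data.frame(serial = 1:2, vVdw = c(10, 10), vSe = c(0, 10))
  x <- makeFixture("dimer", separation = 4)
  # the dimer's atoms are separate residues: per-residue PD equals atom PD
  rp <- residuePacking(vols, x)
  expect_equal(rp$packingDensity, c(1, 0.5))
  # pooling them into one residue gives the volume-weighted 20/30
  one <- x
  one@atoms$resSeq <- 1L
  rp1 <- residuePacking(vols, one)
  expect_equal(rp1$packingDensity, 2 / 3)

  # a one-residue structure pools across its atoms
  ch <- makeFixture("toy_chain", nRes = 3, seed = 8)
  g <- assignVoxels(detectVoids(computeSolventExcluded(
    buildGrid(ch, gridSpec(0.4)), ch)), ch)
  v <- accumulateVolumes(g, ch)
  rp2 <- residuePacking(v, ch)
  key <- voropack:::.residueKey(atoms(ch))
  for (k in unique(key)) {
    sel <- key == k
    expect_equal(rp2$packingDensity[match(k, paste(rp2$chainId, rp2$resSeq,
                                                   rp2$iCode, rp2$resName,
                                                   sep = "|"))],
                 sum(v$vVdw[sel]) / sum(v$vVdw[sel] + v$vSe[sel]))
  }
})

test_that("atoms and residues with no assigned volume get sentinels", {
  # a tiny atom engulfed by a big one never wins the weighted distance
  d <- makeFixture("dimer", radii = c(1.88, 0.3), separation = 0.4)
  g <- assignVoxels(detectVoids(computeSolventExcluded(
    buildGrid(d, gridSpec(0.2)), d)), d)
  v <- accumulateVolumes(g, d)
  expect_true(v$noVolume[2])
  expect_true(is.na(v$packingDensity[2]))
  rp <- residuePacking(v, d)
  expect_equal(rp$packingDensity[rp$resSeq == 2], 0)
  expect_true(rp$noVolume[rp$resSeq == 2])
})

test_that("partition conservation is exact in voxel counts, voids included", {
  fixtures <- list(
    makeFixture("hollow_shell", shellRadius = 6),
    makeFixture("cluster", nAtoms = 40, seed = 12),
    makeFixture("toy_chain", nRes = 12, seed = 3)
  )
  for (x in fixtures) {
    g <- assignVoxels(detectVoids(computeSolventExcluded(
      buildGrid(x, gridSpec(0.4)), x)), x)
    v <- accumulateVolumes(g, x)
    ct <- labelCounts(g)
    expect_identical(sum(v$nVdw) + sum(v$nSe) + unname(ct["void"]),
                     unname(ct["se_envelope"] + ct["inside_vdw"] + ct["void"]))
  }
})

test_that("compacting a cluster raises its mean packing density", {
  x1 <- makeFixture("cluster", nAtoms = 13, seed = 7, scale = 1)
  x2 <- makeFixture("cluster", nAtoms = 13, seed = 7, scale = 1.3)
  pd <- vapply(list(x1, x2), function(x) {
    g <- assignVoxels(detectVoids(computeSolventExcluded(
      buildGrid(x, gridSpec(0.4)), x)), x)
    mean(accumulateVolumes(g, x)$packingDensity, na.rm = TRUE)
  }, numeric(1))
  expect_gt(pd[1], pd[2])
})
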