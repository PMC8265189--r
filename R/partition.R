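#' Assign solvent-excluded voxels to atoms (weighted Voronoi)
#'
#' Every `inside_vdw` and `se_envelope` voxel is assigned to the atom
#' minimizing the additively weighted distance
#' `|voxel centre - atom centre| - radius` (an Apollonius diagram, whose
#' bisectors are hyperboloid sheets). Ties are broken by the lowest atom
#' serial. The production path restricts the search to atoms within
#' `radius + probeRadius + 2 * spacing` of each voxel and falls back to an
#' exhaustive scan wherever that bound cannot certify the winner, so the
#' result always equals the brute-force argmin over all atoms
#' (`bruteForce = TRUE` runs the exhaustive scan everywhere).
#'
#' Run [detectVoids()] first: void voxels belong to cavities, not atoms,
#' and are not assigned.
#'
#' @param grid a labelled [VoxelGrid-class].
#' @param x the corresponding [AtomSet-class].
#' @param bruteForce use the exhaustive scan for every voxel.
#' @return the grid with voxel ownership filled in.
#' @export
assignVoxels <- function(grid, x, bruteForce = FALSE) {
  if (!length(grid@flags)) stop("label the grid first (computeSolventExcluded)")
  a <- atoms(x)
  grid@owner <- cpp_assign_owners(grid@flags, grid@origin, grid@spacing,
                                  grid@dims, atomCoords(x), a$radius,
                                  a$serial, grid@probeRadius, bruteForce)
  grid
}

#' Accumulate per-atom volumes and packing densities
#'
#' For each atom, `vVdw` is the volume of its owned voxels inside its own
#' vdW sphere and `vSe` the owned solvent-excluded volume outside it (void
#' voxels are excluded — they belong to cavities). The packing density is
#' `PD = vVdw / (vVdw + vSe)`; atoms that own no voxels get `NA` and
#' `noVolume = TRUE`.
#'
#' @param grid a [VoxelGrid-class] with ownership assigned.
#' @param x the corresponding [AtomSet-class].
#' @param burial optional data.frame from [classifyBurial()]; merged in as
#'   a `buried` column.
#' @return data.frame with one row per atom: identifiers, integer voxel
#'   counts (`nVdw`, `nSe`), volumes in Angstrom^3, `packingDensity` and
#'   flags.
#' @export
accumulateVolumes <- function(grid, x, burial = NULL) {
  if (!length(grid@owner)) stop("assign voxel ownership first (assignVoxels)")
  a <- atoms(x)
  counts <- cpp_accumulate(grid@flags, grid@owner, nrow(a))
  h3 <- grid@spacing^3
  out <- data.frame(
    serial = a$serial, name = a$name, resName = a$resName,
    chainId = a$chainId, resSeq = a$resSeq, iCode = a$iCode,
    isHetero = a$isHetero, isWater = a$isWater,
    nVdw = counts[, 1], nSe = counts[, 2],
    vVdw = counts[, 1] * h3, vSe = counts[, 2] * h3
  )
  tot <- out$vVdw + out$vSe
  out$packingDensity <- ifelse(tot > 0, out$vVdw / tot, NA_real_)
  out$noVolume <- tot == 0
  if (!is.null(burial))
    out$buried <- burial$buried[match(out$serial, burial$serial)]
  out
}

#' Pool packing density per residue
#'
#' The residue packing density is the volume-weighted (pooled) value
#' `sum(vVdw) / sum(vVdw + vSe)` over the residue's atoms. Residues with
#' zero assigned volume get the sentinel 0 and `noVolume = TRUE`.
#'
#' @param volumes data.frame from [accumulateVolumes()].
#' @param x the corresponding [AtomSet-class].
#' @return data.frame with one row per residue: identifiers,
#'   `packingDensity`, `nAtoms`, `nBuriedAtoms`, `noVolume`.
#' @export
residuePacking <- function(volumes, x) {
  a <- atoms(x)
  key <- .residueKey(a)
  ord <- !duplicated(key)
  vv <- tapply(volumes$vVdw, key, sum)
  vt <- tapply(volumes$vVdw + volumes$vSe, key, sum)
  keys <- key[ord]
  out <- data.frame(
    chainId = a$chainId[ord], resSeq = a$resSeq[ord],
    iCode = a$iCode[ord], resName = a$resName[ord],
    nAtoms = as.integer(table(key)[keys]),
    packingDensity = unname(ifelse(vt[keys] > 0, vv[keys] / vt[keys], 0)),
    noVolume = unname(vt[keys] == 0),
    nBuriedAtoms = if ("buried" %in% names(volumes))
      as.integer(tapply(volumes$buried %in% TRUE, key, sum)[keys])
    else NA_integer_
  )
  rownames(out) <- NULL
  out
}
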