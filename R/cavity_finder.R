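#' Detect buried internal voids
#'
#' A void is buried space large enough to accommodate a water-size probe
#' (1.4 A). Seed voxels are solvent-excluded envelope voxels where a probe
#' centre fits (weighted distance to every atom >= probeRadius) but which
#' are not probe-accessible from the boundary; the void region is the
#' probe-swept volume of those seeds — their dilation by
#' `probeRadius + spacing/2`, restricted to envelope voxels — mirroring how
#' the solvent region is built from the accessible set. Sub-probe crevices
#' contain no seed and keep the `se_envelope` label (they are assigned to
#' atoms by the partition).
#'
#' @param grid a labelled [VoxelGrid-class] (after
#'   [computeSolventExcluded()]).
#' @return the grid with qualifying voxels relabelled `void`.
#' @export
detectVoids <- function(grid) {
  if (!length(grid@flags)) stop("label the grid first (computeSolventExcluded)")
  grid@flags <- cpp_detect_voids(grid@flags, grid@dims, grid@spacing,
                                 grid@probeRadius, grid@spacing / 2)
  grid
}

#' Cluster void voxels into cavities
#'
#' 26-connected components of void voxels. Volume is
#' `spacing^3 * voxel count`, the centroid is the mean of voxel centres and
#' the equivalent radius is that of the equal-volume sphere. Ids are
#' deterministic: descending volume, then lexicographic centroid.
#'
#' @param grid a [VoxelGrid-class] after [detectVoids()].
#' @return data.frame with one row per cavity: `id`, `nVox`, `volume`,
#'   `cx`, `cy`, `cz`, `eqRadius` and a `voxels` list-column of linear
#'   voxel indices.
#' @export
clusterCavities <- function(grid) {
  if (!length(grid@flags)) stop("label the grid first (computeSolventExcluded)")
  comp <- cpp_void_components(grid@flags, grid@dims)
  idx <- which(comp > 0L)
  empty <- data.frame(id = integer(), nVox = integer(), volume = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      eqRadius = numeric())
  empty$voxels <- list()
  if (!length(idx)) return(empty)
  grp <- split(idx, comp[idx])
  h3 <- grid@spacing^3
  geo <- lapply(grp, function(vx) {
    ctr <- .voxelCenters(grid, vx)
    c(n = length(vx), colMeans(ctr))
  })
  geo <- do.call(rbind, geo)
  n <- geo[, 1]
  ord <- order(-n, geo[, 2], geo[, 3], geo[, 4])
  out <- data.frame(
    id = seq_along(ord), nVox = as.integer(n[ord]), volume = n[ord] * h3,
    cx = geo[ord, 2], cy = geo[ord, 3], cz = geo[ord, 4],
    eqRadius = (3 * n[ord] * h3 / (4 * pi))^(1 / 3)
  )
  out$voxels <- unname(grp[ord])
  rownames(out) <- NULL
  out
}

#' Find cavity-lining residues and neighboring heteroatoms
#'
#' A residue lines a cavity when at least one of its atoms has its vdW
#' surface within `cutoff` (default 2.8 A, one water diameter) of a cavity
#' voxel centre; heteroatoms satisfying the same criterion are recorded as
#' neighbors. Heteroatoms *contained* in the cavity are detected with the
#' help of the het-free rerun when available: a het atom is contained if
#' its centre's voxel is void space once heteroatoms are removed and its
#' vdW surface lies within the probe radius of the cavity. Without a
#' het-free grid the fallback is centre-in-cavity (dilated by one voxel).
#'
#' @param cavities data.frame from [clusterCavities()].
#' @param grid the [VoxelGrid-class] the cavities were found in.
#' @param x the corresponding [AtomSet-class].
#' @param cutoff contact cutoff in Angstrom (vdW surface to voxel centre).
#' @param hetFreeGrid optional [VoxelGrid-class] from the het-free rerun
#'   (same spacing, snapped origins).
#' @return `cavities` with list-columns `lining` (residue keys
#'   `"chain|resSeq|iCode|resName"`), `liningSerials`, `neighborHet` and
#'   `containedHet` (heteroatom serials).
#' @export
liningResidues <- function(cavities, grid, x, cutoff = 2.8, hetFreeGrid = NULL) {
  a <- atoms(x)
  key <- .residueKey(a)
  xyz <- atomCoords(x)
  hetFreeVoidKeys <- NULL
  if (!is.null(hetFreeGrid) && length(hetFreeGrid@flags)) {
    vidx <- which(voxelLabels(hetFreeGrid) == 3L)
    hetFreeVoidKeys <- .globalVoxelKeys(hetFreeGrid, vidx)
  }
  lining <- liningSerials <- neighborHet <- containedHet <- vector("list", nrow(cavities))
  for (ci in seq_len(nrow(cavities))) {
    ctr <- .voxelCenters(grid, cavities$voxels[[ci]])
    # min weighted distance from each atom's vdW surface to the cavity voxels
    mind <- vapply(seq_len(nrow(a)), function(ai) {
      d <- sqrt((ctr[, 1] - xyz[ai, 1])^2 + (ctr[, 2] - xyz[ai, 2])^2 +
                  (ctr[, 3] - xyz[ai, 3])^2)
      min(d) - a$radius[ai]
    }, numeric(1))
    near <- mind <= cutoff
    lin <- near & !a$isHetero
    if (!any(near))
      stop("cavity ", cavities$id[ci], " has an empty lining; ",
           "this should be impossible for a buried void")
    lining[[ci]] <- unique(key[lin])
    liningSerials[[ci]] <- a$serial[lin]
    hetNear <- near & a$isHetero
    if (!is.null(hetFreeVoidKeys)) {
      inVoid <- rep(FALSE, nrow(a))
      hk <- .pointVoxel(hetFreeGrid, xyz)
      ok <- !is.na(hk)
      inVoid[ok] <- .globalVoxelKeys(hetFreeGrid, hk[ok]) %in% hetFreeVoidKeys
      contained <- a$isHetero & inVoid & mind <= grid@probeRadius
    } else {
      # literal fallback: centre within the cavity voxel set dilated by one voxel
      keys <- .globalVoxelKeys(grid, cavities$voxels[[ci]])
      av <- .pointVoxel(grid, xyz)
      contained <- rep(FALSE, nrow(a))
      ok <- a$isHetero & !is.na(av)
      if (any(ok)) {
        akeys <- .globalVoxelKeys(grid, av[ok])
        off <- expand.grid(c(-1, 0, 1), c(-65536, 0, 65536),
                           c(-(65536^2), 0, 65536^2))
        offs <- rowSums(off)
        contained[ok] <- vapply(akeys, function(k) any((k + offs) %in% keys),
                                logical(1))
      }
    }
    containedHet[[ci]] <- a$serial[contained]
    neighborHet[[ci]] <- setdiff(a$serial[hetNear], containedHet[[ci]])
  }
  cavities$lining <- lining
  cavities$liningSerials <- liningSerials
  cavities$neighborHet <- neighborHet
  cavities$containedHet <- containedHet
  cavities
}

#' Average hydrophobicity and polarity class of cavities
#'
#' The mean hydrophobicity is the unweighted mean of the scale values over
#' the lining residues (each residue counted once); the polarity class uses
#' the same cutoffs as residues (< 0 hydrophobic, \[0, 1.45\] medium polar,
#' > 1.45 polar). Lining residues absent from the scale are ignored in the
#' mean; a cavity whose lining is entirely unknown is classed medium polar
#' with `NA` mean.
#'
#' @param cavities data.frame from [liningResidues()].
#' @param scale a scale from [loadHydrophobicityScale()].
#' @return `cavities` with `meanHydrophobicity` and `polarityClass`.
#' @export
characterizeCavities <- function(cavities, scale = loadHydrophobicityScale()) {
  mh <- vapply(cavities$lining, function(keys) {
    res <- vapply(strsplit(keys, "|", fixed = TRUE), `[`, character(1), 4)
    v <- scale$values[res]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  cls <- ifelse(is.na(mh), "medium_polar",
                as.character(classifyHydrophobicity(ifelse(is.na(mh), 0, mh), scale)))
  cavities$meanHydrophobicity <- mh
  cavities$polarityClass <- factor(cls, levels = c("hydrophobic", "medium_polar", "polar"))
  cavities
}

#' Classify cavities into the four types
#'
#' Type 4: contains heteroatoms. Type 2: empty, but heteroatoms are direct
#' neighbors. Type 1: empty with no heteroatom neighbors. Type 3: a cavity
#' that only appears when the heteroatoms are removed — found in the
#' het-free rerun and sharing no voxel (on the global lattice) with any
#' type-1/2/4 cavity of the standard run; such cavities are appended to the
#' result with their het-free geometry.
#'
#' @param cavities standard-run cavities from [liningResidues()] /
#'   [characterizeCavities()].
#' @param x the analysed [AtomSet-class].
#' @param grid the standard-run [VoxelGrid-class].
#' @param hetFree `NULL`, or a list with elements `grid` and `cavities`
#'   (the het-free rerun, already lined/characterized). Required when the
#'   structure contains heteroatoms (unless the het-free structure would be
#'   empty).
#' @return the combined cavity data.frame with a `type` column (integer
#'   1-4).
#' @export
classifyCavityTypes <- function(cavities, x, grid, hetFree = NULL) {
  a <- atoms(x)
  hasHet <- any(a$isHetero)
  if (hasHet && is.null(hetFree) && sum(!a$isHetero) > 0)
    stop("structure contains heteroatoms: the het-free rerun is required ",
         "to classify cavity types")
  type <- integer(nrow(cavities))
  for (ci in seq_len(nrow(cavities))) {
    if (length(cavities$containedHet[[ci]])) type[ci] <- 4L
    else if (length(cavities$neighborHet[[ci]])) type[ci] <- 2L
    else type[ci] <- 1L
  }
  cavities$type <- type
  if (is.null(hetFree) || nrow(hetFree$cavities) == 0) return(cavities)

  stdKeys <- if (nrow(cavities))
    unlist(lapply(cavities$voxels, function(v) .globalVoxelKeys(grid, v)))
  else numeric(0)
  hf <- hetFree$cavities
  revealed <- vapply(seq_len(nrow(hf)), function(ci) {
    !any(.globalVoxelKeys(hetFree$grid, hf$voxels[[ci]]) %in% stdKeys)
  }, logical(1))
  if (any(revealed)) {
    add <- hf[revealed, , drop = FALSE]
    add$type <- 3L
    add$id <- if (nrow(cavities)) max(cavities$id) + seq_len(nrow(add))
    else seq_len(nrow(add))
    cavities <- rbind(cavities, add)
    rownames(cavities) <- NULL
  }
  cavities
}
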