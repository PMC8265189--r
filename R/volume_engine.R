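#' Build a voxel grid over a structure
#'
#' The grid covers the atom bounding box plus padding on every side; the
#' default padding, `2 * (probeRadius + max radius) + 2 * spacing`,
#' guarantees that every boundary-face voxel is bulk solvent. With
#' `snap = TRUE` (default) the origin is snapped down to a multiple of the
#' spacing so that voxel centres lie on a global lattice and results are
#' reproducible and comparable across runs.
#'
#' @param x an [AtomSet-class] with radii assigned.
#' @param spec a [GridSpec-class].
#' @return An unlabelled [VoxelGrid-class].
#' @export
buildGrid <- function(x, spec = gridSpec()) {
  a <- atoms(x)
  if (nrow(a) == 0) stop("cannot build a grid over an empty structure")
  if (nrow(a) > spec@maxAtoms)
    stop("structure has ", nrow(a), " atoms, above the configured cap of ",
         spec@maxAtoms)
  r <- a$radius
  if (anyNA(r)) stop("all atoms need radii before building a grid; run assignRadii()")
  h <- spec@spacing
  pad <- spec@padding
  if (is.na(pad)) pad <- 2 * (spec@probeRadius + max(r)) + 2 * h
  lo <- c(min(a$x - r), min(a$y - r), min(a$z - r)) - pad
  hi <- c(max(a$x + r), max(a$y + r), max(a$z + r)) + pad
  origin <- if (spec@snap) h * floor(lo / h) else lo
  dims <- as.integer(ceiling((hi - origin) / h))
  nv <- prod(as.numeric(dims))
  if (nv > spec@voxelCap)
    stop("grid would need ", format(nv, big.mark = ","),
         " voxels (cap ", format(spec@voxelCap, big.mark = ","),
         "); use a coarser spacing")
  new("VoxelGrid", origin = origin, spacing = h,
      probeRadius = spec@probeRadius, dims = dims,
      flags = raw(0), owner = integer(0))
}

#' Label the solvent-excluded region (rolling-probe closure)
#'
#' Morphological closing of the van der Waals body with a spherical probe:
#' (1) voxels whose centre lies within `radius + probeRadius` of an atom
#' centre are probe-excluded; (2) probe-accessible space is flood-filled
#' (6-connectivity) from the grid boundary; (3) voxels within
#' `probeRadius + spacing/2` of the accessible set and outside all vdW
#' spheres revert to solvent (the half-voxel term compensates the lattice
#' quantization of the accessible boundary). What remains is the
#' solvent-excluded region: voxels inside a vdW sphere are labelled
#' `inside_vdw`, the rest `se_envelope` (buried empty space keeps that
#' label until [detectVoids()]).
#'
#' @param grid a [VoxelGrid-class] from [buildGrid()].
#' @param x the same [AtomSet-class] the grid was built for.
#' @return the grid with labels filled in.
#' @export
computeSolventExcluded <- function(grid, x) {
  a <- atoms(x)
  grid@flags <- cpp_se_label(grid@origin, grid@spacing, grid@dims,
                             atomCoords(x), a$radius,
                             grid@probeRadius, grid@spacing / 2)
  grid
}

#' Dump a labelled grid as run-length-encoded text
#'
#' Debug output: one header line (origin, spacing, dims) followed by
#' `label:runlength` pairs in linear voxel order (x fastest).
#'
#' @param grid a labelled [VoxelGrid-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dumpGrid <- function(grid, path) {
  lab <- voxelLabels(grid)
  r <- rle(lab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# origin", paste(sprintf("%.6f", grid@origin), collapse = " "),
                   "spacing", grid@spacing,
                   "dims", paste(grid@dims, collapse = " ")), con)
  writeLines(paste(r$values, r$lengths, sep = ":", collapse = " "), con)
  invisible(path)
}

#' Classify atoms as buried or exposed
#'
#' An atom is exposed iff at least one voxel inside its vdW sphere is
#' 6-adjacent to a solvent voxel; all other atoms are buried. Also reports
#' the per-atom count of such solvent-contact voxels.
#'
#' @param grid a labelled [VoxelGrid-class].
#' @param x the corresponding [AtomSet-class].
#' @return data.frame with `serial`, `buried` (logical) and `nContacts`.
#' @export
classifyBurial <- function(grid, x) {
  if (!length(grid@flags)) stop("label the grid first (computeSolventExcluded)")
  a <- atoms(x)
  res <- cpp_burial(grid@flags, grid@origin, grid@spacing, grid@dims,
                    atomCoords(x), a$radius)
  data.frame(serial = a$serial, buried = !res$exposed,
             nContacts = res$contacts)
}
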