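#' @useDynLib voropack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats runif rnorm setNames sd
#' @importFrom utils read.delim write.table unzip packageVersion head
NULL

.water_names <- c("HOH", "WAT", "H2O", "DOD")

#' AtomSet: a normalized single-model structure
#'
#' Holds one model of a macromolecular structure as an ordered atom table.
#' Atoms are united-atom heavy atoms (hydrogens/deuteriums are dropped on
#' reading); each atom carries its PDB identifiers, coordinates, hetero and
#' water flags and, after [assignRadii()], a van der Waals radius.
#'
#' The atom table columns are: `serial`, `name`, `altLoc`, `resName`,
#' `chainId`, `resSeq`, `iCode`, `x`, `y`, `z`, `element`, `isHetero`,
#' `isWater`, `occupancy`, `bFactor`, `radius`.
#'
#' @slot atoms data.frame with one row per atom (columns above).
#' @slot sourceName character, name of the originating file or fixture.
#' @slot modelNumber integer, model retained from the source (always the
#'   first model of a multi-model file).
#' @slot nFallbackRadii integer, number of atoms whose radius came from an
#'   element or generic fallback during the last [assignRadii()] call.
#' @export
setClass("AtomSet",
  representation(
    atoms = "data.frame",
    sourceName = "character",
    modelNumber = "integer",
    nFallbackRadii = "integer"
  ),
  prototype(
    sourceName = "",
    modelNumber = 1L,
    nFallbackRadii = 0L
  )
)

setValidity("AtomSet", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "altLoc", "resName", "chainId", "resSeq",
            "iCode", "x", "y", "z", "element", "isHetero", "isWater",
            "occupancy", "bFactor", "radius")
  miss <- setdiff(need, names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (anyDuplicated(a$serial)) return("atom serial numbers must be unique")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("atom coordinates must be finite")
    if (any(!is.na(a$radius) & a$radius <= 0))
      return("assigned radii must be positive")
    if (any(a$isWater & !a$isHetero))
      return("water atoms must be flagged hetero after normalization")
  }
  TRUE
})

#' @rdname AtomSet-class
#' @param atoms data.frame of atoms (see class description).
#' @param sourceName name of the source file or fixture.
#' @param modelNumber model number retained.
#' @export
AtomSet <- function(atoms, sourceName = "", modelNumber = 1L) {
  rownames(atoms) <- NULL
  new("AtomSet", atoms = atoms, sourceName = sourceName,
      modelNumber = as.integer(modelNumber))
}

#' GridSpec: voxel grid parameters
#'
#' @slot spacing voxel edge in Angstrom (default 0.4; high accuracy 0.1).
#' @slot probeRadius solvent probe radius in Angstrom (1.4, a water).
#' @slot padding Angstrom added beyond the bounding box on every side;
#'   `NA` means the default `2 * (probeRadius + max radius) + 2 * spacing`,
#'   which guarantees that the grid boundary is bulk solvent.
#' @slot snap snap the grid origin down to a multiple of the spacing so
#'   voxel centres lie on a global lattice (reproducible, comparable grids).
#' @slot voxelCap maximum number of voxels allowed before erroring.
#' @slot maxAtoms maximum number of atoms allowed.
#' @export
setClass("GridSpec",
  representation(spacing = "numeric", probeRadius = "numeric",
                 padding = "numeric", snap = "logical",
                 voxelCap = "numeric", maxAtoms = "numeric"))

setValidity("GridSpec", function(object) {
  if (object@spacing <= 0 || object@spacing > 1)
    return("spacing must be in (0, 1] Angstrom")
  if (object@probeRadius <= 0) return("probeRadius must be positive")
  TRUE
})

#' Construct a GridSpec
#'
#' @param spacing voxel edge (Angstrom); the server presets are 0.4
#'   (default) and 0.1 (high accuracy), but any value in (0, 1] is allowed.
#' @param probeRadius solvent probe radius (Angstrom).
#' @param padding padding beyond the bounding box; `NA` = automatic.
#' @param snap snap the origin to a multiple of the spacing.
#' @param voxelCap maximum voxel count.
#' @param maxAtoms maximum atom count.
#' @return A [GridSpec-class] object.
#' @export
gridSpec <- function(spacing = 0.4, probeRadius = 1.4, padding = NA_real_,
                     snap = TRUE, voxelCap = 6e8, maxAtoms = 1e5) {
  new("GridSpec", spacing = spacing, probeRadius = probeRadius,
      padding = as.numeric(padding), snap = snap,
      voxelCap = voxelCap, maxAtoms = maxAtoms)
}

#' VoxelGrid: labelled cubic grid over a structure
#'
#' Axis-aligned cubic grid whose voxels are labelled bulk solvent (0),
#' solvent-excluded envelope (1), inside a van der Waals sphere (2) or
#' internal void (3). After [assignVoxels()] each solvent-excluded voxel
#' also has an owning atom. The raw `flags` vector additionally records,
#' per voxel, whether a probe centre fits there (bit 2) and whether the
#' voxel is probe-accessible from the boundary (bit 3).
#'
#' @slot origin numeric(3), lower corner of the grid (Angstrom).
#' @slot spacing voxel edge (Angstrom).
#' @slot probeRadius probe radius used for the labelling (Angstrom).
#' @slot dims integer(3), voxels per axis.
#' @slot flags raw vector of per-voxel flags (empty until
#'   [computeSolventExcluded()] is run).
#' @slot owner integer vector of 1-based owning-atom indices (0 = none;
#'   empty until [assignVoxels()] is run).
#' @export
setClass("VoxelGrid",
  representation(origin = "numeric", spacing = "numeric",
                 probeRadius = "numeric", dims = "integer",
                 flags = "raw", owner = "integer"))

setValidity("VoxelGrid", function(object) {
  if (length(object@dims) != 3 || any(object@dims < 1))
    return("dims must be three positive integers")
  n <- prod(as.numeric(object@dims))
  if (length(object@flags) && length(object@flags) != n)
    return("flags length must equal prod(dims)")
  if (length(object@owner) && length(object@owner) != n)
    return("owner length must equal prod(dims)")
  TRUE
})

#' ResultBundle: the products of one packing-density run
#'
#' @slot structure the analysed [AtomSet-class] (after water policy).
#' @slot atomTable per-atom volumes and packing densities.
#' @slot residueTable per-residue pooled packing densities.
#' @slot cavityTable per-cavity geometry and chemistry.
#' @slot files named character vector of written file paths (empty when the
#'   bundle was not written to disk).
#' @slot manifest list of every option that affects the results.
#' @export
setClass("ResultBundle",
  representation(structure = "AtomSet", atomTable = "data.frame",
                 residueTable = "data.frame", cavityTable = "data.frame",
                 files = "character", manifest = "list"))

# ---- accessors ----

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' Atom table of an AtomSet
#' @param x an [AtomSet-class].
#' @return data.frame of atoms.
#' @export
setMethod("atoms", "AtomSet", function(x) x@atoms)

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname atoms
#' @export
setMethod("nAtoms", "AtomSet", function(x) nrow(x@atoms))

#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' Coordinate matrix (n x 3) of an AtomSet
#' @param x an [AtomSet-class].
#' @export
setMethod("atomCoords", "AtomSet", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @export
setGeneric("atomRadii", function(x) standardGeneric("atomRadii"))
#' Assigned van der Waals radii of an AtomSet
#' @param x an [AtomSet-class].
#' @export
setMethod("atomRadii", "AtomSet", function(x) x@atoms$radius)

#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname VoxelGrid-class
#' @param x a [VoxelGrid-class].
#' @export
setMethod("gridDims", "VoxelGrid", function(x) x@dims)

#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname VoxelGrid-class
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname VoxelGrid-class
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @export
setGeneric("voxelLabels", function(x) standardGeneric("voxelLabels"))
#' Per-voxel labels of a VoxelGrid
#'
#' 0 = bulk solvent, 1 = solvent-excluded envelope, 2 = inside vdW sphere,
#' 3 = internal void.
#' @param x a [VoxelGrid-class].
#' @return integer vector of length `prod(gridDims(x))`.
#' @export
setMethod("voxelLabels", "VoxelGrid", function(x) {
  if (!length(x@flags)) stop("grid has not been labelled yet")
  cpp_labels(x@flags)
})

#' @export
setGeneric("voxelOwners", function(x) standardGeneric("voxelOwners"))
#' @rdname voxelLabels
#' @export
setMethod("voxelOwners", "VoxelGrid", function(x) {
  if (!length(x@owner)) stop("voxel ownership has not been assigned yet")
  x@owner
})

#' @export
setGeneric("labelCounts", function(x) standardGeneric("labelCounts"))
#' Voxel counts per label
#' @param x a labelled [VoxelGrid-class].
#' @return named integer vector (solvent, se_envelope, inside_vdw, void).
#' @export
setMethod("labelCounts", "VoxelGrid", function(x) {
  if (!length(x@flags)) stop("grid has not been labelled yet")
  setNames(cpp_count_labels(x@flags),
           c("solvent", "se_envelope", "inside_vdw", "void"))
})

#' @export
setGeneric("seVolume", function(x) standardGeneric("seVolume"))
#' Total solvent-excluded volume of a labelled grid (Angstrom^3)
#' @param x a labelled [VoxelGrid-class].
#' @export
setMethod("seVolume", "VoxelGrid", function(x) {
  ct <- labelCounts(x)
  sum(ct[c("se_envelope", "inside_vdw", "void")]) * x@spacing^3
})

# ---- show methods ----

setMethod("show", "AtomSet", function(object) {
  a <- object@atoms
  cat("AtomSet:", nrow(a), "atoms")
  if (nzchar(object@sourceName)) cat(" from", object@sourceName)
  cat("\n")
  if (nrow(a)) {
    cat("  residues:", length(unique(paste(a$chainId, a$resSeq, a$iCode))),
        " chains:", paste(unique(a$chainId), collapse = ","), "\n")
    cat("  hetero:", sum(a$isHetero), " waters:", sum(a$isWater),
        " radii assigned:", sum(!is.na(a$radius)), "\n")
  }
  invisible(object)
})

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "),
      sprintf("voxels @ %.3g A (probe %.3g A)\n",
              object@spacing, object@probeRadius))
  if (length(object@flags)) {
    ct <- labelCounts(object)
    cat("  labels:", paste(names(ct), ct, sep = "=", collapse = " "), "\n")
    cat(sprintf("  solvent-excluded volume: %.2f A^3\n", seVolume(object)))
  } else cat("  (not yet labelled)\n")
  invisible(object)
})

setMethod("show", "ResultBundle", function(object) {
  cat("ResultBundle:", nrow(object@atomTable), "atoms,",
      nrow(object@residueTable), "residues,",
      nrow(object@cavityTable), "cavities\n")
  if (length(object@files))
    cat("  files:", paste(basename(object@files), collapse = ", "), "\n")
  invisible(object)
})

# residue identity key shared across modules
.residueKey <- function(a) paste(a$chainId, a$resSeq, a$iCode, a$resName, sep = "|")

# global lattice keys for voxel-overlap comparisons between snapped grids
.globalVoxelKeys <- function(grid, idx) {
  nx <- grid@dims[1]; ny <- grid@dims[2]
  i0 <- (idx - 1L) %% nx
  rest <- (idx - 1L) %/% nx
  j0 <- rest %% ny
  k0 <- rest %/% ny
  off <- round(grid@origin / grid@spacing)
  gx <- off[1] + i0; gy <- off[2] + j0; gz <- off[3] + k0
  (gx + 32768) + 65536 * (gy + 32768) + 65536^2 * (gz + 32768)
}

# centres of voxels given linear indices
.voxelCenters <- function(grid, idx) {
  nx <- grid@dims[1]; ny <- grid@dims[2]
  i0 <- (idx - 1L) %% nx
  rest <- (idx - 1L) %/% nx
  j0 <- rest %% ny
  k0 <- rest %/% ny
  cbind(grid@origin[1] + (i0 + 0.5) * grid@spacing,
        grid@origin[2] + (j0 + 0.5) * grid@spacing,
        grid@origin[3] + (k0 + 0.5) * grid@spacing)
}

# linear voxel index of points (NA when outside the grid)
.pointVoxel <- function(grid, pts) {
  pts <- matrix(pts, ncol = 3)
  i0 <- floor((pts[, 1] - grid@origin[1]) / grid@spacing)
  j0 <- floor((pts[, 2] - grid@origin[2]) / grid@spacing)
  k0 <- floor((pts[, 3] - grid@origin[3]) / grid@spacing)
  ok <- i0 >= 0 & i0 < grid@dims[1] & j0 >= 0 & j0 < grid@dims[2] &
    k0 >= 0 & k0 < grid@dims[3]
  out <- rep(NA_integer_, nrow(pts))
  out[ok] <- as.integer(1 + i0[ok] + grid@dims[1] * (j0[ok] + grid@dims[2] * k0[ok]))
  out
}
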