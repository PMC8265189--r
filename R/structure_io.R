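#' Read a PDB structure
#'
#' Parses a PDB file into an [AtomSet-class], keeping the first model only.
#' Hydrogens and deuteriums are dropped (the engine uses united-atom radii
#' that absorb them). For alternate-location groups the highest-occupancy
#' conformer is kept; ties go to the alphabetically first altLoc. Water
#' residues (HOH, WAT, H2O, DOD) are flagged and treated as hetero atoms.
#'
#' @param path path to a PDB file with at least one ATOM/HETATM record.
#' @return An [AtomSet-class].
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  nmodels <- tryCatch({
    lines <- readLines(path, warn = FALSE)
    sum(startsWith(lines, "MODEL "))
  }, error = function(e) stop("unreadable file: ", path))
  if (nmodels > 1)
    warning(sprintf("%s: %d models found; keeping the first only",
                    basename(path), nmodels))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file ", path, ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no atoms found in ", path)

  element <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  # derive the element from the atom name where the column is blank
  blank <- !nzchar(element)
  if (any(blank)) {
    nm <- gsub("[^A-Za-z].*$", "", sub("^[0-9]*", "", trimws(at$elety[blank])))
    element[blank] <- toupper(substr(nm, 1, 1))
    two <- toupper(trimws(at$elety[blank])) %in%
      c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "SE", "CU", "NI", "CO", "K")
    element[blank][two] <- toupper(trimws(at$elety[blank]))[two]
  }

  a <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    altLoc = ifelse(is.na(at$alt), "", trimws(at$alt)),
    resName = trimws(at$resid),
    chainId = ifelse(is.na(at$chain), "", trimws(at$chain)),
    resSeq = as.integer(at$resno),
    iCode = ifelse(is.na(at$insert), "", trimws(at$insert)),
    x = at$x, y = at$y, z = at$z,
    element = element,
    isHetero = at$type == "HETATM",
    isWater = trimws(at$resid) %in% .water_names,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bFactor = ifelse(is.na(at$b), 0, at$b),
    radius = NA_real_,
    stringsAsFactors = FALSE
  )
  a$isHetero <- a$isHetero | a$isWater

  # drop hydrogens/deuteriums (united-atom model)
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]

  # alt-loc resolution: keep the highest-occupancy conformer per atom site
  if (any(nzchar(a$altLoc))) {
    key <- paste(a$chainId, a$resSeq, a$iCode, a$resName, a$name, sep = "|")
    ord <- order(key, -a$occupancy, a$altLoc)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(match(a$serial, sort(a$serial))), , drop = FALSE]
    a <- a[order(a$serial), , drop = FALSE]
  }
  if (nrow(a) == 0)
    stop("no atoms remain after filtering in ", path)
  if (anyDuplicated(a$serial))
    a$serial <- seq_len(nrow(a))
  AtomSet(a, sourceName = basename(path), modelNumber = 1L)
}

#' Write an AtomSet as a PDB file
#'
#' Fixed-column PDB output (occupancy and b-factor as %6.2f). `b` and `o`
#' override the per-atom b-factor/occupancy columns.
#'
#' @param x an [AtomSet-class].
#' @param path output path.
#' @param b,o optional numeric vectors (length `nAtoms(x)`) written to the
#'   b-factor / occupancy columns.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path, b = NULL, o = NULL) {
  a <- atoms(x)
  if (!nrow(a)) {
    writeLines("END", path)
    return(invisible(path))
  }
  if (is.null(b)) b <- a$bFactor
  if (is.null(o)) o <- a$occupancy
  b <- pmin(pmax(b, -99.99), 999.99)
  o <- pmin(pmax(o, -99.99), 999.99)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$isHetero, "HETATM", "ATOM"),
    resno = a$resSeq, resid = a$resName, eleno = a$serial,
    elety = a$name, chain = ifelse(nzchar(a$chainId), a$chainId, " "),
    insert = ifelse(nzchar(a$iCode), a$iCode, ""),
    o = o, b = b, elesy = a$element
  )
  invisible(path)
}

#' Load a united-atom radius table
#'
#' Reads a tab-separated table with columns `res_name`, `atom_name`,
#' `radius` (Angstrom). Rows with `res_name == ".ELEMENT"` define per-element
#' fallback radii; a row with `res_name == ".DEFAULT"` defines the generic
#' default. The bundled table reconstructs the ProtOr/NucProt united-atom
#' class radii for standard amino acids, nucleotides and water; `#` lines
#' are comments and carry the provenance.
#'
#' @param path table path; default = the bundled table.
#' @return A list with `entries` (named numeric, names `"RES|ATOM"`),
#'   `elementFallback` (named numeric), `defaultRadius` and `provenance`.
#' @export
loadRadiusTable <- function(path = system.file("extdata", "united_atom_radii.tsv",
                                               package = "voropack")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("res_name", "atom_name", "radius") %in% names(tab)))
  if (any(tab$radius <= 0)) stop("radius table contains non-positive radii")
  el <- tab$res_name == ".ELEMENT"
  def <- tab$res_name == ".DEFAULT"
  hdr <- readLines(path, n = 5)
  prov <- sub("^#\\s*", "", hdr[startsWith(hdr, "#")][1])
  list(
    entries = setNames(tab$radius[!el & !def],
                       paste(tab$res_name[!el & !def], tab$atom_name[!el & !def],
                             sep = "|")),
    elementFallback = setNames(tab$radius[el], tab$atom_name[el]),
    defaultRadius = if (any(def)) tab$radius[def][1] else 1.70,
    provenance = if (is.na(prov)) basename(path) else prov
  )
}

#' Assign united-atom van der Waals radii
#'
#' Looks every atom up by (residue name, atom name); waters get the water
#' oxygen radius; unresolved atoms fall back to the per-element radius and,
#' failing that, to the generic default (with a warning reporting the count).
#'
#' @param x an [AtomSet-class].
#' @param table a radius table from [loadRadiusTable()].
#' @return `x` with the `radius` column filled; the number of fallback
#'   assignments is stored in the `nFallbackRadii` slot.
#' @export
assignRadii <- function(x, table = loadRadiusTable()) {
  a <- atoms(x)
  if (!nrow(a)) return(x)
  nm <- gsub("\\*", "'", a$name)  # old-style primes in nucleotide names
  key <- paste(a$resName, nm, sep = "|")
  key[a$isWater] <- "HOH|O"
  r <- unname(table$entries[key])
  fb <- is.na(r)
  if (any(fb)) {
    r[fb] <- unname(table$elementFallback[a$element[fb]])
    still <- is.na(r)
    if (any(still)) {
      r[still] <- table$defaultRadius
      warning(sum(still), " atom(s) received the generic default radius of ",
              table$defaultRadius, " A")
    }
  }
  x@atoms$radius <- r
  x@nFallbackRadii <- sum(fb)
  validObject(x)
  x
}

#' Load a residue hydrophobicity scale
#'
#' Tab-separated table with columns `res_name`, `value` (free-energy-like
#' units). The bundled scale is the biological (membrane-insertion)
#' hydrophobicity scale; the class cutoffs are 0 and 1.45, the latter being
#' the midpoint of the gap between the medium-polar and polar residues of
#' that scale.
#'
#' @param path table path; default = the bundled scale.
#' @return list with `values` (named numeric), `cutoffLow`, `cutoffHigh`.
#' @export
loadHydrophobicityScale <- function(path = system.file("extdata",
                                                       "biological_hydrophobicity.tsv",
                                                       package = "voropack")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("res_name", "value") %in% names(tab)))
  list(values = setNames(tab$value, tab$res_name),
       cutoffLow = 0.0, cutoffHigh = 1.45)
}

#' Classify hydrophobicity into polarity classes
#'
#' Values below 0 are hydrophobic, values in the closed interval
#' \[0, 1.45\] medium polar, values above 1.45 polar. Residue names are
#' looked up in the scale first; unknown residues map to medium polar.
#'
#' @param x numeric scale values, or character residue names.
#' @param scale a scale from [loadHydrophobicityScale()] (used when `x` is
#'   character, and for the cutoffs).
#' @return factor with levels hydrophobic, medium_polar, polar.
#' @export
classifyHydrophobicity <- function(x, scale = loadHydrophobicityScale()) {
  if (is.character(x)) {
    v <- unname(scale$values[x])
    if (anyNA(v)) {
      message("unknown residue(s) mapped to medium polar: ",
              paste(unique(x[is.na(v)]), collapse = ", "))
      v[is.na(v)] <- (scale$cutoffLow + scale$cutoffHigh) / 2
    }
    x <- v
  }
  cls <- ifelse(x < scale$cutoffLow, "hydrophobic",
                ifelse(x <= scale$cutoffHigh, "medium_polar", "polar"))
  factor(cls, levels = c("hydrophobic", "medium_polar", "polar"))
}

#' Apply a water policy
#'
#' `keep_all` returns the structure unchanged; `remove_all` drops every
#' water; `internal_only` (the default policy of the pipeline) keeps only
#' waters classified as buried — see [classifyWaterBurial()], which treats
#' waters as probes in space (they do not occlude themselves).
#'
#' @param x an [AtomSet-class].
#' @param mode one of `"keep_all"`, `"internal_only"`, `"remove_all"`.
#' @param waterBuried logical per-atom vector (TRUE for buried waters),
#'   required for `internal_only`.
#' @return the filtered [AtomSet-class].
#' @export
applyWaterPolicy <- function(x, mode = c("internal_only", "keep_all", "remove_all"),
                             waterBuried = NULL) {
  mode <- match.arg(mode)
  a <- atoms(x)
  if (mode == "keep_all") return(x)
  if (mode == "remove_all") {
    x@atoms <- a[!a$isWater, , drop = FALSE]
    rownames(x@atoms) <- NULL
    return(x)
  }
  if (is.null(waterBuried))
    stop("internal_only water policy requires per-atom burial flags; ",
         "run classifyWaterBurial() first")
  keep <- !a$isWater | (waterBuried %in% TRUE)
  x@atoms <- a[keep, , drop = FALSE]
  rownames(x@atoms) <- NULL
  x
}

#' Classify waters as internal (buried) or external
#'
#' Runs the solvent-excluded labelling and void detection on the non-water
#' atoms only (a water must not shield itself from solvent) and flags each
#' water whose oxygen centre falls in a buried void voxel.
#'
#' @param x an [AtomSet-class] with radii assigned.
#' @param spec a [GridSpec-class].
#' @return logical vector over all atoms: TRUE for buried waters, FALSE for
#'   exposed waters, NA for non-water atoms.
#' @export
classifyWaterBurial <- function(x, spec = gridSpec()) {
  a <- atoms(x)
  out <- rep(NA, nrow(a))
  wat <- a$isWater
  if (!any(wat)) return(out)
  out[wat] <- FALSE
  dry <- x
  dry@atoms <- a[!wat, , drop = FALSE]
  if (nrow(dry@atoms) == 0) return(out)
  grid <- buildGrid(dry, spec)
  grid <- computeSolventExcluded(grid, dry)
  grid <- detectVoids(grid)
  lab <- voxelLabels(grid)
  idx <- .pointVoxel(grid, as.matrix(a[wat, c("x", "y", "z")]))
  inside <- !is.na(idx) & lab[idx] == 3L
  out[wat] <- inside
  out
}
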