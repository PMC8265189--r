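# Result bundles, the single-structure pipeline, batch mode and the
# grid-accuracy study.

# full geometric pipeline on a prepared structure (radii set, waters
# resolved); returns grid + tables, optionally with cavity chemistry
.analyzeGeometry <- function(x, spec, scale, cutoff, hetFree = NULL,
                             verbose = FALSE) {
  tic <- function() proc.time()[["elapsed"]]
  say <- function(stage, t0) if (verbose)
    message(sprintf("  %-22s %6.2f s", stage, tic() - t0))
  t0 <- tic(); grid <- buildGrid(x, spec)
  grid <- computeSolventExcluded(grid, x); say("solvent-excluded", t0)
  t0 <- tic(); grid <- detectVoids(grid); say("void detection", t0)
  t0 <- tic(); burial <- classifyBurial(grid, x); say("burial", t0)
  t0 <- tic(); grid <- assignVoxels(grid, x); say("voronoi partition", t0)
  vols <- accumulateVolumes(grid, x, burial)
  resid <- residuePacking(vols, x)
  t0 <- tic()
  cavs <- clusterCavities(grid)
  if (nrow(cavs)) {
    cavs <- liningResidues(cavs, grid, x, cutoff = cutoff,
                           hetFreeGrid = hetFree$grid)
    cavs <- characterizeCavities(cavs, scale)
  } else {
    cavs$lining <- list(); cavs$liningSerials <- list()
    cavs$neighborHet <- list(); cavs$containedHet <- list()
    cavs$meanHydrophobicity <- numeric(0)
    cavs$polarityClass <- factor(character(0),
                                 levels = c("hydrophobic", "medium_polar", "polar"))
  }
  say("cavities", t0)
  list(grid = grid, burial = burial, volumes = vols, residues = resid,
       cavities = cavs)
}

#' Run the full packing-density pipeline on one structure
#'
#' Stages: read (if `input` is a path), radius assignment, water policy
#' (with a preliminary water-free burial pass for `internal_only`), grid
#' construction, solvent-excluded labelling, void detection, burial
#' classification, weighted-Voronoi partition, volume accumulation, cavity
#' clustering and characterization, and — when heteroatoms are present — a
#' het-free auxiliary rerun for cavity-type classification. Deterministic
#' given identical inputs and options.
#'
#' @param input path to a PDB file, or an [AtomSet-class] (radii are
#'   (re)assigned from `radiusTable` unless already set).
#' @param spacing grid spacing in Angstrom (0.4 default, 0.1 high
#'   accuracy).
#' @param probeRadius solvent probe radius (Angstrom).
#' @param water water policy: `"internal"` (default), `"all"`, `"none"`.
#' @param outDir optional output directory: when given, the three PDB
#'   products, the TSV tables and the manifest are written via
#'   [writeBundle()].
#' @param radiusTable radius table from [loadRadiusTable()].
#' @param hydrophobicityScale scale from [loadHydrophobicityScale()].
#' @param liningCutoff contact cutoff for cavity lining (Angstrom).
#' @param snap snap the grid origin to the global lattice.
#' @param verbose log stage timings to stderr.
#' @return A [ResultBundle-class].
#' @export
runSingle <- function(input, spacing = 0.4, probeRadius = 1.4,
                      water = c("internal", "all", "none"), outDir = NULL,
                      radiusTable = loadRadiusTable(),
                      hydrophobicityScale = loadHydrophobicityScale(),
                      liningCutoff = 2.8, snap = TRUE, verbose = FALSE) {
  water <- match.arg(water)
  spec <- gridSpec(spacing = spacing, probeRadius = probeRadius, snap = snap)
  if (is.character(input)) {
    x <- readStructure(input)
    x <- assignRadii(x, radiusTable)
  } else {
    x <- input
    if (anyNA(atomRadii(x))) x <- assignRadii(x, radiusTable)
  }
  mode <- c(internal = "internal_only", all = "keep_all", none = "remove_all")[water]
  if (mode == "internal_only" && any(atoms(x)$isWater)) {
    wb <- classifyWaterBurial(x, spec)
    x <- applyWaterPolicy(x, mode, waterBuried = wb)
  } else {
    x <- applyWaterPolicy(x, mode, waterBuried = logical(nAtoms(x)))
  }
  if (nAtoms(x) == 0)
    stop("no atoms remain after applying the water policy",
         if (nzchar(x@sourceName)) paste0(" (", x@sourceName, ")"))

  a <- atoms(x)
  hetFree <- NULL
  if (any(a$isHetero) && sum(!a$isHetero) > 0) {
    dry <- x
    dry@atoms <- a[!a$isHetero, , drop = FALSE]
    rownames(dry@atoms) <- NULL
    if (verbose) message("het-free auxiliary run:")
    hf <- .analyzeGeometry(dry, spec, hydrophobicityScale, liningCutoff,
                           verbose = verbose)
    hetFree <- list(grid = hf$grid, cavities = hf$cavities)
  }
  if (verbose) message("standard run:")
  res <- .analyzeGeometry(x, spec, hydrophobicityScale, liningCutoff,
                          hetFree = hetFree, verbose = verbose)
  cavs <- classifyCavityTypes(res$cavities, x, res$grid, hetFree)

  manifest <- list(
    package = "voropack",
    version = as.character(packageVersion("voropack")),
    source = x@sourceName,
    spacing = spacing, probeRadius = probeRadius,
    waterPolicy = water, liningCutoff = liningCutoff, snap = snap,
    radiusTable = radiusTable$provenance,
    hydrophobicityCutoffs = c(hydrophobicityScale$cutoffLow,
                              hydrophobicityScale$cutoffHigh),
    nAtoms = nAtoms(x), nCavities = nrow(cavs),
    seVolume = seVolume(res$grid)
  )
  bundle <- new("ResultBundle", structure = x, atomTable = res$volumes,
                residueTable = res$residues, cavityTable = cavs,
                files = character(0), manifest = manifest)
  if (!is.null(outDir))
    bundle <- writeBundle(bundle, outDir, scale = hydrophobicityScale)
  bundle
}

#' Write the three PDB products and tables of a run
#'
#' Products, mirroring the server's downloadable files:
#' \describe{
#'   \item{`<base>_packing.pdb`}{the whole structure with the residue
#'     packing density (raw fraction, 2 decimals) in the b-factor of every
#'     atom of the residue.}
#'   \item{`<base>_cavities.pdb`}{one HETATM pseudo-atom per cavity
#'     (residue CAV, chain z, serials from 9000, element X) with the
#'     equivalent radius in the b-factor and the mean lining
#'     hydrophobicity in the occupancy column.}
#'   \item{`<base>_lining.pdb`}{all atoms of every cavity-lining residue,
#'     with the residue hydrophobicity in the b-factor.}
#' }
#' plus `<base>_atoms.tsv`, `<base>_cavities.tsv`, `<base>_residues.tsv`,
#' `<base>_manifest.json`, a column-description README, and — when a zip
#' program is available — `<base>_bundle.zip` containing everything.
#'
#' @param bundle a [ResultBundle-class] from [runSingle()].
#' @param outDir output directory (created if needed).
#' @param scale hydrophobicity scale used for the lining product.
#' @return the bundle with the `files` slot filled.
#' @export
writeBundle <- function(bundle, outDir, scale = loadHydrophobicityScale()) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  x <- bundle@structure
  a <- atoms(x)
  base <- gsub("[^A-Za-z0-9._-]", "_",
               sub("\\.pdb$", "", basename(x@sourceName), ignore.case = TRUE))
  if (!nzchar(base)) base <- "structure"
  fp <- function(suffix) file.path(outDir, paste0(base, suffix))

  # 1. packing densities: residue PD in the b-factor of each atom
  resid <- bundle@residueTable
  rkey <- .residueKey(a)
  reskey <- paste(resid$chainId, resid$resSeq, resid$iCode, resid$resName, sep = "|")
  pdres <- resid$packingDensity[match(rkey, reskey)]
  writeStructure(x, fp("_packing.pdb"), b = round(pdres, 2))

  # 2. cavities as pseudo-atoms
  cavs <- bundle@cavityTable
  if (nrow(cavs)) {
    ps <- .newAtoms(cbind(cavs$cx, cavs$cy, cavs$cz), name = "CAV",
                    resName = "CAV", chainId = "z", element = "X",
                    isHetero = TRUE, radius = 1)
    ps$serial <- 9000L + seq_len(nrow(cavs)) - 1L
    ps$resSeq <- cavs$id
    cavSet <- AtomSet(ps, sourceName = "cavities")
    writeStructure(cavSet, fp("_cavities.pdb"),
                   b = cavs$eqRadius,
                   o = ifelse(is.na(cavs$meanHydrophobicity), 0,
                              cavs$meanHydrophobicity))
  } else writeLines("END", fp("_cavities.pdb"))

  # 3. lining residues with residue hydrophobicity in the b-factor
  linKeys <- unique(unlist(cavs$lining))
  if (length(linKeys)) {
    sel <- rkey %in% linKeys
    lin <- x
    lin@atoms <- a[sel, , drop = FALSE]
    rownames(lin@atoms) <- NULL
    hv <- scale$values[lin@atoms$resName]
    writeStructure(lin, fp("_lining.pdb"), b = ifelse(is.na(hv), 0, hv))
  } else writeLines("END", fp("_lining.pdb"))

  # tables
  at <- bundle@atomTable
  at$packingDensity <- round(at$packingDensity, 6)
  at$vVdw <- round(at$vVdw, 6); at$vSe <- round(at$vSe, 6)
  write.table(at, fp("_atoms.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- bundle@residueTable
  rt$packingDensity <- round(rt$packingDensity, 6)
  write.table(rt, fp("_residues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- cavs
  if (nrow(ct)) {
    ct$lining <- vapply(ct$lining, paste, character(1), collapse = ",")
    ct$liningSerials <- vapply(ct$liningSerials, paste, character(1), collapse = ",")
    ct$neighborHet <- vapply(ct$neighborHet, paste, character(1), collapse = ",")
    ct$containedHet <- vapply(ct$containedHet, paste, character(1), collapse = ",")
  }
  ct$voxels <- NULL
  write.table(ct, fp("_cavities.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(bundle@manifest, fp("_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readme <- fp("_README.txt")
  writeLines(c(
    "Column guide:",
    "  *_packing.pdb : b-factor = residue packing density (fraction, 2 dp)",
    "  *_cavities.pdb: pseudo-atoms; b-factor = equivalent radius (A),",
    "                  occupancy = mean lining hydrophobicity",
    "  *_lining.pdb  : cavity-lining residues; b-factor = residue hydrophobicity",
    "  *_atoms.tsv   : per-atom vVdw, vSe (A^3), packingDensity, buried flag",
    "  *_residues.tsv: pooled residue packing densities",
    "  *_cavities.tsv: cavity geometry, type (1-4), polarity, lining"
  ), readme)

  files <- c(packing = fp("_packing.pdb"), cavities = fp("_cavities.pdb"),
             lining = fp("_lining.pdb"), atoms = fp("_atoms.tsv"),
             residues = fp("_residues.tsv"), cavityTable = fp("_cavities.tsv"),
             manifest = fp("_manifest.json"), readme = readme)
  zipOk <- tryCatch({
    zp <- fp("_bundle.zip")
    if (file.exists(zp)) unlink(zp)
    status <- suppressWarnings(
      utils::zip(zp, files = files, flags = "-jq9X"))
    status == 0 && file.exists(zp)
  }, error = function(e) FALSE)
  if (zipOk) files <- c(files, archive = fp("_bundle.zip"))
  bundle@files <- files
  bundle
}

#' Run the pipeline over a directory or zip archive of PDB files
#'
#' Limits mirror the server's batch upload: at most `maxFiles` structures
#' and `maxBytes` total uncompressed size, checked before any processing.
#' One failing file does not abort the batch.
#'
#' @param input a directory, or a `.zip` archive of PDB files.
#' @param outDir optional output directory; each structure gets a
#'   subdirectory.
#' @param maxFiles maximum number of structure files (default 100).
#' @param maxBytes maximum total uncompressed bytes (default 10 MB).
#' @param ... passed to [runSingle()].
#' @return list with `bundles` (named list of [ResultBundle-class] for the
#'   successes) and `summary` (data.frame: file, ok, message).
#' @export
runBatch <- function(input, outDir = NULL, maxFiles = 100, maxBytes = 10e6, ...) {
  cleanup <- NULL
  if (length(input) == 1 && grepl("\\.zip$", input, ignore.case = TRUE)) {
    listing <- unzip(input, list = TRUE)
    listing <- listing[!grepl("/$", listing$Name), , drop = FALSE]
    if (nrow(listing) > maxFiles)
      stop("batch limit exceeded: ", nrow(listing), " files (max ", maxFiles, ")")
    if (sum(listing$Length) > maxBytes)
      stop("batch limit exceeded: ", sum(listing$Length),
           " uncompressed bytes (max ", maxBytes, ")")
    exdir <- tempfile("voropack_batch_")
    unzip(input, exdir = exdir)
    cleanup <- exdir
    on.exit(unlink(cleanup, recursive = TRUE), add = TRUE)
    paths <- list.files(exdir, pattern = "\\.(pdb|ent)$", ignore.case = TRUE,
                        recursive = TRUE, full.names = TRUE)
  } else if (dir.exists(input)) {
    paths <- list.files(input, pattern = "\\.(pdb|ent)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(paths) > maxFiles)
      stop("batch limit exceeded: ", length(paths), " files (max ", maxFiles, ")")
    if (sum(file.size(paths)) > maxBytes)
      stop("batch limit exceeded: ", sum(file.size(paths)),
           " bytes (max ", maxBytes, ")")
  } else stop("input must be a directory or a .zip archive: ", input)
  paths <- sort(paths)

  bundles <- list()
  summary <- data.frame(file = basename(paths), ok = FALSE, message = "",
                        stringsAsFactors = FALSE)
  for (i in seq_along(paths)) {
    nm <- basename(paths[i])
    res <- tryCatch({
      od <- if (is.null(outDir)) NULL
      else file.path(outDir, sub("\\.(pdb|ent)$", "", nm, ignore.case = TRUE))
      b <- runSingle(paths[i], outDir = od, ...)
      bundles[[nm]] <- b
      "ok"
    }, error = function(e) conditionMessage(e))
    summary$ok[i] <- identical(res, "ok")
    summary$message[i] <- if (summary$ok[i]) "" else res
  }
  list(bundles = bundles, summary = summary)
}

#' Grid-accuracy study: default vs high-accuracy spacing
#'
#' Quantifies the accuracy cost of the default 0.4 A grid relative to the
#' 0.1 A high-accuracy grid on a seeded set of synthetic structures
#' (FCC-clipped clusters and toy polymer chains of 50-500 atoms). For every
#' atom the assigned volume `vVdw + vSe` and the packing density are
#' computed at both spacings and compared as relative differences
#' `(v(coarse) - v(fine)) / v(fine)`.
#'
#' Two statistics are reported, both in percent. The headline accuracy
#' loss is aggregate: per structure, the magnitude of the mean signed
#' per-atom relative difference (per-atom voxel-counting jitter, which
#' averages out over a structure, does not contribute), then the mean and
#' SD across structures (`meanVolumePct`, `meanDensityPct`). Also returned
#' is the mean of per-atom absolute relative differences pooled over all
#' atoms (`perAtomAbsVolumePct`, `perAtomAbsDensityPct`), which includes
#' that jitter and is therefore bounded below by roughly one percent at
#' 0.4 A regardless of systematic accuracy.
#'
#' @param seeds integer seeds, one per structure (default 1:10).
#' @param spacings numeric(2): coarse and fine spacing.
#' @param verbose print per-structure progress.
#' @return list with `meanVolumePct`, `meanDensityPct`, `sdVolumePct`,
#'   `sdDensityPct`, `perAtomAbsVolumePct`, `perAtomAbsDensityPct`,
#'   `nAtoms` and a `perStructure` data.frame.
#' @export
gridAccuracyStudy <- function(seeds = 1:10, spacings = c(0.4, 0.1),
                              verbose = FALSE) {
  kinds <- list(
    list(kind = "cluster", nAtoms = 50), list(kind = "cluster", nAtoms = 200),
    list(kind = "cluster", nAtoms = 500), list(kind = "cluster", nAtoms = 100),
    list(kind = "cluster", nAtoms = 300), list(kind = "toy_chain", nRes = 15),
    list(kind = "toy_chain", nRes = 30), list(kind = "toy_chain", nRes = 60),
    list(kind = "toy_chain", nRes = 90), list(kind = "toy_chain", nRes = 125)
  )
  per <- vector("list", length(seeds))
  volDiffs <- pdDiffs <- numeric(0)
  for (si in seq_along(seeds)) {
    kk <- kinds[[(si - 1) %% length(kinds) + 1]]
    x <- if (kk$kind == "cluster")
      makeFixture("cluster", nAtoms = kk$nAtoms, seed = seeds[si])
    else makeFixture("toy_chain", nRes = kk$nRes, seed = seeds[si])
    vols <- lapply(spacings, function(h) {
      spec <- gridSpec(spacing = h)
      grid <- buildGrid(x, spec)
      grid <- computeSolventExcluded(grid, x)
      grid <- detectVoids(grid)
      grid <- assignVoxels(grid, x)
      v <- accumulateVolumes(grid, x)
      rm(grid); gc(FALSE)
      v
    })
    vc <- vols[[1]]$vVdw + vols[[1]]$vSe
    vf <- vols[[2]]$vVdw + vols[[2]]$vSe
    pc <- vols[[1]]$packingDensity
    pf <- vols[[2]]$packingDensity
    ok <- vf > 0 & vc > 0 & !is.na(pc) & !is.na(pf) & pf > 0
    dv <- (vc[ok] - vf[ok]) / vf[ok]
    dp <- (pc[ok] - pf[ok]) / pf[ok]
    volDiffs <- c(volDiffs, dv)
    pdDiffs <- c(pdDiffs, dp)
    per[[si]] <- data.frame(
      seed = seeds[si], kind = kk$kind, nAtoms = nAtoms(x),
      volumeLossPct = 100 * abs(mean(dv)), densityLossPct = 100 * abs(mean(dp)),
      perAtomAbsVolumePct = 100 * mean(abs(dv)),
      perAtomAbsDensityPct = 100 * mean(abs(dp))
    )
    if (verbose)
      message(sprintf("seed %d (%s, %d atoms): vol %.3f%%, pd %.3f%%",
                      seeds[si], kk$kind, nAtoms(x),
                      100 * abs(mean(dv)), 100 * abs(mean(dp))))
  }
  per <- do.call(rbind, per)
  list(meanVolumePct = mean(per$volumeLossPct),
       meanDensityPct = mean(per$densityLossPct),
       sdVolumePct = sd(per$volumeLossPct),
       sdDensityPct = sd(per$densityLossPct),
       perAtomAbsVolumePct = 100 * mean(abs(volDiffs)),
       perAtomAbsDensityPct = 100 * mean(abs(pdDiffs)),
       nAtoms = length(volDiffs),
       perStructure = per)
}
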