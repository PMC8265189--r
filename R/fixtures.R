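# Synthetic test structures with known geometry: single spheres, dimers,
# close-packed clusters, sealed hollow shells with engineered voids and toy
# polymer chains. Everything is seeded and deterministic.

.fibonacciSphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.newAtoms <- function(xyz, name = "CA", resName = "ALA", chainId = "A",
                      element = "C", isHetero = FALSE, isWater = FALSE,
                      radius = NA_real_, resSeq = NULL) {
  n <- nrow(xyz)
  if (is.null(resSeq)) resSeq <- seq_len(n)
  data.frame(
    serial = seq_len(n), name = rep_len(name, n), altLoc = "",
    resName = rep_len(resName, n), chainId = rep_len(chainId, n),
    resSeq = rep_len(resSeq, n), iCode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep_len(element, n), isHetero = rep_len(isHetero, n),
    isWater = rep_len(isWater, n), occupancy = 1, bFactor = 0,
    radius = rep_len(radius, n), stringsAsFactors = FALSE
  )
}

# FCC lattice points closest to the origin
.fccPoints <- function(n, nn) {
  m <- ceiling((n * 4)^(1 / 3)) + 2
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, ]  # FCC as checkerboard sublattice
  a <- nn / sqrt(2)                      # cubic sublattice edge
  pts <- cbind(g$i, g$j, g$k) * a
  d2 <- rowSums(pts^2)
  pts[order(d2), , drop = FALSE][seq_len(n), , drop = FALSE]
}

.randomRotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic structure
#'
#' Fixture kinds:
#' \describe{
#'   \item{single_atom}{one ALA CA-like atom of radius `radius`.}
#'   \item{dimer}{two atoms on the x axis at centre distance `separation`,
#'     radii `radii`.}
#'   \item{cluster}{`nAtoms` atoms on an FCC lattice (nearest-neighbour
#'     distance `nn`) clipped to a ball, randomly rotated, jittered by
#'     `jitter` and expanded about the centroid by `scale`. Radii are drawn
#'     from the united-atom class radii with protein-like frequencies.}
#'   \item{hollow_shell}{`nAtoms` atoms of radius `atomRadius` on a sphere
#'     of radius `shellRadius`, spaced so every surface gap is below the
#'     probe diameter (the interior chamber is sealed; verified by a
#'     sampled covering check unless `mouth = TRUE`). `mouth = TRUE`
#'     removes a polar cap of aperture radius `mouthRadius`, opening a
#'     probe-sized mouth. `center = "water"` places a water, `center =
#'     "ligand"` a het pseudo-ligand, at the shell centre.}
#'   \item{toy_chain}{an idealized self-avoiding polymer of `nRes`
#'     glycine-like residues (N, CA, C, O per residue) for residue-level
#'     tests; radii from the bundled table.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param radius,radii,separation,nAtoms,nn,jitter,scale,shellRadius,
#'   atomRadius,mouth,mouthRadius,center,nRes geometric parameters.
#' @param seed RNG seed; identical seeds give identical structures.
#' @param file optional path: also write the structure as a PDB file.
#' @return An [AtomSet-class] with radii assigned.
#' @export
makeFixture <- function(kind = c("single_atom", "dimer", "cluster",
                                 "hollow_shell", "toy_chain"),
                        radius = 1.88, radii = c(1.8, 1.8), separation = 10,
                        nAtoms = NULL, nn = 3.8, jitter = 0.15, scale = 1,
                        shellRadius = 6, atomRadius = 1.8, mouth = FALSE,
                        mouthRadius = 4.5, center = c("none", "water", "ligand"),
                        nRes = 20, seed = 42, file = NULL) {
  kind <- match.arg(kind)
  center <- match.arg(center)
  set.seed(seed)
  at <- switch(kind,
    single_atom = .newAtoms(matrix(0, 1, 3), radius = radius),
    dimer = {
      xyz <- rbind(c(-separation / 2, 0, 0), c(separation / 2, 0, 0))
      .newAtoms(xyz, radius = radii)
    },
    cluster = {
      if (is.null(nAtoms)) nAtoms <- 50
      pts <- .fccPoints(nAtoms, nn) %*% .randomRotation()
      pts <- pts + matrix(runif(3 * nAtoms, -jitter, jitter), ncol = 3)
      pts <- scale * scale(pts, center = TRUE, scale = FALSE)
      r <- sample(c(1.88, 1.76, 1.64, 1.42), nAtoms, replace = TRUE,
                  prob = c(0.5, 0.2, 0.15, 0.15))
      .newAtoms(pts, radius = r)
    },
    hollow_shell = {
      if (is.null(nAtoms)) nAtoms <- ceiling(4 * pi * shellRadius^2 / 1.8^2)
      pts <- .fibonacciSphere(nAtoms, shellRadius)
      if (mouth) {
        capAngle <- asin(min(1, mouthRadius / shellRadius))
        keep <- acos(pmin(1, pmax(-1, pts[, 3] / shellRadius))) > capAngle
        pts <- pts[keep, , drop = FALSE]
      } else {
        # sealed: every point of the mid-sphere must be within
        # atomRadius + probe of an atom centre, so no probe centre crosses
        dirs <- .fibonacciSphere(4096, shellRadius)
        cover <- max(apply(dirs, 1, function(p)
          min(sqrt(colSums((t(pts) - p)^2)))))
        if (cover >= atomRadius + 1.4 - 0.1)
          stop("infeasible hollow_shell geometry: surface gaps admit the probe ",
               sprintf("(covering distance %.2f A); increase nAtoms", cover))
      }
      at <- .newAtoms(pts, radius = atomRadius)
      if (center == "water") {
        w <- .newAtoms(matrix(0, 1, 3), name = "O", resName = "HOH",
                       chainId = "W", element = "O", isHetero = TRUE,
                       isWater = TRUE, radius = 1.46)
        w$serial <- nrow(at) + 1L; w$resSeq <- nrow(at) + 1L
        at <- rbind(at, w)
      } else if (center == "ligand") {
        l <- .newAtoms(matrix(0, 1, 3), name = "S1", resName = "LIG",
                       chainId = "L", element = "S", isHetero = TRUE,
                       radius = 1.77)
        l$serial <- nrow(at) + 1L; l$resSeq <- nrow(at) + 1L
        at <- rbind(at, l)
      }
      at
    },
    toy_chain = {
      tab <- loadRadiusTable()
      ca <- matrix(0, nRes, 3)
      dir <- c(1, 0, 0)
      # compact globule: confine the walk to a ball sized like a folded
      # protein of this length (max radius ~ 2.8 * nRes^(1/3) + 3 A)
      rmax <- 2.8 * nRes^(1 / 3) + 3
      for (i in 2:nRes) {
        tries <- 0
        repeat {
          prop <- dir + rnorm(3, sd = 0.8)
          prop <- prop / sqrt(sum(prop^2))
          cand <- ca[i - 1, ] + 3.8 * prop
          tries <- tries + 1
          if (tries > 200) rmax <- rmax * 1.05
          okClash <- i == 2 ||
            min(sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE],
                                   2, cand)^2))) > 4.2
          if (okClash && sqrt(sum(cand^2)) <= rmax) break
        }
        ca[i, ] <- cand
        dir <- prop
      }
      rows <- vector("list", nRes)
      for (i in seq_len(nRes)) {
        fwd <- if (i < nRes) ca[min(i + 1, nRes), ] - ca[i, ] else ca[i, ] - ca[i - 1, ]
        fwd <- fwd / sqrt(sum(fwd^2))
        up <- c(0, 0, 1)
        if (abs(sum(up * fwd)) > 0.9) up <- c(0, 1, 0)
        side <- .cross(fwd, up)
        side <- side / sqrt(sum(side^2))
        xyz <- rbind(
          ca[i, ] - 1.46 * fwd + 0.3 * side,  # N
          ca[i, ],                            # CA
          ca[i, ] + 1.53 * fwd - 0.3 * side,  # C
          ca[i, ] + 1.53 * fwd - 0.3 * side + 1.23 * side  # O
        )
        rows[[i]] <- .newAtoms(xyz, name = c("N", "CA", "C", "O"),
                               resName = "GLY", resSeq = i,
                               element = c("N", "C", "C", "O"))
      }
      at <- do.call(rbind, rows)
      at$serial <- seq_len(nrow(at))
      at$radius <- unname(tab$entries[paste("GLY", at$name, sep = "|")])
      at
    }
  )
  x <- AtomSet(at, sourceName = sprintf("fixture:%s:seed%d", kind, seed))
  validObject(x)
  if (!is.null(file)) writeStructure(x, file)
  x
}

# minimal cross product
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Combine two structures into one
#'
#' Concatenates the atom tables and renumbers serials sequentially.
#' Residue numbering is offset in the second structure so residue keys stay
#' unique per chain.
#'
#' @param x,y [AtomSet-class] objects.
#' @return the combined [AtomSet-class].
#' @export
combineStructures <- function(x, y) {
  ax <- atoms(x); ay <- atoms(y)
  ay$resSeq <- ay$resSeq + if (nrow(ax)) max(ax$resSeq) else 0L
  out <- rbind(ax, ay)
  out$serial <- seq_len(nrow(out))
  AtomSet(out, sourceName = paste(x@sourceName, y@sourceName, sep = "+"))
}

#' Translate a structure
#'
#' @param x an [AtomSet-class].
#' @param shift numeric(3) displacement in Angstrom.
#' @return the shifted [AtomSet-class].
#' @export
translateStructure <- function(x, shift) {
  x@atoms$x <- x@atoms$x + shift[1]
  x@atoms$y <- x@atoms$y + shift[2]
  x@atoms$z <- x@atoms$z + shift[3]
  x
}
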