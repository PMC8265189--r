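# Independent oracles used by the tests. These deliberately avoid the
# package's C++ engine: closed-form geometry, plain-R flood fills and a
# plain-R exhaustive weighted-Voronoi argmin.

sphereVolume <- function(r) 4 / 3 * pi * r^3

# union volume of two equal spheres radius r at centre distance d (< 2r)
unionVolumeEqualSpheres <- function(r, d) {
  if (d >= 2 * r) return(2 * sphereVolume(r))
  lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  2 * sphereVolume(r) - lens
}

# plain-R voxel flood fill: which grid points can a probe centre reach from
# the outside? Returns the feasible and accessible logical arrays plus axes.
oracleProbeAccess <- function(x, h = 0.2, probe = 1.4, pad = 4) {
  a <- atoms(x)
  ax <- seq(min(a$x) - pad, max(a$x) + pad, by = h)
  ay <- seq(min(a$y) - pad, max(a$y) + pad, by = h)
  az <- seq(min(a$z) - pad, max(a$z) + pad, by = h)
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  minwd <- array(Inf, c(nx, ny, nz))
  X <- array(ax, c(nx, ny, nz))
  Y <- aperm(array(ay, c(ny, nx, nz)), c(2, 1, 3))
  Z <- aperm(array(az, c(nz, nx, ny)), c(2, 3, 1))
  for (i in seq_len(nrow(a))) {
    d <- sqrt((X - a$x[i])^2 + (Y - a$y[i])^2 + (Z - a$z[i])^2) - a$radius[i]
    minwd <- pmin(minwd, d)
  }
  feas <- minwd >= probe
  acc <- array(FALSE, dim(feas))
  acc[1, , ] <- feas[1, , ]; acc[nx, , ] <- feas[nx, , ]
  acc[, 1, ] <- acc[, 1, ] | feas[, 1, ]; acc[, ny, ] <- acc[, ny, ] | feas[, ny, ]
  acc[, , 1] <- acc[, , 1] | feas[, , 1]; acc[, , nz] <- acc[, , nz] | feas[, , nz]
  grow <- function(m) {
    g <- m
    g[-1, , ] <- g[-1, , ] | m[-nx, , ]
    g[-nx, , ] <- g[-nx, , ] | m[-1, , ]
    g[, -1, ] <- g[, -1, ] | m[, -ny, ]
    g[, -ny, ] <- g[, -ny, ] | m[, -1, ]
    g[, , -1] <- g[, , -1] | m[, , -nz]
    g[, , -nz] <- g[, , -nz] | m[, , -1]
    g
  }
  repeat {
    nxt <- grow(acc) & feas
    if (identical(nxt, acc)) break
    acc <- nxt
  }
  list(ax = ax, ay = ay, az = az, feasible = feas, accessible = acc)
}

# can a probe reach the given point from outside?
oracleProbeReaches <- function(x, point = c(0, 0, 0), h = 0.2, probe = 1.4) {
  o <- oracleProbeAccess(x, h = h, probe = probe)
  ii <- which.min(abs(o$ax - point[1]))
  jj <- which.min(abs(o$ay - point[2]))
  kk <- which.min(abs(o$az - point[3]))
  # reachable if any accessible voxel lies within probe of the point
  idx <- which(o$accessible, arr.ind = TRUE)
  if (!nrow(idx)) return(FALSE)
  d2 <- (o$ax[idx[, 1]] - point[1])^2 + (o$ay[idx[, 2]] - point[2])^2 +
    (o$az[idx[, 3]] - point[3])^2
  min(d2) <= probe^2 || o$accessible[ii, jj, kk]
}

# exhaustive additively weighted argmin, replicating the documented
# tie-break (equal weighted distance -> lowest serial, atoms scanned in
# table order)
oracleOwners <- function(grid, x, idx) {
  a <- atoms(x)
  ctr <- voropack:::.voxelCenters(grid, idx)
  best <- rep(Inf, length(idx))
  own <- integer(length(idx))
  for (i in seq_len(nrow(a))) {
    wd <- sqrt((ctr[, 1] - a$x[i])^2 + (ctr[, 2] - a$y[i])^2 +
                 (ctr[, 3] - a$z[i])^2) - a$radius[i]
    take <- wd < best |
      (wd == best & own > 0 & a$serial[i] < a$serial[pmax(own, 1L)])
    best[take] <- wd[take]
    own[take] <- i
  }
  own
}

# --- fixed-column PDB line for parser tests ---
pdbLine <- function(serial, name, res, chain, resno, x, y, z,
                    occ = 1, b = 0, el = "C", record = "ATOM",
                    alt = " ", icode = " ") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, res, chain, resno, icode,
          x, y, z, occ, b, el)
}

writePdbText <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# --- minimal store-only zip writer (test-only; no zip binary available) ---
.crc32Table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crc32Table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

writeStoredZip <- function(files, zipPath) {
  con <- file(zipPath, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  offsets <- integer(length(files))
  entries <- list()
  pos <- 0L
  dosdate <- bitwOr(bitwShiftL(40L, 9L), bitwOr(bitwShiftL(1L, 5L), 1L))
  for (i in seq_along(files)) {
    data <- readBin(files[i], "raw", file.size(files[i]))
    nm <- charToRaw(basename(files[i]))
    crc <- crc32(data)
    offsets[i] <- pos
    w4(0x04034b50); w2(20); w2(0); w2(0); w2(0); w2(dosdate)
    w4(crc); w4(length(data)); w4(length(data)); w2(length(nm)); w2(0)
    writeBin(nm, con); writeBin(data, con)
    pos <- pos + 30L + length(nm) + length(data)
    entries[[i]] <- list(nm = nm, crc = crc, size = length(data))
  }
  cdStart <- pos
  for (i in seq_along(files)) {
    e <- entries[[i]]
    w4(0x02014b50); w2(20); w2(20); w2(0); w2(0); w2(0); w2(dosdate)
    w4(e$crc); w4(e$size); w4(e$size); w2(length(e$nm)); w2(0); w2(0)
    w2(0); w2(0); w4(0); w4(offsets[i])
    writeBin(e$nm, con)
    pos <- pos + 46L + length(e$nm)
  }
  w4(0x06054b50); w2(0); w2(0); w2(length(files)); w2(length(files))
  w4(pos - cdStart); w4(cdStart); w2(0)
  invisible(zipPath)
}
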