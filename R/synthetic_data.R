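# Synthetic two-unit structures with planted class structure.  Units are
# serpentine chains of 4-atom residues (N, CA, C, O) on a jittered 3.5 A
# lattice; geometry places the units in contact, as touching blocks, or far
# apart, and the B-factor model optionally plants interface rigidity.

#' Synthetic-structure configuration
#'
#' @param residuesPerChain residues in each chain.
#' @param chainsPerUnit chains per binding partner.
#' @param geometry `"slab-contact"` (flat interface, default),
#'   `"sphere-pair"` (compact blocks touching), or `"separated"`
#'   (100 A gap, no interface).
#' @param bfactorModel `"uniform"` (B factors independent of position,
#'   the packing-like null), `"burial-gradient"` (B grows towards the
#'   surface), or `"interface-rigid"` (uniform base with interfacial-zone
#'   atoms shifted down, the biological-like signal).
#' @param interfaceRigidity effect size: how many unit standard deviations
#'   the interfacial-zone B factors are lowered under
#'   `"interface-rigid"`.
#' @param seed integer RNG seed; generation is deterministic per seed.
#' @return validated config list.
#' @export
syntheticConfig <- function(residuesPerChain = 30L, chainsPerUnit = 2L,
                            geometry = c("slab-contact", "sphere-pair",
                                         "separated"),
                            bfactorModel = c("uniform", "burial-gradient",
                                             "interface-rigid"),
                            interfaceRigidity = 1.0, seed = 1L) {
  geometry <- match.arg(geometry)
  bfactorModel <- match.arg(bfactorModel)
  stopifnot(residuesPerChain >= 2, chainsPerUnit >= 1,
            interfaceRigidity >= 0, is.numeric(seed))
  nres <- residuesPerChain * chainsPerUnit
  if (nres > 5000L)
    stop("geometry cannot host ", nres, " residues per unit")
  list(residuesPerChain = as.integer(residuesPerChain),
       chainsPerUnit = as.integer(chainsPerUnit), geometry = geometry,
       bfactorModel = bfactorModel, interfaceRigidity = interfaceRigidity,
       seed = as.integer(seed))
}

# serpentine residue-centre path over an nx x ny x nz grid (row-major,
# direction alternating) so consecutive residues are lattice neighbours
.serpentine <- function(n, nx, ny, spacing) {
  k <- seq_len(n) - 1L
  layer <- k %/% (nx * ny)
  r <- (k %% (nx * ny)) %/% nx
  cidx <- k %% nx
  cidx <- ifelse(r %% 2L == 1L, nx - 1L - cidx, cidx)  # snake along x
  r2 <- ifelse(layer %% 2L == 1L, ny - 1L - r, r)      # snake along y
  cbind(x = cidx * spacing, y = r2 * spacing, z = layer * spacing)
}

.buildUnitAtoms <- function(cfg, side, zsign, zoff, nz, spacing = 3.5) {
  nres <- cfg$residuesPerChain * cfg$chainsPerUnit
  nx <- ceiling(sqrt(nres / nz))
  ny <- ceiling(nres / (nx * nz))
  centres <- .serpentine(nres, nx, ny, spacing)
  centres[, "x"] <- centres[, "x"] - mean(range(centres[, "x"]))
  centres[, "y"] <- centres[, "y"] - mean(range(centres[, "y"]))
  centres[, "z"] <- zsign * (zoff + centres[, "z"])
  # direction towards the next residue centre (last keeps the previous)
  d <- diff(centres)
  d <- rbind(d, d[nrow(d), , drop = FALSE])
  d <- d / sqrt(rowSums(d^2))
  lat <- cbind(-d[, 2], d[, 1], 0)  # in-plane lateral axis
  nl <- sqrt(rowSums(lat^2))
  lat[nl < 1e-8, ] <- rep(c(1, 0, 0), each = sum(nl < 1e-8))
  nl[nl < 1e-8] <- 1
  lat <- lat / nl

  atoms <- list(N = centres - 1.1 * d, CA = centres + 0.7 * lat,
                C = centres + 1.1 * d, O = centres - 0.7 * lat)
  xyz <- do.call(rbind, lapply(seq_len(nres), function(r)
    rbind(atoms$N[r, ], atoms$CA[r, ], atoms$C[r, ], atoms$O[r, ])))
  xyz <- xyz + matrix(runif(length(xyz), -0.15, 0.15), ncol = 3)
  chain <- rep(rep(LETTERS[seq_len(cfg$chainsPerUnit)],
                   each = cfg$residuesPerChain), each = 4L)
  if (side == "B")
    chain <- rep(rep(LETTERS[cfg$chainsPerUnit + seq_len(cfg$chainsPerUnit)],
                     each = cfg$residuesPerChain), each = 4L)
  data.frame(
    name = rep(c("N", "CA", "C", "O"), nres),
    element = rep(c("N", "C", "C", "O"), nres),
    chain = chain,
    resno = rep(rep(seq_len(cfg$residuesPerChain), cfg$chainsPerUnit),
                each = 4L),
    resid = "ALA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
}

.assignBfactors <- function(atoms, cfg, otherXyz) {
  n <- nrow(atoms)
  mu <- runif(1, 25, 40)
  sdev <- runif(1, 8, 12)
  b <- rnorm(n, mu, sdev)
  if (cfg$bfactorModel == "burial-gradient") {
    ctr <- colMeans(atoms[, c("x", "y", "z")])
    depth <- sqrt((atoms$x - ctr[1])^2 + (atoms$y - ctr[2])^2 +
                    (atoms$z - ctr[3])^2)
    g <- (depth - mean(depth)) / stats::sd(depth)
    b <- mu + sdev * (0.8 * g + 0.6 * rnorm(n))
  }
  if (cfg$bfactorModel == "interface-rigid" && nrow(otherXyz)) {
    # interfacial zone: atoms within 4.5 A of the partner unit
    dmin <- vapply(seq_len(n), function(i) {
      min(sqrt((otherXyz[, 1] - atoms$x[i])^2 +
                 (otherXyz[, 2] - atoms$y[i])^2 +
                 (otherXyz[, 3] - atoms$z[i])^2))
    }, 1)
    zone <- dmin < 4.5
    b[zone] <- b[zone] - cfg$interfaceRigidity * sdev
  }
  pmax(b, 1)
}

#' Generate a synthetic two-unit complex
#'
#' Builds two chain-partitioned units in the configured geometry, assigns
#' raw-scale B factors from the configured model, writes the structure
#' through the standard PDB writer and re-reads it, so the full structure
#' I/O path is exercised, and returns the assembled [ComplexPair].
#'
#' @param cfg a [syntheticConfig()].
#' @param label class label to attach (`"biological"`, `"packing"`,
#'   `"unknown"`).
#' @return a [ComplexPair].
#' @export
syntheticComplex <- function(cfg, label = "unknown") {
  set.seed(cfg$seed)
  zoff <- switch(cfg$geometry, "slab-contact" = 1.7, "sphere-pair" = 1.7,
                 "separated" = 50)
  nz <- switch(cfg$geometry, "slab-contact" = 2L, "separated" = 2L,
               "sphere-pair" = max(2L, ceiling((cfg$residuesPerChain *
                                                  cfg$chainsPerUnit)^(1 / 3))))
  ua <- .buildUnitAtoms(cfg, "A", -1, zoff, nz)
  ub <- .buildUnitAtoms(cfg, "B", +1, zoff, nz)
  ua$b <- .assignBfactors(ua, cfg, as.matrix(ub[, c("x", "y", "z")]))
  ub$b <- .assignBfactors(ub, cfg, as.matrix(ua[, c("x", "y", "z")]))
  all <- rbind(ua, ub)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  bio3d::write.pdb(file = tmp,
                   xyz = as.numeric(t(as.matrix(all[, c("x", "y", "z")]))),
                   resno = all$resno, resid = all$resid,
                   eleno = seq_len(nrow(all)), elety = all$name,
                   chain = all$chain, o = rep(1, nrow(all)), b = all$b,
                   elesy = all$element)
  struct <- readStructure(tmp)
  struct$entryId <- sprintf("SYN%06d", cfg$seed %% 1000000L)
  complexFromChains(struct,
                    chainsA = unique(ua$chain), chainsB = unique(ub$chain),
                    label = label)
}

#' Generate a synthetic scored dataset
#'
#' Gaussian feature scores per class with attached labels; biological
#' scores are drawn at `muPos`, packing scores at `muNeg`.
#'
#' @param nPos,nNeg class sizes (`nNeg = 0` gives a positives-only set
#'   usable by [quantileThreshold()] only).
#' @param muPos,muNeg class means.
#' @param sigma common standard deviation (> 0).
#' @param seed RNG seed.
#' @param featureName carried in the output.
#' @return data.frame with columns `entryId`, `feature`, `score`, `label`.
#' @export
syntheticScores <- function(nPos, nNeg, muPos = -3, muNeg = 3, sigma = 1,
                            seed = 1L, featureName = "synthetic") {
  stopifnot(nPos > 0, nNeg >= 0, sigma > 0)
  set.seed(seed)
  score <- c(rnorm(nPos, muPos, sigma), rnorm(nNeg, muNeg, sigma))
  data.frame(
    entryId = sprintf("S%04d", seq_len(nPos + nNeg)),
    feature = featureName, score = score,
    label = rep(c("biological", "packing"), c(nPos, nNeg)),
    stringsAsFactors = FALSE)
}
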