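# Solvent-accessible surface area (Shrake-Rupley) and the buried-area
# baseline deltaASA = (ASA1 + ASA2 - ASAC) / 2.

#' Solvent-accessible surface area
#'
#' Numeric Shrake-Rupley SASA: each atom's sphere is inflated by the probe
#' radius and sampled with a deterministic golden-spiral lattice; the
#' accessible fraction of lattice points gives the per-atom area.  The same
#' lattice is used for every atom, so results are exactly reproducible for
#' a given `nSpherePoints`.
#'
#' @param x a [BioUnit], atom data.frame, or numeric coordinate matrix.
#' @param radii van der Waals radii; taken from the atoms when `x` carries
#'   them.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param nSpherePoints lattice points per atom.
#' @return list with `total` (Angstrom^2), `perAtom`, `probe`,
#'   `nSpherePoints`.
#' @export
sasa <- function(x, radii = NULL, probe = 1.4, nSpherePoints = 960) {
  if (probe <= 0) stop("probe radius must be positive")
  if (nSpherePoints < 1) stop("need at least one lattice point")
  if (is(x, "BioUnit")) x <- x@atoms
  if (is.data.frame(x)) {
    if (is.null(radii)) radii <- x$vdw
    x <- as.matrix(x[, c("x", "y", "z")])
  } else {
    x <- as.matrix(x)
  }
  if (is.null(radii)) stop("van der Waals radii are required")
  stopifnot(length(radii) == nrow(x), all(radii > 0))
  per <- .cppSasa(x, radii, probe, as.integer(nSpherePoints))
  list(total = sum(per), perAtom = per, probe = probe,
       nSpherePoints = as.integer(nSpherePoints))
}

#' Buried surface area of a complex
#'
#' `deltaASA = (ASA1 + ASA2 - ASAC) / 2`: half the solvent-accessible
#' area buried when the two units form the complex.  `avgDeltaASA`
#' divides by `log(minR + 1)` like the B-factor features.
#'
#' @param pair a [ComplexPair].
#' @param probe,nSpherePoints see [sasa()].
#' @param logBase log base of the size normalizer.
#' @return list with `deltaASA`, `avgDeltaASA`, `asa1`, `asa2`, `asaC`.
#' @export
deltaASA <- function(pair, probe = 1.4, nSpherePoints = 960,
                     logBase = exp(1)) {
  a <- pair@unitA@atoms
  b <- pair@unitB@atoms
  sa <- sasa(a, probe = probe, nSpherePoints = nSpherePoints)$total
  sb <- sasa(b, probe = probe, nSpherePoints = nSpherePoints)$total
  comb <- rbind(as.matrix(a[, c("x", "y", "z")]),
                as.matrix(b[, c("x", "y", "z")]))
  sc <- sasa(comb, radii = c(a$vdw, b$vdw), probe = probe,
             nSpherePoints = nSpherePoints)$total
  dA <- (sa + sb - sc) / 2
  list(deltaASA = dA,
       avgDeltaASA = dA / log(minR(pair) + 1, base = logBase),
       asa1 = sa, asa2 = sb, asaC = sc)
}
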