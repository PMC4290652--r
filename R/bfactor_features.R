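# Per-unit B-factor normalization and the B-factor interface features.

#' Normalize B factors within a binding unit
#'
#' Each atom's raw B factor is centred and scaled over all standard-residue
#' atoms of its own unit: `bNormRaw = (B - mean(B)) / (sd(B) * 1.645)`,
#' then clamped to \[-1, 1\].  The 1.645 constant maps the 90% normal
#' confidence interval onto \[-1, 1\], so values outside it saturate at the
#' nearer bound.  The standard deviation is the population form (divide by
#' N).  Normalization is always per contact partner, never over the whole
#' complex, so the two units' B-factor scales never mix.
#'
#' @param unit a [BioUnit] with at least 2 atoms.
#' @return data.frame with one row per atom of the unit: `atom` (row
#'   index), `bRaw`, `bNormRaw`, `bNorm`.
#' @export
normalizeBfactors <- function(unit) {
  a <- unit@atoms
  if (nrow(a) < 2L) stop("need at least 2 atoms to normalize B factors")
  ref <- a$b[a$isStandard]
  if (!length(ref)) ref <- a$b
  mu <- mean(ref)
  sdev <- sqrt(mean((ref - mu)^2))  # population sd
  if (sdev == 0) {
    warning("all B factors identical in unit ", unit@unitId,
            "; normalized B set to 0")
    raw <- rep(0, nrow(a))
  } else {
    raw <- (a$b - mu) / (sdev * 1.645)
  }
  data.frame(atom = seq_len(nrow(a)), bRaw = a$b, bNormRaw = raw,
             bNorm = pmin(pmax(raw, -1), 1))
}

#' Chain-size normalizer min_r
#'
#' For each unit, the mean number of standard residues per chain; `minR` is
#' the smaller of the two means.  It enters the smoothed features through
#' `log(minR + 1)` to damp the dependence of interface size on protein
#' size.
#'
#' @param pair a [ComplexPair].
#' @return single numeric value (residues).
#' @export
minR <- function(pair) {
  ra <- pair@unitA@residuesPerChain
  rb <- pair@unitB@residuesPerChain
  if (!length(ra) || !length(rb))
    stop("empty unit: residue counts unavailable")
  min(mean(ra), mean(rb))
}

#' Compute the B-factor interface features
#'
#' Given the interfacial atoms of both units and their normalized B
#' factors:
#' `sigmaB` is the sum of clamped normalized B factors over all interfacial
#' atoms of both units; `noB` counts interfacial atoms with strictly
#' negative normalized B; `avgSigmaB = sigmaB / log(minR + 1)` and
#' `avgNoB = noB / log(minR + 1)`; the compound score is
#' `avgNoB * avgSigmaB / 100`.  A pair with no interfacial atoms yields
#' all-zero features with `emptyInterface = TRUE` (tiny crystal contacts
#' are a legitimate outcome, not an error).
#'
#' @param pair a [ComplexPair].
#' @param interfacial list from [interfacialAtoms()].
#' @param normalized list with elements `A`, `B`: outputs of
#'   [normalizeBfactors()] per unit.
#' @param deltaASA optional buried-area value (Angstrom^2) to attach;
#'   `NA` leaves the area features unset.
#' @param logBase base of the logarithm in the size normalizer (natural
#'   log by default).
#' @return an [InterfaceFeatures] object.
#' @export
computeFeatures <- function(pair, interfacial, normalized,
                            deltaASA = NA_real_, logBase = exp(1)) {
  bA <- normalized$A$bNorm[interfacial$unitA]
  bB <- normalized$B$bNorm[interfacial$unitB]
  bn <- c(bA, bB)
  nInt <- length(bn)
  sigmaB <- sum(bn)
  noB <- sum(bn < 0)
  mr <- minR(pair)
  denom <- log(mr + 1, base = logBase)
  avgSigmaB <- sigmaB / denom
  avgNoB <- noB / denom
  new("InterfaceFeatures", entryId = pair@entryId,
      sigmaB = sigmaB, noB = as.numeric(noB), minR = mr,
      avgSigmaB = avgSigmaB, avgNoB = avgNoB,
      product = avgNoB * avgSigmaB / 100,
      deltaASA = deltaASA,
      avgDeltaASA = if (is.finite(deltaASA)) deltaASA / denom else NA_real_,
      nInterfacial = nInt, emptyInterface = nInt == 0L, logBase = logBase)
}

#' Full feature pipeline for one complex
#'
#' Runs beta-contact detection, interfacial-atom selection, per-unit B
#' normalization, optionally the buried-area baseline, and assembles an
#' [InterfaceFeatures] object.
#'
#' @param pair a [ComplexPair].
#' @param params [contactParams()].
#' @param withDeltaASA also compute the buried solvent-accessible area.
#' @param probe,nSpherePoints SASA settings (see [sasa()]).
#' @param logBase log base for the size normalizer.
#' @return an [InterfaceFeatures] object.
#' @export
interfaceFeatures <- function(pair, params = contactParams(),
                              withDeltaASA = TRUE, probe = 1.4,
                              nSpherePoints = 960, logBase = exp(1)) {
  contacts <- betaContacts(pair, params)
  ints <- interfacialAtoms(pair, contacts)
  norm <- list(A = normalizeBfactors(pair@unitA),
               B = normalizeBfactors(pair@unitB))
  da <- NA_real_
  if (withDeltaASA)
    da <- deltaASA(pair, probe = probe, nSpherePoints = nSpherePoints)$deltaASA
  computeFeatures(pair, ints, norm, deltaASA = da, logBase = logBase)
}
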