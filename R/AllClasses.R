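#' @useDynLib CrystalContact, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats sd quantile rnorm runif
#' @importFrom utils head read.table write.table
NULL

#' BioUnit: one binding partner of a protein complex
#'
#' A biological unit is the set of chains (possibly symmetry-generated copies)
#' that acts as one binding partner.  Atoms are held as a data.frame with one
#' row per non-hydrogen, non-water atom; the covalent bond graph is stored as
#' a two-column edge matrix over atom row indices.
#'
#' @slot unitId single identifier string.
#' @slot atoms data.frame with columns `serial`, `name`, `element`, `chain`,
#'   `resno`, `insert`, `resid`, `x`, `y`, `z`, `b`, `occupancy`,
#'   `isStandard`, `vdw`. Symmetry copies carry a suffixed chain id.
#' @slot bonds integer matrix, two columns of atom row indices (i < j).
#' @slot chains character vector of chain ids present.
#' @slot residuesPerChain named integer vector: standard-residue count per
#'   chain, used for the `min_r` size normalizer.
#' @exportClass BioUnit
setClass("BioUnit",
  representation(unitId = "character", atoms = "data.frame",
                 bonds = "matrix", chains = "character",
                 residuesPerChain = "integer"))

setValidity("BioUnit", function(object) {
  a <- object@atoms
  msg <- character()
  need <- c("serial", "name", "element", "chain", "resno", "insert",
            "resid", "x", "y", "z", "b", "occupancy", "isStandard", "vdw")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms lacks columns:",
                        paste(setdiff(need, names(a)), collapse = ", ")))
  else {
    if (nrow(a) > 0) {
      if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
        msg <- c(msg, "non-finite atom coordinates")
      if (any(!is.finite(a$b)) || any(a$b < 0))
        msg <- c(msg, "B factors must be finite and >= 0")
      if (any(!is.finite(a$vdw)) || any(a$vdw <= 0))
        msg <- c(msg, "van der Waals radii must be > 0")
      if (!all(a$chain %in% object@chains))
        msg <- c(msg, "atom chain id not listed in unit chains")
    }
    if (ncol(object@bonds) != 2)
      msg <- c(msg, "bonds must have two columns")
    else if (nrow(object@bonds) > 0) {
      b <- object@bonds
      if (min(b) < 1 || max(b) > nrow(a))
        msg <- c(msg, "bond indices outside the unit's atoms")
    }
    if (length(object@residuesPerChain) &&
        any(object@residuesPerChain < 1))
      msg <- c(msg, "residue counts must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' ComplexPair: two biological units from one entry
#'
#' @slot entryId PDB id or other entry label.
#' @slot unitA,unitB the two [BioUnit] partners.
#' @slot label one of `"biological"`, `"packing"`, `"unknown"`.
#' @slot resolution resolution in Angstrom (`NA_real_` when absent).
#' @exportClass ComplexPair
setClass("ComplexPair",
  representation(entryId = "character", unitA = "BioUnit", unitB = "BioUnit",
                 label = "character", resolution = "numeric"))

setValidity("ComplexPair", function(object) {
  msg <- character()
  if (!object@label %in% c("biological", "packing", "unknown"))
    msg <- c(msg, "label must be biological, packing or unknown")
  if (identical(object@unitA@unitId, object@unitB@unitId))
    msg <- c(msg, "the two units must have distinct unitIds")
  if (length(msg)) msg else TRUE
})

#' InterfaceFeatures: per-interface B-factor and area scores
#'
#' Holds the sum of clamped normalized B factors over interfacial atoms
#' (`sigmaB`), the count with negative normalized B (`noB`), the chain-size
#' normalizer `minR`, the smoothed scores `avgSigmaB = sigmaB/log(minR+1)` and
#' `avgNoB = noB/log(minR+1)`, the compound `product = avgNoB * avgSigmaB/100`,
#' and the buried-area baseline `deltaASA` (with `avgDeltaASA`), `NA` when not
#' computed.
#'
#' @exportClass InterfaceFeatures
setClass("InterfaceFeatures",
  representation(entryId = "character", sigmaB = "numeric", noB = "numeric",
                 minR = "numeric", avgSigmaB = "numeric", avgNoB = "numeric",
                 product = "numeric", deltaASA = "numeric",
                 avgDeltaASA = "numeric", nInterfacial = "integer",
                 emptyInterface = "logical", logBase = "numeric"))

setValidity("InterfaceFeatures", function(object) {
  msg <- character()
  if (object@noB < 0) msg <- c(msg, "noB must be >= 0")
  if (object@noB > object@nInterfacial)
    msg <- c(msg, "noB cannot exceed the number of interfacial atoms")
  if (abs(object@sigmaB) > object@nInterfacial + 1e-9)
    msg <- c(msg, "|sigmaB| cannot exceed the number of interfacial atoms")
  if (is.finite(object@product) &&
      abs(object@product - object@avgNoB * object@avgSigmaB / 100) > 1e-9)
    msg <- c(msg, "product must equal avgNoB * avgSigmaB / 100")
  if (length(msg)) msg else TRUE
})

#' ThresholdModel: a learned single-feature decision rule
#'
#' @slot featureName feature the rule applies to.
#' @slot threshold learned split value (same units as the score).
#' @slot direction `"positive-is-biological"` (score above threshold is
#'   called biological) or `"negative-is-biological"`.
#' @slot topFraction fraction of best-ranked candidate splits averaged.
#' @slot candidateSplits the split points that were averaged.
#' @slot meta list of provenance details (n, method, quantile type, ...).
#' @exportClass ThresholdModel
setClass("ThresholdModel",
  representation(featureName = "character", threshold = "numeric",
                 direction = "character", topFraction = "numeric",
                 candidateSplits = "numeric", meta = "list"))

setValidity("ThresholdModel", function(object) {
  msg <- character()
  if (!object@direction %in%
      c("positive-is-biological", "negative-is-biological"))
    msg <- c(msg, "unknown direction")
  if (length(object@candidateSplits) &&
      abs(object@threshold - mean(object@candidateSplits)) > 1e-9)
    msg <- c(msg, "threshold must be the mean of candidateSplits")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BioUnit", function(object) {
  cat("BioUnit", object@unitId, "|",
      nrow(object@atoms), "atoms,",
      length(object@chains), "chain(s):",
      paste(object@chains, collapse = ","), "\n")
  cat("  residues/chain:",
      paste(sprintf("%s=%d", names(object@residuesPerChain),
                    object@residuesPerChain), collapse = " "),
      "| bonds:", nrow(object@bonds), "\n")
})

setMethod("show", "ComplexPair", function(object) {
  cat("ComplexPair", object@entryId, sprintf("[%s]", object@label),
      if (is.finite(object@resolution))
        sprintf("%.2f A", object@resolution) else "", "\n")
  cat("  A:", object@unitA@unitId, sprintf("(%d atoms)", nrow(object@unitA@atoms)),
      " B:", object@unitB@unitId, sprintf("(%d atoms)", nrow(object@unitB@atoms)), "\n")
})

setMethod("show", "InterfaceFeatures", function(object) {
  cat("InterfaceFeatures", object@entryId, "\n")
  cat(sprintf("  sigmaB=%.3f noB=%g minR=%.2f\n",
              object@sigmaB, object@noB, object@minR))
  cat(sprintf("  avgSigmaB=%.3f avgNoB=%.3f product=%.4f\n",
              object@avgSigmaB, object@avgNoB, object@product))
  cat(sprintf("  deltaASA=%.2f A^2 avgDeltaASA=%.3f (n interfacial=%d%s)\n",
              object@deltaASA, object@avgDeltaASA, object@nInterfacial,
              if (object@emptyInterface) ", empty interface" else ""))
})

setMethod("show", "ThresholdModel", function(object) {
  cat("ThresholdModel for", object@featureName, "\n")
  cat(sprintf("  threshold=%.4f direction=%s (%d splits averaged, top %.0f%%)\n",
              object@threshold, object@direction,
              length(object@candidateSplits), 100 * object@topFraction))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for CrystalContact objects
#'
#' @param x a `BioUnit`, `ComplexPair`, `InterfaceFeatures` or
#'   `ThresholdModel`.
#' @return `unitAtoms`: the atom data.frame; `unitBonds`: the covalent edge
#'   matrix; `unitChains`: chain ids; `residuesPerChain`: named residue
#'   counts; `pairUnits`: list of the two `BioUnit`s; `pairLabel`: the class
#'   label; `featureVector`: named numeric vector of all interface scores;
#'   `modelThreshold` / `modelDirection`: the learned rule.
#' @name accessors
NULL

#' @rdname accessors
#' @export
unitAtoms <- function(x) x@atoms

#' @rdname accessors
#' @export
unitBonds <- function(x) x@bonds

#' @rdname accessors
#' @export
unitChains <- function(x) x@chains

#' @rdname accessors
#' @export
residuesPerChain <- function(x) x@residuesPerChain

#' @rdname accessors
#' @export
pairUnits <- function(x) list(A = x@unitA, B = x@unitB)

#' @rdname accessors
#' @export
pairLabel <- function(x) x@label

#' @rdname accessors
#' @export
featureVector <- function(x) {
  c(sigmaB = x@sigmaB, noB = x@noB, minR = x@minR,
    avgSigmaB = x@avgSigmaB, avgNoB = x@avgNoB, product = x@product,
    deltaASA = x@deltaASA, avgDeltaASA = x@avgDeltaASA)
}

#' @rdname accessors
#' @export
modelThreshold <- function(x) x@threshold

#' @rdname accessors
#' @export
modelDirection <- function(x) x@direction
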