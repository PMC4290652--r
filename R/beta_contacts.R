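# Atomic beta contacts: distance criterion + shared Voronoi facet + empty
# beta-skeleton forbidden region, followed by the local-contact rule that
# selects interfacial atoms.

#' Contact-detection parameters
#'
#' @param td distance slack added to the summed van der Waals radii,
#'   Angstrom. The default 2.8 A is roughly a water diameter.
#' @param betaAngle forbidden-region angle threshold in degrees; 90 degrees
#'   gives the Gabriel-graph (empty diametral sphere) criterion.
#' @return validated list with elements `td`, `betaAngle`.
#' @export
contactParams <- function(td = 2.8, betaAngle = 90) {
  stopifnot(is.numeric(td), td > 0,
            is.numeric(betaAngle), betaAngle > 0, betaAngle <= 180)
  list(td = td, betaAngle = betaAngle)
}

.checkGeometry <- function(coords) {
  if (nrow(coords) < 5L)
    stop("degenerate geometry: at least 5 points are needed for a 3-D ",
         "Voronoi diagram")
  cc <- sweep(coords, 2, colMeans(coords))
  sv <- svd(cc, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: points are (near-)coplanar")
  invisible(TRUE)
}

#' Voronoi facet-sharing atom pairs
#'
#' Determines which atom pairs share a Voronoi facet of positive area.  The
#' facet of pair (i, j) is the region of the bisector plane at least as
#' close to i and j as to every other atom; it is computed exactly by
#' clipping the plane with one halfplane per other atom, so the facet area
#' is available and near-degenerate (cospherical) configurations resolve by
#' the area threshold.
#'
#' @param coords numeric matrix, one row per atom (x, y, z).
#' @param pairs optional two-column matrix of candidate pairs (1-based row
#'   indices); default all pairs.
#' @param minArea facets below this area (Angstrom^2) are not counted.
#' @return data.frame with columns `i`, `j` (i < j), `area`, one row per
#'   facet-sharing pair.
#' @export
voronoiFacetPairs <- function(coords, pairs = NULL, minArea = 1e-12) {
  coords <- as.matrix(coords)
  .checkGeometry(coords)
  n <- nrow(coords)
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- cbind(idx[, "row"], idx[, "col"])
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  ext <- max(apply(coords, 2, function(v) diff(range(v))))
  areas <- .cppFacetAreas(coords, pairs, halfWidth = 1e7 + 10 * ext)
  keep <- areas >= minArea
  data.frame(i = pairs[keep, 1], j = pairs[keep, 2], area = areas[keep])
}

#' Is the forbidden region of a pair empty?
#'
#' The forbidden region of atoms i, j is the locus of points subtending an
#' angle of at least `betaAngle` over the segment ij; at 90 degrees it is
#' the sphere with ij as diameter.  The region is empty when every other
#' atom subtends a strictly smaller angle.
#'
#' @param i,j atom row indices.
#' @param coords numeric matrix of all atom coordinates.
#' @param betaAngle angle threshold, degrees.
#' @return logical.
#' @export
forbiddenRegionEmpty <- function(i, j, coords, betaAngle = 90) {
  stopifnot(i != j)
  coords <- as.matrix(coords)
  as.logical(.cppForbiddenEmpty(coords, cbind(as.integer(i), as.integer(j)),
                                cos(betaAngle * pi / 180)))
}

#' Compute beta contacts across an interface
#'
#' A cross-unit atom pair is a beta contact when (i) its distance is below
#' `td` plus the summed van der Waals radii, (ii) the two atoms share a
#' Voronoi facet in the diagram of the whole complex, and (iii) the
#' beta-skeleton forbidden region of the pair contains no other atom.
#' Hetero atoms are never contact candidates but act as geometric blockers
#' in (ii) and (iii) unless `includeHetBlockers = FALSE`.
#'
#' @param pair a [ComplexPair].
#' @param params a [contactParams()] list.
#' @param includeHetBlockers keep non-water hetero atoms in the Voronoi /
#'   forbidden-region geometry.
#' @return data.frame of contact records: `iA`, `iB` (atom row indices in
#'   each unit), atom/residue identities, `distance`, and the three
#'   criterion flags `passedDistance`, `sharedFacet`, `frEmpty` with their
#'   conjunction `isBeta`.
#' @export
betaContacts <- function(pair, params = contactParams(),
                         includeHetBlockers = TRUE) {
  ua <- pair@unitA@atoms
  ub <- pair@unitB@atoms
  if (nrow(ua) == 0L || nrow(ub) == 0L) stop("empty biological unit")
  candA <- which(ua$isStandard)
  candB <- which(ub$isStandard)
  blockA <- if (includeHetBlockers) seq_len(nrow(ua)) else candA
  blockB <- if (includeHetBlockers) seq_len(nrow(ub)) else candB

  cp <- .cppCrossPairs(as.matrix(ua[candA, c("x", "y", "z")]),
                       as.matrix(ub[candB, c("x", "y", "z")]),
                       ua$vdw[candA], ub$vdw[candB], params$td)
  empty <- data.frame(iA = integer(), iB = integer(),
                      chainA = character(), resnoA = integer(),
                      nameA = character(), chainB = character(),
                      resnoB = integer(), nameB = character(),
                      distance = numeric(), passedDistance = logical(),
                      sharedFacet = logical(), frEmpty = logical(),
                      isBeta = logical())
  if (nrow(cp) == 0L) return(empty)

  combined <- rbind(as.matrix(ua[blockA, c("x", "y", "z")]),
                    as.matrix(ub[blockB, c("x", "y", "z")]))
  .checkGeometry(combined)
  mapA <- match(candA[cp$i], blockA)
  mapB <- match(candB[cp$j], blockB) + length(blockA)
  pr <- cbind(mapA, mapB)
  ext <- max(apply(combined, 2, function(v) diff(range(v))))
  areas <- .cppFacetAreas(combined, pr, halfWidth = 1e7 + 10 * ext)
  fr <- as.logical(.cppForbiddenEmpty(combined, pr,
                                      cos(params$betaAngle * pi / 180)))
  iA <- candA[cp$i]
  iB <- candB[cp$j]
  data.frame(iA = iA, iB = iB,
             chainA = ua$chain[iA], resnoA = ua$resno[iA], nameA = ua$name[iA],
             chainB = ub$chain[iB], resnoB = ub$resno[iB], nameB = ub$name[iB],
             distance = cp$distance, passedDistance = TRUE,
             sharedFacet = areas >= 1e-12, frEmpty = fr,
             isBeta = areas >= 1e-12 & fr)
}

.localContactCounts <- function(unit, contactIdx) {
  # contactIdx: atom row index of each beta contact on this side
  n <- nrow(unit@atoms)
  own <- tabulate(contactIdx, nbins = n)
  touched <- which(own > 0L)
  local <- integer(n)
  for (a in touched) local[a] <- sum(own[covalentNearby(unit, a)])
  # atoms without their own contact can still accumulate via neighbours,
  # but only contact-bearing atoms are candidates, so `touched` suffices
  list(own = own, local = local)
}

#' Select interfacial atoms by the local-contact rule
#'
#' An atom is interfacial when it has at least one beta contact across the
#' interface and its number of local contacts exceeds 2, local contacts
#' being the beta contacts of the atom itself plus those of its
#' covalently-bonded nearby atoms (within two bond steps).  The rule keeps
#' only non-isolated atomic contacts.
#'
#' @param pair a [ComplexPair].
#' @param contacts output of [betaContacts()] for the same pair.
#' @return list with integer vectors `unitA`, `unitB` of interfacial atom
#'   row indices.
#' @export
interfacialAtoms <- function(pair, contacts) {
  beta <- contacts[contacts$isBeta, , drop = FALSE]
  if (nrow(beta) == 0L) return(list(unitA = integer(), unitB = integer()))
  ca <- .localContactCounts(pair@unitA, beta$iA)
  cb <- .localContactCounts(pair@unitB, beta$iB)
  list(unitA = which(ca$own > 0L & ca$local > 2L),
       unitB = which(cb$own > 0L & cb$local > 2L))
}
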