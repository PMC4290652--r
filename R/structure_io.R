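# Reading PDB structures, assembling biological units, covalent bonds and
# entry-level quality control.

.guessElement <- function(elesy, elety) {
  e <- toupper(trimws(elesy))
  bad <- is.na(e) | e == ""
  if (any(bad)) {
    # fall back to the atom name: strip digits/primes, take the leading
    # element symbol (two-letter only when it matches a known element)
    nm <- toupper(gsub("[0-9' ]", "", elety[bad]))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    known2 <- two %in% names(.vdwTable) & nchar(nm) > 1 &
      !(one %in% c("C", "N", "O", "S", "P", "H"))
    e[bad] <- ifelse(known2, two, one)
  }
  e
}

.resolveAltloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (!any(alt != "")) return(atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, atom$resid,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atom)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- occ[idx]
    best <- idx[o == max(o)]
    if (length(best) > 1L) best <- best[order(alt[best])][1L]  # tie -> 'A'
    best[1L]
  }), use.names = FALSE)
  atom[sort(keep), , drop = FALSE]
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (through [bio3d::read.pdb()]), resolves
#' alternate locations to the highest-occupancy conformer (ties broken
#' towards altloc `A`), removes hydrogens and waters, and extracts the
#' experimental method, resolution and REMARK 350 biological-assembly
#' definitions.
#'
#' @param x path to a PDB file, or a character vector of PDB-format lines.
#' @return an object of class `PDBStructure`: a list with elements `atoms`
#'   (data.frame of retained atoms with element, vdW radius and
#'   standard-residue flag), `biomolecules` (parsed REMARK 350, see
#'   [parseRemark350()]), `method`, `resolution` and `entryId`.
#' @details Hetero (non-water HETATM) atoms are retained and flagged
#'   `isStandard = FALSE`; downstream contact detection uses them as
#'   geometric blockers but never as interfacial-atom candidates.
#' @export
readStructure <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    entry <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(x))
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    entry <- "UNKNOWN"
  }
  isAtomLine <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtomLine)) stop("no ATOM records found: empty structure")

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom

  badnum <- which(!is.finite(atom$x) | !is.finite(atom$y) |
                    !is.finite(atom$z) | !is.finite(atom$b))
  if (length(badnum)) {
    lineno <- which(isAtomLine)[badnum[1L]]
    stop(sprintf("malformed coordinate or B-factor field at line %d", lineno))
  }

  hdr <- lines[grepl("^(REMARK   2|EXPDTA|HEADER)", lines)]
  res <- NA_real_
  m <- regmatches(hdr, regexpr("RESOLUTION\\.\\s+([0-9.]+)", hdr))
  if (length(m)) res <- as.numeric(sub(".*RESOLUTION\\.\\s+", "", m[1L]))
  method <- NA_character_
  ex <- lines[grepl("^EXPDTA", lines)]
  if (length(ex)) method <- trimws(substring(ex[1L], 11))
  idl <- lines[grepl("^HEADER", lines)]
  if (length(idl) && nchar(idl[1L]) >= 66) {
    id <- trimws(substring(idl[1L], 63, 66))
    if (nzchar(id)) entry <- id
  }

  atom <- .resolveAltloc(atom)
  atom$insert[is.na(atom$insert)] <- ""
  elem <- .guessElement(atom$elesy, atom$elety)
  water <- atom$resid %in% .waterResidues
  hydro <- elem %in% c("H", "D")
  atom <- atom[!water & !hydro, , drop = FALSE]
  elem <- elem[!water & !hydro]
  if (nrow(atom) == 0L) stop("no heavy atoms left after filtering")

  b <- atom$b
  b[b < 0] <- 0  # rare deposition artifacts; spec-level invariant b >= 0
  occ <- atom$o
  occ[is.na(occ)] <- 1
  out <- data.frame(
    serial = atom$eleno, name = trimws(atom$elety), element = elem,
    chain = atom$chain, resno = atom$resno, insert = atom$insert,
    resid = atom$resid, x = atom$x, y = atom$y, z = atom$z, b = b,
    occupancy = occ,
    isStandard = atom$resid %in% .standardResidues,  # incl. HETATM MSE
    vdw = vdwRadius(elem),
    stringsAsFactors = FALSE)
  structure(list(atoms = out, biomolecules = parseRemark350(lines),
                 method = method, resolution = res, entryId = entry),
            class = "PDBStructure")
}

#' Parse REMARK 350 biological-assembly records
#'
#' @param lines character vector of PDB lines.
#' @return list with one element per biomolecule, each a list with `id` and
#'   `groups`; every group has `chains` and `transforms` (a list of 3x4
#'   rotation+translation matrices to apply to those chains).
#' @export
parseRemark350 <- function(lines) {
  r <- lines[grepl("^REMARK 350", lines)]
  # record stream: (biomolecule, group index within biomolecule) per line
  bioId <- NA_integer_
  grpIdx <- 0L
  recBio <- integer(); recGrp <- integer(); recKind <- character()
  recPayload <- list()
  for (ln in r) {
    if (grepl("BIOMOLECULE:", ln)) {
      bioId <- as.integer(sub(".*BIOMOLECULE:\\s*", "", ln))
      grpIdx <- 0L
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:", ln)) {
      grpIdx <- grpIdx + 1L
      recBio <- c(recBio, bioId); recGrp <- c(recGrp, grpIdx)
      recKind <- c(recKind, "chains")
      recPayload <- c(recPayload,
                      list(trimws(strsplit(sub(".*TO CHAINS:\\s*", "", ln), ",")[[1]])))
    } else if (grepl("AND CHAINS:", ln) && grpIdx > 0L) {
      recBio <- c(recBio, bioId); recGrp <- c(recGrp, grpIdx)
      recKind <- c(recKind, "chains")
      recPayload <- c(recPayload,
                      list(trimws(strsplit(sub(".*AND CHAINS:\\s*", "", ln), ",")[[1]])))
    } else if (grepl("BIOMT[123]", ln) && grpIdx > 0L) {
      k <- as.integer(sub(".*BIOMT([123]).*", "\\1", ln))
      body <- sub(".*BIOMT[123]\\s+", "", ln)
      vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
      if (length(vals) < 5 || anyNA(vals))
        stop("malformed BIOMT record: ", ln)
      # vals[1] is the operator number; vals[2:5] the matrix row
      recBio <- c(recBio, bioId); recGrp <- c(recGrp, grpIdx)
      recKind <- c(recKind, "biomt")
      recPayload <- c(recPayload, list(c(k, vals[1], vals[2:5])))
    }
  }
  out <- list()
  for (id in unique(recBio)) {
    groups <- list()
    for (g in unique(recGrp[recBio == id])) {
      sel <- which(recBio == id & recGrp == g)
      chains <- unique(unlist(recPayload[sel[recKind[sel] == "chains"]]))
      bi <- recPayload[sel[recKind[sel] == "biomt"]]
      transforms <- list()
      if (length(bi)) {
        ops <- vapply(bi, function(v) v[2], 1)
        for (op in unique(ops)) {
          rows <- bi[ops == op]
          ks <- vapply(rows, function(v) v[1], 1)
          m <- matrix(NA_real_, 3, 4)
          for (q in seq_along(rows)) m[ks[q], ] <- rows[[q]][3:6]
          if (anyNA(m)) stop("incomplete BIOMT operator ", op,
                             " in biomolecule ", id)
          transforms[[length(transforms) + 1L]] <- m
        }
      }
      if (!length(transforms)) transforms <- list(cbind(diag(3), c(0, 0, 0)))
      groups[[length(groups) + 1L]] <- list(chains = chains,
                                            transforms = transforms)
    }
    out[[length(out) + 1L]] <- list(id = id, groups = groups)
  }
  out
}

.applyTransform <- function(xyz, mat) {
  rot <- mat[, 1:3, drop = FALSE]
  if (abs(det(rot)) < 1e-8) stop("singular transform matrix")
  sweep(as.matrix(xyz) %*% t(rot), 2, mat[, 4], `+`)
}

#' Assemble a biological unit from selected chains
#'
#' Applies each rotation+translation in `transforms` to the selected chains
#' and stacks the copies into one [BioUnit]; the covalent bond graph and
#' per-chain residue counts are computed on the result.  Symmetry copies
#' after the first get a `.k` suffix on their chain id.
#'
#' @param struct a `PDBStructure` from [readStructure()], or an atom
#'   data.frame in the same layout.
#' @param chains chain ids to include.
#' @param transforms list of 3x4 (or 4x4) matrices; `NULL` means identity.
#' @param unitId identifier for the unit.
#' @return a [BioUnit].
#' @export
assembleBioUnit <- function(struct, chains, transforms = NULL,
                            unitId = paste(chains, collapse = "")) {
  atoms <- if (inherits(struct, "PDBStructure")) struct$atoms else struct
  if (length(chains) == 0L) stop("chain selection is empty")
  missing <- setdiff(chains, unique(atoms$chain))
  if (length(missing))
    stop("unknown chain id(s): ", paste(missing, collapse = ", "))
  if (is.null(transforms)) transforms <- list(cbind(diag(3), c(0, 0, 0)))
  sel <- atoms[atoms$chain %in% chains, , drop = FALSE]
  copies <- vector("list", length(transforms))
  for (t in seq_along(transforms)) {
    mat <- transforms[[t]]
    if (nrow(mat) == 4L) mat <- mat[1:3, , drop = FALSE]
    cp <- sel
    cp[, c("x", "y", "z")] <- .applyTransform(sel[, c("x", "y", "z")], mat)
    if (t > 1L) cp$chain <- paste0(cp$chain, ".", t - 1L)
    copies[[t]] <- cp
  }
  all <- do.call(rbind, copies)
  rownames(all) <- NULL
  std <- all[all$isStandard, , drop = FALSE]
  if (nrow(std)) {
    key <- paste(std$resno, std$insert, sep = "\r")
    rpc <- vapply(split(key, std$chain), function(k) length(unique(k)), 1L)
  } else rpc <- integer()
  unit <- new("BioUnit", unitId = unitId, atoms = all,
              bonds = matrix(integer(), ncol = 2), chains = unique(all$chain),
              residuesPerChain = rpc)
  unit@bonds <- inferCovalentBonds(unit)
  validObject(unit)
  unit
}

#' Infer covalent bonds within a unit
#'
#' An edge joins atoms i, j when their distance is at most the sum of their
#' covalent radii plus `tol` and they belong to the same residue, or are the
#' peptide pair C(r)-N(r+1) of adjacent residues in one chain; disulfides
#' (S-S <= 2.3 A) are added irrespective of residue.
#'
#' @param unit a [BioUnit] (or atom data.frame).
#' @param tol distance tolerance over summed covalent radii, Angstrom.
#' @return integer matrix with columns `i`, `j` (atom row indices, i < j).
#' @export
inferCovalentBonds <- function(unit, tol = 0.4) {
  atoms <- if (is(unit, "BioUnit")) unit@atoms else unit
  n <- nrow(atoms)
  if (n < 2L) return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  covr <- covalentRadius(atoms$element)
  cand <- .cppClosePairs(as.matrix(atoms[, c("x", "y", "z")]),
                         pmax(covr, 1.05),  # S has the largest radius in play
                         tol)
  if (nrow(cand) == 0L)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  i <- cand$i; j <- cand$j; d <- cand$distance
  withinCov <- d <= covr[i] + covr[j] + tol
  sameRes <- atoms$chain[i] == atoms$chain[j] &
    atoms$resno[i] == atoms$resno[j] & atoms$insert[i] == atoms$insert[j]
  pep <- atoms$chain[i] == atoms$chain[j] &
    ((atoms$resno[j] - atoms$resno[i] == 1L & atoms$name[i] == "C" &
        atoms$name[j] == "N") |
       (atoms$resno[i] - atoms$resno[j] == 1L & atoms$name[j] == "C" &
          atoms$name[i] == "N"))
  ss <- atoms$element[i] == "S" & atoms$element[j] == "S" & d <= 2.3
  keep <- (withinCov & (sameRes | pep)) | ss
  cbind(i = as.integer(i[keep]), j = as.integer(j[keep]))
}

#' Atoms within two covalent-bond steps
#'
#' Returns the covalently-bonded nearby atoms of `atomIdx`: every atom at
#' bond-graph distance 0, 1 or 2 (the atom itself included).
#'
#' @param unit a [BioUnit], or a bond edge matrix.
#' @param atomIdx atom row index to query.
#' @param depth number of bond steps (default 2).
#' @return sorted integer vector of atom row indices.
#' @export
covalentNearby <- function(unit, atomIdx, depth = 2L) {
  bonds <- if (is(unit, "BioUnit")) unit@bonds else unit
  n <- if (is(unit, "BioUnit")) nrow(unit@atoms) else max(c(bonds, atomIdx))
  if (atomIdx < 1L || atomIdx > n) stop("unknown atom id: ", atomIdx)
  frontier <- atomIdx
  seen <- atomIdx
  for (step in seq_len(depth)) {
    if (!length(frontier) || nrow(bonds) == 0L) break
    nb <- c(bonds[bonds[, 1] %in% frontier, 2],
            bonds[bonds[, 2] %in% frontier, 1])
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  sort(unique(as.integer(seen)))
}

#' Entry-level quality filter
#'
#' Applies the construction rules used when compiling complexes from
#' affinity-annotated PDB entries: (i) X-ray crystallography, (ii)
#' resolution better than 2.5 A, (iii) at least 3 atoms per residue
#' (crude error screen), (iv) both partners longer than 5 residues,
#' (v) under 20% of interface contacts from non-standard residues.
#'
#' @param method experimental method string.
#' @param resolution resolution, Angstrom.
#' @param nAtoms,nResidues entry-wide atom and residue counts.
#' @param partnerResidues integer vector of length 2: residues per partner.
#' @param nonstdContactFraction fraction of interface atomic contacts made
#'   by non-standard residues, in \[0, 1\].
#' @return list with `pass` (logical) and `failed` (character vector of
#'   violated rule tags among "i".."v").
#' @export
filterComplexEntry <- function(method, resolution, nAtoms, nResidues,
                               partnerResidues, nonstdContactFraction) {
  args <- list(method = method, resolution = resolution, nAtoms = nAtoms,
               nResidues = nResidues, partnerResidues = partnerResidues,
               nonstdContactFraction = nonstdContactFraction)
  for (nm in names(args))
    if (length(args[[nm]]) == 0L || anyNA(args[[nm]]))
      stop("missing QC field: ", nm)
  if (nonstdContactFraction < 0 || nonstdContactFraction > 1)
    stop("nonstdContactFraction must be in [0, 1]")
  failed <- character()
  if (!grepl("X-RAY", toupper(method))) failed <- c(failed, "i")
  if (!(resolution < 2.5)) failed <- c(failed, "ii")
  if (!(nAtoms >= 3 * nResidues)) failed <- c(failed, "iii")
  if (!all(partnerResidues > 5)) failed <- c(failed, "iv")
  if (!(nonstdContactFraction < 0.20)) failed <- c(failed, "v")
  list(pass = length(failed) == 0L, failed = failed)
}

#' Build a ComplexPair from two chain groups
#'
#' @param struct a `PDBStructure`.
#' @param chainsA,chainsB chain ids of the two partners.
#' @param transformsA,transformsB optional transform lists per partner.
#' @param label `"biological"`, `"packing"` or `"unknown"`.
#' @param entryId entry label (defaults to the structure's).
#' @return a [ComplexPair].
#' @export
complexFromChains <- function(struct, chainsA, chainsB,
                              transformsA = NULL, transformsB = NULL,
                              label = "unknown", entryId = NULL) {
  if (is.null(entryId))
    entryId <- if (inherits(struct, "PDBStructure")) struct$entryId else "UNKNOWN"
  ua <- assembleBioUnit(struct, chainsA, transformsA,
                        unitId = paste0("A:", paste(chainsA, collapse = "")))
  ub <- assembleBioUnit(struct, chainsB, transformsB,
                        unitId = paste0("B:", paste(chainsB, collapse = "")))
  res <- if (inherits(struct, "PDBStructure")) struct$resolution else NA_real_
  new("ComplexPair", entryId = entryId, unitA = ua, unitB = ub,
      label = label, resolution = if (is.null(res)) NA_real_ else res)
}

#' Build a ComplexPair from a REMARK 350 biomolecule
#'
#' The biomolecule's (chain group x transform) combinations become the two
#' binding partners: a single chain group with two BIOMT operators yields
#' the identity copy versus the symmetry copy; a single-operator group of
#' two chains yields one unit per chain.  Anything more complex must be
#' specified explicitly through [complexFromChains()].
#'
#' @param struct a `PDBStructure` with REMARK 350 records.
#' @param biomolecule biomolecule number as given in REMARK 350.
#' @param label,entryId as in [complexFromChains()].
#' @return a [ComplexPair].
#' @export
complexFromBiomolecule <- function(struct, biomolecule, label = "unknown",
                                   entryId = struct$entryId) {
  ids <- vapply(struct$biomolecules, function(b) b$id, 1L)
  k <- match(biomolecule, ids)
  if (is.na(k)) stop("biomolecule ", biomolecule, " not present in REMARK 350")
  bm <- struct$biomolecules[[k]]
  combos <- list()
  for (g in bm$groups)
    for (t in seq_along(g$transforms))
      combos[[length(combos) + 1L]] <-
        list(chains = g$chains, transform = g$transforms[[t]])
  if (length(combos) == 1L && length(combos[[1L]]$chains) == 2L) {
    ch <- combos[[1L]]$chains
    tr <- list(combos[[1L]]$transform)
    return(complexFromChains(struct, ch[1L], ch[2L], tr, tr, label, entryId))
  }
  if (length(combos) != 2L)
    stop("biomolecule ", biomolecule, " does not define exactly two units; ",
         "specify the partners with complexFromChains()")
  ua <- assembleBioUnit(struct, combos[[1L]]$chains,
                        list(combos[[1L]]$transform), unitId = "A")
  ub <- assembleBioUnit(struct, combos[[2L]]$chains,
                        list(combos[[2L]]$transform), unitId = "B")
  res <- struct$resolution
  new("ComplexPair", entryId = entryId, unitA = ua, unitB = ub, label = label,
      resolution = if (is.null(res)) NA_real_ else res)
}

#' Write a BioUnit to PDB format
#'
#' Chain ids longer than one character (symmetry copies) are remapped to
#' unused single letters.
#'
#' @param unit a [BioUnit].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeUnitPDB <- function(unit, file) {
  a <- unit@atoms
  ch <- a$chain
  long <- nchar(ch) > 1L
  if (any(long)) {
    pool <- setdiff(c(LETTERS, letters, 0:9), unique(ch[!long]))
    map <- stats::setNames(pool[seq_along(unique(ch[long]))], unique(ch[long]))
    ch[long] <- map[ch[long]]
  }
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = a$serial,
                   elety = a$name, chain = ch, insert = a$insert,
                   o = a$occupancy, b = a$b, elesy = a$element)
  invisible(file)
}
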