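# Shared fixtures and independent geometry oracles used across the suite.

# one fixed-format PDB ATOM/HETATM line
pdbLine <- function(serial, name, resid, chain, resno, x, y, z,
                    occ = 1, b = 10, elem = substr(name, 1, 1),
                    record = "ATOM", alt = " ", icode = " ") {
  nm <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resid, chain, resno, icode,
          x, y, z, occ, b, elem)
}

# minimal BioUnit straight from coordinates (element C unless given)
makeUnit <- function(coords, element = "C", chain = "A", b = 10,
                     unitId = "U", resno = NULL, name = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  element <- rep_len(element, n)
  b <- rep_len(b, n)
  if (is.null(resno)) resno <- seq_len(n)
  resno <- rep_len(resno, n)
  chain <- rep_len(chain, n)
  if (is.null(name)) name <- paste0(element, seq_len(n))
  atoms <- data.frame(serial = seq_len(n), name = name, element = element,
                      chain = chain, resno = resno, insert = "",
                      resid = "ALA", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], b = b, occupancy = 1,
                      isStandard = TRUE, vdw = vdwRadius(element),
                      stringsAsFactors = FALSE)
  unit <- methods::new("BioUnit", unitId = unitId, atoms = atoms,
                       bonds = matrix(integer(), ncol = 2),
                       chains = unique(atoms$chain),
                       residuesPerChain = vapply(split(resno, chain),
                                                 function(r)
                                                   length(unique(r)), 1L))
  unit@bonds <- inferCovalentBonds(unit)
  unit
}

makePair <- function(coordsA, coordsB, bA = 10, bB = 10, label = "unknown") {
  methods::new("ComplexPair", entryId = "TOY",
               unitA = makeUnit(coordsA, b = bA, unitId = "A"),
               unitB = makeUnit(coordsB, b = bB, unitId = "B", chain = "B"),
               label = label, resolution = NA_real_)
}

# brute-force Gabriel graph: edge iff the sphere on ij as diameter is empty
bruteGabriel <- function(x) {
  n <- nrow(x)
  prs <- t(utils::combn(n, 2))
  keep <- vapply(seq_len(nrow(prs)), function(q) {
    i <- prs[q, 1]; j <- prs[q, 2]
    m <- (x[i, ] + x[j, ]) / 2
    r2 <- sum((x[i, ] - m)^2)
    d2 <- rowSums((x - matrix(m, n, 3, byrow = TRUE))^2)
    d2[c(i, j)] <- Inf
    all(d2 > r2)
  }, TRUE)
  prs[keep, , drop = FALSE]
}

# brute-force Delaunay adjacency by empty-circumsphere enumeration over all
# 4-point subsets; practical for small n only
bruteDelaunayEdges <- function(x) {
  n <- nrow(x)
  quads <- utils::combn(n, 4)
  edges <- character()
  for (q in seq_len(ncol(quads))) {
    idx <- quads[, q]
    p <- x[idx, ]
    # circumcenter: solve 2 (p_i - p_1) . c = |p_i|^2 - |p_1|^2
    A <- 2 * sweep(p[-1, , drop = FALSE], 2, p[1, ])
    bb <- rowSums(p[-1, , drop = FALSE]^2) - sum(p[1, ]^2)
    if (abs(det(A)) < 1e-10) next  # degenerate tetrahedron
    ctr <- solve(A, bb)
    r2 <- sum((p[1, ] - ctr)^2)
    d2 <- rowSums((x - matrix(ctr, n, 3, byrow = TRUE))^2)
    d2[idx] <- Inf
    if (all(d2 > r2 * (1 + 1e-9))) {
      pr <- utils::combn(sort(idx), 2)
      edges <- c(edges, paste(pr[1, ], pr[2, ]))
    }
  }
  unique(edges)
}

# scipy Delaunay adjacency (independent implementation route)
scipyDelaunayEdges <- function(x) {
  ptsf <- tempfile(fileext = ".txt")
  edf <- tempfile(fileext = ".txt")
  on.exit(unlink(c(ptsf, edf)))
  utils::write.table(x, ptsf, row.names = FALSE, col.names = FALSE)
  code <- paste0(
    "import numpy as np\n",
    "from scipy.spatial import Delaunay\n",
    "x = np.loadtxt('", ptsf, "')\n",
    "t = Delaunay(x)\n",
    "e = set()\n",
    "for s in t.simplices:\n",
    "    for i in range(4):\n",
    "        for j in range(i+1,4):\n",
    "            a,b = sorted((int(s[i]),int(s[j]))); e.add((a+1,b+1))\n",
    "np.savetxt('", edf, "', sorted(e), fmt='%d')\n")
  pyf <- tempfile(fileext = ".py")
  writeLines(code, pyf)
  status <- system2("python", pyf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/scipy oracle unavailable")
  ed <- utils::read.table(edf)
  paste(ed$V1, ed$V2)
}

rotationMatrix <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
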