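test_that("a well-formed ATOM line parses into a matching atom", {
  txt <- c(pdbLine(1, "CA", "ALA", "A", 1, 1.234, -2.5, 3.75, b = 42.17),
           pdbLine(2, "N", "ALA", "A", 1, 2.0, 0.0, 1.0, b = 7.07),
           "END")
  s <- readStructure(txt)
  expect_equal(nrow(s$atoms), 2)
  a <- s$atoms[1, ]
  expect_equal(c(a$x, a$y, a$z), c(1.234, -2.5, 3.75))
  expect_equal(a$b, 42.17)
  expect_equal(a$element, "C")
  expect_equal(a$chain, "A")
})

test_that("altloc duplicates collapse to the highest-occupancy conformer", {
  txt <- c(pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, b = 10, alt = "A"),
           pdbLine(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, b = 20, alt = "B"),
           pdbLine(3, "N", "ALA", "A", 1, 0, 2, 0),
           "END")
  s <- readStructure(txt)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$b, 20)  # occupancy 0.6 wins

  # equal occupancy: altloc A preferred
  txt2 <- c(pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, b = 10, alt = "B"),
            pdbLine(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.5, b = 20, alt = "A"),
            "END")
  s2 <- readStructure(txt2)
  expect_equal(s2$atoms$b, 20)
})

test_that("waters and hydrogens are dropped; empty input errors", {
  txt <- c(pdbLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
           pdbLine(2, "H", "ALA", "A", 1, 0.5, 0, 0, elem = "H"),
           pdbLine(3, "O", "HOH", "W", 90, 9, 9, 9, record = "HETATM"),
           "END")
  s <- readStructure(txt)
  expect_equal(nrow(s$atoms), 1)
  expect_error(readStructure(c("REMARK blah", "END")), "ATOM")
})

test_that("REMARK 350 parsing recovers chain groups and BIOMT operators", {
  lines <- c(
    "REMARK 350 BIOMOLECULE: 1",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A, B",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350 BIOMOLECULE: 2",
    "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000       10.00000",
    "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000")
  bm <- parseRemark350(lines)
  expect_length(bm, 2)
  expect_equal(bm[[1]]$id, 1)
  expect_equal(bm[[1]]$groups[[1]]$chains, c("A", "B"))
  expect_length(bm[[2]]$groups[[1]]$transforms, 2)
  m2 <- bm[[2]]$groups[[1]]$transforms[[2]]
  expect_equal(m2[, 1:3], diag(c(-1, -1, 1)))
  expect_equal(m2[, 4], c(10, 0, 0))
})

test_that("assembleBioUnit applies transforms and counts residues", {
  txt <- c(pdbLine(1, "N", "GLY", "A", 1, 1, 0, 0),
           pdbLine(2, "CA", "GLY", "A", 1, 2, 0, 0),
           pdbLine(3, "C", "GLY", "A", 1, 3, 1, 0),
           pdbLine(4, "N", "GLY", "A", 2, 4, 2, 1),
           pdbLine(5, "CA", "GLY", "B", 1, 0, 5, 0),
           "END")
  s <- readStructure(txt)
  u <- assembleBioUnit(s, "A")
  expect_equal(nrow(unitAtoms(u)), 4)
  expect_equal(unname(residuesPerChain(u)["A"]), 2L)

  # identity + 180-degree rotation about z through x=5: hand-computed copy
  rot <- cbind(rotationMatrix(c(0, 0, 1), 180), c(10, 0, 0))
  u2 <- assembleBioUnit(s, "A", transforms = list(cbind(diag(3), c(0, 0, 0)), rot))
  a2 <- unitAtoms(u2)
  expect_equal(nrow(a2), 8)
  # atom 1 at (1,0,0) -> (-1, 0, 0) + (10,0,0) = (9, 0, 0)
  expect_equal(unlist(a2[5, c("x", "y", "z")], use.names = FALSE), c(9, 0, 0),
               tolerance = 1e-8)
  expect_length(unitChains(u2), 2)
  # no coincident coordinates between the copies
  d <- as.matrix(dist(a2[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_gt(min(d), 1e-6)

  expect_error(assembleBioUnit(s, "Z"), "unknown chain")
  sing <- list(cbind(matrix(0, 3, 3), c(0, 0, 0)))
  expect_error(assembleBioUnit(s, "A", transforms = sing), "singular")
})

test_that("covalent bonds: peptide geometry bonds, far atoms do not", {
  # backbone N-CA at 1.46 A -> bonded; atoms 10 A apart -> not
  u <- makeUnit(rbind(c(0, 0, 0), c(1.46, 0, 0), c(11.46, 0, 0)),
                element = c("N", "C", "C"), resno = c(1, 1, 1),
                name = c("N", "CA", "CB"))
  b <- unitBonds(u)
  expect_true(any(b[, 1] == 1 & b[, 2] == 2))
  expect_false(any(b[, 1] == 2 & b[, 2] == 3 | b[, 1] == 1 & b[, 2] == 3))

  # a 5-atom linear chain within one residue -> path graph with 4 edges
  chain5 <- cbind(seq(0, 4 * 1.5, by = 1.5), 0, 0)
  u5 <- makeUnit(chain5, element = "C", resno = 1,
                 name = paste0("C", 1:5))
  expect_equal(nrow(unitBonds(u5)), 4)

  # peptide bond requires the C/N naming across adjacent residues
  u6 <- makeUnit(rbind(c(0, 0, 0), c(1.33, 0, 0)), element = c("C", "N"),
                 resno = c(1, 2), name = c("C", "N"))
  expect_equal(nrow(unitBonds(u6)), 1)
  u7 <- makeUnit(rbind(c(0, 0, 0), c(1.33, 0, 0)), element = c("C", "C"),
                 resno = c(1, 2), name = c("CB", "CG"))
  expect_equal(nrow(unitBonds(u7)), 0)
})

test_that("covalentNearby returns the two-step neighbourhood", {
  # linear chain i-j-k-l-m: from i the nearby atoms are {i, j, k}
  chain5 <- cbind(seq(0, 4 * 1.5, by = 1.5), 0, 0)
  u5 <- makeUnit(chain5, element = "C", resno = 1, name = paste0("C", 1:5))
  expect_equal(covalentNearby(u5, 1), c(1L, 2L, 3L))
  expect_equal(covalentNearby(u5, 3), 1:5)

  # isolated atom -> itself
  iso <- makeUnit(rbind(c(0, 0, 0), c(10, 0, 0)), resno = c(1, 2),
                  name = c("CA", "CB"))
  expect_equal(covalentNearby(iso, 1), 1L)
  expect_error(covalentNearby(iso, 99), "unknown atom")

  # star graph: BFS oracle to depth 2 over an explicit edge list
  edges <- cbind(i = c(1L, 1L, 1L, 1L, 2L), j = c(2L, 3L, 4L, 5L, 6L))
  bfs <- function(edges, start, depth) {
    seen <- start
    frontier <- start
    for (s in seq_len(depth)) {
      nb <- c(edges[edges[, 1] %in% frontier, 2],
              edges[edges[, 2] %in% frontier, 1])
      frontier <- setdiff(nb, seen)
      seen <- union(seen, frontier)
    }
    sort(seen)
  }
  expect_equal(covalentNearby(edges, 1), bfs(edges, 1, 2))
  expect_equal(covalentNearby(edges, 6), bfs(edges, 6, 2))
  # monotone: depth-2 set contains depth-1 set contains self
  d1 <- covalentNearby(edges, 2, depth = 1L)
  d2 <- covalentNearby(edges, 2, depth = 2L)
  expect_true(all(2L %in% d1, d1 %in% d2))
})

test_that("entry quality filter applies all five construction rules", {
  ok <- filterComplexEntry("X-RAY DIFFRACTION", 2.4, 3000, 400,
                           c(100, 120), 0.05)
  expect_true(ok$pass)
  expect_length(ok$failed, 0)

  bad <- filterComplexEntry("X-RAY DIFFRACTION", 2.6, 3000, 400,
                            c(100, 120), 0.05)
  expect_false(bad$pass)
  expect_equal(bad$failed, "ii")

  # a 5-residue partner fails rule (iv): the bound is strict
  bad2 <- filterComplexEntry("X-RAY DIFFRACTION", 2.4, 3000, 400,
                             c(5, 120), 0.05)
  expect_equal(bad2$failed, "iv")

  bad3 <- filterComplexEntry("SOLUTION NMR", 2.4, 1100, 400,
                             c(100, 120), 0.25)
  expect_setequal(bad3$failed, c("i", "iii", "v"))

  expect_error(filterComplexEntry("X-RAY", NA, 10, 3, c(9, 9), 0.1),
               "resolution")
})

test_that("writing a unit to PDB and re-reading round-trips", {
  p <- syntheticComplex(syntheticConfig(seed = 5, residuesPerChain = 10L,
                                        chainsPerUnit = 1L))
  u <- pairUnits(p)$A
  f <- tempfile(fileext = ".pdb")
  writeUnitPDB(u, f)
  s2 <- readStructure(f)
  a1 <- unitAtoms(u)
  a2 <- s2$atoms
  expect_equal(nrow(a2), nrow(a1))
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                      as.matrix(a2[, c("x", "y", "z")]))), 5.1e-4)
  expect_lt(max(abs(a1$b - a2$b)), 5.1e-3)
  unlink(f)
})

test_that("bond graph degree stays chemically plausible (<= 6)", {
  p <- syntheticComplex(syntheticConfig(seed = 8))
  for (u in pairUnits(p)) {
    deg <- tabulate(c(unitBonds(u)), nbins = nrow(unitAtoms(u)))
    expect_lte(max(deg), 6)
  }
})
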