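test_that("tetrahedron centroid shares a facet with all four vertices", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  pts <- rbind(tet, colMeans(tet))
  fp <- voronoiFacetPairs(pts)
  centroidPairs <- fp[fp$i == 5 | fp$j == 5, ]
  expect_equal(nrow(centroidPairs), 4)
})

test_that("degenerate inputs raise geometry errors", {
  expect_error(voronoiFacetPairs(matrix(rnorm(12), 4, 3)), "degenerate")
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(voronoiFacetPairs(flat), "coplanar")
})

test_that("facet pairs equal Delaunay adjacency on random clouds", {
  set.seed(421)
  # small n: pure-R empty-circumsphere enumeration oracle
  x <- matrix(rnorm(36), 12, 3) * 4
  fp <- voronoiFacetPairs(x)
  expect_setequal(paste(fp$i, fp$j), bruteDelaunayEdges(x))

  # larger n: scipy Delaunay as an independent implementation
  for (rep in 1:3) {
    n <- sample(25:45, 1)
    y <- matrix(rnorm(n * 3), n, 3) * runif(1, 2, 8)
    fp <- voronoiFacetPairs(y)
    expect_setequal(paste(fp$i, fp$j), scipyDelaunayEdges(y))
  }
})

test_that("forbidden region test matches the definition", {
  i <- c(0, 0, 0); j <- c(4, 0, 0)
  # vacuous: no third atom
  expect_true(forbiddenRegionEmpty(1, 2, rbind(i, j)))
  # collinear blocker at the midpoint: angle is 180 degrees
  expect_false(forbiddenRegionEmpty(1, 2, rbind(i, j, c(2, 0, 0))))
  # atom far to the side subtends a small angle
  expect_true(forbiddenRegionEmpty(1, 2, rbind(i, j, c(2, 30, 0))))
  # coincident with an endpoint: geometry error
  expect_error(forbiddenRegionEmpty(1, 2, rbind(i, j, i)), "coincident")

  # random clouds agree with a direct all-k angle scan
  set.seed(33)
  for (rep in 1:5) {
    x <- matrix(rnorm(60), 20, 3) * 3
    th <- sample(c(60, 90, 120), 1)
    prs <- t(utils::combn(20, 2))
    got <- vapply(seq_len(nrow(prs)), function(q)
      forbiddenRegionEmpty(prs[q, 1], prs[q, 2], x, betaAngle = th), TRUE)
    want <- vapply(seq_len(nrow(prs)), function(q) {
      i <- prs[q, 1]; j <- prs[q, 2]
      ang <- vapply(setdiff(1:20, c(i, j)), function(k) {
        a <- x[i, ] - x[k, ]; b <- x[j, ] - x[k, ]
        acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
      }, 1)
      all(ang < th)
    }, TRUE)
    expect_equal(got, want)
  }
})

test_that("beta-skeleton edges at 90 degrees equal the Gabriel graph", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(15:60, 1)
    x <- matrix(rnorm(n * 3), n, 3) * runif(1, 2, 6)
    prs <- t(utils::combn(n, 2))
    fr <- vapply(seq_len(nrow(prs)), function(q)
      forbiddenRegionEmpty(prs[q, 1], prs[q, 2], x), TRUE)
    g <- bruteGabriel(x)
    expect_setequal(paste(prs[fr, 1], prs[fr, 2]), paste(g[, 1], g[, 2]))
  }
})

test_that("distance criterion uses Td plus summed vdW radii", {
  # two C atoms 3.0 A apart pass (3.0 < 2.8 + 1.70 + 1.70); 6.5 A fails
  base <- rbind(c(0, 0, 1.5), c(1.5, 0, -1.2), c(0, 1.5, 0), c(-1.5, 0, 0.4))
  pa <- makePair(rbind(c(0, 0, 0), base + 5),
                 rbind(c(3, 0, 0), base + 12))
  ct <- betaContacts(pa)
  expect_true(any(ct$iA == 1 & ct$iB == 1))
  pa2 <- makePair(rbind(c(0, 0, 0), base + 5),
                  rbind(c(6.5, 0, 0), base + 12))
  ct2 <- betaContacts(pa2)
  expect_false(any(ct2$iA == 1 & ct2$iB == 1))
})

test_that("a blocker at the segment midpoint defeats the contact", {
  spread <- rbind(c(8, 8, 8), c(-8, 8, -8), c(8, -8, -8), c(-8, -8, 8))
  pa <- makePair(rbind(c(0, 0, 0), spread), rbind(c(3, 0, 0), spread + 20))
  ct <- betaContacts(pa)
  expect_true(ct$isBeta[ct$iA == 1 & ct$iB == 1])
  # same geometry plus a midpoint atom in unit A
  pb <- makePair(rbind(c(0, 0, 0), c(1.5, 0, 0), spread),
                 rbind(c(3, 0, 0), spread + 20))
  ct2 <- betaContacts(pb)
  expect_false(ct2$isBeta[ct2$iA == 1 & ct2$iB == 1])
})

test_that("beta contacts are a small subset of distance contacts", {
  p <- syntheticComplex(syntheticConfig(seed = 3))
  ct <- betaContacts(p)
  expect_gt(nrow(ct), 0)
  expect_lt(sum(ct$isBeta), nrow(ct))            # strict subset
  expect_true(all(ct$isBeta == (ct$sharedFacet & ct$frEmpty & ct$passedDistance)))
  expect_true(all(ct$distance > 0))
})

test_that("beta contacts are invariant under rigid motion", {
  p <- syntheticComplex(syntheticConfig(seed = 4, residuesPerChain = 12L,
                                        chainsPerUnit = 1L))
  ct <- betaContacts(p)
  R <- rotationMatrix(c(1, 2, 3), 71)
  shift <- c(5, -3, 9)
  move <- function(u) {
    a <- unitAtoms(u)
    a[, c("x", "y", "z")] <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R),
                                   2, shift, `+`)
    u@atoms <- a
    u
  }
  p2 <- p
  p2@unitA <- move(p@unitA)
  p2@unitB <- move(p@unitB)
  ct2 <- betaContacts(p2)
  expect_equal(ct$iA, ct2$iA)
  expect_equal(ct$iB, ct2$iB)
  expect_equal(ct$isBeta, ct2$isBeta)
  expect_equal(ct$distance, ct2$distance, tolerance = 1e-8)
})

test_that("swapping the units transposes the contact records", {
  p <- syntheticComplex(syntheticConfig(seed = 6, residuesPerChain = 10L,
                                        chainsPerUnit = 1L))
  ct <- betaContacts(p)
  q <- methods::new("ComplexPair", entryId = p@entryId, unitA = p@unitB,
                    unitB = p@unitA, label = p@label,
                    resolution = p@resolution)
  ct2 <- betaContacts(q)
  k1 <- paste(ct$iA, ct$iB, ct$isBeta)
  k2 <- paste(ct2$iB, ct2$iA, ct2$isBeta)
  expect_setequal(k1, k2)
})

test_that("local-contact rule: more than 2 local contacts required", {
  ct <- data.frame(iA = 1L, iB = 1L, isBeta = TRUE)
  spread <- rbind(c(8, 8, 8), c(-8, 8, -8), c(8, -8, -8), c(-8, -8, 8))
  pa <- makePair(rbind(c(0, 0, 0), spread), rbind(c(3, 0, 0), spread + 20))
  # single isolated contact: local contacts = 1, excluded
  expect_length(interfacialAtoms(pa, ct)$unitA, 0)

  # bonded-chain unit: atom 1 contacts once, neighbours 2 and 3 once each
  chainA <- makeUnit(cbind(seq(0, 4 * 1.5, by = 1.5), 0, 0), resno = 1,
                     name = paste0("C", 1:5), unitId = "A")
  other <- makeUnit(rbind(c(0, 0, 4), c(1.5, 0, 4), c(3, 0, 4), c(9, 9, 9)),
                    chain = "B", unitId = "B")
  pr <- methods::new("ComplexPair", entryId = "T", unitA = chainA,
                     unitB = other, label = "unknown",
                     resolution = NA_real_)
  ct3 <- data.frame(iA = c(1L, 2L, 3L), iB = c(1L, 2L, 3L),
                    isBeta = TRUE)
  ia <- interfacialAtoms(pr, ct3)
  # atom 1's local contacts: own 1 + atom2 1 + atom3 1 = 3 > 2 -> included
  expect_true(1L %in% ia$unitA)

  # empty contact list -> empty set
  expect_length(interfacialAtoms(pr, ct3[0, ])$unitA, 0)
})

test_that("criterion subset chain: beta set within facet and distance sets", {
  p <- syntheticComplex(syntheticConfig(seed = 10, residuesPerChain = 15L,
                                        chainsPerUnit = 1L))
  ct <- betaContacts(p)
  expect_true(all(ct$isBeta <= ct$sharedFacet))
  expect_true(all(ct$isBeta <= ct$passedDistance))
  expect_true(all(ct$isBeta <= ct$frEmpty))
})
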