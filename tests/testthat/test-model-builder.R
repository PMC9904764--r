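# Topology construction, rigid groups, phospho states and initializers.

test_that("chains carry canonical residue numbering", {
  ch <- chainFromSequence("GS", offset = 327)
  expect_equal(ch$resNum, c(327L, 328L))
  expect_equal(ch$code, c("G", "S"))
  expect_error(chainFromSequence(""), "empty")
  expect_error(chainFromSequence("GSX"), "position 3")
  s <- synthSequence(75, seed = 3)
  expect_equal(nrow(chainFromSequence(s)), nchar(s))
})

test_that("rigid groups come from structures and preserve geometry", {
  topo <- buildTopology(chainFromSequence("GGGGGGGG"))
  topo <- rigidFromStructure(topo, tetraStructure(resOffset = 2), "core")
  g <- rigidGroups(topo)[[1]]
  expect_length(g$ids, 4)
  expect_equal(dim(g$refCoords), c(4L, 3L))
  # structure residue absent from topology is fatal
  expect_error(
    rigidFromStructure(buildTopology(chainFromSequence("GGG")),
                       tetraStructure(resOffset = 2), "x"),
    "absent from topology")
  # sequence letter conflicts are fatal and listed
  st <- tetraStructure(resOffset = 2)
  st$code <- c("G", "G", "A", "G")
  expect_error(rigidFromStructure(
    buildTopology(chainFromSequence("GGGGGGGG")), st, "x"), "mismatch")
  # a dimeric structure spanning two chains becomes one rigid group
  dimer <- buildTopology(list(chainFromSequence("GGGG", chainId = "A"),
                              chainFromSequence("GGGG", chainId = "B")))
  st2 <- rbind(tetraStructure("A"), tetraStructure("B"))
  st2[5:8, c("x", "y", "z")] <- st2[5:8, c("x", "y", "z")] + 20
  dimer <- rigidFromStructure(dimer, st2, "FBAR")
  expect_length(rigidGroups(dimer), 1)
  expect_length(rigidGroups(dimer)[[1]]$ids, 8)
})

test_that("phosphosite application counts, idempotence and commutativity", {
  fa <- readFasta(system.file("extdata", "cdc15_idr_synthetic.fasta",
                              package = "cgphos"))
  topo <- buildTopology(chainFromSequence(fa[[1]], offset = 327))
  counts <- c(Kin1 = 5L, Shk1 = 11L, Pom1 = 22L, Pck1 = 1L)
  for (k in names(counts)) {
    sites <- readPhosphoSites(kinase = k)
    t2 <- applyPhosphoSites(topo, sites, state = toupper(k))
    expect_equal(sum(beads(t2)$code %in% c("pS", "pT")),
                 unname(counts[k]), info = k)
  }
  full <- readPhosphoSites()
  tFull <- applyPhosphoSites(topo, full, state = "FULL")
  expect_equal(sum(beads(tFull)$code %in% c("pS", "pT")), 31)
  expect_equal(nBeads(tFull), nBeads(topo))
  expect_identical(tFull@bonds, topo@bonds)
  # idempotent for the same set
  expect_identical(beads(applyPhosphoSites(tFull, full, "FULL")),
                   beads(tFull))
  # commutative across disjoint sets
  a <- readPhosphoSites(kinase = "Kin1")
  b <- readPhosphoSites(kinase = "Shk1")
  b <- b[!b$site %in% a$site, ]
  ab <- applyPhosphoSites(applyPhosphoSites(topo, a), b)
  ba <- applyPhosphoSites(applyPhosphoSites(topo, b), a)
  expect_identical(beads(ab), beads(ba))
  # empty set is the identity
  expect_identical(beads(applyPhosphoSites(topo, integer(0))), beads(topo))
  # non-S/T site is fatal
  notST <- which(beads(topo)$code == "G")[1] + 326
  expect_error(applyPhosphoSites(topo, notST), "not S/T")
})

test_that("dimer phosphorylation changes net charge by -2 per site per chain", {
  ff <- loadForceField("HPS")
  fa <- readFasta(system.file("extdata", "cdc15_idr_synthetic.fasta",
                              package = "cgphos"))
  dimer <- buildTopology(list(
    chainFromSequence(fa[[1]], offset = 327, chainId = "A"),
    chainFromSequence(fa[[1]], offset = 327, chainId = "B")))
  q0 <- netCharge(dimer, ff)
  dimerP <- applyPhosphoSites(dimer, readPhosphoSites(), state = "FULL")
  expect_equal(sum(beads(dimerP)$code %in% c("pS", "pT")), 62)
  expect_equal(netCharge(dimerP, ff) - q0, -2 * 31 * 2)
})

test_that("straight-line initialization is collinear with exact spacing", {
  topo <- buildTopology(chainFromSequence(strrep("G", 10)))
  X <- initStraight(topo, 3.81)
  expect_equal(sqrt(sum((X[10, ] - X[1, ])^2)), 9 * 3.81)
  bl <- sqrt(rowSums((X[1:9, ] - X[2:10, ])^2))
  expect_equal(bl, rep(3.81, 9))
  # closed-form Rg of N collinear equal-mass beads
  for (N in c(10, 57)) {
    t2 <- buildTopology(chainFromSequence(strrep("G", N)))
    X2 <- initStraight(t2, 3.81)
    expect_equal(radiusOfGyration(X2), 3.81 * sqrt((N^2 - 1) / 12),
                 tolerance = 1e-12)
  }
  rigidTopo <- rigidFromStructure(topo, tetraStructure(resOffset = 3), "x")
  expect_error(initStraight(rigidTopo), "flexible")
})

test_that("semi-relaxed generator hits the target Rg deterministically", {
  ff <- loadForceField("HPS")
  topo <- buildTopology(chainFromSequence(synthSequence(80, seed = 2)))
  m <- ff@residues[beads(topo)$code, "mass"]
  X <- initSemiRelaxed(topo, ff, targetRg = 25, seed = 42)
  expect_equal(radiusOfGyration(X, masses = m), 25, tolerance = 1e-6)
  expect_identical(X, initSemiRelaxed(topo, ff, targetRg = 25, seed = 42))
  expect_false(identical(X, initSemiRelaxed(topo, ff, 25, seed = 43)))
  expect_false(anyNA(X))
  expect_error(initSemiRelaxed(topo, ff, targetRg = 1, seed = 1),
               "packing bound")
})

test_that("dimer-apart geometry extends arms oppositely from the tips", {
  topo <- toyDimerTopology(armSeq40())
  X <- initDimerApart(topo)
  expect_false(anyNA(X))
  selA <- beadSelect(topo, chain = "A", flexible = TRUE)
  selB <- beadSelect(topo, chain = "B", flexible = TRUE)
  # opposite extension: arm COMs far beyond half the contour length
  expect_gt(comSeparation(X, selA, selB), 40 * 3.81 / 2)
  # first arm bead sits one bond length from its anchor
  g <- rigidGroups(topo)[[1]]
  b <- beads(topo)
  firstA <- selA[which.min(b$resNum[selA])]
  anchorA <- g$ids[b$chain[g$ids] == "A"][
    which.max(b$resNum[g$ids[b$chain[g$ids] == "A"]])]
  expect_equal(sqrt(sum((X[firstA, ] - X[anchorA, ])^2)), 3.81,
               tolerance = 1e-9)
  # inversion symmetry through the dumbbell center
  expect_equal(X[selA, ], -X[selB, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("compaction-relaxation shrinks the box and keeps bonds sane", {
  ff <- loadForceField("HPS")
  topo <- toyDimerTopology(synthSequence(12, seed = 8),
                           dumbbell = toyRigidDumbbell(6, 30))
  X <- initDimerApart(topo)
  p <- simParams(seed = 2, outStride = 1000L, cap = 0.1)
  res <- compactionRelax(topo, X, ff, p, nsStage = 0.05)
  expect_equal(res$topology@box, topo@box / 10)
  bnd <- res$topology@bonds
  rigidIds <- rigidGroups(topo)[[1]]$ids
  keep <- !(bnd[, 1] %in% rigidIds & bnd[, 2] %in% rigidIds)
  bl <- sqrt(rowSums((res$coords[bnd[keep, 1], ] -
                        res$coords[bnd[keep, 2], ])^2))
  expect_true(all(bl > 2 & bl < 6))
  # rigid internal geometry untouched by the affine scaling + dynamics
  g <- rigidGroups(res$topology)[[1]]
  expect_equal(as.numeric(dist(res$coords[g$ids, ])),
               as.numeric(dist(g$refCoords)), tolerance = 1e-9)
})

test_that("forced-interaction protocol drives SH3 groups across the midplane", {
  ff <- loadForceField("HPS")
  topo <- toyDimerTopology(synthSequence(8, fcr = 0, seed = 3),
                           dumbbell = toyRigidDumbbell(6, 30),
                           withSH3 = TRUE)
  X <- initDimerApart(topo)
  p <- simParams(seed = 9, outStride = 5000L)
  g <- rigidGroups(topo)
  fbar <- g[[1]]
  sh3 <- g[-1]
  axis <- X[fbar$ids[1], ] - colMeans(X[fbar$ids, ])
  axis <- axis / sqrt(sum(axis^2))
  proj0 <- vapply(sh3, function(s)
    sum(colMeans(X[s$ids, , drop = FALSE]) * axis), numeric(1))
  Xc <- initDimerInteracting(topo, X, ff, p, forceMag = 1.5,
                             maxTimeNs = 10, relaxNs = 0.05)
  proj1 <- vapply(sh3, function(s)
    sum(colMeans(Xc[s$ids, , drop = FALSE]) * axis), numeric(1))
  expect_equal(sign(proj1), -sign(proj0))
  # zero force cannot cross: timeout error
  expect_error(initDimerInteracting(topo, X, ff, p, forceMag = 0,
                                    maxTimeNs = 0.3, relaxNs = 0.05),
               "did not cross")
})
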