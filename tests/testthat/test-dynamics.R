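# Engine correctness: oracle equivalence, integrator properties, rigid
# bodies, capping, minimization.

test_that("engine energies match the R brute-force oracle on random systems", {
  ff <- loadForceField("HPS")
  for (seed in 1:8) {
    n <- sample(30:100, 1)
    sys <- randomChainSystem(n, seed)
    fe <- computeForces(sys$topology, sys$coords, ff)
    ref <- bruteEnergy(sys$topology, sys$coords, ff)
    expect_equal(fe$eBond, ref$eBond, tolerance = 1e-9)
    expect_equal(fe$eAH, ref$eAH, tolerance = 1e-9)
    expect_equal(fe$eDH, ref$eDH, tolerance = 1e-9)
    # Newton's third law on an isolated system (relative to force scale)
    expect_lt(max(abs(colSums(fe$forces))) / max(1, max(abs(fe$forces))),
              1e-8)
  }
})

test_that("SASA pair scaling multiplies into the nonbonded energy", {
  ff <- loadForceField("HPS")
  topo <- buildTopology(chainFromSequence("GGGGGGGG"))
  topo <- rigidFromStructure(topo, tetraStructure(resOffset = 3), "core")
  ids <- rigidGroups(topo)[[1]]$ids
  sasa <- sasaScaleFactors(topo, setNames(c(52, 20, 80, 0), ids))
  X <- initSemiRelaxed(buildTopology(chainFromSequence("GGGGGGGG")),
                       ff, targetRg = 6, seed = 2)
  fe <- computeForces(topo, X, ff, sasa = sasa)
  ref <- bruteEnergy(topo, X, ff, sasa = sasa)
  expect_equal(fe$eAH, ref$eAH, tolerance = 1e-9)
})

test_that("forces are the exact negative gradient of the energy", {
  ff <- loadForceField("HPS")
  sys <- randomChainSystem(20, 3)
  fe <- computeForces(sys$topology, sys$coords, ff)
  h <- 1e-6
  set.seed(1)
  for (k in 1:25) {
    i <- sample(20, 1); d <- sample(3, 1)
    Xp <- sys$coords; Xp[i, d] <- Xp[i, d] + h
    Xm <- sys$coords; Xm[i, d] <- Xm[i, d] - h
    fd <- -(computeForces(sys$topology, Xp, ff)$eTotal -
              computeForces(sys$topology, Xm, ff)$eTotal) / (2 * h)
    expect_equal(fe$forces[i, d], fd,
                 tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("neighbor-list run energies equal brute-force frame energies", {
  ff <- loadForceField("HPS")
  sys <- randomChainSystem(40, 4)
  tr <- runDynamics(sys$topology, sys$coords, ff,
                    simParams(seed = 2, outStride = 100L), 1000)
  el <- energyLog(tr)
  for (f in seq_len(nFrames(tr))) {
    ref <- bruteEnergy(sys$topology, frameCoords(tr, f), ff)
    expect_equal(el$bond[f] + el$ah[f] + el$dh[f], ref$eTotal,
                 tolerance = 1e-8)
  }
})

test_that("two neutral beads beyond the cutoff feel no force", {
  ff <- loadForceField("HPS")
  topo <- buildTopology(chainFromSequence("GG"))
  topo@bonds <- matrix(integer(0), 0, 2)
  X <- rbind(c(0, 0, 0), c(3 * 4.5 + 1, 0, 0)) # beyond 3 sigma for G-G
  fe <- computeForces(topo, X, ff)
  expect_equal(max(abs(fe$forces)), 0)
  expect_equal(fe$eTotal, 0)
})

test_that("trajectories are deterministic given the seed", {
  ff <- loadForceField("HPS")
  sys <- randomChainSystem(25, 5)
  p <- simParams(seed = 77, outStride = 50L)
  t1 <- runDynamics(sys$topology, sys$coords, ff, p, 500)
  t2 <- runDynamics(sys$topology, sys$coords, ff, p, 500)
  expect_identical(t1@coords, t2@coords)
  t3 <- runDynamics(sys$topology, sys$coords, ff,
                    simParams(seed = 78, outStride = 50L), 500)
  expect_false(identical(t1@coords, t3@coords))
})

# (NVE drift, Langevin equipartition and the bond-length Boltzmann KS test
# are exercised with their quantitative bounds in test-acceptance.R.)

test_that("a short Langevin run thermostats near the target temperature", {
  ffi <- loadForceField("HPS", hpsEpsilon = 0)
  topo <- buildTopology(chainFromSequence(
    synthSequence(60, fcr = 0, ncpr = 0, stDensity = 0.5, seed = 2)))
  tr <- runDynamics(topo, initStraight(topo), ffi,
                    simParams(seed = 6, outStride = 100L), 50000,
                    bondKScale = 0)
  temps <- energyLog(tr)$temperature[-(1:100)]
  expect_equal(mean(temps), 300, tolerance = 0.05)
})

test_that("rigid groups keep geometry and reduce to point particles", {
  ff <- loadForceField("HPS", hpsEpsilon = 0)
  topo <- buildTopology(chainFromSequence("GGGG"))
  topo <- rigidFromStructure(topo, tetraStructure(), "body")
  X <- rigidGroups(topo)[[1]]$refCoords
  # zero force, zero temperature: nothing moves
  p0 <- simParams(seed = 1, friction = 0, temperature = 0,
                  outStride = 100L)
  tr0 <- runDynamics(topo, X, ff, p0, 1000, bondKScale = 0)
  expect_equal(frameCoords(tr0, nFrames(tr0)), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  # rigidity over 1e4 thermostatted steps
  tr <- runDynamics(topo, X, ff, simParams(seed = 3, outStride = 1000L),
                    10000, bondKScale = 0)
  Xf <- frameCoords(tr, nFrames(tr))
  expect_equal(as.numeric(dist(Xf)), as.numeric(dist(X)),
               tolerance = 1e-6)
  # constant force, no torque: COM accelerates like the total mass (NVE)
  m <- ff@residues[beads(topo)$code, "mass"]
  Fext <- matrix(0, 4, 3); Fext[, 1] <- 1 # uniform: no torque about COM
  trF <- runDynamics(topo, X, ff, p0, 1000, extForce = Fext,
                     bondKScale = 0)
  com0 <- colSums(X * m) / sum(m)
  com1 <- colSums(frameCoords(trF, nFrames(trF)) * m) / sum(m)
  t <- 1000 * 10 # fs
  expect_equal(unname(com1[1] - com0[1]),
               0.5 * (4 / sum(m)) * (1 / 48.88821291^2) * t^2,
               tolerance = 1e-3)
  expect_equal(unname(com1[2] - com0[2]), 0, tolerance = 1e-6)
  # collinear groups are rejected at setup
  lin <- buildTopology(chainFromSequence("GGGG"))
  lin <- rigidFromStructure(
    lin, data.frame(resNum = 1:4, chain = "A",
                    x = c(0, 3.8, 7.6, 11.4), y = 0, z = 0), "line")
  expect_error(runDynamics(lin, rigidGroups(lin)[[1]]$refCoords, ff,
                           simParams(seed = 1), 10),
               "collinear")
})

test_that("displacement caps rescale steps and tame overlaps", {
  ff <- loadForceField("HPS", hpsEpsilon = 0)
  topo <- buildTopology(chainFromSequence("GG"))
  topo@bonds <- matrix(integer(0), 0, 2)
  X <- rbind(c(0, 0, 0), c(100, 0, 0))
  # deterministic: T = 0, friction 0, constant force chosen so the free
  # first step would be 0.5 A; capped result is exactly 0.1 A along x
  m <- ff@residues["G", "mass"]
  Fmag <- m * 48.88821291^2 / 10^2 # free first-step displacement = 0.5 A
  Fext <- matrix(0, 2, 3); Fext[, 1] <- Fmag
  p <- simParams(seed = 1, friction = 0, temperature = 0, cap = 0.1,
                 outStride = 1L)
  tr <- runDynamics(topo, X, ff, p, 1, extForce = Fext, bondKScale = 0)
  d <- frameCoords(tr, 2) - X
  expect_equal(d[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(d[1, 2:3], c(0, 0))
  # below the cap the step is untouched
  pBig <- simParams(seed = 1, friction = 0, temperature = 0, cap = 10,
                    outStride = 1L)
  trU <- runDynamics(topo, X, ff, pBig, 1, extForce = Fext,
                     bondKScale = 0)
  expect_equal(frameCoords(trU, 2)[1, 1] - X[1, 1], 0.5,
               tolerance = 1e-12)
  # an overlapping pair survives 1000 capped steps
  ffFull <- loadForceField("HPS")
  Xov <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  pc <- simParams(seed = 2, cap = 0.1, outStride = 100L)
  trOv <- runDynamics(topo, Xov, ffFull, pc, 1000)
  expect_false(anyNA(trOv@coords))
  # without a cap the same start is a detected blow-up
  expect_error(runDynamics(topo, Xov, ffFull,
                           simParams(seed = 2, outStride = 100L), 1000),
               class = "cgphosBlowup")
})

test_that("minimization reaches analytic minima", {
  ff <- loadForceField("HPS")
  # two-bead AH system at lambda ~ 1: separation 2^(1/6) sigma
  topo <- buildTopology(chainFromSequence("FF"))
  topo@bonds <- matrix(integer(0), 0, 2)
  res <- minimizeEnergy(topo, rbind(c(0, 0, 0), c(7.5, 0, 0)), ff,
                        tol = 1e-10)
  expect_equal(as.numeric(dist(res$coords)), 2^(1 / 6) * 6.36,
               tolerance = 1e-7)
  # already-minimal input is returned unchanged within tolerance
  res2 <- minimizeEnergy(topo, res$coords, ff, tol = 1e-10)
  expect_equal(res2$coords, res$coords, tolerance = 1e-8)
  expect_lt(res2$iterations, res$iterations)
})

test_that("zero-step runs return the single initial frame", {
  ff <- loadForceField("HPS")
  sys <- randomChainSystem(10, 6)
  tr <- runDynamics(sys$topology, sys$coords, ff, simParams(seed = 1), 0)
  expect_equal(nFrames(tr), 1)
  expect_equal(frameCoords(tr, 1), unname(sys$coords), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("excluded-volume chains show self-avoiding Rg scaling", {
  # lambda = 0, uncharged beads of moderate diameter (4.5 A on 3.81 A
  # bonds): repulsive-only chain; effective exponent in [0.55, 0.65]
  ff0 <- loadForceField("HPS")
  ff0@residues["G", "charge"] <- 0
  ff0@residues["G", "lambda"] <- 0
  ff0@pairLambda["G", ] <- 0
  ff0@pairLambda[, "G"] <- 0
  Ns <- c(25, 50, 100, 200)
  rg <- vapply(Ns, function(N) {
    topo <- buildTopology(chainFromSequence(strrep("G", N)))
    # start near the expected self-avoiding size to shorten equilibration
    X0 <- initSemiRelaxed(topo, ff0, targetRg = 0.42 * 3.81 * N^0.6,
                          seed = N)
    # capped warmup resolves residual overlaps from the rescaled walk
    warm <- runDynamics(topo, X0, ff0,
                        simParams(seed = N + 1, outStride = 5000L,
                                  cap = 0.1), 20000)
    tr <- runDynamics(topo, attr(warm, "finalCoords"), ff0,
                      simParams(seed = N, outStride = 2000L),
                      2e5 + 600 * N^1.5)
    v <- seriesValues(rgSeries(tr, ff0))
    mean(v[-seq_len(length(v) %/% 2)])
  }, numeric(1))
  nu <- coef(lm(log(rg) ~ log(Ns)))[2]
  expect_gt(nu, 0.55)
  expect_lt(nu, 0.65)
})
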