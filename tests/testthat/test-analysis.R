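# Observables and statistics.

test_that("radius of gyration matches analytic and brute-force values", {
  expect_equal(radiusOfGyration(matrix(c(5, 2, 9), 1)), 0)
  X2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radiusOfGyration(X2), 1)
  # mass-weighted direct-sum oracle on random beads
  set.seed(4)
  X <- matrix(rnorm(30), 10)
  m <- runif(10, 50, 200)
  com <- colSums(X * m) / sum(m)
  ref <- sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / sum(m))
  expect_equal(radiusOfGyration(X, masses = m), ref, tolerance = 1e-12)
  expect_error(radiusOfGyration(X, selection = integer(0)), "empty")
})

test_that("COM separation is the distance between weighted centroids", {
  set.seed(5)
  X <- matrix(rnorm(60, sd = 10), 20)
  m <- runif(20, 50, 200)
  a <- 1:8; b <- 9:20
  comA <- colSums(X[a, ] * m[a]) / sum(m[a])
  comB <- colSums(X[b, ] * m[b]) / sum(m[b])
  expect_equal(comSeparation(X, a, b, m), sqrt(sum((comA - comB)^2)),
               tolerance = 1e-12)
  # mirror-symmetric configurations
  Xm <- rbind(X[a, ], -X[a, ])
  expect_equal(comSeparation(Xm, 1:8, 9:16, rep(m[a], 2)),
               2 * sqrt(sum(comA^2)), tolerance = 1e-12)
  # pure translation
  Xt <- rbind(X[a, ], sweep(X[a, ], 2, c(100, 0, 0), `+`))
  expect_equal(comSeparation(Xt, 1:8, 9:16, rep(m[a], 2)), 100)
  expect_error(comSeparation(X, 1:5, 4:10), "overlap")
})

test_that("fractionAbove counts strictly-greater frames and pools lists", {
  expect_equal(fractionAbove(c(90, 110, 120, 80), 100), 0.5)
  expect_equal(fractionAbove(c(10, 20, 30), 100), 0)
  expect_equal(fractionAbove(c(100, 100), 100), 0) # strict inequality
  # pooling weights trajectories by frame count
  s1 <- observableSeries(rep(150, 30), 1)
  s2 <- observableSeries(rep(50, 10), 1)
  expect_equal(fractionAbove(list(s1, s2)), 0.75)
  expect_equal(fractionAboveByTrajectory(list(s1, s2)), c(1, 0))
  # constructed series are exact
  for (fh in c(0, 0.5, 1)) {
    v <- twoStateComTrajectory(fh, 100, nFrames = 100, seed = 3)
    expect_equal(fractionAbove(v, 100), fh)
  }
  # trimming is respected
  s <- observableSeries(c(rep(200, 10), rep(0, 10)), 1, trimIndex = 10L)
  expect_equal(fractionAbove(s), 0)
})

test_that("relaxation time recovers OU time constants and flags edge cases", {
  for (tau in c(10, 100)) {
    est <- relaxationTime(ouSeries(tau, length = 1e5, seed = 1))$tau
    expect_lt(abs(est - tau) / tau, 0.2)
  }
  # white noise decorelates within a step
  wn <- relaxationTime(ouSeries(0.05, length = 5000, seed = 2))
  expect_lt(wn$tau, 1)
  expect_error(relaxationTime(rep(3, 100)), "zero-variance")
  expect_error(relaxationTime(rnorm(20)), "too short")
  # under-sampling flag when tau rivals the series length
  us <- relaxationTime(ouSeries(200, length = 400, seed = 3))
  expect_true(us$underSampled)
})

test_that("equilibration trim removes frames before twice tau", {
  s <- observableSeries(rnorm(1000), frameNs = 1)
  tr <- equilibrationTrim(s, tau = 100)
  expect_equal(tr@trimIndex, 200L)
  expect_length(seriesValues(tr), 800)
  # tau = 0 is the identity
  expect_equal(equilibrationTrim(s, 0)@trimIndex, 0L)
  # unequilibrated series is fatal
  expect_error(equilibrationTrim(s, tau = 600), "unequilibrated")
})

test_that("five-block errors match hand computation and iid theory", {
  b <- blockError5(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  expect_equal(b$mean, 3)
  expect_equal(b$error, sd(1:5))
  expect_equal(round(b$error, 4), 1.5811)
  expect_equal(blockError5(rep(7, 25))$error, 0)
  expect_error(blockError5(1:4), "at least 5")
  # remainder frames are truncated: appending one wild value changes nothing
  v <- rnorm(100)
  expect_equal(blockError5(c(v, 1e6))$mean, blockError5(v)$mean)
  # iid Gaussian: block error ~ sd/sqrt(5 * per-block n) in expectation
  set.seed(8)
  errs <- replicate(200, blockError5(rnorm(500))$error)
  expect_equal(mean(errs), 1 / sqrt(100), tolerance = 0.1)
})

test_that("contact maps count close pairs per frame", {
  ff <- loadForceField("HPS")
  topo <- buildTopology(chainFromSequence("GGGGG"))
  # three hand-built frames
  coords <- array(0, c(5, 3, 3))
  coords[, 1, 1] <- c(0, 5, 40, 60, 80)    # frame 1: pair (1,2) at 5 A
  coords[, 1, 2] <- c(0, 25, 50, 75, 100)  # frame 2: nothing close
  coords[, 1, 3] <- c(0, 5, 12, 60, 80)    # frame 3: (1,2), (2,3)
  tr <- new("Trajectory", coords = coords, timeNs = 0:2,
            energies = data.frame(), params = simParams(),
            topology = topo)
  M <- contactMap(tr, 1:2, 3:5, cutoff = 10)
  ref <- matrix(0, 2, 3)
  ref[2, 1] <- 1 / 3 # bead 2 - bead 3 close in frame 3 only
  expect_equal(unname(M), ref)
  Mself <- contactMap(tr, 1:5, 1:5, cutoff = 10)
  expect_true(isSymmetric(unname(Mself)))
  expect_true(all(Mself >= 0 & Mself <= 1))
  expect_equal(unname(diag(Mself)), rep(1, 5))
  expect_equal(Mself[1, 2], 2 / 3)
  expect_error(contactMap(tr, 1:2, 3:5, cutoff = -1), "cutoff")
})

test_that("F-BAR tips are the outermost beads along the long axis", {
  topo <- toyDimerTopology(armSeq40())
  tips <- fbarTips(topo, fraction = 0.1)
  g <- rigidGroups(topo)[[1]]
  s <- g$refCoords[, 1] # dumbbell long axis is x
  expect_setequal(tips, g$ids[c(which.min(s), which.max(s))])
})

test_that("Rg-vs-charge table orders phospho states by net charge", {
  ff <- loadForceField("HPS")
  fa <- readFasta(system.file("extdata", "cdc15_idr_synthetic.fasta",
                              package = "cgphos"))
  base <- buildTopology(chainFromSequence(fa[[1]], offset = 327))
  states <- list(DEPH = character(0), KIN1 = "Kin1", SHK1 = "Shk1",
                 POM1 = "Pom1", FULL = NULL)
  conds <- list()
  fakeRg <- observableSeries(rnorm(100, 50), 1)
  for (s in names(states)) {
    topo <- if (identical(states[[s]], character(0))) base
            else applyPhosphoSites(base, readPhosphoSites(kinase = states[[s]]), s)
    conds[[s]] <- list(topology = topo, ff = ff, series = fakeRg)
  }
  tab <- rgVsChargeTable(conds)
  expect_equal(tab$label, names(states))
  # net charge strictly decreasing DEPH > KIN1 > SHK1 > POM1 > FULL
  expect_true(all(diff(tab$netCharge) < 0))
  expect_equal(tab$netCharge[tab$label == "FULL"] -
                 tab$netCharge[tab$label == "DEPH"], -62)
  expect_true(all(tab$blockError >= 0))
})

test_that("temperature scan summary reports T* and trivial cases", {
  mk <- function(state, T, mu) list(state = state, temperature = T,
                                    series = observableSeries(rep(mu, 50), 1))
  res <- list(mk("a", 250, 20), mk("a", 300, 25), mk("a", 350, 30),
              mk("b", 250, 20), mk("b", 300, 35), mk("b", 350, 31))
  out <- temperatureScanSummary(res)
  expect_equal(nrow(out$table), 6)
  expect_equal(out$tStar, 300) # maximal relative difference
  # identical states: zero relative difference everywhere
  res2 <- c(res[1:3], lapply(res[1:3], function(r) { r$state <- "b"; r }))
  out2 <- temperatureScanSummary(res2)
  a <- out2$table[out2$table$state == "a", "meanRg"]
  b <- out2$table[out2$table$state == "b", "meanRg"]
  expect_equal(a, b)
  expect_error(temperatureScanSummary(res[c(1, 2, 4, 5)]), "3 temperatures")
})

test_that("charge metrics classify diagram-of-states regions", {
  pk <- chargeMetrics(strrep("K", 20))
  expect_equal(pk$fplus, 1)
  expect_equal(pk$fcr, 1)
  expect_equal(pk$ncpr, 1)
  expect_equal(pk$region, "positive polyelectrolyte")
  ek <- chargeMetrics(strrep("EK", 10))
  expect_equal(ek$fcr, 1)
  expect_equal(ek$ncpr, 0)
  expect_equal(ek$region, "coil/hairpin/chimera")
  gg <- chargeMetrics(strrep("G", 10))
  expect_equal(gg$region, "globule/tadpole")
  # phosphorylation strictly decreases NCPR, one site at a time
  seqStr <- "KKSSSTTGGG"
  for (k in 1:5) {
    prev <- chargeMetrics(seqStr, phosphoSites = 2 + seq_len(k - 1))
    ph <- chargeMetrics(seqStr, phosphoSites = 2 + seq_len(k))
    expect_lt(ph$ncpr, prev$ncpr)
    expect_lt(ph$ncprWeighted, prev$ncprWeighted)
  }
  # the -1.5e mode changes the weighted but not the count-based metrics
  a <- chargeMetrics(seqStr, phosphoSites = 3:5, phosphoCharge = -2)
  b <- chargeMetrics(seqStr, phosphoSites = 3:5, phosphoCharge = -1.5)
  expect_equal(a$fminus, b$fminus)
  expect_lt(a$ncprWeighted, b$ncprWeighted)
})
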