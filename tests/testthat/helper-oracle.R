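# Shared helpers: an R-level brute-force energy oracle (built on the scalar
# energy functions, independent of the compiled engine) and small system
# factories.

minImage <- function(d, L) if (L > 0) d - L * round(d / L) else d

# O(N^2) double-loop energy from the exported scalar terms.
bruteEnergy <- function(topology, coords, ff, sasa = NULL, bondKScale = 1) {
  b <- beads(topology)
  n <- nrow(b)
  coords <- as.matrix(coords)
  if (is.null(sasa)) sasa <- rep(1, n)
  rigid <- integer(n)
  for (k in seq_along(rigidGroups(topology)))
    rigid[rigidGroups(topology)[[k]]$ids] <- k
  L <- topology@box
  bnd <- topology@bonds
  bondKey <- character(0)
  eb <- 0
  if (nrow(bnd)) {
    bondKey <- paste(pmin(bnd[, 1], bnd[, 2]), pmax(bnd[, 1], bnd[, 2]))
    for (k in seq_len(nrow(bnd))) {
      i <- bnd[k, 1]; j <- bnd[k, 2]
      if (rigid[i] != 0 && rigid[i] == rigid[j]) next
      r <- sqrt(sum(minImage(coords[i, ] - coords[j, ], L)^2))
      eb <- eb + bondEnergy(r, ff@bond$r0, ff@bond$K * bondKScale)
    }
  }
  q <- ff@residues[b$code, "charge"]
  ea <- ed <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      if (rigid[i] != 0 && rigid[i] == rigid[j]) next
      if (paste(i, j) %in% bondKey) next
      r <- sqrt(sum(minImage(coords[i, ] - coords[j, ], L)^2))
      p <- pairParams(ff, b$code[i], b$code[j])
      ea <- ea + ahPairEnergy(r, p$sigma, p$lambda,
                              p$epsilon * sasa[i] * sasa[j])
      ed <- ed + dhPairEnergy(r, q[i], q[j], ff@elec$debyeLength,
                              ff@elec$dielectric, ff@elec$cutoff)
    }
  list(eBond = eb, eAH = ea, eDH = ed, eTotal = eb + ea + ed)
}

# A random flexible chain with coordinates in a compact blob.
randomChainSystem <- function(n, seed, includePhospho = TRUE) {
  set.seed(seed)
  seqStr <- synthSequence(n, fcr = 0.3, ncpr = -0.1, stDensity = 0.5,
                          seed = seed)
  topo <- buildTopology(chainFromSequence(seqStr))
  if (includePhospho && seed %% 2 == 0) {
    st <- which(strsplit(seqStr, "")[[1]] %in% c("S", "T"))
    topo <- applyPhosphoSites(topo, st[seq_len(min(4, length(st)))])
  }
  # compact self-avoiding walk: non-neighbors approach to ~3.2 A but
  # never overlap (keeps forces finite for dynamics starts)
  coords <- matrix(0, n, 3)
  i <- 2L
  while (i <= n) {
    u <- rnorm(3)
    cand <- coords[i - 1L, ] + runif(1, 3.6, 4.0) * u / sqrt(sum(u^2))
    prev <- coords[seq_len(i - 2L), , drop = FALSE]
    if (i == 2L || all(colSums((t(prev) - cand)^2) > 3.2^2)) {
      coords[i, ] <- cand
      i <- i + 1L
    }
  }
  list(topology = topo, coords = coords)
}

# A four-bead rigid tetrahedron structure table.
tetraStructure <- function(chain = "A", resOffset = 1) {
  data.frame(resNum = resOffset:(resOffset + 3), chain = chain,
             x = c(0, 3.5, 1.75, 1.75),
             y = c(0, 0, 3.0, 1.0),
             z = c(0, 0, 0, 3.0))
}

armSeq40 <- function() synthSequence(40, fcr = 0.2, ncpr = 0,
                                     stDensity = 0.5, seed = 5)
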