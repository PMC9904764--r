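# Synthetic-data generators: everything the pipeline consumes can be
# produced here deterministically, in the same formats as real inputs.

#' Random charge-patterned sequence
#'
#' Draws a sequence with prescribed fraction of charged residues (FCR) and
#' net charge per residue (NCPR), using K/R for positives, D/E for
#' negatives, and S/T/G/N for neutrals with a prescribed phosphorylatable
#' (S/T) fraction. Realized FCR/NCPR match the targets to within 1/length
#' (integer rounding). Deterministic given the seed.
#'
#' The defaults emulate the regime of an IDR that sits in the weak
#' polyampholyte (globule/tadpole) region when dephosphorylated and is
#' pushed toward the polyelectrolyte/coil regions by multi-site
#' phosphorylation.
#'
#' @param length sequence length
#' @param fcr target fraction of charged residues
#' @param ncpr target net charge per residue
#' @param stDensity phosphorylatable (S/T) fraction among neutral residues
#' @param seed RNG seed
#' @return one-letter residue string
#' @export
synthSequence <- function(length = 60, fcr = 0.2, ncpr = 0,
                          stDensity = 0.5, seed = 1) {
  if (abs(ncpr) > fcr || fcr > 1) stop("need |NCPR| <= FCR <= 1")
  npos <- round(length * (fcr + ncpr) / 2)
  nneg <- round(length * (fcr - ncpr) / 2)
  if (npos < 0 || nneg < 0 || npos + nneg > length)
    stop("infeasible composition for length ", length)
  nneu <- length - npos - nneg
  nst <- round(nneu * stDensity)
  .withSeed(seed, {
    pos <- sample(c("K", "R"), npos, replace = TRUE)
    neg <- sample(c("D", "E"), nneg, replace = TRUE)
    st <- sample(c("S", "T"), nst, replace = TRUE, prob = c(0.6, 0.4))
    oth <- sample(c("G", "N"), nneu - nst, replace = TRUE)
    paste(sample(c(pos, neg, st, oth)), collapse = "")
  })
}

#' Toy rigid dumbbell (minimal F-BAR stand-in)
#'
#' An elongated rigid body: beads along the x axis between the two tips at
#' -length/2 and +length/2, zig-zagged off-axis so the group is
#' non-collinear. The two tip beads double as the anchors for attaching
#' flexible arms, symmetric about the center.
#'
#' @param nBeads number of beads (>= 4)
#' @param length tip-to-tip distance, A
#' @param code residue code assigned to the beads
#' @return list(codes, coords, tips, anchors); coords is nBeads x 3, tips
#'   and anchors index rows of coords
#' @export
toyRigidDumbbell <- function(nBeads = 10, length = 60, code = "A") {
  if (nBeads < 4) stop("need >= 4 beads")
  x <- seq(-length / 2, length / 2, length.out = nBeads)
  y <- rep(c(1.5, -1.5), length.out = nBeads)
  y[c(1, nBeads)] <- 0 # tips exactly at +- length/2 on the axis
  coords <- cbind(x = x, y = y, z = 0)
  list(codes = rep(code, nBeads), coords = coords,
       tips = c(1L, nBeads), anchors = c(1L, nBeads))
}

#' Toy dimer topology: rigid dumbbell with two flexible arms
#'
#' Builds the minimal analogue of an F-BAR dimer with two IDR arms: one
#' rigid dumbbell whose halves carry the chain ids of the two arms, each
#' arm a flexible chain bonded to a dumbbell tip, and optionally a small
#' rigid cap ("SH3") at each arm end.
#'
#' @param armSeq residue string for each arm
#' @param dumbbell a [toyRigidDumbbell()] result (even bead count)
#' @param withSH3 append a 4-bead rigid cap at each arm end?
#' @param box periodic box edge, A
#' @return a [Topology-class] (rigid groups named "FBAR" and, if present,
#'   "SH3_A"/"SH3_B")
#' @export
toyDimerTopology <- function(armSeq, dumbbell = toyRigidDumbbell(),
                             withSH3 = FALSE, box = 2000) {
  nd <- length(dumbbell$codes)
  if (nd %% 2 != 0) stop("dumbbell bead count must be even")
  half <- nd / 2
  arm <- strsplit(armSeq, "")[[1]]
  na <- length(arm)
  ncap <- if (withSH3) 4L else 0L
  mk <- function(id) {
    codes <- c(rep(dumbbell$codes[1], half), arm,
               if (withSH3) rep("G", ncap))
    chainFromSequence(paste(codes, collapse = ""), offset = 1, chainId = id)
  }
  topo <- buildTopology(list(mk("A"), mk("B")), box = box)
  # Dumbbell beads are the first `half` residues of each chain; each
  # chain's residue `half` (the bead bonded to its arm) sits on a tip:
  # chain A occupies the left half ending at tip 1, chain B the right half
  # ending at tip 2.
  refA <- dumbbell$coords[half:1, , drop = FALSE]        # resNum half -> tip 1
  refB <- dumbbell$coords[(half + 1):nd, , drop = FALSE] # resNum half -> tip 2
  topo <- rigidFromStructure(
    topo,
    data.frame(resNum = c(seq_len(half), seq_len(half)),
               chain = rep(c("A", "B"), each = half),
               x = c(refA[, 1], refB[, 1]),
               y = c(refA[, 2], refB[, 2]),
               z = c(refA[, 3], refB[, 3])),
    name = "FBAR")
  if (withSH3) {
    cap <- rbind(c(0, 0, 0), c(3.5, 0, 0), c(1.75, 3, 0), c(1.75, 1, 3))
    for (id in c("A", "B")) {
      rs <- half + na + seq_len(ncap)
      topo <- rigidFromStructure(
        topo, data.frame(resNum = rs, chain = id,
                         x = cap[, 1], y = cap[, 2], z = cap[, 3]),
        name = paste0("SH3_", id))
    }
  }
  topo
}

#' Ornstein-Uhlenbeck reference series
#'
#' Exact-discretization OU process with autocorrelation `exp(-k/tau)`:
#' the oracle for [relaxationTime()].
#'
#' @param tau relaxation time, steps
#' @param mean,sd stationary mean and standard deviation
#' @param length series length
#' @param seed RNG seed
#' @return numeric vector
#' @export
ouSeries <- function(tau, mean = 0, sd = 1, length = 1e4, seed = 1) {
  if (tau <= 0) stop("tau must be > 0")
  phi <- exp(-1 / tau)
  .withSeed(seed, {
    x1 <- stats::rnorm(1, 0, sd)
    innov <- stats::rnorm(length - 1, 0, sd * sqrt(1 - phi^2))
    mean + c(x1, as.numeric(
      stats::filter(innov, phi, method = "recursive", init = x1)))
  })
}

#' Toy per-kinase phosphosite sets
#'
#' Draws nested (or partially overlapping) site sets of the requested sizes
#' from the S/T positions of a sequence, mimicking the overlapping
#' per-kinase structure of multi-kinase phosphoregulation.
#'
#' @param seq residue string
#' @param sizes set sizes, e.g. c(5, 11, 22)
#' @param seed RNG seed
#' @param nested nested sets (each contains the smaller ones)? Otherwise
#'   sets are drawn independently.
#' @return named list of integer site vectors (1-based positions), with
#'   attribute `union` holding the union of all sites
#' @export
toyPhosphoSets <- function(seq, sizes, seed = 1, nested = TRUE) {
  codes <- strsplit(seq, "")[[1]]
  st <- which(codes %in% c("S", "T"))
  if (max(sizes, 0) > length(st))
    stop("only ", length(st), " S/T positions; cannot draw ", max(sizes))
  sets <- .withSeed(seed, {
    if (nested) {
      big <- sort(sample(st, max(sizes)))
      lapply(sizes, function(k) sort(big[seq_len(k)]))
    } else {
      lapply(sizes, function(k) sort(sample(st, k)))
    }
  })
  names(sets) <- paste0("set", sizes)
  attr(sets, "union") <- sort(unique(unlist(sets)))
  sets
}

#' Constructed two-state COM-separation series
#'
#' A series with exactly `round(fracHigh * nFrames)` values strictly above
#' the threshold: the oracle for [fractionAbove()].
#'
#' @param fracHigh fraction of frames in the "separated" state
#' @param threshold separation threshold, A
#' @param nFrames series length
#' @param seed RNG seed
#' @return numeric vector
#' @export
twoStateComTrajectory <- function(fracHigh, threshold = 100,
                                  nFrames = 100, seed = 1) {
  if (fracHigh < 0 || fracHigh > 1) stop("fracHigh must be in [0,1]")
  nh <- round(fracHigh * nFrames)
  .withSeed(seed, {
    v <- c(threshold + 10 + abs(stats::rnorm(nh, 0, 5)),
           threshold - 10 - abs(stats::rnorm(nFrames - nh, 0, 5)))
    sample(v)
  })
}
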