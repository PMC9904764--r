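# Observables and the statistical procedures applied to them.

.beadMasses <- function(topology, ff) ff@residues[topology@beads$code, "mass"]

#' Radius of gyration of a configuration
#'
#' Mass-weighted by default:
#' `Rg = sqrt(sum m_i |r_i - r_com|^2 / sum m_i)`.
#'
#' @param coords beads x 3 coordinate matrix
#' @param selection bead ids (default: all rows)
#' @param masses per-bead masses for the whole coordinate set; NULL gives
#'   uniform weights
#' @return Rg, A
#' @export
radiusOfGyration <- function(coords, selection = NULL, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(selection)) selection <- seq_len(nrow(coords))
  if (length(selection) == 0) stop("empty selection")
  x <- coords[selection, , drop = FALSE]
  m <- if (is.null(masses)) rep(1, length(selection)) else masses[selection]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' Center-of-mass separation of two selections
#'
#' @param coords beads x 3 coordinate matrix
#' @param selA,selB disjoint bead id vectors
#' @param masses per-bead masses (NULL = uniform)
#' @return Euclidean COM distance, A
#' @export
comSeparation <- function(coords, selA, selB, masses = NULL) {
  if (length(intersect(selA, selB)) > 0) stop("selections overlap")
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  com <- function(sel) {
    m <- masses[sel]
    colSums(coords[sel, , drop = FALSE] * m) / sum(m)
  }
  sqrt(sum((com(selA) - com(selB))^2))
}

#' Per-frame radius of gyration of a trajectory
#'
#' @param traj a [Trajectory-class]
#' @param ff a [ForceField-class] (bead masses); NULL gives uniform weights
#' @param selection bead ids (default all)
#' @return an [ObservableSeries-class] in A
#' @export
rgSeries <- function(traj, ff = NULL, selection = NULL) {
  m <- if (is.null(ff)) NULL else .beadMasses(traj@topology, ff)
  v <- vapply(seq_len(nFrames(traj)), function(f)
    radiusOfGyration(frameCoords(traj, f), selection, m), numeric(1))
  dtNs <- if (length(traj@timeNs) > 1) diff(traj@timeNs[1:2]) else 1
  observableSeries(v, dtNs, label = "Rg", unit = "A")
}

#' Per-frame COM separation of two selections in a trajectory
#'
#' @inheritParams rgSeries
#' @param selA,selB disjoint bead id vectors
#' @return an [ObservableSeries-class] in A
#' @export
comSeparationSeries <- function(traj, selA, selB, ff = NULL) {
  m <- if (is.null(ff)) NULL else .beadMasses(traj@topology, ff)
  v <- vapply(seq_len(nFrames(traj)), function(f)
    comSeparation(frameCoords(traj, f), selA, selB, m), numeric(1))
  dtNs <- if (length(traj@timeNs) > 1) diff(traj@timeNs[1:2]) else 1
  observableSeries(v, dtNs, label = "COM separation", unit = "A")
}

#' Fraction of frames above a threshold
#'
#' Proportion of (post-trim) frames strictly greater than the threshold.
#' A list of series is pooled with each trajectory weighted by its frame
#' count; [fractionAboveByTrajectory()] gives the per-trajectory
#' time-fraction variant.
#'
#' @param x an [ObservableSeries-class], numeric vector, or list of either
#' @param threshold A (default 100)
#' @return fraction in \[0, 1\]
#' @export
fractionAbove <- function(x, threshold = 100) {
  if (is(x, "ObservableSeries") || is.numeric(x)) x <- list(x)
  v <- unlist(lapply(x, seriesValues))
  if (length(v) == 0) stop("empty series")
  mean(v > threshold)
}

#' @rdname fractionAbove
#' @export
fractionAboveByTrajectory <- function(x, threshold = 100) {
  if (is(x, "ObservableSeries") || is.numeric(x)) x <- list(x)
  vapply(x, function(s) fractionAbove(s, threshold), numeric(1))
}

#' Relaxation time from the autocorrelation function
#'
#' Computes the normalized autocorrelation of the series and fits a single
#' exponential `exp(-t/tau)` on the log scale over lags up to the first
#' zero crossing or 20% of the series, whichever is smaller.
#'
#' @param x an [ObservableSeries-class] or numeric vector
#' @param frameNs frame interval (taken from the series when available)
#' @return list(tau, lags, acf, underSampled); `tau` is in the same time
#'   units as `frameNs` (ns for a series). The `underSampled` flag is set
#'   when tau exceeds a quarter of the series duration.
#' @export
relaxationTime <- function(x, frameNs = NULL) {
  if (is(x, "ObservableSeries")) {
    if (is.null(frameNs)) frameNs <- x@frameNs
    x <- x@values
  }
  if (is.null(frameNs)) frameNs <- 1
  n <- length(x)
  if (n < 50) stop("series too short (need >= 50 frames)")
  if (stats::sd(x) == 0) stop("zero-variance series: no relaxation to fit")
  maxLag <- max(2L, floor(0.2 * n))
  # full autocorrelation by FFT (same 1/n normalization as stats::acf),
  # then the fit window: deep lags are excluded (acf < 0.2) where
  # log-scale noise would bias the fit
  xc <- x - mean(x)
  np <- stats::nextn(2L * n, 2)
  ft <- stats::fft(c(xc, numeric(np - n)))
  ac <- Re(stats::fft(ft * Conj(ft), inverse = TRUE))[seq_len(maxLag + 1)]
  ac <- (ac / ac[1])[-1]
  zero <- which(ac <= 0)
  kmax <- if (length(zero)) max(1L, zero[1] - 1L) else length(ac)
  low <- which(ac < 0.2)
  if (length(low)) kmax <- min(kmax, max(1L, low[1] - 1L))
  if (ac[1] <= 0) { # decorrelated within one frame
    tau <- 0.5 * frameNs
    return(list(tau = tau, lags = frameNs, acf = ac[1],
                underSampled = FALSE))
  }
  k <- seq_len(kmax)
  logc <- log(ac[k])
  slope <- sum(k * logc) / sum(k^2) # through the origin: log C(k) = -k/tau
  tau <- if (is.finite(slope) && slope < 0) -1 / slope else Inf
  tau <- tau * frameNs
  decayed <- any(ac <= 0.2) # correlation decays inside the fit window
  list(tau = tau, lags = k * frameNs, acf = ac[k],
       underSampled = !decayed || !is.finite(tau) ||
         tau > n * frameNs / 4)
}

#' Exclude unequilibrated frames
#'
#' Drops frames with time below twice the relaxation time and records the
#' trim index on the series.
#'
#' @param x an [ObservableSeries-class]
#' @param tau relaxation time, same units as the frame interval
#' @return the series with its trim index set
#' @export
equilibrationTrim <- function(x, tau) {
  stopifnot(is(x, "ObservableSeries"))
  duration <- length(x@values) * x@frameNs
  if (2 * tau >= duration)
    stop("unequilibrated: 2 tau (", round(2 * tau, 2),
         ") >= series duration (", round(duration, 2), ")")
  tvals <- (seq_along(x@values) - 1) * x@frameNs
  x@trimIndex <- as.integer(sum(tvals < 2 * tau))
  validObject(x)
  x
}

#' Five-block mean and error
#'
#' Splits the (post-trim) series into five equal contiguous parts
#' (truncating the remainder), and returns the grand mean together with the
#' standard deviation of the five part means (n-1 denominator) -- the error
#' bar convention used throughout the scans.
#'
#' @param x an [ObservableSeries-class] or numeric vector
#' @return list(mean, error)
#' @export
blockError5 <- function(x) {
  v <- seriesValues(x)
  if (length(v) < 5) stop("need at least 5 frames for 5-block errors")
  per <- length(v) %/% 5
  v <- v[seq_len(5 * per)]
  means <- vapply(split(v, rep(1:5, each = per)), mean, numeric(1))
  list(mean = mean(v), error = stats::sd(means))
}

#' Contact frequency map between two selections
#'
#' Entry (i, j) is the fraction of frames in which beads `selA[i]` and
#' `selB[j]` are closer than the cutoff. Symmetric when the selections are
#' identical.
#'
#' @param traj a [Trajectory-class]
#' @param selA,selB bead id vectors
#' @param cutoff contact distance, A (default 10, the alpha-carbon scale)
#' @param skipFrames leading frames to exclude (equilibration trim)
#' @return matrix of contact frequencies in \[0, 1\]
#' @export
contactMap <- function(traj, selA, selB, cutoff = 10, skipFrames = 0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  frames <- setdiff(seq_len(nFrames(traj)), seq_len(skipFrames))
  M <- matrix(0, length(selA), length(selB),
              dimnames = list(selA, selB))
  for (f in frames) {
    X <- frameCoords(traj, f)
    d2 <- outer(rowSums(X[selA, , drop = FALSE]^2),
                rowSums(X[selB, , drop = FALSE]^2), `+`) -
      2 * X[selA, , drop = FALSE] %*% t(X[selB, , drop = FALSE])
    M <- M + (d2 < cutoff^2)
  }
  M / length(frames)
}

#' F-BAR tip bead selection
#'
#' The outermost fraction of rigid-group beads along the group's long axis
#' (first principal component of its reference coordinates), on both ends.
#'
#' @param topology a [Topology-class] with the named rigid group
#' @param name rigid group name (default "FBAR")
#' @param fraction outermost fraction per end (default 0.1)
#' @return integer bead ids
#' @export
fbarTips <- function(topology, name = "FBAR", fraction = 0.1) {
  g <- .findGroup(topology, name)
  if (is.null(g)) stop("no rigid group named '", name, "'")
  ref <- sweep(g$refCoords, 2, colMeans(g$refCoords))
  ax <- svd(ref)$v[, 1]
  s <- as.numeric(ref %*% ax)
  k <- max(1L, ceiling(fraction * length(s)))
  ends <- c(order(s)[seq_len(k)], order(-s)[seq_len(k)])
  g$ids[ends]
}

#' Mean Rg versus net chain charge, by condition
#'
#' One row per condition (phospho state x charge mode) with the net charge
#' computed from the topology under its force field, the pooled mean Rg,
#' and the five-block error.
#'
#' @param conditions named list; each entry is
#'   list(topology=, ff=, series=) with `series` a trimmed
#'   [ObservableSeries-class] or list of them (one per trajectory)
#' @return data.frame(label, netCharge, meanRg, blockError, nFrames)
#' @export
rgVsChargeTable <- function(conditions) {
  rows <- lapply(names(conditions), function(lab) {
    cond <- conditions[[lab]]
    ser <- cond$series
    if (is(ser, "ObservableSeries")) ser <- list(ser)
    v <- unlist(lapply(ser, seriesValues))
    be <- blockError5(v)
    data.frame(label = lab,
               netCharge = netCharge(cond$topology, cond$ff),
               meanRg = be$mean, blockError = be$error,
               nFrames = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rg across a temperature grid, by state
#'
#' Per-state, per-temperature mean Rg with five-block errors, plus the
#' temperature of maximal relative Rg difference between the first two
#' states (when two or more states are present).
#'
#' @param results list; each entry is list(state=, temperature=, series=)
#'   with `series` a trimmed [ObservableSeries-class] or list of them
#' @return list(table = data.frame(state, temperature, meanRg, blockError),
#'   tStar = temperature of maximal relative difference or NA)
#' @export
temperatureScanSummary <- function(results) {
  tab <- do.call(rbind, lapply(results, function(r) {
    ser <- r$series
    if (is(ser, "ObservableSeries")) ser <- list(ser)
    be <- blockError5(unlist(lapply(ser, seriesValues)))
    data.frame(state = r$state, temperature = r$temperature,
               meanRg = be$mean, blockError = be$error,
               stringsAsFactors = FALSE)
  }))
  temps <- sort(unique(tab$temperature))
  if (length(temps) < 3) stop("need at least 3 temperatures")
  states <- unique(tab$state)
  tStar <- NA_real_
  if (length(states) >= 2) {
    a <- tab[tab$state == states[1], ]
    b <- tab[tab$state == states[2], ]
    shared <- intersect(a$temperature, b$temperature)
    if (length(shared)) {
      rel <- vapply(shared, function(T) {
        ra <- a$meanRg[a$temperature == T]
        rb <- b$meanRg[b$temperature == T]
        abs(ra - rb) / min(ra, rb)
      }, numeric(1))
      tStar <- shared[which.max(rel)]
    }
  }
  list(table = tab, tStar = tStar)
}

#' Sequence charge composition and diagram-of-states region
#'
#' Computes the fraction of positive (`fplus`) and negative (`fminus`)
#' residues, FCR = fplus + fminus, NCPR = fplus - fminus, and classifies
#' the sequence into the standard charge-patterning diagram-of-states
#' regions. Phosphorylated positions count as one negatively charged
#' residue each for the count-based fractions; `ncprWeighted` additionally
#' weights them by the phospho charge magnitude.
#'
#' @param seq residue string or vector of codes (may contain pS/pT)
#' @param phosphoSites optional residue positions (1-based within `seq`)
#'   to treat as phosphorylated
#' @param phosphoCharge charge per phospho residue for the weighted NCPR
#' @return list(fplus, fminus, fcr, ncpr, ncprWeighted, region)
#' @export
chargeMetrics <- function(seq, phosphoSites = NULL, phosphoCharge = -2) {
  codes <- if (length(seq) == 1 && is.character(seq) && nchar(seq) > 1)
    strsplit(seq, "")[[1]] else as.character(seq)
  if (!is.null(phosphoSites)) {
    if (!all(codes[phosphoSites] %in% c("S", "T", "pS", "pT")))
      stop("phosphosites must be S/T")
    codes[phosphoSites] <- ifelse(codes[phosphoSites] %in% c("S", "pS"),
                                  "pS", "pT")
  }
  n <- length(codes)
  pos <- codes %in% c("K", "R")
  phos <- codes %in% c("pS", "pT")
  neg <- codes %in% c("D", "E") | phos
  fplus <- sum(pos) / n
  fminus <- sum(neg) / n
  fcr <- fplus + fminus
  ncpr <- fplus - fminus
  ncprW <- (sum(pos) - sum(codes %in% c("D", "E")) +
              phosphoCharge * sum(phos)) / n
  region <-
    if (fplus > 0.35 && fminus > 0.35) "coil/hairpin/chimera"
    else if (fplus > 0.35) "positive polyelectrolyte"
    else if (fminus > 0.35) "negative polyelectrolyte"
    else if (fcr > 0.35) "coil/hairpin/chimera"
    else if (fcr >= 0.25) "boundary"
    else "globule/tadpole"
  list(fplus = fplus, fminus = fminus, fcr = fcr, ncpr = ncpr,
       ncprWeighted = ncprW, region = region)
}
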