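# Force-field construction and the analytic pair/bond energy terms.
# Units: A, fs, g/mol, kcal/mol, K, elementary charges.

.kB <- 0.0019872041            # kcal/(mol K)
.coulomb <- 332.0637           # kcal A / (mol e^2)
.canonicalAA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.extfile <- function(name) {
  dir <- getOption("cgphos.extdata") # overridable for testing
  path <- if (!is.null(dir)) file.path(dir, name)
          else system.file("extdata", name, package = "cgphos")
  if (!nzchar(path) || !file.exists(path))
    stop("parameter data file missing: ", name)
  path
}

.readParamTable <- function(name) {
  path <- .extfile(name)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

.verifyChecksum <- function(name) {
  sums <- utils::read.table(.extfile("CHECKSUMS"), header = FALSE,
                            col.names = c("md5", "file"),
                            stringsAsFactors = FALSE)
  expected <- sums$md5[match(name, sums$file)]
  if (is.na(expected)) stop("no recorded checksum for data file: ", name)
  got <- unname(tools::md5sum(.extfile(name)))
  if (!identical(got, expected))
    stop("corrupt parameter data file (checksum mismatch): ", name)
  got
}

#' Load a coarse-grained force field (HPS or KH model D)
#'
#' Reads the shipped residue parameter tables, verifies their checksums,
#' and assembles the type-pair interaction tables for all 22 residue types
#' (20 canonical plus phosphoserine `pS` and phosphothreonine `pT`).
#'
#' For `"HPS"`, pair attraction strength is `epsilon = 0.2` kcal/mol for
#' every pair and `lambda_ij` is the arithmetic mean of the per-residue
#' hydropathies. For `"KH-D"`, pair energies derive from a residue-residue
#' contact matrix via `epsilon_ij = |alpha (e_ij - e0)|` with the tail sign
#' given by [khPairFromMJ()]; phospho residues take the aspartate row of the
#' contact matrix while keeping their own charge and diameter.
#'
#' @param model "HPS" or "KH-D".
#' @param phosphoChargeMode charge per phospho residue: -2 (default) or -1.5.
#' @param hisCharge histidine charge, default 0 (neutral-pH convention).
#' @param debyeLength electrostatic screening length, A.
#' @param dielectric uniform relative dielectric constant.
#' @param dhCutoff Debye-Hueckel truncation distance, A.
#' @param bondR0,bondK harmonic bond equilibrium length (A) and constant
#'   (kcal/(mol A^2)) in the convention `U = K (r - r0)^2`.
#' @param hpsEpsilon HPS pair well depth, kcal/mol.
#' @return a [ForceField-class]
#' @examples
#' ff <- loadForceField("HPS")
#' pairParams(ff, "F", "F")
#' @export
loadForceField <- function(model = c("HPS", "KH-D"),
                           phosphoChargeMode = -2,
                           hisCharge = 0,
                           debyeLength = 10, dielectric = 80,
                           dhCutoff = 35,
                           bondR0 = 3.81, bondK = 378,
                           hpsEpsilon = 0.2) {
  model <- match.arg(model)
  if (!phosphoChargeMode %in% c(-2, -1.5))
    stop("phosphoChargeMode must be -2 or -1.5")
  sums <- c(hps_params.tsv = .verifyChecksum("hps_params.tsv"),
            phospho = .verifyChecksum("phospho_params_synthetic.tsv"))
  res <- .readParamTable("hps_params.tsv")
  if (!setequal(res$code, .canonicalAA))
    stop("residue parameter table incomplete")
  res$charge[res$code == "H"] <- hisCharge
  pho <- .readParamTable("phospho_params_synthetic.tsv")
  pho$charge <- phosphoChargeMode
  res <- rbind(res, pho)
  rownames(res) <- res$code
  codes <- res$code
  nt <- length(codes)

  sig <- outer(res$sigma, res$sigma, function(a, b) (a + b) / 2)
  dimnames(sig) <- list(codes, codes)
  if (model == "HPS") {
    lam <- outer(res$lambda, res$lambda, function(a, b) (a + b) / 2)
    eps <- matrix(hpsEpsilon, nt, nt)
  } else {
    sums <- c(sums, mj = .verifyChecksum("mj_matrix_synthetic.tsv"),
              khd = .verifyChecksum("khd_constants.tsv"))
    kh <- .readParamTable("khd_constants.tsv")
    alpha <- kh$value[kh$key == "alpha"]
    e0 <- kh$value[kh$key == "e0"]
    mjt <- .readParamTable("mj_matrix_synthetic.tsv")
    mj <- as.matrix(mjt[, -1])
    rownames(mj) <- mjt$code
    if (!isSymmetric(unname(mj))) stop("contact matrix must be symmetric")
    # phospho residues take the aspartate contact row
    mapcode <- ifelse(codes %in% c("pS", "pT"), "D", codes)
    lam <- matrix(0, nt, nt)
    eps <- matrix(0, nt, nt)
    for (i in seq_len(nt))
      for (j in seq_len(nt)) {
        k <- khPairFromMJ(mj[mapcode[i], mapcode[j]], alpha, e0)
        eps[i, j] <- k$epsilon
        lam[i, j] <- k$lambdaSign
      }
  }
  dimnames(lam) <- dimnames(eps) <- list(codes, codes)

  new("ForceField", model = model, residues = res,
      pairSigma = sig, pairLambda = lam, pairEpsilon = eps,
      elec = list(debyeLength = debyeLength, dielectric = dielectric,
                  coulombConstant = .coulomb, cutoff = dhCutoff),
      bond = list(r0 = bondR0, K = bondK),
      phosphoCharge = phosphoChargeMode, checksums = sums)
}

#' Pair parameters for a residue-type pair
#' @param ff a [ForceField-class]
#' @param codeI,codeJ residue codes (e.g. "F", "pS")
#' @return list(sigma, lambda, epsilon)
#' @export
pairParams <- function(ff, codeI, codeJ) {
  if (!codeI %in% rownames(ff@pairSigma) ||
      !codeJ %in% rownames(ff@pairSigma))
    stop("unknown residue code")
  list(sigma = ff@pairSigma[codeI, codeJ],
       lambda = ff@pairLambda[codeI, codeJ],
       epsilon = ff@pairEpsilon[codeI, codeJ])
}

#' Ashbaugh-Hatch pair energy
#'
#' Hydropathy-scaled Lennard-Jones potential: with
#' `phi(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`, returns
#' `phi + (1 - lambda) eps` for `r <= 2^(1/6) sigma`, `lambda * phi` up to
#' the 3 sigma cutoff, and 0 beyond. Continuous at the minimum; plain
#' truncation (no shift) at the cutoff.
#'
#' @param r distance(s), A (> 0)
#' @param sigma pair diameter, A
#' @param lambda hydropathy weight (HPS: mean of per-residue lambdas in
#'   \[0,1\]; KH: +-1 tail sign)
#' @param epsilon well depth, kcal/mol
#' @return energy, kcal/mol
#' @examples
#' ahPairEnergy(2^(1/6) * 6, sigma = 6, lambda = 1, epsilon = 0.2) # -0.2
#' @export
ahPairEnergy <- function(r, sigma, lambda, epsilon = 0.2) {
  if (any(r <= 0)) stop("r must be > 0")
  sr6 <- (sigma / r)^6
  phi <- 4 * epsilon * (sr6^2 - sr6)
  rmin <- 2^(1 / 6) * sigma
  out <- ifelse(r <= rmin, phi + (1 - lambda) * epsilon, lambda * phi)
  out[r > 3 * sigma] <- 0
  out
}

#' Debye-Hueckel screened Coulomb pair energy
#'
#' `C qi qj / (dielectric r) * exp(-r / debyeLength)`, truncated at the
#' configured cutoff. `C = 332.0637` kcal A / (mol e^2).
#'
#' @param r distance(s), A (> 0)
#' @param qi,qj charges, e
#' @param debyeLength screening length, A
#' @param dielectric relative dielectric constant
#' @param cutoff truncation distance, A
#' @return energy, kcal/mol
#' @examples
#' dhPairEnergy(10, 1, 1) # ~0.1527
#' @export
dhPairEnergy <- function(r, qi, qj, debyeLength = 10, dielectric = 80,
                         cutoff = 35) {
  if (any(r <= 0)) stop("r must be > 0")
  out <- .coulomb * qi * qj / (dielectric * r) * exp(-r / debyeLength)
  out[r > cutoff] <- 0
  out
}

#' Harmonic bond energy
#'
#' `U = K (r - r0)^2` (LAMMPS `bond_style harmonic` convention: the
#' effective spring constant is `2 K`).
#'
#' @param r distance(s), A (> 0)
#' @param r0 equilibrium length, A
#' @param K bond constant, kcal/(mol A^2)
#' @return energy, kcal/mol
#' @export
bondEnergy <- function(r, r0 = 3.81, K = 378) {
  if (any(r <= 0)) stop("r must be > 0")
  K * (r - r0)^2
}

#' Kim-Hummer pair mapping from a contact energy
#'
#' `epsilon = |alpha (e_mj - e0)|`; the Ashbaugh-Hatch tail weight is `+1`
#' (attractive) when `alpha (e_mj - e0) <= 0` and `-1` (repulsive tail)
#' otherwise.
#'
#' @param eMJ contact energy, kcal/mol
#' @param alpha,e0 scaling constants of the model-D mapping
#' @return list(epsilon, lambdaSign)
#' @export
khPairFromMJ <- function(eMJ, alpha, e0) {
  v <- alpha * (eMJ - e0)
  list(epsilon = abs(v), lambdaSign = ifelse(v <= 0, 1, -1))
}

# Free-chain reference solvent-accessible surface areas per residue type
# (theoretical maximum ASA, A^2); phospho values are parent + phosphate
# estimates.
.maxASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174,
             pS = 200, pT = 217)

#' SASA-based interaction scale factors
#'
#' The KH model D scales nonbonded pair interactions by the solvent
#' accessibility of each residue relative to a free chain. Flexible beads
#' get factor 1.0; beads inside rigid groups get
#' `SASA_folded / SASA_free`, clipped to `[floor, 1]`. The pair scale used
#' by the engine is the product of the two per-residue factors.
#'
#' @param topology a [Topology-class]
#' @param domainSasa folded-state SASA (A^2) for every rigid-group bead:
#'   a numeric vector named by bead id, or a data.frame(beadId, sasa)
#' @param floor lower clip for buried residues (default 0.01)
#' @return numeric vector of per-bead factors in (0, 1]
#' @export
sasaScaleFactors <- function(topology, domainSasa = NULL, floor = 0.01) {
  n <- nBeads(topology)
  fac <- rep(1.0, n)
  rig <- unlist(lapply(topology@rigid, `[[`, "ids"))
  if (length(rig) == 0) return(fac)
  if (is.data.frame(domainSasa)) {
    v <- domainSasa$sasa
    names(v) <- domainSasa$beadId
    domainSasa <- v
  }
  miss <- setdiff(as.character(rig), names(domainSasa))
  if (length(miss))
    stop("missing SASA for rigid-group bead(s): ",
         paste(miss, collapse = ", "))
  ref <- .maxASA[topology@beads$code[rig]]
  fac[rig] <- pmin(1, pmax(floor, domainSasa[as.character(rig)] / ref))
  fac
}

#' Net charge of a topology under a force field
#' @param topology a [Topology-class]
#' @param ff a [ForceField-class]
#' @return total charge, e
#' @export
netCharge <- function(topology, ff) {
  sum(ff@residues[topology@beads$code, "charge"])
}

# ----------------------------------------------------------------- internal

# Pack topology + force field into the list consumed by the C++ kernels.
.sysList <- function(topology, ff, sasa = NULL) {
  codes <- rownames(ff@residues)
  type <- match(topology@beads$code, codes)
  if (anyNA(type))
    stop("residue code(s) absent from force field: ",
         paste(unique(topology@beads$code[is.na(type)]), collapse = ", "))
  n <- nBeads(topology)
  rigid <- integer(n)
  for (k in seq_along(topology@rigid)) rigid[topology@rigid[[k]]$ids] <- k
  if (is.null(sasa)) sasa <- rep(1.0, n)
  list(type = as.integer(type - 1L),
       charge = as.numeric(ff@residues$charge[type]),
       sasa = as.numeric(sasa),
       mass = as.numeric(ff@residues$mass[type]),
       sig2 = ff@pairSigma^2,
       lam = ff@pairLambda,
       eps = ff@pairEpsilon,
       bonds = matrix(as.integer(topology@bonds), ncol = 2),
       bondR0 = ff@bond$r0, bondK = ff@bond$K,
       rigid = as.integer(rigid),
       box = topology@box,
       elec = c(ff@elec$coulombConstant / ff@elec$dielectric,
                ff@elec$debyeLength, ff@elec$cutoff))
}
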