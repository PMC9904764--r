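# Building SystemTopology objects: chains, rigid groups, phospho states.

.validCodes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "pS", "pT")

#' Build a chain bead table from a residue sequence
#'
#' @param seq one-letter residue string (canonical amino acids)
#' @param offset residue number of the first residue, so that canonical
#'   site labels (e.g. S668) address the right bead
#' @param chainId chain identifier
#' @return data.frame(code, resNum, chain), one row per bead
#' @examples
#' chainFromSequence("GS", offset = 327)  # residues 327, 328
#' @export
chainFromSequence <- function(seq, offset = 1L, chainId = "A") {
  if (!nzchar(seq)) stop("empty sequence")
  codes <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!codes %in% .validCodes[1:20])
  if (length(bad))
    stop("unknown residue letter '", codes[bad[1]], "' at position ", bad[1])
  data.frame(code = codes,
             resNum = seq_along(codes) + as.integer(offset) - 1L,
             chain = chainId, stringsAsFactors = FALSE)
}

#' Assemble a topology from chains
#'
#' Connects sequence neighbors (contiguous residue numbers within a chain)
#' with harmonic bonds and places the system in a periodic cubic box.
#'
#' @param chains a chain data.frame from [chainFromSequence()] or a list of
#'   them
#' @param box periodic cubic box edge, A
#' @param phosphoState state label (default "DEPH")
#' @return a [Topology-class]
#' @export
buildTopology <- function(chains, box = 2000, phosphoState = "DEPH") {
  if (is.data.frame(chains)) chains <- list(chains)
  b <- do.call(rbind, chains)
  rownames(b) <- NULL
  bonds <- matrix(integer(0), 0, 2)
  offset <- 0L
  for (ch in chains) {
    n <- nrow(ch)
    if (n > 1) {
      i <- offset + seq_len(n - 1)
      contig <- diff(ch$resNum) == 1L
      bonds <- rbind(bonds, cbind(i[contig], i[contig] + 1L))
    }
    offset <- offset + n
  }
  new("Topology", beads = b, bonds = bonds, rigid = list(),
      phosphoState = phosphoState,
      phosphoSites = data.frame(site = integer(0), chain = character(0)),
      box = box)
}

#' Declare a rigid group from numbered C-alpha coordinates
#'
#' Beads whose (chain, residue number) match a structure coordinate become
#' one rigid group with those coordinates as reference geometry; residues
#' of the span without coordinates stay flexible. A structure spanning two
#' chains (an F-BAR dimer) yields a single rigid group.
#'
#' @param topology a [Topology-class]
#' @param caCoords data.frame(resNum, chain, x, y, z) and optionally `code`
#'   for sequence checking, e.g. from [readPdbCa()] or [toyRigidDumbbell()]
#' @param name group name (e.g. "FBAR", "SH3_A")
#' @return the topology with the rigid group appended
#' @export
rigidFromStructure <- function(topology, caCoords, name = "rigid") {
  b <- topology@beads
  key <- paste(b$chain, b$resNum)
  skey <- paste(caCoords$chain, caCoords$resNum)
  if (anyDuplicated(skey))
    stop("duplicate residue numbers in structure")
  ids <- match(skey, key)
  if (anyNA(ids))
    stop("structure residue(s) absent from topology: ",
         paste(utils::head(skey[is.na(ids)], 5), collapse = ", "))
  if (!is.null(caCoords$code)) {
    bad <- which(caCoords$code != b$code[ids])
    if (length(bad))
      stop("sequence/structure residue mismatch at: ",
           paste(utils::head(paste0(caCoords$chain[bad], ":",
                                    caCoords$resNum[bad]), 5),
                 collapse = ", "))
  }
  taken <- unlist(lapply(topology@rigid, `[[`, "ids"))
  if (any(ids %in% taken))
    stop("bead(s) already belong to a rigid group")
  grp <- list(ids = as.integer(ids),
              refCoords = as.matrix(caCoords[, c("x", "y", "z")]),
              name = name)
  topology@rigid <- c(topology@rigid, list(grp))
  validObject(topology)
  topology
}

#' Read a phosphosite table
#'
#' Reads a site-list file (TSV with columns site, residue, kinases) such as
#' the shipped synthetic-membership Cdc15 fixture, optionally filtered to
#' one kinase.
#'
#' @param path file path; default is the shipped fixture
#'   `cdc15_phosphosites_synthetic.tsv`
#' @param kinase optional kinase name (e.g. "Pom1"); NULL returns the union
#' @return data.frame(site, residue, kinases)
#' @export
readPhosphoSites <- function(path = NULL, kinase = NULL) {
  if (is.null(path)) path <- .extfile("cdc15_phosphosites_synthetic.tsv")
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("site", "residue") %in% names(s)))
    stop("phosphosite table needs columns site, residue")
  if (anyDuplicated(s$site)) stop("duplicate phosphosites")
  if (!is.null(kinase)) {
    hit <- vapply(strsplit(s$kinases, ","), function(k) kinase %in% k,
                  logical(1))
    s <- s[hit, , drop = FALSE]
  }
  rownames(s) <- NULL
  s
}

#' Apply a phosphosite set to a topology
#'
#' Replaces serine/threonine codes at the given residue numbers with
#' pS/pT on every chain (a dimer gets both copies phosphorylated). Bead
#' count, bonds and rigid groups are untouched; only residue types (and
#' hence charges under the force field) change. Already-phosphorylated
#' positions are left as-is, so the operation is idempotent.
#'
#' @param topology a [Topology-class]
#' @param sites integer residue numbers, or a data.frame with a `site`
#'   column (e.g. from [readPhosphoSites()])
#' @param state new phospho-state label (e.g. "POM1", "FULL")
#' @return the modified topology
#' @export
applyPhosphoSites <- function(topology, sites, state = "custom") {
  if (is.data.frame(sites)) sites <- sites$site
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) stop("phosphosites must be unique")
  b <- topology@beads
  if (length(sites) == 0) return(topology)
  applied <- data.frame(site = integer(0), chain = character(0))
  rigidIds <- unlist(lapply(topology@rigid, `[[`, "ids"))
  for (s in sites) {
    hit <- which(b$resNum == s)
    if (length(hit) == 0) stop("site ", s, " absent from topology")
    code <- b$code[hit]
    if (!all(code %in% c("S", "T", "pS", "pT")))
      stop("site ", s, " is not S/T (found ",
           paste(unique(code), collapse = ","), ")")
    if (any(hit %in% rigidIds))
      warning("phosphosite ", s, " lies inside a rigid group; applied anyway")
    b$code[hit] <- ifelse(code %in% c("S", "pS"), "pS", "pT")
    applied <- rbind(applied,
                     data.frame(site = s, chain = b$chain[hit]))
  }
  topology@beads <- b
  topology@phosphoState <- state
  topology@phosphoSites <- applied
  topology
}

#' Select bead ids by chain, residue range, or flexibility
#'
#' @param topology a [Topology-class]
#' @param chain optional chain id(s)
#' @param resRange optional c(first, last) residue numbers (inclusive)
#' @param flexible TRUE: only beads outside rigid groups; FALSE: only
#'   rigid-group beads; NULL: both
#' @return integer bead ids
#' @export
beadSelect <- function(topology, chain = NULL, resRange = NULL,
                       flexible = NULL) {
  b <- topology@beads
  keep <- rep(TRUE, nrow(b))
  if (!is.null(chain)) keep <- keep & b$chain %in% chain
  if (!is.null(resRange))
    keep <- keep & b$resNum >= resRange[1] & b$resNum <= resRange[2]
  if (!is.null(flexible)) {
    rig <- rep(FALSE, nrow(b))
    rig[unlist(lapply(topology@rigid, `[[`, "ids"))] <- TRUE
    keep <- keep & (if (flexible) !rig else rig)
  }
  ids <- which(keep)
  if (length(ids) == 0) stop("empty bead selection")
  ids
}
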