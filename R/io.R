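# Readers and writers for the external formats, plus provenance helpers.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file
#' @return named character vector of uppercase sequences
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0) stop("no sequences in ", path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*", "", names(set))
  out
}

#' Read C-alpha coordinates from a PDB file
#'
#' Keeps CA atom records only, resolving alternate locations by highest
#' occupancy (then first). Insertion codes are rejected; duplicate residues
#' after altloc resolution are an error.
#'
#' @param path PDB file
#' @param chain optional chain filter (e.g. "A")
#' @return data.frame(resNum, chain, code, x, y, z), one row per residue
#' @export
readPdbCa <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  a <- a[a$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no CA atoms in ", path)
  if (any(!is.na(a$insert) & a$insert != ""))
    stop("insertion codes are not supported")
  key <- paste(a$chain, a$resno)
  if (anyDuplicated(key)) {
    a$o[is.na(a$o)] <- 0
    a <- a[order(key, -a$o), , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno)), , drop = FALSE]
    if (anyDuplicated(paste(a$chain, a$resno)))
      stop("duplicate residues after altloc resolution")
  }
  code <- bio3d::aa321(a$resid)
  if (any(code == "X"))
    stop("non-standard residue(s): ",
         paste(unique(a$resid[code == "X"]), collapse = ", "))
  data.frame(resNum = a$resno, chain = a$chain, code = code,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

.trajFormatVersion <- 1L

#' Write / read a trajectory container
#'
#' Lossless round trip of coordinates, energy log, parameters and topology
#' (an RDS container with a format version; a version mismatch on read is
#' an error).
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @return `writeTrajectory` returns the path invisibly; `readTrajectory`
#'   the [Trajectory-class]
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  saveRDS(list(format = "cgphos-trajectory",
               version = .trajFormatVersion, traj = traj), path)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable trajectory file '",
                                           path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "cgphos-trajectory"))
    stop("not a trajectory container: ", path)
  if (!identical(obj$version, .trajFormatVersion))
    stop("trajectory format version ", obj$version,
         " does not match reader version ", .trajFormatVersion)
  obj$traj
}

#' Export a trajectory as plain-text XYZ
#'
#' One snapshot per frame: bead count line, comment line with the time,
#' then one `code x y z` line per bead (%.3f A).
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeXYZ <- function(traj, path) {
  n <- dim(traj@coords)[1]
  codes <- traj@topology@beads$code
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    X <- frameCoords(traj, f)
    writeLines(c(as.character(n),
                 paste0("t= ", format(traj@timeNs[f], digits = 6), " ns")),
               con)
    writeLines(sprintf("%s %.3f %.3f %.3f", codes, X[, 1], X[, 2], X[, 3]),
               con)
  }
  invisible(path)
}

#' Read an XYZ trajectory file
#' @param path XYZ file
#' @return list(codes, coords = beads x 3 x frames array)
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty XYZ file")
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("malformed XYZ header")
  per <- n + 2
  if (length(lines) %% per != 0)
    stop("truncated XYZ file: ", length(lines), " lines not a multiple of ",
         per)
  nf <- length(lines) %/% per
  coords <- array(NA_real_, c(n, 3, nf))
  codes <- NULL
  for (f in seq_len(nf)) {
    block <- lines[(f - 1) * per + 2 + seq_len(n)]
    parts <- strsplit(trimws(block), "\\s+")
    codes <- vapply(parts, `[`, character(1), 1)
    coords[, , f] <- t(vapply(parts, function(p)
      as.numeric(p[2:4]), numeric(3)))
  }
  if (any(!is.finite(coords))) stop("malformed XYZ coordinates")
  list(codes = codes, coords = coords)
}

#' Write a TSV table with a provenance header
#'
#' @param df data.frame
#' @param path output file
#' @param provenance named list recorded as `# key: value` header lines
#' @return the path, invisibly
#' @export
writeTSV <- function(df, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(paste0("# ", k, ": ", provenance[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
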