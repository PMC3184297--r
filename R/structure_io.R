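#' @importFrom stats sd rnorm runif pnorm setNames cor quantile
#' @importFrom utils head tail
NULL

# 20 standard amino acids: 3-letter -> 1-letter.
AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' The 20 standard amino-acid one-letter codes, alphabetical
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() sort(unname(AA3))

# Common modified residues with an obvious parent type; MODRES records in the
# file extend this at parse time.
MODIFIED_PARENT <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", SEP = "SER", TPO = "THR",
  PTR = "TYR", CSO = "CYS", HYP = "PRO", MLY = "LYS", KCX = "LYS",
  CME = "CYS", CSD = "CYS", OCS = "CYS", FME = "MET", HIC = "HIS"
)

new_mainchain <- function(id, aa, n, ca, c, cb = NULL, resno = NULL,
                          breaks = NULL, source_path = NA_character_) {
  nr <- length(aa)
  stopifnot(nrow(n) == nr, nrow(ca) == nr, nrow(c) == nr)
  if (is.null(resno)) resno <- seq_len(nr)
  if (is.null(breaks)) breaks <- rep(FALSE, max(nr - 1L, 0L))
  structure(
    list(id = id, aa = aa, n = n, ca = ca, c = c, cb = cb,
         resno = as.integer(resno), breaks = breaks,
         source_path = source_path),
    class = "mainchain"
  )
}

#' Number of residues in a main-chain structure
#' @param s A `mainchain` structure.
#' @return Integer residue count.
#' @export
n_residues <- function(s) length(s$aa)

#' @export
print.mainchain <- function(x, ...) {
  cat(sprintf("<mainchain> %s: %d residues, %d chain break(s)\n",
              x$id, n_residues(x), sum(x$breaks)))
  cat(" sequence:", paste(x$aa, collapse = ""), "\n")
  invisible(x)
}

# Validate the structure invariants; errors on violation.
validate_mainchain <- function(s) {
  stopifnot(inherits(s, "mainchain"))
  if (n_residues(s) == 0L) stop("empty structure")
  if (!all(s$aa %in% aa_alphabet())) stop("nonstandard residue type present")
  dn <- sqrt(rowSums((s$n - s$ca)^2))
  dc <- sqrt(rowSums((s$c - s$ca)^2))
  if (!all(is.finite(dn)) || !all(is.finite(dc)) || any(dn <= 0) || any(dc <= 0))
    stop("invalid main-chain bond geometry")
  invisible(s)
}

#' Parse a main-chain structure from PDB-format text
#'
#' Reads ATOM/HETATM records for one chain (the first, unless `chain` is
#' given) of the first MODEL, keeping only main-chain N, CA, C atoms plus an
#' optional CB (parsed but never used in scoring). Alternate locations are
#' resolved to the highest occupancy (first listed on ties). MODRES records
#' and a built-in table map modified residues (e.g. selenomethionine) to
#' their parent type; residues with no parent mapping, or missing any of
#' N/CA/C, are dropped with a warning and a chain break is recorded between
#' their neighbours.
#'
#' @param pdb_text PDB file content as a single string or character vector of
#'   lines.
#' @param id Identifier to give the structure.
#' @param chain Optional chain identifier; default takes the first chain.
#' @return A `mainchain` structure.
#' @export
parse_mainchain <- function(pdb_text, id = "structure", chain = NULL) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1L]] else pdb_text
  # first MODEL only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]

  # MODRES: columns 13-15 modified name, 25-27 standard name
  modres <- lines[startsWith(lines, "MODRES")]
  modmap <- MODIFIED_PARENT
  for (ln in modres) {
    from <- trimws(substr(ln, 13L, 15L))
    to <- trimws(substr(ln, 25L, 27L))
    if (nzchar(from) && to %in% names(AA3)) modmap[from] <- to
  }

  atom <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(atom)) stop("no ATOM records in input")
  fields <- data.frame(
    name    = trimws(substr(atom, 13L, 16L)),
    altloc  = substr(atom, 17L, 17L),
    resname = trimws(substr(atom, 18L, 20L)),
    chain   = substr(atom, 22L, 22L),
    resno   = suppressWarnings(as.integer(substr(atom, 23L, 26L))),
    icode   = substr(atom, 27L, 27L),
    x = as.numeric(substr(atom, 31L, 38L)),
    y = as.numeric(substr(atom, 39L, 46L)),
    z = as.numeric(substr(atom, 47L, 54L)),
    occ = suppressWarnings(as.numeric(substr(atom, 55L, 60L))),
    stringsAsFactors = FALSE
  )
  fields$occ[is.na(fields$occ)] <- 1
  fields <- fields[fields$name %in% c("N", "CA", "C", "CB") &
                     !is.na(fields$resno), , drop = FALSE]
  if (!nrow(fields)) stop("no parsable main-chain ATOM records")
  if (is.null(chain)) chain <- fields$chain[1L]
  fields <- fields[fields$chain == chain, , drop = FALSE]
  if (!nrow(fields)) stop(sprintf("no ATOM records for chain '%s'", chain))

  # residue key preserving (resno, icode); order by resno then insertion code
  key <- paste(fields$resno, fields$icode, sep = "|")
  ukey <- unique(key[order(fields$resno, fields$icode)])
  nres <- length(ukey)
  aa <- character(nres); resno <- integer(nres)
  nmat <- camat <- cmat <- cbmat <- matrix(NA_real_, nres, 3L)
  keep <- logical(nres)
  dropped <- character(0)
  for (r in seq_len(nres)) {
    rec <- fields[key == ukey[r], , drop = FALSE]
    resno[r] <- rec$resno[1L]
    rn <- rec$resname[1L]
    if (!rn %in% names(AA3) && rn %in% names(modmap)) rn <- modmap[[rn]]
    if (!rn %in% names(AA3)) {
      dropped <- c(dropped, sprintf("%s%d (unmapped type %s)",
                                    rec$resname[1L], resno[r], rec$resname[1L]))
      next
    }
    aa[r] <- AA3[[rn]]
    pick <- function(an) {
      sub <- rec[rec$name == an, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      # altloc: highest occupancy, then first listed
      sub[order(-sub$occ)[1L], c("x", "y", "z")]
    }
    pn <- pick("N"); pca <- pick("CA"); pc <- pick("C")
    if (is.null(pn) || is.null(pca) || is.null(pc)) {
      dropped <- c(dropped, sprintf("%s%d (incomplete main chain)",
                                    rec$resname[1L], resno[r]))
      next
    }
    nmat[r, ] <- as.numeric(pn); camat[r, ] <- as.numeric(pca)
    cmat[r, ] <- as.numeric(pc)
    pcb <- pick("CB")
    if (!is.null(pcb)) cbmat[r, ] <- as.numeric(pcb)
    keep[r] <- TRUE
  }
  if (length(dropped))
    warning(sprintf("%s: dropped %d residue(s): %s", id, length(dropped),
                    paste(dropped, collapse = ", ")), call. = FALSE)
  if (!any(keep)) stop("no residues with complete main chains")

  aa <- aa[keep]; resno <- resno[keep]
  nmat <- nmat[keep, , drop = FALSE]; camat <- camat[keep, , drop = FALSE]
  cmat <- cmat[keep, , drop = FALSE]; cbmat <- cbmat[keep, , drop = FALSE]
  # chain break after residue k when author numbering is not consecutive
  # (covers both gaps in the file and residues dropped above)
  breaks <- if (length(aa) > 1L) diff(resno) != 1L else logical(0)
  s <- new_mainchain(id, aa, nmat, camat, cmat, cb = cbmat, resno = resno,
                     breaks = breaks)
  validate_mainchain(s)
}

#' Read a main-chain structure from a PDB file
#' @param path Path to a PDB-format file.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @param chain Optional chain identifier.
#' @return A `mainchain` structure with `source_path` set.
#' @export
read_mainchain <- function(path, id = NULL, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  s <- parse_mainchain(readLines(path, warn = FALSE), id = id, chain = chain)
  s$source_path <- path
  s
}

#' Write a main-chain structure as PDB ATOM records
#'
#' @param s A `mainchain` structure.
#' @param path Output path; if `NULL` the text is returned invisibly instead.
#' @return The PDB text, invisibly.
#' @export
write_mainchain <- function(s, path = NULL) {
  validate_mainchain(s)
  aa3 <- names(AA3)[match(s$aa, AA3)]
  serial <- 0L
  out <- character(0)
  fmt <- "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  for (i in seq_len(n_residues(s))) {
    atoms <- list(N = s$n[i, ], CA = s$ca[i, ], C = s$c[i, ])
    if (!is.null(s$cb) && all(is.finite(s$cb[i, ]))) atoms$CB <- s$cb[i, ]
    for (an in names(atoms)) {
      serial <- serial + 1L
      el <- substr(an, 1L, 1L)
      out <- c(out, sprintf(fmt, serial, paste0(" ", an), aa3[i],
                            s$resno[i], atoms[[an]][1L], atoms[[an]][2L],
                            atoms[[an]][3L], el))
    }
  }
  out <- c(out, "TER", "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(out, path)
  invisible(txt)
}

#' Assemble a decoy set from parsed structures
#'
#' @param native The native `mainchain` structure.
#' @param decoys A list of `mainchain` structures; members whose sequence or
#'   length differs from the native are rejected with a warning.
#' @param name Set name.
#' @return A `decoy_set`: native, accepted decoys, cached C-alpha RMSD labels
#'   (`rmsd`, named by structure id, native included at 0), and a
#'   `rejected` character vector naming refused members.
#' @export
decoy_set <- function(native, decoys, name = native$id) {
  validate_mainchain(native)
  ok <- vapply(decoys, function(d)
    n_residues(d) == n_residues(native) && identical(d$aa, native$aa),
    logical(1L))
  rejected <- vapply(decoys[!ok], `[[`, character(1L), "id")
  if (length(rejected))
    warning(sprintf("decoy set %s: rejected %d structure(s) with mismatched sequence: %s",
                    name, length(rejected), paste(rejected, collapse = ", ")),
            call. = FALSE)
  decoys <- decoys[ok]
  if (!length(decoys)) stop("no accepted decoys in set")
  ids <- vapply(decoys, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate decoy ids in set")
  names(decoys) <- ids
  rmsd <- c(0, vapply(decoys, function(d) ca_rmsd(native, d), numeric(1L)))
  names(rmsd) <- c(native$id, ids)
  structure(list(name = name, native = native, decoys = decoys,
                 rmsd = rmsd, rejected = rejected),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("<decoy_set> %s: native %s (%d res), %d decoys, RMSD %.2f-%.2f A\n",
              x$name, x$native$id, n_residues(x$native), length(x$decoys),
              min(x$rmsd[-1L]), max(x$rmsd[-1L])))
  invisible(x)
}

#' Load a decoy set from disk
#'
#' Expects one directory per set holding the decoy PDB files, with the native
#' given separately (conventionally `native.pdb` in the same directory).
#' Decoys failing to parse or mismatching the native sequence are skipped
#' with a warning and reported in the returned set's `rejected` field.
#'
#' @param native_path Path to the native PDB file (fatal if unreadable).
#' @param decoy_dir Directory of decoy PDB files (the native file itself is
#'   excluded if it lives there).
#' @param name Set name; defaults to the directory name.
#' @return A `decoy_set` with C-alpha RMSD labels computed against the
#'   native.
#' @export
load_decoy_set <- function(native_path, decoy_dir, name = basename(decoy_dir)) {
  native <- read_mainchain(native_path)
  files <- list.files(decoy_dir, pattern = "\\.pdb$", full.names = TRUE)
  files <- files[normalizePath(files) != normalizePath(native_path)]
  if (!length(files)) stop("no decoy files found")
  decoys <- list(); failed <- character(0)
  for (f in files) {
    d <- tryCatch(read_mainchain(f), error = function(e) NULL)
    if (is.null(d)) failed <- c(failed, basename(f)) else decoys[[length(decoys) + 1L]] <- d
  }
  if (length(failed))
    warning(sprintf("unparsable decoy file(s): %s", paste(failed, collapse = ", ")),
            call. = FALSE)
  ds <- decoy_set(native, decoys, name = name)
  ds$rejected <- c(ds$rejected, failed)
  ds
}
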