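#' @include AllGenerics.R
NULL

#' Van der Waals radii used for SASA (Angstrom)
#'
#' NACCESS-like element radii: C 1.70, N 1.55, O 1.52, S 1.80. Deposited
#' models at ~2-3 A resolution carry no hydrogens, so only heavy elements
#' are listed; other elements need an explicit \code{fallbackRadius}.
#'
#' @format Named numeric vector (element -> radius in Angstrom).
#' @export
defaultRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses the file with bio3d (\code{read.pdb} / \code{read.cif}) and
#' flattens it to a \linkS4class{Structure} atom table with author chain ids
#' and residue numbers. Waters and other hetero records are excluded by
#' default; of alternate locations only the highest-occupancy atom is kept
#' (first on ties).
#'
#' @param path File path; format is taken from the extension
#'   (\code{.pdb}/\code{.ent} vs \code{.cif}) unless given.
#' @param format \code{"auto"}, \code{"pdb"} or \code{"cif"}.
#' @param includeHetero Keep non-water HETATM records (default \code{FALSE}).
#' @return A \linkS4class{Structure}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          includeHetero = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  keep <- a$type == "ATOM"
  if (includeHetero)
    keep <- keep | (a$type == "HETATM" & !(a$resid %in% c("HOH", "WAT", "DOD")))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms retained from ", path)
  occ <- a$o
  occ[is.na(occ)] <- 1
  # alternate locations: keep the highest-occupancy copy of each atom
  key <- paste(a$chain, a$resno, a$elety, sep = "\r")
  ord <- order(key, -occ)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a <- a[order(match(a$chain, unique(a$chain)), a$resno), , drop = FALSE]
  element <- a$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(a))
  miss <- is.na(element) | !nzchar(trimws(element))
  element[miss] <- .elementFromName(a$elety[miss])
  Structure(data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                       elety = trimws(a$elety), element = toupper(trimws(element)),
                       x = a$x, y = a$y, z = a$z,
                       occ = ifelse(is.na(a$o), 1, a$o),
                       stringsAsFactors = FALSE))
}

.elementFromName <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", trimws(elety))
  toupper(substr(nm, 1L, 1L))
}

#' Select atoms by chain and residue range
#'
#' Selection strings follow \code{chain[:resStart-resEnd]}: \code{"A"} is all
#' of chain A, \code{"A:1-90"} restricts to residues 1-90. A character
#' vector combines selections (union).
#'
#' @param x A \linkS4class{Structure}.
#' @param selection Character vector of selection strings.
#' @return Integer row indices into \code{atoms(x)}.
#' @examples
#' s <- toyStructure("mini_interface")
#' length(selectAtoms(s, "A"))
#' @export
selectAtoms <- function(x, selection) {
  stopifnot(is(x, "Structure"), is.character(selection), length(selection) >= 1L)
  a <- atoms(x)
  idx <- integer()
  for (sel in selection) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    ch <- parts[1]
    take <- a$chain == ch
    if (length(parts) == 2L) {
      rng <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
      if (length(rng) != 2L || any(is.na(rng)))
        stop("malformed residue range in selection '", sel, "'")
      take <- take & a$resno >= rng[1] & a$resno <= rng[2]
    } else if (length(parts) > 2L) {
      stop("malformed selection '", sel, "'")
    }
    idx <- union(idx, which(take))
  }
  sort(idx)
}

#' Extract a sub-structure
#'
#' @param x A \linkS4class{Structure}.
#' @param selection As in \code{\link{selectAtoms}}, or integer row indices.
#' @return A \linkS4class{Structure} containing only the selected atoms.
#' @export
subsetStructure <- function(x, selection) {
  idx <- if (is.character(selection)) selectAtoms(x, selection) else selection
  if (length(idx) == 0) stop("selection matches no atoms")
  Structure(atoms(x)[idx, , drop = FALSE])
}

#' Write a Structure as a minimal PDB file
#'
#' Emits plain ATOM records (serial, atom name, residue, chain, residue
#' number, coordinates, occupancy, element); sufficient for interchange with
#' other analysis tools and for the toy fixtures.
#'
#' @param x A \linkS4class{Structure}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeStructurePdb <- function(x, path) {
  stopifnot(is(x, "Structure"))
  a <- atoms(x)
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
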