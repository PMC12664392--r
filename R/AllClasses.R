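#' @import methods
NULL

#' The twenty canonical amino acids, one-letter code, alphabetical
#'
#' Residue alphabet used throughout: positional-scan matrices have one column
#' per canonical residue, motif classes are subsets of this set, and proteome
#' scanning treats any other letter (X, B, Z, U, *) as a non-match.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' ActivationMatrix: positional-scanning T cell activation data
#'
#' Holds percent-activation readouts (e.g. % IFN-gamma positive CD8+ T cells)
#' for every single-residue variant of a reference peptide, one layer per
#' replicate. Cells are addressed by (position, residue, replicate); a cell
#' that was not measured is \code{NA}. The wild-type cell at each position
#' must be present in every replicate, because it is the normalization anchor.
#'
#' @slot wildType Reference peptide sequence (uppercase, canonical residues).
#' @slot values Numeric array \code{L x 20 x nrep} with dimnames
#'   \code{position} (\code{"1"..."L"}), \code{residue} (the 20 canonical
#'   letters), \code{replicate}.
#' @slot normalized Logical; \code{TRUE} once values are scaled so the
#'   wild-type cell at each position equals 100 exactly.
#'
#' @export
setClass("ActivationMatrix",
  representation(wildType = "character",
                 values = "array",
                 normalized = "logical"))

setValidity("ActivationMatrix", function(object) {
  wt <- object@wildType
  v <- object@values
  msg <- character()
  if (length(wt) != 1L || nchar(wt) < 1L)
    msg <- c(msg, "wildType must be a single non-empty string")
  wtres <- strsplit(wt, "")[[1]]
  if (!all(wtres %in% AA_ALPHABET20))
    msg <- c(msg, "wildType contains non-canonical residues")
  if (length(dim(v)) != 3L)
    msg <- c(msg, "values must be a 3-d array (position x residue x replicate)")
  else {
    if (dim(v)[1] != nchar(wt))
      msg <- c(msg, "first dimension of values must equal nchar(wildType)")
    if (!identical(dimnames(v)[[2]], AA_ALPHABET20))
      msg <- c(msg, "residue dimnames must be the 20 canonical letters (alphabetical)")
    fin <- v[!is.na(v)]
    if (any(!is.finite(fin)))
      msg <- c(msg, "all measured values must be finite")
    if (any(fin < 0))
      msg <- c(msg, "percent activation cannot be negative")
    if (length(msg) == 0L) {
      wtcells <- vapply(seq_along(wtres), function(i) all(!is.na(v[i, wtres[i], ])),
                        logical(1))
      if (!all(wtcells))
        msg <- c(msg, sprintf("wild-type cell missing at position(s) %s",
                              paste(which(!wtcells), collapse = ", ")))
      if (isTRUE(object@normalized)) {
        anchors <- vapply(seq_along(wtres), function(i) all(v[i, wtres[i], ] == 100),
                          logical(1))
        if (!all(anchors))
          msg <- c(msg, "normalized matrix must have wild-type cells equal to 100")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ActivationMatrix
#'
#' @param wildType Reference peptide (uppercase one-letter string).
#' @param values Numeric array \code{L x 20 x nrep} (replicate dimension may
#'   be dropped for a single replicate; residue columns in the order of
#'   \code{AA_ALPHABET20}). Unmeasured cells are \code{NA}.
#' @param normalized Logical flag, default \code{FALSE} (raw data).
#'
#' @return An \linkS4class{ActivationMatrix}.
#' @examples
#' v <- matrix(NA_real_, 2, 20, dimnames = list(c("1", "2"), AA_ALPHABET20))
#' v["1", "S"] <- 80; v["2", "L"] <- 90; v["1", "A"] <- 10; v["2", "A"] <- 70
#' ActivationMatrix("SL", v)
#' @export
ActivationMatrix <- function(wildType, values, normalized = FALSE) {
  if (length(dim(values)) == 2L)
    values <- array(values, dim = c(dim(values), 1L),
                    dimnames = c(dimnames(values), list("1")))
  dn <- dimnames(values)
  if (is.null(dn)) dn <- vector("list", 3L)
  if (is.null(dn[[1]])) dn[[1]] <- as.character(seq_len(dim(values)[1]))
  if (is.null(dn[[2]])) dn[[2]] <- AA_ALPHABET20
  if (is.null(dn[[3]])) dn[[3]] <- as.character(seq_len(dim(values)[3]))
  names(dn) <- c("position", "residue", "replicate")
  dimnames(values) <- dn
  new("ActivationMatrix", wildType = toupper(wildType), values = values,
      normalized = normalized)
}

#' ToleranceProfile: per-position sets of tolerated residues
#'
#' The product of thresholding a normalized \linkS4class{ActivationMatrix}:
#' for each peptide position the set of residues whose normalized activation
#' exceeds the threshold. The wild-type residue is always a member (its
#' normalized value is 100 by construction).
#'
#' @slot wildType Reference peptide sequence.
#' @slot allowed List (one element per position) of character vectors of
#'   tolerated residues, each sorted alphabetically.
#' @slot threshold Percent activation cutoff (strict inequality), default 30.
#'
#' @export
setClass("ToleranceProfile",
  representation(wildType = "character", allowed = "list",
                 threshold = "numeric"))

setValidity("ToleranceProfile", function(object) {
  wt <- strsplit(object@wildType, "")[[1]]
  msg <- character()
  if (length(object@allowed) != length(wt))
    msg <- c(msg, "one allowed set per peptide position required")
  else {
    ok <- vapply(object@allowed, function(s)
      length(s) > 0L && all(s %in% AA_ALPHABET20), logical(1))
    if (!all(ok))
      msg <- c(msg, "every allowed set must be a non-empty subset of the canonical residues")
    inwt <- vapply(seq_along(wt), function(i) wt[i] %in% object@allowed[[i]],
                   logical(1))
    if (length(msg) == 0L && !all(inwt))
      msg <- c(msg, sprintf("wild-type residue excluded at position(s) %s",
                            paste(which(!inwt), collapse = ", ")))
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a ToleranceProfile
#'
#' @param wildType Reference peptide sequence.
#' @param allowed List of character vectors, one per position.
#' @param threshold Percent threshold the sets were called at (default 30).
#' @return A \linkS4class{ToleranceProfile}.
#' @export
ToleranceProfile <- function(wildType, allowed, threshold = 30) {
  allowed <- lapply(allowed, function(s) sort(unique(toupper(s))))
  new("ToleranceProfile", wildType = toupper(wildType), allowed = allowed,
      threshold = threshold)
}

#' PeptideMotif: a PROSITE-style pattern of residue classes
#'
#' An ordered list of residue classes, one per peptide position; textual form
#' is the PROSITE convention \code{[ACILMQV]} for multi-residue classes, a
#' bare letter for singletons, elements joined by \code{-}.
#'
#' @slot id Motif label, e.g. \code{"NY_1"}.
#' @slot classes List of character vectors (sorted, unique, canonical).
#'
#' @export
setClass("PeptideMotif",
  representation(id = "character", classes = "list"))

setValidity("PeptideMotif", function(object) {
  if (length(object@classes) < 1L)
    return("motif must have at least one position class")
  ok <- vapply(object@classes, function(s)
    length(s) > 0L && all(s %in% AA_ALPHABET20) && !is.unsorted(s) &&
      !anyDuplicated(s), logical(1))
  if (!all(ok))
    return("every class must be a sorted, duplicate-free, non-empty subset of the canonical residues")
  TRUE
})

#' Construct a PeptideMotif
#'
#' @param classes List of character vectors (or a single multi-letter string
#'   per class); duplicates collapse, order is normalised to alphabetical.
#' @param id Motif label (default \code{"motif"}).
#' @return A \linkS4class{PeptideMotif}.
#' @export
PeptideMotif <- function(classes, id = "motif") {
  classes <- lapply(classes, function(s) {
    if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "")[[1]]
    sort(unique(toupper(s)))
  })
  new("PeptideMotif", id = id, classes = classes)
}

#' AlanineScanResult: per-position alanine-substitution sensitivity
#'
#' Normalized activation of each alanine (or joint double-anchor) variant and
#' the derived sensitivity call: a position is sensitive when substituting it
#' drops activation to at most the threshold.
#'
#' @slot position Character labels; single positions are \code{"3"}, the
#'   jointly mutated anchor pair is e.g. \code{"2+9"}.
#' @slot value Normalized percent activation of each variant.
#' @slot sensitive Logical flags (\code{value <= threshold}).
#' @slot threshold Percent cutoff used.
#'
#' @export
setClass("AlanineScanResult",
  representation(position = "character", value = "numeric",
                 sensitive = "logical", threshold = "numeric"))

setValidity("AlanineScanResult", function(object) {
  n <- length(object@position)
  if (length(object@value) != n || length(object@sensitive) != n)
    return("position, value and sensitive must be parallel vectors")
  if (!identical(object@sensitive, unname(object@value <= object@threshold)))
    return("sensitivity flags must equal value <= threshold")
  TRUE
})

#' DoseResponseFit: three-parameter log(agonist) vs response model
#'
#' Least-squares fit of \code{response = bottom + (top - bottom) /
#' (1 + 10^(log10(EC50) - log10(dose)))}, the unit-Hill-slope three-parameter
#' logistic. Fitted parameters, fitted values and residuals are stored.
#'
#' @slot bottom Lower plateau (response units).
#' @slot top Upper plateau (response units).
#' @slot ec50 Half-maximal effective concentration (same units as the doses,
#'   typically molar).
#' @slot data The (dose, response) table that was fitted.
#' @slot fitted Fitted responses.
#' @slot residuals Observed minus fitted.
#'
#' @export
setClass("DoseResponseFit",
  representation(bottom = "numeric", top = "numeric", ec50 = "numeric",
                 data = "data.frame", fitted = "numeric",
                 residuals = "numeric"))

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (object@top < object@bottom) msg <- c(msg, "top must be >= bottom")
  if (!(object@ec50 > 0)) msg <- c(msg, "ec50 must be positive")
  if (length(msg)) msg else TRUE
})

#' Structure: atomic model as a flat atom table
#'
#' A light-weight container for a macromolecular model: one row per atom with
#' author chain id, author residue number, residue name, atom name, element,
#' occupancy and orthogonal coordinates in Angstrom. Built by
#' \code{\link{readStructure}} (PDB/mmCIF via bio3d) or by the toy-structure
#' simulator.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety} (atom name), \code{element}, \code{x},
#'   \code{y}, \code{z}, \code{occ}.
#'
#' @export
setClass("Structure", representation(atoms = "data.frame"))

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z", "occ")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0 && !all(is.finite(c(a$x, a$y, a$z))))
    return("all coordinates must be finite")
  TRUE
})

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{element}, \code{x}, \code{y},
#'   \code{z} and optionally \code{occ} (defaults to 1).
#' @return A \linkS4class{Structure}.
#' @export
Structure <- function(atoms) {
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element))
    atoms$element <- substr(trimws(atoms$elety), 1L, 1L)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms)
}

#' InterfaceReport: buried-area and contact summary for a two-group partition
#'
#' @slot area Total interface area in Angstrom^2, defined as half the solvent
#'   accessible surface area lost upon complexation (the PISA convention).
#' @slot perResidue data.frame (\code{side}, \code{chain}, \code{resno},
#'   \code{resid}, \code{buried}) of per-residue buried areas, both sides.
#' @slot contacts data.frame of typed atomic contacts across the interface.
#' @slot backboneFraction Named numeric (sides \code{A}, \code{B}): share of
#'   each side's buried area contributed by backbone atoms N, CA, C, O.
#' @slot config List of the SASA parameters used.
#'
#' @export
setClass("InterfaceReport",
  representation(area = "numeric", perResidue = "data.frame",
                 contacts = "data.frame", backboneFraction = "numeric",
                 config = "list"))

setValidity("InterfaceReport", function(object) {
  if (nrow(object@perResidue) > 0 && any(object@perResidue$buried < 0))
    return("per-residue buried areas must be non-negative")
  TRUE
})
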