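#' @include sasa.R
NULL

# hydrogen-bond donor / acceptor heavy atoms (N/O only; deposited models at
# this resolution carry no hydrogens, so typing is per-residue by atom name)
.hbDonorAtoms <- list(
  backbone = "N",                # all residues except proline
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  TRP = "NE1")

.hbAcceptorAtoms <- list(
  backbone = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"))

# apolar carbons: carbon atoms bonded only to carbon or hydrogen in the
# standard amino-acid topologies (carbons attached to N, O or S are polar)
.apolarCarbons <- list(
  ALA = "CB",
  ARG = c("CB", "CG"),
  ASN = "CB",
  ASP = "CB",
  CYS = character(),
  GLN = c("CB", "CG"),
  GLU = c("CB", "CG"),
  GLY = character(),
  HIS = "CB",
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD"),
  MET = "CB",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"),
  SER = character(),
  THR = "CG2",
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2"))

.isDonor <- function(resid, elety) {
  (elety == "N" & resid != "PRO") |
    mapply(function(r, e) e %in% (.hbDonorAtoms[[r]] %||% character()),
           resid, elety, USE.NAMES = FALSE)
}

.isAcceptor <- function(resid, elety) {
  (elety %in% .hbAcceptorAtoms$backbone) |
    mapply(function(r, e) e %in% (.hbAcceptorAtoms[[r]] %||% character()),
           resid, elety, USE.NAMES = FALSE)
}

.isApolarCarbon <- function(resid, elety, element) {
  element == "C" &
    mapply(function(r, e) e %in% (.apolarCarbons[[r]] %||% character()),
           resid, elety, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect typed atomic contacts across a two-group partition
#'
#' Two contact classes are reported. Hydrogen bonds: donor/acceptor-typed
#' nitrogen or oxygen atoms on opposite sides at heavy-atom distance at most
#' \code{hbondCutoff} (angles are not evaluated; the models carry no
#' hydrogens). Hydrophobic contacts: apolar carbon atoms (carbons bonded
#' only to C/H in the standard residue topologies) on opposite sides within
#' \code{hydrophobicCutoff}. Each qualifying atom pair is reported once with
#' its distance.
#'
#' @param x A \linkS4class{Structure}.
#' @param groupA,groupB Disjoint selections (see \code{\link{selectAtoms}}),
#'   as selection strings or integer atom indices.
#' @param hbondCutoff Heavy-atom hydrogen-bond cutoff, Angstrom (default 3.5).
#' @param hydrophobicCutoff Apolar carbon-carbon cutoff, Angstrom
#'   (default 4.5).
#' @return data.frame with one row per contact: chain/residue/atom for both
#'   partners, \code{distance}, and \code{type} (\code{"hydrogen_bond"} or
#'   \code{"hydrophobic"}).
#' @export
detectContacts <- function(x, groupA, groupB, hbondCutoff = 3.5,
                           hydrophobicCutoff = 4.5) {
  part <- .resolvePartition(x, groupA, groupB)
  a <- atoms(x)
  A <- a[part$A, , drop = FALSE]
  B <- a[part$B, , drop = FALSE]
  dAB <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2 +
                outer(A$z, B$z, "-")^2)
  rows <- list()
  addPairs <- function(ij, type) {
    if (nrow(ij) == 0) return()
    i <- ij[, 1]; j <- ij[, 2]
    rows[[length(rows) + 1L]] <<- data.frame(
      chainA = A$chain[i], resnoA = A$resno[i], residA = A$resid[i],
      atomA = A$elety[i],
      chainB = B$chain[j], resnoB = B$resno[j], residB = B$resid[j],
      atomB = B$elety[j],
      distance = dAB[ij], type = type, stringsAsFactors = FALSE)
  }
  donA <- .isDonor(A$resid, A$elety); accA <- .isAcceptor(A$resid, A$elety)
  donB <- .isDonor(B$resid, B$elety); accB <- .isAcceptor(B$resid, B$elety)
  close_hb <- dAB <= hbondCutoff
  hb <- (outer(donA, accB, "&") | outer(accA, donB, "&")) & close_hb
  addPairs(which(hb, arr.ind = TRUE), "hydrogen_bond")
  apA <- .isApolarCarbon(A$resid, A$elety, A$element)
  apB <- .isApolarCarbon(B$resid, B$elety, B$element)
  hp <- outer(apA, apB, "&") & (dAB <= hydrophobicCutoff)
  addPairs(which(hp, arr.ind = TRUE), "hydrophobic")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chainA = character(), resnoA = integer(), residA = character(),
               atomA = character(), chainB = character(), resnoB = integer(),
               residB = character(), atomB = character(),
               distance = numeric(), type = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$type, out$resnoA, out$resnoB, out$distance), ]
  rownames(out) <- NULL
  out
}

.resolvePartition <- function(x, groupA, groupB) {
  idxA <- if (is.character(groupA)) selectAtoms(x, groupA) else as.integer(groupA)
  idxB <- if (is.character(groupB)) selectAtoms(x, groupB) else as.integer(groupB)
  if (length(idxA) == 0 || length(idxB) == 0)
    stop("both sides of the partition must select at least one atom")
  if (length(intersect(idxA, idxB)) > 0)
    stop("partition sides overlap; selections must be disjoint")
  list(A = idxA, B = idxB)
}

#' Buried interface area and per-residue footprint between two groups
#'
#' The interface area follows the PISA convention: half the total solvent
#' accessible surface area lost when the two groups associate,
#' \code{0.5 * (SASA(A) + SASA(B) - SASA(A+B))}, with each side's SASA
#' computed on the isolated group at unchanged coordinates. Per-residue
#' buried areas are the residue's SASA alone minus in the complex, clipped
#' at zero (quadrature noise can produce tiny negatives). The backbone
#' fraction of each side is the share of its buried area contributed by
#' atoms N, CA, C, O. Contacts are typed by \code{\link{detectContacts}}.
#'
#' @param x A \linkS4class{Structure} of the complex.
#' @param groupA,groupB Disjoint selections, e.g. the binder vs the HLA
#'   heavy chain + beta-2 microglobulin + peptide.
#' @param probe,nPoints,radii,fallbackRadius SASA parameters, see
#'   \code{\link{sasa}}.
#' @param hbondCutoff,hydrophobicCutoff Contact cutoffs, see
#'   \code{\link{detectContacts}}.
#' @return An \linkS4class{InterfaceReport}.
#' @examples
#' s <- toyStructure("mini_interface")
#' analyzeInterface(s, "A", "B")
#' @export
analyzeInterface <- function(x, groupA, groupB, probe = 1.4, nPoints = 960,
                             radii = defaultRadii, fallbackRadius = NULL,
                             hbondCutoff = 3.5, hydrophobicCutoff = 4.5) {
  part <- .resolvePartition(x, groupA, groupB)
  a <- atoms(x)
  both <- c(part$A, part$B)
  complexS <- Structure(a[both, , drop = FALSE])
  sideLen <- c(length(part$A), length(part$B))
  subA <- Structure(a[part$A, , drop = FALSE])
  subB <- Structure(a[part$B, , drop = FALSE])
  sasaA <- sasa(subA, probe, nPoints, radii, fallbackRadius)
  sasaB <- sasa(subB, probe, nPoints, radii, fallbackRadius)
  sasaC <- sasa(complexS, probe, nPoints, radii, fallbackRadius)
  alone <- c(sasaA, sasaB)
  dAtom <- alone - sasaC          # per-atom SASA lost upon complexation
  area <- 0.5 * (sum(alone) - sum(sasaC))
  ca <- atoms(complexS)
  side <- rep(c("A", "B"), sideLen)
  key <- paste(side, ca$chain, ca$resno, sep = "\r")
  first <- !duplicated(key)
  perResAtomSums <- tapply(dAtom, key, sum)
  perRes <- data.frame(side = side[first], chain = ca$chain[first],
                       resno = ca$resno[first], resid = ca$resid[first],
                       buried = pmax(0, unname(perResAtomSums[key[first]])),
                       stringsAsFactors = FALSE)
  perRes <- perRes[order(perRes$side, perRes$chain, perRes$resno), ]
  rownames(perRes) <- NULL
  dPos <- pmax(0, dAtom)
  bb <- ca$elety %in% BACKBONE_ATOMS
  bf <- vapply(c("A", "B"), function(s) {
    tot <- sum(dPos[side == s])
    if (tot == 0) return(0)
    sum(dPos[side == s & bb]) / tot
  }, numeric(1))
  contacts <- detectContacts(x, part$A, part$B, hbondCutoff, hydrophobicCutoff)
  new("InterfaceReport", area = area, perResidue = perRes,
      contacts = contacts, backboneFraction = bf,
      config = list(probe = probe, nPoints = nPoints, radii = radii,
                    hbondCutoff = hbondCutoff,
                    hydrophobicCutoff = hydrophobicCutoff))
}

#' Backbone fraction of the buried area, per side
#'
#' @param report An \linkS4class{InterfaceReport}.
#' @return Named numeric (\code{A}, \code{B}): share of each side's buried
#'   area contributed by backbone atoms (N, CA, C, O); 0 when the side
#'   buries nothing.
#' @export
backboneFraction <- function(report) {
  stopifnot(is(report, "InterfaceReport"))
  report@backboneFraction
}

#' Residues on one side contacting the other side
#'
#' Convenience accessor over \code{\link{detectContacts}} output: the set of
#' residues of side A involved in any typed contact, formatted like
#' \code{"K89"} (one-letter residue code + author residue number).
#'
#' @param contacts Contact table from \code{\link{detectContacts}} or the
#'   \code{contacts} slot of an \linkS4class{InterfaceReport}.
#' @param side \code{"A"} or \code{"B"}.
#' @return Character vector of unique residue labels, sorted by number.
#' @export
contactResidues <- function(contacts, side = c("A", "B")) {
  side <- match.arg(side)
  if (is(contacts, "InterfaceReport")) contacts <- contacts@contacts
  if (nrow(contacts) == 0) return(character())
  res <- contacts[[paste0("resid", side)]]
  num <- contacts[[paste0("resno", side)]]
  three2one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                 GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                 LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                 SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  one <- three2one[res]
  one[is.na(one)] <- "X"
  lab <- paste0(one, num)
  lab[!duplicated(num)][order(unique(num))]
}
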