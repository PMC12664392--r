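#' @include AllGenerics.R
NULL

#' Parse a PROSITE-style peptide motif
#'
#' Accepts the dash-separated textual convention used by ScanProSite:
#' each element is either a bracketed residue class (\code{[ACILMQV]}) or a
#' single bare residue (\code{W}). Duplicate letters inside a class collapse;
#' class order is normalised to alphabetical.
#'
#' @param text Motif string.
#' @param id Label to attach (default \code{"motif"}).
#' @return A \linkS4class{PeptideMotif}.
#' @examples
#' parseMotif("[FILMT]-W-[QT]", id = "mini")
#' @export
parseMotif <- function(text, id = "motif") {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty motif string")
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  classes <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    el <- parts[i]
    if (grepl("^\\[[A-Za-z]+\\]$", el)) {
      letters_ <- strsplit(substr(el, 2L, nchar(el) - 1L), "")[[1]]
    } else if (grepl("^[A-Za-z]$", el)) {
      letters_ <- el
    } else {
      stop(sprintf("malformed motif element %d ('%s'): expected [CLASS] or a bare residue",
                   i, el))
    }
    letters_ <- toupper(letters_)
    bad <- setdiff(letters_, AA_ALPHABET20)
    if (length(bad) > 0)
      stop(sprintf("illegal residue letter '%s' in motif element %d",
                   bad[1], i))
    classes[[i]] <- letters_
  }
  PeptideMotif(classes, id = id)
}

#' Serialize a peptide motif to its PROSITE-style text
#'
#' Classes with two or more members are emitted as alphabetically sorted
#' bracketed lists, singleton classes as the bare letter, elements joined by
#' \code{-}. Emission is deterministic, and \code{parseMotif(emitMotif(m))}
#' reproduces \code{m}.
#'
#' @param motif A \linkS4class{PeptideMotif}.
#' @return The motif string.
#' @examples
#' emitMotif(PeptideMotif(list("S", "L", c("T", "Q"))))
#' @export
emitMotif <- function(motif) {
  stopifnot(is(motif, "PeptideMotif"))
  paste(vapply(motif@classes, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "-")
}

#' Convert a tolerance profile to a peptide motif
#'
#' @param x A \linkS4class{ToleranceProfile}.
#' @param id Motif label (defaults to the wild-type peptide).
#' @return A \linkS4class{PeptideMotif} whose classes are the tolerated sets.
#' @export
asMotif <- function(x, id = wildType(x)) {
  stopifnot(is(x, "ToleranceProfile"))
  PeptideMotif(allowedResidues(x), id = id)
}

#' Test a peptide against a motif
#'
#' @param peptide Peptide string, same length as the motif. Non-canonical
#'   letters (X, B, Z, U, *) never match any class.
#' @param motif A \linkS4class{PeptideMotif}.
#' @return \code{TRUE} iff every residue is a member of its position class.
#' @examples
#' m <- parseMotif("[FILMT]-W-[QT]")
#' matchPeptide("MWQ", m)
#' matchPeptide("MWP", m)
#' @export
matchPeptide <- function(peptide, motif) {
  stopifnot(is(motif, "PeptideMotif"))
  res <- strsplit(toupper(peptide), "")[[1]]
  if (length(res) != length(motif@classes))
    stop(sprintf("peptide length %d does not match motif length %d",
                 length(res), length(motif@classes)))
  all(vapply(seq_along(res), function(i)
    res[i] %in% motif@classes[[i]], logical(1)))
}

.motifRegex <- function(motif) {
  body <- paste(vapply(motif@classes, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
  paste0("(?=(", body, "))")   # lookahead so overlapping windows all report
}

#' Scan one sequence for all windows matching a motif
#'
#' Every window of motif length is tested; overlapping matches are all
#' reported. Offsets are 1-based inclusive (the ScanProSite convention).
#'
#' @param sequence Amino-acid sequence (string); non-canonical letters fail
#'   every class.
#' @param motif A \linkS4class{PeptideMotif}.
#' @return data.frame with columns \code{offset} (integer) and
#'   \code{peptide}; zero rows when nothing matches or the sequence is
#'   shorter than the motif.
#' @examples
#' ny1 <- parseMotif(
#'   "[ACFGHILMNQRSTVWY]-[ACILMQV]-[ACDFGHILMNPQSTVW]-[FILMT]-W-[FILMV]-[CFILMQRSTVY]-[QT]-[ACITV]",
#'   id = "NY_1")
#' scanSequence("AASLLMWITQVAA", ny1)
#' @export
scanSequence <- function(sequence, motif) {
  stopifnot(is(motif, "PeptideMotif"))
  sequence <- toupper(as.character(sequence))
  L <- length(motif@classes)
  empty <- data.frame(offset = integer(), peptide = character(),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) < L) return(empty)
  m <- gregexpr(.motifRegex(motif), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  off <- as.integer(m)
  data.frame(offset = off,
             peptide = substring(sequence, off, off + L - 1L),
             stringsAsFactors = FALSE)
}

#' Scan a proteome for motif matches and summarise candidate peptides
#'
#' Runs \code{\link{scanSequence}} for every motif over every record and
#' returns both the raw hit list and a deduplicated unique-peptide summary
#' (deduplication key is the peptide string, per motif): a peptide present in
#' several proteins is one candidate with its occurrence count and the list
#' of source proteins. Excluded peptides (typically the index epitope
#' itself, a self peptide by definition) are removed from the summary but
#' retained in the raw hit list.
#'
#' @param records Proteome: a \code{Biostrings::AAStringSet}, or a named
#'   character vector of sequences. Record id is the first whitespace token
#'   of the name (UniProt-style headers tolerated).
#' @param motifs A \linkS4class{PeptideMotif} or list of them.
#' @param exclude Character vector of peptides to drop from the candidate
#'   summary (default none).
#' @return List with elements \code{hits} (data.frame \code{motif_id},
#'   \code{protein_id}, \code{offset}, \code{peptide}), \code{summary}
#'   (data.frame \code{motif_id}, \code{peptide}, \code{n_occurrences},
#'   \code{n_proteins}, \code{proteins}), and \code{n_skipped} (records with
#'   empty id or sequence, skipped with a warning).
#' @export
scanProteome <- function(records, motifs, exclude = character()) {
  if (is(motifs, "PeptideMotif")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L,
            all(vapply(motifs, is, logical(1), "PeptideMotif")))
  ids <- names(records)
  seqs <- unname(as.character(records))
  if (is.null(ids)) ids <- rep("", length(seqs))
  ids <- vapply(strsplit(ids, "\\s+"), function(t)
    if (length(t) >= 1L) t[1] else "", character(1))
  usable <- nzchar(ids) & nzchar(seqs)
  n_skipped <- sum(!usable)
  if (n_skipped > 0)
    warning(sprintf("skipped %d unreadable record(s) (empty id or sequence)",
                    n_skipped))
  seqs <- seqs[usable]
  ids <- ids[usable]
  out <- list()
  for (m in motifs) {
    per <- lapply(seq_along(seqs), function(j) {
      h <- scanSequence(seqs[j], m)
      if (nrow(h) == 0) return(NULL)
      data.frame(motif_id = motifId(m), protein_id = ids[j],
                 offset = h$offset, peptide = h$peptide,
                 stringsAsFactors = FALSE)
    })
    out[[motifId(m)]] <- do.call(rbind, per)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    hits <- data.frame(motif_id = character(), protein_id = character(),
                       offset = integer(), peptide = character(),
                       stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  keep <- !(hits$peptide %in% exclude)
  hk <- hits[keep, , drop = FALSE]
  if (nrow(hk) > 0) {
    key <- paste(hk$motif_id, hk$peptide, sep = "\r")
    agg <- split(seq_len(nrow(hk)), key)
    summary <- do.call(rbind, lapply(agg, function(idx) {
      data.frame(motif_id = hk$motif_id[idx[1]],
                 peptide = hk$peptide[idx[1]],
                 n_occurrences = length(idx),
                 n_proteins = length(unique(hk$protein_id[idx])),
                 proteins = paste(sort(unique(hk$protein_id[idx])),
                                  collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    summary <- summary[order(summary$motif_id, summary$peptide), ]
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(motif_id = character(), peptide = character(),
                          n_occurrences = integer(), n_proteins = integer(),
                          proteins = character(), stringsAsFactors = FALSE)
  }
  list(hits = hits, summary = summary, n_skipped = n_skipped)
}

#' High-level cross-reactivity candidate search
#'
#' Converts tolerance profiles to motifs and scans a proteome; by default the
#' wild-type (index) epitope is excluded from the candidate summary, since
#' candidates of interest are non-self peptides distinct from the target.
#'
#' @param profiles A \linkS4class{ToleranceProfile} or list of them.
#' @param records Proteome as in \code{\link{scanProteome}}.
#' @param excludeWildType Drop each profile's wild-type peptide from the
#'   summary (default \code{TRUE}).
#' @return As \code{\link{scanProteome}}.
#' @export
crossReactivityCandidates <- function(profiles, records, excludeWildType = TRUE) {
  if (is(profiles, "ToleranceProfile")) profiles <- list(profiles)
  motifs <- lapply(profiles, asMotif)
  exclude <- if (excludeWildType)
    unique(vapply(profiles, wildType, character(1))) else character()
  scanProteome(records, motifs, exclude = exclude)
}

#' Read a proteome FASTA file
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet}; record ids are the
#' first whitespace token of each header.
#'
#' @param path FASTA file.
#' @return An \code{AAStringSet}.
#' @export
readProteome <- function(path) {
  Biostrings::readAAStringSet(path)
}

#' Write motifs to / read motifs from JSON
#'
#' The JSON form is a named object: motif id -> PROSITE-style string.
#'
#' @param motifs A \linkS4class{PeptideMotif} or list of them.
#' @param path Output file.
#' @return \code{writeMotifJson}: the path, invisibly; \code{readMotifJson}:
#'   a named list of \linkS4class{PeptideMotif}.
#' @export
writeMotifJson <- function(motifs, path) {
  if (is(motifs, "PeptideMotif")) motifs <- list(motifs)
  obj <- stats::setNames(lapply(motifs, emitMotif),
                         vapply(motifs, motifId, character(1)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeMotifJson
#' @export
readMotifJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(lapply(names(obj), function(nm) parseMotif(obj[[nm]], id = nm)),
                  names(obj))
}
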