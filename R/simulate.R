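#' @include AllGenerics.R
NULL

.seedRNG <- function(seed) {
  if (!is.null(seed))
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
}

#' Approximate SwissProt residue background frequencies
#'
#' Amino-acid composition of the reviewed UniProt/SwissProt database
#' (percent, renormalised to sum to 1), for simulating proteome sequences
#' with a realistic background instead of the uniform default.
#'
#' @format Named numeric vector over the 20 canonical residues, summing to 1.
#' @export
uniprotResidueFreqs <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
})

#' Simulate positional-scanning activation matrices with known truth
#'
#' Emulates an X-scan experiment against a designed tolerance structure:
#' every cell whose residue is tolerated at its position (including the
#' wild-type cells) is drawn from Normal(activeMean, noiseSd), every other
#' cell from Normal(inactiveMean, noiseSd); draws are clipped at 0 to stay
#' on the percent-activation scale. The separation between the two levels
#' must exceed four noise standard deviations so the designed profile is
#' recoverable at the standard threshold with margin well beyond the noise.
#'
#' @param profile Target \linkS4class{ToleranceProfile} (the ground truth).
#' @param activeMean Mean percent activation of tolerated cells (default 80).
#' @param inactiveMean Mean of non-tolerated cells (default 5).
#' @param noiseSd Measurement noise standard deviation (default 5).
#' @param replicates Number of replicate layers (default 2).
#' @param seed Integer seed for reproducibility (Mersenne-Twister /
#'   inversion sampling); \code{NULL} uses the current RNG state.
#' @return List with \code{matrix} (raw \linkS4class{ActivationMatrix} with
#'   all replicate layers) and \code{profile} (the truth handed in).
#' @examples
#' prof <- ToleranceProfile("SLW", list(c("S", "T"), "L", c("W", "F")))
#' sim <- simXScan(prof, seed = 1)
#' sim$matrix
#' @export
simXScan <- function(profile, activeMean = 80, inactiveMean = 5, noiseSd = 5,
                     replicates = 2, seed = NULL) {
  stopifnot(is(profile, "ToleranceProfile"), replicates >= 1, noiseSd >= 0)
  if (!(activeMean - inactiveMean > 4 * noiseSd))
    stop("active and inactive levels must be separated by more than 4 noise SDs")
  .seedRNG(seed)
  wt <- strsplit(wildType(profile), "")[[1]]
  L <- length(wt)
  allowed <- allowedResidues(profile)
  v <- array(NA_real_, c(L, 20L, replicates),
             dimnames = list(as.character(seq_len(L)), AA_ALPHABET20,
                             paste0("rep", seq_len(replicates))))
  for (k in seq_len(replicates)) for (i in seq_len(L)) {
    mu <- ifelse(AA_ALPHABET20 %in% allowed[[i]], activeMean, inactiveMean)
    v[i, , k] <- pmax(0, stats::rnorm(20, mean = mu, sd = noiseSd))
  }
  list(matrix = ActivationMatrix(wildType(profile), v, normalized = FALSE),
       profile = profile)
}

#' Simulate a proteome FASTA with planted motif matches
#'
#' Random protein sequences at a chosen residue background, with given
#' peptides spliced in at recorded (or random non-overlapping) positions.
#' The returned manifest lists every planted occurrence, so scanner output
#' can be checked against guaranteed hits.
#'
#' @param nProteins Number of proteins (default 50).
#' @param proteinLength Length of each protein, recycled (default 300).
#' @param residueFreqs Named residue sampling weights over the canonical
#'   alphabet; default uniform. See \code{\link{uniprotResidueFreqs}}.
#' @param planted Either a character vector of peptides (each planted once
#'   at a random position) or a data.frame with columns \code{peptide},
#'   \code{protein} (1-based index) and \code{offset} (1-based start).
#'   Overlapping planted sites are an error (re-run with another seed or
#'   explicit offsets).
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return List with \code{records} (\code{AAStringSet}, ids
#'   \code{P0001}...) and \code{manifest} (data.frame \code{protein_id},
#'   \code{offset}, \code{peptide}).
#' @examples
#' sim <- simProteome(nProteins = 5, proteinLength = 60,
#'                    planted = "SLLMWITQV", seed = 7)
#' sim$manifest
#' @export
simProteome <- function(nProteins = 50, proteinLength = 300,
                        residueFreqs = NULL, planted = character(),
                        seed = NULL) {
  stopifnot(nProteins >= 1, all(proteinLength >= 1))
  .seedRNG(seed)
  if (is.null(residueFreqs))
    residueFreqs <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
  if (!all(names(residueFreqs) %in% AA_ALPHABET20))
    stop("residueFreqs must be named by canonical residues")
  lens <- rep_len(proteinLength, nProteins)
  ids <- sprintf("P%04d", seq_len(nProteins))
  seqs <- vapply(lens, function(L)
    paste(sample(names(residueFreqs), L, replace = TRUE,
                 prob = residueFreqs), collapse = ""), character(1))
  if (is.character(planted) && length(planted) > 0) {
    planted <- data.frame(
      peptide = planted,
      protein = sample.int(nProteins, length(planted), replace = TRUE),
      offset = NA_integer_, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(planted))) {
      L <- lens[planted$protein[r]]
      w <- nchar(planted$peptide[r])
      if (w > L) stop("planted peptide longer than its protein")
      planted$offset[r] <- sample.int(L - w + 1L, 1L)
    }
  }
  manifest <- data.frame(protein_id = character(), offset = integer(),
                         peptide = character(), stringsAsFactors = FALSE)
  if (is.data.frame(planted) && nrow(planted) > 0) {
    stopifnot(all(c("peptide", "protein", "offset") %in% names(planted)))
    occupied <- vector("list", nProteins)
    for (r in seq_len(nrow(planted))) {
      p <- planted$protein[r]
      w <- nchar(planted$peptide[r])
      span <- planted$offset[r]:(planted$offset[r] + w - 1L)
      if (planted$offset[r] < 1L || max(span) > lens[p])
        stop("planted peptide does not fit inside protein ", p)
      if (any(span %in% occupied[[p]]))
        stop("planted sites collide in protein ", p,
             "; choose explicit offsets or another seed")
      occupied[[p]] <- c(occupied[[p]], span)
      substr(seqs[p], planted$offset[r], max(span)) <-
        toupper(planted$peptide[r])
    }
    manifest <- data.frame(protein_id = ids[planted$protein],
                           offset = planted$offset,
                           peptide = toupper(planted$peptide),
                           stringsAsFactors = FALSE)
  }
  records <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  list(records = records, manifest = manifest)
}

#' Simulate three-parameter dose-response data
#'
#' Exact model responses at the given doses plus Gaussian noise; used for
#' parameter-recovery checks of the dose-response fitter.
#'
#' @param doses Agonist concentrations (> 0, non-empty).
#' @param bottom,top,ec50 True model parameters (defaults 0, 100, 1e-9).
#' @param noiseSd Gaussian noise SD in response units (default 0).
#' @param replicates Replicate measurements per dose (default 1).
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @return data.frame with \code{dose}, \code{response}, \code{replicate}.
#' @export
simDoseResponse <- function(doses, bottom = 0, top = 100, ec50 = 1e-9,
                            noiseSd = 0, replicates = 1, seed = NULL) {
  if (length(doses) == 0) stop("dose list must not be empty")
  stopifnot(all(doses > 0), replicates >= 1, noiseSd >= 0)
  .seedRNG(seed)
  d <- rep(doses, times = replicates)
  mu <- doseResponseModel(d, bottom, top, ec50)
  data.frame(dose = d,
             response = mu + stats::rnorm(length(d), 0, noiseSd),
             replicate = rep(seq_len(replicates), each = length(doses)))
}

#' Toy structures with analytically known surface properties
#'
#' Handcrafted coordinate sets for validating the structural module against
#' closed forms: \code{"single_atom"} is one carbon (SASA exactly
#' \code{4 pi (1.70 + probe)^2}); \code{"two_spheres"} is two carbons at a
#' set separation (SASA from the spherical-cap formula), one per chain;
#' \code{"mini_interface"} is two three-residue polyalanine strands whose
#' CB atoms face each other 4 Angstrom apart (hydrophobic contacts, no
#' hydrogen bonds).
#'
#' @param kind One of \code{"single_atom"}, \code{"two_spheres"},
#'   \code{"mini_interface"}.
#' @param separation Centre separation for \code{"two_spheres"}, Angstrom
#'   (default 4).
#' @return A \linkS4class{Structure}.
#' @examples
#' toyStructure("two_spheres", separation = 5)
#' @export
toyStructure <- function(kind = c("single_atom", "two_spheres",
                                  "mini_interface"), separation = 4) {
  kind <- match.arg(kind)
  mk <- function(chain, resno, elety, x, y, z, resid = "ALA") {
    data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
               element = substr(elety, 1, 1), x = x, y = y, z = z, occ = 1,
               stringsAsFactors = FALSE)
  }
  if (kind == "single_atom")
    return(Structure(mk("A", 1L, "CB", 0, 0, 0)))
  if (kind == "two_spheres")
    return(Structure(rbind(mk("A", 1L, "CB", 0, 0, 0),
                           mk("B", 1L, "CB", separation, 0, 0))))
  res <- function(chain, i, ymul) {
    x0 <- (i - 1) * 3.8
    if (ymul > 0) {  # strand B, mirrored so the CB atoms face strand A
      rbind(mk(chain, i, "N",  x0,       7.8, 0),
            mk(chain, i, "CA", x0 + 1.2, 7.3, 0),
            mk(chain, i, "C",  x0 + 2.4, 7.8, 0),
            mk(chain, i, "O",  x0 + 2.4, 9.0, 0),
            mk(chain, i, "CB", x0 + 1.2, 5.9, 0))
    } else {
      rbind(mk(chain, i, "N",  x0,       0.0, 0),
            mk(chain, i, "CA", x0 + 1.2, 0.5, 0),
            mk(chain, i, "C",  x0 + 2.4, 0.0, 0),
            mk(chain, i, "O",  x0 + 2.4, -1.2, 0),
            mk(chain, i, "CB", x0 + 1.2, 1.9, 0))
    }
  }
  Structure(rbind(res("A", 1, -1), res("A", 2, -1), res("A", 3, -1),
                  res("B", 1, +1), res("B", 2, +1), res("B", 3, +1)))
}
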