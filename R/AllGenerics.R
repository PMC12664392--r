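#' @include AllClasses.R
NULL

#' @rdname averageReplicates
#' @export
setGeneric("averageReplicates", function(x, ...) standardGeneric("averageReplicates"))

#' @rdname normalizeToWildType
#' @export
setGeneric("normalizeToWildType", function(x, ...) standardGeneric("normalizeToWildType"))

#' @rdname toleranceProfile
#' @export
setGeneric("toleranceProfile", function(x, threshold = 30, ...) standardGeneric("toleranceProfile"))

#' @rdname alanineSensitivity
#' @export
setGeneric("alanineSensitivity", function(x, ...) standardGeneric("alanineSensitivity"))

#' Accessors for the core classes
#'
#' \code{wildType} returns the reference peptide; \code{activationValues} the
#' raw value array; \code{isNormalized} the normalization flag;
#' \code{allowedResidues} the per-position tolerated sets;
#' \code{profileThreshold} the percent cutoff; \code{motifId} and
#' \code{motifClasses} the motif label and class list; \code{atoms} the atom
#' table of a \linkS4class{Structure}; \code{ec50} the fitted half-maximal
#' concentration; \code{interfaceArea} the buried interface area of an
#' \linkS4class{InterfaceReport}.
#'
#' @param x An object of the documented class.
#' @return The slot value described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wildType", function(x) standardGeneric("wildType"))
#' @rdname accessors
#' @export
setGeneric("activationValues", function(x) standardGeneric("activationValues"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("allowedResidues", function(x) standardGeneric("allowedResidues"))
#' @rdname accessors
#' @export
setGeneric("profileThreshold", function(x) standardGeneric("profileThreshold"))
#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @rdname accessors
#' @export
setGeneric("motifClasses", function(x) standardGeneric("motifClasses"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("ec50", function(x) standardGeneric("ec50"))
#' @rdname accessors
#' @export
setGeneric("interfaceArea", function(x, ...) standardGeneric("interfaceArea"))

#' @rdname accessors
setMethod("wildType", "ActivationMatrix", function(x) x@wildType)
#' @rdname accessors
setMethod("wildType", "ToleranceProfile", function(x) x@wildType)
#' @rdname accessors
setMethod("activationValues", "ActivationMatrix", function(x) x@values)
#' @rdname accessors
setMethod("isNormalized", "ActivationMatrix", function(x) x@normalized)
#' @rdname accessors
setMethod("allowedResidues", "ToleranceProfile", function(x) x@allowed)
#' @rdname accessors
setMethod("profileThreshold", "ToleranceProfile", function(x) x@threshold)
#' @rdname accessors
setMethod("motifId", "PeptideMotif", function(x) x@id)
#' @rdname accessors
setMethod("motifClasses", "PeptideMotif", function(x) x@classes)
#' @rdname accessors
setMethod("atoms", "Structure", function(x) x@atoms)
#' @rdname accessors
setMethod("ec50", "DoseResponseFit", function(x) x@ec50)
#' @rdname accessors
setMethod("interfaceArea", "InterfaceReport", function(x, ...) x@area)

#' Number of replicate layers in an activation matrix
#' @param x An \linkS4class{ActivationMatrix}.
#' @return Integer replicate count.
#' @export
nReplicates <- function(x) {
  stopifnot(is(x, "ActivationMatrix"))
  dim(x@values)[3]
}

#' @param object Object to display.
#' @rdname ActivationMatrix-class
#' @export
setMethod("show", "ActivationMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ActivationMatrix: %s (%d positions x %d residues, %d replicate%s, %s)\n",
              object@wildType, d[1], d[2], d[3], if (d[3] == 1) "" else "s",
              if (object@normalized) "normalized" else "raw"))
  cat(sprintf("  measured cells: %d of %d\n",
              sum(!is.na(object@values)), length(object@values)))
})

#' @param object Object to display.
#' @rdname ToleranceProfile-class
#' @export
setMethod("show", "ToleranceProfile", function(object) {
  cat(sprintf("ToleranceProfile: %s (threshold > %g%%)\n",
              object@wildType, object@threshold))
  wt <- strsplit(object@wildType, "")[[1]]
  for (i in seq_along(object@allowed))
    cat(sprintf("  p%d (%s): %s\n", i, wt[i],
                paste(object@allowed[[i]], collapse = "")))
})

#' @param object Object to display.
#' @rdname PeptideMotif-class
#' @export
setMethod("show", "PeptideMotif", function(object) {
  cat(sprintf("PeptideMotif %s: %s\n", object@id, emitMotif(object)))
})

#' @param object Object to display.
#' @rdname AlanineScanResult-class
#' @export
setMethod("show", "AlanineScanResult", function(object) {
  cat(sprintf("AlanineScanResult (threshold <= %g%%):\n", object@threshold))
  print(data.frame(position = object@position, value = round(object@value, 2),
                   sensitive = object@sensitive))
})

#' @param object Object to display.
#' @rdname DoseResponseFit-class
#' @export
setMethod("show", "DoseResponseFit", function(object) {
  cat("DoseResponseFit (3-parameter log(agonist) vs response, Hill slope 1)\n")
  cat(sprintf("  bottom = %.4g, top = %.4g, EC50 = %.4g\n",
              object@bottom, object@top, object@ec50))
  cat(sprintf("  n = %d points, RMS residual = %.4g\n",
              nrow(object@data), sqrt(mean(object@residuals^2))))
})

#' @param object Object to display.
#' @rdname Structure-class
#' @export
setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
              nrow(a), nrow(unique(a[, c("chain", "resno")])),
              paste(unique(a$chain), collapse = ", ")))
})

#' @param object Object to display.
#' @rdname InterfaceReport-class
#' @export
setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("InterfaceReport: interface area %.1f A^2\n", object@area))
  cat(sprintf("  buried residues: %d (side A), %d (side B)\n",
              sum(object@perResidue$side == "A" & object@perResidue$buried > 0),
              sum(object@perResidue$side == "B" & object@perResidue$buried > 0)))
  cat(sprintf("  contacts: %d hydrogen bonds, %d hydrophobic\n",
              sum(object@contacts$type == "hydrogen_bond"),
              sum(object@contacts$type == "hydrophobic")))
  cat(sprintf("  backbone fraction of buried area: A %.3f, B %.3f\n",
              object@backboneFraction[["A"]], object@backboneFraction[["B"]]))
})
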