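#' @include AllGenerics.R
NULL

#' Average replicate activation measurements cell-wise
#'
#' Collapses the replicate dimension of a positional-scanning matrix by the
#' arithmetic mean, the first step of the profiling pipeline (replicates are
#' averaged before normalization). A cell measured in one replicate but
#' missing in another is an error: silently imputing it would bias the mean
#' and, downstream, shrink the tolerance sets.
#'
#' @param x An \linkS4class{ActivationMatrix}, or a list of them with
#'   identical wild-type peptides and one replicate layer each.
#' @param ... Unused.
#'
#' @return An \linkS4class{ActivationMatrix} with a single replicate layer
#'   (\code{"mean"}), marked un-normalized.
#' @examples
#' v <- array(NA_real_, c(1, 20, 2),
#'            dimnames = list("1", AA_ALPHABET20, c("r1", "r2")))
#' v[1, "S", ] <- c(80, 90); v[1, "A", ] <- c(40, 60)
#' activationValues(averageReplicates(ActivationMatrix("S", v)))[1, "A", 1]
#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "ActivationMatrix", function(x, ...) {
  v <- x@values
  if (x@normalized)
    stop("averageReplicates() expects raw data; normalization comes after averaging")
  measured <- !is.na(v)
  seen <- apply(measured, c(1, 2), any)
  everywhere <- apply(measured, c(1, 2), all)
  partial <- which(seen & !everywhere, arr.ind = TRUE)
  if (nrow(partial) > 0) {
    i <- partial[1, ]
    stop(sprintf(
      "cell missing in some replicates: position %s, residue %s",
      rownames(seen)[i[1]], colnames(seen)[i[2]]))
  }
  m <- apply(v, c(1, 2), mean)   # NA where unmeasured in all replicates
  out <- array(m, dim = c(dim(m), 1L),
               dimnames = c(dimnames(m), list("mean")))
  ActivationMatrix(x@wildType, out, normalized = FALSE)
})

#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "list", function(x, ...) {
  stopifnot(length(x) >= 1L, all(vapply(x, is, logical(1), "ActivationMatrix")))
  wts <- vapply(x, wildType, character(1))
  if (length(unique(wts)) != 1L)
    stop("replicates disagree on the wild-type peptide: ",
         paste(unique(wts), collapse = " vs "))
  layers <- lapply(x, function(m) m@values)
  nrep <- sum(vapply(layers, function(a) dim(a)[3], integer(1)))
  v <- array(NA_real_, c(dim(layers[[1]])[1:2], nrep),
             dimnames = c(dimnames(layers[[1]])[1:2],
                          list(as.character(seq_len(nrep)))))
  k <- 0L
  for (a in layers) for (j in seq_len(dim(a)[3])) {
    k <- k + 1L
    v[, , k] <- a[, , j]
  }
  averageReplicates(ActivationMatrix(wts[1], v))
})

#' Normalize activation values to the wild-type residue at each position
#'
#' Scales every value at position i by \code{100 / value(i, wildType[i])}, so
#' the wild-type cell at each position becomes exactly 100. Values above 100
#' (variants more stimulatory than wild type) are legal and preserved. A
#' matrix that is already normalized is rejected: normalizing twice would
#' silently hide a pipeline ordering bug.
#'
#' @param x An un-normalized \linkS4class{ActivationMatrix}. Multi-replicate
#'   input is normalized layer by layer against each replicate's own
#'   wild-type cells (per-replicate normalization, the non-default order).
#' @param ... Unused.
#'
#' @return The normalized \linkS4class{ActivationMatrix}.
#' @rdname normalizeToWildType
#' @export
setMethod("normalizeToWildType", "ActivationMatrix", function(x, ...) {
  if (x@normalized)
    stop("matrix is already normalized")
  v <- x@values
  wt <- strsplit(x@wildType, "")[[1]]
  for (k in seq_len(dim(v)[3])) {
    anchors <- vapply(seq_along(wt), function(i) v[i, wt[i], k], numeric(1))
    bad <- which(!(anchors > 0))
    if (length(bad) > 0)
      stop(sprintf(
        "wild-type activation not positive at position(s) %s; normalization undefined",
        paste(bad, collapse = ", ")))
    slice <- matrix(v[, , k], nrow = dim(v)[1], ncol = dim(v)[2])
    v[, , k] <- sweep(slice, 1, 100 / anchors, `*`)
    for (i in seq_along(wt)) v[i, wt[i], k] <- 100   # anchor is exact
  }
  ActivationMatrix(x@wildType, v, normalized = TRUE)
})

#' Call per-position tolerated residue sets from a normalized matrix
#'
#' A residue is tolerated at a position when its normalized activation
#' strictly exceeds the threshold (default 30%). The wild-type residue is a
#' member of every set by construction, since its normalized value is 100.
#' The matrix must be fully measured (all positions x 20 residues) and
#' reduced to a single (averaged) replicate layer first.
#'
#' @param x A normalized, single-replicate \linkS4class{ActivationMatrix}
#'   with complete residue coverage.
#' @param threshold Percent activation cutoff, strict inequality (default 30).
#' @param ... Unused.
#'
#' @return A \linkS4class{ToleranceProfile}.
#' @rdname toleranceProfile
#' @export
setMethod("toleranceProfile", "ActivationMatrix", function(x, threshold = 30, ...) {
  if (!x@normalized)
    stop("toleranceProfile() requires a normalized matrix")
  if (dim(x@values)[3] != 1L)
    stop("average replicates before calling tolerance sets")
  m <- matrix(x@values[, , 1], nrow = dim(x@values)[1],
              dimnames = dimnames(x@values)[1:2])
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss) > 0)
    stop(sprintf("unmeasured cell at position %s, residue %s; a full scan is required",
                 rownames(m)[miss[1, 1]], colnames(m)[miss[1, 2]]))
  allowed <- lapply(seq_len(nrow(m)), function(i)
    AA_ALPHABET20[m[i, ] > threshold])
  ToleranceProfile(x@wildType, allowed, threshold = threshold)
})

#' Alanine-scan sensitivity calls
#'
#' Flags each peptide position as sensitive when the normalized activation of
#' its alanine-substituted variant is at most the threshold. The two MHC
#' anchor positions (p2 and p9 for HLA-A*02:01 9-mers) are typically mutated
#' jointly as a single double-mutant variant; that variant is carried as one
#' pseudo-position labelled e.g. \code{"2+9"}.
#'
#' @param x Either a named numeric vector of normalized percent activations
#'   (names are position labels, e.g. \code{c("1" = 85, "2+9" = 4)}), or a
#'   normalized \linkS4class{ActivationMatrix} whose alanine column supplies
#'   the per-position values.
#' @param threshold Percent cutoff; sensitive means \code{value <= threshold}
#'   (default 30).
#' @param jointAnchors For the matrix method: integer positions mutated
#'   jointly (default \code{c(2, 9)} when the peptide has 9 or more
#'   residues, none otherwise).
#' @param jointValue For the matrix method: normalized activation of the
#'   joint double-anchor variant; required when \code{jointAnchors} is
#'   non-empty.
#' @param ... Unused.
#'
#' @return An \linkS4class{AlanineScanResult}.
#' @examples
#' alanineSensitivity(c("1" = 95, "3" = 12, "2+9" = 2))
#' @rdname alanineSensitivity
#' @export
setMethod("alanineSensitivity", "numeric", function(x, threshold = 30, ...) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("values must be named by position label")
  if (any(!is.finite(x)) || any(x < 0))
    stop("activation values must be finite and non-negative")
  new("AlanineScanResult", position = names(x), value = unname(x),
      sensitive = unname(x <= threshold), threshold = threshold)
})

#' @rdname alanineSensitivity
#' @export
setMethod("alanineSensitivity", "ActivationMatrix",
          function(x, threshold = 30,
                   jointAnchors = if (nchar(wildType(x)) >= 9) c(2L, 9L) else integer(),
                   jointValue = NULL, ...) {
  if (!x@normalized)
    stop("alanineSensitivity() requires a normalized matrix")
  if (dim(x@values)[3] != 1L)
    stop("average replicates before calling alanine sensitivity")
  wt <- strsplit(x@wildType, "")[[1]]
  single <- setdiff(seq_along(wt), jointAnchors)
  vals <- x@values[, "A", 1]
  if (length(wt) == 1L) vals <- stats::setNames(vals, "1")
  missing_ala <- single[is.na(vals[single])]
  if (length(missing_ala) > 0)
    stop(sprintf("alanine cell missing at position(s) %s",
                 paste(missing_ala, collapse = ", ")))
  out <- stats::setNames(vals[single], as.character(single))
  if (length(jointAnchors) > 0) {
    if (is.null(jointValue))
      stop("jointValue for the combined anchor variant (positions ",
           paste(jointAnchors, collapse = "+"), ") is required")
    out <- c(out, stats::setNames(jointValue,
                                  paste(jointAnchors, collapse = "+")))
  }
  alanineSensitivity(out, threshold = threshold)
})

#' Read / write positional-scanning matrices as long-format TSV
#'
#' The on-disk format is tab-separated long form with columns
#' \code{replicate}, \code{position} (1-based), \code{residue} (one-letter)
#' and \code{value} (percent activation), preceded by a header comment line
#' \code{#wt=SLLMWITQV} carrying the wild-type peptide (and optionally
#' \code{#normalized=TRUE}).
#'
#' @param path File path.
#' @return \code{readActivationMatrix}: an \linkS4class{ActivationMatrix}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' v <- matrix(NA_real_, 1, 20, dimnames = list("1", AA_ALPHABET20))
#' v[1, "S"] <- 80; v[1, "A"] <- 12
#' writeActivationMatrix(ActivationMatrix("S", v), tf)
#' readActivationMatrix(tf)
#' @export
readActivationMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  wtline <- grep("^#wt=", hdr, value = TRUE)
  if (length(wtline) != 1L)
    stop("expected exactly one '#wt=' header line in ", path)
  wt <- toupper(sub("^#wt=", "", trimws(wtline)))
  normalized <- any(grepl("^#normalized=\\s*TRUE", hdr, ignore.case = TRUE))
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  need <- c("replicate", "position", "residue", "value")
  if (!all(need %in% names(df)))
    stop("matrix TSV needs columns: ", paste(need, collapse = ", "))
  reps <- sort(unique(as.character(df$replicate)))
  L <- nchar(wt)
  v <- array(NA_real_, c(L, 20L, length(reps)),
             dimnames = list(as.character(seq_len(L)), AA_ALPHABET20, reps))
  bad <- !(df$residue %in% AA_ALPHABET20) | df$position < 1 | df$position > L
  if (any(bad))
    stop("invalid residue/position in rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  v[cbind(as.character(df$position), df$residue, as.character(df$replicate))] <-
    df$value
  ActivationMatrix(wt, v, normalized = normalized)
}

#' @param x An \linkS4class{ActivationMatrix} to write.
#' @return \code{writeActivationMatrix}: the path, invisibly.
#' @rdname readActivationMatrix
#' @export
writeActivationMatrix <- function(x, path) {
  stopifnot(is(x, "ActivationMatrix"))
  v <- x@values
  idx <- which(!is.na(v), arr.ind = TRUE)
  dn <- dimnames(v)
  df <- data.frame(replicate = dn[[3]][idx[, 3]],
                   position = as.integer(dn[[1]][idx[, 1]]),
                   residue = dn[[2]][idx[, 2]],
                   value = v[idx], stringsAsFactors = FALSE)
  df <- df[order(df$replicate, df$position, df$residue), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#wt=%s", x@wildType), con)
  if (x@normalized) writeLines("#normalized=TRUE", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
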