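# Independent oracles and small fixture builders used across the suite.

# naive per-window set-membership scan: the reference the fast scanner is
# checked against
naiveScanSequence <- function(sequence, motif) {
  classes <- motifClasses(motif)
  L <- length(classes)
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  if (n < L) return(data.frame(offset = integer(), peptide = character(),
                               stringsAsFactors = FALSE))
  hits <- integer()
  for (o in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(res[o + j - 1L] %in% classes[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, o)
  }
  data.frame(offset = hits,
             peptide = vapply(hits, function(o)
               paste(res[o:(o + L - 1L)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

# profile grid search for the 3PL: for each candidate log10(EC50) the model is
# linear in (bottom, top), solved by lm(); the best grid point is returned
gridSearchEC50 <- function(dose, response, gridFrom = log10(min(dose)) - 2,
                           gridTo = log10(max(dose)) + 2, gridBy = 0.01) {
  grid <- seq(gridFrom, gridTo, by = gridBy)
  best <- NULL
  bestSS <- Inf
  for (le in grid) {
    f <- 1 / (1 + 10^(le - log10(dose)))
    fit <- stats::lm(response ~ f)
    ss <- sum(stats::residuals(fit)^2)
    if (ss < bestSS) {
      bestSS <- ss
      cf <- stats::coef(fit)
      best <- c(bottom = unname(cf[1]), top = unname(cf[1] + cf[2]),
                ec50 = 10^le)
    }
  }
  best
}

# closed-form SASA of two intersecting equal spheres of radius R at centre
# distance d < 2R: each loses a cap of height h = R - d/2
twoSphereCapSasa <- function(d, r = 1.70, probe = 1.4) {
  R <- r + probe
  if (d >= 2 * R) return(rep(4 * pi * R^2, 2))
  h <- R - d / 2
  rep(4 * pi * R^2 - 2 * pi * R * h, 2)
}

# fully measured random activation matrix (values uniform on [0, 120])
randomFullMatrix <- function(wt = "SLLMWITQV", nrep = 2) {
  L <- nchar(wt)
  v <- array(runif(L * 20 * nrep, 0, 120), c(L, 20, nrep),
             dimnames = list(as.character(seq_len(L)), AA_ALPHABET20,
                             paste0("r", seq_len(nrep))))
  # keep wild-type cells comfortably positive so normalization is defined
  wtres <- strsplit(wt, "")[[1]]
  for (i in seq_len(L)) v[i, wtres[i], ] <- runif(nrep, 50, 120)
  ActivationMatrix(wt, v)
}

randomMotif <- function(L = 9) {
  classes <- lapply(seq_len(L), function(i)
    sample(AA_ALPHABET20, sample(1:8, 1)))
  PeptideMotif(classes, id = sprintf("rand%d", L))
}

randomSequence <- function(n, letters_ = AA_ALPHABET20) {
  paste(sample(letters_, n, replace = TRUE), collapse = "")
}

# printed tolerance patterns of the two anti-HLA/NY-ESO-1 binders
NY1_PATTERN <- "[ACFGHILMNQRSTVWY]-[ACILMQV]-[ACDFGHILMNPQSTVW]-[FILMT]-W-[FILMV]-[CFILMQRSTVY]-[QT]-[ACITV]"
NY2_PATTERN <- "[ACFHIMNPQRSTVWY]-[FILMVW]-[ILMQV]-[IM]-W-[FILMPVW]-[ACFGILMNQRSTV]-[ACDEFGHKLMNPQRSTVWY]-[ACFGILSTV]"
WT_EPITOPE <- "SLLMWITQV"

# rigid-transform helper for invariance tests
applyRigid <- function(s, angle = 0.7, axis = c(0, 0, 1), shift = c(5, -3, 2)) {
  a <- atoms(s)
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  Structure(a)
}
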