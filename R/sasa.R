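#' @include structure.R
NULL

# deterministic golden-spiral quadrature points on the unit sphere
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.atomRadii <- function(element, radii, fallbackRadius) {
  r <- unname(radii[element])
  if (anyNA(r)) {
    if (is.null(fallbackRadius)) {
      bad <- unique(element[is.na(r)])
      stop("no van der Waals radius for element(s): ",
           paste(bad, collapse = ", "),
           "; supply fallbackRadius or extend the radius table")
    }
    r[is.na(r)] <- fallbackRadius
  }
  r
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the model: for each atom, quadrature points are
#' placed on the probe-inflated sphere (radius r_vdw + probe) along a
#' deterministic golden spiral, and the accessible fraction is the share of
#' points inside no other inflated sphere. Per-atom SASA is that fraction
#' times the sphere area.
#'
#' @param x A \linkS4class{Structure}.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param nPoints Quadrature points per atom (default 960; at least 92).
#' @param radii Element radius table (default \code{\link{defaultRadii}}).
#' @param fallbackRadius Radius for unlisted elements; default \code{NULL}
#'   (unlisted elements are an error).
#' @return Numeric vector of per-atom areas in Angstrom^2 (sum for the total).
#' @examples
#' s <- toyStructure("single_atom")
#' sum(sasa(s))               # ~ 4 * pi * (1.70 + 1.4)^2
#' @export
sasa <- function(x, probe = 1.4, nPoints = 960, radii = defaultRadii,
                 fallbackRadius = NULL) {
  stopifnot(is(x, "Structure"), probe >= 0, nPoints >= 92)
  a <- atoms(x)
  n <- nrow(a)
  R <- .atomRadii(a$element, radii, fallbackRadius) + probe
  xyz <- cbind(a$x, a$y, a$z)
  pts <- .spherePoints(nPoints)
  areas <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & d2 > 0)
    # surface points of atom i, in absolute coordinates
    px <- pts[, 1] * R[i] + xyz[i, 1]
    py <- pts[, 2] * R[i] + xyz[i, 2]
    pz <- pts[, 3] * R[i] + xyz[i, 3]
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dd <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
      acc <- acc & (dd >= R[j]^2)
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(acc) / nPoints
  }
  areas
}

#' Total and per-residue SASA
#'
#' @param x A \linkS4class{Structure}.
#' @param ... Passed to \code{\link{sasa}}.
#' @return data.frame (\code{chain}, \code{resno}, \code{resid},
#'   \code{area}) of per-residue solvent accessible areas.
#' @export
sasaByResidue <- function(x, ...) {
  a <- atoms(x)
  areas <- sasa(x, ...)
  key <- paste(a$chain, a$resno, sep = "\r")
  first <- !duplicated(key)
  agg <- tapply(areas, key, sum)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             resid = a$resid[first],
             area = unname(agg[key[first]]),
             stringsAsFactors = FALSE)
}
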